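test_that("build_objective_spec wires modes and epsilon overrides", {
  sF <- build_objective_spec(sampler_config("ffbm"))
  expect_equal(nrow(sF), 2)
  expect_true(all(sF$direction == "minimize"))
  expect_equal(sF$epsilon, c(5, 3))

  sM <- build_objective_spec(sampler_config("mecbm"))
  expect_equal(nrow(sM), 4)
  expect_equal(sM$direction, c("minimize", "minimize", "maximize", "maximize"))
  expect_equal(sM$epsilon, c(5, 3, 0.4, 0.1))

  ov <- sampler_config("mecbm", epsilons = c(2, 1, 0.3, 0.05))
  expect_equal(build_objective_spec(ov)$epsilon, c(2, 1, 0.3, 0.05))

  bad <- sampler_config("ffbm"); bad$mode <- "annealing"
  expect_error(build_objective_spec(bad), "unknown sampler mode")
  expect_error(sampler_config("ffbm", energy_window = 0), "energy_window")
})

test_that("energy window keeps exactly the conformers within 20 kcal/mol", {
  confs <- lapply(c(0, 19.9, 20.1), stub_conf)
  expect_length(energy_window_filter(confs, 20), 2)
  same <- lapply(c(3, 3, 3, 3), stub_conf)
  expect_length(energy_window_filter(same, 20), 4)
  expect_length(energy_window_filter(confs, 0), 1)   # window 0: minima only
  expect_length(energy_window_filter(list(), 20), 0)
})

test_that("deduplication keeps one representative per cluster", {
  fx <- make_fixture(fixture_spec(7, "chain", seed = 8))
  rbs <- perceive_rotatable_bonds(fx$mol)
  base_tv <- measure_torsions(fx$mol, fx$conf, rbs)

  two_same <- list(set_torsions(fx$mol, fx$conf, base_tv, rbs),
                   set_torsions(fx$mol, fx$conf, base_tv, rbs))
  expect_length(deduplicate(two_same, 0.2, fx$mol), 1)

  distant <- lapply(c(0, 120, -120), function(o)
    set_torsions(fx$mol, fx$conf, wrap_angle(base_tv + o), rbs))
  expect_length(deduplicate(distant, 0.2, fx$mol), 3)

  # 3 planted clusters x 4 near-duplicates (intra < 0.2 A < inter)
  clusters <- unlist(lapply(c(0, 120, -120), function(ctr)
    lapply(c(0, 0.5, 1.0, 1.5), function(jit)
      set_torsions(fx$mol, fx$conf, wrap_angle(base_tv + ctr + jit), rbs))),
    recursive = FALSE)
  kept <- deduplicate(clusters, 0.2, fx$mol)
  expect_length(kept, 3)
  for (i in seq_along(kept)) for (j in seq_along(kept))
    if (i < j) expect_gte(best_fit_rmsd(kept[[i]], kept[[j]], fx$mol), 0.2)
})

test_that("a rigid molecule yields the input conformation alone", {
  eth <- make_fixture(fixture_spec(2, "chain", seed = 1))
  expect_equal(eth$n_rotatable, 0)
  ens <- generate_ensemble(eth$mol, eth$conf,
                           sampler_config("mecbm", n_pop = 10, n_gen = 2,
                                          seed = 3))
  expect_length(ens$conformers, 1)
  expect_equal(ens$conformers[[1]]$coords, eth$conf$coords)
})

test_that("ensembles are reproducible and respect window/dedup/cap", {
  fx <- make_fixture(fixture_spec(10, "chain", seed = 14))
  cfg <- sampler_config("mecbm", n_pop = 50, n_gen = 40, seed = 19,
                        max_conformers = 8)
  e1 <- generate_ensemble(fx$mol, fx$conf, cfg)
  e2 <- generate_ensemble(fx$mol, fx$conf, cfg)
  tv1 <- lapply(e1$conformers, `[[`, "torsions")
  tv2 <- lapply(e2$conformers, `[[`, "torsions")
  expect_identical(tv1, tv2)                        # bitwise determinism

  expect_lte(length(e1$conformers), cfg$max_conformers)
  fe <- vapply(e1$conformers, `[[`, numeric(1), "filter_energy")
  expect_true(all(fe <= min(fe) + cfg$energy_window))
  expect_false(is.unsorted(fe))
  for (i in seq_along(e1$conformers)) for (j in seq_along(e1$conformers))
    if (i < j)
      expect_gte(best_fit_rmsd(e1$conformers[[i]], e1$conformers[[j]], fx$mol),
                 cfg$dedup_rmsd)
  expect_equal(e1$n_evaluations, 50 + 50 * 40)
})

test_that("MECBM ensembles are larger and span wider Rg than FFBM", {
  fx <- make_fixture(fixture_spec(11, "chain", seed = 23))   # 8 torsions
  expect_gte(fx$n_rotatable, 8)
  eF <- generate_ensemble(fx$mol, fx$conf,
                          sampler_config("ffbm", n_pop = 80, n_gen = 80,
                                         seed = 7))
  eM <- generate_ensemble(fx$mol, fx$conf,
                          sampler_config("mecbm", n_pop = 80, n_gen = 80,
                                         seed = 7))
  expect_gt(length(eM$conformers), length(eF$conformers))
  rgF <- vapply(eF$conformers, radius_of_gyration, numeric(1), mol = fx$mol)
  rgM <- vapply(eM$conformers, radius_of_gyration, numeric(1), mol = fx$mol)
  expect_gt(diff(range(rgM)), diff(range(rgF)))
})

test_that("post-minimization does not increase mean energy and re-filters", {
  fx <- make_fixture(fixture_spec(6, "chain", seed = 31))
  raw <- generate_ensemble(fx$mol, fx$conf,
                           sampler_config("mecbm", n_pop = 30, n_gen = 20,
                                          seed = 11))
  mean_total_raw <- mean(vapply(raw$conformers, function(cf)
    evaluate_terms(fx$mol, cf, "mmff94")$total_no_elec, numeric(1)))
  mini <- generate_ensemble(fx$mol, fx$conf,
                            sampler_config("mecbm", n_pop = 30, n_gen = 20,
                                           seed = 11, minimize = TRUE))
  expect_true(all(vapply(mini$conformers, `[[`, logical(1), "minimized")))
  mean_total_min <- mean(vapply(mini$conformers, function(cf)
    cf$energy_terms$total_no_elec, numeric(1)))
  expect_lte(mean_total_min, mean_total_raw)

  # mixed-force-field refinement records the minimization backend
  mixed <- generate_ensemble(fx$mol, fx$conf,
                             sampler_config("mecbm", n_pop = 20, n_gen = 10,
                                            seed = 4, minimize = TRUE,
                                            minimization_ff = "tripos"))
  expect_true(all(vapply(mixed$conformers, `[[`, character(1),
                         "source_ff") == "tripos"))
})

test_that("the compiled sampler loop is bitwise-equal to the R reference", {
  fx <- make_fixture(fixture_spec(9, "chain", seed = 41))
  rbs <- perceive_rotatable_bonds(fx$mol)
  sys <- ff_system(fx$mol, fx$conf, "mmff94", rbs)
  for (mode in c("ffbm", "mecbm")) {
    cfg <- sampler_config(mode)
    spec <- build_objective_spec(cfg)
    sgn <- ifelse(spec$direction == "maximize", -1, 1)
    mecbm <- mode == "mecbm"
    init <- measure_torsions(fx$mol, fx$conf, rbs)
    set.seed(55)
    fast <- confevo:::cpp_run_emoea(sys$ptr, mecbm, spec$epsilon, sgn,
                                    25L, 6L, init, 0.9, 1 / length(rbs),
                                    cfg$energy_window)
    set.seed(55)
    ref <- run_emoea(function(tv) confevo:::cpp_sys_evaluate(sys$ptr, tv, mecbm),
                     spec, length(rbs), 25, 6, init = init,
                     energy_window = cfg$energy_window)
    expect_identical(unname(ref$genotypes), unname(fast$genotypes))
    expect_identical(unname(ref$objectives), unname(fast$objectives))
    expect_identical(unname(ref$boxes), unname(fast$boxes))
    expect_equal(ref$n_evaluations, fast$n_evaluations)
  }
})
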