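# Conformer-generation orchestration: objective set construction, the
# epsilon-MOEA run in torsion space, the 20 kcal/mol energy window,
# RMSD deduplication, the ensemble cap, and optional post-minimization
# (possibly under a different force field: the mixed-force-field strategy).
#
# "Filter energy" during sampling is vdw + torsion -- the two terms the
# force-field objectives actually compute; after minimization the window is
# re-applied on total_no_elec, the quantity the minimizer optimizes.

#' Sampler configuration
#'
#' Defaults encode the published protocol: population and generation counts
#' of 200, at most 600 conformers, a 20 kcal/mol energy window, epsilons of
#' 5.0/3.0 kcal/mol on the force-field objectives and 0.4/0.1 Angstrom on the
#' geometric objectives, and minimization bounded by 100 conjugate-gradient
#' steps or a 0.01 kcal/mol/Angstrom gradient norm.
#'
#' @param mode \code{"ffbm"} (force-field objectives only) or \code{"mecbm"}
#'   (adds geometric dissimilarity and gyration radius, both maximized).
#' @param sampling_ff force-field backend used during sampling
#'   (\code{"mmff94"} or \code{"tripos"}).
#' @param minimize logical; post-refine every windowed conformer.
#' @param minimization_ff backend for refinement; may differ from
#'   \code{sampling_ff} (mixed-force-field strategy).
#' @param epsilons optional named epsilon override, one per objective.
#' @param n_pop,n_gen evolution budget (default 200 each).
#' @param max_conformers ensemble cap (default 600).
#' @param energy_window window above the lowest energy, kcal/mol (default 20).
#' @param min_max_steps,min_grad_tol minimizer bounds (100 steps,
#'   0.01 kcal/mol/Angstrom).
#' @param dedup_rmsd heavy-atom best-fit RMSD below which two conformers are
#'   duplicates (default 0.2 Angstrom).
#' @param seed integer RNG seed.
#' @return object of class \code{sampler_config}.
#' @export
sampler_config <- function(mode = c("mecbm", "ffbm"), sampling_ff = "mmff94",
                           minimize = FALSE, minimization_ff = sampling_ff,
                           epsilons = NULL, n_pop = 200, n_gen = 200,
                           max_conformers = 600, energy_window = 20,
                           min_max_steps = 100, min_grad_tol = 0.01,
                           dedup_rmsd = 0.2, seed = 1) {
  mode <- match.arg(mode)
  .assert(max_conformers >= 1, "max_conformers must be >= 1")
  .assert(energy_window > 0, "energy_window must be > 0")
  defaults <- if (mode == "ffbm") c(vdw = 5.0, torsion = 3.0)
              else c(vdw = 5.0, torsion = 3.0, gd = 0.4, gr = 0.1)
  if (!is.null(epsilons)) {
    .assert(length(epsilons) == length(defaults),
            "expected %d epsilons for mode '%s'", length(defaults), mode)
    defaults[] <- epsilons
  }
  structure(list(mode = mode, sampling_ff = sampling_ff, minimize = minimize,
                 minimization_ff = minimization_ff, epsilons = defaults,
                 n_pop = n_pop, n_gen = n_gen, max_conformers = max_conformers,
                 energy_window = energy_window, min_max_steps = min_max_steps,
                 min_grad_tol = min_grad_tol, dedup_rmsd = dedup_rmsd,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Build the objective specification for a sampler configuration
#'
#' FFBM: van der Waals and torsion energy, both minimized, epsilons
#' 5.0 and 3.0 kcal/mol.  MECBM: those two plus geometric dissimilarity
#' (epsilon 0.4 Angstrom) and gyration radius (epsilon 0.1 Angstrom), both
#' maximized.  Epsilon overrides in the config propagate verbatim.
#'
#' @param config a \code{\link{sampler_config}}.
#' @return an \code{\link{objective_spec}}.
#' @export
build_objective_spec <- function(config) {
  .assert(inherits(config, "sampler_config") &&
            config$mode %in% c("ffbm", "mecbm"),
          "unknown sampler mode")
  if (config$mode == "ffbm")
    objective_spec(c("vdw", "torsion"), c("minimize", "minimize"),
                   unname(config$epsilons))
  else
    objective_spec(c("vdw", "torsion", "gd", "gr"),
                   c("minimize", "minimize", "maximize", "maximize"),
                   unname(config$epsilons))
}

#' Apply the energy window
#'
#' Keeps exactly the conformers whose filter energy lies within
#' \code{window} of the set minimum (recomputed from the given set).
#'
#' @param conformers list of \code{conformation} objects carrying
#'   \code{filter_energy}.
#' @param window width in kcal/mol (default 20).
#' @return the filtered list.
#' @export
energy_window_filter <- function(conformers, window = 20) {
  if (length(conformers) == 0) return(conformers)
  e <- vapply(conformers, function(cf) cf$filter_energy, numeric(1))
  conformers[e <= min(e) + window]
}

#' Greedy RMSD deduplication
#'
#' Scans conformers in the given (energy-ascending) order and keeps one iff
#' its heavy-atom best-fit RMSD to every already-kept conformer is at least
#' \code{dedup_rmsd}; the all-pairs property then holds on the output.
#'
#' @param conformers list of conformations sorted by filter energy ascending.
#' @param dedup_rmsd duplicate threshold in Angstrom.
#' @param mol molecule record (for heavy atoms and graph symmetry).
#' @param autos optional precomputed automorphisms.
#' @return deduplicated list.
#' @export
deduplicate <- function(conformers, dedup_rmsd, mol, autos = NULL) {
  if (length(conformers) <= 1) return(conformers)
  autos <- autos %||% heavy_automorphisms(mol)
  kept <- list(conformers[[1]])
  for (cf in conformers[-1]) {
    dup <- FALSE
    for (kc in kept) {
      if (best_fit_rmsd(cf, kc, mol, autos) < dedup_rmsd) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- cf
  }
  kept
}

#' Generate a conformer ensemble for one molecule
#'
#' Runs the epsilon-MOEA over the molecule's torsion space with the
#' configured objective set, realizes the archive as Cartesian conformers,
#' applies the energy window, deduplicates, truncates to the energy-ranked
#' \code{max_conformers} best, and (optionally) post-minimizes every
#' surviving conformer before re-applying window and deduplication.  A
#' molecule with no rotatable bonds returns its input conformation alone.
#' Fully reproducible given \code{config$seed}.
#'
#' @param mol molecule record.
#' @param input_conf input conformation (defaults to the reference geometry).
#' @param config a \code{\link{sampler_config}}.
#' @return object of class \code{conf_ensemble}: molecule, conformers sorted
#'   by filter energy, config, \code{wall_time_s}, \code{n_evaluations}.
#' @export
generate_ensemble <- function(mol, input_conf = NULL, config = sampler_config()) {
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)
  input_conf <- input_conf %||% conformation(mol$coords)
  rbs <- perceive_rotatable_bonds(mol)
  spec <- build_objective_spec(config)
  sys <- ff_system(mol, input_conf, config$sampling_ff, rbs)
  mecbm <- config$mode == "mecbm"

  if (length(rbs) == 0) {
    cf <- .realize_conformer(sys, mol, measure_torsions(mol, input_conf, rbs),
                             coords = .coords_of(input_conf))
    ens <- .finish_ensemble(mol, list(cf), config, t0, n_eval = 1)
    return(ens)
  }

  init <- measure_torsions(mol, input_conf, rbs)
  sgn <- ifelse(spec$direction == "maximize", -1, 1)
  res <- cpp_run_emoea(sys$ptr, mecbm, spec$epsilon, sgn,
                       as.integer(config$n_pop), as.integer(config$n_gen),
                       init, 0.9, 1 / length(rbs), config$energy_window)
  confs <- lapply(seq_len(nrow(res$genotypes)), function(i)
    .realize_conformer(sys, mol, res$genotypes[i, ],
                       objectives = res$objectives[i, ]))
  .finish_ensemble(mol, confs, config, t0, n_eval = res$n_evaluations)
}

.realize_conformer <- function(sys, mol, tv, objectives = NULL, coords = NULL) {
  if (is.null(coords)) coords <- cpp_sys_coords(sys$ptr, tv)
  cf <- conformation(coords, torsions = wrap_angle(tv),
                     source_ff = sys$model$name)
  if (is.null(objectives)) {
    e <- cpp_sys_energy(sys$ptr, coords)
    cf$energy_terms <- as.list(e)
    cf$filter_energy <- unname(e[["vdw"]] + e[["torsion"]])
  } else {
    cf$objective_values <- objectives
    cf$energy_terms <- list(vdw = objectives[1], torsion = objectives[2])
    cf$filter_energy <- objectives[1] + objectives[2]
  }
  cf
}

.finish_ensemble <- function(mol, confs, config, t0, n_eval) {
  autos <- heavy_automorphisms(mol)
  ord <- order(vapply(confs, function(cf) cf$filter_energy, numeric(1)))
  confs <- confs[ord]
  confs <- energy_window_filter(confs, config$energy_window)
  confs <- deduplicate(confs, config$dedup_rmsd, mol, autos)
  if (length(confs) > config$max_conformers)
    confs <- confs[seq_len(config$max_conformers)]

  if (isTRUE(config$minimize)) {
    confs <- lapply(confs, function(cf) {
      mc <- minimize_conformation(mol, cf, config$minimization_ff,
                                  config$min_max_steps, config$min_grad_tol)
      mc$torsions <- tryCatch(measure_torsions(mol, mc), error = function(e) NULL)
      mc$filter_energy <- mc$energy_terms$total_no_elec
      mc
    })
    ord <- order(vapply(confs, function(cf) cf$filter_energy, numeric(1)))
    confs <- confs[ord]
    confs <- energy_window_filter(confs, config$energy_window)
    confs <- deduplicate(confs, config$dedup_rmsd, mol, autos)
    if (length(confs) > config$max_conformers)
      confs <- confs[seq_len(config$max_conformers)]
  }

  structure(list(molecule = mol, conformers = confs, config = config,
                 wall_time_s = proc.time()[["elapsed"]] - t0,
                 n_evaluations = n_eval),
            class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble> %s: %d conformers (%s/%s), %.2f s, %s evaluations\n",
              x$molecule$name, length(x$conformers), toupper(x$config$mode),
              x$config$sampling_ff, x$wall_time_s, format(x$n_evaluations)))
  invisible(x)
}
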