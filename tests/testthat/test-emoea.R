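spec2 <- objective_spec(c("f1", "f2"), c("minimize", "minimize"), c(5, 3))

test_that("objective_spec validates its invariants", {
  expect_error(objective_spec("one", "minimize", 1), "at least 2")
  expect_error(objective_spec(c("a", "b"), c("minimize", "minimize"),
                              c(1, 0)), "epsilons")
  expect_error(objective_spec(c("a", "b"), c("min", "max"), c(1, 1)),
               "direction")
})

test_that("canonicalize flips only maximized objectives", {
  expect_equal(canonicalize(c(5, 2), spec2), c(5, 2))
  mixed <- objective_spec(c("a", "b"), c("minimize", "maximize"), c(1, 1))
  expect_equal(canonicalize(c(5, 2), mixed), c(5, -2))
  allmax <- objective_spec(c("a", "b"), c("maximize", "maximize"), c(1, 1))
  v <- c(3.2, -1.7)
  expect_equal(canonicalize(canonicalize(v, allmax), allmax), v)
  expect_error(canonicalize(c(1, 2, 3), spec2), "length")
})

test_that("pareto_dominates implements the strict componentwise relation", {
  expect_true(pareto_dominates(c(1, 1), c(2, 2)))
  expect_false(pareto_dominates(c(1, 2), c(2, 1)))
  expect_false(pareto_dominates(c(2, 1), c(1, 2)))
  expect_false(pareto_dominates(c(1, 1), c(1, 1)))
  expect_true(pareto_dominates(c(1, 1), c(1, 2)))
  expect_error(pareto_dominates(c(1, 1), c(1, 1, 1)), "length")
})

test_that("box_index floors componentwise, including negatives", {
  expect_equal(box_index(c(7.4, 2.9), spec2), c(1, 0))
  expect_equal(box_index(c(0, 0), spec2), c(0, 0))
  mecbm_like <- objective_spec(c("gd", "gr"), c("minimize", "minimize"),
                               c(0.4, 0.1))
  expect_equal(box_index(c(-0.1, 0.1), mecbm_like), c(-1, 1))
  expect_error(box_index(c(NaN, 1), spec2), "finite")
})

test_that("archive acceptance follows the epsilon-dominance rules", {
  a <- new_archive(spec2, n_genes = 1)
  r1 <- archive_accept(a, list(genotype = 1, objectives = c(7, 4)))
  expect_true(r1$accepted)                       # empty archive accepts

  # candidate box (0,0) evicts the sole member in box (1,1)
  r2 <- archive_accept(r1$archive, list(genotype = 2, objectives = c(2, 1)))
  expect_true(r2$accepted)
  expect_equal(nrow(r2$archive$genotypes), 1)
  expect_equal(unname(r2$archive$objectives[1, ]), c(2, 1))

  # same box (0,0), incomparable pair: epsilon-normalized corner distances
  # candidate (0.5,2): 0.1^2 + (2/3)^2 = 0.454; member (2,1): 0.4^2 + (1/3)^2
  # = 0.271 -> incumbent closer, candidate rejected
  r3 <- archive_accept(r2$archive, list(genotype = 3, objectives = c(0.5, 2)))
  expect_false(r3$accepted)
  expect_equal(unname(r3$archive$objectives[1, ]), c(2, 1))

  # same box, candidate closer to the corner: replaces the member
  r3b <- archive_accept(r3$archive, list(genotype = 5, objectives = c(1, 0.5)))
  # (1,0.5): 0.2^2 + (1/6)^2 = 0.068 < 0.271
  expect_true(r3b$accepted)
  expect_equal(unname(r3b$archive$objectives[1, ]), c(1, 0.5))

  # dominated-box candidate is rejected
  r4 <- archive_accept(r3b$archive, list(genotype = 4, objectives = c(11, 7)))
  expect_false(r4$accepted)
  expect_equal(nrow(r4$archive$genotypes), 1)
})

test_that("a hand-traced candidate stream yields the expected archive", {
  # epsilons (1,1): boxes are integer floors; stream chosen so every rule fires
  sp <- objective_spec(c("f1", "f2"), c("minimize", "minimize"), c(1, 1))
  stream <- list(c(3.5, 0.5),   # box (3,0)  accepted (empty archive)
                 c(0.5, 3.5),   # box (0,3)  accepted (incomparable boxes)
                 c(3.4, 0.4),   # box (3,0)  same box, dominates member 1
                 c(1.5, 1.5),   # box (1,1)  accepted (incomparable)
                 c(0.6, 0.6))   # box (0,0)  dominates every other box
  a <- new_archive(sp, n_genes = 1)
  accepted <- logical(5)
  for (i in seq_along(stream)) {
    r <- archive_accept(a, list(genotype = i, objectives = stream[[i]]))
    a <- r$archive
    accepted[i] <- r$accepted
  }
  expect_equal(accepted, c(TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(sort_box_rows(unname(a$boxes)), rbind(c(0, 0)))
  expect_equal(unname(a$objectives), rbind(c(0.6, 0.6)))
})

test_that("archive equals the brute-force epsilon-Pareto filter on streams", {
  set.seed(123)
  for (rep in 1:20) {
    m <- 2 + rep %% 3
    sp <- objective_spec(paste0("f", 1:m), rep("minimize", m),
                         runif(m, 0.5, 2))
    pts <- matrix(runif(60 * m, -10, 10), 60, m)
    a <- new_archive(sp, n_genes = 1)
    for (i in seq_len(nrow(pts)))
      a <- archive_accept(a, list(genotype = i, objectives = pts[i, ]))$archive
    expect_equal(sort_box_rows(unname(a$boxes)),
                 sort_box_rows(brute_eps_boxes(pts, sp$epsilon)))
    # archive invariant: mutual epsilon-non-domination, one member per box
    B <- a$boxes
    expect_equal(nrow(unique(B)), nrow(B))
    for (i in seq_len(nrow(B))) for (j in seq_len(nrow(B)))
      if (i != j) expect_false(all(B[i, ] <= B[j, ]) && any(B[i, ] < B[j, ]))
  }
})

test_that("vary respects identity limit, domain closure and determinism", {
  p1 <- c(10, -170, 90); p2 <- c(-40, 160, 0)
  expect_identical(vary(p1, p2, cx_rate = 0, mut_rate = 0), p1)
  set.seed(4)
  for (i in 1:200) {
    child <- vary(runif(5, -180, 180), runif(5, -180, 180))
    expect_true(all(child >= -180 & child < 180))
  }
  set.seed(77); c1 <- vary(p1, p2)
  set.seed(77); c2 <- vary(p1, p2)
  expect_identical(c1, c2)
  expect_error(vary(p1, p2[1:2]), "length")
})

test_that("run_emoea accounts evaluations exactly and is seed-deterministic", {
  counts <- new.env(); counts$n <- 0L
  counter <- function(g) {
    counts$n <- counts$n + 1L
    c(sum(g^2), sum((g - 90)^2))
  }
  a <- run_emoea(counter, spec2, n_genes = 3, n_pop = 10, n_gen = 4, seed = 5)
  expect_equal(counts$n, 10 + 10 * 4)
  expect_equal(a$n_evaluations, 50)

  f <- function(g) c(sum(g^2), sum((g - 90)^2))
  a1 <- run_emoea(f, spec2, n_genes = 3, n_pop = 15, n_gen = 3, seed = 9)
  a2 <- run_emoea(f, spec2, n_genes = 3, n_pop = 15, n_gen = 3, seed = 9)
  expect_identical(a1$genotypes, a2$genotypes)
  expect_identical(a1$objectives, a2$objectives)
})

test_that("n_gen = 0 returns the epsilon-filtered initial population", {
  f <- function(g) c(sum(g^2), sum((g - 90)^2))
  set.seed(21)
  a <- run_emoea(f, spec2, n_genes = 2, n_pop = 30, n_gen = 0)
  set.seed(21)
  pop <- t(replicate(30, runif(2, -180, 180)))
  objs <- t(apply(pop, 1, f))
  expect_equal(sort_box_rows(unname(a$boxes)),
               sort_box_rows(brute_eps_boxes(objs, spec2$epsilon)))
  expect_equal(a$n_evaluations, 30)
})

test_that("the archive converges onto the brute-force front of a toy problem", {
  # two torsions; smooth objectives with an analytic trade-off in theta1
  f <- function(g) c((g[1] + 90)^2 / 100 + (g[2] / 180)^2,
                     (g[1] - 90)^2 / 100)
  sp <- objective_spec(c("f1", "f2"), c("minimize", "minimize"), c(5, 5))
  a <- run_emoea(f, sp, n_genes = 2, n_pop = 80, n_gen = 60, seed = 33)
  # 1-degree grid oracle for the epsilon-Pareto front
  grid <- as.matrix(expand.grid(th1 = seq(-180, 179, by = 1),
                                th2 = seq(-180, 179, by = 15)))
  gobjs <- t(apply(grid, 1, f))
  front <- sort_box_rows(brute_eps_boxes(gobjs, sp$epsilon))
  # every archive member's box within one box of a true front box
  for (i in seq_len(nrow(a$boxes))) {
    d <- apply(front, 1, function(b) max(abs(b - a$boxes[i, ])))
    expect_lte(min(d), 1)
  }
})

test_that("evaluator failures propagate with context", {
  bad <- function(g) stop("backend exploded")
  expect_error(run_emoea(bad, spec2, n_genes = 2, n_pop = 5, n_gen = 1,
                         seed = 2),
               "generation 0, individual 1")
})
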