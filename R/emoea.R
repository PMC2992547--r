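# Generic epsilon-dominance multi-objective evolutionary engine.
#
# The archive discretizes canonical (minimization-form) objective space into
# epsilon-sized boxes and keeps at most one mutually non-dominated
# representative per occupied box: box-level Pareto dominance governs
# acceptance/eviction, and within a box the Pareto-dominating individual (or,
# if incomparable, the one nearer the box's lower corner in epsilon-
# normalized distance) wins, with the incumbent keeping ties.
#
# The evolutionary loop is steady-state: one offspring per iteration, bred
# from a binary-tournament population parent and a random archive co-parent.
# This file is the readable reference; generate_ensemble() runs a compiled
# twin (cpp_run_emoea) that consumes R's RNG stream in exactly the same
# order, so the two are bitwise interchangeable (tested).

#' Define an objective specification
#'
#' @param name character vector of objective names.
#' @param direction per-objective \code{"minimize"} or \code{"maximize"}.
#' @param epsilon per-objective epsilon (box width) in the objective's units;
#'   all must be positive.
#' @return data.frame of class \code{objective_spec}.
#' @export
objective_spec <- function(name, direction, epsilon) {
  .assert(length(name) >= 2, "need at least 2 objectives")
  .assert(length(direction) == length(name) && length(epsilon) == length(name),
          "name/direction/epsilon lengths differ")
  .assert(all(direction %in% c("minimize", "maximize")),
          "direction must be 'minimize' or 'maximize'")
  .assert(all(is.finite(epsilon) & epsilon > 0), "all epsilons must be > 0")
  structure(data.frame(name = name, direction = direction, epsilon = epsilon,
                       stringsAsFactors = FALSE),
            class = c("objective_spec", "data.frame"))
}

#' Canonicalize an objective vector to minimization form
#'
#' Sign-flips maximized objectives, preserving order; applying it twice under
#' an all-maximize spec returns the original vector.
#'
#' @param objvec raw objective vector.
#' @param spec an \code{\link{objective_spec}}.
#' @return canonical (all-minimize) vector.
#' @export
canonicalize <- function(objvec, spec) {
  .assert(length(objvec) == nrow(spec), "objective vector length mismatch")
  ifelse(spec$direction == "maximize", -objvec, objvec)
}

#' Pareto dominance (minimization form)
#'
#' @param a,b canonical objective vectors of equal length.
#' @return \code{TRUE} iff \code{a <= b} componentwise with at least one
#'   strict inequality.
#' @export
pareto_dominates <- function(a, b) {
  .assert(length(a) == length(b), "vector length mismatch")
  all(a <= b) && any(a < b)
}

#' Epsilon-box index of a canonical objective vector
#'
#' @param objvec canonical vector.
#' @param spec an \code{\link{objective_spec}}.
#' @return integer-valued vector \code{floor(objvec / epsilon)}.
#' @export
box_index <- function(objvec, spec) {
  .assert(all(is.finite(objvec)), "non-finite objective value")
  floor(objvec / spec$epsilon)
}

#' Create an empty epsilon-dominance archive
#'
#' @param spec an \code{\link{objective_spec}}.
#' @param n_genes genotype length (torsion count) of stored individuals.
#' @return object of class \code{emoea_archive}.
#' @export
new_archive <- function(spec, n_genes = 0) {
  structure(list(genotypes = matrix(numeric(0), 0, n_genes),
                 canonical = matrix(numeric(0), 0, nrow(spec)),
                 objectives = matrix(numeric(0), 0, nrow(spec)),
                 boxes = matrix(numeric(0), 0, nrow(spec)),
                 spec = spec, n_evaluations = 0),
            class = "emoea_archive")
}

#' @export
print.emoea_archive <- function(x, ...) {
  cat(sprintf("<emoea_archive> %d members, %d objectives, %s evaluations\n",
              nrow(x$genotypes), ncol(x$canonical),
              format(x$n_evaluations)))
  invisible(x)
}

# Core acceptance rules; operates on and returns the archive list.
.arch_accept <- function(arch, genotype, canon, raw) {
  eps <- arch$spec$epsilon
  m <- length(canon)
  b <- floor(canon / eps)
  n <- nrow(arch$boxes)
  if (n > 0) {
    same <- which(rowSums(arch$boxes == matrix(b, n, m, byrow = TRUE)) == m)
    if (length(same) > 0) {
      k <- same[1]
      mc <- arch$canonical[k, ]
      take <- if (pareto_dominates(canon, mc)) TRUE
              else if (pareto_dominates(mc, canon)) FALSE
              else {
                corner <- b * eps
                sum(((canon - corner) / eps)^2) < sum(((mc - corner) / eps)^2)
              }
      if (take) {
        arch$genotypes[k, ] <- genotype
        arch$canonical[k, ] <- canon
        arch$objectives[k, ] <- raw
      }
      return(list(archive = arch, accepted = take))
    }
    bm <- matrix(b, n, m, byrow = TRUE)
    le <- arch$boxes <= bm
    member_dom <- rowSums(le) == m & rowSums(arch$boxes < bm) > 0
    if (any(member_dom)) return(list(archive = arch, accepted = FALSE))
    ge <- arch$boxes >= bm
    evict <- rowSums(ge) == m & rowSums(arch$boxes > bm) > 0
    if (any(evict)) {
      keep <- !evict
      arch$genotypes <- arch$genotypes[keep, , drop = FALSE]
      arch$canonical <- arch$canonical[keep, , drop = FALSE]
      arch$objectives <- arch$objectives[keep, , drop = FALSE]
      arch$boxes <- arch$boxes[keep, , drop = FALSE]
    }
  }
  arch$genotypes <- rbind(arch$genotypes, genotype)
  arch$canonical <- rbind(arch$canonical, canon)
  arch$objectives <- rbind(arch$objectives, raw)
  arch$boxes <- rbind(arch$boxes, b)
  list(archive = arch, accepted = TRUE)
}

#' Offer a candidate to an epsilon-dominance archive
#'
#' Acceptance rules: (i) reject if any member's box Pareto-dominates the
#' candidate's box; (ii) otherwise evict all members whose boxes the
#' candidate's box dominates and insert; (iii) if a member occupies the same
#' box, keep the Pareto-dominating individual, or if incomparable the one
#' with the smaller epsilon-normalized distance to the box's lower corner
#' (the incumbent keeps ties).
#'
#' @param archive an \code{\link{new_archive}} object.
#' @param candidate list with \code{genotype} (numeric vector) and
#'   \code{objectives} (raw objective vector).
#' @param spec objective spec (defaults to the archive's own).
#' @return list with \code{archive} (updated) and \code{accepted} (logical).
#' @export
archive_accept <- function(archive, candidate, spec = archive$spec) {
  canon <- canonicalize(candidate$objectives, spec)
  .arch_accept(archive, candidate$genotype, canon, candidate$objectives)
}

#' Breed a child torsion vector
#'
#' Blend crossover on angles (shortest angular path, applied with probability
#' \code{cx_rate}) followed by per-gene mutation that replaces an angle with
#' a uniform draw from \code{[-180, 180)}.  With both rates zero the child
#' equals \code{parent1} exactly.  Deterministic given the RNG state.
#'
#' @param parent1,parent2 torsion vectors of equal length (degrees).
#' @param cx_rate crossover probability (default 0.9).
#' @param mut_rate per-gene mutation probability (default \code{1/length}).
#' @return child torsion vector, wrapped to \code{[-180, 180)}.
#' @export
vary <- function(parent1, parent2, cx_rate = 0.9, mut_rate = NULL) {
  ng <- length(parent1)
  .assert(length(parent2) == ng, "parent length mismatch")
  if (is.null(mut_rate)) mut_rate <- 1 / max(1, ng)
  child <- parent1
  if (cx_rate > 0 && runif(1) < cx_rate) {
    u <- runif(ng)
    child <- wrap_angle(parent1 + u * wrap_angle(parent2 - parent1))
  }
  if (mut_rate > 0) {
    mut <- runif(ng) < mut_rate
    if (any(mut)) child[mut] <- runif(sum(mut), -180, 180)
  }
  child
}

#' Run the steady-state epsilon-MOEA
#'
#' Performs exactly \code{n_pop} initial evaluations plus
#' \code{n_pop * n_gen} offspring evaluations.  Initialization draws uniform
#' random torsion vectors, optionally seeding individual 1 with \code{init}
#' (the input conformation's torsions, so the geometric-dissimilarity
#' reference point is represented).  Fully reproducible given the RNG state.
#'
#' @param evaluator function mapping a genotype (numeric vector of length
#'   \code{n_genes}) to a raw objective vector.
#' @param spec an \code{\link{objective_spec}}.
#' @param n_genes genotype length (>= 1).
#' @param n_pop,n_gen population size and generation count (default 200).
#' @param init optional seed genotype injected as individual 1.
#' @param cx_rate,mut_rate variation rates (see \code{\link{vary}}).
#' @param seed optional RNG seed set before the run.
#' @param energy_window optional in-run discard threshold: an individual
#'   whose filter energy (the sum of the canonical objectives named by
#'   \code{window_idx}) exceeds the running minimum by more than this is
#'   discarded as soon as it is identified -- it is neither archived nor
#'   inserted into the population (it still counts as an evaluation).
#'   Default \code{Inf} disables the discard.
#' @param window_idx canonical objective indices summed into the filter
#'   energy (default the first two: the force-field terms).
#' @return an \code{emoea_archive} of mutually epsilon-non-dominated
#'   individuals, with \code{n_evaluations} recorded.
#' @export
run_emoea <- function(evaluator, spec, n_genes, n_pop = 200, n_gen = 200,
                      init = NULL, cx_rate = 0.9, mut_rate = NULL,
                      seed = NULL, energy_window = Inf,
                      window_idx = c(1L, 2L)) {
  .assert(n_genes >= 1, "need at least one gene")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mut_rate)) mut_rate <- 1 / n_genes
  sgn <- ifelse(spec$direction == "maximize", -1, 1)
  m <- nrow(spec)

  pop_g <- matrix(0, n_pop, n_genes)
  for (p in seq_len(n_pop)) pop_g[p, ] <- runif(n_genes, -180, 180)
  if (!is.null(init)) pop_g[1, ] <- wrap_angle(init)
  pop_c <- matrix(0, n_pop, m)
  pop_r <- matrix(0, n_pop, m)
  for (p in seq_len(n_pop)) {
    o <- .eval_checked(evaluator, pop_g[p, ], m, 0L, p)
    pop_r[p, ] <- o
    pop_c[p, ] <- sgn * o
  }
  n_eval <- n_pop
  fe_of <- function(cvec) sum(cvec[window_idx])
  fe_min <- min(apply(pop_c, 1, fe_of))
  arch <- new_archive(spec, n_genes)
  for (p in seq_len(n_pop))
    if (fe_of(pop_c[p, ]) <= fe_min + energy_window)
      arch <- .arch_accept(arch, pop_g[p, ], pop_c[p, ], pop_r[p, ])$archive

  n_iter <- n_pop * n_gen
  for (it in seq_len(n_iter)) {
    i1 <- floor(runif(1) * n_pop) + 1
    i2 <- floor(runif(1) * n_pop) + 1
    p1 <- if (pareto_dominates(pop_c[i1, ], pop_c[i2, ])) i1
          else if (pareto_dominates(pop_c[i2, ], pop_c[i1, ])) i2
          else if (runif(1) < 0.5) i1 else i2
    ai <- floor(runif(1) * nrow(arch$genotypes)) + 1
    child <- vary(pop_g[p1, ], arch$genotypes[ai, ], cx_rate, mut_rate)
    gen_no <- ((it - 1) %/% n_pop) + 1L
    oc <- .eval_checked(evaluator, child, m, gen_no, it)
    cc <- sgn * oc
    n_eval <- n_eval + 1
    fe <- fe_of(cc)
    if (fe < fe_min) fe_min <- fe
    if (fe > fe_min + energy_window) next    # discard as soon as identified
    arch <- .arch_accept(arch, child, cc, oc)$archive
    member_dom <- rowSums(pop_c <= matrix(cc, n_pop, m, byrow = TRUE)) == m &
                  rowSums(pop_c < matrix(cc, n_pop, m, byrow = TRUE)) > 0
    if (!any(member_dom)) {
      child_dom <- rowSums(pop_c >= matrix(cc, n_pop, m, byrow = TRUE)) == m &
                   rowSums(pop_c > matrix(cc, n_pop, m, byrow = TRUE)) > 0
      r <- if (any(child_dom)) {
        w <- which(child_dom)
        w[floor(runif(1) * length(w)) + 1]
      } else floor(runif(1) * n_pop) + 1
      pop_g[r, ] <- child
      pop_c[r, ] <- cc
    }
  }
  arch$n_evaluations <- n_eval
  rownames(arch$genotypes) <- rownames(arch$canonical) <- NULL
  rownames(arch$objectives) <- rownames(arch$boxes) <- NULL
  arch
}

.eval_checked <- function(evaluator, g, m, gen_no, idx) {
  o <- tryCatch(evaluator(g), error = function(e)
    stop(sprintf("evaluator failed at generation %d, individual %d: %s",
                 gen_no, idx, conditionMessage(e)), call. = FALSE))
  .assert(length(o) == m && all(is.finite(o)),
          "evaluator returned a bad objective vector (generation %d, individual %d)",
          gen_no, idx)
  o
}
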