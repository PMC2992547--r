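# Backend-agnostic energy models.
#
# Two interchangeable empirical parameterizations are provided behind one
# contract: "mmff94" (buffered 14-7 van der Waals, full-strength 1-4
# interactions) and "tripos" (Lennard-Jones 12-6, 1-4 scaled by 0.5), each
# with a three-term cosine torsion potential and harmonic bond/angle terms
# restrained to the molecule's reference geometry.  Electrostatics is
# excluded everywhere by construction.  The parameter sets are documented
# approximations of the named families, not reproductions of the full
# published tables; the sampling method itself is force-field-agnostic and
# its behaviour is insensitive to the backend choice (tested).

.VDW_TABLES <- list(
  mmff94 = data.frame(
    element = c("H", "C", "N", "O", "S", "F", "Cl", "Br", "P"),
    rstar   = c(1.49, 1.91, 1.82, 1.66, 2.00, 1.75, 1.95, 2.10, 2.10),
    eps     = c(0.016, 0.086, 0.170, 0.210, 0.250, 0.061, 0.265, 0.320, 0.200),
    stringsAsFactors = FALSE),
  tripos = data.frame(
    element = c("H", "C", "N", "O", "S", "F", "Cl", "Br", "P"),
    rstar   = c(1.50, 1.70, 1.55, 1.52, 1.80, 1.47, 1.75, 1.85, 1.80),
    eps     = c(0.042, 0.107, 0.095, 0.116, 0.314, 0.109, 0.314, 0.434, 0.314),
    stringsAsFactors = FALSE)
)

.TORSION_TABLES <- list(
  #         single  double  aromatic amide   (V1, V2, V3) per quad
  mmff94 = list("1" = c(0, 0, 0.32), "2" = c(0, 10.0, 0),
                "ar" = c(0, 8.0, 0), "am" = c(0, 6.0, 0)),
  tripos = list("1" = c(0, 0, 0.20), "2" = c(0, 12.5, 0),
                "ar" = c(0, 8.0, 0), "am" = c(0, 6.3, 0))
)

.BACKEND_CONST <- list(
  mmff94 = list(vdw_form = 1L, bond_k = 350, ang_k = 60, scale14 = 1.0),
  tripos = list(vdw_form = 0L, bond_k = 600, ang_k = 80, scale14 = 0.5)
)

#' Construct an energy model
#'
#' @param name backend identifier, \code{"mmff94"} or \code{"tripos"}
#'   (alias \code{"tripos-like"}).
#' @return object of class \code{energy_model}.
#' @export
energy_model <- function(name = c("mmff94", "tripos", "tripos-like")) {
  name <- match.arg(name)
  if (name == "tripos-like") name <- "tripos"
  structure(c(list(name = name,
                   vdw_table = .VDW_TABLES[[name]],
                   torsion_table = .TORSION_TABLES[[name]]),
              .BACKEND_CONST[[name]]),
            class = "energy_model")
}

.as_energy_model <- function(model) {
  if (inherits(model, "energy_model")) model else energy_model(model)
}

.angle_triples <- function(mol, adj) {
  out <- matrix(integer(0), 0, 3)
  for (j in seq_along(mol$elements)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    pairs <- utils::combn(sort(nb), 2)
    out <- rbind(out, cbind(pairs[1, ], j, pairs[2, ]))
  }
  out
}

.torsion_quads <- function(mol, adj) {
  out <- matrix(integer(0), 0, 4)
  vv <- character(0)
  for (e in seq_len(nrow(mol$bonds))) {
    j <- mol$bonds$i[e]; k <- mol$bonds$j[e]
    ni <- setdiff(adj[[j]], k); nl <- setdiff(adj[[k]], j)
    if (length(ni) == 0 || length(nl) == 0) next
    for (i in ni) for (l in nl) {
      if (i == l) next                      # three-membered ring
      out <- rbind(out, c(i, j, k, l))
      vv <- c(vv, mol$bonds$order[e])
    }
  }
  list(quads = out, orders = vv)
}

# Builds the typed system consumed by the compiled evaluator.  Reference
# bond lengths and angles (r0, theta0) are taken from the molecule's input
# geometry: sampling holds them fixed, and minimization restrains to them.
.ff_params <- function(mol, model) {
  model <- .as_energy_model(model)
  vt <- model$vdw_table
  miss <- which(!(mol$elements %in% vt$element))
  if (length(miss) > 0)
    stop(sprintf("atom typing failed: atom %d (%s) has no %s parameters",
                 miss[1], mol$elements[miss[1]], model$name), call. = FALSE)
  X0 <- mol$coords
  n <- length(mol$elements)
  adj <- lapply(seq_len(n), function(a)
    c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a]))

  bond_idx <- cbind(mol$bonds$i, mol$bonds$j)
  bond_r0 <- sqrt(rowSums((X0[bond_idx[, 1], , drop = FALSE] -
                           X0[bond_idx[, 2], , drop = FALSE])^2))
  ang_idx <- .angle_triples(mol, adj)
  ang_th0 <- apply(ang_idx, 1, function(q) {
    u <- X0[q[1], ] - X0[q[2], ]; w <- X0[q[3], ] - X0[q[2], ]
    acos(max(-1, min(1, sum(u * w) / (.norm3(u) * .norm3(w)))))
  })
  tq <- .torsion_quads(mol, adj)
  tor_v <- t(vapply(tq$orders, function(o)
    model$torsion_table[[o]] %||% c(0, 0, 0), numeric(3)))
  if (nrow(tq$quads) == 0) tor_v <- matrix(0, 0, 3)

  # nonbonded pairs: graph distance >= 3; 1-4 pairs scaled
  g <- .mol_graph(mol)
  D <- igraph::distances(g)
  prm <- vt[match(mol$elements, vt$element), ]
  pairs <- which(upper.tri(D) & D >= 3, arr.ind = TRUE)
  vdw_idx <- pairs
  vdw_eps <- sqrt(prm$eps[pairs[, 1]] * prm$eps[pairs[, 2]])
  vdw_rstar <- prm$rstar[pairs[, 1]] + prm$rstar[pairs[, 2]]
  vdw_scale <- ifelse(D[pairs] == 3, model$scale14, 1.0)

  list(X0 = X0,
       bond_idx = bond_idx, bond_r0 = bond_r0,
       bond_k = rep(model$bond_k, nrow(bond_idx)),
       ang_idx = ang_idx, ang_th0 = as.numeric(ang_th0),
       ang_k = rep(model$ang_k, nrow(ang_idx)),
       tor_idx = tq$quads, tor_v = tor_v,
       vdw_idx = vdw_idx, vdw_eps = vdw_eps, vdw_rstar = vdw_rstar,
       vdw_scale = vdw_scale, vdw_form = model$vdw_form)
}

#' Build a typed force-field system
#'
#' Precomputes parameters and uploads them to the compiled evaluator.  The
#' returned handle is consumed by the sampler's hot loop; regular users call
#' \code{\link{evaluate_terms}} / \code{\link{minimize_conformation}} instead.
#'
#' @param mol molecule record (its reference geometry defines r0 / theta0).
#' @param input_conf conformation whose heavy-atom geometry is the geometric-
#'   dissimilarity reference (defaults to the molecule's reference geometry).
#' @param model energy model or backend name.
#' @param rbs optional precomputed rotatable bonds.
#' @return object of class \code{ff_system} holding an external pointer.
#' @export
ff_system <- function(mol, input_conf = NULL, model = "mmff94", rbs = NULL) {
  model <- .as_energy_model(model)
  rbs <- rbs %||% perceive_rotatable_bonds(mol)
  par <- .ff_params(mol, model)
  Xin <- if (is.null(input_conf)) mol$coords else .coords_of(input_conf)
  par$X0 <- Xin          # torsion driving starts from the input conformation
  nr <- length(rbs)
  par$rot_quad <- if (nr > 0) t(vapply(rbs, function(r) r$quad, integer(4)))
                  else matrix(integer(0), 0, 4)
  par$rot_moving <- lapply(rbs, function(r) r$moving)
  par$heavy <- mol$heavy_idx
  par$ref_heavy <- Xin[mol$heavy_idx, , drop = FALSE]
  structure(list(ptr = cpp_build_system(par), model = model, rbs = rbs,
                 mol = mol), class = "ff_system")
}

#' Evaluate force-field energy terms
#'
#' Deterministic, term-wise evaluation: van der Waals, torsion, bond and
#' angle energies plus their sum \code{total_no_elec}.  Charge-charge terms
#' are excluded by construction.  Overlapping geometries yield a large finite
#' van der Waals value (capped at 1e6 kcal/mol), never NaN/Inf.
#'
#' @param mol molecule record.
#' @param conf conformation to evaluate.
#' @param model energy model or backend name.
#' @return object of class \code{energy_breakdown}: list with \code{vdw},
#'   \code{torsion}, \code{bond}, \code{angle}, \code{total_no_elec}
#'   (kcal/mol).
#' @export
evaluate_terms <- function(mol, conf, model = "mmff94") {
  sys <- ff_system(mol, model = model, rbs = list())
  e <- cpp_sys_energy(sys$ptr, .coords_of(conf))
  structure(as.list(e), class = "energy_breakdown")
}

#' Conjugate-gradient energy minimization
#'
#' Refines a conformation under the full force field excluding electrostatics
#' with a Polak-Ribiere conjugate-gradient minimizer, stopping at the
#' gradient max-norm tolerance or after \code{max_steps} steps, whichever
#' comes first.  The returned energy never exceeds the input energy.
#'
#' @param mol molecule record.
#' @param conf starting conformation.
#' @param model energy model or backend name used for refinement.
#' @param max_steps maximum number of accepted CG steps (default 100).
#' @param grad_tol gradient max-norm convergence threshold in
#'   kcal/mol/Angstrom (default 0.01).
#' @return minimized \code{conformation} with \code{minimized = TRUE},
#'   \code{source_ff} recorded, cached \code{energy_terms}, and attributes
#'   \code{steps} and \code{converged}.
#' @export
minimize_conformation <- function(mol, conf, model = "mmff94",
                                  max_steps = 100, grad_tol = 0.01) {
  model <- .as_energy_model(model)
  sys <- ff_system(mol, model = model, rbs = list())
  res <- cpp_minimize(sys$ptr, .coords_of(conf), as.integer(max_steps), grad_tol)
  out <- conformation(res$coords, minimized = TRUE, source_ff = model$name,
                      energy_terms = as.list(res$energy))
  attr(out, "steps") <- res$steps
  attr(out, "converged") <- res$converged
  out
}
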