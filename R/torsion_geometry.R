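# Rotatable-bond perception, torsion driving under fixed internal
# coordinates, and the geometric quantities used as objectives and benchmark
# metrics (radius of gyration, geometric dissimilarity, symmetry-aware
# best-fit RMSD).
#
# Conventions fixed here and used throughout:
#  * rotatable bond = acyclic single-order bond, not to a terminal atom,
#    whose rotation moves at least one heavy atom on each side; amide C-N
#    bonds are excluded;
#  * all RMSD / Rg / GD computations are over heavy atoms with unit weights;
#  * the moving set is the smaller graph side of the bond (contains k, not j);
#  * dihedrals are signed, in degrees, wrapped to [-180, 180).

.mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = length(mol$elements), directed = FALSE)
  if (nrow(mol$bonds) > 0)
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  g
}

.is_amide <- function(mol, j, k, adj) {
  # single C-N bond where the C carries a double bond to O
  for (ord in list(c(j, k), c(k, j))) {
    cc <- ord[1]; nn <- ord[2]
    if (mol$elements[cc] == "C" && mol$elements[nn] == "N") {
      dbl <- mol$bonds$order == "2" &
        ((mol$bonds$i == cc & mol$elements[mol$bonds$j] == "O") |
         (mol$bonds$j == cc & mol$elements[mol$bonds$i] == "O"))
      if (any(dbl)) return(TRUE)
    }
  }
  FALSE
}

#' Perceive rotatable bonds
#'
#' Deterministic, order-stable perception: acyclic single-order bonds whose
#' rotation moves at least one heavy atom on each side; amide C-N bonds are
#' excluded.  Each rotatable bond carries the dihedral quad used to measure
#' its angle and the index set of atoms displaced by its rotation (the
#' smaller graph side, containing the second axis atom).
#'
#' @param mol a \code{\link{mol_record}} with a connected bond graph.
#' @return list of \code{rot_bond} objects with fields \code{axis} (atom pair
#'   \code{c(j, k)}), \code{quad} (dihedral atoms \code{c(i, j, k, l)}) and
#'   \code{moving} (atom indices moved by rotation).
#' @export
perceive_rotatable_bonds <- function(mol) {
  g <- .mol_graph(mol)
  .assert(igraph::components(g)$no == 1, "molecular graph is disconnected")
  if (nrow(mol$bonds) == 0) return(list())
  bridge_ids <- as.integer(igraph::bridges(g))
  adj <- lapply(seq_along(mol$elements), function(a)
    c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a]))
  is_heavy <- mol$elements != "H"
  out <- list()
  ord <- order(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  for (e in ord) {
    if (mol$bonds$order[e] != "1") next
    if (!(e %in% bridge_ids)) next                    # in a ring
    j <- min(mol$bonds$i[e], mol$bonds$j[e])
    k <- max(mol$bonds$i[e], mol$bonds$j[e])
    hj <- setdiff(adj[[j]][is_heavy[adj[[j]]]], k)
    hk <- setdiff(adj[[k]][is_heavy[adj[[k]]]], j)
    if (length(hj) == 0 || length(hk) == 0) next      # terminal / only H moves
    if (.is_amide(mol, j, k, adj)) next
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    side_k <- which(comp == comp[k])
    if (length(side_k) > length(mol$elements) / 2) {  # rotate the smaller side
      tmp <- j; j <- k; k <- tmp
      side_k <- which(comp == comp[k])
      hj <- setdiff(adj[[j]][is_heavy[adj[[j]]]], k)
      hk <- setdiff(adj[[k]][is_heavy[adj[[k]]]], j)
    }
    out[[length(out) + 1]] <- structure(
      list(axis = c(j, k),
           quad = c(min(hj), j, k, min(hk)),
           moving = sort(side_k)),
      class = "rot_bond")
  }
  out
}

.dihedral_deg <- function(X, q) {
  b1 <- X[q[2], ] - X[q[1], ]
  b2 <- X[q[3], ] - X[q[2], ]
  b3 <- X[q[4], ] - X[q[3], ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  .assert(.norm3(n1) >= 1e-10 && .norm3(n2) >= 1e-10,
          "undefined dihedral (collinear atoms)")
  wrap_angle(atan2(sum(.cross3(n1, n2) * b2) / .norm3(b2),
                   sum(n1 * n2)) * 180 / pi)
}

#' Construct a conformation
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param torsions optional cached torsion vector (degrees).
#' @param energy_terms optional cached energy breakdown.
#' @param minimized logical flag.
#' @param source_ff name of the force field that produced the geometry.
#' @return object of class \code{conformation}.
#' @export
conformation <- function(coords, torsions = NULL, energy_terms = NULL,
                         minimized = FALSE, source_ff = NA_character_) {
  coords <- as.matrix(coords)
  .assert(all(is.finite(coords)), "non-finite coordinates")
  structure(list(coords = unname(coords), torsions = torsions,
                 energy_terms = energy_terms, objective_values = NULL,
                 filter_energy = NA_real_,
                 minimized = minimized, source_ff = source_ff),
            class = "conformation")
}

.coords_of <- function(x) {
  if (inherits(x, "conformation")) x$coords
  else if (is.matrix(x)) x
  else stop("expected a conformation or coordinate matrix")
}

#' Measure the torsion vector of a conformation
#'
#' @param mol molecule record.
#' @param conf conformation (or coordinate matrix).
#' @param rbs rotatable bonds from \code{\link{perceive_rotatable_bonds}}
#'   (re-perceived when omitted).
#' @return numeric vector of signed dihedrals in degrees, wrapped to
#'   \code{[-180, 180)}, one per rotatable bond in perception order.
#' @export
measure_torsions <- function(mol, conf, rbs = NULL) {
  rbs <- rbs %||% perceive_rotatable_bonds(mol)
  X <- .coords_of(conf)
  vapply(rbs, function(rb) .dihedral_deg(X, rb$quad), numeric(1))
}

#' Drive torsions under fixed bond lengths and angles
#'
#' Rebuilds a conformation from \code{base} so that the measured dihedral of
#' every rotatable bond equals \code{tv}.  Each rotation is rigid about the
#' bond axis, so every bond length and bond angle of \code{base} is preserved
#' exactly (to floating-point accuracy).
#'
#' @param mol molecule record.
#' @param base conformation supplying the fixed internal coordinates.
#' @param tv target torsion vector in degrees (length = rotatable-bond count).
#' @param rbs optional precomputed rotatable bonds.
#' @return a new \code{conformation} with cached torsions.
#' @export
set_torsions <- function(mol, base, tv, rbs = NULL) {
  rbs <- rbs %||% perceive_rotatable_bonds(mol)
  .assert(length(tv) == length(rbs),
          "torsion vector length %d != rotatable-bond count %d",
          length(tv), length(rbs))
  X <- .coords_of(base)
  for (r in seq_along(rbs)) {
    rb <- rbs[[r]]
    cur <- .dihedral_deg(X, rb$quad)
    delta <- (tv[r] - cur) * pi / 180
    a <- X[rb$axis[1], ]
    u <- .unit3(X[rb$axis[2], ] - a)
    co <- cos(delta); si <- sin(delta)
    for (idx in rb$moving) {
      v <- X[idx, ] - a
      X[idx, ] <- a + v * co + .cross3(u, v) * si + u * sum(u * v) * (1 - co)
    }
  }
  conformation(X, torsions = wrap_angle(tv))
}

#' Radius of gyration
#'
#' Root-mean-square distance of the heavy atoms from their centroid, with
#' unit weights.  Invariant under rigid motion.
#'
#' @param conf conformation or coordinate matrix.
#' @param mol optional molecule record; when given, only heavy atoms enter.
#' @return gyration radius in Angstrom.
#' @export
radius_of_gyration <- function(conf, mol = NULL) {
  X <- .coords_of(conf)
  if (!is.null(mol)) X <- X[mol$heavy_idx, , drop = FALSE]
  ctr <- colMeans(X)
  sqrt(mean(rowSums((X - matrix(ctr, nrow(X), 3, byrow = TRUE))^2)))
}

#' Least-squares superposition RMSD
#'
#' Rigid-body-minimized RMSD (Kabsch superposition) over a set of paired
#' atoms.  Symmetric in its arguments and non-negative.
#'
#' @param conf_a,conf_b conformations or coordinate matrices.
#' @param atom_map two-column integer matrix pairing atoms of \code{conf_a}
#'   (column 1) with atoms of \code{conf_b} (column 2).  Defaults to the
#'   identity pairing over heavy atoms when \code{mol} is given, else over
#'   all atoms.
#' @param mol optional molecule record used for the default heavy-atom map.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(conf_a, conf_b, atom_map = NULL, mol = NULL) {
  A <- .coords_of(conf_a); B <- .coords_of(conf_b)
  if (is.null(atom_map)) {
    idx <- if (!is.null(mol)) mol$heavy_idx else seq_len(nrow(A))
    atom_map <- cbind(idx, idx)
  }
  .assert(nrow(atom_map) >= 3, "need at least 3 atom pairs for superposition")
  Am <- A[atom_map[, 1], , drop = FALSE]
  Bm <- B[atom_map[, 2], , drop = FALSE]
  sv <- svd(scale(Am, scale = FALSE))$d
  .assert(sv[2] > 1e-8 * max(sv[1], 1), "degenerate (collinear) reference atoms")
  cpp_kabsch_rmsd(Am, Bm)
}

#' Enumerate heavy-atom graph automorphisms
#'
#' Element-colored automorphisms of the heavy-atom bond graph, enumerated by
#' closing the generator set reported by bliss (via igraph).  When the group
#' order exceeds \code{cap} the identity permutation alone is returned with a
#' warning, keeping highly symmetric molecules bounded.
#'
#' @param mol molecule record.
#' @param cap maximum number of automorphisms to enumerate (default 10000).
#' @return list of integer permutations of \code{seq_along(mol$heavy_idx)}.
#' @export
heavy_automorphisms <- function(mol, cap = 10000) {
  heavy <- mol$heavy_idx
  nh <- length(heavy)
  ident <- seq_len(nh)
  if (nh <= 2) return(list(ident))
  remap <- match(seq_along(mol$elements), heavy)
  bh <- mol$bonds[mol$bonds$i %in% heavy & mol$bonds$j %in% heavy, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nh, directed = FALSE)
  if (nrow(bh) > 0) g <- igraph::add_edges(g, rbind(remap[bh$i], remap[bh$j]))
  colors <- as.integer(factor(mol$elements[heavy]))
  size <- suppressWarnings(as.numeric(
    igraph::count_automorphisms(g, colors = colors)$group_size))
  if (!is.finite(size) || size > cap) {
    warning(sprintf("automorphism group too large (%s > %d); using identity mapping",
                    format(size), cap))
    return(list(ident))
  }
  gens <- igraph::automorphism_group(g, colors = colors)
  gens <- lapply(gens, as.integer)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(p) paste(p, collapse = ",")
  assign(key(ident), TRUE, envir = seen)
  out <- list(ident)
  queue <- list(ident)
  while (length(queue) > 0 && length(out) < cap) {
    p <- queue[[1]]; queue <- queue[-1]
    for (gen in gens) {
      q <- gen[p]
      k <- key(q)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1]] <- q
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  out
}

#' Symmetry-aware best-fit RMSD
#'
#' Minimum superposition RMSD over the element-colored automorphisms of the
#' heavy-atom graph; never larger than the identity-mapping RMSD.
#'
#' @param conf,ref conformations (same molecule topology).
#' @param mol molecule record.
#' @param autos optional precomputed automorphism list (see
#'   \code{\link{heavy_automorphisms}}).
#' @return RMSD in Angstrom.
#' @export
best_fit_rmsd <- function(conf, ref, mol, autos = NULL) {
  autos <- autos %||% heavy_automorphisms(mol)
  A <- .coords_of(conf)[mol$heavy_idx, , drop = FALSE]
  B <- .coords_of(ref)[mol$heavy_idx, , drop = FALSE]
  best <- Inf
  for (p in autos) {
    r <- cpp_kabsch_rmsd(A[p, , drop = FALSE], B)
    if (r < best) best <- r
  }
  best
}

#' Geometric dissimilarity to the input conformation
#'
#' Heavy-atom superposition RMSD under the identity mapping between a
#' conformation and the sampling input conformation; this is the GD diversity
#' objective of the multiple-empirical-criteria mode.
#'
#' @param conf conformation under evaluation.
#' @param input_conf the sampling input conformation.
#' @param mol molecule record.
#' @return GD in Angstrom (0 iff the geometries coincide after rigid
#'   alignment).
#' @export
geometric_dissimilarity <- function(conf, input_conf, mol) {
  superpose_rmsd(conf, input_conf, mol = mol)
}
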