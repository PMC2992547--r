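# Synthetic test molecules: sp3-idealized chain / branched / ring-containing
# skeletons of C, N and O with explicit hydrogens, built from internal
# coordinates (NeRF placement) so geometry is chemically sane and exactly
# reproducible from the seed.  A planted target conformation turns any
# fixture into a parameter-recovery benchmark case.

.BOND_LEN <- c(C = 1.53, N = 1.47, O = 1.43)       # X-C bond lengths, Angstrom
.H_LEN <- c(C = 1.09, N = 1.01, O = 0.96)
.VALENCE <- c(C = 4L, N = 3L, O = 2L)
.TET <- 109.4712206344907                           # tetrahedral angle, degrees

#' Fixture specification
#'
#' @param n_heavy number of heavy atoms (>= 2; >= 7 for ring topologies).
#' @param topology \code{"chain"}, \code{"branched"} or \code{"ring"}.
#' @param seed integer seed controlling element choice, branching and
#'   starting torsions.
#' @param planted_torsions optional torsion vector applied to the built
#'   geometry (length must match the perceived rotatable-bond count).
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_heavy, topology = c("chain", "branched", "ring"),
                         seed = 1, planted_torsions = NULL) {
  topology <- match.arg(topology)
  .assert(n_heavy >= 2, "need at least 2 heavy atoms")
  if (topology == "ring")
    .assert(n_heavy >= 7,
            "ring fixture needs a 6-ring plus a tail (>= 7 heavy atoms)")
  structure(list(n_heavy = as.integer(n_heavy), topology = topology,
                 seed = as.integer(seed), planted_torsions = planted_torsions),
            class = "fixture_spec")
}

# NeRF: place an atom at distance r from C, angle theta (deg) at C against B,
# dihedral phi (deg) about B-C against A.
.nerf <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- .unit3(C - B)
  n <- .unit3(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Unit directions completing a tetrahedral center, given the unit vectors u
# toward the already-placed neighbors; returns q new directions.
.tet_dirs <- function(u, q) {
  ang <- .TET * pi / 180
  if (length(u) == 1) {
    ref <- if (abs(u[[1]][1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- .unit3(.cross3(u[[1]], ref))
    e2 <- .cross3(u[[1]], e1)
    return(lapply(seq_len(q), function(i) {
      ph <- 2 * pi * (i - 1) / 3
      .unit3(cos(ang) * u[[1]] + sin(ang) * (cos(ph) * e1 + sin(ph) * e2))
    }))
  }
  if (length(u) == 2) {
    b <- .unit3(-(u[[1]] + u[[2]]))
    w <- .unit3(.cross3(u[[1]], u[[2]]))
    half <- 0.5 * ang
    return(list(.unit3(cos(half) * b + sin(half) * w),
                .unit3(cos(half) * b - sin(half) * w))[seq_len(q)])
  }
  list(.unit3(-Reduce(`+`, u)))[seq_len(q)]
}

#' Build a synthetic molecule with an input conformation
#'
#' Heavy atoms are placed on idealized sp3 internal coordinates (tetrahedral
#' angles, standard bond lengths) with seeded staggered backbone torsions
#' drawn from \{180, 60, -60\} degrees; hydrogens complete every valence.
#' Interior non-branching positions are C with occasional seeded N/O
#' substitution, so every fixture passes the organic element filter and both
#' force-field backends can type it.  Deterministic given the seed.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return list with \code{mol} (a \code{mol_record}), \code{conf} (the input
#'   \code{conformation}) and \code{n_rotatable}.
#' @export
make_fixture <- function(spec) {
  .assert(inherits(spec, "fixture_spec"), "expected a fixture_spec")
  set.seed(spec$seed)
  n <- spec$n_heavy

  # topology: parent pointers (atom 1 is the root)
  parent <- integer(n)
  if (spec$topology == "chain") {
    parent <- c(0L, seq_len(n - 1))
  } else if (spec$topology == "branched") {
    parent[1:2] <- c(0L, 1L)
    deg <- c(1L, 1L, rep(0L, n - 2))
    tip <- 2L
    for (a in seq_len(n)[-(1:2)]) {
      p <- tip
      if (runif(1) < 0.25) {
        cand <- which(seq_len(n) < a & deg >= 1 & deg <= 2)
        cand <- setdiff(cand, tip)
        if (length(cand) > 0) p <- cand[floor(runif(1) * length(cand)) + 1]
      }
      parent[a] <- p
      deg[p] <- deg[p] + 1L
      deg[a] <- 1L
      if (p == tip) tip <- a
    }
  } else {  # ring: atoms 1-6 are a chair, the tail 7..n hangs off atom 1
    parent <- c(0L, 1L, 2L, 3L, 4L, 5L, 1L,
                if (n > 7) 7:(n - 1) else integer(0))
  }

  # elements: seeded N/O substitution on interior degree-2 positions
  child_count <- tabulate(parent[parent > 0], nbins = n)
  elements <- rep("C", n)
  for (a in seq_len(n)) {
    in_ring <- spec$topology == "ring" && a <= 6
    if (parent[a] > 0 && child_count[a] == 1 && !in_ring &&
        elements[parent[a]] == "C" && runif(1) < 0.2)
      elements[a] <- c("N", "O")[floor(runif(1) * 2) + 1]
  }

  # heavy-atom geometry
  X <- matrix(NA_real_, n, 3)
  # heteroatom bonds take the shorter (heteroatom) reference length
  blen <- function(a) min(.BOND_LEN[[elements[a]]],
                          .BOND_LEN[[elements[max(parent[a], 1L)]]])
  th <- .TET * pi / 180
  X[1, ] <- c(0, 0, 0)
  X[2, ] <- c(blen(2), 0, 0)
  ring_closed <- spec$topology == "ring"
  if (ring_closed) {
    X[3, ] <- X[2, ] + blen(3) * c(-cos(th), sin(th), 0)
    # ideal chair = diamond-lattice fragment: ring torsions alternate +-60
    X[4, ] <- .nerf(X[1, ], X[2, ], X[3, ], blen(4), .TET, 60)
    X[5, ] <- .nerf(X[2, ], X[3, ], X[4, ], blen(5), .TET, -60)
    X[6, ] <- .nerf(X[3, ], X[4, ], X[5, ], blen(6), .TET, 60)
  }
  first <- if (ring_closed) 7L else 3L
  nbrs <- function(a, upto) {
    nb <- c(parent[a], which(parent == a))
    if (ring_closed && a == 1) nb <- c(nb, 6L)
    if (ring_closed && a == 6) nb <- c(nb, 1L)
    nb[nb > 0 & nb < upto]
  }
  if (n >= first) {
    for (a in first:n) {
      p <- parent[a]
      placed <- nbrs(p, a)
      if (length(placed) >= 2) {
        dirs <- .tet_dirs(lapply(placed, function(b) .unit3(X[b, ] - X[p, ])),
                          1)
        X[a, ] <- X[p, ] + blen(a) * dirs[[1]]
      } else {
        gp <- placed[1]
        ref <- setdiff(nbrs(gp, a), p)
        Aref <- if (length(ref) > 0) X[ref[1], ] else X[gp, ] + c(0, -1, 0)
        # anti backbone: the input conformation is an extended chain, the
        # way standard 2D->3D embedders emit their single low-energy guess
        X[a, ] <- .nerf(Aref, X[gp, ], X[p, ], blen(a), .TET, 180)
      }
    }
  }

  heavy_bonds <- data.frame(i = parent[parent > 0], j = which(parent > 0),
                            order = "1", stringsAsFactors = FALSE)
  if (ring_closed)
    heavy_bonds <- rbind(heavy_bonds,
                         data.frame(i = 6L, j = 1L, order = "1",
                                    stringsAsFactors = FALSE))

  # hydrogens complete each valence with tetrahedral directions
  all_elements <- elements
  all_X <- X
  all_bonds <- heavy_bonds
  deg <- tabulate(c(heavy_bonds$i, heavy_bonds$j), nbins = n)
  for (a in seq_len(n)) {
    need <- .VALENCE[[elements[a]]] - deg[a]
    if (need <= 0) next
    nb <- c(heavy_bonds$j[heavy_bonds$i == a],
            heavy_bonds$i[heavy_bonds$j == a])
    dirs <- .tet_dirs(lapply(nb, function(b) .unit3(X[b, ] - X[a, ])), need)
    for (d in dirs) {
      all_X <- rbind(all_X, X[a, ] + .H_LEN[[elements[a]]] * d)
      all_elements <- c(all_elements, "H")
      all_bonds <- rbind(all_bonds,
                         data.frame(i = a, j = nrow(all_X), order = "1",
                                    stringsAsFactors = FALSE))
    }
  }

  mol <- mol_record(sprintf("fixture_%s_h%d_s%d", spec$topology, n, spec$seed),
                    all_elements, all_X, all_bonds)
  rbs <- perceive_rotatable_bonds(mol)
  if (!is.null(spec$planted_torsions)) {
    conf <- set_torsions(mol, conformation(mol$coords),
                         spec$planted_torsions, rbs)
    mol$coords <- conf$coords
  }
  list(mol = mol, conf = conformation(mol$coords), n_rotatable = length(rbs))
}

#' Plant a target conformation
#'
#' Drives the rotatable torsions of \code{base_conf} to
#' \code{target_torsions}; the result serves as the synthetic "bioactive"
#' reference in parameter-recovery benchmarks.
#'
#' @param mol molecule record.
#' @param base_conf base conformation supplying fixed internal coordinates.
#' @param target_torsions torsion vector in degrees.
#' @return a \code{conformation}.
#' @export
plant_target <- function(mol, base_conf, target_torsions) {
  set_torsions(mol, base_conf, target_torsions)
}
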