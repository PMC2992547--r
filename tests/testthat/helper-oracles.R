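# Shared fixtures and independent oracles.  Everything here is deliberately
# implemented without touching the package's own code paths for the same
# quantity, so oracle and implementation can disagree.

# --- independent quaternion (Horn) superposition oracle ----------------------
quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# --- brute-force epsilon-Pareto box filter -----------------------------------
# Non-dominated boxes of a canonical point stream, by exhaustive comparison.
brute_eps_boxes <- function(canon, eps) {
  B <- t(apply(canon, 1, function(v) floor(v / eps)))
  if (ncol(canon) == 1) B <- t(B)
  ub <- unique(B)
  dominated <- vapply(seq_len(nrow(ub)), function(i) {
    any(vapply(seq_len(nrow(ub)), function(j) {
      if (i == j) return(FALSE)
      all(ub[j, ] <= ub[i, ]) && any(ub[j, ] < ub[i, ])
    }, logical(1)))
  }, logical(1))
  ub[!dominated, , drop = FALSE]
}

sort_box_rows <- function(B) {
  B[do.call(order, as.data.frame(B)), , drop = FALSE]
}

# --- hand-built molecules ----------------------------------------------------
ethane_mol <- function() {
  # 2 C + 6 H, staggered
  X <- rbind(c(0, 0, 0), c(1.53, 0, 0))
  d <- 1.09
  for (ph in c(0, 120, 240) * pi / 180) {
    a <- 109.47 * pi / 180
    X <- rbind(X, c(-d * cos(a), d * sin(a) * cos(ph), d * sin(a) * sin(ph)))
  }
  for (ph in (c(60, 180, 300)) * pi / 180) {
    a <- 109.47 * pi / 180
    X <- rbind(X, c(1.53 + d * cos(a), d * sin(a) * cos(ph), d * sin(a) * sin(ph)))
  }
  bonds <- data.frame(i = c(1, 1, 1, 1, 2, 2, 2),
                      j = c(2, 3, 4, 5, 6, 7, 8),
                      order = "1", stringsAsFactors = FALSE)
  mol_record("ethane", c("C", "C", rep("H", 6)), X, bonds)
}

cyclohexane_mol <- function() {
  # heavy ring only is what perception looks at; planar placement is fine
  ang <- seq(0, 300, by = 60) * pi / 180
  X <- cbind(1.53 * cos(ang), 1.53 * sin(ang), 0)
  XH1 <- cbind(2.4 * cos(ang), 2.4 * sin(ang), 0.6)
  XH2 <- cbind(2.4 * cos(ang), 2.4 * sin(ang), -0.6)
  bonds <- data.frame(i = c(1:6, 1:6, 1:6),
                      j = c(2:6, 1, 7:12, 13:18),
                      order = "1", stringsAsFactors = FALSE)
  mol_record("cyclohexane", c(rep("C", 6), rep("H", 12)),
             rbind(X, XH1, XH2), bonds)
}

benzene_mol <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  XC <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  XH <- cbind(2.48 * cos(ang), 2.48 * sin(ang), 0)
  bonds <- data.frame(i = c(1:6, 1:6), j = c(2:6, 1, 7:12),
                      order = c(rep("ar", 6), rep("1", 6)),
                      stringsAsFactors = FALSE)
  mol_record("benzene", c(rep("C", 6), rep("H", 6)), rbind(XC, XH), bonds)
}

random_rigid_motion <- function(X) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  sweep(X %*% t(R), 2, stats::rnorm(3, sd = 5), `+`)
}

# minimal stub conformer carrying a filter energy (for window/dedup tests)
stub_conf <- function(energy, coords = diag(3)) {
  cf <- conformation(coords)
  cf$filter_energy <- energy
  cf
}

# tiny hand-written mol2 text: 3 atoms, 2 bonds (water-like connectivity)
TINY_MOL2 <- c(
  "@<TRIPOS>MOLECULE",
  "tiny",
  " 3 2 0 0 0",
  "SMALL",
  "NO_CHARGES",
  "@<TRIPOS>ATOM",
  "  1 O1  0.0000 0.0000 0.0000 O.3  1 MOL 0.0000",
  "  2 H1  0.9600 0.0000 0.0000 H    1 MOL 0.0000",
  "  3 H2 -0.2400 0.9300 0.0000 H    1 MOL 0.0000",
  "@<TRIPOS>BOND",
  "  1 1 2 1",
  "  2 1 3 1")
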