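# Fixtures built in code: tiny PDB texts, simple surrogate systems, and
# independent numerical oracles.

# A minimal hand-written PDB: one glycine (7 atoms incl. hydrogens) plus an
# optional water.
toy_gly_pdb <- function(with_water = FALSE) {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.300   2.400   0.100  1.00  0.00           O",
    "ATOM      5  H   GLY A   1      -0.500  -0.800   0.200  1.00  0.00           H",
    "ATOM      6  HA2 GLY A   1       1.800  -0.500   0.900  1.00  0.00           H",
    "ATOM      7  HA3 GLY A   1       1.800  -0.600  -0.800  1.00  0.00           H")
  if (with_water) {
    lines <- c(lines,
      "HETATM    8  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O")
  }
  paste(c(lines, "END"), collapse = "\n")
}

# n-residue straight-chain model with one atom (CA) per residue at spacing
# `gap` Angstrom; simple geometry for selection tests.
chain_model <- function(n, gap = 2) {
  atom_table(seq_len(n), "CA", "C", "GLY", "A", seq_len(n),
             gap * seq_len(n), 0, 0) |> structure_model()
}

# A harmonic dimer model + surrogate backend with known spring constant.
harmonic_dimer <- function(d = 1.2, r0 = 1.2, k = 300) {
  m <- structure_model(atom_table(1:2, c("C1", "O1"), c("C", "O"), "LIG",
                                  "A", 1, c(0, d), 0, 0, hetero = TRUE))
  p <- surrogate_params(bonds = data.frame(i = 1, j = 2, r0 = r0, k = k))
  list(model = m, params = p, backend = surrogate_backend(p, m))
}

# Independent finite-difference gradient of any energy function.
numeric_gradient <- function(f, xyz, h = 1e-5) {
  g <- xyz * 0
  for (i in seq_len(nrow(xyz))) {
    for (j in 1:3) {
      xp <- xyz; xp[i, j] <- xp[i, j] + h
      xm <- xyz; xm[i, j] <- xm[i, j] - h
      g[i, j] <- (f(xp) - f(xm)) / (2 * h)
    }
  }
  g
}

# Independent barrier oracle: exhaustive enumeration of the
# highest-point-minus-lowest-point-before-it rule over all (prefix, max)
# pairs.
barrier_oracle <- function(e) {
  best <- -Inf
  imax <- which(e == max(e))[1]
  ref <- if (imax == 1) imax else which.min(e[1:(imax - 1)])
  e[imax] - e[ref]
}

# Independent superposition oracle: numerical search over rotation space
# (Euler angles), multi-start, after centering both point sets.
rmsd_rotation_oracle <- function(P, Q, n_starts = 12) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) {
    R <- rot(ang)
    sqrt(sum((Qc - Pc %*% t(R))^2) / nrow(Pc))
  }
  starts <- rbind(c(0, 0, 0),
                  matrix(runif(3 * (n_starts - 1), -pi, pi), ncol = 3))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    r <- optim(starts[s, ], obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
    r <- optim(r$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 2000))
    best <- min(best, r$value)
  }
  best
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr(M)
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# A fake engine output in the MOPAC dialect, for parser tests.
fake_engine_output <- function(hof = -1234.56789, xyz = NULL, scf = 42,
                               failed = FALSE, truncated = FALSE) {
  lines <- c(" *  MOPAC-STYLE OUTPUT", "")
  if (failed) lines <- c(lines, " SCF FAILED TO CONVERGE")
  if (!truncated) {
    lines <- c(lines,
      sprintf(" FINAL HEAT OF FORMATION = %15.5f KCAL/MOL", hof),
      sprintf(" GRADIENT NORM = %12.5f", 0.4321),
      sprintf(" NUMBER OF SCF CALCULATIONS  = %d", scf))
    if (!is.null(xyz)) {
      lines <- c(lines, "", "   CARTESIAN COORDINATES", "",
                 "  NO.  ATOM  X  Y  Z", "")
      el <- rep(c("C", "O", "N", "H"), length.out = nrow(xyz))
      lines <- c(lines, sprintf("  %4d %4s %14.8f %14.8f %14.8f",
                                seq_len(nrow(xyz)), el,
                                xyz[, 1], xyz[, 2], xyz[, 3]))
    }
  }
  paste(lines, collapse = "\n")
}
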