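# shared fixtures and independent oracles, built in code at test time

# ideal alpha-helical chain of length L
make_helix_chain <- function(L = 20, phi = -57, psi = -47) {
  chain_from_dihedrals(
    dihedral_series(c(NA, rep(phi, L - 1)), c(rep(psi, L - 1), NA)),
    strrep("A", L))
}

# deterministic random proper rotation + translation
random_rigid <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = rnorm(3, sd = 10))
}

# hand-written 3-residue PDB fixture with known CA coordinates
fixture_pdb_3res <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       2.009   1.421   0.000  1.00  0.00",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00",
    "ATOM      6  CA  GLY A   2       4.000   2.800   0.100  1.00  0.00",
    "ATOM      7  C   GLY A   2       5.500   2.700   0.200  1.00  0.00",
    "ATOM      8  O   GLY A   2       6.100   1.650   0.300  1.00  0.00",
    "ATOM      9  N   SER A   3       6.100   3.900   0.200  1.00  0.00",
    "ATOM     10  CA  SER A   3       7.550   4.000   0.300  1.00  0.00",
    "ATOM     11  C   SER A   3       8.100   5.400   0.100  1.00  0.00",
    "ATOM     12  O   SER A   3       7.400   6.400   0.000  1.00  0.00",
    "TER",
    "END")
  writeLines(lines, path)
  path
}

# same fixture with residue 2 lacking its N atom
fixture_pdb_missing_n <- function(path) {
  lines <- readLines(fixture_pdb_3res(path))
  writeLines(lines[!grepl("^ATOM      5", lines)], path)
  path
}

# brute-force oracle: best RMSD over a dense axis-angle rotation grid with
# centroid-matching translation; exact-in-angle via the closed form
# E(ang) = a*cos^2 + b*sin^2 + ... of the Rodrigues expansion
grid_search_rmsd <- function(x, y, axis_step = 10, angle_step = 1) {
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  angles <- seq(0, 359, by = angle_step) * pi / 180
  ca <- cos(angles); sa <- sin(angles)
  best <- Inf
  for (th in seq(0, 180, by = axis_step)) {
    for (ph in seq(0, 359, by = axis_step)) {
      ax <- c(sin(th * pi / 180) * cos(ph * pi / 180),
              sin(th * pi / 180) * sin(ph * pi / 180),
              cos(th * pi / 180))
      K <- cbind(ax[2] * xc[, 3] - ax[3] * xc[, 2],
                 ax[3] * xc[, 1] - ax[1] * xc[, 3],
                 ax[1] * xc[, 2] - ax[2] * xc[, 1])
      D <- (xc %*% ax) %*% t(ax)
      A <- xc - D          # rotates as cos
      B <- K               # rotates as sin
      Cm <- D - yc         # constant minus target
      sAA <- sum(A * A); sBB <- sum(B * B); sCC <- sum(Cm * Cm)
      sAB <- sum(A * B); sAC <- sum(A * Cm); sBC <- sum(B * Cm)
      E <- sAA * ca^2 + sBB * sa^2 + sCC + 2 * sAB * ca * sa +
        2 * sAC * ca + 2 * sBC * sa
      best <- min(best, min(E))
    }
  }
  sqrt(best / nrow(x))
}

# independent affine-gap Needleman-Wunsch score (global, end gaps
# penalised; a length-k gap costs go + k*ge)
nw_affine_score <- function(a, b, mat, go, ge) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) Ix[i, 1] <- -(go + (i - 1) * ge)
  if (m >= 1) for (j in 2:(m + 1)) Iy[1, j] <- -(go + (j - 1) * ge)
  for (i in seq_len(n) + 1) for (j in seq_len(m) + 1) {
    s <- mat[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - go - ge, Ix[i - 1, j] - ge)
    Iy[i, j] <- max(M[i, j - 1] - go - ge, Iy[i, j - 1] - ge)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# random amino-acid sequence
random_protein <- function(L, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L, TRUE),
        collapse = "")
}

# random valid PB frequency profile over L positions (for metric checks)
random_profile <- function(L, seed) {
  set.seed(seed)
  f <- matrix(rexp(L * 16), L)
  f <- f / rowSums(f)
  colnames(f) <- letters[1:16]
  structure(list(freq = f, counts = f * 100,
                 support = rep(100L, L), n_sequences = 100L),
            class = "pb_profile")
}

# 125-residue VHH-like region override (the curated bounds of a 125-mer
# case used throughout region tests)
override_125 <- list(FR1 = c(1, 25), CDR1 = c(26, 36), FR2 = c(37, 54),
                     CDR2 = c(55, 62), FR3 = c(63, 96), CDR3 = c(97, 110),
                     FR4 = c(111, 125))
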