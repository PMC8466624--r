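test_that("self-superposition is the identity with zero RMSD", {
  ch <- make_helix_chain(10)
  sp <- superpose_calpha(ch, ch)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(sp$n_atoms, 10L)
})

test_that("a rigidly moved copy superposes back to numerical zero", {
  ch <- make_helix_chain(15, phi = -130, psi = 140)
  for (s in 6:8) {
    rt <- random_rigid(s)
    moved <- transform_chain(ch, rt$rotation, rt$translation)
    sp <- superpose_calpha(moved, ch)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  }
})

test_that("RMSD is symmetric and invariant to pre-transforming either side", {
  set.seed(14)
  a <- make_helix_chain(12)
  b <- a
  b$CA <- b$CA + matrix(rnorm(36, sd = 0.4), 12)
  r_ab <- superpose_calpha(a, b)$rmsd
  r_ba <- superpose_calpha(b, a)$rmsd
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
  rt <- random_rigid(99)
  expect_equal(superpose_calpha(transform_chain(a, rt$rotation,
                                                rt$translation), b)$rmsd,
               r_ab, tolerance = 1e-9)
  expect_equal(superpose_calpha(a, transform_chain(b, rt$rotation,
                                                   rt$translation))$rmsd,
               r_ab, tolerance = 1e-9)
})

test_that("superposition RMSD matches a brute-force rotation-grid search", {
  # 4-point toys; the SVD optimum must never be beaten by any grid rotation
  # and the dense grid must approach it within its resolution bound
  set.seed(41)
  for (case in 1:3) {
    x <- matrix(rnorm(12, sd = 1), 4)
    y <- matrix(rnorm(12, sd = 1), 4)
    chx <- backbone_chain(rep("A", 4), x, x, x, x)
    chy <- backbone_chain(rep("A", 4), y, y, y, y)
    opt <- superpose_calpha(chx, chy)$rmsd
    grid <- grid_search_rmsd(x, y, axis_step = 10, angle_step = 1)
    expect_lte(opt, grid + 1e-9)
    # resolution bound: total rotation discretisation ~0.15 rad x max radius
    rmax <- max(sqrt(rowSums(sweep(x, 2, colMeans(x))^2)))
    expect_lte(grid - opt, 0.15 * rmax + 1e-6)
  }
})

test_that("degenerate superposition inputs are rejected", {
  ch <- make_helix_chain(10)
  expect_error(superpose_calpha(ch, ch, cbind(1:2, 1:2)), "at least 3")
  line <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), 4, byrow = TRUE)
  chl <- backbone_chain(rep("A", 4), line, line, line, line)
  expect_error(superpose_calpha(chl, chl), "collinear")
})

test_that("region RMSD equals the global fit for a whole-chain region and is zero for identical chains", {
  ch <- make_helix_chain(21)
  whole <- region_map(list(FR1 = c(1, 3), CDR1 = c(4, 6), FR2 = c(7, 9),
                           CDR2 = c(10, 12), FR3 = c(13, 15),
                           CDR3 = c(16, 18), FR4 = c(19, 21)))
  rr <- region_rmsd(ch, ch, whole, "local_fit")
  expect_equal(unname(rr), rep(0, 7), tolerance = 1e-9)
  rrf <- region_rmsd(ch, ch, whole, "frame_fit")
  expect_equal(unname(rrf), rep(0, 7), tolerance = 1e-9)

  set.seed(3)
  b <- ch
  b$CA <- b$CA + matrix(rnorm(63, sd = 0.3), 21)
  expect_equal(unname(region_rmsd(b, ch, whole, "local_fit")["FR4"]),
               superpose_calpha(b, ch, cbind(19:21, 19:21))$rmsd,
               tolerance = 1e-9)
})

test_that("a perturbation confined to CDR3 shows up only there under frame_fit", {
  native <- make_helix_chain(35)
  rm_ <- region_map(list(FR1 = c(1, 6), CDR1 = c(7, 10), FR2 = c(11, 16),
                         CDR2 = c(17, 20), FR3 = c(21, 26), CDR3 = c(27, 31),
                         FR4 = c(32, 35)))
  set.seed(8)
  model <- native
  idx <- 27:31
  model$CA[idx, ] <- model$CA[idx, ] + matrix(rnorm(15, sd = 1.5), 5)
  rr <- region_rmsd(model, native, rm_, "frame_fit")
  expect_gt(rr["CDR3"], 0.5)
  expect_true(all(rr[setdiff(names(rr), "CDR3")] < 1e-9))
})

test_that("local_fit rejects sub-3-residue regions and out-of-chain regions errors", {
  ch <- make_helix_chain(21)
  one <- region_map(list(FR1 = c(1, 1), CDR1 = c(2, 2), FR2 = c(3, 3),
                         CDR2 = c(4, 4), FR3 = c(5, 5), CDR3 = c(6, 6),
                         FR4 = c(7, 21)))
  expect_error(region_rmsd(ch, ch, one, "local_fit"), "shorter than 3")
  short <- make_helix_chain(20)
  expect_error(region_rmsd(short, ch, one), "share length")
})

test_that("loop termini distances are Euclidean and rigid-invariant", {
  ca <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 0, 1), c(3, 4, 0))
  ch <- backbone_chain(rep("A", 4), ca, ca, ca, ca)
  expect_equal(loop_termini_distance(ch, c(1, 4)), 5)
  rt <- random_rigid(55)
  moved <- transform_chain(ch, rt$rotation, rt$translation)
  expect_equal(loop_termini_distance(moved, c(1, 4)), 5, tolerance = 1e-9)
  ch$CA[4, ] <- NA_real_
  ch$complete[4] <- FALSE
  expect_error(loop_termini_distance(ch, c(1, 4)), "incomplete")
  expect_error(loop_termini_distance(ch, c(2, 9)), "outside")
})

test_that("Ramachandran fractions classify the canonical basins", {
  helix <- compute_backbone_dihedrals(make_helix_chain(12))
  fr <- ramachandran_fractions(helix)
  expect_equal(unname(fr["favored"]), 100)
  expect_equal(sum(fr), 100)

  odd <- dihedral_series(c(NA, rep(60, 9)), c(rep(-120, 9), NA))
  fo <- ramachandran_fractions(odd)
  expect_equal(unname(fo["unfavorable"]), 100)

  left <- dihedral_series(c(NA, rep(60, 5)), c(rep(40, 5), NA))
  expect_equal(unname(ramachandran_fractions(left)["allowed"]), 100)

  none <- dihedral_series(c(NA, NA), c(NA, NA))
  expect_error(ramachandran_fractions(none), "no positions")
})

test_that("mean global RMSD grows with angular noise (Spearman over kappa grid)", {
  kgrid <- c(1, 5, 50, 500, 5000)
  mean_rmsd <- vapply(seq_along(kgrid), function(i) {
    spec <- ensemble_spec(strrep("A", 30), reference_pb = strrep("d", 30),
                          kappa = kgrid[i], n_models = 50, seed = 400 + i)
    mean(generate_ensemble(spec)$scores$rmsd_ref)
  }, numeric(1))
  rho <- suppressWarnings(
    cor(1 / kgrid, mean_rmsd, method = "spearman"))
  expect_gt(rho, 0.9)
})
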