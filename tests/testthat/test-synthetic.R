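test_that("an ideal helix build has consecutive CA-CA distances near 3.8 A", {
  ch <- make_helix_chain(20)
  d <- sqrt(rowSums((ch$CA[-1, ] - ch$CA[-20, ])^2))
  expect_true(all(abs(d - 3.8) < 0.1))
})

test_that("dihedrals survive the build/measure round trip to 1e-6 degrees", {
  set.seed(2)
  for (rep_i in 1:3) {
    L <- 15
    phi <- c(NA, runif(L - 1, -179, 179))
    psi <- c(runif(L - 1, -179, 179), NA)
    ch <- chain_from_dihedrals(dihedral_series(phi, psi), strrep("G", L))
    d <- compute_backbone_dihedrals(ch)
    expect_equal(d$phi[-1], phi[-1], tolerance = 1e-6)
    expect_equal(d$psi[-L], psi[-L], tolerance = 1e-6)
  }
})

test_that("single-residue chains build without dihedrals and interior gaps are rejected", {
  ch <- chain_from_dihedrals(dihedral_series(NA_real_, NA_real_), "A")
  expect_length(ch, 1L)
  expect_true(ch$complete)
  bad_phi <- c(NA, -57, NA, -57)
  expect_error(chain_from_dihedrals(
    dihedral_series(bad_phi, c(-47, -47, -47, NA)), "AAAA"),
    "undefined interior dihedral")
})

test_that("PB strings map to their prototypes' central angles", {
  tab <- pb_reference_table()
  d <- pb_string_to_dihedrals(strrep("m", 8))
  expect_equal(d$phi[-1], rep(unname(tab["m", "phi"]), 7))
  expect_equal(d$psi[-8], rep(unname(tab["m", "psi"]), 7))
  mix <- pb_string_to_dihedrals("dmdm")
  expect_equal(mix$phi[2:4],
               unname(tab[c("m", "d", "m"), "phi"]))
  expect_error(pb_string_to_dihedrals("dmZ"), "no Z")
})

test_that("homogeneous runs of the repetitive prototypes close the loop exactly", {
  # only the periodic helix/strand prototypes are fixed points of
  # central-angle flattening; transitional letters describe non-repeatable
  # motifs and legitimately re-assign
  for (l in c("m", "d")) {
    s <- strrep(l, 11)
    ch <- chain_from_dihedrals(pb_string_to_dihedrals(s), strrep("A", 11))
    back <- assign_pb_sequence(compute_backbone_dihedrals(ch))
    expect_identical(back[3:9], rep(l, 7))
    expect_identical(back[c(1, 2, 10, 11)], rep("Z", 4))
  }
})

test_that("ensemble generation is bit-identical under a fixed seed", {
  spec <- ensemble_spec(strrep("A", 20), reference_pb = strrep("m", 20),
                        kappa = 10, n_models = 5, seed = 77)
  e1 <- generate_ensemble(spec)
  e2 <- generate_ensemble(spec)
  expect_identical(e1$scores, e2$scores)
  expect_identical(e1$models[[5]]$CA, e2$models[[5]]$CA)
})

test_that("the zero-noise limit collapses the ensemble onto the reference", {
  spec <- ensemble_spec(strrep("A", 20), reference_pb = strrep("m", 20),
                        kappa = 1e6, n_models = 20, seed = 3,
                        score_noise = 1e-6)
  ens <- generate_ensemble(spec)
  pbs <- ensemble_pb_strings(ens)
  expect_equal(length(unique(pbs)), 1L)
  prof <- pb_frequency_profile(pbs)
  neq <- neq_profile(prof)
  expect_equal(unname(neq[!is.na(neq)]),
               rep(1, sum(!is.na(neq))), tolerance = 1e-12)
  expect_lt(max(ens$scores$rmsd_ref), 0.05)
})

test_that("a low-kappa window concentrates conformational diversity", {
  kappa <- rep(500, 40); kappa[15:24] <- 2
  spec <- ensemble_spec(strrep("A", 40), reference_pb = strrep("d", 40),
                        kappa = kappa, n_models = 100, seed = 19)
  ens <- generate_ensemble(spec)
  neq <- neq_profile(pb_frequency_profile(ensemble_pb_strings(ens)))
  inside <- 15:24
  outside <- setdiff(which(!is.na(neq)), inside)
  expect_gt(mean(neq[inside]), mean(neq[outside]))
})

test_that("mean Neq decreases as kappa grows", {
  kgrid <- c(1, 5, 50, 500)
  mean_neq <- vapply(seq_along(kgrid), function(i) {
    spec <- ensemble_spec(strrep("A", 25), reference_pb = strrep("d", 25),
                          kappa = kgrid[i], n_models = 50, seed = 500 + i)
    neq <- neq_profile(pb_frequency_profile(
      ensemble_pb_strings(generate_ensemble(spec))))
    mean(neq, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_neq) <= 0))
})

test_that("anchored ensembles keep the framework and vary only the window", {
  kappa <- rep(500, 60); kappa[45:54] <- 2
  spec <- ensemble_spec(strrep("A", 60), reference_pb = strrep("d", 60),
                        kappa = kappa, n_models = 30, seed = 11)
  ens <- generate_ensemble(spec, anchor = c(45, 54))
  rm_ <- region_map(list(FR1 = c(1, 10), CDR1 = c(11, 14), FR2 = c(15, 24),
                         CDR2 = c(25, 28), FR3 = c(29, 44), CDR3 = c(45, 54),
                         FR4 = c(55, 60)))
  rr <- region_rmsd(ens$models[[1]], ens$reference, rm_, "frame_fit")
  expect_gt(rr["CDR3"], max(rr[setdiff(names(rr), "CDR3")]))
  expect_error(generate_ensemble(spec, anchor = c(2, 10)),
               ">= 3 residues")
})

test_that("family generation validates its target and reports errors", {
  expect_error(generate_vhh_like_family(1, 64), ">= 2")
  expect_error(generate_vhh_like_family(3, 0), "target_identity")
  expect_error(generate_vhh_like_family(3, 2), "unreachable")
})

test_that("FASTA output round-trips", {
  fam <- generate_vhh_like_family(4, 64, seed = 2)
  f <- tempfile(fileext = ".fasta")
  write_fasta(fam, f)
  expect_identical(read_fasta(f), fam)
})
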