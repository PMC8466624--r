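test_that("global alignment identity behaves on identical and near-identical pairs", {
  a <- global_align("MKVLA", "MKVLA")
  expect_equal(a$identity_percent, 100)
  expect_false(grepl("-", a$aligned_a))
  b <- global_align("AAAA", "AATA")
  expect_equal(b$identity_percent, 75)
  expect_equal(gsub("-", "", b$aligned_a), "AAAA")
  expect_equal(gsub("-", "", b$aligned_b), "AATA")
  expect_error(global_align("", "AA"), "empty")
  expect_error(global_align("AB1", "AA"), "non amino-acid")
  expect_error(global_align("AAA", "AAA", sub_matrix = "NOSUCH"), "unknown")
})

test_that("alignment scores equal an independent DP oracle on random 10-mers", {
  mat <- as.matrix(local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  }))
  for (s in 1:10) {
    a <- random_protein(10, 1000 + s)
    b <- random_protein(10, 2000 + s)
    aln <- global_align(a, b)
    expect_equal(aln$score, nw_affine_score(a, b, mat, 10, 0.5))
  }
  # and with length mismatch, where gaps are forced
  for (s in 1:5) {
    a <- random_protein(12, 3000 + s)
    b <- random_protein(8, 4000 + s)
    aln <- global_align(a, b)
    expect_equal(aln$score, nw_affine_score(a, b, mat, 10, 0.5))
  }
})

test_that("aligned column pairs index only mutually aligned residues", {
  aln <- global_align("MKVLAGH", "MKLAGH")
  expect_true(all(aln$pairs[, 1] >= 1 & aln$pairs[, 1] <= 7))
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  expect_equal(nrow(aln$pairs), sum(ca != "-" & cb != "-"))
})

test_that("identity matrices are symmetric with unit diagonal", {
  seqs <- c(s1 = "MKVLAGHW", s2 = "MKVLAGHW", s3 = "MKVAAGHF")
  m <- build_identity_matrix(seqs)
  expect_equal(unname(diag(m)), rep(100, 3))
  expect_equal(m, t(m))
  expect_equal(m["s1", "s2"], 100)
  expect_equal(m["s1", "s3"],
               global_align(seqs[["s1"]], seqs[["s3"]])$identity_percent)
  expect_error(build_identity_matrix(c(a = "MK", a = "MK")), "unique")
  expect_error(build_identity_matrix(c(a = "MKVL")), "at least 2")
})

test_that("a synthetic family hits its target mean identity", {
  fam <- generate_vhh_like_family(20, 64, seed = 101)
  m <- build_identity_matrix(fam)
  expect_gte(mean(m[upper.tri(m)]), 61)
  expect_lte(mean(m[upper.tri(m)]), 67)
  same <- generate_vhh_like_family(3, 100, seed = 5)
  expect_equal(unname(same[1]), unname(same[2]))
  expect_identical(generate_vhh_like_family(4, 64, seed = 7),
                   generate_vhh_like_family(4, 64, seed = 7))
})

test_that("scenario selections match hand-computed argmax/argmin/top-3", {
  ids <- c("A", "B", "C", "D")
  im <- matrix(100, 4, 4, dimnames = list(ids, ids))
  im["A", c("B", "C", "D")] <- im[c("B", "C", "D"), "A"] <- c(80, 70, 60)
  rm_ <- matrix(0, 4, 4, dimnames = list(ids, ids))
  rm_["A", c("B", "C", "D")] <- rm_[c("B", "C", "D"), "A"] <- c(2.0, 0.9, 1.5)

  s1 <- select_templates("A", im, scenario = "bestSeqIdTemp")
  expect_equal(s1$template_ids, "B")
  expect_equal(s1$identity, 80)

  s2 <- select_templates("A", im, rm_, scenario = "bestStructTemp")
  expect_equal(s2$template_ids, "C")
  expect_equal(s2$template_rmsd, 0.9)

  s3 <- select_templates("A", im, scenario = "3bestSeqIdTemp")
  expect_equal(s3$template_ids, c("B", "C", "D"))
  expect_equal(s3$identity, 70)  # MSI = mean(80, 70, 60)

  s4 <- select_templates("A", im, scenario = "All")
  expect_equal(s4$template_ids, c("B", "C", "D"))
  expect_false("A" %in% s4$template_ids)
  # best identity template dominates every other candidate
  expect_true(all(s1$identity >= im["A", s4$template_ids]))

  expect_error(select_templates("A", im, scenario = "bestStructTemp"),
               "rmsd_matrix")
  expect_error(select_templates("Z", im, scenario = "bestSeqIdTemp"),
               "not in identity matrix")
  expect_error(select_templates("A", im[1:3, 1:3],
                                scenario = "3bestSeqIdTemp"), ">= 3")
})

test_that("best-model selection takes the score minimum with lexicographic ties", {
  expect_equal(select_best_model(c(m1 = -13000, m2 = -12000)), "m1")
  expect_equal(select_best_model(c(only = 5)), "only")
  expect_equal(select_best_model(c(b = 1, a = 1)), "a")
  expect_error(select_best_model(numeric(0)), "no scored")
  expect_error(select_best_model(c(m1 = NaN)), "non-finite")
})

test_that("score-guided selection lands in the low-RMSD quartile of an ensemble", {
  hits <- vapply(1:20, function(s) {
    spec <- ensemble_spec(strrep("A", 25), reference_pb = strrep("d", 25),
                          kappa = 5, n_models = 40, seed = 7000 + s,
                          score_noise = 0.05)
    ens <- generate_ensemble(spec)
    best <- select_best_model(setNames(ens$scores$score,
                                       ens$scores$model_id))
    r <- ens$scores$rmsd_ref[ens$scores$model_id == best]
    r <= quantile(ens$scores$rmsd_ref, 0.25)
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("greedy redundancy filtering keeps the first of each near-identical group", {
  ids <- c("A", "B", "C")
  m <- matrix(c(100, 97, 50, 97, 100, 50, 50, 50, 100), 3,
              dimnames = list(ids, ids))
  expect_equal(redundancy_filter(m, 95), c("A", "C"))
  expect_equal(redundancy_filter(m, 99), ids)
})

test_that("PIR files round-trip for single- and multi-template alignments", {
  q <- "MKVLAGHWQE"
  t1 <- "MKVLGHWQE"   # deletion relative to query
  t2 <- "MKVLAAGHWQE" # insertion relative to query
  a1 <- global_align(q, t1)
  a2 <- global_align(q, t2)
  f <- tempfile(fileext = ".pir")
  write_pir_alignment("query1", list(temp1 = a1), f)
  back <- read_pir_alignment(f)
  expect_identical(names(back), c("temp1", "query1"))
  expect_equal(gsub("-", "", back[["query1"]]), q)
  expect_equal(gsub("-", "", back[["temp1"]]), t1)

  f3 <- tempfile(fileext = ".pir")
  write_pir_alignment("query1", list(temp1 = a1, temp2 = a2,
                                     temp3 = global_align(q, q)), f3)
  back3 <- read_pir_alignment(f3)
  expect_length(back3, 4L)
  expect_equal(names(back3)[4], "query1")
  # all rows equal length; no gap-only column
  w <- nchar(back3)
  expect_equal(unname(w), rep(w[[1]], 4))
  cols <- do.call(rbind, strsplit(unname(back3), ""))
  expect_false(any(colSums(cols == "-") == 4))

  aX <- global_align("MKVLAGHWQA", t1)
  expect_error(write_pir_alignment("query1", list(t1 = a1, tX = aX),
                                   tempfile()),
               "inconsistent query")
})
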