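#' Per-position PB frequency profile of an ensemble
#'
#' Counts PB letters column-wise over an ensemble of equal-length PB
#' sequences and normalises to frequencies. The undefined placeholder `Z` is
#' excluded from counts (the PB statistics sum over the 16 letters only);
#' positions where every sequence is `Z` carry zero support and are reported
#' as "no data" (`NA` frequencies).
#'
#' @param ensemble character vector of PB strings, or list of letter vectors,
#'   all of one length.
#' @return Object of class `pb_profile`: list with `freq` (L x 16 matrix,
#'   rows summing to 1 where supported, `NA` rows otherwise), `counts`,
#'   `support` (non-Z observations per position) and `n_sequences`.
#' @export
pb_frequency_profile <- function(ensemble) {
  if (length(ensemble) < 1L) stop("ensemble must contain at least 1 sequence")
  seqs <- lapply(ensemble, .pb_letters)
  L <- length(seqs[[1]])
  if (any(vapply(seqs, length, integer(1)) != L))
    stop("all PB sequences in an ensemble must have equal length")
  M <- do.call(rbind, seqs)
  counts <- vapply(letters[1:16], function(l) colSums(M == l),
                   numeric(L))
  counts <- matrix(counts, nrow = L,
                   dimnames = list(NULL, letters[1:16]))
  support <- rowSums(counts)
  freq <- counts / ifelse(support > 0, support, NA_real_)
  structure(list(freq = freq, counts = counts, support = as.integer(support),
                 n_sequences = length(seqs)),
            class = "pb_profile")
}

#' @export
print.pb_profile <- function(x, ...) {
  cat(sprintf("<pb_profile> %d positions, %d sequences, %d supported\n",
              nrow(x$freq), x$n_sequences, sum(x$support > 0)))
  invisible(x)
}

.check_profile_pair <- function(a, b) {
  stopifnot(inherits(a, "pb_profile"), inherits(b, "pb_profile"))
  if (nrow(a$freq) != nrow(b$freq))
    stop("profiles must cover the same number of positions")
}

#' Neq: the per-position equivalent number of PBs
#'
#' Exponential of the Shannon entropy of the per-position PB distribution,
#' `Neq = exp(-sum_x f_x ln f_x)` with `0 ln 0 = 0`. Neq is 1 when a single
#' PB letter is observed and 16 for a uniform distribution over the full
#' alphabet. Undefined (`NA`) at positions with no supported observation.
#'
#' @param profile a [pb_frequency_profile()].
#' @return Numeric vector of per-position Neq values in \[1, 16\].
#' @export
neq_profile <- function(profile) {
  stopifnot(inherits(profile, "pb_profile"))
  apply(profile$freq, 1, function(f) {
    if (anyNA(f)) return(NA_real_)
    f <- f[f > 0]
    exp(-sum(f * log(f)))
  })
}

#' Per-position difference of Neq between two ensembles
#'
#' Signed difference `Neq_A - Neq_B`; take the absolute value for
#' magnitude-only reporting. `NA` where either profile has no data.
#'
#' @param profile_a,profile_b [pb_frequency_profile()] objects over the same
#'   positions.
#' @return Numeric vector of per-position differences.
#' @export
delta_neq <- function(profile_a, profile_b) {
  .check_profile_pair(profile_a, profile_b)
  neq_profile(profile_a) - neq_profile(profile_b)
}

#' Per-position PB profile distance (delta-PB)
#'
#' L1 distance between two per-position PB frequency distributions,
#' `sum_x |f1_x - f2_x|`, ranging from 0 (identical distributions) to 2
#' (disjoint support). Equals twice the total-variation distance.
#'
#' @param profile_a,profile_b [pb_frequency_profile()] objects over the same
#'   positions.
#' @return Numeric vector of per-position values in \[0, 2\].
#' @export
delta_pb <- function(profile_a, profile_b) {
  .check_profile_pair(profile_a, profile_b)
  rowSums(abs(profile_a$freq - profile_b$freq))
}

#' Position-by-letter PB map
#'
#' The per-position frequency (or count) matrix of an ensemble, the tabular
#' form of the classical PB map.
#'
#' @param profile a [pb_frequency_profile()].
#' @param counts if `TRUE`, return raw counts instead of frequencies.
#' @return L x 16 matrix with columns `a`..`p` and a `position` attribute-free
#'   row order of 1..L.
#' @export
pb_map <- function(profile, counts = FALSE) {
  stopifnot(inherits(profile, "pb_profile"))
  if (counts) profile$counts else profile$freq
}

#' Write / read a PB map as TSV
#'
#' @param map matrix from [pb_map()].
#' @param path file path.
#' @return `write_pb_map` invisibly returns `path`; `read_pb_map` returns the
#'   matrix.
#' @export
write_pb_map <- function(map, path) {
  df <- data.frame(position = seq_len(nrow(map)), map, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pb_map
#' @export
read_pb_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, letters[1:16], drop = FALSE])
  rownames(m) <- NULL
  m
}
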