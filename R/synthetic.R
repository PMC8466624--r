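# ideal backbone geometry (Angstrom, degrees); omega torsions fixed trans
.GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
              a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
              a_ca_c_o = 120.8, omega = 180)

# NeRF placement: position D given A-B-C, bond length |C-D|, bond angle
# B-C-D and torsion A-B-C-D (degrees)
.place_atom <- function(A, B, C, len, angle, torsion) {
  th <- angle * pi / 180; chi <- torsion * pi / 180
  bc <- C - B; bcn <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - A, bcn)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bcn)
  C + bcn * (-len * cos(th)) + m * (len * sin(th) * cos(chi)) +
    n * (len * sin(th) * sin(chi))
}

#' Build a Cartesian backbone from dihedral angles
#'
#' Reconstructs N, CA, C, O coordinates from per-residue (phi, psi) using
#' ideal bond lengths and angles, with every peptide omega torsion fixed
#' trans (180 degrees). [compute_backbone_dihedrals()] applied to the result
#' recovers the input angles to machine precision. The carbonyl oxygen is
#' placed anti to the next residue's nitrogen (torsion N-CA-C-O =
#' psi + 180; the C-terminal residue, whose psi is undefined, uses 180).
#'
#' @param dihedrals a [dihedral_series()]; all interior angles (phi from
#'   residue 2 on, psi up to residue L-1) must be defined.
#' @param sequence amino-acid string of the same length.
#' @param chain_id chain identifier for the result.
#' @return A [backbone_chain()].
#' @export
chain_from_dihedrals <- function(dihedrals, sequence, chain_id = "A") {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  if (nrow(dihedrals) != L)
    stop("dihedral series and sequence lengths differ")
  phi <- dihedrals$phi; psi <- dihedrals$psi
  if (L >= 2L && (anyNA(phi[2:L]) || anyNA(psi[1:(L - 1)])))
    stop("undefined interior dihedral")
  g <- .GEOM
  N <- CA <- C <- O <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  al <- pi - g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(al), sin(al), 0)
  if (L >= 2L) {
    for (i in 1:(L - 1)) {
      N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n,
                                g$a_ca_c_n, psi[i])
      CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca,
                                 g$a_c_n_ca, g$omega)
      C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                                g$a_n_ca_c, phi[i + 1])
    }
  }
  for (i in seq_len(L)) {
    tor <- if (i < L) .wrap_angle(psi[i] + 180) else 180
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, tor)
  }
  backbone_chain(aa = aa, N = N, CA = CA, C = C, O = O, chain_id = chain_id)
}

#' Dihedral series implied by a PB string
#'
#' Maps each PB letter to the central-residue (phi, psi) of its prototype.
#' Only the repetitive prototypes (`m`, helix; `d`, strand) are fixed points
#' of this flattening -- a homogeneous run of a transitional letter rebuilt
#' from its central angles legitimately re-assigns to a different letter,
#' because transitional prototypes describe non-repeatable local motifs.
#'
#' @param pb PB letters (string or vector) from `a`..`p`; the undefined
#'   placeholder `Z` is rejected.
#' @param table PB prototype table (default [pb_reference_table()]).
#' @return A [dihedral_series()] (phi of residue 1 and psi of residue L are
#'   undefined, as always).
#' @export
pb_string_to_dihedrals <- function(pb, table = pb_reference_table()) {
  lets <- .pb_letters(pb)
  if (any(!lets %in% letters[1:16]))
    stop("PB string may only contain letters a..p (no Z)")
  phi <- unname(table[lets, "phi"])
  psi <- unname(table[lets, "psi"])
  L <- length(lets)
  phi[1] <- NA_real_
  psi[L] <- NA_real_
  dihedral_series(phi, psi)
}

# Best & Fisher (1979) rejection sampler, mean 0, radians
.rvonmises <- function(n, kappa) {
  if (!is.finite(kappa) || kappa <= 0) stop("invalid kappa (must be > 0)")
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  out
}

#' Specification of a synthetic model ensemble
#'
#' Describes an ensemble of backbone models sharing one query sequence,
#' built from a reference conformation with position-dependent angular
#' noise: each model's (phi, psi) are the reference angles plus independent
#' von Mises deviates (mean 0, per-position concentration kappa), rebuilt to
#' Cartesian coordinates with ideal geometry. Low kappa inside CDR-like
#' windows and high kappa elsewhere reproduces the loop-concentrated
#' conformational diversity that comparative-model ensembles display. Each
#' model also receives a synthetic quality score
#' `score_scale * RMSD(model, reference) + N(0, score_noise)`, emulating a
#' lower-is-better statistical potential that correlates with model quality.
#'
#' @param sequence amino-acid string of the modeled chain.
#' @param reference_pb PB string defining the reference conformation
#'   (converted via [pb_string_to_dihedrals()]); alternatively supply
#'   `reference_dihedrals`.
#' @param reference_dihedrals a [dihedral_series()]; overrides
#'   `reference_pb`.
#' @param kappa von Mises concentration (dimensionless), scalar or
#'   per-position vector of the sequence length; all entries > 0.
#' @param n_models number of models (>= 1).
#' @param seed integer seed; a fixed seed makes the ensemble bit-identical.
#' @param score_noise standard deviation of the score noise (score units).
#' @param score_scale slope linking RMSD (Angstrom) to the score.
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(sequence, reference_pb = NULL,
                          reference_dihedrals = NULL, kappa = 100,
                          n_models = 100L, seed = 1L, score_noise = 0.05,
                          score_scale = 1) {
  L <- nchar(sequence)
  if (is.null(reference_dihedrals)) {
    if (is.null(reference_pb))
      stop("supply reference_pb or reference_dihedrals")
    if (length(.pb_letters(reference_pb)) != L)
      stop("reference_pb length must match the sequence")
    reference_dihedrals <- pb_string_to_dihedrals(reference_pb)
  }
  if (nrow(reference_dihedrals) != L)
    stop("reference dihedrals length must match the sequence")
  kappa <- rep_len(as.numeric(kappa), L)
  if (any(!is.finite(kappa)) || any(kappa <= 0))
    stop("invalid kappa (must be > 0 everywhere)")
  if (n_models < 1L) stop("n_models must be >= 1")
  structure(list(sequence = sequence, reference = reference_dihedrals,
                 kappa = kappa, n_models = as.integer(n_models),
                 seed = as.integer(seed), score_noise = score_noise,
                 score_scale = score_scale),
            class = "ensemble_spec")
}

#' Generate a synthetic model ensemble
#'
#' Draws `n_models` perturbed copies of the reference conformation described
#' by an [ensemble_spec()] and rebuilds each to Cartesian coordinates. The
#' random draw order is fixed and documented (per model: phi deviates for
#' residues 2..L, then psi deviates for residues 1..L-1, then the score
#' noise), so a given seed reproduces the ensemble bit-identically.
#'
#' Two constructions are offered. The default (free) construction rebuilds
#' the whole chain from the noised dihedrals, so angular noise inside a
#' window also rigidly displaces everything downstream of it -- a lever-arm
#' effect that real comparative-model ensembles do not show, because
#' modeling engines keep the framework anchored while loops vary. Passing an
#' `anchor` window switches to the anchored-loop construction: the rebuilt
#' chain is cut at the window bounds, the upstream piece (which carries the
#' window) is rigidly fitted to the reference over the upstream positions
#' and the downstream piece over the downstream positions, and the pieces
#' are spliced. Conformational diversity is then confined to the window (up
#' to the small off-window noise), at the cost of a geometric discontinuity
#' at the downstream splice point.
#'
#' @param spec an [ensemble_spec()].
#' @param anchor optional inclusive `c(start, end)` window for the
#'   anchored-loop construction; requires at least 3 residues on each side.
#' @return Object of class `model_ensemble`: list with `models` (list of
#'   [backbone_chain()]), `scores` (data frame `model_id`, `score`,
#'   `rmsd_ref`), `reference` (the reference [backbone_chain()]) and `spec`.
#' @export
generate_ensemble <- function(spec, anchor = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  L <- nchar(spec$sequence)
  if (!is.null(anchor)) {
    anchor <- as.integer(anchor[1:2])
    if (anchor[1] < 4L || anchor[2] > L - 3L || anchor[1] > anchor[2])
      stop("anchor window must leave >= 3 residues on each side")
  }
  ref_chain <- chain_from_dihedrals(spec$reference, spec$sequence)
  models <- vector("list", spec$n_models)
  scores <- numeric(spec$n_models)
  rmsds <- numeric(spec$n_models)
  ids <- sprintf("model_%03d", seq_len(spec$n_models))
  phi0 <- spec$reference$phi; psi0 <- spec$reference$psi
  for (mdl in seq_len(spec$n_models)) {
    phi <- phi0; psi <- psi0
    for (i in seq_len(L)) {
      if (i >= 2L)
        phi[i] <- .wrap_angle(phi0[i] +
                                .rvonmises(1, spec$kappa[i]) * 180 / pi)
    }
    for (i in seq_len(L)) {
      if (i <= L - 1L)
        psi[i] <- .wrap_angle(psi0[i] +
                                .rvonmises(1, spec$kappa[i]) * 180 / pi)
    }
    ch <- chain_from_dihedrals(dihedral_series(phi, psi), spec$sequence)
    if (!is.null(anchor)) ch <- .splice_anchored(ch, ref_chain, anchor)
    rmsds[mdl] <- superpose_calpha(ch, ref_chain)$rmsd
    scores[mdl] <- spec$score_scale * rmsds[mdl] +
      stats::rnorm(1, 0, spec$score_noise)
    models[[mdl]] <- ch
  }
  structure(list(models = stats::setNames(models, ids),
                 scores = data.frame(model_id = ids, score = scores,
                                     rmsd_ref = rmsds,
                                     stringsAsFactors = FALSE),
                 reference = ref_chain, spec = spec),
            class = "model_ensemble")
}

# anchored-loop splice: fit the model's upstream piece (carrying the
# window) and downstream piece separately onto the reference and join them
.splice_anchored <- function(model, reference, anchor) {
  L <- length(model)
  up <- 1:(anchor[1] - 1L)
  down <- (anchor[2] + 1L):L
  sp_up <- superpose_calpha(model, reference, cbind(up, up))
  sp_down <- superpose_calpha(model, reference, cbind(down, down))
  fitted_up <- apply_superposition(model, sp_up)
  fitted_down <- apply_superposition(model, sp_down)
  keep_up <- 1:anchor[2]
  for (e in c("N", "CA", "C", "O")) {
    model[[e]][keep_up, ] <- fitted_up[[e]][keep_up, , drop = FALSE]
    model[[e]][down, ] <- fitted_down[[e]][down, , drop = FALSE]
  }
  model
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d models of %d residues (seed %d)\n",
              length(x$models), nchar(x$spec$sequence), x$spec$seed))
  invisible(x)
}

#' PB strings of every model in an ensemble
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param table PB prototype table.
#' @return Character vector of PB strings, one per model.
#' @export
ensemble_pb_strings <- function(ensemble, table = pb_reference_table()) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  vapply(ensemble$models, function(ch)
    pb_string(assign_pb_sequence(compute_backbone_dihedrals(ch), table)),
    character(1))
}

# VHH-like ancestor used by the family generator: 125 residues with the
# conserved framework cysteines (positions 22 and 100) and the FR4 WGQG
# motif (position 115) that the annotation heuristic anchors on
.VHH_ANCESTOR <- paste0(
  "QVQLVESGGGLVQAGGSLRLSCAAS",  # FR1   1-25
  "GFDFDNFDDYA",                # CDR1 26-36
  "IGWFRQAPGKEREGVAAI",         # FR2  37-54
  "DPSDGSTS",                   # CDR2 55-62
  "YYADSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYC",  # FR3 63-100
  "SAWTLFHSDEYDYD",             # CDR3 103-114 (heuristic bounds)
  "WGQGTQVTVSS")                # FR4 115-125

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a family of VHH-like sequences at a target identity
#'
#' Mutates a common ancestor independently per sequence, at a per-position
#' substitution rate solved analytically so that the expected pairwise
#' identity between two family members matches the target: two sequences
#' mutated at rate `p` agree at a position with probability
#' `(1-p)^2 + p^2/19` (substitutions are uniform over the 19 other residues).
#'
#' @param n_sequences number of sequences (>= 2).
#' @param target_identity expected pairwise percent identity, in (0, 100].
#' @param seed integer seed.
#' @param ancestor ancestor sequence (default: the package's 125-residue
#'   VHH-like ancestor).
#' @return Named character vector of sequences (`vhh_001`, ...).
#' @export
generate_vhh_like_family <- function(n_sequences, target_identity = 64,
                                     seed = 1L, ancestor = .VHH_ANCESTOR) {
  if (n_sequences < 2L) stop("n_sequences must be >= 2")
  if (target_identity <= 0 || target_identity > 100)
    stop("target_identity must be in (0, 100]")
  t <- target_identity / 100
  f <- function(p) (1 - p)^2 + p^2 / 19 - t
  if (t == 1) {
    p <- 0
  } else {
    if (f(0.97) > 0) stop("unreachable target identity")
    p <- stats::uniroot(f, c(0, 0.97), tol = 1e-10)$root
  }
  set.seed(seed)
  anc <- strsplit(ancestor, "")[[1]]
  out <- vapply(seq_len(n_sequences), function(k) {
    s <- anc
    hit <- stats::runif(length(s)) < p
    for (i in which(hit)) s[i] <- sample(setdiff(.AA20, s[i]), 1)
    paste(s, collapse = "")
  }, character(1))
  stats::setNames(out, sprintf("vhh_%03d", seq_len(n_sequences)))
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector of protein sequences.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
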