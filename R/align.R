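.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

.load_sub_matrix <- function(name) {
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% known) stop("unknown substitution matrix: ", name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed by
#' [Biostrings::pairwiseAlignment()] (a length-k gap costs
#' `gap_open + k * gap_extend`). Percent identity is defined as the number
#' of identical columns divided by the number of alignment columns after
#' excluding terminal-gap columns (columns outside the region where both
#' sequences have started and not yet ended); this definition is stable
#' under length mismatch and is recomputable from the aligned strings.
#'
#' @param seq_a,seq_b non-empty protein sequences over the 20-letter
#'   alphabet plus `X`.
#' @param sub_matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @return Object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped strings), `score`, `identity_percent` and `pairs`
#'   (2-column matrix of aligned residue indices, both non-gap).
#' @export
global_align <- function(seq_a, seq_b, sub_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("empty sequence")
    bad <- setdiff(strsplit(s, "")[[1]], .AA_ALPHABET)
    if (length(bad))
      stop("sequence contains non amino-acid letters: ",
           paste(unique(bad), collapse = ""))
  }
  mat <- .load_sub_matrix(sub_matrix)
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  a <- as.character(Biostrings::alignedPattern(aln))
  b <- as.character(Biostrings::alignedSubject(aln))
  out <- list(aligned_a = unname(a), aligned_b = unname(b),
              score = Biostrings::score(aln),
              sub_matrix = sub_matrix, gap_open = gap_open,
              gap_extend = gap_extend)
  ca <- strsplit(out$aligned_a, "")[[1]]
  cb <- strsplit(out$aligned_b, "")[[1]]
  if (paste(ca[ca != "-"], collapse = "") != seq_a ||
      paste(cb[cb != "-"], collapse = "") != seq_b)
    stop("internal error: de-gapped alignment does not match input")
  out$identity_percent <- .alignment_identity(ca, cb)
  both <- ca != "-" & cb != "-"
  out$pairs <- cbind(query = cumsum(ca != "-")[both],
                     template = cumsum(cb != "-")[both])
  structure(out, class = "pairwise_alignment")
}

# identity over columns, terminal-gap columns excluded
.alignment_identity <- function(ca, cb) {
  started <- function(x) {
    ng <- which(x != "-")
    c(min(ng), max(ng))
  }
  ra <- started(ca); rb <- started(cb)
  lo <- max(ra[1], rb[1]); hi <- min(ra[2], rb[2])
  if (hi < lo) return(0)
  idx <- lo:hi
  100 * sum(ca[idx] == cb[idx] & ca[idx] != "-") / length(idx)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, identity %.1f%%\n",
              x$score, x$identity_percent))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Pairwise sequence-identity matrix
#'
#' All-against-all [global_align()] identity, in percent. The diagonal is
#' 100 and the matrix is symmetric.
#'
#' @param sequences named character vector (or named list) of protein
#'   sequences; names must be unique.
#' @param ... passed to [global_align()].
#' @return Symmetric numeric matrix of `identity_percent` values.
#' @export
build_identity_matrix <- function(sequences, ...) {
  sequences <- unlist(sequences)
  ids <- names(sequences)
  if (length(sequences) < 2L) stop("at least 2 sequences required")
  if (is.null(ids) || anyDuplicated(ids)) stop("sequence ids must be unique")
  n <- length(sequences)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idp <- global_align(sequences[[i]], sequences[[j]], ...)$identity_percent
    m[i, j] <- m[j, i] <- idp
  }
  m
}

#' Template selection under the four classical scenarios
#'
#' Given a query and the candidate pool described by an identity matrix (and
#' an RMSD matrix for the structure-based scenario), selects templates:
#' \describe{
#'   \item{bestSeqIdTemp}{the single template of highest sequence identity
#'     to the query (classical homology-modeling choice);}
#'   \item{bestStructTemp}{the single template of lowest C-alpha RMSD to the
#'     query's solved structure (a theoretical best, requires the native);}
#'   \item{3bestSeqIdTemp}{the three templates of highest identity jointly,
#'     reported with their mean sequence identity (MSI);}
#'   \item{All}{every candidate, ranked by identity.}
#' }
#' Ties are broken by lexicographic template id.
#'
#' @param query_id id of the query row/column.
#' @param identity_matrix symmetric percent-identity matrix with dimnames.
#' @param rmsd_matrix symmetric RMSD matrix (Angstrom); required for
#'   `bestStructTemp`.
#' @param scenario one of `"bestSeqIdTemp"`, `"bestStructTemp"`,
#'   `"3bestSeqIdTemp"`, `"All"`.
#' @return Object of class `scenario_result`: list with `query_id`,
#'   `scenario`, `template_ids` (ordered), `identity` (SI, or MSI for the
#'   multi-template scenario) and placeholders `best_model_id`,
#'   `best_model_rmsd` to be filled by model assessment.
#' @export
select_templates <- function(query_id, identity_matrix, rmsd_matrix = NULL,
                             scenario = c("bestSeqIdTemp", "bestStructTemp",
                                          "3bestSeqIdTemp", "All")) {
  scenario <- match.arg(scenario)
  ids <- rownames(identity_matrix)
  if (!query_id %in% ids) stop("query ", query_id, " not in identity matrix")
  cand <- setdiff(ids, query_id)
  if (!length(cand)) stop("no candidate templates")
  si <- identity_matrix[query_id, cand]
  ord <- cand[order(-si, cand)]
  res <- list(query_id = query_id, scenario = scenario,
              best_model_id = NA_character_, best_model_rmsd = NA_real_)
  if (scenario == "bestSeqIdTemp") {
    res$template_ids <- ord[1]
    res$identity <- unname(si[ord[1]])
  } else if (scenario == "bestStructTemp") {
    if (is.null(rmsd_matrix)) stop("bestStructTemp requires an rmsd_matrix")
    if (!query_id %in% rownames(rmsd_matrix))
      stop("query ", query_id, " not in rmsd matrix")
    rm_ <- rmsd_matrix[query_id, cand]
    pick <- cand[order(rm_, cand)][1]
    res$template_ids <- pick
    res$identity <- unname(si[pick])
    res$template_rmsd <- unname(rm_[pick])
  } else if (scenario == "3bestSeqIdTemp") {
    if (length(cand) < 3L) stop("3bestSeqIdTemp requires >= 3 candidates")
    res$template_ids <- ord[1:3]
    res$identity <- mean(si[ord[1:3]])
  } else {
    res$template_ids <- ord
    res$identity <- unname(si[ord])
  }
  structure(res, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s / %s: %s (SI/MSI %.1f)\n", x$query_id,
              x$scenario, paste(x$template_ids, collapse = ","),
              x$identity[1]))
  invisible(x)
}

#' Select the best model by an external quality score
#'
#' Picks the model with the minimum score (statistical-potential scores such
#' as DOPE are lower-is-better); ties are broken by lexicographic id.
#'
#' @param model_scores named numeric vector of finite scores.
#' @return The id of the selected model.
#' @export
select_best_model <- function(model_scores) {
  if (!length(model_scores)) stop("no scored models")
  if (is.null(names(model_scores)) || !all(nzchar(names(model_scores))))
    stop("model scores must be named")
  if (any(!is.finite(model_scores))) stop("non-finite model score")
  ord <- order(model_scores, names(model_scores))
  names(model_scores)[ord[1]]
}

#' Greedy redundancy filter on an identity matrix
#'
#' Keeps ids in order, dropping any id whose identity to an already kept id
#' reaches the threshold (the classical dataset-assembly redundancy filter).
#'
#' @param identity_matrix symmetric percent-identity matrix with dimnames.
#' @param threshold percent identity at or above which a sequence is
#'   considered redundant (default 95).
#' @return Character vector of retained ids.
#' @export
redundancy_filter <- function(identity_matrix, threshold = 95) {
  ids <- rownames(identity_matrix)
  kept <- character(0)
  for (id in ids) {
    if (!length(kept) || all(identity_matrix[id, kept] < threshold))
      kept <- c(kept, id)
  }
  kept
}

# merge pairwise query-template alignments into one multiple alignment,
# master-slave on the query coordinates: insertions relative to the query
# are pooled per query position and left-justified
.merge_on_query <- function(alignments) {
  qseqs <- vapply(alignments, function(a)
    gsub("-", "", a$aligned_a), character(1))
  if (length(unique(qseqs)) != 1L)
    stop("inconsistent query sequence across alignments")
  qseq <- strsplit(qseqs[[1]], "")[[1]]
  Lq <- length(qseq)
  parsed <- lapply(alignments, function(a) {
    ca <- strsplit(a$aligned_a, "")[[1]]
    cb <- strsplit(a$aligned_b, "")[[1]]
    if (any(ca == "-" & cb == "-")) stop("gap-only column in alignment")
    qpos <- cumsum(ca != "-")          # 0 before the query starts
    at <- rep(list(character(0)), Lq + 1L)  # insertions after qpos 0..Lq
    res <- rep("-", Lq)
    for (k in seq_along(ca)) {
      if (ca[k] != "-") {
        res[qpos[k]] <- cb[k]
      } else {
        at[[qpos[k] + 1L]] <- c(at[[qpos[k] + 1L]], cb[k])
      }
    }
    list(residues = res, insertions = at)
  })
  ins_len <- vapply(seq_len(Lq + 1L), function(p)
    max(vapply(parsed, function(pp) length(pp$insertions[[p]]), integer(1))),
    integer(1))
  build_row <- function(res, at) {
    out <- character(0)
    for (p in seq_len(Lq + 1L)) {
      blk <- at[[p]]
      out <- c(out, blk, rep("-", ins_len[p] - length(blk)))
      if (p <= Lq) out <- c(out, res[p])
    }
    paste(out, collapse = "")
  }
  templates <- vapply(parsed, function(pp)
    build_row(pp$residues, pp$insertions), character(1))
  query_row <- build_row(qseq, rep(list(character(0)), Lq + 1L))
  list(query = query_row, templates = templates)
}

#' Write a PIR-dialect alignment file for comparative modeling
#'
#' Writes the query and its template(s) in the PIR dialect consumed by
#' comparative-modeling engines: a `>P1;id` header, a structure/sequence
#' descriptor line, and the gapped sequence terminated by `*`. With several
#' templates, the pairwise alignments are merged on the query coordinates
#' into a single multiple alignment (template insertions pooled per query
#' position); template entries come first and the query entry last.
#'
#' @param query_id id written for the query entry.
#' @param alignments named list of [global_align()] results, each with the
#'   query as the first sequence; names are the template ids.
#' @param path output file path.
#' @param template_refs optional named list of
#'   `list(file=, chain=, first=, last=)` descriptors per template id.
#' @return Invisibly, `path`.
#' @export
write_pir_alignment <- function(query_id, alignments, path,
                                template_refs = NULL) {
  if (!length(alignments)) stop("at least one alignment required")
  if (inherits(alignments, "pairwise_alignment"))
    alignments <- list(template = alignments)
  if (is.null(names(alignments)) || !all(nzchar(names(alignments))))
    stop("alignments must be named by template id")
  merged <- .merge_on_query(alignments)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignments)) {
    id <- names(alignments)[i]
    ref <- template_refs[[id]]
    desc <- sprintf("structureX:%s:%s:%s:%s:%s::::",
                    ref$file %||% id,
                    ref$first %||% "FIRST", ref$chain %||% "@",
                    ref$last %||% "LAST", ref$chain %||% "@")
    writeLines(c(sprintf(">P1;%s", id), desc,
                 paste0(merged$templates[i], "*")), con)
  }
  writeLines(c(sprintf(">P1;%s", query_id),
               sprintf("sequence:%s::::::::", query_id),
               paste0(merged$query, "*")), con)
  invisible(path)
}

#' Read a PIR-dialect alignment file
#'
#' @param path file written by [write_pir_alignment()].
#' @return Named character vector of gapped sequences (query last).
#' @export
read_pir_alignment <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>P1;", lines)
  if (!length(starts)) stop("not a PIR file: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- character(0)
  for (k in seq_along(starts)) {
    id <- sub("^>P1;", "", lines[starts[k]])
    body <- paste(lines[(starts[k] + 2L):ends[k]], collapse = "")
    if (!grepl("\\*", body)) stop("unterminated PIR entry: ", id)
    out[id] <- sub("\\*.*$", "", body)
  }
  out
}
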