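#' The Protein Blocks reference table
#'
#' Returns the canonical 16 x 8 table of dihedral prototypes defining the
#' Protein Blocks structural alphabet (letters a to p). Each prototype is the
#' series of 8 phi/psi angles of a 5-residue window centred on residue i, in
#' the order psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1),
#' psi(i+1), phi(i+2). The table ships with the package
#' (`extdata/pb_prototypes.tsv`) and originates from the PB literature; `m`
#' and `d` are the repetitive alpha-helix and central beta-strand
#' prototypes, the other 14 letters describe caps and coils.
#'
#' @return Numeric 16 x 8 matrix with rownames `a`..`p`.
#' @export
pb_reference_table <- function() {
  if (is.null(.vhhpb_cache$pb_table)) {
    path <- system.file("extdata", "pb_prototypes.tsv", package = "vhhpb",
                        mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$pb
    validate_pb_table(m)
    .vhhpb_cache$pb_table <- m
  }
  .vhhpb_cache$pb_table
}

#' Validate a PB prototype table
#'
#' Checks the structural-alphabet invariants: exactly 16 uniquely labelled
#' prototypes `a`..`p`, 8 angles each, all in (-180, 180].
#'
#' @param table numeric matrix as returned by [pb_reference_table()].
#' @return Invisibly `table`; errors on violation.
#' @export
validate_pb_table <- function(table) {
  if (!is.matrix(table) || nrow(table) != 16L || ncol(table) != 8L)
    stop("PB table must be a 16 x 8 numeric matrix")
  if (!identical(rownames(table), letters[1:16]))
    stop("PB table rows must be uniquely labelled a..p in order")
  if (any(!is.finite(table)) || any(table <= -180) || any(table > 180))
    stop("PB prototype angles must lie in (-180, 180]")
  invisible(table)
}

#' Angular RMSD between a dihedral window and a prototype
#'
#' Root mean square of the 8 per-component angular differences, each wrapped
#' to \[-180, 180\] degrees, i.e. the RMSDA dissimilarity used for PB
#' assignment.
#'
#' @param window,prototype numeric 8-vectors of angles in degrees, fully
#'   defined.
#' @return Non-negative scalar (degrees).
#' @export
rmsda <- function(window, prototype) {
  if (length(window) != 8L || length(prototype) != 8L)
    stop("window and prototype must have 8 components")
  if (anyNA(window) || anyNA(prototype))
    stop("rmsda requires fully defined angle vectors")
  d <- ((window - prototype + 180) %% 360) - 180
  sqrt(mean(d^2))
}

# L x 8 window matrix for positions 3..L-2 (NA elsewhere)
.pb_windows <- function(phi, psi) {
  L <- length(phi)
  W <- matrix(NA_real_, L, 8)
  if (L >= 5L) {
    i <- 3:(L - 2)
    W[i, 1] <- psi[i - 2]; W[i, 2] <- phi[i - 1]; W[i, 3] <- psi[i - 1]
    W[i, 4] <- phi[i];     W[i, 5] <- psi[i]
    W[i, 6] <- phi[i + 1]; W[i, 7] <- psi[i + 1]; W[i, 8] <- phi[i + 2]
  }
  W
}

#' Assign a Protein Blocks sequence from backbone dihedrals
#'
#' Each position with a fully defined 8-angle window (positions 3..L-2 of an
#' unbroken chain) receives the letter of the minimum-RMSDA prototype; ties
#' are broken alphabetically. Window-incomplete positions -- the two first,
#' the two last, and any position touching an undefined dihedral -- are the
#' placeholder `"Z"`.
#'
#' @param dihedrals a [dihedral_series()].
#' @param table PB prototype table (default [pb_reference_table()]).
#' @return Character vector of per-position letters (`a`..`p` or `Z`), of the
#'   chain's length.
#' @export
assign_pb_sequence <- function(dihedrals, table = pb_reference_table()) {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  validate_pb_table(table)
  W <- .pb_windows(dihedrals$phi, dihedrals$psi)
  out <- rep("Z", nrow(W))
  ok <- which(rowSums(is.na(W)) == 0L)
  if (length(ok)) {
    # squared wrapped distance to each of the 16 prototypes, vectorised
    D <- vapply(seq_len(16), function(p) {
      d <- ((W[ok, , drop = FALSE] -
               matrix(table[p, ], length(ok), 8, byrow = TRUE) + 180) %%
              360) - 180
      rowSums(d^2)
    }, numeric(length(ok)))
    D <- matrix(D, nrow = length(ok))
    out[ok] <- letters[apply(D, 1, which.min)]
  }
  out
}

#' Collapse a PB letter vector into a string
#'
#' @param pb character vector of PB letters.
#' @return Single string.
#' @export
pb_string <- function(pb) paste(pb, collapse = "")

.pb_letters <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L) strsplit(x, "")[[1]] else x
}

#' Count mismatching PB positions
#'
#' Positions where either sequence carries the undefined placeholder `Z` are
#' excluded from the count.
#'
#' @param s1,s2 PB sequences of equal length, as letter vectors or single
#'   strings.
#' @return Integer mismatch count.
#' @export
pb_mismatch_count <- function(s1, s2) {
  a <- .pb_letters(s1); b <- .pb_letters(s2)
  if (length(a) != length(b)) stop("PB sequences must have equal length")
  sum(a != b & a != "Z" & b != "Z")
}
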