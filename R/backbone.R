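#' Backbone chain objects
#'
#' A `backbone_chain` holds the four backbone heavy atoms (N, CA, C, O) of
#' one polypeptide chain, with one-letter residue identities and the original
#' author-assigned residue numbering. Residues are re-indexed internally to a
#' contiguous 1-based index; all region ranges used elsewhere in the package
#' refer to this contiguous index (inclusive ends). Residues missing any of
#' the four atoms are kept but flagged `complete = FALSE`; their coordinates
#' are `NA` rows.
#'
#' @param aa character vector of one-letter amino-acid codes (non-standard
#'   residues as `"X"`).
#' @param N,CA,C,O numeric matrices (length(aa) x 3) of coordinates in
#'   Angstrom; rows may be `NA` for missing atoms.
#' @param seq_number integer vector of author residue numbers (default
#'   `1:length(aa)`).
#' @param ins_code character vector of insertion codes (`""` when absent).
#' @param chain_id single-character chain identifier.
#'
#' @return An object of class `backbone_chain`: a list with elements
#'   `chain_id`, `aa`, `seq_number`, `ins_code`, `complete` and the four
#'   coordinate matrices.
#' @export
backbone_chain <- function(aa, N, CA, C, O,
                           seq_number = seq_along(aa),
                           ins_code = rep("", length(aa)),
                           chain_id = "A") {
  L <- length(aa)
  if (L < 1L) stop("a backbone chain must contain at least one residue")
  as_mat <- function(m, what) {
    m <- as.matrix(m)
    if (is.vector(m)) m <- matrix(m, ncol = 3)
    if (nrow(m) != L || ncol(m) != 3)
      stop(sprintf("%s coordinates must be a %d x 3 matrix", what, L))
    storage.mode(m) <- "double"
    unname(m)
  }
  N <- as_mat(N, "N"); CA <- as_mat(CA, "CA")
  C <- as_mat(C, "C"); O <- as_mat(O, "O")
  ord <- order(seq_number, ins_code)
  if (any(ord != seq_len(L)))
    stop("residues must be ordered by (seq_number, insertion_code)")
  complete <- rowSums(is.finite(N)) == 3 & rowSums(is.finite(CA)) == 3 &
    rowSums(is.finite(C)) == 3 & rowSums(is.finite(O)) == 3
  structure(list(chain_id = chain_id, aa = as.character(aa),
                 seq_number = as.integer(seq_number),
                 ins_code = as.character(ins_code),
                 complete = complete, N = N, CA = CA, C = C, O = O),
            class = "backbone_chain")
}

#' @export
length.backbone_chain <- function(x) length(x$aa)

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain> chain %s, %d residues (%d complete)\n",
              x$chain_id, length(x), sum(x$complete)))
  cat(" sequence:", chain_sequence(x), "\n")
  invisible(x)
}

#' Amino-acid sequence of a backbone chain
#'
#' @param chain a [backbone_chain()].
#' @return Single string of one-letter codes.
#' @export
chain_sequence <- function(chain) paste(chain$aa, collapse = "")

#' Read one chain from a PDB file
#'
#' Parses fixed-column ATOM records through [bio3d::read.pdb()] and extracts
#' the backbone (N, CA, C, O) of a single chain. HETATM records are excluded.
#' Alternate locations are resolved per atom by keeping the highest-occupancy
#' record (ties prefer blank altloc, then "A", then alphabetical). When the
#' file holds several MODEL records, `model_index` selects one.
#'
#' @param path path to a PDB file.
#' @param chain_id chain identifier to extract; `NULL` takes the first chain
#'   present.
#' @param model_index 1-based MODEL number (default first).
#' @return A [backbone_chain()].
#' @export
read_pdb_chain <- function(path, chain_id = NULL, model_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at$row <- seq_len(nrow(at))
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain_id)) chain_id <- at$chain[1L]
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain not found: '", chain_id, "' in ", path)

  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > nmod)
    stop("model_index ", model_index, " out of range (file has ", nmod,
         " model(s))")
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else as.numeric(pdb$xyz)

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # highest-occupancy altloc per (residue, atom); ties: "" then "A" then a-z
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  pref <- order(key, -at$o, at$alt != "", at$alt)
  at <- at[pref, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "\r")), ,
           drop = FALSE]
  at <- at[order(at$row), , drop = FALSE]

  reskey <- paste(at$resno, at$insert, sep = "\r")
  ures <- unique(reskey)
  L <- length(ures)
  if (L == 0L) stop("zero parsable residues for chain ", chain_id)
  get_xyz <- function(rows) {
    out <- matrix(NA_real_, length(rows), 3)
    ok <- !is.na(rows)
    idx <- rows[ok]
    out[ok, ] <- cbind(xyz[3 * idx - 2], xyz[3 * idx - 1], xyz[3 * idx])
    out
  }
  coord_for <- function(elety) {
    sel <- at[at$elety == elety, , drop = FALSE]
    rows <- sel$row[match(ures, paste(sel$resno, sel$insert, sep = "\r"))]
    get_xyz(rows)
  }
  first <- at[!duplicated(reskey), , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(first$resid))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  ord <- order(first$resno, first$insert)
  chain <- backbone_chain(aa = aa[ord],
                          N = coord_for("N")[ord, , drop = FALSE],
                          CA = coord_for("CA")[ord, , drop = FALSE],
                          C = coord_for("C")[ord, , drop = FALSE],
                          O = coord_for("O")[ord, , drop = FALSE],
                          seq_number = first$resno[ord],
                          ins_code = first$insert[ord],
                          chain_id = chain_id)
  chain
}

#' Write a backbone chain as a PDB file
#'
#' Emits standard fixed-column ATOM records (N, CA, C, O per residue,
#' skipping missing atoms) via [bio3d::write.pdb()]. Coordinates survive a
#' write/read round trip to the 3-decimal precision of the format.
#'
#' @param chain a [backbone_chain()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "backbone_chain"))
  if (length(chain) < 1L) stop("cannot write an empty chain")
  elety <- c("N", "CA", "C", "O")
  L <- length(chain)
  rows <- list()
  for (i in seq_len(L)) {
    for (e in elety) {
      xyz <- chain[[e]][i, ]
      if (!all(is.finite(xyz))) next
      rows[[length(rows) + 1L]] <- list(resno = chain$seq_number[i],
                                        insert = chain$ins_code[i],
                                        aa = chain$aa[i], elety = e, xyz = xyz)
    }
  }
  if (length(rows) == 0L) stop("chain has no finite coordinates to write")
  aa123 <- function(a) ifelse(a == "X", "UNK", suppressWarnings(bio3d::aa123(a)))
  xyz <- as.numeric(vapply(rows, function(r) r$xyz, numeric(3)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = rep("ATOM", length(rows)),
    resno = vapply(rows, function(r) r$resno, integer(1)),
    resid = aa123(vapply(rows, function(r) r$aa, character(1))),
    eleno = seq_along(rows),
    elety = vapply(rows, function(r) r$elety, character(1)),
    chain = rep(chain$chain_id, length(rows)),
    insert = vapply(rows, function(r) r$insert, character(1)),
    o = rep(1, length(rows)), b = rep(0, length(rows)))
  invisible(path)
}

# torsion angle (degrees) of four points; NA with a warning when the
# contributing atoms are nearly collinear
.dihedral4 <- function(p1, p2, p3, p4) {
  if (anyNA(c(p1, p2, p3, p4))) return(NA_real_)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  scale <- max(sqrt(sum(b1^2)), nb2, sqrt(sum(b3^2)))
  if (sqrt(sum(n1^2)) < 1e-9 * scale^2 || sqrt(sum(n2^2)) < 1e-9 * scale^2) {
    warning("torsion undefined: contributing atoms nearly collinear")
    return(NA_real_)
  }
  m1 <- .cross3(n1, b2 / nb2)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  .wrap_angle(ang)
}

#' Dihedral angle series
#'
#' Container for per-residue backbone (phi, psi) in degrees, each in
#' (-180, 180] or `NA` where undefined. By construction phi is undefined at
#' the first residue and psi at the last.
#'
#' @param phi,psi numeric vectors of equal length.
#' @return A data frame of class `dihedral_series` with columns `phi`, `psi`.
#' @export
dihedral_series <- function(phi, psi) {
  stopifnot(length(phi) == length(psi))
  L <- length(phi)
  if (L >= 1L && !is.na(phi[1L]))
    stop("phi of the first residue must be undefined")
  if (L >= 1L && !is.na(psi[L]))
    stop("psi of the last residue must be undefined")
  rng <- c(phi, psi)
  rng <- rng[!is.na(rng)]
  if (length(rng) && (any(rng <= -180) || any(rng > 180)))
    stop("angles must lie in (-180, 180]")
  structure(data.frame(phi = as.numeric(phi), psi = as.numeric(psi)),
            class = c("dihedral_series", "data.frame"))
}

#' Backbone dihedrals of a chain
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i); psi(i) is
#' N(i)-CA(i)-C(i)-N(i+1). Angles are reported in degrees in (-180, 180].
#' Any position whose contributing atoms include a missing atom (or a
#' near-collinear quadruple) is `NA`.
#'
#' @param chain a [backbone_chain()] of length >= 2.
#' @return A [dihedral_series()] with one row per residue.
#' @export
compute_backbone_dihedrals <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  L <- length(chain)
  if (L < 2L) stop("chain must contain at least 2 residues")
  phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
  for (i in 2:L)
    phi[i] <- .dihedral4(chain$C[i - 1, ], chain$N[i, ], chain$CA[i, ],
                         chain$C[i, ])
  for (i in 1:(L - 1))
    psi[i] <- .dihedral4(chain$N[i, ], chain$CA[i, ], chain$C[i, ],
                         chain$N[i + 1, ])
  dihedral_series(phi, psi)
}

#' Apply a rigid-body transform to a chain
#'
#' @param chain a [backbone_chain()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector (Angstrom).
#' @return The transformed [backbone_chain()].
#' @export
transform_chain <- function(chain, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  stopifnot(inherits(chain, "backbone_chain"))
  for (e in c("N", "CA", "C", "O"))
    chain[[e]] <- sweep(chain[[e]] %*% t(rotation), 2, -translation)
  chain
}
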