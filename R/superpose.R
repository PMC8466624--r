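#' Least-squares rigid superposition of paired C-alpha atoms
#'
#' Solves the orthogonal Procrustes problem by the standard SVD solution
#' with reflection correction (a proper rotation, det = +1), minimising
#' `sum ||R x + t - y||^2` over the paired C-alpha coordinates, and reports
#' the minimised RMSD.
#'
#' @param mobile,reference [backbone_chain()] objects.
#' @param pairing 2-column integer matrix of (mobile index, reference index)
#'   pairs; default pairs identical positions (chains must then share
#'   length).
#' @return Object of class `superposition`: list with `rotation` (3x3),
#'   `translation` (length 3, Angstrom), `rmsd` (Angstrom) and `n_atoms`.
#' @export
superpose_calpha <- function(mobile, reference, pairing = NULL) {
  stopifnot(inherits(mobile, "backbone_chain"),
            inherits(reference, "backbone_chain"))
  if (is.null(pairing)) {
    if (length(mobile) != length(reference))
      stop("chains differ in length; an explicit pairing is required")
    pairing <- cbind(seq_len(length(mobile)), seq_len(length(reference)))
  }
  pairing <- as.matrix(pairing)
  x <- mobile$CA[pairing[, 1], , drop = FALSE]
  y <- reference$CA[pairing[, 2], , drop = FALSE]
  keep <- rowSums(is.finite(x)) == 3 & rowSums(is.finite(y)) == 3
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  fit <- .kabsch(x, y)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_atoms = nrow(x)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, rmsd %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

.kabsch <- function(x, y) {
  n <- nrow(x)
  if (n < 3L) stop("superposition requires at least 3 paired atoms")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  sx <- svd(xc)$d
  if (sx[2] < 1e-8 * max(sx[1], 1))
    stop("superposition undefined: all paired atoms are collinear")
  H <- crossprod(xc, yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cy - R %*% cx)
  resid <- sweep(x %*% t(R), 2, -tr) - y
  list(rotation = R, translation = tr, rmsd = sqrt(mean(rowSums(resid^2))))
}

#' Apply a superposition to a chain
#'
#' @param chain a [backbone_chain()].
#' @param superposition result of [superpose_calpha()].
#' @return The transformed chain.
#' @export
apply_superposition <- function(chain, superposition) {
  transform_chain(chain, superposition$rotation, superposition$translation)
}

#' Region-wise C-alpha RMSD between a model and its native structure
#'
#' Two conventions are offered. `local_fit` superposes on each region's own
#' C-alpha atoms before measuring that region (region values are then
#' mutually independent); `frame_fit` superposes once on all framework (FR)
#' C-alpha atoms and measures every region in that fixed frame, so CDR
#' values reflect displacement relative to the beta-sandwich scaffold.
#'
#' @param model,native [backbone_chain()] objects of one length (models of
#'   the same query share numbering positionally).
#' @param regions a [region_map()].
#' @param mode `"local_fit"` (default) or `"frame_fit"`.
#' @return Named numeric vector, one RMSD (Angstrom) per region.
#' @export
region_rmsd <- function(model, native, regions,
                        mode = c("local_fit", "frame_fit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "backbone_chain"),
            inherits(native, "backbone_chain"))
  if (length(model) != length(native))
    stop("model and native must share length/numbering")
  regions <- as_region_map(regions, length(model))
  rng <- lapply(regions, function(r) seq.int(r[1], r[2]))
  if (any(vapply(rng, max, numeric(1)) > length(model)))
    stop("region outside chain")
  if (mode == "local_fit") {
    out <- vapply(names(rng), function(nm) {
      idx <- rng[[nm]]
      if (length(idx) < 3L)
        stop("region ", nm, " is shorter than 3 residues (local_fit)")
      superpose_calpha(model, native, cbind(idx, idx))$rmsd
    }, numeric(1))
  } else {
    fr_idx <- unlist(rng[grepl("^FR", names(rng))], use.names = FALSE)
    sp <- superpose_calpha(model, native, cbind(fr_idx, fr_idx))
    moved <- apply_superposition(model, sp)
    out <- vapply(rng, function(idx) {
      resid <- moved$CA[idx, , drop = FALSE] - native$CA[idx, , drop = FALSE]
      sqrt(mean(rowSums(resid^2)))
    }, numeric(1))
  }
  out
}

#' C-alpha distance between the termini of a loop region
#'
#' Euclidean distance between the C-alpha atoms of the first and last
#' residues of an inclusive region -- the anchor-to-anchor span of a CDR
#' loop.
#'
#' @param chain a [backbone_chain()].
#' @param region inclusive 1-based `c(start, end)` range.
#' @return Distance in Angstrom.
#' @export
loop_termini_distance <- function(chain, region) {
  stopifnot(inherits(chain, "backbone_chain"), length(region) == 2L)
  region <- as.integer(region)
  if (region[1] < 1L || region[2] > length(chain) || region[1] > region[2])
    stop("region outside chain")
  if (!chain$complete[region[1]] || !chain$complete[region[2]])
    stop("incomplete terminal residue in region")
  sqrt(sum((chain$CA[region[1], ] - chain$CA[region[2], ])^2))
}

.rama_polygons <- function() {
  if (is.null(.vhhpb_cache$rama)) {
    path <- system.file("extdata", "ramachandran_regions.tsv",
                        package = "vhhpb", mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    .vhhpb_cache$rama <- split(tab, paste(tab$class, tab$polygon, sep = "."))
  }
  .vhhpb_cache$rama
}

#' Ramachandran region fractions of a dihedral series
#'
#' Classifies every defined (phi, psi) pair by the simplified region
#' polygons shipped with the package (see `extdata/ramachandran_regions.tsv`)
#' into favored, allowed and unfavorable, and returns the three percentages
#' (summing to 100) over the defined positions.
#'
#' @param dihedrals a [dihedral_series()] with at least one position where
#'   both angles are defined.
#' @return Named numeric vector `c(favored=, allowed=, unfavorable=)` in
#'   percent.
#' @export
ramachandran_fractions <- function(dihedrals) {
  stopifnot(inherits(dihedrals, "dihedral_series"))
  ok <- !is.na(dihedrals$phi) & !is.na(dihedrals$psi)
  if (!any(ok)) stop("no positions with both phi and psi defined")
  phi <- dihedrals$phi[ok]; psi <- dihedrals$psi[ok]
  polys <- .rama_polygons()
  in_any <- function(class) {
    hit <- rep(FALSE, length(phi))
    for (p in polys[grepl(paste0("^", class, "\\."), names(polys))])
      hit <- hit | as.logical(pracma::inpolygon(phi, psi, p$phi, p$psi,
                                                boundary = TRUE))
    hit
  }
  fav <- in_any("favored")
  alw <- !fav & in_any("allowed")
  unf <- !fav & !alw
  100 * c(favored = mean(fav), allowed = mean(alw), unfavorable = mean(unf))
}
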