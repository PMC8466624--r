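.REGION_NAMES <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Framework/CDR region map of a VHH domain
#'
#' An ordered partition of a chain into the seven canonical immunoglobulin
#' variable-domain segments FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4, each an
#' inclusive 1-based residue range over the package's contiguous index. The
#' segments must be contiguous, non-overlapping, in order, and jointly cover
#' `1..length`.
#'
#' @param ranges named list (or 2-column matrix rownames) of `c(start, end)`
#'   integer pairs for the seven segments.
#' @param length chain length the map must cover; inferred from the last
#'   segment when `NULL`.
#' @return Object of class `region_map`: named list of integer ranges.
#' @export
region_map <- function(ranges, length = NULL) {
  if (is.matrix(ranges))
    ranges <- stats::setNames(lapply(seq_len(nrow(ranges)),
                                     function(i) ranges[i, ]),
                              rownames(ranges))
  if (!identical(names(ranges), .REGION_NAMES))
    stop("region map must contain exactly the segments ",
         paste(.REGION_NAMES, collapse = ", "), " in order")
  ranges <- lapply(ranges, function(r) as.integer(r[1:2]))
  starts <- vapply(ranges, `[`, integer(1), 1L)
  ends <- vapply(ranges, `[`, integer(1), 2L)
  if (any(ends < starts)) stop("region end before start")
  if (starts[1] != 1L) stop("regions must start at position 1")
  gaps <- starts[-1] - ends[-length(ends)]
  if (any(gaps > 1L)) stop("regions leave a gap")
  if (any(gaps < 1L)) stop("regions overlap")
  L <- length %||% ends[[7]]
  if (ends[[7]] != L)
    stop("regions must cover positions 1..", L, " exactly")
  structure(ranges, class = "region_map")
}

as_region_map <- function(x, length = NULL) {
  if (inherits(x, "region_map")) x else region_map(x, length)
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>",
      paste(sprintf("%s:%d-%d", names(x),
                    vapply(x, `[`, integer(1), 1),
                    vapply(x, `[`, integer(1), 2)),
            collapse = " "), "\n")
  invisible(x)
}

#' Annotate FR and CDR regions of a VHH sequence
#'
#' With `override`, the given ranges are validated as a full partition and
#' returned verbatim -- the recommended route whenever curated bounds are
#' available, since no single CDR delimitation scheme is universal. Without
#' an override, a conservative anchor heuristic is applied: the two
#' conserved framework cysteines (near positions 22 and 96) and the FR4
#' `WGxG` motif are located; CDR1 spans the 4th through 14th residue after
#' the first cysteine, CDR2 a fixed offset window after CDR1, and CDR3 runs
#' from two residues after the second cysteine to the residue preceding the
#' motif tryptophan. If any anchor is missing or the implied bounds are
#' inconsistent, annotation fails with a request for an explicit override.
#'
#' @param sequence amino-acid string, 100-140 residues.
#' @param override optional named list of seven ranges, passed to
#'   [region_map()].
#' @return A [region_map()].
#' @export
annotate_regions <- function(sequence, override = NULL) {
  L <- nchar(sequence)
  if (L < 100L || L > 140L)
    stop("sequence length ", L, " outside the VHH domain range 100-140")
  if (!is.null(override)) return(region_map(override, length = L))
  aa <- strsplit(sequence, "")[[1]]
  pick_cys <- function(lo, hi, target) {
    cand <- which(aa == "C")
    cand <- cand[cand >= lo & cand <= hi]
    if (!length(cand)) return(NA_integer_)
    cand[which.min(abs(cand - target))]
  }
  cys1 <- pick_cys(15L, 30L, 22L)
  cys2 <- pick_cys(85L, 104L, 96L)
  w <- NA_integer_
  if (!is.na(cys2)) {
    m <- gregexpr("WG.G", sequence)[[1]]
    m <- m[m > cys2 + 3L]
    if (length(m) && m[1] > 0) w <- m[1]
  }
  fail <- function() stop("annotation failed, supply override")
  if (is.na(cys1) || is.na(cys2) || is.na(w)) fail()
  cdr1 <- c(cys1 + 4L, cys1 + 14L)
  cdr2 <- c(cys1 + 33L, cys1 + 40L)
  cdr3 <- c(cys2 + 3L, w - 1L)
  bounds <- c(1L, cdr1, cdr2, cdr3, w, L)
  if (any(diff(bounds) < 1L)) fail()
  ranges <- list(FR1 = c(1L, cdr1[1] - 1L), CDR1 = cdr1,
                 FR2 = c(cdr1[2] + 1L, cdr2[1] - 1L), CDR2 = cdr2,
                 FR3 = c(cdr2[2] + 1L, cdr3[1] - 1L), CDR3 = cdr3,
                 FR4 = c(w, L))
  tryCatch(region_map(ranges, length = L), error = function(e) fail())
}

#' Read / write a region map as JSON or YAML
#'
#' Serialised as `{name: [start, end]}` with 1-based inclusive ranges; the
#' format is chosen by file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param map a [region_map()].
#' @param path file path.
#' @return `write_region_map` invisibly returns `path`; `read_region_map`
#'   returns a [region_map()].
#' @export
write_region_map <- function(map, path) {
  stopifnot(inherits(map, "region_map"))
  lst <- lapply(map, as.integer)
  if (grepl("\\.(yml|yaml)$", path)) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  lst <- if (grepl("\\.(yml|yaml)$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  region_map(lapply(lst, as.integer))
}

#' Region map as a data frame
#'
#' @param map a [region_map()].
#' @return Data frame with columns `region`, `start`, `end`.
#' @export
regions_to_df <- function(map) {
  stopifnot(inherits(map, "region_map"))
  data.frame(region = names(map),
             start = vapply(map, `[`, integer(1), 1),
             end = vapply(map, `[`, integer(1), 2),
             row.names = NULL)
}
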