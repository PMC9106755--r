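#' Construct a band-presence matrix
#'
#' A `band_matrix` holds dominant fingerprint scores for a germplasm panel:
#' one row per genotype, one column per scored band locus, cells 1 (band
#' present), 0 (absent) or `NA` (not scored). Column names encode the locus
#' identity as `"PRIMER|SYSTEM|band"` (e.g. `"OPC-08|RAPD|750bp"`), so
#' per-primer statistics need no side table.
#'
#' @param x numeric/integer matrix with genotype row names and
#'   `"PRIMER|SYSTEM|band"` column names; cells in `{0, 1, NA}`.
#' @return an object of class `band_matrix` (an integer matrix with a
#'   `loci` attribute: data frame of `locus`, `primer`, `system`, `band`).
#' @export
#' @examples
#' m <- matrix(c(1, 0, NA, 1), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("P1|RAPD|300", "P1|RAPD|500")))
#' band_matrix(m)
band_matrix <- function(x) {
  if (!is.matrix(x)) stop_musadiv("band matrix input must be a matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_musadiv("band matrix needs genotype row names and locus column names")
  storage.mode(x) <- "integer"
  validate_band_matrix(x)
  attr(x, "loci") <- parse_locus_ids(colnames(x))
  class(x) <- c("band_matrix", class(x))
  x
}

validate_band_matrix <- function(x) {
  gid <- rownames(x)
  if (anyDuplicated(gid))
    stop_musadiv("duplicate genotype id(s): ",
                 paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_musadiv("duplicate locus id(s): ",
                 paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!(x %in% c(0L, 1L, NA)), arr.ind = FALSE)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop_musadiv("cell outside {0,1,NA} at genotype '", rownames(x)[i[1]],
                 "', locus '", colnames(x)[i[2]], "' (value ", x[bad[1]], ")")
  }
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing))
    stop_musadiv("locus with no scored cells: ",
                 paste(colnames(x)[all_missing], collapse = ", "))
  invisible(x)
}

parse_locus_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != 3))
    stop_musadiv("locus id not of the form PRIMER|SYSTEM|band: ",
                 paste(ids[n != 3], collapse = ", "))
  df <- data.frame(
    locus  = ids,
    primer = vapply(parts, `[`, "", 1),
    system = vapply(parts, `[`, "", 2),
    band   = vapply(parts, `[`, "", 3),
    stringsAsFactors = FALSE
  )
  bad <- !df$system %in% MARKER_SYSTEMS
  if (any(bad))
    stop_musadiv("unknown marker system in locus id(s): ",
                 paste(df$locus[bad], collapse = ", "))
  # a primer belongs to exactly one marker system
  sys_per_primer <- tapply(df$system, df$primer, function(s) length(unique(s)))
  if (any(sys_per_primer > 1))
    stop_musadiv("primer(s) assigned to more than one marker system: ",
                 paste(names(sys_per_primer)[sys_per_primer > 1], collapse = ", "))
  df
}

#' Locus metadata of a band matrix
#'
#' @param x a [band_matrix()].
#' @return data frame with columns `locus`, `primer`, `system`, `band`.
#' @export
loci_info <- function(x) {
  stopifnot(inherits(x, "band_matrix"))
  attr(x, "loci")
}

#' Restrict a band matrix to one marker system
#'
#' @param x a [band_matrix()].
#' @param system `"RAPD"`, `"ISSR"`, `"SSR"` or `"all"`.
#' @return a [band_matrix()] with only the selected loci.
#' @export
subset_system <- function(x, system = "all") {
  stopifnot(inherits(x, "band_matrix"))
  if (identical(system, "all")) return(x)
  system <- match.arg(system, MARKER_SYSTEMS)
  keep <- loci_info(x)$system == system
  if (!any(keep)) stop_musadiv("no loci for marker system ", system)
  band_matrix(unclass(x)[, keep, drop = FALSE])
}

#' @export
print.band_matrix <- function(x, ...) {
  li <- loci_info(x)
  cat("band_matrix: ", nrow(x), " genotypes x ", ncol(x), " loci (",
      length(unique(li$primer)), " primers; systems: ",
      paste(sort(unique(li$system)), collapse = ", "), ")\n", sep = "")
  cat("missing cells:", sum(is.na(x)), "\n")
  invisible(x)
}
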