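#' Kovats retention index from an alkane ladder
#'
#' Linear (temperature-programmed) convention: with bracketing alkanes of
#' carbon numbers \eqn{n} and \eqn{n'} eluting at \eqn{RT_n < rt \le
#' RT_{n'}},
#' \eqn{RI = 100 n + 100 (n' - n) (rt - RT_n) / (RT_{n'} - RT_n)}; a
#' retention time exactly at an alkane anchor gives \eqn{100 n}.
#'
#' @param rt retention time(s), minutes; must lie within the ladder span.
#' @param ladder an [alkane_ladder()].
#' @return retention index (vectorised over `rt`).
#' @export
#' @examples
#' lad <- alkane_ladder(data.frame(carbon = 8:9, rt_min = c(10, 12)))
#' kovats_ri(11, lad)  # 850
kovats_ri <- function(rt, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  rts <- ladder$rt_min
  cs <- ladder$carbon
  if (any(rt < rts[1] | rt > rts[length(rts)]))
    stop_musadiv("retention time outside the alkane ladder span [",
                 rts[1], ", ", rts[length(rts)], "] min")
  i <- findInterval(rt, rts, rightmost.closed = TRUE)
  i <- pmin(i, length(rts) - 1)
  100 * (cs[i] + (cs[i + 1] - cs[i]) * (rt - rts[i]) / (rts[i + 1] - rts[i]))
}

#' Match an experimental retention index against a reference
#'
#' @param experimental_ri,reference_ri retention indices (vectorised).
#' @param tolerance maximum absolute deviation counted as a match;
#'   default 15 index units (typical for semi-standard non-polar columns).
#' @return data frame with `delta` (signed, experimental - reference) and
#'   `match`.
#' @export
#' @examples
#' match_compound(785, 781)  # match, delta +4
match_compound <- function(experimental_ri, reference_ri, tolerance = 15) {
  if (tolerance <= 0) stop_musadiv("tolerance must be positive")
  delta <- experimental_ri - reference_ri
  data.frame(delta = delta, match = abs(delta) <= tolerance)
}

#' Chemical-class composition of a volatile table
#'
#' Counts compounds per chemical class, overall and per cultivar (a
#' compound counts for a cultivar iff marked present). Percentages are
#' reported both exact and rounded half-up to integers, the convention
#' used in published composition figures (30/54 esters prints as 56%).
#'
#' @param x a `volatile_table`.
#' @return list of class `class_composition`: `total_compounds`, `counts`
#'   (per class), `percent` (exact), `percent_rounded`,
#'   `cultivar_class_counts` (cultivar x class matrix).
#' @export
class_composition <- function(x) {
  stopifnot(inherits(x, "volatile_table"))
  cultivars <- attr(x, "cultivars")
  cls <- factor(x$chemical_class, levels = VOLATILE_CLASSES)
  counts <- table(cls)
  total <- nrow(x)
  pct <- 100 * as.numeric(counts) / total
  names(pct) <- names(counts)
  mat <- vapply(VOLATILE_CLASSES, function(cl) {
    rows <- x$chemical_class == cl
    vapply(cultivars, function(cv) sum(x[[cv]][rows]), 0)
  }, numeric(length(cultivars)))
  if (length(cultivars) == 1) mat <- matrix(mat, 1, dimnames = list(cultivars, VOLATILE_CLASSES))
  structure(list(
    total_compounds = total,
    counts = counts,
    percent = pct,
    percent_rounded = round_half_up(pct),
    cultivar_class_counts = mat
  ), class = "class_composition")
}

#' @export
print.class_composition <- function(x, ...) {
  cat("class_composition:", x$total_compounds, "compounds\n")
  df <- data.frame(class = names(x$counts),
                   n = as.integer(x$counts),
                   percent = round(x$percent, 1),
                   rounded = x$percent_rounded)
  print(df[df$n > 0, ], row.names = FALSE)
  invisible(x)
}

#' Per-cultivar volatile counts
#'
#' Total compounds present per cultivar plus the per-class breakdown.
#' When the table carries a reported totals row (see
#' [read_volatile_table()]), computed totals are cross-checked against it
#' and mismatches reported in the result (and as a warning), never
#' silently corrected.
#'
#' @param x a `volatile_table`.
#' @return list: `totals` (named vector), `by_class` (cultivar x class),
#'   `ester_share_pct` (half-up-rounded percent of each cultivar's
#'   volatiles that are esters), `reported_totals`, `total_mismatches`.
#' @export
cultivar_counts <- function(x) {
  stopifnot(inherits(x, "volatile_table"))
  cultivars <- attr(x, "cultivars")
  comp <- class_composition(x)
  totals <- vapply(cultivars, function(cv) sum(x[[cv]]), 0)
  ester <- comp$cultivar_class_counts[, "ester"]
  share <- ifelse(totals > 0, round_half_up(100 * ester / totals), NA_real_)
  reported <- attr(x, "reported_totals")
  mism <- character(0)
  if (!is.null(reported)) {
    reported <- reported[cultivars]
    off <- which(!is.na(reported) & reported != totals)
    if (length(off)) {
      mism <- cultivars[off]
      warning("computed totals disagree with the table's reported totals for: ",
              paste(mism, collapse = ", "))
    }
  }
  list(totals = totals, by_class = comp$cultivar_class_counts,
       ester_share_pct = share, reported_totals = reported,
       total_mismatches = mism)
}

#' UPGMA clustering of cultivars by volatile presence
#'
#' Builds the cultivar x compound 0/1 matrix, computes shared-band (Dice)
#' similarity between cultivars and clusters `1 - S` with [upgma()] —
#' the same machinery used for DNA fingerprints.
#'
#' @param x a `volatile_table` with >= 2 cultivars.
#' @param coefficient see [shared_band_similarity()].
#' @return an `hclust` tree over cultivars.
#' @export
cultivar_volatile_clustering <- function(x, coefficient = "dice") {
  stopifnot(inherits(x, "volatile_table"))
  cultivars <- attr(x, "cultivars")
  if (length(cultivars) < 2) stop_musadiv("need >= 2 cultivars to cluster")
  m <- t(as.matrix(as.data.frame(x)[, cultivars]))
  colnames(m) <- x$compound
  empty <- rowSums(m) == 0
  if (any(empty))
    stop_musadiv("cultivar(s) with zero compounds (similarity undefined): ",
                 paste(cultivars[empty], collapse = ", "))
  S <- similarity_matrix(m, coefficient = coefficient)
  upgma(similarity_to_distance(S))
}
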