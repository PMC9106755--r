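#' Allele frequencies at a dominant locus
#'
#' For a dominant band locus the observable is the band frequency
#' \eqn{\bar p} (fraction of scored genotypes showing the band). Under
#' random union of `m` allele copies, absence requires all copies null, so
#' the null-allele frequency is \eqn{q = (1 - \bar p)^{1/m}} and the
#' presence-allele frequency \eqn{p = 1 - q}. The default scheme is the
#' diploid Hardy-Weinberg estimator (`m = 2`, i.e. \eqn{q = \sqrt{1-\bar p}});
#' `scheme = "ploidy_aware"` takes the panel ploidy `m` explicitly, which
#' matters for triploid/tetraploid banana panels.
#'
#' @param x a [band_matrix()].
#' @param locus locus id (column name).
#' @param scheme `"diploid_hwe"` or `"ploidy_aware"`.
#' @param ploidy allele copies `m` used when `scheme = "ploidy_aware"`.
#' @return list with `locus`, `band_freq`, `p`, `q`, `n_scored`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 1, 0), 4, 1, dimnames = list(letters[1:4], "P|RAPD|b1"))
#' estimate_allele_freqs(band_matrix(m), "P|RAPD|b1")  # q = sqrt(0.25) = 0.5
estimate_allele_freqs <- function(x, locus,
                                  scheme = c("diploid_hwe", "ploidy_aware"),
                                  ploidy = 2) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(x, "band_matrix"))
  if (!locus %in% colnames(x)) stop_musadiv("unknown locus: ", locus)
  cells <- unclass(x)[, locus]
  n <- sum(!is.na(cells))
  if (n == 0) stop_musadiv("all cells missing at locus ", locus)
  pbar <- sum(cells == 1, na.rm = TRUE) / n
  m <- if (scheme == "diploid_hwe") 2 else ploidy
  if (m < 1) stop_musadiv("ploidy must be >= 1")
  q <- (1 - pbar)^(1 / m)
  list(locus = locus, band_freq = pbar, p = 1 - q, q = q, n_scored = n)
}

#' Two-allele locus diversity statistics
#'
#' From allele frequencies `p + q = 1` and sample size `N`:
#' number of observed alleles `Na`, effective allele number
#' \eqn{Ne = 1/(p^2 + q^2)}, Shannon information index
#' \eqn{I = -(p \ln p + q \ln q)} (with \eqn{0 \ln 0 = 0}), expected
#' heterozygosity \eqn{He = 2pq}, and its unbiased small-sample version
#' \eqn{uHe = \frac{2N}{2N-1} He}.
#'
#' @param p presence-allele frequency.
#' @param N number of genotypes scored.
#' @return list with `Na`, `Ne`, `I`, `He`, `uHe`.
#' @export
#' @examples
#' locus_diversity(0.5, 20)  # Ne = 2, I = log(2), He = 0.5, uHe = 0.5128
locus_diversity <- function(p, N) {
  if (N < 1) stop_musadiv("N must be >= 1")
  if (p < 0 || p > 1) stop_musadiv("p must lie in [0, 1]")
  q <- 1 - p
  xlogx <- function(z) ifelse(z > 0, z * log(z), 0)
  list(
    Na = sum(c(p, q) > 0),
    Ne = 1 / (p^2 + q^2),
    I = -(xlogx(p) + xlogx(q)),
    He = 2 * p * q,
    uHe = (2 * N / (2 * N - 1)) * 2 * p * q
  )
}

#' Polymorphic information content of a dominant locus
#'
#' The dominant-marker convention \eqn{PIC = 2\bar p(1-\bar p)} on the
#' band frequency, with ceiling 0.5 at \eqn{\bar p = 0.5}. The codominant
#' form \eqn{1 - \sum p_i^2} is available via `method` for band-scored
#' loci treated as biallelic on (p, q).
#'
#' @param pbar band frequency in `[0, 1]`.
#' @param method `"dominant"` (default, `2p(1-p)` on the band frequency)
#'   or `"one_minus_sum_sq"` (on the inferred allele frequencies under the
#'   diploid scheme).
#' @return PIC value.
#' @export
pic_dominant <- function(pbar, method = c("dominant", "one_minus_sum_sq")) {
  method <- match.arg(method)
  if (any(pbar < 0 | pbar > 1)) stop_musadiv("band frequency outside [0, 1]")
  if (method == "dominant") {
    2 * pbar * (1 - pbar)
  } else {
    q <- sqrt(1 - pbar)
    1 - ((1 - q)^2 + q^2)
  }
}

#  Per-locus summaries for one primer's loci: band freq, polymorphism,
#  counts and diversity statistics.
locus_stats_for <- function(x, loci, scheme, ploidy) {
  m <- unclass(x)[, loci, drop = FALSE]
  t(vapply(loci, function(lc) {
    cells <- m[, lc]
    n <- sum(!is.na(cells))
    ones <- sum(cells == 1, na.rm = TRUE)
    pbar <- ones / n
    fr <- estimate_allele_freqs(x, lc, scheme = scheme, ploidy = ploidy)
    dv <- locus_diversity(fr$p, n)
    c(pbar = pbar, ones = ones, n = n,
      poly = as.numeric(ones > 0 && ones < n),
      PIC = pic_dominant(pbar), Na = dv$Na, Ne = dv$Ne, I = dv$I,
      He = dv$He, uHe = dv$uHe, Ib = 1 - 2 * abs(0.5 - pbar))
  }, numeric(11)))
}

#' Per-primer informativeness summary
#'
#' Amplicon-counting semantics: an amplicon is a 1-cell; a locus is
#' polymorphic when its scored cells contain both 0 and 1;
#' `total_amplicons` counts 1-cells over all the primer's loci and
#' `polymorphic_amplicons` over polymorphic loci only. PIC, Na, Ne, I, He
#' and uHe are locus means; resolving power is
#' \eqn{RP = \sum_b (1 - 2|0.5 - \bar p_b|)} and the marker index is
#' mean PIC times the effective multiplex ratio
#' \eqn{EMR = n_{poly} \cdot (n_{poly}/n_{loci})}.
#'
#' @param x a [band_matrix()].
#' @param primer primer name.
#' @param scheme,ploidy passed to [estimate_allele_freqs()].
#' @return one-row data frame of primer statistics.
#' @export
primer_summary <- function(x, primer,
                           scheme = c("diploid_hwe", "ploidy_aware"),
                           ploidy = 2) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(x, "band_matrix"))
  li <- loci_info(x)
  loci <- li$locus[li$primer == primer]
  if (!length(loci)) stop_musadiv("primer has no loci in matrix: ", primer)
  st <- locus_stats_for(x, loci, scheme, ploidy)
  n_gen <- nrow(x)
  total <- sum(st[, "ones"])
  poly <- st[, "poly"] == 1
  poly_amp <- sum(st[poly, "ones"])
  if (total == 0) {
    warning("primer ", primer, " has zero amplicons; polymorphism % reported as 0")
    pct <- 0
  } else {
    pct <- 100 * poly_amp / total
  }
  n_poly <- sum(poly)
  n_loci <- length(loci)
  data.frame(
    primer = primer,
    system = li$system[match(primer, li$primer)],
    polymorphic_amplicons = poly_amp,
    total_amplicons = total,
    percent_polymorphism = pct,
    avg_polymorphic_bands_per_genotype = poly_amp / n_gen,
    total_loci = n_loci,
    polymorphic_loci = n_poly,
    PIC = mean(st[, "PIC"]),
    Na = mean(st[, "Na"]),
    Ne = mean(st[, "Ne"]),
    I = mean(st[, "I"]),
    He = mean(st[, "He"]),
    uHe = mean(st[, "uHe"]),
    RP = sum(st[, "Ib"]),
    MI = mean(st[, "PIC"]) * n_poly * (n_poly / n_loci),
    stringsAsFactors = FALSE
  )
}

#' Primer statistics for a whole panel
#'
#' @param x a [band_matrix()].
#' @param system `"RAPD"`, `"ISSR"`, `"SSR"` or `"all"`.
#' @inheritParams primer_summary
#' @return data frame, one row per primer (sorted by primer name).
#' @export
marker_summary <- function(x, system = "all",
                           scheme = c("diploid_hwe", "ploidy_aware"),
                           ploidy = 2) {
  scheme <- match.arg(scheme)
  x <- subset_system(x, system)
  primers <- sort(unique(loci_info(x)$primer))
  do.call(rbind, lapply(primers, primer_summary, x = x,
                        scheme = scheme, ploidy = ploidy))
}

#' Mean row(s) over primer statistics, by marker system
#'
#' Arithmetic means of each statistic across a system's primers; the mean
#' polymorphism percentage averages the per-primer percentages (recomputed
#' from the amplicon counts), while the amplicon columns are averaged as
#' counts.
#'
#' @param stats data frame from [marker_summary()] (or rows of
#'   [primer_summary()]).
#' @return data frame with one mean row per marker system present.
#' @export
panel_summary <- function(stats) {
  if (!nrow(stats)) stop_musadiv("no primer statistics to summarise")
  num <- vapply(stats, is.numeric, TRUE)
  out <- lapply(split(stats, stats$system), function(s) {
    row <- as.data.frame(lapply(s[num], mean))
    row$percent_polymorphism <-
      mean(100 * s$polymorphic_amplicons / s$total_amplicons)
    cbind(data.frame(primer = "Mean", system = s$system[1],
                     stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, names(stats)]
}

#' Aggregate published primer screening counts
#'
#' Summarises a table of per-primer amplicon and locus counts (columns
#' `primer`, `polymorphic`, `total`, `loci`) of the kind reported in
#' marker screening studies: totals and the mean of per-primer
#' polymorphism percentages.
#'
#' @param counts data frame with columns `primer`, `polymorphic`, `total`,
#'   `loci`.
#' @return list with `n_primers`, `total_polymorphic_amplicons`,
#'   `total_amplicons`, `mean_polymorphism_pct`, `total_loci`,
#'   `mean_loci_per_primer`.
#' @export
summarize_primer_counts <- function(counts) {
  need <- c("primer", "polymorphic", "total", "loci")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop_musadiv("counts table missing column(s): ",
                                 paste(miss, collapse = ", "))
  if (any(counts$polymorphic > counts$total))
    stop_musadiv("polymorphic amplicons exceed totals for: ",
                 paste(counts$primer[counts$polymorphic > counts$total],
                       collapse = ", "))
  list(
    n_primers = nrow(counts),
    total_polymorphic_amplicons = sum(counts$polymorphic),
    total_amplicons = sum(counts$total),
    mean_polymorphism_pct = mean(100 * counts$polymorphic / counts$total),
    total_loci = sum(counts$loci),
    mean_loci_per_primer = mean(counts$loci)
  )
}
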