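#' Squared (band-mismatch) distance matrix
#'
#' For dominant 0/1 fingerprints the squared inter-genotype distance is
#' the number of jointly scored loci at which the band scores differ —
#' the squared Euclidean distance on the 0/1 vectors, which is the
#' standard input to AMOVA for binary data.
#'
#' @param x a [band_matrix()] (or plain 0/1 matrix with row names).
#' @return symmetric matrix of mismatch counts, zero diagonal.
#' @export
squared_distance_matrix <- function(x) {
  m <- unclass(x)
  if (nrow(m) < 2) stop_musadiv("need >= 2 genotypes")
  n <- nrow(m)
  if (!anyNA(m)) {
    D2 <- m %*% t(1 - m) + (1 - m) %*% t(m)
  } else {
    D2 <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        keep <- !is.na(m[i, ]) & !is.na(m[j, ])
        if (!any(keep))
          stop_musadiv("genotypes '", rownames(m)[i], "' and '", rownames(m)[j],
                       "' share no scored loci")
        D2[i, j] <- D2[j, i] <- sum(m[i, keep] != m[j, keep])
      }
    }
  }
  dimnames(D2) <- list(rownames(m), rownames(m))
  D2
}

#  SS partition for a one-level AMOVA from a squared-distance matrix.
amova_ss <- function(D2, pop) {
  N <- nrow(D2)
  ut <- upper.tri(D2)
  ss_total <- sum(D2[ut]) / N
  ss_within <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p)
    if (length(idx) > 1) {
      sub <- D2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

phi_from_ss <- function(ss, df_among, df_within, n0) {
  ms_among <- ss["among"] / df_among
  ms_within <- ss["within"] / df_within
  var_within <- unname(ms_within)
  var_among <- unname((ms_among - ms_within) / n0)
  tot <- var_among + var_within
  phi <- if (tot == 0) NA_real_ else var_among / tot
  list(ms_among = unname(ms_among), ms_within = unname(ms_within),
       var_among = var_among, var_within = var_within, phi = phi)
}

#' Phi-ST from variance components
#'
#' \eqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}, the
#' AMOVA-based analogue of F-ST.
#'
#' @param var_among among-population variance component.
#' @param var_within within-population variance component.
#' @return Phi-ST.
#' @export
#' @examples
#' phi_from_components(0.859, 2.876)  # 0.23
phi_from_components <- function(var_among, var_within) {
  var_among / (var_among + var_within)
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions the total squared genetic distance into among- and
#' within-population components (Excoffier-style sums of squares computed
#' from the distance matrix), estimates the variance components via the
#' average sample-size coefficient
#' \eqn{n_0 = (N - \sum n_p^2/N)/(k-1)}, and tests
#' \eqn{\Phi_{ST} = \sigma^2_a/(\sigma^2_a+\sigma^2_w)} by permuting
#' genotype-to-population labels. The permutation p-value uses the
#' add-one estimator \eqn{(1 + \#\{\Phi^* \ge \Phi\})/(1 + n_{perm})}.
#' A negative among component (MS_among < MS_within) is reported as-is,
#' so Phi can be slightly negative for unstructured data.
#'
#' @param D2 squared-distance matrix from [squared_distance_matrix()].
#' @param map a `pop_map` (or a named vector/factor of population labels
#'   in `rownames(D2)` order).
#' @param n_perm number of label permutations (>= 99 for a p-value;
#'   `0` skips the test and reports `p_value = NA`).
#' @param seed optional integer seed for the permutation RNG.
#' @return object of class `amova_result`: the AMOVA `table`
#'   (Source/df/SS/MS), `n0`, variance components, percentages, `phi_st`,
#'   `p_value`, `n_perm`.
#' @export
amova <- function(D2, map, n_perm = 999, seed = NULL) {
  check_square(D2, "squared-distance matrix")
  pop <- pop_labels_for(map, rownames(D2))
  N <- nrow(D2)
  k <- length(unique(pop))
  if (k < 2) stop_musadiv("AMOVA needs >= 2 populations")
  if (n_perm != 0 && n_perm < 99)
    stop_musadiv("use n_perm >= 99 for a permutation p-value (or 0 to skip)")

  ss <- amova_ss(D2, pop)
  df_among <- k - 1
  df_within <- N - k
  if (df_within < 1) stop_musadiv("no within-population degrees of freedom")
  n_p <- table(pop)
  n0 <- (N - sum(n_p^2) / N) / (k - 1)
  est <- phi_from_ss(ss, df_among, df_within, n0)
  phi <- est$phi
  if (is.na(phi)) {
    warning("all genotypes identical: Phi-ST undefined, reported as 0")
    phi <- 0
  }
  if (est$var_among < 0)
    message("note: negative among-population variance component (reported as-is)")

  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(pop)
      pss <- amova_ss(D2, perm)
      pphi <- phi_from_ss(pss, df_among, df_within, n0)$phi
      if (!is.na(pphi) && pphi >= phi) ge <- ge + 1L
    }
    p_value <- (1 + ge) / (1 + n_perm)
  }

  tot_var <- est$var_among + est$var_within
  pct_among <- if (tot_var == 0) 0 else 100 * est$var_among / tot_var
  tab <- data.frame(
    source = c("Among populations", "Within populations", "Total"),
    df = c(df_among, df_within, N - 1),
    SS = unname(c(ss["among"], ss["within"], ss["total"])),
    MS = c(est$ms_among, est$ms_within, NA),
    est_variance = c(est$var_among, est$var_within, tot_var),
    percent = c(pct_among, 100 - pct_among, 100),
    stringsAsFactors = FALSE
  )
  structure(list(
    table = tab, n0 = n0,
    var_among = est$var_among, var_within = est$var_within,
    percent_among = pct_among, percent_within = 100 - pct_among,
    phi_st = phi, p_value = p_value, n_perm = n_perm
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("One-level AMOVA\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 3); tab$MS <- round(tab$MS, 3)
  tab$est_variance <- round(tab$est_variance, 3)
  tab$percent <- round(tab$percent, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("Phi-ST = %.3f", x$phi_st))
  if (!is.na(x$p_value))
    cat(sprintf("  (p = %.4g, %d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

pop_labels_for <- function(map, ids) {
  if (inherits(map, "pop_map") || is.data.frame(map)) {
    idx <- match(ids, map$genotype)
    if (anyNA(idx))
      stop_musadiv("genotype(s) absent from population map: ",
                   paste(ids[is.na(idx)], collapse = ", "))
    as.character(map$population[idx])
  } else {
    pop <- as.character(map)
    if (!is.null(names(map))) pop <- pop[match(ids, names(map))]
    if (length(pop) != length(ids) || anyNA(pop))
      stop_musadiv("population labels do not cover all genotypes")
    pop
  }
}

#' Pairwise Phi-ST between populations
#'
#' Runs [amova()] restricted to each population pair. Pairs involving a
#' singleton population have undefined Phi and are reported as `NA`.
#'
#' @inheritParams amova
#' @return list with `phi` (symmetric matrix, zero diagonal), `p_value`
#'   matrix (when permutations requested), and `undefined_pairs`.
#' @export
pairwise_phist <- function(D2, map, n_perm = 0, seed = NULL) {
  check_square(D2, "squared-distance matrix")
  pop <- pop_labels_for(map, rownames(D2))
  pops <- sort(unique(pop))
  k <- length(pops)
  phi <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  undef <- character(0)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      idx <- which(pop %in% c(pops[i], pops[j]))
      if (sum(pop == pops[i]) < 2 || sum(pop == pops[j]) < 2) {
        phi[i, j] <- phi[j, i] <- NA_real_
        undef <- c(undef, paste(pops[i], pops[j], sep = "-"))
        next
      }
      res <- suppressWarnings(suppressMessages(
        amova(D2[idx, idx, drop = FALSE], map = setNames(pop[idx], rownames(D2)[idx]),
              n_perm = n_perm)
      ))
      phi[i, j] <- phi[j, i] <- res$phi_st
      pmat[i, j] <- pmat[j, i] <- res$p_value
    }
  }
  list(phi = phi, p_value = pmat, undefined_pairs = undef)
}

#' Per-population gene diversity and heterozygosity
#'
#' For dominant band data, allele frequencies within each population are
#' inferred per locus from the band frequency (see
#' [estimate_allele_freqs()]); gene diversity is the locus mean of
#' \eqn{1 - \sum_i p_i^2}, multiplied by the small-sample factor
#' \eqn{n/(n-1)} when the population has \eqn{n \ge 2} members, and
#' heterozygosity is the Lynch-Milligan-style expected value
#' \eqn{2pq} averaged over loci.
#'
#' @param x a [band_matrix()].
#' @param map a `pop_map` covering the matrix genotypes.
#' @param scheme,ploidy passed to the allele-frequency estimator.
#' @return data frame with columns `population`, `n`, `gene_diversity`,
#'   `heterozygosity`, `corrected` (whether the small-sample factor was
#'   applied).
#' @export
population_diversity <- function(x, map,
                                 scheme = c("diploid_hwe", "ploidy_aware"),
                                 ploidy = 2) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(x, "band_matrix"))
  pop <- pop_labels_for(map, rownames(x))
  m <- if (scheme == "diploid_hwe") 2 else ploidy
  out <- lapply(sort(unique(pop)), function(pl) {
    idx <- which(pop == pl)
    sub <- unclass(x)[idx, , drop = FALSE]
    n <- length(idx)
    gd <- he <- numeric(0)
    for (lc in colnames(sub)) {
      cells <- sub[, lc]
      ns <- sum(!is.na(cells))
      if (ns == 0) next  # locus unscored in this population
      pbar <- sum(cells == 1, na.rm = TRUE) / ns
      q <- (1 - pbar)^(1 / m)
      p <- 1 - q
      gd <- c(gd, 1 - (p^2 + q^2))
      he <- c(he, 2 * p * q)
    }
    corr <- n >= 2
    if (!corr)
      warning("population ", pl, " has a single member; ",
              "small-sample correction skipped")
    data.frame(
      population = pl, n = n,
      gene_diversity = mean(gd) * if (corr) n / (n - 1) else 1,
      heterozygosity = mean(he),
      corrected = corr,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
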