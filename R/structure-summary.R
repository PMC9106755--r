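#' Evanno delta-K model-order selection
#'
#' From replicate log-probabilities of external Bayesian clustering runs
#' over a contiguous range of K: per-K mean and sd of LnP(D), the first
#' difference \eqn{L'(K) = \bar L(K) - \bar L(K-1)}, the absolute second
#' difference \eqn{|L''(K)| = |L'(K+1) - L'(K)|}, and
#' \eqn{\Delta K = |L''(K)| / sd(K)}. Delta-K is defined only for
#' interior K with positive sd; K values with zero replicate sd are
#' flagged with `NA`. The optimum is the interior K maximising delta-K.
#'
#' @param runs a `structure_runs` object (see [structure_runs()]).
#' @return data frame of class `delta_k_table` with columns `K`,
#'   `n_reps`, `mean_lnpd`, `sd_lnpd`, `Lp`, `Lpp_abs`, `delta_K`;
#'   attribute `optimum_k` holds the selected K.
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(inherits(runs, "structure_runs"))
  ln <- runs$lnpd
  Ks <- sort(unique(ln$K))
  if (length(Ks) < 4)
    stop_musadiv("delta-K needs >= 4 contiguous K values (>= 3 interior-evaluable)")
  if (any(diff(Ks) != 1))
    stop_musadiv("K values must be contiguous; got ", paste(Ks, collapse = ", "))
  n_reps <- vapply(Ks, function(k) sum(ln$K == k), 0L)
  if (any(n_reps < 2))
    stop_musadiv("need >= 2 replicates per K; offending K: ",
                 paste(Ks[n_reps < 2], collapse = ", "))
  mu <- vapply(Ks, function(k) mean(ln$lnpd[ln$K == k]), 0)
  sdv <- vapply(Ks, function(k) sd(ln$lnpd[ln$K == k]), 0)
  nk <- length(Ks)
  Lp <- c(NA, diff(mu))                        # L'(K), defined for K >= min+1
  Lpp <- c(NA, abs(diff(Lp[-1])), NA)          # |L''(K)|, interior K only
  dK <- Lpp / sdv
  dK[sdv == 0] <- NA
  tab <- data.frame(K = Ks, n_reps = n_reps, mean_lnpd = mu, sd_lnpd = sdv,
                    Lp = Lp, Lpp_abs = Lpp, delta_K = dK)
  opt <- if (all(is.na(dK))) NA_integer_ else Ks[which.max(dK)]
  structure(tab, optimum_k = opt, class = c("delta_k_table", "data.frame"))
}

#' Optimum K from a delta-K table
#'
#' @param x a `delta_k_table` from [evanno_delta_k()].
#' @return the K maximising delta-K.
#' @export
optimum_k <- function(x) attr(x, "optimum_k")

#' Threshold-based membership classification from a Q-matrix
#'
#' Each genotype is assigned to its largest ancestry cluster. With
#' membership threshold `C`, a genotype whose maximum ancestry is below
#' `C` is `unassigned`; otherwise it is `pure` when the maximum reaches
#' `purity_threshold` and `admixture` when it falls between the two.
#' The purity rule is a convention of this package (thresholding on
#' maximum ancestry); `purity_threshold` makes it explicit and tunable.
#'
#' @param Q genotype x cluster ancestry matrix; rows sum to 1 (tolerance
#'   1e-6).
#' @param C membership threshold in (0, 1); default 0.44.
#' @param purity_threshold minimum ancestry for a `pure` call; default 0.7.
#' @return list with `calls` (data frame: `genotype`, `assigned_cluster`,
#'   `max_q`, `status`) and `tally` (cluster x status counts).
#' @export
classify_membership <- function(Q, C = 0.44, purity_threshold = 0.7) {
  if (!is.matrix(Q)) Q <- as.matrix(Q)
  check_q_matrix(Q)
  if (C <= 0 || C >= 1) stop_musadiv("C must lie in (0, 1)")
  cl_names <- colnames(Q) %||% paste0("cluster", seq_len(ncol(Q)))
  assigned <- max.col(Q, ties.method = "first")
  max_q <- Q[cbind(seq_len(nrow(Q)), assigned)]
  status <- ifelse(max_q < C, "unassigned",
                   ifelse(max_q >= purity_threshold, "pure", "admixture"))
  calls <- data.frame(
    genotype = rownames(Q) %||% as.character(seq_len(nrow(Q))),
    assigned_cluster = cl_names[assigned],
    max_q = max_q, status = status, stringsAsFactors = FALSE
  )
  tally <- table(
    cluster = factor(calls$assigned_cluster, levels = cl_names),
    status = factor(calls$status, levels = c("pure", "admixture", "unassigned"))
  )
  list(calls = calls, tally = tally)
}
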