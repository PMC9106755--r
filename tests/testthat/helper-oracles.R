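# Independent brute-force oracles, deliberately written from first
# principles rather than reusing package internals.

# Dice similarity by explicit enumeration over loci.
oracle_dice <- function(a, b) {
  shared <- 0; in_a <- 0; in_b <- 0
  for (k in seq_along(a)) {
    if (is.na(a[k]) || is.na(b[k])) next
    if (a[k] == 1 && b[k] == 1) shared <- shared + 1
    if (a[k] == 1) in_a <- in_a + 1
    if (b[k] == 1) in_b <- in_b + 1
  }
  2 * shared / (in_a + in_b)
}

# UPGMA by the definition: cluster-pair distance is the plain mean of all
# member-pair distances in the ORIGINAL matrix (no incremental update).
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  co <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dd <- mean(D[clusters[[i]], clusters[[j]]])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    ci <- clusters[[best[1]]]; cj <- clusters[[best[2]]]
    co[ci, cj] <- bestd; co[cj, ci] <- bestd
    clusters[[best[1]]] <- c(ci, cj)
    clusters[[best[2]]] <- NULL
  }
  dimnames(co) <- dimnames(D)
  co
}

# AMOVA sums of squares via centroid deviations in band space (valid
# because mismatch counts are squared Euclidean distances on 0/1 data).
oracle_amova_ss <- function(m, pop) {
  centroid <- colMeans(m)
  ss_total <- sum(sweep(m, 2, centroid)^2)
  ss_within <- 0
  for (p in unique(pop)) {
    sub <- m[pop == p, , drop = FALSE]
    ss_within <- ss_within + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# pairwise Euclidean distances among recovered PCoA coordinates
coord_distances <- function(coords) {
  as.matrix(dist(coords))
}

rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    agree <- agree + (same_a == same_b)
    tot <- tot + 1
  }
  unname(agree / tot)
}
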