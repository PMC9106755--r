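#' Shared-band similarity between two fingerprint lanes
#'
#' The shared-amplification-product coefficient
#' \eqn{S = 2a / (n_a + n_b)}, where `a` is the number of bands present in
#' both lanes and `n_a`, `n_b` the band counts of each lane over loci
#' scored in both. This is the Dice / Nei-Li coefficient: joint absences
#' do not contribute. Jaccard and simple-matching alternatives are offered
#' behind `coefficient`; Dice is the default.
#'
#' @param a,b 0/1/NA vectors of equal length.
#' @param coefficient `"dice"` (default), `"jaccard"` or
#'   `"simple_matching"`.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' shared_band_similarity(c(1, 1, 0, 1), c(1, 0, 1, 1))  # 2*2/(3+3)
shared_band_similarity <- function(a, b,
                                   coefficient = c("dice", "jaccard",
                                                   "simple_matching")) {
  coefficient <- match.arg(coefficient)
  if (length(a) != length(b)) stop_musadiv("lanes differ in length")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n11 <- sum(a == 1 & b == 1)
  na1 <- sum(a == 1)
  nb1 <- sum(b == 1)
  switch(coefficient,
    dice = {
      if (na1 + nb1 == 0)
        stop_musadiv("similarity undefined: no bands present in either lane ",
                     "after pairwise exclusion")
      2 * n11 / (na1 + nb1)
    },
    jaccard = {
      u <- na1 + nb1 - n11
      if (u == 0)
        stop_musadiv("similarity undefined: no bands present in either lane ",
                     "after pairwise exclusion")
      n11 / u
    },
    simple_matching = {
      if (length(a) == 0)
        stop_musadiv("similarity undefined: no jointly scored loci")
      (n11 + sum(a == 0 & b == 0)) / length(a)
    }
  )
}

#' Pairwise shared-band similarity matrix
#'
#' @param x a [band_matrix()] (or plain 0/1 matrix with row names).
#' @param system restrict to one marker system (`"all"` for the combined
#'   fingerprint); ignored for plain matrices.
#' @param coefficient see [shared_band_similarity()].
#' @return symmetric similarity matrix with unit diagonal, class
#'   `similarity_matrix`.
#' @export
similarity_matrix <- function(x, system = "all",
                              coefficient = c("dice", "jaccard",
                                              "simple_matching")) {
  coefficient <- match.arg(coefficient)
  if (inherits(x, "band_matrix")) x <- subset_system(x, system)
  m <- unclass(x)
  n <- nrow(m)
  if (n < 2) stop_musadiv("similarity needs >= 2 genotypes")
  S <- diag(1, n)
  dimnames(S) <- list(rownames(m), rownames(m))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <-
        shared_band_similarity(m[i, ], m[j, ], coefficient)
    }
  }
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Distance matrix from a similarity matrix
#'
#' @param S a similarity matrix in `[0, 1]`.
#' @return `1 - S` with class stripped.
#' @export
similarity_to_distance <- function(S) {
  D <- 1 - unclass(S)
  diag(D) <- 0
  D
}

#' UPGMA (average-linkage) clustering with deterministic tie-breaking
#'
#' Iteratively merges the cluster pair with the smallest size-weighted
#' average distance. Ties (within `1e-12`) are broken by the
#' lexicographically smallest pair of cluster labels, where a cluster is
#' labelled by its alphabetically first member; the result is therefore
#' independent of input row order. Heights are the full merge distances
#' (cophenetic convention); [write_newick()] halves them into branch
#' lengths.
#'
#' @param D symmetric distance matrix with zero diagonal (typically
#'   `1 - S` from [similarity_matrix()]), or a `dist` object.
#' @return an object of class `hclust` (so [stats::cophenetic()],
#'   [stats::cutree()] and plotting work as usual).
#' @export
upgma <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  check_square(D, "distance matrix")
  if (any(D < 0)) stop_musadiv("distance matrix has negative entries")
  if (max(abs(diag(D))) > 1e-12) stop_musadiv("distance matrix diagonal must be zero")
  n <- nrow(D)
  labs <- rownames(D) %||% as.character(seq_len(n))
  if (n < 2) stop_musadiv("need >= 2 items to cluster")

  d <- D; diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  key <- labs                 # lexicographic cluster label = smallest member
  node <- -seq_len(n)         # hclust ids: negative leaves, positive merges
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best_i <- best_j <- 0L; best_d <- Inf; best_key <- NULL
    for (ai in seq_along(idx)) {
      i <- idx[ai]
      for (aj in seq_along(idx)) {
        j <- idx[aj]
        if (j <= i) next
        dij <- d[i, j]
        if (dij > best_d + 1e-12) next
        k <- sort(c(key[i], key[j]))
        take <- dij < best_d - 1e-12 ||
          is.null(best_key) ||
          k[1] < best_key[1] ||
          (k[1] == best_key[1] && k[2] < best_key[2])
        if (take) {
          best_i <- i; best_j <- j; best_d <- dij; best_key <- k
        }
      }
    }
    i <- best_i; j <- best_j
    # children ordered by cluster label so serialized trees are deterministic
    merge[step, ] <- if (key[i] <= key[j]) c(node[i], node[j]) else c(node[j], node[i])
    height[step] <- best_d
    # size-weighted average linkage update, stored in slot i
    others <- setdiff(which(active), c(i, j))
    if (length(others)) {
      d[i, others] <- d[others, i] <-
        (size[i] * d[i, others] + size[j] * d[j, others]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    node[i] <- step
    active[j] <- FALSE
  }

  out <- list(
    merge = merge, height = height,
    order = hclust_leaf_order(merge, n),
    labels = labs, method = "average",
    call = match.call(), dist.method = "user"
  )
  class(out) <- "hclust"
  out
}

#  Leaf ordering by left-to-right traversal of the merge tree.
hclust_leaf_order <- function(merge, n) {
  walk <- function(id) {
    if (id < 0) return(-id)
    c(walk(merge[id, 1]), walk(merge[id, 2]))
  }
  walk(nrow(merge))
}

#' Cut a dendrogram at a similarity level
#'
#' Genotypes are grouped together when their cophenetic distance is at
#' most `1 - s`; at `s = 1` only exact duplicates (merged at height 0)
#' share a group, and at `s = 0` all leaves form one group.
#'
#' @param tree an `hclust` tree on distances `1 - S`.
#' @param s similarity level in `[0, 1]`.
#' @return named integer vector of group memberships (as [stats::cutree()]).
#' @export
cut_at_similarity <- function(tree, s) {
  stopifnot(inherits(tree, "hclust"), s >= 0, s <= 1)
  cutree(tree, h = (1 - s) + 1e-12)
}

#' Cophenetic correlation of a dendrogram with its source distances
#'
#' Pearson correlation between the tree's cophenetic distances and the
#' original distance matrix over the upper triangle; 1 means the tree
#' represents the distances perfectly (exactly ultrametric input).
#'
#' @param tree an `hclust` tree.
#' @param D the distance matrix the tree was built from.
#' @return correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  check_square(D, "distance matrix")
  co <- as.matrix(cophenetic(tree))
  co <- co[rownames(D), colnames(D)]
  x <- D[upper.tri(D)]
  y <- co[upper.tri(co)]
  if (sd(x) == 0 || sd(y) == 0)
    stop_musadiv("cophenetic correlation undefined for constant distances")
  cor(x, y)
}
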