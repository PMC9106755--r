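#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centres the squared distances (Gower transformation
#' \eqn{B = -\frac12 J D^2 J}), eigendecomposes `B`, and returns
#' coordinates scaled by the square roots of the positive eigenvalues.
#' Shared-band distances are generally non-Euclidean, so negative
#' eigenvalues can arise; they are reported but excluded from the
#' coordinates and from the variance-explained denominator (standard
#' Gower treatment, keeping cumulative percentages at 100). Each axis's
#' sign is fixed so that its largest-magnitude loading is positive.
#'
#' @param D symmetric distance matrix with zero diagonal (or `dist`).
#' @param axes maximum number of axes to return (default: all positive).
#' @param tol eigenvalues with absolute value below `tol * max(|eigen|)`
#'   are treated as zero.
#' @return list of class `pcoa_result`: `coordinates` (genotype x axis),
#'   `eigenvalues` (all, descending), `percent_variance` and
#'   `cumulative_percent` (per positive axis), `negative_eigenvalues`.
#' @export
pcoa <- function(D, axes = NULL, tol = 1e-8) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  check_square(D, "distance matrix")
  if (max(abs(diag(D))) > 1e-12) stop_musadiv("distance matrix diagonal must be zero")
  n <- nrow(D)
  labs <- rownames(D) %||% as.character(seq_len(n))
  A <- -0.5 * D^2
  # Gower double-centering: B = J A J with J = I - 11'/n
  B <- sweep(A, 1, rowMeans(A))
  B <- sweep(B, 2, colMeans(B))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  cutoff <- tol * max(abs(ev), 1e-300)
  pos <- which(ev > cutoff)
  if (!length(pos)) stop_musadiv("no positive eigenvalues: degenerate configuration")
  k <- if (is.null(axes)) length(pos) else min(axes, length(pos))
  use <- pos[seq_len(k)]
  coords <- e$vectors[, use, drop = FALSE] %*% diag(sqrt(ev[use]), k)
  # deterministic axis orientation
  for (j in seq_len(k)) {
    imax <- which.max(abs(coords[, j]))
    if (coords[imax, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(labs, paste0("axis", seq_len(k)))
  pos_sum <- sum(ev[pos])
  pct <- 100 * ev[pos] / pos_sum
  structure(list(
    coordinates = coords,
    eigenvalues = ev,
    positive_eigenvalues = ev[pos],
    percent_variance = pct,
    cumulative_percent = cumsum(pct),
    negative_eigenvalues = ev[ev < -cutoff]
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3, length(x$percent_variance))
  cat("pcoa_result:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "axes returned\n")
  cat("variance explained (first", k, "axes):",
      paste0(sprintf("%.1f%%", x$percent_variance[seq_len(k)]), collapse = ", "),
      sprintf("(cumulative %.1f%%)\n", x$cumulative_percent[k]))
  if (length(x$negative_eigenvalues))
    cat("negative eigenvalues (non-Euclidean input):",
        length(x$negative_eigenvalues), "\n")
  invisible(x)
}
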