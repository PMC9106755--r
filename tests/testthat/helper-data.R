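# In-code fixture builders shared across test files.

make_bm <- function(values, genotypes = NULL, loci = NULL) {
  m <- as.matrix(values)
  if (!is.null(genotypes)) rownames(m) <- genotypes
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (!is.null(loci)) colnames(m) <- loci
  if (is.null(colnames(m)))
    colnames(m) <- paste0("P1|RAPD|b", seq_len(ncol(m)))
  band_matrix(m)
}

random_bm <- function(n, l, seed, p = 0.5, missing = 0) {
  set.seed(seed)
  m <- matrix(rbinom(n * l, 1, p), n, l,
              dimnames = list(sprintf("g%02d", 1:n),
                              paste0("P1|RAPD|b", 1:l)))
  if (missing > 0) m[runif(n * l) < missing] <- NA
  band_matrix(m)
}

# symmetric random distance matrix with zero diagonal, continuous entries
random_distance <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 2), n, 2)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(LETTERS[1:n], LETTERS[1:n])
  D
}

extdata <- function(f) system.file("extdata", f, package = "musadiv")
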