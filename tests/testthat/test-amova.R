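test_that("squared distance is the band-mismatch count", {
  bm <- make_bm(rbind(c(1, 0, 1), c(0, 0, 1), c(1, 0, 1)))
  D2 <- squared_distance_matrix(bm)
  expect_equal(D2[1, 2], 1)
  expect_equal(D2[1, 3], 0)
  bm2 <- random_bm(5, 8, seed = 17, missing = 0.1)
  D2b <- squared_distance_matrix(bm2)
  m <- unclass(bm2)
  for (i in 1:4) for (j in (i + 1):5) {
    keep <- !is.na(m[i, ]) & !is.na(m[j, ])
    expect_equal(D2b[i, j], sum(m[i, keep] != m[j, keep]))
  }
})

test_that("AMOVA SS partition matches the centroid-deviation oracle on small panels", {
  for (seed in 1:5) {
    bm <- random_bm(8, 12, seed = 400 + seed)
    pop <- rep(c("p1", "p2"), each = 4)
    names(pop) <- rownames(bm)
    res <- suppressMessages(amova(squared_distance_matrix(bm), pop, n_perm = 0))
    ss <- oracle_amova_ss(unclass(bm), pop)
    expect_equal(res$table$SS, unname(ss[c("among", "within", "total")]),
                 tolerance = 1e-8)
  }
})

test_that("AMOVA SS partition agrees with vegan::adonis2 on the same distances", {
  skip_if_not_installed("vegan")
  bm <- random_bm(12, 30, seed = 55)
  pop <- factor(rep(c("a", "b", "c"), each = 4))
  D2 <- squared_distance_matrix(bm)
  res <- suppressMessages(amova(D2, setNames(as.character(pop), rownames(bm)),
                                n_perm = 0))
  ad <- vegan::adonis2(as.dist(sqrt(D2)) ~ pop, permutations = 0)
  expect_equal(res$table$SS[1], ad$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(res$table$SS[2], ad$SumOfSqs[2], tolerance = 1e-8)
})

test_that("published variance components give Phi = 0.23 with a 23/77 partition", {
  expect_equal(round(phi_from_components(0.859, 2.876), 2), 0.23)
  expect_equal(round(100 * 0.859 / (0.859 + 2.876), 0), 23)
})

test_that("complete between-population differentiation gives Phi = 1", {
  m <- rbind(matrix(1L, 3, 6), matrix(0L, 3, 6))
  rownames(m) <- paste0("g", 1:6)
  colnames(m) <- paste0("P1|RAPD|b", 1:6)
  pop <- setNames(rep(c("A", "B"), each = 3), rownames(m))
  res <- amova(squared_distance_matrix(band_matrix(m)), pop, n_perm = 0)
  expect_equal(res$phi_st, 1)
  expect_equal(res$percent_among, 100)
})

test_that("unstructured data with random labels gives Phi near zero and calibrated p-values", {
  phis <- numeric(20); ps <- numeric(20)
  for (s in 1:20) {
    bm <- random_bm(24, 40, seed = 900 + s)
    set.seed(s)
    pop <- setNames(sample(rep(c("a", "b", "c"), each = 8)), rownames(bm))
    res <- suppressMessages(
      amova(squared_distance_matrix(bm), pop, n_perm = 99, seed = s))
    phis[s] <- res$phi_st; ps[s] <- res$p_value
  }
  expect_lt(abs(mean(phis)), 0.05)
  expect_gt(mean(ps), 0.2)  # no spurious significance under the null
})

test_that("permutation p-value is reproducible bit-exactly under a fixed seed", {
  sim <- simulate_structured_bands(sizes = c(6, 6), fst = 0.3,
    primers = data.frame(name = "P1", system = "RAPD", n_loci = 50),
    ploidy = 2, seed = 3)
  D2 <- squared_distance_matrix(sim$matrix)
  r1 <- amova(D2, sim$map, n_perm = 199, seed = 10)
  r2 <- amova(D2, sim$map, n_perm = 199, seed = 10)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
})

test_that("conservation: SS additivity, df partition and percentages hold on arbitrary input", {
  sim <- simulate_structured_bands(sizes = c(5, 7, 4), fst = 0.2,
    primers = data.frame(name = "P1", system = "ISSR", n_loci = 40),
    ploidy = c(rep(2, 8), rep(3, 8)), seed = 77)
  res <- amova(squared_distance_matrix(sim$matrix), sim$map, n_perm = 0)
  tab <- res$table
  expect_equal(tab$SS[1] + tab$SS[2], tab$SS[3], tolerance = 1e-8)
  expect_equal(tab$df[1] + tab$df[2], tab$df[3])
  expect_equal(tab$df[3], 15)
  expect_equal(tab$percent[1] + tab$percent[2], 100, tolerance = 1e-6)
  expect_equal(tab$MS[1:2], tab$SS[1:2] / tab$df[1:2])
})

test_that("pairwise Phi-ST is symmetric, zero for identical populations, NA for singletons", {
  m <- rbind(matrix(c(1L, 0L), 4, 6), matrix(c(1L, 0L), 4, 6),
             matrix(1L, 1, 6))
  rownames(m) <- paste0("g", 1:9)
  colnames(m) <- paste0("P1|RAPD|b", 1:6)
  pop <- setNames(c(rep("A", 4), rep("B", 4), "C"), rownames(m))
  D2 <- squared_distance_matrix(band_matrix(m))
  pw <- suppressMessages(pairwise_phist(D2, pop))
  expect_equal(pw$phi, t(pw$phi))
  expect_lte(pw$phi["A", "B"], 0)  # identical composition: no differentiation
  expect_true(is.na(pw$phi["A", "C"]))
  expect_true("A-C" %in% pw$undefined_pairs)

  sim <- simulate_structured_bands(sizes = c(8, 8, 8), fst = 0.3,
    primers = data.frame(name = "P1", system = "RAPD", n_loci = 100),
    ploidy = 2, seed = 5)
  pw2 <- pairwise_phist(squared_distance_matrix(sim$matrix), sim$map)
  expect_equal(unname(diag(pw2$phi)), rep(0, 3))
  expect_true(all(pw2$phi[upper.tri(pw2$phi)] > 0))
})

test_that("population diversity: fixed loci give zero; equifrequent alleles approach 0.5", {
  m <- cbind(rep(1L, 6), rep(1L, 6), rep(0L, 6))
  rownames(m) <- paste0("g", 1:6)
  colnames(m) <- paste0("P1|RAPD|b", 1:3)
  map <- data.frame(genotype = rownames(m), population = rep(c("A", "B"), 3))
  pd <- population_diversity(band_matrix(m), map)
  expect_equal(pd$gene_diversity, c(0, 0))
  expect_equal(pd$heterozygosity, c(0, 0))

  # many genotypes, band frequency 0.75 -> p = q = 0.5 -> 2pq = 0.5
  set.seed(2)
  n <- 4000
  m2 <- matrix(rbinom(n, 1, 0.75), n, 1,
               dimnames = list(sprintf("g%04d", 1:n), "P1|RAPD|b1"))
  map2 <- data.frame(genotype = rownames(m2), population = "A")
  pd2 <- population_diversity(band_matrix(m2), map2)
  expect_equal(pd2$heterozygosity, 0.5, tolerance = 0.02)
  expect_equal(pd2$gene_diversity, 0.5, tolerance = 0.02)
  expect_true(pd2$corrected)
})

test_that("Phi-ST recovers the simulated differentiation and orders nested divergence", {
  # three populations at divergence F = 0.1 vs 0.3 from the ancestral pool
  lows <- numeric(10); highs <- numeric(10)
  for (s in 1:10) {
    base <- data.frame(name = "P1", system = "RAPD", n_loci = 150)
    lo <- simulate_structured_bands(sizes = c(15, 15), fst = 0.1,
                                    primers = base, ploidy = 1, seed = 6000 + s)
    hi <- simulate_structured_bands(sizes = c(15, 15), fst = 0.3,
                                    primers = base, ploidy = 1, seed = 7000 + s)
    lows[s] <- amova(squared_distance_matrix(lo$matrix), lo$map, n_perm = 0)$phi_st
    highs[s] <- amova(squared_distance_matrix(hi$matrix), hi$map, n_perm = 0)$phi_st
  }
  expect_lt(mean(lows), mean(highs))
  expect_equal(mean(lows), 0.1, tolerance = 0.05)
  expect_equal(mean(highs), 0.3, tolerance = 0.05)
})
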