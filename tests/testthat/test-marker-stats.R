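test_that("allele frequencies follow the dominant null-root estimator", {
  bm <- make_bm(matrix(c(1, 1, 1, 0), 4, 1))
  fr <- estimate_allele_freqs(bm, colnames(bm)[1])  # band freq 0.75
  expect_equal(fr$q, 0.5)
  expect_equal(fr$p, 0.5)
  expect_equal(fr$n_scored, 4)

  # boundary: band never seen
  bm0 <- make_bm(matrix(0, 3, 1))
  fr0 <- estimate_allele_freqs(bm0, colnames(bm0)[1])
  expect_equal(fr0$q, 1)
  expect_equal(fr0$p, 0)

  # ploidy-aware: cube root of the absence frequency
  bm3 <- make_bm(matrix(c(rep(1, 7), 0), 8, 1))  # band freq 0.875
  fr3 <- estimate_allele_freqs(bm3, colnames(bm3)[1],
                               scheme = "ploidy_aware", ploidy = 3)
  expect_equal(fr3$q, 0.5, tolerance = 1e-12)

  # missing cells are excluded locus-wise
  bmna <- make_bm(matrix(c(1, NA, 0, 1), 4, 1))
  expect_equal(estimate_allele_freqs(bmna, colnames(bmna)[1])$n_scored, 3)
})

test_that("locus diversity statistics match the footnote formulas", {
  d <- locus_diversity(0.5, 20)
  expect_equal(d$Ne, 2)
  expect_equal(d$I, log(2))
  expect_equal(d$He, 0.5)
  expect_equal(d$uHe, 40 / 39 * 0.5)

  fixed <- locus_diversity(1, 10)
  expect_equal(fixed$Na, 1)
  expect_equal(fixed$Ne, 1)
  expect_equal(fixed$I, 0)
  expect_equal(fixed$He, 0)
  expect_equal(fixed$uHe, 0)

  d8 <- locus_diversity(0.8, 10)
  expect_equal(d8$Ne, 1 / 0.68, tolerance = 1e-4)
  expect_equal(d8$I, -(0.8 * log(0.8) + 0.2 * log(0.2)), tolerance = 1e-12)
  expect_equal(round(d8$I, 4), 0.5004)
  expect_equal(d8$He, 0.32)
  expect_equal(d8$uHe, 20 / 19 * 0.32, tolerance = 1e-12)
  expect_equal(round(d8$uHe, 4), 0.3368)
})

test_that("dominant PIC is 2p(1-p) with the expected ceiling", {
  expect_equal(pic_dominant(0.5), 0.5)
  expect_equal(pic_dominant(0), 0)
  expect_equal(pic_dominant(1), 0)
  expect_equal(pic_dominant(0.7), 0.42)
  # property: never exceeds 0.5
  expect_true(all(pic_dominant(seq(0, 1, 0.01)) <= 0.5))
})

test_that("primer amplicon accounting reproduces the published pattern of a mostly polymorphic primer", {
  # 20 genotypes, 8 loci, one locus fixed-present, the others carrying 94
  # presence calls in total: 94/114 amplicons polymorphic, 82.46%, 4.70
  # polymorphic bands per genotype.
  set.seed(5)
  n <- 20
  poly <- matrix(0L, n, 7)
  target <- c(14, 14, 14, 14, 14, 12, 12)  # 94 ones, each locus polymorphic
  for (j in 1:7) poly[sample(n, target[j]), j] <- 1L
  m <- cbind(poly, 1L)
  colnames(m) <- paste0("OPA-13|RAPD|b", 1:8)
  rownames(m) <- sprintf("g%02d", 1:n)
  st <- primer_summary(band_matrix(m), "OPA-13")
  expect_equal(st$polymorphic_amplicons, 94)
  expect_equal(st$total_amplicons, 114)
  expect_equal(round(st$percent_polymorphism, 2), 82.46)
  expect_equal(round(st$avg_polymorphic_bands_per_genotype, 2), 4.70)
  expect_equal(st$total_loci, 8)
})

test_that("resolving power and marker index follow the band-informativeness definitions", {
  # single all-present locus: no polymorphism, I_b = 1 - 2*0.5 = 0
  bm1 <- make_bm(matrix(1, 5, 1))
  st1 <- primer_summary(bm1, "P1")
  expect_equal(st1$percent_polymorphism, 0)
  expect_equal(st1$RP, 0)
  expect_equal(st1$MI, 0)

  # two loci at band frequency 0.5: RP = 2, mean PIC = 0.5, EMR = 2*(2/2)
  bm2 <- make_bm(matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2))
  st2 <- primer_summary(bm2, "P1")
  expect_equal(st2$RP, 2)
  expect_equal(st2$PIC, 0.5)
  expect_equal(st2$MI, 0.5 * 2 * (2 / 2))
})

test_that("marker summaries are invariant to genotype and locus reordering", {
  bm <- random_bm(12, 20, seed = 31, missing = 0.05)
  st <- primer_summary(bm, "P1")
  m <- unclass(bm)
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  st2 <- primer_summary(band_matrix(perm), "P1")
  for (cl in c("percent_polymorphism", "total_amplicons", "PIC", "He", "RP", "MI"))
    expect_equal(st2[[cl]], st[[cl]])
})

test_that("panel means over published screening counts reproduce the reported aggregates", {
  rapd <- summarize_primer_counts(read.csv(extdata("rapd_primer_counts.csv")))
  expect_equal(rapd$total_polymorphic_amplicons, 725)
  expect_equal(rapd$total_loci, 75)
  expect_equal(round(rapd$mean_polymorphism_pct, 2), 89.97)
  issr <- summarize_primer_counts(read.csv(extdata("issr_primer_counts.csv")))
  expect_equal(issr$total_loci, 69)
  expect_equal(round(issr$mean_loci_per_primer, 2), 6.27)
  expect_equal(round(issr$mean_polymorphism_pct, 2), 79.62)
})

test_that("panel_summary averages primers within marker system; single primer is its own mean", {
  bm <- random_bm(10, 6, seed = 7)
  st <- marker_summary(bm)
  mean_row <- panel_summary(st)
  expect_equal(nrow(mean_row), 1)
  expect_equal(mean_row$PIC, st$PIC)
  expect_equal(mean_row$percent_polymorphism, st$percent_polymorphism)
})

test_that("He <= uHe with equality only at zero (invariant)", {
  for (p in seq(0, 1, 0.1)) {
    for (N in c(1, 2, 5, 20)) {
      d <- locus_diversity(p, N)
      expect_gte(d$uHe, d$He)
      if (d$He > 0 && N >= 1) expect_gt(d$uHe, d$He)
    }
  }
})

test_that("mean He over simulated loci tracks the generator's expected band heterozygosity", {
  sim <- simulate_structured_bands(sizes = c(60, 60), fst = 0,
    primers = data.frame(name = "P1", system = "RAPD", n_loci = 200),
    ploidy = 2, seed = 99)
  st <- primer_summary(sim$matrix, "P1")
  # expected He = E[2 p q] with q = sqrt((1-p0)^2) = 1 - p0 at F = 0
  pband <- 1 - (1 - sim$truth$p0)^2
  q <- sqrt(1 - pband)
  expect_equal(st$He, mean(2 * (1 - q) * q), tolerance = 0.03)
})
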