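ladder2 <- function(carbons, rts) alkane_ladder(data.frame(carbon = carbons, rt_min = rts))

test_that("Kovats retention index interpolates linearly and hits anchors exactly", {
  lad <- ladder2(8:9, c(10, 12))
  expect_equal(kovats_ri(11, lad), 850)
  lad10 <- ladder2(8:11, c(10, 12, 14, 16))
  expect_equal(kovats_ri(14, lad10), 1000)   # exactly at C10
  lad1213 <- ladder2(12:13, c(20, 23))
  expect_equal(kovats_ri(21.2, lad1213), 1240)
  expect_error(kovats_ri(9, lad), "outside")
  expect_error(ladder2(c(8, 9), c(12, 10)), "strictly increasing")
  # strictly increasing in rt, exact at every anchor
  lad_full <- ladder2(8:20, cumsum(c(5, runif(12, 2, 5))))
  rts <- seq(min(lad_full$rt_min), max(lad_full$rt_min), length.out = 101)
  ri <- kovats_ri(rts, lad_full)
  expect_true(all(diff(ri) > 0))
  expect_equal(kovats_ri(lad_full$rt_min, lad_full), 100 * (8:20))
})

test_that("RI matching reports signed deltas against a tolerance window", {
  res <- match_compound(785, 781, tolerance = 15)
  expect_true(res$match)
  expect_equal(res$delta, 4)
  expect_true(match_compound(900, 900)$match)
  expect_false(match_compound(1000, 900, tolerance = 15)$match)
})

test_that("the packaged volatile table reproduces the published composition", {
  vt <- read_volatile_table(extdata("banana_volatiles.csv"))
  comp <- class_composition(vt)
  expect_equal(comp$total_compounds, 54)
  expect_equal(unname(comp$percent_rounded["ester"]), 56)
  expect_equal(unname(as.integer(comp$counts["ester"])), 30)
  expect_equal(sum(comp$percent), 100)          # exact percents sum to 100
  expect_equal(unname(comp$percent_rounded["carboxylic acid"]), 2)

  cc <- cultivar_counts(vt)
  expect_equal(unname(cc$totals["Borkal Baista"]), 29)
  expect_equal(unname(cc$totals["Birbutia"]), 16)
  expect_equal(unname(cc$by_class["Borkal Baista", "ester"]), 18)
  expect_equal(unname(cc$ester_share_pct["Grand Nain"]), 78)
  expect_equal(length(cc$total_mismatches), 0)  # matches the stored totals row
})

test_that("totals cross-check reports (not repairs) disagreement with a stored totals row", {
  vt <- read_volatile_table(extdata("banana_volatiles.csv"))
  tot <- attr(vt, "reported_totals")
  tot["Ankur"] <- tot["Ankur"] + 1
  attr(vt, "reported_totals") <- tot
  expect_warning(cc <- cultivar_counts(vt), "Ankur")
  expect_equal(cc$total_mismatches, "Ankur")
  expect_equal(unname(cc$totals["Ankur"]), 23)  # computed value untouched
})

test_that("single-compound and degenerate tables behave", {
  df <- data.frame(sr = 1, chemical_class = "ketone", rt_min = 10,
                   compound = "x", reference_ri = 900, experimental_ri = 905,
                   cv1 = 1, cv2 = 0)
  vt <- volatile_table(df)
  comp <- class_composition(vt)
  expect_equal(unname(comp$percent["ketone"]), 100)
  cc <- cultivar_counts(vt)
  expect_equal(unname(cc$totals), c(1, 0))
  expect_error(volatile_table(transform(df, chemical_class = "terpene")),
               "unknown chemical class")
})

test_that("cultivar clustering by volatiles matches the Dice+UPGMA oracle and ignores all-absent compounds", {
  vt <- read_volatile_table(extdata("banana_volatiles.csv"))
  tree <- cultivar_volatile_clustering(vt)
  cultivars <- attr(vt, "cultivars")
  m <- t(as.matrix(as.data.frame(vt)[, cultivars]))
  D <- matrix(0, 9, 9, dimnames = list(cultivars, cultivars))
  for (i in 1:8) for (j in (i + 1):9)
    D[i, j] <- D[j, i] <- 1 - oracle_dice(m[i, ], m[j, ])
  co <- as.matrix(cophenetic(tree))
  co_oracle <- oracle_upgma_cophenetic(D)
  expect_lt(max(abs(co - co_oracle[rownames(co), colnames(co)])), 1e-10)

  # a compound absent everywhere changes nothing (joint-absence invariance)
  df2 <- as.data.frame(vt)
  extra <- df2[1, ]; extra$sr <- 99; extra$compound <- "ghost"
  extra[cultivars] <- 0
  vt2 <- volatile_table(rbind(df2, extra))
  expect_equal(as.matrix(cophenetic(cultivar_volatile_clustering(vt2))), co)

  # identical profiles merge at height zero
  df3 <- df2[, c("sr", "chemical_class", "rt_min", "compound",
                 "reference_ri", "experimental_ri", "Rajeli", "Ankur")]
  df3$Twin <- df3$Rajeli
  tr3 <- cultivar_volatile_clustering(volatile_table(df3))
  expect_equal(as.matrix(cophenetic(tr3))["Rajeli", "Twin"], 0)
})

test_that("simulated volatile tables are seeded, ladder-consistent, and hit the requested sizes", {
  sim <- simulate_volatile_table(seed = 8)
  expect_equal(nrow(sim$table), 54)
  comp <- class_composition(sim$table)
  expect_equal(unname(comp$percent_rounded["ester"]), 56)
  # experimental RI recomputes from the ladder
  expect_equal(sim$table$experimental_ri,
               round(kovats_ri(sim$table$rt_min, sim$ladder), 1))
  sim2 <- simulate_volatile_table(seed = 8)
  expect_identical(as.data.frame(sim$table), as.data.frame(sim2$table))
  # presence_prob = 1 marks every compound present in every cultivar
  simall <- simulate_volatile_table(cultivars = c("a", "b"),
                                    presence_prob = 1, seed = 2)
  cc <- cultivar_counts(simall$table)
  expect_equal(unname(cc$totals), c(54, 54))
})
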