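#  Seeded generators with the statistical structure the downstream
#  analyses assume: Balding-Nichols structured band frequencies, kinked
#  LnP(D) curves for model-order selection, and volatile tables with a
#  calibrated alkane ladder.

#' Default primer panel for simulations
#'
#' 11 RAPD and 11 ISSR primers with the published per-primer locus counts
#' of a 34-primer banana screening panel, plus 12 SSR primers with 1-5
#' band loci each, giving a mixed dominant panel of realistic size.
#'
#' @return data frame with columns `name`, `system`, `n_loci`.
#' @export
default_primer_panel <- function() {
  rbind(
    data.frame(name = c("OPC-08", "OPA-10", "OPA-11", "OPA-12", "OPA-13",
                        "OPA-17", "OPA-18", "OPD-15", "OPD-20", "OPD-18",
                        "OPN-02"),
               system = "RAPD",
               n_loci = c(6, 7, 5, 6, 8, 7, 5, 5, 8, 10, 8)),
    data.frame(name = c("ISSR-815", "ISSR-818", "ISSR-822", "ISSR-827",
                        "ISSR-825", "ISSR-841", "ISSR-857", "UBC-810",
                        "UBC-820", "UBC-826", "UBC-858"),
               system = "ISSR",
               n_loci = c(8, 8, 7, 7, 5, 6, 6, 9, 5, 5, 3)),
    data.frame(name = c("CNMPF-8", "CNMPF-9", "CNMPF-10", "CNMPF-12",
                        "CNMPF-13", "CNMPF-16", "CNMPF-19", "CNMPF-21",
                        "Ma-1-16", "Ma-3-2", "Ma-3-103", "Agmi-93-94"),
               system = "SSR",
               n_loci = c(3, 3, 2, 1, 4, 1, 5, 1, 2, 1, 2, 2))
  )
}

#' Simulate a structured dominant fingerprint panel
#'
#' Balding-Nichols model: each locus has an ancestral band-allele
#' frequency \eqn{p_0 \sim U(0.1, 0.9)}; each population draws its own
#' frequency \eqn{p_k \sim Beta(p_0 (1-F)/F,\ (1-p_0)(1-F)/F)}, so `F`
#' is the expected differentiation (at `F = 0`, \eqn{p_k = p_0}
#' exactly). A genotype of ploidy `m` shows the band when at least one of
#' its `m` allele copies carries it: presence probability
#' \eqn{1 - (1-p_k)^m} (dominant expression). One seed drives all draws.
#'
#' @param sizes integer vector of population sizes (each >= 2); the
#'   number of populations is `length(sizes)`. Default `c(5, 5, 5, 5)`:
#'   a 20-genotype panel in 4 subpopulations.
#' @param primers data frame `name`/`system`/`n_loci`
#'   (default [default_primer_panel()]).
#' @param fst target differentiation F in `[0, 0.95)`; default 0.23.
#' @param ploidy either a single value for all genotypes or a vector of
#'   length `sum(sizes)` over `{1, 2, 3, 4}`. Default samples genome
#'   groups AA/AB/AAA/AAB/ABB/AAAB. `ploidy = 1` expresses each band
#'   directly from one allele copy (codominant-equivalent scoring), under
#'   which band-level Phi-ST estimates the allele-level `F`; at ploidy
#'   `>= 2` dominant masking inflates band-frequency differentiation
#'   above `F`.
#' @param missing_rate per-cell missing probability (default 0).
#' @param seed integer seed; the run is fully reproducible from it.
#' @return list with `matrix` (a [band_matrix()]), `map` (a `pop_map`)
#'   and `truth` (a `simulation_truth` list: `seed`, `fst`, `p0`, `p_k`
#'   per population x locus, assignments, ploidy).
#' @export
simulate_structured_bands <- function(sizes = c(5, 5, 5, 5),
                                      primers = default_primer_panel(),
                                      fst = 0.23,
                                      ploidy = NULL,
                                      missing_rate = 0,
                                      seed = 1) {
  if (any(sizes < 2)) stop_musadiv("every population size must be >= 2")
  if (fst < 0 || fst >= 0.95)
    stop_musadiv("fst must lie in [0, 0.95): Beta parameters degenerate beyond")
  if (any(primers$n_loci < 1)) stop_musadiv("every primer needs >= 1 locus")
  set.seed(seed)

  n_pops <- length(sizes)
  N <- sum(sizes)
  pop_names <- paste0("SP", seq_len(n_pops))
  assignment <- rep(pop_names, sizes)
  genotype_ids <- sprintf("G%02d_%s", seq_len(N), assignment)

  genome_groups <- c("AA", "AB", "AAA", "AAB", "ABB", "AAAB")
  if (is.null(ploidy)) {
    gg <- sample(genome_groups, N, replace = TRUE,
                 prob = c(1, 2, 3, 6, 5, 1) / 18)  # triploid-heavy, like field panels
    ploidy <- nchar(gg)
  } else {
    if (length(ploidy) == 1) ploidy <- rep(ploidy, N)
    if (length(ploidy) != N) stop_musadiv("ploidy must have length 1 or sum(sizes)")
    if (any(!ploidy %in% 1:4)) stop_musadiv("ploidy values must be in 1..4")
    gg <- vapply(ploidy, function(m) paste(rep("A", m), collapse = ""), "")
  }

  loci <- do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
    data.frame(primer = primers$name[i], system = primers$system[i],
               band = paste0("b", seq_len(primers$n_loci[i])))
  }))
  locus_ids <- paste(loci$primer, loci$system, loci$band, sep = "|")
  L <- nrow(loci)

  p0 <- runif(L, 0.1, 0.9)
  if (fst == 0) {
    p_k <- matrix(rep(p0, each = n_pops), n_pops, L)
  } else {
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    p_k <- matrix(rbeta(n_pops * L, rep(a, each = n_pops), rep(b, each = n_pops)),
                  n_pops, L)
    # keep frequencies off the exact boundary so every locus stays usable
    p_k <- pmin(pmax(p_k, 1e-9), 1 - 1e-9)
  }
  rownames(p_k) <- pop_names

  pop_idx <- match(assignment, pop_names)
  pres_prob <- 1 - (1 - p_k[pop_idx, , drop = FALSE])^ploidy
  m <- matrix(rbinom(N * L, 1, pres_prob), N, L,
              dimnames = list(genotype_ids, locus_ids))
  if (missing_rate > 0) {
    drop <- matrix(runif(N * L) < missing_rate, N, L)
    m[drop] <- NA
    # guarantee each locus keeps at least one scored cell
    empty <- colSums(!is.na(m)) == 0
    m[1, empty] <- rbinom(sum(empty), 1, pres_prob[1, empty])
  }

  map <- data.frame(
    genotype = genotype_ids, population = assignment,
    genome_group = gg, ploidy = ploidy, stringsAsFactors = FALSE
  )
  # cultivar-map invariants (ploidy 2-4) only apply when they can hold
  if (all(ploidy %in% 2:4)) map <- pop_map(map)
  truth <- structure(list(
    seed = seed, n_populations = n_pops, sizes = sizes, fst = fst,
    p0 = setNames(p0, locus_ids),
    p_k = `colnames<-`(p_k, locus_ids),
    assignment = setNames(assignment, genotype_ids),
    ploidy = setNames(ploidy, genotype_ids)
  ), class = "simulation_truth")
  list(matrix = band_matrix(m), map = map, truth = truth)
}

#' Simulate clustering-run log-probability summaries
#'
#' Builds a mean LnP(D) curve that rises steeply up to the true K and
#' nearly plateaus after it, so the largest absolute second difference
#' (and hence delta-K) sits at `true_k`; replicates add Gaussian noise.
#'
#' @param true_k the K at which the curvature kink is placed.
#' @param K_range contiguous integer range of K values (length >= 4).
#' @param n_reps replicates per K (>= 2).
#' @param noise_sd replicate noise standard deviation (default 0.5).
#' @param seed integer seed.
#' @return a `structure_runs` object.
#' @export
simulate_structure_runs <- function(true_k, K_range = 1:10, n_reps = 5,
                                    noise_sd = 0.5, seed = 1) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) < 4)
    stop_musadiv("K_range must contain >= 4 contiguous values")
  if (any(diff(K_range) != 1)) stop_musadiv("K_range must be contiguous")
  if (n_reps < 2) stop_musadiv("delta-K needs >= 2 replicates per K")
  if (!true_k %in% K_range[-c(1, length(K_range))])
    stop_musadiv("true_k must be interior to K_range")
  set.seed(seed)
  slope_before <- 40; slope_after <- 2
  mu <- -500 + slope_before * pmin(K_range, true_k) +
    slope_after * pmax(K_range - true_k, 0)
  ln <- data.frame(
    K = rep(K_range, each = n_reps),
    replicate = rep(seq_len(n_reps), length(K_range)),
    lnpd = rep(mu, each = n_reps) + rnorm(length(K_range) * n_reps, 0, noise_sd)
  )
  structure_runs(ln)
}

#' Simulate a volatile-compound table with an alkane ladder
#'
#' Emulates a GC-MS presence/absence screening of banana cultivars:
#' retention times uniform over `rt_range` (sorted), experimental
#' retention indices computed from a monotone C8-C20 alkane ladder
#' spanning the run, reference indices perturbed by `N(0, 5)` library
#' error, and per-cultivar presence drawn independently. Default class
#' counts mirror a published 54-compound banana volatilome (30 esters,
#' i.e. an ester share that rounds to 56%).
#'
#' @param cultivars character vector of cultivar names.
#' @param class_counts named integer vector over the nine canonical
#'   chemical classes.
#' @param presence_prob either one probability or one per cultivar.
#' @param rt_range GC run window in minutes (must sit inside the ladder).
#' @param seed integer seed.
#' @return list with `table` (a `volatile_table`) and `ladder`
#'   (an `alkane_ladder` spanning `rt_range`).
#' @export
simulate_volatile_table <- function(cultivars = paste0("CV", 1:9),
                                    class_counts = c(
                                      "ester" = 30, "aromatic aldehyde" = 2,
                                      "alcohol" = 7, "hydrocarbon" = 3,
                                      "ketone" = 2, "ether" = 3,
                                      "carboxylic acid" = 1,
                                      "diverse functional group" = 5,
                                      "chlorine-containing" = 1),
                                    presence_prob = 0.4,
                                    rt_range = c(4, 59),
                                    seed = 1) {
  if (sum(class_counts) < 1) stop_musadiv("need >= 1 compound")
  bad <- !names(class_counts) %in% VOLATILE_CLASSES
  if (any(bad)) stop_musadiv("unknown class: ",
                             paste(names(class_counts)[bad], collapse = ", "))
  if (any(presence_prob < 0 | presence_prob > 1))
    stop_musadiv("presence_prob must lie in [0, 1]")
  if (length(presence_prob) == 1)
    presence_prob <- rep(presence_prob, length(cultivars))
  if (length(presence_prob) != length(cultivars))
    stop_musadiv("presence_prob must have length 1 or length(cultivars)")
  set.seed(seed)

  # ladder spans slightly beyond the run window so every rt is bracketed
  carbons <- 8:20
  pad <- 0.02 * diff(rt_range)
  anchors <- seq(rt_range[1] - pad, rt_range[2] + pad, length.out = length(carbons))
  anchors <- anchors + c(0, cumsum(runif(length(carbons) - 1, 0, pad / 10)))
  ladder <- alkane_ladder(data.frame(carbon = carbons, rt_min = anchors))
  if (rt_range[1] < anchors[1] || rt_range[2] > anchors[length(anchors)])
    stop_musadiv("rt_range outside the alkane ladder span")

  n <- sum(class_counts)
  rt <- sort(runif(n, rt_range[1], rt_range[2]))
  cls <- rep(names(class_counts), class_counts)[order(runif(n))]
  exp_ri <- kovats_ri(rt, ladder)
  ref_ri <- pmax(100, exp_ri + rnorm(n, 0, 5))
  df <- data.frame(
    sr = seq_len(n), chemical_class = cls, rt_min = rt,
    compound = sprintf("compound_%02d", seq_len(n)),
    reference_ri = round(ref_ri, 1), experimental_ri = round(exp_ri, 1),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(cultivars))
    df[[cultivars[i]]] <- rbinom(n, 1, presence_prob[i])
  list(table = volatile_table(df), ladder = ladder)
}
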