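#  End-to-end orchestration: read inputs, run every stage available for
#  them, write a deterministic artifact bundle plus a manifest.

#' Run the full diversity/volatilome pipeline
#'
#' Executes all stages for which inputs are configured, writing a
#' deterministic artifact bundle: per-primer statistics per marker system
#' (with mean rows), similarity matrices and Newick dendrograms per
#' system and combined, PCoA coordinates with the eigenvalue block, AMOVA
#' and pairwise Phi-ST tables, per-population diversity, the delta-K
#' table, and volatile composition plus the cultivar dendrogram. Stages
#' whose inputs are absent are skipped with a log line. A JSON manifest
#' records the package version, seed, input checksums and the files
#' written; rerunning with the same inputs and seed reproduces the bundle
#' byte for byte.
#'
#' @param config either a named list or the path to a YAML file with
#'   entries: `band_matrix`, `population_map`, `structure_lnpd`,
#'   `structure_q`, `volatile_table` (input CSV paths, each optional
#'   except `band_matrix` unless only volatiles are analysed);
#'   `out_dir`; and optional settings `coefficient` (default `"dice"`),
#'   `amova_permutations` (default 999), `seed` (default 1),
#'   `membership_C` (0.44), `purity_threshold` (0.7),
#'   `ri_tolerance` (15), `cut_similarity` (optional group-cut level).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop_musadiv("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  coefficient <- config$coefficient %||% "dice"
  n_perm <- config$amova_permutations %||% 999
  files <- character(0)
  skipped <- character(0)
  log <- function(...) message("[musadiv] ", ...)

  put <- function(name) {
    files <<- c(files, name)
    file.path(out_dir, name)
  }
  write_table <- function(df, name, digits_cols = NULL) {
    p <- put(name)
    for (cl in names(df)) if (is.numeric(df[[cl]]) && !is.integer(df[[cl]]))
      df[[cl]] <- fmt_num(df[[cl]])
    write.csv(df, p, row.names = FALSE, quote = TRUE, na = "NA")
  }

  bm <- NULL
  if (!is.null(config$band_matrix)) {
    bm <- read_band_matrix(config$band_matrix)
    log("band matrix: ", nrow(bm), " genotypes x ", ncol(bm), " loci")
  } else skipped <- c(skipped, "marker stages (no band matrix)")

  map <- NULL
  if (!is.null(config$population_map)) {
    map <- read_population_map(config$population_map)
    if (!is.null(bm)) check_map_matches(map, bm)
  }

  combined_D <- NULL
  if (!is.null(bm)) {
    systems <- intersect(c(MARKER_SYSTEMS), unique(loci_info(bm)$system))
    # per-primer statistics per system, with mean rows
    for (sys in systems) {
      st <- marker_summary(bm, system = sys)
      st <- rbind(st, panel_summary(st))
      write_table(st, paste0("primer_stats_", sys, ".csv"))
    }
    # similarity + dendrogram per system and combined
    for (sys in c(systems, "all")) {
      S <- similarity_matrix(bm, system = sys, coefficient = coefficient)
      tree <- upgma(similarity_to_distance(S))
      sdf <- data.frame(genotype = rownames(S), unclass(S), check.names = FALSE)
      write_table(sdf, paste0("similarity_", sys, ".csv"))
      write_newick(tree, put(paste0("dendrogram_", sys, ".nwk")))
      if (sys == "all") {
        combined_D <- similarity_to_distance(S)
        if (!is.null(config$cut_similarity)) {
          grp <- cut_at_similarity(tree, config$cut_similarity)
          write_table(data.frame(genotype = names(grp), group = grp),
                      "similarity_groups.csv")
        }
      }
    }
    # ordination on the combined distance
    pc <- pcoa(combined_D)
    k <- ncol(pc$coordinates)
    coords <- data.frame(genotype = rownames(pc$coordinates),
                         pc$coordinates, check.names = FALSE)
    write_table(coords, "pcoa_coordinates.csv")
    write_table(data.frame(axis = seq_len(k),
                           eigenvalue = pc$positive_eigenvalues[seq_len(k)],
                           percent = pc$percent_variance[seq_len(k)],
                           cumulative = pc$cumulative_percent[seq_len(k)]),
                "pcoa_eigenvalues.csv")

    if (!is.null(map)) {
      D2 <- squared_distance_matrix(bm)
      am <- amova(D2, map, n_perm = n_perm, seed = seed)
      tab <- am$table
      tab$phi_st <- c(am$phi_st, NA, NA)
      tab$p_value <- c(am$p_value, NA, NA)
      write_table(tab, "amova.csv")
      pw <- pairwise_phist(D2, map, n_perm = 0)
      write_table(data.frame(population = rownames(pw$phi), pw$phi,
                             check.names = FALSE), "pairwise_phist.csv")
      write_table(population_diversity(bm, map), "population_diversity.csv")
    } else skipped <- c(skipped, "AMOVA/diversity (no population map)")
  }

  if (!is.null(config$structure_lnpd)) {
    runs <- read_structure_runs(config$structure_lnpd, config$structure_q)
    dk <- evanno_delta_k(runs)
    write_table(as.data.frame(dk), "delta_k.csv")
    if (!is.null(runs$Q)) {
      mem <- classify_membership(runs$Q, C = config$membership_C %||% 0.44,
                                 purity_threshold = config$purity_threshold %||% 0.7)
      write_table(mem$calls, "membership_calls.csv")
    }
  } else skipped <- c(skipped, "delta-K (no run summaries)")

  if (!is.null(config$volatile_table)) {
    vt <- read_volatile_table(config$volatile_table)
    comp <- class_composition(vt)
    write_table(data.frame(class = names(comp$counts),
                           n = as.integer(comp$counts),
                           percent = comp$percent,
                           percent_rounded = comp$percent_rounded),
                "volatile_composition.csv")
    cc <- cultivar_counts(vt)
    write_table(data.frame(cultivar = names(cc$totals), total = cc$totals,
                           ester_share_pct = cc$ester_share_pct,
                           cc$by_class, check.names = FALSE),
                "cultivar_counts.csv")
    write_newick(cultivar_volatile_clustering(vt),
                 put("volatile_dendrogram.nwk"))
  } else skipped <- c(skipped, "volatilome (no volatile table)")

  for (s in skipped) log("skipped: ", s)

  inputs <- Filter(Negate(is.null),
                   config[c("band_matrix", "population_map", "structure_lnpd",
                            "structure_q", "volatile_table")])
  manifest <- list(
    package = "musadiv",
    version = as.character(packageVersion("musadiv")),
    seed = seed,
    settings = list(coefficient = coefficient, amova_permutations = n_perm),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    artifacts = sort(files),
    skipped = skipped
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
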