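#  All delimited I/O uses one dialect: comma-separated, UTF-8, "NA" for
#  missing, deterministic column order, floats as %.4f.

#' Read a band-presence matrix from CSV
#'
#' Expects a header row of `"PRIMER|SYSTEM|band"` locus ids, a first column
#' of genotype ids, and cells in `{0, 1, NA}`.
#'
#' @param path file path.
#' @return a [band_matrix()].
#' @export
read_band_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (ncol(df) < 2) stop_musadiv("band matrix file needs a genotype column and >= 1 locus")
  gid <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(m %in% c("0", "1", "NA", NA)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop_musadiv("cell outside {0,1,NA} at genotype '", gid[i[1]],
                 "', locus '", colnames(m)[i[2]], "' (value '", m[bad[1]], "')")
  }
  mm <- matrix(suppressWarnings(as.integer(m)), nrow(m), ncol(m),
               dimnames = list(gid, colnames(m)))
  band_matrix(mm)
}

#' Write a band-presence matrix to CSV
#'
#' @param x a [band_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(x, path) {
  stopifnot(inherits(x, "band_matrix"))
  df <- data.frame(genotype = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a genotype-to-population map from CSV
#'
#' Columns: `genotype`, `population`, `genome_group`, `ploidy`. The genome
#' group is a string over `{A, B}` (the two wild Musa progenitor genomes);
#' its length must equal the ploidy, which must be 2, 3 or 4.
#'
#' @param path file path.
#' @return a `pop_map` data frame.
#' @export
read_population_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pop_map(df)
}

#' Construct/validate a population map
#'
#' @param df data frame with columns `genotype`, `population`,
#'   `genome_group`, `ploidy`.
#' @return the validated data frame, class `pop_map`.
#' @export
pop_map <- function(df) {
  need <- c("genotype", "population", "genome_group", "ploidy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_musadiv("population map missing column(s): ",
                                 paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop_musadiv("population map contains no genotypes")
  if (anyDuplicated(df$genotype))
    stop_musadiv("duplicate genotype(s) in population map: ",
                 paste(unique(df$genotype[duplicated(df$genotype)]), collapse = ", "))
  df$ploidy <- as.integer(df$ploidy)
  bad_p <- !df$ploidy %in% 2:4
  if (any(bad_p))
    stop_musadiv("ploidy outside {2,3,4} for: ",
                 paste(df$genotype[bad_p], collapse = ", "))
  bad_g <- grepl("[^AB]", df$genome_group) | nchar(df$genome_group) == 0
  if (any(bad_g))
    stop_musadiv("genome group not a string over {A,B} for: ",
                 paste(df$genotype[bad_g], collapse = ", "))
  inconsistent <- nchar(df$genome_group) != df$ploidy
  if (any(inconsistent))
    stop_musadiv("genome group length disagrees with ploidy for: ",
                 paste(df$genotype[inconsistent], collapse = ", "))
  class(df) <- c("pop_map", "data.frame")
  df
}

#' Check that a population map covers a band matrix exactly
#'
#' @param map a `pop_map`.
#' @param x a [band_matrix()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_map_matches <- function(map, x) {
  missing_g <- setdiff(rownames(x), map$genotype)
  if (length(missing_g))
    stop_musadiv("genotype(s) absent from population map: ",
                 paste(missing_g, collapse = ", "))
  invisible(TRUE)
}

#' Read Bayesian-clustering run summaries
#'
#' Plain-text summaries of external admixture-model runs (e.g. STRUCTURE):
#' a CSV of per-replicate log-probabilities with columns `K`, `replicate`,
#' `lnpd`, and optionally a CSV ancestry (Q) matrix with a `genotype`
#' column followed by one column per cluster.
#'
#' @param lnpd_path CSV of log-probabilities.
#' @param q_path optional CSV Q-matrix for the chosen K.
#' @return a `structure_runs` list with elements `lnpd` (data frame) and
#'   `Q` (matrix or `NULL`).
#' @export
read_structure_runs <- function(lnpd_path, q_path = NULL) {
  ln <- read.csv(lnpd_path, stringsAsFactors = FALSE)
  need <- c("K", "replicate", "lnpd")
  miss <- setdiff(need, names(ln))
  if (length(miss)) stop_musadiv("lnpd file missing column(s): ",
                                 paste(miss, collapse = ", "))
  Q <- NULL
  if (!is.null(q_path)) {
    qdf <- read.csv(q_path, stringsAsFactors = FALSE, check.names = FALSE)
    Q <- as.matrix(qdf[, -1, drop = FALSE])
    rownames(Q) <- qdf[[1]]
    check_q_matrix(Q)
  }
  structure_runs(ln, Q)
}

#' Construct/validate clustering-run summaries
#'
#' @param lnpd data frame with columns `K`, `replicate`, `lnpd`.
#' @param Q optional genotype x cluster ancestry matrix (rows sum to 1).
#' @return a `structure_runs` list.
#' @export
structure_runs <- function(lnpd, Q = NULL) {
  lnpd$K <- as.integer(lnpd$K)
  if (any(lnpd$K < 1)) stop_musadiv("K values must be >= 1")
  if (!is.null(Q)) check_q_matrix(Q)
  structure(list(lnpd = lnpd, Q = Q), class = "structure_runs")
}

check_q_matrix <- function(Q, tol = 1e-6) {
  if (any(Q < 0)) stop_musadiv("Q matrix has negative ancestry fractions")
  rs <- rowSums(Q)
  bad <- abs(rs - 1) > tol
  if (any(bad))
    stop_musadiv("Q rows not summing to 1: ",
                 paste(rownames(Q)[bad] %||% which(bad), collapse = ", "))
  invisible(Q)
}

#' Read a volatile-compound table from CSV
#'
#' Columns: `sr` (record id), `chemical_class` (one of the nine canonical
#' classes), `rt_min` (retention time, minutes), `compound`,
#' `reference_ri`, `experimental_ri`, then one 0/1 presence column per
#' cultivar, and optionally `ambiguous` (semicolon-separated cultivars
#' whose presence mark was typographically unclear in the source table).
#' A final row with `compound == "Total"` is treated as a reported
#' per-cultivar totals row and kept aside for cross-checking.
#'
#' @param path file path.
#' @return a `volatile_table` data frame; attribute `cultivars` names the
#'   presence columns and attribute `reported_totals` holds the totals row
#'   when present.
#' @export
read_volatile_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  volatile_table(df)
}

#' Construct/validate a volatile-compound table
#'
#' @param df data frame as described in [read_volatile_table()].
#' @return a `volatile_table`.
#' @export
volatile_table <- function(df) {
  fixed <- c("sr", "chemical_class", "rt_min", "compound",
             "reference_ri", "experimental_ri")
  miss <- setdiff(fixed, names(df))
  if (length(miss)) stop_musadiv("volatile table missing column(s): ",
                                 paste(miss, collapse = ", "))
  cultivars <- setdiff(names(df), c(fixed, "ambiguous"))
  if (!length(cultivars)) stop_musadiv("volatile table has no cultivar columns")
  totals <- NULL
  is_total <- df$compound == "Total"
  if (any(is_total)) {
    totals <- unlist(df[which(is_total)[1], cultivars])
    df <- df[!is_total, , drop = FALSE]
  }
  if (nrow(df) == 0) stop_musadiv("volatile table has no compound records")
  bad_cls <- !df$chemical_class %in% VOLATILE_CLASSES
  if (any(bad_cls))
    stop_musadiv("unknown chemical class: ",
                 paste(unique(df$chemical_class[bad_cls]), collapse = ", "))
  if (any(df$rt_min <= 0)) stop_musadiv("retention times must be positive")
  ri <- c(df$reference_ri, df$experimental_ri)
  if (any(ri < 100, na.rm = TRUE)) stop_musadiv("retention indices must be >= 100")
  for (cv in cultivars) {
    df[[cv]] <- as.integer(df[[cv]])
    if (any(!df[[cv]] %in% c(0L, 1L)))
      stop_musadiv("presence column '", cv, "' must be 0/1")
  }
  rownames(df) <- NULL
  structure(df, cultivars = cultivars, reported_totals = totals,
            class = c("volatile_table", "data.frame"))
}

#' Read an n-alkane calibration ladder from CSV
#'
#' Columns `carbon` (carbon number, 8-20 for a C8-C20 standard mix) and
#' `rt_min` (retention time, minutes); both must be strictly increasing.
#'
#' @param path file path.
#' @return an `alkane_ladder` data frame.
#' @export
read_alkane_ladder <- function(path) {
  alkane_ladder(read.csv(path, stringsAsFactors = FALSE))
}

#' Construct/validate an alkane ladder
#'
#' @param df data frame with columns `carbon`, `rt_min`.
#' @return an `alkane_ladder`.
#' @export
alkane_ladder <- function(df) {
  miss <- setdiff(c("carbon", "rt_min"), names(df))
  if (length(miss)) stop_musadiv("alkane ladder missing column(s): ",
                                 paste(miss, collapse = ", "))
  if (nrow(df) < 2) stop_musadiv("alkane ladder needs >= 2 anchors")
  if (any(diff(df$carbon) <= 0)) stop_musadiv("carbon numbers must be strictly increasing")
  if (any(diff(df$rt_min) <= 0)) stop_musadiv("retention times must be strictly increasing")
  class(df) <- c("alkane_ladder", "data.frame")
  df
}

#' Serialize an ultrametric dendrogram to Newick
#'
#' Branch lengths are half the merge heights, so leaf-to-leaf path lengths
#' reproduce the cophenetic distances. Labels containing spaces or Newick
#' metacharacters are single-quoted.
#'
#' @param tree an `hclust`-compatible tree, e.g. from [upgma()].
#' @param path optional file to write to.
#' @return the Newick string (invisibly when `path` is given).
#' @export
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' write_newick(upgma(d))  # "(A:0.2,B:0.2);"
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  lab <- vapply(tree$labels, quote_newick_label, "")
  n <- length(lab)
  build <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%s", lab[-id], format(parent_h / 2, digits = 15))
    } else {
      h <- tree$height[id]
      kids <- tree$merge[id, ]
      inner <- paste(build(kids[1], h), build(kids[2], h), sep = ",")
      sprintf("(%s):%s", inner, format((parent_h - h) / 2, digits = 15))
    }
  }
  if (n == 1) {
    nwk <- sprintf("%s:0;", lab[1])
  } else {
    root <- nrow(tree$merge)
    h <- tree$height[root]
    kids <- tree$merge[root, ]
    nwk <- sprintf("(%s,%s);", build(kids[1], h), build(kids[2], h))
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

quote_newick_label <- function(x) {
  if (grepl("[][ ,:;()']", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}
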