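#' Define a gene set
#'
#' @param name Set name.
#' @param gene_ids Character vector of gene ids; duplicates are removed.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = name, gene_ids = gene_ids), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$name, "-", length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Read a gene set from a plain-text file
#'
#' One gene id per line; `#` starts a comment.
#'
#' @param path Input path.
#' @param name Set name; defaults to the file name without extension.
#' @return A [gene_set].
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(sub("#.*$", "", readLines(path)))
  gene_set(name, lines[nzchar(lines)])
}

#' Monte Carlo test configuration
#'
#' Holds the parameters of the random-gene-set resampling null. The
#' defaults mirror the published procedure: 2000 random sets of 750 genes
#' each, drawn from a universe of genes longer than 500 bp. The observed
#' sets need not have the null set size — the test statistic is a mean
#' per promoter, whose expectation does not depend on set size — so a
#' single fixed null size serves both the up- and downregulated sets.
#'
#' @param universe A [gene_set]: the sampling universe for random sets,
#'   already filtered by gene length.
#' @param n_random_sets Number of random sets (default 2000).
#' @param random_set_size Genes per random set (default 750).
#' @param min_gene_length Length filter (bp, exclusive) the universe is
#'   expected to satisfy; recorded in outputs (default 500).
#' @param seed Integer seed making the null sets reproducible.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(universe, n_random_sets = 2000,
                      random_set_size = 750, min_gene_length = 500,
                      seed = 1L) {
  stopifnot(inherits(universe, "gene_set"))
  if (n_random_sets < 1) stop("n_random_sets must be >= 1")
  if (random_set_size < 1) stop("random_set_size must be >= 1")
  if (random_set_size > length(universe$gene_ids)) {
    stop("random_set_size (", random_set_size,
         ") exceeds the universe size (", length(universe$gene_ids), ")")
  }
  structure(list(universe = universe,
                 n_random_sets = as.integer(n_random_sets),
                 random_set_size = as.integer(random_set_size),
                 min_gene_length = min_gene_length,
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Mean motif count per promoter of a gene set
#'
#' @param table A `count_table` from [count_occurrences()].
#' @param set A [gene_set] (or character vector of gene ids).
#' @param motif_name Column of `table` to average.
#' @return The arithmetic mean occurrence count per promoter.
#' @export
mean_count <- function(table, set, motif_name) {
  ids <- if (inherits(set, "gene_set")) set$gene_ids else as.character(set)
  if (length(ids) == 0) stop("empty gene set")
  missing <- setdiff(ids, rownames(table))
  if (length(missing) > 0) {
    stop("gene(s) absent from the count table: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ..." else "")
  }
  if (!motif_name %in% colnames(table)) {
    stop("motif '", motif_name, "' not in the count table")
  }
  mean(table[ids, motif_name])
}

#' Draw random gene sets from the universe
#'
#' Each set is sampled uniformly without replacement within the set,
#' independently across sets, reproducibly from the configuration seed.
#'
#' @param config An [mc_config()].
#' @return A list of `n_random_sets` character vectors of gene ids.
#' @export
sample_null_sets <- function(config) {
  ids <- config$universe$gene_ids
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_random_sets), function(i) {
      ids[sample.int(length(ids), config$random_set_size)]
    })
  })
}

#' Empirical p-value of an observed mean against Monte Carlo null means
#'
#' The strict empirical p-value is the proportion of null means strictly
#' greater than the observed mean (ties count as "not higher"). Because
#' the strict proportion can be exactly 0, the conservative estimator
#' `(k + 1) / (R + 1)` is reported alongside.
#'
#' @param observed_mean Observed set mean.
#' @param null_means Numeric vector of null set means.
#' @return A list with `p_strict`, `p_conservative`, `k` (number of null
#'   means exceeding the observed mean) and `R` (number of null sets).
#' @export
empirical_p <- function(observed_mean, null_means) {
  if (length(null_means) == 0) stop("null_means is empty")
  k <- sum(null_means > observed_mean)
  R <- length(null_means)
  list(p_strict = k / R, p_conservative = (k + 1) / (R + 1), k = k, R = R)
}

# Empirical CDF of the null means, scaled to percent: one point per
# distinct mean, nondecreasing, reaching exactly 100 at the maximum.
null_curve <- function(null_means) {
  s <- sort(null_means)
  means <- unique(s)
  data.frame(mean = means,
             cumulative_pct = 100 * findInterval(means, s) / length(s))
}

#' Run the Monte Carlo motif enrichment test
#'
#' For each motif, compares the mean occurrence count per promoter of the
#' observed gene set against the means of random gene sets drawn from the
#' universe. A single family of null sets is shared across all motifs
#' (one sampling pass), matching the design of plotting one family of
#' null curves; per-motif p-values are reported without multiple-testing
#' correction.
#'
#' @param table A `count_table` covering the observed set and universe.
#' @param observed_set A [gene_set].
#' @param motif_names Motifs (columns of `table`) to test; default all.
#' @param config An [mc_config()].
#' @return An object of class `mc_test`: a list of per-motif results,
#'   each with `motif_name`, `set_name`, `observed_mean`, `null_means`,
#'   `p_strict`, `p_conservative`, and `curve` (the null empirical CDF in
#'   percent). Use [as.data.frame()] for the summary table.
#' @export
run_mc_test <- function(table, observed_set, motif_names = colnames(table),
                        config) {
  stopifnot(inherits(observed_set, "gene_set"), inherits(config, "mc_config"))
  missing_u <- setdiff(config$universe$gene_ids, rownames(table))
  if (length(missing_u) > 0) {
    stop("universe gene(s) absent from the count table: ",
         paste(utils::head(missing_u, 10), collapse = ", "))
  }
  null_sets <- sample_null_sets(config)
  results <- lapply(motif_names, function(mn) {
    obs <- mean_count(table, observed_set, mn)
    col <- table[, mn]
    nulls <- vapply(null_sets, function(ids) mean(col[ids]), numeric(1))
    p <- empirical_p(obs, nulls)
    list(motif_name = mn, set_name = observed_set$name,
         observed_mean = obs, null_means = nulls,
         p_strict = p$p_strict, p_conservative = p$p_conservative,
         k = p$k, R = p$R, curve = null_curve(nulls))
  })
  structure(list(results = stats::setNames(results, motif_names),
                 config = config),
            class = "mc_test")
}

#' @export
print.mc_test <- function(x, ...) {
  cat("<mc_test>", length(x$results), "motif(s), R =",
      x$config$n_random_sets, "null sets of",
      x$config$random_set_size, "genes\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Summary table of a Monte Carlo enrichment test
#'
#' @param x An `mc_test` from [run_mc_test()].
#' @param ... Ignored.
#' @return A data.frame with one row per motif: observed mean, strict and
#'   conservative empirical p-values, and the resampling parameters.
#' @export
as.data.frame.mc_test <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(motif = r$motif_name, set = r$set_name,
               observed_mean = r$observed_mean,
               p_strict = r$p_strict, p_conservative = r$p_conservative,
               R = r$R, set_size = x$config$random_set_size,
               seed = x$config$seed,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write Monte Carlo test results and null curves
#'
#' @param x An `mc_test`.
#' @param results_path Tab-separated summary table output path.
#' @param curves_path Optional path for the long-format null curves
#'   (motif, mean, cumulative_pct).
#' @return `results_path`, invisibly.
#' @export
write_mc_results <- function(x, results_path, curves_path = NULL) {
  utils::write.table(as.data.frame(x), results_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(curves_path)) {
    curves <- do.call(rbind, lapply(x$results, function(r) {
      data.frame(motif = r$motif_name, r$curve,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    utils::write.table(curves, curves_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(results_path)
}

#' Plot cumulative null curves with observed means overlaid
#'
#' Cumulative percentage of random gene sets against mean motif
#' occurrences per promoter, one curve per motif, with the observed set
#' means marked on their curves.
#'
#' @param x An `mc_test` (or a list of them, e.g. up- and downregulated
#'   sets sharing one null family).
#' @return A ggplot object.
#' @export
plot_mc_curves <- function(x) {
  tests <- if (inherits(x, "mc_test")) list(x) else x
  curves <- do.call(rbind, lapply(tests, function(t) {
    do.call(rbind, lapply(t$results, function(r) {
      data.frame(motif = r$motif_name, r$curve, row.names = NULL)
    }))
  }))
  curves <- unique(curves)
  obs <- do.call(rbind, lapply(tests, function(t) {
    do.call(rbind, lapply(t$results, function(r) {
      data.frame(motif = r$motif_name, set = r$set_name,
                 observed_mean = r$observed_mean,
                 at_pct = 100 * mean(r$null_means <= r$observed_mean),
                 row.names = NULL)
    }))
  }))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = mean, y = cumulative_pct,
                               colour = motif)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = observed_mean, y = at_pct,
                   colour = motif, shape = set),
      size = 3, inherit.aes = FALSE) +
    ggplot2::labs(x = "mean motif occurrences per promoter",
                  y = "cumulative % of random gene sets",
                  shape = "observed set") +
    ggplot2::theme_classic()
}

#' Overlap of up-/downregulated gene sets with a reference list
#'
#' Exact intersection sizes between each query set and a reference gene
#' list (e.g. published UPR target catalogues). Warns when the up and
#' down query sets are not disjoint.
#'
#' @param query_up,query_down Query [gene_set]s.
#' @param reference Reference [gene_set].
#' @return An object of class `overlap_report`: a list with
#'   `n_reference`, `n_up_overlap`, `n_down_overlap` and the three sets.
#' @export
overlap_counts <- function(query_up, query_down, reference) {
  stopifnot(inherits(query_up, "gene_set"),
            inherits(query_down, "gene_set"),
            inherits(reference, "gene_set"))
  shared <- intersect(query_up$gene_ids, query_down$gene_ids)
  if (length(shared) > 0) {
    warning("query_up and query_down share ", length(shared), " gene(s)")
  }
  structure(list(
    query_up = query_up, query_down = query_down, reference = reference,
    n_reference = length(reference$gene_ids),
    n_up_overlap = length(intersect(query_up$gene_ids,
                                    reference$gene_ids)),
    n_down_overlap = length(intersect(query_down$gene_ids,
                                      reference$gene_ids))
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> reference '", x$reference$name, "' (",
      x$n_reference, " genes): ", x$n_up_overlap, " in '",
      x$query_up$name, "', ", x$n_down_overlap, " in '",
      x$query_down$name, "'\n", sep = "")
  invisible(x)
}
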