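#' Read a flat key-value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are kept
#' as strings; numeric fields are coerced where they are used. Entries in
#' `overrides` (e.g. parsed command-line flags) take precedence over the
#' file, which takes precedence over function defaults.
#'
#' @param path Optional configuration file path.
#' @param overrides Named list merged over the file's entries.
#' @return A named list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- trimws(sub("#.*$", "", readLines(path)))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop("malformed config line: ", ln)
      config[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  utils::modifyList(config, overrides)
}

stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

run_manifest <- function(out_dir, inputs, params) {
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    package = "motifmc",
    version = as.character(utils::packageVersion("motifmc")),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    parameters = params
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the promoter motif enrichment pipeline
#'
#' End-to-end analysis: read genome and annotation, filter genes by
#' length, extract strand-aware promoter windows, scan motifs, count
#' occurrences, and run the Monte Carlo enrichment test for each observed
#' gene set. Writes the result table, null curves, count table,
#' dropped-gene report and a machine-readable run manifest (input
#' checksums, seed, parameters) into `out_dir`.
#'
#' @param config A named list (or [read_run_config()] output) with
#'   entries: `genome` (FASTA path), `annotation` (GFF3 path), one or
#'   both of `motifs_consensus` / `motifs_meme` (motif file paths),
#'   `gene_sets` (named character vector of gene-set file paths),
#'   optional `universe` (gene-set file; default all genes passing the
#'   length filter), `out_dir`, and optional numeric fields
#'   `min_gene_length` (500), `upstream` (100), `downstream` (100),
#'   `n_random_sets` (2000), `random_set_size` (750), `seed` (1).
#' @return A named list of `mc_test` objects (one per observed gene
#'   set), invisibly.
#' @export
run_motif_mc <- function(config) {
  for (field in c("genome", "annotation", "gene_sets", "out_dir")) {
    if (is.null(config[[field]])) stop("config is missing '", field, "'")
  }
  if (is.null(config$motifs_consensus) && is.null(config$motifs_meme)) {
    stop("config needs 'motifs_consensus' and/or 'motifs_meme'")
  }
  paths <- c(config$genome, config$annotation, config$motifs_consensus,
             config$motifs_meme, unlist(config$gene_sets), config$universe)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  num <- function(field, default) {
    if (is.null(config[[field]])) default else as.numeric(config[[field]])
  }
  min_len <- num("min_gene_length", 500)
  upstream <- num("upstream", 100)
  downstream <- num("downstream", 100)
  n_sets <- num("n_random_sets", 2000)
  set_size <- num("random_set_size", 750)
  seed <- as.integer(num("seed", 1))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage_log("read", "genome: ", config$genome)
  genome <- read_genome_fasta(config$genome)
  genes <- read_gff_genes(config$annotation)
  stage_log("read", nrow(genes), " gene records")
  kept <- filter_by_length(genes, min_len)
  stage_log("filter", nrow(kept), " genes > ", min_len, " bp (",
            nrow(genes) - nrow(kept), " dropped)")
  promoters <- extract_promoters(genome, kept, upstream, downstream)
  stage_log("extract", nrow(promoters), " promoters, ",
            nrow(attr(promoters, "dropped")), " dropped at contig edges")

  motifs <- list()
  if (!is.null(config$motifs_consensus)) {
    motifs <- c(motifs, read_motifs_consensus(config$motifs_consensus))
  }
  if (!is.null(config$motifs_meme)) {
    motifs <- c(motifs, read_motifs_meme(config$motifs_meme))
  }
  stage_log("scan", length(motifs), " motif(s) over ",
            nrow(promoters), " promoters")
  counts <- count_occurrences(promoters, motifs)

  universe <- if (!is.null(config$universe)) {
    u <- read_gene_set(config$universe, "universe")
    gene_set("universe", intersect(u$gene_ids, rownames(counts)))
  } else {
    gene_set("universe", rownames(counts))
  }
  mc <- mc_config(universe, n_random_sets = n_sets,
                  random_set_size = min(set_size,
                                        length(universe$gene_ids)),
                  min_gene_length = min_len, seed = seed)

  set_paths <- config$gene_sets
  if (is.null(names(set_paths)) || any(!nzchar(names(set_paths)))) {
    names(set_paths) <- sub("\\.[^.]*$", "", basename(unlist(set_paths)))
  }
  tests <- list()
  for (set_name in names(set_paths)) {
    gs <- read_gene_set(set_paths[[set_name]], set_name)
    present <- intersect(gs$gene_ids, rownames(counts))
    if (length(present) < length(gs$gene_ids)) {
      stage_log("mc", set_name, ": ",
                length(gs$gene_ids) - length(present),
                " gene(s) not among scanned promoters, excluded")
    }
    gs <- gene_set(set_name, present)
    stage_log("mc", "testing set '", set_name, "' (",
              length(gs$gene_ids), " genes) against R = ",
              mc$n_random_sets, " null sets")
    tests[[set_name]] <- run_mc_test(counts, gs, config = mc)
    write_mc_results(
      tests[[set_name]],
      file.path(config$out_dir, paste0("mc_results_", set_name, ".tsv")),
      file.path(config$out_dir, paste0("mc_curves_", set_name, ".tsv")))
  }
  write_count_table(counts, file.path(config$out_dir, "counts.tsv"))
  write_dropped_report(promoters,
                       file.path(config$out_dir, "dropped_genes.tsv"))
  run_manifest(config$out_dir,
               inputs = list(genome = config$genome,
                             annotation = config$annotation,
                             motifs_consensus = config$motifs_consensus,
                             motifs_meme = config$motifs_meme,
                             universe = config$universe),
               params = list(min_gene_length = min_len,
                             upstream = upstream, downstream = downstream,
                             n_random_sets = n_sets,
                             random_set_size = mc$random_set_size,
                             seed = seed,
                             gene_sets = as.list(set_paths)))
  invisible(tests)
}

#' Run the behavioral assay statistics pipeline
#'
#' Computes per-assay statistics from food-leaving event logs and
#' exploration grid masks, and writes a tidy results table (one row per
#' assay and statistic, with the aggregation and geometry modes echoed).
#'
#' @param config A named list with optional entries: `leaving_logs`
#'   (path to a combined per-minute log table, see
#'   [read_leaving_logs()]), `off_food_grids` and `on_food_grids`
#'   (character vectors of grid mask files), `aggregation`
#'   (default "sum"), `geometry` (default "chebyshev"), and `out_dir`.
#' @return The results data.frame, invisibly.
#' @export
run_behavior <- function(config) {
  if (is.null(config$out_dir)) stop("config is missing 'out_dir'")
  if (is.null(config$leaving_logs) && is.null(config$off_food_grids) &&
        is.null(config$on_food_grids)) {
    stop("config names no behavioral inputs")
  }
  aggregation <- if (is.null(config$aggregation)) "sum" else
    config$aggregation
  geometry <- if (is.null(config$geometry)) "chebyshev" else
    config$geometry
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(assay_id, genotype, timepoint_h, statistic, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      assay_id = assay_id, genotype = genotype,
      timepoint_h = timepoint_h, statistic = statistic, value = value,
      aggregation = aggregation, geometry_mode = geometry,
      stringsAsFactors = FALSE)
  }
  if (!is.null(config$leaving_logs)) {
    logs <- read_leaving_logs(config$leaving_logs)
    stage_log("behavior", length(logs), " leaving log(s)")
    for (log in logs) {
      add(attr(log, "assay_id"), attr(log, "genotype"),
          attr(log, "timepoint_h"), "leaving_probability",
          leaving_probability(log))
    }
  }
  for (f in config$off_food_grids) {
    grid <- read_grid(f)
    add(sub("\\.[^.]*$", "", basename(f)), NA_character_, NA_real_,
        "off_food_score", off_food_score(grid, aggregation,
                                         geometry)$total)
  }
  for (f in config$on_food_grids) {
    grid <- read_grid(f)
    add(sub("\\.[^.]*$", "", basename(f)), NA_character_, NA_real_,
        "on_food_coverage_pct", on_food_coverage(grid))
  }
  results <- do.call(rbind, rows)
  out <- file.path(config$out_dir, "behavior_results.tsv")
  utils::write.table(results, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  means <- stats::aggregate(value ~ statistic, data = results, FUN = mean)
  utils::write.table(means,
                     file.path(config$out_dir, "behavior_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("behavior", nrow(results), " statistic rows written")
  invisible(results)
}
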