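#' Read a genome FASTA file
#'
#' Loads all records of a FASTA file into a [Biostrings::DNAStringSet].
#' Headers are truncated at the first whitespace to form contig names and
#' sequences are uppercased. Only the alphabet \{A, C, G, T, N\} is
#' accepted; any other character is an error.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) stop("malformed FASTA '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    ),
    # readDNAStringSet silently drops codes outside its alphabet; treat
    # that as a parse error rather than accepting altered sequence
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes",
                conditionMessage(w))) {
        stop("malformed FASTA '", path, "': invalid sequence characters",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(genome) == 0) stop("malformed FASTA '", path, "': no records")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  if (any(Biostrings::width(genome) == 0)) {
    stop("malformed FASTA '", path, "': empty sequence for contig(s) ",
         paste(names(genome)[Biostrings::width(genome) == 0], collapse = ", "))
  }
  freq <- Biostrings::alphabetFrequency(genome)
  extra <- rowSums(freq) -
    rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0)) {
    stop("FASTA '", path, "': contig(s) ",
         paste(names(genome)[extra > 0], collapse = ", "),
         " contain characters outside {A,C,G,T,N}")
  }
  genome
}

#' Read gene records from a GFF3 annotation
#'
#' Parses the nine-column GFF3 table and returns one row per feature of
#' `feature_type`, with `gene_id` taken from the `ID` attribute. Rows of the
#' requested type with a missing `ID` or inverted coordinates (start > end)
#' are collected and reported in a single error.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type (GFF column 3) to keep; default "gene".
#' @return A data.frame with columns `gene_id`, `contig`, `strand`,
#'   `start`, `end` (1-based inclusive) and `length` (bp).
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  fasta_at <- which(lines == "##FASTA")
  if (length(fasta_at) > 0) lines <- lines[seq_len(fasta_at[1] - 1L)]
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(gene_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9)) {
    stop("unparseable GFF3 '", path, "': line(s) without 9 tab-separated ",
         "columns: ", paste(utils::head(which(lengths(fields) != 9), 5),
                            collapse = ", "))
  }
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- c("contig", "source", "type", "start", "end",
                  "score", "strand", "phase", "attributes")
  tab <- tab[tab$type == feature_type, , drop = FALSE]
  if (nrow(tab) == 0) {
    return(data.frame(gene_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  id <- ifelse(grepl("(^|;)ID=", tab$attributes),
               sub(".*(?:^|;)ID=([^;]+).*", "\\1", tab$attributes), NA)
  problems <- character(0)
  bad_id <- is.na(id) | !nzchar(id)
  if (any(bad_id)) {
    problems <- c(problems, paste0("row ", which(bad_id), ": missing ID"))
  }
  bad_coord <- !bad_id & (is.na(start) | is.na(end) | start > end)
  if (any(bad_coord)) {
    problems <- c(problems, paste0("row ", which(bad_coord), " (",
                                   id[bad_coord],
                                   "): invalid or inverted coordinates"))
  }
  if (length(problems) > 0) {
    stop("GFF3 '", path, "' contains invalid ", feature_type, " rows:\n  ",
         paste(problems, collapse = "\n  "))
  }
  if (anyDuplicated(id)) {
    stop("GFF3 '", path, "': duplicate gene ID(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  data.frame(gene_id = id, contig = tab$contig, strand = tab$strand,
             start = start, end = end, length = end - start + 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter genes by length
#'
#' Retains genes strictly longer than `min_length` base pairs, preserving
#' input order. The strict inequality reflects the convention of keeping
#' only genes "longer than" the cutoff, which excludes the many very short
#' genes that would otherwise bias promoter count comparisons.
#'
#' @param genes Gene data.frame as returned by [read_gff_genes()].
#' @param min_length Minimum length in bp (exclusive); default 500.
#' @return The subset of `genes` with `length > min_length`.
#' @export
filter_by_length <- function(genes, min_length = 500) {
  genes[genes$length > min_length, , drop = FALSE]
}

#' Extract strand-aware promoter windows around transcription start sites
#'
#' For each gene the TSS is the 5' end of the annotated feature (`start`
#' for plus-strand genes, `end` for minus-strand genes). The promoter
#' window covers `upstream` bp before the TSS and `downstream` bp from the
#' TSS onwards, in transcription orientation; minus-strand sequences are
#' reverse-complemented so all promoters read 5'->3' relative to their
#' gene. Internally coordinates are 0-based half-open; a plus-strand gene
#' with 1-based start `s` yields the genomic window `[s-1-upstream,
#' s-1+downstream)`.
#'
#' Windows that extend past a contig edge are dropped by default (keeping
#' all promoters the same length, so set mean counts stay comparable), or
#' clipped and flagged with `edge_policy = "clip"`. Dropped genes are
#' recorded in the `"dropped"` attribute of the result.
#'
#' @param genome A [Biostrings::DNAStringSet] from [read_genome_fasta()].
#' @param genes Gene data.frame as returned by [read_gff_genes()].
#' @param upstream,downstream Window extent in bp around the TSS
#'   (defaults 100/100, i.e. a 200 bp window).
#' @param edge_policy `"drop"` (default) or `"clip"` for windows crossing
#'   a contig boundary.
#' @return A data.frame of class `promoter_set` with columns `gene_id`,
#'   `contig`, `strand`, `window_start`, `window_end` (0-based half-open
#'   genomic), `clipped` and `sequence`; attribute `"dropped"` holds a
#'   data.frame (`gene_id`, `reason`) of excluded genes.
#' @export
extract_promoters <- function(genome, genes, upstream = 100,
                              downstream = 100,
                              edge_policy = c("drop", "clip")) {
  edge_policy <- match.arg(edge_policy)
  unknown <- setdiff(unique(genes$contig), names(genome))
  if (length(unknown) > 0) {
    offenders <- genes$gene_id[genes$contig %in% unknown]
    stop("gene(s) reference contig(s) absent from the genome: ",
         paste(utils::head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) ", ..." else "")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id(s) in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  }
  contig_len <- stats::setNames(Biostrings::width(genome), names(genome))
  n <- nrow(genes)
  tss0 <- ifelse(genes$strand == "+", genes$start - 1L, genes$end - 1L)
  ws <- ifelse(genes$strand == "+", tss0 - upstream, tss0 - downstream + 1L)
  we <- ifelse(genes$strand == "+", tss0 + downstream, tss0 + upstream + 1L)
  len <- contig_len[genes$contig]
  out_of_bounds <- ws < 0L | we > len

  keep <- rep(TRUE, n)
  clipped <- rep(FALSE, n)
  if (edge_policy == "drop") {
    keep <- !out_of_bounds
  } else {
    clipped <- out_of_bounds
  }
  ws_c <- pmax(ws, 0L)
  we_c <- pmin(we, len)

  idx <- which(keep)
  contig_str <- stats::setNames(as.character(genome), names(genome))
  seqs <- substring(contig_str[genes$contig[idx]], ws_c[idx] + 1L,
                    we_c[idx])
  minus <- genes$strand[idx] == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  }
  promoters <- data.frame(
    gene_id = genes$gene_id[idx],
    contig = genes$contig[idx],
    strand = genes$strand[idx],
    window_start = as.integer(ws_c[idx]),
    window_end = as.integer(we_c[idx]),
    clipped = clipped[idx],
    sequence = seqs,
    stringsAsFactors = FALSE, row.names = NULL
  )
  dropped <- data.frame(
    gene_id = genes$gene_id[!keep],
    reason = rep("window outside contig bounds", sum(!keep)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(promoters, "dropped") <- dropped
  attr(promoters, "upstream") <- upstream
  attr(promoters, "downstream") <- downstream
  class(promoters) <- c("promoter_set", "data.frame")
  promoters
}

#' Write promoter sequences to FASTA
#'
#' @param promoters A `promoter_set` from [extract_promoters()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters$sequence)
  names(x) <- promoters$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the dropped-gene report of a promoter extraction
#'
#' @param promoters A `promoter_set` from [extract_promoters()].
#' @param path Output path for a tab-separated (gene_id, reason) table.
#' @return `path`, invisibly.
#' @export
write_dropped_report <- function(promoters, path) {
  utils::write.table(attr(promoters, "dropped"), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
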