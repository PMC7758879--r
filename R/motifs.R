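#' Define a consensus motif
#'
#' A named motif given as an IUPAC consensus string (e.g. the palindromic
#' `ACGT` core or a `CCACG`-box-style element). Consensus motifs match
#' exactly (hit score 0); use [pwm_motif()] for probabilistic models.
#'
#' @param name Motif name.
#' @param consensus IUPAC consensus string.
#' @return An object of class `motif` with `kind = "consensus"`.
#' @export
consensus_motif <- function(name, consensus) {
  consensus <- toupper(consensus)
  iupac_mask(consensus)  # validates codes
  structure(list(name = name, kind = "consensus", consensus = consensus,
                 length = nchar(consensus)),
            class = "motif")
}

#' Define a position weight matrix motif
#'
#' A PWM motif scored by log-odds (bits) against a background base
#' composition. A pseudocount is added to each column before taking
#' log-odds so that zero entries stay finite, and per-position scores are
#' discretized to `bin_width`-bit bins; the exact score-distribution
#' dynamic programming ([pwm_score_threshold()]) and the scanner
#' ([scan_motif()]) both operate on these binned scores, so the threshold
#' is exact with respect to what the scanner computes.
#'
#' @param name Motif name.
#' @param matrix A 4 x L numeric matrix of base probabilities (rows A, C,
#'   G, T; columns positions; each column sums to 1 within 1e-9).
#' @param background Background base probabilities (A, C, G, T), summing
#'   to 1; default uniform.
#' @param pvalue_threshold Match p-value cutoff used to derive the score
#'   threshold; default 1e-4 (the conventional FIMO-style default).
#' @param pseudocount Added to every matrix entry before log-odds;
#'   default 0.01.
#' @param bin_width Score discretization in bits; default 0.01.
#' @return An object of class `motif` with `kind = "pwm"`, carrying the
#'   binned log-odds matrix and the precomputed score threshold.
#' @export
pwm_motif <- function(name, matrix, background = rep(0.25, 4),
                      pvalue_threshold = 1e-4, pseudocount = 0.01,
                      bin_width = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 1) stop("PWM must have at least one position")
  if (any(matrix < 0) || any(matrix > 1)) {
    stop("PWM probabilities must lie in [0, 1]")
  }
  if (any(abs(colSums(matrix) - 1) > 1e-9)) {
    stop("every PWM column must sum to 1 (within 1e-9)")
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 ||
      any(background < 0)) {
    stop("background must be 4 probabilities summing to 1")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  padj <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  if (any(background == 0 & padj > 0)) {
    stop("zero background probability for a base with nonzero matrix ",
         "probability gives infinite log-odds")
  }
  logodds <- log2(padj / background)
  binned <- round(logodds / bin_width)
  storage.mode(binned) <- "integer"
  motif <- structure(
    list(name = name, kind = "pwm", matrix = matrix,
         background = background, pvalue_threshold = pvalue_threshold,
         pseudocount = pseudocount, bin_width = bin_width,
         logodds = logodds, binned = binned, length = ncol(matrix)),
    class = "motif"
  )
  motif$threshold <- pwm_score_threshold(motif)
  motif
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif>", x$name, " kind:", x$kind, " length:", x$length, "\n")
  if (x$kind == "consensus") {
    cat("  consensus:", x$consensus, "\n")
  } else {
    cat("  p-value threshold:", x$pvalue_threshold,
        " score threshold (bits):", x$threshold$threshold_bits, "\n")
  }
  invisible(x)
}

# Reverse complement of a PWM probability (or binned score) matrix:
# reverse the positions and swap A<->T, C<->G.
revcomp_matrix <- function(m) {
  m[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(m))), drop = FALSE]
}

# A motif is palindromic when it matches its own reverse complement:
# for consensus motifs, string equality of the IUPAC reverse complement;
# for PWMs, equality of the probability matrix with its reverse complement.
is_palindromic <- function(motif) {
  if (motif$kind == "consensus") {
    revcomp_iupac(motif$consensus) == motif$consensus
  } else {
    max(abs(motif$matrix - revcomp_matrix(motif$matrix))) < 1e-9
  }
}

#' Read consensus motifs from a tab-separated file
#'
#' Each non-comment line holds `name<TAB>IUPAC_consensus`.
#'
#' @param path Input path.
#' @return A named list of consensus [motif] objects.
#' @export
read_motifs_consensus <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no motifs in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("motif file '", path, "': expected name<TAB>consensus on line(s) ",
         paste(which(lengths(parts) < 2), collapse = ", "))
  }
  motifs <- lapply(parts, function(p) consensus_motif(p[1], p[2]))
  stats::setNames(motifs, vapply(motifs, `[[`, character(1), "name"))
}

#' Read PWM motifs from MEME-format text
#'
#' Parses minimal MEME motif format: optional `Background letter
#' frequencies` line, then `MOTIF <name>` headers each followed by a
#' `letter-probability matrix` block with one row per position (columns
#' A, C, G, T).
#'
#' @param path Input path.
#' @param pvalue_threshold,pseudocount,bin_width Passed to [pwm_motif()].
#' @return A named list of PWM [motif] objects.
#' @export
read_motifs_meme <- function(path, pvalue_threshold = 1e-4,
                             pseudocount = 0.01, bin_width = 0.01) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0 && bg_at[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    background <- vals[!is.na(vals)]
    if (length(background) != 4) {
      stop("MEME file '", path, "': malformed background line")
    }
  }
  motif_at <- grep("^MOTIF\\s+", lines)
  if (length(motif_at) == 0) stop("MEME file '", path, "': no MOTIF blocks")
  bounds <- c(motif_at, length(lines) + 1L)
  motifs <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    block <- lines[motif_at[k]:(bounds[k + 1L] - 1L)]
    name <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    mat_at <- grep("letter-probability matrix", block)
    if (length(mat_at) == 0) {
      stop("MEME file '", path, "': motif ", name,
           " lacks a letter-probability matrix")
    }
    rows <- list()
    for (ln in block[-seq_len(mat_at[1])]) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(tok))
      if (length(vals) == 4 && !anyNA(vals)) {
        rows[[length(rows) + 1L]] <- vals
      } else if (length(rows) > 0) {
        break
      }
    }
    if (length(rows) == 0) {
      stop("MEME file '", path, "': empty matrix for motif ", name)
    }
    mat <- t(do.call(rbind, rows))  # 4 x L, rows A C G T
    motifs[[k]] <- pwm_motif(name, mat, background = background,
                             pvalue_threshold = pvalue_threshold,
                             pseudocount = pseudocount,
                             bin_width = bin_width)
  }
  stats::setNames(motifs, vapply(motifs, `[[`, character(1), "name"))
}
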