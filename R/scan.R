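#' Match an IUPAC consensus against a sequence
#'
#' Reports every offset at which the consensus matches, on the forward
#' strand and (with `both_strands = TRUE`) on the reverse strand, i.e.
#' wherever the reverse complement of the consensus matches the forward
#' sequence. Overlapping matches are all reported. A base matches a
#' consensus position when its IUPAC set is contained in the consensus
#' position's set; consequently a sequence `N` is matched only by a
#' consensus `N`. If the consensus is palindromic (equal to its own IUPAC
#' reverse complement), every reverse-strand match duplicates a
#' forward-strand match at the same offset and is reported once, with
#' strand `"+"`.
#'
#' @param sequence Nucleotide string over \{A,C,G,T,N\}.
#' @param consensus IUPAC consensus string.
#' @param both_strands Also scan the reverse strand; default TRUE.
#' @return A data.frame with columns `offset` (0-based start within
#'   `sequence`) and `strand`, sorted by offset.
#' @export
match_consensus <- function(sequence, consensus, both_strands = TRUE) {
  cm <- iupac_mask(consensus)
  sm <- sequence_mask(sequence)
  fwd <- match_mask_offsets(sm, cm)
  hits <- data.frame(offset = fwd, strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)
  if (both_strands && !identical(revcomp_iupac(consensus), toupper(consensus))) {
    rev_off <- match_mask_offsets(sm, iupac_mask(revcomp_iupac(consensus)))
    hits <- rbind(hits, data.frame(offset = rev_off,
                                   strand = rep("-", length(rev_off)),
                                   stringsAsFactors = FALSE))
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

# 0-based offsets where pattern mask cm matches subject mask sm under the
# subset rule (sequence base set contained in consensus set).
match_mask_offsets <- function(sm, cm) {
  n <- length(sm)
  L <- length(cm)
  if (L > n) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (i in seq_len(L)) {
    s <- sm[i:(n - L + i)]
    ok <- ok & bitwAnd(s, cm[i]) == s
  }
  which(ok) - 1L
}

#' Exact score distribution of a PWM under its background model
#'
#' Computes, by dynamic programming (one convolution per position over
#' the discretized per-position score distributions), the exact
#' probability distribution of the binned log-odds score of a random
#' L-mer drawn i.i.d. from the motif's background composition.
#'
#' @param motif A PWM [motif].
#' @return A list with `bins` (integer score bins, ascending; multiply by
#'   `motif$bin_width` for bits) and `prob` (their probabilities, summing
#'   to 1).
#' @export
pwm_score_distribution <- function(motif) {
  stopifnot(motif$kind == "pwm")
  b <- motif$binned
  bg <- motif$background
  dist <- 1
  lo <- 0L
  for (j in seq_len(ncol(b))) {
    bj <- b[, j]
    new_lo <- lo + min(bj)
    new_hi <- lo + length(dist) - 1L + max(bj)
    new <- numeric(new_hi - new_lo + 1L)
    for (k in 1:4) {
      at <- (lo + bj[k] - new_lo + 1L):(lo + bj[k] - new_lo + length(dist))
      new[at] <- new[at] + dist * bg[k]
    }
    dist <- new
    lo <- new_lo
  }
  list(bins = seq.int(lo, length.out = length(dist)), prob = dist)
}

#' Score threshold for a PWM at a match p-value cutoff
#'
#' Returns the smallest discretized log-odds score `s*` such that the
#' probability, under the background model, that a random L-mer scores at
#' least `s*` is no greater than `pvalue_threshold`. The tail is computed
#' exactly from [pwm_score_distribution()], never by sampling. When even
#' the maximum attainable score has tail probability above the cutoff
#' (e.g. a matrix equal to the background, where all words score ~0), the
#' threshold exceeds the maximum score and no word is admitted.
#'
#' @param motif A PWM [motif].
#' @param pvalue_threshold Cutoff; defaults to the motif's own.
#' @return A list with `threshold_bits`, `threshold_bin` (integer bin),
#'   and `tail_prob`, the exact background tail probability at the
#'   threshold.
#' @export
pwm_score_threshold <- function(motif,
                                pvalue_threshold = motif$pvalue_threshold) {
  d <- pwm_score_distribution(motif)
  tail <- rev(cumsum(rev(d$prob)))
  ok <- which(tail <= pvalue_threshold)
  if (length(ok) > 0) {
    bin <- d$bins[ok[1]]
    tp <- tail[ok[1]]
  } else {
    bin <- d$bins[length(d$bins)] + 1L
    tp <- 0
  }
  list(threshold_bits = bin * motif$bin_width, threshold_bin = bin,
       tail_prob = tp)
}

#' Scan a sequence with a motif
#'
#' For consensus motifs this is [match_consensus()] with hit score 0. For
#' PWM motifs, every window whose binned log-odds score reaches the
#' motif's precomputed threshold is reported, on both strands unless
#' `both_strands = FALSE`; windows containing `N` never match. A
#' palindromic PWM (equal to its reverse complement) is scanned on the
#' forward strand only, since every reverse-strand hit would duplicate a
#' forward hit at the same offset with the same score.
#'
#' @param sequence Nucleotide string over \{A,C,G,T,N\}.
#' @param motif A [motif].
#' @param both_strands Scan both strands; default TRUE.
#' @return A data.frame with columns `offset` (0-based), `strand`, and
#'   `score` (binned log-odds bits; 0 for consensus matches).
#' @export
scan_motif <- function(sequence, motif, both_strands = TRUE) {
  if (motif$kind == "consensus") {
    hits <- match_consensus(sequence, motif$consensus, both_strands)
    hits$score <- rep(0, nrow(hits))
    return(hits)
  }
  idx <- sequence_index(sequence)
  thr <- motif$threshold$threshold_bin
  fwd <- pwm_window_bins(idx, motif$binned)
  keep_f <- which(!is.na(fwd) & fwd >= thr)
  hits <- data.frame(offset = keep_f - 1L,
                     strand = rep("+", length(keep_f)),
                     score = fwd[keep_f] * motif$bin_width,
                     stringsAsFactors = FALSE)
  if (both_strands && !is_palindromic(motif)) {
    rev_scores <- pwm_window_bins(idx, revcomp_matrix(motif$binned))
    keep_r <- which(!is.na(rev_scores) & rev_scores >= thr)
    hits <- rbind(hits, data.frame(offset = keep_r - 1L,
                                   strand = rep("-", length(keep_r)),
                                   score = rev_scores[keep_r] * motif$bin_width,
                                   stringsAsFactors = FALSE))
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

# Binned window scores at every offset (1-based vector position = offset+1);
# NA where the window contains a non-ACGT base or the sequence is shorter
# than the motif.
pwm_window_bins <- function(idx, binned) {
  n <- length(idx)
  L <- ncol(binned)
  if (L > n) return(integer(0))
  sc <- integer(n - L + 1L)
  for (i in seq_len(L)) {
    sc <- sc + binned[cbind(idx[i:(n - L + i)], i)]
  }
  sc
}

# Number of hits of a motif in a sequence; same semantics as
# scan_motif() without the per-hit bookkeeping (hot path for counting).
count_motif_hits <- function(sequence, motif, both_strands = TRUE) {
  if (motif$kind == "consensus") {
    sm <- sequence_mask(sequence)
    n <- length(match_mask_offsets(sm, iupac_mask(motif$consensus)))
    if (both_strands) {
      rc <- revcomp_iupac(motif$consensus)
      if (!identical(rc, toupper(motif$consensus))) {
        n <- n + length(match_mask_offsets(sm, iupac_mask(rc)))
      }
    }
    return(n)
  }
  idx <- sequence_index(sequence)
  thr <- motif$threshold$threshold_bin
  sc <- pwm_window_bins(idx, motif$binned)
  n <- sum(!is.na(sc) & sc >= thr)
  if (both_strands && !is_palindromic(motif)) {
    sc <- pwm_window_bins(idx, revcomp_matrix(motif$binned))
    n <- n + sum(!is.na(sc) & sc >= thr)
  }
  as.integer(n)
}

#' Count motif occurrences per promoter
#'
#' Scans every promoter with every motif and tabulates raw occurrence
#' counts. Overlapping occurrences are all counted; promoters with no
#' hits appear with count 0.
#'
#' @param promoters A `promoter_set` from [extract_promoters()], or any
#'   data.frame with `gene_id` and `sequence` columns.
#' @param motifs A list of [motif] objects.
#' @param both_strands Scan both strands; default TRUE.
#' @return An integer matrix of class `count_table`, rows = promoter/gene
#'   ids, columns = motif names.
#' @export
count_occurrences <- function(promoters, motifs, both_strands = TRUE) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  if (anyDuplicated(promoters$gene_id)) {
    stop("duplicate promoter id(s): ",
         paste(unique(promoters$gene_id[duplicated(promoters$gene_id)]),
               collapse = ", "))
  }
  motif_names <- vapply(motifs, `[[`, character(1), "name")
  counts <- matrix(0L, nrow = nrow(promoters), ncol = length(motifs),
                   dimnames = list(promoters$gene_id, motif_names))
  for (m in seq_along(motifs)) {
    counts[, m] <- vapply(promoters$sequence, count_motif_hits,
                          integer(1), motif = motifs[[m]],
                          both_strands = both_strands, USE.NAMES = FALSE)
  }
  class(counts) <- c("count_table", class(counts))
  counts
}

#' Write a count table as tab-separated text
#'
#' @param counts A `count_table` from [count_occurrences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts),
                   as.data.frame(unclass(counts)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
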