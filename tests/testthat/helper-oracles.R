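# Independent brute-force oracles and small fixture builders. These
# deliberately share no code with the package internals they check.

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

oracle_revcomp_iupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y",
            W = "W", S = "S", Y = "R", K = "M", V = "B", H = "D",
            D = "H", B = "V", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Forward-strand consensus offsets (0-based) by per-character loops;
# a sequence N is matched only by a consensus N.
oracle_consensus_offsets <- function(sequence, consensus) {
  sq <- strsplit(sequence, "")[[1]]
  cs <- strsplit(consensus, "")[[1]]
  L <- length(cs)
  n <- length(sq)
  out <- integer(0)
  if (L > n) return(out)
  for (o in 0:(n - L)) {
    ok <- TRUE
    for (i in seq_len(L)) {
      b <- sq[o + i]
      if (b == "N") {
        if (cs[i] != "N") { ok <- FALSE; break }
      } else if (!(b %in% oracle_iupac_sets[[cs[i]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, o)
  }
  out
}

# Both-strand occurrence count with the palindromic-consensus rule.
oracle_consensus_count <- function(sequence, consensus,
                                   both_strands = TRUE) {
  n <- length(oracle_consensus_offsets(sequence, consensus))
  if (both_strands) {
    rc <- oracle_revcomp_iupac(consensus)
    if (rc != consensus) {
      n <- n + length(oracle_consensus_offsets(sequence, rc))
    }
  }
  n
}

# Exact background tail probability P(binned score >= threshold_bin) by
# enumerating all 4^L words of a PWM motif.
oracle_pwm_tail <- function(motif, threshold_bin) {
  L <- motif$length
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  tot <- 0
  for (r in seq_len(nrow(words))) {
    w <- words[r, ]
    sbin <- sum(motif$binned[cbind(w, seq_len(L))])
    if (sbin >= threshold_bin) tot <- tot + prod(motif$background[w])
  }
  tot
}

random_pwm <- function(L, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(4 * L, 1), 4, L)
    sweep(m, 2, colSums(m), "/")
  })
}

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Chebyshev-geometry ring score by direct distance arithmetic.
oracle_ring_score <- function(square, center, max_score = 5) {
  d <- max(abs(square[1] - center[1]), abs(square[2] - center[2]))
  min(max(d, 1), max_score)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
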