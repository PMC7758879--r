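# IUPAC nucleotide codes as 4-bit sets over (A, C, G, T).
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

#' Reverse complement of an IUPAC consensus string
#'
#' Complements every IUPAC ambiguity code set-wise (e.g. `R` = \{A,G\}
#' becomes `Y` = \{C,T\}) and reverses the string, so the result matches
#' the opposite strand wherever the input matches the forward strand.
#'
#' @param x A single IUPAC nucleotide string.
#' @return The reverse-complemented IUPAC string, uppercase.
#' @examples
#' revcomp_iupac("ACGT")  # palindromic: "ACGT"
#' revcomp_iupac("CCACG")
#' @export
revcomp_iupac <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_COMPLEMENT))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  }
  paste(rev(IUPAC_COMPLEMENT[chars]), collapse = "")
}

# Bitmask vector for an IUPAC pattern string; errors on invalid codes.
iupac_mask <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- IUPAC_BITS[chars]
  if (anyNA(m)) {
    stop("invalid IUPAC code(s): ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# Lookup tables indexed by character code, for fast per-base conversion.
.seq_mask_lut <- local({
  lut <- rep(NA_integer_, 128)
  for (b in c("A", "C", "G", "T", "N")) {
    lut[utf8ToInt(b)] <- IUPAC_BITS[[b]]
    lut[utf8ToInt(tolower(b))] <- IUPAC_BITS[[b]]
  }
  lut
})

.seq_index_lut <- local({
  lut <- rep(NA_integer_, 128)
  for (i in 1:4) {
    b <- c("A", "C", "G", "T")[i]
    lut[utf8ToInt(b)] <- i
    lut[utf8ToInt(tolower(b))] <- i
  }
  lut
})

# Bitmask vector for a subject sequence over {A,C,G,T,N}. A sequence N is
# the full set {A,C,G,T}; under the subset matching rule it is only matched
# by a consensus N (an unknown base satisfies no specific requirement).
sequence_mask <- function(x) {
  code <- utf8ToInt(x)
  if (any(code > 128L)) stop("sequence contains non-ASCII characters")
  m <- .seq_mask_lut[code]
  if (anyNA(m)) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    stop("sequence contains non-ACGTN character(s): ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  }
  m
}

# Integer encoding A=1 C=2 G=3 T=4, N/other -> NA (used for PWM scoring).
sequence_index <- function(x) {
  code <- utf8ToInt(x)
  if (any(code > 128L)) stop("sequence contains non-ASCII characters")
  .seq_index_lut[code]
}

# Plain-DNA reverse complement for character strings (A,C,G,T,N only).
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
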