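# Internal DNA alphabet encoding shared by all modules.
#
# Mononucleotides are coded 1..4 (A,C,G,T); code 5 is the ambiguity base N.
# Dinucleotides are coded 1..16 in first-letter-major order (AA, AC, ..., TT);
# code 17 marks a pair containing at least one N. Ambiguous symbols never get
# their own model column: wherever they occur they contribute a uniform
# 1/4 (mono) or 1/16 (di) split across the real alphabet.

MONO_LETTERS <- c("A", "C", "G", "T")
DI_LETTERS <- paste0(rep(MONO_LETTERS, each = 4L), MONO_LETTERS)
N_CODE_MONO <- 5L
N_CODE_DI <- 17L

alphabet_letters <- function(kind) {
  if (kind == "mono") MONO_LETTERS else DI_LETTERS
}

alphabet_size <- function(kind) {
  if (kind == "mono") 4L else 16L
}

#' @noRd
encode_dna <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]],
                 c(MONO_LETTERS, "N"))
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  codes
}

decode_dna <- function(codes) {
  paste(c(MONO_LETTERS, "N")[codes], collapse = "")
}

# Pair codes for positions (p, p+1), p = 1..L-1; length-<2 input gives
# integer(0).
pair_codes <- function(codes) {
  L <- length(codes)
  if (L < 2L) return(integer(0L))
  a <- codes[-L]
  b <- codes[-1L]
  out <- (a - 1L) * 4L + b
  out[a == N_CODE_MONO | b == N_CODE_MONO] <- N_CODE_DI
  out
}

# Expand a symbol-code vector into fractional per-symbol counts: the
# ambiguity code spreads uniformly over the k real symbols.
symbol_counts <- function(syms, k) {
  out <- numeric(k)
  real <- syms[syms <= k]
  if (length(real)) {
    tb <- tabulate(real, nbins = k)
    out <- out + tb
  }
  n_amb <- sum(syms == k + 1L)
  if (n_amb) out <- out + n_amb / k
  out
}

revcomp_codes <- function(codes) {
  rev(c(4L, 3L, 2L, 1L, 5L)[codes])
}
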