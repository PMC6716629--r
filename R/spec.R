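#' Define a bipartite motif search problem
#'
#' A bipartite motif consists of a left block of width `l_left` and a right
#' block of width `l_right`, separated by an unconstrained spacer (gap) whose
#' length may vary between `gap_min` and `gap_max` bases, written in the
#' field's shorthand as `l_left<[gap_min,gap_max]>l_right`. Setting
#' `l_right = 0` (which forces a zero gap) degenerates to an ordinary
#' one-block motif.
#'
#' @param l_left Width of the left block in bases (>= 1).
#' @param l_right Width of the right block in bases (>= 0). `0` means a
#'   one-block motif and requires `gap_min = gap_max = 0`.
#' @param gap_min,gap_max Inclusive bounds on the gap length in bases.
#' @param kind Matrix model: `"mono"` for a position weight matrix over
#'   single bases, `"di"` for a dinucleotide weight matrix over adjacent
#'   within-block base pairs.
#' @param mode Occurrence model: `"oops"` (exactly one site per sequence),
#'   `"zoops"` (zero or one) or `"anr"` (any number of repeats).
#'
#' @return An object of class `bipartite_spec`.
#' @examples
#' bipartite_spec(6, 6, 8, 12)
#' bipartite_spec(22, 0, 0, 0, kind = "mono")  # one-block, 22 bp
#' @export
bipartite_spec <- function(l_left, l_right, gap_min, gap_max,
                           kind = c("mono", "di"),
                           mode = c("oops", "zoops", "anr")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  l_left <- as.integer(l_left)
  l_right <- as.integer(l_right)
  gap_min <- as.integer(gap_min)
  gap_max <- as.integer(gap_max)
  if (l_left < 1L) stop("l_left must be >= 1", call. = FALSE)
  if (l_right < 0L) stop("l_right must be >= 0", call. = FALSE)
  if (gap_min < 0L || gap_max < gap_min) {
    stop("need 0 <= gap_min <= gap_max", call. = FALSE)
  }
  if (l_right == 0L && (gap_min != 0L || gap_max != 0L)) {
    stop("a one-block motif (l_right = 0) requires gap_min = gap_max = 0",
         call. = FALSE)
  }
  if (kind == "di" && (l_left < 2L || (l_right != 0L && l_right < 2L))) {
    stop("kind = 'di' needs every block at least 2 bases wide", call. = FALSE)
  }
  structure(
    list(l_left = l_left, l_right = l_right,
         gap_min = gap_min, gap_max = gap_max,
         kind = kind, mode = mode),
    class = "bipartite_spec"
  )
}

#' @export
print.bipartite_spec <- function(x, ...) {
  gap <- if (x$gap_min == x$gap_max) x$gap_min else
    paste0(x$gap_min, ",", x$gap_max)
  cat(sprintf("bipartite motif spec %d<[%s]>%d  (%s matrix, %s mode)\n",
              x$l_left, gap, x$l_right,
              if (x$kind == "mono") "mononucleotide" else "dinucleotide",
              toupper(x$mode)))
  invisible(x)
}

# Number of model columns: one per motif position (mono) or one per adjacent
# within-block pair (di) -- pairs never span the gap or the block junction.
spec_ncols <- function(spec) {
  if (spec$kind == "mono") {
    spec$l_left + spec$l_right
  } else {
    (spec$l_left - 1L) + max(spec$l_right - 1L, 0L)
  }
}

spec_nsym <- function(spec) alphabet_size(spec$kind)

spec_block_width <- function(spec) spec$l_left + spec$l_right

spec_min_width <- function(spec) spec$l_left + spec$gap_min + spec$l_right

# Column labels for reports and matrix export; the L/R prefix marks the
# block boundary.
spec_col_labels <- function(spec) {
  if (spec$kind == "mono") {
    c(if (spec$l_left) paste0("L", seq_len(spec$l_left)),
      if (spec$l_right) paste0("R", seq_len(spec$l_right)))
  } else {
    left <- if (spec$l_left >= 2L)
      paste0("L", seq_len(spec$l_left - 1L), "L", seq_len(spec$l_left - 1L) + 1L)
    right <- if (spec$l_right >= 2L)
      paste0("R", seq_len(spec$l_right - 1L), "R", seq_len(spec$l_right - 1L) + 1L)
    c(left, right)
  }
}

# Validate one placement (left_start 0-based, gap) against a sequence length.
validate_placement <- function(left_start, gap, seq_len, spec,
                               what = "placement") {
  if (gap < spec$gap_min || gap > spec$gap_max) {
    stop(sprintf("%s: gap %d outside [%d, %d]", what, gap,
                 spec$gap_min, spec$gap_max), call. = FALSE)
  }
  if (left_start < 0L ||
      left_start + spec$l_left + gap + spec$l_right > seq_len) {
    stop(sprintf("%s: site [%d, %d) exceeds sequence length %d", what,
                 left_start, left_start + spec$l_left + gap + spec$l_right,
                 seq_len), call. = FALSE)
  }
  invisible(TRUE)
}

# Canonical empty placement table.
empty_placements <- function() {
  data.frame(seq_index = integer(0), left_start = integer(0),
              gap = integer(0), present = logical(0),
              strand = character(0), stringsAsFactors = FALSE)
}

as_placements <- function(seq_index, left_start, gap, present = TRUE,
                          strand = "+") {
  n <- length(seq_index)
  data.frame(seq_index = as.integer(seq_index),
             left_start = as.integer(left_start),
             gap = as.integer(gap),
             present = rep_len(as.logical(present), n),
             strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}
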