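#' Tally motif-site symbol counts
#'
#' Builds the per-column symbol count matrix from the sites selected by
#' `placements`. Under the mononucleotide model each motif position (left
#' block positions first, then right block; the gap is excluded) is one
#' column over `{A,C,G,T}`. Under the dinucleotide model each *within-block*
#' adjacent pair is one column over the 16 dinucleotides -- no pair spans
#' the gap or the junction between the two blocks, so a `l_left`/`l_right`
#' spec yields `(l_left-1) + (l_right-1)` columns. An `N` base contributes a
#' uniform fractional count (1/4 or 1/16) to its column.
#'
#' @param sequences Sequence set from [read_sequences()] (or any data frame
#'   with `id`, `seq`).
#' @param placements Placement table (`seq_index`, `left_start`, `gap`,
#'   `present`); only present rows contribute.
#' @param spec A [bipartite_spec()].
#' @return A `count_matrix` object: list with `kind`, `counts`
#'   (columns x symbols), `n_eff` (number of contributing sites) and `spec`.
#' @export
count_sites <- function(sequences, placements, spec) {
  k <- spec_nsym(spec)
  j <- spec_ncols(spec)
  counts <- matrix(0, nrow = j, ncol = k,
                   dimnames = list(spec_col_labels(spec),
                                   alphabet_letters(spec$kind)))
  n_eff <- 0L
  codes_list <- lapply(sequences$seq, encode_dna)
  placements <- normalize_placements(placements)
  pl <- placements[placements$present, , drop = FALSE]
  for (r in seq_len(nrow(pl))) {
    i <- pl$seq_index[r]
    validate_placement(pl$left_start[r], pl$gap[r],
                       length(codes_list[[i]]), spec,
                       what = paste0("sequence ", i))
    syms <- site_symbols(codes_list[[i]], pl$left_start[r], pl$gap[r], spec,
                         strand = pl$strand[r])
    counts <- counts + symbol_increment(syms, j, k)
    n_eff <- n_eff + 1L
  }
  structure(list(kind = spec$kind, counts = counts, n_eff = n_eff,
                 spec = spec),
            class = "count_matrix")
}

# Symbol codes of one site, one per model column. `codes` is the encoded
# sequence; for the minus strand the site is read off the reverse
# complement of the window.
site_symbols <- function(codes, left_start, gap, spec, strand = "+") {
  w <- spec$l_left + gap + spec$l_right
  win <- codes[(left_start + 1L):(left_start + w)]
  if (!identical(strand, "+")) win <- revcomp_codes(win)
  left <- win[seq_len(spec$l_left)]
  right <- if (spec$l_right)
    win[(spec$l_left + gap + 1L):(spec$l_left + gap + spec$l_right)]
  else integer(0)
  if (spec$kind == "mono") {
    c(left, right)
  } else {
    c(pair_codes(left), pair_codes(right))
  }
}

# j x k increment matrix for one site's symbols (N spread uniformly).
symbol_increment <- function(syms, j, k) {
  inc <- matrix(0, j, k)
  real <- syms <= k
  inc[cbind(which(real), syms[real])] <- 1
  if (any(!real)) inc[!real, ] <- inc[!real, , drop = FALSE] + 1 / k
  inc
}

#' Tally background symbol counts
#'
#' Counts every symbol *not* covered by a present placement's blocks. Gap
#' positions count as background (the spacer is unconstrained in the model).
#' Under the dinucleotide model a pair is background only when both of its
#' positions are background. `N` contributes uniform fractional counts.
#'
#' @inheritParams count_sites
#' @return A `background_counts` object: list with `g` (length-k counts) and
#'   `n` (total tallied items, `sum(g)`).
#' @export
background_counts <- function(sequences, placements, spec) {
  k <- spec_nsym(spec)
  g <- stats::setNames(numeric(k), alphabet_letters(spec$kind))
  placements <- normalize_placements(placements)
  pl <- placements[placements$present, , drop = FALSE]
  for (i in seq_len(nrow(sequences))) {
    codes <- encode_dna(sequences$seq[i])
    sel <- pl$seq_index == i
    cover <- coverage_mask(length(codes), pl$left_start[sel], pl$gap[sel],
                           spec)
    g <- g + seq_background_counts(codes, cover, spec$kind, k)
  }
  structure(list(g = g, n = sum(g)), class = "background_counts")
}

# Logical mask of block-covered positions for one sequence.
coverage_mask <- function(len, left_start, gap, spec) {
  cover <- logical(len)
  for (r in seq_along(left_start)) {
    ls <- left_start[r]
    cover[(ls + 1L):(ls + spec$l_left)] <- TRUE
    if (spec$l_right) {
      rs <- ls + spec$l_left + gap[r]
      cover[(rs + 1L):(rs + spec$l_right)] <- TRUE
    }
  }
  cover
}

seq_background_counts <- function(codes, cover, kind, k) {
  if (kind == "mono") {
    symbol_counts(codes[!cover], k)
  } else {
    pc <- pair_codes(codes)
    keep <- !cover[-length(cover)] & !cover[-1L]
    symbol_counts(pc[keep], k)
  }
}

#' Convert counts to a pseudo-counted probability model
#'
#' Applies the additive pseudo-count rule: column probabilities
#' `p_i(x) = (f_i(x) + beta/k) / (n_eff + beta)` and background
#' `b(x) = (g(x) + beta/k) / (n + beta)`, where `k` is the alphabet size
#' (4 mono / 16 di) and `beta` is the *total* pseudo-count mass, split
#' evenly over the symbols. Every column and the background then sum to 1.
#'
#' @param counts A `count_matrix` from [count_sites()].
#' @param bg A `background_counts` from [background_counts()].
#' @param beta Total pseudo-count (default 1).
#' @return A `motif_model` object: list with `kind`, `probs`
#'   (columns x symbols), `background`, `beta`, `n_eff`, `spec`.
#' @export
to_model <- function(counts, bg, beta = 1) {
  if (counts$n_eff == 0 && beta == 0) {
    stop("empty model: no sites and no pseudo-count", call. = FALSE)
  }
  k <- ncol(counts$counts)
  probs <- (counts$counts + beta / k) / (counts$n_eff + beta)
  background <- (bg$g + beta / k) / (bg$n + beta)
  structure(list(kind = counts$kind, probs = probs, background = background,
                 beta = beta, n_eff = counts$n_eff, spec = counts$spec),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif model (%s, %d columns, %d sites, beta = %g)\n",
              x$kind, nrow(x$probs), x$n_eff, x$beta))
  cat("consensus:", model_consensus(x), "\n")
  invisible(x)
}

model_consensus <- function(model) {
  letters <- alphabet_letters(model$kind)
  paste(letters[apply(model$probs, 1L, which.max)],
        collapse = if (model$kind == "di") "," else "")
}

#' Information content of a motif model
#'
#' The search objective: the summed signed relative entropy of the motif
#' columns against the background,
#' `IC = sum_i sum_x -p_i(x) * log2(p_i(x) / b(x))`.
#' With the leading minus sign the value *decreases* as columns become more
#' concentrated relative to the background, so the motif search is a
#' minimization; a model identical to its background scores exactly 0.
#'
#' @param model A `motif_model`.
#' @return The information content in bits (scalar, typically negative for a
#'   conserved motif).
#' @export
information_content <- function(model) {
  b <- model$background
  if (any(b <= 0 & colSums(model$probs) > 0)) {
    stop("background probability 0 with positive motif probability",
         call. = FALSE)
  }
  ic_from_probs(model$probs, b)
}

ic_from_probs <- function(probs, b) {
  ratio <- sweep(probs, 2L, b, "/")
  term <- -probs * log2(ratio)
  term[probs == 0] <- 0
  sum(term)
}

# IC directly from count-state quantities (hot path helper).
ic_from_counts <- function(fmat, n_eff, g, n, beta) {
  k <- ncol(fmat)
  probs <- (fmat + beta / k) / (n_eff + beta)
  b <- (g + beta / k) / (n + beta)
  ic_from_probs(probs, b)
}

#' Log-odds score of one candidate site
#'
#' Sum over the motif columns of `log2(p_i(x) / b(x))` for the symbols read
#' at the placement (mono or di per the spec). Columns reading an `N` score
#' the uniform average `(1/k) * sum_x log2(p_i(x)/b(x))`.
#'
#' @param model A `motif_model`.
#' @param seq A DNA string (or an encoded integer vector).
#' @param left_start 0-based start of the left block.
#' @param gap Gap length.
#' @param spec A [bipartite_spec()]; defaults to the model's spec.
#' @param strand `"+"` (default) or `"-"` to read the reverse complement of
#'   the window.
#' @return Score in bits.
#' @export
site_log_odds <- function(model, seq, left_start, gap, spec = model$spec,
                          strand = "+") {
  codes <- if (is.character(seq)) encode_dna(seq) else seq
  validate_placement(left_start, gap, length(codes), spec)
  syms <- site_symbols(codes, left_start, gap, spec, strand = strand)
  lods <- log2(sweep(model$probs, 2L, model$background, "/"))
  k <- ncol(lods)
  score <- 0
  for (t in seq_along(syms)) {
    s <- syms[t]
    score <- score + if (s <= k) lods[t, s] else mean(lods[t, ])
  }
  score
}

#' Export a probability matrix as tab-delimited text
#'
#' Rows are symbols (4 or 16), columns are motif positions labelled
#' `L1..`/`R1..` (mono) or `L1L2..`/`R1R2..` (di) so the block boundary is
#' visible; a leading comment line records the spec. Probabilities are
#' written at full precision so [read_matrix()] round-trips exactly.
#'
#' @param model A `motif_model`.
#' @param path Output file path.
#' @return Invisibly, `model`.
#' @export
export_matrix <- function(model, path) {
  spec <- model$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bipartite motif %d<[%d,%d]>%d kind=%s beta=%s n_eff=%d",
                     spec$l_left, spec$gap_min, spec$gap_max, spec$l_right,
                     spec$kind, format(model$beta, digits = 17),
                     model$n_eff), con)
  m <- t(model$probs)  # symbols x positions
  writeLines(paste(c("symbol", colnames(m)), collapse = "\t"), con)
  for (s in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[s],
                       format(m[s, ], digits = 17, scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(model)
}

#' Read back an exported probability matrix
#'
#' @param path File written by [export_matrix()].
#' @return A numeric matrix, positions x symbols (same orientation as
#'   `model$probs`).
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]][-1L]
  body <- parts[-1L]
  syms <- vapply(body, `[[`, "", 1L)
  vals <- t(vapply(body, function(p) as.numeric(p[-1L]),
                   numeric(length(header))))
  out <- t(vals)
  dimnames(out) <- list(header, syms)
  out
}
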