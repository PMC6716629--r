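#' Nucleotide-level confusion counts
#'
#' Per-base set arithmetic between known and predicted site annotations:
#' `nTP` positions in both, `nFN` known only, `nFP` predicted only, `nTN`
#' neither. The four tallies always sum to the total sequence length of the
#' dataset.
#'
#' @param known,predicted Site annotation data frames (`seq_id`, `start`,
#'   `end`, 0-based half-open) as from [read_sites()].
#' @param lengths Named integer vector of sequence lengths, names = seq ids;
#'   defines the evaluation universe.
#' @return A `confusion_counts` list: `nTP`, `nFN`, `nFP`, `nTN`.
#' @export
confusion_counts <- function(known, predicted, lengths) {
  ids <- names(lengths)
  for (ann in list(known, predicted)) {
    unknown <- setdiff(unique(ann$seq_id), ids)
    if (length(unknown)) {
      stop("annotations refer to unknown sequence ids: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad <- ann$end > lengths[ann$seq_id]
    if (any(bad)) {
      stop("site interval out of bounds for sequence '",
           ann$seq_id[which(bad)[1L]], "'", call. = FALSE)
    }
  }
  nTP <- nFN <- nFP <- nTN <- 0L
  for (id in ids) {
    L <- lengths[[id]]
    km <- interval_mask(known[known$seq_id == id, , drop = FALSE], L)
    pm <- interval_mask(predicted[predicted$seq_id == id, , drop = FALSE], L)
    nTP <- nTP + sum(km & pm)
    nFN <- nFN + sum(km & !pm)
    nFP <- nFP + sum(!km & pm)
    nTN <- nTN + sum(!km & !pm)
  }
  structure(list(nTP = nTP, nFN = nFN, nFP = nFP, nTN = nTN),
            class = "confusion_counts")
}

interval_mask <- function(ann, L) {
  m <- logical(L)
  for (r in seq_len(nrow(ann))) {
    m[(ann$start[r] + 1L):ann$end[r]] <- TRUE
  }
  m
}

#' Nucleotide-level correlation coefficient
#'
#' The Matthews-type correlation over per-base site membership:
#' `nCC = (nTP*nTN - nFN*nFP) / sqrt((nTP+nFN)(nTN+nFP)(nTP+nFP)(nTN+nFN))`.
#' When any factor of the denominator is zero the value is undefined and
#' `NA` is returned (never silently coerced to 0).
#'
#' @param c A `confusion_counts` (or list with the four tallies).
#' @return A value in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
ncc <- function(c) {
  f <- as.numeric(c(c$nTP + c$nFN, c$nTN + c$nFP, c$nTP + c$nFP,
                    c$nTN + c$nFN))
  if (any(f == 0)) return(NA_real_)
  (as.numeric(c$nTP) * c$nTN - as.numeric(c$nFN) * c$nFP) /
    sqrt(prod(f))
}

#' Combined nCC over several datasets
#'
#' Pools the four tallies by addition across the parts, then applies the
#' nCC formula once (not a mean of per-part values).
#'
#' @param parts List of `confusion_counts`.
#' @return The pooled nCC (or `NA` when undefined).
#' @export
combined_ncc <- function(parts) {
  stopifnot(length(parts) >= 1L)
  tot <- list(nTP = 0, nFN = 0, nFP = 0, nTN = 0)
  for (p in parts) {
    tot$nTP <- tot$nTP + p$nTP
    tot$nFN <- tot$nFN + p$nFN
    tot$nFP <- tot$nFP + p$nFP
    tot$nTN <- tot$nTN + p$nTN
  }
  ncc(tot)
}

#' Sequence-level detection rates
#'
#' For noise-spiking benchmarks: `TPR` = fraction of motif-bearing
#' sequences called present, `FPR` = fraction of motif-free (noise)
#' sequences called present.
#'
#' @param truth_labels Named character vector, `"motif"` or `"noise"` per
#'   sequence id.
#' @param predictions Named logical vector (or `"present"`/`"absent"`
#'   character), aligned by name.
#' @return List with `TPR` and `FPR` (either may be `NA` when its
#'   denominator is zero).
#' @export
sequence_rates <- function(truth_labels, predictions) {
  if (is.character(predictions)) predictions <- predictions == "present"
  ids <- names(truth_labels)
  if (!all(ids %in% names(predictions))) {
    stop("predictions missing for some sequences", call. = FALSE)
  }
  pred <- predictions[ids]
  motif <- truth_labels == "motif"
  tpr <- if (sum(motif) == 0L) NA_real_ else sum(pred & motif) / sum(motif)
  fpr <- if (sum(!motif) == 0L) NA_real_ else sum(pred & !motif) / sum(!motif)
  list(TPR = tpr, FPR = fpr)
}

#' Pairwise positional mutual information of aligned sites
#'
#' For every pair of positions `(a, b)` of an aligned, equal-width site
#' collection, the empirical mutual information in bits,
#' `MI(a,b) = sum_{x,y} p_ab(x,y) log2(p_ab(x,y) / (p_a(x) p_b(y)))`,
#' using raw frequencies without pseudo-counts (`0*log 0 = 0`). The
#' diagonal holds the marginal column entropies; the matrix is symmetric
#' and non-negative.
#'
#' @param sites Character vector of aligned site strings over `{A,C,G,T}`,
#'   all the same width; at least 2 sites.
#' @return A `width x width` numeric matrix (bits).
#' @export
mutual_information <- function(sites) {
  if (length(sites) < 2L) stop("need at least 2 sites", call. = FALSE)
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites must all have the same width",
                            call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(sites), "", fixed = TRUE))
  if (!all(mat %in% MONO_LETTERS)) {
    stop("sites must use only {A,C,G,T}", call. = FALSE)
  }
  n <- nrow(mat)
  marg <- lapply(seq_len(w), function(a) {
    table(factor(mat[, a], levels = MONO_LETTERS)) / n
  })
  out <- matrix(0, w, w)
  for (a in seq_len(w)) {
    for (b in a:w) {
      joint <- table(factor(mat[, a], levels = MONO_LETTERS),
                     factor(mat[, b], levels = MONO_LETTERS)) / n
      pp <- outer(as.numeric(marg[[a]]), as.numeric(marg[[b]]))
      term <- joint * log2(joint / pp)
      term[joint == 0] <- 0
      out[a, b] <- out[b, a] <- sum(term)
    }
  }
  out
}

#' Convert placements to site annotations
#'
#' Predicted site positions are the block positions only by default -- the
#' gap is unconstrained in the model and is not counted as predicted; set
#' `count_gap = TRUE` to annotate one interval spanning blocks and gap (for
#' sensitivity checks of nucleotide-level scores).
#'
#' @param placements Placement data frame.
#' @param spec A [bipartite_spec()].
#' @param seq_ids Character vector mapping `seq_index` to sequence id.
#' @param count_gap Count gap positions as predicted site positions?
#' @return A site annotation data frame (`seq_id`, `start`, `end`).
#' @export
placements_to_sites <- function(placements, spec, seq_ids,
                                count_gap = FALSE) {
  pl <- normalize_placements(placements)
  pl <- pl[pl$present, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(pl))) {
    id <- seq_ids[pl$seq_index[r]]
    ls <- pl$left_start[r]
    gap <- pl$gap[r]
    le <- ls + spec$l_left
    rs <- le + gap
    re <- rs + spec$l_right
    out[[length(out) + 1L]] <-
      if (count_gap || spec$l_right == 0L) {
        data.frame(seq_id = id, start = ls,
                   end = if (count_gap) re else le,
                   stringsAsFactors = FALSE)
      } else if (gap == 0L) {
        data.frame(seq_id = id, start = ls, end = re,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(seq_id = c(id, id), start = c(ls, rs), end = c(le, re),
                   stringsAsFactors = FALSE)
      }
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  validate_sites(do.call(rbind, out))
}
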