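# Incremental count state for the entropy search.
#
# The search objective couples every placement through both the motif count
# matrix and the placement-dependent background composition, so the state
# tracks both and updates them per-sequence: removing or adding one
# sequence's placements touches only that sequence's site symbols and its
# background contribution. The total IC is always recomputable from the
# counts in O(columns x alphabet).
#
# Hot-path placement rows are plain lists of parallel vectors ("plr"), not
# data frames; data frames appear only at the API boundary.

plr <- function(left_start = integer(0), gap = integer(0),
                present = logical(0), strand = character(0)) {
  n <- length(left_start)
  list(left_start = as.integer(left_start), gap = as.integer(gap),
       present = rep_len(as.logical(present), n),
       strand = rep_len(as.character(strand), n))
}

plr_empty <- plr()

plr_site <- function(left_start, gap, strand = "+") {
  list(left_start = as.integer(left_start), gap = as.integer(gap),
       present = TRUE, strand = strand)
}

plr_absent <- list(left_start = 0L, gap = 0L, present = FALSE, strand = "+")

plr_equal <- function(a, b) {
  ka <- a$present
  kb <- b$present
  sum(ka) == sum(kb) &&
    all(a$left_start[ka] == b$left_start[kb]) &&
    all(a$gap[ka] == b$gap[kb]) &&
    all(a$strand[ka] == b$strand[kb])
}

# Split a placement data frame into per-sequence plr lists.
split_placements <- function(placements, nseq) {
  placements <- normalize_placements(placements)
  out <- rep(list(plr_empty), nseq)
  for (i in unique(placements$seq_index)) {
    sel <- placements$seq_index == i
    out[[i]] <- plr(placements$left_start[sel], placements$gap[sel],
                    placements$present[sel], placements$strand[sel])
  }
  out
}

# Fill optional placement columns with their defaults.
normalize_placements <- function(pl) {
  if (is.null(pl$present)) pl$present <- rep(TRUE, nrow(pl))
  if (is.null(pl$strand)) pl$strand <- rep("+", nrow(pl))
  pl
}

#' Build an incremental motif count state
#'
#' The state carries, for a fixed sequence set and spec, the motif count
#' matrix, the background tallies, and each sequence's current placements.
#' [delta_ic_remove_add()] and the search sweeps mutate it in place
#' (it is an environment).
#'
#' @inheritParams count_sites
#' @param beta Total pseudo-count (default 1).
#' @return A `motif_state` environment.
#' @export
motif_state <- function(sequences, placements, spec, beta = 1) {
  st <- new.env(parent = emptyenv())
  st$spec <- spec
  st$beta <- beta
  st$k <- spec_nsym(spec)
  st$j <- spec_ncols(spec)
  st$codes <- lapply(sequences$seq, encode_dna)
  st$len <- lengths(st$codes)
  st$nseq <- length(st$codes)
  st$fmat <- matrix(0, st$j, st$k,
                    dimnames = list(spec_col_labels(spec),
                                    alphabet_letters(spec$kind)))
  st$n_eff <- 0L
  # per-sequence background contribution with *no* placements
  st$free_bg <- lapply(st$codes, function(cd)
    seq_background_counts(cd, logical(length(cd)), spec$kind, st$k))
  st$gvec <- Reduce(`+`, st$free_bg, numeric(st$k))
  st$pl <- rep(list(plr_empty), st$nseq)
  # candidate-cache index of each sequence's single committed placement
  # (sweep fast path); NA when absent, foreign or multi-site
  st$cur_idx <- rep(NA_integer_, st$nseq)
  class(st) <- "motif_state"
  rows <- split_placements(placements, st$nseq)
  for (i in seq_len(st$nseq)) {
    if (length(rows[[i]]$left_start)) st_set(st, i, rows[[i]])
  }
  st
}

# Background contribution of sequence i under plr `p`.
st_seq_bg <- function(st, i, p) {
  keep <- p$present
  if (!any(keep)) return(st$free_bg[[i]])
  cover <- coverage_mask(st$len[i], p$left_start[keep], p$gap[keep],
                         st$spec)
  seq_background_counts(st$codes[[i]], cover, st$spec$kind, st$k)
}

# Replace sequence i's placements with plr `p`.
st_set <- function(st, i, p) {
  old <- st$pl[[i]]
  for (r in which(old$present)) {
    syms <- site_symbols(st$codes[[i]], old$left_start[r], old$gap[r],
                         st$spec, strand = old$strand[r])
    st$fmat <- st$fmat - symbol_increment(syms, st$j, st$k)
    st$n_eff <- st$n_eff - 1L
  }
  for (r in which(p$present)) {
    validate_placement(p$left_start[r], p$gap[r], st$len[i], st$spec,
                       what = paste0("sequence ", i))
    syms <- site_symbols(st$codes[[i]], p$left_start[r], p$gap[r],
                         st$spec, strand = p$strand[r])
    st$fmat <- st$fmat + symbol_increment(syms, st$j, st$k)
    st$n_eff <- st$n_eff + 1L
  }
  st$gvec <- st$gvec - st_seq_bg(st, i, old) + st_seq_bg(st, i, p)
  st$pl[[i]] <- p
  st$cur_idx[i] <- NA_integer_
  invisible(st)
}

# Sweep fast path: detach/commit one forward-strand placement through the
# precomputed candidate tables, avoiding symbol re-derivation. Exact same
# count arithmetic as st_set.
st_detach_fast <- function(st, i, cache_i) {
  idx <- st$cur_idx[i]
  if (is.na(idx)) {
    if (any(st$pl[[i]]$present)) st_set(st, i, plr_empty)
    else st$pl[[i]] <- plr_empty
    return(invisible(st))
  }
  syms <- cache_i$S[idx, ]
  real <- syms <= st$k
  if (all(real)) {
    pos <- cbind(seq_len(st$j), syms)
    st$fmat[pos] <- st$fmat[pos] - 1
  } else {
    pos <- cbind(which(real), syms[real])
    st$fmat[pos] <- st$fmat[pos] - 1
    st$fmat[!real, ] <- st$fmat[!real, , drop = FALSE] - 1 / st$k
  }
  st$n_eff <- st$n_eff - 1L
  st$gvec <- st$gvec + cache_i$C[idx, ]
  st$pl[[i]] <- plr_empty
  st$cur_idx[i] <- NA_integer_
  invisible(st)
}

st_commit_fast <- function(st, i, idx, cache_i) {
  syms <- cache_i$S[idx, ]
  real <- syms <= st$k
  if (all(real)) {
    pos <- cbind(seq_len(st$j), syms)
    st$fmat[pos] <- st$fmat[pos] + 1
  } else {
    pos <- cbind(which(real), syms[real])
    st$fmat[pos] <- st$fmat[pos] + 1
    st$fmat[!real, ] <- st$fmat[!real, , drop = FALSE] + 1 / st$k
  }
  st$n_eff <- st$n_eff + 1L
  st$gvec <- st$gvec - cache_i$C[idx, ]
  st$pl[[i]] <- plr_site(cache_i$cand$start[idx], cache_i$cand$gap[idx])
  st$cur_idx[i] <- idx
  invisible(st)
}

#' Total information content of the current state
#'
#' @param st A [motif_state()].
#' @return IC in bits, identical (to floating-point noise) to rebuilding the
#'   model with [count_sites()], [background_counts()], [to_model()] and
#'   [information_content()].
#' @export
state_entropy <- function(st) {
  ic_from_counts(st$fmat, st$n_eff, st$gvec, sum(st$gvec), st$beta)
}

#' Current placements held by a state
#'
#' @param st A [motif_state()].
#' @return A placement data frame (all sequences, row-bound).
#' @export
state_placements <- function(st) {
  n_rows <- vapply(st$pl, function(p) length(p$left_start), 0L)
  as_placements(
    seq_index = rep(seq_len(st$nseq), n_rows),
    left_start = unlist(lapply(st$pl, `[[`, "left_start")),
    gap = unlist(lapply(st$pl, `[[`, "gap")),
    present = as.logical(unlist(lapply(st$pl, `[[`, "present"))),
    strand = as.character(unlist(lapply(st$pl, `[[`, "strand")))
  )
}

#' Incremental entropy change of a placement swap
#'
#' Replaces one sequence's placement set and returns
#' `IC(after) - IC(before)`, computed by updating only that sequence's
#' motif-column and background tallies. The state is left holding the new
#' placement. Agrees with a from-scratch recomputation to well below 1e-9.
#'
#' @param st A [motif_state()].
#' @param seq_index Sequence to update (1-based).
#' @param new_placements Replacement placement rows for that sequence (data
#'   frame with `left_start`, `gap` and optionally `present`, `strand`; may
#'   be empty or non-present for a ZOOPS removal).
#' @return The entropy change in bits.
#' @export
delta_ic_remove_add <- function(st, seq_index, new_placements) {
  before <- state_entropy(st)
  p <- normalize_placements(new_placements)
  st_set(st, seq_index, plr(p$left_start, p$gap, p$present, p$strand))
  state_entropy(st) - before
}
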