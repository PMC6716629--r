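#' Search configuration
#'
#' Tunable knobs of the entropy-minimizing search. Defaults: 100 random
#' restarts, convergence tolerance `epsilon = 1e-8` on the change in
#' entropy between sweeps, a safety cap of 500 sweeps per restart, a ZOOPS
#' inclusion threshold of 0 bits (a site must beat the background to be
#' kept), and at most 10 sites per sequence under ANR.
#'
#' @param restarts Number of independent random restarts (>= 1).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param epsilon Convergence tolerance on the entropy difference between
#'   successive sweeps (bits).
#' @param max_sweeps Cap on greedy sweeps per restart.
#' @param zoops_threshold Minimum per-site log-odds (bits) for an occurrence
#'   to be kept under ZOOPS/ANR.
#' @param anr_max_sites Cap on sites per sequence under ANR.
#' @param beta Total pseudo-count for the probability model.
#' @param shuffle_order Visit sequences in a freshly shuffled order each
#'   sweep instead of fixed index order (consumes the seeded RNG).
#' @param both_strands Also scan the reverse complement when placing ANR
#'   sites and scoring; model training itself reads the forward strand.
#' @return A `search_config` list.
#' @export
search_config <- function(restarts = 100L, seed = NULL, epsilon = 1e-8,
                          max_sweeps = 500L, zoops_threshold = 0,
                          anr_max_sites = 10L, beta = 1,
                          shuffle_order = FALSE, both_strands = FALSE) {
  stopifnot(restarts >= 1L, epsilon > 0, max_sweeps >= 1L, beta > 0)
  structure(list(restarts = as.integer(restarts), seed = seed,
                 epsilon = epsilon, max_sweeps = as.integer(max_sweeps),
                 zoops_threshold = zoops_threshold,
                 anr_max_sites = as.integer(anr_max_sites), beta = beta,
                 shuffle_order = shuffle_order, both_strands = both_strands),
            class = "search_config")
}

# All feasible (left_start, gap) pairs for a sequence of length L, ordered
# by start then gap; that order makes which.min() implement the documented
# tie-break (smallest left_start, then smallest gap).
enumerate_candidates <- function(L, spec) {
  pieces <- lapply(spec$gap_min:spec$gap_max, function(g) {
    smax <- L - (spec$l_left + g + spec$l_right)
    if (smax < 0L) return(NULL)
    data.frame(start = 0L:smax, gap = g)
  })
  cand <- do.call(rbind, pieces)
  if (is.null(cand)) {
    return(data.frame(start = integer(0), gap = integer(0)))
  }
  cand[order(cand$start, cand$gap), , drop = FALSE]
}

# Per-sequence candidate tables used by the vectorized scorer:
#   S: ncand x j matrix of site symbol codes (N coded k+1),
#   M: ncand x k fractional motif-count additions,
#   C: ncand x k fractional background-count removals.
# Under the mono model C == M (block letters leave the background); under
# the di model C also covers the pairs that straddle a block edge, counted
# over the union of the per-block exclusion ranges.
build_seq_cache <- function(codes, spec) {
  L <- length(codes)
  cand <- enumerate_candidates(L, spec)
  ncand <- nrow(cand)
  j <- spec_ncols(spec)
  k <- spec_nsym(spec)
  if (ncand == 0L) {
    return(list(cand = cand, S = matrix(0L, 0L, j), M = matrix(0, 0L, k),
                C = matrix(0, 0L, k)))
  }
  start <- cand$start
  gap <- cand$gap
  rs <- start + spec$l_left + gap          # 0-based right-block start
  S <- matrix(0L, ncand, j)
  if (spec$kind == "mono") {
    for (t in seq_len(spec$l_left)) S[, t] <- codes[start + t]
    if (spec$l_right) {
      for (t in seq_len(spec$l_right)) S[, spec$l_left + t] <- codes[rs + t]
    }
  } else {
    px <- pair_codes(codes)
    for (t in seq_len(spec$l_left - 1L)) S[, t] <- px[start + t]
    if (spec$l_right >= 2L) {
      off <- spec$l_left - 1L
      for (t in seq_len(spec$l_right - 1L)) S[, off + t] <- px[rs + t]
    }
  }
  M <- matrix(0, ncand, k)
  for (x in seq_len(k)) M[, x] <- rowSums(S == x)
  amb <- rowSums(S == k + 1L)
  if (any(amb > 0)) M <- M + amb / k
  if (spec$kind == "mono") {
    C <- M
  } else {
    # cumulative pair-symbol counts: Pcum[p + 1, x] = count in pairs 1..p
    npair <- L - 1L
    P <- matrix(0, npair, 17L)
    P[cbind(seq_len(npair), px)] <- 1
    Pcum <- rbind(0, apply(P, 2L, cumsum))
    range_counts <- function(s, e) {
      s <- pmax(s, 1L); e <- pmin(e, npair)
      ok <- s <= e
      out <- matrix(0, ncand, 17L)
      if (any(ok)) {
        out[ok, ] <- Pcum[e[ok] + 1L, , drop = FALSE] -
          Pcum[s[ok], , drop = FALSE]
      }
      out
    }
    merged <- spec$l_right > 0L & gap == 0L
    C17 <- matrix(0, ncand, 17L)
    # left-block exclusion pairs: p in [start, start + l_left]
    e_left <- ifelse(merged, start + spec$l_left + spec$l_right,
                     start + spec$l_left)
    C17 <- C17 + range_counts(start, e_left)
    if (spec$l_right > 0L) {
      s_right <- ifelse(merged, 1L, rs)        # dummy empty when merged
      e_right <- ifelse(merged, 0L, rs + spec$l_right)
      C17 <- C17 + range_counts(s_right, e_right)
    }
    C <- C17[, 1:16, drop = FALSE] + C17[, 17L] / 16
  }
  list(cand = cand, S = S, M = M, C = C)
}

# Lazily build and attach the per-sequence candidate caches to a state.
get_cand_cache <- function(st) {
  if (is.null(st$cand_cache)) {
    st$cand_cache <- lapply(st$codes, build_seq_cache, spec = st$spec)
  }
  st$cand_cache
}

# Score every candidate placement of sequence i (which must currently hold
# no placements in the state) plus the no-occurrence option. Returns the
# exact total IC that committing each option would produce.
score_candidates <- function(st, i, cache_i) {
  beta <- st$beta
  k <- st$k
  j <- st$j
  bk <- beta / k
  f_base <- st$fmat
  neff0 <- st$n_eff
  g_all <- st$gvec
  n_all <- sum(g_all)
  # no-occurrence option
  p0 <- (f_base + bk) / (neff0 + beta)
  b0 <- (g_all + bk) / (n_all + beta)
  ic_absent <- ic_from_probs(p0, b0)

  ncand <- nrow(cache_i$cand)
  if (ncand == 0L) return(list(ic = numeric(0), ic_absent = ic_absent))
  denom <- neff0 + 1 + beta
  # column-entropy part: depends on the added symbol only. With
  # h(z) = z*log2(z), the column entropy after adding one count at symbol
  # s is -(S_h - h(v_s) + h(v_s + 1))/denom + log2(denom), where v is the
  # pseudo-counted base column and S_h = sum_x h(v_x).
  h <- function(z) z * log2(z)
  V <- f_base + bk
  H1 <- h(V)
  S_h <- rowSums(H1)
  Aent <- cbind(-(S_h - H1 + h(V + 1)) / denom + log2(denom),
                -rowSums(h(V + 1 / k)) / denom + log2(denom))
  # cross term with the candidate-dependent background
  gprime <- matrix(g_all, ncand, k, byrow = TRUE) - cache_i$C
  nprime <- n_all - rowSums(cache_i$C)
  logb <- log2(gprime + bk) - log2(nprime + beta)
  colTot <- colSums(f_base)
  B <- (logb %*% (colTot + j * bk) + rowSums(cache_i$M * logb)) / denom
  A <- numeric(ncand)
  for (t in seq_len(j)) A <- A + Aent[t, cache_i$S[, t]]
  list(ic = unname(A + as.vector(B)), ic_absent = unname(ic_absent))
}

# Leave-one-out log-odds of candidate row `idx` of sequence i against the
# model built from the detached state.
loo_log_odds <- function(st, cache_i, idx) {
  bk <- st$beta / st$k
  p <- (st$fmat + bk) / (st$n_eff + st$beta)
  b <- (st$gvec + bk) / (sum(st$gvec) + st$beta)
  lods <- log2(sweep(p, 2L, b, "/"))
  syms <- cache_i$S[idx, ]
  sc <- 0
  for (t in seq_along(syms)) {
    s <- syms[t]
    sc <- sc + if (s <= st$k) lods[t, s] else mean(lods[t, ])
  }
  sc
}

# One greedy update of sequence i; returns TRUE when the committed
# placement differs from the incumbent. The committed option never has
# higher total IC than the incumbent configuration, so sweeps are
# entropy-monotone; under ZOOPS the log-odds threshold picks between the
# best placement and absence whenever that choice does not worsen the
# objective.
update_seq <- function(st, cache, i, config, zoops_active = TRUE) {
  mode <- st$spec$mode
  incumbent <- st$pl[[i]]
  cache_i <- cache[[i]]
  st_detach_fast(st, i, cache_i)
  sc <- score_candidates(st, i, cache_i)
  best_idx <- which.min(sc$ic)
  cand <- cache_i$cand
  best_pl <- plr_site(cand$start[best_idx], cand$gap[best_idx])
  if (mode != "zoops" || !zoops_active) {
    st_commit_fast(st, i, best_idx, cache_i)
    return(!plr_equal(incumbent, best_pl))
  }
  # ZOOPS compares configurations with different occupancy counts, where
  # the per-site entropy alone is degenerate (it always prefers a small
  # clique of near-identical sites). The mode's objective is a description
  # length: L = n_eff * IC + sum over present sequences of the position
  # cost log2(ncand_i) + zoops_threshold -- compression gained by the
  # motif minus the bits spent to say where each occurrence sits. At fixed
  # occupancy argmin L = argmin IC, and an occurrence pays for itself
  # exactly when its log-odds beats its position cost, so the threshold
  # rule and the objective agree to first order; the explicit gate below
  # makes every committed move non-increasing in L.
  neff0 <- st$n_eff   # sites currently present in the other sequences
  cost_i <- log2(nrow(cand)) + config$zoops_threshold
  inc_present <- any(incumbent$present)
  L_incumbent <- if (inc_present) {
    r <- which(incumbent$present)[1L]
    (neff0 + 1) * sc$ic[which(cand$start == incumbent$left_start[r] &
                                cand$gap == incumbent$gap[r])[1L]] + cost_i
  } else if (length(incumbent$left_start)) neff0 * sc$ic_absent else Inf
  L_best <- (neff0 + 1) * sc$ic[best_idx] + cost_i
  L_absent <- neff0 * sc$ic_absent
  if (neff0 < 2L) {
    # degeneracy guard: with fewer than 2 other sites present the absent
    # option is disabled for this sweep
    choice <- best_pl
  } else {
    # the occurrence must beat the background by more than its position
    # cost (the best-of-ncand selection), plus the user threshold
    lo <- loo_log_odds(st, cache_i, best_idx)
    keep <- lo >= cost_i
    L_choice <- if (keep) L_best else L_absent
    if (L_choice > L_incumbent + 1e-9) {
      # never commit a move that worsens the objective: fall back to the
      # incumbent occupancy state (with best placement if present)
      keep <- inc_present
    }
    choice <- if (keep) best_pl else plr_absent
  }
  if (any(choice$present)) {
    st_commit_fast(st, i, best_idx, cache_i)
  } else {
    st$pl[[i]] <- plr_absent
  }
  !plr_equal(incumbent, choice)
}

# The objective logged in traces and compared across restarts: plain IC
# under fixed occupancy (OOPS/ANR training); under ZOOPS the description
# length n_eff * IC + the summed position costs of the present
# occurrences.
state_objective <- function(st, config = NULL) {
  ic <- state_entropy(st)
  if (st$spec$mode != "zoops") return(ic)
  thr <- if (is.null(config)) 0 else config$zoops_threshold
  # an infinite threshold (e.g. -Inf = force OOPS) still needs a finite
  # logged objective; the occupancy decisions themselves use the real one
  if (!is.finite(thr)) thr <- 0
  cache <- get_cand_cache(st)
  pres <- vapply(st$pl, function(p) any(p$present), NA)
  costs <- vapply(cache[pres], function(ci) log2(nrow(ci$cand)), 0) + thr
  st$n_eff * ic + sum(costs)
}

#' One greedy sweep over all sequences
#'
#' Visits each sequence once (fixed index order unless
#' `config$shuffle_order`), re-places it at the feasible (start, gap) pair
#' minimizing the total information content given all other placements, and
#' returns the updated entropy. Because the incumbent placement is always
#' among the evaluated options, the entropy never increases.
#'
#' @param st A [motif_state()].
#' @param config A [search_config()].
#' @return List with `entropy` (the mode's objective after the sweep: IC in
#'   bits, occupancy-weighted under ZOOPS) and `changed` (did any placement
#'   move?).
#' @export
greedy_sweep <- function(st, config = search_config(), zoops_active = TRUE) {
  cache <- get_cand_cache(st)
  ord <- seq_len(st$nseq)
  if (isTRUE(config$shuffle_order)) ord <- sample(ord)
  changed <- FALSE
  for (i in ord) {
    changed <- update_seq(st, cache, i, config, zoops_active) || changed
  }
  list(entropy = state_objective(st, config), changed = changed)
}

#' Randomly initialize placements
#'
#' For each sequence, draws the gap uniformly from the feasible subset of
#' `[gap_min, gap_max]` and the left start uniformly from the valid starts
#' for that gap. All sequences start present (ANR starts with one site per
#' sequence). Errors if any sequence is too short for the minimal motif
#' width.
#'
#' @inheritParams count_sites
#' @return A placement data frame (one present row per sequence).
#' @export
initialize_placements <- function(sequences, spec) {
  n <- nrow(sequences)
  left_start <- integer(n)
  gap <- integer(n)
  for (i in seq_len(n)) {
    L <- nchar(sequences$seq[i])
    if (L < spec_min_width(spec)) {
      stop(sprintf("sequence '%s' (length %d) is shorter than the minimal motif width %d",
                   sequences$id[i], L, spec_min_width(spec)), call. = FALSE)
    }
    gaps_ok <- (spec$gap_min:spec$gap_max)[
      spec$gap_min:spec$gap_max <= L - spec$l_left - spec$l_right]
    g <- gaps_ok[sample.int(length(gaps_ok), 1L)]
    smax <- L - (spec$l_left + g + spec$l_right)
    left_start[i] <- sample.int(smax + 1L, 1L) - 1L
    gap[i] <- g
  }
  as_placements(seq_len(n), left_start, gap)
}

#' Run a single restart to convergence
#'
#' Initializes placements at random, then sweeps greedily until no
#' placement moves or the entropy change between sweeps drops below
#' `config$epsilon`, up to `config$max_sweeps` (a capped-out restart is
#' flagged unconverged, not an error). Uses the current RNG state.
#'
#' @inheritParams count_sites
#' @param config A [search_config()].
#' @param st Optionally, a prebuilt [motif_state()] for `sequences`/`spec`
#'   (reused across restarts by [bimotif_search()]).
#' @return List with `placements`, `entropy`, `trace` (entropy after each
#'   sweep, starting with the post-initialization value) and `converged`.
#' @export
run_restart <- function(sequences, spec, config = search_config(),
                        st = NULL) {
  if (is.null(st)) st <- motif_state(sequences, empty_placements(), spec,
                                     beta = config$beta)
  init <- initialize_placements(sequences, spec)
  cache <- get_cand_cache(st)
  for (i in seq_len(st$nseq)) {
    st_detach_fast(st, i, cache[[i]])
    idx <- which(cache[[i]]$cand$start == init$left_start[i] &
                   cache[[i]]$cand$gap == init$gap[i])[1L]
    st_commit_fast(st, i, idx, cache[[i]])
  }
  trace <- state_objective(st, config)
  converged <- FALSE
  # Under ZOOPS, a warm-up phase first converges the all-present (OOPS)
  # placements so the occupancy competition starts from a formed model;
  # against an unformed model no site beats its position cost and the
  # occupancy would collapse to the degeneracy guard.
  warm <- st$spec$mode == "zoops"
  for (sw in seq_len(config$max_sweeps)) {
    res <- greedy_sweep(st, config, zoops_active = !warm)
    trace <- c(trace, res$entropy)
    settled <- !res$changed ||
      abs(trace[length(trace)] - trace[length(trace) - 1L]) <
        config$epsilon
    if (settled) {
      if (warm) {
        warm <- FALSE
      } else {
        converged <- TRUE
        break
      }
    }
  }
  list(placements = state_placements(st), entropy = state_objective(st, config),
       trace = trace, converged = converged)
}

#' Discover a bipartite motif by entropy minimization
#'
#' The main search: `config$restarts` independent restarts, each from
#' random initial placements, each improved by greedy per-sequence updates
#' that minimize the information content of the concatenated two-block
#' motif against the placement-dependent background. The restart with the
#' lowest final entropy wins (ties go to the earliest restart). Under ANR
#' the winning model is used for a final non-overlapping scan that may
#' place zero or several sites per sequence.
#'
#' Under ZOOPS the quantity minimized, logged in the traces and compared
#' across restarts is the occupancy-weighted entropy `n_eff * IC` (see
#' [greedy_sweep()]); under OOPS the plain IC, so there `entropy` equals
#' `min(restart_entropies)` exactly.
#'
#' @inheritParams count_sites
#' @param config A [search_config()].
#' @return A `bimotif_result`: list with `placements`, `model`, `entropy`,
#'   `restart_entropies`, `restart_traces`, `restart_converged`,
#'   `best_restart`, `unconverged`, `spec`, `config`, `sequences`.
#' @examples
#' set.seed(1)
#' seqs <- data.frame(
#'   id = paste0("s", 1:6),
#'   seq = vapply(1:6, function(i) {
#'     bg <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
#'     s <- sample(0:20, 1)
#'     bg[(s + 1):(s + 6)] <- strsplit("TTGACA", "")[[1]]
#'     bg[(s + 15):(s + 20)] <- strsplit("TATAAT", "")[[1]]
#'     paste(bg, collapse = "")
#'   }, ""))
#' spec <- bipartite_spec(6, 6, 8, 8)
#' res <- bimotif_search(seqs, spec, search_config(restarts = 5, seed = 42))
#' res$entropy
#' @export
bimotif_search <- function(sequences, spec, config = search_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  train_spec <- spec
  if (spec$mode == "anr") {
    # ANR trains like OOPS, then scans with the learned model
    train_spec <- spec
    train_spec$mode <- "oops"
  }
  st <- motif_state(sequences, empty_placements(), train_spec,
                    beta = config$beta)
  entropies <- numeric(config$restarts)
  traces <- vector("list", config$restarts)
  conv <- logical(config$restarts)
  best <- NULL
  for (r in seq_len(config$restarts)) {
    rr <- run_restart(sequences, train_spec, config, st = st)
    entropies[r] <- rr$entropy
    traces[[r]] <- rr$trace
    conv[r] <- rr$converged
    if (is.null(best) || rr$entropy < best$entropy - 1e-12) {
      best <- rr
      best$index <- r
    }
  }
  placements <- best$placements
  model <- to_model(count_sites(sequences, placements, train_spec),
                    background_counts(sequences, placements, train_spec),
                    beta = config$beta)
  if (spec$mode == "anr") {
    placements <- anr_scan(sequences, model, spec, config)
    model <- to_model(count_sites(sequences, placements, spec),
                      background_counts(sequences, placements, spec),
                      beta = config$beta)
  }
  structure(list(
    placements = placements,
    model = model,
    entropy = information_content(model),
    restart_entropies = entropies,
    restart_traces = traces,
    restart_converged = conv,
    best_restart = best$index,
    unconverged = !any(conv),
    spec = spec,
    config = config,
    sequences = sequences
  ), class = "bimotif_result")
}

#' @export
print.bimotif_result <- function(x, ...) {
  print(x$spec)
  cat(sprintf("final entropy: %.6f bits (best of %d restarts%s)\n",
              x$entropy, length(x$restart_entropies),
              if (x$unconverged) ", UNCONVERGED" else ""))
  cat(sprintf("sites placed: %d of %d sequences\n",
              sum(x$placements$present),
              length(unique(x$placements$seq_index))))
  cat("consensus:", model_consensus(x$model), "\n")
  invisible(x)
}

#' Scan sequences for repeated motif occurrences
#'
#' ANR placement: for each sequence, scores every feasible (start, gap)
#' pair (both strands when `config$both_strands`) against a trained model
#' and greedily accepts non-overlapping sites in descending log-odds order,
#' while the score stays at or above `config$zoops_threshold` and at most
#' `config$anr_max_sites` per sequence. Overlap is judged on block
#' positions only; gaps may overlap other sites.
#'
#' @inheritParams count_sites
#' @param model A trained `motif_model`.
#' @param config A [search_config()].
#' @return A placement data frame; sequences with no accepted site get one
#'   non-present sentinel row.
#' @export
anr_scan <- function(sequences, model, spec, config = search_config()) {
  out <- empty_placements()
  for (i in seq_len(nrow(sequences))) {
    codes <- encode_dna(sequences$seq[i])
    cand <- enumerate_candidates(length(codes), spec)
    strands <- if (isTRUE(config$both_strands)) c("+", "-") else "+"
    rows <- do.call(rbind, lapply(strands, function(sd) {
      cbind(cand, strand = sd,
            score = vapply(seq_len(nrow(cand)), function(r) {
              site_log_odds(model, codes, cand$start[r], cand$gap[r], spec,
                            strand = sd)
            }, numeric(1)))
    }))
    rows <- rows[order(-rows$score, rows$start, rows$gap), , drop = FALSE]
    cover <- logical(length(codes))
    picked <- empty_placements()
    for (r in seq_len(nrow(rows))) {
      if (rows$score[r] < config$zoops_threshold) break
      if (nrow(picked) >= config$anr_max_sites) break
      ls <- rows$start[r]
      gap <- rows$gap[r]
      pos <- c((ls + 1L):(ls + spec$l_left),
               if (spec$l_right)
                 (ls + spec$l_left + gap + 1L):
                 (ls + spec$l_left + gap + spec$l_right))
      if (any(cover[pos])) next
      cover[pos] <- TRUE
      picked <- rbind(picked, as_placements(i, ls, gap,
                                            strand = rows$strand[r]))
    }
    if (nrow(picked) == 0L) {
      picked <- as_placements(i, 0L, spec$gap_min, present = FALSE)
    }
    out <- rbind(out, picked)
  }
  rownames(out) <- NULL
  out
}

#' Exhaustively minimize entropy over all joint placements
#'
#' Brute-force reference for tiny instances: enumerates every combination
#' of one placement per sequence and returns the minimum achievable
#' information content. Intended for validating the stochastic search on
#' problems with at most a handful of short sequences (the state space
#' grows as the product of per-sequence candidate counts).
#'
#' @inheritParams count_sites
#' @param beta Total pseudo-count.
#' @return List with `entropy` (the global minimum) and `placements`
#'   (one argmin configuration).
#' @export
exhaustive_search <- function(sequences, spec, beta = 1) {
  st <- motif_state(sequences, empty_placements(), spec, beta = beta)
  cache <- get_cand_cache(st)
  n <- st$nseq
  if (any(vapply(cache, function(ci) nrow(ci$cand), 0L) == 0L)) {
    stop("a sequence admits no placement under this spec", call. = FALSE)
  }
  best <- list(entropy = Inf, placements = NULL)
  current_start <- integer(n)
  current_gap <- integer(n)
  rec <- function(i) {
    ci <- cache[[i]]
    if (i == n) {
      sc <- score_candidates(st, i, ci)
      idx <- which.min(sc$ic)
      if (sc$ic[idx] < best$entropy - 1e-12) {
        current_start[n] <<- ci$cand$start[idx]
        current_gap[n] <<- ci$cand$gap[idx]
        best <<- list(entropy = sc$ic[idx],
                      placements = as_placements(seq_len(n), current_start,
                                                 current_gap))
      }
      return(invisible(NULL))
    }
    for (cidx in seq_len(nrow(ci$cand))) {
      st_set(st, i, plr_site(ci$cand$start[cidx], ci$cand$gap[cidx]))
      current_start[i] <<- ci$cand$start[cidx]
      current_gap[i] <<- ci$cand$gap[cidx]
      rec(i + 1L)
      st_set(st, i, plr_empty)
    }
  }
  rec(1L)
  best
}
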