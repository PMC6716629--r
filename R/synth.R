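#' Per-position block model from a consensus string
#'
#' Builds a mononucleotide block model putting `conservation` probability
#' mass on the consensus letter at each position and spreading the rest
#' evenly; `conservation = 1` gives a deterministic block. 0.85 emulates a
#' strongly conserved bacterial binding-site block.
#'
#' @param consensus Consensus string over `{A,C,G,T}`.
#' @param conservation Probability of the consensus letter per position.
#' @return A block model: `list(type = "pwm", probs = 4 x width matrix)`.
#' @export
consensus_pwm <- function(consensus, conservation = 0.85) {
  stopifnot(conservation >= 0.25, conservation <= 1)
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  stopifnot(all(letters %in% MONO_LETTERS))
  w <- length(letters)
  probs <- matrix((1 - conservation) / 3, 4L, w,
                  dimnames = list(MONO_LETTERS, NULL))
  probs[cbind(match(letters, MONO_LETTERS), seq_len(w))] <- conservation
  list(type = "pwm", probs = probs)
}

#' Dependency-engineered block model
#'
#' A first-order letter-chain block whose per-position marginals are all
#' uniform over `{A,C,G,T}` but whose adjacent positions carry mutual
#' information that grows with `coupling`: successive letters stay in the
#' same purine/pyrimidine group with probability `(1 + coupling)/2`
#' (alternating with `(1 - coupling)/2` at odd transitions, which breaks
#' translational self-similarity), and the letter within the group is
#' chosen uniformly. The analytic adjacent-pair MI is
#' `1 - H2((1 + coupling)/2)` bits, where `H2` is the binary entropy;
#' `coupling = 0` gives i.i.d. uniform letters and `coupling = 1` gives
#' exactly 1 bit per adjacent pair. A mononucleotide model sees nothing of
#' this structure -- only a dinucleotide model can exploit it.
#'
#' @param coupling Dependency strength in `[0, 1]`.
#' @param width Block width in bases (>= 2).
#' @return A block model:
#'   `list(type = "chain", init, trans, mi_bits)` where `trans` is a list
#'   of `width - 1` transition matrices and `mi_bits` the analytic adjacent
#'   MI.
#' @export
dependency_motif <- function(coupling, width) {
  stopifnot(coupling >= 0, coupling <= 1, width >= 2)
  s <- (1 + coupling) / 2
  same_group <- outer(c(1, 2, 1, 2), c(1, 2, 1, 2), "==")  # purine/pyrimidine
  make_trans <- function(p_same) {
    tr <- ifelse(same_group, p_same / 2, (1 - p_same) / 2)
    dimnames(tr) <- list(MONO_LETTERS, MONO_LETTERS)
    tr
  }
  trans <- lapply(seq_len(width - 1L), function(t) {
    make_trans(if (t %% 2L == 1L) s else 1 - s)
  })
  h2 <- function(p) {
    terms <- c(p, 1 - p)
    -sum(ifelse(terms > 0, terms * log2(terms), 0))
  }
  list(type = "chain", init = stats::setNames(rep(0.25, 4), MONO_LETTERS),
       trans = trans, mi_bits = 1 - h2(s))
}

# Draw one block realization (vector of letter codes 1..4).
sample_block <- function(model, width) {
  if (model$type == "pwm") {
    stopifnot(ncol(model$probs) == width)
    vapply(seq_len(width), function(t) {
      sample.int(4L, 1L, prob = model$probs[, t])
    }, 0L)
  } else {
    stopifnot(length(model$trans) == width - 1L)
    out <- integer(width)
    out[1L] <- sample.int(4L, 1L, prob = model$init)
    for (t in seq_len(width - 1L)) {
      out[t + 1L] <- sample.int(4L, 1L, prob = model$trans[[t]][out[t], ])
    }
    out
  }
}

sample_background <- function(background, L) {
  if (background$type == "iid") {
    sample.int(4L, L, replace = TRUE, prob = background$freqs)
  } else {
    out <- integer(L)
    init <- if (!is.null(background$init)) background$init else rep(0.25, 4)
    out[1L] <- sample.int(4L, 1L, prob = init)
    for (p in seq_len(L - 1L)) {
      out[p + 1L] <- sample.int(4L, 1L, prob = background$trans[out[p], ])
    }
    out
  }
}

#' Synthetic dataset configuration
#'
#' Describes a benchmark dataset with planted bipartite motifs: `n_sequences`
#' background sequences of length `seq_length`, of which a
#' `noise_fraction` share carry no motif, and the rest carry exactly one
#' planted site (gap drawn from `gap_weights` over
#' `[spec$gap_min, spec$gap_max]`, blocks drawn from the block models,
#' left start uniform among fitting positions).
#'
#' @param n_sequences Number of sequences.
#' @param seq_length Sequence length in bases (all sequences equal length).
#' @param spec A [bipartite_spec()] giving the planted widths and gap range.
#' @param left_model,right_model Block models from [consensus_pwm()] or
#'   [dependency_motif()]; `right_model` ignored when `spec$l_right = 0`.
#' @param gap_weights Sampling weights over the gap range (default
#'   uniform).
#' @param background `list(type = "iid", freqs = ...)` (default uniform) or
#'   `list(type = "markov1", trans = 4x4, init = ...)`.
#' @param noise_fraction Share of sequences left motif-free, in `[0, 1]`.
#' @param seed Optional RNG seed applied by [synth_generate()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sequences, seq_length, spec,
                         left_model, right_model = NULL,
                         gap_weights = NULL,
                         background = list(type = "iid",
                                           freqs = rep(0.25, 4)),
                         noise_fraction = 0, seed = NULL) {
  stopifnot(n_sequences >= 1, noise_fraction >= 0, noise_fraction <= 1)
  if (seq_length < spec_min_width(spec)) {
    stop("seq_length too short for the planted spec", call. = FALSE)
  }
  gaps <- spec$gap_min:spec$gap_max
  if (is.null(gap_weights)) gap_weights <- rep(1, length(gaps))
  stopifnot(length(gap_weights) == length(gaps), all(gap_weights >= 0),
            sum(gap_weights) > 0)
  if (spec$l_right > 0L && is.null(right_model)) {
    stop("right_model required when spec$l_right > 0", call. = FALSE)
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length), spec = spec,
                 left_model = left_model, right_model = right_model,
                 gap_weights = gap_weights, background = background,
                 noise_fraction = noise_fraction, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic planted-motif dataset
#'
#' Fully reproducible from `config$seed`. Noise sequences are drawn from
#' the background model alone; every other sequence receives one planted
#' site whose blocks overwrite the background at a uniformly chosen fitting
#' position.
#'
#' @param config A [synth_config()].
#' @return List with `sequences` (data frame `id`, `seq`), `truth` (site
#'   annotations of the planted block intervals), `labels` (named
#'   `"motif"`/`"noise"` per sequence) and `placements` (the planted
#'   placement table).
#' @export
synth_generate <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  spec <- config$spec
  n <- config$n_sequences
  L <- config$seq_length
  gaps <- spec$gap_min:spec$gap_max
  n_noise <- round(config$noise_fraction * n)
  is_noise <- seq_len(n) %in% sample.int(n, n_noise)
  ids <- sprintf("s%03d", seq_len(n))
  seqs <- character(n)
  truth <- list()
  pl <- empty_placements()
  for (i in seq_len(n)) {
    codes <- sample_background(config$background, L)
    if (!is_noise[i]) {
      gap <- gaps[sample.int(length(gaps), 1L,
                             prob = config$gap_weights)]
      w <- spec$l_left + gap + spec$l_right
      start <- sample.int(L - w + 1L, 1L) - 1L
      codes[(start + 1L):(start + spec$l_left)] <-
        sample_block(config$left_model, spec$l_left)
      if (spec$l_right) {
        rs <- start + spec$l_left + gap
        codes[(rs + 1L):(rs + spec$l_right)] <-
          sample_block(config$right_model, spec$l_right)
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = c(ids[i], ids[i]),
          start = c(start, rs),
          end = c(start + spec$l_left, rs + spec$l_right),
          stringsAsFactors = FALSE)
      } else {
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = ids[i], start = start, end = start + spec$l_left,
          stringsAsFactors = FALSE)
      }
      pl <- rbind(pl, as_placements(i, start, gap))
    }
    seqs[i] <- decode_dna(codes)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(seq_id = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  list(sequences = data.frame(id = ids, seq = seqs,
                              stringsAsFactors = FALSE),
       truth = truth,
       labels = stats::setNames(ifelse(is_noise, "noise", "motif"), ids),
       placements = pl)
}
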