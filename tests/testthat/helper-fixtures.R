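# Shared fixtures: everything is generated in code at test time.

DI_LETTERS_test <- function() bimotif:::DI_LETTERS
empty_pl <- function() bimotif:::empty_placements()
spec_ncols_test <- function(spec) bimotif:::spec_ncols(spec)

seq_set <- function(...) {
  seqs <- c(...)
  data.frame(id = if (is.null(names(seqs))) paste0("s", seq_along(seqs))
             else names(seqs),
             seq = unname(seqs), stringsAsFactors = FALSE)
}

# Random uniform DNA string.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small planted-motif dataset used across sampler tests.
planted_dataset <- function(n = 20, L = 100, conservation = 0.9,
                            spec = bipartite_spec(6, 6, 8, 12),
                            seed = 42, noise_fraction = 0) {
  synth_generate(synth_config(
    n, L, spec,
    left_model = consensus_pwm("TTGACA", conservation),
    right_model = consensus_pwm("TATAAT", conservation),
    noise_fraction = noise_fraction, seed = seed))
}

# From-scratch IC of a placement set via the public model-building path;
# the independent check for the incremental state.
scratch_ic <- function(sequences, placements, spec, beta = 1) {
  information_content(to_model(count_sites(sequences, placements, spec),
                               background_counts(sequences, placements, spec),
                               beta = beta))
}

# Recovery rate: fraction of planted left starts matched within +-1.
recovery_rate <- function(result, truth_placements) {
  found <- result$placements[result$placements$present, ]
  found <- found[order(found$seq_index), ]
  tr <- truth_placements[order(truth_placements$seq_index), ]
  common <- intersect(found$seq_index, tr$seq_index)
  mean(abs(found$left_start[match(common, found$seq_index)] -
             tr$left_start[match(common, tr$seq_index)]) <= 1)
}

# Recovery nCC of a search result against generator truth.
recovery_ncc <- function(d, result, spec) {
  lens <- stats::setNames(nchar(d$sequences$seq), d$sequences$id)
  pred <- placements_to_sites(result$placements, spec, d$sequences$id)
  ncc(confusion_counts(d$truth, pred, lens))
}

# Present/absent calls of a result as a named logical vector.
presence_calls <- function(d, result) {
  pred <- stats::setNames(rep(FALSE, nrow(d$sequences)), d$sequences$id)
  pr <- result$placements[result$placements$present, , drop = FALSE]
  pred[d$sequences$id[pr$seq_index]] <- TRUE
  pred
}
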