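test_that("initialization draws valid placements and is seed-deterministic", {
  spec <- bipartite_spec(6, 6, 8, 12)
  set.seed(2)
  seqs <- seq_set(a = rand_dna(100), b = rand_dna(100), c = rand_dna(24))
  set.seed(5)
  for (rep in 1:200) {
    pl <- initialize_placements(seqs, spec)
    W <- 12 + pl$gap
    expect_true(all(pl$left_start >= 0))
    expect_true(all(pl$left_start + W <= nchar(seqs$seq)[pl$seq_index]))
    expect_true(all(pl$gap >= 8 & pl$gap <= 12))
  }
  # a sequence of exactly the minimal width admits only (start 0, gap min)
  spec_fix <- bipartite_spec(6, 6, 8, 8)
  pl_min <- initialize_placements(seq_set(m = rand_dna(20)), spec_fix)
  expect_equal(pl_min$left_start, 0L)
  expect_equal(pl_min$gap, 8L)
  set.seed(9); a <- initialize_placements(seqs, spec)
  set.seed(9); b <- initialize_placements(seqs, spec)
  expect_identical(a, b)
  short <- seq_set(tiny = "ACGTACGT")
  expect_error(initialize_placements(short, spec), "tiny")
})

test_that("a sweep never increases entropy and matches per-sequence argmin", {
  set.seed(17)
  spec <- bipartite_spec(3, 3, 1, 2)
  seqs <- seq_set(s = rand_dna(16))
  # single sequence: the sweep's choice equals exhaustive enumeration with
  # full IC recomputation over every feasible (start, gap)
  st <- motif_state(seqs, data.frame(seq_index = 1L, left_start = 0L,
                                     gap = 1L), spec)
  greedy_sweep(st)
  chosen <- state_placements(st)
  best <- Inf; best_pl <- NULL
  for (gap in 1:2) {
    for (start in 0:(16 - 6 - gap)) {
      pl <- data.frame(seq_index = 1L, left_start = start, gap = gap)
      ic <- scratch_ic(seqs, pl, spec)
      if (ic < best - 1e-12) { best <- ic; best_pl <- pl }
    }
  }
  expect_equal(chosen$left_start, best_pl$left_start)
  expect_equal(chosen$gap, best_pl$gap)
  expect_equal(state_entropy(st), best, tolerance = 1e-9)

  # multi-sequence: entropy after sweep <= before, always
  d <- planted_dataset(n = 8, L = 60, seed = 91)
  spec6 <- bipartite_spec(6, 6, 8, 12)
  set.seed(3)
  st2 <- motif_state(d$sequences, initialize_placements(d$sequences, spec6),
                     spec6)
  e <- state_entropy(st2)
  for (sw in 1:5) {
    res <- greedy_sweep(st2)
    expect_lte(res$entropy, e + 1e-9)
    e <- res$entropy
  }
})

test_that("a dataset sitting on its optimum is a fixed point", {
  spec <- bipartite_spec(4, 4, 2, 2)
  # identical sequences, deterministic planted blocks: the planted
  # configuration is optimal and the sweep must not move
  d <- synth_generate(synth_config(
    6, 30, spec, left_model = consensus_pwm("TTGA", 1),
    right_model = consensus_pwm("TAAT", 1), seed = 55))
  st <- motif_state(d$sequences, d$placements, spec)
  e0 <- state_entropy(st)
  res <- greedy_sweep(st)
  expect_false(res$changed)
  expect_equal(res$entropy, e0, tolerance = 1e-12)
})

test_that("search is reproducible and restart bookkeeping is consistent", {
  d <- planted_dataset(n = 8, L = 60, seed = 12)
  spec <- bipartite_spec(6, 6, 8, 12)
  cfg <- search_config(restarts = 4, seed = 123)
  r1 <- bimotif_search(d$sequences, spec, cfg)
  r2 <- bimotif_search(d$sequences, spec, cfg)
  expect_identical(r1$placements, r2$placements)
  expect_identical(r1$entropy, r2$entropy)
  expect_identical(r1$restart_entropies, r2$restart_entropies)
  # under OOPS the final entropy is the minimum across restarts and equals
  # the IC of the model rebuilt from the returned placements
  expect_equal(r1$entropy, min(r1$restart_entropies), tolerance = 1e-9)
  expect_equal(r1$entropy,
               scratch_ic(d$sequences, r1$placements, spec),
               tolerance = 1e-9)
  # restarts = 1 reproduces a single restart exactly
  cfg1 <- search_config(restarts = 1, seed = 7)
  ra <- bimotif_search(d$sequences, spec, cfg1)
  set.seed(7)
  rb <- run_restart(d$sequences, spec, cfg1)
  expect_equal(ra$entropy, rb$entropy, tolerance = 1e-12)
  expect_equal(ra$placements$left_start,
               rb$placements$left_start[order(rb$placements$seq_index)])
})

test_that("entropy traces are non-increasing and converge below epsilon", {
  d <- planted_dataset(n = 10, L = 80, seed = 40)
  for (mode in c("oops", "zoops")) {
    spec <- bipartite_spec(6, 6, 8, 12, mode = mode)
    res <- bimotif_search(d$sequences, spec,
                          search_config(restarts = 4, seed = 2))
    for (r in seq_along(res$restart_traces)) {
      tr <- res$restart_traces[[r]]
      expect_true(all(diff(tr) <= 1e-9))
      if (res$restart_converged[r]) {
        expect_lt(abs(tr[length(tr)] - tr[length(tr) - 1L]), 1e-8 + 1e-12)
      }
    }
  }
})

test_that("ZOOPS separates motif from noise and degenerates to OOPS", {
  spec <- bipartite_spec(6, 6, 8, 12, mode = "zoops")
  d <- planted_dataset(n = 30, L = 100, seed = 66, noise_fraction = 0.3)
  res <- bimotif_search(d$sequences, spec, search_config(restarts = 6,
                                                         seed = 3))
  calls <- presence_calls(d, res)
  r <- sequence_rates(d$labels, calls)
  expect_gte(r$TPR, 0.8)
  expect_lte(r$FPR, 0.3)
  # threshold -Inf disables the absent option: all sequences placed
  res_inf <- bimotif_search(d$sequences, spec,
                            search_config(restarts = 3, seed = 3,
                                          zoops_threshold = -Inf))
  expect_true(all(res_inf$placements$present))
})

test_that("ANR scan reports repeats, thresholds and non-overlap", {
  spec <- bipartite_spec(5, 5, 3, 3, mode = "anr")
  # hand-built sequences: two disjoint planted sites in s1, none in s2
  site <- function() paste0("GGACT", "AAA", "TCCGG")
  set.seed(8)
  s1 <- paste0(site(), rand_dna(10), site(), rand_dna(5))
  s2 <- rand_dna(nchar(s1))
  train <- synth_generate(synth_config(
    12, 40, bipartite_spec(5, 5, 3, 3),
    left_model = consensus_pwm("GGACT", 0.95),
    right_model = consensus_pwm("TCCGG", 0.95), seed = 44))
  model <- to_model(count_sites(train$sequences, train$placements,
                                bipartite_spec(5, 5, 3, 3)),
                    background_counts(train$sequences, train$placements,
                                      bipartite_spec(5, 5, 3, 3)))
  scan <- anr_scan(seq_set(a = s1, b = s2), model, spec,
                   search_config(zoops_threshold = 5))
  hits1 <- scan[scan$seq_index == 1 & scan$present, ]
  expect_equal(sort(hits1$left_start), c(0L, 23L))
  # block positions of accepted sites never overlap
  expect_true(all(diff(sort(hits1$left_start)) >= 13))
  hits2 <- scan[scan$seq_index == 2, ]
  expect_true(all(!hits2$present) || nrow(hits2) == 0)
})

test_that("reverse-complement scanning finds minus-strand sites", {
  spec <- bipartite_spec(5, 5, 3, 3)
  train <- synth_generate(synth_config(
    12, 40, spec,
    left_model = consensus_pwm("GGACT", 0.95),
    right_model = consensus_pwm("TCCGG", 0.95), seed = 45))
  model <- to_model(count_sites(train$sequences, train$placements, spec),
                    background_counts(train$sequences, train$placements,
                                      spec))
  # plant the reverse complement of the consensus site
  rc_site <- "CCGGATTTAGTCC"   # revcomp of GGACT AAA TCCGG
  set.seed(10)
  s <- paste0(rand_dna(8), rc_site, rand_dna(8))
  spec_anr <- bipartite_spec(5, 5, 3, 3, mode = "anr")
  fwd_only <- anr_scan(seq_set(x = s), model, spec_anr,
                       search_config(zoops_threshold = 5))
  both <- anr_scan(seq_set(x = s), model, spec_anr,
                   search_config(zoops_threshold = 5, both_strands = TRUE))
  minus <- both[both$present & both$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$left_start, 8L)
  expect_true(all(fwd_only$strand[fwd_only$present] == "+"))
})

test_that("exhaustive search equals the greedy result on trivial instances", {
  # one sequence: greedy with one restart already is exhaustive per sweep
  set.seed(26)
  spec <- bipartite_spec(3, 3, 1, 2)
  seqs <- seq_set(s1 = rand_dna(14), s2 = rand_dna(14))
  ex <- exhaustive_search(seqs, spec)
  res <- bimotif_search(seqs, spec, search_config(restarts = 50, seed = 1))
  expect_equal(res$entropy, ex$entropy, tolerance = 1e-9)
})
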