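test_that("site counting tallies blocks and excludes gap and junction pairs", {
  # spec 2<[1,1]>2, site "AC g TG": mono tallies the four block letters,
  # di tallies only the within-block pairs AC and TG
  seqs <- seq_set(s1 = "ACGTG")
  pl <- data.frame(seq_index = 1L, left_start = 0L, gap = 1L)
  spec_m <- bipartite_spec(2, 2, 1, 1, kind = "mono")
  cm <- count_sites(seqs, pl, spec_m)
  expect_equal(dim(cm$counts), c(4L, 4L))
  expect_equal(unname(cm$counts[1, ]), c(1, 0, 0, 0))   # A
  expect_equal(unname(cm$counts[2, ]), c(0, 1, 0, 0))   # C
  expect_equal(unname(cm$counts[3, ]), c(0, 0, 0, 1))   # T
  expect_equal(unname(cm$counts[4, ]), c(0, 0, 1, 0))   # G
  expect_equal(cm$n_eff, 1L)

  spec_d <- bipartite_spec(2, 2, 1, 1, kind = "di")
  cd <- count_sites(seqs, pl, spec_d)
  expect_equal(dim(cd$counts), c(2L, 16L))
  expect_equal(unname(cd$counts[1, ]),
               as.numeric(DI_LETTERS_test() == "AC"))
  expect_equal(unname(cd$counts[2, ]),
               as.numeric(DI_LETTERS_test() == "TG"))
  # no C-T junction pair anywhere
  expect_equal(sum(cd$counts[, DI_LETTERS_test() == "CT"]), 0)

  # three identical sites reading "AC" -> direct tallies
  seqs3 <- seq_set(a = "ACAA", b = "AACA", c = "CACC")
  pl3 <- data.frame(seq_index = 1:3, left_start = c(0L, 1L, 1L), gap = 0L)
  cm3 <- count_sites(seqs3, pl3, bipartite_spec(2, 0, 0, 0))
  expect_equal(unname(cm3$counts[, 1]), c(3, 0))
  expect_equal(unname(cm3$counts[, 2]), c(0, 3))
})

test_that("background counting respects coverage and pair adjacency", {
  spec <- bipartite_spec(2, 0, 0, 0)
  # no placements: the whole sequence is background
  bg <- background_counts(seq_set(s = "ACGT"), empty_pl(), spec)
  expect_equal(unname(bg$g), c(1, 1, 1, 1))
  expect_equal(bg$n, 4)

  # fully covered one-block placement leaves no background
  spec4 <- bipartite_spec(4, 0, 0, 0)
  bg0 <- background_counts(seq_set(s = "AAAA"),
                           data.frame(seq_index = 1L, left_start = 0L,
                                      gap = 0L), spec4)
  expect_equal(bg0$n, 0)

  # block covering positions 2-3 of AACCGG: mono background {A:2, G:2};
  # di background pairs only AA and GG (pairs touching the block excluded)
  seqs <- seq_set(s = "AACCGG")
  pl <- data.frame(seq_index = 1L, left_start = 2L, gap = 0L)
  bgm <- background_counts(seqs, pl, bipartite_spec(2, 0, 0, 0))
  expect_equal(unname(bgm$g), c(2, 0, 2, 0))
  expect_equal(bgm$n, 4)
  bgd <- background_counts(seqs, pl, bipartite_spec(2, 0, 0, 0, kind = "di"))
  expect_equal(bgd$n, 2)
  expect_equal(unname(bgd$g[DI_LETTERS_test() == "AA"]), 1)
  expect_equal(unname(bgd$g[DI_LETTERS_test() == "GG"]), 1)
})

test_that("pseudo-count model matches the closed-form probabilities", {
  # mono: f = {A:3}, N_eff = 3, beta = 1 -> p(A) = 3.25/4, others 0.25/4
  seqs3 <- seq_set(a = "AC", b = "AC", c = "AC")
  pl3 <- data.frame(seq_index = 1:3, left_start = 0L, gap = 0L)
  spec <- bipartite_spec(2, 0, 0, 0)
  m <- to_model(count_sites(seqs3, pl3, spec),
                background_counts(seqs3, pl3, spec), beta = 1)
  expect_equal(unname(m$probs[1, ]), c(0.8125, 0.0625, 0.0625, 0.0625),
               tolerance = 1e-12)
  # empty background with beta = 1 -> uniform b
  expect_equal(unname(m$background), rep(0.25, 4), tolerance = 1e-12)

  # di: f = {AC:2}, N_eff = 2, beta = 1 -> p(AC) = (2 + 1/16)/3
  seqs2 <- seq_set(a = "AC", b = "AC")
  pl2 <- data.frame(seq_index = 1:2, left_start = 0L, gap = 0L)
  spec_d <- bipartite_spec(2, 0, 0, 0, kind = "di")
  md <- to_model(count_sites(seqs2, pl2, spec_d),
                 background_counts(seqs2, pl2, spec_d), beta = 1)
  expect_equal(unname(md$probs[1, DI_LETTERS_test() == "AC"]),
               (2 + 1 / 16) / 3, tolerance = 1e-12)
  # columns and background always sum to 1
  expect_equal(unname(rowSums(md$probs)), rep(1, nrow(md$probs)),
               tolerance = 1e-12)
  expect_equal(sum(md$background), 1, tolerance = 1e-12)

  expect_error(
    to_model(count_sites(seqs2, empty_pl(), spec_d),
             background_counts(seqs2, empty_pl(), spec_d), beta = 0),
    "empty model")
})

test_that("information content follows the signed relative-entropy form", {
  fake_model <- function(probs, background) {
    structure(list(kind = "mono", probs = probs, background = background,
                   beta = 1, n_eff = 1), class = "motif_model")
  }
  # p = b (any distribution) -> 0
  b <- c(0.1, 0.2, 0.3, 0.4)
  m0 <- fake_model(matrix(b, 1, 4, byrow = TRUE), b)
  expect_equal(information_content(m0), 0, tolerance = 1e-12)
  # degenerate column vs uniform background -> exactly -2 bits
  m1 <- fake_model(matrix(c(1, 0, 0, 0), 1, 4, byrow = TRUE), rep(0.25, 4))
  expect_equal(information_content(m1), -2, tolerance = 1e-12)
  # a 2-column model equals the term-by-term brute-force sum
  set.seed(9)
  probs <- t(apply(matrix(rexp(8), 2), 1, function(x) x / sum(x)))
  bg <- c(0.3, 0.3, 0.2, 0.2)
  brute <- 0
  for (i in 1:2) for (x in 1:4) {
    brute <- brute - probs[i, x] * log2(probs[i, x] / bg[x])
  }
  expect_equal(information_content(fake_model(probs, bg)), brute,
               tolerance = 1e-12)
  # concentrating a column below background strictly decreases IC
  m_sharp <- fake_model(matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4, byrow = TRUE),
                        rep(0.25, 4))
  expect_lt(information_content(m_sharp), 0)
})

test_that("site log-odds sums per-column log ratios", {
  seqs3 <- seq_set(a = "AC", b = "AC", c = "AC")
  pl3 <- data.frame(seq_index = 1:3, left_start = 0L, gap = 0L)
  spec <- bipartite_spec(1, 0, 0, 0)
  m <- to_model(count_sites(seqs3, pl3, spec),
                background_counts(seqs3, pl3, spec))
  # consensus site of the 0.8125 model, uniform-ish background
  sc <- site_log_odds(m, "A", 0L, 0L, spec)
  expect_equal(sc, log2(0.8125 / m$background[["A"]]), tolerance = 1e-12)

  # random site vs a wider model equals the per-column sum
  set.seed(11)
  d <- planted_dataset(n = 8, L = 40)
  spec6 <- bipartite_spec(6, 6, 8, 12)
  md <- to_model(count_sites(d$sequences, d$placements, spec6),
                 background_counts(d$sequences, d$placements, spec6))
  s <- d$sequences$seq[1]
  sc2 <- site_log_odds(md, s, 2L, 9L, spec6)
  site <- paste0(substr(s, 3, 8), substr(s, 18, 23))
  brute <- 0
  for (t in 1:12) {
    x <- substr(site, t, t)
    brute <- brute + log2(md$probs[t, x] / md$background[[x]])
  }
  expect_equal(sc2, brute, tolerance = 1e-12)
  expect_error(site_log_odds(md, s, 35L, 9L, spec6), "exceeds")
})

test_that("matrix export round-trips probabilities exactly", {
  set.seed(4)
  d <- planted_dataset(n = 6, L = 40)
  for (kind in c("mono", "di")) {
    spec <- bipartite_spec(6, 6, 8, 12, kind = kind)
    m <- to_model(count_sites(d$sequences, d$placements, spec),
                  background_counts(d$sequences, d$placements, spec))
    f <- withr::local_tempfile(fileext = ".tsv")
    export_matrix(m, f)
    back <- read_matrix(f)
    expect_identical(dim(back), dim(m$probs))
    expect_equal(back, m$probs, tolerance = 0, ignore_attr = TRUE)
  }
  # column-count rule: di 4<[..]>8 gives (4-1) + (8-1) columns
  expect_equal(nrow(matrix(0, spec_ncols_test(bipartite_spec(4, 8, 2, 2,
                                                             kind = "di")),
                           1)), 10L)
})
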