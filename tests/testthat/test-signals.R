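# Signal scanning against a naive oracle, and exon-candidate enumeration
# semantics (kinds, frames, in-frame TGA bookkeeping, no internal stops).

dummy_markov <- function() train_markov("ATGGCCAAGTGA", "ACGTACGTACGT", k = 0)

test_that("scan_signals reports overlapping motifs and sorts by position", {
  sites <- scan_signals("ATGAAATAA")
  expect_equal(sites$pos[sites$kind == "start"], 0L)
  expect_equal(sites$pos[sites$kind == "tga"], 1L)    # overlaps the ATG
  expect_equal(sites$pos[sites$kind == "stop"], 6L)
  expect_false(is.unsorted(sites$pos))
  # no G or T anywhere -> no donor
  expect_equal(sum(scan_signals("ACACACAC")$kind == "donor"), 0L)
})

test_that("scan counts equal a sliding-window oracle on random sequences", {
  for (i in 1:10) {
    s <- rand_dna(10000, 500 + i)
    sites <- scan_signals(s)
    expect_identical(sites$pos[sites$kind == "start"], oracle_motif_positions(s, "ATG"))
    expect_identical(sites$pos[sites$kind == "donor"], oracle_motif_positions(s, "GT"))
    expect_identical(sites$pos[sites$kind == "acceptor"], oracle_motif_positions(s, "AG"))
    expect_identical(sites$pos[sites$kind == "tga"], oracle_motif_positions(s, "TGA"))
    expect_identical(sites$pos[sites$kind == "stop"],
                     sort(c(oracle_motif_positions(s, "TAA"),
                            oracle_motif_positions(s, "TAG"))))
  }
})

test_that("a single exon with an in-frame TGA is emitted with tga_offsets", {
  #        ATG TGA AAA ... TAA  (in-frame TGA then downstream stop)
  s <- paste0("ATGTGAAAAGCCGCTGCAGCTGCTGCTTACGCTTAA", rand_dna(40, 31))
  sites <- scan_signals(s)
  cands <- enumerate_exons(s, sites, dummy_markov(), limits = list(min_exon = 20L))
  single <- cands[cands$kind == "single" & cands$start == 0L, ]
  expect_equal(nrow(single), 1L)
  expect_true(single$has_inframe_tga)
  expect_equal(single$tga_offsets[[1]], 3L)
  expect_equal(single$end, 36L)   # ends at the TAA, not at the TGA
})

test_that("no emitted exon contains a complete in-frame TAA/TAG", {
  s <- rand_dna(5000, 32)
  sites <- scan_signals(s)
  cands <- enumerate_exons(s, sites, dummy_markov(), limits = list(min_exon = 20L))
  expect_gt(nrow(cands), 0)
  for (i in seq_len(nrow(cands))) {
    ex <- cands[i, ]
    c0 <- ex$start + (3L - ex$frame5) %% 3L
    codon_starts <- seq(c0, ex$end - 3L, by = 3L)
    codons <- substring(s, codon_starts + 1L, codon_starts + 3L)
    internal <- if (ex$kind %in% c("terminal", "single")) head(codons, -1) else codons
    expect_false(any(internal %in% c("TAA", "TAG")))
    # every in-frame TGA is recorded
    expect_identical(ex$tga_offsets[[1]],
                     as.integer(codon_starts[codons == "TGA"] - ex$start))
  }
})

test_that("enumeration matches an exhaustive signal-pair oracle on a synthetic locus", {
  cfg <- generator_config(genome_length = 12000L, n_genes = 1L, n_decoy_pseudo = 0L,
                          n_decoy_cys = 0L, exon_range = c(3L, 3L), seed = 33L)
  sim <- simulate_benchmark(cfg)
  s <- substr(sim$genome$seq[[1]], 1, 5000)
  sites <- scan_signals(s)
  mk <- dummy_markov()
  lim <- list(min_exon = 30L, max_exon = 1000L)
  cands <- enumerate_exons(s, sites, mk, lim)

  # oracle: direct nested loops over motif occurrences
  starts <- oracle_motif_positions(s, "ATG")
  donors <- oracle_motif_positions(s, "GT")
  acceptors <- oracle_motif_positions(s, "AG")
  stops <- sort(c(oracle_motif_positions(s, "TAA"), oracle_motif_positions(s, "TAG")))
  n <- nchar(s)
  first_stop_after <- function(p, cls) {
    v <- stops[stops %% 3L == cls & stops >= p]
    if (length(v)) v[1] else n + 3L
  }
  keys <- character()
  add <- function(st, en, kind, f5) keys <<- c(keys, paste(st, en, kind, f5))
  for (st in starts) {
    t1 <- first_stop_after(st, st %% 3L)
    if (t1 + 3L <= n && t1 + 3L - st >= 30L && t1 + 3L - st <= 1000L) {
      add(st, t1 + 3L, "single", 0L)
    }
    for (d in donors[donors >= st + 30L & donors <= min(st + 1000L, t1 + 2L, n)]) {
      add(st, d, "initial", 0L)
    }
  }
  for (q in acceptors) {
    e0 <- q + 2L
    if (e0 >= n) next
    for (p in 0:2) {
      c0 <- e0 + (3L - p) %% 3L
      t1 <- first_stop_after(c0, c0 %% 3L)
      for (d in donors[donors >= e0 + 30L & donors <= min(e0 + 1000L, t1 + 2L, n)]) {
        add(e0, d, "internal", p)
      }
      if (t1 + 3L <= n && t1 + 3L - e0 >= 30L && t1 + 3L - e0 <= 1000L) {
        add(e0, t1 + 3L, "terminal", p)
      }
    }
  }
  got <- paste(cands$start, cands$end, cands$kind, cands$frame5)
  expect_setequal(got, keys)
})

test_that("relaxing the coding-potential threshold never removes candidates", {
  s <- rand_dna(4000, 34)
  sites <- scan_signals(s)
  mk <- dummy_markov()
  strict <- enumerate_exons(s, sites, mk, limits = list(min_coding = 5))
  loose <- enumerate_exons(s, sites, mk, limits = list(min_coding = -100))
  key <- function(d) paste(d$start, d$end, d$kind, d$frame5)
  expect_true(all(key(strict) %in% key(loose)))
  expect_error(enumerate_exons(s, sites, mk, limits = list(min_exon = 100L, max_exon = 50L)),
               "degenerate")
})

test_that("trained PWMs rank true splice sites above background occurrences", {
  cfg <- generator_config(genome_length = 100000L, n_genes = 5L, n_decoy_pseudo = 0L,
                          n_decoy_cys = 0L, exon_range = c(2L, 5L), seed = 35L)
  sim <- simulate_benchmark(cfg)
  model <- train_signal_model(sim$genome, sim$truth)
  td <- tidy(model)
  expect_true(all(c("kind", "position", "base", "log_odds") %in% names(td)))
  # every planted donor scores above the enumeration threshold
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    if (tr$n_exons < 2L) next
    L <- sim$genome$length[[1]]
    s <- if (tr$strand == "+") sim$genome$seq[[1]] else reverse_complement(sim$genome$seq[[1]])
    ee <- sort(tr$exon_ends[[1]])
    if (tr$strand == "-") {
      r <- reflect_interval(sort(tr$exon_starts[[1]]), ee, L)
      ee <- sort(r$end)
    }
    sites <- scan_signals(s, model)
    for (d in head(ee, -1)) {
      sc <- sites$score[sites$kind == "donor" & sites$pos == d]
      expect_gte(sc, model$thresholds[["donor"]])
    }
  }
})
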