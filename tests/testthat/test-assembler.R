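# Chain compatibility, the assembly DP against exhaustive enumeration,
# translation, and the gene-model validator.

test_that("compatible follows the gap / frame / kind adjacency rules", {
  mk <- function(kind, start, end, f5) {
    tibble::tibble(kind = kind, start = start, end = end,
                   frame5 = f5, frame3 = (f5 + end - start) %% 3L)
  }
  a <- mk("internal", 100L, 200L, 1L)   # frame3 = (1 + 100) %% 3 = 2
  b_ok <- mk("internal", 300L, 400L, 2L)
  expect_true(compatible(a, b_ok, min_intron = 40L))
  expect_false(compatible(a, mk("internal", 230L, 400L, 2L), min_intron = 40L))  # gap 30
  expect_false(compatible(a, mk("internal", 300L, 400L, 1L), min_intron = 40L))  # frame break
  expect_false(compatible(a, b_ok, min_intron = 40L, max_intron = 50L))          # gap 100 > 50
})

test_that("kind/phase adjacency matches an enumeration oracle", {
  kinds <- c("initial", "internal", "terminal", "single")
  for (ka in kinds) for (kb in kinds) for (fa in 0:2) for (fb in 0:2) {
    lena <- 90L + fa           # makes frame3(a) == fa + ... deterministic
    a <- tibble::tibble(kind = ka, start = 0L, end = lena,
                        frame5 = 0L, frame3 = (0L + lena) %% 3L)
    b <- tibble::tibble(kind = kb, start = lena + 100L, end = lena + 200L,
                        frame5 = fb, frame3 = (fb + 100L) %% 3L)
    expected <- ka %in% c("initial", "internal") &&
      kb %in% c("internal", "terminal") &&
      a$frame3 == fb
    expect_identical(compatible(a, b, min_intron = 40L), expected)
  }
})

test_that("a lone valid single exon assembles to itself", {
  s <- paste0("ATGTGAAAAGCCGCTGCAGCTGCTGCTTACGCTTAA", rand_dna(60, 41))
  sites <- scan_signals(s)
  mk <- train_markov("ATGGCCAAGTGA", "ACGTACGTACGT", k = 0)
  cands <- enumerate_exons(s, sites, mk, limits = list(min_exon = 20L))
  focal <- cands$exon_id[cands$kind == "single" & cands$has_inframe_tga][1]
  m <- assemble_best_orf(focal, cands, s)
  expect_equal(m$n_exons, 1L)
  expect_equal(m$total_score, cands$coding_potential[cands$exon_id == focal])
  expect_equal(m$protein, translate_gene(m))
  expect_true(check_gene_model(m, s))
})

test_that("DP optimum equals exhaustive chain enumeration on 100 random instances", {
  n_checked <- 0L
  n_with_chain <- 0L
  for (seed in 1:100) {
    inst <- oracle_random_instance(seed)
    focals <- inst$cands$exon_id[inst$cands$has_inframe_tga]
    if (!length(focals)) next
    focal <- focals[1]
    got <- assemble_best_orf(focal, inst$cands, inst$seq)
    want <- oracle_best_chain_score(inst$cands, focal)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_with_chain <- n_with_chain + 1L
      expect_equal(got$total_score, want$score, tolerance = 1e-9)
      expect_equal(got$n_exons, want$nexons)
      expect_equal(min(got$exon_starts[[1]]), want$start)
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 90L)     # nearly every random instance has a focal
  expect_gte(n_with_chain, 20L)  # and a good share admit a full chain
})

test_that("translate decodes in-frame TGA as U and drops the terminal stop", {
  expect_equal(translate_cds("ATGTGATAA"), "MU")
  expect_equal(translate_cds("ATGTGTTGA"), "MCU")  # trailing TGA is Sec, not stop
  expect_error(translate_cds("ATGTAATGATAA"), "internal stop")
  expect_error(translate_cds("ATGAA"), "divisible")
})

test_that("assembled models satisfy every gene-model invariant", {
  cfg <- generator_config(genome_length = 120000L, n_genes = 4L, n_decoy_pseudo = 0L,
                          n_decoy_cys = 0L, seed = 43L)
  sim <- simulate_benchmark(cfg)
  mods <- fit_models_from_truth(sim$genome, sim$truth, k = 4)
  s <- sim$genome$seq[[1]]
  sites <- scan_signals(s, mods$signal)
  cands <- enumerate_exons(s, sites, mods$markov,
                           limits = list(min_signal = mods$signal$thresholds))
  am <- assemble_orfs(cands, s)
  expect_gt(nrow(am), 0)
  for (i in seq_len(nrow(am))) {
    expect_true(check_gene_model(am[i, ], s))
    expect_equal(am$protein[[i]], translate_gene(am[i, ]))
    # focal TGA is always among the Sec positions
    expect_true(am$focal_tga[[i]] %in% am$sec_positions[[i]])
  }
  # determinism: identical inputs give identical chains
  am2 <- assemble_orfs(cands, s)
  expect_identical(am, am2)
})

test_that("multi-Sec multi-exon architecture is recovered with all Sec positions", {
  fx <- make_selp_fixture(seed = 7)
  tr <- fx$truth
  s <- fx$genome$seq[[1]]
  mods <- fit_models_from_truth(fx$genome, fx$truth, k = 4)
  sites <- scan_signals(s, mods$signal)
  cands <- enumerate_exons(s, sites, mods$markov,
                           limits = list(min_signal = mods$signal$thresholds))
  am <- assemble_orfs(cands, s)
  best <- am[which.max(am$total_score), ]
  expect_equal(best$n_exons, 8L)
  expect_identical(sort(best$sec_positions[[1]]), sort(tr$sec_positions[[1]]))
  expect_equal(length(best$sec_positions[[1]]), 5L)
  expect_equal(best$protein[[1]], tr$protein[[1]])
})

test_that("overlapping models sharing most of their CDS are deduplicated", {
  s <- paste0("ATGTGATGCTGTGCTGCAGCTGCTGCTTACGCTTAA", rand_dna(60, 44))
  sites <- scan_signals(s)
  mk <- train_markov("ATGGCCAAGTGA", "ACGTACGTACGT", k = 0)
  cands <- enumerate_exons(s, sites, mk, limits = list(min_exon = 20L))
  am <- assemble_orfs(cands, s)
  expect_gte(nrow(am), 1L)
  expect_false(is.unsorted(-am$total_score))
  # no two retained models share >= 50% of their coding bases
  if (nrow(am) > 1L) {
    for (i in 2:nrow(am)) {
      for (j in 1:(i - 1)) {
        ov <- 0L
        si <- am$exon_starts[[i]]; ei <- am$exon_ends[[i]]
        sj <- am$exon_starts[[j]]; ej <- am$exon_ends[[j]]
        for (k in seq_along(si)) {
          ov <- ov + sum(pmax(0L, pmin(ei[k], ej) - pmax(si[k], sj)))
        }
        expect_lt(ov / min(sum(ei - si), sum(ej - sj)), 0.5)
      }
    }
  }
})
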