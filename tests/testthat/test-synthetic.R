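# The benchmark generator: determinism, composition, truth/genome
# consistency, homolog identity, EST error rate, and the closed identity
# loop through the full pipeline.

test_that("background generation is deterministic and hits the GC target", {
  a <- generate_background(1000, 0.5, seed = 7)
  b <- generate_background(1000, 0.5, seed = 7)
  expect_identical(a, b)
  expect_true(all(strsplit(generate_background(500, 1.0, seed = 8), "")[[1]] %in% c("G", "C")))
  big <- generate_background(1e6, 0.4, seed = 9)
  gc <- sum(strsplit(big, "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.4), 0.01)
})

test_that("a planted cassette carries the requested structure", {
  set.seed(71)
  plan <- list(n_exons = 3L, n_codons = 150L, sec_codons = c(30L, 80L),
               secis = tibble::tibble(offset = c(400L, 1200L),
                                      motif_class = c("AUGA_AA", "GUGA_AA")),
               type = "gene")
  out <- plant_selenogene(plan, generator_config())
  tr <- out$truth
  expect_equal(tr$n_exons, 3L)
  expect_equal(length(tr$sec_positions[[1]]), 2L)
  expect_equal(nrow(tr$secis[[1]]), 2L)
  expect_equal(tr$secis[[1]]$motif_class, c("AUGA_AA", "GUGA_AA"))
  expect_equal(sum(strsplit(tr$protein, "")[[1]] == "U"), 2L)
  # splicing the planted exons out of the cassette reproduces the CDS
  cds <- spliced_seq(out$seq, tr$exon_starts[[1]], tr$exon_ends[[1]], "+")
  expect_identical(cds, tr$cds)
  # each Sec position points at a TGA codon in the cassette
  for (p in tr$sec_positions[[1]]) {
    expect_equal(substr(out$seq, p + 1L, p + 3L), "TGA")
  }
})

test_that("benchmark truth is consistent with the genome on both strands", {
  cfg <- generator_config(genome_length = 300000L, n_genes = 6L,
                          n_decoy_pseudo = 2L, n_decoy_cys = 2L, seed = 72L)
  sim <- simulate_benchmark(cfg)
  expect_equal(nrow(sim$truth), 10L)
  expect_setequal(unique(sim$truth$type), c("gene", "pseudo", "cys"))
  g <- sim$genome$seq[[1]]
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    cds <- spliced_seq(g, tr$exon_starts[[1]], tr$exon_ends[[1]], tr$strand)
    expect_identical(cds, tr$cds)
    expect_identical(translate_cds(cds), tr$protein)
    # planted SECIS elements sit downstream of the gene on the coding strand
    secis <- tr$secis[[1]]
    if (nrow(secis)) {
      if (tr$strand == "+") {
        expect_true(all(secis$start >= max(tr$exon_ends[[1]])))
      } else {
        expect_true(all(secis$end <= min(tr$exon_starts[[1]])))
      }
    }
  }
  # features do not overlap each other
  spans <- cbind(purrr::map_int(sim$truth$exon_starts, min),
                 purrr::map_int(sim$truth$exon_ends, max))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
})

test_that("homolog database hits the identity target and the U/C switch works", {
  cfg <- generator_config(genome_length = 200000L, n_genes = 5L,
                          n_decoy_pseudo = 0L, n_decoy_cys = 0L, seed = 73L)
  sim <- simulate_benchmark(cfg)
  ident_of <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    mean(x == y)
  }
  db06 <- make_homolog_db(sim$truth, 0.6, cys_substitute = TRUE, seed = 1)
  ids <- vapply(seq_len(nrow(db06)), function(i) {
    ident_of(chartr("U", "C", sim$truth$protein[[i]]), db06$seq[[i]])
  }, numeric(1))
  expect_lt(abs(mean(ids) - 0.6), 0.05)
  expect_false(any(grepl("U", db06$seq)))
  # identity 1 with substitution: exact sequences up to U -> C
  db1 <- make_homolog_db(sim$truth, 1.0, cys_substitute = TRUE, seed = 1)
  expect_identical(db1$seq, chartr("U", "C", sim$truth$protein))
  # Sec-form homologs keep the U
  dbU <- make_homolog_db(sim$truth, 1.0, cys_substitute = FALSE, seed = 1)
  expect_true(any(grepl("U", dbU$seq)))
})

test_that("EST fragments are exact substrings at error 0 and hit the error target", {
  cfg <- generator_config(genome_length = 200000L, n_genes = 5L,
                          n_decoy_pseudo = 0L, n_decoy_cys = 0L, seed = 74L)
  sim <- simulate_benchmark(cfg)
  e0 <- make_ests(sim$truth, 50L, c(150L, 300L), error_rate = 0, seed = 2)
  for (i in seq_len(nrow(e0))) {
    src <- sim$truth$mrna[sim$truth$gene_id == e0$gene_id[i]]
    expect_identical(substr(src, e0$offset[i] + 1L, e0$offset[i] + nchar(e0$seq[i])),
                     e0$seq[i])
  }
  expect_equal(nrow(make_ests(sim$truth, 0L, c(150L, 300L), 0.01, seed = 2)), 0L)
  # realized error rate within 20% relative at ~100 kb sampled
  e1 <- make_ests(sim$truth, 300L, c(300L, 500L), error_rate = 0.01, seed = 3)
  n_err <- 0L; n_tot <- 0L
  for (i in seq_len(nrow(e1))) {
    src <- sim$truth$mrna[sim$truth$gene_id == e1$gene_id[i]]
    frag <- substr(src, e1$offset[i] + 1L, e1$offset[i] + nchar(e1$seq[i]))
    n_err <- n_err + sum(strsplit(frag, "")[[1]] != strsplit(e1$seq[i], "")[[1]])
    n_tot <- n_tot + nchar(frag)
  }
  expect_gt(n_tot, 1e5)
  expect_lt(abs(n_err / n_tot - 0.01) / 0.01, 0.2)
})

test_that("every planted gene is confirmed in the closed identity-1.0 loop", {
  cfg <- generator_config(genome_length = 150000L, n_genes = 3L,
                          n_decoy_pseudo = 0L, n_decoy_cys = 0L,
                          homolog_identity = 1.0, seed = 75L)
  sim <- simulate_benchmark(cfg)
  mods <- fit_models_from_truth(sim$genome, sim$truth, k = 5)
  calls <- run_pipeline(sim$genome, sim$proteins, NULL,
                        pipeline_config(seed = 1, organism = "loop"), mods)
  metrics <- benchmark_metrics(calls, sim$truth)
  expect_equal(metrics$sensitivity, 1)
})

test_that("the selenoprotein-P-like fixture mirrors its published architecture", {
  fx <- make_selp_fixture(seed = 7)
  tr <- fx$truth
  expect_equal(tr$n_exons, 8L)
  expect_equal(length(tr$sec_positions[[1]]), 5L)
  expect_equal(nrow(tr$secis[[1]]), 2L)
  # the first three Sec codons sit on coding exons 1, 3 and 5
  es <- tr$exon_starts[[1]]; ee <- tr$exon_ends[[1]]
  exon_of <- vapply(tr$sec_positions[[1]], function(p) {
    which(p >= es & p < ee)
  }, integer(1))
  expect_equal(exon_of[1:3], c(1L, 3L, 5L))
  expect_equal(exon_of[4:5], c(8L, 8L))
  expect_identical(spliced_seq(fx$genome$seq[[1]], es, ee, "+"), tr$cds)
})
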