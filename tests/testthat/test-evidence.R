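# Sec-flank extraction, local alignment against a textbook oracle, U/C
# pairing, family assignment, and EST read-through support.

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

random_peptide <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}

test_that("extract_sec_flank slices the expected neighbourhood", {
  expect_equal(extract_sec_flank("AAUAA", 3, window = 1), "AUA")
  expect_equal(extract_sec_flank("UAAAAAAA", 1, window = 5), "UAAAAA")
  expect_error(extract_sec_flank("AAUAA", 2, window = 1), "U residue")
  set.seed(51)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    u_at <- sample(n, 1)
    p <- strsplit(random_peptide(n, 51 + i), "")[[1]]
    p[u_at] <- "U"
    p <- paste(p, collapse = "")
    w <- sample(1:25, 1)
    got <- extract_sec_flank(p, u_at, w)
    expect_identical(got, substr(p, max(1, u_at - w), min(n, u_at + w)))
  }
})

test_that("identical peptides align with identity 1 and the diagonal score", {
  q <- "MKVLCDEWHYKNPQRS"
  hit <- local_align(q, q)
  expect_equal(hit$identity, 1)
  b <- blosum62()
  expect_equal(hit$score, sum(diag(b[strsplit(q, "")[[1]], strsplit(q, "")[[1]]])))
})

test_that("U aligns as C: single residues pair and scores are U/C-invariant", {
  hit <- local_align("U", "C")
  b <- blosum62()
  expect_equal(hit$score, b["C", "C"])
  q <- "MKUVLCDEW"
  s <- "MKCVLUDEW"
  expect_equal(local_align(q, s)$score,
               local_align(chartr("U", "C", q), chartr("U", "C", s))$score)
})

test_that("alignment scores equal an independent quadratic-space SW oracle", {
  b <- blosum62()
  set.seed(52)
  for (i in 1:50) {
    q <- random_peptide(sample(10:40, 1), 520 + i)
    s <- random_peptide(sample(10:60, 1), 570 + i)
    expect_equal(local_align(q, s)$score, oracle_sw_score(q, s, b))
  }
})

test_that("U/C pairing detects the Cys-substituted flank itself", {
  flank <- "MKVLUDEWHYKNPQRSTAW"
  db <- tibble::tibble(id = "self", seq = chartr("U", "C", flank), family = "Gpx")
  ev <- find_uc_pairing(flank, db, min_score = 20)
  expect_true(ev$positive)
  expect_gte(ev$n_cys_paired, 1L)
  expect_equal(ev$best_family, "Gpx")
  expect_error(find_uc_pairing("MKVL", db), "exactly one U")
  empty <- find_uc_pairing(flank, db[0, ], min_score = 20)
  expect_false(empty$positive)
  expect_equal(empty$n_cys_paired, 0L)
})

test_that("U/C pairing is rarely positive against unrelated random peptides", {
  set.seed(53)
  flank <- strsplit(random_peptide(41, 530), "")[[1]]
  flank[21] <- "U"
  flank <- paste(flank, collapse = "")
  db <- tibble::tibble(id = sprintf("r%03d", 1:100),
                       seq = vapply(1:100, function(i) random_peptide(200, 5300 + i),
                                    character(1)),
                       family = "none")
  thr <- calibrate_align_threshold(flank, db[1:20, ], seed = 99)
  ev <- find_uc_pairing(flank, db, min_score = thr)
  expect_lte(ev$n_cys_paired, 5L)   # < 5% of 100 random subjects
})

test_that("a planted homolog at 60% identity with conserved Cys is detected", {
  cfg <- generator_config(genome_length = 60000L, n_genes = 2L, n_decoy_pseudo = 0L,
                          n_decoy_cys = 0L, seed = 54L)
  sim <- simulate_benchmark(cfg)
  tr <- sim$truth[1, ]
  u_at <- which(strsplit(tr$protein, "")[[1]] == "U")[1]
  flank <- extract_sec_flank(tr$protein, u_at, 20L)
  if (sum(strsplit(flank, "")[[1]] == "U") > 1L) {
    fl <- strsplit(chartr("U", "C", flank), "")[[1]]
    fl[min(u_at, 21L)] <- "U"
    flank <- paste(fl, collapse = "")
  }
  ev <- find_uc_pairing(flank, sim$proteins, min_score = 30)
  expect_true(ev$positive)
})

test_that("family assignment collapses subfamilies and rejects random queries", {
  db <- tibble::tibble(
    id = c("g1", "d1", "d3"),
    seq = c(random_peptide(120, 55), random_peptide(120, 56), random_peptide(120, 57)),
    family = c("Gpx", "DI1", "DI3"))
  expect_equal(assign_family(db$seq[[1]], db), "Gpx")
  expect_equal(assign_family(db$seq[[2]], db), "DI")   # DI1 collapses to DI
  expect_equal(collapse_subfamily(c("DI1", "DI2", "SelU3", "Gpx_a", "SelP")),
               c("DI", "DI", "SelU", "Gpx", "SelP"))
  expect_equal(assign_family(random_peptide(80, 58), db), "novel")
})

test_that("EST support counts transcripts spanning the Sec codon with anchors", {
  cfg <- generator_config(genome_length = 60000L, n_genes = 1L, n_decoy_pseudo = 0L,
                          n_decoy_cys = 0L, sec_range = c(1L, 1L), seed = 59L,
                          n_ests = 200L, est_error = 0.01)
  sim <- simulate_benchmark(cfg)
  tr <- sim$truth[1, ]
  mrna <- tr$mrna
  sec_off <- tr$sec_cds_offsets[[1]]
  # the full transcript as a single error-free EST spans every Sec codon
  full <- est_support(mrna, sec_off, tibble::tibble(id = "e", seq = mrna))
  expect_equal(full$n_spanning, length(sec_off))
  # ESTs that end before the TGA never count
  before <- substr(mrna, 1, sec_off[1] - 10L)
  none <- est_support(mrna, sec_off, tibble::tibble(id = "e", seq = before))
  expect_equal(none$n_spanning, 0L)
  # generator ESTs match a direct coverage oracle (provenance + offsets)
  ests <- sim$ests[sim$ests$gene_id == tr$gene_id, ]
  got <- est_support(mrna, sec_off, ests, anchor = 50L, min_identity = 0.95)
  oracle <- 0L
  for (i in seq_len(nrow(ests))) {
    lo <- ests$offset[i]
    hi <- lo + nchar(ests$seq[i])
    for (off in sec_off) {
      if (lo <= off - 50L && hi >= off + 3L + 50L) oracle <- oracle + 1L
    }
  }
  # identity filtering can only remove pairs relative to the pure coverage
  # count; at 1% error virtually all qualify
  expect_lte(got$n_spanning, oracle)
  expect_gte(got$n_spanning, floor(0.8 * oracle))
})

test_that("batch and single-pair alignment paths agree", {
  q <- random_peptide(40, 60)
  subs <- vapply(1:5, function(i) random_peptide(150, 600 + i), character(1))
  single <- vapply(subs, function(s) local_align(q, s)$score, numeric(1))
  db <- tibble::tibble(id = letters[1:5], seq = subs, family = "x")
  thr <- min(single) - 1
  ev <- find_uc_pairing(sub("^(.{20}).", "\\1U", q), db, min_identity = 0,
                        min_score = thr)
  expect_true(is.logical(ev$positive))
  expect_identical(unname(single),
                   unname(vapply(subs, function(s) oracle_sw_score(q, s, blosum62()),
                                 numeric(1))))
})
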