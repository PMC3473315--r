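# FASTA/GFF3 round trips, coordinate conventions, reverse complement, and
# the spliced product-to-genome mapper.

test_that("read_fasta parses records, normalises case and U, rejects bad input", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgu", ">b", "NNN"), tf)
  g <- read_fasta(tf)
  expect_equal(g$id, c("a", "b"))
  expect_equal(g$seq, c("ACGT", "NNN"))
  expect_equal(g$length, c(4L, 3L))

  writeLines(c(">a", "ACGT", ">a", "GGG"), tf)
  expect_error(read_fasta(tf), "duplicate")
  writeLines(c(">a", "", ">b", "ACGT"), tf)
  expect_error(read_fasta(tf), "empty sequence")
  writeLines(character(), tf)
  expect_error(read_fasta(tf))
})

test_that("write_fasta / read_fasta round-trips 100 random records", {
  set.seed(401)
  recs <- tibble::tibble(
    id = sprintf("rec%03d", 1:100),
    seq = vapply(1:100, function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), sample(20:300, 1), replace = TRUE,
                   prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    }, character(1))
  )
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, tf)
  back <- read_fasta(tf)
  expect_equal(back$id, recs$id)
  expect_equal(back$seq, recs$seq)
})

test_that("reverse_complement is a Watson-Crick involution", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("NAN"), "NTN")
  expect_error(reverse_complement("ATGX"), "outside")
  set.seed(402)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1), replace = TRUE),
               collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("map_product_to_genome recovers a planted single-exon gene exactly", {
  set.seed(403)
  cds <- "ATGAAACTTTGACCCGGATAA"   # M K L U P G *
  left <- rand_dna(300, 403)
  right <- rand_dna(300, 404)
  locus <- tiny_genome(paste0(left, cds, right))
  hit <- map_product_to_genome(translate_cds(cds), locus)
  expect_equal(hit$n_exons, 1L)
  expect_equal(hit$exon_starts[[1]], 300L)
  expect_equal(hit$exon_ends[[1]], 300L + nchar(cds))
  expect_equal(hit$sec_positions[[1]], 300L + 9L)
})

test_that("spliced mapping recovers planted multi-exon structure, both strands", {
  cfg <- generator_config(genome_length = 30000L, n_genes = 1L,
                          n_decoy_pseudo = 0L, n_decoy_cys = 0L,
                          exon_range = c(3L, 3L), seed = 17L)
  sim <- simulate_benchmark(cfg)
  tr <- sim$truth[1, ]
  hit <- map_product_to_genome(tr$protein, sim$genome)
  expect_equal(hit$n_exons, 3L)
  expect_identical(hit$exon_starts[[1]], tr$exon_starts[[1]])
  expect_identical(hit$exon_ends[[1]], tr$exon_ends[[1]])
  expect_identical(hit$strand, tr$strand)
  expect_identical(sort(hit$sec_positions[[1]]), sort(tr$sec_positions[[1]]))

  # strand mirror: the same product maps to the reverse-complemented locus
  # at reflected coordinates on the opposite strand
  L <- sim$genome$length[[1]]
  flipped <- tiny_genome(reverse_complement(sim$genome$seq[[1]]), id = sim$genome$id[[1]])
  hit2 <- map_product_to_genome(tr$protein, flipped)
  expect_false(hit2$strand == hit$strand)
  r <- reflect_interval(hit$exon_starts[[1]], hit$exon_ends[[1]], L)
  expect_equal(sort(r$start), hit2$exon_starts[[1]])
  expect_equal(sort(r$end), hit2$exon_ends[[1]])
})

test_that("mapping fails cleanly when the product is not encoded in the locus", {
  locus <- tiny_genome(rand_dna(500, 405))
  expect_error(map_product_to_genome("MKLVDEERRTW", locus), "mapping")
})

test_that("GFF3 emission uses 1-based inclusive coordinates and round-trips", {
  call <- tibble::tibble(
    call_id = "c1", seqid = "chr", strand = "-",
    exon_starts = list(c(10L, 100L)), exon_ends = list(c(40L, 160L)),
    sec_positions = list(25L), total_score = 12.5,
    secis = list(tibble::tibble(start = 300L, end = 360L,
                                motif_class = "AUGA_AA", score = 28)),
    family = "Gpx", status = "confirmed"
  )
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(call, tf)
  lines <- readLines(tf)
  cds <- lines[grepl("\tCDS\t", lines)]
  # internal [10, 40) must print as GFF3 columns 11..40
  expect_true(any(grepl("\t11\t40\t", cds)))
  expect_true(all(grepl("\t-\t", cds)))
  back <- read_gff3(tf)
  expect_identical(back$exon_starts[[1]], call$exon_starts[[1]])
  expect_identical(back$exon_ends[[1]], call$exon_ends[[1]])
  expect_identical(back$sec_positions[[1]], call$sec_positions[[1]])
  expect_identical(back$secis[[1]]$start, 300L)
  expect_identical(back$secis[[1]]$end, 360L)
  expect_error(write_gff3(call, tf, record_lengths = c(chr = 100L)), "bounds")
})

test_that("GFF3 output is byte-identical across repeated writes", {
  cfg <- generator_config(genome_length = 60000L, n_genes = 3L,
                          n_decoy_pseudo = 0L, n_decoy_cys = 0L, seed = 23L)
  sim <- simulate_benchmark(cfg)
  calls <- tibble::tibble(
    call_id = sprintf("t%02d", seq_len(nrow(sim$truth))),
    seqid = sim$truth$seqid, strand = sim$truth$strand,
    exon_starts = sim$truth$exon_starts, exon_ends = sim$truth$exon_ends,
    sec_positions = sim$truth$sec_positions, total_score = 1,
    secis = purrr::map(sim$truth$secis, ~ dplyr::mutate(.x, score = 25)),
    family = sim$truth$family, status = "confirmed"
  )
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gff3(calls, f1)
  write_gff3(calls, f2)
  expect_identical(readLines(f1), readLines(f2))
})
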