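# Synthetic benchmark generator: genomes with planted multi-exon
# selenoprotein genes (GT/AG introns, in-frame TGA codons, downstream
# SECIS hairpins), decoy pseudogenes lacking SECIS, Cys-paralog decoys,
# mutated homolog databases and error-bearing EST fragments, together with
# ground truth for every planted feature.

#' Generator configuration
#'
#' Defaults define the standard desk-scale benchmark: a 2 Mb genome at GC
#' 0.40 with 20 planted selenoprotein genes (1-9 exons, 1-3 Sec codons,
#' occasionally two SECIS elements), 5 pseudogene decoys (complete
#' selenoprotein gene structure but no SECIS), 5 Cys-paralog decoys,
#' homologs mutated to 60% identity with U changed to C, and 2,000 ESTs of
#' 150-600 nt at 1% error, seed 42.
#'
#' @param ... Overrides for any default field.
#' @return A list of class `selenoscan_generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    genome_length = 2e6, gc = 0.40, n_genes = 20L,
    exon_range = c(1L, 9L), codon_range = c(120L, 400L),
    intron_range = c(60L, 1500L), sec_range = c(1L, 3L),
    two_secis_prob = 0.15,
    n_decoy_pseudo = 5L, n_decoy_cys = 5L,
    homolog_identity = 0.6, cys_substitute = TRUE,
    n_ests = 2000L, est_len = c(150L, 600L), est_error = 0.01,
    flank3 = 3000L, min_gap = 2000L, seed = 42L
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "selenoscan_generator_config")
}

#' Generate background genomic sequence
#'
#' I.i.d. bases at the requested GC fraction; deterministic per seed.
#'
#' @param length Number of bases.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return DNA string.
#' @export
generate_background <- function(length, gc, seed = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

# codon-usage weights over the 61 sense codons, drawn once per genome so
# planted coding sequence has learnable three-periodic structure without
# matching any fixed scoring table
draw_codon_weights <- function() {
  all_codons <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0))
  sense <- setdiff(all_codons, c(STOP_CODONS, SEC_CODON))
  w <- stats::rgamma(length(sense), shape = 0.8)
  setNames(w / sum(w), sense)
}

sample_codons <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

# sample() treats a length-1 numeric as 1:x; always sample from the set
pick <- function(x, n = 1L) x[sample.int(length(x), n)]

#' Build a SECIS element sequence
#'
#' Constructs a stem-loop with the requested geometry: helix I of `h1`
#' Watson-Crick pairs, internal loop (`l1`/`l2` nt, the last 5' loop base
#' being the class base A or G), helix II of `h2` pairs whose first four
#' are the UGA-opening non-Watson-Crick quartet, and an apical loop of
#' `apical` nt containing AA.
#'
#' @param motif_class `"AUGA_AA"` or `"GUGA_AA"`.
#' @param h1,h2 Helix lengths (bp).
#' @param l1,l2 Internal loop sizes (nt per side).
#' @param apical Apical loop size (nt, >= 8).
#' @return List: `seq` (DNA string) and `quartet_offset` (0-based offset of
#'   the TGA within the element).
#' @export
build_secis_element <- function(motif_class = "AUGA_AA", h1 = 8L, l1 = 3L, l2 = 3L,
                                h2 = 10L, apical = 10L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # non-WC, non-GU partner for each quartet base
  nonpair <- c(A = "G", C = "A", G = "A", T = "C")
  arm1 <- sample(DNA_BASES, h1, replace = TRUE)
  class_base <- if (motif_class == "AUGA_AA") "A" else "G"
  loop5 <- c(sample(DNA_BASES, l1 - 1L, replace = TRUE), class_base)
  quartet5 <- c("T", "G", "A", sample(DNA_BASES, 1L))
  rest5 <- sample(DNA_BASES, h2 - 4L, replace = TRUE)
  arm2_5 <- c(quartet5, rest5)
  ap <- sample(c("C", "G", "T"), apical, replace = TRUE)  # avoid stray A runs
  aa_at <- sample.int(apical - 1L, 1L)
  ap[aa_at] <- "A"; ap[aa_at + 1L] <- "A"
  # 3' arm of helix II: pair i of arm2_5 partners position h2-1-i (0-based)
  arm2_3 <- rev(vapply(seq_len(h2), function(i) {
    if (i <= 4L) nonpair[[arm2_5[i]]] else comp[[arm2_5[i]]]
  }, character(1)))
  loop3 <- sample(DNA_BASES, l2, replace = TRUE)
  arm1_3 <- rev(vapply(arm1, function(b) comp[[b]], character(1)))
  seq <- paste(c(arm1, loop5, arm2_5, ap, arm2_3, loop3, arm1_3), collapse = "")
  list(seq = seq, quartet_offset = h1 + l1)
}

# polypyrimidine-rich acceptor tail + branch-free intron body
make_intron <- function(len) {
  stopifnot(len >= 40L)
  body <- sample(DNA_BASES, len - 20L, replace = TRUE)
  py <- sample(DNA_BASES, 11L, replace = TRUE, prob = c(0.05, 0.45, 0.05, 0.45))
  paste(c("GTAAGT", body, py, "CAG"), collapse = "")
}

start_context <- function() {
  consensus <- c("G", "C", "C", "A", "C", "C")
  vapply(consensus, function(b) {
    if (runif(1) < 0.7) b else sample(DNA_BASES, 1L)
  }, character(1)) |> paste(collapse = "")
}

#' Plant one selenoprotein gene cassette
#'
#' Builds a complete gene: Kozak-like start context, coding exons sampled
#' from the genome's codon-usage table with TGA at the requested Sec codon
#' indices, GT..AG introns with donor/acceptor consensus, a TAA/TAG stop,
#' and SECIS elements at the requested offsets in the 3' flank. Exon splits
#' may fall inside codons but never inside a Sec codon.
#'
#' @param plan List: `n_exons`, `n_codons`, `sec_codons` (1-based internal
#'   codon indices), `secis` (tibble with `offset`, `motif_class`; may have
#'   zero rows), `type` (`"gene"`, `"pseudo"` or `"cys"`).
#' @param cfg A [generator_config()].
#' @param codon_weights Codon-usage weights.
#' @return List: `seq` (cassette string), `truth` (one-row tibble with
#'   cassette-local coordinates).
#' @export
plant_selenogene <- function(plan, cfg = generator_config(), codon_weights = NULL) {
  if (is.null(codon_weights)) codon_weights <- draw_codon_weights()
  n_cod <- plan$n_codons
  codons <- sample_codons(n_cod - 2L, codon_weights)
  sec_cod <- sort(plan$sec_codons)
  stopifnot(all(sec_cod > 1L), all(sec_cod < n_cod))
  if (plan$type == "cys") {
    codons[sec_cod - 1L] <- "TGC"
  } else {
    codons[sec_cod - 1L] <- SEC_CODON
  }
  cds <- paste(c("ATG", codons, pick(STOP_CODONS)), collapse = "")
  cds_len <- nchar(cds)
  # exon cut points (0-based CDS offsets), never inside a Sec codon
  n_ex <- plan$n_exons
  sec_nt <- (sec_cod - 1L) * 3L   # 0-based CDS offset of each Sec codon start
  cuts <- integer()
  if (n_ex > 1L) {
    for (attempt in 1:200) {
      cand <- sort(sample(seq(35L, cds_len - 35L), n_ex - 1L))
      if (n_ex > 2L && any(diff(cand) < 35L)) next
      inside_sec <- any(vapply(cand, function(cp) any(cp > sec_nt & cp < sec_nt + 3L), logical(1)))
      if (!inside_sec) { cuts <- cand; break }
    }
    if (!length(cuts)) stop("could not place exon boundaries", call. = FALSE)
  }
  bounds <- c(0L, cuts, cds_len)
  exon_cds <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- if (n_ex > 1L) {
    vapply(seq_len(n_ex - 1L),
           function(i) make_intron(pick(cfg$intron_range[1]:cfg$intron_range[2])),
           character(1))
  } else character()
  ctx <- start_context()
  body <- character(2L * n_ex - 1L)
  body[seq(1L, 2L * n_ex - 1L, 2L)] <- exon_cds
  if (n_ex > 1L) body[seq(2L, 2L * n_ex - 2L, 2L)] <- introns
  gene_seq <- paste(body, collapse = "")
  # 3' flank with SECIS elements
  gc <- cfg$gc
  p_bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  flank <- sample(DNA_BASES, cfg$flank3, replace = TRUE, prob = p_bg)
  secis_rows <- list()
  if (!is.null(plan$secis) && nrow(plan$secis)) {
    for (i in seq_len(nrow(plan$secis))) {
      el <- build_secis_element(plan$secis$motif_class[i])
      off <- plan$secis$offset[i]
      el_chars <- strsplit(el$seq, "")[[1]]
      flank[(off + 1L):(off + length(el_chars))] <- el_chars
      secis_rows[[i]] <- tibble::tibble(offset = off, len = length(el_chars),
                                        quartet_offset = el$quartet_offset,
                                        motif_class = plan$secis$motif_class[i])
    }
  }
  flank <- paste(flank, collapse = "")
  cassette <- paste0(ctx, gene_seq, flank)
  # cassette-local exon coordinates
  exon_lens <- nchar(exon_cds)
  intron_lens <- nchar(introns)
  starts <- integer(n_ex)
  pos <- nchar(ctx)
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    pos <- pos + exon_lens[i]
    if (i < n_ex) pos <- pos + intron_lens[i]
  }
  ends <- starts + exon_lens
  gene_end <- ends[n_ex]
  # cassette-local Sec codon positions (genomic start of each TGA codon)
  sec_pos <- vapply(sec_nt, function(off) cds_to_cassette(off, bounds, starts), integer(1))
  secis_tbl <- if (length(secis_rows)) {
    sr <- dplyr::bind_rows(secis_rows)
    tibble::tibble(start = gene_end + sr$offset, end = gene_end + sr$offset + sr$len,
                   quartet_pos = gene_end + sr$offset + sr$quartet_offset,
                   motif_class = sr$motif_class)
  } else {
    tibble::tibble(start = integer(), end = integer(), quartet_pos = integer(),
                   motif_class = character())
  }
  protein <- translate_cds(cds, sec_readthrough = TRUE)
  mrna <- paste0(cds, flank)
  truth <- tibble::tibble(
    type = plan$type, n_exons = n_ex,
    exon_starts = list(starts), exon_ends = list(ends),
    sec_positions = list(if (plan$type == "cys") integer() else as.integer(sec_pos)),
    sec_cds_offsets = list(if (plan$type == "cys") integer() else as.integer(sec_nt)),
    secis = list(secis_tbl), protein = protein, cds = cds, mrna = mrna,
    cassette_len = nchar(cassette), gene_end = gene_end
  )
  list(seq = cassette, truth = truth)
}

# 0-based CDS offset -> cassette-local coordinate given exon bounds/starts
cds_to_cassette <- function(off, bounds, starts) {
  ex <- findInterval(off, bounds[-length(bounds)], rightmost.closed = FALSE)
  as.integer(starts[ex] + (off - bounds[ex]))
}

#' Simulate the full benchmark data set
#'
#' Generates the background genome, plants genes and decoys on random
#' strands at non-overlapping positions, and derives the homolog database
#' and EST set. All randomness is governed by `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return List: `genome` (tibble), `truth` (tibble with genomic
#'   coordinates, one row per planted feature), `proteins` (homolog db
#'   tibble), `ests` (tibble), `codon_weights`, `config`.
#' @export
simulate_benchmark <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  weights <- draw_codon_weights()
  fams <- c("Gpx", "DI", "SelP", "SelW", "SelT", "TR", "SelU", "SelK", "SelM", "Sps")
  n_feat <- cfg$n_genes + cfg$n_decoy_pseudo + cfg$n_decoy_cys
  types <- c(rep("gene", cfg$n_genes), rep("pseudo", cfg$n_decoy_pseudo),
             rep("cys", cfg$n_decoy_cys))
  plans <- lapply(seq_len(n_feat), function(i) {
    n_ex <- pick(cfg$exon_range[1]:cfg$exon_range[2])
    n_cod <- pick(cfg$codon_range[1]:cfg$codon_range[2])
    n_ex <- min(n_ex, max(1L, (3L * n_cod) %/% 60L))   # room for >=35 nt exons
    n_sec <- pick(cfg$sec_range[1]:cfg$sec_range[2])
    sec_codons <- sort(sample(10:(n_cod - 10L), n_sec))
    # keep Sec codons in distinct codons
    while (any(diff(sec_codons) < 2L)) {
      sec_codons <- sort(sample(10:(n_cod - 10L), n_sec))
    }
    secis <- if (types[i] == "gene") {
      n_secis <- if (runif(1) < cfg$two_secis_prob) 2L else 1L
      offs <- sort(sample(seq(150L, cfg$flank3 - 400L), n_secis))
      while (n_secis > 1L && diff(offs) < 150L) {
        offs <- sort(sample(seq(150L, cfg$flank3 - 400L), n_secis))
      }
      tibble::tibble(offset = offs,
                     motif_class = sample(c("AUGA_AA", "GUGA_AA"), n_secis,
                                          replace = TRUE, prob = c(0.7, 0.3)))
    } else {
      tibble::tibble(offset = integer(), motif_class = character())
    }
    list(n_exons = n_ex, n_codons = n_cod, sec_codons = sec_codons,
         secis = secis, type = types[i])
  })
  cassettes <- lapply(plans, plant_selenogene, cfg = cfg, codon_weights = weights)
  lens <- vapply(cassettes, function(x) nchar(x$seq), integer(1))
  total <- sum(lens)
  free <- cfg$genome_length - total - (n_feat + 1L) * cfg$min_gap
  if (free < 0L) stop("genome too short for requested features", call. = FALSE)
  extra <- stats::rmultinom(1L, size = free, prob = rep(1, n_feat + 1L))[, 1]
  gaps <- cfg$min_gap + extra
  bg <- strsplit(generate_background(cfg$genome_length, cfg$gc, seed = cfg$seed + 1L),
                 "")[[1]]
  pos <- 0L
  rows <- vector("list", n_feat)
  strands <- sample(c("+", "-"), n_feat, replace = TRUE)
  for (i in seq_len(n_feat)) {
    pos <- pos + gaps[i]
    cass <- cassettes[[i]]$seq
    strand <- strands[i]
    if (strand == "-") cass <- reverse_complement(cass)
    bg[(pos + 1L):(pos + lens[i])] <- strsplit(cass, "")[[1]]
    tr <- cassettes[[i]]$truth
    L <- lens[i]
    es <- tr$exon_starts[[1]]; ee <- tr$exon_ends[[1]]
    secp <- tr$sec_positions[[1]]
    secis <- tr$secis[[1]]
    if (strand == "-") {
      r <- reflect_interval(es, ee, L)
      es <- sort(r$start); ee <- sort(r$end)
      secp <- sort(L - secp - 3L)
      if (nrow(secis)) {
        rs <- reflect_interval(secis$start, secis$end, L)
        secis <- tibble::tibble(start = rs$start, end = rs$end,
                                quartet_pos = L - secis$quartet_pos - 3L,
                                motif_class = secis$motif_class)
        secis <- dplyr::arrange(secis, .data$start)
      }
    }
    rows[[i]] <- tibble::tibble(
      gene_id = sprintf("%s_%03d", tr$type, i), type = tr$type,
      seqid = "synthetic_1", strand = strand, family = fams[(i - 1L) %% length(fams) + 1L],
      n_exons = tr$n_exons,
      exon_starts = list(es + pos), exon_ends = list(ee + pos),
      sec_positions = list(secp + pos),
      sec_cds_offsets = tr$sec_cds_offsets,
      secis = list(if (nrow(secis)) dplyr::mutate(secis,
        start = .data$start + pos, end = .data$end + pos,
        quartet_pos = .data$quartet_pos + pos) else secis),
      protein = tr$protein, cds = tr$cds, mrna = tr$mrna
    )
    pos <- pos + lens[i]
  }
  truth <- dplyr::bind_rows(rows)
  genome <- tibble::tibble(id = "synthetic_1", seq = paste(bg, collapse = ""),
                           length = as.integer(cfg$genome_length))
  proteins <- make_homolog_db(truth, cfg$homolog_identity, cfg$cys_substitute,
                              seed = cfg$seed + 2L)
  ests <- make_ests(truth, cfg$n_ests, cfg$est_len, cfg$est_error, seed = cfg$seed + 3L)
  list(genome = genome, truth = truth, proteins = proteins, ests = ests,
       codon_weights = weights, config = cfg)
}

#' Derive a mutated homolog database from planted proteins
#'
#' Each planted protein yields one database entry at approximately the
#' target identity: residues are substituted independently with
#' probability `1 - identity` (the Sec/Cys position itself is left
#' untouched so the catalytic column stays alignable). With
#' `cys_substitute`, `U` residues become `C` (Cys-form homologs);
#' otherwise they stay `U` (Sec-form homologs).
#'
#' @param truth Truth tibble from [simulate_benchmark()] (needs `gene_id`,
#'   `protein`, `family`, `sec_cds_offsets`).
#' @param identity Target sequence identity in `(0, 1]`.
#' @param cys_substitute Replace U by C in the homologs.
#' @param seed RNG seed.
#' @return Tibble `id`, `seq`, `family`.
#' @export
make_homolog_db <- function(truth, identity, cys_substitute = TRUE, seed = 1L) {
  stopifnot(identity > 0, identity <= 1)
  set.seed(seed)
  rows <- purrr::map(seq_len(nrow(truth)), function(i) {
    aa <- strsplit(truth$protein[[i]], "")[[1]]
    u_idx <- which(aa == "U")
    mut <- runif(length(aa)) < (1 - identity)
    mut[u_idx] <- FALSE
    repl <- vapply(aa[mut], function(a) sample(setdiff(AA_LETTERS, a), 1L), character(1))
    aa[mut] <- repl
    if (cys_substitute) aa[u_idx] <- "C"
    tibble::tibble(id = paste0("hom_", truth$gene_id[[i]]),
                   seq = paste(aa, collapse = ""),
                   family = truth$family[[i]])
  })
  dplyr::bind_rows(rows)
}

#' Draw EST fragments from planted transcripts
#'
#' Uniform substrings of the planted spliced mRNAs with independent point
#' errors at the requested rate; provenance (source gene and offset) is
#' recorded for oracle checks.
#'
#' @param truth Truth tibble (rows with an `mrna` are eligible).
#' @param n Number of ESTs.
#' @param len_range Length range (nt).
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @return Tibble `id`, `seq`, `gene_id`, `offset`.
#' @export
make_ests <- function(truth, n, len_range = c(150L, 600L), error_rate = 0.01, seed = 1L) {
  set.seed(seed)
  src <- truth[!is.na(truth$mrna) & nchar(truth$mrna) >= len_range[1], ]
  if (n == 0L || nrow(src) == 0L) {
    return(tibble::tibble(id = character(), seq = character(),
                          gene_id = character(), offset = integer()))
  }
  rows <- purrr::map(seq_len(n), function(i) {
    j <- sample.int(nrow(src), 1L)
    m <- src$mrna[[j]]
    len <- pick(len_range[1]:min(len_range[2], nchar(m)))
    off <- sample.int(nchar(m) - len + 1L, 1L) - 1L
    frag <- strsplit(substr(m, off + 1L, off + len), "")[[1]]
    err <- runif(len) < error_rate
    if (any(err)) {
      frag[err] <- vapply(frag[err], function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
    }
    tibble::tibble(id = sprintf("est_%05d", i), seq = paste(frag, collapse = ""),
                   gene_id = src$gene_id[[j]], offset = off)
  })
  dplyr::bind_rows(rows)
}

#' Synthetic selenoprotein-P-like worked-example locus
#'
#' Builds a single-gene genome with the dual-strategy selenoprotein P
#' architecture: 8 coding exons, Sec codons on coding exons 1, 3 and 5
#' (the three thioredoxin-like repeat regions), two additional Sec codons
#' near the C-terminus of the last exon, and two SECIS elements in the 3'
#' UTR. The locus is synthetic: it reproduces the published architecture,
#' not any published sequence.
#'
#' @param seed RNG seed.
#' @return List: `genome`, `truth` (one row), `proteins` (Cys-form homolog
#'   db), `config`.
#' @export
make_selp_fixture <- function(seed = 7L) {
  set.seed(seed)
  cfg <- generator_config(genome_length = 30000L, n_genes = 1L,
                          n_decoy_pseudo = 0L, n_decoy_cys = 0L, seed = seed)
  weights <- draw_codon_weights()
  n_cod <- 360L
  n_ex <- 8L
  # fixed exon sizes in codons so Sec codons land on chosen exons
  ex_codons <- c(45L, 45L, 45L, 45L, 45L, 45L, 45L, 45L)
  bounds_cod <- cumsum(c(0L, ex_codons))
  sec_codons <- c(20L,                        # on coding exon 1
                  bounds_cod[3] + 20L,        # on coding exon 3
                  bounds_cod[5] + 20L,        # on coding exon 5
                  n_cod - 8L, n_cod - 4L)     # two near the C-terminus (exon 8)
  plan <- list(n_exons = n_ex, n_codons = n_cod, sec_codons = sec_codons,
               secis = tibble::tibble(offset = c(300L, 900L),
                                      motif_class = c("AUGA_AA", "AUGA_AA")),
               type = "gene")
  # exon cuts at fixed codon-derived positions (use plant_selenogene's cds
  # construction but force boundaries by codon blocks with a 1-nt shift to
  # exercise split codons)
  cass <- plant_selp_cassette(plan, cfg, weights, ex_codons)
  pad5 <- generate_background(4000L, cfg$gc, seed = seed + 1L)
  pad3 <- generate_background(30000L - 4000L - nchar(cass$seq), cfg$gc, seed = seed + 2L)
  gseq <- paste0(pad5, cass$seq, pad3)
  tr <- cass$truth
  truth <- tibble::tibble(
    gene_id = "selp_like_1", type = "gene", seqid = "selp_locus", strand = "+",
    family = "SelP", n_exons = tr$n_exons,
    exon_starts = list(tr$exon_starts[[1]] + 4000L),
    exon_ends = list(tr$exon_ends[[1]] + 4000L),
    sec_positions = list(tr$sec_positions[[1]] + 4000L),
    sec_cds_offsets = tr$sec_cds_offsets,
    secis = list(dplyr::mutate(tr$secis[[1]], start = .data$start + 4000L,
                               end = .data$end + 4000L,
                               quartet_pos = .data$quartet_pos + 4000L)),
    protein = tr$protein, cds = tr$cds, mrna = tr$mrna
  )
  genome <- tibble::tibble(id = "selp_locus", seq = gseq, length = nchar(gseq))
  proteins <- make_homolog_db(truth, identity = 0.7, cys_substitute = TRUE,
                              seed = seed + 3L)
  list(genome = genome, truth = truth, proteins = proteins, config = cfg)
}

# selenoprotein-P fixture cassette with prescribed per-exon codon blocks;
# exon boundaries are codon boundaries shifted by one to keep split codons
# in play
plant_selp_cassette <- function(plan, cfg, weights, ex_codons) {
  n_cod <- plan$n_codons
  codons <- sample_codons(n_cod - 2L, weights)
  codons[plan$sec_codons - 1L] <- SEC_CODON
  cds <- paste(c("ATG", codons, pick(STOP_CODONS)), collapse = "")
  cds_len <- nchar(cds)
  cuts <- cumsum(ex_codons[-length(ex_codons)]) * 3L + 1L   # +1 nt: split codons
  sec_nt <- (plan$sec_codons - 1L) * 3L
  stopifnot(!any(vapply(cuts, function(cp) any(cp > sec_nt & cp < sec_nt + 3L), logical(1))))
  bounds <- c(0L, cuts, cds_len)
  exon_cds <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- vapply(seq_len(plan$n_exons - 1L),
                    function(i) make_intron(pick(200:800)), character(1))
  ctx <- start_context()
  body <- character(2L * plan$n_exons - 1L)
  body[seq(1L, length(body), 2L)] <- exon_cds
  body[seq(2L, length(body) - 1L, 2L)] <- introns
  gene_seq <- paste(body, collapse = "")
  p_bg <- c(0.3, 0.2, 0.2, 0.3)
  flank <- sample(DNA_BASES, cfg$flank3, replace = TRUE, prob = p_bg)
  secis_rows <- list()
  for (i in seq_len(nrow(plan$secis))) {
    el <- build_secis_element(plan$secis$motif_class[i])
    off <- plan$secis$offset[i]
    el_chars <- strsplit(el$seq, "")[[1]]
    flank[(off + 1L):(off + length(el_chars))] <- el_chars
    secis_rows[[i]] <- tibble::tibble(offset = off, len = length(el_chars),
                                      quartet_offset = el$quartet_offset,
                                      motif_class = plan$secis$motif_class[i])
  }
  flank <- paste(flank, collapse = "")
  cassette <- paste0(ctx, gene_seq, flank)
  exon_lens <- nchar(exon_cds)
  starts <- integer(plan$n_exons)
  pos <- nchar(ctx)
  for (i in seq_len(plan$n_exons)) {
    starts[i] <- pos
    pos <- pos + exon_lens[i]
    if (i < plan$n_exons) pos <- pos + nchar(introns[i])
  }
  ends <- starts + exon_lens
  gene_end <- ends[plan$n_exons]
  sec_pos <- vapply(sec_nt, function(off) cds_to_cassette(off, bounds, starts), integer(1))
  sr <- dplyr::bind_rows(secis_rows)
  secis_tbl <- tibble::tibble(start = gene_end + sr$offset,
                              end = gene_end + sr$offset + sr$len,
                              quartet_pos = gene_end + sr$offset + sr$quartet_offset,
                              motif_class = sr$motif_class)
  truth <- tibble::tibble(
    type = "gene", n_exons = plan$n_exons,
    exon_starts = list(starts), exon_ends = list(ends),
    sec_positions = list(as.integer(sec_pos)),
    sec_cds_offsets = list(as.integer(sec_nt)),
    secis = list(secis_tbl),
    protein = translate_cds(cds), cds = cds, mrna = paste0(cds, flank),
    cassette_len = nchar(cassette), gene_end = gene_end
  )
  list(seq = cassette, truth = truth)
}

#' Fit scoring models from planted ground truth
#'
#' Trains the signal PWMs on the planted gene structures and the Markov
#' coding model on the planted CDS set, with noncoding material taken as
#' evenly spaced windows of the genome (overwhelmingly background at the
#' default gene density).
#'
#' @param genome Genome tibble.
#' @param truth Truth tibble.
#' @param k Markov order.
#' @return List: `signal` (a `selenoscan_signal_model`), `markov`
#'   (a `selenoscan_markov`).
#' @export
fit_models_from_truth <- function(genome, truth, k = 5L) {
  genes <- truth[truth$type %in% c("gene", "pseudo", "cys"), ]
  signal <- train_signal_model(genome, genes)
  L <- nchar(genome$seq[[1]])
  win_starts <- seq(0L, max(0L, L - 2000L), by = max(2000L, L %/% 50L))
  noncoding <- substring(genome$seq[[1]], win_starts + 1L, win_starts + 2000L)
  markov <- train_markov(genes$cds, noncoding, k = k)
  list(signal = signal, markov = markov)
}
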