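# End-to-end orchestration: scan -> enumerate -> assemble -> translate ->
# Sec/Cys pairing -> SECIS -> EST support, followed by the confirmation
# filter, family summaries and tandem-cluster detection. Confirmation
# requires BOTH positive U/C pairing and at least one SECIS element; EST
# support is reported as corroborating annotation only.

#' Pipeline configuration
#'
#' Collects the per-module parameter blocks, validated once before any
#' work. `min_total_score` (bits) filters assembled models before evidence
#' gathering; the default 0 requires a positive overall coding potential.
#'
#' @param seed Seed governing every stochastic step (alignment-threshold
#'   calibration shuffles).
#' @param organism Organism tag attached to calls.
#' @param k Markov order for the coding model.
#' @param limits Exon-enumeration limits (see [enumerate_exons()]).
#' @param assembler Assembler parameters (see [assemble_orfs()]).
#' @param evidence List: `flank_window`, `min_identity`, `min_score`
#'   (`NULL` calibrates from shuffled subjects), `est_anchor`,
#'   `est_identity`, `family_min_score`, `family_min_identity`.
#' @param secis A [secis_params()] object.
#' @param min_total_score Minimum model score (bits) to enter evidence
#'   evaluation.
#' @param min_protein_length Minimum model length in residues. Real
#'   selenoproteins are rarely under ~80 residues (SelW, SelK are among the
#'   shortest); the conservative default of 50 discards sub-gene-sized
#'   chance ORFs before evidence gathering.
#' @param cluster_max_gap Tandem-cluster gap threshold (nt).
#' @return A list of class `selenoscan_config`.
#' @export
pipeline_config <- function(seed = 1L, organism = "unknown", k = 5L,
                            limits = list(), assembler = list(),
                            evidence = list(), secis = secis_params(),
                            min_total_score = 0, min_protein_length = 50L,
                            cluster_max_gap = 50000L) {
  ev <- utils::modifyList(list(flank_window = 20L, min_identity = 0.3,
                               min_score = NULL, est_anchor = 50L,
                               est_identity = 0.95, family_min_score = 60,
                               family_min_identity = 0.25), evidence)
  if (!inherits(secis, "secis_params")) stop("secis must be a secis_params() object", call. = FALSE)
  if (ev$flank_window < 1L) stop("flank_window must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), organism = organism, k = as.integer(k),
                 limits = limits, assembler = assembler, evidence = ev,
                 secis = secis, min_total_score = min_total_score,
                 min_protein_length = as.integer(min_protein_length),
                 cluster_max_gap = as.integer(cluster_max_gap)),
            class = "selenoscan_config")
}

#' Run the selenoprotein identification pipeline
#'
#' Executes the five identification stages on every record and strand of
#' the genome. Assembled models with positive coding potential are checked
#' for Sec/Cys pairing of their Sec-flanking peptides against the protein
#' database, for SECIS elements in the 3' window downstream of their stop,
#' and (confirmed calls only) for spliced-EST read-through support.
#' Confirmed calls carry a family label from their best database hit.
#'
#' @param genome Genome tibble from [read_fasta()].
#' @param proteins Homolog database tibble (`id`, `seq`, optional
#'   `family`); FASTA headers of the form `id family=NAME` are parsed by
#'   [read_protein_db()].
#' @param ests Optional EST tibble (`id`, `seq`).
#' @param config A [pipeline_config()].
#' @param models Scoring models: list with `signal` and `markov`
#'   (e.g. from [fit_models_from_truth()] or user training data).
#' @param out_dir Optional output directory; when given, writes
#'   `calls.gff3`, `proteins.faa`, `secis.bed`, `summary.tsv`, `audit.tsv`
#'   and `run.log`.
#' @return Tibble of calls (confirmed and rejected; see `status` and
#'   `reject_reason`), with genomic coordinates.
#' @export
run_pipeline <- function(genome, proteins, ests = NULL, config = pipeline_config(),
                         models, out_dir = NULL) {
  stopifnot(inherits(config, "selenoscan_config"))
  set.seed(config$seed)
  ev <- config$evidence
  # calibrate one raw-score threshold for U/C pairing (flanks share scale)
  uc_min_score <- ev$min_score
  if (is.null(uc_min_score) && !is.null(proteins) && nrow(proteins)) {
    probe <- paste(sample(AA_LETTERS, 2L * ev$flank_window + 1L, replace = TRUE),
                   collapse = "")
    uc_min_score <- calibrate_align_threshold(probe, proteins, seed = config$seed)
  }
  limits <- config$limits
  if (is.null(limits$min_signal)) {
    limits$min_signal <- models$signal$thresholds
  }
  all_calls <- list()
  log_lines <- c("selenoscan run", paste("organism:", config$organism),
                 paste("seed:", config$seed),
                 paste("uc_min_score:", format(uc_min_score %||% NA)))
  for (ri in seq_len(nrow(genome))) {
    rec <- genome[ri, ]
    L <- nchar(rec$seq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") rec$seq else reverse_complement(rec$seq)
      sites <- scan_signals(s, models$signal, strand = strand, seqid = rec$id)
      cands <- enumerate_exons(s, sites, models$markov, limits)
      mods <- assemble_orfs(cands, s, config$assembler, dedup = FALSE)
      log_lines <- c(log_lines,
                     sprintf("record %s strand %s: %d sites, %d candidates, %d models",
                             rec$id, strand, nrow(sites), nrow(cands), nrow(mods)))
      if (!nrow(mods)) next
      # models arrive sorted by score; filter before the quadratic dedup
      mods <- mods[mods$total_score >= config$min_total_score &
                     nchar(mods$protein) >= config$min_protein_length, ]
      if (!nrow(mods)) next
      par <- utils::modifyList(default_assembler_params(), config$assembler)
      mods <- dedup_models(mods, par$dedup_overlap)
      for (mi in seq_len(nrow(mods))) {
        m <- mods[mi, ]
        call <- evaluate_model(m, s, rec, strand, L, proteins, ests, config,
                               uc_min_score)
        all_calls[[length(all_calls) + 1L]] <- call
      }
    }
  }
  calls <- dplyr::bind_rows(all_calls)
  if (nrow(calls)) {
    calls <- resolve_shared_secis(calls)
    calls <- dplyr::arrange(calls, .data$seqid,
                            purrr::map_int(.data$exon_starts, ~ as.integer(min(.x))),
                            .data$strand)
    calls$call_id <- sprintf("%s_call%04d", config$organism, seq_len(nrow(calls)))
    calls <- dplyr::relocate(calls, "call_id")
  } else {
    calls <- empty_calls()
  }
  calls$organism <- rep(config$organism, nrow(calls))
  log_lines <- c(log_lines,
                 sprintf("calls: %d confirmed / %d total",
                         sum(calls$status == "confirmed"), nrow(calls)))
  if (!is.null(out_dir)) {
    write_pipeline_outputs(calls, genome, out_dir, log_lines)
  }
  calls
}

# one gene per SECIS: when two confirmed calls on the same record and
# strand claim the same SECIS element (same quartet anchor), only the
# higher-scoring model survives; the others are demoted to the audit set
resolve_shared_secis <- function(calls) {
  conf <- which(calls$status == "confirmed")
  if (length(conf) < 2L) return(calls)
  ord <- conf[order(-calls$total_score[conf])]
  claimed <- character()
  for (i in ord) {
    h <- calls$secis[[i]]
    keys <- paste(calls$seqid[i], calls$strand[i], h$quartet_pos)
    if (any(keys %in% claimed)) {
      calls$status[i] <- "rejected"
      calls$reject_reason[i] <- "secis_claimed_by_better_model"
    } else {
      claimed <- c(claimed, keys)
    }
  }
  calls
}

empty_calls <- function() {
  tibble::tibble(call_id = character(), seqid = character(), strand = character(),
                 exon_starts = list(), exon_ends = list(), sec_positions = list(),
                 sec_cds_offsets = list(), n_exons = integer(), total_score = numeric(),
                 cds = character(), protein = character(),
                 uc_positive = logical(), uc_n_cys_paired = integer(),
                 uc_best_subject = character(), uc_best_identity = numeric(),
                 secis = list(), n_secis = integer(), est_n_spanning = integer(),
                 family = character(), status = character(), reject_reason = character())
}

# evidence bundle for one strand-local model; returns a one-row call tibble
# in genomic coordinates
evaluate_model <- function(m, s, rec, strand, L, proteins, ests, config, uc_min_score) {
  ev <- config$evidence
  prot <- m$protein[[1]]
  u_idx <- which(strsplit(prot, "")[[1]] == "U")
  uc <- NULL
  for (ui in u_idx) {
    flank <- extract_sec_flank(prot, ui, ev$flank_window)
    # neighbouring Sec residues inside the window are scored as C anyway;
    # keep only the focal U so the pairing column is unambiguous
    focal_at <- min(ui, ev$flank_window + 1L)
    fl <- strsplit(chartr("U", "C", flank), "")[[1]]
    fl[focal_at] <- "U"
    flank <- paste(fl, collapse = "")
    res <- find_uc_pairing(flank, proteins, min_identity = ev$min_identity,
                           min_score = uc_min_score %||% 0)
    if (is.null(uc) || (res$positive && !uc$positive)) uc <- res
    if (res$positive) break
  }
  if (is.null(uc)) {
    uc <- tibble::tibble(sec_column_found = FALSE, n_cys_paired = 0L, positive = FALSE,
                         flank_identity = NA_real_, best_subject = NA_character_,
                         best_score = NA_real_, best_identity = NA_real_,
                         best_family = NA_character_)
  }
  gene_end_local <- max(m$exon_ends[[1]])
  secis_hits <- if (uc$positive) {
    find_secis(s, gene_end_local, config$secis)
  } else {
    tibble::tibble(start = integer(), end = integer(), quartet_pos = integer(),
                   motif_class = character(), helix1_bp = integer(),
                   helix2_bp = integer(), apical_len = integer(),
                   n_wc = integer(), n_gu = integer(), score = numeric())
  }
  confirmed <- uc$positive && nrow(secis_hits) > 0L
  reason <- if (confirmed) NA_character_
            else if (!uc$positive) "no_uc_pairing"
            else "no_secis"
  est_n <- NA_integer_
  family <- NA_character_
  if (confirmed) {
    family <- assign_family(prot, proteins, ev$family_min_score, ev$family_min_identity)
    if (!is.null(ests) && nrow(ests)) {
      utr <- substr(s, gene_end_local + 1L, min(nchar(s), gene_end_local + 600L))
      mrna <- paste0(m$cds[[1]], utr)
      est_res <- est_support(mrna, m$sec_cds_offsets[[1]], ests,
                             anchor = ev$est_anchor, min_identity = ev$est_identity)
      est_n <- est_res$n_spanning[[1]]
    }
  }
  es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
  secs <- m$sec_positions[[1]]
  if (strand == "-") {
    r <- reflect_interval(es, ee, L)
    es <- sort(r$start); ee <- sort(r$end)
    secs <- sort(L - secs - 3L)
    if (nrow(secis_hits)) {
      rs <- reflect_interval(secis_hits$start, secis_hits$end, L)
      secis_hits$start <- rs$start
      secis_hits$end <- rs$end
      secis_hits$quartet_pos <- L - secis_hits$quartet_pos - 3L
    }
  }
  tibble::tibble(
    seqid = rec$id, strand = strand,
    exon_starts = list(es), exon_ends = list(ee), sec_positions = list(secs),
    sec_cds_offsets = list(m$sec_cds_offsets[[1]]), n_exons = m$n_exons[[1]],
    total_score = m$total_score[[1]], cds = m$cds[[1]], protein = prot,
    uc_positive = uc$positive, uc_n_cys_paired = uc$n_cys_paired,
    uc_best_subject = uc$best_subject, uc_best_identity = uc$best_identity,
    secis = list(secis_hits), n_secis = nrow(secis_hits),
    est_n_spanning = est_n, family = family,
    status = if (confirmed) "confirmed" else "rejected",
    reject_reason = reason
  )
}

#' Read a family-labelled protein database FASTA
#'
#' Headers of the form `>id family=NAME` yield the `family` column;
#' entries without the tag get `NA`.
#'
#' @param path FASTA file.
#' @return Tibble `id`, `seq`, `family`.
#' @export
read_protein_db <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  fam <- ifelse(grepl("family=", full), sub(".*family=([^ ]+).*", "\\1", full), NA_character_)
  tibble::tibble(id = ids, seq = toupper(unname(as.character(set))), family = fam)
}

write_pipeline_outputs <- function(calls, genome, out_dir, log_lines) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  confirmed <- calls[calls$status == "confirmed", ]
  lens <- setNames(nchar(genome$seq), genome$id)
  write_gff3(confirmed, file.path(out_dir, "calls.gff3"), record_lengths = lens)
  prot_tbl <- tibble::tibble(
    id = paste0(confirmed$call_id, " family=", confirmed$family),
    seq = confirmed$protein
  )
  write_fasta(prot_tbl, file.path(out_dir, "proteins.faa"))
  secis_all <- purrr::map2(confirmed$secis, seq_len(nrow(confirmed)), function(h, i) {
    if (!nrow(h)) return(NULL)
    tibble::tibble(seqid = confirmed$seqid[i], start = h$start, end = h$end,
                   motif_class = h$motif_class, score = h$score,
                   strand = confirmed$strand[i])
  })
  secis_all <- dplyr::bind_rows(secis_all)
  if (!nrow(secis_all)) {
    secis_all <- tibble::tibble(seqid = character(), start = integer(), end = integer(),
                                motif_class = character(), score = numeric(),
                                strand = character())
  }
  write_bed(secis_all, file.path(out_dir, "secis.bed"))
  fam <- summarize_families(confirmed)
  readr::write_tsv(fam, file.path(out_dir, "summary.tsv"))
  audit <- calls[calls$status != "confirmed",
                 c("call_id", "seqid", "strand", "n_exons", "total_score",
                   "uc_positive", "n_secis", "reject_reason")]
  audit$start <- purrr::map_int(calls$exon_starts[calls$status != "confirmed"],
                                ~ as.integer(min(.x)))
  readr::write_tsv(audit, file.path(out_dir, "audit.tsv"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Detect tandem clusters of same-family calls
#'
#' Single-linkage grouping of calls of one (collapsed) family on one
#' record: consecutive genes whose gap is at most `max_gap` join a
#' cluster. Strand is ignored for membership and recorded per member.
#'
#' @param calls Calls tibble (confirmed calls are typically passed).
#' @param max_gap Maximum inter-gene gap (nt).
#' @param min_members Minimum cluster size to report.
#' @return Tibble: `cluster_id`, `seqid`, `family`, `start`, `end`,
#'   `n_members`, list-columns `members` and `strands`.
#' @export
detect_clusters <- function(calls, max_gap = 50000L, min_members = 2L) {
  empty <- tibble::tibble(cluster_id = character(), seqid = character(),
                          family = character(), start = integer(), end = integer(),
                          n_members = integer(), members = list(), strands = list())
  if (!nrow(calls)) return(empty)
  d <- calls
  d$family2 <- collapse_subfamily(d$family)
  d$gstart <- purrr::map_int(d$exon_starts, ~ as.integer(min(.x)))
  d$gend <- purrr::map_int(d$exon_ends, ~ as.integer(max(.x)))
  out <- list()
  for (grp in split(seq_len(nrow(d)), paste(d$seqid, d$family2, sep = "\r"))) {
    idx <- grp[order(d$gstart[grp])]
    runs <- split(idx, cumsum(c(0L, as.integer(d$gstart[idx][-1] - d$gend[idx][-length(idx)] > max_gap))))
    for (r in runs) {
      if (length(r) < min_members) next
      out[[length(out) + 1L]] <- tibble::tibble(
        cluster_id = NA_character_, seqid = d$seqid[r[1]], family = d$family2[r[1]],
        start = min(d$gstart[r]), end = max(d$gend[r]), n_members = length(r),
        members = list(d$call_id[r]), strands = list(d$strand[r]))
    }
  }
  if (!length(out)) return(empty)
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$seqid, .data$start)
  res$cluster_id <- sprintf("cluster%03d", seq_len(nrow(res)))
  res
}

#' Family count matrix across organisms
#'
#' Counts confirmed calls per (collapsed) family and organism and appends
#' a TOTAL row, in the style of a per-species selenoproteome table.
#'
#' @param calls Calls tibble with `family` and `organism` columns (rejected
#'   calls, if present, are excluded).
#' @return Tibble: `family` column, one count column per organism, TOTAL
#'   row last.
#' @export
summarize_families <- function(calls) {
  if (nrow(calls) && "status" %in% names(calls)) {
    calls <- calls[calls$status == "confirmed", ]
  }
  if (!nrow(calls)) {
    return(tibble::tibble(family = "TOTAL"))
  }
  d <- tibble::tibble(family = collapse_subfamily(calls$family),
                      organism = calls$organism)
  counts <- dplyr::count(d, .data$family, .data$organism)
  wide <- tidyr::pivot_wider(counts, names_from = "organism", values_from = "n",
                             values_fill = 0L)
  wide <- dplyr::arrange(wide, .data$family)
  tot <- dplyr::summarise(wide, dplyr::across(-"family", sum))
  tot$family <- "TOTAL"
  dplyr::bind_rows(wide, tot)
}

#' Recovery metrics against planted ground truth
#'
#' A confirmed call recovers a planted gene when it lies on the same
#' record and strand, shares at least half of the planted coding bases,
#' and reports at least one planted Sec position. Sensitivity is the
#' fraction of planted genes recovered; precision the fraction of
#' confirmed calls that recover some planted gene.
#'
#' @param calls Calls tibble from [run_pipeline()].
#' @param truth Truth tibble from [simulate_benchmark()].
#' @return One-row tibble: `n_truth`, `n_confirmed`, `n_recovered`,
#'   `sensitivity`, `precision`, `n_decoys_confirmed`.
#' @export
benchmark_metrics <- function(calls, truth) {
  conf <- calls[calls$status == "confirmed", ]
  genes <- truth[truth$type == "gene", ]
  matched_truth <- logical(nrow(genes))
  call_matches <- logical(nrow(conf))
  for (i in seq_len(nrow(conf))) {
    for (j in seq_len(nrow(genes))) {
      if (conf$seqid[i] != genes$seqid[j] || conf$strand[i] != genes$strand[j]) next
      ov <- exon_set_overlap(conf$exon_starts[[i]], conf$exon_ends[[i]],
                             genes$exon_starts[[j]], genes$exon_ends[[j]])
      tlen <- sum(genes$exon_ends[[j]] - genes$exon_starts[[j]])
      sec_hit <- length(intersect(conf$sec_positions[[i]], genes$sec_positions[[j]])) > 0L
      if (ov >= 0.5 * tlen && sec_hit) {
        matched_truth[j] <- TRUE
        call_matches[i] <- TRUE
      }
    }
  }
  decoys <- truth[truth$type != "gene", ]
  decoy_conf <- 0L
  for (i in seq_len(nrow(conf))) {
    if (call_matches[i]) next
    for (j in seq_len(nrow(decoys))) {
      if (conf$seqid[i] != decoys$seqid[j] || conf$strand[i] != decoys$strand[j]) next
      ov <- exon_set_overlap(conf$exon_starts[[i]], conf$exon_ends[[i]],
                             decoys$exon_starts[[j]], decoys$exon_ends[[j]])
      if (ov > 0L) { decoy_conf <- decoy_conf + 1L; break }
    }
  }
  tibble::tibble(
    n_truth = nrow(genes), n_confirmed = nrow(conf), n_recovered = sum(matched_truth),
    sensitivity = if (nrow(genes)) sum(matched_truth) / nrow(genes) else NA_real_,
    precision = if (nrow(conf)) sum(call_matches) / nrow(conf) else NA_real_,
    n_decoys_confirmed = decoy_conf
  )
}
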