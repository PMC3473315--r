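# Homology evidence: Sec/Cys pairing of the Sec-flanking peptide against a
# protein database, family assignment, and EST read-through support.
# Local alignment is Smith-Waterman (BLOSUM62, gap open 11 / extend 1) via
# Biostrings; selenocysteine is scored as cysteine throughout (U == C).

#' Extract the peptide flanking a Sec residue
#'
#' Up to `window` residues on each side of the `U`, truncated at the
#' protein termini; the `U` itself is retained.
#'
#' @param protein Amino-acid string containing `U`.
#' @param sec_index 1-based position of the `U` in `protein`.
#' @param window Residues to keep on each side.
#' @return The flanking peptide.
#' @export
extract_sec_flank <- function(protein, sec_index, window = 20L) {
  if (substr(protein, sec_index, sec_index) != "U") {
    stop("sec_index does not point at a U residue", call. = FALSE)
  }
  a <- max(1L, sec_index - window)
  b <- min(nchar(protein), sec_index + window)
  substr(protein, a, b)
}

#' Smith-Waterman local alignment of two peptides
#'
#' Optimal local alignment under BLOSUM62 with affine gaps (a gap of
#' length L costs `gap_open + L * gap_extend`). `U` residues are scored as
#' `C` on both sides, so scores are invariant under U/C substitution.
#'
#' @param query,subject Peptides (may contain `U`).
#' @param matrix Substitution matrix name (a Biostrings data set).
#' @param gap_open,gap_extend Gap penalties (positive).
#' @return One-row tibble: aligned strings (in U-as-C space), `score`,
#'   `identity` (matching columns / alignment length), and 1-based
#'   query/subject start/end of the aligned region.
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (!nchar(query) || !nchar(subject)) stop("empty peptide", call. = FALSE)
  q <- chartr("U", "C", toupper(query))
  s <- chartr("U", "C", toupper(subject))
  mat <- get_submatrix(matrix)
  pa <- Biostrings::pairwiseAlignment(q, s, type = "local", substitutionMatrix = mat,
                                      gapOpening = gap_open, gapExtension = gap_extend)
  qa <- as.character(Biostrings::alignedPattern(pa))
  sa <- as.character(Biostrings::alignedSubject(pa))
  qs <- strsplit(qa, "")[[1]]; ss <- strsplit(sa, "")[[1]]
  ident <- if (length(qs)) sum(qs == ss & qs != "-") / length(qs) else 0
  tibble::tibble(query = query, subject = subject,
                 q_aligned = qa, s_aligned = sa,
                 score = Biostrings::score(pa), identity = ident,
                 q_start = pa@pattern@range@start,
                 q_end = pa@pattern@range@start + pa@pattern@range@width - 1L,
                 s_start = pa@subject@range@start,
                 s_end = pa@subject@range@start + pa@subject@range@width - 1L)
}

get_submatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Calibrate a raw-score acceptance threshold from shuffled subjects
#'
#' Emulates a BLAST E-value cutoff without database-size statistics:
#' aligns the query against residue-shuffled copies of the database
#' entries and returns the `q` quantile of the null score distribution.
#'
#' @param query Peptide.
#' @param db Tibble with a `seq` column.
#' @param n_shuffle Shuffled copies per subject.
#' @param q Null quantile to use as threshold.
#' @param seed RNG seed (shuffling is the only randomness).
#' @return Numeric score threshold.
#' @export
calibrate_align_threshold <- function(query, db, n_shuffle = 5L, q = 0.99, seed = 1L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    shuffled <- unlist(lapply(db$seq, function(s) {
      vapply(seq_len(n_shuffle), function(i) {
        paste(sample(strsplit(chartr("U", "C", s), "")[[1]]), collapse = "")
      }, character(1))
    }))
    null_scores <- align_scores_to_set(query, shuffled)
    unname(quantile(null_scores, q, type = 1))
  })
}

#' Sec/Cys pairing evidence for a Sec-flanking peptide
#'
#' Aligns the flank against every database entry and counts subjects that
#' place a cysteine opposite the query's `U` column with at least
#' `min_identity` over the aligned region and an alignment score at or
#' above `min_score`. Evidence is positive when at least one such subject
#' exists. Sec-form homologs (subject `U` at the column) count as C, per
#' the U==C convention.
#'
#' @param flank Peptide containing exactly one `U`.
#' @param db Tibble with columns `id`, `seq` and optionally `family`.
#' @param min_identity Minimum aligned identity.
#' @param min_score Minimum alignment score; `NULL` calibrates one from
#'   shuffled subjects via [calibrate_align_threshold()].
#' @param seed Seed used only when calibrating.
#' @return One-row tibble: `sec_column_found`, `n_cys_paired`, `positive`,
#'   `flank_identity`, best-hit columns (`best_subject`, `best_score`,
#'   `best_identity`, `best_family`).
#' @export
find_uc_pairing <- function(flank, db, min_identity = 0.3, min_score = NULL, seed = 1L) {
  u_pos <- which(strsplit(flank, "")[[1]] == "U")
  if (length(u_pos) != 1L) stop("flank must contain exactly one U", call. = FALSE)
  empty <- tibble::tibble(sec_column_found = FALSE, n_cys_paired = 0L, positive = FALSE,
                          flank_identity = NA_real_, best_subject = NA_character_,
                          best_score = NA_real_, best_identity = NA_real_,
                          best_family = NA_character_)
  if (is.null(db) || nrow(db) == 0L) return(empty)
  if (is.null(min_score)) {
    min_score <- calibrate_align_threshold(flank, db, seed = seed)
  }
  # cheap score-only pass first; alignment objects only for passing subjects
  scores <- align_scores_to_set(flank, db$seq)
  cand <- which(scores >= min_score)
  if (!length(cand)) return(empty)
  ali <- align_query_to_set(flank, db$seq[cand])
  opp <- vapply(seq_len(nrow(ali)), function(i) {
    query_opposite_char(ali$q_aligned[i], ali$s_aligned[i], ali$q_start[i], u_pos)
  }, character(1))
  col_found <- any(!is.na(opp))
  paired <- !is.na(opp) & opp == "C" & ali$identity >= min_identity
  if (!any(paired)) {
    out <- empty
    out$sec_column_found <- col_found
    return(out)
  }
  bi <- which(paired)[which.max(ali$score[paired])]
  gi <- cand[bi]
  tibble::tibble(sec_column_found = TRUE, n_cys_paired = sum(paired), positive = TRUE,
                 flank_identity = ali$identity[bi], best_subject = db$seq[[gi]],
                 best_score = ali$score[bi], best_identity = ali$identity[bi],
                 best_family = if ("family" %in% names(db)) db$family[[gi]] else NA_character_)
}

# batched score-only Smith-Waterman: query vs every sequence in seqs
align_scores_to_set <- function(query, seqs, matrix = "BLOSUM62",
                                gap_open = 11, gap_extend = 1) {
  q <- chartr("U", "C", toupper(query))
  subjects <- Biostrings::AAStringSet(chartr("U", "C", toupper(seqs)))
  mat <- get_submatrix(matrix)
  Biostrings::pairwiseAlignment(subjects, q, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = gap_open, gapExtension = gap_extend,
                                scoreOnly = TRUE)
}

# one batched Smith-Waterman call: query vs every sequence in seqs (U -> C
# on both sides). Returns a tibble with per-subject aligned strings, score,
# identity and the 1-based query start of the aligned region.
align_query_to_set <- function(query, seqs, matrix = "BLOSUM62",
                               gap_open = 11, gap_extend = 1) {
  q <- chartr("U", "C", toupper(query))
  subjects <- Biostrings::AAStringSet(chartr("U", "C", toupper(seqs)))
  mat <- get_submatrix(matrix)
  # Biostrings aligns a *set of patterns* against one subject, so the db
  # entries take the pattern role and the query the subject role
  pa <- Biostrings::pairwiseAlignment(subjects, q, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open, gapExtension = gap_extend)
  qa <- as.character(Biostrings::alignedSubject(pa))
  sa <- as.character(Biostrings::alignedPattern(pa))
  nchar_q <- nchar(qa)
  n_match <- vapply(seq_along(qa), function(i) {
    x <- strsplit(qa[i], "")[[1]]; y <- strsplit(sa[i], "")[[1]]
    sum(x == y & x != "-")
  }, numeric(1))
  tibble::tibble(score = Biostrings::score(pa),
                 identity = ifelse(nchar_q > 0, n_match / nchar_q, 0),
                 q_aligned = qa, s_aligned = sa,
                 q_start = pa@subject@range@start)
}

# character of the aligned partner opposite query position qpos, given the
# aligned query/partner strings; NA outside the alignment or opposite a gap
query_opposite_char <- function(q_aligned, s_aligned, q_start, qpos) {
  qs <- strsplit(q_aligned, "")[[1]]
  ss <- strsplit(s_aligned, "")[[1]]
  qi <- q_start - 1L
  for (j in seq_along(qs)) {
    if (qs[j] != "-") {
      qi <- qi + 1L
      if (qi == qpos) return(if (ss[j] == "-") NA_character_ else ss[j])
    }
  }
  NA_character_
}

# subject character aligned opposite query position qpos (1-based), in
# U-as-C space; NA when qpos is outside the local alignment or opposite a gap
subject_char_at <- function(hit, qpos) {
  if (qpos < hit$q_start || qpos > hit$q_end) return(NA_character_)
  qs <- strsplit(hit$q_aligned, "")[[1]]
  ss <- strsplit(hit$s_aligned, "")[[1]]
  qi <- hit$q_start - 1L
  for (j in seq_along(qs)) {
    if (qs[j] != "-") {
      qi <- qi + 1L
      if (qi == qpos) {
        return(if (ss[j] == "-") NA_character_ else ss[j])
      }
    }
  }
  NA_character_
}

#' Collapse a subfamily label to its family
#'
#' Trailing digits and lettered variant suffixes are dropped, so DI1, DI2
#' and DI3 all collapse to DI, and labels like `Gpx_a` to Gpx.
#'
#' @param label Character vector of (sub)family labels.
#' @return Collapsed family labels.
#' @export
collapse_subfamily <- function(label) {
  out <- sub("[_.][a-z]$", "", label)
  sub("[0-9]+$", "", out)
}

#' Assign a protein to a selenoprotein family by best local alignment
#'
#' The family label of the best-scoring database hit above the thresholds,
#' with subfamilies collapsed ([collapse_subfamily()]); `"novel"` when no
#' hit qualifies.
#'
#' @param protein Query protein (may contain `U`).
#' @param db Tibble with `id`, `seq`, `family`.
#' @param min_score Minimum alignment score.
#' @param min_identity Minimum aligned identity.
#' @return A single family label.
#' @export
assign_family <- function(protein, db, min_score = 60, min_identity = 0.25) {
  if (is.null(db) || nrow(db) == 0L) return("novel")
  scores <- align_scores_to_set(protein, db$seq)
  cand <- which(scores >= min_score)
  if (!length(cand)) return("novel")
  cand <- cand[order(-scores[cand])]
  ali <- align_query_to_set(protein, db$seq[cand])
  ok <- which(ali$identity >= min_identity)
  if (!length(ok)) return("novel")
  collapse_subfamily(db$family[[cand[ok[1]]]])
}

#' EST read-through support for the Sec codons of a gene
#'
#' Counts (EST, Sec codon) pairs in which an EST aligns across a Sec-TGA
#' codon of the spliced transcript with at least `anchor` nt aligned on
#' each side at `min_identity` or better. Candidate ESTs are prefiltered
#' by exact shared 16-mers before alignment.
#'
#' @param mrna Spliced transcript (CDS plus UTRs).
#' @param sec_offsets 0-based offsets of Sec-TGA codon starts within `mrna`.
#' @param ests Tibble with `id`, `seq` (or a character vector).
#' @param anchor Minimum aligned nt on each side of the codon.
#' @param min_identity Minimum identity of the EST-transcript alignment.
#' @return One-row tibble: `n_spanning`, list-column `identities`.
#' @export
est_support <- function(mrna, sec_offsets, ests, anchor = 50L, min_identity = 0.95) {
  if (is.data.frame(ests)) ests <- ests$seq
  out_empty <- tibble::tibble(n_spanning = 0L, identities = list(numeric()))
  if (!length(ests) || !length(sec_offsets)) return(out_empty)
  mers <- substring(mrna, seq_len(max(0L, nchar(mrna) - 15L)),
                    seq_len(max(0L, nchar(mrna) - 15L)) + 15L)
  mer_set <- unique(mers)
  keep <- vapply(ests, function(est) {
    if (nchar(est) < 2L * anchor) return(FALSE)
    starts <- seq(1L, max(1L, nchar(est) - 15L), by = 8L)
    any(substring(est, starts, starts + 15L) %in% mer_set)
  }, logical(1))
  ests <- ests[keep]
  if (!length(ests)) return(out_empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(ests), mrna,
                                      type = "local", substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  s_start <- pa@subject@range@start            # 1-based on mrna
  s_end <- s_start + pa@subject@range@width - 1L
  ident <- Biostrings::pid(pa) / 100
  n_span <- 0L
  idents <- numeric()
  for (i in seq_along(ests)) {
    if (ident[i] < min_identity) next
    for (off in sec_offsets) {
      lo <- off + 1L           # 1-based codon start on mrna
      hi <- off + 3L
      if (s_start[i] <= lo - anchor && s_end[i] >= hi + anchor) {
        n_span <- n_span + 1L
        idents <- c(idents, ident[i])
      }
    }
  }
  tibble::tibble(n_spanning = n_span, identities = list(idents))
}
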