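# SECIS element detection: enumerate stem-loops anchored on UGA quartets
# in the 3' flank of a gene and score them with an additive structural
# score. The modelled topology is the canonical eukaryotic form: helix I,
# internal loop, helix II whose first four pairs are the non-Watson-Crick
# quartet opening with UGA (preceded by an unpaired A or G), and an apical
# loop containing AA. Scores are bespoke and not comparable to covariance
# model (SECISearch) scores.

#' SECIS search parameters
#'
#' Geometry ranges and the score threshold for [fold_hairpin()] and
#' [find_secis()]. Defaults follow the human-like eukaryotic consensus:
#' helix I 6-16 bp, internal loop 1-20 nt per side, helix II 8-18 bp (the
#' first 4 pairs form the non-Watson-Crick quartet), apical loop 8-22 nt
#' containing AA, searched in a 3000 nt window downstream of the stop. The
#' default `min_score` of 24 was calibrated on uniform-random sequence so
#' that fewer than 1% of 300-nt windows yield a hit.
#'
#' @param window Search window length (nt) downstream of the stop codon.
#' @param helix1,helix2 Length ranges (bp) for the two helices.
#' @param internal_loop Internal-loop size range (nt per side).
#' @param apical Apical-loop size range (nt).
#' @param allow_gu Count G:U wobble pairs as pairing.
#' @param min_score Minimum structural score for a reported hit.
#' @return A list of class `secis_params`.
#' @export
secis_params <- function(window = 3000L, helix1 = c(6L, 16L), helix2 = c(8L, 18L),
                         internal_loop = c(1L, 20L), apical = c(8L, 22L),
                         allow_gu = TRUE, min_score = 24) {
  stopifnot(window > 0L, helix1[1] <= helix1[2], helix2[1] <= helix2[2],
            internal_loop[1] <= internal_loop[2], apical[1] <= apical[2],
            helix2[1] >= 4L)
  structure(list(window = window, helix1 = helix1, helix2 = helix2,
                 internal_loop = internal_loop, apical = apical,
                 allow_gu = allow_gu, min_score = min_score),
            class = "secis_params")
}

# pairing classes on DNA letters: 2 = Watson-Crick, 1 = G:U wobble, 0 = none
PAIR_CLASS <- local({
  m <- matrix(0L, 5L, 5L)
  wc <- rbind(c(1L, 4L), c(4L, 1L), c(2L, 3L), c(3L, 2L))
  gu <- rbind(c(3L, 4L), c(4L, 3L))
  m[wc] <- 2L
  m[gu] <- 1L
  m
})

#' Enumerate stem-loops in a window and return the best SECIS candidate
#'
#' Anchors on every TGA occurrence, treats it as the 5' opening of the
#' quartet (all four quartet pairs must be non-Watson-Crick, the base
#' directly preceding the TGA must be an unpaired A or G), requires the
#' remaining helix-II pairs and at least `helix1[1]` helix-I pairs to pair
#' (Watson-Crick, or G:U if allowed), and an apical loop containing AA.
#' Score: `2*(WC pairs) + 1*(GU pairs) - 0.5*(loop nt beyond minima) + 3`
#' (core-motif bonus).
#'
#' @param window_seq DNA string (a 3' flank window, coding strand).
#' @param params A [secis_params()] object.
#' @param all Return every scored candidate instead of only the best.
#' @return One-row tibble (best hit), `NULL` when nothing meets the
#'   constraints and score threshold, or all candidates when `all = TRUE`.
#' @export
fold_hairpin <- function(window_seq, params = secis_params(), all = FALSE) {
  s <- seq_to_int(toupper(window_seq))
  L <- length(s)
  hits <- list()
  h2r <- params$helix2; apr <- params$apical; h1r <- params$helix1
  ilr <- params$internal_loop
  min_pair <- if (params$allow_gu) 1L else 2L
  tga <- which(s[seq_len(max(0L, L - 2L))] == 4L & s[-1][seq_len(max(0L, L - 2L))] == 3L &
                 s[-(1:2)][seq_len(max(0L, L - 2L))] == 1L)
  for (t in tga) {       # t: 1-based position of T of TGA
    if (t < 2L) next
    pre <- s[t - 1L]
    if (!(pre == 1L || pre == 3L)) next   # A or G directly preceding
    for (h2 in h2r[1]:h2r[2]) {
      # 5' arm: t .. t+h2-1 ; apical a nt ; 3' arm: t+h2+a .. t+2*h2+a-1
      if (t + 2L * h2 + apr[1] - 1L > L) break
      arm5 <- s[t:(t + h2 - 1L)]
      for (a in apr[1]:apr[2]) {
        hi3 <- t + 2L * h2 + a - 1L
        if (hi3 > L) break
        arm3 <- s[hi3:(t + h2 + a)]       # aligned with arm5
        pc <- PAIR_CLASS[cbind(arm5, arm3)]
        if (any(pc[1:4] == 2L)) next      # quartet must be non-Watson-Crick
        if (h2 > 4L && any(pc[5:h2] < min_pair)) next
        # apical loop must contain AA
        loop <- s[(t + h2):(t + h2 + a - 1L)]
        if (!any(loop[-length(loop)] == 1L & loop[-1] == 1L)) next
        # helix I: choose internal loop sizes and a maximal pairing run
        best1 <- NULL
        for (l1 in ilr[1]:ilr[2]) {
          e1 <- t - 1L - l1              # 1-based end of helix-I 5' arm
          if (e1 < 1L) break
          for (l2 in ilr[1]:ilr[2]) {
            b3 <- hi3 + l2 + 1L          # 1-based start of helix-I 3' arm
            if (b3 > L) break
            m <- 0L
            wc1 <- 0L; gu1 <- 0L
            while (m < h1r[2] && e1 - m >= 1L && b3 + m <= L) {
              cls <- PAIR_CLASS[s[e1 - m], s[b3 + m]]
              if (cls < min_pair) break
              if (cls == 2L) wc1 <- wc1 + 1L else gu1 <- gu1 + 1L
              m <- m + 1L
            }
            if (m < h1r[1]) next
            pen <- 0.5 * ((l1 - ilr[1]) + (l2 - ilr[1]))
            sc1 <- 2 * wc1 + gu1 - pen
            if (is.null(best1) || sc1 > best1$sc) {
              best1 <- list(sc = sc1, l1 = l1, l2 = l2, m = m, wc = wc1, gu = gu1)
            }
          }
        }
        if (is.null(best1)) next
        wc2 <- sum(pc == 2L); gu2 <- sum(pc == 1L)
        score <- 2 * wc2 + gu2 + best1$sc - 0.5 * (a - apr[1]) + 3
        start0 <- t - 1L - best1$l1 - best1$m          # 0-based stem-loop start
        end0 <- hi3 + best1$l2 + best1$m               # 0-based half-open end
        hits[[length(hits) + 1L]] <- tibble::tibble(
          start = start0, end = end0,
          quartet_pos = t - 1L,
          motif_class = if (pre == 1L) "AUGA_AA" else "GUGA_AA",
          helix1_bp = best1$m, helix2_bp = h2, apical_len = a,
          n_wc = wc2 + best1$wc, n_gu = gu2 + best1$gu,
          score = score)
      }
    }
  }
  if (!length(hits)) return(NULL)
  hits <- dplyr::bind_rows(hits)
  hits <- hits[hits$score >= params$min_score, ]
  if (!nrow(hits)) return(NULL)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$start)
  if (all) hits else hits[1L, ]
}

#' Find SECIS elements downstream of a gene model
#'
#' Scans `params$window` nt downstream of the gene's stop codon on the
#' coding strand and returns non-overlapping hits (greedy by score). A
#' gene near the contig edge simply gets a truncated window.
#'
#' @param seq Strand-local sequence the gene model lives on.
#' @param gene_end 0-based half-open end of the gene (position after the
#'   stop codon) on `seq`.
#' @param params A [secis_params()] object.
#' @return Tibble of hits with window-relative coordinates shifted to
#'   `seq` coordinates, sorted by score.
#' @export
find_secis <- function(seq, gene_end, params = secis_params()) {
  L <- nchar(seq)
  win_start <- gene_end
  win_end <- min(L, gene_end + params$window)
  empty <- tibble::tibble(start = integer(), end = integer(), quartet_pos = integer(),
                          motif_class = character(), helix1_bp = integer(),
                          helix2_bp = integer(), apical_len = integer(),
                          n_wc = integer(), n_gu = integer(), score = numeric())
  if (win_end - win_start < 30L) return(empty)
  window_seq <- substr(seq, win_start + 1L, win_end)
  hits <- fold_hairpin(window_seq, params, all = TRUE)
  if (is.null(hits)) return(empty)
  # one candidate per quartet anchor, then greedy non-overlap by score
  hits <- dplyr::slice_max(dplyr::group_by(hits, .data$quartet_pos), .data$score,
                           n = 1L, with_ties = FALSE)
  hits <- dplyr::arrange(dplyr::ungroup(hits), dplyr::desc(.data$score), .data$start)
  keep <- integer()
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (k in keep) {
      if (overlap_len(hits$start[i], hits$end[i], hits$start[k], hits$end[k]) > 0L) {
        ok <- FALSE; break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  hits <- hits[keep, ]
  hits$start <- hits$start + win_start
  hits$end <- hits$end + win_start
  hits$quartet_pos <- hits$quartet_pos + win_start
  hits
}

#' Classify the core motif of a SECIS hit
#'
#' `AUGA_AA` when the unpaired base directly preceding the UGA quartet is
#' A, `GUGA_AA` when it is G; any other preceding base violates the hit
#' invariants and is an error.
#'
#' @param hit One-row SECIS hit tibble (needs `motif_class` or the
#'   underlying sequence context via `seq`).
#' @param seq Optional sequence to re-derive the class from `quartet_pos`.
#' @return `"AUGA_AA"` or `"GUGA_AA"`.
#' @export
classify_motif <- function(hit, seq = NULL) {
  if (!is.null(seq)) {
    pre <- substr(seq, hit$quartet_pos, hit$quartet_pos)  # base before 0-based pos
    if (pre == "A") return("AUGA_AA")
    if (pre == "G") return("GUGA_AA")
    stop("base preceding the quartet is neither A nor G", call. = FALSE)
  }
  hit$motif_class
}
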