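# Gene-signal scanning and typed exon-candidate enumeration.
#
# Signals: start (ATG), stop (TAA/TAG), donor (GT), acceptor (AG) and
# in-frame-candidate TGA codons. Start/donor/acceptor carry position weight
# matrix log-odds scores (bits, vs the genomic background); stop and TGA
# are exact motifs. Positions are 0-based anchors of the motif's first
# base, in the coordinates of the scanned strand (the minus strand is
# scanned on the reverse complement).

SIGNAL_WINDOWS <- list(
  start    = list(up = 6L, motif = 3L, down = 3L),   # -6..+5 around ATG
  donor    = list(up = 3L, motif = 2L, down = 5L),   # -3..+6 around GT
  acceptor = list(up = 14L, motif = 2L, down = 1L)   # -14..+2 around AG
)

#' Train position weight matrices for start/donor/acceptor signals
#'
#' Builds log-odds PWMs (bits, relative to the background base composition
#' of the genome) from the planted or annotated gene structures in `genes`.
#' Windows are start -6..+5 around the ATG, donor -3..+6 around the GT, and
#' acceptor -14..+2 around the AG. Per-kind score thresholds for candidate
#' enumeration are set from the training-site score distribution (5th
#' percentile minus one bit), so that annotated sites are retained while
#' most random motif occurrences are not.
#'
#' @param genome Genome tibble (`id`, `seq`).
#' @param genes Tibble with `seqid`, `strand` and list-columns
#'   `exon_starts`, `exon_ends` (genomic, 0-based half-open).
#' @param pseudocount Additive pseudocount per PWM cell.
#' @return An object of class `selenoscan_signal_model`.
#' @export
train_signal_model <- function(genome, genes, pseudocount = 0.5) {
  wins <- list(start = character(), donor = character(), acceptor = character())
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rec <- genome$seq[genome$id == g$seqid][[1]]
    L <- nchar(rec)
    s <- if (g$strand == "+") rec else reverse_complement(rec)
    es <- sort(g$exon_starts[[1]]); ee <- sort(g$exon_ends[[1]])
    if (g$strand == "-") {
      r <- reflect_interval(es, ee, L)
      es <- sort(r$start); ee <- sort(r$end)
    }
    n <- length(es)
    wins$start <- c(wins$start, signal_window(s, es[1], "start"))
    if (n > 1L) {
      wins$donor <- c(wins$donor, purrr::map_chr(ee[-n], ~ signal_window(s, .x, "donor")))
      wins$acceptor <- c(wins$acceptor, purrr::map_chr(es[-1], ~ signal_window(s, .x - 2L, "acceptor")))
    }
  }
  bg <- background_freqs(genome$seq)
  model <- list(pwm = list(), background = bg,
                thresholds = c(start = -Inf, donor = -Inf, acceptor = -Inf))
  for (kind in names(wins)) {
    w <- wins[[kind]][!is.na(wins[[kind]])]
    if (!length(w)) stop("no training windows for signal kind ", kind, call. = FALSE)
    model$pwm[[kind]] <- build_pwm(w, bg, pseudocount)
  }
  cls <- structure(model, class = "selenoscan_signal_model")
  for (kind in names(wins)) {
    sc <- pwm_score_windows(cls$pwm[[kind]], wins[[kind]])
    # keep every training site: the 5th percentile minus one bit, floored
    # half a bit under the weakest annotated site
    cls$thresholds[[kind]] <- min(unname(quantile(sc, 0.05, na.rm = TRUE)) - 1,
                                  min(sc, na.rm = TRUE) - 0.5)
  }
  cls
}

# extract the training window around a signal anchored at pos (anchor =
# first motif base: A of ATG, G of GT, A of AG); NA if out of range
signal_window <- function(s, pos, kind) {
  w <- SIGNAL_WINDOWS[[kind]]
  a <- pos - w$up
  b <- pos + w$motif + w$down - 1L
  if (a < 0L || b >= nchar(s)) return(NA_character_)
  substr(s, a + 1L, b + 1L)
}

background_freqs <- function(seqs) {
  x <- seq_to_int(paste(seqs, collapse = ""))
  x <- x[x <= 4L]
  tab <- tabulate(x, 4L)
  p <- tab / sum(tab)
  setNames(p, DNA_BASES)
}

build_pwm <- function(windows, bg, pseudocount) {
  mat <- do.call(rbind, lapply(windows, seq_to_int))
  w <- ncol(mat)
  pwm <- matrix(-Inf, 5L, w)
  for (j in seq_len(w)) {
    cnt <- tabulate(mat[, j][mat[, j] <= 4L], 4L) + pseudocount
    p <- cnt / sum(cnt)
    pwm[1:4, j] <- log2(p / bg)
  }
  pwm
}

pwm_score_windows <- function(pwm, windows) {
  purrr::map_dbl(windows, function(win) {
    if (is.na(win)) return(NA_real_)
    x <- seq_to_int(win)
    sum(pwm[cbind(x, seq_along(x))])
  })
}

# vectorized PWM scoring of anchors on an encoded sequence; -Inf where the
# window runs off the record or contains N
pwm_score_positions <- function(xint, pwm, pos, kind) {
  w <- SIGNAL_WINDOWS[[kind]]
  width <- w$up + w$motif + w$down
  L <- length(xint)
  out <- numeric(length(pos))
  a <- pos - w$up
  valid <- a >= 0L & (a + width) <= L
  out[!valid] <- -Inf
  idx <- which(valid)
  if (length(idx)) {
    acc <- numeric(length(idx))
    for (j in seq_len(width)) {
      acc <- acc + pwm[cbind(xint[a[idx] + j], j)]
    }
    out[idx] <- acc
  }
  out
}

#' Scan a sequence for gene signals
#'
#' Reports every occurrence of each signal motif with its PWM score
#' (start/donor/acceptor) or score 0 (stop, TGA), sorted by position.
#' Positions are 0-based anchors on the scanned sequence; for the minus
#' strand pass the reverse complement and `strand = "-"`.
#'
#' @param seq DNA string (one record, one strand).
#' @param model A `selenoscan_signal_model`, or `NULL` for motif-only scores.
#' @param strand Strand label attached to the output.
#' @param seqid Record id attached to the output.
#' @return Tibble `seqid`, `strand`, `kind`, `pos`, `score`.
#' @export
scan_signals <- function(seq, model = NULL, strand = "+", seqid = "seq") {
  seq <- toupper(seq)
  x <- seq_to_int(seq)
  find <- function(motifs) {
    sort(unlist(lapply(motifs, function(m) locate_all(seq, m))))
  }
  sites <- list(
    start = locate_all(seq, "ATG"),
    stop = find(STOP_CODONS),
    tga = locate_all(seq, "TGA"),
    donor = locate_all(seq, "GT"),
    acceptor = locate_all(seq, "AG")
  )
  score_for <- function(kind, pos) {
    if (!length(pos)) return(numeric())
    if (is.null(model) || !kind %in% names(model$pwm)) return(rep(0, length(pos)))
    pwm_score_positions(x, model$pwm[[kind]], pos, kind)
  }
  out <- purrr::imap(sites, function(pos, kind) {
    sc <- score_for(kind, pos)
    tibble::tibble(seqid = seqid, strand = strand, kind = kind,
                   pos = as.integer(pos), score = sc)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$pos, .data$kind)
}

#' Enumerate typed exon candidates from signal sites
#'
#' Builds all initial (ATG..donor), internal (acceptor..donor), terminal
#' (acceptor..stop) and single (ATG..stop) exon candidates compatible with
#' the signal sites, within the configured length bounds. An exon's reading
#' frame at its 5' end (`frame5`) is the number of bases of the current
#' codon already consumed upstream; `frame3 = (frame5 + length) mod 3`.
#' Candidates never contain a complete in-frame TAA/TAG; in-frame TGA
#' codons are recorded in `tga_offsets` (codon start offsets from the exon
#' start), not rejected. `coding_potential` is the sum of the exon's signal
#' scores plus the Markov log-likelihood ratio of its sequence.
#'
#' @param seq DNA string the sites were scanned from.
#' @param sites Output of [scan_signals()] on `seq`.
#' @param coding A `selenoscan_markov` model.
#' @param limits List: `min_exon`, `max_exon`, `min_signal` (named vector of
#'   per-kind score cutoffs), `min_coding` (coding-potential cutoff or
#'   `-Inf`), `max_per_mb` (candidate cap per megabase, by score).
#' @return Tibble of exon candidates; columns include `start`, `end`,
#'   `kind`, `frame5`, `frame3`, `has_inframe_tga`, `tga_offsets`
#'   (list-column), `coding_potential`, and the junction fragments
#'   `head_frag`/`tail_frag` used by the assembler.
#' @export
enumerate_exons <- function(seq, sites, coding, limits = list()) {
  lim <- utils::modifyList(list(min_exon = 30L, max_exon = 6000L,
                                min_signal = c(start = -Inf, donor = -Inf, acceptor = -Inf),
                                min_coding = -Inf, max_per_mb = 50000L), limits)
  if (lim$min_exon > lim$max_exon) stop("degenerate exon length limits", call. = FALSE)
  seq <- toupper(seq)
  L <- nchar(seq)
  profile <- genome_llr_profile(seq, coding)
  gets <- function(kind) {
    d <- sites[sites$kind == kind & is.finite(sites$score), ]
    thr <- lim$min_signal[[kind]] %||% -Inf
    d[d$score >= thr, c("pos", "score")]
  }
  starts <- gets("start")
  donors <- gets("donor")
  acceptors <- gets("acceptor")
  stop_pos <- sort(sites$pos[sites$kind == "stop"])
  tga_pos <- sort(sites$pos[sites$kind == "tga"])
  stops_by_class <- lapply(0:2, function(f) stop_pos[stop_pos %% 3L == f])
  tga_by_class <- lapply(0:2, function(f) tga_pos[tga_pos %% 3L == f])

  # first in-frame stop at or after each position (vectorized)
  first_stop <- function(f, p) {
    v <- stops_by_class[[f + 1L]]
    i <- findInterval(p - 1L, v) + 1L
    out <- rep(L + 3L, length(p))
    out[i <= length(v)] <- v[i[i <= length(v)]]
    out
  }

  pieces <- list()

  # five-prime anchored exons share this expansion: for each anchor with an
  # allowed donor window [dmin, dmax], emit one candidate per donor inside
  expand_donors <- function(estart, dmin, dmax, base_score, kind, frame5) {
    if (!nrow(donors) || !length(estart)) return(NULL)
    lo <- findInterval(dmin - 1L, donors$pos) + 1L
    hi <- findInterval(dmax, donors$pos)
    n <- pmax(0L, hi - lo + 1L)
    keep <- n > 0L
    if (!any(keep)) return(NULL)
    idx <- sequence(n[keep]) + rep(lo[keep], n[keep]) - 1L
    tibble::tibble(
      start = rep(estart[keep], n[keep]),
      end = donors$pos[idx],
      kind = kind,
      frame5 = rep(frame5, sum(n[keep])),
      sig_score = rep(base_score[keep], n[keep]) + donors$score[idx]
    )
  }

  # initial and single exons -------------------------------------------------
  if (nrow(starts)) {
    s <- starts$pos
    f <- s %% 3L
    t1 <- rep(NA_integer_, length(s))
    for (ff in 0:2) {
      sel <- f == ff
      if (any(sel)) t1[sel] <- first_stop(ff, s[sel])
    }
    len_single <- t1 + 3L - s
    ok <- t1 + 3L <= L & len_single >= lim$min_exon & len_single <= lim$max_exon
    if (any(ok)) {
      pieces$single <- tibble::tibble(start = s[ok], end = t1[ok] + 3L, kind = "single",
                                      frame5 = 0L, sig_score = starts$score[ok])
    }
    pieces$initial <- expand_donors(s, s + lim$min_exon,
                                    pmin(s + lim$max_exon, t1 + 2L, L),
                                    starts$score, "initial", 0L)
  }

  # internal and terminal exons ---------------------------------------------
  if (nrow(acceptors)) {
    for (p in 0:2) {
      e0 <- acceptors$pos + 2L
      asc <- acceptors$score
      inb <- e0 < L
      e0 <- e0[inb]; asc <- asc[inb]
      if (!length(e0)) next
      c0 <- e0 + ((3L - p) %% 3L)
      f <- c0 %% 3L
      t1 <- rep(NA_integer_, length(e0))
      for (ff in 0:2) {
        sel <- f == ff
        if (any(sel)) t1[sel] <- first_stop(ff, c0[sel])
      }
      pieces[[paste0("internal", p)]] <-
        expand_donors(e0, e0 + lim$min_exon, pmin(e0 + lim$max_exon, t1 + 2L, L),
                      asc, "internal", p)
      len <- t1 + 3L - e0
      ok <- t1 + 3L <= L & len >= lim$min_exon & len <= lim$max_exon
      if (any(ok)) {
        pieces[[paste0("terminal", p)]] <-
          tibble::tibble(start = e0[ok], end = t1[ok] + 3L, kind = "terminal",
                         frame5 = p, sig_score = asc[ok])
      }
    }
  }

  out <- dplyr::bind_rows(pieces)
  if (!nrow(out)) {
    return(tibble::tibble(start = integer(), end = integer(), kind = character(),
                          frame5 = integer(), frame3 = integer(),
                          has_inframe_tga = logical(), tga_offsets = list(),
                          coding_potential = numeric(), head_frag = character(),
                          tail_frag = character(), exon_id = integer()))
  }
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$frame5 <- as.integer(out$frame5)
  out$frame3 <- (out$frame5 + (out$end - out$start)) %% 3L
  fclass <- (out$start + ((3L - out$frame5) %% 3L)) %% 3L
  c0 <- out$start + ((3L - out$frame5) %% 3L)
  # in-frame TGA offsets per candidate
  tga_lo <- integer(nrow(out)); tga_hi <- integer(nrow(out))
  for (ff in 0:2) {
    v <- tga_by_class[[ff + 1L]]
    sel <- fclass == ff
    tga_lo[sel] <- findInterval(c0[sel] - 1L, v) + 1L
    tga_hi[sel] <- findInterval(out$end[sel] - 3L, v)
  }
  tga_list <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    if (tga_hi[i] >= tga_lo[i]) {
      v <- tga_by_class[[fclass[i] + 1L]]
      tga_list[[i]] <- as.integer(v[tga_lo[i]:tga_hi[i]] - out$start[i])
    } else tga_list[[i]] <- integer()
  }
  out$has_inframe_tga <- tga_hi >= tga_lo
  out$tga_offsets <- tga_list
  llr <- numeric(nrow(out))
  for (ff in 0:2) {
    sel <- fclass == ff
    if (any(sel)) llr[sel] <- profile_llr(profile, ff, out$start[sel], out$end[sel])
  }
  out$coding_potential <- out$sig_score + llr
  out$sig_score <- NULL
  out$head_frag <- ifelse(out$frame5 == 0L, "",
                          substring(seq, out$start + 1L, out$start + (3L - out$frame5)))
  out$tail_frag <- ifelse(out$frame3 == 0L, "",
                          substring(seq, out$end - out$frame3 + 1L, out$end))
  out <- out[out$coding_potential >= lim$min_coding, ]
  cap <- ceiling(as.numeric(lim$max_per_mb) * max(1, L / 1e6))
  if (nrow(out) > cap) {
    out <- out[order(-out$coding_potential), ][seq_len(cap), ]
  }
  out <- dplyr::arrange(out, .data$start, .data$end, .data$frame5, .data$kind)
  out$exon_id <- seq_len(nrow(out))
  out
}
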