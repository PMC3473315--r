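# Independent oracles used by the test suite. These deliberately share no
# code with the implementation paths they check: naive regex scans, a
# textbook quadratic-space Smith-Waterman, exhaustive chain enumeration,
# and brute-force pairwise linkage.

# --- naive signal scan: motif occurrences by sliding window -----------------
oracle_motif_positions <- function(seq, motif) {
  n <- nchar(seq)
  w <- nchar(motif)
  if (n < w) return(integer())
  hits <- integer()
  for (i in seq_len(n - w + 1L)) {
    if (substr(seq, i, i + w - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# --- textbook affine-gap local alignment (gap of length L costs
# open + L * extend), quadratic space, scores only ---------------------------
oracle_sw_score <- function(q, s, mat, open = 11, extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa); m <- length(sa)
  H <- matrix(0, n + 1L, m + 1L)   # best ending in match
  E <- matrix(-Inf, n + 1L, m + 1L) # gap in s (horizontal)
  F <- matrix(-Inf, n + 1L, m + 1L) # gap in q (vertical)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - extend, E[i, j - 1L] - extend)
      F[i, j] <- max(H[i - 1L, j] - open - extend, F[i - 1L, j] - extend)
      sub <- mat[qa[i - 1L], sa[j - 1L]]
      H[i, j] <- max(0, H[i - 1L, j - 1L] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- exhaustive chain enumeration through a focal exon ----------------------
# mirrors the declared gene model: chains start initial / end terminal (or a
# lone single exon), adjacent exons need gap >= min_intron, continuing
# frames, and a junction codon that is not TAA/TAG; score is the sum of
# coding potentials minus (open + per_nt * intron length) per intron.
oracle_best_chain_score <- function(cands, focal_id, min_intron = 40L,
                                    open = 5, per_nt = 0.02) {
  n <- nrow(cands)
  focal <- which(cands$exon_id == focal_id)
  best <- NULL
  consider <- function(idx) {
    gaps <- if (length(idx) > 1L) {
      cands$start[idx][-1] - cands$end[idx][-length(idx)]
    } else numeric()
    sc <- sum(cands$coding_potential[idx]) - length(gaps) * open - per_nt * sum(gaps)
    cand <- list(score = sc, nexons = length(idx), start = cands$start[idx][1])
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$nexons < best$nexons) ||
        (cand$score == best$score && cand$nexons == best$nexons &&
         cand$start < best$start)) {
      best <<- cand
    }
  }
  pair_ok <- function(a, b) {
    gap <- cands$start[b] - cands$end[a]
    if (gap < min_intron) return(FALSE)
    if (!cands$kind[a] %in% c("initial", "internal")) return(FALSE)
    if (!cands$kind[b] %in% c("internal", "terminal")) return(FALSE)
    if (cands$frame3[a] != cands$frame5[b]) return(FALSE)
    jc <- paste0(cands$tail_frag[a], cands$head_frag[b])
    !(jc %in% c("TAA", "TAG"))
  }
  extend <- function(chain) {
    last <- chain[length(chain)]
    if (cands$kind[last] == "terminal" && focal %in% chain) consider(chain)
    if (cands$kind[last] %in% c("initial", "internal")) {
      for (b in seq_len(n)) {
        if (pair_ok(last, b)) extend(c(chain, b))
      }
    }
  }
  if (cands$kind[focal] == "single") consider(focal)
  for (st in which(cands$kind == "initial")) extend(st)
  best
}

# random small candidate sets derived from genuine enumeration on a short
# random sequence (so junction fragments and frames are real)
oracle_random_instance <- function(seed, max_cands = 12L) {
  set.seed(seed)
  cfg <- generator_config(flank3 = 120L, intron_range = c(60L, 150L), seed = seed)
  plan <- list(n_exons = sample(2:3, 1L), n_codons = sample(60:90, 1L),
               sec_codons = sample(10:40, 1L),
               secis = tibble::tibble(offset = integer(), motif_class = character()),
               type = "gene")
  cass <- plant_selenogene(plan, cfg, codon_weights = NULL)
  seq <- paste0(rand_dna(150, seed + 7000), cass$seq, rand_dna(150, seed + 8000))
  dummy <- train_markov("ATGAAACCCGGGTTTTAA", c("ACGTACGTACGTACGT"), k = 0)
  sites <- scan_signals(seq, model = NULL)
  cands <- enumerate_exons(seq, sites, dummy,
                           limits = list(min_exon = 20L, max_exon = 500L))
  # identify the planted exon candidates (interval + frame match) and keep
  # them in the subset; the remainder is drawn at random
  es <- cass$truth$exon_starts[[1]] + 150L
  ee <- cass$truth$exon_ends[[1]] + 150L
  lens <- ee - es
  f5 <- c(0L, cumsum(lens)[-length(lens)] %% 3L)
  true_idx <- integer()
  for (i in seq_along(es)) {
    hit <- which(cands$start == es[i] & cands$end == ee[i] & cands$frame5 == f5[i])
    if (length(hit)) true_idx <- c(true_idx, hit[1])
  }
  others <- setdiff(seq_len(nrow(cands)), true_idx)
  extra <- sample(others, min(length(others), max_cands - length(true_idx)))
  cands <- cands[sort(c(true_idx, extra)), ]
  list(seq = seq, cands = cands)
}

# --- brute-force single-linkage clustering oracle ---------------------------
oracle_clusters <- function(starts, ends, families, seqids, max_gap) {
  n <- length(starts)
  # adjacency: same family/seqid and interval gap <= max_gap
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (families[i] != families[j] || seqids[i] != seqids[j]) next
      gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
      if (gap <= max_gap) adj[i, j] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# small helper: genome tibble from a bare string
tiny_genome <- function(seq, id = "rec1") {
  tibble::tibble(id = id, seq = seq, length = nchar(seq))
}

# random DNA of given length under a fixed local seed
rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
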