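# ORF assembly over exon-candidate chains: for every exon carrying an
# in-frame TGA, build the maximal-coding-potential gene model containing
# it. A forward dynamic program finds the best chain prefix (starting at an
# initial exon) ending at each candidate, a backward pass the best suffix
# (ending at a terminal exon); the best gene through a focal exon combines
# the two. Intron cost is an opening penalty plus a linear per-nucleotide
# term, which keeps the recurrence a running prefix-maximum per
# (phase, junction-fragment) bucket.

default_assembler_params <- function() {
  list(min_intron = 40L, intron_open = 5, intron_per_nt = 0.02, dedup_overlap = 0.5)
}

#' Can exon `b` directly follow exon `a` in a gene model?
#'
#' True iff `b` starts at least `min_intron` past the end of `a` (and at
#' most `max_intron`), the reading frame continues (`a$frame3 ==
#' b$frame5`), and the kinds can be adjacent (initial/internal before
#' internal/terminal).
#'
#' @param a,b One-row exon-candidate tibbles (or lists with fields `kind`,
#'   `frame3`/`frame5`, `start`, `end`).
#' @param min_intron Minimum intron length (nt).
#' @param max_intron Maximum intron length (nt).
#' @return Logical.
#' @export
compatible <- function(a, b, min_intron = 40L, max_intron = Inf) {
  gap <- b$start - a$end
  a$kind %in% c("initial", "internal") &&
    b$kind %in% c("internal", "terminal") &&
    gap >= min_intron && gap <= max_intron &&
    a$frame3 == b$frame5
}

# junction codon formed when a (frame3 = p > 0) is followed by b:
# last p bases of a plus first 3 - p bases of b
junction_codon <- function(tail_frag, head_frag) paste0(tail_frag, head_frag)

# bucket key encoding for the forward DP: phase 0 -> 1; phase 1, tail base
# t -> 1 + t; phase 2, tail t1 t2 -> 5 + (t1-1)*4 + t2  (keys 1..21)
fwd_key <- function(frame3, tail_frag) {
  if (frame3 == 0L) return(1L)
  x <- match(strsplit(tail_frag, "")[[1]], DNA_BASES)
  if (anyNA(x)) return(NA_integer_)
  if (frame3 == 1L) 1L + x[1] else 5L + (x[1] - 1L) * 4L + x[2]
}

bwd_key <- function(frame5, head_frag) {
  if (frame5 == 0L) return(1L)
  x <- match(strsplit(head_frag, "")[[1]], DNA_BASES)
  if (anyNA(x)) return(NA_integer_)
  if (frame5 == 1L) 1L + (x[1] - 1L) * 4L + x[2] else 17L + x[1]
}

# keys a query may read, given its own phase and boundary fragment, with
# junction stop codons excluded
fwd_query_keys <- function(frame5, head_frag) {
  if (frame5 == 0L) return(1L)
  if (frame5 == 1L) {
    # tails are single bases; junction = tail + head (2 bases)
    bad <- if (head_frag %in% c("AA", "AG")) "T" else character()
    keep <- setdiff(DNA_BASES, bad)
    1L + match(keep, DNA_BASES)
  } else {
    tails <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))  # t2 fast? no: build explicitly
    tails <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
    keys <- 5L + (rep(1:4, each = 4L) - 1L) * 4L + rep(1:4, 4L)
    cod <- paste0(tails, head_frag)
    keep <- !(cod %in% STOP_CODONS)
    keys[keep]
  }
}

bwd_query_keys <- function(frame3, tail_frag) {
  if (frame3 == 0L) return(1L)
  if (frame3 == 1L) {
    heads <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
    keys <- 1L + (rep(1:4, each = 4L) - 1L) * 4L + rep(1:4, 4L)
    cod <- paste0(tail_frag, heads)
    keep <- !(cod %in% STOP_CODONS)
    keys[keep]
  } else {
    bad <- if (tail_frag == "TA") c("A", "G") else character()
    keep <- setdiff(DNA_BASES, bad)
    17L + match(keep, DNA_BASES)
  }
}

# lexicographic improvement test: higher value, then fewer exons, then
# smaller start
tuple_better <- function(v1, n1, s1, v2, n2, s2) {
  if (v1 != v2) return(v1 > v2)
  if (n1 != n2) return(n1 < n2)
  s1 < s2
}

#' Assemble best gene models through in-frame-TGA exons
#'
#' Runs the chain dynamic program over all candidates and returns, for each
#' focal exon carrying an in-frame TGA, the highest-scoring valid gene
#' model (initial ... terminal chain, or a single exon) containing it.
#' `total_score` is the sum of member coding potentials minus
#' `intron_open + intron_per_nt * length` per intron. Ties are broken by
#' fewer exons, then leftmost gene start. Models from different focal exons
#' that share at least `dedup_overlap` of their coding bases are
#' deduplicated keeping the best score.
#'
#' @param candidates Exon-candidate tibble from [enumerate_exons()].
#' @param seq The sequence the candidates live on (strand-local).
#' @param params List overriding [default_assembler_params()].
#' @param focal_ids Optional subset of `exon_id`s to use as focals.
#' @param dedup Deduplicate overlapping models (default `TRUE`).
#' @return Tibble of gene models, one row per retained focal: `exon_ids`,
#'   `exon_starts`, `exon_ends` (list-columns), `focal_tga`,
#'   `sec_positions`, `n_exons`, `total_score`, `cds`, `protein`.
#' @export
assemble_orfs <- function(candidates, seq, params = list(), focal_ids = NULL, dedup = TRUE) {
  par <- utils::modifyList(default_assembler_params(), params)
  n <- nrow(candidates)
  if (n == 0L) return(empty_models())
  cand <- candidates[order(candidates$start, candidates$end), ]
  kind <- cand$kind
  cstart <- cand$start; cend <- cand$end
  f5 <- cand$frame5; f3 <- cand$frame3
  cp <- cand$coding_potential
  headf <- cand$head_frag; tailf <- cand$tail_frag
  open <- par$intron_open; cnt <- par$intron_per_nt; min_intron <- par$min_intron

  # ---- forward DP: best prefix ending at each exon ----
  pre_val <- rep(-Inf, n); pre_nex <- rep(NA_integer_, n)
  pre_start <- rep(NA_integer_, n); pre_parent <- rep(NA_integer_, n)
  init <- kind == "initial"
  pre_val[init] <- cp[init]; pre_nex[init] <- 1L; pre_start[init] <- cstart[init]
  nb <- 21L
  b_val <- rep(-Inf, nb); b_nex <- integer(nb); b_start <- integer(nb); b_idx <- integer(nb)
  ins_ord <- which(kind %in% c("initial", "internal"))
  ins_ord <- ins_ord[order(cend[ins_ord])]
  qry_ord <- which(kind %in% c("internal", "terminal"))
  qry_ord <- qry_ord[order(cstart[qry_ord])]
  ip <- 1L
  for (b in qry_ord) {
    while (ip <= length(ins_ord) && cend[ins_ord[ip]] + min_intron <= cstart[b]) {
      a <- ins_ord[ip]; ip <- ip + 1L
      if (is.finite(pre_val[a])) {
        key <- fwd_key(f3[a], tailf[a])
        if (!is.na(key)) {
          v <- pre_val[a] + cnt * cend[a]
          if (tuple_better(v, pre_nex[a], pre_start[a], b_val[key], b_nex[key], b_start[key])) {
            b_val[key] <- v; b_nex[key] <- pre_nex[a]
            b_start[key] <- pre_start[a]; b_idx[key] <- a
          }
        }
      }
    }
    best_v <- -Inf; best_n <- 0L; best_s <- 0L; best_i <- 0L
    for (key in fwd_query_keys(f5[b], headf[b])) {
      if (b_idx[key] > 0L &&
          tuple_better(b_val[key], b_nex[key], b_start[key], best_v, best_n, best_s)) {
        best_v <- b_val[key]; best_n <- b_nex[key]; best_s <- b_start[key]; best_i <- b_idx[key]
      }
    }
    if (best_i > 0L) {
      pre_val[b] <- best_v - cnt * cstart[b] - open + cp[b]
      pre_nex[b] <- best_n + 1L
      pre_start[b] <- best_s
      pre_parent[b] <- best_i
    }
  }

  # ---- backward DP: best suffix starting at each exon ----
  suf_val <- rep(-Inf, n); suf_nex <- rep(NA_integer_, n)
  suf_pos <- rep(NA_integer_, n); suf_child <- rep(NA_integer_, n)
  term <- kind == "terminal"
  suf_val[term] <- cp[term]; suf_nex[term] <- 1L; suf_pos[term] <- cstart[term]
  b_val <- rep(-Inf, nb); b_nex <- integer(nb); b_start <- integer(nb); b_idx <- integer(nb)
  ins_ord2 <- which(kind %in% c("internal", "terminal"))
  ins_ord2 <- ins_ord2[order(-cstart[ins_ord2])]
  qry_ord2 <- which(kind %in% c("initial", "internal"))
  qry_ord2 <- qry_ord2[order(-cend[qry_ord2])]
  ip <- 1L
  for (a in qry_ord2) {
    while (ip <= length(ins_ord2) && cstart[ins_ord2[ip]] - min_intron >= cend[a]) {
      b2 <- ins_ord2[ip]; ip <- ip + 1L
      if (is.finite(suf_val[b2])) {
        key <- bwd_key(f5[b2], headf[b2])
        if (!is.na(key)) {
          v <- suf_val[b2] - cnt * cstart[b2]
          if (tuple_better(v, suf_nex[b2], suf_pos[b2], b_val[key], b_nex[key], b_start[key])) {
            b_val[key] <- v; b_nex[key] <- suf_nex[b2]
            b_start[key] <- suf_pos[b2]; b_idx[key] <- b2
          }
        }
      }
    }
    best_v <- -Inf; best_n <- 0L; best_s <- 0L; best_i <- 0L
    for (key in bwd_query_keys(f3[a], tailf[a])) {
      if (b_idx[key] > 0L &&
          tuple_better(b_val[key], b_nex[key], b_start[key], best_v, best_n, best_s)) {
        best_v <- b_val[key]; best_n <- b_nex[key]; best_s <- b_start[key]; best_i <- b_idx[key]
      }
    }
    if (best_i > 0L) {
      suf_val[a] <- best_v + cnt * cend[a] - open + cp[a]
      suf_nex[a] <- best_n + 1L
      suf_pos[a] <- cstart[a]
      suf_child[a] <- best_i
    }
  }

  # ---- combine per focal ----
  if (is.null(focal_ids)) {
    focal_rows <- which(cand$has_inframe_tga)
  } else {
    focal_rows <- which(cand$exon_id %in% focal_ids)
  }
  models <- vector("list", length(focal_rows))
  for (m in seq_along(focal_rows)) {
    fidx <- focal_rows[m]
    total <- -Inf
    if (kind[fidx] == "single") {
      total <- cp[fidx]
      chain <- fidx
    } else {
      pv <- if (kind[fidx] == "initial") cp[fidx] else pre_val[fidx]
      sv <- if (kind[fidx] == "terminal") cp[fidx] else suf_val[fidx]
      if (is.finite(pv) && is.finite(sv)) {
        total <- pv + sv - cp[fidx]
        back <- fidx
        chain <- fidx
        while (!is.na(pre_parent[back]) && kind[back] != "initial") {
          back <- pre_parent[back]
          chain <- c(back, chain)
        }
        fwd <- fidx
        while (!is.na(suf_child[fwd]) && kind[fwd] != "terminal") {
          fwd <- suf_child[fwd]
          chain <- c(chain, fwd)
        }
      }
    }
    if (!is.finite(total)) next
    models[[m]] <- build_model(cand, chain, fidx, total, seq)
  }
  models <- dplyr::bind_rows(models[!purrr::map_lgl(models, is.null)])
  if (!nrow(models)) return(empty_models())
  models <- dplyr::arrange(models, dplyr::desc(.data$total_score),
                           purrr::map_int(.data$exon_starts, ~ min(.x)))
  if (dedup) models <- dedup_models(models, par$dedup_overlap)
  models$model_id <- seq_len(nrow(models))
  models
}

empty_models <- function() {
  tibble::tibble(model_id = integer(), focal_id = integer(), focal_tga = integer(),
                 exon_ids = list(), exon_starts = list(), exon_ends = list(),
                 sec_positions = list(), sec_cds_offsets = list(), n_exons = integer(),
                 total_score = numeric(), cds = character(), protein = character())
}

build_model <- function(cand, chain, fidx, total, seq) {
  es <- cand$start[chain]; ee <- cand$end[chain]
  secs <- integer()
  for (j in seq_along(chain)) {
    offs <- cand$tga_offsets[[chain[j]]]
    if (length(offs)) secs <- c(secs, cand$start[chain[j]] + offs)
  }
  # junction codons spanning introns may themselves be TGA (Sec)
  if (length(chain) > 1L) {
    for (j in seq_len(length(chain) - 1L)) {
      a <- chain[j]; b <- chain[j + 1L]
      if (cand$frame3[a] > 0L) {
        cod <- junction_codon(cand$tail_frag[a], cand$head_frag[b])
        if (cod == SEC_CODON) secs <- c(secs, cand$end[a] - cand$frame3[a])
      }
    }
  }
  cds <- paste(substring(seq, es + 1L, ee), collapse = "")
  prot <- tryCatch(translate_cds(cds), error = function(e) NA_character_)
  if (is.na(prot)) return(NULL)   # defensive: junction checks should prevent this
  secs <- sort(unique(secs))
  # CDS offset (0-based) of each Sec codon start
  cum <- cumsum(c(0L, ee - es))
  sec_cds <- vapply(secs, function(p) {
    ex <- findInterval(p, es)
    as.integer(cum[ex] + (p - es[ex]))
  }, integer(1))
  focal_offs <- cand$tga_offsets[[fidx]]
  tibble::tibble(model_id = NA_integer_, focal_id = cand$exon_id[fidx],
                 focal_tga = cand$start[fidx] + focal_offs[1],
                 exon_ids = list(cand$exon_id[chain]),
                 exon_starts = list(es), exon_ends = list(ee),
                 sec_positions = list(secs), sec_cds_offsets = list(sec_cds),
                 n_exons = length(chain), total_score = total,
                 cds = cds, protein = prot)
}

dedup_models <- function(models, min_share) {
  keep <- integer()
  for (i in seq_len(nrow(models))) {
    dup <- FALSE
    si <- models$exon_starts[[i]]; ei <- models$exon_ends[[i]]
    len_i <- sum(ei - si)
    for (k in keep) {
      sk <- models$exon_starts[[k]]; ek <- models$exon_ends[[k]]
      ov <- exon_set_overlap(si, ei, sk, ek)
      if (ov / min(len_i, sum(ek - sk)) >= min_share) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  models[keep, ]
}

#' Best gene model through one focal exon
#'
#' Convenience wrapper over [assemble_orfs()] for a single focal candidate;
#' returns `NULL` when no valid start..stop chain through the focal exists.
#'
#' @inheritParams assemble_orfs
#' @param focal `exon_id` of the focal in-frame-TGA exon (must be in
#'   `candidates`).
#' @return One-row gene-model tibble, or `NULL`.
#' @export
assemble_best_orf <- function(focal, candidates, seq, params = list()) {
  if (!focal %in% candidates$exon_id) stop("focal exon not among candidates", call. = FALSE)
  out <- assemble_orfs(candidates, seq, params, focal_ids = focal, dedup = FALSE)
  if (!nrow(out)) NULL else out
}

#' Translate an assembled gene model
#'
#' Splices the model's exons and translates with in-frame TGA decoded as
#' `U`; the terminal stop is not included.
#'
#' @param model One-row gene-model tibble from [assemble_orfs()].
#' @return Amino-acid string.
#' @export
translate_gene <- function(model) {
  translate_cds(model$cds[[1]])
}

#' Validate a gene model against the chain invariants
#'
#' Checks that the chain starts with an ATG, ends with a TAA/TAG stop, that
#' consecutive exons are splice-compatible with introns at least
#' `min_intron` long, that the spliced CDS length is divisible by 3 with no
#' internal stop, and that every in-frame TGA appears in `sec_positions`.
#'
#' @param model One-row gene-model tibble.
#' @param seq The underlying sequence.
#' @param min_intron Minimum intron length.
#' @return `TRUE`, or an error describing the violated invariant.
#' @export
check_gene_model <- function(model, seq, min_intron = 40L) {
  es <- model$exon_starts[[1]]; ee <- model$exon_ends[[1]]
  if (is.unsorted(es)) stop("exons not in increasing order")
  if (length(es) > 1L) {
    gaps <- es[-1] - ee[-length(ee)]
    if (any(gaps < min_intron)) stop("intron shorter than minimum")
    introns_ok <- purrr::map2_lgl(ee[-length(ee)], es[-1], function(a, b) {
      substr(seq, a + 1L, a + 2L) == "GT" && substr(seq, b - 1L, b) == "AG"
    })
    if (!all(introns_ok)) stop("intron without GT..AG boundaries")
  }
  cds <- model$cds[[1]]
  if (substr(cds, 1L, 3L) != "ATG") stop("chain does not start with ATG")
  if (nchar(cds) %% 3L != 0L) stop("spliced CDS length not divisible by 3")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% STOP_CODONS) stop("chain does not end with TAA/TAG")
  codons <- split_codons(cds)
  internal <- codons[-length(codons)]
  if (any(internal %in% STOP_CODONS)) stop("internal in-frame stop codon")
  # every in-frame TGA must be a recorded Sec position
  tga_idx <- which(internal == SEC_CODON)
  secs <- model$sec_positions[[1]]
  if (length(tga_idx) != length(secs)) stop("sec_positions inconsistent with in-frame TGAs")
  if (!model$focal_tga[[1]] %in% secs) stop("focal TGA not among sec_positions")
  TRUE
}
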