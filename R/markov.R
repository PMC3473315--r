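# Three-periodic Markov coding model vs homogeneous noncoding model.
# The log-likelihood-ratio term of every exon's coding potential comes from
# here. All log-probabilities are base 2.

#' Train the coding/noncoding Markov model
#'
#' Fits an order-`k` three-periodic Markov chain on coding sequence (one
#' transition table per codon phase; phase 0 is the first base of a codon)
#' and a homogeneous order-`k` chain on noncoding sequence, by maximum
#' likelihood with an additive pseudocount. Positions whose context
#' contains `N` are skipped. Sec-TGA codons in the training CDS are ordinary
#' coding triplets.
#'
#' @param coding_seqs Character vector of CDS strings (lengths divisible by 3).
#' @param noncoding_seqs Character vector of noncoding strings.
#' @param k Markov order (>= 0).
#' @param pseudocount Additive pseudocount per transition.
#' @return An object of class `selenoscan_markov` with elements `k`,
#'   `coding` (list of 3 matrices, `4^k` contexts x 4 bases, log2
#'   probabilities), `noncoding` (one such matrix) and `pseudocount`.
#' @export
train_markov <- function(coding_seqs, noncoding_seqs, k = 5L, pseudocount = 1) {
  if (length(coding_seqs) == 0L || length(noncoding_seqs) == 0L) {
    stop("empty training set", call. = FALSE)
  }
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  if (any(nchar(coding_seqs) %% 3L != 0L)) {
    stop("coding training sequences must have length divisible by 3", call. = FALSE)
  }
  nc <- 4L^k
  cod_counts <- lapply(1:3, function(i) matrix(0, nc, 4L))
  non_counts <- matrix(0, nc, 4L)
  tally <- function(seq, counts, periodic) {
    x <- seq_to_int(toupper(seq))
    L <- length(x)
    if (L < k + 1L) return(counts)
    idx <- (k + 1L):L
    ctx <- context_ids(x, k)[idx]
    base <- x[idx]
    ok <- base <= 4L & !is.na(ctx)
    if (periodic) {
      ph <- ((idx - 1L) %% 3L) + 1L
      for (p in 1:3) {
        sel <- ok & ph == p
        if (any(sel)) {
          t2 <- table(factor(ctx[sel], levels = seq_len(nc)), factor(base[sel], levels = 1:4))
          counts[[p]] <- counts[[p]] + unclass(t2)
        }
      }
      counts
    } else {
      t2 <- table(factor(ctx[ok], levels = seq_len(nc)), factor(base[ok], levels = 1:4))
      counts + unclass(t2)
    }
  }
  for (s in coding_seqs) cod_counts <- tally(s, cod_counts, periodic = TRUE)
  for (s in noncoding_seqs) non_counts <- tally(s, non_counts, periodic = FALSE)
  norm <- function(m) {
    m <- unname(as.matrix(m)) + pseudocount
    dimnames(m) <- NULL
    log2(m / rowSums(m))
  }
  structure(list(k = as.integer(k),
                 coding = lapply(cod_counts, norm),
                 noncoding = norm(non_counts),
                 pseudocount = pseudocount),
            class = "selenoscan_markov")
}

# context id (1-based) of each position: encodes the k previous bases,
# most recent base in the lowest digit; NA where context incomplete or
# containing N
context_ids <- function(x, k) {
  L <- length(x)
  if (k == 0L) return(rep(1L, L))
  ctx <- rep(0, L)
  bad <- rep(FALSE, L)
  for (j in 1:k) {
    prev <- c(rep(NA_integer_, j), x[seq_len(L - j)])
    bad <- bad | is.na(prev) | prev > 4L
    ctx <- ctx + ifelse(is.na(prev) | prev > 4L, 0, (prev - 1L)) * 4^(j - 1)
  }
  ctx <- ctx + 1
  ctx[bad] <- NA
  as.integer(ctx)
}

#' Score a sequence with the coding-vs-noncoding log-likelihood ratio
#'
#' Sum over positions of `log2 P_coding(base | context, phase) -
#' log2 P_noncoding(base | context)`, in bits. Positions without a full
#' `k`-base context (the first `k` positions, unless `context` supplies
#' preceding bases) and positions involving `N` contribute 0. Scores are
#' additive over concatenation when the second call is given the phase
#' shift and the trailing context of the first piece.
#'
#' @param model A `selenoscan_markov` model.
#' @param seq DNA string.
#' @param phase Codon phase of the first base of `seq` (0, 1 or 2).
#' @param context Optional string of bases immediately preceding `seq`.
#' @return Score in bits.
#' @export
score_llr <- function(model, seq, phase = 0L, context = "") {
  assert_dna(toupper(seq), "sequence")
  x <- seq_to_int(toupper(paste0(context, seq)))
  skip <- nchar(context)
  k <- model$k
  L <- length(x)
  if (L - skip < 1L) return(0)
  ctx <- context_ids(x, k)
  pos <- (skip + 1L):L
  pos <- pos[pos > k]   # need a full context
  if (!length(pos)) return(0)
  base <- x[pos]
  cx <- ctx[pos]
  ph <- ((pos - skip - 1L + phase) %% 3L) + 1L
  ok <- !is.na(cx) & base <= 4L
  total <- 0
  for (p in 1:3) {
    sel <- ok & ph == p
    if (any(sel)) {
      total <- total + sum(model$coding[[p]][cbind(cx[sel], base[sel])]) -
        sum(model$noncoding[cbind(cx[sel], base[sel])])
    }
  }
  total
}

# Per-position LLR contributions over a whole record, one vector per
# genomic frame class f in {0,1,2}: position i (0-based) is scored with
# codon phase (i - f) mod 3. Used to score exon candidates in O(1) via
# cumulative sums.
genome_llr_profile <- function(seq, model) {
  x <- seq_to_int(toupper(seq))
  k <- model$k
  L <- length(x)
  ctx <- context_ids(x, k)
  base <- x
  ok <- !is.na(ctx) & base <= 4L
  idx <- which(ok)
  non <- numeric(L)
  non[idx] <- model$noncoding[cbind(ctx[idx], base[idx])]
  cod_by_phase <- lapply(1:3, function(p) {
    v <- numeric(L)
    v[idx] <- model$coding[[p]][cbind(ctx[idx], base[idx])]
    v
  })
  lapply(0:2, function(f) {
    ph <- ((seq_len(L) - 1L - f) %% 3L) + 1L
    contrib <- numeric(L)
    for (p in 1:3) {
      sel <- ph == p
      contrib[sel] <- cod_by_phase[[p]][sel] - non[sel]
    }
    cumsum(c(0, contrib))   # C[f][i+1] = sum of first i positions
  })
}

# exon LLR via the precomputed profile: bases [start, end) (0-based),
# frame class f in 0:2
profile_llr <- function(profile, f, start, end) {
  profile[[f + 1L]][end + 1L] - profile[[f + 1L]][start + 1L]
}

#' Simulate sequence from one side of a Markov model
#'
#' Draws a sequence from the coding (three-periodic, starting at the given
#' phase) or noncoding chain of a `selenoscan_markov` model. The first `k`
#' bases are drawn uniformly.
#'
#' @param model A `selenoscan_markov` model.
#' @param length Number of bases.
#' @param which `"coding"` or `"noncoding"`.
#' @param phase Codon phase of the first emitted base (coding only).
#' @return DNA string.
#' @export
simulate_markov <- function(model, length, which = c("coding", "noncoding"), phase = 0L) {
  which <- match.arg(which)
  k <- model$k
  out <- integer(length)
  for (i in seq_len(length)) {
    if (i <= k) {
      out[i] <- sample.int(4L, 1L)
      next
    }
    cx <- 1L
    if (k > 0L) {
      prev <- out[(i - k):(i - 1L)]
      cx <- sum((prev - 1L) * 4^((k:1) - 1L)) + 1L
    }
    probs <- if (which == "coding") {
      2^model$coding[[(((i - 1L + phase) %% 3L)) + 1L]][cx, ]
    } else {
      2^model$noncoding[cx, ]
    }
    out[i] <- sample.int(4L, 1L, prob = probs)
  }
  int_to_seq(out)
}

#' Serialize a Markov model to a self-describing text file
#'
#' @param model A `selenoscan_markov` model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_markov_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# selenoscan markov model", paste("k", model$k),
               paste("pseudocount", format(model$pseudocount, digits = 17))), con)
  dump_mat <- function(name, m) {
    writeLines(paste("table", name, nrow(m), ncol(m)), con)
    writeLines(apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  }
  for (p in 1:3) dump_mat(paste0("coding", p - 1L), model$coding[[p]])
  dump_mat("noncoding", model$noncoding)
  invisible(path)
}

#' Read a serialized Markov model
#'
#' @param path File written by [write_markov_model()].
#' @return A `selenoscan_markov` model; the round trip is exact.
#' @export
read_markov_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- strsplit(lines, " +")
  k <- NULL; pc <- NULL
  tabs <- list()
  i <- 1L
  while (i <= length(kv)) {
    f <- kv[[i]]
    if (f[1] == "k") { k <- as.integer(f[2]); i <- i + 1L }
    else if (f[1] == "pseudocount") { pc <- as.numeric(f[2]); i <- i + 1L }
    else if (f[1] == "table") {
      nr <- as.integer(f[3]); ncl <- as.integer(f[4])
      rows <- kv[(i + 1L):(i + nr)]
      m <- do.call(rbind, lapply(rows, as.numeric))
      dimnames(m) <- NULL
      tabs[[f[2]]] <- m
      i <- i + nr + 1L
    } else i <- i + 1L
  }
  structure(list(k = k,
                 coding = list(tabs$coding0, tabs$coding1, tabs$coding2),
                 noncoding = tabs$noncoding,
                 pseudocount = pc),
            class = "selenoscan_markov")
}
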