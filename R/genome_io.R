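# Sequence and annotation input/output. FASTA parsing is delegated to
# Biostrings; this module owns the coordinate conventions (0-based
# half-open internally, 1-based inclusive in GFF3/BED) and the spliced
# mapping of products back onto genomic loci.

#' Read a FASTA file into a tibble
#'
#' One row per record. In `type = "dna"` mode sequences are uppercased and
#' `U` is mapped to `T`; only `{A,C,G,T,N}` are accepted.
#'
#' @param path FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    if (type == "dna") {
      Biostrings::readBStringSet(path)
    } else {
      Biostrings::readAAStringSet(path)
    },
    error = function(e) stop("malformed FASTA: ", conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("malformed FASTA header", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path, call. = FALSE)
  seqs <- unname(toupper(as.character(set)))
  if (type == "dna") {
    seqs <- chartr("U", "T", seqs)
    for (s in seqs) assert_dna(s)
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence under a FASTA header", call. = FALSE)
  tibble::tibble(id = unname(ids), seq = unname(seqs), length = nchar(seqs))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with columns `id` and `seq` (a genome or protein set).
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  lines <- purrr::map2(x$id, x$seq, function(id, s) {
    body <- substring(s, seq(1L, nchar(s), width), pmin(seq(width, nchar(s) + width - 1L, width), nchar(s)))
    c(paste0(">", id), body)
  })
  writeLines(unlist(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Characters outside
#' `{A,C,G,T,N}` are an error.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  assert_dna(paste(seq, collapse = ""), "sequence")
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

# GFF3 coordinate conversion: internal [start, end) -> 1-based inclusive
to_gff3 <- function(start, end) list(start = start + 1L, end = end)
from_gff3 <- function(start, end) list(start = start - 1L, end = end)

#' Map a protein or mRNA product onto a genomic locus
#'
#' Recovers the exon/intron structure of a product by exact spliced
#' matching against the locus: matches are extended until they fail, and
#' failures are resolved by introducing GT..AG introns (an intron may
#' interrupt a codon at any of its three positions). When
#' `allow_sec_readthrough` is set, genomic TGA codons match `U` residues.
#' Both strands are tried; the minus strand is handled by scanning the
#' reverse complement and reflecting coordinates.
#'
#' @param product Amino-acid string (may contain `U`) or mRNA/CDS DNA string.
#' @param locus One-row genome tibble (or a plain DNA string).
#' @param allow_sec_readthrough Match `U`/TGA and require a TAA/TAG terminal stop.
#' @param min_intron,max_intron Intron length bounds used during mapping.
#' @return One-row tibble: `seqid`, `strand`, `n_exons`, plus list-columns
#'   `exon_starts`, `exon_ends` (0-based half-open, genomic), `sec_positions`
#'   (genomic starts of TGA codons decoded as Sec), and `protein`, `cds`.
#' @export
map_product_to_genome <- function(product, locus, allow_sec_readthrough = TRUE,
                                  min_intron = 40L, max_intron = 10000L) {
  if (is.data.frame(locus)) {
    seqid <- locus$id[[1]]
    gseq <- locus$seq[[1]]
  } else {
    seqid <- "locus"
    gseq <- locus
  }
  gseq <- toupper(gseq)
  product <- toupper(product)
  is_protein <- grepl("[^ACGTN]", product)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") gseq else reverse_complement(gseq)
    hit <- if (is_protein) {
      map_protein_scan(product, s, allow_sec_readthrough, min_intron, max_intron)
    } else {
      map_mrna_scan(product, s, min_intron, max_intron)
    }
    if (!is.null(hit)) {
      L <- nchar(gseq)
      starts <- hit$starts; ends <- hit$ends; secs <- hit$secs
      if (strand == "-") {
        r <- reflect_interval(starts, ends, L)
        ord <- order(r$start)
        starts <- r$start[ord]; ends <- r$end[ord]
        secs <- if (length(secs)) sort(L - secs - 3L) else integer()
      }
      cds <- spliced_seq(gseq, starts, ends, strand)
      prot <- if (is_protein) product else translate_cds(cds, allow_sec_readthrough)
      return(tibble::tibble(
        seqid = seqid, strand = strand, n_exons = length(starts),
        exon_starts = list(as.integer(starts)), exon_ends = list(as.integer(ends)),
        sec_positions = list(as.integer(secs)), protein = prot, cds = cds
      ))
    }
  }
  stop("no full-length spliced mapping of product onto locus", call. = FALSE)
}

#' Extract and splice exon intervals from a genomic sequence
#'
#' Concatenates the exon substrings (0-based half-open, ascending genomic
#' order) and reverse-complements the result for minus-strand genes, so
#' the returned string reads in transcription order.
#'
#' @param gseq Genomic sequence (plus strand).
#' @param starts,ends Exon intervals.
#' @param strand `"+"` or `"-"`.
#' @return Spliced sequence string.
#' @export
spliced_seq <- function(gseq, starts, ends, strand) {
  pieces <- substring(gseq, starts + 1L, ends)
  cds <- paste(pieces, collapse = "")
  if (strand == "-") cds <- reverse_complement(cds)
  cds
}

# protein-level spliced matcher on one strand (strand-local coordinates).
# Returns list(starts, ends, secs) or NULL.
map_protein_scan <- function(protein, s, sec_ok, min_intron, max_intron) {
  n <- nchar(s)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  tab <- codon_table(sec_readthrough = sec_ok)
  seed_len <- min(length(aa), 8L)
  seed <- paste(aa[seq_len(seed_len)], collapse = "")
  # candidate anchors: translate each frame and search for the seed
  anchors <- integer()
  for (f in 0:2) {
    m <- n - f
    ncod <- m %/% 3L
    if (ncod < seed_len) next
    st <- f + seq(0L, by = 3L, length.out = ncod)
    cod <- substring(s, st + 1L, st + 3L)
    tr <- tab[cod]
    tr[is.na(tr)] <- "X"
    trs <- paste(tr, collapse = "")
    hits <- gregexpr(seed, trs, fixed = TRUE)[[1]]
    if (hits[1] != -1L) anchors <- c(anchors, st[hits])
  }
  for (g0 in sort(anchors)) {
    res <- map_protein_dfs(aa, s, g0, sec_ok, min_intron, max_intron, tab)
    if (!is.null(res)) {
      res$starts <- c(g0, res$intron_ends)
      res$ends <- c(res$intron_starts, res$gene_end)
      return(res)
    }
  }
  NULL
}

# spliced extension from genomic pos g0. Codon matching is iterative;
# recursion happens only when an intron is inserted, so the stack depth is
# bounded by the intron count. On a mismatch the matcher backs off up to 4
# codons (a chance in-frame match can extend past a junction) and tries a
# GT..AG intron at each codon offset, requiring 3 further residues to match
# beyond the junction before committing.
map_protein_dfs <- function(aa, s, g0, sec_ok, min_intron, max_intron, tab) {
  n <- nchar(s)
  nres <- length(aa)
  stops <- if (sec_ok) STOP_CODONS else c(STOP_CODONS, "TGA")
  try_intron_at <- function(i, p, introns) {
    # attempt an intron interrupting the codon of residue i at position p
    for (o in 0:2) {
      d <- p + o
      if (d + 2L > n || substr(s, d + 1L, d + 2L) != "GT") next
      qmax <- min(n - 2L, d + max_intron - 2L)
      q <- d + min_intron - 2L
      while (q <= qmax) {
        if (substr(s, q + 1L, q + 2L) == "AG") {
          r <- q + 2L
          need <- 3L - o
          if (r + need <= n) {
            cod2 <- paste0(substr(s, p + 1L, p + o), substr(s, r + 1L, r + need))
            if (!is.na(tab[cod2]) && tab[[cod2]] == aa[i]) {
              peek <- 0L
              ok <- TRUE
              while (peek < 3L && i + peek < nres) {
                pk <- r + need + 3L * peek
                if (pk + 3L > n) { ok <- FALSE; break }
                cpk <- substr(s, pk + 1L, pk + 3L)
                if (is.na(tab[cpk]) || tab[[cpk]] != aa[i + 1L + peek]) { ok <- FALSE; break }
                peek <- peek + 1L
              }
              if (ok) {
                res <- rec(i + 1L, r + need, rbind(introns, c(d, r)))
                if (!is.null(res)) return(res)
              }
            }
          }
        }
        q <- q + 1L
      }
    }
    NULL
  }
  rec <- function(i, p, introns) {
    # i: next residue index (1-based); p: genomic pos of next codon base
    run <- 0L
    while (i <= nres) {
      if (p + 3L > n) return(NULL)
      cod <- substr(s, p + 1L, p + 3L)
      if (!is.na(tab[cod]) && tab[[cod]] == aa[i]) {
        i <- i + 1L
        p <- p + 3L
        run <- run + 1L
        next
      }
      # mismatch: try introns here and, in case the match ran past a
      # junction by chance, at a few preceding codons
      for (back in 0:min(4L, run)) {
        res <- try_intron_at(i - back, p - 3L * back, introns)
        if (!is.null(res)) return(res)
      }
      return(NULL)
    }
    # all residues consumed: require a complete terminal stop codon
    if (p + 3L > n) return(NULL)
    last <- substr(s, p + 1L, p + 3L)
    if (!(last %in% stops)) return(NULL)
    list(intron_starts = if (is.null(introns)) integer() else as.integer(introns[, 1]),
         intron_ends = if (is.null(introns)) integer() else as.integer(introns[, 2]),
         gene_end = p + 3L)
  }
  res <- rec(1L, g0, NULL)
  if (is.null(res)) return(NULL)
  # locate Sec codons (TGA decoded as U) back on the genome
  secs <- integer()
  if (any(strsplit(paste(aa, collapse = ""), "")[[1]] == "U")) {
    pos <- codon_genomic_positions(g0, res$intron_starts, res$intron_ends)
    u_idx <- which(aa == "U")
    secs <- pos[u_idx]
  }
  res$secs <- secs
  res
}

# genomic start position of each codon given intron structure
codon_genomic_positions <- function(g0, istarts, iends) {
  # walk exon blocks, emitting genomic positions of codon first bases
  starts <- c(g0, iends)
  ends <- c(istarts, Inf)
  pos <- integer(0)
  carry <- 0L
  for (b in seq_along(starts)) {
    blk_start <- starts[b]
    blk_end <- ends[b]
    p <- blk_start
    if (carry > 0L) {
      p <- p + carry
      carry <- 0L
    }
    if (is.infinite(blk_end)) {
      pos <- c(pos, seq(p, by = 3L, length.out = 100000L))
      break
    }
    while (p + 3L <= blk_end) {
      pos <- c(pos, p)
      p <- p + 3L
    }
    if (p < blk_end) {
      pos <- c(pos, p)  # codon starts here, completed after the intron
      carry <- 3L - (blk_end - p)
    }
  }
  pos
}

# mRNA-level exact spliced matcher (strand-local)
map_mrna_scan <- function(mrna, s, min_intron, max_intron) {
  n <- nchar(s)
  m <- nchar(mrna)
  seed_len <- min(m, 20L)
  seed <- substr(mrna, 1L, seed_len)
  anchors <- locate_all(s, seed)
  for (g0 in anchors) {
    res <- map_mrna_dfs(mrna, s, g0, min_intron, max_intron)
    if (!is.null(res)) {
      res$starts <- c(g0, res$intron_ends)
      res$ends <- c(res$intron_starts, res$gene_end)
      res$secs <- integer()
      return(res)
    }
  }
  NULL
}

map_mrna_dfs <- function(mrna, s, g0, min_intron, max_intron) {
  n <- nchar(s)
  m <- nchar(mrna)
  rec <- function(i, p, introns) {
    # extend exact match
    run <- 0L
    while (i <= m && p < n && substr(mrna, i, i) == substr(s, p + 1L, p + 1L)) {
      i <- i + 1L
      p <- p + 1L
      run <- run + 1L
    }
    if (i > m) {
      return(list(intron_starts = if (is.null(introns)) integer() else as.integer(introns[, 1]),
                  intron_ends = if (is.null(introns)) integer() else as.integer(introns[, 2]),
                  gene_end = p))
    }
    # mismatch: the donor usually sits at the failure point, but the match
    # run may have extended into the intron by chance (intron starting with
    # the same bases the mRNA continues with), so back off a few positions
    for (back in 0:min(10L, run)) {
      d <- p - back
      ii <- i - back
      if (d + 2L > n || substr(s, d + 1L, d + 2L) != "GT") next
      qmax <- min(n - 2L, d + max_intron - 2L)
      nxt <- substr(mrna, ii, min(m, ii + 11L))
      q <- d + min_intron - 2L
      while (q <= qmax) {
        if (substr(s, q + 1L, q + 2L) == "AG") {
          r <- q + 2L
          if (substr(s, r + 1L, r + nchar(nxt)) == nxt) {
            res <- rec(ii, r, rbind(introns, c(d, r)))
            if (!is.null(res)) return(res)
          }
        }
        q <- q + 1L
      }
    }
    NULL
  }
  rec(1L, g0, NULL)
}

locate_all <- function(s, pattern) {
  hits <- gregexpr(pattern, s, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits) - 1L
}

# GFF3 emission / parsing ----------------------------------------------------

#' Write selenoprotein calls as GFF3
#'
#' Emits gene/mRNA/CDS features with 1-based inclusive coordinates. Sec
#' codon positions (1-based genomic starts), SECIS intervals, family and
#' confirmation status travel as mRNA attributes, so that [read_gff3()]
#' reproduces the internal 0-based coordinates exactly.
#'
#' @param calls Calls tibble (see [run_pipeline()]).
#' @param path Output file.
#' @param record_lengths Optional named lengths for bounds validation.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(calls, path, record_lengths = NULL) {
  lines <- "##gff-version 3"
  if (nrow(calls)) {
    calls <- dplyr::arrange(calls, .data$seqid, purrr::map_int(.data$exon_starts, ~ as.integer(min(.x))))
    for (i in seq_len(nrow(calls))) {
      row <- calls[i, ]
      es <- sort(row$exon_starts[[1]])
      ee <- sort(row$exon_ends[[1]])
      check_interval(es, ee, record_lengths[[row$seqid]])
      g <- to_gff3(min(es), max(ee))
      id <- row$call_id
      secs <- row$sec_positions[[1]]
      attr_sec <- paste(secs + 1L, collapse = ",")
      secis <- row$secis[[1]]
      attr_secis <- if (!is.null(secis) && nrow(secis)) {
        paste(sprintf("%d-%d:%s:%.1f", secis$start + 1L, secis$end, secis$motif_class, secis$score),
              collapse = "|")
      } else ""
      fam <- row$family %||% "novel"
      status <- row$status %||% "candidate"
      lines <- c(lines,
        sprintf("%s\tselenoscan\tgene\t%d\t%d\t%.3f\t%s\t.\tID=%s", row$seqid, g$start, g$end,
                row$total_score, row$strand, id),
        sprintf("%s\tselenoscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s;family=%s;status=%s;sec_pos=%s;secis=%s",
                row$seqid, g$start, g$end, row$strand, id, id, fam, status, attr_sec, attr_secis))
      # CDS phase: bases to discard to reach the next codon start, in
      # transcription order
      ord <- if (row$strand == "+") order(es) else order(es, decreasing = TRUE)
      phase <- integer(length(es))
      consumed <- 0L
      for (j in seq_along(ord)) {
        k <- ord[j]
        phase[k] <- (3L - (consumed %% 3L)) %% 3L
        consumed <- consumed + (ee[k] - es[k])
      }
      for (k in seq_along(es)) {
        gg <- to_gff3(es[k], ee[k])
        lines <- c(lines,
          sprintf("%s\tselenoscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
                  row$seqid, gg$start, gg$end, row$strand, phase[k], id, id))
      }
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a selenoscan GFF3 file back into a calls-shaped tibble
#'
#' @param path GFF3 file written by [write_gff3()].
#' @return Tibble with `call_id`, `seqid`, `strand`, exon/Sec list-columns
#'   and the `family`/`status` attributes.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (!length(raw)) {
    return(tibble::tibble(call_id = character(), seqid = character(), strand = character(),
                          exon_starts = list(), exon_ends = list(), sec_positions = list(),
                          family = character(), status = character(), secis = list()))
  }
  f <- strsplit(raw, "\t", fixed = TRUE)
  typ <- purrr::map_chr(f, 3)
  attr_field <- purrr::map_chr(f, 9)
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  mrna <- which(typ == "mRNA")
  cds <- which(typ == "CDS")
  cds_parent <- purrr::map_chr(attr_field[cds], get_attr, "Parent")
  out <- purrr::map(mrna, function(i) {
    a <- attr_field[i]
    tid <- get_attr(a, "ID")
    gid <- get_attr(a, "Parent")
    mine <- cds[cds_parent == tid]
    starts <- sort(purrr::map_int(f[mine], ~ as.integer(.x[4])) - 1L)
    ends <- sort(purrr::map_int(f[mine], ~ as.integer(.x[5])))
    sec_raw <- get_attr(a, "sec_pos")
    secs <- if (is.na(sec_raw) || sec_raw == "") integer() else as.integer(strsplit(sec_raw, ",")[[1]]) - 1L
    secis_raw <- get_attr(a, "secis")
    secis <- if (is.na(secis_raw) || secis_raw == "") {
      tibble::tibble(start = integer(), end = integer(), motif_class = character(), score = numeric())
    } else {
      parts <- strsplit(strsplit(secis_raw, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
      se <- purrr::map(parts, ~ as.integer(strsplit(.x[1], "-")[[1]]))
      tibble::tibble(start = purrr::map_int(se, 1) - 1L,
                     end = purrr::map_int(se, 2),
                     motif_class = purrr::map_chr(parts, 2),
                     score = as.numeric(purrr::map_chr(parts, 3)))
    }
    tibble::tibble(call_id = gid, seqid = f[[i]][1], strand = f[[i]][7],
                   exon_starts = list(starts), exon_ends = list(ends),
                   sec_positions = list(secs),
                   family = get_attr(a, "family"), status = get_attr(a, "status"),
                   secis = list(secis))
  })
  dplyr::bind_rows(out)
}

#' Write SECIS hits as a BED track
#'
#' BED uses 0-based half-open coordinates, matching the internal convention;
#' motif class goes in the name column and the structural score in the score
#' column.
#'
#' @param hits Tibble with `seqid`, `start`, `end`, `motif_class`, `score`,
#'   `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  lines <- if (nrow(hits)) {
    sprintf("%s\t%d\t%d\t%s\t%.1f\t%s", hits$seqid, hits$start, hits$end,
            hits$motif_class, hits$score, hits$strand)
  } else character()
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
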