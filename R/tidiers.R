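# broom-style tidiers for the fitted models and ggplot2 autoplot methods
# for the main result types.

#' Tidy a Markov coding model
#'
#' One row per (component, phase, context, base) with the log2 transition
#' probability.
#'
#' @param x A `selenoscan_markov` model.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy selenoscan_markov
#' @export
tidy.selenoscan_markov <- function(x, ...) {
  k <- x$k
  ctx_labels <- context_labels(k)
  rows <- list()
  for (p in 1:3) {
    m <- x$coding[[p]]
    rows[[p]] <- tibble::tibble(
      component = "coding", phase = p - 1L,
      context = rep(ctx_labels, times = 4L),
      base = rep(DNA_BASES, each = nrow(m)),
      log2_prob = as.vector(m))
  }
  rows[[4]] <- tibble::tibble(
    component = "noncoding", phase = NA_integer_,
    context = rep(ctx_labels, times = 4L),
    base = rep(DNA_BASES, each = nrow(x$noncoding)),
    log2_prob = as.vector(x$noncoding))
  dplyr::bind_rows(rows)
}

context_labels <- function(k) {
  if (k == 0L) return("")
  labs <- ""
  for (j in seq_len(k)) {
    labs <- as.vector(outer(labs, DNA_BASES, function(a, b) paste0(b, a)))
  }
  # order must match context_ids(): digit j (1 = most recent) has weight
  # 4^(j-1); enumerate ids 1..4^k and decode
  ids <- 0:(4L^k - 1L)
  dec <- vapply(ids, function(id) {
    chars <- character(k)
    for (j in seq_len(k)) {
      chars[j] <- DNA_BASES[(id %% 4L) + 1L]   # j-th previous base
      id <- id %/% 4L
    }
    paste(rev(chars), collapse = "")           # oldest first, reading order
  }, character(1))
  dec
}

#' Model-level summary of a Markov coding model
#'
#' @param x A `selenoscan_markov` model.
#' @param ... Unused.
#' @return One-row tibble: order, table sizes, pseudocount.
#' @method glance selenoscan_markov
#' @export
glance.selenoscan_markov <- function(x, ...) {
  tibble::tibble(k = x$k, n_contexts = nrow(x$noncoding),
                 n_parameters = 4L * nrow(x$noncoding) * 4L,
                 pseudocount = x$pseudocount)
}

#' Tidy a signal PWM model
#'
#' One row per (signal kind, window position, base) with the log-odds
#' score in bits.
#'
#' @param x A `selenoscan_signal_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy selenoscan_signal_model
#' @export
tidy.selenoscan_signal_model <- function(x, ...) {
  rows <- purrr::imap(x$pwm, function(pwm, kind) {
    w <- SIGNAL_WINDOWS[[kind]]
    offs <- seq_len(ncol(pwm)) - w$up - 1L
    tibble::tibble(kind = kind,
                   position = rep(offs, each = 4L),
                   base = rep(DNA_BASES, times = ncol(pwm)),
                   log_odds = as.vector(pwm[1:4, ]))
  })
  dplyr::bind_rows(rows)
}

#' Model-level summary of a signal model
#'
#' @param x A `selenoscan_signal_model`.
#' @param ... Unused.
#' @return One-row tibble with window widths and enumeration thresholds.
#' @method glance selenoscan_signal_model
#' @export
glance.selenoscan_signal_model <- function(x, ...) {
  tibble::tibble(start_width = ncol(x$pwm$start), donor_width = ncol(x$pwm$donor),
                 acceptor_width = ncol(x$pwm$acceptor),
                 start_threshold = x$thresholds[["start"]],
                 donor_threshold = x$thresholds[["donor"]],
                 acceptor_threshold = x$thresholds[["acceptor"]])
}

#' Gene-structure plot of selenoprotein calls
#'
#' Draws exons as boxes on a genomic axis, Sec codons as vertical ticks
#' and SECIS elements as diamonds, one row per call.
#'
#' @param object Calls tibble from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selenoscan_calls
#' @export
autoplot.selenoscan_calls <- function(object, ...) {
  calls <- tibble::as_tibble(object)
  calls$y <- seq_len(nrow(calls))
  exons <- tidyr::unnest(
    dplyr::transmute(calls, .data$call_id, .data$y, .data$strand,
                     start = .data$exon_starts, end = .data$exon_ends),
    c("start", "end"))
  secs <- tidyr::unnest(
    dplyr::transmute(calls, .data$call_id, .data$y, pos = .data$sec_positions),
    "pos")
  secis <- dplyr::bind_rows(purrr::map2(calls$secis, calls$y, function(h, y) {
    if (is.null(h) || !nrow(h)) return(NULL)
    tibble::tibble(y = y, pos = (h$start + h$end) / 2)
  }))
  p <- ggplot2::ggplot(exons) +
    ggplot2::geom_segment(
      data = dplyr::summarise(dplyr::group_by(exons, .data$y),
                              xmin = min(.data$start), xmax = max(.data$end)),
      ggplot2::aes(x = .data$xmin, xend = .data$xmax, y = .data$y, yend = .data$y),
      linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$y - 0.3, ymax = .data$y + 0.3,
                                    fill = .data$strand)) +
    ggplot2::scale_y_continuous(breaks = calls$y, labels = calls$call_id) +
    ggplot2::labs(x = "genomic position (nt)", y = NULL, fill = "strand") +
    ggplot2::theme_minimal()
  if (nrow(secs)) {
    p <- p + ggplot2::geom_segment(
      data = secs, ggplot2::aes(x = .data$pos, xend = .data$pos,
                                y = .data$y - 0.45, yend = .data$y + 0.45),
      colour = "red")
  }
  if (!is.null(secis) && nrow(secis)) {
    p <- p + ggplot2::geom_point(data = secis,
                                 ggplot2::aes(x = .data$pos, y = .data$y),
                                 shape = 18, size = 3, colour = "orange")
  }
  p
}

#' Plot calls as a gene-structure diagram
#'
#' Convenience wrapper adding the `selenoscan_calls` class so
#' [autoplot.selenoscan_calls()] dispatches.
#'
#' @param calls Calls tibble.
#' @return A ggplot object.
#' @export
plot_calls <- function(calls) {
  class(calls) <- c("selenoscan_calls", class(calls))
  autoplot(calls)
}

#' Heatmap of a family count matrix
#'
#' @param object Output of [summarize_families()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selenoscan_family_summary
#' @export
autoplot.selenoscan_family_summary <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$family != "TOTAL", ]
  long <- tidyr::pivot_longer(d, -"family", names_to = "organism", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$organism, y = .data$family,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white", size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = "genes") +
    ggplot2::theme_minimal()
}

#' Plot a family summary heatmap
#'
#' @param summary Output of [summarize_families()].
#' @return A ggplot object.
#' @export
plot_family_summary <- function(summary) {
  class(summary) <- c("selenoscan_family_summary", class(summary))
  autoplot(summary)
}
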