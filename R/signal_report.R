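# Multiplicity adjustment, volcano coordinates and ranked report assembly.
# The only test statistic defined for these screens is the Yates chi-square,
# so volcano p-values are its 1-df upper tail, adjusted across all events at
# a level by Benjamini-Hochberg.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, order-preserving by input index (a thin validated front on
#' [stats::p.adjust()]). Adjusted values are never smaller than the raw
#' ones, and re-adjusting an already adjusted monotone sequence changes
#' nothing.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p-values must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Volcano coordinates for a signal screen
#'
#' Each event becomes a point at `x = log2(PRR)` and `y = -log10(adjusted
#' p)`, where the raw p-value is the upper tail of the event's Yates
#' chi-square on 1 df and adjustment is [bh_adjust()] across all events in
#' the screen. A point is significant when `x > 0` and `y > 1.3`
#' (`1.3 ~ -log10(0.05)`): reported more than proportionally, and credibly
#' so after multiplicity control. Events with an infinite or undefined PRR
#' have no finite coordinate; they are returned with `NA` coordinates and
#' `excluded = TRUE` rather than silently dropped.
#'
#' @param scores A tibble with columns `event`, `prr`, `chisq` (e.g. a
#'   `faers_signals` from [signal_scores()]).
#' @param y_threshold Significance line on the y axis (default 1.3).
#' @return A `faers_volcano` tibble: `event`, `p`, `p_adjusted`, `x`, `y`,
#'   `significant`, `excluded`.
#' @export
volcano_points <- function(scores, y_threshold = 1.3) {
  stopifnot(all(c("event", "prr", "chisq") %in% names(scores)))
  p <- pchisq(scores$chisq, df = 1, lower.tail = FALSE)
  p_adj <- bh_adjust(p)
  finite <- is.finite(scores$prr) & scores$prr > 0
  out <- tibble(
    event = scores$event,
    p = p,
    p_adjusted = p_adj,
    x = ifelse(finite, log2(scores$prr), NA_real_),
    y = ifelse(finite, -log10(p_adj), NA_real_),
    excluded = !finite
  ) |>
    mutate(significant = !.data$excluded & .data$x > 0 & .data$y > y_threshold)
  attr(out, "y_threshold") <- y_threshold
  structure(out, class = c("faers_volcano", class(out)))
}

#' Plot a volcano screen
#'
#' @param object A `faers_volcano` from [volcano_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_volcano
#' @export
autoplot.faers_volcano <- function(object, ...) {
  thr <- attr(object, "y_threshold") %||% 1.3
  df <- filter(object, !.data$excluded)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = "significant"
    ) +
    ggplot2::labs(
      x = expression(log[2] ~ PRR),
      y = expression(-log[10] ~ "adjusted p")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.faers_volcano
#' @param x A `faers_volcano`.
#' @export
plot.faers_volcano <- function(x, ...) print(autoplot(x, ...))

.fmt_est_ci <- function(est, lo, hi, digits = 2) {
  ifelse(
    is.finite(est) & is.finite(lo) & is.finite(hi),
    sprintf("%.*f (%.*f, %.*f)", digits, est, digits, lo, digits, hi),
    NA_character_
  )
}

#' Ranked signal table in the conventional published layout
#'
#' Formats a scored screen as the familiar ranked table: case reports,
#' `ROR (95% CI)`, `PRR (95% CI)`, chi-square, `IC (IC-2SD)`,
#' `EBGM (EBGM05)`, sorted by descending ROR. Events with an infinite
#' estimate (empty comparison cell, no continuity correction) are excluded
#' from the ranking; how many were excluded is recorded in the
#' `n_excluded_infinite` attribute.
#'
#' @param scores A `faers_signals` tibble from [signal_scores()].
#' @param signals_only Keep only rows with the combined `signal` flag.
#' @return A tibble with formatted character columns plus the raw flags.
#' @export
signal_table <- function(scores, signals_only = FALSE) {
  finite <- is.finite(scores$ror) & is.finite(scores$prr)
  out <- scores[finite, , drop = FALSE] |>
    arrange(desc(.data$ror)) |>
    transmute(
      event = .data$event,
      case_reports = .data$a,
      ror_ci = .fmt_est_ci(.data$ror, .data$ror_low, .data$ror_high),
      prr_ci = .fmt_est_ci(.data$prr, .data$prr_low, .data$prr_high),
      chisq = round(.data$chisq, 2),
      ic = sprintf("%.2f (%.2f)", .data$eic, .data$ic_2sd),
      ebgm = sprintf("%.2f (%.2f)", .data$ebgm, .data$ebgm05),
      ror_signal = .data$ror_signal,
      prr_signal = .data$prr_signal,
      bcpnn_signal = .data$bcpnn_signal,
      signal = .data$signal
    )
  if (signals_only) out <- filter(out, .data$signal)
  attr(out, "n_excluded_infinite") <- sum(!finite)
  out
}

#' Summarise a scored screen
#'
#' One-row overview of a `faers_signals` tibble: how many events were
#' scored and how many met each algorithm's criteria.
#'
#' @param x A `faers_signals` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_ror_signal = sum(x$ror_signal, na.rm = TRUE),
    n_prr_signal = sum(x$prr_signal, na.rm = TRUE),
    n_bcpnn_signal = sum(x$bcpnn_signal, na.rm = TRUE),
    n_signal = sum(x$signal, na.rm = TRUE),
    n_infinite = sum(!is.finite(x$ror))
  )
}
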