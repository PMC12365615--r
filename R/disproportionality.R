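# The four disproportionality algorithms on the case/non-case fourfold
# table:
#
#               event of interest   all other events
#   cases               a                  b
#   non-cases           c                  d
#
# ROR = ad/bc, PRR = [a/(a+b)]/[c/(c+d)], the Yates continuity-corrected
# chi-square, the BCPNN information component, and (in mgps.R) the
# gamma-Poisson shrinker EBGM. All score functions are vectorised over
# parallel cell vectors so a whole screen is one call.

# validates cells and returns them as doubles (margin products overflow
# 32-bit integers even at moderate database sizes)
.check_cells <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) abort("cell counts must be non-negative")
  if (any(a + b + c + d <= 0, na.rm = TRUE)) abort("table total must be positive")
  list(
    a = as.numeric(a), b = as.numeric(b), c = as.numeric(c), d = as.numeric(d)
  )
}

#' Build case/non-case contingency tables for every event
#'
#' For each event term (PT, or SOC after mapping) forms the 2x2 table of the
#' case/non-case design. Counting is at report level within each cell: a
#' report counts once toward `a` however many times it lists the event, and
#' once per SOC even when several of its PTs share that SOC. Two margin
#' conventions are supported. Under `counting = "report"` (default) the
#' columns split *reports*: `b` is the case reports without the event and
#' `n` is the total report count — the natural reading of the case/non-case
#' design, under which a planted odds multiplier in the simulator equals the
#' population ROR. Under `counting = "unit"` the columns split
#' (report, event) *units*: `b` is the remaining case units and `n` the
#' total unit count, the convention matching published totals quoted as
#' reaction-record counts.
#'
#' @param cohort A `faers_cohort` from [flag_cases()].
#' @param level `"pt"` or `"soc"`.
#' @param map A [pt_soc_map()], required for `level = "soc"`.
#' @param counting `"report"` or `"unit"` margin convention (see above).
#' @return A tibble with one row per event: `event`, `a`, `b`, `c`, `d`,
#'   `n`, `expected` (`(a+b)(a+c)/n`).
#' @export
contingency_tables <- function(cohort, level = c("pt", "soc"), map = NULL,
                               counting = c("report", "unit")) {
  stopifnot(inherits(cohort, "faers_cohort"))
  level <- match.arg(level)
  counting <- match.arg(counting)
  units <- cohort$units
  if (nrow(units) == 0) {
    return(tibble(
      event = character(), a = double(), b = double(), c = double(),
      d = double(), n = double(), expected = double()
    ))
  }
  if (level == "soc") {
    if (is.null(map)) abort("SOC-level tables need a pt_soc_map")
    units <- units |>
      mutate(event = pt_to_soc(.data$pt, map)) |>
      distinct(.data$report_id, .data$event, .data$is_case)
  } else {
    units <- units |> rename(event = "pt")
  }
  counts <- units |>
    group_by(.data$event) |>
    summarise(
      a = as.numeric(sum(.data$is_case)), c = as.numeric(sum(!.data$is_case)),
      .groups = "drop"
    )
  if (counting == "report") {
    n_case <- as.numeric(sum(cohort$reports$is_case))
    n_noncase <- as.numeric(sum(!cohort$reports$is_case))
    counts |>
      mutate(
        b = n_case - .data$a, d = n_noncase - .data$c,
        n = n_case + n_noncase
      ) |>
      transmute(
        .data$event, .data$a, .data$b, .data$c, .data$d, .data$n,
        expected = (.data$a + .data$b) * (.data$a + .data$c) / .data$n
      )
  } else {
    u_case <- as.numeric(sum(units$is_case))
    u_noncase <- as.numeric(sum(!units$is_case))
    counts |>
      mutate(
        b = u_case - .data$a, d = u_noncase - .data$c,
        n = u_case + u_noncase
      ) |>
      transmute(
        .data$event, .data$a, .data$b, .data$c, .data$d, .data$n,
        expected = (.data$a + .data$b) * (.data$a + .data$c) / .data$n
      )
  }
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = ad / bc` with the log-scale Wald interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. With an empty `b` or
#' `c` cell the estimate is infinite and returned as `Inf` (screens exclude
#' such rows from ranked output unless a continuity correction was applied
#' upstream).
#'
#' @param a,b,c,d Parallel vectors of cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `ror`, `ror_low`, `ror_high`.
#' @examples
#' ror_ci(20, 80, 100, 9800) # 24.5 (14.45, 41.55)
#' @export
ror_ci <- function(a, b, c, d, conf_level = 0.95) {
  cells <- .check_cells(a, b, c, d)
  a <- cells$a
  b <- cells$b
  c <- cells$c
  d <- cells$d
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(
    ror = ror,
    ror_low = exp(log(ror) - z * se),
    ror_high = exp(log(ror) + z * se)
  )
}

#' Yates continuity-corrected chi-square for a 2x2 table
#'
#' `chisq = n * (|ad - bc| - n/2)^2 / [(a+b)(a+c)(c+d)(b+d)]`, with the
#' correction floored: tables where `|ad - bc| < n/2` score 0 rather than a
#' spurious positive value.
#'
#' @param a,b,c,d Parallel vectors of cell counts.
#' @return Numeric vector of statistics.
#' @export
yates_chisq <- function(a, b, c, d) {
  cells <- .check_cells(a, b, c, d)
  a <- cells$a
  b <- cells$b
  c <- cells$c
  d <- cells$d
  n <- a + b + c + d
  num <- pmax(abs(a * d - b * c) - n / 2, 0)
  n * num^2 / ((a + b) * (a + c) * (c + d) * (b + d))
}

#' Proportional reporting ratio with Wald interval and Yates chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; its log-Wald interval uses the standard
#' variance `1/a - 1/(a+b) + 1/c - 1/(c+d)`. The accompanying test statistic
#' is [yates_chisq()]. An empty `c` cell gives an infinite estimate.
#'
#' @param a,b,c,d Parallel vectors of cell counts.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `prr`, `prr_low`, `prr_high`, `chisq`.
#' @examples
#' prr_chisq(20, 80, 100, 9800) # prr 19.8, chisq 285.3
#' @export
prr_chisq <- function(a, b, c, d, conf_level = 0.95) {
  cells <- .check_cells(a, b, c, d)
  a <- cells$a
  b <- cells$b
  c <- cells$c
  d <- cells$d
  if (any(a + b <= 0) || any(c + d <= 0)) {
    abort("PRR needs a non-empty case row and non-case row")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  prr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  tibble(
    prr = prr,
    prr_low = exp(log(prr) - z * se),
    prr_high = exp(log(prr) + z * se),
    chisq = yates_chisq(a, b, c, d)
  )
}

#' BCPNN hyperparameters
#'
#' Prior constants of the Bayesian confidence propagation neural network
#' information component. The defaults are the conventional uninformative
#' choice `alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma11 = 1`; `gamma`
#' itself is derived per table so that the prior IC is centred at zero.
#'
#' @param alpha1,beta1,alpha,beta,gamma11 Positive reals.
#' @return A `bcpnn_hyperparams` object.
#' @export
bcpnn_hyperparams <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                              gamma11 = 1) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta, gamma11 = gamma11)
  if (any(vals <= 0)) abort("BCPNN hyperparameters must be positive")
  structure(as.list(vals), class = "bcpnn_hyperparams")
}

#' BCPNN information component
#'
#' The information component is a shrunk `log2` observed/expected measure of
#' the dependence between drug and event. With margins `C = n`,
#' `Cx = a + b`, `Cy = a + c`, `Cxy = a` and the derived
#' `gamma = gamma11 (C+alpha)(C+beta) / [(Cx+alpha1)(Cy+beta1)]`:
#'
#' `EIC = log2[ (Cxy+gamma11)(C+alpha)(C+beta) /
#'              ((C+gamma)(Cx+alpha1)(Cy+beta1)) ]`
#'
#' and its posterior variance `VIC` is `1/ln(2)^2` times the sum of the
#' three per-margin terms
#' `(C - Cxy + gamma - gamma11) / [(Cxy+gamma11)(1+C+gamma)]` (and the
#' analogous `Cx`, `Cy` terms). The signal bound is
#' `IC - 2SD = EIC - 2 sqrt(VIC)`; a positive value means the shrunk IC is
#' credibly above independence.
#'
#' @param a,b,c,d Parallel vectors of cell counts.
#' @param hyper A [bcpnn_hyperparams()] object.
#' @return A tibble: `eic`, `vic`, `ic_2sd`.
#' @examples
#' bcpnn_ic(1, 1, 1, 1) # eic exactly 0 at independence
#' @export
bcpnn_ic <- function(a, b, c, d, hyper = bcpnn_hyperparams()) {
  cells <- .check_cells(a, b, c, d)
  a <- cells$a
  b <- cells$b
  c <- cells$c
  d <- cells$d
  stopifnot(inherits(hyper, "bcpnn_hyperparams"))
  C <- a + b + c + d
  Cx <- a + b
  Cy <- a + c
  Cxy <- a
  g <- hyper$gamma11 * (C + hyper$alpha) * (C + hyper$beta) /
    ((Cx + hyper$alpha1) * (Cy + hyper$beta1))
  eic <- log2(
    (Cxy + hyper$gamma11) * (C + hyper$alpha) * (C + hyper$beta) /
      ((C + g) * (Cx + hyper$alpha1) * (Cy + hyper$beta1))
  )
  vic <- (1 / log(2)^2) * (
    (C - Cxy + g - hyper$gamma11) / ((Cxy + hyper$gamma11) * (1 + C + g)) +
      (C - Cx + hyper$alpha - hyper$alpha1) / ((Cx + hyper$alpha1) * (1 + C + hyper$alpha)) +
      (C - Cy + hyper$beta - hyper$beta1) / ((Cy + hyper$beta1) * (1 + C + hyper$beta))
  )
  tibble(eic = eic, vic = vic, ic_2sd = eic - 2 * sqrt(vic))
}

#' Apply the signal criteria of the four algorithms
#'
#' The conventional threshold sets: ROR signals when `a >= 3`, `ROR >= 2`
#' and the CI lower bound exceeds 1; PRR signals when `a >= 3`, `PRR >= 2`
#' and `chisq >= 4`; BCPNN signals when `a >= 3` and `IC - 2SD > 0`. The
#' combined `signal` flag is the conservative all-of conjunction; the
#' per-algorithm flags are always kept so any other convention can be
#' recovered. All thresholds are exposed as arguments.
#'
#' @param scores A tibble with at least `a`, `ror`, `ror_low`, `prr`,
#'   `chisq`, `ic_2sd` (e.g. from [signal_scores()]).
#' @param min_a,min_ror,ci_threshold,min_prr,min_chisq,min_ic The thresholds.
#' @return `scores` with logical columns `ror_signal`, `prr_signal`,
#'   `bcpnn_signal`, `signal` appended.
#' @export
evaluate_criteria <- function(scores, min_a = 3, min_ror = 2, ci_threshold = 1,
                              min_prr = 2, min_chisq = 4, min_ic = 0) {
  scores |>
    mutate(
      ror_signal = .data$a >= min_a & .data$ror >= min_ror &
        .data$ror_low > ci_threshold,
      prr_signal = .data$a >= min_a & .data$prr >= min_prr &
        .data$chisq >= min_chisq,
      bcpnn_signal = .data$a >= min_a & .data$ic_2sd > min_ic,
      signal = .data$ror_signal & .data$prr_signal & .data$bcpnn_signal
    )
}

#' Score every event table with all four algorithms
#'
#' Convenience wrapper: takes the output of [contingency_tables()] and binds
#' on ROR, PRR/chi-square, BCPNN IC and EBGM columns plus the signal flags.
#' Zero cells make ROR/PRR infinite; `zero_cell = "haldane"` instead adds
#' 0.5 to every cell of the affected tables (Haldane-Anscombe correction)
#' before scoring them.
#'
#' @param tables Tibble from [contingency_tables()].
#' @param prior An [mgps_prior()]; `NULL` fits one from the tables when
#'   there are at least 10, otherwise uses the default prior.
#' @param hyper A [bcpnn_hyperparams()].
#' @param zero_cell `"none"` or `"haldane"`.
#' @param ... Threshold overrides passed to [evaluate_criteria()].
#' @return A `faers_signals` tibble: the table columns plus all scores and
#'   flags, sorted by descending ROR.
#' @export
signal_scores <- function(tables, prior = NULL, hyper = bcpnn_hyperparams(),
                          zero_cell = c("none", "haldane"), ...) {
  zero_cell <- match.arg(zero_cell)
  if (nrow(tables) == 0) {
    out <- tables |> mutate(
      ror = double(), ror_low = double(), ror_high = double(),
      prr = double(), prr_low = double(), prr_high = double(),
      chisq = double(), eic = double(), vic = double(), ic_2sd = double(),
      ebgm = double(), ebgm05 = double(),
      ror_signal = logical(), prr_signal = logical(),
      bcpnn_signal = logical(), signal = logical()
    )
    return(structure(out, class = c("faers_signals", class(out))))
  }
  a <- tables$a
  b <- tables$b
  c <- tables$c
  d <- tables$d
  if (zero_cell == "haldane") {
    zc <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * zc
    b <- b + 0.5 * zc
    c <- c + 0.5 * zc
    d <- d + 0.5 * zc
  }
  if (is.null(prior)) {
    prior <- if (nrow(tables) >= 10) {
      fit_mgps_prior(tables$a, tables$expected)
    } else {
      mgps_prior()
    }
  }
  out <- bind_cols(
    tables,
    ror_ci(a, b, c, d),
    prr_chisq(a, b, c, d),
    bcpnn_ic(a, b, c, d, hyper),
    mgps_ebgm(tables$a, tables$expected, prior)
  ) |>
    evaluate_criteria(...) |>
    arrange(desc(.data$ror))
  structure(out, class = c("faers_signals", class(out)))
}

#' Reconstruct a fourfold table from its summary statistics
#'
#' Published screens print, per event, the case count `a`, the database
#' total `n`, and the ROR and PRR — enough to invert the table. Eliminating
#' the event margin via the PRR equation
#' (`Cy = a + a (n - Cx) / (PRR * Cx)`) leaves a one-dimensional
#' root-finding problem in the case margin `Cx`, solved by bisection on the
#' log-ROR residual over `Cx` in `(a, n - a)` to 1e-10 relative tolerance.
#' Cells are returned unrounded; rounding of the printed ROR/PRR propagates
#' into them, so statistics recomputed from a reconstruction carry that
#' rounding error. Requires `ror > prr > 1`, the solvable branch (at
#' `ror = prr` the system is degenerate).
#'
#' @param a Case count with the event.
#' @param n Table total.
#' @param ror,prr The printed point estimates.
#' @return A one-row tibble with real-valued `a`, `b`, `c`, `d`, `n`,
#'   `expected`.
#' @examples
#' reconstruct_contingency(20, 10000, ror = 24.5, prr = 19.8)
#' @export
reconstruct_contingency <- function(a, n, ror, prr) {
  if (!(ror > prr && prr > 1)) {
    abort("reconstruction requires ror > prr > 1 (the solvable branch)")
  }
  if (a <= 0 || a >= n) abort("need 0 < a < n")
  resid <- function(Cx) {
    Cy <- a + a * (n - Cx) / (prr * Cx)
    b <- Cx - a
    c <- Cy - a
    d <- n - Cx - Cy + a
    if (b <= 0 || c <= 0 || d <= 0) {
      return(NA_real_)
    }
    log(a * d / (b * c)) - log(ror)
  }
  lo <- a * (1 + 1e-9)
  hi <- n - a
  # the residual is monotone decreasing in Cx on the feasible branch; locate
  # a sign change on a log-spaced grid before bisecting
  grid <- exp(seq(log(lo), log(hi), length.out = 128))
  fg <- vapply(grid, resid, numeric(1))
  valid <- which(!is.na(fg))
  bracket <- NULL
  for (j in seq_len(max(length(valid) - 1, 0))) {
    i1 <- valid[j]
    i2 <- valid[j + 1]
    if (fg[i1] > 0 && fg[i2] <= 0) {
      bracket <- c(grid[i1], grid[i2])
      break
    }
  }
  if (is.null(bracket)) {
    abort("no feasible table reproduces the given (a, n, ror, prr)")
  }
  root <- uniroot(resid, bracket, tol = 1e-10 * n)$root
  Cx <- root
  Cy <- a + a * (n - Cx) / (prr * Cx)
  tibble(
    a = a, b = Cx - a, c = Cy - a, d = n - Cx - Cy + a, n = n,
    expected = Cx * Cy / n
  )
}
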