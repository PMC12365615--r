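test_that("ROR point estimate and Wald interval match hand evaluation", {
  r <- ror_ci(20, 80, 100, 9800)
  expect_equal(r$ror, 24.5)
  expect_equal(r$ror_low, 14.448136, tolerance = 1e-6)
  expect_equal(r$ror_high, 41.545152, tolerance = 1e-6)
})

test_that("a balanced table gives ROR 1 with a log-symmetric interval", {
  r <- ror_ci(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_equal(log(r$ror_high), -log(r$ror_low), tolerance = 1e-12)
})

test_that("PRR and the Yates statistic match hand evaluation", {
  p <- prr_chisq(20, 80, 100, 9800)
  expect_equal(p$prr, 19.8)
  expect_equal(p$chisq, 285.3212, tolerance = 1e-4)
  flat <- prr_chisq(10, 10, 10, 10)
  expect_equal(flat$prr, 1)
  expect_equal(flat$chisq, 0) # continuity correction floors at zero
})

test_that("the Yates statistic equals the standard corrected implementation", {
  tabs <- random_tables(100, seed = 21)
  ours <- yates_chisq(tabs$a, tabs$b, tabs$c, tabs$d)
  reference <- vapply(seq_len(nrow(tabs)), function(i) {
    m <- matrix(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]), 2, byrow = TRUE)
    unname(suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic)
  }, numeric(1))
  expect_equal(ours, reference, tolerance = 1e-9)
})

test_that("near-null tables agree with the corrected oracle including the floor", {
  tabs <- random_tables(50, seed = 22, lambda = c(5, 5, 5, 5))
  ours <- yates_chisq(tabs$a, tabs$b, tabs$c, tabs$d)
  reference <- vapply(seq_len(nrow(tabs)), function(i) {
    m <- matrix(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]), 2, byrow = TRUE)
    unname(suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic)
  }, numeric(1))
  expect_equal(ours, reference, tolerance = 1e-9)
})

test_that("BCPNN IC is exactly zero on the unit independent table", {
  ic <- bcpnn_ic(1, 1, 1, 1)
  expect_equal(ic$eic, 0, tolerance = 1e-12)
  expect_equal(ic$vic, 1.288467, tolerance = 1e-5)
  expect_equal(ic$ic_2sd, -2.270213, tolerance = 1e-5)
})

test_that("independent tables have near-zero IC at realistic sizes", {
  set.seed(31)
  for (i in 1:20) {
    # construct ad = bc exactly
    p <- runif(1, 0.02, 0.3)
    q <- runif(1, 0.05, 0.5)
    n <- 1e4 + sample(1e4, 1)
    a <- n * p * q
    b <- n * p * (1 - q)
    c <- n * (1 - p) * q
    d <- n * (1 - p) * (1 - q)
    ic <- bcpnn_ic(a, b, c, d)
    expect_lt(abs(ic$eic), 0.01)
  }
})

test_that("all scores increase strictly in a at fixed margins", {
  n <- 10000
  Cx <- 300
  Cy <- 500
  a <- seq(20, 200, by = 20)
  tabs <- tibble::tibble(a = a, b = Cx - a, c = Cy - a, d = n - Cx - Cy + a)
  r <- ror_ci(tabs$a, tabs$b, tabs$c, tabs$d)$ror
  p <- prr_chisq(tabs$a, tabs$b, tabs$c, tabs$d)$prr
  e <- bcpnn_ic(tabs$a, tabs$b, tabs$c, tabs$d)$eic
  g <- mgps_ebgm(tabs$a, (Cx * Cy) / n + 0 * a, mgps_prior())$ebgm
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(e) > 0))
  expect_true(all(diff(g) > 0))
})

test_that("signal criteria follow the published threshold sets", {
  base <- tibble::tibble(
    event = "x", a = 2, ror = 50, ror_low = 10, prr = 50, chisq = 100,
    ic_2sd = 1
  )
  expect_false(evaluate_criteria(base)$ror_signal) # a below 3 blocks everything

  flat <- tibble::tibble(
    event = "x", a = 10, ror = 1, ror_low = 0.5, prr = 1, chisq = 0,
    ic_2sd = -2
  )
  flags <- evaluate_criteria(flat)
  expect_false(any(flags$ror_signal, flags$prr_signal, flags$bcpnn_signal))

  strong <- dplyr::bind_cols(
    tibble::tibble(event = "y", a = 20),
    ror_ci(20, 80, 100, 9800),
    prr_chisq(20, 80, 100, 9800),
    bcpnn_ic(20, 80, 100, 9800)
  )
  flags <- evaluate_criteria(strong)
  expect_true(flags$ror_signal)
  expect_true(flags$prr_signal)
})

test_that("zero cells give infinite markers, or finite ones under Haldane", {
  r <- ror_ci(5, 0, 3, 10)
  expect_true(is.infinite(r$ror))
  tabs <- tibble::tibble(
    event = c("x", "y"), a = c(5, 4), b = c(0, 6), c = c(3, 3), d = c(10, 9),
    n = 18, expected = c(5 + 0, 4 + 6) * c(8, 7) / 18
  )
  sc_none <- signal_scores(tabs, prior = mgps_prior())
  expect_true(any(is.infinite(sc_none$ror)))
  sc_h <- signal_scores(tabs, prior = mgps_prior(), zero_cell = "haldane")
  expect_true(all(is.finite(sc_h$ror)))
  # the table without zeros is untouched by the correction
  expect_equal(
    sc_h$ror[sc_h$event == "y"], sc_none$ror[sc_none$event == "y"]
  )
})

test_that("contingency tables count reports once per event with shared margins", {
  units <- tibble::tibble(
    report_id = c("1", "2", "2", "3", "4", "5", "6", "7", "8", "9", "10"),
    pt = c("x", "x", "y", "x", "x", "y", "y", "z", "z", "z", "z"),
    is_case = c(TRUE, rep(FALSE, 10))
  )
  cohort <- make_cohort(
    tibble::tibble(report_id = as.character(1:10), is_case = c(TRUE, rep(FALSE, 9))),
    units = units
  )
  tabs <- contingency_tables(cohort, "pt")
  x <- tabs[tabs$event == "x", ]
  expect_equal(unlist(x[, c("a", "b", "c", "d")]), c(a = 1, b = 0, c = 3, d = 6))
  # a + b is the case-report total for every event; n is shared
  expect_true(all(tabs$a + tabs$b == 1))
  expect_equal(unique(tabs$n), 10)

  shuffled <- cohort
  shuffled$units <- units[sample(nrow(units)), ]
  expect_equal(contingency_tables(shuffled, "pt"), tabs)
})

test_that("SOC tables count a report once per SOC", {
  map <- pt_soc_map(tibble::tibble(pt = c("x", "y"), soc = "s1"))
  units <- tibble::tibble(
    report_id = c("1", "1", "2"), pt = c("x", "y", "x"),
    is_case = c(TRUE, TRUE, FALSE)
  )
  cohort <- make_cohort(
    tibble::tibble(report_id = c("1", "2"), is_case = c(TRUE, FALSE)),
    units = units
  )
  tabs <- contingency_tables(cohort, "soc", map = map)
  expect_equal(tabs$a[tabs$event == "s1"], 1) # both PTs of report 1 count once
})

test_that("reconstruction inverts the summary statistics", {
  rec <- reconstruct_contingency(20, 10000, ror = 24.5, prr = 19.8)
  expect_equal(rec$b, 80, tolerance = 1e-6)
  expect_equal(rec$c, 100, tolerance = 1e-6)
  expect_equal(rec$d, 9800, tolerance = 1e-6)
  expect_error(reconstruct_contingency(20, 10000, 5, 5), "ror > prr")
})

test_that("reconstruction round-trips random real-valued tables", {
  tabs <- random_tables(20, seed = 41, lambda = c(40, 400, 600, 20000))
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$a[i]
    n <- sum(tabs[i, c("a", "b", "c", "d")])
    ror <- ror_ci(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])$ror
    prr <- prr_chisq(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])$prr
    if (!(ror > prr && prr > 1)) next
    rec <- reconstruct_contingency(a, n, ror, prr)
    expect_equal(rec$b, tabs$b[i], tolerance = 1e-6)
    expect_equal(rec$c, tabs$c[i], tolerance = 1e-6)
    expect_equal(rec$d, tabs$d[i], tolerance = 1e-6)
  }
})
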