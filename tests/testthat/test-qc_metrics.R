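# per-sample metrics, size bins, trend fits

make_records <- function(n, mapped, multi = 0L, len = 50L) {
  mapq <- c(rep(0L, multi), rep(37L, mapped - multi), rep(0L, n - mapped))
  alignment_records(
    sprintf("r%03d", seq_len(n)),
    strrep("A", rep_len(len, n)),
    is_mapped = rep(c(TRUE, FALSE), c(mapped, n - mapped)),
    mapq = mapq,
    cigar = ifelse(rep(c(TRUE, FALSE), c(mapped, n - mapped)),
                   paste0(rep_len(len, n), "M"), ""),
    ref_name = "chr1", ref_start = 0L)
}

test_that("sample metrics match the identity and degenerate cases", {
  m <- compute_sample_metrics(make_records(10, 10, multi = 0))
  expect_equal(m$r_m, 1.0)
  expect_equal(m$r_m0, 0.0)
  expect_equal(m$a_l, 50.0)

  m0 <- compute_sample_metrics(make_records(10, 0, len = c(40L, 60L)))
  expect_equal(m0$r_m, 0.0)
  expect_true(is.na(m0$r_m0))
  expect_equal(m0$a_l, 50.0)

  empty <- make_records(4, 2)
  empty$is_primary <- FALSE
  expect_error(compute_sample_metrics(empty), "empty sample")
})

test_that("metrics equal the single-pass counting oracle on simulated data", {
  sm <- small_sim()
  rec <- sm$sim$records
  m <- compute_sample_metrics(rec)
  o <- oracle_sample_metrics(rec)
  expect_identical(m$n_total, o$n_total)
  expect_identical(m$n_mapped, o$n_mapped)
  expect_identical(m$n_multi, o$n_multi)
  expect_identical(m$r_m, o$r_m)
  expect_identical(m$r_m0, o$r_m0)
  expect_equal(m$a_l, o$a_l)
  # permutation invariance
  set.seed(1)
  perm <- rec[sample.int(nrow(rec)), ]
  expect_equal(compute_sample_metrics(perm)$r_m, m$r_m)
})

test_that("duplicate handling and A_L scope switches work", {
  rec <- make_records(10, 6, multi = 2)
  rec$is_duplicate[1:2] <- TRUE
  with_dup <- compute_sample_metrics(rec)
  no_dup <- compute_sample_metrics(rec, count_duplicates = FALSE)
  expect_equal(with_dup$n_total, 10L)
  expect_equal(no_dup$n_total, 8L)
  expect_equal(no_dup$n_mapped, 4L)

  rec2 <- make_records(4, 2, len = c(30L, 30L, 90L, 90L))
  expect_equal(compute_sample_metrics(rec2)$a_l, 60)
  expect_equal(compute_sample_metrics(rec2, a_l_scope = "mapped")$a_l, 30)
})

test_that("multi-mapping definition can switch to the XT tag", {
  rec <- make_records(6, 6, multi = 2)
  rec$xt <- c("U", "U", "R", "R", "R", NA)
  expect_equal(compute_sample_metrics(rec)$n_multi, 2L)
  expect_equal(compute_sample_metrics(rec, multi_def = "xt_r")$n_multi, 3L)
})

test_that("size bins partition the length range at step multiples", {
  rec <- make_records(20, 20, len = rep(45L, 20))
  b <- bin_by_read_size(rec, step = 10, min_reads = 1)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$lower, b$upper, b$midpoint), c(40, 50, 45))

  lens <- rep(c(30L, 42L, 59L), times = c(5L, 5L, 5L))
  rec2 <- make_records(15, 15, len = lens)
  b2 <- bin_by_read_size(rec2, step = 10, min_reads = 1)
  expect_equal(b2$midpoint, c(35, 45, 55))
  expect_equal(b2$n_total, c(5L, 5L, 5L))
})

test_that("bin counts conserve the sample totals and match a filter oracle", {
  sm <- small_sim()
  rec <- sm$sim$records
  b <- bin_by_read_size(rec, step = 10, min_reads = 100)
  m <- compute_sample_metrics(rec)
  expect_equal(sum(b$n_total), m$n_total)
  expect_equal(sum(b$n_mapped), m$n_mapped)
  expect_equal(sum(b$n_multi), m$n_multi)
  # brute-force filter-then-count oracle per bin
  for (i in seq_len(nrow(b))) {
    sel <- rec$length >= b$lower[i] & rec$length < b$upper[i] &
      rec$is_primary
    expect_equal(b$n_total[i], sum(sel))
    expect_equal(b$n_mapped[i], sum(sel & rec$is_mapped))
  }
  expect_true(all(b$included_in_fit == (b$n_total >= 100)))
})

test_that("trend fit reproduces exact lines and the OLS normal equations", {
  bins <- data.frame(midpoint = c(35, 45, 55, 65, 75),
                     r_m = -0.01 * c(35, 45, 55, 65, 75) + 1,
                     included_in_fit = TRUE)
  fit <- fit_size_trend(bins, "r_m")
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  const <- data.frame(midpoint = c(35, 45, 55), r_m = 0.4,
                      included_in_fit = TRUE)
  fitc <- fit_size_trend(const, "r_m")
  expect_equal(fitc$slope, 0)
  expect_equal(fitc$r_squared, 0)

  # hand-entered points vs closed-form normal equations
  x <- c(30, 40, 50, 70, 90); y <- c(0.9, 0.75, 0.8, 0.5, 0.45)
  pts <- data.frame(midpoint = x, r_m0 = y, included_in_fit = TRUE)
  fit2 <- fit_size_trend(pts, "r_m0")
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_o <- mean(y) - slope_o * mean(x)
  r2_o <- 1 - sum((y - int_o - slope_o * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit2$slope, slope_o, tolerance = 1e-12)
  expect_equal(fit2$intercept, int_o, tolerance = 1e-12)
  expect_equal(fit2$r_squared, r2_o, tolerance = 1e-12)

  expect_error(fit_size_trend(pts[1:2, ], "r_m0"), "at least 3")
  same_x <- data.frame(midpoint = 45, r_m = c(0.1, 0.2, 0.3),
                       included_in_fit = TRUE)
  expect_error(fit_size_trend(same_x, "r_m"), "distinct midpoints")
})

test_that("r_m recovers the generative endogenous fraction within 3 SE", {
  ref <- simulate_reference(20000, 0.42, seed = 11)
  f <- 0.6; n <- 5000L
  ok <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(seed = 1000L + s, ref_length = 20000L,
                             n_reads = n, endogenous_fraction = f,
                             len_max = 150L)
    m <- compute_sample_metrics(
      simulate_reads(cfg, ref, emit_sam = FALSE)$records)
    if (abs(m$r_m - f) <= 3 * sqrt(f * (1 - f) / n)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})
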