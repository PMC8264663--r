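test_that("residual maps are elementwise absolute differences", {
  p <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9), 3, 3)
  y <- matrix(c(0.2, 0.2, 0.1, 0.9, 0.5, 0.3, 0.4, 0.8, 1.0), 3, 3)
  expect_equal(residual_map(p, y), abs(y - p))
  expect_identical(residual_map(y, y), matrix(0, 3, 3))
  expect_equal(residual_map(y + 0.1, y), matrix(0.1, 3, 3))
  expect_error(residual_map(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
})

test_that("relative residuals are masked where the truth is below the floor", {
  y <- matrix(c(0, 0.5, 1e-4, 0.25), 2, 2)
  p <- matrix(c(0.1, 0.45, 0, 0.30), 2, 2)
  r <- relative_residual_map(p, y, floor = 1e-3)
  expect_true(is.na(r[1, 1]) && is.na(r[1, 2]))
  expect_equal(r[2, 1], 0.1)
  expect_equal(r[2, 2], 0.2)
  # fully-zero truth: everything masked, nothing non-finite
  rz <- relative_residual_map(p, matrix(0, 2, 2))
  expect_true(all(is.na(rz)))
  expect_false(any(is.infinite(rz)))
})

test_that("pooled summaries use type-7 percentiles over all pixels", {
  # 99 residuals of 0.01 and one of 1.0
  p <- array(0, c(10, 10, 1))
  y <- array(0.01, c(10, 10, 1))
  y[10, 10, 1] <- 1
  s <- summarize_residuals(p, y)
  expect_equal(s$mean, 0.0199)
  expect_equal(s$p99, 0.0199)  # 0.01 + 0.01 * (1.0 - 0.01) interpolated
  expect_identical(s$max, 1)
  expect_true(s$mean <= s$p99 && s$p99 <= s$max)

  z <- summarize_residuals(y, y)
  expect_identical(unlist(z), c(mean = 0, p99 = 0, max = 0))
  cs <- summarize_residuals(array(0.3, c(4, 4)), array(0.5, c(4, 4)))
  expect_equal(unlist(cs), c(mean = 0.2, p99 = 0.2, max = 0.2))
})

test_that("slice statistics match a brute-force per-pixel binning oracle", {
  set.seed(10)
  y <- array(runif(500), c(10, 10, 5))
  p <- pmin(pmax(y + rnorm(500, 0, 0.05), 0), 1)
  sl <- slice_statistics(p, y, n_slices = 10L)
  r <- abs(y - p)
  for (k in 1:10) {
    sel <- y >= (k - 1) / 10 & (y < k / 10 | (k == 10 & y <= 1))
    expect_identical(sl$count[k], sum(sel))
    if (sum(sel) > 0) {
      expect_equal(sl$mean[k], mean(r[sel]))
      expect_equal(sl$std[k], sqrt(mean(r[sel]^2) - mean(r[sel])^2))
    } else {
      expect_true(is.na(sl$mean[k]))
    }
  }
  expect_identical(sum(sl$count), 500L)
  # n_slices = 1 reproduces the pooled mean
  one <- slice_statistics(p, y, n_slices = 1L)
  expect_equal(one$mean[1], summarize_residuals(p, y)$mean)
})

test_that("slices bin targets left-closed with sources in the top slice", {
  y <- array(c(0.05, 0.15, 0.1, 1.0), c(2, 2))
  p <- y - c(0.01, 0.03, 0.02, 0.04)
  sl <- slice_statistics(p, y)
  expect_equal(sl$mean[1], 0.01)
  expect_equal(sl$mean[2], mean(c(0.03, 0.02)))  # 0.1 belongs to slice 2
  expect_equal(sl$mean[10], 0.04)                # y = 1 closes the last slice
  expect_identical(sl$count[3:9], rep(0L, 7))
})

test_that("slice aggregates average and maximize over populated slices only", {
  ag <- slice_aggregate(c(0.1, 0.3, NA), c(0.01, 0.05, NA))
  expect_equal(ag$mean_avg, 0.2)
  expect_equal(ag$mean_max, 0.3)
  expect_equal(ag$std_avg, 0.03)
  expect_equal(ag$std_max, 0.05)
  one <- slice_aggregate(c(NA, 0.2), c(NA, 0.07))
  expect_equal(one$mean_avg, 0.2)
  expect_equal(one$mean_max, 0.2)
  expect_error(slice_aggregate(c(NA, NA), c(NA, NA)), "empty")
})

test_that("field-value densities normalize to 1 and localize correctly", {
  z <- field_pdf(array(0, c(5, 5, 2)), n_bins = 10L)
  expect_equal(sum(z$density * diff(z$breaks)), 1)
  expect_identical(z$counts[1], 50L)
  expect_true(all(z$counts[-1] == 0L))

  set.seed(11)
  u <- field_pdf(runif(1e5), n_bins = 20L)
  expect_equal(sum(u$density * diff(u$breaks)), 1, tolerance = 1e-9)
  # chi-squared sanity: uniform draws give an approximately flat density
  expect_gt(stats::chisq.test(u$counts)$p.value, 1e-4)
  expect_warning(field_pdf(c(0.5, 1.7)), "clipped")
})

test_that("histogram intersection is 1 for identical densities and smaller otherwise", {
  set.seed(12)
  a <- field_pdf(runif(1000))
  expect_equal(histogram_intersection(a, a), 1)
  b <- field_pdf(runif(1000, 0, 0.5))
  hi <- histogram_intersection(a, b)
  expect_true(hi > 0 && hi < 1)
})

test_that("residual reports assemble consistent metrics for a model and dataset", {
  g <- grid_spec(16)
  ds <- generate_dataset(10, seed = 3, grid = g, radius = 2)
  m <- tiny_surrogate(seed = 2)
  rep <- residual_report(m, ds, split = "test")
  expect_s3_class(rep, "residual_report")
  expect_identical(rep$n_images, 2L)
  expect_true(rep$mean_residual <= rep$p99_residual)
  expect_true(rep$p99_residual <= rep$max_residual)
  expect_identical(sum(rep$slice_counts), 2L * 16L * 16L)
  expect_equal(sum(rep$pdf_truth$density * diff(rep$pdf_truth$breaks)), 1)
})
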