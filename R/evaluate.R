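#' Per-pixel residual map
#'
#' Elementwise absolute difference `|y - yhat|` between ground truth and
#' prediction.
#'
#' @param prediction,target numeric arrays of identical shape.
#' @return Array of the same shape.
#' @export
residual_map <- function(prediction, target) {
  if (!identical(dim(prediction) %||% length(prediction),
                 dim(target) %||% length(target)))
    stop("prediction and target shapes differ")
  abs(target - prediction)
}

#' Masked relative residual map
#'
#' `|y - yhat| / y` where the ground truth is at least `floor`; pixels below
#' the floor are `NA` and excluded from summaries. The relative residual
#' diverges as the true value approaches zero — which it does identically at
#' the absorbing boundary — so an unmasked relative error is not meaningful
#' there.
#'
#' @param prediction,target numeric arrays of identical shape.
#' @param floor positive mask threshold on the ground truth (default 1e-3).
#' @return Array of the same shape with `NA` at masked pixels.
#' @export
relative_residual_map <- function(prediction, target, floor = 1e-3) {
  stopifnot(floor > 0)
  r <- residual_map(prediction, target)
  out <- ifelse(target >= floor, r / target, NA_real_)
  if (!is.null(dim(r))) dim(out) <- dim(r)
  out
}

#' Pooled residual summary: mean, 99th percentile, max
#'
#' Pools the per-pixel residuals of every (prediction, target) pair and
#' returns their mean, 99th percentile (linear interpolation between closest
#' order statistics, inclusive — `quantile` type 7) and maximum.
#'
#' @param prediction_set,target_set arrays (`L x L x n` or any matching shape)
#'   of predictions and ground truths.
#' @param probs percentile level for the middle statistic (default 0.99).
#' @return List with `mean`, `p99`, `max`.
#' @export
summarize_residuals <- function(prediction_set, target_set, probs = 0.99) {
  r <- as.numeric(residual_map(prediction_set, target_set))
  if (length(r) == 0L) stop("empty residual pool")
  list(mean = mean(r),
       p99 = unname(stats::quantile(r, probs, type = 7)),
       max = max(r))
}

#' Residual statistics per ground-truth value slice
#'
#' Pixels are binned by their ground-truth value into `n_slices` equal bands
#' over `[0, 1]` (left-closed, right-open; the last band closed at 1, so
#' source pixels fall in the top slice), and the mean and population standard
#' deviation of the residual are computed within each band. This compensates
#' for the rarity of high field values, which a pooled mean washes out.
#'
#' @param prediction_set,target_set matching numeric arrays.
#' @param n_slices number of value bands (default 10).
#' @return List with numeric vectors `mean`, `std` (NA for empty slices) and
#'   integer `count`.
#' @export
slice_statistics <- function(prediction_set, target_set, n_slices = 10L) {
  stopifnot(n_slices >= 1L)
  r <- as.numeric(residual_map(prediction_set, target_set))
  y <- as.numeric(target_set)
  k <- pmin(floor(y * n_slices) + 1L, n_slices)
  mean_s <- rep(NA_real_, n_slices)
  std_s <- rep(NA_real_, n_slices)
  count <- integer(n_slices)
  for (s in seq_len(n_slices)) {
    sel <- k == s
    count[s] <- sum(sel)
    if (count[s] > 0L) {
      rs <- r[sel]
      mean_s[s] <- mean(rs)
      std_s[s] <- sqrt(mean(rs^2) - mean(rs)^2)
    }
  }
  list(mean = mean_s, std = std_s, count = count)
}

#' Aggregate per-slice residual statistics
#'
#' Unweighted average and maximum over populated slices of the per-slice mean
#' and standard deviation, giving equal weight to every value band regardless
#' of how many pixels it holds.
#'
#' @param per_slice_mean,per_slice_std numeric vectors (NA = empty slice).
#' @return List with `mean_avg`, `mean_max`, `std_avg`, `std_max`.
#' @export
slice_aggregate <- function(per_slice_mean, per_slice_std) {
  ok <- !is.na(per_slice_mean)
  if (!any(ok)) stop("all slices are empty")
  list(mean_avg = mean(per_slice_mean[ok]),
       mean_max = max(per_slice_mean[ok]),
       std_avg = mean(per_slice_std[ok], na.rm = TRUE),
       std_max = max(per_slice_std[ok], na.rm = TRUE))
}

#' Probability density of field values
#'
#' Density-normalized histogram of all pixel values over `[0, 1]` with
#' `n_bins` equal-width bins. Values outside `[0, 1]` (possible for an
#' untrained surrogate, whose ReLU output is unbounded above) are clipped
#' into range with a warning.
#'
#' @param image_set numeric array of field values.
#' @param n_bins number of bins (default 100).
#' @return List with `breaks` (length `n_bins + 1`), `density`, `counts`.
#' @export
field_pdf <- function(image_set, n_bins = 100L) {
  v <- as.numeric(image_set)
  if (length(v) == 0L) stop("empty image set")
  if (any(v < -1e-9) || any(v > 1 + 1e-6))
    warning(sprintf("%d value(s) outside [0, 1] clipped for the density",
                    sum(v < -1e-9 | v > 1 + 1e-6)))
  v <- pmin(pmax(v, 0), 1)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(breaks = breaks, density = h$density, counts = h$counts)
}

#' Overlap (intersection) of two field-value densities
#'
#' The histogram intersection \eqn{\sum_b \min(p_b, q_b)\,\Delta} of two
#' densities on the same breaks: 1 for identical distributions, smaller for
#' mismatched ones. Used to compare how closely the predicted field-value
#' distribution tracks the ground truth.
#'
#' @param pdf1,pdf2 outputs of [field_pdf()] on identical breaks.
#' @return Scalar in `[0, 1]`.
#' @export
histogram_intersection <- function(pdf1, pdf2) {
  if (!isTRUE(all.equal(pdf1$breaks, pdf2$breaks)))
    stop("histograms must share breaks")
  dx <- diff(pdf1$breaks)
  sum(pmin(pdf1$density, pdf2$density) * dx)
}

#' Full residual report for a model on a dataset split
#'
#' Predicts every pair of the split, then assembles the evaluation metrics:
#' pooled mean/99-percentile/max residual, per-slice residual statistics and
#' their aggregates, and the field-value densities of prediction and truth.
#'
#' @param model a `surrogate_model`.
#' @param dataset a `diff_dataset` on the model's grid.
#' @param split `"test"` (default) or `"train"`.
#' @param n_slices value bands for [slice_statistics()].
#' @param n_bins bins for [field_pdf()].
#' @param rel_floor mask threshold for the relative residual summary.
#' @param chunk prediction batch size.
#' @return A list of class `residual_report`.
#' @export
residual_report <- function(model, dataset, split = "test", n_slices = 10L,
                            n_bins = 100L, rel_floor = 1e-3, chunk = 64L) {
  stopifnot(inherits(model, "surrogate_model"), inherits(dataset, "diff_dataset"))
  idx <- if (split == "test") dataset$test_idx else dataset$train_idx
  L <- dataset$meta$L
  x <- dataset$inputs[, , idx, drop = FALSE]
  y <- dataset$targets[, , idx, drop = FALSE]
  n <- length(idx)
  pred <- array(0, dim = c(L, L, n))
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    pred[, , start:end] <- predict(model, x[, , start:end, drop = FALSE])
  }
  summ <- summarize_residuals(pred, y)
  sl <- slice_statistics(pred, y, n_slices)
  rel <- relative_residual_map(pred, y, floor = rel_floor)
  structure(list(
    split = split, n_images = n,
    mean_residual = summ$mean, p99_residual = summ$p99, max_residual = summ$max,
    mean_relative_residual = mean(rel, na.rm = TRUE),
    per_slice_mean = sl$mean, per_slice_std = sl$std, slice_counts = sl$count,
    slice_summary = slice_aggregate(sl$mean, sl$std),
    pdf_predicted = field_pdf(pred, n_bins),
    pdf_truth = field_pdf(y, n_bins)
  ), class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report> %s split, %d images\n", x$split, x$n_images))
  cat(sprintf("  mean residual: %.4g   99-percentile: %.4g   max: %.4g\n",
              x$mean_residual, x$p99_residual, x$max_residual))
  cat(sprintf("  mean relative residual (masked): %.4g\n",
              x$mean_relative_residual))
  cat(sprintf("  PDF overlap (prediction vs truth): %.3f\n",
              histogram_intersection(x$pdf_predicted, x$pdf_truth)))
  invisible(x)
}
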