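#' Mean absolute error between two images
#'
#' Mean over all pixels of `|pred - truth|`, background included.
#'
#' @param pred,truth numeric matrices of equal shape.
#' @return nonnegative scalar.
#' @export
mae <- function(pred, truth) {
  assert_matrix(pred, "pred"); assert_matrix(truth, "truth", dims = dim(pred))
  mean(abs(pred - truth))
}

gaussian_kernel_1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

# separable valid-window filtering with a 1D kernel
filter_valid <- function(img, k) {
  n <- length(k)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H - n + 1, W)
  for (i in seq_len(n)) out <- out + k[i] * img[i:(H - n + i), , drop = FALSE]
  out2 <- matrix(0, H - n + 1, W - n + 1)
  for (i in seq_len(n)) out2 <- out2 + k[i] * out[, i:(W - n + i), drop = FALSE]
  out2
}

#' Structural similarity index (SSIM) between two images
#'
#' Windowed SSIM with Gaussian weighting (default 7 x 7, sigma 1.5 — sized for
#' 32 x 32 frames), stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, averaged
#' over all valid window positions.
#'
#' @param pred,truth numeric matrices of equal shape.
#' @param data_range dynamic range `L` of the data (> 0).
#' @param win_size Gaussian window size (odd, <= image side).
#' @param sigma Gaussian window standard deviation (pixels).
#' @return scalar in [-1, 1].
#' @export
ssim <- function(pred, truth, data_range, win_size = 7L, sigma = 1.5) {
  assert_matrix(pred, "pred"); assert_matrix(truth, "truth", dims = dim(pred))
  assert_scalar_num(data_range, "data_range")
  if (data_range <= 0) stop("`data_range` must be positive")
  if (win_size > min(dim(pred))) stop("window exceeds image size")
  k <- gaussian_kernel_1d(win_size, sigma)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu1 <- filter_valid(pred, k); mu2 <- filter_valid(truth, k)
  s11 <- filter_valid(pred * pred, k) - mu1^2
  s22 <- filter_valid(truth * truth, k) - mu2^2
  s12 <- filter_valid(pred * truth, k) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Mean and standard deviation of lifetimes over a region
#'
#' Population (divide-by-n) standard deviation over mask-true pixels,
#' matching the mean +/- sd convention of region-of-interest lifetime tables.
#'
#' @param lifetime_image numeric matrix (ns).
#' @param mask logical matrix, at least one `TRUE`.
#' @return named numeric vector `c(mean, sd)` in ns.
#' @export
region_stats <- function(lifetime_image, mask) {
  assert_matrix(lifetime_image, "lifetime_image")
  if (!is.logical(mask) || !all(dim(mask) == dim(lifetime_image)))
    stop("mask must be a logical matrix matching the image")
  if (!any(mask)) stop("mask is empty")
  v <- lifetime_image[mask]
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
}

#' Evaluate reconstructions against ground-truth scenes
#'
#' Computes per-sample intensity/lifetime MAE and SSIM (all pixels; a
#' foreground-only lifetime MAE is reported alongside) plus aggregates, with
#' optional stratification by photon level.
#'
#' @param results list of `recon_result` objects.
#' @param truths list of [lifetime_scene()] objects with matching `scene_id`s.
#' @param intensity_range SSIM dynamic range for intensity images (counts).
#' @param lifetime_range SSIM dynamic range for lifetime images (ns).
#' @return object of class `eval_report`: `per_sample` data.frame (one row per
#'   sample), `aggregate` (mean and sd of each metric), `by_level` (aggregates
#'   per photon level), `method`.
#' @export
evaluate_recon <- function(results, truths, intensity_range = 1600,
                           lifetime_range = 1.5) {
  if (length(results) != length(truths))
    stop("results and truths differ in length")
  ids_r <- vapply(results, function(r) r$scene_id %||% NA_character_, character(1))
  ids_t <- vapply(truths, function(s) s$scene_id, character(1))
  if (!all(is.na(ids_r))) {
    if (!setequal(ids_r, ids_t)) stop("scene ids of results and truths differ")
    truths <- truths[match(ids_r, ids_t)]
  }
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]; s <- truths[[i]]
    data.frame(
      scene_id = s$scene_id, level = s$level,
      intensity_mae = mae(r$intensity, s$intensity),
      lifetime_mae = mae(r$lifetime, s$lifetime),
      lifetime_mae_fg = if (any(s$mask))
        mean(abs(r$lifetime[s$mask] - s$lifetime[s$mask])) else NA_real_,
      intensity_ssim = ssim(r$intensity, s$intensity, intensity_range),
      lifetime_ssim = ssim(r$lifetime, s$lifetime, lifetime_range),
      stringsAsFactors = FALSE
    )
  })
  per_sample <- do.call(rbind, rows)
  metrics <- c("intensity_mae", "lifetime_mae", "lifetime_mae_fg",
               "intensity_ssim", "lifetime_ssim")
  agg <- function(df) {
    m <- colMeans(df[metrics], na.rm = TRUE)
    s <- vapply(df[metrics], function(v) stats::sd(v, na.rm = TRUE), numeric(1))
    data.frame(metric = metrics, mean = as.numeric(m), sd = as.numeric(s),
               stringsAsFactors = FALSE)
  }
  by_level <- lapply(split(per_sample, per_sample$level), agg)
  structure(list(per_sample = per_sample, aggregate = agg(per_sample),
                 by_level = by_level,
                 method = results[[1]]$method %||% NA_character_,
                 n = nrow(per_sample)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s on %d samples\n", x$method, x$n))
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-16s %8.4f +/- %.4f\n", a$metric[i], a$mean[i], a$sd[i]))
  invisible(x)
}

#' Write an evaluation report to CSV (per sample) and JSON (aggregates)
#'
#' @param report an `eval_report`.
#' @param path_prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @return invisibly, the two paths written.
#' @export
write_eval_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "eval_report"))
  csv <- paste0(path_prefix, ".csv")
  jsn <- paste0(path_prefix, ".json")
  utils::write.csv(report$per_sample, csv, row.names = FALSE)
  agg <- stats::setNames(as.list(report$aggregate$mean), report$aggregate$metric)
  jsonlite::write_json(list(method = report$method, n = report$n,
                            aggregate_mean = agg),
                       jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = jsn))
}
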