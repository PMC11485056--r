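## Accuracy and consistency metrics. Accuracy metrics (RMSE, MAE, R^2) are
## pooled over both components' ln gamma at all test points; R^2 uses a
## single pooled label variance. Consistency metrics (GD-RMSE) are audited
## at interior compositions only: the test compositions of the split
## (GD-RMSE_test) and an external 0.05-step grid excluding the data grid
## (GD-RMSE_ext), which for the default 7-point grid is the 14-point set
## {0.05, 0.15, 0.2, 0.25, 0.35, 0.4, 0.45, 0.55, 0.6, 0.65, 0.75, 0.8,
## 0.85, 0.95}.

#' Pooled accuracy metrics of activity-coefficient predictions
#'
#' @param predictions,labels Aligned data frames with `ln_gamma_1`,
#'   `ln_gamma_2` (both components are pooled into one error vector).
#' @return A one-row tibble with `rmse`, `mae`, `r2`, `n`.
#' @examples
#' y <- tibble::tibble(x1 = c(.1, .5, .9), ln_gamma_1 = 0:2, ln_gamma_2 = 0:2)
#' p <- dplyr::mutate(y, ln_gamma_1 = c(0, 1, 3), ln_gamma_2 = c(0, 1, 3))
#' accuracy_metrics(p, y)
#' @export
accuracy_metrics <- function(predictions, labels) {
  check_aligned(predictions, labels)
  if (nrow(labels) == 0) stop("empty prediction/label set", call. = FALSE)
  err <- c(predictions$ln_gamma_1 - labels$ln_gamma_1,
           predictions$ln_gamma_2 - labels$ln_gamma_2)
  y <- c(labels$ln_gamma_1, labels$ln_gamma_2)
  ss_res <- sum(err^2)
  ss_tot <- sum((y - mean(y))^2)
  tibble::tibble(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = length(err)
  )
}

#' External composition grid for consistency audits
#'
#' All multiples of 0.05 strictly inside (0, 1) that are not part of the
#' data grid; for the default grid `{0, 0.1, 0.3, 0.5, 0.7, 0.9, 1}` this
#' is exactly the 14-point external set.
#'
#' @param train_compositions The data composition grid.
#' @return Sorted numeric vector.
#' @examples
#' external_grid(c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1))  # 14 values
#' @export
external_grid <- function(train_compositions = DEFAULT_GRID) {
  cand <- seq(0.05, 0.95, by = 0.05)
  keep <- vapply(cand, function(x) {
    all(abs(x - train_compositions) > 1e-9)
  }, logical(1))
  round(cand[keep], 2)
}

#' Absolute-error histogram with outlier threshold
#'
#' Pools the absolute errors of both components, bins them, and reports the
#' fraction of errors below 0.05 together with the outlier threshold
#' defined by the top 1% of the highest errors (the smallest error among
#' the top `ceiling(0.01 n)` when sorted descending).
#'
#' @inheritParams accuracy_metrics
#' @param bin_width Histogram bin width (default 0.01).
#' @return A list with `histogram` (tibble `bin_low`, `bin_high`, `count`),
#'   `fraction_below_0.05` and `outlier_threshold_top1pct`.
#' @export
error_histogram <- function(predictions, labels, bin_width = 0.01) {
  check_aligned(predictions, labels)
  if (nrow(labels) == 0) stop("empty prediction/label set", call. = FALSE)
  e <- abs(c(predictions$ln_gamma_1 - labels$ln_gamma_1,
             predictions$ln_gamma_2 - labels$ln_gamma_2))
  breaks <- seq(0, max(e, bin_width) + bin_width, by = bin_width)
  cnt <- table(cut(e, breaks, include.lowest = TRUE, right = FALSE))
  n_top <- max(1L, ceiling(0.01 * length(e)))
  thr <- sort(e, decreasing = TRUE)[n_top]
  list(
    histogram = tibble::tibble(
      bin_low = utils::head(breaks, -1),
      bin_high = utils::tail(breaks, -1),
      count = as.integer(cnt)
    ),
    fraction_below_0.05 = mean(e < 0.05),
    outlier_threshold_top1pct = thr
  )
}

#' Full metric report for a fitted model on one split fold
#'
#' Computes the accuracy metrics on the test records, the Gibbs-Duhem RMSE
#' at the interior test compositions (`gd_rmse_test`) and at the external
#' 0.05-step grid over all test mixtures (`gd_rmse_ext`, pooled over all
#' (mixture, composition) pairs), plus the error-distribution summaries.
#'
#' @param model A `gegnn_fit` or `gegnn_model`.
#' @param data The mixture-record tibble.
#' @param split A `split_assignment` built on `data`.
#' @param fold Fold index.
#' @param data_grid The data composition grid (defaults to the grid
#'   attribute of `data`, else the observed unique compositions).
#' @return A one-row tibble: `rmse`, `mae`, `r2`, `gd_rmse_test`,
#'   `gd_rmse_ext`, `fraction_below_0.05`, `outlier_threshold_top1pct`,
#'   `n_test`.
#' @export
evaluate_model <- function(model, data, split, fold = 1L, data_grid = NULL) {
  model <- as_model(model)
  test <- split_test(split, data, fold)
  if (nrow(test) == 0) stop("empty test set for fold ", fold, call. = FALSE)
  data_grid <- data_grid %||% attr(data, "grid") %||% sort(unique(data$x1))
  preds <- predict_activity(model, test)
  acc <- accuracy_metrics(preds, test)
  hist <- error_histogram(preds, test)

  ext <- external_grid(data_grid)
  mixtures <- dplyr::distinct(test, .data$mixture_id, .data$smiles_1,
                              .data$smiles_2)
  res_test <- c(); res_ext <- c()
  for (i in seq_len(nrow(mixtures))) {
    afn <- model_activity_fn(model, mixtures$smiles_1[i], mixtures$smiles_2[i])
    xs <- test$x1[test$mixture_id == mixtures$mixture_id[i]]
    xs <- xs[xs > 0 & xs < 1]
    if (length(xs)) res_test <- c(res_test, gibbs_duhem_residual(afn, xs))
    if (length(ext)) res_ext <- c(res_ext, gibbs_duhem_residual(afn, ext))
  }
  tibble::tibble(
    rmse = acc$rmse, mae = acc$mae, r2 = acc$r2,
    gd_rmse_test = if (length(res_test)) sqrt(mean(res_test^2)) else NA_real_,
    gd_rmse_ext = if (length(res_ext)) sqrt(mean(res_ext^2)) else NA_real_,
    fraction_below_0.05 = hist$fraction_below_0.05,
    outlier_threshold_top1pct = hist$outlier_threshold_top1pct,
    n_test = nrow(test)
  )
}
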