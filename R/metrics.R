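#' Regression evaluation metrics
#'
#' Computes the three standard biomass-regression metrics over n samples:
#' RMSE `sqrt(mean((y - yhat)^2))`, MAE `mean(|y - yhat|)`, and MAPE
#' `mean(|y - yhat| / y)` reported as a fraction (0.107, not 10.7).
#' MAPE divides by the observed label, so it is undefined when any label
#' is zero; in that case RMSE/MAE are still reported and `mape` is `NA`
#' with `mape_defined = FALSE`.
#'
#' @param labels observed values (length n >= 1).
#' @param predictions predicted values (same length).
#' @return Object of class `metrics_report`: list(rmse, mae, mape, n,
#'   mape_defined).
#' @export
compute_metrics <- function(labels, predictions) {
  n <- length(labels)
  if (n < 1 || length(predictions) != n) {
    stop_invalid("labels and predictions must be non-empty and equal length")
  }
  if (any(!is.finite(labels)) || any(!is.finite(predictions))) {
    stop_invalid("labels/predictions must be finite")
  }
  e <- labels - predictions
  rmse <- sqrt(mean(e^2))
  mae <- mean(abs(e))
  mape_defined <- all(labels != 0)
  mape <- if (mape_defined) mean(abs(e) / abs(labels)) else NA_real_
  structure(list(rmse = rmse, mae = mae, mape = mape, n = n,
                 mape_defined = mape_defined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  RMSE = %.4f  MAE = %.4f  MAPE = %s\n",
              x$n, x$rmse, x$mae,
              if (x$mape_defined) sprintf("%.4f", x$mape) else "undefined (zero label)"))
  invisible(x)
}

#' Write a metrics report to JSON (and residuals to CSV)
#'
#' @param report a [compute_metrics()] result.
#' @param path JSON output path.
#' @param residuals optional data frame of per-sample residuals; written
#'   next to `path` with suffix `_residuals.csv`.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path, residuals = NULL) {
  jsonlite::write_json(report[c("rmse", "mae", "mape", "n")], path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(residuals)) {
    utils::write.csv(residuals,
                     sub("\\.json$", "_residuals.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

spearman_cor <- function(a, b) stats::cor(a, b, method = "spearman")
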