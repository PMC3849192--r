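## Paired-ratio concordance statistics: squared Pearson correlation and
## within-k-fold agreement for predicted vs reference Kp,uu values.

#' Squared Pearson correlation of paired ratios
#'
#' The square of the sample Pearson correlation coefficient between two
#' ratio vectors, computed on untransformed values by default. The
#' untransformed scale is the package's reporting convention for the
#' packaged validation dataset; `log = TRUE` computes the statistic on log
#' ratios instead (requires strictly positive values).
#'
#' @param x,y Numeric vectors of equal length (n >= 3) with nonzero
#'   variance.
#' @param log Correlate log-transformed values instead (default `FALSE`).
#' @return The squared correlation, in `[0, 1]`.
#' @examples
#' t2 <- kpuu_table2()
#' pearson_r2(t2$invivo_slice, t2$invivo_homog)
#' @export
pearson_r2 <- function(x, y, log = FALSE) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_kpuu("`x` and `y` must be numeric vectors of equal length")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_kpuu("need at least 3 complete pairs")
  if (log) {
    if (any(x <= 0) || any(y <= 0)) {
      stop_kpuu("log-scale correlation requires strictly positive values")
    }
    x <- log(x); y <- log(y)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_kpuu("undefined correlation: zero variance in x or y")
  }
  cor(x, y)^2
}

#' Within-k-fold agreement of paired ratios
#'
#' Counts pairs agreeing within a fold threshold: a pair `(x, y)` of
#' positive values is within `k`-fold when `max(x/y, y/x) <= k`, boundary
#' inclusive. Pairs with a nonpositive value cannot be assessed on a fold
#' scale; they are excluded with a warning and recorded in the result.
#'
#' @param x,y Numeric vectors of equal length (e.g. predicted and reference
#'   Kp,uu).
#' @param k Fold threshold (>= 1, default 2).
#' @param labels Optional pair labels (compound names) used to report
#'   discordant pairs.
#' @return An object of class `"fold_concordance"` with fields `n`, `k`,
#'   `within_count`, `within_fraction`, `over_count`, `discordant`
#'   (labels of pairs beyond `k`-fold), and `excluded`.
#' @examples
#' t2 <- kpuu_table2()
#' within_fold_stats(t2$invitro_ss, t2$invivo_slice, k = 2,
#'                   labels = t2$compound)
#' @export
within_fold_stats <- function(x, y, k = 2, labels = NULL) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_kpuu("`x` and `y` must be numeric vectors of equal length")
  }
  check_number(k, "k", 1)
  if (is.null(labels)) labels <- as.character(seq_along(x))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (any(!ok)) {
    warning(sprintf("%d pair(s) with nonpositive or missing values excluded",
                    sum(!ok)), call. = FALSE)
  }
  fold <- pmax(x[ok] / y[ok], y[ok] / x[ok])
  within <- fold <= k
  structure(list(n = sum(ok), k = k,
                 within_count = sum(within),
                 within_fraction = mean(within),
                 over_count = sum(!within),
                 discordant = labels[ok][!within],
                 fold = stats::setNames(fold, labels[ok]),
                 excluded = labels[!ok]),
            class = "fold_concordance")
}

#' @export
print.fold_concordance <- function(x, ...) {
  cat(sprintf("Within %g-fold: %d of %d pairs (%.0f%%); %d beyond\n",
              x$k, x$within_count, x$n, 100 * x$within_fraction, x$over_count))
  if (length(x$discordant)) {
    cat("  discordant:", paste(x$discordant, collapse = ", "), "\n")
  }
  if (length(x$excluded)) {
    cat("  excluded (nonpositive):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Concordance report over a compound table
#'
#' Runs the paired-ratio statistics ([pearson_r2()] and
#' [within_fold_stats()]) for each requested pair of columns of a compound
#' table, e.g. in vitro steady-state vs in vivo (slice) Kp,uu.
#'
#' @param dataset A data frame of compound records (see [kpuu_table2()],
#'   [kpuu_table3()]).
#' @param comparisons A named list; each element is a character vector of
#'   two column names `c(x, y)`.
#' @param k Fold threshold passed to [within_fold_stats()].
#' @param log Compute r² on the log scale (default `FALSE`).
#' @return An object of class `"concordance_report"`: a named list with one
#'   element per comparison, each holding `n`, `r2` and the
#'   `"fold_concordance"` object. Fold fractions recomputed from printed
#'   two-decimal values are boundary-sensitive near the threshold; the
#'   print method marks pairs whose fold sits within 5% of `k`.
#' @examples
#' concordance_report(kpuu_table2(),
#'   list(invitro_vs_slice = c("invitro_ss", "invivo_slice")))
#' @export
concordance_report <- function(dataset, comparisons, k = 2, log = FALSE) {
  stopifnot(is.data.frame(dataset))
  if (!is.list(comparisons) || is.null(names(comparisons)) ||
      any(!nzchar(names(comparisons)))) {
    stop_kpuu("`comparisons` must be a named list of column pairs")
  }
  labels <- if ("compound" %in% names(dataset)) {
    as.character(dataset$compound)
  } else NULL
  out <- lapply(names(comparisons), function(nm) {
    cols <- comparisons[[nm]]
    if (length(cols) != 2L) {
      stop_kpuu(sprintf("comparison `%s` must name exactly two columns", nm))
    }
    missing <- setdiff(cols, names(dataset))
    if (length(missing)) {
      stop_kpuu(sprintf("column `%s` not found in dataset", missing[[1L]]))
    }
    x <- dataset[[cols[[1L]]]]
    y <- dataset[[cols[[2L]]]]
    if (!is.numeric(x) || !is.numeric(y)) {
      stop_kpuu(sprintf("columns for comparison `%s` must be numeric", nm))
    }
    fold <- within_fold_stats(x, y, k = k, labels = labels)
    list(x = cols[[1L]], y = cols[[2L]], n = sum(is.finite(x) & is.finite(y)),
         r2 = pearson_r2(x, y, log = log), fold = fold)
  })
  names(out) <- names(comparisons)
  structure(out, class = "concordance_report", k = k)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance report\n")
  for (nm in names(x)) {
    cmp <- x[[nm]]
    cat(sprintf("\n%s (%s vs %s, n = %d)\n", nm, cmp$x, cmp$y, cmp$n))
    cat(sprintf("  r2 = %.4f\n", cmp$r2))
    cat("  "); print(cmp$fold)
    near <- cmp$fold$fold[abs(cmp$fold$fold - cmp$fold$k) <= 0.05 * cmp$fold$k]
    if (length(near)) {
      cat(sprintf(
        "  note: %d pair(s) within 5%% of the %g-fold boundary (rounding-sensitive): %s\n",
        length(near), cmp$fold$k, paste(names(near), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Scatter plot of a paired-ratio comparison
#'
#' Log-log scatter of predicted vs reference ratios with the identity line
#' and k-fold guide lines.
#'
#' @param x,y Positive ratio vectors.
#' @param k Fold threshold drawn as dashed guides (default 2).
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_concordance <- function(x, y, k = 2,
                             xlab = "predicted Kp,uu",
                             ylab = "reference Kp,uu", ...) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  graphics::plot(x[ok], y[ok], log = "xy", xlab = xlab, ylab = ylab, ...)
  graphics::abline(a = 0, b = 1, untf = TRUE)
  lim <- range(c(x[ok], y[ok]))
  xs <- exp(seq(log(lim[1]), log(lim[2]), length.out = 2))
  lines(xs, xs * k, lty = 2)
  lines(xs, xs / k, lty = 2)
  invisible(NULL)
}
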