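#' Two-way random-effects, absolute-agreement, single-measures ICC
#'
#' The intraclass correlation used for inter-reader agreement of slope
#' measurements: ICC(A,1) in the McGraw & Wong taxonomy (ICC(2,1) in
#' Shrout & Fleiss), from the two-way ANOVA decomposition of a complete
#' subjects-by-readers table into subject (`MS_rows`), reader (`MS_cols`)
#' and residual (`MS_error`) mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' The confidence interval is the standard F-based construction for this
#' form, with Satterthwaite degrees of freedom for the lower-tail
#' denominator.
#'
#' Negative estimates are reported as computed (with a warning), not
#' truncated at zero.
#'
#' @param ratings Numeric n x k matrix (or [as_ratings_matrix()]), subjects in
#'   rows, readers in columns, no missing cells, n >= 2, k >= 2.
#' @param alpha Two-sided confidence level is `1 - alpha`. Default 0.05.
#' @return An object of class `icc_result`: `estimate`, `ci_lower`,
#'   `ci_upper`, `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `alpha`.
#' @examples
#' m <- cbind(r1 = c(7.5, 9.1, 6.2, 11.0), r2 = c(7.3, 9.4, 6.0, 10.7))
#' icc_a1(m)
#' @export
icc_a1 <- function(ratings, alpha = 0.05) {
  m <- as_ratings_matrix(unclass(ratings))
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  resid <- m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || (msr == 0 && msc == 0 && mse == 0)) {
    stop("ICC undefined: the ratings table has zero total variance",
         call. = FALSE)
  }
  est <- (msr - mse) / denom
  if (est < 0) {
    warning("negative ICC estimate (", sprintf("%.3f", est),
            "): between-subject variance is below the error variance",
            call. = FALSE)
  }
  if (mse == 0 && msc == 0) {
    ci <- c(est, est)                    # perfect agreement, F interval degenerate
  } else {
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lower, upper)
  }
  structure(list(estimate = est, ci_lower = ci[1], ci_upper = ci[2],
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k, alpha = alpha),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f, %d%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$estimate, round(100 * (1 - x$alpha)), x$ci_lower, x$ci_upper,
              x$n, x$k))
  invisible(x)
}

#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, conf_level = 1 - x$alpha)
}

#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, ms_rows = x$ms_rows,
                 ms_cols = x$ms_cols, ms_error = x$ms_error, n = x$n, k = x$k)
}

#' Descriptive summary of slope values
#'
#' Mean, sample SD (n - 1 denominator), and range, matching how reader-level
#' slope distributions are reported. A single value has an undefined SD
#' (returned as `NA`).
#'
#' @param values Numeric vector, degrees; at least one value.
#' @return A one-row tibble: `n`, `mean`, `sd`, `min`, `max`.
#' @export
summarize_slopes <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("no values to summarise", call. = FALSE)
  if (anyNA(values)) stop("missing values in slope vector", call. = FALSE)
  tibble::tibble(n = length(values), mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else NA_real_,
                 min = min(values), max = max(values))
}

#' Inter-reader reliability study over all measured regions
#'
#' Computes, for every region in the input, the per-reader descriptive
#' statistics and the inter-reader ICC(A,1) with its confidence interval —
#' the layout of a classic reader-agreement table (one column per measured
#' quantity, reader rows, ICC row). A region observed by fewer than two
#' readers is skipped with a warning.
#'
#' @param data Either a long tibble/data.frame with columns `subject`,
#'   `reader`, `region` and a value column (default `slope_deg`), or a named
#'   list of subjects-by-readers matrices (one per region, e.g.
#'   `generate_reader_study()$ratings`).
#' @param value_col Name of the value column for long input.
#' @param alpha CI level parameter, default 0.05 (a 95 percent CI).
#' @return An object of class `reader_study` with `icc` (tibble: `region`,
#'   `n`, `k`, `estimate`, `ci_lower`, `ci_upper`) and `descriptives`
#'   (tibble: `region`, `reader`, `n`, `mean`, `sd`, `min`, `max`).
#' @export
reader_study <- function(data, value_col = "slope_deg", alpha = 0.05) {
  mats <- if (is.data.frame(data)) {
    need <- c("subject", "reader", "region", value_col)
    miss <- setdiff(need, names(data))
    if (length(miss)) {
      stop("long input lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    regions <- unique(as.character(data$region))
    stats::setNames(lapply(regions, function(rg) {
      sub <- data[data$region == rg, , drop = FALSE]
      wide <- tidyr::pivot_wider(
        sub[, c("subject", "reader", value_col)],
        names_from = "reader", values_from = dplyr::all_of(value_col))
      m <- as.matrix(wide[, -1, drop = FALSE])
      rownames(m) <- as.character(wide$subject)
      m
    }), regions)
  } else if (is.list(data)) {
    data
  } else {
    stop("data must be a long data frame or a named list of matrices",
         call. = FALSE)
  }
  icc_rows <- list(); desc_rows <- list()
  for (rg in names(mats)) {
    m <- mats[[rg]]
    if (is.null(dim(m)) || ncol(m) < 2L) {
      warning("region \"", rg, "\" has fewer than 2 readers; skipped",
              call. = FALSE)
      next
    }
    fit <- icc_a1(m, alpha = alpha)
    icc_rows[[rg]] <- tibble::tibble(region = rg, n = fit$n, k = fit$k,
                                     estimate = fit$estimate,
                                     ci_lower = fit$ci_lower,
                                     ci_upper = fit$ci_upper)
    cn <- colnames(m) %||% paste0("reader", seq_len(ncol(m)))
    desc_rows[[rg]] <- dplyr::bind_rows(lapply(seq_len(ncol(m)), function(j) {
      dplyr::bind_cols(tibble::tibble(region = rg, reader = cn[j]),
                       summarize_slopes(m[, j]))
    }))
  }
  if (!length(icc_rows)) stop("no region with at least 2 readers", call. = FALSE)
  structure(list(icc = dplyr::bind_rows(icc_rows),
                 descriptives = dplyr::bind_rows(desc_rows),
                 alpha = alpha),
            class = "reader_study")
}

#' @export
print.reader_study <- function(x, ...) {
  cat("<reader_study> per-region inter-reader agreement\n")
  print(x$icc)
  cat("\nper-reader descriptives:\n")
  print(x$descriptives)
  invisible(x)
}

#' @method tidy reader_study
#' @export
tidy.reader_study <- function(x, ...) x$icc

#' @method glance reader_study
#' @export
glance.reader_study <- function(x, ...) {
  tibble::tibble(regions = nrow(x$icc),
                 min_icc = min(x$icc$estimate),
                 max_icc = max(x$icc$estimate),
                 conf_level = 1 - x$alpha)
}

#' ICC point-range plot for a reader study
#'
#' @param object A [reader_study()] result.
#' @param ... Unused.
#' @return A ggplot object: ICC estimate with confidence interval per region.
#' @method autoplot reader_study
#' @export
autoplot.reader_study <- function(object, ...) {
  df <- object$icc
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::coord_cartesian(ylim = c(min(0.5, min(df$ci_lower)), 1)) +
    ggplot2::labs(x = NULL, y = "ICC(A,1)",
                  title = sprintf("inter-reader agreement (%d%% CI)",
                                  round(100 * (1 - object$alpha)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
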