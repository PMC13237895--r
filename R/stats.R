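#' Pearson correlation matrix of portfolio variables
#'
#' @param data A data frame of project records.
#' @param vars Character vector of numeric columns to correlate; defaults to
#'   all numeric columns.
#' @return A symmetric correlation matrix with unit diagonal. Variables with
#'   zero variance produce `NA` entries and a warning (undefined, never
#'   silently 0).
#' @export
correlation_matrix <- function(data, vars = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0) {
    abort(paste0("unknown variable(s): ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[vars])
  if (nrow(X) < 3) abort("at least 3 records are required.")
  if (anyNA(X) || any(!is.finite(X))) abort("variables must be finite.")
  degenerate <- vars[apply(X, 2, stats::sd) == 0]
  if (length(degenerate) > 0) {
    warn(paste0("zero-variance variable(s), correlations undefined: ",
                paste(degenerate, collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  r
}

#' Compare a statistic across LHS states
#'
#' Per-state median and IQR (25th and 75th percentiles, linear
#' interpolation) of a project statistic, with a Kruskal-Wallis rank test
#' across the nonempty states (standard tie correction, chi-square
#' approximation).
#'
#' @param data Project records with a `state` column (e.g. from
#'   [simulate_portfolio()] or [run_monte_carlo()]`$projects`).
#' @param statistic Column to compare: `"cti"`, `"roi"`, `"tei"`, or any
#'   numeric column name.
#' @param state_col Name of the grouping column.
#' @return An object of class `lhs_group_comparison` with the per-group
#'   table, the test statistic `H`, degrees of freedom and p-value.
#'   `tidy()` returns the group table; `glance()` the test.
#' @export
compare_states <- function(data, statistic = c("cti", "roi", "tei"),
                           state_col = "state") {
  data <- tibble::as_tibble(data)
  statistic <- if (length(statistic) > 1) match.arg(statistic) else statistic
  if (!statistic %in% names(data)) {
    abort(sprintf("column `%s` not found.", statistic))
  }
  if (!state_col %in% names(data)) {
    abort(sprintf("grouping column `%s` not found.", state_col))
  }
  g <- factor(data[[state_col]])
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("at least 2 nonempty groups are required.")
  x <- data[[statistic]]
  groups <- tibble::tibble(state = g, value = x) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      q25 = stats::quantile(.data$value, 0.25, names = FALSE),
      q75 = stats::quantile(.data$value, 0.75, names = FALSE),
      .groups = "drop"
    )
  kw <- stats::kruskal.test(x, g)
  structure(
    list(statistic_name = statistic, groups = groups,
         H = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value),
    class = "lhs_group_comparison"
  )
}

#' @export
print.lhs_group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis comparison of `%s` across LHS states\n",
              x$statistic_name))
  print(x$groups)
  cat(sprintf("H = %.3f, df = %d, p = %.3g\n", x$H, x$df, x$p_value))
  invisible(x)
}

#' @rdname compare_states
#' @param x An `lhs_group_comparison` object.
#' @param ... Unused.
#' @export
tidy.lhs_group_comparison <- function(x, ...) x$groups

#' @rdname compare_states
#' @export
glance.lhs_group_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$H, df = x$df, p.value = x$p_value,
                 method = "Kruskal-Wallis rank sum test")
}

#' Multivariate model of global ROI
#'
#' Ordinary least-squares fit of project ROI on CTI, global TEI and the
#' mission-weighted mean velocity, with adjusted R-squared and
#' variance-inflation factors. A negative fitted CTI coefficient conditional
#' on TEI and Vmean can occur and is reported as-is; it is a conditioning
#' artifact among collinear predictors, not a causal claim.
#'
#' @param data Project records with columns `roi`, `cti`, `tei` and `vmean`
#'   (as produced by [simulate_portfolio()]); more than 10 rows required.
#' @param predictors Predictor column names (default `cti`, `tei`, `vmean`).
#' @return An object of class `roi_fit` wrapping the `lm` fit with `vif`,
#'   `adj_r_squared` and `n`. `tidy()` gives the coefficient table,
#'   `glance()` the fit summary.
#' @export
fit_roi_model <- function(data, predictors = c("cti", "tei", "vmean")) {
  data <- tibble::as_tibble(data)
  needed <- c("roi", predictors)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) <= 10) abort("more than 10 records are required.")
  X <- as.matrix(data[predictors])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1
    abort(paste0("perfectly collinear predictor(s): ",
                 paste(predictors[dropped], collapse = ", ")))
  }
  fml <- stats::reformulate(predictors, response = "roi")
  fit <- stats::lm(fml, data = data)
  # VIF_j = 1 / (1 - R_j^2), the diagonal of the inverse predictor
  # correlation matrix
  vif <- if (length(predictors) > 1) {
    stats::setNames(diag(solve(stats::cor(X))), predictors)
  } else {
    stats::setNames(1, predictors)
  }
  structure(
    list(fit = fit, vif = vif,
         adj_r_squared = summary(fit)$adj.r.squared,
         r_squared = summary(fit)$r.squared,
         n = nrow(data), predictors = predictors),
    class = "roi_fit"
  )
}

#' @export
print.roi_fit <- function(x, ...) {
  cf <- stats::coef(x$fit)
  eq <- paste0("ROI = ", sprintf("%.4f", cf[1]), " ",
               paste(sprintf("%+.4f*%s", cf[-1], names(cf)[-1]),
                     collapse = " "))
  cat(eq, "\n")
  cat(sprintf("adjusted R^2 = %.4f, n = %d, max VIF = %.2f\n",
              x$adj_r_squared, x$n, max(x$vif)))
  invisible(x)
}

#' @rdname fit_roi_model
#' @param x A `roi_fit` object.
#' @param ... Unused.
#' @export
tidy.roi_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"],
    vif = c(NA_real_, unname(x$vif[rownames(s)[-1]]))
  )
}

#' @rdname fit_roi_model
#' @export
glance.roi_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = x$adj_r_squared,
    sigma = s$sigma,
    statistic = unname(s$fstatistic["value"]),
    p.value = unname(stats::pf(s$fstatistic["value"], s$fstatistic["numdf"],
                               s$fstatistic["dendf"], lower.tail = FALSE)),
    max_vif = max(x$vif),
    nobs = x$n
  )
}
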