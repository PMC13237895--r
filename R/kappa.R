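#' Weighted Cohen's kappa for paired 0-4 ordinal ratings
#'
#' Chance-corrected agreement between two raters on the 5-category rubric
#' scale, with linear or quadratic agreement weights. Quadratic weights are
#' the default, as is conventional for ordinal rubrics.
#'
#' Kappa is undefined when the chance-expected weighted agreement equals 1
#' (both raters constant); this is signaled by returning `NA` with a warning
#' rather than silently reporting 0.
#'
#' @param x,y Equal-length integer vectors of ratings in `{0,...,4}`, `n >= 2`.
#' @param scheme `"quadratic"` (default) or `"linear"` disagreement weighting.
#' @return A single numeric kappa in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' weighted_kappa(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)) # 1
#' weighted_kappa(c(0, 4, 0, 4), c(4, 0, 4, 0))       # -1
#' @export
weighted_kappa <- function(x, y, scheme = c("quadratic", "linear")) {
  scheme <- match.arg(scheme)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("at least 2 paired ratings are required.")
  normalize_rating(x)  # range validation only
  normalize_rating(y)
  k <- 5L
  lev <- 0:4
  d <- abs(outer(lev, lev, "-"))
  w <- if (scheme == "quadratic") 1 - (d / (k - 1))^2 else 1 - d / (k - 1)
  O <- table(factor(x, levels = lev), factor(y, levels = lev)) / length(x)
  px <- rowSums(O)
  py <- colSums(O)
  po <- sum(w * O)
  pe <- sum(w * outer(px, py))
  if (abs(1 - pe) < 1e-12) {
    warn("weighted kappa is undefined: chance-expected agreement is 1 (constant marginals).")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Inter-rater reliability report for a CTI scoring period
#'
#' Computes pairwise weighted kappas between the A, H and C raters for each
#' domain (and pooled over domains), marks kappas below the reliability
#' target, and flags every (project, period, domain) where the three raw
#' ratings spread by 2 or more rubric points -- a major discrepancy to be
#' resolved by consensus review, never auto-resolved.
#'
#' @inheritParams aggregate_raters
#' @param threshold Reliability target; kappas below it are marked
#'   (default 0.75).
#' @param scheme Kappa weighting scheme, `"quadratic"` or `"linear"`.
#' @return An object of class `cti_reliability`: a list with tibbles
#'   `kappas` (rater pair x domain), `pooled` (rater pair, all domains
#'   stacked), and `flags` (major discrepancies), plus the scheme and
#'   threshold used. `tidy()` returns the per-domain kappa table.
#' @examples
#' r <- generate_rating_fixtures(n_projects = 6, agreement = "high", seed = 2)
#' reliability_report(r)
#' @export
reliability_report <- function(ratings, threshold = 0.75,
                               scheme = c("quadratic", "linear")) {
  scheme <- match.arg(scheme)
  ratings <- tibble::as_tibble(ratings)
  validate_ratings(ratings)
  n_raters <- ratings |>
    dplyr::count(.data$project_id, .data$period) |>
    dplyr::filter(.data$n < 2)
  if (nrow(n_raters) > 0) {
    abort(sprintf("project %s, period %s has fewer than 2 raters.",
                  n_raters$project_id[1], n_raters$period[1]))
  }

  raters <- sort(unique(ratings$rater))
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  wide <- ratings |>
    tidyr::pivot_longer(dplyr::all_of(domain_cols), names_to = "domain",
                        values_to = "rating") |>
    tidyr::pivot_wider(names_from = "rater", values_from = "rating")

  pair_kappa <- function(pair, dom = NULL) {
    sub <- if (is.null(dom)) wide else dplyr::filter(wide, .data$domain == dom)
    x <- sub[[pair[1]]]
    y <- sub[[pair[2]]]
    keep <- stats::complete.cases(x, y)
    if (sum(keep) < 2) return(NA_real_)
    suppressWarnings(weighted_kappa(x[keep], y[keep], scheme = scheme))
  }

  kappas <- tidyr::expand_grid(
    pair = purrr::map_chr(pairs, paste, collapse = "-"),
    domain = domain_cols
  ) |>
    dplyr::mutate(
      kappa = purrr::map2_dbl(.data$pair, .data$domain,
                              ~ pair_kappa(strsplit(.x, "-")[[1]], .y)),
      below_target = !is.na(.data$kappa) & .data$kappa < threshold
    )

  pooled <- tibble::tibble(
    pair = purrr::map_chr(pairs, paste, collapse = "-"),
    kappa = purrr::map_dbl(pairs, pair_kappa),
  ) |>
    dplyr::mutate(below_target = !is.na(.data$kappa) & .data$kappa < threshold)

  flags <- ratings |>
    tidyr::pivot_longer(dplyr::all_of(domain_cols), names_to = "domain",
                        values_to = "rating") |>
    dplyr::group_by(.data$project_id, .data$period, .data$domain) |>
    dplyr::summarise(spread = max(.data$rating) - min(.data$rating),
                     .groups = "drop") |>
    dplyr::filter(.data$spread >= 2)

  structure(
    list(kappas = kappas, pooled = pooled, flags = flags,
         scheme = scheme, threshold = threshold),
    class = "cti_reliability"
  )
}

#' @export
print.cti_reliability <- function(x, ...) {
  cat(sprintf("CTI inter-rater reliability (%s-weighted kappa, target >= %.2f)\n",
              x$scheme, x$threshold))
  cat(sprintf("  pooled kappas: %s\n",
              paste(sprintf("%s %.3f", x$pooled$pair, x$pooled$kappa),
                    collapse = ", ")))
  cat(sprintf("  domains below target: %d of %d; major discrepancies flagged: %d\n",
              sum(x$kappas$below_target, na.rm = TRUE), nrow(x$kappas),
              nrow(x$flags)))
  invisible(x)
}

#' @rdname reliability_report
#' @param x A `cti_reliability` object.
#' @param ... Unused.
#' @export
tidy.cti_reliability <- function(x, ...) x$kappas
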