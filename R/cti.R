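#' Domain weights for the Community Transmission Index
#'
#' The CTI is a weighted sum of eight normalized domain scores (D1 shared
#' governance, D2 bidirectional accountability, D3 data transparency,
#' D4 participatory data governance, D5 feedback closure, D6 co-production,
#' D7 trust capital, D8 equity integration). Two presets are shipped:
#' `"default"` (the balanced-drivetrain weights) and `"equity_forward"`,
#' which raises D8 to 0.20 and shrinks D2, D3 and D4 by a common factor so
#' the weights still sum to one.
#'
#' @param preset `"default"`, `"equity_forward"`, or `"custom"` (with `values`).
#' @param values For `preset = "custom"`, a numeric vector of 8 nonnegative
#'   weights summing to 1 (named `D1`..`D8` or in that order).
#' @return A named numeric vector of length 8 summing to 1.
#' @examples
#' cti_weights()
#' cti_weights("equity_forward")
#' @export
cti_weights <- function(preset = c("default", "equity_forward", "custom"),
                        values = NULL) {
  preset <- match.arg(preset)
  w <- c(D1 = 0.16, D2 = 0.10, D3 = 0.12, D4 = 0.10,
         D5 = 0.16, D6 = 0.12, D7 = 0.12, D8 = 0.12)
  if (preset == "equity_forward") {
    # D8 rises to 0.20; the 0.08 increase is taken from the D2-D4 pool
    # proportionally (common factor 0.24/0.32 = 0.75)
    pool <- c("D2", "D3", "D4")
    scale <- (sum(w[pool]) - (0.20 - w[["D8"]])) / sum(w[pool])
    w[pool] <- w[pool] * scale
    w[["D8"]] <- 0.20
  } else if (preset == "custom") {
    if (is.null(values)) {
      abort("`values` must be supplied when preset = \"custom\".")
    }
    values <- as.numeric(values)
    if (length(values) != 8) abort("custom weights must have length 8.")
    w[] <- values
  }
  validate_domain_weights(w)
  w
}

validate_domain_weights <- function(w) {
  if (length(w) != 8 || anyNA(w)) abort("domain weights must be 8 finite values.")
  if (any(w < 0)) abort("domain weights must be nonnegative.")
  if (abs(sum(w) - 1) > 1e-9) {
    abort(sprintf("domain weights must sum to 1 (got %.12f).", sum(w)))
  }
  invisible(w)
}

domain_cols <- paste0("D", 1:8)

#' Normalize a 0-4 rubric rating to the unit interval
#'
#' @param r Integer rating(s) in `{0, 1, 2, 3, 4}`.
#' @param context Optional label (project/domain/rater) used in error messages.
#' @return `r / 4`, exactly.
#' @examples
#' normalize_rating(3) # 0.75
#' @export
normalize_rating <- function(r, context = NULL) {
  if (length(r) == 0 || anyNA(r) || !all(r %in% 0:4)) {
    bad <- r[is.na(r) | !(r %in% 0:4)]
    abort(paste0(
      "ratings must be integers in {0,...,4}; got ",
      paste(utils::head(bad, 3L), collapse = ", "),
      if (!is.null(context)) paste0(" [", context, "]") else ""
    ))
  }
  as.numeric(r) / 4
}

validate_ratings <- function(ratings, require_full_panel = FALSE) {
  required <- c("project_id", "period", "rater", domain_cols)
  missing <- setdiff(required, names(ratings))
  if (length(missing) > 0) {
    abort(paste0("ratings are missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_rater <- setdiff(unique(ratings$rater), c("A", "H", "C"))
  if (length(bad_rater) > 0) {
    abort(paste0("unknown rater tag(s): ", paste(bad_rater, collapse = ", "),
                 " (expected A, H, C)."))
  }
  for (d in domain_cols) {
    v <- ratings[[d]]
    bad <- which(is.na(v) | !(v %in% 0:4) | v != round(v))
    if (length(bad) > 0) {
      i <- bad[1]
      abort(sprintf(
        "invalid rating %s in domain %s (project %s, period %s, rater %s).",
        as.character(v[i]), d, ratings$project_id[i], ratings$period[i],
        ratings$rater[i]))
    }
  }
  dup <- ratings |>
    dplyr::count(.data$project_id, .data$period, .data$rater) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate rater sheet: project %s, period %s, rater %s.",
                  dup$project_id[1], dup$period[1], dup$rater[1]))
  }
  if (require_full_panel) {
    panel <- ratings |>
      dplyr::count(.data$project_id, .data$period) |>
      dplyr::filter(.data$n != 3)
    if (nrow(panel) > 0) {
      abort(sprintf(
        "project %s, period %s has %d rater sheet(s); exactly one each of A, H, C is required.",
        panel$project_id[1], panel$period[1], panel$n[1]))
    }
  }
  invisible(ratings)
}

#' Aggregate the three rater sheets of a project/period into domain scores
#'
#' Each domain is rated 0-4 independently by an academic (A), a health-system
#' (H) and a community (C) evaluator; ratings are normalized to `[0, 1]` and
#' averaged across the three raters.
#'
#' @param ratings A data frame with columns
#'   `project_id, period, rater, D1..D8`, holding exactly one row per rater
#'   tag A, H, C for each project/period.
#' @return A tibble with one row per project/period and columns `S1..S8`,
#'   each in `[0, 1]`.
#' @examples
#' r <- generate_rating_fixtures(n_projects = 2, seed = 1)
#' aggregate_raters(r)
#' @export
aggregate_raters <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  validate_ratings(ratings, require_full_panel = TRUE)
  out <- ratings |>
    dplyr::group_by(.data$project_id, .data$period) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(domain_cols),
                                   ~ mean(.x / 4)),
                     .groups = "drop")
  names(out)[match(domain_cols, names(out))] <- paste0("S", 1:8)
  out
}

#' Composite CTI from domain scores
#'
#' `CTI = sum_d w_d * S_d` over the eight domains; lies in `[0, 1]` for valid
#' weights and scores.
#'
#' @param S Numeric vector of 8 domain scores in `[0, 1]` (or a matrix with 8
#'   columns, one row per project).
#' @param weights Domain weights from [cti_weights()].
#' @return The weighted sum (one value per row of `S`).
#' @examples
#' composite_cti(c(1, 0.75, 0.5, 0.75, 1, 0.5, 0.75, 0.25)) # 0.71
#' @export
composite_cti <- function(S, weights = cti_weights()) {
  validate_domain_weights(weights)
  if (is.matrix(S) || is.data.frame(S)) {
    S <- as.matrix(S)
    if (ncol(S) != 8) abort("`S` must have 8 columns (one per domain).")
  } else {
    if (length(S) != 8) abort("`S` must have 8 domain scores.")
    S <- matrix(S, nrow = 1)
  }
  if (anyNA(S) || any(S < 0 | S > 1)) abort("domain scores must lie in [0, 1].")
  drop(S %*% as.numeric(weights))
}

#' Classify a CTI value into its maturity band
#'
#' Bands are left-closed: `[0, 0.25)` Transactional, `[0.25, 0.50)` Advisory,
#' `[0.50, 0.70)` Collaborative, `[0.70, 0.85)` SharedGovernance,
#' `[0.85, 1.00]` CommunityAnchored.
#'
#' @param cti Numeric CTI value(s) in `[0, 1]`.
#' @return A factor with the five band levels.
#' @examples
#' classify_cti_band(c(0, 0.25, 0.849, 1))
#' @export
classify_cti_band <- function(cti) {
  if (anyNA(cti) || any(cti < 0 | cti > 1)) {
    abort("CTI values must lie in [0, 1].")
  }
  cut(cti, breaks = cti_band_cuts, labels = cti_band_levels,
      right = FALSE, include.lowest = TRUE)
}

#' Score the CTI instrument from multi-rater rating sheets
#'
#' The full scoring pipeline: validate the rating sheets, normalize each 0-4
#' rating to `[0, 1]`, average the three raters per domain, apply the domain
#' weights and classify the maturity band.
#'
#' @inheritParams aggregate_raters
#' @param weights Domain weights ([cti_weights()]); fixed for the scoring run.
#' @return A tibble with columns
#'   `project_id, period, S1..S8, cti, band`.
#' @examples
#' generate_rating_fixtures(n_projects = 3, seed = 7) |> score_cti()
#' @export
score_cti <- function(ratings, weights = cti_weights()) {
  scores <- aggregate_raters(ratings)
  S <- as.matrix(scores[paste0("S", 1:8)])
  scores |>
    dplyr::mutate(cti = composite_cti(S, weights),
                  band = classify_cti_band(.data$cti))
}
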