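ratings_header <- c("project_id", "period", "rater", paste0("D", 1:8))

#' Read CTI rating sheets from CSV
#'
#' The file must carry the exact header
#' `project_id,period,rater,D1,D2,D3,D4,D5,D6,D7,D8` with rater tags in
#' `{A, H, C}` and integer rating cells in `{0,...,4}`. Malformed rows are
#' rejected with their line number.
#'
#' @param path Path to the ratings CSV.
#' @return A tibble of validated rating sheets (possibly empty, with a
#'   warning, for a header-only file).
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) abort(sprintf("ratings file not found: %s", path))
  header <- strsplit(readr::read_lines(path, n_max = 1), ",")[[1]]
  if (!identical(header, ratings_header)) {
    abort(paste0("malformed header: expected ",
                 paste(ratings_header, collapse = ","), "."))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warn(sprintf("ratings file is empty (header only): %s", path))
    out <- tibble::as_tibble(stats::setNames(
      c(list(character(0), character(0), character(0)),
        rep(list(integer(0)), 8)), ratings_header))
    return(out)
  }
  # line number in the file = data row + header line
  line <- seq_len(nrow(raw)) + 1L
  bad_rater <- which(!raw$rater %in% c("A", "H", "C"))
  if (length(bad_rater) > 0) {
    i <- bad_rater[1]
    abort(sprintf("line %d: unknown rater tag \"%s\" (expected A, H, C).",
                  line[i], raw$rater[i]))
  }
  for (d in paste0("D", 1:8)) {
    v <- suppressWarnings(as.numeric(raw[[d]]))
    bad <- which(is.na(v) | v != round(v) | v < 0 | v > 4)
    if (length(bad) > 0) {
      i <- bad[1]
      abort(sprintf("line %d: invalid rating \"%s\" in %s (must be an integer 0-4).",
                    line[i], raw[[d]][i], d))
    }
    raw[[d]] <- as.integer(v)
  }
  validate_ratings(raw)
  raw
}

#' Write CTI scores to CSV
#'
#' Columns: `project_id, period, S1..S8, cti, band`.
#'
#' @param scores Output of [score_cti()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cti_scores <- function(scores, path) {
  scores <- dplyr::mutate(scores, band = as.character(.data$band))
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}

#' Read a milestone-weight table from CSV
#'
#' Expects columns `milestone,clinical,education,research,governance` with
#' one row per milestone; every row of wheel weights must sum to 1.
#'
#' @param path Path to the CSV (the canonical table ships at
#'   `system.file("extdata", "milestone_weights.csv", package = "lhsdrive")`).
#' @return A validated milestone-weight tibble.
#' @export
read_milestone_weights <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  mw <- readr::read_csv(path, col_types = "cdddd", progress = FALSE)
  validate_milestone_weights(mw)
}

#' Generate synthetic CTI rating fixtures
#'
#' Emulates multi-rater scoring sheets with controllable inter-rater
#' agreement and an optional target maturity band; reproducible under a
#' seed. Each project/period receives one sheet per rater (A, H, C): a base
#' 0-4 rating per domain consistent with the project's target CTI, perturbed
#' per rater according to the agreement regime.
#'
#' @param n_projects Number of projects.
#' @param n_periods Number of quarterly periods per project.
#' @param agreement `"perfect"` (identical raters), `"high"` (occasional
#'   one-point deviations), or `"low"` (frequent deviations up to 2 points).
#' @param band_target Optional band name (e.g. `"CommunityAnchored"`): the
#'   generated composite CTI (default weights) is guaranteed to fall in that
#'   band.
#' @param seed Optional integer seed.
#' @return A ratings tibble (columns `project_id, period, rater, D1..D8`).
#' @export
generate_rating_fixtures <- function(n_projects, n_periods = 1,
                                     agreement = c("high", "perfect", "low"),
                                     band_target = NULL, seed = NULL) {
  agreement <- match.arg(agreement)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(band_target) && !band_target %in% cti_band_levels) {
    abort(paste0("`band_target` must be one of: ",
                 paste(cti_band_levels, collapse = ", ")))
  }
  target_range <- if (is.null(band_target)) c(0.05, 0.95) else {
    i <- match(band_target, cti_band_levels)
    c(cti_band_cuts[i], cti_band_cuts[i + 1])
  }
  perturb <- function(base) {
    delta <- switch(agreement,
                    perfect = rep(0L, 8),
                    high = sample(c(-1L, 0L, 1L), 8, replace = TRUE,
                                  prob = c(0.1, 0.8, 0.1)),
                    low = sample(-2:2, 8, replace = TRUE,
                                 prob = c(0.1, 0.2, 0.4, 0.2, 0.1)))
    pmin(pmax(base + delta, 0L), 4L)
  }
  one_sheet <- function(project, period) {
    for (try in 1:200) {
      target <- stats::runif(1, target_range[1], target_range[2])
      base <- pmin(pmax(as.integer(round(
        target * 4 + stats::rnorm(8, 0, 0.5))), 0L), 4L)
      sheets <- purrr::map(c("A", "H", "C"), function(r) {
        tibble::tibble(project_id = project, period = period, rater = r) |>
          dplyr::bind_cols(stats::setNames(as.list(perturb(base)),
                                           paste0("D", 1:8)))
      }) |> purrr::list_rbind()
      cti <- score_cti(sheets)$cti
      ok <- if (is.null(band_target)) TRUE else {
        as.character(classify_cti_band(cti)) == band_target
      }
      if (ok) return(sheets)
    }
    abort("could not generate a sheet matching the target band.")
  }
  grid <- tidyr::expand_grid(
    project = sprintf("P%03d", seq_len(n_projects)),
    period = sprintf("2026-Q%d", seq_len(n_periods))
  )
  purrr::map2(grid$project, grid$period, one_sheet) |> purrr::list_rbind()
}

#' Write a complete fixture set (ratings CSV + config YAML)
#'
#' @inheritParams generate_rating_fixtures
#' @param dir Output directory (created if needed).
#' @param cfg Configuration to ship alongside the ratings.
#' @return Invisibly, the paths written (`ratings`, `config`).
#' @export
generate_fixtures <- function(dir, n_projects = 6, n_periods = 1,
                              agreement = "high", band_target = NULL,
                              seed = 1, cfg = default_lhs_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ratings <- generate_rating_fixtures(n_projects, n_periods,
                                      agreement = agreement,
                                      band_target = band_target, seed = seed)
  ratings_path <- file.path(dir, "ratings.csv")
  readr::write_csv(ratings, ratings_path, progress = FALSE)
  config_path <- file.path(dir, "config.yaml")
  write_lhs_config(cfg, config_path)
  invisible(list(ratings = ratings_path, config = config_path))
}
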