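#' Mission weights over the four LHS cycles
#'
#' Nonnegative weights `alpha_j` summing to 1 used in the weighted-mean system
#' velocity, TEI-B and (by default) the TEI-G norm.
#'
#' @param alpha Numeric vector of 4 nonnegative weights summing to 1.
#' @return A validated named numeric vector.
#' @export
mission_weights <- function(alpha = rep(0.25, 4)) {
  alpha <- as.numeric(alpha)
  if (length(alpha) != 4 || anyNA(alpha)) abort("`alpha` must be 4 finite values.")
  if (any(alpha < 0)) abort("mission weights must be nonnegative.")
  if (abs(sum(alpha) - 1) > 1e-9) abort("mission weights must sum to 1.")
  stats::setNames(alpha, lhs_cycles)
}

#' Translational velocity from latency
#'
#' Velocity is the inverse of the latency to scale or sustainment: a latency
#' of 1 month is a velocity of 1 month^-1, 5 months is 0.2 month^-1.
#'
#' @param latency_months Positive latency (months), vectorized.
#' @return Velocity in month^-1.
#' @export
velocity_from_latency <- function(latency_months) {
  if (anyNA(latency_months) || any(latency_months <= 0)) {
    abort("latency must be positive (months).")
  }
  1 / latency_months
}

tei_w_norm <- function(x, weights, norm) {
  switch(norm,
         euclidean = sqrt(sum(weights * x^2)),
         l1 = sum(weights * abs(x)))
}

#' Gain-based translational efficiency index (TEI-G)
#'
#' The amplification produced by cross-cycle learning spillovers:
#' `TEI-G = ||v||_W / ||f||_W`, the ratio of weighted norms of the coupled
#' velocities to the direct drives. Equals 1 when coupling has no effect and
#' is at least 1 whenever `v` was produced from `f` by a nonnegative
#' spillover matrix. The default norm is the weighted Euclidean norm
#' `sqrt(sum(W_j x_j^2))` with `W` the mission weights; a weighted 1-norm is
#' selectable (for which TEI-G is a ratio of weighted means).
#'
#' @param v Coupled velocities (4-vector).
#' @param f Direct drives (4-vector), not all zero.
#' @param weights Mission weights ([mission_weights()]).
#' @param norm `"euclidean"` (default) or `"l1"`.
#' @return A single nonnegative ratio.
#' @export
tei_gain <- function(v, f, weights = mission_weights(),
                     norm = c("euclidean", "l1")) {
  norm <- match.arg(norm)
  weights <- mission_weights(weights)
  if (length(v) != 4 || length(f) != 4) abort("`v` and `f` must have length 4.")
  nf <- tei_w_norm(f, weights, norm)
  if (nf == 0) abort("TEI-G is undefined: direct drive has zero weighted norm.")
  tei_w_norm(v, weights, norm) / nf
}

#' Bottleneck translational efficiency index (TEI-B)
#'
#' The degree to which the system is constrained by its slowest learning
#' cycle: `TEI-B = min_j(v_j) / sum_j(alpha_j v_j)`. At most 1, with equality
#' exactly when all cycle velocities are equal (for strictly positive
#' weights).
#'
#' @param v Positive cycle velocities (4-vector).
#' @inheritParams tei_gain
#' @return A ratio in `(0, 1]`.
#' @export
tei_bottleneck <- function(v, weights = mission_weights()) {
  weights <- mission_weights(weights)
  if (length(v) != 4) abort("`v` must have length 4.")
  if (anyNA(v) || any(v <= 0)) abort("all cycle velocities must be positive.")
  min(v) / sum(weights * v)
}

#' Global translational efficiency index
#'
#' `TEI = TEI-G x TEI-B`: amplification from spillovers discounted by the
#' drivetrain bottleneck.
#'
#' @param tei_g,tei_b Nonnegative efficiency indices (vectorized).
#' @return Their product.
#' @examples
#' tei(1.495, 0.833)
#' @export
tei <- function(tei_g, tei_b) {
  if (anyNA(tei_g) || anyNA(tei_b) || any(tei_g < 0) || any(tei_b < 0)) {
    abort("`tei_g` and `tei_b` must be nonnegative.")
  }
  tei_g * tei_b
}

#' System-level velocity summaries
#'
#' The bottleneck speed (the drivetrain-limiting wheel, `min_j v_j`) and the
#' mission-weighted mean speed `sum_j alpha_j v_j`.
#'
#' @inheritParams tei_bottleneck
#' @return A tibble with columns `bottleneck` and `weighted_mean`.
#' @export
system_velocities <- function(v, weights = mission_weights()) {
  weights <- mission_weights(weights)
  if (length(v) != 4 || anyNA(v)) abort("`v` must be 4 finite velocities.")
  tibble::tibble(bottleneck = min(v), weighted_mean = sum(weights * v))
}

#' Percentile-anchor scaling of a velocity
#'
#' Rescales a velocity against institutional or national 5th/95th percentile
#' anchors: `(V - q5) / (q95 - q5)`. Values outside `[0, 1]` (beyond the
#' anchors) are returned unclamped, with a warning and an `out_of_range`
#' attribute marking them.
#'
#' @param V Velocity value(s).
#' @param q5,q95 The 5th and 95th percentile anchors, `q95 > q5`.
#' @return Scaled value(s) with attribute `out_of_range`.
#' @export
scale_percentile <- function(V, q5, q95) {
  if (!is.finite(q5) || !is.finite(q95) || q95 <= q5) {
    abort("degenerate anchors: `q95` must exceed `q5`.")
  }
  out <- (V - q5) / (q95 - q5)
  oor <- out < 0 | out > 1
  if (any(oor)) {
    warn(sprintf("%d scaled velocity value(s) fall outside the [q5, q95] anchors.",
                 sum(oor)))
  }
  attr(out, "out_of_range") <- oor
  out
}

#' Typology thresholds on the (TEI-G, TEI-B) plane
#'
#' @param teig_cut,teib_cut Fixed cut values (required for `mode = "fixed"`);
#'   ignored in `"median-split"` mode, where the cuts are the cohort medians.
#' @param mode `"median-split"` (default, used for cohort analyses) or
#'   `"fixed"`.
#' @return A list of class `typology_thresholds`.
#' @export
typology_thresholds <- function(teig_cut = NULL, teib_cut = NULL,
                                mode = c("median-split", "fixed")) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(teig_cut) || is.null(teib_cut) ||
        !is.finite(teig_cut) || !is.finite(teib_cut) ||
        teig_cut <= 0 || teib_cut <= 0) {
      abort("fixed mode requires positive `teig_cut` and `teib_cut`.")
    }
  }
  structure(list(teig_cut = teig_cut, teib_cut = teib_cut, mode = mode),
            class = "typology_thresholds")
}

#' Classify LHS state from efficiency indices
#'
#' Partitions the (TEI-G, TEI-B) plane into the four LHS states: Fragmented
#' (low gain, low balance), Emerging (high gain, low balance -- spillover-rich
#' but constrained by a slow wheel), Functional (low gain, high balance --
#' balanced but weakly coupled), and FullyIntegrated (high gain, high
#' balance). Values at or above a cut classify as "high".
#'
#' @param scores A data frame with columns `tei_g` and `tei_b` (e.g. a
#'   portfolio from [simulate_portfolio()]).
#' @param thresholds A [typology_thresholds()]; in `"median-split"` mode the
#'   cuts are the medians of the supplied cohort (which must have at least
#'   2 rows).
#' @return `scores` with an added factor column `state`.
#' @export
classify_typology <- function(scores, thresholds = typology_thresholds()) {
  stopifnot(inherits(thresholds, "typology_thresholds"))
  scores <- tibble::as_tibble(scores)
  if (!all(c("tei_g", "tei_b") %in% names(scores))) {
    abort("`scores` must have columns `tei_g` and `tei_b`.")
  }
  if (thresholds$mode == "median-split") {
    if (nrow(scores) < 2) {
      abort("median-split mode requires a cohort of at least 2.")
    }
    gcut <- stats::median(scores$tei_g)
    bcut <- stats::median(scores$tei_b)
  } else {
    gcut <- thresholds$teig_cut
    bcut <- thresholds$teib_cut
  }
  high_g <- scores$tei_g >= gcut
  high_b <- scores$tei_b >= bcut
  state <- dplyr::case_when(
    high_g & high_b ~ "FullyIntegrated",
    high_g & !high_b ~ "Emerging",
    !high_g & high_b ~ "Functional",
    TRUE ~ "Fragmented"
  )
  scores$state <- factor(state, levels = lhs_state_levels)
  scores
}

#' Hub-level gain efficiency
#'
#' The hub summary of TEI-G is the median over all projects and periods.
#'
#' @param per_project_teig Nonempty numeric vector of project/period TEI-G
#'   values.
#' @return The median.
#' @export
hub_tei_g <- function(per_project_teig) {
  if (length(per_project_teig) == 0 || anyNA(per_project_teig)) {
    abort("`per_project_teig` must be a nonempty vector without NA.")
  }
  stats::median(per_project_teig)
}

#' Milestone-to-wheel interpretation weights
#'
#' Eight canonical translational milestones (K1 community priority
#' identification through K8 sustained integration), each distributing its
#' contribution across the four LHS wheels with row-stochastic weights.
#' Early stages are dominated by research and governance, mid-stages by
#' clinical and education, and sustainment by governance.
#'
#' @return A tibble with columns
#'   `milestone, clinical, education, research, governance`; rows sum to 1.
#' @export
milestone_weights <- function() {
  mw <- tibble::tribble(
    ~milestone, ~clinical, ~education, ~research, ~governance,
    "K1", 0.20, 0.15, 0.25, 0.40,
    "K2", 0.10, 0.25, 0.50, 0.15,
    "K3", 0.05, 0.05, 0.70, 0.20,
    "K4", 0.45, 0.20, 0.25, 0.10,
    "K5", 0.35, 0.30, 0.25, 0.10,
    "K6", 0.25, 0.15, 0.20, 0.40,
    "K7", 0.50, 0.20, 0.15, 0.15,
    "K8", 0.30, 0.20, 0.15, 0.35
  )
  validate_milestone_weights(mw)
}

validate_milestone_weights <- function(mw) {
  mw <- tibble::as_tibble(mw)
  required <- c("milestone", lhs_cycles)
  if (!identical(names(mw), required)) {
    abort(paste0("milestone weights must have columns ",
                 paste(required, collapse = ", "), "."))
  }
  m <- as.matrix(mw[lhs_cycles])
  if (anyNA(m) || any(m < 0)) abort("milestone weights must be nonnegative.")
  bad <- which(abs(rowSums(m) - 1) > 1e-9)
  if (length(bad) > 0) {
    abort(sprintf("milestone weight row %s does not sum to 1 (sum %.12f).",
                  mw$milestone[bad[1]], rowSums(m)[bad[1]]))
  }
  mw
}

#' Attribute milestone latencies to the four wheels
#'
#' Wheel `j` receives `sum_k m_kj * latency_k`; because each milestone's
#' weights sum to 1, the total attributed latency equals the total observed
#' latency (conservation).
#'
#' @param milestone_latencies Numeric vector of 8 nonnegative latencies
#'   (days or months), in milestone order K1..K8.
#' @param mw A milestone-weight table ([milestone_weights()]).
#' @return A named numeric 4-vector of wheel-attributed latency.
#' @export
attribute_milestones <- function(milestone_latencies, mw = milestone_weights()) {
  mw <- validate_milestone_weights(mw)
  if (length(milestone_latencies) != nrow(mw) || anyNA(milestone_latencies) ||
      any(milestone_latencies < 0)) {
    abort(sprintf("`milestone_latencies` must be %d nonnegative values.",
                  nrow(mw)))
  }
  drop(milestone_latencies %*% as.matrix(mw[lhs_cycles]))
}
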