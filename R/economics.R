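#' Economic coefficients of the four LHS cycles
#'
#' Parameterizes the innovation, revenue and cost functions. Innovation
#' throughput is linear in velocity, `N_j = max(0, b0_j + b1_j v_j)`.
#' Revenue is `R_j = rho0_j + rho1_j v_j + rho2_j N_j` (abstract dollars per
#' period) and cost is
#' `E_j = kappa0_j + kappa1_j v_j + kappa_p PDCA_p + kappa_d PDCA_d + kappa_i PDCA_i`,
#' the simplest parameterized forms consistent with monotone
#' return-on-investment in velocity. PDCA phase intensities (practice, data
#' analysis, implementation) default to unit intensity.
#'
#' @param b0,b1 Innovation intercept and slope per wheel (length 4; counts
#'   per unit velocity).
#' @param rho0,rho1,rho2 Revenue coefficients per wheel (length 4; $).
#' @param kappa0,kappa1 Base and velocity-linked cost per wheel (length 4; $).
#' @param kappa_p,kappa_d,kappa_i Cost per unit PDCA phase intensity
#'   (scalars; $).
#' @param pdca PDCA phase intensities, a named vector `c(p=, d=, i=)`.
#' @return A validated list of class `econ_params`.
#' @export
econ_params <- function(b0 = rep(0, 4), b1 = c(8, 6, 7, 5),
                        rho0 = rep(0, 4),
                        rho1 = c(22000, 16000, 20000, 15000),
                        rho2 = c(2600, 2200, 2500, 2300),
                        kappa0 = c(9000, 7000, 9000, 7000),
                        kappa1 = c(6000, 5000, 6000, 5000),
                        kappa_p = 500, kappa_d = 500, kappa_i = 500,
                        pdca = c(p = 1, d = 1, i = 1)) {
  vec4 <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) == 1) x <- rep(x, 4)
    if (length(x) != 4 || anyNA(x)) abort(sprintf("`%s` must be 4 finite values.", nm))
    x
  }
  p <- list(b0 = vec4(b0, "b0"), b1 = vec4(b1, "b1"),
            rho0 = vec4(rho0, "rho0"), rho1 = vec4(rho1, "rho1"),
            rho2 = vec4(rho2, "rho2"),
            kappa0 = vec4(kappa0, "kappa0"), kappa1 = vec4(kappa1, "kappa1"),
            kappa_p = as.numeric(kappa_p), kappa_d = as.numeric(kappa_d),
            kappa_i = as.numeric(kappa_i),
            pdca = c(p = unname(pdca["p"]), d = unname(pdca["d"]),
                     i = unname(pdca["i"])))
  if (anyNA(p$pdca) || any(p$pdca < 0)) abort("PDCA intensities must be nonnegative.")
  if (any(c(p$rho0, p$rho1, p$rho2, p$kappa0, p$kappa1,
            p$kappa_p, p$kappa_d, p$kappa_i) < 0)) {
    abort("revenue and cost coefficients must be nonnegative.")
  }
  structure(p, class = "econ_params")
}

#' Innovation throughput from cycle velocities
#'
#' `N_j = max(0, b0_j + b1_j v_j)`: expected innovation counts per period,
#' reported as reals so downstream correlations stay smooth.
#'
#' @param v Cycle velocities: a 4-vector or a matrix with 4 columns.
#' @param params An [econ_params()].
#' @return Innovation counts in the shape of `v`.
#' @export
innovation_throughput <- function(v, params = econ_params()) {
  stopifnot(inherits(params, "econ_params"))
  vec <- is.null(dim(v))
  vm <- if (vec) matrix(v, nrow = 1) else as.matrix(v)
  if (ncol(vm) != 4) abort("`v` must have 4 cycle entries.")
  N <- pmax(sweep(sweep(vm, 2, params$b1, "*"), 2, params$b0, "+"), 0)
  colnames(N) <- lhs_cycles
  if (vec) drop(N) else N
}

#' Per-wheel and global economics of a project
#'
#' Computes revenue `R_j`, expense `E_j` and `ROI_j = R_j / E_j` for each
#' wheel, plus global sums and the global `ROI = R / E` (ratio of summed
#' revenue to summed expense).
#'
#' @param v Cycle velocities (4-vector).
#' @param N Innovation counts (4-vector), e.g. from
#'   [innovation_throughput()].
#' @param params An [econ_params()].
#' @return A list of class `econ_result` with elements `N`, `revenue`,
#'   `expense`, `roi` (per-wheel vectors) and `global_N`, `global_revenue`,
#'   `global_expense`, `global_roi`.
#' @export
wheel_economics <- function(v, N = innovation_throughput(v, params),
                            params = econ_params()) {
  stopifnot(inherits(params, "econ_params"))
  if (length(v) != 4 || length(N) != 4) abort("`v` and `N` must have length 4.")
  if (anyNA(v) || anyNA(N) || any(v < 0) || any(N < 0)) {
    abort("velocities and innovation counts must be nonnegative.")
  }
  revenue <- params$rho0 + params$rho1 * v + params$rho2 * N
  pdca_cost <- params$kappa_p * params$pdca[["p"]] +
    params$kappa_d * params$pdca[["d"]] +
    params$kappa_i * params$pdca[["i"]]
  expense <- params$kappa0 + params$kappa1 * v + pdca_cost
  if (any(expense == 0 & revenue > 0)) {
    abort("undefined ROI: zero expense with nonzero revenue.")
  }
  roi <- ifelse(expense > 0, revenue / expense, 0)
  ge <- sum(expense)
  structure(list(
    N = stats::setNames(N, lhs_cycles),
    revenue = stats::setNames(revenue, lhs_cycles),
    expense = stats::setNames(expense, lhs_cycles),
    roi = stats::setNames(roi, lhs_cycles),
    global_N = sum(N),
    global_revenue = sum(revenue),
    global_expense = ge,
    global_roi = if (ge > 0) sum(revenue) / ge else 0
  ), class = "econ_result")
}

#' Incremental translational efficiency dV/dE
#'
#' Velocity gain per unit additional expense: the change in mission-weighted
#' mean velocity divided by the change in expense.
#'
#' @param v_before,v_after Cycle velocities (4-vectors).
#' @param e_before,e_after Total expenses ($), `e_after != e_before`.
#' @param weights Mission weights ([mission_weights()]).
#' @return `(vbar_after - vbar_before) / (e_after - e_before)` in month^-1
#'   per dollar.
#' @export
incremental_efficiency <- function(v_before, v_after, e_before, e_after,
                                   weights = mission_weights()) {
  weights <- mission_weights(weights)
  if (length(v_before) != 4 || length(v_after) != 4) {
    abort("velocity vectors must have length 4.")
  }
  de <- e_after - e_before
  if (!is.finite(de) || de == 0) abort("zero expense change: dV/dE undefined.")
  (sum(weights * v_after) - sum(weights * v_before)) / de
}
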