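config_blocks <- c("seed", "transmission", "wheels", "coupling", "cti_beta",
                   "engine", "friction_env", "economics", "mission_weights",
                   "tei_norm", "typology", "monte_carlo")

#' Default run configuration
#'
#' The shipped study conditions for the deterministic and Monte Carlo
#' simulation protocols: transmission constants, per-wheel velocity caps,
#' the spillover matrix, sampling distributions for project CTI (beta) and
#' engine/friction resources (log-normal), economic coefficients,
#' mission weights, typology mode, and the Monte Carlo design
#' (500 iterations, rounded-normal(25, 3) projects per iteration, uniform
#' hyperparameter ranges, a stochastic coupling scale). Velocity caps and
#' economic coefficients were calibrated once so that the default portfolio's
#' mean CTI sits near 0.52 and mean cycle velocities near 0.59-0.75 month^-1;
#' the calibration rationale is described in the package vignette.
#'
#' @return A nested list of class `lhs_config`.
#' @export
default_lhs_config <- function() {
  cfg <- list(
    seed = 20260422L,
    transmission = list(a = 10, m0 = 0.5, r_max = 0.6, eta = 2, c = 0.5),
    wheels = list(v_max = c(clinical = 1.40, education = 1.13,
                            research = 1.39, governance = 1.26)),
    coupling = list(K = unname(apply(default_coupling_matrix(), 1, as.list,
                                     simplify = FALSE))),
    cti_beta = list(shape1 = 2.2, shape2 = 2.0),
    engine = list(meanlog = rep(0, 4), sdlog = rep(0.3, 4)),
    friction_env = list(meanlog = rep(0, 4), sdlog = rep(0.3, 4)),
    economics = list(b0 = rep(0, 4), b1 = c(8, 6, 7, 5),
                     rho0 = rep(0, 4),
                     rho1 = c(27000, 20000, 25000, 18500),
                     rho2 = c(3200, 2700, 3100, 2850),
                     kappa0 = c(9600, 7500, 9600, 7500),
                     kappa1 = c(6400, 5300, 6400, 5300),
                     kappa_p = 530, kappa_d = 530, kappa_i = 530,
                     pdca = c(p = 1, d = 1, i = 1)),
    mission_weights = rep(0.25, 4),
    tei_norm = "euclidean",
    typology = list(mode = "median-split", teig_cut = NULL, teib_cut = NULL),
    monte_carlo = list(
      n_iterations = 500L,
      n_projects = list(mean = 25, sd = 3),
      hyper_ranges = list(a = c(6, 14), m0 = c(0.4, 0.6),
                          r_max = c(0.4, 0.8), eta = c(1.5, 3),
                          c = c(0.3, 0.7)),
      k_scale_range = c(0.5, 1.5)
    )
  )
  validate_lhs_config(cfg)
}

#' Validate a run configuration
#'
#' Checks every block against its owning module's invariants before any
#' computation; unknown keys are errors, not warnings.
#'
#' @param cfg A configuration list (e.g. from [read_lhs_config()]).
#' @return The validated `lhs_config` object, invisibly usable downstream.
#' @export
validate_lhs_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_blocks)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(config_blocks, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("config is missing block(s): ", paste(missing, collapse = ", ")))
  }
  do.call(transmission_params, cfg$transmission)
  if (length(cfg$wheels$v_max) != 4 || any(cfg$wheels$v_max <= 0)) {
    abort("`wheels$v_max` must be 4 positive velocities.")
  }
  coupling_matrix(cfg$coupling$K)
  with(cfg$cti_beta, {
    if (shape1 <= 0 || shape2 <= 0) abort("beta shapes must be positive.")
  })
  for (blk in c("engine", "friction_env")) {
    b <- cfg[[blk]]
    if (length(b$meanlog) != 4 || length(b$sdlog) != 4 || any(b$sdlog <= 0)) {
      abort(sprintf("`%s` must supply 4 log-means and 4 positive log-sds.", blk))
    }
  }
  do.call(econ_params, cfg$economics)
  mission_weights(cfg$mission_weights)
  if (!cfg$tei_norm %in% c("euclidean", "l1")) {
    abort("`tei_norm` must be \"euclidean\" or \"l1\".")
  }
  typology_thresholds(cfg$typology$teig_cut, cfg$typology$teib_cut,
                      mode = cfg$typology$mode)
  mc <- cfg$monte_carlo
  if (mc$n_iterations < 1) abort("`n_iterations` must be >= 1.")
  if (is.list(mc$n_projects)) {
    if (is.null(mc$n_projects$mean) || is.null(mc$n_projects$sd) ||
        mc$n_projects$mean < 1 || mc$n_projects$sd < 0) {
      abort("`n_projects` spec needs mean >= 1 and sd >= 0.")
    }
  } else if (mc$n_projects < 0) {
    abort("`n_projects` must be >= 0.")
  }
  for (nm in names(mc$hyper_ranges)) {
    r <- mc$hyper_ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      abort(sprintf("hyper range `%s` must be (low, high) with low <= high.", nm))
    }
  }
  ks <- mc$k_scale_range
  if (length(ks) != 2 || ks[1] > ks[2] || ks[1] < 0) {
    abort("`k_scale_range` must be nonnegative (low, high).")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort("`seed` must be a single integer.")
  }
  structure(cfg, class = "lhs_config")
}

#' Read and write run configurations (YAML)
#'
#' @param path File path of the YAML configuration.
#' @return `read_lhs_config()` returns a validated `lhs_config`;
#'   `write_lhs_config()` writes `cfg` and returns `path` invisibly.
#' @export
read_lhs_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  # yaml returns vectors of length 1 as scalars and nested K as list of lists
  for (blk in c("engine", "friction_env")) {
    cfg[[blk]]$meanlog <- as.numeric(unlist(cfg[[blk]]$meanlog))
    cfg[[blk]]$sdlog <- as.numeric(unlist(cfg[[blk]]$sdlog))
  }
  cfg$wheels$v_max <- stats::setNames(as.numeric(unlist(cfg$wheels$v_max)),
                                      lhs_cycles)
  cfg$economics <- lapply(cfg$economics, unlist)
  if (!is.null(cfg$economics$pdca)) {
    cfg$economics$pdca <- stats::setNames(as.numeric(cfg$economics$pdca),
                                          c("p", "d", "i"))
  }
  cfg$mission_weights <- as.numeric(unlist(cfg$mission_weights))
  if (is.list(cfg$monte_carlo$n_projects) &&
      !is.null(cfg$monte_carlo$n_projects$mean)) {
    # keep as spec list
  } else {
    cfg$monte_carlo$n_projects <- as.numeric(unlist(cfg$monte_carlo$n_projects))
  }
  cfg$monte_carlo$hyper_ranges <- lapply(cfg$monte_carlo$hyper_ranges,
                                         as.numeric)
  cfg$monte_carlo$k_scale_range <- as.numeric(unlist(cfg$monte_carlo$k_scale_range))
  validate_lhs_config(cfg)
}

#' @rdname read_lhs_config
#' @param cfg A validated `lhs_config`.
#' @export
write_lhs_config <- function(cfg, path) {
  cfg <- validate_lhs_config(cfg)
  out <- unclass(cfg)
  out$wheels$v_max <- as.numeric(out$wheels$v_max)
  out$economics <- lapply(out$economics, function(x) as.numeric(x))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Content hash of a resolved configuration
#'
#' Used in run logs so outputs can be traced to the exact configuration.
#'
#' @param cfg An `lhs_config`.
#' @return A short hash string.
#' @export
config_hash <- function(cfg) {
  rlang::hash(unclass(validate_lhs_config(cfg)))
}

config_coupling <- function(cfg) coupling_matrix(cfg$coupling$K)
config_params <- function(cfg) do.call(transmission_params, cfg$transmission)
config_econ <- function(cfg) do.call(econ_params, as.list(cfg$economics))
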