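#' Draw transmission hyperparameters and a coupling scale
#'
#' At the start of a Monte Carlo iteration the five transmission constants
#' (`a`, `m0`, `r_max`, `eta`, `c`) are drawn from independent uniform
#' distributions over their configured ranges, and a stochastic scale factor
#' for the spillover matrix is drawn from its own uniform range. Uses the
#' current RNG state; callers seed it for reproducibility.
#'
#' @param cfg An `lhs_config` (see [default_lhs_config()]).
#' @return A list with elements `params` ([transmission_params()]) and
#'   `k_scale` (numeric scale for the coupling matrix).
#' @export
sample_hyperparameters <- function(cfg = default_lhs_config()) {
  hr <- cfg$monte_carlo$hyper_ranges
  draw <- function(nm) stats::runif(1, hr[[nm]][1], hr[[nm]][2])
  params <- transmission_params(a = draw("a"), m0 = draw("m0"),
                                r_max = draw("r_max"), eta = draw("eta"),
                                c = draw("c"))
  ks <- cfg$monte_carlo$k_scale_range
  list(params = params, k_scale = stats::runif(1, ks[1], ks[2]))
}

#' Scale the coupling matrix with stability enforcement
#'
#' Multiplies `K` elementwise by `factor`. If the scaled matrix would have a
#' spectral radius of 1 or more, it is rescaled down to a spectral radius of
#' 0.95 and flagged (`attr(., "stability_enforced")`), so no iteration ever
#' proceeds with an unstable coupling.
#'
#' @param K_base A [coupling_matrix()].
#' @param factor Positive scale factor.
#' @return The scaled (and, if needed, stabilized) coupling matrix with a
#'   logical attribute `stability_enforced`.
#' @export
scale_coupling <- function(K_base, factor) {
  if (!is.finite(factor) || factor < 0) abort("`factor` must be nonnegative.")
  K <- as.matrix(K_base) * factor
  rho <- spectral_radius(K)
  enforced <- FALSE
  if (rho >= 1) {
    K <- K * (0.95 / rho)
    enforced <- TRUE
  }
  K <- coupling_matrix(K)
  attr(K, "stability_enforced") <- enforced
  K
}

draw_n_projects <- function(spec) {
  if (is.list(spec)) {
    max(1L, as.integer(round(stats::rnorm(1, spec$mean, spec$sd))))
  } else {
    as.integer(spec)
  }
}

# vectorized economics over a portfolio (rows = projects); the scalar
# wheel_economics() presents the same formulas for a single project
portfolio_economics <- function(vm, econ) {
  Nm <- innovation_throughput(vm, econ)
  if (is.null(dim(Nm))) Nm <- matrix(Nm, nrow = 1)
  rev <- sweep(sweep(vm, 2, econ$rho1, "*"), 2, econ$rho0, "+") +
    sweep(Nm, 2, econ$rho2, "*")
  pdca_cost <- econ$kappa_p * econ$pdca[["p"]] +
    econ$kappa_d * econ$pdca[["d"]] + econ$kappa_i * econ$pdca[["i"]]
  exp_ <- sweep(sweep(vm, 2, econ$kappa1, "*"), 2, econ$kappa0 + pdca_cost, "+")
  list(N = Nm, revenue = rev, expense = exp_)
}

#' Simulate a portfolio of translational projects
#'
#' For each project: draw a CTI maturity `M` from the configured beta
#' distribution and per-wheel engine power and contextual friction from
#' log-normal distributions; compute the direct drives `f`, the coupled
#' velocities `v = (I - K)^-1 f`, the efficiency indices (TEI-G, TEI-B,
#' TEI), the LHS state, and the economic outcomes. Deterministic given the
#' RNG state (use `seed` for a self-contained reproducible call).
#'
#' @param n_projects Number of projects (0 gives an empty portfolio).
#' @param cfg An `lhs_config`.
#' @param params Transmission parameters; defaults to the config block.
#' @param K Coupling matrix; defaults to the config block.
#' @param econ Economic parameters; defaults to the config block.
#' @param seed Optional integer seed applied before sampling.
#' @return A tibble with one row per project: `project, cti, band, f1..f4,
#'   v1..v4, tei_g, tei_b, tei, bottleneck, vmean, state, N1..N4, R1..R4,
#'   E1..E4, revenue, expense, roi`.
#' @examples
#' simulate_portfolio(5, seed = 1)
#' @export
simulate_portfolio <- function(n_projects, cfg = default_lhs_config(),
                               params = NULL, K = NULL, econ = NULL,
                               seed = NULL) {
  cfg <- validate_lhs_config(cfg)
  params <- params %||% config_params(cfg)
  K <- coupling_matrix(K %||% config_coupling(cfg))
  econ <- econ %||% config_econ(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_projects)
  if (n < 0) abort("`n_projects` must be nonnegative.")
  w <- mission_weights(cfg$mission_weights)
  norm <- cfg$tei_norm

  if (n == 0) {
    return(empty_portfolio())
  }

  M <- stats::rbeta(n, cfg$cti_beta$shape1, cfg$cti_beta$shape2)
  E <- sapply(1:4, function(j) stats::rlnorm(n, cfg$engine$meanlog[j],
                                             cfg$engine$sdlog[j]))
  F_ <- sapply(1:4, function(j) stats::rlnorm(n, cfg$friction_env$meanlog[j],
                                              cfg$friction_env$sdlog[j]))
  E <- matrix(E, nrow = n)
  F_ <- matrix(F_, nrow = n)
  vmax <- matrix(rep(as.numeric(cfg$wheels$v_max), each = n), nrow = n)

  alloc <- wheel_allocation(E, F_, vmax)
  f <- wheel_drive(M, alloc, params)
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  v <- coupled_velocities(f, K)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)

  wnorm <- function(x) {
    if (norm == "euclidean") sqrt(drop(x^2 %*% w)) else drop(abs(x) %*% w)
  }
  tei_g <- wnorm(v) / wnorm(f)
  vbar <- drop(v %*% w)
  tei_b <- apply(v, 1, min) / vbar
  ec <- portfolio_economics(v, econ)
  revenue <- rowSums(ec$revenue)
  expense <- rowSums(ec$expense)

  out <- tibble::tibble(
    project = seq_len(n),
    cti = M,
    band = classify_cti_band(M)
  )
  add_mat <- function(out, m, prefix) {
    colnames(m) <- paste0(prefix, 1:4)
    dplyr::bind_cols(out, tibble::as_tibble(m))
  }
  out <- add_mat(out, f, "f")
  out <- add_mat(out, v, "v")
  out <- out |>
    dplyr::mutate(tei_g = tei_g, tei_b = tei_b, tei = tei_g * tei_b,
                  bottleneck = apply(v, 1, min), vmean = vbar)
  thr <- typology_thresholds(cfg$typology$teig_cut, cfg$typology$teib_cut,
                             mode = cfg$typology$mode)
  out <- classify_typology(out, thr)
  out <- add_mat(out, ec$N, "N")
  out <- add_mat(out, ec$revenue, "R")
  out <- add_mat(out, ec$expense, "E")
  out |>
    dplyr::mutate(revenue = revenue, expense = expense,
                  roi = revenue / expense)
}

empty_portfolio <- function() {
  cols <- c("project", "cti", "band", paste0("f", 1:4), paste0("v", 1:4),
            "tei_g", "tei_b", "tei", "bottleneck", "vmean", "state",
            paste0("N", 1:4), paste0("R", 1:4), paste0("E", 1:4),
            "revenue", "expense", "roi")
  out <- tibble::as_tibble(stats::setNames(
    lapply(cols, function(x) numeric(0)), cols))
  out$project <- integer(0)
  out$band <- factor(character(0), levels = cti_band_levels)
  out$state <- factor(character(0), levels = lhs_state_levels)
  out
}

iteration_summary <- function(projects, w) {
  p <- projects
  spearman <- function(x, y) suppressWarnings(stats::cor(x, y, method = "spearman"))
  pearson <- function(x, y) suppressWarnings(stats::cor(x, y))
  props <- prop.table(table(p$state))
  tibble::tibble(
    n_projects = nrow(p),
    mean_cti = mean(p$cti),
    mean_v1 = mean(p$v1), mean_v2 = mean(p$v2),
    mean_v3 = mean(p$v3), mean_v4 = mean(p$v4),
    mean_bottleneck = mean(p$bottleneck),
    mean_vmean = mean(p$vmean),
    median_tei_g = stats::median(p$tei_g),
    median_tei_b = stats::median(p$tei_b),
    median_tei = stats::median(p$tei),
    total_N = sum(p$N1 + p$N2 + p$N3 + p$N4),
    total_revenue = sum(p$revenue),
    total_expense = sum(p$expense),
    roi_ratio_of_means = sum(p$revenue) / sum(p$expense),
    roi_mean_of_ratios = mean(p$roi),
    cor_cti_tei = pearson(p$cti, p$tei),
    cor_cti_roi = pearson(p$cti, p$roi),
    spearman_cti_tei = spearman(p$cti, p$tei),
    spearman_cti_roi = spearman(p$cti, p$roi),
    prop_fragmented = unname(props["Fragmented"]),
    prop_emerging = unname(props["Emerging"]),
    prop_functional = unname(props["Functional"]),
    prop_fully_integrated = unname(props["FullyIntegrated"])
  )
}

#' Run the Monte Carlo uncertainty simulation
#'
#' Each iteration draws transmission hyperparameters from uniform ranges and
#' a stochastic coupling scale (stability-enforced), simulates a portfolio of
#' projects (each deterministic given the iteration's parameters and draws),
#' and records iteration-level summaries: median efficiency indices, mean
#' velocities, innovation and financial totals, CTI-TEI and CTI-ROI
#' correlations, and LHS state proportions. Cross-iteration aggregates
#' report mean, SD, median and the 2.5th-97.5th percentile simulation
#' interval of every summary.
#'
#' Reproducibility: one master seed generates an independent child seed per
#' iteration, so iteration results do not depend on execution order and two
#' runs with the same seed and configuration are identical.
#'
#' @param cfg An `lhs_config`.
#' @param seed Master seed (defaults to `cfg$seed`).
#' @param n_iterations,n_projects Optional overrides of the config's Monte
#'   Carlo design (`n_projects` may be a count or a
#'   `list(mean =, sd =)` rounded-normal spec).
#' @return An object of class `lhs_mc`: a list with tibbles `projects`
#'   (every project record, with its iteration), `iterations` (one summary
#'   row per iteration), `summary` (cross-iteration aggregates),
#'   `state_proportions` (pooled over all records), and the `seed` and
#'   `config_hash` of the run.
#' @examples
#' mc <- run_monte_carlo(n_iterations = 5, n_projects = 20, seed = 1)
#' glance(mc)
#' @export
run_monte_carlo <- function(cfg = default_lhs_config(), seed = NULL,
                            n_iterations = NULL, n_projects = NULL) {
  cfg <- validate_lhs_config(cfg)
  seed <- as.integer(seed %||% cfg$seed)
  n_iter <- as.integer(n_iterations %||% cfg$monte_carlo$n_iterations)
  np_spec <- n_projects %||% cfg$monte_carlo$n_projects
  if (n_iter < 1) abort("`n_iterations` must be >= 1.")
  hash <- config_hash(cfg)
  message(sprintf("lhsdrive montecarlo: seed=%d config=%s iterations=%d",
                  seed, hash, n_iter))

  set.seed(seed)
  # independent draws (with replacement) so the seed stream for iteration i
  # does not depend on how many iterations follow it
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter, replace = TRUE)
  K_base <- config_coupling(cfg)
  econ <- config_econ(cfg)
  w <- mission_weights(cfg$mission_weights)

  one_iteration <- function(i) {
    set.seed(iter_seeds[i])
    hp <- sample_hyperparameters(cfg)
    K <- scale_coupling(K_base, hp$k_scale)
    n_p <- draw_n_projects(np_spec)
    projects <- simulate_portfolio(n_p, cfg, params = hp$params, K = K,
                                   econ = econ)
    s <- iteration_summary(projects, w) |>
      dplyr::mutate(iteration = i, k_scale = hp$k_scale,
                    stability_enforced = attr(K, "stability_enforced"),
                    a = hp$params$a, m0 = hp$params$m0,
                    r_max = hp$params$r_max, eta = hp$params$eta,
                    c = hp$params$c, .before = 1)
    list(projects = dplyr::mutate(projects, iteration = i, .before = 1),
         summary = s)
  }

  res <- purrr::map(seq_len(n_iter), one_iteration)
  projects <- purrr::list_rbind(purrr::map(res, "projects"))
  iterations <- purrr::list_rbind(purrr::map(res, "summary"))

  stat_cols <- setdiff(names(iterations),
                       c("iteration", "stability_enforced"))
  if (n_iter == 1) {
    warn("single iteration: cross-iteration SD is undefined and intervals collapse to the point.")
  }
  summary <- iterations |>
    tidyr::pivot_longer(dplyr::all_of(stat_cols), names_to = "statistic",
                        values_to = "value") |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (dplyr::n() > 1) stats::sd(.data$value, na.rm = TRUE) else NA_real_,
      median = stats::median(.data$value, na.rm = TRUE),
      q025 = stats::quantile(.data$value, 0.025, na.rm = TRUE, names = FALSE),
      q975 = stats::quantile(.data$value, 0.975, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )

  state_proportions <- projects |>
    dplyr::count(.data$state, .drop = FALSE) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))

  structure(
    list(projects = projects, iterations = iterations, summary = summary,
         state_proportions = state_proportions, seed = seed,
         config_hash = hash, n_iterations = n_iter, n_projects_spec = np_spec),
    class = "lhs_mc"
  )
}

#' @export
print.lhs_mc <- function(x, ...) {
  cat(sprintf("LHS Monte Carlo run: %d iterations, %d project records (seed %d, config %s)\n",
              x$n_iterations, nrow(x$projects), x$seed, x$config_hash))
  med <- function(st) x$summary$median[x$summary$statistic == st]
  cat(sprintf("  median TEI-G %.3f, TEI-B %.3f, TEI %.3f; mean CTI %.3f\n",
              med("median_tei_g"), med("median_tei_b"), med("median_tei"),
              med("mean_cti")))
  cat("  state proportions: ",
      paste(sprintf("%s %.1f%%", x$state_proportions$state,
                    100 * x$state_proportions$proportion), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname run_monte_carlo
#' @param x An `lhs_mc` object.
#' @param ... Unused.
#' @export
tidy.lhs_mc <- function(x, ...) x$summary

#' @rdname run_monte_carlo
#' @export
glance.lhs_mc <- function(x, ...) {
  med <- function(st) x$summary$median[x$summary$statistic == st]
  tibble::tibble(
    n_iterations = x$n_iterations,
    n_projects = nrow(x$projects),
    median_tei_g = med("median_tei_g"),
    median_tei_b = med("median_tei_b"),
    median_tei = med("median_tei"),
    mean_cti = med("mean_cti"),
    roi_ratio_of_means = med("roi_ratio_of_means"),
    roi_mean_of_ratios = med("roi_mean_of_ratios"),
    prop_fully_integrated = with(x$state_proportions,
                                 proportion[state == "FullyIntegrated"])
  )
}
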