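#' Fit the cytokine production model to a donor-paired panel
#'
#' Estimates production levels, edge strengths and the global
#' half-saturation constant of a [network_config()] by least squares on
#' log10 concentrations.  Observations are donor-averaged (geometric mean)
#' endpoint concentrations per condition and analyte; the objective is
#' \deqn{\sum_{i,c} [\log_{10}(obs_{ic} + \epsilon) -
#'   \log_{10}(sim_{ic} + \epsilon)]^2,}
#' minimised by bounded quasi-Newton local search
#' ([stats::nlminb()]) from Latin-hypercube multi-starts.
#'
#' In `steady_state` mode the 16-hour endpoint is approximated by the
#' model fixed point (degradation rates then cancel and are not free
#' parameters); `timecourse` mode integrates the ODE to `T` hours and
#' additionally estimates per-node degradation rates.
#'
#' @param config A [network_config()].
#' @param panel Panel `data.frame` (columns `donor_id`, `condition_id`,
#'   `analyte`, `concentration_pg_ml`) covering the modelled analytes
#'   under at least two of `conditions`.
#' @param conditions Named list of [condition()] objects; names must match
#'   `condition_id` values.
#' @param mode `"steady_state"` (default, fast) or `"timecourse"`.
#' @param n_restarts Number of optimisation starts (first is a data-driven
#'   heuristic, the rest Latin-hypercube draws; default 16).
#' @param seed Integer seed for the multi-start draws (recorded).
#' @param start Optional named vector of log10 parameter values used as an
#'   additional warm start (names as in `$par_names`).
#' @param epsilon Detection floor added before taking log10 (pg/mL).
#' @param rss_floor Per-observation floor applied to the RSS inside the
#'   AIC (numerical resolution of the log10 residuals; default `1e-8`,
#'   i.e. 1e-4 log10 units per observation).
#' @param T Horizon in hours (timecourse mode).
#' @param receptor_map See [default_receptor_map()].
#' @param control Passed to [stats::nlminb()] (merged over defaults).
#' @return An object of class `cytokine_fit` with components `params`
#'   (natural scale), `rss`, `n_obs`, `k`, `aic`, `aicc`, `converged`,
#'   `n_restarts`, `seed` and the fitted log10 concentration matrix.
#' @seealso [rank_models()], [edge_weights()], [mediation_analysis()]
#' @export
fit_network <- function(config, panel, conditions,
                        mode = c("steady_state", "timecourse"),
                        n_restarts = 16, seed = NULL, start = NULL,
                        epsilon = 1, rss_floor = 1e-8, T = 16,
                        receptor_map = default_receptor_map(),
                        control = list()) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "network_config"))
  assert_panel(panel)
  conditions <- conditions[names(conditions) %in% unique(panel$condition_id)]
  if (length(conditions) < 2)
    stop("panel must cover the modelled analytes under at least two conditions")

  nodes <- config$nodes
  obslog <- aggregate_panel_log10(panel, nodes, names(conditions), epsilon)
  stim <- vapply(conditions, function(cc) cc$stimulus != "none", logical(1))

  # parameter layout (all free parameters live on log10 scale)
  elab <- edge_labels(config$edges)
  par_names <- c(
    if (any(!stim)) paste0("s0.", nodes),
    if (any(stim)) paste0("sL.", nodes),
    if (mode == "timecourse") paste0("delta.", nodes),
    if (length(elab)) paste0("w.", elab),
    "K")
  k <- length(par_names)
  lower <- rep(-2, k); upper <- rep(6, k)
  lower[grepl("^w\\.", par_names)] <- -4; upper[grepl("^w\\.", par_names)] <- 3
  lower[grepl("^delta\\.", par_names)] <- -1.3
  upper[grepl("^delta\\.", par_names)] <- 1
  lower[par_names == "K"] <- -1; upper[par_names == "K"] <- 5
  names(lower) <- names(upper) <- par_names

  n_obs <- sum(!is.na(obslog))
  if (n_obs <= k)
    stop("model not identifiable: ", n_obs, " observations for ", k,
         " free parameters")

  cm <- condition_matrices(config,
                           model_params(stats::setNames(rep(1, length(nodes)), nodes),
                                        stats::setNames(rep(1, length(nodes)), nodes),
                                        stats::setNames(rep(1, length(nodes)), nodes),
                                        rep(1, nrow(config$edges)), 1),
                           conditions, receptor_map)

  theta_to_params <- function(theta) {
    v <- 10^theta
    names(v) <- par_names
    s0 <- if (any(!stim)) v[paste0("s0.", nodes)] else stats::setNames(rep(0, length(nodes)), nodes)
    sL <- if (any(stim)) v[paste0("sL.", nodes)] else stats::setNames(rep(0, length(nodes)), nodes)
    delta <- if (mode == "timecourse") v[paste0("delta.", nodes)] else
      stats::setNames(rep(1, length(nodes)), nodes)
    names(s0) <- names(sL) <- names(delta) <- nodes
    w <- if (length(elab)) unname(v[paste0("w.", elab)]) else numeric()
    model_params(s0 = s0, sL = sL, delta = delta,
                 w = stats::setNames(w, elab), K = unname(v["K"]))
  }

  gradient <- NULL
  objective <- if (mode == "steady_state") {
    # analytic adjoint gradient on the log10 parameter scale
    gradient <- function(theta) {
      p <- theta_to_params(theta)
      s <- matrix(0, length(nodes), length(conditions))
      s[, stim] <- p$sL; s[, !stim] <- p$s0
      gr <- .ss_rss_grad_cpp(s, cm$esrc, cm$edst, cm$esign, unname(p$w),
                             p$K, cm$dose, cm$blocked, cm$clamp, obslog,
                             epsilon)
      g <- stats::setNames(numeric(k), par_names)
      ln10 <- log(10)
      if (any(!stim))
        g[paste0("s0.", nodes)] <-
          rowSums(gr$g_s[, !stim, drop = FALSE]) * p$s0 * ln10
      if (any(stim))
        g[paste0("sL.", nodes)] <-
          rowSums(gr$g_s[, stim, drop = FALSE]) * p$sL * ln10
      if (length(elab)) g[paste0("w.", elab)] <- gr$g_w * unname(p$w) * ln10
      g["K"] <- gr$g_K * p$K * ln10
      g
    }
    function(theta) {
      p <- theta_to_params(theta)
      s <- matrix(0, length(nodes), length(conditions))
      s[, stim] <- p$sL; s[, !stim] <- p$s0
      .ss_rss_cpp(s, cm$esrc, cm$edst, cm$esign, unname(p$w), p$K,
                  cm$dose, cm$blocked, cm$clamp, obslog, epsilon)
    }
  } else {
    # initial state: added doses on their modelled nodes
    C0 <- matrix(0, length(nodes), length(conditions))
    for (cc in seq_along(conditions)) {
      add <- intersect(names(conditions[[cc]]$additions), nodes)
      C0[match(add, nodes), cc] <- conditions[[cc]]$additions[add]
    }
    function(theta) {
      p <- theta_to_params(theta)
      s <- matrix(0, length(nodes), length(conditions))
      s[, stim] <- p$sL; s[, !stim] <- p$s0
      beta <- s * p$delta[nodes]
      h <- min(0.05, 0.25 / max(p$delta))
      .tc_rss_cpp(beta, unname(p$delta[nodes]), cm$esrc, cm$edst, cm$esign,
                  unname(p$w), p$K, cm$dose, cm$blocked, cm$clamp, C0,
                  T, h, obslog, epsilon)
    }
  }

  # data-driven heuristic start
  heur <- stats::setNames(numeric(k), par_names)
  mean_level <- function(cols) {
    m <- rowMeans(obslog[, cols, drop = FALSE], na.rm = TRUE)
    pmin(pmax(log10(pmax(10^m - epsilon, 0.01)), lower[1]), 6)
  }
  if (any(!stim)) heur[paste0("s0.", nodes)] <- mean_level(which(!stim))
  if (any(stim)) heur[paste0("sL.", nodes)] <- mean_level(which(stim))
  if (mode == "timecourse") heur[paste0("delta.", nodes)] <- 0
  if (length(elab)) heur[paste0("w.", elab)] <- 0
  heur["K"] <- stats::median(obslog, na.rm = TRUE)

  starts <- list(heur)
  if (!is.null(start)) {
    s1 <- heur
    common <- intersect(names(start), par_names)
    s1[common] <- pmin(pmax(start[common], lower[common]), upper[common])
    starts <- c(list(s1), starts)
  }
  n_lhs <- max(0L, n_restarts - length(starts))
  if (n_lhs > 0) {
    u <- with_seed(seed, lhs::randomLHS(n_lhs, k))
    for (r in seq_len(n_lhs))
      starts[[length(starts) + 1L]] <-
        stats::setNames(lower + u[r, ] * (upper - lower), par_names)
  }

  ctrl <- utils::modifyList(
    list(iter.max = 500, eval.max = 4000, rel.tol = 1e-10), control)
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::nlminb(st, objective, gradient = gradient,
                    lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimisation starts failed")

  theta <- stats::setNames(best$par, par_names)
  params <- theta_to_params(theta)
  rss <- best$objective
  converged <- is.finite(rss) && rss < 1e5
  sim <- simulate_network(config, params, conditions, mode = mode, T = T,
                          receptor_map = receptor_map)
  fittedlog <- log10(sim + epsilon)
  aic <- n_obs * log(max(rss, n_obs * rss_floor) / n_obs) + 2 * k
  aicc <- if (n_obs - k - 1 > 0) aic + 2 * k * (k + 1) / (n_obs - k - 1) else NA_real_

  structure(list(config = config, conditions = conditions, mode = mode,
                 params = params, theta = theta, par_names = par_names,
                 rss = rss, n_obs = n_obs, k = k, aic = aic, aicc = aicc,
                 converged = converged, n_restarts = length(starts),
                 seed = seed, epsilon = epsilon, rss_floor = rss_floor,
                 T = T, receptor_map = receptor_map,
                 obs = obslog, fitted_log10 = fittedlog),
            class = "cytokine_fit")
}

# Donor-averaged log10(conc + eps) matrix: geometric-mean aggregation.
aggregate_panel_log10 <- function(panel, analytes, condition_ids, epsilon) {
  panel <- panel[panel$analyte %in% analytes &
                 panel$condition_id %in% condition_ids, , drop = FALSE]
  out <- matrix(NA_real_, length(analytes), length(condition_ids),
                dimnames = list(analytes, condition_ids))
  if (!nrow(panel)) return(out)
  lg <- log10(panel$concentration_pg_ml + epsilon)
  agg <- tapply(lg, list(factor(panel$analyte, analytes),
                         factor(panel$condition_id, condition_ids)),
                mean)
  out[] <- agg
  out
}

#' @export
print.cytokine_fit <- function(x, ...) {
  cat("Cytokine network model fit (", x$mode, " mode)\n", sep = "")
  cat("  edges:", if (nrow(x$config$edges))
    paste(edge_labels(x$config$edges), collapse = ", ") else "(none)", "\n")
  cat(sprintf("  RSS = %.6g on %d observations, k = %d, AIC = %.2f\n",
              x$rss, x$n_obs, x$k, x$aic))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.cytokine_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cytokine_fit")
}

#' @export
print.summary.cytokine_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nParameters (natural scale):\n")
  print(f$params)
  cat(sprintf("\nAICc = %.2f; restarts = %d; seed = %s\n", f$aicc,
              f$n_restarts, f$seed %||% "NULL"))
  invisible(x)
}

#' @export
coef.cytokine_fit <- function(object, ...) {
  stats::setNames(10^object$theta, object$par_names)
}

#' Predict endpoint concentrations from a fitted network model
#'
#' @param object A `cytokine_fit`.
#' @param conditions Named list of [condition()] objects (defaults to the
#'   fitted conditions).
#' @param mode Simulation mode (defaults to the fit's mode).
#' @param clamp Optional named numeric of clamped node concentrations.
#' @param ... Unused.
#' @return Matrix of predicted concentrations (pg/mL), nodes x conditions.
#' @export
predict.cytokine_fit <- function(object, conditions = NULL, mode = NULL,
                                 clamp = NULL, ...) {
  conditions <- conditions %||% object$conditions
  mode <- mode %||% object$mode
  simulate_network(object$config, object$params, conditions, mode = mode,
                   T = object$T, receptor_map = object$receptor_map,
                   clamp = clamp)
}

#' @export
fitted.cytokine_fit <- function(object, ...) {
  pmax(10^object$fitted_log10 - object$epsilon, 0)
}

#' @export
residuals.cytokine_fit <- function(object, ...) {
  object$obs - object$fitted_log10
}

#' Simulate donor panels from a fitted network model
#'
#' Draws synthetic donor-paired panels from the fitted model with
#' multiplicative lognormal noise, mirroring the synthetic cohort
#' generator.
#'
#' @param object A `cytokine_fit`.
#' @param nsim Number of panels.
#' @param seed Integer seed.
#' @param n_donors Donors per panel.
#' @param noise_sd Lognormal sigma on measurements.
#' @param donor_effect_sd Lognormal sigma of the shared per-donor scale.
#' @param conditions Conditions to simulate (default: fitted conditions).
#' @param ... Unused.
#' @return A panel `data.frame`, or a list of them if `nsim > 1`.
#' @export
simulate.cytokine_fit <- function(object, nsim = 1, seed = NULL,
                                  n_donors = 8, noise_sd = 0.3,
                                  donor_effect_sd = 0.2,
                                  conditions = NULL, ...) {
  conditions <- conditions %||% object$conditions
  gt <- fit_to_ground_truth(object)
  out <- with_seed(seed, lapply(seq_len(nsim), function(i) {
    spec <- cohort_spec(n_donors = n_donors, conditions = conditions,
                        noise_sd = noise_sd,
                        donor_effect_sd = donor_effect_sd,
                        mode = object$mode)
    simulate_cohort_panel(gt, spec)
  }))
  if (nsim == 1) out[[1]] else out
}

# Reconstruct a ground-truth-network view of a fitted model.
fit_to_ground_truth <- function(fit) {
  p <- fit$params
  edges <- fit$config$edges
  if (nrow(edges)) edges$strength <- unname(p$w)
  ground_truth_network(
    fit$config$nodes, edges,
    basal_unstim = p$s0 * p$delta,
    basal_stim = pmax(p$sL - p$s0, 0) * p$delta,
    degradation = p$delta,
    half_saturation = p$K,
    exogenous = fit$config$exogenous)
}

#' @export
plot.cytokine_fit <- function(x, ...) {
  obs <- as.vector(x$obs); fit <- as.vector(x$fitted_log10)
  ok <- !is.na(obs)
  plot(fit[ok], obs[ok],
       xlab = "fitted log10(concentration + eps)",
       ylab = "observed log10(concentration + eps)",
       main = "Cytokine network fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
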