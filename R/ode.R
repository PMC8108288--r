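#' Model parameters for the cytokine production ODE
#'
#' The production model for node i is
#' \deqn{dC_i/dt = \beta_i(cond) \prod_{(j \to i,+)} (1 + w_e h(\tilde C_j))
#'   \prod_{(j \to i,-)} \frac{1}{1 + w_e h(\tilde C_j)} - \delta_i C_i}
#' with saturating regulation \eqn{h(C) = C / (K + C)}.  The effective
#' upstream signal \eqn{\tilde C_j} is the node concentration plus any
#' exogenous dose, and is zero when the ligand (or its receptor) is
#' blocked.  Basal production is \eqn{\beta_i = \delta_i s^0_i} without
#' stimulus and \eqn{\delta_i s^L_i} with an active stimulus.
#'
#' Parameters are stored as steady levels (`s0`, `sL`, pg/mL), which are
#' the natural scale for 16-hour endpoint data; production rates are
#' recovered as level times degradation.
#'
#' @param s0 Named per-node unstimulated steady level (pg/mL).
#' @param sL Named per-node stimulated steady level (pg/mL).
#' @param delta Named per-node degradation rate (1/h), > 0.
#' @param w Per-edge regulation strength (>= 0), in configuration edge
#'   order.
#' @param K Global half-saturation constant (pg/mL), > 0.
#' @return An object of class `model_params`.
#' @export
model_params <- function(s0, sL, delta, w, K) {
  if (any(s0 < 0) || any(sL < 0)) stop("steady levels must be non-negative")
  if (any(delta <= 0)) stop("degradation rates must be strictly positive")
  if (any(w < 0)) stop("edge strengths must be non-negative")
  if (K <= 0) stop("half-saturation K must be strictly positive")
  structure(list(s0 = s0, sL = sL, delta = delta, w = w, K = K),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Cytokine model parameters (K =", format(x$K, digits = 4), "pg/mL)\n")
  print(round(data.frame(s0 = x$s0, sL = x$sL, delta = x$delta), 4))
  if (length(x$w)) {
    cat("edge strengths:\n")
    print(round(x$w, 4))
  }
  invisible(x)
}

# Assemble per-condition matrices consumed by the steady-state kernel and
# the ODE right-hand side.  Sources are ordered c(nodes, exogenous).
condition_matrices <- function(config, params, conditions,
                               receptor_map = default_receptor_map(),
                               clamp = NULL) {
  nodes <- config$nodes
  sources <- c(nodes, config$exogenous)
  n <- length(nodes); m <- length(sources); nc <- length(conditions)
  if (is.null(names(conditions)))
    names(conditions) <- paste0("condition_", seq_len(nc))
  s <- matrix(0, n, nc, dimnames = list(nodes, names(conditions)))
  dose <- matrix(0, m, nc, dimnames = list(sources, names(conditions)))
  blocked <- matrix(0L, m, nc, dimnames = list(sources, names(conditions)))
  clampm <- matrix(NA_real_, n, nc, dimnames = list(nodes, names(conditions)))
  for (c in seq_len(nc)) {
    cond <- conditions[[c]]
    stopifnot(inherits(cond, "culture_condition"))
    unknown <- setdiff(names(cond$additions), sources)
    if (length(unknown))
      stop("condition adds unknown cytokine: ", paste(unknown, collapse = ", "))
    bl <- blocked_ligands(cond, receptor_map)
    unknown <- setdiff(bl, sources)
    if (length(unknown))
      stop("condition blocks unknown cytokine: ", paste(unknown, collapse = ", "))
    stim <- cond$stimulus != "none"
    s[, c] <- if (stim) params$sL[nodes] else params$s0[nodes]
    dose[names(cond$additions), c] <- cond$additions
    blocked[bl, c] <- 1L
  }
  if (!is.null(clamp)) {
    unknown <- setdiff(names(clamp), nodes)
    if (length(unknown))
      stop("cannot clamp unknown node: ", paste(unknown, collapse = ", "))
    clampm[names(clamp), ] <- clamp
  }
  edges <- config$edges
  list(s = s, dose = dose, blocked = blocked, clamp = clampm,
       esrc = match(edges$source, sources), edst = match(edges$target, nodes),
       esign = as.integer(edges$sign), w = as.numeric(params$w), K = params$K,
       nodes = nodes, sources = sources)
}

#' Time-derivative function of the cytokine network
#'
#' Returns the right-hand side of the production ODE for one condition,
#' suitable for [deSolve::lsoda()] (and used internally by
#' [simulate_network()] in timecourse mode).
#'
#' @inheritParams simulate_network
#' @param cond A single [condition()].
#' @return A function `f(t, C, ...)` returning `list(dC)`.
#' @export
network_rhs <- function(config, params, cond,
                        receptor_map = default_receptor_map(), clamp = NULL) {
  cm <- condition_matrices(config, params, list(cond), receptor_map, clamp)
  n <- length(cm$nodes)
  beta <- cm$s[, 1] * params$delta[cm$nodes]
  delta <- params$delta[cm$nodes]
  dose <- cm$dose[, 1]; blk <- cm$blocked[, 1] > 0
  clamped <- !is.na(cm$clamp[, 1])
  esrc <- cm$esrc; edst <- cm$edst; esign <- cm$esign
  w <- cm$w; K <- cm$K
  function(t, C, ...) {
    u <- c(C, numeric(length(cm$sources) - n)) + dose
    u[blk] <- 0
    h <- u / (K + u)
    logA <- numeric(n)
    if (length(esrc)) {
      f <- log1p(w * h[esrc]) * esign
      for (e in seq_along(esrc)) logA[edst[e]] <- logA[edst[e]] + f[e]
    }
    dC <- beta * exp(logA) - delta * C
    dC[clamped] <- 0
    list(dC)
  }
}

#' Simulate endpoint cytokine concentrations
#'
#' Runs the production model for a set of conditions and returns the
#' endpoint concentration of every modelled node.  `timecourse` mode
#' integrates the ODE from the initial state (added doses on their nodes,
#' zero elsewhere) to the horizon `T`; `steady_state` mode solves the
#' fixed point \eqn{C_i^* = s_i A_i(C^*)} by damped iteration and fails if
#' the residual does not converge.
#'
#' @param config A [network_config()].
#' @param params A [model_params()].
#' @param conditions Named list of [condition()] objects.
#' @param mode `"timecourse"` or `"steady_state"`.
#' @param T Culture horizon in hours (default 16).
#' @param receptor_map See [default_receptor_map()].
#' @param clamp Optional named numeric: nodes held fixed at the given
#'   concentration (mediation analysis).
#' @param tol Fixed-point residual tolerance (steady-state mode).
#' @return Matrix of concentrations (pg/mL), nodes x conditions.
#' @export
simulate_network <- function(config, params, conditions,
                             mode = c("timecourse", "steady_state"),
                             T = 16, receptor_map = default_receptor_map(),
                             clamp = NULL, tol = 1e-10) {
  mode <- match.arg(mode)
  if (inherits(conditions, "culture_condition")) conditions <- list(conditions)
  cm <- condition_matrices(config, params, conditions, receptor_map, clamp)
  if (mode == "steady_state") {
    sol <- .ss_solve_cpp(cm$s, cm$esrc, cm$edst, cm$esign, cm$w, cm$K,
                         cm$dose, cm$blocked, cm$clamp, maxit = 5000L,
                         tol = tol)
    if (!all(sol$converged))
      stop("steady-state iteration did not converge for condition(s) ",
           paste(colnames(cm$s)[!sol$converged], collapse = ", "),
           " (last residual ", format(max(sol$residual), digits = 3), ")")
    out <- sol$C
    dimnames(out) <- dimnames(cm$s)
    return(out)
  }
  n <- length(cm$nodes)
  out <- matrix(NA_real_, n, ncol(cm$s), dimnames = dimnames(cm$s))
  for (c in seq_along(conditions)) {
    C0 <- numeric(n)
    names(C0) <- cm$nodes
    add <- intersect(names(conditions[[c]]$additions), cm$nodes)
    C0[add] <- conditions[[c]]$additions[add]
    cl <- cm$clamp[, c]
    C0[!is.na(cl)] <- cl[!is.na(cl)]
    f <- network_rhs(config, params, conditions[[c]], receptor_map,
                     clamp = if (any(!is.na(cl))) cl[!is.na(cl)] else NULL)
    traj <- deSolve::lsoda(C0, c(0, T), function(t, y, p) f(t, y), NULL,
                           rtol = 1e-9, atol = 1e-9)
    endpoint <- traj[nrow(traj), -1]
    if (any(endpoint < -1e-8))
      stop("internal error: negative concentration in trajectory")
    out[, c] <- pmax(endpoint, 0)
  }
  out
}
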