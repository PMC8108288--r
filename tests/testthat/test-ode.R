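test_that("an unregulated node follows the linear ODE closed form", {
  cfg <- network_config(c("A", "B"))
  params <- model_params(s0 = c(A = 5, B = 2), sL = c(A = 100, B = 40),
                         delta = c(A = 0.4, B = 1.5), w = numeric(), K = 100)
  cond <- condition("LPS", additions = c(B = 300))
  out <- simulate_network(cfg, params, list(x = cond), mode = "timecourse", T = 16)
  closed <- function(s, delta, C0, T) s * (1 - exp(-delta * T)) + C0 * exp(-delta * T)
  expect_equal(out["A", 1], closed(100, 0.4, 0, 16), tolerance = 1e-6)
  expect_equal(out["B", 1], closed(40, 1.5, 300, 16), tolerance = 1e-6)
  # steady state of the same system is beta / delta
  ss <- simulate_network(cfg, params, list(x = condition("LPS")),
                         mode = "steady_state")
  expect_equal(unname(ss[, 1]), c(100, 40), tolerance = 1e-8)
})

test_that("steady state and a long-horizon timecourse agree on a random network", {
  set.seed(7)
  nodes <- c("A", "B", "C", "D")
  edges <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
                      sign = c(1L, -1L, 1L))
  cfg <- network_config(nodes, edges)
  params <- model_params(
    s0 = stats::setNames(runif(4, 1, 10), nodes),
    sL = stats::setNames(runif(4, 100, 1000), nodes),
    delta = stats::setNames(rep(1, 4), nodes),
    w = runif(3, 0.5, 5), K = 100)
  conds <- list(x = condition("LPS"))
  ss <- simulate_network(cfg, params, conds, mode = "steady_state")
  tc <- simulate_network(cfg, params, conds, mode = "timecourse", T = 200)
  expect_equal(ss, tc, tolerance = 0.01)
})

test_that("saturating regulation approaches the (1 + w) multiplier limit", {
  cfg <- network_config(c("A", "B"),
                        data.frame(source = "A", target = "B", sign = 1L))
  params <- model_params(s0 = c(A = 0, B = 0), sL = c(A = 10, B = 50),
                         delta = c(A = 1, B = 1), w = 3, K = 100)
  huge <- simulate_network(cfg, params,
                           list(x = condition("LPS", additions = c(A = 1e9))),
                           mode = "steady_state")
  expect_equal(unname(huge["B", 1]), 50 * (1 + 3), tolerance = 1e-4)
})

test_that("ligand blockade equals deleting all edges from that source", {
  gt <- gt_fixture
  cfg <- as_network_config(gt)
  params <- as_model_params(gt)
  blocked <- simulate_network(cfg, params,
                              list(x = condition("LPS", ligand_blockades = "IL-10")),
                              mode = "steady_state")
  cfg_del <- network_config(cfg$nodes,
                            cfg$edges[cfg$edges$source != "IL-10", ],
                            exogenous = cfg$exogenous)
  params_del <- model_params(params$s0, params$sL, params$delta,
                             params$w[cfg$edges$source != "IL-10"], params$K)
  deleted <- simulate_network(cfg_del, params_del, list(x = condition("LPS")),
                              mode = "steady_state")
  expect_equal(blocked, deleted, tolerance = 1e-10)
})

test_that("receptor blockade equals simultaneous blockade of all mapped ligands", {
  cfg <- as_network_config(gt_fixture)
  params <- as_model_params(gt_fixture)
  via_receptor <- simulate_network(
    cfg, params, list(x = condition("LPS", receptor_blockades = "IL-1R1")),
    mode = "steady_state")
  via_ligands <- simulate_network(
    cfg, params, list(x = condition("LPS", ligand_blockades = c("IL-1a", "IL-1b"))),
    mode = "steady_state")
  expect_identical(via_receptor, via_ligands)
})

test_that("removing an edge moves the target steady state monotonically", {
  set.seed(17)
  nodes <- c("S", "T")
  for (rep in 1:10) {
    sgn <- if (rep %% 2) 1L else -1L
    cfg <- network_config(nodes, data.frame(source = "S", target = "T", sign = sgn))
    params <- model_params(
      s0 = c(S = 1, `T` = 1),
      sL = c(S = runif(1, 50, 2000), `T` = runif(1, 50, 2000)),
      delta = c(S = 1, `T` = 1), w = runif(1, 0.1, 20), K = runif(1, 10, 500))
    with_edge <- simulate_network(cfg, params, list(x = condition("LPS")),
                                  mode = "steady_state")["T", 1]
    cfg0 <- network_config(nodes)
    params0 <- model_params(params$s0, params$sL, params$delta, numeric(), params$K)
    without <- simulate_network(cfg0, params0, list(x = condition("LPS")),
                                mode = "steady_state")["T", 1]
    if (sgn > 0) expect_gte(with_edge, without) else expect_lte(with_edge, without)
  }
})

test_that("trajectories and steady states stay non-negative", {
  cfg <- as_network_config(gt_fixture)
  params <- as_model_params(gt_fixture)
  for (mode in c("timecourse", "steady_state")) {
    out <- simulate_network(cfg, params, conds_fixture, mode = mode)
    expect_true(all(out >= 0))
  }
})

test_that("conditions referencing unknown entities are rejected by name", {
  cfg <- as_network_config(gt_fixture)
  params <- as_model_params(gt_fixture)
  expect_error(
    simulate_network(cfg, params, list(x = condition("LPS", additions = c(IL17 = 10)))),
    "IL17")
  expect_error(
    simulate_network(cfg, params,
                     list(x = condition("LPS", receptor_blockades = "IL-6R"))),
    "IL-6R")
})

test_that("network_rhs exposes the stated derivative at a point", {
  cfg <- network_config(c("A", "B"),
                        data.frame(source = "A", target = "B", sign = -1L))
  params <- model_params(s0 = c(A = 1, B = 2), sL = c(A = 10, B = 20),
                         delta = c(A = 0.5, B = 2), w = 4, K = 100)
  f <- network_rhs(cfg, params, condition("LPS"))
  C <- c(A = 50, B = 5)
  h <- 50 / (100 + 50)
  expected <- c(10 * 0.5 - 0.5 * 50, 20 * 2 / (1 + 4 * h) - 2 * 5)
  expect_equal(unname(f(0, C)[[1]]), expected, tolerance = 1e-12)
})
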