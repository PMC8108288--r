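test_that("configuration counts follow 2^E - 1 and the iterator matches", {
  expect_equal(count_configurations(31), 2^31 - 1)
  expect_equal(count_configurations(31), 2147483647)
  for (E in 1:20) expect_equal(count_configurations(E), 2^E - 1)
  # explicit subset listing for E <= 12
  mk_cand <- function(E) candidate_edge_set(data.frame(
    source = paste0("S", seq_len(E)), target = "T",
    sign = 1L, p = 0.001, p_adj = 0.001))
  for (E in c(1, 4, 8, 12)) {
    en <- enumerate_configurations(mk_cand(E))
    seen <- character()
    while (!is.null(idx <- en$next_config()))
      seen <- c(seen, paste(idx, collapse = ","))
    expect_equal(length(seen), 2^E - 1)
    expect_equal(length(seen), en$total)
    expect_false(anyDuplicated(seen) > 0)
  }
  expect_equal(enumerate_configurations(mk_cand(1))$total, 1)
})

test_that("mandatory edges and max_edges constrain the enumeration", {
  cand <- candidate_edge_set(data.frame(
    source = paste0("S", 1:5), target = "T", sign = 1L,
    p = 0.001, p_adj = 0.001,
    mandatory = c(TRUE, FALSE, FALSE, FALSE, FALSE)))
  en <- enumerate_configurations(cand)
  expect_equal(en$total, 2^4)      # subsets containing the mandatory edge
  n <- 0
  while (!is.null(idx <- en$next_config())) {
    expect_true(1 %in% idx)
    n <- n + 1
  }
  expect_equal(n, en$total)
  en2 <- enumerate_configurations(cand, max_edges = 2)
  expect_equal(en2$total, 1 + 4)   # mandatory alone or with one more
})

test_that("oversized enumerations are refused with guidance", {
  cand <- candidate_edge_set(data.frame(
    source = paste0("S", 1:31), target = "T", sign = 1L,
    p = 0.001, p_adj = 0.001))
  en <- enumerate_configurations(cand)
  expect_equal(en$total, 2147483647)        # count always available
  expect_error(en$next_config(), "max_edges")
})

test_that("candidate screening flags ground-truth edges with the right sign", {
  cand <- screen_candidate_edges(panel0_fixture, conds_fixture)
  adm <- cand$edges[cand$edges$admissible, ]
  lab <- edge_labels(adm)
  expect_true(all(true_edge_labels %in% lab))
  # self-pairs are never tested
  expect_false(any(cand$edges$source == cand$edges$target))
  # admissibility is exactly the BH threshold rule
  expect_identical(cand$edges$admissible, cand$edges$p_adj < cand$alpha)
})

test_that("candidate screening controls the FDR under the null generator", {
  admitted <- tested <- 0
  for (r in 1:50) {
    spec <- cohort_spec(n_donors = 20, conditions = conds_fixture,
                        seed = 7000 + r)
    panel <- simulate_cohort_panel(null_gt_fixture, spec)
    cand <- screen_candidate_edges(panel, conds_fixture)
    admitted <- admitted + sum(cand$edges$admissible)
    tested <- tested + nrow(cand$edges)
  }
  expect_lt(admitted / tested, 0.05)
})

test_that("exhaustive ranking recovers a 3-edge truth among 6 candidates", {
  nodes <- c("A", "B", "C", "D")
  edges <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
                      sign = c(1L, -1L, 1L), strength = c(5, 8, 4))
  gt <- ground_truth_network(
    nodes, edges,
    basal_unstim = stats::setNames(rep(5, 4), nodes),
    basal_stim = stats::setNames(c(995, 495, 795, 295), nodes),
    degradation = stats::setNames(rep(1, 4), nodes))
  conds <- perturbation_conditions(as_network_config(gt))
  panel <- simulate_cohort_panel(
    gt, cohort_spec(n_donors = 12, conditions = conds, noise_sd = 0,
                    donor_effect_sd = 0, seed = 2))
  truth_lab <- sort(edge_labels(gt$edges))
  cand <- candidate_edge_set(rbind(
    cbind(edges[, c("source", "target", "sign")], p = NA, p_adj = NA,
          admissible = TRUE),
    data.frame(source = c("D", "A", "C"), target = c("A", "C", "B"),
               sign = 1L, p = NA, p_adj = NA, admissible = TRUE)))
  rk <- rank_models(cand, panel, conds, search = "exhaustive",
                    n_restarts = 2, seed = 1, refit_timecourse = FALSE)
  expect_equal(ranked_edge_labels(rk), truth_lab)
  expect_equal(rk$table$delta_aic[1], 0)
  expect_true(all(diff(rk$table$aic) >= 0))
  # greedy search lands on the same configuration
  rg <- rank_models(cand, panel, conds, search = "greedy",
                    n_restarts = 2, seed = 1, refit_timecourse = FALSE)
  expect_equal(ranked_edge_labels(rg), truth_lab)
})

test_that("edge weights normalise, respect conventions and rank edge importance", {
  # single-edge configuration has weight 1 by convention
  cfg1 <- network_config(c("A", "B"),
                         data.frame(source = "A", target = "B", sign = 1L))
  gt1 <- ground_truth_network(
    c("A", "B"), data.frame(source = "A", target = "B", sign = 1L, strength = 5),
    basal_unstim = c(A = 5, B = 5), basal_stim = c(A = 995, B = 95),
    degradation = c(A = 1, B = 1))
  conds1 <- perturbation_conditions(as_network_config(gt1))
  panel1 <- simulate_cohort_panel(
    gt1, cohort_spec(n_donors = 8, conditions = conds1, noise_sd = 0,
                     donor_effect_sd = 0, seed = 3))
  ew1 <- edge_weights(cfg1, panel1, conds1, n_restarts = 2, seed = 1)
  expect_equal(ew1$weight, 1)
  # one strong and one near-zero edge: the strong edge dominates
  gt2 <- ground_truth_network(
    c("A", "B", "C"),
    data.frame(source = c("A", "C"), target = c("B", "B"),
               sign = c(1L, 1L), strength = c(10, 0.02)),
    basal_unstim = c(A = 5, B = 5, C = 5),
    basal_stim = c(A = 995, B = 95, C = 495),
    degradation = c(A = 1, B = 1, C = 1))
  conds2 <- perturbation_conditions(as_network_config(gt2))
  panel2 <- simulate_cohort_panel(
    gt2, cohort_spec(n_donors = 8, conditions = conds2, noise_sd = 0,
                     donor_effect_sd = 0, seed = 4))
  ew2 <- edge_weights(as_network_config(gt2), panel2, conds2,
                      n_restarts = 2, seed = 1)
  expect_equal(sum(ew2$weight), 1, tolerance = 1e-9)
  # AIC-based weights order the edges; the RSS-share variant isolates the
  # dominant contribution sharply (log-scale AIC compresses the contrast)
  expect_gt(ew2$weight[ew2$source == "A"], ew2$weight[ew2$source == "C"])
  ew2r <- edge_weights(as_network_config(gt2), panel2, conds2,
                       method = "rss_share", n_restarts = 2, seed = 1)
  expect_equal(sum(ew2r$weight), 1, tolerance = 1e-9)
  expect_gt(ew2r$weight[ew2r$source == "A"], 0.8)
})

test_that("edge weights are equivariant under node relabelling", {
  gt <- ground_truth_network(
    c("A", "B", "C"),
    data.frame(source = c("A", "C"), target = c("B", "B"),
               sign = c(1L, -1L), strength = c(6, 3)),
    basal_unstim = c(A = 5, B = 5, C = 5),
    basal_stim = c(A = 995, B = 195, C = 495),
    degradation = c(A = 1, B = 1, C = 1))
  conds <- perturbation_conditions(as_network_config(gt))
  panel <- simulate_cohort_panel(
    gt, cohort_spec(n_donors = 8, conditions = conds, noise_sd = 0,
                    donor_effect_sd = 0, seed = 5))
  ew <- edge_weights(as_network_config(gt), panel, conds,
                     n_restarts = 2, seed = 2)
  # relabel A <-> C everywhere (nodes, conditions, panel)
  swap <- function(x) chartr("AC", "CA", x)
  gt2 <- ground_truth_network(
    swap(gt$nodes),
    within(gt$edges, source <- swap(source)),
    basal_unstim = stats::setNames(gt$basal_unstim, swap(names(gt$basal_unstim))),
    basal_stim = stats::setNames(gt$basal_stim, swap(names(gt$basal_stim))),
    degradation = stats::setNames(gt$degradation, swap(names(gt$degradation))))
  panel2 <- panel
  panel2$analyte <- swap(panel2$analyte)
  conds2 <- lapply(conds, function(cc) {
    cc$ligand_blockades <- swap(cc$ligand_blockades)
    if (length(cc$additions)) names(cc$additions) <- swap(names(cc$additions))
    cc
  })
  ew2 <- edge_weights(as_network_config(gt2), panel2, conds2,
                      n_restarts = 2, seed = 2)
  m <- match(paste(swap(ew$source), swap(ew$target)),
             paste(ew2$source, ew2$target))
  expect_equal(ew$weight, ew2$weight[m], tolerance = 1e-6)
})

test_that("mediation analysis separates direct and mediated routes", {
  gtA <- mediation_gt_indirect()
  ma <- mediation_analysis(
    as_network_config(gtA), as_model_params(gtA),
    base = condition("LPS"),
    perturbed = condition("LPS", additions = c("IFN-g" = 1e4)),
    target = "IL-1a", mediator = "IL-10")
  expect_gt(ma$total, 0)
  expect_gt(ma$proportion_mediated, 0.9)
  gtB <- mediation_gt_direct()
  mb <- mediation_analysis(
    as_network_config(gtB), as_model_params(gtB),
    base = condition("LPS"),
    perturbed = condition("LPS", additions = c("IFN-g" = 1e4)),
    target = "IL-23", mediator = "IL-10")
  expect_gt(mb$direct / mb$total, 0.5)
  # a mediator with no path to the target mediates nothing
  mc <- mediation_analysis(
    as_network_config(gt_fixture), as_model_params(gt_fixture),
    base = condition("LPS"),
    perturbed = condition("LPS", additions = c("IL-1b" = 1e4)),
    target = "IL-23", mediator = "TNF")
  expect_equal(mc$mediated, 0, tolerance = 1e-8)
  # clamping the perturbed entity itself is refused
  expect_error(mediation_analysis(
    as_network_config(gt_fixture), as_model_params(gt_fixture),
    base = condition("LPS"),
    perturbed = condition("LPS", additions = c("IL-1b" = 1e4)),
    target = "IL-23", mediator = "IL-1b"), "perturbed entity")
})
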