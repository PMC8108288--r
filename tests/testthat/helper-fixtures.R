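# Shared fixtures built in code.  The noiseless perturbation panel of the
# example ground truth is used by several files; build it once.

gt_fixture <- example_ground_truth()
conds_fixture <- perturbation_conditions(as_network_config(gt_fixture))
panel0_fixture <- simulate_cohort_panel(
  gt_fixture,
  cohort_spec(n_donors = 20, conditions = conds_fixture,
              noise_sd = 0, donor_effect_sd = 0, seed = 1))

# Null ground truth: same production rates, empty edge set.
null_gt_fixture <- ground_truth_network(
  gt_fixture$nodes, gt_fixture$edges[0, ],
  basal_unstim = gt_fixture$basal_unstim,
  basal_stim = gt_fixture$basal_stim,
  degradation = gt_fixture$degradation,
  exogenous = "IFN-g")

# Candidate set used for exhaustive ranking: the screened edges of a
# noiseless panel padded with a-priori-admitted decoy edges up to E = 8.
acceptance_candidates <- function(panel, conds) {
  cand <- screen_candidate_edges(panel, conds)
  adm <- cand$edges[cand$edges$admissible,
                    c("source", "target", "sign", "p", "p_adj")]
  adm$admissible <- TRUE
  decoys <- data.frame(
    source = c("IL-6", "TNF", "IFN-g"),
    target = c("IL-23", "IL-6", "IL-1b"),
    sign = c(1L, 1L, 1L),
    p = NA_real_, p_adj = NA_real_, admissible = TRUE)
  decoys <- decoys[seq_len(max(0, 8 - nrow(adm))), , drop = FALSE]
  candidate_edge_set(rbind(adm, decoys))
}

true_edge_labels <- sort(c("IL-1b->IL-23", "IL-10-|IL-23",
                           "IL-10-|IL-1a", "IL-1a->IL-6"))

ranked_edge_labels <- function(ranking) {
  sort(strsplit(ranking$table$edges[1], ",", fixed = TRUE)[[1]])
}

# Mediation instance A: IFN-g touches IL-1a only through IL-10 suppression.
mediation_gt_indirect <- function() {
  ground_truth_network(
    c("IL-1a", "IL-10"),
    data.frame(source = c("IFN-g", "IL-10"), target = c("IL-10", "IL-1a"),
               sign = c(-1L, -1L), strength = c(8, 6)),
    basal_unstim = c(`IL-1a` = 8, `IL-10` = 20),
    basal_stim = c(`IL-1a` = 792, `IL-10` = 1980),
    degradation = c(`IL-1a` = 1, `IL-10` = 1),
    exogenous = "IFN-g")
}

# Mediation instance B: strong direct IFN-g -> IL-23 edge plus a weaker
# IFN-g -| IL-10 -| IL-23 route.
mediation_gt_direct <- function() {
  ground_truth_network(
    c("IL-23", "IL-10"),
    data.frame(source = c("IFN-g", "IFN-g", "IL-10"),
               target = c("IL-23", "IL-10", "IL-23"),
               sign = c(1L, -1L, -1L), strength = c(5, 2, 2)),
    basal_unstim = c(`IL-23` = 0.5, `IL-10` = 20),
    basal_stim = c(`IL-23` = 49.5, `IL-10` = 1980),
    degradation = c(`IL-23` = 1, `IL-10` = 1),
    exogenous = "IFN-g")
}
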