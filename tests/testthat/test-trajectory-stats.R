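# Ensemble reducers, checked on hand-built trajectories with known answers.

test_that("length statistics and median", {
  ens <- synthetic_ensemble(list(
    synthetic_trajectory(rep("DFRt", 3), rep(0.1, 3)),
    synthetic_trajectory(rep("DFRt", 4), rep(0.1, 4)),
    synthetic_trajectory(rep("DFRt", 5), rep(0.1, 5))))
  ls <- trajectory_length_stats(ens)
  expect_equal(ls$median, 4)
  expect_equal(sort(ls$lengths), c(3, 4, 5))
  # a single trajectory of length k has median k
  one <- synthetic_ensemble(list(synthetic_trajectory(rep("DFRt", 7),
                                                      rep(0.1, 7))))
  expect_equal(trajectory_length_stats(one)$median, 7)
  # capped trajectories are excluded by default but counted
  ens2 <- synthetic_ensemble(list(
    synthetic_trajectory(rep("DFRt", 3), rep(0.1, 3)),
    synthetic_trajectory(rep("DFRt", 9), rep(0.1, 9),
                         outcome = "hit_iteration_cap")))
  ls2 <- trajectory_length_stats(ens2)
  expect_equal(ls2$lengths, 3L)
  expect_equal(ls2$n_capped, 1)
})

test_that("hotspot share counts fixed mutations by enzyme", {
  ens <- synthetic_ensemble(list(
    synthetic_trajectory(c("DFRt", "k_DFR_DHK"), c(0.1, 0.2))))
  expect_equal(hotspot_share(ens), 1.0)
  expect_equal(hotspot_share(ens, loci = character(0)), 0)
  mixed <- synthetic_ensemble(list(
    synthetic_trajectory(c("DFRt", "CHSt", "F35pHt", "Km_FLS_DHQ"),
                         rep(0.1, 4))))
  expect_equal(hotspot_share(mixed), 0.75)
})

test_that("mutation-type split normalizes by parameter-class size", {
  # only Et mutations: regulatory fraction 1 wherever counts exist
  ens <- synthetic_ensemble(list(
    synthetic_trajectory(c("DFRt", "DFRt", "F3pHt"), rep(0.1, 3))))
  ts <- mutation_type_split(ens)
  expect_equal(ts$prop_regulatory_raw[ts$enzyme == "DFR"], 1)
  expect_equal(ts$prop_regulatory_normalized[ts$enzyme == "F3pH"], 1)
  expect_equal(regulatory_share(ens), 1)
  # DFR with equal raw counts in each of its 7 parameters:
  # normalized biochemical rate (6/6) equals regulatory rate (1/1)
  pars <- c("k_DFR_DHK", "Km_DFR_DHK", "k_DFR_DHQ", "Km_DFR_DHQ",
            "k_DFR_DHM", "Km_DFR_DHM", "DFRt")
  ens7 <- synthetic_ensemble(list(synthetic_trajectory(pars, rep(0.1, 7))))
  ts7 <- mutation_type_split(ens7)
  row <- ts7[ts7$enzyme == "DFR", ]
  expect_equal(row$n_biochemical_params, 6)
  expect_equal(row$rate_biochemical, row$rate_regulatory)
  expect_equal(row$prop_regulatory_normalized, 0.5)
})

test_that("directional shifts per mutation and per end state", {
  tr <- synthetic_trajectory("DFRt", 0.1, gamma_draws = 3)
  ens <- synthetic_ensemble(list(tr))
  pm <- directional_shifts(ens, "per_mutation")
  expect_equal(pm$shift, 2)  # a x3 mutation has delta 2
  es <- directional_shifts(ens, "end_state")
  expect_equal(es$shift[es$parameter == "DFRt"], 2)
  # untouched parameters shift by 0
  expect_equal(es$shift[es$parameter == "FLSt"], 0)
})

test_that("stepwise selection-coefficient summaries", {
  ens <- synthetic_ensemble(list(
    synthetic_trajectory(c("DFRt", "FLSt"), c(0.05, 0.2)),
    synthetic_trajectory(c("DFRt", "FLSt"), c(0.15, 0.4))))
  sw <- stepwise_s_distributions(ens)
  expect_equal(sw$step, c(1, 2))
  expect_equal(sw$median, c(0.1, 0.3))
  expect_equal(sw$n, c(2, 2))
  one <- synthetic_ensemble(list(synthetic_trajectory(c("DFRt", "FLSt"),
                                                      c(0.3, 0.1))))
  sw1 <- stepwise_s_distributions(one)
  expect_equal(sw1$median, c(0.3, 0.1))  # single values per step
})

test_that("step-2-vs-step-1 ranking fraction", {
  asc <- synthetic_ensemble(list(
    synthetic_trajectory(c("DFRt", "FLSt"), c(0.1, 0.2)),
    synthetic_trajectory(c("DFRt", "FLSt"), c(0.1, 0.3))))
  expect_equal(as.numeric(step2_gt_step1_fraction(asc)), 1.0)
  desc <- synthetic_ensemble(list(
    synthetic_trajectory(c("DFRt", "FLSt"), c(0.3, 0.2))))
  expect_equal(as.numeric(step2_gt_step1_fraction(desc)), 0.0)
  # length-1 trajectories are excluded and counted
  mix <- synthetic_ensemble(list(
    synthetic_trajectory("DFRt", 0.1),
    synthetic_trajectory(c("DFRt", "FLSt"), c(0.1, 0.2))))
  out <- step2_gt_step1_fraction(mix)
  expect_equal(as.numeric(out), 1.0)
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("fixation-step heatmap counts, threshold, and normalization", {
  trs <- c(
    replicate(99, synthetic_trajectory(c("DFRt", "F35pHt"), c(0.1, 0.1)),
              simplify = FALSE),
    list(synthetic_trajectory(c("CHSt", "DFRt"), c(0.1, 0.1))))
  ens <- synthetic_ensemble(trs)
  hm <- fixation_step_heatmap(ens, min_share = 0.01)
  # CHSt carries 1/200 of fixations: below the 1% threshold
  expect_false("CHSt" %in% rownames(hm$counts))
  # unnormalized rows sum to the parameter totals
  expect_equal(unname(rowSums(hm$counts)[c("DFRt", "F35pHt")]),
               c(100, 99))
  # a parameter fixed only at step 1 normalizes to [1, 0, ...]
  expect_equal(unname(hm$normalized["F35pHt", ]), c(0, 1))
  expect_true(all(apply(hm$normalized, 1, max) == 1))
  expect_true(all(apply(hm$normalized, 1, min) == 0))
})

test_that("sensitivity values are |s/delta| over recorded proposals", {
  tr <- synthetic_trajectory("DFRt", 0.1)
  tr$proposals <- data.frame(parameter = c("DFRt", "FLSt", "FLSt"),
                             delta = c(0.5, -0.5, 0),
                             s = c(0.02, 0, 0.1))
  ens <- synthetic_ensemble(list(tr))
  sd_ <- sensitivity_distributions(ens)
  expect_equal(sd_$values$sensitivity[sd_$values$parameter == "DFRt"], 0.04)
  expect_equal(sd_$values$sensitivity[sd_$values$parameter == "FLSt"], 0)
  expect_equal(attr(sd_, "n_zero_delta"), 1)  # delta = 0 skipped, counted
})

test_that("pigment-space trajectory starts at the shared phenotype", {
  ens <- synthetic_ensemble(list(
    synthetic_trajectory(c("DFRt", "FLSt"), c(0.1, 0.2)),
    synthetic_trajectory("DFRt", 0.1)))
  pt <- pigment_space_trajectory(ens)
  expect_equal(pt$step, 0:2)
  expect_equal(pt$del_mean[1], 0.35)
  expect_equal(pt$pel_sd[1], 0)
  # ratios sum to one at every aggregated step
  expect_equal(pt$pel_mean + pt$cya_mean + pt$del_mean, rep(1, 3))
  # step alignment: only the longer trajectory contributes at step 2
  expect_equal(pt$n, c(2, 2, 1))
})
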