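# Origin-fixation engine: kernel, fitness machinery, walks, ensembles.

test_that("fitness, selection coefficient and fixation probability identities", {
  expect_equal(fitness(0.9, 0.9), 1)
  expect_equal(fitness(0.5, 0.9), exp(-0.16))
  expect_equal(fitness(0.8, 0.9), fitness(1.0, 0.9))  # even in the distance
  expect_equal(selection_coefficient(0.9, 0.9), 0)
  expect_equal(selection_coefficient(1.1 * 0.8, 0.8), 0.1)
  expect_lt(selection_coefficient(0.7, 0.8), 0)
  expect_equal(fixation_probability(0.1), 1 - exp(-0.1), tolerance = 1e-12)
  expect_equal(fixation_probability(0.1), 0.09516, tolerance = 1e-4)
  expect_lt(fixation_probability(1e-9), 1e-8)  # p -> 0 as s -> 0+
  s <- sort(stats::runif(10, 0.01, 2))
  expect_true(all(diff(fixation_probability(s)) > 0))
})

test_that("production filter accepts within 10% and rejects beyond", {
  expect_true(production_filter(1, 1))
  expect_true(production_filter(0.95, 1))
  expect_true(production_filter(1.10, 1))
  expect_false(production_filter(1.15, 1))
  expect_false(production_filter(0.85, 1))
  expect_error(production_filter(1, 0), "degenerate")
})

test_that("mutation kernel matches Gamma(shape 0.8, scale 3)", {
  m <- build_full_pathway()
  set.seed(10)
  props <- vapply(seq_len(2e5), function(i) draw_mutation(m)$gamma_draw,
                  numeric(1))
  expect_true(all(props > 0))
  expect_equal(mean(props), 0.8 * 3, tolerance = 0.02)
  expect_equal(mean(props < 1), stats::pgamma(1, shape = 0.8, scale = 3),
               tolerance = 0.01)
  # parameters chosen uniformly over the evolvable set
  set.seed(11)
  picks <- vapply(seq_len(2e4), function(i) draw_mutation(m)$parameter_name,
                  character(1))
  freq <- table(factor(picks, levels = m$evolvable)) / length(picks)
  expect_true(all(abs(freq - 1 / 38) < 0.01))
  # multiplicative semantics preserve sign
  mu <- draw_mutation(m)
  expect_equal(mu$new_value, mu$old_value * mu$gamma_draw)
})

test_that("the kernel is static: draws from evolved states match the naive", {
  # step-dependence of fixed effects must be emergent, not built in
  m_naive <- build_full_pathway()
  m_evolved <- build_full_pathway(list(DFRt = 37, F35pHt = 0.01,
                                       Km_DFR_DHK = 12))
  set.seed(12)
  d1 <- vapply(1:5e4, function(i) draw_mutation(m_naive)$gamma_draw,
               numeric(1))
  set.seed(12)
  d2 <- vapply(1:5e4, function(i) draw_mutation(m_evolved)$gamma_draw,
               numeric(1))
  expect_identical(d1, d2)
})

test_that("trajectories are reproducible and replayable", {
  stage <- transition_stage("naive_to_del", build_full_pathway(),
                            target = "del")
  t1 <- evolve_trajectory(stage, 123)
  t2 <- evolve_trajectory(stage, 123)
  expect_identical(t1$fixed_mutations, t2$fixed_mutations)
  expect_identical(t1$final_params, t2$final_params)
  expect_identical(t1$iterations_used, t2$iterations_used)
  # every fixed mutation is beneficial
  expect_true(all(t1$fixed_mutations$s > 0))
  # replay of the multiplicative record reproduces the end state exactly
  expect_identical(replay_state(t1), t1$final_params)
  # intermediate states are consistent with the record
  k <- nrow(t1$fixed_mutations)
  if (k >= 2) {
    mid <- replay_state(t1, 1)
    expect_equal(mid[[t1$fixed_mutations$parameter[1]]],
                 t1$fixed_mutations$new_value[1])
  }
})

test_that("a start state already at the optimum gives a length-0 walk", {
  stage <- transition_stage("already_red", build_full_pathway(),
                            target = "pel", ratio_opt = 0.47,
                            optimum_tol = 0.10)
  tr <- evolve_trajectory(stage, 1)
  expect_equal(nrow(tr$fixed_mutations), 0)
  expect_equal(tr$outcome, "reached_optimum")
  expect_equal(tr$iterations_used, 0)
})

test_that("ensembles derive distinct seeds and aggregate correctly", {
  stage <- transition_stage("naive_to_del", build_full_pathway(),
                            target = "del")
  ens1 <- run_ensemble(stage, 1, 77)
  expect_length(ens1$trajectories, 1)
  ens <- run_ensemble(stage, 8, 77)
  expect_false(any(duplicated(ens$seeds)))
  # counting consistency: pooled table rows = summed lengths
  fx <- fixed_mutation_table(ens)
  lens <- trajectory_length_stats(ens)$lengths
  expect_equal(nrow(fx), sum(lens))
  # mean evolved state is the arithmetic mean of the end states
  ms <- mean_evolved_state(ens)
  trs <- completed_trajectories(ens)
  manual <- rowMeans(vapply(trs, function(tr) tr$final_params,
                            numeric(38)))
  expect_equal(ms, manual)
})

test_that("degenerate-phenotype proposals are never fixed", {
  # DFRt = 0 kills all three anthocyanins; fitness 0 means a walk away
  # from it can never fix a mutation into it, and a walk from a healthy
  # state never accepts the degenerate proposal (s = -1)
  stage <- transition_stage("naive_to_del", build_full_pathway(),
                            target = "del", max_iterations = 300)
  tr <- evolve_trajectory(stage, 5)
  final_model <- set_params(build_full_pathway(), tr$final_params)
  ph <- phenotype(steady_state(final_model), "del")
  expect_false(ph$degenerate)
})

test_that("control-experiment walks raise pelargonidin with the ratio held", {
  # branched pathway: redistribution plus capacity growth reaches the
  # threefold optimum
  stage_b <- transition_stage("branched_pel3x", build_full_pathway(),
                              mode = "production3x")
  trb <- evolve_trajectory(stage_b, 1)
  expect_equal(trb$outcome, "reached_optimum")
  pel0 <- steady_state(build_full_pathway())$concentrations[["pel"]]
  finalb <- set_params(build_full_pathway(), trb$final_params)
  pelb <- steady_state(finalb)$concentrations[["pel"]]
  expect_lt(abs(pelb / pel0 - 3), 0.3 + 1e-12)
  # linear chain: stabilizing selection keeps the pel : other-species
  # ratio near its start value while pelargonidin climbs; only CHS can
  # move pelargonidin directly, so progress is gradual
  stage <- transition_stage("linear_pel3x", build_linear_pathway(),
                            mode = "production3x", max_iterations = 8000)
  tr <- evolve_trajectory(stage, 21)
  fx <- tr$fixed_mutations
  expect_gt(nrow(fx), 0)
  expect_true(all(fx$s > 0))
  conc0 <- steady_state(build_linear_pathway())$concentrations
  final <- set_params(build_linear_pathway(), tr$final_params)
  conc1 <- steady_state(final)$concentrations
  expect_gt(conc1[["pel"]], conc0[["pel"]])
  other <- c("cha", "nar", "DHK", "LCP")
  r0 <- conc0[["pel"]] / sum(conc0[other])
  r1 <- conc1[["pel"]] / sum(conc1[other])
  # deviation stays far below the ~3x the unconstrained optimum implies
  expect_lt(abs(r1 / r0 - 1), 0.5)
})
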