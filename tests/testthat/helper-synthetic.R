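# Minimal hand-built trajectory/ensemble objects for exact arithmetic
# checks of the reducers (no simulation involved).

synthetic_trajectory <- function(parameters, s, start_params = NULL,
                                 gamma_draws = NULL,
                                 ratios = NULL,
                                 outcome = "reached_optimum") {
  k <- length(parameters)
  if (is.null(start_params))
    start_params <- build_full_pathway()$params
  if (is.null(gamma_draws)) gamma_draws <- rep(2, k)
  if (is.null(ratios))
    ratios <- matrix(rep(c(0.1, 0.1, 0.8), each = k), nrow = k)
  final <- start_params
  old <- new <- numeric(k)
  for (i in seq_len(k)) {
    old[i] <- final[[parameters[i]]]
    new[i] <- old[i] * gamma_draws[i]
    final[[parameters[i]]] <- new[i]
  }
  fx <- data.frame(step = seq_len(k), parameter = parameters,
                   old_value = old, new_value = new,
                   gamma_draw = gamma_draws, delta = gamma_draws - 1,
                   s = s, W_before = 0.9, W_after = 0.9 * (1 + s),
                   pel_ratio = ratios[, 1], cya_ratio = ratios[, 2],
                   del_ratio = ratios[, 3],
                   total_production = 0.5, phenotype_value = ratios[, 3])
  if (k == 0) fx <- anthowalk:::evolve_trajectory_empty_fixed()
  structure(list(seed = 1L, stage_name = "synthetic", target = "del",
                 mode = "ratio", start_params = start_params,
                 final_params = final,
                 start_ratios = c(pel = 0.45, cya = 0.2, del = 0.35),
                 start_phenotype = 0.35, fixed_mutations = fx,
                 outcome = outcome, iterations_used = 10L,
                 n_nonconverged = 0L, proposals = NULL),
            class = "anthowalk_trajectory")
}

synthetic_ensemble <- function(trajectories) {
  stage <- transition_stage("synthetic", build_full_pathway(),
                            target = "del")
  structure(list(stage = stage, base_seed = 1L,
                 seeds = seq_along(trajectories),
                 trajectories = trajectories),
            class = "anthowalk_ensemble")
}
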