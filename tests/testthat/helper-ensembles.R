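# Shared reduced-ensemble fixtures for the acceptance tests, built once per
# test run. Ensemble sizes: 300 walks for the naive->del stage (used only to
# chain the start states) and 500 for each focal transition; the linear
# control uses 40 replicates. All seeds fixed.

.ens_cache <- new.env(parent = emptyenv())

acceptance_focal_ensembles <- function() {
  if (!exists("focal", envir = .ens_cache)) {
    res <- run_sequential_experiment(n_trajectories = c(300, 500, 500),
                                     base_seed = 1905)
    assign("focal", res, envir = .ens_cache)
  }
  get("focal", envir = .ens_cache)
}

acceptance_linear_control <- function() {
  if (!exists("linear_control", envir = .ens_cache)) {
    stage <- transition_stage("linear_pel3x", build_linear_pathway(),
                              mode = "production3x")
    assign("linear_control", run_ensemble(stage, 40, 1906),
           envir = .ens_cache)
  }
  get("linear_control", envir = .ens_cache)
}

# normalized regulatory proportion pooled over the hotspot enzymes
# (per-parameter fixation rates, correcting for each enzyme's 2m biochemical
# vs 1 regulatory parameter count)
hotspot_regulatory_normalized <- function(ensemble,
                                          loci = c("F35pH", "F3pH",
                                                   "DFR", "FLS")) {
  ts <- mutation_type_split(ensemble)
  hot <- ts[ts$enzyme %in% loci, ]
  rr <- sum(hot$n_regulatory) / sum(hot$n_regulatory_params)
  rb <- sum(hot$n_biochemical) / sum(hot$n_biochemical_params)
  rr / (rr + rb)
}
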