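# Origin-fixation adaptive-walk engine.
#
# One mutation arises per iteration: a multiplicative gamma-distributed shift
# to one uniformly chosen kinetic or enzyme-concentration parameter. The
# mutant's steady state is recomputed; mutations that move total end-product
# production beyond a 10% tolerance are discarded (stabilizing constraint),
# the survivor's selection coefficient s = W_mut/W_curr - 1 is computed from
# the Gaussian ratio fitness, neutral/deleterious mutations are discarded,
# and beneficial ones fix with probability 1 - exp(-s). The walk stops when
# the target-pigment ratio is within tolerance of the optimum or after a
# fixed iteration cap.

#' Gaussian fitness on the target-pigment ratio
#'
#' W = exp(-(ratio_current - ratio_opt)^2); maximal (W = 1) exactly at the
#' optimum and symmetric about it.
#'
#' @param ratio_current realized target-anthocyanin ratio in \[0,1\].
#' @param ratio_opt optimum ratio in (0,1\].
#' @return fitness in (0, 1\].
#' @export
fitness <- function(ratio_current, ratio_opt) {
  exp(-(ratio_current - ratio_opt)^2)
}

#' Selection coefficient of a mutant relative to the resident
#'
#' s = W_mut / W_curr - 1, the standard relative-fitness convention of
#' origin-fixation models.
#'
#' @param w_mut,w_curr mutant and resident fitness; `w_curr` must be > 0.
#' @return selection coefficient (s > 0 beneficial).
#' @export
selection_coefficient <- function(w_mut, w_curr) {
  stopifnot(w_curr > 0)
  w_mut / w_curr - 1
}

#' Fixation probability of a beneficial mutation
#'
#' p = 1 - exp(-s); strictly increasing in s with p -> 0 as s -> 0+.
#'
#' @param s selection coefficient (meaningful for s > 0; neutral and
#'   deleterious mutations are discarded upstream).
#' @return fixation probability.
#' @export
fixation_probability <- function(s) -expm1(-s)

#' Stabilizing filter on total pathway production
#'
#' Accepts a mutation only when |total_mut - total_ref| / total_ref <= tol,
#' holding total steady-state output near the resident level so that
#' selection acts on pigment identity, not amount.
#'
#' @param total_mut,total_ref mutant and reference total production (>= 0).
#' @param tol relative tolerance (default 0.10).
#' @return logical.
#' @export
production_filter <- function(total_mut, total_ref, tol = 0.10) {
  if (total_ref <= 0) stop("degenerate reference state: zero total production")
  # small guard so exact-boundary ratios are not lost to rounding
  abs(total_mut - total_ref) / total_ref <= tol * (1 + 1e-12)
}

#' Propose one multiplicative mutation
#'
#' Chooses one evolvable parameter uniformly at random and multiplies it by
#' a draw from Gamma(shape = 0.8, scale = 3) (mean 2.4), so the kernel
#' produces both near-complete losses (factors near 0) and multi-fold gains.
#' Uses R's RNG stream; seed upstream for reproducibility.
#'
#' @param model a `pathway_model`.
#' @param shape,scale gamma kernel parameters.
#' @return list with `parameter_name`, `old_value`, `gamma_draw`,
#'   `new_value`.
#' @export
draw_mutation <- function(model, shape = 0.8, scale = 3) {
  i <- sample.int(length(model$evolvable), 1L)
  nm <- model$evolvable[i]
  fac <- stats::rgamma(1L, shape = shape, scale = scale)
  old <- model$params[[nm]]
  list(parameter_name = nm, old_value = old, gamma_draw = fac,
       new_value = old * fac)
}

#' Define one selective stage of a transition experiment
#'
#' @param name stage label (e.g. `"del_to_cya"`).
#' @param start_model `pathway_model` giving the stage's start state.
#' @param target pigment under selection (`"pel"`, `"cya"`, `"del"`), or
#'   ignored when `mode = "production3x"`.
#' @param ratio_opt phenotypic optimum for the target ratio (default 0.9).
#' @param optimum_tol stopping tolerance on the optimum (default 0.10,
#'   interpreted per `tolerance_mode`).
#' @param production_tol tolerance of the stabilizing filter (default 0.10).
#' @param max_iterations proposal cap per trajectory (default 50000).
#' @param mode `"ratio"` for the pigment-ratio experiments; `"production3x"`
#'   for the alternative-fitness control experiments, where fitness is
#'   W = exp(-((pel/pel_start - fold)/fold)^2 - (r/r_start - 1)^2) with
#'   r the ratio of pelargonidin to the summed other dynamic species:
#'   directional selection on the fold-increase plus stabilizing selection
#'   holding that ratio constant (no hard production filter is applied in
#'   this mode).
#' @param tolerance_mode `"relative"` stops at |ratio - opt| <= tol * opt;
#'   `"absolute"` at |ratio - opt| <= tol.
#' @param filter_anchor `"current"` compares the mutant's total production
#'   with the resident state (default); `"start"` anchors the filter to the
#'   stage's start state, bounding cumulative drift.
#' @param gamma_shape,gamma_scale mutation kernel.
#' @param fold_target fold-increase optimum of the control experiments.
#' @return a `transition_stage` object.
#' @export
transition_stage <- function(name, start_model,
                             target = c("pel", "cya", "del"),
                             ratio_opt = 0.9, optimum_tol = 0.10,
                             production_tol = 0.10,
                             max_iterations = 50000L,
                             mode = c("ratio", "production3x"),
                             tolerance_mode = c("relative", "absolute"),
                             filter_anchor = c("current", "start"),
                             gamma_shape = 0.8, gamma_scale = 3,
                             fold_target = 3) {
  mode <- match.arg(mode)
  structure(
    list(name = name, start_model = start_model,
         target = if (mode == "ratio") match.arg(target) else "pel",
         ratio_opt = ratio_opt, optimum_tol = optimum_tol,
         production_tol = production_tol,
         max_iterations = as.integer(max_iterations), mode = mode,
         tolerance_mode = match.arg(tolerance_mode),
         filter_anchor = match.arg(filter_anchor),
         gamma_shape = gamma_shape, gamma_scale = gamma_scale,
         fold_target = fold_target),
    class = "transition_stage")
}

# solve a parameter state within a stage, reusing the packed-vector fast
# path for the full topology
.stage_solver <- function(stage) {
  model <- stage$start_model
  if (model$topology == "linear") {
    boundary <- model$boundary
    pack_idx <- match(.LINEAR_PACK_ORDER, names(model$params))
    function(params, guess = NULL) {
      v <- c(unname(params[pack_idx]), boundary[["PCoA"]],
             boundary[["ksink"]])
      raw <- .c_steady_state_linear(v)
      list(converged = raw$converged, conc = raw$conc, status = raw$status)
    }
  } else {
    boundary <- model$boundary
    two_sub <- "DHK" %in% model$f35ph_substrates
    pack_idx <- match(.FULL_PACK_ORDER, names(model$params))
    function(params, guess = NULL) {
      v <- rep(1, 40)
      v[seq_len(38)][!is.na(pack_idx)] <-
        unname(params[pack_idx[!is.na(pack_idx)]])
      v[39] <- boundary[["PCoA"]]
      v[40] <- boundary[["ksink"]]
      raw <- .c_steady_state_full(v, two_sub, guess)
      list(converged = raw$converged, conc = raw$conc, status = raw$status)
    }
  }
}

# concentrations as plain vector in canonical species order
.stage_conc <- function(stage, sol) sol$conc

#' Run one adaptive walk
#'
#' Fully reproducible from `seed`: the same stage and seed give a
#' bit-identical trajectory. The walk's state after each fixation is exactly
#' the start state with the recorded multiplicative mutations applied, so
#' intermediate states can be reconstructed by replay.
#'
#' @param stage a `transition_stage`.
#' @param seed integer RNG seed for this trajectory.
#' @param record_proposals if `TRUE`, also record (parameter, delta, s) for
#'   every evaluated proposal that passed the production filter — the input
#'   to mutational-sensitivity analyses.
#' @return an `anthowalk_trajectory`: seed, start/final parameter states,
#'   the ordered table of fixed mutations with their selection coefficients
#'   and post-fixation pigment ratios, outcome
#'   (`"reached_optimum"`/`"hit_iteration_cap"`), and iteration count.
#' @export
evolve_trajectory <- function(stage, seed, record_proposals = FALSE) {
  stopifnot(inherits(stage, "transition_stage"))
  set.seed(seed)
  model <- stage$start_model
  params <- model$params
  np <- length(params)
  pnames <- names(params)
  solver <- .stage_solver(stage)
  species <- model$species
  is_full <- model$topology == "full"
  anth_idx <- match(.ANTHOCYANINS, species)
  end_idx <- match(intersect(species, .END_PRODUCTS), species)
  core_idx <- if (is_full) 4:6 else NULL
  pel_idx <- match("pel", species)
  dyn_idx <- which(species != "PCoA")

  sol <- solver(params)
  if (!isTRUE(sol$converged))
    stop("stage start state does not converge to a steady state")
  conc <- .stage_conc(stage, sol)

  prod_of <- function(cc) sum(cc[end_idx], na.rm = TRUE)
  anth_of <- function(cc) {
    a <- cc[anth_idx]
    a[is.na(a)] <- 0
    a
  }
  ratio_mode <- stage$mode == "ratio"
  pel_start <- conc[pel_idx]
  r_other_start <- if (!ratio_mode)
    pel_start / sum(conc[setdiff(dyn_idx, pel_idx)]) else NA_real_

  w_of <- if (ratio_mode) {
    tgt_idx <- match(stage$target, .ANTHOCYANINS)
    function(cc) {
      a <- anth_of(cc)
      den <- sum(a)
      if (den <= .Machine$double.eps) return(list(w = 0, ratio = NA_real_))
      r <- a[tgt_idx] / den
      list(w = exp(-(r - stage$ratio_opt)^2), ratio = r)
    }
  } else {
    # directional selection on the pelargonidin fold-increase combined
    # with stabilizing selection holding the pel : other-species ratio
    # at its start value; both deviations normalized to O(1) so the two
    # components share the curvature of the main Gaussian fitness
    ft <- stage$fold_target
    other_idx <- setdiff(dyn_idx, pel_idx)
    function(cc) {
      fold <- cc[pel_idx] / pel_start
      rr <- cc[pel_idx] / sum(cc[other_idx])
      list(w = exp(-((fold - ft) / ft)^2 - (rr / r_other_start - 1)^2),
           ratio = fold)
    }
  }

  stop_tol <- if (ratio_mode) {
    if (stage$tolerance_mode == "relative")
      stage$optimum_tol * stage$ratio_opt else stage$optimum_tol
  } else {
    stage$optimum_tol * stage$fold_target
  }
  opt_value <- if (ratio_mode) stage$ratio_opt else stage$fold_target
  at_optimum <- function(r) !is.na(r) && abs(r - opt_value) <= stop_tol

  filter_ok <- if (ratio_mode) {
    anchor_total <- prod_of(conc)
    use_start <- stage$filter_anchor == "start"
    function(cc_mut, total_curr) {
      ref <- if (use_start) anchor_total else total_curr
      abs(prod_of(cc_mut) - ref) / ref <= stage$production_tol
    }
  } else {
    # the ratio constraint is part of the fitness here, not a hard
    # filter: in the linear chain the capacity mutations that restore
    # the ratio are neutral for pelargonidin itself and could otherwise
    # never fix
    function(cc_mut, total_curr) TRUE
  }

  cur <- w_of(conc)
  w_curr <- cur$w
  start_ratios <- if (is_full) {
    a <- anth_of(conc); a / max(sum(a), .Machine$double.eps)
  } else c(1, 0, 0)
  start_ratio <- cur$ratio

  fixed <- vector("list", 64L)
  nfix <- 0L
  prop_par <- integer(0); prop_delta <- numeric(0); prop_s <- numeric(0)
  if (record_proposals) {
    prop_par <- integer(2048L); prop_delta <- numeric(2048L)
    prop_s <- numeric(2048L)
  }
  nprop <- 0L
  n_nonconverged <- 0L
  iter <- 0L
  reached <- at_optimum(cur$ratio)
  total_curr <- prod_of(conc)
  guess <- if (is_full) conc[core_idx] else NULL

  while (!reached && iter < stage$max_iterations) {
    iter <- iter + 1L
    i <- sample.int(np, 1L)
    fac <- stats::rgamma(1L, shape = stage$gamma_shape,
                         scale = stage$gamma_scale)
    old <- params[[i]]
    newp <- params
    newp[[i]] <- old * fac
    sol_m <- solver(newp, guess)
    if (!isTRUE(sol_m$converged)) {
      n_nonconverged <- n_nonconverged + 1L
      next
    }
    cc_m <- .stage_conc(stage, sol_m)
    if (!filter_ok(cc_m, total_curr)) next
    mut <- w_of(cc_m)
    s <- mut$w / w_curr - 1
    if (record_proposals) {
      nprop <- nprop + 1L
      if (nprop > length(prop_par)) {
        prop_par <- c(prop_par, integer(length(prop_par)))
        prop_delta <- c(prop_delta, numeric(length(prop_delta)))
        prop_s <- c(prop_s, numeric(length(prop_s)))
      }
      prop_par[nprop] <- i
      prop_delta[nprop] <- fac - 1
      prop_s[nprop] <- s
    }
    if (s <= 0) next
    if (stats::runif(1L) >= -expm1(-s)) next
    # fixation
    nfix <- nfix + 1L
    if (nfix > length(fixed)) fixed <- c(fixed, vector("list", length(fixed)))
    a <- anth_of(cc_m)
    aden <- max(sum(a), .Machine$double.eps)
    fixed[[nfix]] <- c(step = nfix, parameter = i, old_value = old,
                       new_value = old * fac, gamma_draw = fac,
                       delta = fac - 1, s = s, W_before = w_curr,
                       W_after = mut$w, pel_ratio = a[1] / aden,
                       cya_ratio = a[2] / aden, del_ratio = a[3] / aden,
                       total_production = prod_of(cc_m),
                       phenotype_value = mut$ratio)
    params <- newp
    conc <- cc_m
    total_curr <- prod_of(conc)
    w_curr <- mut$w
    if (is_full) guess <- conc[core_idx]
    reached <- at_optimum(mut$ratio)
  }

  fx <- if (nfix > 0) {
    m <- do.call(rbind, fixed[seq_len(nfix)])
    df <- as.data.frame(m)
    df$parameter <- pnames[df$parameter]
    df
  } else {
    df <- data.frame(step = integer(0), parameter = character(0),
                     old_value = numeric(0), new_value = numeric(0),
                     gamma_draw = numeric(0), delta = numeric(0),
                     s = numeric(0), W_before = numeric(0),
                     W_after = numeric(0), pel_ratio = numeric(0),
                     cya_ratio = numeric(0), del_ratio = numeric(0),
                     total_production = numeric(0),
                     phenotype_value = numeric(0))
    df
  }

  proposals <- NULL
  if (record_proposals && nprop > 0) {
    proposals <- data.frame(parameter = pnames[prop_par[seq_len(nprop)]],
                            delta = prop_delta[seq_len(nprop)],
                            s = prop_s[seq_len(nprop)])
  }

  structure(
    list(seed = seed, stage_name = stage$name, target = stage$target,
         mode = stage$mode,
         start_params = model$params, final_params = params,
         start_ratios = stats::setNames(start_ratios, .ANTHOCYANINS),
         start_phenotype = start_ratio,
         fixed_mutations = fx,
         outcome = if (reached) "reached_optimum" else "hit_iteration_cap",
         iterations_used = iter, n_nonconverged = n_nonconverged,
         proposals = proposals),
    class = "anthowalk_trajectory")
}

#' @export
print.anthowalk_trajectory <- function(x, ...) {
  cat(sprintf("<anthowalk_trajectory: %s, seed %d>\n", x$stage_name, x$seed))
  cat(sprintf("  %d fixed mutations, %s after %d iterations\n",
              nrow(x$fixed_mutations), x$outcome, x$iterations_used))
  invisible(x)
}

#' Run an ensemble of independent adaptive walks
#'
#' Per-trajectory seeds are derived deterministically from `base_seed`
#' (distinct by construction), so the whole ensemble is reproducible from
#' the stage definition and the single master seed.
#'
#' @param stage a `transition_stage`.
#' @param n number of trajectories.
#' @param base_seed master seed.
#' @param record_proposals forwarded to [evolve_trajectory()].
#' @return an `anthowalk_ensemble`.
#' @export
run_ensemble <- function(stage, n, base_seed, record_proposals = FALSE) {
  stopifnot(n >= 1)
  set.seed(base_seed)
  seeds <- sample.int(2147483646L, n)
  trajectories <- lapply(seeds, function(sd)
    evolve_trajectory(stage, sd, record_proposals = record_proposals))
  structure(
    list(stage = stage, base_seed = base_seed, seeds = seeds,
         trajectories = trajectories),
    class = "anthowalk_ensemble")
}

#' @export
print.anthowalk_ensemble <- function(x, ...) {
  n <- length(x$trajectories)
  done <- sum(vapply(x$trajectories,
                     function(tr) tr$outcome == "reached_optimum", logical(1)))
  cat(sprintf("<anthowalk_ensemble: %s, %d trajectories (%d completed)>\n",
              x$stage$name, n, done))
  invisible(x)
}

#' Completed trajectories of an ensemble
#'
#' Trajectories that hit the iteration cap are retained in storage but
#' excluded from length/step statistics by default.
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @return list of trajectories with outcome `"reached_optimum"`.
#' @export
completed_trajectories <- function(ensemble) {
  Filter(function(tr) tr$outcome == "reached_optimum",
         ensemble$trajectories)
}

#' Pooled fixed-mutation table of an ensemble
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @param completed_only drop capped trajectories (default `TRUE`).
#' @return data frame with one row per fixed mutation: `trajectory_id`,
#'   `step`, `parameter`, `old_value`, `new_value`, `gamma_draw`, `delta`,
#'   `s`, `W_before`, `W_after`, `pel_ratio`, `cya_ratio`, `del_ratio`,
#'   `total_production`.
#' @export
fixed_mutation_table <- function(ensemble, completed_only = TRUE) {
  trs <- if (completed_only) completed_trajectories(ensemble)
         else ensemble$trajectories
  if (length(trs) == 0)
    return(cbind(data.frame(trajectory_id = integer(0)),
                 evolve_trajectory_empty_fixed()))
  out <- lapply(seq_along(trs), function(i) {
    fx <- trs[[i]]$fixed_mutations
    if (nrow(fx) == 0) return(NULL)
    cbind(data.frame(trajectory_id = i), fx)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- cbind(data.frame(trajectory_id = integer(0)),
                 evolve_trajectory_empty_fixed())
  rownames(out) <- NULL
  out
}

# empty fixed-mutation schema (shared by the reducers)
evolve_trajectory_empty_fixed <- function() {
  data.frame(step = integer(0), parameter = character(0),
             old_value = numeric(0), new_value = numeric(0),
             gamma_draw = numeric(0), delta = numeric(0), s = numeric(0),
             W_before = numeric(0), W_after = numeric(0),
             pel_ratio = numeric(0), cya_ratio = numeric(0),
             del_ratio = numeric(0), total_production = numeric(0),
             phenotype_value = numeric(0))
}

#' Mean evolved parameter state of an ensemble
#'
#' Arithmetic mean of each parameter's end-state value across completed
#' trajectories; used to chain sequential transition stages.
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @return named numeric vector of parameter values.
#' @export
mean_evolved_state <- function(ensemble) {
  trs <- completed_trajectories(ensemble)
  if (length(trs) == 0)
    stop("no completed trajectories: mean evolved state undefined")
  m <- vapply(trs, function(tr) tr$final_params,
              numeric(length(trs[[1]]$final_params)))
  rowMeans(m)
}

#' Run the staged flower-colour transition experiment
#'
#' Executes naive -> blue (90% delphinidin), blue -> purple (90% cyanidin)
#' and purple -> red (90% pelargonidin) in order. Each stage starts from the
#' mean evolved parameter state of the previous stage's completed
#' trajectories.
#'
#' @param n_trajectories number of trajectories per stage; scalar or
#'   length-3 vector in stage order.
#' @param base_seed master seed; stage seeds are derived from it.
#' @param naive_model starting model (default the naive full pathway).
#' @param ratio_opt,optimum_tol,production_tol,max_iterations,gamma_shape,gamma_scale
#'   forwarded to every stage.
#' @param record_proposals forwarded to the trajectory runner.
#' @param stages subset of `c("naive_to_del","del_to_cya","cya_to_pel")` to
#'   run (in order); later stages require the earlier ones.
#' @return named list of `anthowalk_ensemble` objects, one per stage, with
#'   the mean evolved state attached as attribute `"mean_state"`.
#' @export
run_sequential_experiment <- function(n_trajectories, base_seed,
                                      naive_model = build_full_pathway(),
                                      ratio_opt = 0.9, optimum_tol = 0.10,
                                      production_tol = 0.10,
                                      max_iterations = 50000L,
                                      gamma_shape = 0.8, gamma_scale = 3,
                                      record_proposals = FALSE,
                                      stages = c("naive_to_del",
                                                 "del_to_cya",
                                                 "cya_to_pel")) {
  defs <- list(naive_to_del = "del", del_to_cya = "cya", cya_to_pel = "pel")
  stages <- match.arg(stages, names(defs), several.ok = TRUE)
  if (length(n_trajectories) == 1)
    n_trajectories <- rep(n_trajectories, length(stages))
  stopifnot(length(n_trajectories) == length(stages))
  set.seed(base_seed)
  stage_seeds <- sample.int(2147483646L, length(stages))
  model <- naive_model
  out <- list()
  for (k in seq_along(stages)) {
    nm <- stages[k]
    stage <- transition_stage(nm, model, target = defs[[nm]],
                              ratio_opt = ratio_opt,
                              optimum_tol = optimum_tol,
                              production_tol = production_tol,
                              max_iterations = max_iterations,
                              gamma_shape = gamma_shape,
                              gamma_scale = gamma_scale)
    ens <- run_ensemble(stage, n_trajectories[k], stage_seeds[k],
                        record_proposals = record_proposals)
    mean_state <- mean_evolved_state(ens)
    attr(ens, "mean_state") <- mean_state
    out[[nm]] <- ens
    model <- set_params(model, mean_state)
  }
  out
}

#' Run the alternative-fitness control experiments
#'
#' Experiment A evolves the linear pelargonidin sub-pathway, and experiment
#' B the full naive branched model, toward a threefold increase in
#' steady-state pelargonidin concentration, with the ratio of pelargonidin
#' to all other dynamic species held near its start value by a stabilizing
#' fitness component (see [transition_stage()], mode `"production3x"`).
#'
#' @param n_replicates replicates per experiment (default 2000, as in the
#'   headline design; reduce for quick checks).
#' @param base_seed master seed.
#' @param production_tol retained for interface symmetry (the ratio
#'   constraint is enforced through the fitness in this mode).
#' @param optimum_tol stopping tolerance on the fold-increase (default 0.10).
#' @param max_iterations proposal cap (default 50000).
#' @param record_proposals forwarded to the trajectory runner.
#' @return list with ensembles `linear` and `branched`.
#' @export
run_control_experiments <- function(n_replicates = 2000, base_seed,
                                    production_tol = 0.10,
                                    optimum_tol = 0.10,
                                    max_iterations = 50000L,
                                    record_proposals = FALSE) {
  set.seed(base_seed)
  seeds <- sample.int(2147483646L, 2)
  stage_a <- transition_stage("linear_pel3x", build_linear_pathway(),
                              mode = "production3x",
                              production_tol = production_tol,
                              optimum_tol = optimum_tol,
                              max_iterations = max_iterations)
  stage_b <- transition_stage("branched_pel3x", build_full_pathway(),
                              mode = "production3x",
                              production_tol = production_tol,
                              optimum_tol = optimum_tol,
                              max_iterations = max_iterations)
  list(linear = run_ensemble(stage_a, n_replicates, seeds[1],
                             record_proposals = record_proposals),
       branched = run_ensemble(stage_b, n_replicates, seeds[2],
                               record_proposals = record_proposals))
}

#' Replay a trajectory's fixed mutations
#'
#' Applies the recorded multiplicative mutations to the start state,
#' reproducing every intermediate parameter state exactly.
#'
#' @param trajectory an `anthowalk_trajectory`.
#' @param through_step replay up to this step (default all).
#' @return named parameter vector after `through_step` fixations.
#' @export
replay_state <- function(trajectory, through_step = NULL) {
  fx <- trajectory$fixed_mutations
  k <- if (is.null(through_step)) nrow(fx) else through_step
  stopifnot(k >= 0, k <= nrow(fx))
  params <- trajectory$start_params
  for (i in seq_len(k)) params[[fx$parameter[i]]] <- fx$new_value[i]
  params
}
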