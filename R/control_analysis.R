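# Metabolic control analysis: scaled concentration control coefficients
# CC[S][E] = d ln [S]_ss / d ln Et_E, by log-central finite differences.

#' Concentration control coefficient matrix
#'
#' For each enzyme, the enzyme concentration is perturbed multiplicatively
#' to Et*(1+h) and Et/(1+h) and the scaled coefficient computed as
#' (ln S(+) - ln S(-)) / (2 ln(1+h)). Entries where the species
#' concentration is zero (or the perturbed state fails to converge) are
#' `NA`.
#'
#' @param model a converged `pathway_model` state.
#' @param rel_step relative perturbation h (default 0.01).
#' @return matrix (species x enzymes) of class `cc_matrix`, with the
#'   evaluation state's concentrations attached as attribute `"state"`.
#' @export
control_coefficients <- function(model, rel_step = 0.01) {
  base <- steady_state(model)
  if (!base$converged) stop("model does not converge to a steady state")
  enzymes <- unique(model$reactions$enzyme)
  species <- model$species
  cc <- matrix(NA_real_, nrow = length(species), ncol = length(enzymes),
               dimnames = list(species, enzymes))
  logstep <- log1p(rel_step)
  for (e in enzymes) {
    et_name <- paste0(e, "t")
    et <- model$params[[et_name]]
    up <- steady_state(set_params(model, stats::setNames(et * (1 + rel_step),
                                                         et_name)))
    dn <- steady_state(set_params(model, stats::setNames(et / (1 + rel_step),
                                                         et_name)))
    if (!up$converged || !dn$converged) next
    cp <- up$concentrations[species]
    cm <- dn$concentrations[species]
    c0 <- base$concentrations[species]
    ok <- is.finite(cp) & is.finite(cm) & is.finite(c0) &
      cp > 0 & cm > 0 & c0 > 0
    cc[ok, e] <- (log(cp[ok]) - log(cm[ok])) / (2 * logstep)
    cc[species == "PCoA", e] <- 0  # boundary species is held fixed
  }
  structure(cc, class = c("cc_matrix", "matrix"),
            rel_step = rel_step, state = base$concentrations)
}

#' Relative control of CHS over a target species
#'
#' |CC_CHS,target / sum_E CC_E,target| — the absolute value of the ratio of
#' the CHS coefficient to the summed coefficients over all enzymes. The
#' alternative normalization |CC_CHS| / sum_E |CC_E| is available via
#' `method = "abs_ratio"`.
#'
#' @param matrix a `cc_matrix`.
#' @param target species name (row of the matrix).
#' @param method `"ratio_abs"` (default, literal ratio-then-absolute-value)
#'   or `"abs_ratio"`.
#' @return value in \[0, 1\] (`NA` when the denominator is zero or entries
#'   are undefined).
#' @export
chs_relative_control <- function(matrix, target,
                                 method = c("ratio_abs", "abs_ratio")) {
  method <- match.arg(method)
  row <- matrix[target, ]
  if (anyNA(row)) return(NA_real_)
  denom <- if (method == "ratio_abs") sum(row) else sum(abs(row))
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  if (method == "ratio_abs") abs(row[["CHS"]] / denom)
  else abs(row[["CHS"]]) / denom
}

#' CHS relative-control trajectory of an ensemble
#'
#' Replays each completed trajectory's fixed mutations, computes the CHS
#' relative control over the target species at every step state, and
#' aggregates across trajectories by step index (statistics at step k use
#' the trajectories that have a state at step k).
#'
#' @param ensemble an `anthowalk_ensemble` over the full model.
#' @param target species the stage selects on (default the stage target).
#' @param rel_step finite-difference perturbation.
#' @param method forwarded to [chs_relative_control()].
#' @param max_trajectories optional cap on the number of trajectories
#'   analysed (control analysis costs ~17 steady-state solves per state).
#' @return data frame (step, mean, sd, n); step 0 is the shared start state.
#' @export
control_trajectory <- function(ensemble, target = NULL, rel_step = 0.01,
                               method = c("ratio_abs", "abs_ratio"),
                               max_trajectories = NULL) {
  method <- match.arg(method)
  if (is.null(target)) target <- ensemble$stage$target
  model <- ensemble$stage$start_model
  trs <- completed_trajectories(ensemble)
  if (!is.null(max_trajectories) && length(trs) > max_trajectories)
    trs <- trs[seq_len(max_trajectories)]
  vals <- list()
  for (ti in seq_along(trs)) {
    tr <- trs[[ti]]
    for (k in 0:nrow(tr$fixed_mutations)) {
      st <- set_params(model, replay_state(tr, k))
      v <- tryCatch(
        chs_relative_control(control_coefficients(st, rel_step), target,
                             method = method),
        error = function(e) NA_real_)
      vals[[length(vals) + 1L]] <- c(step = k, value = v)
    }
  }
  df <- as.data.frame(do.call(rbind, vals))
  out <- do.call(rbind, lapply(split(df$value, df$step), function(v) {
    v <- v[!is.na(v)]
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  out <- cbind(step = as.integer(rownames(out)), out)
  out$sd[out$n == 1] <- 0
  rownames(out) <- NULL
  out[order(out$step), ]
}
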