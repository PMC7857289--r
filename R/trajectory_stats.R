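# Ensemble reducers: the summary statistics of the transition experiments.

.HOTSPOTS <- c("F35pH", "F3pH", "DFR", "FLS")

#' Trajectory length distribution and median
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @param completed_only exclude capped trajectories (default `TRUE`).
#' @return list with `lengths` (integer vector), `median`, `histogram`
#'   (table), and `n_capped`.
#' @export
trajectory_length_stats <- function(ensemble, completed_only = TRUE) {
  trs <- if (completed_only) completed_trajectories(ensemble)
         else ensemble$trajectories
  lens <- vapply(trs, function(tr) nrow(tr$fixed_mutations), integer(1))
  n_capped <- sum(vapply(ensemble$trajectories,
                         function(tr) tr$outcome == "hit_iteration_cap",
                         logical(1)))
  list(lengths = lens, median = stats::median(lens),
       histogram = table(lens), n_capped = n_capped)
}

#' Share of fixed mutations at the hotspot enzymes
#'
#' @param ensemble an `anthowalk_ensemble` (or a pooled fixed-mutation
#'   table).
#' @param loci enzyme identifiers counted as hotspots; default
#'   F3'5'H, F3'H, DFR, FLS.
#' @return fraction of fixed mutations whose parameter belongs to a listed
#'   enzyme.
#' @export
hotspot_share <- function(ensemble, loci = .HOTSPOTS) {
  fx <- if (is.data.frame(ensemble)) ensemble
        else fixed_mutation_table(ensemble)
  if (nrow(fx) == 0) return(NA_real_)
  if (length(loci) == 0) return(0)
  mean(param_enzyme(fx$parameter) %in% loci)
}

#' Biochemical vs regulatory fixation summary per enzyme
#'
#' Counts fixed mutations per enzyme split into biochemical (kcat/KM) and
#' regulatory (Et) classes, normalized by the number of parameters of each
#' class the enzyme carries (an enzyme with m substrates has 2m biochemical
#' parameters and one Et).
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @return data frame with per-enzyme raw counts, class sizes, per-parameter
#'   normalized rates, and the normalized regulatory proportion
#'   `rate_regulatory / (rate_regulatory + rate_biochemical)`.
#' @export
mutation_type_split <- function(ensemble) {
  fx <- fixed_mutation_table(ensemble)
  model <- ensemble$stage$start_model
  enzymes <- unique(model$reactions$enzyme)
  nsub <- table(factor(model$reactions$enzyme, levels = enzymes))
  enz <- param_enzyme(fx$parameter)
  reg <- is_regulatory(fx$parameter)
  out <- data.frame(
    enzyme = enzymes,
    n_substrates = as.integer(nsub),
    n_biochemical_params = 2L * as.integer(nsub),
    n_regulatory_params = 1L,
    n_biochemical = vapply(enzymes, function(e) sum(enz == e & !reg),
                           integer(1)),
    n_regulatory = vapply(enzymes, function(e) sum(enz == e & reg),
                          integer(1))
  )
  out$rate_biochemical <- out$n_biochemical / out$n_biochemical_params
  out$rate_regulatory <- out$n_regulatory / out$n_regulatory_params
  tot <- out$rate_biochemical + out$rate_regulatory
  out$prop_regulatory_normalized <- ifelse(tot > 0,
                                           out$rate_regulatory / tot,
                                           NA_real_)
  raw_tot <- out$n_biochemical + out$n_regulatory
  out$prop_regulatory_raw <- ifelse(raw_tot > 0,
                                    out$n_regulatory / raw_tot, NA_real_)
  rownames(out) <- NULL
  out
}

#' Raw regulatory share of fixations at a set of enzymes
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @param loci enzymes to restrict to (default the hotspots).
#' @return fraction of fixed mutations at `loci` that hit an Et parameter.
#' @export
regulatory_share <- function(ensemble, loci = .HOTSPOTS) {
  fx <- fixed_mutation_table(ensemble)
  fx <- fx[param_enzyme(fx$parameter) %in% loci, , drop = FALSE]
  if (nrow(fx) == 0) return(NA_real_)
  mean(is_regulatory(fx$parameter))
}

#' Directional shifts of fixed mutations or end states
#'
#' `per_mutation`: the normalized size delta = (new - old)/old of every
#' fixed mutation. `end_state`: (final - initial)/initial per parameter per
#' completed trajectory.
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @param mode `"per_mutation"` or `"end_state"`.
#' @return data frame (parameter, shift) with one row per observation
#'   (`end_state` mode also carries `trajectory_id`).
#' @export
directional_shifts <- function(ensemble,
                               mode = c("per_mutation", "end_state")) {
  mode <- match.arg(mode)
  if (mode == "per_mutation") {
    fx <- fixed_mutation_table(ensemble)
    return(data.frame(parameter = fx$parameter, shift = fx$delta))
  }
  trs <- completed_trajectories(ensemble)
  out <- lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    data.frame(trajectory_id = i,
               parameter = names(tr$start_params),
               shift = (tr$final_params - tr$start_params) /
                 tr$start_params,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Per-step distributions of fixed selection coefficients
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @param completed_only restrict to completed trajectories (default
#'   `TRUE`); set `FALSE` for experiments where walks routinely run into
#'   the iteration cap but their fixed steps are still informative.
#' @return data frame (step, n, median, q1, q3, mean) over the fixed
#'   mutations at each step index (trajectories shorter than a step do not
#'   contribute to it).
#' @export
stepwise_s_distributions <- function(ensemble, completed_only = TRUE) {
  fx <- fixed_mutation_table(ensemble, completed_only = completed_only)
  if (nrow(fx) == 0)
    return(data.frame(step = integer(0), n = integer(0), median = numeric(0),
                      q1 = numeric(0), q3 = numeric(0), mean = numeric(0)))
  out <- do.call(rbind, lapply(split(fx$s, fx$step), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               mean = mean(v))
  }))
  out <- cbind(step = as.integer(rownames(out)), out)
  rownames(out) <- NULL
  out[order(out$step), ]
}

#' Fraction of trajectories whose second fixed mutation outranks the first
#'
#' Considers only completed trajectories with at least two fixed mutations;
#' the count of shorter trajectories is attached as attribute
#' `"n_excluded"`.
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @return fraction with s(step 2) > s(step 1).
#' @export
step2_gt_step1_fraction <- function(ensemble) {
  trs <- completed_trajectories(ensemble)
  s12 <- lapply(trs, function(tr) {
    fx <- tr$fixed_mutations
    if (nrow(fx) < 2) return(NULL)
    c(fx$s[1], fx$s[2])
  })
  keep <- !vapply(s12, is.null, logical(1))
  m <- do.call(rbind, s12[keep])
  out <- if (is.null(m)) NA_real_ else mean(m[, 2] > m[, 1])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Fixation-order heatmap
#'
#' Counts fixation events per (parameter, step), restricted to parameters
#' carrying at least `min_share` of all fixed mutations, ordered by
#' descending total count, with a row-wise MinMax-normalized copy.
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @param min_share minimum share of total fixations for a row (default
#'   0.01).
#' @return list with `counts` and `normalized` matrices (rows parameters,
#'   columns steps).
#' @export
fixation_step_heatmap <- function(ensemble, min_share = 0.01) {
  fx <- fixed_mutation_table(ensemble)
  if (nrow(fx) == 0) return(list(counts = NULL, normalized = NULL))
  steps <- seq_len(max(fx$step))
  counts <- table(factor(fx$parameter), factor(fx$step, levels = steps))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  share <- rowSums(counts) / nrow(fx)
  counts <- counts[share >= min_share, , drop = FALSE]
  counts <- counts[order(-rowSums(counts)), , drop = FALSE]
  normalized <- t(apply(counts, 1, function(r) {
    if (max(r) == min(r)) return(as.numeric(r > 0))
    (r - min(r)) / (max(r) - min(r))
  }))
  dimnames(normalized) <- dimnames(counts)
  list(counts = counts, normalized = normalized)
}

#' Mutational sensitivity distributions per parameter
#'
#' Sensitivity of a proposal is |s / delta| with delta = (new - old)/old,
#' computed over all evaluated proposals with a recorded selection
#' coefficient (not only fixed ones); run the ensemble with
#' `record_proposals = TRUE`.
#'
#' @param ensemble an `anthowalk_ensemble` run with proposal recording.
#' @return list with `values` (data frame parameter, sensitivity) and
#'   `summary` (per-parameter n, mean sensitivity, total fixations);
#'   proposals with delta = 0 are skipped and counted in
#'   attribute `"n_zero_delta"`.
#' @export
sensitivity_distributions <- function(ensemble) {
  props <- lapply(ensemble$trajectories, function(tr) tr$proposals)
  props <- do.call(rbind, props[!vapply(props, is.null, logical(1))])
  if (is.null(props) || nrow(props) == 0)
    stop("no recorded proposals; run the ensemble with record_proposals = TRUE")
  zero <- props$delta == 0
  props <- props[!zero, , drop = FALSE]
  values <- data.frame(parameter = props$parameter,
                       sensitivity = abs(props$s / props$delta))
  fx <- fixed_mutation_table(ensemble)
  nfix <- table(factor(fx$parameter, levels = unique(values$parameter)))
  summary <- do.call(rbind, lapply(split(values$sensitivity,
                                         values$parameter), function(v)
    data.frame(n = length(v), mean_sensitivity = mean(v))))
  summary <- cbind(parameter = rownames(summary), summary)
  summary$n_fixed <- as.integer(nfix[summary$parameter])
  rownames(summary) <- NULL
  out <- list(values = values, summary = summary)
  attr(out, "n_zero_delta") <- sum(zero)
  out
}

#' Mean trajectory through pigment space
#'
#' Per-step mean and standard deviation of the three anthocyanin ratios
#' across completed trajectories; step 0 is the shared start phenotype.
#' Statistics at step k use the trajectories of length >= k.
#'
#' @param ensemble an `anthowalk_ensemble`.
#' @return data frame (step, n, pel_mean, pel_sd, cya_mean, cya_sd,
#'   del_mean, del_sd).
#' @export
pigment_space_trajectory <- function(ensemble) {
  trs <- completed_trajectories(ensemble)
  if (length(trs) == 0) return(NULL)
  rows <- lapply(trs, function(tr) {
    fx <- tr$fixed_mutations
    rbind(c(0, tr$start_ratios),
          if (nrow(fx) > 0)
            cbind(fx$step, fx$pel_ratio, fx$cya_ratio, fx$del_ratio))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("step", "pel", "cya", "del")
  out <- do.call(rbind, lapply(split(as.data.frame(m), m[, "step"]),
                               function(d) {
    data.frame(step = d$step[1], n = nrow(d),
               pel_mean = mean(d$pel), pel_sd = stats::sd(d$pel),
               cya_mean = mean(d$cya), cya_sd = stats::sd(d$cya),
               del_mean = mean(d$del), del_sd = stats::sd(d$del))
  }))
  out$pel_sd[out$n == 1] <- 0
  out$cya_sd[out$n == 1] <- 0
  out$del_sd[out$n == 1] <- 0
  rownames(out) <- NULL
  out[order(out$step), ]
}
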