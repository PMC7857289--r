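# Steady-state solution and derived phenotypes.

# canonical packing order for the compiled full-model solver (length 38 + 2)
.FULL_PACK_ORDER <- c(
  "k_CHS_PCoA", "Km_CHS_PCoA", "CHSt",
  "k_CHI_cha", "Km_CHI_cha", "CHIt",
  "k_F3H_nar", "Km_F3H_nar", "F3Ht",
  "k_F3pH_DHK", "Km_F3pH_DHK", "F3pHt",
  "k_F35pH_DHK", "Km_F35pH_DHK", "k_F35pH_DHQ", "Km_F35pH_DHQ", "F35pHt",
  "k_DFR_DHK", "Km_DFR_DHK", "k_DFR_DHQ", "Km_DFR_DHQ",
  "k_DFR_DHM", "Km_DFR_DHM", "DFRt",
  "k_FLS_DHK", "Km_FLS_DHK", "k_FLS_DHQ", "Km_FLS_DHQ",
  "k_FLS_DHM", "Km_FLS_DHM", "FLSt",
  "k_ANS_LCP", "Km_ANS_LCP", "k_ANS_LCC", "Km_ANS_LCC",
  "k_ANS_LCD", "Km_ANS_LCD", "ANSt")

.FLUX_NAMES_FULL <- c(
  "CHS_PCoA", "CHI_cha", "F3H_nar", "F3pH_DHK", "F35pH_DHK", "F35pH_DHQ",
  "DFR_DHK", "DFR_DHQ", "DFR_DHM", "FLS_DHK", "FLS_DHQ", "FLS_DHM",
  "ANS_LCP", "ANS_LCC", "ANS_LCD",
  "sink_pel", "sink_cya", "sink_del", "sink_kam", "sink_que", "sink_myr")

.LINEAR_PACK_ORDER <- c(
  "k_CHS_PCoA", "Km_CHS_PCoA", "CHSt",
  "k_CHI_cha", "Km_CHI_cha", "CHIt",
  "k_F3H_nar", "Km_F3H_nar", "F3Ht",
  "k_DFR_DHK", "Km_DFR_DHK", "DFRt",
  "k_ANS_LCP", "Km_ANS_LCP", "ANSt")

.pack_full <- function(params, boundary) {
  v <- rep(1, 40)
  idx <- match(.FULL_PACK_ORDER, names(params))
  v[seq_len(38)][!is.na(idx)] <- unname(params[idx[!is.na(idx)]])
  v[39] <- boundary[["PCoA"]]
  v[40] <- boundary[["ksink"]]
  v
}

.ss_result <- function(converged, status, conc, flux, method) {
  structure(
    list(converged = converged, status = status,
         concentrations = conc, fluxes = flux,
         total_production = if (converged)
           sum(conc[intersect(names(conc), .END_PRODUCTS)]) else NA_real_,
         method = method),
    class = "steady_state_result")
}

# fast path used by the evolution inner loop: full model, packed parameters
.ss_full_raw <- function(packed, two_sub = TRUE, guess = NULL) {
  .c_steady_state_full(packed, two_sub, guess)
}

.ss_linear <- function(params, boundary) {
  pcoa <- boundary[["PCoA"]]
  ksink <- boundary[["ksink"]]
  vin <- params[["CHSt"]] * params[["k_CHS_PCoA"]] * pcoa /
    (params[["Km_CHS_PCoA"]] + pcoa)
  chain <- list(c("CHI", "cha"), c("F3H", "nar"), c("DFR", "DHK"),
                c("ANS", "LCP"))
  conc <- stats::setNames(numeric(6), .SPECIES_LINEAR)
  conc["PCoA"] <- pcoa
  ok <- TRUE
  for (st in chain) {
    vmax <- params[[paste0(st[1], "t")]] *
      params[[paste0("k_", st[1], "_", st[2])]]
    km <- params[[paste0("Km_", st[1], "_", st[2])]]
    if (vin <= 0) { conc[st[2]] <- 0 } else if (vmax > vin) {
      conc[st[2]] <- vin * km / (vmax - vin)
    } else { ok <- FALSE; break }
  }
  if (ok) conc["pel"] <- vin / ksink else conc[] <- NA_real_
  flux <- c(rep(vin, 5), vin)
  names(flux) <- c("CHS_PCoA", "CHI_cha", "F3H_nar", "DFR_DHK", "ANS_LCP",
                   "sink_pel")
  if (!ok) flux[] <- NA_real_
  .ss_result(ok, if (ok) 0L else 1L, conc, flux, "closed_form")
}

#' Solve a pathway model for its steady state
#'
#' For the linear chain the solution is closed-form (the influx set by CHS
#' propagates unchanged through every step, so each intermediate follows
#' from inverting its consuming Michaelis-Menten law and the end product is
#' influx/ksink). The full branched model is solved by the compiled cascade
#' solver (closed forms for the unbranched segments, damped Newton on the
#' dihydroflavonol core, closed form for the ANS layer), with numerical
#' integration of the full ODE system as a last-resort fallback.
#'
#' A model whose downstream capacity cannot carry the CHS influx (so that an
#' intermediate accumulates without bound) has no steady state; this is
#' reported as `converged = FALSE` rather than an error, and the
#' evolutionary engine treats such proposals as rejected.
#'
#' @param model a `pathway_model`.
#' @param guess optional length-3 non-negative vector used to warm-start the
#'   Newton iteration on (DHK, DHQ, DHM); purely a performance hint.
#' @return a `steady_state_result` with fields `converged`, `concentrations`
#'   (all species), `fluxes` (enzymatic reactions and sinks),
#'   `total_production` (sum of the six end products) and `method`.
#' @export
steady_state <- function(model, guess = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  if (model$topology == "linear")
    return(.ss_linear(model$params, model$boundary))
  packed <- .pack_full(model$params, model$boundary)
  two_sub <- "DHK" %in% model$f35ph_substrates
  raw <- .ss_full_raw(packed, two_sub, guess)
  if (!raw$converged && raw$status == 2L) {
    ode <- .steady_state_ode(model)
    if (ode$converged) return(ode)
  }
  conc <- stats::setNames(raw$conc, .SPECIES_FULL)
  flux <- stats::setNames(raw$flux, .FLUX_NAMES_FULL)
  .ss_result(raw$converged, raw$status, conc, flux, "cascade")
}

# vectorized RHS closure over the model's reaction table; avoids per-call
# data-frame work so lsoda can evaluate it cheaply
.compile_rhs <- function(model) {
  rx <- .reactions_with_kinetics(model)
  sub_idx <- match(rx$substrate, model$species)
  prod_idx <- match(rx$product, model$species)
  enz <- factor(rx$enzyme, levels = unique(rx$enzyme))
  ends <- match(intersect(model$species, .END_PRODUCTS), model$species)
  ksink <- model$boundary[["ksink"]]
  pcoa_idx <- match("PCoA", model$species)
  km <- rx$km; kcat <- rx$kcat; et <- rx$et
  enz_split <- split(seq_len(nrow(rx)), enz)
  function(y) {
    u <- y[sub_idx] / km
    v <- numeric(length(u))
    for (rows in enz_split) {
      D <- 1 + sum(u[rows])
      v[rows] <- et[rows] * kcat[rows] * u[rows] / D
    }
    d <- numeric(length(y))
    for (i in seq_along(v)) {
      d[sub_idx[i]] <- d[sub_idx[i]] - v[i]
      d[prod_idx[i]] <- d[prod_idx[i]] + v[i]
    }
    d[ends] <- d[ends] - ksink * y[ends]
    d[pcoa_idx] <- 0
    d
  }
}

# ODE-integration solver (deSolve); fallback and reference path
.steady_state_ode <- function(model, t_chunk = 2000, max_chunks = 25,
                              tol = 1e-9) {
  y0 <- stats::setNames(rep(0, length(model$species)), model$species)
  y0["PCoA"] <- model$boundary[["PCoA"]]
  rhs_fn <- .compile_rhs(model)
  rhs <- function(t, y, parms) list(rhs_fn(y))
  y <- y0
  converged <- FALSE
  for (i in seq_len(max_chunks)) {
    out <- suppressWarnings(deSolve::lsoda(y, c(0, t_chunk), rhs, NULL,
                                           rtol = 1e-10, atol = 1e-12))
    y <- stats::setNames(out[nrow(out), -1], model$species)
    # a species growing without bound means no steady state exists
    if (any(!is.finite(y)) || any(y > 1e7)) break
    d <- rhs_fn(y)
    if (max(abs(d)) < tol * max(1, max(y))) { converged <- TRUE; break }
  }
  conc <- pmax(y, 0)
  flux <- if (converged) model_rates(model, as.list(conc)) else NULL
  if (!converged) {
    conc[] <- NA_real_
    flux <- stats::setNames(
      rep(NA_real_, nrow(model$reactions) +
            length(intersect(model$species, .END_PRODUCTS))), NULL)
  }
  .ss_result(converged, if (converged) 0L else 2L, conc, flux, "ode")
}

#' @export
print.steady_state_result <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<steady_state_result: NOT converged (status %d)>\n",
                x$status))
    return(invisible(x))
  }
  cat(sprintf("<steady_state_result: converged (%s)>\n", x$method))
  cat(sprintf("  total end-product production: %.6g\n", x$total_production))
  anth <- intersect(names(x$concentrations), .ANTHOCYANINS)
  if (length(anth) == 3) {
    r <- x$concentrations[anth] / sum(x$concentrations[anth])
    cat(sprintf("  anthocyanin ratios: pel %.3f, cya %.3f, del %.3f\n",
                r[["pel"]], r[["cya"]], r[["del"]]))
  }
  invisible(x)
}

#' Pigment phenotype of a steady state
#'
#' The phenotype under selection is the ratio of a target anthocyanin to the
#' summed anthocyanins, plus the total end-product production used by the
#' stabilizing production filter.
#'
#' @param result a converged `steady_state_result`.
#' @param target one of `"pel"`, `"cya"`, `"del"`.
#' @return list with `ratio_current` (fraction in \[0,1\], `NA` when the
#'   phenotype is degenerate), `total_production`, and `degenerate` (`TRUE`
#'   when all three anthocyanins are at machine-epsilon level, in which case
#'   the caller assigns fitness 0).
#' @export
phenotype <- function(result, target = c("pel", "cya", "del")) {
  target <- match.arg(target)
  stopifnot(inherits(result, "steady_state_result"))
  if (!result$converged) stop("phenotype of a non-converged steady state")
  anth <- result$concentrations[intersect(names(result$concentrations),
                                          .ANTHOCYANINS)]
  denom <- sum(anth)
  if (!is.finite(denom) || denom <= .Machine$double.eps) {
    return(list(ratio_current = NA_real_,
                total_production = result$total_production,
                degenerate = TRUE))
  }
  tgt <- if (target %in% names(anth)) anth[[target]] else 0
  list(ratio_current = tgt / denom,
       total_production = result$total_production,
       degenerate = FALSE)
}

#' All three anthocyanin ratios of a steady state
#'
#' @param result a converged `steady_state_result`.
#' @return named numeric vector `c(pel=, cya=, del=)`; `NA` if degenerate.
#' @export
anthocyanin_ratios <- function(result) {
  anth <- result$concentrations[.ANTHOCYANINS]
  anth[is.na(anth)] <- 0
  denom <- sum(anth)
  if (denom <= .Machine$double.eps)
    return(stats::setNames(rep(NA_real_, 3), .ANTHOCYANINS))
  stats::setNames(unname(anth / denom), .ANTHOCYANINS)
}
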