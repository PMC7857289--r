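# Independent oracles for the steady-state solver.
#
# The mass balances here are written out by hand, species by species, so the
# ODE oracle does not share code with the package's cascade solver (which
# never assembles these balances numerically).

# time derivatives of the full branched model, hand-coded
oracle_full_rhs <- function(concs, p, two_sub = TRUE) {
  with(as.list(c(concs, p)), {
    v_chs <- CHSt * k_CHS_PCoA * PCoA / (Km_CHS_PCoA + PCoA)
    v_chi <- CHIt * k_CHI_cha * cha / (Km_CHI_cha + cha)
    v_f3h <- F3Ht * k_F3H_nar * nar / (Km_F3H_nar + nar)
    v_f3ph <- F3pHt * k_F3pH_DHK * DHK / (Km_F3pH_DHK + DHK)
    d35 <- 1 + (if (two_sub) DHK / Km_F35pH_DHK else 0) + DHQ / Km_F35pH_DHQ
    v_f35ph_k <- if (two_sub)
      F35pHt * k_F35pH_DHK * (DHK / Km_F35pH_DHK) / d35 else 0
    v_f35ph_q <- F35pHt * k_F35pH_DHQ * (DHQ / Km_F35pH_DHQ) / d35
    dd <- 1 + DHK / Km_DFR_DHK + DHQ / Km_DFR_DHQ + DHM / Km_DFR_DHM
    v_dfr_k <- DFRt * k_DFR_DHK * (DHK / Km_DFR_DHK) / dd
    v_dfr_q <- DFRt * k_DFR_DHQ * (DHQ / Km_DFR_DHQ) / dd
    v_dfr_m <- DFRt * k_DFR_DHM * (DHM / Km_DFR_DHM) / dd
    df <- 1 + DHK / Km_FLS_DHK + DHQ / Km_FLS_DHQ + DHM / Km_FLS_DHM
    v_fls_k <- FLSt * k_FLS_DHK * (DHK / Km_FLS_DHK) / df
    v_fls_q <- FLSt * k_FLS_DHQ * (DHQ / Km_FLS_DHQ) / df
    v_fls_m <- FLSt * k_FLS_DHM * (DHM / Km_FLS_DHM) / df
    da <- 1 + LCP / Km_ANS_LCP + LCC / Km_ANS_LCC + LCD / Km_ANS_LCD
    v_ans_p <- ANSt * k_ANS_LCP * (LCP / Km_ANS_LCP) / da
    v_ans_c <- ANSt * k_ANS_LCC * (LCC / Km_ANS_LCC) / da
    v_ans_d <- ANSt * k_ANS_LCD * (LCD / Km_ANS_LCD) / da
    c(PCoA = 0,
      cha = v_chs - v_chi,
      nar = v_chi - v_f3h,
      DHK = v_f3h - v_f3ph - v_f35ph_k - v_dfr_k - v_fls_k,
      DHQ = v_f3ph - v_f35ph_q - v_dfr_q - v_fls_q,
      DHM = v_f35ph_k + v_f35ph_q - v_dfr_m - v_fls_m,
      LCP = v_dfr_k - v_ans_p,
      LCC = v_dfr_q - v_ans_c,
      LCD = v_dfr_m - v_ans_d,
      pel = v_ans_p - ksink * pel,
      cya = v_ans_c - ksink * cya,
      del = v_ans_d - ksink * del,
      kam = v_fls_k - ksink * kam,
      que = v_fls_q - ksink * que,
      myr = v_fls_m - ksink * myr)
  })
}

# brute-force steady state of the full model by long-time integration,
# continued until the hand-coded derivatives vanish (slow relaxation modes
# can need far more than the default horizon)
oracle_full_ss <- function(model, t_chunk = 1e5, max_chunks = 40) {
  p <- c(model$params, model$boundary)
  two_sub <- "DHK" %in% model$f35ph_substrates
  y <- stats::setNames(rep(0, 15),
                       c("PCoA", "cha", "nar", "DHK", "DHQ", "DHM", "LCP",
                         "LCC", "LCD", "pel", "cya", "del", "kam", "que",
                         "myr"))
  y["PCoA"] <- model$boundary[["PCoA"]]
  for (i in seq_len(max_chunks)) {
    out <- deSolve::lsoda(
      y, c(0, t_chunk),
      function(t, y, parms) list(unname(oracle_full_rhs(y, p, two_sub))),
      NULL, rtol = 1e-11, atol = 1e-13)
    y <- stats::setNames(out[nrow(out), -1], names(y))
    if (max(abs(oracle_full_rhs(y, p, two_sub))) < 1e-11 * max(1, max(y)))
      break
  }
  y
}

# closed-form steady state of the linear chain, derived independently:
# the CHS flux propagates unchanged, each intermediate balances its own
# consumption, and the end product is flux/ksink
oracle_linear_ss <- function(params, boundary) {
  vin <- params[["CHSt"]] * params[["k_CHS_PCoA"]] * boundary[["PCoA"]] /
    (params[["Km_CHS_PCoA"]] + boundary[["PCoA"]])
  inv <- function(et, kcat, km) vin * km / (et * kcat - vin)
  c(PCoA = boundary[["PCoA"]],
    cha = inv(params[["CHIt"]], params[["k_CHI_cha"]], params[["Km_CHI_cha"]]),
    nar = inv(params[["F3Ht"]], params[["k_F3H_nar"]], params[["Km_F3H_nar"]]),
    DHK = inv(params[["DFRt"]], params[["k_DFR_DHK"]], params[["Km_DFR_DHK"]]),
    LCP = inv(params[["ANSt"]], params[["k_ANS_LCP"]], params[["Km_ANS_LCP"]]),
    pel = vin / boundary[["ksink"]])
}

# random positive parameter draws around the naive scale
random_full_model <- function() {
  m <- build_full_pathway()
  ov <- stats::setNames(exp(stats::runif(length(m$params), log(0.3), log(3))),
                        names(m$params))
  build_full_pathway(ov)
}
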