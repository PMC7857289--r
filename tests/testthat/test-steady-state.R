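# Steady-state solver against independent oracles, plus phenotype.

test_that("linear chain matches the closed-form oracle on random draws", {
  set.seed(1)
  for (i in 1:30) {
    ov <- stats::setNames(exp(stats::runif(15, log(0.5), log(2))),
                          names(build_linear_pathway()$params))
    m <- build_linear_pathway(ov)
    ss <- steady_state(m)
    ref <- oracle_linear_ss(m$params, m$boundary)
    if (any(ref < 0)) {  # capacity below influx: no steady state
      expect_false(ss$converged)
      next
    }
    expect_true(ss$converged)
    expect_lt(max(abs(ss$concentrations[names(ref)] - ref) /
                    pmax(abs(ref), 1e-12)), 1e-6)
  }
})

test_that("full model agrees with long-time ODE integration", {
  set.seed(2)
  n_checked <- 0
  while (n_checked < 20) {
    m <- random_full_model()
    ss <- steady_state(m)
    if (!ss$converged) next  # infeasible draw: no steady state
    n_checked <- n_checked + 1
    ref <- oracle_full_ss(m)
    expect_lt(max(abs(ss$concentrations - ref) / pmax(abs(ref), 1e-10)),
              1e-5)
  }
})

test_that("flux is conserved at steady state", {
  set.seed(3)
  n_checked <- 0
  for (i in 1:20) {
    m <- random_full_model()
    ss <- steady_state(m)
    if (!ss$converged) next  # capacity below influx: no steady state exists
    n_checked <- n_checked + 1
    influx <- ss$fluxes[["CHS_PCoA"]]
    efflux <- sum(ss$fluxes[grep("^sink_", names(ss$fluxes))])
    expect_lt(abs(influx - efflux), 1e-8 * max(1, influx))
    expect_true(all(ss$concentrations >= 0))
    expect_true(all(is.finite(ss$concentrations)))
  }
  expect_gte(n_checked, 5)
})

test_that("no influx means no downstream production", {
  ss <- steady_state(build_full_pathway(list(CHSt = 0)))
  expect_true(ss$converged)
  expect_equal(unname(ss$concentrations[setdiff(names(ss$concentrations),
                                                "PCoA")]),
               rep(0, 14))
})

test_that("insufficient downstream capacity is reported as non-convergence", {
  # CHI Vmax (0.1) below the CHS influx (0.5): cha accumulates forever
  ss <- steady_state(build_full_pathway(list(CHIt = 0.1)))
  expect_false(ss$converged)
  ssl <- steady_state(build_linear_pathway(list(DFRt = 0.1)))
  expect_false(ssl$converged)
})

test_that("naive model is biased toward pelargonidin", {
  ss <- steady_state(build_full_pathway())
  anth <- ss$concentrations[c("pel", "cya", "del")]
  expect_equal(names(which.max(anth)), "pel")
  r <- anthocyanin_ratios(ss)
  expect_equal(sum(r), 1)
})

test_that("delphinidin responds monotonically to F3'5'H concentration", {
  dels <- vapply(c(0.25, 0.5, 1, 2, 4, 8), function(f) {
    steady_state(build_full_pathway(list(F35pHt = f)))$concentrations[["del"]]
  }, numeric(1))
  expect_true(all(diff(dels) >= -1e-12))
})

test_that("phenotype computes ratios and flags degenerate states", {
  ss <- steady_state(build_full_pathway())
  ph <- phenotype(ss, "pel")
  anth <- ss$concentrations[c("pel", "cya", "del")]
  expect_equal(ph$ratio_current, unname(anth[["pel"]] / sum(anth)))
  expect_equal(ph$total_production, ss$total_production)
  expect_false(ph$degenerate)
  # hand-built ratio checks
  fake <- ss
  fake$concentrations[c("pel", "cya", "del")] <- c(9, 0.5, 0.5)
  expect_equal(phenotype(fake, "pel")$ratio_current, 0.9)
  fake$concentrations[c("pel", "cya", "del")] <- c(2, 2, 2)
  expect_equal(phenotype(fake, "cya")$ratio_current, 1 / 3)
  # dead anthocyanin branch: DFRt = 0 diverts all flux to flavonols
  ss0 <- steady_state(build_full_pathway(list(DFRt = 0)))
  expect_true(ss0$converged)
  expect_true(phenotype(ss0, "del")$degenerate)
})

test_that("warm-start guesses do not change the solution", {
  m <- build_full_pathway(list(DFRt = 3, F35pHt = 0.2, Km_FLS_DHQ = 0.5))
  a <- steady_state(m)
  expect_true(a$converged)
  b <- steady_state(m, guess = c(5, 5, 5))
  expect_lt(max(abs(a$concentrations - b$concentrations)), 1e-7)
})
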