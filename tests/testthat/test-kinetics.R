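test_that("free concentration and saliva concentration arithmetic", {
  expect_equal(free_concentration(10, tcpy()), 0.15)
  unbound <- compound("u", "neutral", fraction_unbound_plasma = 1)
  expect_equal(free_concentration(7, unbound), 7)
  expect_equal(free_concentration(0, tcpy()), 0)
  expect_equal(saliva_concentration(2, 0.058), 0.116)
  expect_equal(saliva_concentration(c(0, 5), 1), c(0, 5))
})

test_that("flow model Q(t) = A t^B + C evaluates and guards t = 0", {
  expect_equal(flow_rate(4, flow_model(2, 0.5, 1)), 5)
  # B = 0: constant A + C
  expect_equal(flow_rate(c(0, 1, 3), flow_model(2, 0, 1)), rep(3, 3))
  # A = 0: constant baseline
  expect_equal(flow_rate(c(0, 2), flow_model(0, 1, 0.7)), rep(0.7, 2))
  # B > 0 at t = 0: baseline
  expect_equal(flow_rate(0, flow_model(2, 0.5, 1)), 1)
  # B < 0 at t = 0: guarded to baseline, with a warning
  expect_warning(q0 <- flow_rate(0, flow_model(2, -0.5, 1)), "singular")
  expect_equal(q0, 1)
  expect_error(flow_model(-1, 0.5, 1), "nonnegative")
  expect_error(flow_model(1, -1.5, 1), "exceed -1")
})

test_that("flow fit recovers exact parameters from noise-free data", {
  t <- seq(0.25, 4, by = 0.25)
  fit <- fit_flow_model(t, 2 * t^0.5 + 1)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(2, 0.5, 1), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  # constant data: A ~ 0, C ~ mean
  cfit <- fit_flow_model(t, rep(3, length(t)))
  expect_equal(unname(coef(cfit)[["A"]]), 0, tolerance = 1e-6)
  expect_equal(unname(coef(cfit)[["C"]]), 3, tolerance = 1e-6)
  expect_error(fit_flow_model(1:3, 1:3), "at least 4")
})

test_that("flow fit recovers parameters within 15% at 5% noise", {
  d <- synthetic_flow_data(n = 40, noise_cv = 0.05, seed = 20150527)
  fit <- fit_flow_model(d$times, d$flows, multiplicative = TRUE)
  expect_true(fit$converged)
  rel_err <- abs(coef(fit) - c(A = 2, B = 0.5, C = 1)) / c(2, 0.5, 1)
  expect_true(all(rel_err < 0.15))
  # prediction interface
  expect_equal(predict(fit, newdata = d$times), fitted(fit))
  expect_equal(length(residuals(fit)), 40)
})

test_that("Michaelis-Menten transport: half-saturation, limits", {
  expect_equal(michaelis_menten_rate(2, Tmax = 10, Km = 2), 5)
  # linear regime well below Km
  Cu <- 2 / 1000
  expect_equal(michaelis_menten_rate(Cu, 10, 2), 10 / 2 * Cu,
               tolerance = 0.01)
  # saturation
  expect_equal(michaelis_menten_rate(1e9, 10, 2), 10, tolerance = 1e-6)
  # monotone increasing
  r <- michaelis_menten_rate(seq(0, 10, by = 0.5), 10, 2)
  expect_true(all(diff(r) > 0))
})

test_that("anesthetized cardiac output allometry", {
  expect_equal(anesthetized_cardiac_output(1), 15)
  expect_equal(anesthetized_cardiac_output(0.25), 5.303301, tolerance = 1e-6)
  expect_equal(anesthetized_cardiac_output(70), 363.0068, tolerance = 1e-6)
})

single_model <- function(P = 0.058, dose = 1, flow = flow_model(0, 0, 0.5),
                         k_elim = 0.4, transport_mode = "passive",
                         Tmax = NA, Km = NA) {
  saliva_pk_model(parent = tcpy(), volume = 0.2, k_met = 0,
                  k_elim = k_elim, partition = P, flow = flow,
                  transport_mode = transport_mode, Tmax = Tmax, Km = Km,
                  dose = dose)
}

test_that("simulate: zero dose, closed-form check, quasi-equilibrium", {
  # zero dose -> identically zero trajectories
  tc0 <- simulate(single_model(dose = 0), t_end = 1)
  expect_true(all(tc0$blood_conc == 0) && all(tc0$saliva_conc == 0))
  # P = 0 (no saliva transfer): blood is the mono-exponential D/V e^{-kt}
  tc <- simulate(single_model(P = 0, k_elim = 0.4), t_end = 2)
  expected <- 1 / 0.2 * exp(-0.4 * tc$time)
  expect_lt(max(abs(tc$blood_conc - expected) / expected), 1e-6)
  expect_true(all(tc$cum_saliva_amount == 0))
  # passive mode: saliva:blood ratio equals P at every time
  tc <- simulate(single_model(P = 0.058), t_end = 2)
  nz <- tc$blood_conc > 0
  expect_equal(tc$saliva_conc[nz] / tc$blood_conc[nz],
               rep(0.058, sum(nz)), tolerance = 1e-12)
})

test_that("simulate: mass balance closes within 0.01%", {
  # two-analyte model with metabolism, elimination and dynamic flow
  met <- compound("metab", "acid", pKa = 5, logKow_neutral = 1,
                  alpha = 0.01, fraction_unbound_plasma = 0.3)
  m <- saliva_pk_model(parent = tcpy(), metabolite = met,
                       volume = c(0.2, 0.3), k_met = 1.5,
                       k_elim = c(0.2, 0.6), partition = c(0.058, 0.4),
                       flow = flow_model(2, 0.5, 1), dose = 2)
  tc <- simulate(m, t_end = 4)
  mb <- attr(tc, "mass_balance")
  expect_true(all(abs(mb - 1) < 1e-4))
  # cumulative amounts nondecreasing, states nonnegative
  for (a in unique(tc$analyte)) {
    d <- tc[tc$analyte == a, ]
    expect_true(all(diff(d$cum_saliva_amount) >= -1e-12))
    expect_true(all(diff(d$cum_eliminated) >= -1e-12))
  }
  expect_true(all(tc$blood_conc >= 0) && all(tc$saliva_conc >= 0))
})

test_that("simulate: AUC ratio equals P in the negligible-loss regime", {
  # tiny constant flow so saliva drains < 1% of dose
  m <- single_model(P = 0.058, flow = flow_model(0, 0, 0.05), k_elim = 2)
  tc <- simulate(m, t_end = 6, n_grid = 601L)
  lost <- max(tc$cum_saliva_amount) / 1
  expect_lt(lost, 0.01)
  auc_ratio <- timecourse_auc(tc, what = "saliva_conc") /
    timecourse_auc(tc, what = "blood_conc")
  expect_equal(auc_ratio, 0.058, tolerance = 1e-3)
})

test_that("simulate: dose linearity in passive mode, broken by saturation", {
  t1 <- simulate(single_model(dose = 1), t_end = 2)
  t2 <- simulate(single_model(dose = 2), t_end = 2)
  expect_equal(t2$blood_conc, 2 * t1$blood_conc, tolerance = 1e-7)
  expect_equal(t2$saliva_conc, 2 * t1$saliva_conc, tolerance = 1e-7)
  # Michaelis-Menten transport saturates above Km: sub-proportional
  # salivary output at doubled dose
  mm1 <- simulate(single_model(dose = 1, transport_mode = "michaelis_menten",
                               Tmax = 0.5, Km = 0.01), t_end = 2)
  mm2 <- simulate(single_model(dose = 2, transport_mode = "michaelis_menten",
                               Tmax = 0.5, Km = 0.01), t_end = 2)
  expect_lt(max(mm2$cum_saliva_amount), 2 * max(mm1$cum_saliva_amount))
})

test_that("simulate: output grid refinement leaves values unchanged", {
  m <- single_model(P = 0.058, flow = flow_model(2, 0.5, 1))
  coarse <- simulate(m, t_end = 2, n_grid = 101L)
  fine <- simulate(m, t_end = 2, n_grid = 201L)
  shared <- fine$time %in% coarse$time
  expect_equal(fine$blood_conc[shared], coarse$blood_conc,
               tolerance = 1e-4)
  expect_equal(fine$cum_saliva_amount[shared], coarse$cum_saliva_amount,
               tolerance = 1e-4)
})

test_that("model validation rejects inconsistent configurations", {
  expect_error(single_model(transport_mode = "michaelis_menten"),
               "Tmax > 0")
  expect_error(saliva_pk_model(parent = tcpy(), volume = 0.2, k_met = 1,
                               k_elim = 0.1, partition = 0.1,
                               dose = 1), "requires a metabolite")
  expect_error(single_model(dose = -1), "nonnegative")
})
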