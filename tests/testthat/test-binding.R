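test_that("one-site fraction bound solves the depletion mass balance", {
  expect_equal(fraction_bound_one_site(0.2, 0, 4.4), 0)
  # non-depleting limit: L / (L + Kd)
  expect_equal(fraction_bound_one_site(1e-9, 4.4, 4.4), 0.5,
               tolerance = 1e-6)
  # depletion regime vs bisection oracle
  for (pars in list(c(0.2, 150, 0.413), c(0.2, 1, 0.413),
                    c(5, 10, 4.4), c(0.2, 0.2, 0.2))) {
    got <- fraction_bound_one_site(pars[1], pars[2], pars[3])
    want <- oracle_one_site_bisection(pars[1], pars[2], pars[3]) / pars[1]
    expect_equal(got, want, tolerance = 1e-8)
  }
  # monotone in ligand; vanishes as Kd grows
  fb <- fraction_bound_one_site(0.2, c(0, 0.5, 1, 5, 20, 150), 4.4)
  expect_true(all(diff(fb) > 0))
  expect_lt(fraction_bound_one_site(0.2, 150, 1e7), 1e-4)
})

test_that("competitive equilibrium conserves mass and nests one-site", {
  eq <- competitive_equilibrium(0.2, 3.125, 10, 4.4, 0.413)
  expect_equal(eq$free + eq$bound1 + eq$bound2, 1, tolerance = 1e-9)
  # explicit mass balances
  b1 <- eq$bound1 * 0.2
  b2 <- eq$bound2 * 0.2
  expect_equal(eq$comp1_free + b1, 3.125, tolerance = 1e-9 * 3.125)
  expect_equal(eq$comp2_free + b2, 10, tolerance = 1e-9 * 10)
  # zero competitor 2 reduces to the one-site result for competitor 1
  eq0 <- competitive_equilibrium(0.2, 3.125, 0, 4.4, 0.413)
  expect_equal(eq0$bound1, fraction_bound_one_site(0.2, 3.125, 4.4),
               tolerance = 1e-9)
  # both absent: all free
  eq00 <- competitive_equilibrium(0.2, 0, 0, 4.4, 0.413)
  expect_equal(eq00$free, 1)
})

test_that("apparent EC50 follows Cheng-Prusoff in the non-depleting regime", {
  kd1 <- 4.4; kd2 <- 0.413; comp1 <- 3.125
  tracer <- 1e-6
  signal <- function(h) {
    vapply(h, function(hh) {
      eq <- competitive_equilibrium(tracer, comp1, hh, kd1, kd2)
      fp_signal(eq, list(free = 50, bound1 = 150, bound2 = 250))
    }, numeric(1))
  }
  ec50 <- xlinkr:::apparent_ec50(signal, 150)
  expect_equal(ec50, kd2 * (1 + comp1 / kd1), tolerance = 0.01)
})

test_that("fp_signal is the fraction-weighted plateau mixture", {
  expect_equal(fp_signal(list(free = 1), list(free = 60)), 60)
  expect_equal(fp_signal(list(free = 0.5, bound1 = 0.5),
                         list(free = 50, bound1 = 150)), 100)
  set.seed(21)
  f <- runif(3); f <- f / sum(f)
  p <- c(free = 40, bound1 = 130, bound2 = 240)
  expect_equal(
    fp_signal(list(free = f[1], bound1 = f[2], bound2 = f[3]), as.list(p)),
    sum(f * p)
  )
})

test_that("one-site fits recover truth from noiseless curves", {
  for (kd in c(4.4, 0.413)) {
    curve <- gen_fp_curve(kd, sigma = 0, seed = 7)
    fit <- fit_one_site(curve)
    expect_true(fit$converged)
    expect_equal(glance(fit)$kd_uM, kd, tolerance = 0.01)
    td <- tidy(fit)
    expect_true(all(c("kd", "fp_min", "fp_max") %in% td$term))
  }
  # flat curve: degenerate fit is flagged or wildly uncertain
  flat <- tibble::tibble(conc_uM = c(150, 75, 37, 18, 9, 0),
                         mP = rep(50, 6))
  ffit <- fit_one_site(flat)
  if (ffit$converged) {
    kd_se <- ffit$estimates$std_error[ffit$estimates$term == "kd"]
    kd_est <- ffit$estimates$estimate[ffit$estimates$term == "kd"]
    expect_true(is.na(kd_se) || kd_se > kd_est)
  } else {
    expect_false(ffit$converged)
  }
})

test_that("competition fits recover the titrant affinity", {
  cc <- gen_competition_curve(4.4, 0.413, sigma = 0, seed = 3)
  fit <- fit_competition(cc, kd1 = 4.4)
  expect_true(fit$converged)
  expect_equal(glance(fit)$kd_uM, 0.413, tolerance = 0.01)
  # with noise and the free plateau known from the direct titration,
  # the median recovered Kd2 over seeds stays within 10%
  kd2s <- vapply(1:10, function(s) {
    ccn <- gen_competition_curve(4.4, 0.413, sigma = 5, seed = s)
    glance(fit_competition(ccn, kd1 = 4.4, fp_free = 50))$kd_uM
  }, numeric(1))
  expect_equal(stats::median(kd2s), 0.413, tolerance = 0.1)
  # zero competitor falls back to the one-site fit
  c0 <- gen_fp_curve(0.413, sigma = 0, seed = 5)
  f0 <- fit_competition(c0, kd1 = 4.4, comp1_conc = 0)
  expect_equal(
    f0$estimates$estimate[f0$estimates$term == "kd"], 0.413,
    tolerance = 0.01
  )
})

test_that("apparent EC50 of fitted competition model matches Cheng-Prusoff at low tracer", {
  cc <- gen_competition_curve(4.4, 0.413, tracer = 0.001, sigma = 0,
                              seed = 6)
  fit <- fit_competition(cc, kd1 = 4.4, tracer_conc = 0.001)
  expect_equal(fit$apparent_ec50, fit$cheng_prusoff_ec50,
               tolerance = 0.15)
})

test_that("median recovered Kd across seeded simulations stays near truth", {
  # reduced-scale version of the full recovery study (full design in the
  # acceptance suite): 25 seeds at one affinity
  kds <- vapply(1:25, function(s) {
    curve <- gen_fp_curve(4.4, sigma = 5, seed = s)
    glance(fit_one_site(curve))$kd_uM
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 4.4) / 4.4, 0.15)
})
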