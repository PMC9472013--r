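make_cycle <- function(delta_app, f_app, delta_ret, f_ret) {
  # assemble an indentation_curve from explicit approach/retract branches
  indentation_curve(c(delta_app, rev(delta_ret)),
                    c(f_app, rev(f_ret)),
                    rep(c("approach", "retract"),
                        c(length(delta_app), length(delta_ret))))
}

test_that("dissipated energy is zero without hysteresis and scales linearly", {
  d <- seq(0, 1, length.out = 60)
  f <- d                                  # 1 nN/um loading line
  cyc0 <- make_cycle(d, f, d, f)          # retract identical to approach
  expect_equal(dissipated_energy(cyc0)$energy, 0, tolerance = 1e-12)

  # retract shifted down 0.2 nN, clipped at F > 0
  f_ret <- pmax(f - 0.2, 0)
  cyc <- make_cycle(d, f, d, f_ret)
  e1 <- dissipated_energy(cyc)$energy
  cyc2 <- make_cycle(d, 2 * f, d, 2 * f_ret)
  expect_equal(dissipated_energy(cyc2)$energy, 2 * e1, tolerance = 1e-9)
})

test_that("dissipated energy equals the polygon-area oracle", {
  # hand-integrable parallelogram: area = 0.2 * 1 minus the clipped
  # triangle near delta = 0.2 -> shoelace oracle computes it exactly
  d <- seq(0, 1, length.out = 501)
  f_app <- d
  f_ret <- pmax(d - 0.2, 0)
  oracle <- shoelace_area(d, f_app, d, f_ret)
  expect_equal(oracle, 0.2 * 1 - 0.5 * 0.2 * 0.2, tolerance = 1e-6)
  got <- dissipated_energy(make_cycle(d, f_app, d, f_ret))$energy
  expect_equal(got, oracle, tolerance = 1e-9)

  # random piecewise-linear cycles share the oracle exactly
  set.seed(61)
  for (i in 1:10) {
    dd <- seq(0, runif(1, 0.5, 2), length.out = 301)
    fa <- cumsum(abs(rnorm(301, sd = 0.01)))
    fr <- pmax(fa - runif(1, 0, 0.3) * max(fa), 0)
    expect_equal(dissipated_energy(make_cycle(dd, fa, dd, fr))$energy,
                 shoelace_area(dd, fa, dd, fr), tolerance = 1e-9)
  }
})

test_that("dissipation on synthetic curves tracks generator viscosity", {
  energies <- sapply(c(0, 0.05, 0.1, 0.2, 0.4), function(h) {
    cfg <- synth_config(seed = 62, hysteresis_level = h,
                        noise_sd_force = 0)
    cv <- baseline_correct(gen_force_curve(cfg, seed = 62))
    dissipated_energy(to_indentation(cv, detect_contact(cv)))$energy
  })
  expect_equal(energies[1], 0, tolerance = 1e-6)
  expect_identical(order(energies), 1:5)   # rank correlation = 1
})

test_that("dissipated_energy validates its inputs", {
  d <- seq(0, 1, length.out = 60)
  only_app <- indentation_curve(d, d, rep("approach", 60))
  expect_error(dissipated_energy(only_app), "retract")
  disjoint <- make_cycle(d, d, d + 5, d)
  expect_error(dissipated_energy(disjoint), "overlap")
})

test_that("two-element Maxwell fit recovers the generating parameters", {
  # noise-free: sub-percent on every parameter
  cfg <- synth_config(seed = 63)
  tr0 <- gen_relaxation(cfg, seed = 63, noise_sd = 0)
  f0 <- fit_maxwell2(tr0)
  expect_false(f0$fallback)
  expect_equal(f0$a0, 0.5, tolerance = 0.005)
  expect_equal(f0$a1, 1.0, tolerance = 0.005)
  expect_equal(f0$a2, 0.5, tolerance = 0.005)
  expect_equal(f0$tau1, 1, tolerance = 0.005)
  expect_equal(f0$tau2, 10, tolerance = 0.005)

  # 1% noise: all five parameters within 10%
  tr1 <- gen_relaxation(cfg, seed = 64)
  f1 <- fit_maxwell2(tr1)
  expect_equal(f1$a0, 0.5, tolerance = 0.10)
  expect_equal(f1$a1, 1.0, tolerance = 0.10)
  expect_equal(f1$a2, 0.5, tolerance = 0.10)
  expect_equal(f1$tau1, 1, tolerance = 0.10)
  expect_equal(f1$tau2, 10, tolerance = 0.10)
  expect_true(f1$tau1 < f1$tau2)
})

test_that("a single-exponential trace triggers the fallback path", {
  cfg <- synth_config(seed = 65, a2 = 0)
  tr <- gen_relaxation(cfg, seed = 65)
  f <- fit_maxwell2(tr)
  expect_true(f$fallback)
  expect_true(f$converged)
  expect_equal(f$tau1, 1, tolerance = 0.05)
})

test_that("viscosity follows the Maxwell relation eta = tau * E", {
  expect_equal(viscosity_from(1, 1), 1)
  expect_equal(viscosity_from(2, 160), 320)
  expect_equal(viscosity_from(4, 160), 2 * viscosity_from(2, 160))
  expect_error(viscosity_from(-1, 10), "> 0")
  expect_error(viscosity_from(1, 0), "> 0")
})

test_that("compartment assignment orders ZP before ooplasm", {
  cfg <- synth_config(seed = 66, tau1_true = 2, tau2_true = 20)
  fit <- fit_maxwell2(gen_relaxation(cfg, seed = 66))
  ca <- assign_compartments(fit)
  expect_equal(ca$zp_tau, min(fit$tau1, fit$tau2))
  expect_equal(ca$ooplasm_tau, max(fit$tau1, fit$tau2))

  # order invariance: a hand-built unordered fit gives the same answer
  swapped <- structure(list(a0 = 0.5, a1 = 0.5, a2 = 1, t0 = 10,
                            tau1 = 20, tau2 = 2, rss = 0,
                            converged = TRUE, fallback = FALSE),
                       class = "maxwell_fit")
  ca2 <- assign_compartments(swapped)
  expect_equal(ca2$zp_tau, 2)
  expect_equal(ca2$ooplasm_tau, 20)

  # viscosities when moduli are supplied
  ca3 <- assign_compartments(swapped, E_zp = 160, E_ooplasm = 90)
  expect_equal(ca3$zp_eta, 2 * 160)
  expect_equal(ca3$ooplasm_eta, 20 * 90)

  fallback <- structure(list(converged = TRUE, fallback = TRUE),
                        class = "maxwell_fit")
  expect_error(assign_compartments(fallback), "single-element")
})

test_that("an aging series of holds shows zp_tau falling, ooplasm flat", {
  zp_taus <- c(2, 1.4, 1)            # ZP relaxation speeds up with aging
  fits <- lapply(seq_along(zp_taus), function(i) {
    cfg <- synth_config(seed = 70 + i, tau1_true = zp_taus[i],
                        tau2_true = 15)
    assign_compartments(fit_maxwell2(gen_relaxation(cfg, seed = 70 + i)))
  })
  zp <- sapply(fits, `[[`, "zp_tau")
  oo <- sapply(fits, `[[`, "ooplasm_tau")
  expect_true(all(diff(zp) < 0))
  expect_equal(oo, rep(15, 3), tolerance = 0.10)
})
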