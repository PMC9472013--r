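test_that("write/read round trip is lossless for all fields", {
  cfg <- synth_config(seed = 21)
  cv <- gen_force_curve(cfg, seed = 21,
                        position = list(row = 2L, col = 3L,
                                        replicate = 1L))
  cv$extra <- list(operator = "synthetic")   # free metadata survives
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curve(cv, path)
  back <- read_curve(path)

  expect_equal(back$z, cv$z, tolerance = 1e-9)
  expect_equal(back$d, cv$d, tolerance = 1e-9)
  expect_equal(back$t, cv$t, tolerance = 1e-9)
  expect_identical(back$segment, cv$segment)
  expect_equal(back$meta$spring_constant, cv$meta$spring_constant)
  expect_equal(back$meta$bead_radius, cv$meta$bead_radius)
  expect_identical(back$position, cv$position)
  expect_identical(back$extra$operator, "synthetic")
})

test_that("header metadata is parsed and malformed files are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  n <- 16
  rows <- sprintf("%g\t%g\t%g\t%s", seq_len(n) / 10, seq_len(n) / 2,
                  rep(0, n), rep("approach", n))
  writeLines(c("# spring_constant_N_per_m: 0.32",
               "t\tz\td\tsegment", rows), path)
  expect_warning(cv <- read_curve(path), "retract")
  expect_equal(cv$meta$spring_constant, 0.32)
  expect_equal(sum(cv$segment == "retract"), 0L)

  # missing mandatory column is named in the error
  writeLines(c("t\tz\tsegment",
               sprintf("%g\t%g\t%s", 1:16 / 10, 1:16 / 2,
                       rep("approach", 16))), path)
  expect_error(read_curve(path), "'d'")

  # non-monotone approach z
  zbad <- c(1:8, 7, 9:15) / 2
  writeLines(c("t\tz\td\tsegment",
               sprintf("%g\t%g\t%g\t%s", 1:16 / 10, zbad, rep(0, 16),
                       rep("approach", 16))), path)
  expect_error(suppressWarnings(read_curve(path)), "monotone")

  expect_error(read_curve(file.path(tempdir(), "nope.tsv")), "no such file")
})

test_that("baseline correction removes additive tilt and is idempotent", {
  cfg <- synth_config(seed = 22, noise_sd_force = 0)
  cv <- gen_force_curve(cfg, seed = 22, drift = 0.01)
  corr <- baseline_correct(cv)
  app <- which(corr$segment == "approach")
  win <- app[seq_len(120)]
  slope <- coef(lm(corr$d[win] ~ corr$z[win]))[2]
  expect_lt(abs(slope), 1e-6)

  # already-flat baseline: a second pass changes nothing
  again <- baseline_correct(corr)
  expect_equal(again$d, corr$d, tolerance = 1e-9)
})

test_that("corrected contact-region force matches generator truth", {
  cfg <- synth_config(seed = 23)
  cv <- gen_force_curve(cfg, seed = 23, drift = 0.02)
  corr <- baseline_correct(cv)
  truth <- cv$extra$truth
  k_nn <- cfg$probe$spring_constant * 1e3
  app <- corr$segment == "approach"
  f_rec <- corr$d[app] * k_nn
  deep <- truth$force_app > 0.5   # contact region well above noise
  expect_equal(f_rec[deep], truth$force_app[deep], tolerance = 0.02)
})

test_that("baseline window shorter than 8 samples is refused", {
  cv <- gen_force_curve(synth_config(seed = 24), seed = 24,
                        n_approach = 20L)
  expect_error(baseline_correct(cv, fraction = 0.05), "at least 8")
})

test_that("to_indentation handles the rigid and free-travel limits", {
  # rigid surface: d rises 1:1 with z past contact -> delta = 0 in contact
  # (contact placed on a sample so the piecewise-linear kink is exact)
  n <- 51
  z <- seq(0, 5, length.out = n)
  zc <- 2.5
  d <- pmax(z - zc, 0)
  cv <- suppressWarnings(force_curve(z = z, d = d, t = seq_len(n),
                                     segment = rep("approach", n)))
  ind <- to_indentation(cv, zc)
  expect_equal(ind$delta[z >= zc], rep(0, sum(z >= zc)), tolerance = 1e-12)

  # zero deflection: delta is the free travel z - contact_z
  cv0 <- suppressWarnings(force_curve(z = z, d = rep(0, n),
                                      t = seq_len(n),
                                      segment = rep("approach", n)))
  ind0 <- to_indentation(cv0, zc)
  expect_equal(ind0$delta, z - zc, tolerance = 1e-12)

  expect_error(to_indentation(cv0, 99), "outside")
})

test_that("recovered indentation matches generator truth within noise", {
  cfg <- synth_config(seed = 25)
  cv <- baseline_correct(gen_force_curve(cfg, seed = 25))
  truth <- cv$extra$truth
  ind <- to_indentation(cv, truth$contact_z)
  app <- ind$segment == "approach"
  noise_d <- cfg$noise_sd_force / (cfg$probe$spring_constant * 1e3)
  expect_lt(max(abs(ind$delta[app] - truth$delta_app)), 6 * noise_d)
  expect_lt(max(abs(ind$force[app] - truth$force_app)),
            6 * cfg$noise_sd_force)
})

test_that("indentation is invariant to a common shift of z and contact", {
  cfg <- synth_config(seed = 26, noise_sd_force = 0)
  cv <- baseline_correct(gen_force_curve(cfg, seed = 26))
  cz <- detect_contact(cv)
  ind1 <- to_indentation(cv, cz)
  shifted <- cv
  shifted$z <- cv$z + 3.7
  ind2 <- to_indentation(shifted, cz + 3.7)
  expect_equal(ind2$delta, ind1$delta, tolerance = 1e-9)
  expect_equal(ind2$force, ind1$force, tolerance = 1e-9)
})

test_that("a 1 nN-setpoint synthetic curve peaks within 5% of 1 nN", {
  for (s in c(31, 32)) {
    cv <- baseline_correct(gen_force_curve(synth_config(seed = s),
                                           seed = s))
    ind <- to_indentation(cv, detect_contact(cv))
    expect_equal(max(ind$force[ind$segment == "approach"]), 1,
                 tolerance = 0.05)
  }
})
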