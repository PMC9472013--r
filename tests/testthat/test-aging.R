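mk_tl <- function(id, t, morph, E2 = NULL, diss = NULL) {
  n <- length(t)
  oocyte_timeline(id, "thawed", t,
                  E2 = if (is.null(E2)) rep(200, n) else E2,
                  dissipation = if (is.null(diss)) rep(50, n) else diss,
                  morphology = morph)
}

test_that("timeline validation enforces the degradation structure", {
  expect_error(mk_tl("a", c(1, 1, 2), rep("healthy", 3)), "increasing")
  expect_error(mk_tl("a", 1:3, c("healthy", "degraded", "healthy")),
               "absorbing")
  expect_error(mk_tl("a", 1:3, c("healthy", "bad", "healthy")), "labels")
})

test_that("alignment re-times degraded oocytes to the degradation event", {
  tl <- mk_tl("a", 2:5, c("healthy", "healthy", "healthy", "degraded"))
  al <- align_to_degradation(tl)
  expect_equal(al$t_rel, c(-3, -2, -1, 0))
  expect_true(al$degraded)

  hl <- mk_tl("b", 0:4, rep("healthy", 5))
  alh <- align_to_degradation(hl)
  expect_equal(alh$t_rel, 0:4)
  expect_false(alh$degraded)
})

test_that("every degraded series in a synthetic cohort ends at zero", {
  co <- gen_cohort(synth_config(seed = 91), seed = 91)
  deg <- classify_groups(co$timelines)$degraded
  ends <- sapply(deg, function(tl) max(align_to_degradation(tl)$t_rel))
  expect_true(all(ends == 0))
})

test_that("group classification partitions the cohort at the horizon", {
  all_h <- list(mk_tl("a", 0:6, rep("healthy", 7)),
                mk_tl("b", 0:6, rep("healthy", 7)))
  grp <- classify_groups(all_h)
  expect_length(grp$degraded, 0)
  expect_length(grp$healthy, 2)

  # degradation exactly at the horizon counts as degraded (closed interval)
  at6 <- mk_tl("c", 0:6, c(rep("healthy", 6), "degraded"))
  expect_length(classify_groups(list(at6), horizon = 6)$degraded, 1)
  # a later degradation does not
  past <- mk_tl("d", 0:7, c(rep("healthy", 7), "degraded"))
  expect_length(classify_groups(list(past), horizon = 6)$degraded, 0)

  # synthetic mixed cohort with the study's group sizes
  co <- gen_cohort(synth_config(seed = 92), seed = 92)
  grp2 <- classify_groups(co$timelines)
  expect_length(grp2$healthy, 15)
  expect_length(grp2$degraded, 20)

  # classification is order-invariant and idempotent over the cohort
  shuf <- classify_groups(rev(co$timelines))
  expect_setequal(sapply(shuf$degraded, `[[`, "oocyte_id"),
                  sapply(grp2$degraded, `[[`, "oocyte_id"))
})

test_that("timelines survive a CSV round trip", {
  co <- gen_cohort(synth_config(seed = 93), seed = 93)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timelines(co$timelines, path)
  back <- read_timelines(path)
  expect_length(back, length(co$timelines))
  orig <- co$timelines[[3]]
  got <- back[[orig$oocyte_id]]
  expect_equal(got$E2, orig$E2, tolerance = 1e-9)
  expect_identical(got$morphology, orig$morphology)
})

test_that("Mann-Whitney agrees with enumeration and the reference", {
  x <- c(1.2, 3.4, 2.2); y <- c(5.1, 4.4, 6.0)
  enum <- mw_enumerate(x, y)
  got <- compare_groups(list(x, y), test = "mann_whitney")
  expect_equal(got$statistic, enum$U)
  expect_equal(got$statistic,
               unname(wilcox.test(x, y)$statistic))

  # identical groups: all ties, U exactly at its null mean, p = 1
  z <- c(1, 2, 3, 4)
  same <- compare_groups(list(z, z), test = "mann_whitney")
  expect_equal(same$statistic, length(z)^2 / 2)
  expect_equal(same$p_value, 1)

  # exhaustive-enumeration oracle across random small fixtures
  set.seed(94)
  for (i in 1:20) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- round(rnorm(n1), 2); y <- round(rnorm(n2, mean = 0.5), 2)
    enum <- mw_enumerate(x, y)
    got <- compare_groups(list(x, y), test = "mann_whitney")
    expect_equal(got$statistic, enum$U)
    # normal approximation with continuity correction tracks the exact
    # enumeration p-value closely even at these sizes
    expect_lt(abs(got$p_value - enum$p), 0.06)
  }
})

test_that("ANOVA and Kruskal-Wallis match the reference implementations", {
  set.seed(95)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) rnorm(sample(4:8, 1), mean = j / 2))
    vals <- unlist(g)
    grp <- factor(rep(seq_along(g), lengths(g)))

    a <- compare_groups(g, test = "anova")
    ref <- summary(aov(vals ~ grp))[[1]]
    expect_equal(a$statistic, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(a$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-9)

    k <- compare_groups(g, test = "kruskal_wallis")
    refk <- kruskal.test(vals, grp)
    expect_equal(k$statistic, unname(refk$statistic), tolerance = 1e-9)
    expect_equal(k$p_value, refk$p.value, tolerance = 1e-9)
  }
  # ties exercise the tie-corrected variance
  gt <- list(c(1, 2, 2, 3, 4), c(2, 3, 3, 5, 5), c(1, 1, 4, 5, 6))
  k2 <- compare_groups(gt, test = "kruskal_wallis")
  refk2 <- kruskal.test(unlist(gt), factor(rep(1:3, each = 5)))
  expect_equal(k2$statistic, unname(refk2$statistic), tolerance = 1e-9)

  expect_error(compare_groups(list(1:5), test = "anova"), "2 groups")
  expect_error(compare_groups(list(1:2, 1:5), test = "anova"), "n >= 3")
  expect_error(compare_groups(list(1:5, 1:5, 1:5), test = "mann_whitney"),
               "exactly 2")
})

test_that("ANOVA holds its nominal type-I error on null data", {
  set.seed(96)
  rej <- mean(replicate(2000, {
    g <- lapply(1:3, function(i) rnorm(5))
    compare_groups(g, test = "anova")$p_value < 0.05
  }))
  # 2 SE of a binomial proportion at p = 0.05, n = 2000 is ~0.0097
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("yield percentages follow the printed rounding convention", {
  counts <- data.frame(group = c("1h", "6h", "control"),
                       total = c(14, 14, 15),
                       two_cell = c(10, 4, 12),
                       early_blast = c(7, 1, 9))
  yt <- yield_table(counts)
  expect_equal(yt$two_cell_pct, c(71, 29, 80))
  expect_equal(yt$early_blast_pct, c(50, 7, 60))

  # the published 77% for 10/14 is annotated as a discrepancy, not copied
  printed <- data.frame(group = counts$group,
                        two_cell = c(77, 29, 80))
  yt2 <- yield_table(counts, printed = printed)
  expect_match(attr(yt2, "discrepancies"), "printed 77", all = FALSE)
  expect_equal(yt2$two_cell_pct[1], 71)

  edge <- data.frame(group = "x", total = 14, s = 0)
  expect_equal(yield_table(edge)$s_pct, 0)
  edge$s <- 14
  expect_equal(yield_table(edge)$s_pct, 100)
  expect_error(yield_table(data.frame(group = "x", total = 0, s = 0)),
               "zero total")
  expect_error(yield_table(data.frame(group = "x", total = 5, s = 7)),
               "exceeds")
})

test_that("the headline summary flags the constructed aging hour", {
  co <- gen_cohort(synth_config(seed = 97), seed = 97)
  deg <- lapply(classify_groups(co$timelines)$degraded,
                align_to_degradation)
  hs <- headline_summary(deg, value = "E2")
  expect_equal(hs$flag_hour, -1)
  expect_equal(hs$direction, 1)        # stiffness rises

  hd <- headline_summary(deg, value = "dissipation")
  expect_equal(hd$flag_hour, -1)
  expect_equal(hd$direction, -1)       # dissipation falls

  # healthy cohort: flat series, no flag
  hl <- lapply(classify_groups(co$timelines)$healthy,
               align_to_degradation)
  expect_true(is.na(headline_summary(hl)$flag_hour))
})
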