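# Contact detection and Hertz-model elasticity fitting.
#
# Approach curves on the oocyte show two slope regimes: a soft outer
# zona-pellucida response (modulus E1) engaging at the first contact point,
# and a stiffer inner response (E2) engaging deeper, at a second contact
# point. The model is the sum of two spherical Hertz contributions:
#
#   F(delta) = H(delta - d0; E1) + [delta - d0 > dc2] H(delta - d0 - dc2; E2')
#
# with H(x; E) = (4/3) E/(1-nu^2) sqrt(R) x^(3/2). The modulus reported as
# E2 is the one a single-layer Hertz fit re-zeroed at the second contact
# point would report for the post-dc2 force increment; the additive
# component E2' is kept alongside (see the methods vignette).

# Hertz prefactor c such that F[nN] = c * E[Pa] * x[um]^(3/2)
.hertz_coef <- function(R, nu) (4 / 3) / (1 - nu^2) * sqrt(R) * .HERTZ_NN

#' Spherical Hertz contact force
#'
#' Force exerted by a rigid sphere of radius `R` indenting an elastic
#' half-space of Young's modulus `E` to depth `delta`:
#' `F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2)`.
#'
#' @param delta Indentation depth in um, `>= 0` (vectorised).
#' @param E Young's modulus in Pa.
#' @param R Indenter radius in um.
#' @param nu Poisson ratio; 0.5 treats the sample as incompressible.
#' @return Force in nN.
#' @export
#' @examples
#' hertz_force(1, E = 160, R = 2.25)  # ~0.43 nN
hertz_force <- function(delta, E, R = 2.25, nu = 0.5) {
  if (any(delta < 0)) stop("delta must be >= 0")
  stopifnot(E > 0, R > 0, nu >= 0, nu <= 0.5)
  .hertz_coef(R, nu) * E * delta^1.5
}

#' Detect the first contact point on an approach curve
#'
#' Scans the baseline-corrected approach segment in the approach direction
#' and returns the height of the first sustained force rise: the earliest
#' sample after which the force exceeds `threshold` baseline noise SDs for
#' at least `m` consecutive samples. A robust rule is needed because the
#' first contact of the soft ZP mesh is not a sharp kink.
#'
#' @param curve A baseline-corrected [force_curve()].
#' @param threshold Multiple of the baseline force noise SD, default 3.
#' @param m Consecutive above-threshold samples required, default 5.
#' @param baseline_fraction Fraction of approach samples used to estimate
#'   the noise SD when [baseline_correct()] has not stored one.
#' @return Contact height `contact_z` in um.
#' @export
detect_contact <- function(curve, threshold = 3, m = 5,
                           baseline_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  app <- which(curve$segment == "approach")
  if (length(app) < 16L) stop("need at least 16 approach samples")
  k_nn <- curve$meta$spring_constant * .K_UM_TO_NN
  f <- curve$d[app] * k_nn

  sd_d <- curve$extra$baseline_noise_sd_um
  if (is.null(sd_d)) {
    nwin <- max(8L, floor(length(app) * baseline_fraction))
    sd_d <- stats::sd(curve$d[app][seq_len(nwin)])
  }
  thr <- max(threshold * sd_d * k_nn, 1e-6)

  above <- f > thr
  run <- 0L
  hit <- NA_integer_
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= m) { hit <- i - m + 1L; break }
  }
  if (is.na(hit))
    stop("no contact: force never exceeds ", signif(thr, 3),
         " nN for ", m, " consecutive samples")
  curve$z[app[hit]]
}

# Post-dc2 reported modulus: project the force increment beyond the second
# contact point onto the shifted Hertz shape x^(3/2). Closed form because
# the model is linear in E.
.project_e2 <- function(x, y_inc, R, nu) {
  keep <- x > 0
  x <- x[keep]; y_inc <- y_inc[keep]
  sum(y_inc * x^1.5) / (.hertz_coef(R, nu) * sum(x^3))
}

#' Fit a single-layer Hertz model to an approach curve
#'
#' Nonlinear least squares of `F = H(delta - delta0; E)` over the modulus
#' `E` and a contact-point refinement `delta0`, with a small deterministic
#' multistart over `delta0` to escape shallow local minima.
#'
#' @param ind An [indentation_curve()] (approach segment is used).
#' @param E0 Optional starting modulus in Pa; estimated from the data when
#'   `NULL`.
#' @param nu Poisson ratio, default 0.5.
#' @param n_starts Number of multistart offsets for `delta0`, default 5.
#' @return A list with `E` (Pa), `contact_delta` (um, refinement of the
#'   detected contact), `rss` (nN^2), `n_points`, `converged`.
#' @export
fit_single_hertz <- function(ind, E0 = NULL, nu = 0.5, n_starts = 5) {
  stopifnot(inherits(ind, "indentation_curve"))
  app <- ind$segment == "approach"
  delta <- ind$delta[app]; f <- ind$force[app]
  if (sum(delta > 0) < 20L)
    stop("need at least 20 in-contact approach samples")
  R <- ind$meta$bead_radius
  cc <- .hertz_coef(R, nu)
  if (is.null(E0)) E0 <- max(.project_e2(delta, f, R, nu), 1)

  span <- max(delta)
  offs <- seq(-0.1, 0.1, length.out = n_starts) * span
  best <- NULL
  for (o in offs) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ f0 + cc * E * pmax(delta - d0, 0)^1.5,
        start = list(E = E0, d0 = o, f0 = 0),
        lower = c(E = 1, d0 = -span, f0 = -Inf),
        upper = c(E = 1e6, d0 = span / 2, f0 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(E = unname(cf["E"]), contact_delta = unname(cf["d0"]),
                   rss = rss, n_points = sum(app), converged = TRUE)
    }
  }
  if (is.null(best))
    best <- list(E = E0, contact_delta = 0, rss = NA_real_,
                 n_points = sum(app), converged = FALSE)
  best
}

#' Fit the two-layer (two-contact-point) Hertz model
#'
#' Grid search over the first-contact refinement `d0` and the second
#' contact depth `dc2` (resolution set by the sample spacing), with the two
#' moduli solved by linear least squares at each candidate pair — the model
#' is linear in (E1, E2') at fixed contact points. The second contribution
#' is accepted only when it improves the residual sum of squares by more
#' than `min_improvement` and `dc2` is interior to the fitted range;
#' otherwise the curve is reported as effectively single-layer.
#'
#' @param ind An [indentation_curve()] (approach segment is used).
#' @param nu Poisson ratio, default 0.5.
#' @param min_improvement Relative rss improvement required to support the
#'   second layer, default 0.05.
#' @param max_candidates Cap on the number of `dc2` grid candidates.
#' @return An object of class `two_layer_fit`: `E1`, `E2` (reported
#'   convention), `E2_add` (additive component), `contact1_delta`,
#'   `contact2_delta` (um), `nu`, `R`, `rss` (nN^2), `n_points`,
#'   `converged`, `second_layer_supported`.
#' @export
fit_two_layer <- function(ind, nu = 0.5, min_improvement = 0.05,
                          max_candidates = 120L) {
  stopifnot(inherits(ind, "indentation_curve"))
  app <- ind$segment == "approach"
  delta <- ind$delta[app]; f <- ind$force[app]
  ord <- order(delta)
  delta <- delta[ord]; f <- f[ord]
  if (sum(delta > 0) < 40L)
    stop("need at least 40 in-contact approach samples")
  R <- ind$meta$bead_radius
  cc <- .hertz_coef(R, nu)
  dmax <- max(delta)
  spacing <- stats::median(diff(delta[delta > 0]))

  # candidate refinements of the first contact (detection can be late on
  # noisy curves because the outer layer is soft)
  d0_lim <- c(max(min(delta), -0.7), min(dmax / 2, 0.2))

  # nested linear solve at fixed contact points; a free force offset f0
  # absorbs the residual zero error left by imperfect contact detection
  rss_for <- function(d0, dc2) {
    x1 <- pmax(delta - d0, 0)^1.5
    X <- if (is.na(dc2)) cbind(1, x1)
         else cbind(1, x1, pmax(delta - d0 - dc2, 0)^1.5)
    b <- tryCatch(qr.solve(crossprod(X), crossprod(X, f)),
                  error = function(e) NULL)
    if (is.null(b)) return(list(rss = Inf, E1 = NA, E2a = NA, f0 = NA))
    e1 <- b[2L] / cc
    e2 <- if (is.na(dc2)) 0 else b[3L] / cc
    if (e1 < 0 || e2 < 0) {
      # refit with the offending component dropped
      X1 <- cbind(1, x1)
      b1 <- qr.solve(crossprod(X1), crossprod(X1, f))
      e1 <- max(b1[2L] / cc, 1e-6); e2 <- 0
      b <- c(b1[1L], e1 * cc, 0)
    }
    fitted <- b[1L] + cc * (e1 * x1 +
      if (is.na(dc2)) 0 else e2 * pmax(delta - d0 - dc2, 0)^1.5)
    list(rss = sum((f - fitted)^2), E1 = e1, E2a = e2, f0 = b[1L])
  }

  search <- function(d0_cand, dc2_fn) {
    best <- NULL
    for (d0 in d0_cand) {
      for (dc2 in dc2_fn(d0)) {
        cand <- rss_for(d0, dc2)
        if (is.null(best) || cand$rss < best$rss) {
          best <- cand; best$d0 <- d0; best$dc2 <- dc2
        }
      }
    }
    best
  }
  dc2_range <- function(d0) {
    hi <- dmax - d0 - 4 * spacing
    if (hi <= 4 * spacing) numeric(0) else c(4 * spacing, hi)
  }

  # single-contribution reference over the full d0 range
  d0_fine_step <- max(spacing, 0.005)
  best1 <- search(seq(d0_lim[1L], d0_lim[2L], by = d0_fine_step),
                  function(d0) NA)

  # two contributions: coarse pass, then local refinement
  coarse <- search(
    seq(d0_lim[1L], d0_lim[2L], by = 3 * d0_fine_step),
    function(d0) {
      r <- dc2_range(d0)
      if (!length(r)) return(numeric(0))
      seq(r[1L], r[2L], length.out = min(max_candidates %/% 2L, 60L))
    })
  best2 <- NULL
  if (!is.null(coarse)) {
    d0_loc <- seq(coarse$d0 - 3 * d0_fine_step,
                  coarse$d0 + 3 * d0_fine_step, by = d0_fine_step / 2)
    d0_loc <- d0_loc[d0_loc >= d0_lim[1L] & d0_loc <= d0_lim[2L]]
    best2 <- search(d0_loc, function(d0) {
      r <- dc2_range(d0)
      if (!length(r)) return(numeric(0))
      loc <- seq(coarse$dc2 - 5 * spacing, coarse$dc2 + 5 * spacing,
                 by = spacing / 2)
      loc[loc >= r[1L] & loc <= r[2L]]
    })
    if (is.null(best2)) best2 <- coarse
  }

  supported <- !is.null(best2) && best2$E2a > 0 &&
    (best1$rss - best2$rss) / max(best1$rss, .Machine$double.eps) >
      min_improvement &&
    best2$dc2 > 2 * spacing && best2$d0 + best2$dc2 < dmax - 2 * spacing

  if (supported) {
    # continuous polish of the contact points from the grid optimum
    polish <- tryCatch(
      minpack.lm::nlsLM(
        f ~ f0 + cc * (E1 * pmax(delta - d0, 0)^1.5 +
                         E2a * pmax(delta - d0 - dc2, 0)^1.5),
        start = list(f0 = best2$f0, E1 = best2$E1, E2a = best2$E2a,
                     d0 = best2$d0, dc2 = best2$dc2),
        lower = c(f0 = -Inf, E1 = 1e-6, E2a = 0,
                  d0 = d0_lim[1L], dc2 = 2 * spacing),
        upper = c(f0 = Inf, E1 = 1e6, E2a = 1e6,
                  d0 = d0_lim[2L], dc2 = dmax),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(polish) &&
        sum(stats::residuals(polish)^2) < best2$rss) {
      cfp <- stats::coef(polish)
      best2 <- list(rss = sum(stats::residuals(polish)^2),
                    E1 = unname(cfp["E1"]), E2a = unname(cfp["E2a"]),
                    f0 = unname(cfp["f0"]), d0 = unname(cfp["d0"]),
                    dc2 = unname(cfp["dc2"]))
    }
    d0 <- best2$d0; dc2 <- best2$dc2
    # reported E2: modulus of the combined post-dc2 response, from the
    # fitted (noise-free) model increment
    xall <- delta[delta - d0 - dc2 > 0]
    x <- xall - d0 - dc2
    y_inc <- cc * best2$E1 * ((xall - d0)^1.5 - dc2^1.5) +
      cc * best2$E2a * x^1.5
    e2_rep <- .project_e2(x, y_inc, R, nu)
    out <- list(E1 = best2$E1, E2 = e2_rep, E2_add = best2$E2a,
                contact1_delta = d0, contact2_delta = dc2,
                nu = nu, R = R, rss = best2$rss,
                n_points = length(delta), converged = TRUE,
                second_layer_supported = TRUE)
  } else {
    out <- list(E1 = best1$E1, E2 = best1$E1, E2_add = 0,
                contact1_delta = best1$d0, contact2_delta = NA_real_,
                nu = nu, R = R, rss = best1$rss,
                n_points = length(delta), converged = TRUE,
                second_layer_supported = FALSE)
  }
  structure(out, class = "two_layer_fit")
}

#' @export
print.two_layer_fit <- function(x, ...) {
  cat(sprintf("<two_layer_fit> E1 = %.3g Pa, E2 = %.3g Pa%s\n",
              x$E1, x$E2,
              if (x$second_layer_supported) "" else " (single-layer)"))
  if (x$second_layer_supported)
    cat(sprintf("  second contact at delta = %.3g um; rss = %.3g nN^2\n",
                x$contact2_delta, x$rss))
  invisible(x)
}

#' Summarise two-layer fits over an indentation grid
#'
#' Aggregates per-curve fits acquired on a rows x cols grid with several
#' replicates per position (the acquisition protocol is a 3 x 3 grid with
#' 3 curves per point, 27 curves per oocyte). Means and SDs are computed
#' over converged fits only; per-position means are retained for
#' heterogeneity maps.
#'
#' @param fits List of [fit_two_layer()] results.
#' @param positions Optional list (same length) of `list(row, col,
#'   replicate)`; taken from names "r.c.k" when `NULL`.
#' @param layout List with `rows`, `cols`, `replicates` declaring the grid.
#' @return An object of class `grid_summary`: `n_curves`, `mean_E1`,
#'   `sd_E1`, `mean_E2`, `sd_E2`, `per_position` (data frame of
#'   per-position means), `complete`.
#' @export
summarize_grid <- function(fits, positions = NULL,
                           layout = list(rows = 3, cols = 3,
                                         replicates = 3)) {
  stopifnot(length(fits) > 0)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv)) stop("no converged fits in grid")
  e1 <- vapply(fits, `[[`, numeric(1), "E1")[conv]
  e2 <- vapply(fits, `[[`, numeric(1), "E2")[conv]

  if (is.null(positions))
    positions <- lapply(seq_along(fits), function(i) {
      rc <- arrayInd(((i - 1L) %/% layout$replicates) + 1L,
                     c(layout$rows, layout$cols))
      list(row = rc[1L], col = rc[2L],
           replicate = ((i - 1L) %% layout$replicates) + 1L)
    })
  pos_key <- vapply(positions, function(p) paste(p$row, p$col, sep = "."),
                    character(1))[conv]
  per_pos <- data.frame(
    position = unique(pos_key),
    mean_E1 = as.numeric(tapply(e1, pos_key, mean)[unique(pos_key)]),
    mean_E2 = as.numeric(tapply(e2, pos_key, mean)[unique(pos_key)]),
    n = as.integer(table(pos_key)[unique(pos_key)]),
    row.names = NULL)

  expected <- layout$rows * layout$cols * layout$replicates
  structure(list(n_curves = length(fits),
                 mean_E1 = mean(e1), sd_E1 = stats::sd(e1),
                 mean_E2 = mean(e2), sd_E2 = stats::sd(e2),
                 n_converged = sum(conv),
                 per_position = per_pos,
                 complete = length(fits) == expected,
                 layout = layout),
            class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat(sprintf(
    "<grid_summary> %d curves (%d converged)%s\n  E1 = %.3g +/- %.3g Pa, E2 = %.3g +/- %.3g Pa\n",
    x$n_curves, x$n_converged, if (x$complete) "" else " [incomplete grid]",
    x$mean_E1, x$sd_E1, x$mean_E2, x$sd_E2))
  invisible(x)
}
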