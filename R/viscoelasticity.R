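# Viscous dissipation from indentation hysteresis and two-element
# generalized Maxwell fitting of whole-cell stress-relaxation traces.

#' Viscous energy dissipated over an indentation cycle
#'
#' Integrates the area enclosed between the approach and retraction
#' branches of a force-indentation cycle, restricted to the positive-force
#' region. The retract branch is linearly interpolated onto the approach
#' indentation grid and the difference is integrated by the trapezoidal
#' rule. With force in nN and indentation in um the area is directly in fJ.
#'
#' @param ind An [indentation_curve()] with both approach and retract
#'   segments on a common indentation axis.
#' @return An object of class `dissipation_result`: `energy` (fJ),
#'   `positive_force_span` (um), `n_points_used`, `flagged` (TRUE when the
#'   energy is more negative than numerical noise allows).
#' @param noise_sd Optional force noise SD in nN used for the negativity
#'   flag; estimated from the pre-contact approach samples when `NULL`.
#' @export
dissipated_energy <- function(ind, noise_sd = NULL) {
  stopifnot(inherits(ind, "indentation_curve"))
  app <- ind$segment == "approach"
  ret <- ind$segment == "retract"
  if (!any(ret)) stop("missing retract segment")

  da <- ind$delta[app]; fa <- ind$force[app]
  dr <- ind$delta[ret]; fr <- ind$force[ret]
  oa <- order(da); da <- da[oa]; fa <- fa[oa]
  orr <- order(dr); dr <- dr[orr]; fr <- fr[orr]

  lo <- max(min(da), min(dr)); hi <- min(max(da), max(dr))
  if (hi <= lo) stop("approach and retract indentation ranges do not overlap")
  keep <- da >= lo & da <= hi
  grid <- da[keep]; f_app <- fa[keep]
  f_ret <- stats::approx(dr, fr, xout = grid, ties = mean)$y

  pos <- f_app > 0 | f_ret > 0
  f_app <- pmax(f_app, 0); f_ret <- pmax(f_ret, 0)
  diffs <- f_app - f_ret
  n <- length(grid)
  energy <- if (n >= 2L)
    sum((diffs[-1L] + diffs[-n]) / 2 * diff(grid)) * .NN_UM_TO_FJ
  else 0

  if (is.null(noise_sd)) {
    pre <- fa[da < 0]
    noise_sd <- if (length(pre) >= 8L) stats::sd(pre) else 0
  }
  span <- if (any(pos)) diff(range(grid[pos])) else 0
  flagged <- energy < -3 * noise_sd * max(span, .Machine$double.eps)
  structure(list(energy = energy, positive_force_span = span,
                 n_points_used = n, flagged = flagged),
            class = "dissipation_result")
}

#' @export
print.dissipation_result <- function(x, ...) {
  cat(sprintf("<dissipation_result> %.3g fJ over %.3g um (%d points)%s\n",
              x$energy, x$positive_force_span, x$n_points_used,
              if (x$flagged) " [flagged: negative beyond noise]" else ""))
  invisible(x)
}

#' Fit a two-element generalized Maxwell model to a relaxation trace
#'
#' Least-squares fit of the hold segment to
#' `F(t) = a0 + a1 exp(-(t - t0)/tau1) + a2 exp(-(t - t0)/tau2)`,
#' the stress relaxation of two Maxwell elements (spring-dashpot in series)
#' in parallel with an equilibrium spring. The initializer peels the two
#' exponentials in stages: a log-linear fit on the tail window gives the
#' slow component, which is subtracted before fitting the head for the fast
#' one. Output is ordered `tau1 < tau2`. When the two time constants are
#' not resolvable (ratio below `min_tau_ratio`) or an amplitude is within
#' noise, a single-element fit is returned with `fallback = TRUE`.
#'
#' @param trace A [relaxation_trace()].
#' @param min_tau_ratio Minimum `tau2/tau1` for the two elements to count
#'   as resolved, default 1.5.
#' @param tail_fraction Fraction of the hold used for the slow-component
#'   initializer, default 0.4.
#' @return An object of class `maxwell_fit`: `a0`, `a1`, `a2` (nN), `t0`
#'   (s), `tau1`, `tau2` (s, `tau1 < tau2`), `rss` (nN^2), `converged`,
#'   `fallback`.
#' @export
fit_maxwell2 <- function(trace, min_tau_ratio = 1.5, tail_fraction = 0.4) {
  stopifnot(inherits(trace, "relaxation_trace"))
  hold <- trace$t >= trace$t0
  if (sum(hold) < 50L) stop("need at least 50 hold samples")
  tt <- trace$t[hold] - trace$t0
  ff <- trace$force[hold]
  dur <- max(tt)

  # --- two-stage exponential peel initializer ---
  a0_0 <- min(ff)
  tail <- tt >= (1 - tail_fraction) * dur
  init_exp <- function(t, y) {
    # log-linear fit of y ~ A exp(-t/tau), y floored to stay positive
    pos <- y > .Machine$double.eps
    if (sum(pos) < 3L) return(NULL)
    co <- unname(stats::lm.fit(cbind(1, t[pos]), log(y[pos]))$coefficients)
    if (co[2L] >= 0) return(NULL)
    list(A = exp(co[1L]), tau = -1 / co[2L])
  }
  slow <- init_exp(tt[tail], ff[tail] - a0_0 +
                     0.05 * (max(ff) - a0_0))  # offset guard vs log(0)
  if (is.null(slow)) slow <- list(A = (max(ff) - a0_0) / 2, tau = dur / 3)
  resid_head <- ff - a0_0 - slow$A * exp(-tt / slow$tau)
  head_win <- tt <= dur * 0.2
  fast <- init_exp(tt[head_win], resid_head[head_win])
  if (is.null(fast)) fast <- list(A = (max(ff) - a0_0) / 2,
                                  tau = slow$tau / 10)

  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      ff ~ a0 + a1 * exp(-tt / tau1) + a2 * exp(-tt / tau2),
      start = list(a0 = a0_0, a1 = fast$A, a2 = slow$A,
                   tau1 = min(fast$tau, slow$tau / 2),
                   tau2 = max(slow$tau, fast$tau * 2)),
      lower = c(a0 = -Inf, a1 = 0, a2 = 0, tau1 = 1e-4, tau2 = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)

  noise <- stats::sd(diff(ff)) / sqrt(2)   # high-frequency noise estimate
  ok2 <- FALSE
  if (!is.null(fit2)) {
    cf <- stats::coef(fit2)
    taus <- sort(c(cf[["tau1"]], cf[["tau2"]]))
    amps <- c(cf[["a1"]], cf[["a2"]])[order(c(cf[["tau1"]], cf[["tau2"]]))]
    ok2 <- taus[2L] / taus[1L] >= min_tau_ratio && all(amps > 2 * noise)
  }

  if (ok2) {
    return(structure(list(a0 = cf[["a0"]], a1 = amps[1L], a2 = amps[2L],
                          t0 = trace$t0, tau1 = taus[1L], tau2 = taus[2L],
                          rss = sum(stats::residuals(fit2)^2),
                          converged = TRUE, fallback = FALSE),
                     class = "maxwell_fit"))
  }

  # single-element fallback (small multistart over tau)
  fit1 <- NULL
  for (tau_try in unique(c(slow$tau, dur / 10, dur / 3, 1))) {
    fit1 <- tryCatch(
      minpack.lm::nlsLM(
        ff ~ a0 + a1 * exp(-tt / tau1),
        start = list(a0 = a0_0, a1 = max(ff) - a0_0, tau1 = tau_try),
        lower = c(a0 = -Inf, a1 = 0, tau1 = 1e-4),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit1)) break
  }
  if (is.null(fit1))
    return(structure(list(a0 = a0_0, a1 = NA_real_, a2 = NA_real_,
                          t0 = trace$t0, tau1 = NA_real_, tau2 = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          fallback = TRUE),
                     class = "maxwell_fit"))
  cf1 <- stats::coef(fit1)
  structure(list(a0 = cf1[["a0"]], a1 = cf1[["a1"]], a2 = 0,
                 t0 = trace$t0, tau1 = cf1[["tau1"]], tau2 = NA_real_,
                 rss = sum(stats::residuals(fit1)^2),
                 converged = TRUE, fallback = TRUE),
            class = "maxwell_fit")
}

#' @export
print.maxwell_fit <- function(x, ...) {
  if (x$fallback)
    cat(sprintf("<maxwell_fit> single-element fallback: a0 = %.3g nN, tau = %.3g s\n",
                x$a0, x$tau1))
  else
    cat(sprintf(
      "<maxwell_fit> a0 = %.3g, a1 = %.3g, a2 = %.3g nN; tau1 = %.3g s, tau2 = %.3g s\n",
      x$a0, x$a1, x$a2, x$tau1, x$tau2))
  invisible(x)
}

#' Viscosity of a Maxwell element from its relaxation time
#'
#' A Maxwell element relaxes with `tau = eta / E`, so `eta = tau * E`.
#'
#' @param tau Relaxation time in s, `> 0`.
#' @param E Young's modulus in Pa, `> 0`.
#' @return Viscosity in Pa s.
#' @export
viscosity_from <- function(tau, E) {
  if (any(tau <= 0) || any(E <= 0)) stop("tau and E must be > 0")
  tau * E
}

#' Assign relaxation times to oocyte compartments
#'
#' The whole-cell relaxation involves both the zona pellucida and the
#' ooplasm; the faster time constant is assigned to the stiffer, less
#' viscous ZP and the slower one to the ooplasm.
#'
#' @param fit A converged two-element [fit_maxwell2()] result.
#' @param E_zp,E_ooplasm Optional Young's moduli (Pa) used to also report
#'   compartment viscosities via [viscosity_from()].
#' @return An object of class `compartment_assignment`: `zp_tau`,
#'   `ooplasm_tau` (s), and `zp_eta`, `ooplasm_eta` (Pa s) when moduli are
#'   supplied.
#' @export
assign_compartments <- function(fit, E_zp = NULL, E_ooplasm = NULL) {
  stopifnot(inherits(fit, "maxwell_fit"))
  if (!isTRUE(fit$converged))
    stop("cannot assign compartments: fit did not converge")
  if (isTRUE(fit$fallback))
    stop("cannot assign compartments: only one relaxation time resolved ",
         "(single-element fallback)")
  zp <- min(fit$tau1, fit$tau2)
  oo <- max(fit$tau1, fit$tau2)
  structure(list(
    zp_tau = zp, ooplasm_tau = oo,
    zp_eta = if (is.null(E_zp)) NA_real_ else viscosity_from(zp, E_zp),
    ooplasm_eta = if (is.null(E_ooplasm)) NA_real_
                  else viscosity_from(oo, E_ooplasm)),
    class = "compartment_assignment")
}
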