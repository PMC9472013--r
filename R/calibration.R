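# Cantilever spring-constant calibration.
#
# Two routes: the thermal-noise (equipartition) method used for the
# bead-mounted microcantilevers, and the spring-on-spring method used for
# the whole-cell macrocantilevers.

#' Thermal deflection record
#'
#' @param d Deflection time series in nm, acquired off-contact.
#' @param sample_rate Sampling rate in Hz.
#' @param temperature Bath temperature in K.
#' @return An object of class `thermal_record`.
#' @export
thermal_record <- function(d, sample_rate, temperature = 300) {
  if (length(d) < 4096L)
    stop("thermal record needs >= 4096 samples, got ", length(d))
  if (temperature < 273 || temperature > 330)
    stop("temperature ", temperature, " K outside the plausible range ",
         "[273, 330] K")
  structure(list(d = as.numeric(d), sample_rate = sample_rate,
                 temperature = temperature),
            class = "thermal_record")
}

#' Spring constant by the thermal-noise method
#'
#' Equipartition assigns `k_B * T / 2` to the cantilever's fundamental
#' bending mode, so `k = correction * k_B * T / <d^2>` with `<d^2>` the
#' variance of the detrended deflection in m^2. The correction factor
#' absorbs the mode shape and optical-lever geometry; the first-mode
#' optical-lever convention gives 0.817.
#'
#' @param rec A [thermal_record()] (deflection in nm).
#' @param correction Unitless correction factor, default 0.817.
#' @return Spring constant in N/m.
#' @export
thermal_noise_k <- function(rec, correction = 0.817) {
  stopifnot(inherits(rec, "thermal_record"))
  d <- rec$d - stats::fitted(stats::lm(rec$d ~ seq_along(rec$d)))
  v <- stats::var(d) * 1e-18  # nm^2 -> m^2
  if (v <= 0) stop("zero variance: no thermal motion recorded")
  correction * .K_BOLTZMANN * rec$temperature / v
}

#' Spring-on-spring deflection-sharing record
#'
#' @param slope Measured deflection per unit piezo displacement, unitless
#'   in (0, 1), while pressing the reference spring.
#' @param k_ref Reference spring constant in N/m.
#' @return An object of class `sos_record`.
#' @export
sos_record <- function(slope, k_ref) {
  if (any(slope <= 0) || any(slope >= 1))
    stop("slope must lie strictly in (0, 1); got ", slope[1L])
  if (k_ref <= 0) stop("k_ref must be > 0")
  structure(list(slope = slope, k_ref = k_ref), class = "sos_record")
}

#' Spring constant by the spring-on-spring method
#'
#' Pressing a reference spring of stiffness `k_ref`, the piezo displacement
#' z splits between cantilever deflection d and reference compression
#' z - d; force balance `k * d = k_ref * (z - d)` inverts to
#' `k = k_ref * (1 - slope) / slope` with `slope = d/z`.
#'
#' @param rec An [sos_record()].
#' @return Spring constant in N/m (vectorised over `slope`).
#' @export
spring_on_spring_k <- function(rec) {
  stopifnot(inherits(rec, "sos_record"))
  rec$k_ref * (1 - rec$slope) / rec$slope
}
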