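# Cortical-granule exocytosis quantification from fluorescence images.
#
# Released alpha-mannose residues accumulate in the perivitelline space
# (PVS), so lectin-conjugated fluorophore intensity forms a ring between
# the ooplasm and the zona. The signal is quantified from line profiles
# through the cell: background-subtracted area under the PVS peak,
# averaged over several profiles, tracked over time and normalized to the
# first acquisition.

#' Extract an intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation along the segment from `p0`
#' to `p1` at a spacing of at most one pixel.
#'
#' @param image Numeric matrix (single-channel intensities, rows = y).
#' @param p0,p1 Numeric length-2 vectors `c(x, y)` in pixel coordinates
#'   (1-based, within the image).
#' @param pixel_size_um Physical pixel size in um, used to express the
#'   position axis in um.
#' @return An object of class `line_profile`: `s` (position along the line
#'   in um), `I` (intensity, ADU), `p0`, `p1`, `pixel_size_um`.
#' @export
extract_profile <- function(image, p0, p1, pixel_size_um = 1) {
  stopifnot(is.matrix(image), length(p0) == 2L, length(p1) == 2L)
  nx <- ncol(image); ny <- nrow(image)
  for (p in list(p0, p1))
    if (p[1L] < 1 || p[1L] > nx || p[2L] < 1 || p[2L] > ny)
      stop("profile endpoint (", p[1L], ", ", p[2L], ") outside image")
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len_px) + 1L)
  tfrac <- seq(0, 1, length.out = n)
  x <- p0[1L] + tfrac * (p1[1L] - p0[1L])
  y <- p0[2L] + tfrac * (p1[2L] - p0[2L])

  x0 <- pmin(pmax(floor(x), 1L), nx - 1L); y0 <- pmin(pmax(floor(y), 1L), ny - 1L)
  fx <- x - x0; fy <- y - y0
  I <- image[cbind(y0,     x0)]     * (1 - fx) * (1 - fy) +
       image[cbind(y0,     x0 + 1)] * fx       * (1 - fy) +
       image[cbind(y0 + 1, x0)]     * (1 - fx) * fy +
       image[cbind(y0 + 1, x0 + 1)] * fx       * fy
  structure(list(s = tfrac * len_px * pixel_size_um, I = as.numeric(I),
                 p0 = p0, p1 = p1, pixel_size_um = pixel_size_um),
            class = "line_profile")
}

#' Locate the PVS peak window on a profile
#'
#' Default window rule: the widest interior run where the intensity
#' exceeds the flank background plus `k_sd` flank SDs.
#'
#' @param profile A [line_profile()].
#' @param flank_fraction Fraction of samples at each end treated as flank;
#'   the default 0.15 keeps the flanks outside the cell for profiles drawn
#'   edge-to-edge through the centroid.
#' @param k_sd Threshold in flank SDs above the flank median, default 2.
#' @return Numeric length-2 window `c(s_lo, s_hi)` in um, or `NULL` when no
#'   interior run exceeds the threshold.
#' @export
find_peak_window <- function(profile, flank_fraction = 0.15, k_sd = 2) {
  stopifnot(inherits(profile, "line_profile"))
  n <- length(profile$s)
  nf <- max(3L, floor(n * flank_fraction))
  flank <- c(profile$I[seq_len(nf)], profile$I[seq.int(n - nf + 1L, n)])
  thr <- stats::median(flank) + k_sd * stats::sd(flank)
  above <- profile$I > thr
  above[c(seq_len(nf), seq.int(n - nf + 1L, n))] <- FALSE
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(profile$s[starts[best]], profile$s[ends[best]])
}

#' Background-subtracted area under the PVS peak
#'
#' Background is the median intensity of the flanking samples (25% of the
#' window width on each side by default); the area is the rectangle-rule
#' sum of the positive part of `I - background` over the window.
#'
#' @param profile A [line_profile()].
#' @param window Numeric `c(s_lo, s_hi)` position interval (um) containing
#'   the peak; located automatically via [find_peak_window()] when `NULL`.
#' @param flank_fraction Fraction of the window width used as flank on each
#'   side for the background estimate.
#' @return An object of class `pvs_signal`: `area` (ADU um, floored at 0),
#'   `background_level` (ADU), `n_profiles = 1`, `se = NA`.
#' @export
pvs_peak_area <- function(profile, window = NULL, flank_fraction = 0.25) {
  stopifnot(inherits(profile, "line_profile"))
  s <- profile$s; I <- profile$I
  if (length(s) < 32L) stop("profile too short: need >= 32 samples")
  if (is.null(window)) window <- find_peak_window(profile)
  if (is.null(window))    # no detectable peak: all background
    return(structure(list(area = 0,
                          background_level = stats::median(I),
                          n_profiles = 1L, se = NA_real_, t = NA_real_),
                     class = "pvs_signal"))
  if (window[1L] < min(s) || window[2L] > max(s))
    stop("peak window wider than the profile")
  inw <- s >= window[1L] & s <= window[2L]
  if (!any(inw)) stop("peak window contains no samples")
  wwidth <- window[2L] - window[1L]
  fl <- flank_fraction * wwidth
  flank <- (s >= window[1L] - fl & s < window[1L]) |
           (s > window[2L] & s <= window[2L] + fl)
  if (!any(flank))   # fall back to everything outside the window
    flank <- !inw
  bg <- stats::median(I[flank])
  ds <- stats::median(diff(s))
  area <- sum(pmax(I[inw] - bg, 0)) * ds
  structure(list(area = max(area, 0), background_level = bg,
                 n_profiles = 1L, se = NA_real_, t = NA_real_),
            class = "pvs_signal")
}

#' Average the PVS signal over several profiles of one cell
#'
#' The acquisition convention is five profiles per cell per timepoint;
#' their background-subtracted areas are averaged arithmetically and the
#' standard error retained.
#'
#' @param signals List of single-profile [pvs_peak_area()] results (or a
#'   numeric vector of areas).
#' @param t Acquisition time (h or min, caller's convention).
#' @return A `pvs_signal` with `area` the mean, `n_profiles`, `se`, `t`.
#' @export
aggregate_signal <- function(signals, t = NA_real_) {
  if (length(signals) == 0L) stop("no signals to aggregate")
  areas <- if (is.numeric(signals)) signals
           else vapply(signals, `[[`, numeric(1), "area")
  bgs <- if (is.numeric(signals)) NA_real_
         else mean(vapply(signals, `[[`, numeric(1), "background_level"))
  n <- length(areas)
  structure(list(area = mean(areas), background_level = bgs,
                 n_profiles = n,
                 se = if (n > 1L) stats::sd(areas) / sqrt(n) else NA_real_,
                 t = t),
            class = "pvs_signal")
}

#' Normalize a time series to its first value
#'
#' Used for both the fluorescence and the stiffness series recorded after
#' activator addition: every value is divided by the first, so the series
#' starts at exactly 1.
#'
#' @param x Numeric series (or list of `pvs_signal`s, whose areas are
#'   taken); first element must be `> 0`.
#' @return Unitless numeric series with `x[1] == 1`.
#' @export
normalize_series <- function(x) {
  if (is.list(x)) x <- vapply(x, `[[`, numeric(1), "area")
  if (length(x) == 0L) stop("empty series")
  if (x[1L] <= 0) stop("first value must be > 0 to normalize")
  x / x[1L]
}

#' Quantify the PVS fluorescence signal of one image
#'
#' Runs the default measurement on a single frame: `n_profiles` line
#' profiles at equally spaced angles through the cell centroid, automatic
#' peak-window location per profile, background-subtracted areas averaged
#' with [aggregate_signal()].
#'
#' @param image Numeric intensity matrix.
#' @param center Cell centroid `c(x, y)` in pixels; intensity-weighted
#'   centroid of the image when `NULL`.
#' @param radius Profile half-length in pixels; reaches the nearest border
#'   when `NULL`.
#' @param n_profiles Number of angular profiles, default 5.
#' @param pixel_size_um Pixel size in um.
#' @param t Acquisition time passed through to the result.
#' @return A `pvs_signal` for the frame.
#' @export
measure_frame <- function(image, center = NULL, radius = NULL,
                          n_profiles = 5, pixel_size_um = 1,
                          t = NA_real_) {
  stopifnot(is.matrix(image))
  nx <- ncol(image); ny <- nrow(image)
  if (is.null(center)) {
    tot <- sum(image)
    center <- if (tot > 0)
      c(sum(col(image) * image) / tot, sum(row(image) * image) / tot)
    else c((nx + 1) / 2, (ny + 1) / 2)
  }
  if (is.null(radius))
    radius <- min(center[1L] - 1, nx - center[1L],
                  center[2L] - 1, ny - center[2L])
  angles <- seq(0, pi, length.out = n_profiles + 1L)[seq_len(n_profiles)]
  sigs <- lapply(angles, function(a) {
    u <- c(cos(a), sin(a))
    pvs_peak_area(extract_profile(image, center - radius * u,
                                  center + radius * u,
                                  pixel_size_um = pixel_size_um))
  })
  aggregate_signal(sigs, t = t)
}
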