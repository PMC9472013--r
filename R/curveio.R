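# Data model and file I/O for force curves and relaxation traces.
#
# Curve files are UTF-8 TSV: '#'-prefixed "key: value" header lines carrying
# probe metadata and units, then a header row and the columns t, z, d,
# segment (tab-separated). One curve per file; a manifest CSV maps files to
# oocyte/grid/replicate.

#' Probe metadata for an AFM force measurement
#'
#' Bundles the cantilever and acquisition parameters needed to convert a raw
#' deflection record into force and indentation.
#'
#' @param spring_constant Cantilever spring constant in N/m.
#' @param bead_radius Radius of the spherical indenter bead in um. The
#'   default 2.25 um corresponds to a 4.5 um silica microbead.
#' @param deflection_sensitivity Optical-lever sensitivity in nm/V, or `NA`
#'   if the deflection channel is already expressed in length units.
#' @param approach_speed Piezo approach speed in um/s.
#' @param setpoint_force Force trigger ending the approach, in nN.
#'
#' @return An object of class `probe_meta`.
#' @export
probe_meta <- function(spring_constant = 0.32, bead_radius = 2.25,
                       deflection_sensitivity = NA_real_,
                       approach_speed = 5, setpoint_force = 1) {
  stopifnot(is.numeric(spring_constant), length(spring_constant) == 1L,
            is.numeric(bead_radius), length(bead_radius) == 1L,
            is.numeric(approach_speed), length(approach_speed) == 1L)
  if (spring_constant <= 0) stop("spring_constant must be > 0")
  if (bead_radius <= 0) stop("bead_radius must be > 0")
  if (approach_speed <= 0) stop("approach_speed must be > 0")
  structure(list(spring_constant = spring_constant,
                 bead_radius = bead_radius,
                 deflection_sensitivity = deflection_sensitivity,
                 approach_speed = approach_speed,
                 setpoint_force = setpoint_force),
            class = "probe_meta")
}

.SEGMENT_LEVELS <- c("approach", "hold", "retract")

#' Construct a validated force curve
#'
#' A force curve is the raw record of one indentation cycle: piezo height,
#' cantilever deflection and time, each sample labelled with the acquisition
#' segment (approach, hold or retract).
#'
#' @param z Piezo height in um; monotone within the approach segment, with
#'   larger z meaning further into the sample.
#' @param d Vertical deflection in um, positive when the cantilever is
#'   pushed up (compressive contact).
#' @param t Time in s.
#' @param segment Character vector of per-sample labels from
#'   `c("approach", "hold", "retract")`.
#' @param meta A [probe_meta()] object.
#' @param position Optional list with grid coordinates `row`, `col` and
#'   `replicate` index.
#' @param extra Optional named list of free metadata (preserved on
#'   round-trip through [write_curve()]/[read_curve()]).
#'
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, d, t, segment, meta = probe_meta(),
                        position = NULL, extra = list()) {
  n <- length(z)
  if (n < 16L) stop("force curve needs at least 16 samples, got ", n)
  if (length(d) != n || length(t) != n || length(segment) != n)
    stop("z, d, t and segment must have equal length")
  if (!all(segment %in% .SEGMENT_LEVELS))
    stop("segment labels must be one of: ",
         paste(.SEGMENT_LEVELS, collapse = ", "))
  if (!inherits(meta, "probe_meta")) stop("meta must be a probe_meta object")

  cv <- structure(list(z = as.numeric(z), d = as.numeric(d),
                       t = as.numeric(t),
                       segment = as.character(segment), meta = meta,
                       position = position, extra = extra),
                  class = "force_curve")
  .check_segment_monotone(cv)
  if (!any(segment == "retract"))
    warning("curve has no retract segment", call. = FALSE)
  cv
}

# approach z must be monotone in one direction; retract in the opposite
.check_segment_monotone <- function(cv) {
  app <- cv$z[cv$segment == "approach"]
  if (length(app) >= 2L) {
    dz <- diff(app)
    up <- all(dz >= 0); down <- all(dz <= 0)
    if (!up && !down) {
      bad <- which(sign(dz) != sign(dz[match(TRUE, dz != 0)]) & dz != 0)[1L]
      stop("approach z is not monotone; first offending index ", bad + 1L)
    }
    ret <- cv$z[cv$segment == "retract"]
    if (length(ret) >= 2L) {
      dr <- diff(ret)
      ok <- if (up) all(dr <= 0) else all(dr >= 0)
      if (!ok) stop("retract z must be monotone opposite to approach")
    }
  }
  invisible(cv)
}

#' @export
print.force_curve <- function(x, ...) {
  segs <- table(factor(x$segment, levels = .SEGMENT_LEVELS))
  cat("<force_curve> ", length(x$z), " samples (",
      paste(sprintf("%s: %d", names(segs), segs), collapse = ", "), ")\n",
      sep = "")
  cat(sprintf("  k = %.3g N/m, R = %.3g um, setpoint = %.3g nN\n",
              x$meta$spring_constant, x$meta$bead_radius,
              x$meta$setpoint_force))
  invisible(x)
}

#' Construct an indentation curve
#'
#' Force versus indentation per segment, as derived from a force curve once
#' a contact point is known. `delta` is zero at the contact point by
#' construction; pre-contact samples keep their negative `delta` for
#' diagnostics.
#'
#' @param delta Indentation in um (positive into the sample).
#' @param force Force in nN (positive compressive).
#' @param segment Per-sample segment labels.
#' @param meta A [probe_meta()] object.
#'
#' @return An object of class `indentation_curve`.
#' @export
indentation_curve <- function(delta, force, segment, meta = probe_meta()) {
  n <- length(delta)
  if (length(force) != n || length(segment) != n)
    stop("delta, force and segment must have equal length")
  structure(list(delta = as.numeric(delta), force = as.numeric(force),
                 segment = as.character(segment), meta = meta),
            class = "indentation_curve")
}

#' Construct a stress-relaxation trace
#'
#' Force versus time while a fixed compression is held on the whole cell.
#'
#' @param t Time in s.
#' @param force Force in nN.
#' @param t0 Time at which the hold starts (end of the loading ramp), in s.
#' @param applied_displacement Compression applied from the contact
#'   position, in um.
#' @param meta A [probe_meta()] object.
#'
#' @return An object of class `relaxation_trace`.
#' @export
relaxation_trace <- function(t, force, t0, applied_displacement,
                             meta = probe_meta()) {
  if (length(t) != length(force)) stop("t and force must have equal length")
  hold <- t >= t0
  if (sum(hold) < 2L || diff(range(t[hold])) < 10)
    stop("hold window must last at least 10 s")
  structure(list(t = as.numeric(t), force = as.numeric(force), t0 = t0,
                 applied_displacement = applied_displacement, meta = meta),
            class = "relaxation_trace")
}

## ---- file dialect -------------------------------------------------------

.META_KEYS <- c(spring_constant = "spring_constant_N_per_m",
                bead_radius = "bead_radius_um",
                deflection_sensitivity = "deflection_sensitivity_nm_per_V",
                approach_speed = "approach_speed_um_per_s",
                setpoint_force = "setpoint_force_nN")

#' Write a force curve to a TSV file
#'
#' @param curve A [force_curve()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_curve()] for the dialect.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# ovomech-curve: 1", con)
  writeLines("# units: t=s z=um d=um", con)
  m <- curve$meta
  for (f in names(.META_KEYS)) {
    v <- m[[f]]
    if (!is.na(v))
      writeLines(sprintf("# %s: %.17g", .META_KEYS[[f]], v), con)
  }
  if (!is.null(curve$position))
    writeLines(sprintf("# position: %d %d %d", curve$position$row,
                       curve$position$col, curve$position$replicate), con)
  for (k in names(curve$extra)) {
    v <- curve$extra[[k]]
    # only scalar free metadata goes in the header (generator truth lists
    # and other structured attachments live in sidecar files)
    if (is.atomic(v) && length(v) == 1L)
      writeLines(sprintf("# %s: %s", k, as.character(v)), con)
  }
  writeLines("t\tz\td\tsegment", con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g\t%s",
                     curve$t, curve$z, curve$d, curve$segment), con)
  invisible(path)
}

.parse_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    i <- regexpr(":", body, fixed = TRUE)
    if (i < 0) next
    key <- trimws(substr(body, 1L, i - 1L))
    val <- trimws(substr(body, i + 1L, nchar(body)))
    kv[[key]] <- val
  }
  kv
}

#' Read a force curve from a TSV file
#'
#' The dialect is UTF-8 TSV with `#`-prefixed `key: value` header lines
#' (probe metadata, units) followed by a header row and the tab-separated
#' columns `t`, `z`, `d`, `segment`. Unknown header keys are preserved in
#' the curve's `extra` metadata.
#'
#' @param path Path to a curve file.
#' @return A validated [force_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- startsWith(lines, "#")
  kv <- .parse_header(lines[hdr])

  body <- lines[!hdr]
  if (!length(body)) stop("format error: no data rows in ", path)
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  for (need in c("t", "z", "d", "segment"))
    if (!need %in% cols)
      stop("format error: missing mandatory column '", need, "'")
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)

  num <- function(key, default) {
    v <- kv[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  meta <- probe_meta(
    spring_constant = num(.META_KEYS[["spring_constant"]], 0.32),
    bead_radius = num(.META_KEYS[["bead_radius"]], 2.25),
    deflection_sensitivity =
      num(.META_KEYS[["deflection_sensitivity"]], NA_real_),
    approach_speed = num(.META_KEYS[["approach_speed"]], 5),
    setpoint_force = num(.META_KEYS[["setpoint_force"]], 1))

  position <- NULL
  if (!is.null(kv[["position"]])) {
    p <- as.integer(strsplit(kv[["position"]], "\\s+")[[1L]])
    position <- list(row = p[1L], col = p[2L], replicate = p[3L])
  }
  known <- c("ovomech-curve", "units", "position", unname(.META_KEYS))
  extra <- kv[setdiff(names(kv), known)]

  force_curve(z = df$z, d = df$d, t = df$t, segment = df$segment,
              meta = meta, position = position, extra = extra)
}

## ---- physical preprocessing --------------------------------------------

#' Subtract the free-travel baseline from the deflection channel
#'
#' Fits a straight line to the first `fraction` of approach samples (assumed
#' out of contact) and subtracts it from the deflection over all segments,
#' removing photodiode offset and linear drift.
#'
#' @param curve A [force_curve()].
#' @param fraction Fraction of approach samples, in (0, 1), treated as the
#'   non-contact window. Default 0.3: grid curves start well away from
#'   contact.
#' @return A corrected copy of `curve`; the mean corrected deflection over
#'   the window is ~0.
#' @export
baseline_correct <- function(curve, fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"), fraction > 0, fraction < 1)
  idx <- which(curve$segment == "approach")
  nwin <- floor(length(idx) * fraction)
  if (nwin < 8L)
    stop("baseline window has ", nwin, " samples; need at least 8")
  win <- idx[seq_len(nwin)]
  fit <- stats::lm.fit(cbind(1, curve$z[win]), curve$d[win])
  curve$d <- curve$d - (fit$coefficients[1L] + fit$coefficients[2L] * curve$z)
  curve$extra$baseline_noise_sd_um <- stats::sd(curve$d[win])
  curve
}

#' Convert a force curve to force versus indentation
#'
#' Past the contact point the piezo travel divides between cantilever
#' bending and sample indentation, so the indentation is the height change
#' minus the deflection change:
#' `delta = (z - contact_z) - (d - d(contact_z))`, and
#' `force = k * (d - d(contact_z))` (converted N/m x um -> nN).
#' Pre-contact samples keep their negative `delta`.
#'
#' @param curve A baseline-corrected [force_curve()].
#' @param contact_z Contact height in um, within the approach z range.
#' @return An [indentation_curve()].
#' @export
to_indentation <- function(curve, contact_z) {
  stopifnot(inherits(curve, "force_curve"))
  app <- curve$segment == "approach"
  zr <- range(curve$z[app])
  if (contact_z < zr[1L] || contact_z > zr[2L])
    stop("contact_z = ", contact_z, " outside approach z range [",
         zr[1L], ", ", zr[2L], "]")
  d_c <- stats::approx(curve$z[app], curve$d[app], xout = contact_z,
                       ties = mean)$y
  sgn <- if (curve$z[app][1L] <= curve$z[app][sum(app)]) 1 else -1
  delta <- sgn * (curve$z - contact_z) - (curve$d - d_c)
  force <- curve$meta$spring_constant * (curve$d - d_c) * .K_UM_TO_NN
  indentation_curve(delta, force, curve$segment, curve$meta)
}
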