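#' Extract a 1D profile from an intensity image
#'
#' For 2D images, samples the row nearest to transverse height `y` (a
#' horizontal line; `vertical = TRUE` samples the column nearest `x`).
#' For 1D images this simply attaches positions.
#'
#' @param img An `intensity_image`.
#' @param y,x Line position in mm (for 2D images).
#' @param vertical Sample a vertical line instead of a horizontal one.
#' @return Object of class `intensity_profile` with fields `x` (positions,
#'   mm), `values` (I/I0), `pitch` (mm), `normalization_region`.
#' @export
extract_profile <- function(img, y = 0, x = 0, vertical = FALSE) {
  stopifnot(inherits(img, "intensity_image"))
  v <- img$values
  g <- img$grid
  if (is.matrix(v)) {
    if (vertical) {
      j <- which.min(abs(g$x - x))
      if (abs(g$x[j] - x) > g$pitch) stop("line position x outside the image")
      out_x <- g$y; out_v <- v[, j]
    } else {
      i <- which.min(abs(g$y - y))
      if (abs(g$y[i] - y) > g$pitch) stop("line position y outside the image")
      out_x <- g$x; out_v <- v[i, ]
    }
  } else {
    out_x <- g$x; out_v <- v
  }
  structure(list(x = out_x, values = as.numeric(out_v), pitch = g$pitch,
                 normalization_region = img$normalization_region),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples at %g um pitch, I/I0 in [%.4g, %.4g]\n",
              length(x$values), x$pitch * 1e3, min(x$values), max(x$values)))
  invisible(x)
}

# coerce inputs to an intensity_profile
as_profile <- function(profile, pitch = NULL) {
  if (inherits(profile, "intensity_profile")) return(profile)
  if (inherits(profile, "intensity_image")) return(extract_profile(profile))
  stopifnot(is.numeric(profile), !is.null(pitch))
  n <- length(profile)
  structure(list(x = pitch * (seq_len(n) - 1L - n / 2),
                 values = as.numeric(profile), pitch = pitch,
                 normalization_region = default_baseline(n)),
            class = "intensity_profile")
}

default_baseline <- function(n) {
  k <- max(1L, floor(n * 0.1))
  c(seq_len(k), seq(n - k + 1L, n))
}

# local extrema of a deviation profile: data.frame(idx, val), in index order
local_extrema <- function(d) {
  n <- length(d)
  if (n < 3L) return(data.frame(idx = integer(0), val = numeric(0)))
  s <- sign(diff(d))
  # collapse zero slopes onto the previous sign so plateaus yield one extremum
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  turns <- which(diff(s) != 0) + 1L
  data.frame(idx = turns, val = d[turns])
}

#' Edge-enhancement measurement at a single interface
#'
#' Quantifies the paired overshoot/undershoot fringe straddling one
#' material interface. Deviations are measured against side-local
#' baselines -- the mean plateau level at each end of the analysis window
#' -- because an interface generally separates two different transmission
#' plateaus and the fringe rides on top of that attenuation step. The
#' width is the span of the contiguous overshoot and undershoot
#' excursions exceeding 25% of the peak deviation (threshold
#' configurable), reported in mm and in sample (pixel) counts.
#'
#' A fringe is detected only when the overshoot rises above the higher of
#' the two plateaus and the undershoot falls below the lower one, each by
#' at least `detection_sigma` times the plateau noise -- so a pure
#' attenuation step (z = 0) returns the no-fringe flag. The window must
#' isolate one interface: a second comparably strong, well-separated
#' excursion is an error.
#'
#' @param profile An `intensity_profile` (or numeric vector with `pitch`)
#'   windowed around one interface, window ends on the flanking plateaus.
#' @param pitch Sample pitch in mm (only when `profile` is a bare vector).
#' @param baseline_frac Fraction of the window used as plateau baseline at
#'   each end (default 0.1, at least 2 samples).
#' @param threshold Fraction of the peak deviation defining the fringe
#'   extent (default 0.25).
#' @param detection_sigma Excursions must exceed this multiple of the
#'   plateau standard deviation (default 3).
#' @return Object of class `edge_measurement`: `interface_position` (mm),
#'   `overshoot_peak`, `undershoot_trough` (I/I0), `width` (mm),
#'   `pixels_spanned`, `no_fringe`.
#' @export
edge_width <- function(profile, pitch = NULL, baseline_frac = 0.1,
                       threshold = 0.25, detection_sigma = 3) {
  p <- as_profile(profile, pitch)
  v <- p$values
  n <- length(v)
  if (n < 6L) stop("analysis window too short")
  k <- max(2L, floor(n * baseline_frac))
  left <- seq_len(k); right <- seq(n - k + 1L, n)
  bl <- mean(v[left]); br <- mean(v[right])
  base_sd <- max(stats::sd(v[left]), stats::sd(v[right]))
  if (!is.finite(base_sd)) base_sd <- 0
  tol <- max(detection_sigma * base_sd, 1e-4 * max(bl, br))

  no_fringe_result <- structure(
    list(interface_position = NA_real_, overshoot_peak = NA_real_,
         undershoot_trough = NA_real_, width = 0, pixels_spanned = 0L,
         no_fringe = TRUE),
    class = "edge_measurement")
  imax <- which.max(v); imin <- which.min(v)
  if (v[imax] < max(bl, br) + tol || v[imin] > min(bl, br) - tol) {
    return(no_fringe_result)
  }

  # each excursion is measured against the plateau on its own side
  devL <- v - bl; devR <- v - br
  dev_o <- if (imax < imin) devL else devR
  dev_u <- if (imin < imax) devL else devR
  peak <- max(dev_o[imax], -dev_u[imin])
  thr <- threshold * peak
  run_around <- function(dev, i, sgn) {
    ok <- sgn * dev >= thr
    lo <- i; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- i; while (hi < n && ok[hi + 1L]) hi <- hi + 1L
    c(lo, hi)
  }
  ro <- run_around(dev_o, imax, +1)
  ru <- run_around(dev_u, imin, -1)
  lo <- min(ro[1L], ru[1L]); hi <- max(ro[2L], ru[2L])

  # single-interface guard: another strong paired excursion well outside
  # the measured span means the window holds more than one edge
  pad <- hi - lo
  outside <- setdiff(seq_len(n), seq(max(1L, lo - pad), min(n, hi + pad)))
  if (length(outside) > 0L) {
    d_out <- ifelse(outside < lo, devL[outside], devR[outside])
    if (max(d_out) > 0.5 * peak && min(d_out) < -0.5 * peak) {
      stop("analysis window appears to contain more than one interface; narrow the window")
    }
  }

  span <- hi - lo + 1L
  structure(
    list(interface_position = (p$x[imax] + p$x[imin]) / 2,
         overshoot_peak = v[imax], undershoot_trough = v[imin],
         width = span * p$pitch, pixels_spanned = as.integer(span),
         no_fringe = FALSE),
    class = "edge_measurement")
}

#' Registration-marginalized edge-enhancement width
#'
#' A fringe pair a few tens of micrometres wide, binned to 50-um detector
#' pixels, can span one, two or three pixels depending on where the pixel
#' boundaries happen to fall relative to the interface. Radiographs
#' contain airways at arbitrary sub-pixel registration, so the canonical
#' detector-limited width is the median of [edge_width()] over a sweep of
#' sub-pixel offsets of the airway against the pixel lattice.
#'
#' @param wall_thickness Airway wall thickness in mm.
#' @param energy_keV Photon energy (default 60).
#' @param z Propagation distance in mm (default 12 m).
#' @param sim_pitch Fine simulation grid pitch in mm (default 2.5 um).
#' @param pixel_pitch Detector pixel pitch in mm (default 50 um).
#' @param n_offsets Number of sub-pixel registrations sampled uniformly
#'   over one pixel (default 10).
#' @param table Material table.
#' @return List with `width_mm` (median), `pixels` (median span),
#'   `spans` (per-offset pixel spans).
#' @export
edge_width_detector_limited <- function(wall_thickness = 0.2,
                                        energy_keV = 60, z = 12000,
                                        sim_pitch = 0.0025,
                                        pixel_pitch = 0.05,
                                        n_offsets = 10,
                                        table = builtin_materials()) {
  offsets <- pixel_pitch * (seq_len(n_offsets) - 1L) / n_offsets
  r_in <- 1  # 2-mm lumen
  spans <- vapply(offsets, function(off) {
    scene <- phantom_scene(
      list(cylinder_airway(2, wall_thickness, center_offset = off)),
      background_thickness = 100, extent = 8)
    tm <- project_scene(scene, grid_spec(sim_pitch, 8))
    wf <- fresnel_propagate(
      transmission_function(tm, table, energy_keV),
      propagation_plan(z))
    px <- bin_to_pixels(intensity_image(wf), pixel_pitch)
    pp <- extract_profile(px)
    sel <- which(pp$x > off + r_in - 0.18 & pp$x < off + r_in + 0.13)
    m <- edge_width(structure(list(x = pp$x[sel], values = pp$values[sel],
                                   pitch = pp$pitch,
                                   normalization_region = NULL),
                              class = "intensity_profile"))
    if (m$no_fringe) NA_integer_ else m$pixels_spanned
  }, integer(1))
  med <- stats::median(spans, na.rm = TRUE)
  list(width_mm = med * pixel_pitch, pixels = med, spans = spans)
}

#' @export
print.edge_measurement <- function(x, ...) {
  if (x$no_fringe) {
    cat("<edge_measurement> no fringe detected\n")
  } else {
    cat(sprintf("<edge_measurement> interface at %.4g mm: overshoot %.4g, undershoot %.4g, width %.3g um (%d px)\n",
                x$interface_position, x$overshoot_peak, x$undershoot_trough,
                x$width * 1e3, x$pixels_spanned))
  }
  invisible(x)
}

#' Fringe visibility of a profile
#'
#' `(I_max - I_min) / (I_max + I_min)` after normalizing the profile to its
#' baseline mean. A flat profile has visibility 0.
#'
#' @inheritParams edge_width
#' @param window Optional index range restricting the analysis window.
#' @return Dimensionless visibility in `[0, 1]`.
#' @export
fringe_visibility <- function(profile, pitch = NULL, baseline_region = NULL,
                              window = NULL) {
  p <- as_profile(profile, pitch)
  v <- p$values
  if (is.null(baseline_region)) baseline_region <- default_baseline(length(v))
  base <- mean(v[baseline_region])
  if (base <= 0) stop("baseline mean must be > 0")
  v <- v / base
  if (!is.null(window)) v <- v[window]
  hi <- max(v); lo <- min(v)
  if (hi + lo <= 0) return(0)
  (hi - lo) / (hi + lo)
}

# parabolic sub-sample refinement of an extremum position
refine_extremum <- function(d, i, x) {
  if (i <= 1L || i >= length(d)) return(x[i])
  den <- d[i - 1L] - 2 * d[i] + d[i + 1L]
  if (den == 0) return(x[i])
  delta <- 0.5 * (d[i - 1L] - d[i + 1L]) / den
  if (abs(delta) > 1) return(x[i])
  x[i] + delta * (x[2L] - x[1L])
}

# fringe pairing: adjacent opposite-sign extrema; returns midpoints, the
# refined undershoot (trough) position of each pair, a strength score and
# the pair's distance range from `origin`
pair_extrema <- function(ex, d, x, origin) {
  if (nrow(ex) < 2L) {
    return(data.frame(center = numeric(0), trough = numeric(0),
                      score = numeric(0), near = numeric(0),
                      far = numeric(0)))
  }
  a <- seq_len(nrow(ex) - 1L)
  opp <- sign(ex$val[a]) != sign(ex$val[a + 1L])
  a <- a[opp]
  trough_idx <- ifelse(ex$val[a] < 0, ex$idx[a], ex$idx[a + 1L])
  da <- abs(x[ex$idx[a]] - origin)
  db <- abs(x[ex$idx[a + 1L]] - origin)
  data.frame(center = (x[ex$idx[a]] + x[ex$idx[a + 1L]]) / 2,
             trough = vapply(trough_idx, function(i) refine_extremum(d, i, x),
                             numeric(1)),
             score = abs(ex$val[a]) + abs(ex$val[a + 1L]),
             near = pmin(da, db), far = pmax(da, db))
}

#' Estimate the airway wall thickness from a fringe profile
#'
#' Estimates the wall thickness as the distance between the inner-edge
#' (air/wall) and outer-edge (wall/background) fringe markers on each side
#' of the lumen, averaged over both sides. Fringes are identified as
#' adjacent overshoot/undershoot extremum pairs; the wall border marker
#' within each pair is, by default, the undershoot trough (with parabolic
#' sub-sample refinement). At a curved interface the diffraction pattern
#' is asymmetric -- the tangent-ray caustic displaces the overshoot well
#' into the low-phase side -- so the pair midpoint systematically
#' overestimates the wall by about one Fresnel-zone width, while the
#' trough tracks the border to a few micrometres (`method = "midpoint"`
#' retains the midpoint convention for comparison). The profile must span
#' one full airway cross-section, centered near `center`.
#'
#' @inheritParams edge_width
#' @param center Approximate lumen center position in mm (default 0, the
#'   grid center for the built-in scenes).
#' @param true_thickness Optional known wall thickness (mm), echoed into
#'   the result for recovery studies.
#' @param max_wall Search limit for the outer fringe beyond the inner one,
#'   mm (default 1.2; walls are at most ~1 mm).
#' @return Object of class `wall_estimate`: `estimated_thickness` (mm),
#'   `per_side` (length 2), `true_thickness`, `method`, `no_estimate`.
#' @export
#' @param method Wall-border marker within each fringe pair: `"trough"`
#'   (default, refined undershoot position) or `"midpoint"` (extremum-pair
#'   midpoint).
wall_thickness_estimate <- function(profile, pitch = NULL,
                                    baseline_region = NULL, center = 0,
                                    true_thickness = NA_real_,
                                    max_wall = 1.2,
                                    detection_sigma = 3,
                                    method = c("trough", "midpoint")) {
  method <- match.arg(method)
  p <- as_profile(profile, pitch)
  v <- p$values
  n <- length(v)
  if (is.null(baseline_region)) baseline_region <- default_baseline(n)
  base <- mean(v[baseline_region])
  base_sd <- stats::sd(v[baseline_region])
  if (!is.finite(base_sd)) base_sd <- 0
  d <- v - base
  peak <- max(abs(d))
  method_label <- paste0("fringe-", method, " distance")
  no_est <- structure(
    list(estimated_thickness = NA_real_, per_side = c(NA_real_, NA_real_),
         true_thickness = true_thickness, method = method_label,
         no_estimate = TRUE),
    class = "wall_estimate")
  if (peak < detection_sigma * base_sd || peak == 0) return(no_est)

  thr <- max(detection_sigma * base_sd, 0.02 * peak)
  side_estimate <- function(side_sign) {
    sel <- which(side_sign * (p$x - center) > 0)
    if (length(sel) < 5L) return(NA_real_)
    # outward-increasing side coordinates make both sides symmetric
    u <- side_sign * (p$x[sel] - center)
    o <- order(u)
    u <- u[o]; ds <- d[sel][o]
    ex <- local_extrema(ds)
    ex <- ex[abs(ex$val) >= thr, , drop = FALSE]
    if (nrow(ex) < 2L) return(NA_real_)
    pr <- pair_extrema(ex, ds, u, origin = 0)
    if (nrow(pr) == 0L) return(NA_real_)
    i1 <- which.max(pr$score)
    P1 <- pr[i1, ]
    cand <- pr[-i1, , drop = FALSE]
    # the partner interface lies within the wall search window and is not
    # vanishingly weak
    cand <- cand[abs(cand$trough - P1$trough) <= max_wall + 2 * p$pitch &
                 cand$score >= 0.1 * P1$score, , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_real_)
    # orientation rule: a primary interface fringe carries its trough on
    # the wall side of its own center (inner edge: outward; outer edge:
    # inward), whereas diffraction-ringing pairs alternate -- so require
    # the candidate's trough to point back toward P1
    beyond <- cand$center > P1$center
    ok <- ifelse(beyond, cand$trough < cand$center, cand$trough > cand$center)
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) return(NA_real_)
    dt <- abs(cand$trough - P1$trough)
    resolved <- dt > p$pitch / 2
    if (any(resolved) && method == "trough") {
      cr <- cand[resolved, , drop = FALSE]
      j <- which.max(cr$score)
      abs(cr$trough[j] - P1$trough)
    } else {
      # merged troughs (wall unresolved at this pitch) or midpoint method:
      # fall back to the extremum-pair midpoint distance
      j <- which.max(cand$score)
      abs(cand$center[j] - P1$center)
    }
  }
  est <- c(side_estimate(-1), side_estimate(+1))
  if (all(is.na(est))) return(no_est)
  structure(
    list(estimated_thickness = mean(est, na.rm = TRUE), per_side = est,
         true_thickness = true_thickness, method = method_label,
         no_estimate = FALSE),
    class = "wall_estimate")
}

#' @export
print.wall_estimate <- function(x, ...) {
  if (x$no_estimate) {
    cat("<wall_estimate> fringes undetected; no estimate\n")
  } else {
    cat(sprintf("<wall_estimate> %.4g mm (sides: %s)%s\n",
                x$estimated_thickness,
                paste(sprintf("%.4g", x$per_side), collapse = ", "),
                if (is.na(x$true_thickness)) ""
                else sprintf("; true %.4g mm", x$true_thickness)))
  }
  invisible(x)
}

#' Flat key-value measurement report for a profile
#'
#' Convenience wrapper running [edge_width()] (on a window isolating the
#' requested interface), [fringe_visibility()] and
#' [wall_thickness_estimate()] and returning a flat named list suitable
#' for [write_report()].
#'
#' @param profile An `intensity_profile`.
#' @param wall_thickness True wall thickness (mm) if known.
#' @param edge_window Optional index range isolating one interface for the
#'   edge-width measurement; default a window around the strongest
#'   deviation.
#' @return Named list of measurements.
#' @export
measure_profile <- function(profile, wall_thickness = NA_real_,
                            edge_window = NULL) {
  p <- as_profile(profile)
  vis <- fringe_visibility(p)
  if (is.null(edge_window)) {
    base <- mean(p$values[default_baseline(length(p$values))])
    i0 <- which.max(abs(p$values - base))
    # asymmetric window: longer tail toward the lumen (grid center), short
    # tail outward, so the window ends rest on the flanking plateaus and
    # exclude the partner interface
    inward <- max(3L, round(0.15 / p$pitch))
    outward <- max(3L, round(0.08 / p$pitch))
    if (p$x[i0] >= 0) {
      edge_window <- max(1L, i0 - inward):min(length(p$values), i0 + outward)
    } else {
      edge_window <- max(1L, i0 - outward):min(length(p$values), i0 + inward)
    }
  }
  ew <- tryCatch(
    edge_width(structure(list(x = p$x[edge_window],
                              values = p$values[edge_window],
                              pitch = p$pitch,
                              normalization_region = NULL),
                         class = "intensity_profile")),
    error = function(e) NULL)
  wall <- wall_thickness_estimate(p, true_thickness = wall_thickness)
  out <- list(
    fringe_visibility = vis,
    edge_interface_position_mm = if (is.null(ew)) NA_real_ else ew$interface_position,
    edge_overshoot_peak = if (is.null(ew)) NA_real_ else ew$overshoot_peak,
    edge_undershoot_trough = if (is.null(ew)) NA_real_ else ew$undershoot_trough,
    edge_width_mm = if (is.null(ew)) NA_real_ else ew$width,
    edge_pixels_spanned = if (is.null(ew)) NA_integer_ else ew$pixels_spanned,
    edge_no_fringe = if (is.null(ew)) NA else ew$no_fringe,
    wall_estimate_mm = wall$estimated_thickness,
    wall_true_mm = wall_thickness
  )
  out
}
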