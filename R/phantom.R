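# Smooth zero-mean random field, unit pixel standard deviation, correlation
# length `scale` px.  White noise is generated on a grid extended by 3*scale
# on every side, low-pass filtered by circular convolution with a Gaussian
# kernel (via FFT), and the borders are cropped so the retained field is
# stationary (no edge effects from the padding or the circular wrap).
smooth_field <- function(height, width, scale) {
  r <- max(1L, ceiling(3 * scale))
  H <- height + 2L * r
  W <- width + 2L * r
  circ_kernel <- function(n) {
    d <- pmin(0:(n - 1L), n - 0:(n - 1L))
    k <- stats::dnorm(d, sd = scale)
    k / sum(k)
  }
  K <- outer(circ_kernel(H), circ_kernel(W))
  noise <- matrix(stats::rnorm(H * W), H, W)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(K), inverse = TRUE)) / (H * W)
  f <- f[(r + 1L):(r + height), (r + 1L):(r + width), drop = FALSE]
  s <- stats::sd(f)
  if (!is.finite(s) || s == 0) matrix(0, height, width) else (f - mean(f)) / s
}

#' Specification of a synthetic facial thermal phantom
#'
#' Describes a hemiface-pair phantom: a shared smooth physiologic
#' temperature texture that is mirror-symmetric between the two hemifaces,
#' plus a smooth contralateral asymmetry field (physiologic departure from
#' perfect symmetry) and independent per-pixel sensor noise.  Magnitudes are
#' standard deviations in deg C.
#'
#' Defaults emulate a healthy adult face: base 33.5 degC, physiologic
#' texture of 1 degC (vascular-scale correlation length 40 px), residual
#' contralateral asymmetry of 0.3 degC — well below the 2 degC moderate
#' cut-off, so healthy phantoms yield empty detections — and 0.1 degC sensor
#' noise.
#'
#' @param height,width Hemiface frame size in pixels (defaults 350 x 250,
#'   a typical analysis ROI).
#' @param base_temp Mean skin temperature, deg C.
#' @param texture_amplitude Standard deviation of the shared smooth texture,
#'   deg C.
#' @param texture_scale Correlation length (Gaussian kernel sigma) of the
#'   texture and asymmetry fields, pixels.
#' @param asymmetry_sigma Standard deviation of the contralateral asymmetry
#'   field, deg C.
#' @param noise_sigma Standard deviation of per-pixel sensor noise, deg C.
#' @param seed Integer RNG seed; one seeded generator drives the whole case.
#' @param band Plausibility band of the resulting frames.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 350L, width = 250L, base_temp = 33.5,
                         texture_amplitude = 1.0, texture_scale = 40,
                         asymmetry_sigma = 0.3, noise_sigma = 0.1,
                         seed = 1L, band = DEFAULT_BAND) {
  if (height < 1L || width < 1L)
    ht_spec_error("phantom must be at least 1x1")
  sig <- c(texture_amplitude, asymmetry_sigma, noise_sigma)
  if (any(!is.finite(sig)) || any(sig < 0))
    ht_spec_error("texture_amplitude, asymmetry_sigma and noise_sigma must be >= 0")
  if (texture_scale <= 0) ht_spec_error("texture_scale must be positive")
  spread <- 3 * sum(sig)
  if (base_temp - spread < band[1] || base_temp + spread > band[2])
    ht_spec_error("base_temp %g +/- 3*(texture+asymmetry+noise) = %g leaves the plausibility band [%g, %g]",
                  base_temp, spread, band[1], band[2])
  structure(list(height = as.integer(height), width = as.integer(width),
                 base_temp = base_temp, texture_amplitude = texture_amplitude,
                 texture_scale = texture_scale,
                 asymmetry_sigma = asymmetry_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed), band = band),
            class = "phantom_spec")
}

#' Specification of an injected inflammation focus
#'
#' An elliptical temperature increment emulating the elongated, island-like
#' hotspot of lateral facial cellulitis.  With `profile = "plateau"` the
#' increment equals `amplitude` everywhere inside the ellipse; with
#' `"gaussian"` it is `amplitude * exp(-r^2 / 2)` where `r` is the
#' normalized elliptical radius (`r = 1` on the ellipse boundary).
#'
#' @param center 0-based `(row, col)` of the focus centre.
#' @param semi_axes `(a, b)` semi-axes in pixels (`a` along `orientation`).
#' @param orientation Major-axis angle in radians (0 = along image rows).
#' @param amplitude Peak temperature increment, deg C, > 0.
#' @param profile `"plateau"` (default) or `"gaussian"`.
#' @return An object of class `hotspot_spec`.
#' @export
hotspot_spec <- function(center = c(175, 125), semi_axes = c(60, 25),
                         orientation = 0.5, amplitude = 3.5,
                         profile = c("plateau", "gaussian")) {
  profile <- match.arg(profile)
  if (!is.numeric(amplitude) || amplitude <= 0)
    ht_spec_error("hotspot amplitude must be positive")
  if (length(center) != 2L || length(semi_axes) != 2L || any(semi_axes <= 0))
    ht_spec_error("center and semi_axes must be length-2, semi_axes positive")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 orientation = as.numeric(orientation),
                 amplitude = as.numeric(amplitude), profile = profile),
            class = "hotspot_spec")
}

# Normalized elliptical radius of every pixel of an height x width grid.
elliptical_radius <- function(height, width, hs) {
  dr <- outer(seq_len(height) - 1 - hs$center[1L], rep(1, width))
  dc <- outer(rep(1, height), seq_len(width) - 1 - hs$center[2L])
  u <- dr * cos(hs$orientation) + dc * sin(hs$orientation)
  w <- -dr * sin(hs$orientation) + dc * cos(hs$orientation)
  sqrt((u / hs$semi_axes[1L])^2 + (w / hs$semi_axes[2L])^2)
}

#' Generate a symmetric healthy hemiface pair
#'
#' Builds the left hemiface as `base + texture + noise` and the right as the
#' mirror of the shared structure plus an independent asymmetry field and
#' noise.  With `asymmetry_sigma = noise_sigma = 0` the differential map of
#' the pair is exactly zero; generation is bit-reproducible for a fixed
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `left` and `right` [thermal_frame()]s.
#' @export
generate_baseline <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    shared <- spec$base_temp +
      if (spec$texture_amplitude > 0)
        spec$texture_amplitude * smooth_field(h, w, spec$texture_scale)
      else matrix(0, h, w)
    asym <- if (spec$asymmetry_sigma > 0)
      spec$asymmetry_sigma * smooth_field(h, w, spec$texture_scale)
    else matrix(0, h, w)
    noise_l <- if (spec$noise_sigma > 0)
      matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
    else matrix(0, h, w)
    noise_r <- if (spec$noise_sigma > 0)
      matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
    else matrix(0, h, w)
    left <- shared + noise_l
    right <- shared[, rev(seq_len(w)), drop = FALSE] + asym + noise_r
    list(left = thermal_frame(left, band = spec$band, subject_id = "phantom"),
         right = thermal_frame(right, band = spec$band, subject_id = "phantom"))
  })
}

#' Inject an inflammation focus into a frame
#'
#' Adds the hotspot's temperature increment to the frame and returns the
#' ground-truth mask: the pixels whose *injected increment* reaches
#' `threshold_for_truth` (the severity cut-off the analysis will use), or —
#' with `truth_rule = "half_max"` — the pixels whose increment reaches half
#' the amplitude.
#'
#' @param frame A [thermal_frame()].
#' @param hs A [hotspot_spec()] whose `r = 1` ellipse lies inside the frame.
#' @param threshold_for_truth Truth cut-off, deg C.
#' @param truth_rule `"threshold"` (default) or `"half_max"`.
#' @return List with `frame` (incremented [thermal_frame()]), `truth`
#'   (logical mask) and `increment` (numeric matrix).
#' @export
inject_hotspot <- function(frame, hs, threshold_for_truth,
                           truth_rule = c("threshold", "half_max")) {
  truth_rule <- match.arg(truth_rule)
  stopifnot(is_thermal_frame(frame), inherits(hs, "hotspot_spec"))
  ext_r <- sqrt((hs$semi_axes[1L] * cos(hs$orientation))^2 +
                  (hs$semi_axes[2L] * sin(hs$orientation))^2)
  ext_c <- sqrt((hs$semi_axes[1L] * sin(hs$orientation))^2 +
                  (hs$semi_axes[2L] * cos(hs$orientation))^2)
  if (hs$center[1L] - ext_r < 0 || hs$center[1L] + ext_r > frame$height - 1 ||
      hs$center[2L] - ext_c < 0 || hs$center[2L] + ext_c > frame$width - 1)
    ht_bounds_error("hotspot ellipse (extent %.1f x %.1f px about (%.0f, %.0f)) overhangs the %dx%d frame",
                    ext_r, ext_c, hs$center[1L], hs$center[2L],
                    frame$height, frame$width)
  r <- elliptical_radius(frame$height, frame$width, hs)
  inc <- switch(hs$profile,
                plateau = hs$amplitude * (r <= 1),
                gaussian = hs$amplitude * exp(-r^2 / 2))
  cut <- switch(truth_rule, threshold = threshold_for_truth,
                half_max = hs$amplitude / 2)
  out <- thermal_frame(frame$temps + inc, emissivity = frame$emissivity,
                       capture_time = frame$capture_time,
                       subject_id = frame$subject_id, band = frame$band)
  list(frame = out, truth = inc >= cut, increment = inc)
}

#' Generate a complete phantom case
#'
#' End-to-end synthetic fixture emulating a lateral facial-cellulitis
#' acquisition: a symmetric healthy hemiface pair, an inflammation focus
#' injected into the designated diseased side, the severity grade's cut-off
#' and the ground-truth mask for that cut-off.  Deterministic under a fixed
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @param hs A [hotspot_spec()] (defaults to the elongated 3.5 degC focus).
#' @param grade Severity grade, see [threshold_for_grade()].
#' @param diseased_side Which hemiface receives the focus.
#' @param truth_rule Passed to [inject_hotspot()].
#' @return An object of class `phantom_case`: a list with `healthy_frame`,
#'   `diseased_frame`, `truth_mask`, `increment`, `spec`, `hotspot`,
#'   `grade`, `threshold_used` and `diseased_side`.
#' @export
#' @examples
#' case <- generate_case(phantom_spec(height = 80, width = 60, seed = 7),
#'                       hotspot_spec(center = c(40, 30), semi_axes = c(15, 7)))
#' case$threshold_used  # 3 (severe)
generate_case <- function(spec, hs = hotspot_spec(), grade = "severe",
                          diseased_side = c("left", "right"),
                          truth_rule = "threshold") {
  diseased_side <- match.arg(diseased_side)
  policy <- threshold_for_grade(grade)
  pair <- generate_baseline(spec)
  diseased0 <- if (diseased_side == "left") pair$left else pair$right
  healthy <- if (diseased_side == "left") pair$right else pair$left
  inj <- inject_hotspot(diseased0, hs, policy$delta_t, truth_rule)
  structure(list(healthy_frame = healthy,
                 diseased_frame = inj$frame,
                 truth_mask = inj$truth,
                 increment = inj$increment,
                 spec = spec, hotspot = hs, grade = policy$grade,
                 threshold_used = policy$delta_t,
                 diseased_side = diseased_side),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %dx%d px, grade %s (cut-off %g degC), %s side diseased\n",
              x$spec$height, x$spec$width, x$grade, x$threshold_used,
              x$diseased_side))
  cat(sprintf("  hotspot: %s, amplitude %g degC, truth mask %d px\n",
              x$hotspot$profile, x$hotspot$amplitude, sum(x$truth_mask)))
  invisible(x)
}

#' Write a phantom case to disk
#'
#' Emits `healthy.csv` / `diseased.csv` temperature grids (with metadata
#' sidecars), `truth_mask.png` (8-bit, 0/255) and `phantom.yaml` recording
#' every generation parameter including the seed.
#'
#' @param case A [generate_case()] result.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_phantom_case <- function(case, outdir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(healthy = file.path(outdir, "healthy.csv"),
                diseased = file.path(outdir, "diseased.csv"),
                truth_mask = file.path(outdir, "truth_mask.png"),
                metadata = file.path(outdir, "phantom.yaml"))
  write_temperature_grid(case$healthy_frame, paths$healthy)
  write_temperature_grid(case$diseased_frame, paths$diseased)
  png::writePNG(case$truth_mask * 1.0, paths$truth_mask)
  meta <- c(unclass(case$spec),
            list(hotspot = unclass(case$hotspot), grade = case$grade,
                 threshold_used = case$threshold_used,
                 diseased_side = case$diseased_side))
  yaml::write_yaml(meta, paths$metadata)
  invisible(paths)
}
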