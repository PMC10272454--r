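# Parametric synthesis of isotropic rough surfaces.
#
# Surfaces are drawn from a prescribed isotropic height power spectral
# density with a flat plateau between a lower cutoff q0 and a roll-off
# wavenumber qr, a self-affine decay (slope -2(1+H), H the Hurst exponent)
# between qr and the upper cutoff q1, and zero power elsewhere. Synthesis is
# spectral: independent complex Gaussian Fourier coefficients scaled by the
# square root of the PSD, inverse transformed to a real field.
#
# Internally PSD arithmetic is in SI units (wavenumber rad/m, PSD m^4);
# heights and grid geometry are carried in millimetres.

#' Spectral parameters of the surface-height PSD
#'
#' @param C plateau amplitude of the PSD (m^4). If `NULL`, `C` is chosen so
#'   that the analytic RMS roughness of the spectrum equals `rms_target`.
#' @param q0 lower wavenumber cutoff (rad/m).
#' @param q1 upper wavenumber cutoff (rad/m).
#' @param qr roll-off wavenumber (rad/m) above which the PSD decays as
#'   `(q/qr)^(-2*(1+H))`.
#' @param H Hurst roughness exponent (dimensionless, 0 < H).
#' @param rms_target target RMS surface roughness after calibration (mm).
#' @return an object of class `spectral_params`.
#' @examples
#' p <- spectral_params()
#' psd_value(p$qr, p) == p$C
#' @export
spectral_params <- function(C = NULL, q0 = 1200, q1 = 3600, qr = 2400,
                            H = 0.8, rms_target = 0.15) {
  if (!(q0 > 0 && q0 <= qr && qr <= q1))
    stop_tex("require 0 < q0 <= qr <= q1", "parameter_error")
  if (!(H > 0)) stop_tex("Hurst exponent H must be positive", "parameter_error")
  if (!(rms_target > 0)) stop_tex("rms_target must be positive", "parameter_error")
  p <- structure(list(C = 1, q0 = q0, q1 = q1, qr = qr, H = H,
                      rms_target = rms_target),
                 class = "spectral_params")
  if (is.null(C)) {
    # variance scales linearly in C: solve for the target roughness
    C <- (rms_target / psd_rms(p))^2
  }
  if (!(C > 0)) stop_tex("C must be positive", "parameter_error")
  p$C <- C
  p
}

#' Height power spectral density at wavenumber magnitude q
#'
#' Piecewise isotropic PSD: `C` on the plateau `[q0, qr]`,
#' `C * (q/qr)^(-2*(1+H))` on `(qr, q1]`, zero otherwise. Continuous at
#' `q = qr` by construction.
#'
#' @param q wavenumber magnitude(s), rad/m; vectorised.
#' @param params a [spectral_params()] object.
#' @return PSD values (m^4), same length as `q`.
#' @export
psd_value <- function(q, params) {
  if (!inherits(params, "spectral_params"))
    stop_tex("params must be a spectral_params object", "parameter_error")
  if (any(q < 0)) stop_tex("wavenumber magnitude must be >= 0", "parameter_error")
  out <- numeric(length(q))
  plateau <- q >= params$q0 & q <= params$qr
  roll <- q > params$qr & q <= params$q1
  out[plateau] <- params$C
  out[roll] <- params$C * (q[roll] / params$qr)^(-2 * (1 + params$H))
  out
}

#' Analytic RMS roughness implied by the PSD
#'
#' Isotropic Parseval relation: `var = (1/2pi) * integral phi(q) q dq`,
#' evaluated in closed form over the plateau and roll-off bands.
#'
#' @param params a [spectral_params()] object.
#' @return RMS height in mm.
#' @export
psd_rms <- function(params) {
  C <- params$C; q0 <- params$q0; q1 <- params$q1; qr <- params$qr
  H <- params$H
  plateau <- C * (qr^2 - q0^2) / 2
  roll <- C * qr^2 / (2 * H) * (1 - (q1 / qr)^(-2 * H))
  sqrt((plateau + roll) / (2 * pi)) * 1000
}

#' Regular grid of surface heights
#'
#' @param heights numeric matrix of heights (mm); rows index the x axis
#'   (along the tile), columns the y axis.
#' @param spacing grid pitch (mm), identical in both axes.
#' @param origin physical coordinate (mm) of the `heights[1, 1]` corner.
#' @return an object of class `height_field`.
#' @export
height_field <- function(heights, spacing, origin = c(0, 0)) {
  stopifnot(is.matrix(heights), spacing > 0, length(origin) == 2)
  structure(list(heights = heights, spacing = spacing, origin = origin),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  ex <- dim(x$heights) * x$spacing
  cat(sprintf("height_field: %d x %d grid, %.3g x %.3g mm, pitch %.3g mm, RMS %.4g mm\n",
              nrow(x$heights), ncol(x$heights), ex[1], ex[2], x$spacing,
              field_rms(x)))
  invisible(x)
}

#' Physical x/y coordinates of a height field's grid lines
#' @param field a [height_field()].
#' @return numeric vector of coordinates (mm).
#' @export
field_x <- function(field) field$origin[1] + (seq_len(nrow(field$heights)) - 1L) * field$spacing

#' @rdname field_x
#' @export
field_y <- function(field) field$origin[2] + (seq_len(ncol(field$heights)) - 1L) * field$spacing

#' RMS height of a field
#'
#' Root mean square about zero. Synthesized fields are exactly zero-mean
#' (the PSD vanishes at q = 0), so this coincides with the RMS roughness.
#' @param field a [height_field()].
#' @return RMS height (mm).
#' @export
field_rms <- function(field) sqrt(mean(field$heights^2))

#' Synthesize a random rough surface with the prescribed PSD
#'
#' Spectral (Fourier) synthesis: a white Gaussian field is transformed,
#' its coefficients scaled by `sqrt(phi(|q|))` on the discrete wavenumber
#' grid, and transformed back; taking the white field real makes the result
#' exactly real and Hermitian-consistent. The field is exactly zero-mean.
#'
#' @param params a [spectral_params()] object.
#' @param extent physical size `c(Lx, Ly)` in mm.
#' @param spacing grid pitch in mm. Must resolve the shortest retained
#'   wavelength `2*pi/q1` with at least 4 samples.
#' @param seed integer seed; identical inputs give bitwise-identical fields.
#' @param origin grid origin (mm); defaults to `-extent/2` so that the field
#'   is centred on the tile-centre coordinate frame.
#' @return a [height_field()] (heights in mm).
#' @export
synthesize_field <- function(params, extent = c(100, 50), spacing = 0.1,
                             seed = 1L, origin = -extent / 2) {
  lambda_min_mm <- 2 * pi / params$q1 * 1000
  if (spacing > lambda_min_mm / 4)
    stop_tex(sprintf(
      "spacing %.3g mm too coarse: need <= %.3g mm (4 samples per shortest wavelength)",
      spacing, lambda_min_mm / 4), "resolution_error")
  nx <- max(2L, round(extent[1] / spacing))
  ny <- max(2L, round(extent[2] / spacing))
  dx <- spacing / 1000  # m
  # signed discrete wavenumbers, rad/m
  qx <- 2 * pi * fft_freq(nx) / (nx * dx)
  qy <- 2 * pi * fft_freq(ny) / (ny * dx)
  qmag <- sqrt(outer(qx^2, qy^2, `+`))
  n_tot <- nx * ny
  dq2 <- (2 * pi)^2 / (n_tot * dx * dx)  # dqx * dqy
  amp <- sqrt(n_tot * psd_value(qmag, params) * dq2) / (2 * pi)
  w <- with_seed(seed, matrix(stats::rnorm(n_tot), nx, ny))
  h_m <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n_tot
  height_field(h_m * 1000, spacing, origin)
}

# Signed FFT bin indices 0, 1, ..., floor((n-1)/2), -floor(n/2), ..., -1
fft_freq <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Rescale a field to a target RMS roughness
#'
#' Multiplies heights by a single scalar so the RMS equals `rms_target`
#' exactly (to floating tolerance). The zero mean of a synthesized field is
#' preserved.
#'
#' @param field a [height_field()].
#' @param rms_target target RMS height (mm).
#' @return the calibrated [height_field()].
#' @export
calibrate_amplitude <- function(field, rms_target = 0.15) {
  r <- field_rms(field)
  if (r == 0) stop_tex("field has zero variance; cannot calibrate", "degenerate_input_error")
  field$heights <- field$heights * (rms_target / r)
  field
}

#' Stimulus tile geometry
#'
#' The printed tile is 100 x 50 mm: 40 mm smooth, a 10 mm central transition
#' where the textures merge, 40 mm rough, and a 10 mm margin (5 mm per end,
#' continuing the adjacent texture) making up the full 100 mm. The stated
#' segments alone sum to 90 mm, so the margin is a modelling choice.
#'
#' @param length_smooth,length_transition,length_rough,width segment sizes (mm).
#' @param margin total extra length (mm), split half per end.
#' @return an object of class `tile_spec`.
#' @export
tile_spec <- function(length_smooth = 40, length_transition = 10,
                      length_rough = 40, width = 50, margin = 10) {
  stopifnot(length_smooth > 0, length_transition > 0, length_rough > 0,
            width > 0, margin >= 0)
  structure(list(length_smooth = length_smooth,
                 length_transition = length_transition,
                 length_rough = length_rough,
                 width = width, margin = margin,
                 total_length = length_smooth + length_transition +
                   length_rough + margin),
            class = "tile_spec")
}

#' Compose the smooth/transition/rough stimulus tile
#'
#' In the tile-centre frame (x = 0 at the middle of the transition region,
#' positive x toward the rough end) the tile height is 0 on the smooth side,
#' equals the rough field on the rough side, and blends by a linear
#' cross-fade weight `w(x)` rising 0 to 1 across the transition, so the
#' height profile has no step discontinuity.
#'
#' @param rough a [height_field()] covering the full tile extent in the
#'   tile-centre frame (e.g. from [synthesize_field()] with defaults).
#' @param tile a [tile_spec()].
#' @return the composed [height_field()].
#' @export
compose_tile <- function(rough, tile = tile_spec()) {
  x <- field_x(rough)
  y <- field_y(rough)
  ht <- tile$length_transition / 2
  need_lo <- -ht                      # weight is 0 below, so smaller x is free
  need_hi <- tile$length_rough + ht + tile$margin / 2
  if (min(x) > need_lo || max(x) < need_hi - rough$spacing)
    stop_tex("rough field does not cover the transition + rough extent of the tile",
             "geometry_error")
  if (diff(range(y)) + rough$spacing < tile$width - rough$spacing)
    stop_tex("rough field narrower than the tile", "geometry_error")
  w <- pmin(1, pmax(0, (x + ht) / tile$length_transition))
  out <- rough
  out$heights <- rough$heights * w
  out
}

#' RMS roughness profile in strips along the tile axis
#'
#' Cuts the field into strips of `strip_width` mm along x and reports the
#' RMS height of each; used to verify the monotone smooth-to-rough blend.
#'
#' @param field a [height_field()].
#' @param strip_width strip size along x (mm).
#' @return data.frame with columns `x_center` (mm) and `rms` (mm).
#' @export
strip_rms <- function(field, strip_width = 1) {
  x <- field_x(field)
  edges <- seq(min(x), max(x) + strip_width, by = strip_width)
  bin <- findInterval(x, edges, rightmost.closed = FALSE)
  ms <- tapply(rowMeans(field$heights^2), bin, mean)
  data.frame(
    x_center = edges[as.integer(names(ms))] + strip_width / 2,
    rms = sqrt(as.vector(ms))
  )
}

#' Radially averaged empirical PSD of a height field
#'
#' Estimates the 2D periodogram `|FFT(h)|^2 dx dy / N` (SI units, m^4) and
#' averages it in bins of wavenumber magnitude.
#'
#' @param field a [height_field()].
#' @param breaks wavenumber bin edges (rad/m); default 40 equal bins up to
#'   the grid Nyquist.
#' @return data.frame with `q` (bin centre, rad/m), `psd` (m^4), `n` (cells).
#' @export
radial_psd <- function(field, breaks = NULL) {
  per <- periodogram_2d(field)
  if (is.null(breaks)) breaks <- seq(0, max(per$qmag), length.out = 41L)
  bin <- cut(per$qmag, breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(bin)
  psd <- tapply(per$power[ok], bin[ok], mean)
  n <- tapply(per$power[ok], bin[ok], length)
  ctr <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(q = ctr[as.integer(names(psd))], psd = as.vector(psd),
             n = as.vector(n))
}

# Full 2D periodogram: list(qmag, power) as matrices/SI units. Internal.
periodogram_2d <- function(field) {
  h <- field$heights / 1000      # m
  nx <- nrow(h); ny <- ncol(h)
  dx <- field$spacing / 1000
  H <- stats::fft(h)
  power <- Mod(H)^2 * dx * dx / (nx * ny)
  qx <- 2 * pi * fft_freq(nx) / (nx * dx)
  qy <- 2 * pi * fft_freq(ny) / (ny * dx)
  list(qmag = sqrt(outer(qx^2, qy^2, `+`)),
       angle = atan2(rep(qy, each = nx), rep(qx, times = ny)),
       power = power)
}
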