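# Morlet continuous wavelet transform and wavelet coherence.
#
# The coherence of the binned series read clockwise against the same
# series read counterclockwise is the symmetry statistic: a symmetric
# rate wave about the origin makes the two directions coherent at the
# wave's scale.  The CWT here uses zero-padded (non-circular) boundary
# handling and reports a cone of influence (coi) inside which edge
# artifacts are negligible; the e-folding criterion is the standard one
# for the Morlet wavelet (Torrence & Compo formulation).

#' Dyadic scale grid
#'
#' @param s_min,s_max smallest and largest scale (in bins; default 2-32).
#' @param voices voices per octave (default 12).
#' @return ascending numeric vector of scales `s_min * 2^(k/voices)`.
#' @export
scale_grid <- function(s_min = 2, s_max = 32, voices = 12L) {
  if (s_min <= 0 || s_max <= s_min) stop("need 0 < s_min < s_max",
                                         call. = FALSE)
  k <- seq.int(0L, ceiling(voices * log2(s_max / s_min)))
  s <- s_min * 2^(k / voices)
  s[s <= s_max * (1 + 1e-12)]
}

#' Morlet continuous wavelet transform
#'
#' Time-domain CWT with the analytic Morlet wavelet
#' `pi^(-1/4) exp(i w0 eta - eta^2/2)`, L2 normalization `s^(-1/2)`, and
#' zero padding beyond the series ends.  The series is demeaned before
#' analysis.  For a cosine of period `p`, `|W|` peaks at the scale whose
#' equivalent Fourier period is `p` (see [to_bins_per_cycle()]).
#'
#' @param x numeric series.
#' @param scales positive ascending scales in sample (bin) units.
#' @param omega0 Morlet center frequency (default 6).
#' @return object of class `cwt`: list with complex matrix `W` (scales in
#'   rows, positions in columns), `scales`, `omega0`, `n`.
#' @export
morlet_cwt <- function(x, scales = scale_grid(), omega0 = 6) {
  if (length(scales) == 0) stop("empty scale grid", call. = FALSE)
  if (any(diff(scales) <= 0) || any(scales <= 0))
    stop("scales must be positive and ascending", call. = FALSE)
  n <- length(x)
  x <- x - mean(x)
  W <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  norm0 <- pi^(-1 / 4)
  for (si in seq_along(scales)) {
    s <- scales[si]
    m_max <- min(n - 1L, ceiling(6 * s))   # Gaussian support beyond 6 sd ~ 0
    m <- seq.int(-m_max, m_max)
    eta <- m / s
    # conj(psi(eta)) so a positive-frequency component exp(i w t) maps to
    # W ~ exp(i w t): a delay of y relative to x yields a positive phase
    kern <- (norm0 / sqrt(s)) * exp(-0.5 * eta^2) * exp(-1i * omega0 * eta)
    for (t in seq_len(n)) {
      u <- t + m
      ok <- u >= 1L & u <= n
      W[si, t] <- sum(x[u[ok]] * kern[ok])
    }
  }
  structure(list(W = W, scales = scales, omega0 = omega0, n = n),
            class = "cwt")
}

#' Equivalent Fourier period of a Morlet scale
#'
#' @param scale scale(s) in bin units (> 0).
#' @param omega0 Morlet center frequency (default 6).
#' @return period in bins per cycle:
#'   `scale * 4 * pi / (omega0 + sqrt(2 + omega0^2))` (about
#'   `1.033 * scale` at `omega0 = 6`).  Multiply by the bin width to get
#'   kb per cycle.
#' @export
to_bins_per_cycle <- function(scale, omega0 = 6) {
  if (any(scale <= 0)) stop("scale must be > 0", call. = FALSE)
  scale * 4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Cone of influence
#'
#' Edge-artifact boundary under the e-folding criterion: position `t`
#' (1-based) is trusted at scale `s` iff its distance to the nearer
#' series end, `min(t - 1, n - t)`, is at least `sqrt(2) * s`.
#'
#' @param n_points series length (>= 2).
#' @return numeric vector of length `n_points`: the maximum trusted scale
#'   at each position (`min(t - 1, n - t) / sqrt(2)`); 0 at the ends,
#'   maximal at the center.
#' @export
coi <- function(n_points) {
  if (n_points < 2) stop("need at least 2 points", call. = FALSE)
  t <- seq_len(n_points)
  pmin(t - 1, n_points - t) / sqrt(2)
}

# Gaussian smoothing along positions, sd = stime * s, kernel renormalized
# over the in-range support (zero padding would bias magnitudes near the
# edges; renormalization keeps a constant field constant)
.smooth_time <- function(row, s, stime) {
  n <- length(row)
  sd <- max(stime * s, 1e-6)
  m_max <- min(n - 1L, ceiling(3 * sd))
  m <- seq.int(-m_max, m_max)
  kern <- exp(-0.5 * (m / sd)^2)
  out <- row
  for (t in seq_len(n)) {
    u <- t + m
    ok <- u >= 1L & u <= n
    out[t] <- sum(row[u[ok]] * kern[ok]) / sum(kern[ok])
  }
  out
}

# boxcar over scales within +/- half_dec decades (log10)
.smooth_scale <- function(M, scales, half_dec) {
  ls <- log10(scales)
  out <- M
  for (i in seq_along(scales)) {
    j <- which(abs(ls - ls[i]) <= half_dec)
    out[i, ] <- colMeans(M[j, , drop = FALSE])
  }
  out
}

#' Magnitude-squared wavelet coherence
#'
#' Localized, scale-resolved squared correlation between two series,
#' computed from smoothed Morlet cross-spectra:
#' `C = |S(Wx conj(Wy))|^2 / (S(|Wx|^2) S(|Wy|^2))`, with `S` a Gaussian
#' smoother along positions (sd proportional to scale) followed by a
#' boxcar over scale.  Values lie in `[0, 1]`.  The phase of the smoothed
#' cross-spectrum gives the local phase lag: 0 = in phase, `pi` = 180
#' degrees out of phase, and a positive phase means `y` lags `x`.
#'
#' @param x,y numeric series of equal length (>= 16 points), non-constant.
#' @param scales scale grid (default [scale_grid()], 2-32 bins, 12
#'   voices/octave).
#' @param omega0 Morlet center frequency (default 6).
#' @param smooth_time_sd Gaussian position-smoothing sd as a multiple of
#'   scale (default 0.6).
#' @param smooth_scale_dec boxcar width over scale in decades (default
#'   0.6, i.e. +/- 0.3).
#' @return object of class `coherence_map`: list with `coherence` and
#'   `phase` matrices (scales x positions), `scales`, `periods` (bins per
#'   cycle), `coi` (max trusted scale per position), `in_coi` logical
#'   matrix, `omega0`, `n`.
#' @export
wavelet_coherence <- function(x, y, scales = scale_grid(), omega0 = 6,
                              smooth_time_sd = 0.6,
                              smooth_scale_dec = 0.6) {
  if (length(x) != length(y))
    stop("series lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 16) stop("need at least 16 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input", call. = FALSE)
  Wx <- morlet_cwt(x, scales, omega0)$W
  Wy <- morlet_cwt(y, scales, omega0)$W
  cross <- Wx * Conj(Wy)
  Sxx <- Mod(Wx)^2
  Syy <- Mod(Wy)^2
  for (si in seq_along(scales)) {
    s <- scales[si]
    cross[si, ] <- complex(real = .smooth_time(Re(cross[si, ]), s, smooth_time_sd),
                           imaginary = .smooth_time(Im(cross[si, ]), s, smooth_time_sd))
    Sxx[si, ] <- .smooth_time(Sxx[si, ], s, smooth_time_sd)
    Syy[si, ] <- .smooth_time(Syy[si, ], s, smooth_time_sd)
  }
  half <- smooth_scale_dec / 2
  crossS <- .smooth_scale(Re(cross), scales, half) +
    1i * .smooth_scale(Im(cross), scales, half)
  SxxS <- .smooth_scale(Sxx, scales, half)
  SyyS <- .smooth_scale(Syy, scales, half)
  prod <- SxxS * SyyS
  # floor relative to the peak smoothed power: keeps coherence exactly 1
  # for identical inputs while guarding scales with negligible energy
  denom <- pmax(prod, 1e-12 * max(prod))
  coh <- pmin(Mod(crossS)^2 / denom, 1)
  phase <- Arg(crossS)
  coi_s <- coi(n)
  in_coi <- outer(scales, coi_s, FUN = `<=`)
  structure(list(coherence = coh, phase = phase, scales = scales,
                 periods = to_bins_per_cycle(scales, omega0),
                 coi = coi_s, in_coi = in_coi, omega0 = omega0, n = n),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf("<coherence_map> %d positions x %d scales (periods %.1f-%.1f bins/cycle)\n",
              x$n, length(x$scales), min(x$periods), max(x$periods)))
  ic <- x$coherence[x$in_coi]
  if (length(ic))
    cat(sprintf("  in-coi coherence: median %.3f, max %.3f\n",
                stats::median(ic), max(ic)))
  invisible(x)
}

#' Mean in-coi coherence per period
#'
#' Averages the coherence over trusted positions at each scale; scales
#' with no trusted position get `NA`.  Used to locate the period band of
#' peak coherence.
#'
#' @param cm a [wavelet_coherence()] result.
#' @return `data.frame` with columns `scale`, `period` (bins/cycle),
#'   `mean_coherence`, `n_positions`.
#' @export
coherence_profile <- function(cm) {
  mc <- vapply(seq_along(cm$scales), function(i) {
    ok <- cm$in_coi[i, ]
    if (!any(ok)) NA_real_ else mean(cm$coherence[i, ok])
  }, numeric(1))
  np <- rowSums(cm$in_coi)
  data.frame(scale = cm$scales, period = cm$periods,
             mean_coherence = mc, n_positions = np)
}

#' Coherence heatmap
#'
#' Simple image of the coherence map with the cone of influence drawn as
#' a dashed line; periods (bins/cycle) on an inverted y axis.
#'
#' @param x a `coherence_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.coherence_map <- function(x, ...) {
  graphics::image(seq_len(x$n), log2(x$periods), t(x$coherence),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "bin", ylab = "log2 period (bins/cycle)",
                  zlim = c(0, 1), ...)
  coi_per <- to_bins_per_cycle(pmax(x$coi, min(x$scales) * 1e-3), x$omega0)
  graphics::lines(seq_len(x$n), log2(pmax(coi_per, min(x$periods))),
                  lty = 2, lwd = 2)
  invisible(x)
}
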