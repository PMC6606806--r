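# Daubechies discrete wavelet transforms with circular (periodized)
# boundary handling.  The chromosome is a circle, so periodization is the
# natural boundary rule: bin 46 is adjacent to bin 1.
#
# Two transforms are provided:
#   * dwt_periodic / idwt_periodic - the decimated orthonormal periodized
#     DWT (requires the length divisible by 2^level); energy-conserving
#     with perfect reconstruction.
#   * wave_smooth - the circular MODWT (maximal-overlap DWT)
#     multiresolution smooth, defined for any series length and level,
#     used for the smoothed rate curves drawn over the binned data.
#
# Scaling filter coefficients are the standard Daubechies extremal-phase
# values (sum = sqrt(2), unit energy), indexed by number of vanishing
# moments; "fourth-order Daubechies" = 4 vanishing moments = 8 taps.

.db_filters <- list(
  `1` = c(0.7071067811865476, 0.7071067811865476),
  `2` = c(0.4829629131445342, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604),
  `3` = c(0.3326705529500826, 0.8068915093110925, 0.4598775021184915,
          -0.1350110200102546, -0.0854412738820267, 0.0352262918857095),
  `4` = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.0279837694168599, -0.1870348117190931, 0.0308413818355608,
          0.0328830116668852, -0.0105974017850690),
  `5` = c(0.1601023979741929, 0.6038292697971896, 0.7243085284377729,
          0.1384281459013207, -0.2422948870663820, -0.0322448695846384,
          0.0775714938400457, -0.0062414902127983, -0.0125807519990820,
          0.0033357252854738),
  `6` = c(0.1115407433501095, 0.4946238903984531, 0.7511339080210954,
          0.3152503517091976, -0.2262646939654398, -0.1297668675672619,
          0.0975016055873230, 0.0275228655303057, -0.0315820393174860,
          0.0005538422011615, 0.0047772575109455, -0.0010773010853085))

#' Daubechies analysis filters
#'
#' @param order number of vanishing moments (1-6); order 4 is the 8-tap
#'   filter pair used by default throughout the package.
#' @return list with the scaling filter `h` and the wavelet (quadrature
#'   mirror) filter `g`, `g[l] = (-1)^(l-1) h[L+1-l]`.
#' @export
daubechies_filter <- function(order = 4L) {
  key <- as.character(as.integer(order))
  if (!key %in% names(.db_filters))
    stop("Daubechies order must be in 1..6", call. = FALSE)
  h <- .db_filters[[key]]
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, length = L)
}

# circular correlation of x with filter f, downsampled by 2:
# out[k] = sum_l f[l] * x[(2(k-1) + l - 1) mod n + 1]
.analysis_step <- function(x, f) {
  n <- length(x)
  ks <- seq.int(0L, n / 2L - 1L)
  out <- numeric(n / 2L)
  for (l in seq_along(f)) {
    out <- out + f[l] * x[((2L * ks + l - 1L) %% n) + 1L]
  }
  out
}

# transpose (synthesis): scatter a and d back through h and g
.synthesis_step <- function(a, d, h, g) {
  n <- 2L * length(a)
  x <- numeric(n)
  ks <- seq.int(0L, length(a) - 1L)
  for (l in seq_along(h)) {
    idx <- ((2L * ks + l - 1L) %% n) + 1L
    add <- h[l] * a + g[l] * d
    # accumulate with possible repeated indices when filter wraps
    x <- x + tabulate_add(idx, add, n)
  }
  x
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  for (i in seq_along(idx)) out[idx[i]] <- out[idx[i]] + val[i]
  out
}

#' Periodized Daubechies wavelet decomposition
#'
#' Orthonormal decimated DWT with circular boundary handling.  Energy is
#' conserved (`sum(x^2)` equals the summed squared coefficients) and
#' [idwt_periodic()] reconstructs the input exactly (to floating point).
#'
#' @param x numeric series; `length(x)` must be divisible by `2^level`.
#' @param level decomposition depth (>= 1).
#' @param order Daubechies order (vanishing moments), default 4.
#' @return object of class `dwt` with fields `approx` (level-`level`
#'   scaling coefficients), `details` (list of wavelet coefficients,
#'   level 1 first), `level`, `order`, `n`.
#' @export
dwt_periodic <- function(x, level = 1L, order = 4L) {
  flt <- daubechies_filter(order)
  n <- length(x)
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  if (n %% 2L^level != 0L || n / 2L^level < 1L)
    stop(sprintf("series length %d is not divisible by 2^%d", n, level),
         call. = FALSE)
  if (n < flt$length)
    stop("series shorter than the wavelet filter", call. = FALSE)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    details[[j]] <- .analysis_step(a, flt$g)
    a <- .analysis_step(a, flt$h)
  }
  structure(list(approx = a, details = details, level = level,
                 order = as.integer(order), n = n),
            class = "dwt")
}

#' Inverse periodized Daubechies wavelet transform
#'
#' @param w a `dwt` object from [dwt_periodic()].
#' @return the reconstructed series, length `w$n`.
#' @export
idwt_periodic <- function(w) {
  flt <- daubechies_filter(w$order)
  a <- w$approx
  for (j in rev(seq_len(w$level))) {
    a <- .synthesis_step(a, w$details[[j]], flt$h, flt$g)
  }
  a
}

# ---- MODWT (maximal-overlap, non-decimated) ------------------------------

# one circular MODWT analysis level: filter f upsampled by 2^(j-1)
.modwt_filter <- function(x, f, step) {
  n <- length(x)
  ts <- seq.int(0L, n - 1L)
  out <- numeric(n)
  for (l in seq_along(f)) {
    out <- out + f[l] * x[(((ts - (l - 1L) * step) %% n) + 1L)]
  }
  out
}

# transpose of .modwt_filter (synthesis direction)
.modwt_filter_t <- function(x, f, step) {
  n <- length(x)
  ts <- seq.int(0L, n - 1L)
  out <- numeric(n)
  for (l in seq_along(f)) {
    out <- out + f[l] * x[(((ts + (l - 1L) * step) %% n) + 1L)]
  }
  out
}

#' Circular MODWT decomposition
#'
#' Maximal-overlap (non-decimated) Daubechies transform with circular
#' boundary handling, defined for any series length and any level whose
#' equivalent filter is no longer than the series.  Energy is conserved:
#' `sum(x^2) = sum_j sum(W_j^2) + sum(V_J^2)`.
#'
#' @inheritParams dwt_periodic
#' @return list with `smooth` (V_J), `details` (list of W_j, level 1
#'   first), `level`, `order`.
#' @export
modwt_periodic <- function(x, level = 2L, order = 4L) {
  flt <- daubechies_filter(order)
  ht <- flt$h / sqrt(2)
  gt <- flt$g / sqrt(2)
  n <- length(x)
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1", call. = FALSE)
  if ((flt$length - 1L) * 2L^(level - 1L) + 1L > n)
    stop("level too deep for this series length", call. = FALSE)
  details <- vector("list", level)
  v <- x
  for (j in seq_len(level)) {
    step <- 2L^(j - 1L)
    details[[j]] <- .modwt_filter(v, gt, step)
    v <- .modwt_filter(v, ht, step)
  }
  list(smooth = v, details = details, level = level,
       order = as.integer(order))
}

#' Wavelet smoothing of a binned series
#'
#' The multiresolution smooth: the circular MODWT is taken to `level` and
#' inverted with all detail coefficients zeroed, leaving the low-frequency
#' component (periods longer than about `2^(level+1)` bins).  The series
#' mean is preserved exactly and the operation is linear and
#' shift-covariant on the circle.  This is the smooth curve drawn over
#' per-bin rate bars.
#'
#' @param x numeric series (any length >= the equivalent filter length).
#' @param level smoothing depth; the default 2 retains periods of roughly
#'   8 bins and longer, keeping the dominant chromosome-scale wave (~12
#'   bins per cycle) at 46 bins while stripping bin-to-bin noise.
#' @param order Daubechies order, default 4 (8-tap).
#' @return smoothed series, same length as `x`.
#' @export
wave_smooth <- function(x, level = 2L, order = 4L) {
  w <- modwt_periodic(x, level = level, order = order)
  flt <- daubechies_filter(order)
  ht <- flt$h / sqrt(2)
  v <- w$smooth
  for (j in rev(seq_len(w$level))) {
    v <- .modwt_filter_t(v, ht, 2L^(j - 1L))
  }
  v
}

#' Smooth a binned series object
#'
#' Convenience wrapper applying [wave_smooth()] to the rates (or counts)
#' of a [binned_series()].
#'
#' @param series a [binned_series()].
#' @param level,order see [wave_smooth()].
#' @param use `"rates"` or `"counts"`.
#' @return `data.frame` with columns `bin`, `value`, `smoothed`.
#' @export
smooth_series <- function(series, level = 2L, order = 4L,
                          use = c("rates", "counts")) {
  use <- match.arg(use)
  v <- series[[use]]
  data.frame(bin = seq_len(series$n_bins), value = v,
             smoothed = wave_smooth(v, level = level, order = order))
}
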