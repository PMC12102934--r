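#' Concatenate sleep-period activity
#'
#' Joins the count vectors of consecutive nights in chronological order with
#' no padding, producing the series analyzed by the wavelet stage.
#'
#' @param nights List of nights from [night_slices()] (or numeric vectors).
#' @return A numeric vector.
#' @export
concatenate_sleep <- function(nights) {
  stopifnot(length(nights) >= 1)
  unlist(purrr::map(nights, function(n) if (is.list(n)) n$counts else n),
         use.names = FALSE)
}

#' Default log-spaced wavelet scales
#'
#' @param window Scale window in epochs (default 1-200, i.e. 1 min to 200 min
#'   at 1-min epochs).
#' @param n_scales Number of scales (default 64).
#' @return Increasing numeric vector of scales.
#' @export
wavelet_scales <- function(window = c(1, 200), n_scales = 64L) {
  exp(seq(log(window[1]), log(window[2]), length.out = n_scales))
}

#' Morlet continuous wavelet transform
#'
#' Computes the CWT of a count series with the Morlet mother wavelet (a
#' complex sinusoid under a Gaussian envelope, center frequency `omega0 = 6`),
#' evaluated in the frequency domain. The returned `corr` matrix is the
#' coefficient magnitude normalized into `[0, 1]`, either by the global
#' maximum over the whole map (default) or per scale.
#'
#' @param x Numeric series (e.g. from [concatenate_sleep()]).
#' @param scales Positive scales in epochs; default [wavelet_scales()].
#' @param omega0 Morlet center frequency (default 6).
#' @param normalization `"global"` or `"per_scale"` rescaling of `|coeff|`.
#' @return A `wavelet_map` list with `scales`, complex matrix `coeffs`
#'   (scales x time) and real matrix `corr` in `[0, 1]`.
#' @export
morlet_cwt <- function(x, scales = wavelet_scales(), omega0 = 6,
                       normalization = c("global", "per_scale")) {
  normalization <- match.arg(normalization)
  if (any(scales <= 0)) abort("scales must be positive")
  n <- length(x)
  if (n <= max(scales)) abort("series must be longer than the largest scale")
  # zero-pad to the next power of two: fast FFT lengths and less wraparound
  n2 <- 2^ceiling(log2(n))
  xh <- fft(c(x, rep(0, n2 - n)))
  k <- 0:(n2 - 1)
  omega <- ifelse(k <= n2 / 2, 2 * pi * k / n2, -2 * pi * (n2 - k) / n2)
  coeffs <- matrix(0i, nrow = length(scales), ncol = n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi_hat <- pi^(-1 / 4) * sqrt(2 * pi * s) * exp(-(s * omega - omega0)^2 / 2)
    psi_hat[omega <= 0] <- 0
    full <- fft(xh * psi_hat, inverse = TRUE) / n2
    coeffs[i, ] <- full[seq_len(n)]
  }
  mag <- Mod(coeffs)
  corr <- if (normalization == "global") {
    m <- max(mag)
    if (m > 0) mag / m else mag
  } else {
    t(apply(mag, 1, function(r) if (max(r) > 0) r / max(r) else r))
  }
  structure(list(scales = scales, coeffs = coeffs, corr = corr),
            class = "wavelet_map")
}

#' Wavelet structure parameters and integrated structure factor
#'
#' The structure parameter at a scale is the fraction of time points whose
#' normalized coefficient magnitude reaches `corr_threshold` -- the occupancy
#' of prominent structure at that time resolution. `structure_pms` integrates
#' the per-scale parameter over the scale window by the trapezoid rule, and
#' `wavelet_fi` = 1 - mean per-scale parameter summarizes the lack of
#' structure as a wavelet fragmentation index.
#'
#' @param map A `wavelet_map` from [morlet_cwt()].
#' @param corr_threshold Occupancy threshold in `(0, 1)` (default 0.7).
#' @param scale_window Integration window in scale units (default the full
#'   1-200 epoch window).
#' @return A `structure_result` list with tibble `per_scale`
#'   (`scale`, `structure`) and scalars `structure_pms`, `wavelet_fi`.
#' @export
structure_params <- function(map, corr_threshold = 0.7, scale_window = c(1, 200)) {
  if (corr_threshold <= 0 || corr_threshold >= 1) {
    abort("corr_threshold must be in (0, 1)")
  }
  per_scale <- rowMeans(map$corr >= corr_threshold)
  inside <- map$scales >= scale_window[1] & map$scales <= scale_window[2]
  structure(list(
    per_scale = tibble::tibble(scale = map$scales, structure = per_scale),
    structure_pms = trapz(map$scales[inside], per_scale[inside]),
    wavelet_fi = 1 - mean(per_scale)
  ), class = "structure_result")
}

#' Wavelet features for one subject
#'
#' Runs the Morlet CWT on the subject's concatenated sleep activity and
#' summarizes it as `structure_pms` and `wavelet_fi`, optionally with the
#' per-scale structure parameters as extra columns `sp_scale_<i>`.
#'
#' @param nights List of nights from [night_slices()].
#' @inheritParams morlet_cwt
#' @inheritParams structure_params
#' @param include_per_scale Emit per-scale columns (default `FALSE`).
#' @return A one-row tibble.
#' @export
wavelet_features <- function(nights, scales = wavelet_scales(),
                             omega0 = 6, normalization = "global",
                             corr_threshold = 0.7, scale_window = c(1, 200),
                             include_per_scale = FALSE) {
  x <- concatenate_sleep(nights)
  if (length(x) <= max(scales)) {
    # too little sleep recorded to resolve the largest scales
    return(tibble::tibble(structure_pms = NA_real_, wavelet_fi = NA_real_))
  }
  map <- morlet_cwt(x, scales = scales, omega0 = omega0,
                    normalization = normalization)
  res <- structure_params(map, corr_threshold = corr_threshold,
                          scale_window = scale_window)
  out <- tibble::tibble(structure_pms = res$structure_pms,
                        wavelet_fi = res$wavelet_fi)
  if (include_per_scale) {
    ps <- setNames(as.list(res$per_scale$structure),
                   paste0("sp_scale_", seq_along(map$scales)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(ps))
  }
  out
}
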