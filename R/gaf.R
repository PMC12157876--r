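#' Rescale a window to [-1, 1]
#'
#' Min-max rescaling `t_i -> ((t_i - max) + (t_i - min)) / (max - min)`, the
#' first step of the Gramian angular field transform. The minimum maps to -1
#' and the maximum to +1 exactly, so any positive affine transform of the
#' input yields the same scaled series.
#'
#' A constant window has no scale and raises a condition of class
#' `"degenerate_window"`; callers are expected to drop such windows and log
#' them rather than impute.
#'
#' @param x Numeric vector with at least 2 samples.
#' @return Numeric vector in `[-1, 1]`.
#' @examples
#' gaf_rescale(c(1, 2, 3)) # -1 0 1
#' @export
gaf_rescale <- function(x) {
  if (length(x) < 2L) stop("window must have at least 2 samples")
  lo <- min(x)
  hi <- max(x)
  if (hi == lo)
    stop(structure(class = c("degenerate_window", "error", "condition"),
                   list(message = "constant window cannot be rescaled to [-1, 1]",
                        call = sys.call(-1))))
  ((x - hi) + (x - lo)) / (hi - lo)
}

#' Polar encoding of a scaled series
#'
#' Maps each scaled sample to an angle on the principal arccos branch,
#' `theta_i = arccos(t_i) in [0, pi]`, with radius `r_i = i/m`. The angular
#' map is injective on `[-1, 1]`, so the encoding is bijective and keeps the
#' temporal order (in the radius).
#'
#' @param x Numeric vector of scaled values in `[-1, 1]`. Values outside the
#'   range by more than `tol` raise an error; within `tol` they are clamped.
#' @param tol Clamping tolerance for floating-point spill.
#' @return List with `theta` (radians) and `radius`.
#' @export
polar_encode <- function(x, tol = 1e-12) {
  if (any(x < -1 - tol | x > 1 + tol))
    stop("scaled values outside [-1, 1]")
  x <- pmin(pmax(x, -1), 1)
  m <- length(x)
  structure(list(theta = acos(x), radius = seq_len(m) / m),
            class = "polar_encoding")
}

#' Gramian angular summation field of a polar encoding
#'
#' The GASF is the Gram-like matrix `G_ij = cos(theta_i + theta_j)`. It is
#' symmetric with entries in `[-1, 1]` and diagonal `2*t_i^2 - 1`, and
#' satisfies the identity `G_ij = t_i t_j - sqrt(1 - t_i^2) sqrt(1 - t_j^2)`
#' in terms of the scaled values.
#'
#' @param p A [polar_encode()] result (or a bare numeric vector of angles).
#' @return An `m x m` numeric matrix.
#' @examples
#' gasf(polar_encode(c(-1, 0, 1)))
#' @export
gasf <- function(p) {
  theta <- if (inherits(p, "polar_encoding")) p$theta else as.numeric(p)
  cos(outer(theta, theta, `+`))
}

#' Full 1-D series to GASF matrix
#'
#' Convenience composition `gasf(polar_encode(gaf_rescale(x)))`.
#'
#' @param x Numeric window (not constant).
#' @return An `m x m` GASF matrix.
#' @export
gaf_transform <- function(x) gasf(polar_encode(gaf_rescale(x)))

#' Piecewise aggregate approximation
#'
#' Reduces a length-`m` series to `k` bin means with floor binning: bin `i`
#' (0-based) averages the samples with indices in
#' `[floor(i*m/k), floor((i+1)*m/k))`. When `k` divides `m` the global mean
#' is preserved exactly. Upsampling (`k > m`) is refused.
#'
#' @param values Numeric vector of length `m`.
#' @param k Target length, `1 <= k <= m`.
#' @return Numeric vector of length `k`.
#' @examples
#' paa(c(1, 2, 3, 4), 2)    # 1.5 3.5
#' paa(c(1, 2, 3, 4, 5), 2) # 1.5 4.0
#' @export
paa <- function(values, k) {
  m <- length(values)
  if (k < 1L || k > m) stop("target length k must satisfy 1 <= k <= m")
  if (k == m) return(values)
  b <- floor((0:k) * m / k) # 0-based bin boundaries
  cs <- c(0, cumsum(values))
  (cs[b[-1] + 1L] - cs[b[-(k + 1L)] + 1L]) / diff(b)
}

#' Assemble a multi-channel GAF image from the two per-foot windows
#'
#' Each channel runs the pipeline PAA (down to `side` samples) -> rescale to
#' `[-1, 1]` -> polar encoding -> GASF. Channels are (left-foot GASF,
#' right-foot GASF, GASF of the elementwise mean of the two PAA-reduced foot
#' series); alternatively the mean-of-feet channel can be replicated three
#' times. Dimensionality reduction happens before the Gram construction, not
#' by image resampling after it.
#'
#' @param left,right Numeric windows covering the same time span.
#' @param side Image side in pixels (64 for the classifier, 128 for the
#'   regressor by convention; any value `<= length(left)` works).
#' @param channel_policy `"left-right-mean"` (default) or
#'   `"replicate-mean"`.
#' @return Object of class `"gaf_image"`: a `side x side x 3` array with
#'   attributes `side` and `channels` (semantics).
#' @export
window_to_image <- function(left, right, side = 64,
                            channel_policy = c("left-right-mean",
                                               "replicate-mean")) {
  channel_policy <- match.arg(channel_policy)
  if (length(left) != length(right))
    stop("left and right windows must cover the same time span")
  pl <- paa(left, side)
  pr <- paa(right, side)
  img <- array(NA_real_, c(side, side, 3L))
  if (channel_policy == "left-right-mean") {
    img[, , 1] <- gaf_transform(pl)
    img[, , 2] <- gaf_transform(pr)
    img[, , 3] <- gaf_transform((pl + pr) / 2)
    sem <- c("left GASF", "right GASF", "mean-of-feet GASF")
  } else {
    g <- gaf_transform((pl + pr) / 2)
    img[, , 1] <- g
    img[, , 2] <- g
    img[, , 3] <- g
    sem <- rep("mean-of-feet GASF", 3)
  }
  structure(img, side = side, channels = sem, class = "gaf_image")
}

#' @export
print.gaf_image <- function(x, ...) {
  cat(sprintf("<gaf_image> %d x %d x 3 [%s]\n", attr(x, "side"),
              attr(x, "side"), paste(attr(x, "channels"), collapse = ", ")))
  invisible(x)
}

#' Plot a GAF image channel
#' @param x A `gaf_image`.
#' @param channel Channel index (1-3).
#' @param ... Passed to [graphics::image()].
#' @export
plot.gaf_image <- function(x, channel = 1, ...) {
  side <- attr(x, "side")
  graphics::image(seq_len(side), seq_len(side),
                  t(unclass(x)[side:1, , channel]),
                  zlim = c(-1, 1), xlab = "time bin", ylab = "time bin",
                  main = attr(x, "channels")[channel],
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
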