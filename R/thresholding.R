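#' Dynamic elimination-threshold model
#'
#' The pixel-elimination threshold applied before clustering is not a
#' fixed constant: over a 60-day fluorescence time series the canopy
#' brightens while the pot stays in a narrow low-intensity band, so the
#' cut that removes pot and residual background drifts.  The drift is
#' modelled by a cubic in the image's position `x` in capture order,
#'
#'   T(x) = p1 x^3 + p2 x^2 + p3 x + p4,
#'
#' fitted upstream to hand-tuned thresholds; the fitted coefficients are
#' the defaults here.  Because the usable elimination band is 11--17
#' intensity units, the evaluated polynomial is clamped into
#' `[clamp_lo, clamp_hi]` as a guard against extrapolation.
#'
#' @param p1,p2,p3,p4 Cubic coefficients (highest degree first).
#' @param clamp_lo,clamp_hi Intensity bounds the threshold is clipped to.
#' @return An object of class `"threshold_model"`.
#' @export
#' @examples
#' m <- threshold_model()
#' dynamic_threshold(0, m)      # clamped
#' attr(dynamic_threshold(0, m), "raw")  # 11.95
threshold_model <- function(p1 = 2.273e-08, p2 = -4.118e-05,
                            p3 = 0.01699, p4 = 11.95,
                            clamp_lo = 11, clamp_hi = 17) {
  coefs <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  if (!all(is.finite(coefs))) stop("threshold coefficients must be finite")
  if (clamp_lo > clamp_hi) stop("clamp_lo must not exceed clamp_hi")
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 clamp_lo = clamp_lo, clamp_hi = clamp_hi),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Dynamic threshold model: T(x) = p1*x^3 + p2*x^2 + p3*x + p4\n")
  cat(sprintf("  p1 = %.4g, p2 = %.4g, p3 = %.4g, p4 = %.4g\n",
              x$p1, x$p2, x$p3, x$p4))
  cat(sprintf("  clamped to [%g, %g]\n", x$clamp_lo, x$clamp_hi))
  invisible(x)
}

#' Evaluate the dynamic elimination threshold at a sequence index
#'
#' @param x Non-negative integer, the image's index in capture order.
#' @param model A [threshold_model()].
#' @param clamp Logical; clip the raw polynomial into the model's band
#'   (default `TRUE`).
#' @return The threshold (numeric scalar).  The unclipped polynomial value
#'   is attached as attribute `"raw"`.
#' @export
dynamic_threshold <- function(x, model = threshold_model(), clamp = TRUE) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0)
  # Horner evaluation
  raw <- ((model$p1 * x + model$p2) * x + model$p3) * x + model$p4
  out <- if (clamp) min(max(raw, model$clamp_lo), model$clamp_hi) else raw
  attr(out, "raw") <- raw
  out
}

#' Zero out pixels below an elimination threshold
#'
#' Pixels with intensity strictly below `T` are set to 0; pixels at or
#' above `T` are untouched ("pixels below T are removed" keeps T itself).
#' Idempotent for a fixed `T`.
#'
#' @param img Numeric intensity matrix.
#' @param T Threshold on the image's intensity scale.
#' @return Matrix of the same dimensions.
#' @export
apply_threshold <- function(img, T) {
  stopifnot(is.matrix(img), is.numeric(T), length(T) == 1L)
  img[img < T] <- 0
  img
}

#' Otsu's global automatic threshold
#'
#' Maximizes the between-class variance over the 256-bin histogram of an
#' 8-bit image.  When several candidate thresholds tie (a flat plateau
#' between two well-separated modes), the middle of the plateau is
#' returned, so a two-valued image thresholds strictly between its
#' values.  A pixel is "above" the threshold when its intensity is
#' strictly greater, matching [baseline_segment()]'s `gat` mode.
#'
#' @param img Numeric matrix with whole-number values in 0--255.
#' @return Integer threshold in 0--254.
#' @export
otsu_threshold <- function(img) {
  stopifnot(is.matrix(img))
  v <- as.vector(img)
  if (length(unique(v)) < 2L) {
    stop("Otsu threshold undefined for a constant image")
  }
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  omega <- cumsum(p)                 # class-0 mass for t = 0..255
  mu <- cumsum(p * lev)              # class-0 first moment
  mu_t <- mu[256L]
  # between-class variance for threshold t (class 0 = levels <= t)
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  sigma_b <- sigma_b[1:255]          # t = 255 leaves class 1 empty
  ties <- which(sigma_b == max(sigma_b))
  as.integer(floor(stats::median(ties))) - 1L
}
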