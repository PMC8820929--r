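#' Histogram-based initial centroids for intensity K-means
#'
#' Rather than seeding the two clusters at random, the seeds come from the
#' histogram of intensities that survive the elimination threshold: the
#' set of occupied intensity levels above `cutoff` (the 255-bin histogram
#' support) gives
#' \itemize{
#'   \item `mean0` -- the mean of the occupied levels (a point inside the
#'     canopy's intensity mass), and
#'   \item `mean1` -- the minimum occupied level (the dimmest surviving
#'     intensity, seeding the background/dim cluster).
#' }
#'
#' @param img Numeric intensity matrix on the 0--255 scale.
#' @param cutoff Intensity cutoff; only pixels with intensity strictly
#'   greater than `cutoff` enter the histogram.
#' @return List with components `mean0` and `mean1` (`mean1 <= mean0`),
#'   class `"centroid_pair"`.
#' @export
initial_centroids <- function(img, cutoff) {
  stopifnot(is.matrix(img), is.numeric(cutoff), length(cutoff) == 1L)
  retained <- img[img > cutoff]
  if (length(retained) == 0L) {
    stop("no pixel above cutoff: cannot seed centroids")
  }
  levels_occ <- sort(unique(round(retained)))
  structure(list(mean0 = mean(levels_occ), mean1 = min(levels_occ)),
            class = "centroid_pair")
}

#' Two-cluster Lloyd iteration on pixel intensities
#'
#' 1-D K-means on the normalized image: each pixel is assigned to the
#' nearest of the two centroids (Euclidean distance on intensity), then
#' each centroid is replaced by the mean of its pixels; iteration stops
#' when the assignment no longer changes or after `max_iter` passes.  An
#' empty cluster keeps its previous centroid.  The canopy label (1) goes
#' to the cluster with the larger final centroid — fluorescence is bright
#' on a dark background.
#'
#' @param img Numeric matrix normalized to \[0, 1\]
#'   (see [normalize_intensity()]).
#' @param centroids A `centroid_pair` (on the 0--255 scale; rescaled
#'   internally) or a numeric vector of starting centroids on the image's
#'   own scale.
#' @param max_iter Maximum Lloyd iterations (default 20).
#' @return List with `mask` (0/1 integer matrix, 1 = canopy),
#'   `centroids` (final, in the seed order given), `iterations`,
#'   `converged`, and `assignment` (integer matrix of cluster indices).
#' @export
kmeans_intensity <- function(img, centroids, max_iter = 20L) {
  stopifnot(is.matrix(img))
  if (inherits(centroids, "centroid_pair")) {
    centers <- c(centroids$mean1, centroids$mean0) / 255
  } else {
    centers <- as.numeric(centroids)
  }
  k <- length(centers)
  stopifnot(k >= 2L)
  x <- as.vector(img)
  assign_prev <- rep.int(0L, length(x))
  iter <- 0L
  converged <- FALSE
  repeat {
    d <- abs(outer(x, centers, "-"))
    assign_cur <- max.col(-d, ties.method = "first")
    if (identical(assign_cur, assign_prev)) { converged <- TRUE; break }
    if (iter >= max_iter) break
    iter <- iter + 1L
    for (j in seq_len(k)) {
      xs <- x[assign_cur == j]
      if (length(xs) > 0L) centers[j] <- mean(xs)  # empty: keep previous
    }
    assign_prev <- assign_cur
  }
  top <- which.max(centers)
  mask <- matrix((assign_cur == top) + 0L, nrow(img), ncol(img))
  list(mask = mask, centroids = centers, iterations = iter,
       converged = converged,
       assignment = matrix(assign_cur, nrow(img), ncol(img)))
}

#' CFitK-means canopy segmentation
#'
#' The hybrid segmenter: (i) standardize the image to the analysis frame,
#' (ii) evaluate the dynamic curve-fit threshold at the image's sequence
#' index `x` and zero out pixels below it (removing pot and residual
#' background), (iii) seed two centroids from the histogram of surviving
#' intensities, (iv) normalize and run two-cluster intensity K-means.
#' Pixels removed by the threshold can never be canopy.
#'
#' If the threshold removes every pixel the result is an all-background
#' mask (with a warning) rather than an error, so a time series can be
#' processed unattended.
#'
#' @param img Numeric intensity matrix on the 0--255 scale.
#' @param x Sequence index of the image in capture order (drives the
#'   dynamic threshold).
#' @param model A [threshold_model()].
#' @param frame Analysis frame `c(width, height)`; `NULL` keeps the
#'   image's own dimensions.
#' @param max_iter Maximum K-means iterations.
#' @return An object of class `"cfitkmeans"`: a list with `mask` (0/1
#'   matrix, 1 = canopy), `threshold` (clamped, with `"raw"` attribute),
#'   `x`, `initial_centroids`, `centroids` (final, \[0,1\] scale),
#'   `iterations`, `converged`, and `dim`.
#' @export
#' @examples
#' sc <- canopy_scene(seed = 1, frame = c(96, 72))
#' fit <- cfitkmeans(sc$image, x = 0, frame = NULL)
#' fit
#' iou(sc$canopy_mask, fit$mask)
cfitkmeans <- function(img, x, model = threshold_model(),
                       frame = c(1388L, 1038L), max_iter = 20L) {
  stopifnot(is.matrix(img))
  if (!is.null(frame)) img <- standardize_frame(img, frame)
  T <- dynamic_threshold(x, model)
  thresholded <- apply_threshold(img, T)
  survivors <- thresholded >= T & thresholded > 0
  empty_fit <- list(mask = matrix(0L, nrow(img), ncol(img)),
                    centroids = NULL, iterations = 0L, converged = TRUE)
  if (!any(thresholded > T)) {
    warning("dynamic threshold removed every pixel; returning ",
            "all-background mask")
    km <- empty_fit
    init <- NULL
  } else {
    init <- initial_centroids(thresholded, cutoff = T)
    km <- kmeans_intensity(normalize_intensity(thresholded), init,
                           max_iter = max_iter)
    km$mask[!survivors] <- 0L   # thresholded-away pixels are background
  }
  structure(list(mask = km$mask, threshold = T, x = x,
                 initial_centroids = init, centroids = km$centroids,
                 iterations = km$iterations, converged = km$converged,
                 dim = dim(img)),
            class = "cfitkmeans")
}

#' @export
print.cfitkmeans <- function(x, ...) {
  cat("CFitK-means canopy segmentation\n")
  cat(sprintf("  frame: %d x %d (w x h), sequence index x = %g\n",
              x$dim[2L], x$dim[1L], x$x))
  cat(sprintf("  elimination threshold: %.3f (raw %.3f)\n",
              as.numeric(x$threshold), attr(x$threshold, "raw")))
  if (!is.null(x$centroids)) {
    cat(sprintf("  final centroids: %s (normalized intensity)\n",
                paste(sprintf("%.4f", x$centroids), collapse = ", ")))
  }
  cat(sprintf("  K-means iterations: %d (%s)\n", x$iterations,
              if (isTRUE(x$converged)) "converged" else "iteration cap"))
  cat(sprintf("  canopy pixels: %d of %d (%.1f%%)\n", sum(x$mask),
              length(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
summary.cfitkmeans <- function(object, ...) {
  print(object)
  if (!is.null(object$initial_centroids)) {
    cat(sprintf("  initial centroids (0-255): mean0 = %.2f, mean1 = %.2f\n",
                object$initial_centroids$mean0,
                object$initial_centroids$mean1))
  }
  invisible(object)
}

#' @export
plot.cfitkmeans <- function(x, ...) {
  graphics::image(t(x$mask[nrow(x$mask):1, , drop = FALSE]),
                  col = c("black", "green3"), axes = FALSE,
                  main = "CFitK-means canopy mask", ...)
  invisible(x)
}

#' Extract the binary canopy mask from a segmentation fit
#' @param x A `"cfitkmeans"` object.
#' @param ... Unused.
#' @return 0/1 integer matrix.
#' @export
as.matrix.cfitkmeans <- function(x, ...) x$mask

#' Baseline canopy segmenters
#'
#' Reference segmenters the hybrid method is compared against:
#' \describe{
#'   \item{`gst`}{Global static threshold: foreground = intensity >= `T`
#'     (default 17, the top of the elimination band).}
#'   \item{`gat`}{Global automatic (Otsu) threshold: foreground =
#'     intensity > [otsu_threshold()].}
#'   \item{`kmeans4`}{Four-centroid intensity K-means seeded at the
#'     quartile midpoints of the observed intensity range; the cluster
#'     with the lowest final centroid is background, the other three are
#'     merged into foreground.}
#' }
#'
#' @param img Numeric intensity matrix on the 0--255 scale.
#' @param method One of `"gst"`, `"gat"`, `"kmeans4"`.
#' @param T Static threshold for `gst`.
#' @param max_iter K-means iteration cap for `kmeans4`.
#' @return 0/1 integer mask matrix.
#' @export
baseline_segment <- function(img, method = c("gst", "gat", "kmeans4"),
                             T = 17, max_iter = 20L) {
  stopifnot(is.matrix(img))
  method <- match.arg(method)
  if (method == "gst") {
    return(matrix((img >= T) + 0L, nrow(img), ncol(img)))
  }
  if (method == "gat") {
    t0 <- otsu_threshold(img)
    return(matrix((img > t0) + 0L, nrow(img), ncol(img)))
  }
  # kmeans4: quartile-midpoint seeds over the observed range
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(0L, nrow(img), ncol(img)))
  centers <- rng[1L] + diff(rng) * c(1, 3, 5, 7) / 8
  km <- kmeans_intensity(normalize_intensity(img), centers / 255,
                         max_iter = max_iter)
  lowest <- which.min(km$centroids)
  (km$assignment != lowest) + 0L
}
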