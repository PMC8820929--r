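#' Intersection over union of two binary masks
#'
#' `|target & prediction| / |target | prediction|`.  Symmetric in its
#' arguments.  Two empty masks agree perfectly on absence, so that case
#' returns 1 with a warning.
#'
#' @param target,prediction 0/1 matrices of equal dimensions.
#' @return Numeric scalar in \[0, 1\].
#' @export
#' @examples
#' a <- matrix(0L, 10, 10); a[1:5, ] <- 1L
#' iou(a, a)
iou <- function(target, prediction) {
  stopifnot(is.matrix(target), is.matrix(prediction))
  if (!all(dim(target) == dim(prediction))) {
    stop("mask dimensions differ")
  }
  t1 <- target != 0; p1 <- prediction != 0
  u <- sum(t1 | p1)
  if (u == 0L) {
    warning("both masks empty; IoU defined as 1")
    return(1)
  }
  sum(t1 & p1) / u
}

#' Random-sampling IoU evaluation of competing segmenters
#'
#' Scores each algorithm on mutually exclusive random samples of the
#' dataset (one seeded shuffle partitioned into consecutive blocks of the
#' requested sizes), counting images whose IoU against ground truth
#' exceeds `cutoff`, and reporting the average IoU as a percentage both
#' per sampling round and over all evaluated images.
#'
#' @param algorithms Named list of functions `f(image, x)` returning a
#'   0/1 mask.
#' @param dataset List of lists with elements `image`, `x`, and `truth`
#'   (ground-truth 0/1 mask).
#' @param sizes Integer sample sizes (default `c(25, 50, 75, 100)`).
#'   The dataset must contain at least `sum(sizes)` images so the samples
#'   can be mutually exclusive.
#' @param cutoff IoU above which a segmentation counts as acceptable
#'   (default 0.5).
#' @param seed Integer seed for the shuffle.
#' @return Object of class `"iou_report"`: list with `counts` (algorithm
#'   x size matrix), `avg_iou_percent` (per algorithm, over all evaluated
#'   images), `round_avg_percent` (algorithm x size), `per_image` (IoU
#'   values per algorithm), `sizes`, `cutoff`, `seed`.
#' @export
evaluate_segmenters <- function(algorithms, dataset,
                                sizes = c(25L, 50L, 75L, 100L),
                                cutoff = 0.5, seed = 1L) {
  stopifnot(is.list(algorithms), length(algorithms) > 0L,
            !is.null(names(algorithms)))
  n <- length(dataset)
  if (n < sum(sizes)) {
    stop("dataset too small: ", n, " images but mutually exclusive ",
         "samples of sizes ", paste(sizes, collapse = "+"), " need ",
         sum(sizes))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  order_ix <- sample.int(n)
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-length(ends)] + 1L)
  algs <- names(algorithms)
  counts <- matrix(0L, length(algs), length(sizes),
                   dimnames = list(algs, paste0("n", sizes)))
  round_avg <- counts * 0
  per_image <- stats::setNames(
    rep(list(numeric(0)), length(algs)), algs)
  for (s in seq_along(sizes)) {
    ix <- order_ix[starts[s]:ends[s]]
    for (a in algs) {
      vals <- vapply(ix, function(k) {
        it <- dataset[[k]]
        iou(it$truth, algorithms[[a]](it$image, it$x))
      }, 0)
      counts[a, s] <- sum(vals > cutoff)
      round_avg[a, s] <- 100 * mean(vals)
      per_image[[a]] <- c(per_image[[a]], vals)
    }
  }
  structure(list(counts = counts,
                 avg_iou_percent = vapply(per_image,
                                          function(v) 100 * mean(v), 0),
                 round_avg_percent = round_avg,
                 per_image = per_image,
                 sizes = sizes, cutoff = cutoff, seed = seed),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat("IoU segmentation evaluation (cutoff ", x$cutoff, ", seed ",
      x$seed, ")\n", sep = "")
  cat("Images with IoU above cutoff, per mutually exclusive sample:\n")
  print(x$counts)
  cat("Average IoU score (%) over all evaluated images:\n")
  print(round(x$avg_iou_percent, 2))
  invisible(x)
}

# set.seed side effects are kept local to seeded package functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
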