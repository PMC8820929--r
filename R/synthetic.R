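#' Simulate one fluorescence-like canopy scene
#'
#' Builds a grayscale scene with the three intensity strata a
#' chlorophyll-fluorescence capture shows: exact-zero background, a pot
#' band in the low 11--17 intensity range, and a brighter canopy formed
#' by a union of elliptical leaf blobs whose truncated-Gaussian
#' intensities stay at or above 18 before noise.  Pot and canopy
#' intensity supports are therefore disjoint by construction, so with
#' `noise_sd = 0` a threshold at 17 recovers the canopy exactly — the
#' exact-recovery fixture used throughout the tests.
#'
#' Growth and stress follow the defaults: the control canopy brightens
#' with `day` (mean `40 + 0.5 * day`), while the drought canopy is dimmer
#' (`35 + 0.3 * day`) and its leaf blobs are scaled by 0.7, exposing more
#' of the pot.  Additive Gaussian noise (sd `noise_sd`) is applied inside
#' the pot and canopy supports only, keeping the background exactly 0,
#' then clipped to \[0, 255\].
#'
#' @param day Day in the 0--59 capture timeline.
#' @param condition `"control"` or `"drought"`.
#' @param seed Integer seed; the same seed gives a bitwise-identical
#'   scene.
#' @param frame `c(width, height)`; the default 347 x 260 is the native
#'   1388 x 1038 frame scaled down 4x so suites run quickly.
#' @param n_leaf_blobs Number of elliptical leaf blobs.
#' @param canopy_mean,canopy_sd Canopy intensity moments before
#'   truncation at 18; `canopy_mean = NULL` uses the growth model above.
#' @param pot_range Pot intensity band (integers), default `c(11, 17)`.
#' @param noise_sd Gaussian noise sd in intensity units (default 0).
#' @return List of class `"canopy_scene"`: `image` (0--255 matrix),
#'   `canopy_mask`, `pot_mask` (0/1 matrices), plus the generating
#'   parameters.
#' @export
#' @examples
#' sc <- canopy_scene(day = 30, condition = "drought", seed = 7,
#'                    frame = c(96, 72))
#' table(sc$image[sc$pot_mask == 1])
canopy_scene <- function(day = 0L, condition = c("control", "drought"),
                         seed = 1L, frame = c(347L, 260L),
                         n_leaf_blobs = 12L, canopy_mean = NULL,
                         canopy_sd = 8, pot_range = c(11L, 17L),
                         noise_sd = 0) {
  condition <- match.arg(condition)
  stopifnot(day >= 0, day <= 59, length(frame) == 2L, frame > 0,
            pot_range[1L] >= 1, pot_range[2L] <= 17,
            pot_range[1L] <= pot_range[2L])
  if (is.null(canopy_mean)) {
    canopy_mean <- if (condition == "control") 40 + 0.5 * day
                   else 35 + 0.3 * day
  }
  if (canopy_mean <= 17) {
    stop("canopy_mean must exceed 17 (pot band) to be distinguishable")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- as.integer(frame[1L]); h <- as.integer(frame[2L])
  img <- matrix(0, h, w)
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)

  # pot: a band across the lower quarter of the frame
  pot <- (rowg > 0.78 * h) & (rowg <= 0.92 * h) &
    (colg > 0.25 * w) & (colg <= 0.75 * w)
  img[pot] <- sample(pot_range[1L]:pot_range[2L], sum(pot),
                     replace = TRUE)

  # canopy: union of elliptical leaf blobs above the pot
  shrink <- if (condition == "drought") 0.7 else 1
  canopy <- matrix(FALSE, h, w)
  if (n_leaf_blobs > 0L) {
    for (b in seq_len(n_leaf_blobs)) {
      cx <- stats::runif(1, 0.25 * w, 0.75 * w)
      cy <- stats::runif(1, 0.18 * h, 0.68 * h)
      a <- shrink * stats::runif(1, 0.05, 0.14) * w   # semi-axes
      bb <- shrink * stats::runif(1, 0.04, 0.10) * h
      th <- stats::runif(1, 0, pi)
      xr <- (colg - cx) * cos(th) + (rowg - cy) * sin(th)
      yr <- -(colg - cx) * sin(th) + (rowg - cy) * cos(th)
      canopy <- canopy | (xr^2 / a^2 + yr^2 / bb^2 <= 1)
    }
  }
  canopy <- canopy & !pot     # pot occludes canopy at the boundary
  n_can <- sum(canopy)
  if (n_can > 0L) {
    vals <- stats::rnorm(n_can, canopy_mean, canopy_sd)
    vals <- pmax(round(vals), 18)          # truncate above the pot band
    img[canopy] <- pmin(vals, 255)
  }
  if (noise_sd > 0) {
    on_support <- pot | canopy
    img[on_support] <- img[on_support] +
      stats::rnorm(sum(on_support), 0, noise_sd)
    img <- pmin(pmax(round(img), 0), 255)
  }
  structure(list(image = img, canopy_mask = canopy + 0L,
                 pot_mask = pot + 0L, day = day, condition = condition,
                 seed = seed, frame = c(w, h), canopy_mean = canopy_mean,
                 canopy_sd = canopy_sd, noise_sd = noise_sd),
            class = "canopy_scene")
}

#' Simulate a capture timeline
#'
#' One scene per day, with the canopy brightening over time (the growth
#' model in [canopy_scene()]).  The element `x` carries the sequence
#' index used by the dynamic threshold.
#'
#' @param n_days Number of days (images), starting at day 0.
#' @param condition `"control"` or `"drought"`.
#' @param seed Base seed; day `d` uses `seed + d` so scenes are
#'   independent but reproducible.
#' @param ... Passed to [canopy_scene()].
#' @return List of `canopy_scene` objects, each with an `x` element.
#' @export
make_timeline <- function(n_days, condition = "control", seed = 1L,
                          ...) {
  stopifnot(n_days >= 1L)
  lapply(seq_len(n_days) - 1L, function(d) {
    sc <- canopy_scene(day = d, condition = condition,
                       seed = seed + d, ...)
    sc$x <- d
    sc
  })
}

#' Simulate a correlated 23-trait feature table
#'
#' Draws rows from a multivariate Gaussian whose correlation matrix has
#' a three-block structure over the 23 traits: correlation `within_r`
#' inside a block and `between_r` across blocks.  The default blocks are
#' the three trait families the clustering layer is expected to recover
#' (variance/contrast family, homogeneity/orderliness family, and the
#' two information-measure traits).
#'
#' @param n_rows Number of instances.
#' @param blocks List of 3 character vectors partitioning
#'   [glcm_trait_names].
#' @param within_r,between_r Target correlations
#'   (`within_r > between_r >= 0`).
#' @param seed Integer seed.
#' @param condition Optional label column value(s), recycled.
#' @return `data.frame` with `condition` plus the 23 trait columns.
#' @export
make_feature_table <- function(n_rows, blocks = default_trait_blocks,
                               within_r = 0.9, between_r = 0,
                               seed = 1L, condition = "control") {
  stopifnot(n_rows >= 2L, within_r > between_r, between_r >= 0)
  vars <- unlist(blocks, use.names = FALSE)
  stopifnot(setequal(vars, glcm_trait_names) ||
              !anyDuplicated(vars))
  p <- length(vars)
  R <- matrix(between_r, p, p, dimnames = list(vars, vars))
  for (blk in blocks) R[blk, blk] <- within_r
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("block correlation target not positive definite")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- MASS::mvrnorm(n_rows, mu = rep(0, p), Sigma = R)
  colnames(x) <- vars
  out <- data.frame(condition = rep_len(condition, n_rows),
                    x[, intersect(glcm_trait_names, vars), drop = FALSE],
                    check.names = FALSE)
  out
}

#' Default three-block partition of the trait panel
#'
#' The variance/contrast family, the homogeneity/orderliness family, and
#' the two information measures of correlation.
#' @export
default_trait_blocks <- list(
  variance = c("autoc", "contr", "corrm", "corrp", "cprom", "cshad",
               "dissi", "entro", "sosvh", "savgh", "svarh", "senth",
               "dvarh", "denth", "idmnc"),
  homogeneity = c("energ", "homom", "homop", "maxpr", "homom1", "indnc"),
  information = c("inf1h", "inf2h"))

#' Write a simulated dataset to disk
#'
#' Renders a mixed control/drought timeline to PNG images and masks plus
#' a manifest CSV (`image_path, x, mask_path, condition`) consumable by
#' [run_pipeline()].
#'
#' @param outdir Output directory (created if missing).
#' @param n_days Days per condition.
#' @param conditions Conditions to simulate.
#' @param seed Base seed.
#' @param ... Passed to [canopy_scene()].
#' @return Path to the manifest CSV, invisibly; the manifest
#'   `data.frame` as attribute `"manifest"`.
#' @export
simulate_dataset <- function(outdir, n_days = 10L,
                             conditions = c("control", "drought"),
                             seed = 1L, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ci in seq_along(conditions)) {
    tl <- make_timeline(n_days, conditions[ci],
                        seed = seed + 1000L * (ci - 1L), ...)
    for (sc in tl) {
      stem <- sprintf("%s_day%02d", conditions[ci], sc$day)
      ip <- file.path(outdir, paste0(stem, ".png"))
      mp <- file.path(outdir, paste0(stem, "_mask.png"))
      write_image(sc$image, ip)
      write_mask(sc$canopy_mask, mp)
      rows[[length(rows) + 1L]] <-
        data.frame(image_path = ip, x = sc$x, mask_path = mp,
                   condition = conditions[ci],
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mf <- file.path(outdir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  attr(mf, "manifest") <- manifest
  invisible(mf)
}
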