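#' Names of the 23 GLCM canopy traits
#'
#' Column order used by every feature table in the package.  `homop` and
#' `homom1` share one formula (inverse difference) and both are kept so
#' the 23-column schema is stable.
#' @export
glcm_trait_names <- c(
  "autoc", "contr", "corrm", "corrp", "cprom", "cshad", "dissi",
  "energ", "entro", "homom", "homop", "maxpr", "sosvh", "savgh",
  "svarh", "senth", "dvarh", "denth", "inf1h", "inf2h", "homom1",
  "indnc", "idmnc")

#' GLCM configuration
#'
#' @param ng Number of grey levels after quantization (default 9, giving
#'   a 9 x 9 cooccurrence matrix).
#' @param offset Integer `c(row_shift, col_shift)` pixel displacement
#'   (default `c(0, 1)`: horizontal neighbour).
#' @param symmetric Logical; accumulate the reverse offset too
#'   (default `TRUE`).
#' @param epsilon Small constant added inside every logarithm so empty
#'   cells contribute nothing (default machine epsilon, 2.2e-16).
#' @param corrections Named logical list toggling departures from the
#'   legacy printed forms of four traits (see Details).
#'
#' @details The trait panel follows a widely circulated formula sheet
#' that contains a few typographical impossibilities; each fix is an
#' explicit toggle so either convention can be reproduced:
#' \describe{
#'   \item{`sosvh_mean_shift` (default `TRUE`)}{sum-of-squares variance
#'     uses `(i - mu)^2` instead of the printed `(1 - mu)^2`.}
#'   \item{`dvarh_mu_xminusy` (default `TRUE`)}{difference variance is
#'     centred on the mean of the difference distribution
#'     `mu_{x-y} = sum k p_{x-y}(k)` rather than on `mu_{x+y}`.}
#'   \item{`senth_sign` (default `TRUE`)}{sum entropy carries the leading
#'     minus sign every entropy needs (the printed form omits it).}
#'   \item{`inf2h_sqrt` (default `FALSE`)}{information measure of
#'     correlation 2 as `sqrt(1 - exp(-2(HXY2 - HXY)))`; the default
#'     follows the printed form without the square root.}
#' }
#' @return List of class `"glcm_config"`.
#' @export
glcm_config <- function(ng = 9L, offset = c(0L, 1L), symmetric = TRUE,
                        epsilon = 2.2e-16,
                        corrections = list(sosvh_mean_shift = TRUE,
                                           dvarh_mu_xminusy = TRUE,
                                           senth_sign = TRUE,
                                           inf2h_sqrt = FALSE)) {
  stopifnot(ng >= 2L, length(offset) == 2L, epsilon > 0)
  if (all(offset == 0L)) stop("offset must be nonzero")
  defaults <- list(sosvh_mean_shift = TRUE, dvarh_mu_xminusy = TRUE,
                   senth_sign = TRUE, inf2h_sqrt = FALSE)
  corrections <- utils::modifyList(defaults, corrections)
  structure(list(ng = as.integer(ng), offset = as.integer(offset),
                 symmetric = isTRUE(symmetric), epsilon = epsilon,
                 corrections = corrections),
            class = "glcm_config")
}

#' Quantize a masked image to Ng grey levels
#'
#' Equal-width binning of the 0--255 range into `ng` levels numbered
#' 1..`ng` (`level = floor(intensity / (256/ng)) + 1`, capped at `ng`).
#' Off-mask pixels are set to `NA` and never form cooccurrence pairs.
#'
#' @param img Numeric intensity matrix, 0--255.
#' @param mask 0/1 matrix of the same dimensions, or `NULL` for the whole
#'   image.
#' @param ng Number of grey levels.
#' @return Integer matrix of levels in 1..`ng` with `NA` off-mask.
#' @export
quantize_image <- function(img, mask = NULL, ng = 9L) {
  stopifnot(is.matrix(img), ng >= 2L)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(img)))
    if (sum(mask) == 0L) stop("empty mask: nothing to quantize")
  }
  q <- pmin(floor(img / (256 / ng)) + 1L, ng)
  storage.mode(q) <- "integer"
  if (!is.null(mask)) q[mask == 0L] <- NA_integer_
  q
}

#' Grey-level cooccurrence matrix
#'
#' Counts ordered level pairs `(q[r, c], q[r + dr, c + dc])` over all
#' positions where both pixels are inside the image and in-mask
#' (non-`NA`); with `symmetric = TRUE` the reverse offset is accumulated
#' as well.  The count matrix is normalized to sum to 1.
#'
#' @param q Quantized level matrix from [quantize_image()].
#' @param config A [glcm_config()].
#' @return `ng` x `ng` matrix `p(i, j)` summing to 1, with attribute
#'   `"pairs"` giving the raw pair count.
#' @export
glcm <- function(q, config = glcm_config()) {
  stopifnot(is.matrix(q))
  ng <- config$ng
  dr <- config$offset[1L]; dc <- config$offset[2L]
  nr <- nrow(q); nc <- ncol(q)
  r0 <- seq_len(nr - abs(dr)); c0 <- seq_len(nc - abs(dc))
  if (dr < 0) r0 <- r0 - dr
  if (dc < 0) c0 <- c0 - dc
  if (length(r0) == 0L || length(c0) == 0L) {
    stop("offset larger than image: no pairs")
  }
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid in-mask pixel pair at the given offset")
  counts <- matrix(0, ng, ng)
  tab <- table(factor(a[ok], levels = 1:ng), factor(b[ok], levels = 1:ng))
  counts <- counts + unclass(tab)
  if (config$symmetric) counts <- counts + t(unclass(tab))
  p <- counts / sum(counts)
  dimnames(p) <- NULL
  attr(p, "pairs") <- sum(counts)
  p
}

#' Marginal distributions and entropy terms of a GLCM
#'
#' From the normalized cooccurrence matrix `p(i, j)` (levels 1..Ng)
#' computes the row/column marginals `px`, `py`, their means and
#' variances, the sum distribution `p_{x+y}(k)` (k = 2..2Ng) and
#' difference distribution `p_{x-y}(k)` (k = 0..Ng-1) with their means,
#' and the base-2 entropy terms `HX`, `HY`, `HXY`, `HXY1`, `HXY2`
#' (epsilon added inside each log).
#'
#' @param p Normalized GLCM matrix.
#' @param epsilon Constant inside the logarithms.
#' @return List of class `"glcm_marginals"`.
#' @export
glcm_marginals <- function(p, epsilon = 2.2e-16) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  ng <- nrow(p)
  i <- 1:ng
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  var_x <- sum((i - mu_x)^2 * px); var_y <- sum((i - mu_y)^2 * py)
  # sum / difference distributions
  ii <- row(p); jj <- col(p)
  p_xplusy <- vapply(2:(2 * ng), function(k) sum(p[ii + jj == k]), 0)
  p_xminusy <- vapply(0:(ng - 1), function(k) sum(p[abs(ii - jj) == k]), 0)
  mu_xplusy <- sum((2:(2 * ng)) * p_xplusy)
  mu_xminusy <- sum((0:(ng - 1)) * p_xminusy)
  HX <- -sum(px * log2(px + epsilon))
  HY <- -sum(py * log2(py + epsilon))
  HXY <- -sum(p * log2(p + epsilon))
  pxy <- outer(px, py)
  HXY1 <- -sum(p * log2(pxy + epsilon))
  HXY2 <- -sum(pxy * log2(pxy + epsilon))
  structure(list(px = px, py = py, mu_x = mu_x, mu_y = mu_y,
                 var_x = var_x, var_y = var_y,
                 p_xplusy = p_xplusy, p_xminusy = p_xminusy,
                 mu_xplusy = mu_xplusy, mu_xminusy = mu_xminusy,
                 HX = HX, HY = HY, HXY = HXY, HXY1 = HXY1, HXY2 = HXY2),
            class = "glcm_marginals")
}

#' The 23 GLCM texture traits
#'
#' Evaluates the full trait panel from a normalized cooccurrence matrix.
#' When the marginal variances vanish (a one-level region), the two
#' correlation traits are undefined and returned as `NaN` with attribute
#' `"degenerate_correlation" = TRUE` on the vector.
#'
#' @param p Normalized GLCM matrix.
#' @param config A [glcm_config()] (supplies epsilon and the formula
#'   toggles).
#' @param marginals Optional precomputed [glcm_marginals()].
#' @return Named numeric vector of length 23, names =
#'   [glcm_trait_names].
#' @export
glcm_features <- function(p, config = glcm_config(),
                          marginals = glcm_marginals(p, config$epsilon)) {
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  ng <- nrow(p)
  eps <- config$epsilon
  corr <- config$corrections
  m <- marginals
  ii <- row(p); jj <- col(p)
  ks <- 2:(2 * ng)          # support of p_{x+y}
  kd <- 0:(ng - 1)          # support of p_{x-y}

  autoc <- sum(ii * jj * p)
  contr <- sum((ii - jj)^2 * p)
  sigma_xy <- sqrt(m$var_x * m$var_y)
  if (sigma_xy > 0) {
    corrm <- sum((ii - m$mu_x) * (jj - m$mu_y) * p) / sigma_xy
    corrp <- (autoc - m$mu_x * m$mu_y) / sigma_xy
  } else {
    corrm <- NaN; corrp <- NaN
  }
  cprom <- sum((ii - m$mu_x + jj - m$mu_y)^4 * p)
  cshad <- sum((ii - m$mu_x + jj - m$mu_y)^3 * p)
  dissi <- sum(abs(ii - jj) * p)
  energ <- sum(p^2)
  entro <- -sum(p * log2(p + eps))
  homom <- sum(p / (1 + (ii - jj)^2))
  homop <- sum(p / (1 + abs(ii - jj)))
  maxpr <- max(p)
  sosvh <- if (isTRUE(corr$sosvh_mean_shift)) {
    sum((ii - m$mu_x)^2 * p)
  } else {
    sum((1 - m$mu_x)^2 * p)
  }
  savgh <- sum(ks * m$p_xplusy)
  svarh <- sum((ks - m$mu_xplusy)^2 * m$p_xplusy)
  senth_raw <- sum(m$p_xplusy * log2(m$p_xplusy + eps))
  senth <- if (isTRUE(corr$senth_sign)) -senth_raw else senth_raw
  mu_d <- if (isTRUE(corr$dvarh_mu_xminusy)) m$mu_xminusy else m$mu_xplusy
  dvarh <- sum((kd - mu_d)^2 * m$p_xminusy)
  denth <- -sum(m$p_xminusy * log2(m$p_xminusy + eps))
  inf1h <- (m$HXY - m$HXY1) / max(m$HX, m$HY)
  inf2h_arg <- 1 - exp(-2 * (m$HXY2 - m$HXY))
  inf2h <- if (isTRUE(corr$inf2h_sqrt)) sqrt(max(inf2h_arg, 0)) else inf2h_arg
  homom1 <- homop
  indnc <- sum(p / (1 + abs(ii - jj) / ng))
  idmnc <- sum(p / (1 + (ii - jj)^2 / ng))

  out <- c(autoc = autoc, contr = contr, corrm = corrm, corrp = corrp,
           cprom = cprom, cshad = cshad, dissi = dissi, energ = energ,
           entro = entro, homom = homom, homop = homop, maxpr = maxpr,
           sosvh = sosvh, savgh = savgh, svarh = svarh, senth = senth,
           dvarh = dvarh, denth = denth, inf1h = inf1h, inf2h = inf2h,
           homom1 = homom1, indnc = indnc, idmnc = idmnc)
  if (sigma_xy == 0) attr(out, "degenerate_correlation") <- TRUE
  out
}

#' Full texture panel for one image + mask
#'
#' Convenience wrapper: quantize the canopy region, build the GLCM, and
#' return the 23 traits.
#'
#' @param img Numeric intensity matrix, 0--255.
#' @param mask 0/1 canopy mask (or `NULL` for the whole image).
#' @param config A [glcm_config()].
#' @return Named numeric vector of length 23.
#' @export
canopy_traits <- function(img, mask = NULL, config = glcm_config()) {
  q <- quantize_image(img, mask, config$ng)
  p <- glcm(q, config)
  glcm_features(p, config)
}

#' Extract a feature table from a list of segmented images
#'
#' One row per image: the 23 traits plus a `condition` label and an `id`.
#' Images whose canopy is degenerate (empty mask, no pairs) are dropped
#' from the table and recorded in the `"skipped"` attribute with the
#' reason.
#'
#' @param images List of lists with elements `image`, `mask`,
#'   `condition`, and optionally `id`.
#' @param config A [glcm_config()].
#' @return `data.frame` with columns `id`, `condition`, and the 23
#'   traits.
#' @export
extract_feature_table <- function(images, config = glcm_config()) {
  stopifnot(is.list(images), length(images) > 0L)
  rows <- vector("list", length(images))
  skipped <- character()
  for (k in seq_along(images)) {
    it <- images[[k]]
    id <- if (!is.null(it$id)) it$id else sprintf("img_%03d", k)
    fv <- tryCatch(canopy_traits(it$image, it$mask, config),
                   error = function(e) e)
    if (inherits(fv, "error")) {
      skipped[id] <- conditionMessage(fv)
      next
    }
    rows[[k]] <- data.frame(id = id,
                            condition = if (!is.null(it$condition))
                              it$condition else NA_character_,
                            as.list(fv),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
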