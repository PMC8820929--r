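#' Correlation analysis with range categorization
#'
#' Computes the pairwise correlation matrix of the 23 traits and sorts
#' each variable into overlapping correlation-range categories by its
#' off-diagonal correlations:
#' A (-1 to 0.09), B (0 to 0.49), C (0.5 to 0.89), D (0.9 to 1.0).
#' A variable belongs to a category when at least one of its off-diagonal
#' correlations falls inside that range (an interpretation flag records
#' this rule in the output); the ranges themselves overlap, so
#' multi-category membership is expected.
#'
#' @param table Feature table (`data.frame`); only the trait columns in
#'   [glcm_trait_names] that are present are used, or all numeric columns
#'   if none match.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return Object of class `"trait_correlations"`: list with `method`,
#'   `matrix`, `categories` (named list A--D of variable names),
#'   `constant` (flagged constant columns), and `membership_rule`.
#' @export
trait_correlations <- function(table,
                               method = c("pearson", "spearman",
                                          "kendall")) {
  method <- match.arg(method)
  x <- .trait_matrix(table)
  if (nrow(x) < 3L) stop("need at least 3 rows for correlation analysis")
  constant <- colnames(x)[apply(x, 2, stats::sd) == 0]
  r <- suppressWarnings(stats::cor(x, method = method))
  ranges <- list(A = c(-1, 0.09), B = c(0, 0.49),
                 C = c(0.5, 0.89), D = c(0.9, 1.0))
  off <- r; diag(off) <- NA
  categories <- lapply(ranges, function(rg) {
    hit <- apply(off, 1, function(v) any(v >= rg[1] & v <= rg[2],
                                         na.rm = TRUE))
    names(hit)[hit]
  })
  structure(list(method = method, matrix = r, categories = categories,
                 constant = constant,
                 membership_rule = paste(
                   "variable listed in a range iff >= 1 off-diagonal",
                   "correlation falls inside it (inferred rule)")),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Trait correlation analysis (", x$method, ")\n", sep = "")
  labs <- c(A = "A (-1..0.09)", B = "B (0..0.49)",
            C = "C (0.5..0.89)", D = "D (0.9..1.0)")
  for (k in names(x$categories)) {
    cat(labs[[k]], ": ", paste(x$categories[[k]], collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$constant)) {
    cat("constant columns flagged: ",
        paste(x$constant, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' KMO compares zero-order correlations with anti-image partial
#' correlations: `sum r_ij^2 / (sum r_ij^2 + sum u_ij^2)` over i != j,
#' where the partials `u_ij = -s_ij / sqrt(s_ii s_jj)` come from the
#' inverse correlation matrix `S = R^{-1}`.  Values near 1 indicate the
#' correlation structure is dominated by shared variance (sampling
#' adequate for factoring); with only two variables the partials equal
#' the correlations and KMO is exactly 0.5.
#'
#' @param table Feature table, or a correlation matrix directly.
#' @return Overall KMO statistic in \[0, 1\], with per-variable MSA
#'   values in attribute `"msa"`.
#' @export
kmo <- function(table) {
  R <- .as_cor(table)
  S <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; KMO undefined"))
  d <- 1 / sqrt(diag(S))
  U <- -S * outer(d, d)          # anti-image partial correlations
  diag(U) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- sum(R0^2); u2 <- sum(U^2)
  msa <- colSums(R0^2) / (colSums(R0^2) + colSums(U^2))
  out <- r2 / (r2 + u2)
  attr(out, "msa") <- msa
  out
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is the identity (variables
#' mutually uncorrelated, hence unsuitable for structure detection):
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param table Feature table with `n` rows and `p` trait columns.
#' @return List `(chi2, df, p_value, n, p)` of class
#'   `"bartlett_sphericity"`.
#' @export
bartlett_sphericity <- function(table) {
  x <- .trait_matrix(table)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("Bartlett's test needs more rows than variables")
  R <- stats::cor(x)
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix not positive definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 n = n, p = p),
            class = "bartlett_sphericity")
}

#' @export
print.bartlett_sphericity <- function(x, ...) {
  cat(sprintf(
    "Bartlett's test of sphericity: chi2 = %.3f, df = %d, p = %.4g\n",
    x$chi2, as.integer(x$df), x$p_value))
  invisible(x)
}

# linkage name -> stats::hclust method (within-groups handled separately)
.linkage_map <- c("between" = "average", "centroid" = "centroid",
                  "furthest" = "complete", "median" = "median",
                  "nearest" = "single", "ward" = "ward.D")

#' Linkage rules available for trait clustering
#' @export
linkage_methods <- c("between", "within", "centroid", "furthest",
                     "median", "nearest", "ward")

#' Agglomerative clustering of the traits
#'
#' Clusters the trait columns (variables as points, image instances as
#' coordinates) bottom-up on squared Euclidean distances, after z-score
#' normalization of each variable so all traits share one scale.  Emits
#' the stage-wise agglomeration schedule (merge pair, similarity
#' coefficient, stages at which each cluster previously appeared, next
#' stage) and the k-cluster membership, with cluster ids canonicalized by
#' first variable appearance so memberships are comparable across
#' linkage rules.
#'
#' Six linkage rules map onto [stats::hclust()] (squared distances in,
#' matching the convention under which centroid/median/Ward coefficients
#' are defined); the within-groups average rule, which measures a merge
#' by the mean of all pairwise distances inside the merged cluster, is
#' computed by a direct O(n^3) agglomerator (n = 23 variables).
#'
#' @param table Feature table.
#' @param linkage One of [linkage_methods]: `between` (average linkage
#'   across groups), `within` (average within merged group), `centroid`,
#'   `furthest` (complete), `median`, `nearest` (single), `ward`.
#' @param k Number of clusters to cut at (default 3).
#' @param scale. Z-score columns first (default `TRUE`; disable for raw
#'   hand-worked examples).
#' @return Object of class `"trait_clustering"`: list with `linkage`,
#'   `schedule` (`data.frame`), `membership` (named integer vector),
#'   `hclust` (the tree, when built via `stats::hclust`), `k`.
#' @export
trait_agglomerate <- function(table, linkage = "nearest", k = 3L,
                              scale. = TRUE) {
  linkage <- match.arg(linkage, linkage_methods)
  x <- .trait_matrix(table)
  p <- ncol(x)
  if (p < k) stop("fewer variables than clusters requested")
  if (scale.) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0   # constant traits: one point
  }
  pts <- t(x)                                  # variables as points
  d2 <- stats::dist(pts)^2                     # squared Euclidean
  if (linkage == "within") {
    res <- .within_groups_agglomerate(as.matrix(d2))
    merge <- res$merge; height <- res$height
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::as.dist(d2),
                        method = .linkage_map[[linkage]])
    merge <- hc$merge; height <- hc$height
  }
  schedule <- .schedule_from_merge(merge, height)
  membership <- .cut_merge(merge, k, labels = rownames(pts))
  membership <- .canonicalize_ids(membership)
  structure(list(linkage = linkage, schedule = schedule,
                 membership = membership, hclust = hc, k = as.integer(k)),
            class = "trait_clustering")
}

#' @export
print.trait_clustering <- function(x, ...) {
  cat("Agglomerative trait clustering (", x$linkage,
      " linkage, squared Euclidean, k = ", x$k, ")\n", sep = "")
  cat("Membership:\n")
  print(x$membership)
  cat("Last merges of the agglomeration schedule:\n")
  print(utils::tail(x$schedule, 4))
  invisible(x)
}

#' @export
plot.trait_clustering <- function(x, ...) {
  if (is.null(x$hclust)) {
    stop("no dendrogram available for the within-groups agglomerator")
  }
  plot(x$hclust, xlab = "trait", sub = "",
       main = paste0("Trait dendrogram (", x$linkage, " linkage)"), ...)
  invisible(x)
}

#' Compare cluster memberships across all seven linkage rules
#'
#' Runs [trait_agglomerate()] under every linkage in [linkage_methods]
#' and tabulates variable-by-linkage cluster ids (ids canonicalized by
#' first appearance, so agreement across columns is meaningful).
#'
#' @inheritParams trait_agglomerate
#' @return `data.frame`, one row per variable, one column per linkage.
#' @export
compare_linkages <- function(table, k = 3L, scale. = TRUE) {
  fits <- lapply(linkage_methods, function(l)
    trait_agglomerate(table, l, k = k, scale. = scale.))
  names(fits) <- linkage_methods
  out <- data.frame(variable = names(fits[[1L]]$membership))
  for (l in linkage_methods) out[[l]] <- unname(fits[[l]]$membership)
  out
}

# ---- internal helpers -------------------------------------------------

# pick the trait columns from a feature table (or any numeric matrix)
.trait_matrix <- function(table) {
  if (is.matrix(table)) {
    x <- table
  } else {
    stopifnot(is.data.frame(table))
    traits <- intersect(glcm_trait_names, names(table))
    if (length(traits) == 0L) {
      traits <- names(table)[vapply(table, is.numeric, TRUE)]
    }
    x <- as.matrix(table[traits])
  }
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

.as_cor <- function(table) {
  if (is.matrix(table) && nrow(table) == ncol(table) &&
      all(abs(diag(table) - 1) < 1e-12)) {
    return(table)
  }
  stats::cor(.trait_matrix(table))
}

# SPSS-style agglomeration schedule from an hclust-style merge matrix:
# clusters are labelled by their lowest original member index.
.schedule_from_merge <- function(merge, height) {
  n <- nrow(merge) + 1L
  lowest <- integer(nrow(merge))   # lowest original index per stage
  appear <- integer(n)             # last stage at which item's cluster formed
  sched <- data.frame(stage = seq_len(nrow(merge)), cluster1 = 0L,
                      cluster2 = 0L, coefficient = height,
                      first_appears1 = 0L, first_appears2 = 0L,
                      next_stage = 0L)
  members <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    side <- function(v) {
      if (v < 0) list(label = -v, first = 0L, mem = -v)
      else list(label = lowest[v], first = v, mem = members[[v]])
    }
    a <- side(merge[s, 1L]); b <- side(merge[s, 2L])
    c1 <- min(a$label, b$label); c2 <- max(a$label, b$label)
    if (a$label > b$label) { tmp <- a; a <- b; b <- tmp }
    sched$cluster1[s] <- c1; sched$cluster2[s] <- c2
    sched$first_appears1[s] <- a$first
    sched$first_appears2[s] <- b$first
    members[[s]] <- c(a$mem, b$mem)
    lowest[s] <- c1
  }
  # next stage at which the newly formed cluster is used again
  for (s in seq_len(nrow(merge))) {
    later <- which(merge[, 1L] == s | merge[, 2L] == s)
    sched$next_stage[s] <- if (length(later)) later[1L] else 0L
  }
  sched
}

# k-cluster membership from a merge matrix (first n-k merges applied)
.cut_merge <- function(merge, k, labels) {
  n <- nrow(merge) + 1L
  grp <- seq_len(n)
  cl_of_stage <- integer(nrow(merge))
  for (s in seq_len(n - k)) {
    ids <- vapply(1:2, function(j) {
      v <- merge[s, j]
      if (v < 0) grp[-v] else cl_of_stage[v]
    }, 0L)
    keep <- min(ids)
    grp[grp %in% ids] <- keep
    cl_of_stage[s] <- keep
  }
  stats::setNames(match(grp, unique(grp)), labels)
}

# first-appearance canonical ids: cluster of the first variable is 1, etc.
.canonicalize_ids <- function(membership) {
  stats::setNames(match(membership, unique(membership)),
                  names(membership))
}

# SPSS "within-groups" average linkage: merge the pair minimizing the
# mean pairwise distance within the union; naive O(n^3), n is small.
.within_groups_agglomerate <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))      # current cluster -> members
  stage_of <- rep(0L, n)               # merge-stage id per active cluster
  active <- seq_along(clusters)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- c(NA, NA); best_val <- Inf
    for (ai in seq_along(active)) {
      for (bi in seq_len(ai - 1L)) {
        u <- c(clusters[[active[ai]]], clusters[[active[bi]]])
        sub <- D[u, u]
        val <- sum(sub[upper.tri(sub)]) / choose(length(u), 2)
        if (val < best_val) { best_val <- val; best <- c(active[bi],
                                                         active[ai]) }
      }
    }
    enc <- function(ci) if (stage_of[ci] == 0L)
      -min(clusters[[ci]]) else stage_of[ci]
    e <- sort(c(enc(best[1L]), enc(best[2L])))
    merge[s, ] <- e
    height[s] <- best_val
    clusters[[best[1L]]] <- c(clusters[[best[1L]]],
                              clusters[[best[2L]]])
    stage_of[best[1L]] <- s
    active <- setdiff(active, best[2L])
  }
  list(merge = merge, height = height)
}
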