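#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain in one serializable
#' list: the analysis frame, the dynamic-threshold model, the GLCM
#' settings, the evaluation protocol, and the trait-analysis options.
#' Round-trips through YAML or JSON via [write_run_config()] /
#' [read_run_config()].
#'
#' @param frame Analysis frame `c(width, height)`.
#' @param threshold A [threshold_model()].
#' @param glcm A [glcm_config()].
#' @param eval_sizes,eval_cutoff,eval_seed Evaluation protocol
#'   (see [evaluate_segmenters()]); `eval_sizes = NULL` skips the
#'   sampling protocol and scores every image once.
#' @param cor_method Correlation method for the trait analysis.
#' @param k Cluster count for the linkage comparison.
#' @param luminance RGB collapse weights (recorded for provenance).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(frame = c(347L, 260L),
                       threshold = threshold_model(),
                       glcm = glcm_config(),
                       eval_sizes = NULL, eval_cutoff = 0.5,
                       eval_seed = 1L,
                       cor_method = "pearson", k = 3L,
                       luminance = .luma_weights) {
  structure(list(frame = as.integer(frame), threshold = threshold,
                 glcm = glcm, eval_sizes = eval_sizes,
                 eval_cutoff = eval_cutoff,
                 eval_seed = as.integer(eval_seed),
                 cor_method = cor_method, k = as.integer(k),
                 luminance = luminance),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$threshold <- unclass(x$threshold)
  x$glcm <- unclass(x$glcm)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  th <- x$threshold
  gl <- x$glcm
  run_config(frame = unlist(x$frame),
             threshold = threshold_model(th$p1, th$p2, th$p3, th$p4,
                                         th$clamp_lo, th$clamp_hi),
             glcm = glcm_config(gl$ng, unlist(gl$offset), gl$symmetric,
                                gl$epsilon, gl$corrections),
             eval_sizes = if (length(x$eval_sizes)) unlist(x$eval_sizes),
             eval_cutoff = x$eval_cutoff, eval_seed = x$eval_seed,
             cor_method = x$cor_method, k = x$k,
             luminance = unlist(x$luminance))
}

#' Run the full analysis pipeline over a dataset manifest
#'
#' Wires the stages end to end: load and standardize each image, segment
#' it with CFitK-means at its sequence index, extract the 23-trait GLCM
#' panel from the canopy, score every segmentation against its
#' ground-truth mask (plus, optionally, the random-sampling protocol),
#' and run the trait statistics (correlation categorization, KMO,
#' Bartlett sphericity, seven-linkage clustering).  All outputs are
#' plain CSV/PNG; given the same manifest, config and seed the outputs
#' are byte-identical across runs.
#'
#' Per-image failures (unreadable file, degenerate canopy) are isolated:
#' the image is recorded in the log and the run continues; the call
#' fails only if every image fails.
#'
#' @param manifest `data.frame` with columns `image_path`, `x`,
#'   `mask_path` (optional, enables evaluation), `condition`; or the
#'   path to such a CSV.
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return List of class `"pipeline_result"` with `features`
#'   (data.frame), `iou` (per-image scores or `NULL`), `report`
#'   ([evaluate_segmenters()] output or `NULL`), `analysis` (list:
#'   correlations, kmo, bartlett, linkages), `log` (character), and
#'   `paths` of the files written.
#' @export
run_pipeline <- function(manifest, config = run_config(), outdir) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0L) stop("empty manifest: nothing to process")
  stopifnot(all(c("image_path", "x") %in% names(manifest)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mask_dir <- file.path(outdir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  has_truth <- "mask_path" %in% names(manifest) &&
    all(nzchar(manifest$mask_path))
  items <- vector("list", nrow(manifest))
  iou_vals <- rep(NA_real_, nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    res <- tryCatch({
      img <- standardize_frame(load_image(row$image_path), config$frame)
      fit <- cfitkmeans(img, x = row$x, model = config$threshold,
                        frame = NULL)
      say("image %s: x=%g threshold=%.3f (raw %.3f) iters=%d canopy=%d",
          basename(row$image_path), row$x, as.numeric(fit$threshold),
          attr(fit$threshold, "raw"), fit$iterations, sum(fit$mask))
      mp <- file.path(mask_dir,
                      sub("\\.(png|tiff?)$", "_canopy.png",
                          basename(row$image_path), ignore.case = TRUE))
      write_mask(fit$mask, mp)
      if (has_truth) {
        truth <- standardize_frame(
          (load_image(row$mask_path) > 127) + 0L, config$frame,
          mask = TRUE)
        iou_vals[k] <- iou(truth, fit$mask)
      }
      list(image = img, mask = fit$mask,
           condition = if ("condition" %in% names(row)) row$condition
                       else NA_character_,
           id = basename(row$image_path))
    }, error = function(e) {
      say("image %s: FAILED (%s)", basename(row$image_path),
          conditionMessage(e))
      NULL
    })
    items[[k]] <- res
  }
  ok <- !vapply(items, is.null, TRUE)
  if (!any(ok)) stop("all images failed; see log")

  features <- extract_feature_table(items[ok], config$glcm)
  fpath <- file.path(outdir, "features.csv")
  utils::write.csv(features, fpath, row.names = FALSE)

  iou_df <- NULL; report <- NULL
  if (has_truth) {
    iou_df <- data.frame(id = vapply(items[ok], `[[`, "", "id"),
                         iou = iou_vals[ok])
    utils::write.csv(iou_df, file.path(outdir, "iou.csv"),
                     row.names = FALSE)
    say("mean IoU over %d images: %.4f", nrow(iou_df),
        mean(iou_df$iou))
    if (!is.null(config$eval_sizes)) {
      ds <- lapply(which(ok), function(k) {
        list(image = items[[k]]$image, x = manifest$x[k],
             truth = standardize_frame(
               (load_image(manifest$mask_path[k]) > 127) + 0L,
               config$frame, mask = TRUE))
      })
      algos <- list(
        cfitkmeans = function(img, x)
          cfitkmeans(img, x, model = config$threshold, frame = NULL)$mask,
        gst = function(img, x) baseline_segment(img, "gst"),
        gat = function(img, x) baseline_segment(img, "gat"),
        kmeans4 = function(img, x) baseline_segment(img, "kmeans4"))
      report <- evaluate_segmenters(algos, ds,
                                    sizes = config$eval_sizes,
                                    cutoff = config$eval_cutoff,
                                    seed = config$eval_seed)
      rp <- data.frame(algorithm = rownames(report$counts),
                       report$counts,
                       avg_iou_percent = report$avg_iou_percent)
      utils::write.csv(rp, file.path(outdir, "report.csv"),
                       row.names = FALSE)
    }
  }

  analysis <- NULL
  if (nrow(features) >= max(3L, config$k + 1L)) {
    cors <- trait_correlations(features, config$cor_method)
    linkages <- compare_linkages(features, k = config$k)
    km <- tryCatch(kmo(features), error = function(e) {
      say("KMO failed: %s", conditionMessage(e)); NA_real_ })
    bt <- tryCatch(bartlett_sphericity(features), error = function(e) {
      say("Bartlett failed: %s", conditionMessage(e)); NULL })
    utils::write.csv(linkages, file.path(outdir, "linkages.csv"),
                     row.names = FALSE)
    if (!is.na(km)) say("KMO = %.4f", as.numeric(km))
    if (!is.null(bt)) say("Bartlett chi2 = %.3f df = %d p = %.4g",
                          bt$chi2, as.integer(bt$df), bt$p_value)
    analysis <- list(correlations = cors, kmo = km, bartlett = bt,
                     linkages = linkages)
  } else {
    say("trait analysis skipped: %d usable rows", nrow(features))
  }
  writeLines(log, file.path(outdir, "pipeline.log"))
  structure(list(features = features, iou = iou_df, report = report,
                 analysis = analysis, log = log,
                 paths = list(outdir = outdir, features = fpath)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", nrow(x$features), "images ->",
      x$paths$outdir, "\n")
  if (!is.null(x$iou)) {
    cat(sprintf("  mean IoU vs ground truth: %.4f\n", mean(x$iou$iou)))
  }
  if (!is.null(x$analysis)) {
    cat(sprintf("  KMO = %.4f; Bartlett p = %.4g\n",
                as.numeric(x$analysis$kmo),
                x$analysis$bartlett$p_value))
  }
  invisible(x)
}
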