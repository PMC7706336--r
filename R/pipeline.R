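#' Run configuration
#'
#' Bundles the site geometry and pipeline constants. The pipeline defaults are
#' the canonical ones: 1000 px patches with 50% overlap, duplicate
#' elimination at 0.75 overlap fraction, 0.80 confidence cut, 0.5 IOU for
#' evaluation matching and 0.2 IOU for detector non-maximum suppression.
#'
#' @param row_spacing Row spacing, m (default 0.17).
#' @param ground_resolution Ground resolution, mm/pixel (default 0.18).
#' @param sampled_area_m2 Sampled ground area per plot, m^2 (`NA` to derive
#'   from image footprints).
#' @param patch_size,overlap,merge_overlap,score_threshold,iou_eval,nms_iou
#'   Pipeline constants (see [run_detection_pipeline()], [match_detections()]
#'   and [detector_config()]).
#' @param seed Integer seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(row_spacing = 0.17, ground_resolution = 0.18,
                       sampled_area_m2 = NA_real_,
                       patch_size = 1000, overlap = 0.5,
                       merge_overlap = 0.75, score_threshold = 0.80,
                       iou_eval = 0.5, nms_iou = 0.2, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys are the arguments of [run_config()], optionally nested
#' under `site` and `pipeline` blocks; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading config files requires the `yaml` package.")
  }
  raw <- yaml::read_yaml(path)
  flat <- c(raw[!names(raw) %in% c("site", "pipeline")],
            raw$site %||% list(), raw$pipeline %||% list())
  known <- names(formals(run_config))
  unknown <- setdiff(names(flat), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", "), "."))
  }
  do.call(run_config, flat)
}

#' Detect stems over a set of images
#'
#' Runs [run_detection_pipeline()] on every image, tagging each detection
#' with its `image_id` (the file name). An unreadable image is reported as a
#' warning and skipped so one corrupt file does not abort a field campaign.
#'
#' @param image_paths Character vector of image files.
#' @param config A [run_config()].
#' @param cfg [detector_config()] for the ring detector.
#' @param out Optional path to also write the detections (CSV or JSON).
#' @return Detection tibble with an `image_id` column.
#' @export
pipeline_detect <- function(image_paths, config = run_config(),
                            cfg = detector_config(), out = NULL) {
  dets <- purrr::map_dfr(image_paths, function(p) {
    img <- tryCatch(read_image(p), error = function(e) {
      warn(paste0("Skipping unreadable image ", p, ": ", conditionMessage(e)))
      NULL
    })
    if (is.null(img)) return(NULL)
    d <- run_detection_pipeline(
      img, cfg = cfg,
      patch_size = config$patch_size, overlap = config$overlap,
      merge_overlap = config$merge_overlap,
      score_threshold = config$score_threshold
    )
    if (nrow(d) > 0) d$image_id <- basename(p)
    d
  })
  if (!is.null(out) && nrow(dets) > 0) write_detections(dets, out)
  dets
}

#' Aggregate per-stem measurements into plot traits
#'
#' Groups a measurement table by `plot_id` and applies [plot_traits()] per
#' plot, joining sampled areas and (optionally) plant heights. Plots absent
#' from the heights table get traits without biovolume, with a warning.
#'
#' @param measurements Per-stem measurement table with a `plot_id` column
#'   (see [measure_stems()]).
#' @param areas Data frame `plot_id`, `sampled_area_m2`.
#' @param heights Optional data frame `plot_id`, `height_m`.
#' @return Plot traits tibble, one row per plot.
#' @export
pipeline_traits <- function(measurements, areas, heights = NULL) {
  measurements <- as_tibble(measurements)
  if (!"plot_id" %in% names(measurements)) abort("`measurements` needs a `plot_id` column.")
  areas <- as_tibble(areas)
  ids <- unique(measurements$plot_id)
  no_height <- character(0)
  out <- purrr::map_dfr(ids, function(id) {
    m <- measurements[measurements$plot_id == id, ]
    a <- areas$sampled_area_m2[match(id, areas$plot_id)]
    if (is.na(a)) abort(paste0("No sampled area for plot ", id, "."))
    h <- NA_real_
    if (!is.null(heights)) {
      h <- heights$height_m[match(id, heights$plot_id)]
      if (is.na(h)) no_height <<- c(no_height, id)
    }
    plot_traits(m, area = a, height = h %||% NA_real_, plot_id = id)
  })
  if (length(no_height) > 0) {
    warn(paste0("No height for plot(s) ", paste(no_height, collapse = ", "),
                "; biovolume not computed there."))
  }
  out
}

#' Evaluate pipeline output against reference data
#'
#' One entry point for the package's evaluation statistics.
#'
#' * `mode = "detection"`: `predicted` is a detection table and `reference` a
#'   labeled box table (both optionally with an `image_id` column; matching
#'   is within image). Returns counts plus precision/recall/bias.
#' * `mode = "density"`, `"ears"` or `"agb"`: both inputs are data frames with
#'   `plot_id` and a value column (`stem_density`, `ear_density` or `agb`);
#'   returns the regression metrics of predicted vs reference.
#' * `mode = "heritability"`: `predicted` is a data frame with `genotype` and
#'   the column named by `trait`; returns the variance components.
#'
#' @param predicted,reference Data frames as described per mode.
#' @param mode Evaluation mode.
#' @param iou_threshold IOU threshold for detection matching (default 0.5).
#' @param trait Value column for density/ears/agb/heritability modes.
#' @return A tibble of metrics (or a `heritability_fit`).
#' @export
pipeline_evaluate <- function(predicted, reference = NULL,
                              mode = c("detection", "density", "ears", "agb",
                                       "heritability"),
                              iou_threshold = 0.5, trait = NULL) {
  mode <- match.arg(mode)
  predicted <- as_tibble(predicted)
  if (mode == "detection") {
    reference <- as_tibble(reference)
    p_img <- "image_id" %in% names(predicted)
    r_img <- "image_id" %in% names(reference)
    imgs <- union(if (p_img) unique(predicted$image_id) else "all",
                  if (r_img) unique(reference$image_id) else "all")
    counts <- purrr::map_dfr(imgs, function(im) {
      p <- if (p_img) predicted[predicted$image_id == im, ] else predicted
      r <- if (r_img) reference[reference$image_id == im, ] else reference
      match_detections(p, r, iou_threshold)
    })
    return(detection_metrics(tibble(tp = sum(counts$tp), fp = sum(counts$fp),
                                    fn = sum(counts$fn))))
  }
  if (mode == "heritability") {
    trait <- trait %||% "stem_density"
    return(heritability(predicted$genotype, predicted[[trait]]))
  }
  trait <- trait %||% switch(mode, density = "stem_density",
                             ears = "ear_density", agb = "agb")
  reference <- as_tibble(reference)
  joined <- dplyr::inner_join(
    predicted[, c("plot_id", trait)], reference[, c("plot_id", trait)],
    by = "plot_id", suffix = c("_pred", "_ref")
  )
  regression_metrics(joined[[paste0(trait, "_pred")]],
                     joined[[paste0(trait, "_ref")]])
}
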