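#' Read stem detections from CSV or JSON
#'
#' Reads externally produced detections (e.g. from a CNN run elsewhere) in the
#' package's exchange dialect: columns `plot_id`, `image_id`, `xmin`, `ymin`,
#' `xmax`, `ymax`, `score`, with coordinates in parent-image pixels. The JSON
#' dialect is an array of objects with the same fields. `plot_id` and
#' `image_id` are optional; any other column is rejected so silent schema
#' drift cannot pass unnoticed.
#'
#' @param path Path to the detections file.
#' @param format `"csv"`, `"json"`, or `"auto"` (default) to infer from the
#'   file extension.
#' @param image_width,image_height Optional parent-image dimensions in pixels;
#'   when given, boxes reaching outside the image are rejected.
#' @return A detection tibble (see [as_boxes()] for the box convention).
#' @export
read_detections <- function(path, format = c("auto", "csv", "json"),
                            image_width = NULL, image_height = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
  if (nrow(df) == 0 && ncol(df) == 0) {
    abort(paste0("No columns found in ", path, "."))
  }
  allowed <- c("plot_id", "image_id", "xmin", "ymin", "xmax", "ymax", "score")
  unknown <- setdiff(names(df), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown column(s) in ", path, ": ",
                 paste(unknown, collapse = ", "), "."))
  }
  need <- c("xmin", "ymin", "xmax", "ymax", "score")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in ", path, ": ",
                 paste(missing, collapse = ", "), "."))
  }
  if (nrow(df) == 0) return(as_tibble(df))
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      abort(paste0("Column `", col, "` in ", path, " is not numeric (first bad row: ",
                   which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1], ")."))
    }
    if (anyNA(df[[col]])) {
      abort(paste0("Missing value in column `", col, "` at row ",
                   which(is.na(df[[col]]))[1], " of ", path, "."))
    }
  }
  bad <- which(!(df$xmax > df$xmin & df$ymax > df$ymin))
  if (length(bad) > 0) {
    abort(paste0("Degenerate box (xmax <= xmin or ymax <= ymin) at row ",
                 bad[1], " of ", path, "."))
  }
  bad <- which(df$score < 0 | df$score > 1)
  if (length(bad) > 0) {
    abort(paste0("Score outside [0, 1] at row ", bad[1], " of ", path, "."))
  }
  if (!is.null(image_width) && !is.null(image_height)) {
    bad <- which(df$xmin < 0 | df$ymin < 0 |
                   df$xmax > image_width | df$ymax > image_height)
    if (length(bad) > 0) {
      abort(paste0("Box outside the ", image_width, "x", image_height,
                   " image at row ", bad[1], " of ", path, "."))
    }
  }
  as_tibble(df)
}

#' Write detections in the CSV or JSON exchange dialect
#'
#' @param dets Detection table.
#' @param path Output path; the extension selects CSV or JSON.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path) {
  dets <- as_tibble(dets)
  cols <- intersect(c("plot_id", "image_id", "xmin", "ymin", "xmax", "ymax", "score"),
                    names(dets))
  dets <- dets[, cols]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(dets, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    readr::write_csv(dets, path)
  }
  invisible(path)
}

#' Read an RGB or grayscale image
#'
#' Supports PNG (always), and TIFF/JPEG when the corresponding reader package
#' is installed. Values are returned on the 8-bit scale `[0, 255]` as a
#' `height x width` matrix (grayscale) or `height x width x 3` array (RGB);
#' an alpha channel is dropped.
#'
#' @param path Image path; format inferred from the extension.
#' @return Numeric matrix or array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("Reading TIFF requires the `tiff` package.")
      }
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort("Reading JPEG requires the `jpeg` package.")
      }
      jpeg::readJPEG(path)
    },
    abort(paste0("Unsupported image extension: .", ext, "."))
  )
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
  img * 255
}

#' Write an image as PNG
#'
#' @param img Matrix (grayscale) or `height x width x 3` array (RGB) with
#'   values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}
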