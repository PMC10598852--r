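#' Read and write detection labels in normalized text format
#'
#' One line per box: `class x_center y_center width height`, all four
#' geometry fields normalized to `[0, 1]` relative to the image size (the
#' format used by single-stage detector training tools). Conversion to and
#' from pixel boxes uses the image dimensions; pixel boxes are 0-based and
#' half-open.
#'
#' @param path Label file path.
#' @param width,height Image size in pixels.
#' @return `read_yolo_labels()` returns a data frame with columns
#'   `class_id, x_min, z_min, x_max, z_max` (integer pixels).
#' @export
read_yolo_labels <- function(path, width, height) {
  stopf(file.exists(path), "label file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(class_id = integer(), x_min = integer(), z_min = integer(),
                      x_max = integer(), z_max = integer()))
  }
  parts <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  stopf(all(lengths(parts) == 5), "each label line must hold 5 fields")
  m <- do.call(rbind, parts)
  stopf(all(m[, 2:5] >= 0 & m[, 2:5] <= 1), "normalized fields must lie in [0, 1]")
  xc <- m[, 2] * width; zc <- m[, 3] * height
  w <- m[, 4] * width;  h <- m[, 5] * height
  data.frame(class_id = as.integer(m[, 1]),
             x_min = pmax(0L, as.integer(round(xc - w / 2))),
             z_min = pmax(0L, as.integer(round(zc - h / 2))),
             x_max = pmin(as.integer(width), as.integer(round(xc + w / 2))),
             z_max = pmin(as.integer(height), as.integer(round(zc + h / 2))))
}

#' @rdname read_yolo_labels
#' @param boxes Data frame with columns `x_min, z_min, x_max, z_max` and
#'   optionally `class_id`.
#' @export
write_yolo_labels <- function(boxes, width, height, path) {
  class_id <- if ("class_id" %in% names(boxes)) boxes$class_id else 0L
  xc <- (boxes$x_min + boxes$x_max) / 2 / width
  zc <- (boxes$z_min + boxes$z_max) / 2 / height
  w <- (boxes$x_max - boxes$x_min) / width
  h <- (boxes$z_max - boxes$z_min) / height
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", class_id, xc, zc, w, h)
  writeLines(lines, path)
  invisible(path)
}
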