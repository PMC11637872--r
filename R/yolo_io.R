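# Reading and writing the standard YOLO label dialect:
# one text file per image, one line per box, "class cx cy w h",
# all coordinates normalized to [0,1].

#' Read a YOLO label file
#'
#' Parses one `class cx cy w h` line per box. Malformed lines raise a parse
#' error naming the line number; out-of-range coordinates raise a validation
#' error.
#'
#' @param path Path to the label file. An empty file yields zero boxes.
#' @return A box `data.frame` (see [bbox()]).
#' @export
read_yolo_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_boxes())
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(fields) != 5L) {
      stop("parse error at line ", i, " of ", path,
           ": expected 5 fields, got ", length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) stop("parse error at line ", i, " of ", path,
                          ": non-numeric field")
    if (vals[1] != floor(vals[1]) || vals[1] < 0) {
      stop("parse error at line ", i, " of ", path, ": class id must be a ",
           "non-negative integer")
    }
    vals
  })
  m <- do.call(rbind, parsed)
  boxes <- data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                      w = m[, 4], h = m[, 5])
  tryCatch(validate_boxes(boxes),
           error = function(e) stop("validation error in ", path, ": ",
                                    conditionMessage(e)))
  boxes
}

#' Write a YOLO label file
#'
#' @param boxes A valid box `data.frame`.
#' @param path Output path. Coordinates are written with 6 decimal places,
#'   so a write/read round trip is exact to 1e-6.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(boxes, path) {
  validate_boxes(boxes)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   boxes$class_id, boxes$cx, boxes$cy, boxes$w, boxes$h)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("I/O failure writing labels to ", path)
  invisible(path)
}
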