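# Plain-text interchange: GMT set databases, TSV tables, PNG images.

#' Read a GMT set database
#'
#' Tab-separated: set name, description, then members (one set per line).
#'
#' @param path file path.
#' @return named list of character member vectors (duplicates removed).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(ln, 1, 60), call. = FALSE)
    out[[f[1]]] <- unique(f[-(1:2)])
  }
  out
}

#' Write a GMT set database
#'
#' @param db named list of character vectors.
#' @param path output path.
#' @param description description column (recycled).
#' @export
write_gmt <- function(db, path, description = "na") {
  stopifnot(length(db) > 0, !is.null(names(db)))
  lines <- vapply(names(db), function(nm) {
    paste(c(nm, description, db[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as TSV (deterministic, UTF-8, header row)
#'
#' @param x data.frame.
#' @param path output path.
#' @param comment optional character vector written as leading `#` lines.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an image or mask as PNG
#'
#' RGB arrays (rows x cols x 3, values in \[0,1\]) become 8-bit RGB PNG;
#' logical masks become single-channel 0/255 PNG; integer label maps become
#' 16-bit single-channel PNG.
#'
#' @param x array, logical matrix or integer label matrix.
#' @param path output path.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) {
    png::writePNG(x * 1, path)
  } else if (is.integer(x) || (is.matrix(x) && all(x == round(x)))) {
    # labels > 255 do not fit one 8-bit channel: split into low/high bytes
    if (max(x) > 65535) stop("label map exceeds 16-bit range", call. = FALSE)
    enc <- array(0, dim = c(nrow(x), ncol(x), 3))
    enc[, , 1] <- (x %% 256) / 255
    enc[, , 2] <- (x %/% 256) / 255
    png::writePNG(enc, path)
  } else {
    png::writePNG(x, path)
  }
  invisible(path)
}

#' Read a label-map PNG written by [write_image_png()]
#'
#' @param path file path.
#' @return integer matrix.
#' @export
read_label_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 2) return(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)))
  lo <- round(m[, , 1] * 255); hi <- round(m[, , 2] * 255)
  matrix(as.integer(lo + 256 * hi), dim(m)[1], dim(m)[2])
}
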