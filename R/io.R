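# Readers and writers for the interchange formats: TIFF/PNG images,
# landmark CSV, punch CSV, deformation-field TIFF, and abundance TSV
# with companion sample metadata.

#' Read a grayscale image from TIFF or PNG
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size pixel size in um; if `NULL` for a TIFF, the file's
#'   resolution tags are used when present.
#' @return raw numeric matrix/array plus the pixel size; pass through
#'   [preprocess()] before registration.
#' @export
read_gray_image <- function(path, pixel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = is.null(pixel_size))
    if (is.null(pixel_size)) {
      xr <- attr(img, "x.resolution"); unit <- attr(img, "resolution.unit")
      if (!is.null(xr) && xr > 0) {
        per_um <- switch(as.character(unit %||% "inch"),
                         cm = xr / 1e4, inch = xr / 25400, xr / 1e4)
        pixel_size <- 1 / per_um
      } else stop_invalid("no resolution tag in ", path,
                          "; supply pixel_size explicitly")
    }
  } else if (ext == "png") {
    if (is.null(pixel_size))
      stop_invalid("pixel_size must be supplied for PNG input")
    img <- png::readPNG(path)
  } else stop_invalid("unsupported image format: .", ext)
  list(pixels = img, pixel_size = pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read paired landmarks from CSV
#'
#' The CSV stores pixel coordinates (`x_pre, y_pre, x_post, y_post`);
#' the per-image pixel sizes convert them to um.
#'
#' @param path CSV path.
#' @param pre_pixel_size,post_pixel_size pixel sizes, um/pixel.
#' @return data.frame of landmark pairs in um.
#' @export
read_landmarks <- function(path, pre_pixel_size, post_pixel_size) {
  lm <- read.csv(path)
  need <- c("x_pre", "y_pre", "x_post", "y_post")
  if (!all(need %in% names(lm)))
    stop_invalid("landmark CSV needs columns ", paste(need, collapse = ", "))
  data.frame(x_pre = lm$x_pre * pre_pixel_size,
             y_pre = lm$y_pre * pre_pixel_size,
             x_post = lm$x_post * post_pixel_size,
             y_post = lm$y_post * post_pixel_size)
}

#' Write / read a deformation field
#'
#' The dense field travels as a plain-text TSV, one row per tissue-mask
#' pixel (`row`, `col`, 1-based grid indices; `dx_um`, `dy_um`), with the
#' grid dimensions and pixel size in `#`-comment header lines.  The
#' format round-trips exactly and stays human-inspectable.
#'
#' @param field a [deformation_field()].
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_deformation_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# deformation_field nrow=%d ncol=%d pixel_size_um=%.10g",
            nrow(field$dx), ncol(field$dx), field$pixel_size),
    "row\tcol\tdx_um\tdy_um"), con)
  pix <- which(field$mask)
  tab <- data.frame(row = (pix - 1L) %% nrow(field$dx) + 1L,
                    col = (pix - 1L) %/% nrow(field$dx) + 1L,
                    dx_um = field$dx[pix], dy_um = field$dy[pix])
  utils::write.table(format(tab, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_deformation_field
#' @export
read_deformation_field <- function(path) {
  hdr <- readLines(path, n = 1L)
  gm <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    if (!length(m)) return(NA_real_)
    as.numeric(sub(".*=", "", m))
  }
  nr <- as.integer(gm("nrow")); nc <- as.integer(gm("ncol"))
  psz <- gm("pixel_size_um")
  if (anyNA(c(nr, nc, psz)))
    stop_invalid("malformed deformation-field header in ", path)
  tab <- read.delim(path, skip = 1L)
  dx <- matrix(NA_real_, nr, nc); dy <- dx
  mask <- matrix(FALSE, nr, nc)
  idx <- (tab$col - 1L) * nr + tab$row
  dx[idx] <- tab$dx_um; dy[idx] <- tab$dy_um; mask[idx] <- TRUE
  structure(list(dx = dx, dy = dy, mask = mask, pixel_size = psz),
            class = "deformation_field")
}

#' Read an abundance matrix from TSV files
#'
#' The intensity TSV has the protein id in the first column and one
#' column per sample; empty fields or `NA` mark missing values.  The
#' metadata TSV has one row per sample (`sample_id`, `genotype`, `age`,
#' `region`, `mouse`, `batch`, `is_pooled_qc`).
#'
#' @param matrix_path intensity TSV path.
#' @param metadata_path sample metadata TSV path; if `NULL`, minimal
#'   metadata is synthesized from the column names.
#' @return an [abundance_matrix()].
#' @export
read_abundance_tsv <- function(matrix_path, metadata_path = NULL) {
  tab <- read.delim(matrix_path, check.names = FALSE,
                    na.strings = c("", "NA"))
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- as.character(tab[[1]])
  meta <- if (!is.null(metadata_path)) read.delim(metadata_path)
          else data.frame(sample_id = colnames(x))
  if (!is.null(meta$is_pooled_qc))
    meta$is_pooled_qc <- as.logical(meta$is_pooled_qc)
  abundance_matrix(x, meta)
}

#' Write an abundance matrix (and its metadata) to TSV
#'
#' @param am an [abundance_matrix()].
#' @param matrix_path intensity TSV path.
#' @param metadata_path optional metadata TSV path.
#' @param id_column name of the protein id column (default `protein_id`).
#' @return `matrix_path`, invisibly.
#' @export
write_abundance_tsv <- function(am, matrix_path, metadata_path = NULL,
                                id_column = "protein_id") {
  tab <- data.frame(rownames(am$intensities), am$intensities,
                    check.names = FALSE)
  names(tab)[1] <- id_column
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(metadata_path))
    utils::write.table(am$samples, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Read a punch annotation table from CSV
#'
#' Pixel coordinates and diameters are converted to um with the
#' post-expansion pixel size.
#'
#' @param path CSV with columns `punch_id`, `sample_id`, `x_px`, `y_px`,
#'   `diameter_px` and optionally `region`, `replicate`.
#' @param pixel_size post-image pixel size, um/pixel.
#' @return data.frame with coordinates in um, ready for
#'   [place_punches()].
#' @export
read_punches <- function(path, pixel_size) {
  p <- read.csv(path)
  need <- c("punch_id", "sample_id", "x_px", "y_px", "diameter_px")
  if (!all(need %in% names(p)))
    stop_invalid("punch CSV needs columns ", paste(need, collapse = ", "))
  p$x_um <- p$x_px * pixel_size
  p$y_um <- p$y_px * pixel_size
  p$diameter_um <- p$diameter_px * pixel_size
  p
}
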