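# Integer label masks: background 0, each positive integer one nucleus.
# Boundaries are extracted as sub-pixel marching-squares contours so that
# perimeter estimates do not inherit the full pixel staircase bias.

#' Read nucleus shapes from an integer label mask
#'
#' Accepts a 2-D integer matrix or a path to a TIFF/PNG file holding one.
#' Each positive label becomes one shape via a marching-squares contour at
#' iso-level 0.5 on the per-label binary image, with vertices at sub-pixel
#' positions, followed by vertex decimation (perpendicular-deviation
#' tolerance 0.05 pixel). Labels touching the image border are incomplete
#' nuclei and are excluded by default.
#'
#' @param mask integer matrix, or path to a TIFF or PNG file.
#' @param pixel_size micrometres per pixel (isotropic).
#' @param include_border keep labels touching the image border
#'   (default `FALSE`).
#' @param case_id case identifier attached to every shape.
#' @param cell_class cell class attached to every shape.
#' @return List of [nucleus_shape()] objects, one per retained label, with
#'   `nucleus_id` `"label_<k>"`.
#' @export
read_label_mask <- function(mask, pixel_size, include_border = FALSE,
                            case_id = "unknown_case", cell_class = "tumour") {
  m <- if (is.character(mask)) .read_mask_file(mask) else mask
  if (!is.matrix(m)) stop("mask must be a 2-D image")
  if (is.double(m)) {
    if (any(abs(m - round(m)) > 1e-9)) {
      stop("mask must contain integer labels")
    }
    m <- round(m)
  }
  storage.mode(m) <- "integer"
  if (any(m < 0L)) stop("mask labels must be non-negative")
  labels <- sort(setdiff(unique(as.vector(m)), 0L))
  n_border <- 0L
  shapes <- list()
  for (lab in labels) {
    hit <- m == lab
    rows <- which(rowSums(hit) > 0)
    cols <- which(colSums(hit) > 0)
    touches <- min(rows) == 1L || max(rows) == nrow(m) ||
      min(cols) == 1L || max(cols) == ncol(m)
    if (touches && !include_border) {
      n_border <- n_border + 1L
      next
    }
    v <- label_contour(hit)
    if (is.null(v)) next
    shapes[[length(shapes) + 1L]] <- nucleus_shape(
      v * pixel_size,
      nucleus_id = paste0("label_", lab),
      case_id = case_id, cell_class = cell_class,
      source_pixel_size = pixel_size
    )
  }
  if (n_border > 0L) {
    message(n_border, " border-touching label(s) excluded")
  }
  shapes
}

# Marching-squares outer contour of a binary matrix, in (x = column,
# y = row) pixel coordinates, decimated at 0.05 px. Returns NULL for labels
# too small to yield a polygon.
label_contour <- function(hit, decimate_tol = 0.05) {
  z <- matrix(0, nrow(hit) + 2L, ncol(hit) + 2L)
  z[2:(nrow(hit) + 1L), 2:(ncol(hit) + 1L)] <- hit * 1
  cl <- grDevices::contourLines(
    x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z, levels = 0.5
  )
  if (!length(cl)) return(NULL)
  # several loops can appear for non-convex labels with enclosed background;
  # keep the outer (largest-area) loop
  areas <- vapply(cl, function(cc) {
    abs(signed_area(cbind(cc$x, cc$y)))
  }, numeric(1))
  cc <- cl[[which.max(areas)]]
  v <- cbind(cc$y - 1, cc$x - 1)  # back to (x = col, y = row), unpad
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(v) < 3L) return(NULL)
  decimate_ring(v, decimate_tol)
}

# Drop vertices whose perpendicular deviation from the chord joining their
# neighbours is below tol; repeats until stable.
decimate_ring <- function(v, tol) {
  repeat {
    n <- nrow(v)
    if (n <= 4L) return(v)
    prv <- c(n, seq_len(n - 1L))
    nxt <- c(seq_len(n)[-1L], 1L)
    ex <- v[nxt, 1L] - v[prv, 1L]
    ey <- v[nxt, 2L] - v[prv, 2L]
    len <- sqrt(ex^2 + ey^2)
    dev <- abs((v[, 1L] - v[prv, 1L]) * ey - (v[, 2L] - v[prv, 2L]) * ex) /
      pmax(len, .Machine$double.eps)
    drop <- dev < tol
    if (!any(drop)) return(v)
    # never drop two adjacent vertices in one pass
    drop[drop & c(FALSE, drop[-n])] <- FALSE
    if (sum(!drop) < 3L) return(v)
    v <- v[!drop, , drop = FALSE]
  }
}

.read_mask_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    m <- png::readPNG(path)
    m <- round(m * 65535)
  } else {
    stop("unsupported mask format: '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Write an integer label mask to a 16-bit grayscale TIFF
#'
#' @param mask integer matrix of labels (0 = background, max 65535).
#' @param path output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  m <- as.matrix(mask)
  if (max(m) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
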