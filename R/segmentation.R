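#' Convert between RGB rasters and point sets
#'
#' An image raster is an H x W x 3 array of integers in [0, 255]. Pixels are
#' flattened row-major (row 1 left to right, then row 2, ...) into an
#' N x 3 point set with N = H*W and columns `red`, `green`, `blue`.
#'
#' @param img H x W x 3 numeric array with values in [0, 255].
#' @return `image_to_points()` returns an N x 3 tibble.
#' @export
#' @examples
#' img <- gen_synthetic_image(6, 8, k = 3)
#' pts <- image_to_points(img)
#' identical(points_to_image(pts, 6, 8), img)
image_to_points <- function(img) {
  check_raster(img)
  tibble(
    red   = as.vector(t(img[, , 1])),
    green = as.vector(t(img[, , 2])),
    blue  = as.vector(t(img[, , 3]))
  )
}

#' @param points N x 3 data frame or matrix of pixel colours, row-major.
#' @param height,width Raster dimensions; `height * width` must equal
#'   `nrow(points)`.
#' @rdname image_to_points
#' @export
points_to_image <- function(points, height, width) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 3, nrow(pts) == height * width)
  img <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pts[, ch], height, width, byrow = TRUE)
  storage.mode(img) <- "double"
  img
}

check_raster <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort("image must be an H x W x 3 array")
  }
  if (min(img) < 0 || max(img) > 255) abort("pixel values must lie in [0, 255]")
  invisible(img)
}

#' Colour-based image segmentation by medoid clustering
#'
#' Clusters the pixels of an RGB image into `k` colour groups with
#' [pam_cluster()] and replaces every pixel by its cluster medoid's colour,
#' so the output palette has at most `k` colours and every output colour is
#' an input pixel colour. With `pes > 1` the parallel engine is used; its
#' output raster is byte-identical to the sequential one.
#'
#' @inheritParams pam_cluster
#' @param img H x W x 3 array of integers in [0, 255].
#' @return A list of class `pam_segmentation`: `image` (segmented raster),
#'   `fit` (the underlying `pam_fit`), `height`, `width`.
#' @export
#' @examples
#' img <- gen_synthetic_image(20, 24, k = 3)
#' seg <- segment_image(img, k = 3)
#' compute_ssim(seg$image, img) # 1: flat regions are reproduced exactly
segment_image <- function(img, k, pes = 1L, metric = "euclidean",
                          init = c("build", "random"), seed = 1L,
                          max_iter = 100L) {
  check_raster(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (k > h * w) abort("k exceeds the number of pixels")
  pts <- image_to_points(img)
  fit <- pam_cluster(pts, k = k, pes = pes, metric = metric, init = init,
                     seed = seed, max_iter = max_iter)
  palette <- fit$points[fit$medoid_ids, , drop = FALSE]
  seg_pts <- palette[fit$tags, , drop = FALSE]
  out <- points_to_image(seg_pts, h, w)
  structure(list(image = out, fit = fit, height = h, width = w),
            class = "pam_segmentation")
}

#' @export
print.pam_segmentation <- function(x, ...) {
  cat(sprintf("<pam_segmentation> %d x %d image, k = %d, P = %d, cost %.6g\n",
              x$height, x$width, x$fit$k, x$fit$pes, x$fit$cost))
  cat(sprintf("  palette: %d distinct output colour(s)\n",
              nrow(unique(image_to_points(x$image)))))
  invisible(x)
}

#' @method autoplot pam_segmentation
#' @export
autoplot.pam_segmentation <- function(object, ...) {
  pts <- image_to_points(object$image)
  df <- tibble(
    x = rep(seq_len(object$width), times = object$height),
    y = rep(seq_len(object$height), each = object$width),
    fill = grDevices::rgb(pts$red, pts$green, pts$blue, maxColorValue = 255)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Read and write raster images
#'
#' Lossless formats are supported natively: PNG (via the png package) and
#' plain/raw PPM (P3/P6). JPEG input is accepted through EBImage when
#' available, with a warning, because lossy compression artifacts change the
#' clustering. Images are returned as H x W x 3 arrays on the [0, 255]
#' integer scale.
#'
#' @param path File path; format from the extension (`.png`, `.ppm`,
#'   `.jpg`/`.jpeg` read-only).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
    if (dim(arr)[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]
    img <- round(arr * 255)
  } else if (ext %in% c("ppm", "pgm")) {
    img <- read_ppm(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("JPEG input requires the EBImage package")
    }
    warn("JPEG is lossy; compression artifacts will change the clustering")
    arr <- EBImage::imageData(EBImage::readImage(path))
    img <- round(aperm(arr, c(2, 1, 3)) * 255)
  } else {
    abort(sprintf("unsupported image format '.%s' (use png or ppm)", ext))
  }
  check_raster(img)
  img
}

#' @param img H x W x 3 array on the [0, 255] scale.
#' @rdname read_image
#' @export
write_image <- function(img, path) {
  check_raster(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext == "ppm") {
    write_ppm(img, path)
  } else {
    abort(sprintf("unsupported output format '.%s' (use png or ppm)", ext))
  }
  invisible(path)
}

# Minimal PPM/PGM reader: plain (P2/P3) and raw (P5/P6), maxval <= 255.
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") abort("unexpected end of PPM header")
      if (ch == "#") { repeat { ch <- readChar(con, 1, useBytes = TRUE)
                                if (ch %in% c("\n", "\r")) break } ; next }
      if (grepl("[[:space:]]", ch)) { if (nzchar(tok)) return(tok) else next }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) abort("not a supported PPM/PGM file")
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (maxval > 255) abort("only 8-bit PPM supported")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  nvals <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = nvals, quiet = TRUE)
  } else {
    as.integer(readBin(con, "raw", n = nvals))
  }
  if (length(vals) != nvals) abort("truncated PPM data")
  px <- matrix(vals, ncol = nch, byrow = TRUE)
  if (nch == 1L) px <- px[, c(1, 1, 1)]
  points_to_image(px, h, w)
}

# Plain-text (P3) PPM writer.
write_ppm <- function(img, path) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- as.matrix(image_to_points(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(apply(round(px), 1, paste, collapse = " "), con)
  invisible(path)
}
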