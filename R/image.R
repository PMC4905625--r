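# Image representation: H x W x 3 numeric array, integer intensities 0-255,
# dimension 1 = rows (y), dimension 2 = columns (x), dimension 3 = R,G,B.

#' Validate a slide image array
#'
#' @param image object to check.
#' @return the image, invisibly, or an error.
#' @keywords internal
check_slide_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop("image has non-positive dimensions", call. = FALSE)
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  invisible(image)
}

#' Pixel luminance
#'
#' Mean of the three colour channels, the intensity scale on which optical
#' density and the tissue/background cutoff are defined.
#'
#' @param image H x W x 3 array with intensities 0-255.
#' @return H x W numeric matrix.
#' @export
luminance <- function(image) {
  check_slide_image(image)
  (image[, , 1] + image[, , 2] + image[, , 3]) / 3
}

#' Read a slide image from PNG or TIFF
#'
#' Returns an H x W x 3 integer-valued array on the 0-255 scale regardless
#' of the on-disk bit depth; an alpha channel, if present, is dropped and
#' greyscale images are expanded to three identical channels.
#'
#' @param path file path; format chosen by extension (.png, .tif, .tiff).
#' @return H x W x 3 numeric array, values 0-255.
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  round(raw * 255)
}

#' Write a slide image to PNG or TIFF
#'
#' @param image H x W x 3 array, values 0-255.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(image, path) {
  check_slide_image(image)
  scaled <- image / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' 8-connected component labelling
#'
#' Labels connected components of a logical mask using 8-connectivity
#' (edge- and corner-adjacent pixels belong to the same object).
#' `EBImage::bwlabel()` provides the 4-connected pass; labels that touch
#' only diagonally are then merged with a union-find sweep.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered 1..n in raster order of first occurrence.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mode(mask) <- "logical"
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(relabel_raster(lab))

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i, j) vs (i+1, j+1) and (i+1, j) vs (i, j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  for (pair in list(cbind(as.vector(a1), as.vector(b1)),
                    cbind(as.vector(a2), as.vector(b2)))) {
    hit <- pair[, 1] > 0L & pair[, 2] > 0L & pair[, 1] != pair[, 2]
    if (any(hit)) {
      for (r in which(hit)) unite(pair[r, 1], pair[r, 2])
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  relabel_raster(lab)
}

# renumber labels 1..k in raster order of first occurrence
relabel_raster <- function(lab) {
  ids <- unique(as.vector(t(lab)))
  ids <- ids[ids > 0L]
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}
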