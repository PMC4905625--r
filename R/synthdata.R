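# Synthetic slide phantoms and cohort feature tables with exact ground
# truth, so every downstream stage is testable without real tissue.

#' Phantom specification
#'
#' Describes a synthetic DAB-stained slide: a tissue region on a pale
#' background, brown positive objects per marker, optional diffuse brown
#' stain of known optical density, blue-dominant counterstain nuclei and
#' dense basophilic calcification blobs.
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param resolution_um_per_px scan resolution, default 0.64.
#' @param tissue_fraction fraction of the image covered by tissue, in (0,1].
#' @param objects list of object groups; each element a list with fields
#'   `marker` (name), `n_objects`, `area_px_range` (length-2 integer
#'   vector), and `chromogen_darkness` (blue-channel value of the rendered
#'   DAB colour, 0-255).
#' @param diffuse_positive_fraction fraction of the tissue covered by
#'   diffuse positive stain, in `[0, 1]`.
#' @param diffuse_mean_od target mean optical density of the diffuse stain.
#' @param diffuse_marker marker name the diffuse compartment belongs to
#'   (default "MBP", the myelin stain).
#' @param n_calcifications number of calcification blobs (rendered dark
#'   blue-purple, carried in truth, never detected by image analysis).
#' @param n_nuclei number of hematoxylin counterstain nuclei.
#' @param background_level background intensity 0-255 (default 250; must
#'   stay above the tissue-segmentation cutoff of 240 to read as glass).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(width_px, height_px, resolution_um_per_px = 0.64,
                         tissue_fraction = 0.9, objects = list(),
                         diffuse_positive_fraction = 0,
                         diffuse_mean_od = 0, diffuse_marker = "MBP",
                         n_calcifications = 0L, n_nuclei = 0L,
                         background_level = 250L) {
  if (width_px < 1 || height_px < 1)
    stop("phantom dimensions must be positive", call. = FALSE)
  if (resolution_um_per_px <= 0)
    stop("resolution_um_per_px must be positive", call. = FALSE)
  if (tissue_fraction <= 0 || tissue_fraction > 1)
    stop("tissue_fraction must lie in (0, 1]", call. = FALSE)
  if (diffuse_positive_fraction < 0 || diffuse_positive_fraction > 1)
    stop("diffuse_positive_fraction must lie in [0, 1]", call. = FALSE)
  if (diffuse_mean_od < 0)
    stop("diffuse_mean_od must be nonnegative", call. = FALSE)
  if (background_level < 0 || background_level > 255)
    stop("background_level must lie in [0, 255]", call. = FALSE)
  for (ob in objects) {
    stopifnot(all(c("marker", "n_objects", "area_px_range",
                    "chromogen_darkness") %in% names(ob)))
    if (any(ob$area_px_range < 1))
      stop("object areas must be >= 1 px", call. = FALSE)
    if (ob$chromogen_darkness < 0 || ob$chromogen_darkness > 255)
      stop("chromogen_darkness must lie in [0, 255]", call. = FALSE)
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 resolution_um_per_px = resolution_um_per_px,
                 tissue_fraction = tissue_fraction, objects = objects,
                 diffuse_positive_fraction = diffuse_positive_fraction,
                 diffuse_mean_od = diffuse_mean_od,
                 diffuse_marker = diffuse_marker,
                 n_calcifications = as.integer(n_calcifications),
                 n_nuclei = as.integer(n_nuclei),
                 background_level = as.integer(background_level)),
            class = "phantom_spec")
}

# compact blob of exactly `a` pixels: a near-square w x h rectangle with
# the surplus trimmed off the end of the last row (stays 8-connected)
blob_cells <- function(a) {
  a <- as.integer(a)
  w <- max(1L, as.integer(floor(sqrt(a))))
  h <- as.integer(ceiling(a / w))
  cells <- cbind(rep(seq_len(h), each = w), rep(seq_len(w), h))
  list(w = w, h = h, cells = cells[seq_len(a), , drop = FALSE])
}

# draw one element uniformly (safe for length-1 vectors, unlike sample())
sample1 <- function(v) v[sample.int(length(v), 1L)]

# rejection-sample a free slot for a blob of `a` px inside `allowed`,
# respecting a 1-px separation margin against `occupied`; returns the
# absolute cell index matrix, or NULL when no slot is found
place_blob <- function(allowed, occupied, a, max_tries = 4000L) {
  b <- blob_cells(a)
  nr <- nrow(allowed); nc <- ncol(allowed)
  rows <- range(which(rowSums(allowed) > 0))
  cols <- range(which(colSums(allowed) > 0))
  if (diff(rows) + 1 < b$h || diff(cols) + 1 < b$w) return(NULL)
  for (i in seq_len(max_tries)) {
    r0 <- sample1(rows[1]:(rows[2] - b$h + 1L))
    c0 <- sample1(cols[1]:(cols[2] - b$w + 1L))
    rr <- r0:(r0 + b$h - 1L); cc <- c0:(c0 + b$w - 1L)
    if (!all(allowed[rr, cc])) next
    mr <- max(1L, r0 - 1L):min(nr, r0 + b$h)
    mc <- max(1L, c0 - 1L):min(nc, c0 + b$w)
    if (any(occupied[mr, mc])) next
    return(cbind(r0 - 1L + b$cells[, 1], c0 - 1L + b$cells[, 2]))
  }
  NULL
}

# luminance -> the brown (r, g, b) used for diffuse stain and objects:
# blue depressed, red raised, green balancing so the mean stays put
brown_for_luminance <- function(lum, depth = 60L) {
  lum <- as.integer(round(lum))
  b <- max(0L, lum - depth)
  r <- min(255L, lum + depth)
  g <- min(255L, max(0L, 3L * lum - r - b))
  c(r = r, g = g, b = b)
}

od_of_colour <- function(rgb) -log10((mean(rgb) + 1) / 256)

#' Render a slide phantom
#'
#' Draws the phantom described by a \code{\link{phantom_spec}}: tissue as a
#' centred rectangle of muted pink, DAB-positive objects as brown
#' rectangles of exact pixel area (blue channel depressed to the configured
#' chromogen darkness), counterstain nuclei as small blue-dominant blobs,
#' calcifications as dark basophilic blobs, and an optional diffuse brown
#' compartment of known mean optical density. Objects are placed by
#' rejection sampling with a one-pixel separation margin, so each rendered
#' object is exactly one 8-connected component and brute-force counting is
#' an exact oracle. All colours are uniform per structure, which makes
#' every stored truth value exact. The same `(spec, seed)` pair yields a
#' bitwise-identical phantom.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param seed integer seed for placement randomness.
#' @return a `slide_phantom` list: `image` (H x W x 3, 0-255), `truth`
#'   (tissue mask, per-marker positive masks, object counts, area
#'   fractions in percent, mean ODs, calcification count and mask), `spec`
#'   and `seed`.
#' @export
render_slide_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(as.integer(seed))
  H <- spec$height_px; W <- spec$width_px
  img <- array(spec$background_level, c(H, W, 3L))

  # centred tissue rectangle of area ~ tissue_fraction * H * W
  target <- round(spec$tissue_fraction * H * W)
  th <- min(H, max(1L, round(sqrt(target * H / W))))
  tw <- min(W, max(1L, round(target / th)))
  r0 <- (H - th) %/% 2L + 1L; c0 <- (W - tw) %/% 2L + 1L
  tissue <- matrix(FALSE, H, W)
  tissue[r0:(r0 + th - 1L), c0:(c0 + tw - 1L)] <- TRUE
  tissue_col <- c(230L, 212L, 222L)  # luminance ~221, below the 240 cutoff
  for (ch in 1:3) {
    plane <- img[, , ch]; plane[tissue] <- tissue_col[ch]
    img[, , ch] <- plane
  }
  n_tissue <- sum(tissue)

  occupied <- matrix(FALSE, H, W)
  paint <- function(idx, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- col[ch]
      img[, , ch] <<- plane
    }
    occupied[idx] <<- TRUE
  }

  total_object_px <- sum(vapply(spec$objects, function(ob)
    ob$n_objects * max(ob$area_px_range), numeric(1)))
  if (total_object_px > n_tissue)
    stop("requested object area exceeds tissue area", call. = FALSE)

  # calcifications: dense dark blue-purple blobs, never DAB-positive
  calc_mask <- matrix(FALSE, H, W)
  calc_col <- c(80L, 70L, 135L)
  for (i in seq_len(spec$n_calcifications)) {
    idx <- place_blob(tissue, occupied, sample(150:500, 1L))
    if (is.null(idx))
      stop("could not place calcification; tissue too crowded",
           call. = FALSE)
    paint(idx, calc_col)
    calc_mask[idx] <- TRUE
  }

  # hematoxylin counterstain nuclei: small, blue-dominant
  nucleus_col <- c(95L, 95L, 170L)
  for (i in seq_len(spec$n_nuclei)) {
    idx <- place_blob(tissue, occupied, sample(20:80, 1L))
    if (is.null(idx)) break  # crowding of counterstain is not an error
    paint(idx, nucleus_col)
  }

  markers <- unique(c(vapply(spec$objects, `[[`, character(1), "marker"),
                      if (spec$diffuse_positive_fraction > 0)
                        spec$diffuse_marker))
  pos_mask <- lapply(markers, function(m) matrix(FALSE, H, W))
  names(pos_mask) <- markers
  count <- stats::setNames(integer(length(markers)), markers)
  od_sum <- stats::setNames(numeric(length(markers)), markers)

  for (ob in spec$objects) {
    dab <- c(min(255L, ob$chromogen_darkness + 100L),
             min(255L, ob$chromogen_darkness + 50L),
             as.integer(ob$chromogen_darkness))
    for (i in seq_len(ob$n_objects)) {
      a <- sample1(ob$area_px_range[1]:ob$area_px_range[2])
      idx <- place_blob(tissue, occupied, a)
      if (is.null(idx))
        stop(sprintf("could not place %s object of %d px; tissue too crowded",
                     ob$marker, a), call. = FALSE)
      paint(idx, dab)
      pos_mask[[ob$marker]][idx] <- TRUE
      count[ob$marker] <- count[ob$marker] + 1L
      od_sum[ob$marker] <- od_sum[ob$marker] + a * od_of_colour(dab)
    }
  }

  if (spec$diffuse_positive_fraction > 0) {
    k <- round(spec$diffuse_positive_fraction * n_tissue)
    lum <- min(255, max(0, 256 * 10^(-spec$diffuse_mean_od) - 1))
    col <- brown_for_luminance(lum)
    # keep a 1-px halo around placed structures so the diffuse compartment
    # never touches an object (objects stay single 8-connected components)
    halo <- matrix(as.logical(EBImage::imageData(
      EBImage::dilate(occupied * 1, EBImage::makeBrush(3L, "box"))) > 0),
      H, W)
    free <- which(t(tissue & !halo))  # raster (row-major) order
    if (length(free) < k)
      stop("diffuse fraction infeasible; tissue too crowded", call. = FALSE)
    take <- free[seq_len(k)]
    idx <- cbind(((take - 1L) %/% W) + 1L, ((take - 1L) %% W) + 1L)
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[idx] <- col[ch]
      img[, , ch] <- plane
    }
    occupied[idx] <- TRUE
    dm <- spec$diffuse_marker
    pos_mask[[dm]][idx] <- TRUE
    count[dm] <- count[dm] + 0L
    od_sum[dm] <- od_sum[dm] + k * od_of_colour(col)
  }

  n_pos <- vapply(pos_mask, sum, numeric(1))
  truth <- list(
    tissue_mask = tissue,
    positive_mask = pos_mask,
    object_count = count,
    area_fraction = 100 * n_pos / n_tissue,
    mean_od = ifelse(n_pos > 0, od_sum / n_pos, NA_real_),
    n_calcifications = spec$n_calcifications,
    calcification_mask = calc_mask
  )
  structure(list(image = img, truth = truth, spec = spec,
                 seed = as.integer(seed)),
            class = "slide_phantom")
}

#' Write a phantom image plus ground-truth sidecar
#'
#' Saves the rendered image (PNG or TIFF by extension) together with a JSON
#' sidecar (`<stem>.truth.json`) holding the scalar ground truth: object
#' counts, area fractions, mean ODs, tissue pixel count and calcification
#' count. Pixel-level truth masks are not serialised; regenerate the
#' phantom from its spec and seed when they are needed.
#'
#' @param phantom a `slide_phantom`.
#' @param path image path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "slide_phantom"))
  write_slide_image(phantom$image, path)
  tr <- phantom$truth
  sidecar <- list(
    seed = phantom$seed,
    resolution_um_per_px = phantom$spec$resolution_um_per_px,
    tissue_px = sum(tr$tissue_mask),
    object_count = as.list(tr$object_count),
    area_fraction_pct = as.list(tr$area_fraction),
    mean_od = as.list(tr$mean_od),
    n_calcifications = tr$n_calcifications
  )
  jsonlite::write_json(sidecar,
                       paste0(tools::file_path_sans_ext(path), ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
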