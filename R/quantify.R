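# Semi-automated IHC quantification: tissue segmentation, DAB-positive area
# fractions, optical density, size-gated cell counting, field densities.

#' Marker detection parameters
#'
#' One record of the detection parameters applied to a marker: the
#' blue-channel brightness threshold separating brown DAB chromogen from
#' background/counterstain, the pixel-area gate used when objects are
#' counted, and the measurement mode.
#'
#' @param name marker name (e.g. "NeuN", "pS6").
#' @param blue_threshold integer 0-255; a pixel can be positive only if its
#'   blue value is at or below this cutoff.
#' @param min_area_px,max_area_px pixel-area gate for counted objects;
#'   `max_area_px = Inf` means unbounded. Ignored for area/OD markers.
#' @param mode `"count"` (cell density), `"area"` (positive-area fraction)
#'   or `"od"` (area fraction plus optical density).
#' @return a `marker_config` list.
#' @export
marker_config <- function(name, blue_threshold, min_area_px = 1L,
                          max_area_px = Inf,
                          mode = c("count", "area", "od")) {
  mode <- match.arg(mode)
  if (blue_threshold < 0 || blue_threshold > 255)
    stop("blue_threshold must lie in [0, 255]", call. = FALSE)
  if (min_area_px < 1) stop("min_area_px must be >= 1", call. = FALSE)
  if (is.finite(max_area_px) && max_area_px < min_area_px)
    stop("min_area_px must not exceed max_area_px", call. = FALSE)
  structure(list(name = name, blue_threshold = as.integer(blue_threshold),
                 min_area_px = as.integer(min_area_px),
                 max_area_px = max_area_px, mode = mode),
            class = "marker_config")
}

#' Default marker panel
#'
#' The full staining panel with its published detection parameters.
#' Counted markers use the blue-channel thresholds NeuN 120; CD3, SMI32 and
#' Olig2 100; CD34 150, and the pixel-area gates NeuN 120-2500, CD3 20-155,
#' Olig2 20-155 (5-120 in autopsy material), CD34 100-unlimited,
#' SMI32 750-5000. Area markers (pS6, GFAP, Cr3/43) and the myelin marker
#' MBP carry no size gate; their threshold defaults to 120.
#'
#' @param autopsy logical; use the autopsy Olig2 gate (5-120 px) instead of
#'   the surgical one (20-155 px).
#' @param area_threshold blue-channel threshold for the area/OD markers,
#'   for which no published value exists; default 120.
#' @return named list of \code{\link{marker_config}} records.
#' @export
default_marker_panel <- function(autopsy = FALSE, area_threshold = 120L) {
  olig2_gate <- if (autopsy) c(5L, 120L) else c(20L, 155L)
  panel <- list(
    marker_config("NeuN",   120L, 120L, 2500L, "count"),
    marker_config("CD3",    100L, 20L,  155L,  "count"),
    marker_config("Olig2",  100L, olig2_gate[1], olig2_gate[2], "count"),
    marker_config("CD34",   150L, 100L, Inf,   "count"),
    marker_config("SMI32",  100L, 750L, 5000L, "count"),
    marker_config("pS6",    area_threshold, mode = "area"),
    marker_config("GFAP",   area_threshold, mode = "area"),
    marker_config("Cr3/43", area_threshold, mode = "area"),
    marker_config("MBP",    area_threshold, mode = "od")
  )
  names(panel) <- vapply(panel, `[[`, character(1), "name")
  panel
}

#' Segment tissue from background
#'
#' Tissue is everything darker than the near-white slide background:
#' pixels with luminance below `background_cutoff` after a morphological
#' closing (to fill small holes) and removal of speckle components smaller
#' than `min_component_px`. The tissue surface area follows from the pixel
#' count and the scan resolution.
#'
#' @param image H x W x 3 array, intensities 0-255.
#' @param resolution_um_per_px microns per pixel (0.64 for the scans the
#'   defaults were derived from).
#' @param background_cutoff luminance cutoff, default 240.
#' @param closing_radius radius (px) of the closing brush; 0 disables.
#' @param min_component_px components below this size are discarded.
#' @return a `tissue_mask` list: `mask` (logical H x W),
#'   `tissue_area_mm2`, and `resolution_um_per_px`. A slide with no tissue
#'   yields an all-false mask, area 0, and a warning.
#' @export
segment_tissue <- function(image, resolution_um_per_px,
                           background_cutoff = 240, closing_radius = 2L,
                           min_component_px = 64L) {
  check_slide_image(image)
  if (resolution_um_per_px <= 0)
    stop("resolution_um_per_px must be positive", call. = FALSE)
  mask <- luminance(image) < background_cutoff
  if (any(mask) && closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, "disc")
    closed <- EBImage::closing(mask * 1, brush)
    mask <- matrix(as.logical(EBImage::imageData(closed) > 0),
                   nrow(mask), ncol(mask))
  }
  if (any(mask) && min_component_px > 1) {
    lab <- label_components(mask)
    keep <- which(tabulate(lab) >= min_component_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) warning("no tissue pixels found", call. = FALSE)
  structure(list(
    mask = mask,
    tissue_area_mm2 = sum(mask) * resolution_um_per_px^2 * 1e-6,
    resolution_um_per_px = resolution_um_per_px
  ), class = "tissue_mask")
}

#' DAB-positive pixel mask
#'
#' A pixel is positive when it lies within tissue, its blue value is at or
#' below the marker threshold (DAB absorbs strongly in blue), and its red
#' value exceeds its blue value (separating brown chromogen from the
#' blue-dominant hematoxylin counterstain). The positive set is
#' nondecreasing in the threshold.
#'
#' @param image H x W x 3 array, intensities 0-255.
#' @param blue_threshold integer 0-255.
#' @param tissue a \code{\link{segment_tissue}} result (or any list with a
#'   logical `mask`).
#' @return logical H x W matrix.
#' @export
positive_pixel_mask <- function(image, blue_threshold, tissue) {
  check_slide_image(image)
  if (blue_threshold < 0 || blue_threshold > 255)
    stop("blue_threshold must lie in [0, 255]", call. = FALSE)
  blue <- image[, , 3]
  red <- image[, , 1]
  tissue$mask & blue <= blue_threshold & red > blue
}

#' Positive-area fraction
#'
#' Percentage of the tissue surface covered by positive pixels.
#'
#' @param positive logical positive-pixel mask (subset of the tissue mask).
#' @param tissue a \code{\link{segment_tissue}} result.
#' @return percentage in `[0, 100]`; `NA` with a warning when the tissue
#'   area is zero (the fraction is undefined, not zero).
#' @export
area_fraction <- function(positive, tissue) {
  n_tissue <- sum(tissue$mask)
  if (n_tissue == 0L) {
    warning("tissue area is zero; area fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(positive) / n_tissue
}

#' Size-gated object counting
#'
#' Connected components (8-connectivity) of the marker's positive-pixel
#' mask are counted after discarding components outside the marker's
#' pixel-area gate; the density is the kept count per mm2 of tissue.
#'
#' @param image H x W x 3 array, intensities 0-255.
#' @param cfg a \code{\link{marker_config}} with `mode = "count"`.
#' @param tissue a \code{\link{segment_tissue}} result.
#' @return list with `count` (integer) and `density_per_mm2` (`NA` with a
#'   warning when the tissue area is zero).
#' @export
count_objects <- function(image, cfg, tissue) {
  if (!inherits(cfg, "marker_config") || cfg$mode != "count")
    stop("cfg must be a marker_config with mode 'count'", call. = FALSE)
  pos <- positive_pixel_mask(image, cfg$blue_threshold, tissue)
  lab <- label_components(pos)
  sizes <- tabulate(lab)
  count <- sum(sizes >= cfg$min_area_px & sizes <= cfg$max_area_px)
  if (tissue$tissue_area_mm2 <= 0) {
    warning("tissue area is zero; density undefined", call. = FALSE)
    density <- NA_real_
  } else {
    density <- count / tissue$tissue_area_mm2
  }
  list(count = count, density_per_mm2 = density)
}

#' Optical density of a stained area
#'
#' Per-pixel optical density is `-log10((L + 1) / 256)` with `L` the pixel
#' luminance; the +1 offset avoids `log(0)` at full absorption and makes a
#' blank (luminance 255) pixel contribute exactly 0. Mean OD averages over
#' the positive pixels; integrated OD sums over them.
#'
#' @param image H x W x 3 array, intensities 0-255.
#' @param positive logical mask of the pixels to measure.
#' @return list with `mean_od` (`NA` with a warning for an empty mask) and
#'   `integrated_od` (0 for an empty mask).
#' @export
optical_density <- function(image, positive) {
  check_slide_image(image)
  n <- sum(positive)
  if (n == 0L) {
    warning("empty positive mask; mean OD undefined", call. = FALSE)
    return(list(mean_od = NA_real_, integrated_od = 0))
  }
  od <- -log10((luminance(image)[positive] + 1) / 256)
  list(mean_od = mean(od), integrated_od = sum(od))
}

#' Overall myelin content
#'
#' Composite stain statistic: the product of stain frequency (positive-area
#' percentage) and stain intensity (mean optical density of the positive
#' area).
#'
#' @param area_pct positive-area percentage in `[0, 100]`.
#' @param mean_od nonnegative mean optical density.
#' @return `area_pct * mean_od`.
#' @export
overall_myelin_content <- function(area_pct, mean_od) {
  if (is.na(area_pct) || is.na(mean_od))
    return(NA_real_)
  if (area_pct < 0 || area_pct > 100)
    stop("area_pct must lie in [0, 100]", call. = FALSE)
  if (mean_od < 0) stop("mean_od must be nonnegative", call. = FALSE)
  area_pct * mean_od
}

#' Field-count configuration
#'
#' @param n_fields number of representative fields counted (default 10).
#' @param field_area_mm2 area of one field in mm2 (default 1.081).
#' @return a `field_count_config` list.
#' @export
field_count_config <- function(n_fields = 10L, field_area_mm2 = 1.081) {
  if (n_fields < 1L) stop("n_fields must be >= 1", call. = FALSE)
  if (field_area_mm2 <= 0)
    stop("field_area_mm2 must be positive", call. = FALSE)
  structure(list(n_fields = as.integer(n_fields),
                 field_area_mm2 = field_area_mm2),
            class = "field_count_config")
}

#' Density from per-field counts
#'
#' Giant cells are tallied by eye in a fixed number of representative
#' fields of known area; the density is the pooled count over the pooled
#' area.
#'
#' @param field_counts integer vector, one count per field; its length must
#'   equal `cfg$n_fields`.
#' @param cfg a \code{\link{field_count_config}}.
#' @return density per mm2.
#' @export
field_density <- function(field_counts, cfg = field_count_config()) {
  if (length(field_counts) != cfg$n_fields)
    stop(sprintf("expected %d field counts, got %d", cfg$n_fields,
                 length(field_counts)), call. = FALSE)
  if (any(field_counts < 0)) stop("negative field count", call. = FALSE)
  sum(field_counts) / (cfg$n_fields * cfg$field_area_mm2)
}

# marker name -> QuantResult column stem
marker_field <- function(name) {
  switch(name,
    "pS6" = "ps6", "GFAP" = "gfap", "Cr3/43" = "cr343", "MBP" = "mbp",
    "NeuN" = "neun", "CD3" = "cd3", "Olig2" = "olig2", "CD34" = "cd34",
    "SMI32" = "smi32",
    tolower(gsub("[^A-Za-z0-9]", "", name)))
}

#' Quantify one sample across its marker panel
#'
#' Applies the same panel parameters to every marker image of one sample:
#' counted markers yield densities per mm2, area markers yield positive
#' percentages, and the myelin marker additionally yields mean and
#' integrated optical density and the overall myelin content
#' (`omc = mbp_pct * mbp_mean_od`, an identity that holds exactly in every
#' emitted result). Giant-cell (vimentin) density comes from eye counts in
#' representative fields, and calcification is an eye-scored binary input
#' from the H&E slide, not an image measurement.
#'
#' @param images named list mapping marker name to an H x W x 3 image; one
#'   image per panel marker, stained sections of the same specimen.
#' @param panel named list of \code{\link{marker_config}} records, as from
#'   \code{\link{default_marker_panel}}.
#' @param resolution_um_per_px scan resolution.
#' @param calcification_flag logical; eye score from the H&E slide.
#' @param vimentin_field_counts integer vector of per-field giant-cell
#'   counts on the vimentin section, or `NULL` if not assessed.
#' @param field_cfg a \code{\link{field_count_config}}.
#' @return one-row data.frame (class `quant_result`) with columns
#'   `ps6_pct`, `gfap_pct`, `cr343_pct`, `mbp_pct`, `mbp_mean_od`,
#'   `mbp_integrated_od`, `omc`, `neun_density`, `cd3_density`,
#'   `olig2_density`, `cd34_density`, `smi32_density`, `vimentin_density`,
#'   `calcification_present`.
#' @export
quantify_sample <- function(images, panel = default_marker_panel(),
                            resolution_um_per_px = 0.64,
                            calcification_flag = FALSE,
                            vimentin_field_counts = NULL,
                            field_cfg = field_count_config()) {
  missing <- setdiff(vapply(panel, `[[`, character(1), "name"),
                     names(images))
  if (length(missing) > 0L)
    stop("missing image for marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (cfg in panel) {
    img <- images[[cfg$name]]
    tissue <- segment_tissue(img, resolution_um_per_px)
    stem <- marker_field(cfg$name)
    if (cfg$mode == "count") {
      res <- count_objects(img, cfg, tissue)
      out[[paste0(stem, "_density")]] <- res$density_per_mm2
    } else {
      pos <- positive_pixel_mask(img, cfg$blue_threshold, tissue)
      pct <- area_fraction(pos, tissue)
      out[[paste0(stem, "_pct")]] <- pct
      if (cfg$mode == "od") {
        od <- if (sum(pos) == 0L)
          list(mean_od = 0, integrated_od = 0)
        else
          optical_density(img, pos)
        out[[paste0(stem, "_mean_od")]] <- od$mean_od
        out[[paste0(stem, "_integrated_od")]] <- od$integrated_od
        out$omc <- overall_myelin_content(pct, od$mean_od)
      }
    }
  }
  out$vimentin_density <- if (is.null(vimentin_field_counts)) NA_real_
    else field_density(vimentin_field_counts, field_cfg)
  out$calcification_present <- isTRUE(calcification_flag)
  cols <- c("ps6_pct", "gfap_pct", "cr343_pct", "mbp_pct", "mbp_mean_od",
            "mbp_integrated_od", "omc", "neun_density", "cd3_density",
            "olig2_density", "cd34_density", "smi32_density",
            "vimentin_density", "calcification_present")
  out <- out[intersect(cols, names(out))]
  structure(as.data.frame(out, check.names = FALSE),
            class = c("quant_result", "data.frame"))
}
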