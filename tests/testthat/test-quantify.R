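test_that("tissue segmentation: blank slide, exact area arithmetic, truth recovery", {
  # uniformly white slide: no tissue, zero area, warning
  white <- flat_image(32, 32, c(255, 255, 255))
  expect_warning(ts <- segment_tissue(white, 0.64), "no tissue")
  expect_equal(ts$tissue_area_mm2, 0)

  # exactly 1e6 non-background pixels at 0.64 um/px -> 0.4096 mm2
  sp <- phantom_spec(1024, 1024, tissue_fraction = 1e6 / 1024^2)
  ph <- render_slide_phantom(sp, seed = 1)
  ts <- segment_tissue(ph$image, 0.64)
  expect_equal(ts$tissue_area_mm2, 1e6 * 0.64^2 * 1e-6)

  # mask matches the generator truth to within 2%
  sp2 <- phantom_spec(192, 192, n_nuclei = 10L,
                      diffuse_positive_fraction = 0.2, diffuse_mean_od = 0.3)
  ph2 <- render_slide_phantom(sp2, seed = 2)
  ts2 <- segment_tissue(ph2$image, 0.64)
  delta <- sum(xor(ts2$mask, ph2$truth$tissue_mask))
  expect_lt(delta / sum(ph2$truth$tissue_mask), 0.02)
})

test_that("positive-pixel rule: bounds, monotonicity, truth overlap", {
  ph <- object_phantom("NeuN", 6L, c(150L, 400L), px = 160L, seed = 3,
                       n_nuclei = 8L)
  ts <- segment_tissue(ph$image, 0.64)
  # threshold 0 on an image whose minimum blue value is positive
  expect_true(min(ph$image[, , 3]) > 0)
  expect_equal(sum(positive_pixel_mask(ph$image, 0, ts)), 0)
  # threshold 255: every tissue pixel with red > blue
  full <- positive_pixel_mask(ph$image, 255, ts)
  expect_identical(full, ts$mask & ph$image[, , 1] > ph$image[, , 3])
  # monotone in the threshold
  prev <- positive_pixel_mask(ph$image, 0, ts)
  for (thr in c(40, 80, 120, 200, 255)) {
    cur <- positive_pixel_mask(ph$image, thr, ts)
    expect_true(all(cur[prev]))  # raising never removes a positive pixel
    prev <- cur
  }
  # Jaccard overlap with the generator truth
  pos <- positive_pixel_mask(ph$image, 120, ts)
  truth <- ph$truth$positive_mask$NeuN
  jacc <- sum(pos & truth) / sum(pos | truth)
  expect_gte(jacc, 0.95)
})

test_that("area fraction: bounds and undefined-tissue signal", {
  ph <- render_slide_phantom(blank_tissue_spec(64L), seed = 1)
  ts <- segment_tissue(ph$image, 0.64)
  expect_equal(area_fraction(ts$mask, ts), 100)
  expect_equal(area_fraction(matrix(FALSE, 64, 64), ts), 0)
  empty <- list(mask = matrix(FALSE, 4, 4), tissue_area_mm2 = 0)
  expect_warning(out <- area_fraction(matrix(FALSE, 4, 4), empty),
                 "undefined")
  expect_true(is.na(out))
})

test_that("size gates include and exclude objects at the published bounds", {
  panel <- default_marker_panel()
  # five disjoint 200-px objects pass the NeuN gate (120-2500)
  ph <- object_phantom("NeuN", 5L, c(200L, 200L), px = 256L, seed = 4)
  ts <- segment_tissue(ph$image, 0.64)
  expect_equal(count_objects(ph$image, panel$NeuN, ts)$count, 5)
  # a 100-px object falls below the NeuN minimum of 120 px
  sp <- phantom_spec(256, 256, objects = list(
    list(marker = "NeuN", n_objects = 4L, area_px_range = c(200L, 200L),
         chromogen_darkness = 60L),
    list(marker = "NeuN", n_objects = 1L, area_px_range = c(100L, 100L),
         chromogen_darkness = 60L)))
  ph2 <- render_slide_phantom(sp, seed = 4)
  ts2 <- segment_tissue(ph2$image, 0.64)
  expect_equal(count_objects(ph2$image, panel$NeuN, ts2)$count, 4)
  # one merged 4000-px component exceeds the NeuN maximum of 2500 px
  ph3 <- object_phantom("NeuN", 1L, c(4000L, 4000L), px = 256L, seed = 5)
  ts3 <- segment_tissue(ph3$image, 0.64)
  expect_equal(count_objects(ph3$image, panel$NeuN, ts3)$count, 0)
  # density = count / tissue area
  res <- count_objects(ph$image, panel$NeuN, ts)
  expect_equal(res$density_per_mm2, 5 / ts$tissue_area_mm2)
})

test_that("8-connected labelling matches the brute-force flood fill", {
  set.seed(42)
  for (i in 1:8) {
    mask <- matrix(runif(48 * 48) < 0.35, 48, 48)
    lab <- label_components(mask)
    expect_equal(max(lab), flood_fill_count(mask))
    # every labelled pixel is masked and vice versa
    expect_identical(lab > 0, mask)
  }
  # diagonal-only touch is one component
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m)), 1)
})

test_that("optical density: closed forms and the integrated identity", {
  img <- flat_image(8, 8, c(255, 255, 255))
  all_mask <- matrix(TRUE, 8, 8)
  expect_equal(optical_density(img, all_mask)$mean_od, 0)
  img127 <- flat_image(8, 8, c(127, 127, 127))
  od <- optical_density(img127, all_mask)
  expect_equal(od$mean_od, log10(2))
  expect_equal(od$integrated_od, od$mean_od * 64)
  expect_warning(res <- optical_density(img, matrix(FALSE, 8, 8)), "empty")
  expect_true(is.na(res$mean_od))
  expect_equal(res$integrated_od, 0)
})

test_that("overall myelin content is the exact area x intensity product", {
  expect_equal(overall_myelin_content(0, 5), 0)
  expect_equal(overall_myelin_content(50, 0.5), 25)
  expect_error(overall_myelin_content(-1, 0.5), "\\[0, 100\\]")
  expect_error(overall_myelin_content(50, -0.1), "nonnegative")
})

test_that("field density pools counts over the pooled field area", {
  expect_equal(field_density(rep(0L, 10)), 0)
  expect_equal(field_density(rep(as.integer(1.081 * 0), 10)), 0)
  expect_equal(field_density(c(2, 1, 0, 3, 1, 2, 0, 1, 1, 0)), 11 / 10.81)
  expect_error(field_density(1:5), "field counts")
  cfg <- field_count_config(n_fields = 4L, field_area_mm2 = 0.5)
  expect_equal(field_density(c(1, 1, 1, 1), cfg), 4 / 2)
})

test_that("quantify_sample recovers generator truth and keeps the OMC identity", {
  panel <- default_marker_panel()
  gates <- list(NeuN = c(150L, 2000L), CD3 = c(30L, 150L),
                Olig2 = c(30L, 150L), CD34 = c(120L, 600L),
                SMI32 = c(800L, 4000L))
  images <- list()
  truth_count <- numeric()
  for (m in names(gates)) {
    ph <- object_phantom(m, 4L, gates[[m]], px = 256L,
                         seed = match(m, names(gates)), n_nuclei = 6L)
    images[[m]] <- ph$image
    truth_count[m] <- ph$truth$object_count[[m]]
  }
  ps_area <- phantom_spec(256, 256, diffuse_positive_fraction = 0.3,
                          diffuse_mean_od = 0.301, diffuse_marker = "MBP",
                          n_nuclei = 6L)
  ph_area <- render_slide_phantom(ps_area, seed = 21)
  for (m in c("pS6", "GFAP", "Cr3/43", "MBP")) images[[m]] <- ph_area$image

  q <- quantify_sample(images, panel, 0.64, calcification_flag = FALSE,
                       vimentin_field_counts = c(2, 1, 0, 3, 1, 2, 0, 1, 1, 0))
  tissue_mm2 <- sum(ph_area$truth$tissue_mask) * 0.64^2 * 1e-6
  for (m in names(gates)) {
    stem <- switch(m, NeuN = "neun", CD3 = "cd3", Olig2 = "olig2",
                   CD34 = "cd34", SMI32 = "smi32")
    truth_density <- truth_count[[m]] / tissue_mm2
    expect_equal(q[[paste0(stem, "_density")]], truth_density,
                 tolerance = 0.1)
  }
  expect_equal(q$mbp_pct, 30, tolerance = 0.5 / 30)
  expect_equal(q$ps6_pct, 30, tolerance = 0.5 / 30)
  # OMC identity holds exactly
  expect_identical(q$omc, q$mbp_pct * q$mbp_mean_od)
  expect_equal(q$vimentin_density, 11 / 10.81)
  expect_false(q$calcification_present)

  # panel order does not matter
  q2 <- quantify_sample(images, rev(panel), 0.64,
                        vimentin_field_counts = c(2, 1, 0, 3, 1, 2, 0, 1, 1, 0))
  expect_equal(q2[, sort(names(q2))], q[, sort(names(q))])

  # missing marker image names the marker
  expect_error(quantify_sample(images[setdiff(names(images), "CD3")], panel),
               "CD3")
})

test_that("unstained tissue yields zero percentages, densities and OMC", {
  ph <- render_slide_phantom(blank_tissue_spec(128L), seed = 6)
  images <- stats::setNames(
    rep(list(ph$image), 9),
    c("NeuN", "CD3", "Olig2", "CD34", "SMI32", "pS6", "GFAP", "Cr3/43",
      "MBP"))
  q <- quantify_sample(images, default_marker_panel(), 0.64,
                       vimentin_field_counts = rep(0L, 10))
  expect_equal(q$ps6_pct, 0)
  expect_equal(q$mbp_pct, 0)
  expect_equal(q$omc, 0)
  expect_equal(q$neun_density, 0)
  expect_equal(q$smi32_density, 0)
  expect_equal(q$vimentin_density, 0)
})

test_that("density estimates are stable under a resolution change", {
  # same physical scene scanned at half the pixel density: object pixel
  # areas quarter, pixel count per mm2 quarters, density stays put
  ph_hi <- object_phantom("CD34", 5L, c(400L, 400L), px = 256L, seed = 8)
  ph_lo <- object_phantom("CD34", 5L, c(100L, 100L), px = 128L, seed = 8,
                          resolution_um_per_px = 1.28)
  cfg <- default_marker_panel()$CD34
  ts_hi <- segment_tissue(ph_hi$image, 0.64)
  ts_lo <- segment_tissue(ph_lo$image, 1.28)
  expect_equal(sum(ts_lo$mask) / sum(ts_hi$mask), 0.25, tolerance = 0.01)
  d_hi <- count_objects(ph_hi$image, cfg, ts_hi)$density_per_mm2
  d_lo <- count_objects(ph_lo$image, cfg, ts_lo)$density_per_mm2
  expect_equal(d_lo, d_hi, tolerance = 0.1)
})
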