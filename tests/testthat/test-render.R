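# Mask rasterization: z-buffer labelling, amodal coverage, cropping,
# shading.

test_that("a frame-filling square leaf covers every pixel", {
  m <- toy_model(list(square_leaf(1, 0, 0, 1, 1, z = 0)))
  ms <- render_masks(m, unit_camera(c(8, 8)), "both")
  expect_equal(sum(ms$visible_masks[["1"]]), 64)
  expect_equal(unname(ms$visibility[["1"]]), 1.0)
  expect_equal(unname(ms$bboxes[["1"]]), c(0, 0, 8, 8))
})

test_that("total occlusion: nearer leaf wins, occluded leaf keeps amodal", {
  # camera looks down -Z, so larger z is nearer the eye
  m <- toy_model(list(square_leaf(1, 0, 0, 1, 1, z = 0),
                      square_leaf(2, 0, 0, 1, 1, z = 0.5)))
  ms <- render_masks(m, unit_camera(c(8, 8)), "both")
  expect_equal(sum(ms$visible_masks[["1"]]), 0)
  expect_equal(sum(ms$visible_masks[["2"]]), 64)
  expect_equal(sum(ms$amodal_masks[["1"]]), 64)
  expect_equal(sum(ms$amodal_masks[["2"]]), 64)
  expect_equal(unname(ms$visibility[["1"]]), 0)
})

test_that("coplanar depth ties resolve to the lower instance id", {
  m <- toy_model(list(square_leaf(2, 0, 0, 1, 1, z = 0.3),
                      square_leaf(1, 0, 0, 1, 1, z = 0.3)))
  ms <- render_masks(m, unit_camera(c(8, 8)), "visible")
  expect_equal(sum(ms$visible_masks[["1"]]), 64)
  expect_equal(sum(ms$visible_masks[["2"]]), 0)
})

test_that("stem organs occlude leaves but label zero", {
  m <- toy_model(list(
    square_leaf(1, 0, 0, 1, 1, z = 0),
    list(instance_id = 0, organ_class = "stem",
         tris = square_leaf(0, 0.25, 0.25, 0.75, 0.75, z = 0.5)$tris)))
  ms <- render_masks(m, unit_camera(c(8, 8)), "both")
  expect_lt(sum(ms$visible_masks[["1"]]), 64)
  expect_equal(sum(ms$amodal_masks[["1"]]), 64)
  expect_true(all(ms$label_image %in% c(0L, 1L)))
  expect_equal(sum(ms$label_image > 0), sum(ms$visible_masks[["1"]]))
})

test_that("visible masks partition the foreground on random rosettes", {
  g <- read_grammar(preset_grammar("rosette"))
  for (seed in 1:4) {
    s <- expand_hierarchical(g, 8, seed)
    m <- interpret(s)
    cam <- auto_camera(m, c(48, 48))
    ms <- render_masks(m, cam, "both")
    total <- Reduce(`+`, ms$visible_masks)
    expect_true(all(total <= 1))                    # pairwise disjoint
    expect_identical(total > 0, ms$label_image > 0) # exact partition
    for (k in names(ms$visible_masks)) {            # amodal containment
      expect_true(all(ms$amodal_masks[[k]] >= ms$visible_masks[[k]]))
    }
  }
})

test_that("z-buffer labels match the brute-force depth-sort oracle", {
  withr::local_seed(7)
  for (i in 1:6) {
    m <- random_triangle_model(n_leaves = sample(2:5, 1),
                               tris_per_leaf = sample(1:3, 1))
    cam <- unit_camera(c(20, 20))
    ms <- render_masks(m, cam, "visible")
    expect_identical(ms$label_image, brute_force_labels(m, cam))
  }
})

test_that("doubling resolution barely changes visible-area fractions", {
  m <- toy_model(list(square_leaf(1, 0.1, 0.2, 0.8, 0.7, z = 0)))
  f <- vapply(c(64, 128), function(n) {
    ms <- render_masks(m, unit_camera(c(n, n)), "visible")
    sum(ms$visible_masks[["1"]]) / n^2
  }, numeric(1))
  expect_lt(abs(f[2] - f[1]) / f[1], 0.02)
})

test_that("crop_patches computes tight padded boxes and skips empties", {
  H <- 10; W <- 12
  mask <- matrix(0L, H, W)
  mask[3:5, 4:8] <- 1L  # rows 2..4, cols 3..7 in 0-based terms
  ms <- structure(list(visible_masks = list(`1` = mask, `2` = matrix(0L, H, W)),
                       amodal_masks = NULL, label_image = mask,
                       bboxes = list(`1` = mask_bbox(mask)),
                       size = c(H, W), mode = "visible"),
                  class = "instance_mask_set")
  ps <- crop_patches(ms, pad = 0, min_area = 1)
  expect_length(ps, 1)  # the all-zero instance is omitted
  expect_equal(unname(ps[[1]]$bbox), c(3, 2, 8, 5))
  expect_equal(dim(ps[[1]]$mask), c(3, 5))
  expect_true(all(ps[[1]]$mask == 1))

  # pad larger than the image clips to the full frame
  ps2 <- crop_patches(ms, pad = 100, min_area = 1)
  expect_equal(unname(ps2[[1]]$bbox), c(0, 0, W, H))

  # min-area threshold skips small instances (15 px here)
  expect_length(crop_patches(ms, pad = 0, min_area = 16), 0)
})

test_that("every bbox edge touches its mask", {
  withr::local_seed(3)
  for (i in 1:10) {
    mask <- random_blob_mask(20, 20)
    if (!sum(mask)) next
    bb <- mask_bbox(mask)
    sub <- mask[(bb[2] + 1):bb[4], (bb[1] + 1):bb[3], drop = FALSE]
    expect_gt(sum(sub[1, ]), 0)
    expect_gt(sum(sub[nrow(sub), ]), 0)
    expect_gt(sum(sub[, 1]), 0)
    expect_gt(sum(sub[, ncol(sub)]), 0)
  }
})

test_that("Lambertian preview obeys the lighting model", {
  m <- toy_model(list(square_leaf(1, 0, 0, 1, 1, z = 0)))  # normal +/-Z
  cam <- unit_camera(c(8, 8))
  amb <- 0.25
  par_img <- shaded_preview(m, cam, light_spec(c(0, 0, -1), amb))
  expect_equal(max(par_img), 1 * (1 - amb) + amb, tolerance = 1e-12)
  perp_img <- shaded_preview(m, cam, light_spec(c(1, 0, 0), amb))
  expect_equal(max(perp_img), amb, tolerance = 1e-12)
  # two-face wedge shades each face by its own normal
  wedge <- toy_model(list(
    list(instance_id = 1, organ_class = "leaf", tris = list(
      rbind(c(0, 0, 0), c(0.5, 0, 0.3), c(0.5, 1, 0.3)),
      rbind(c(0.5, 0, 0.3), c(1, 0, 0), c(1, 1, 0))))))
  img <- shaded_preview(wedge, cam, light_spec(c(0, 0, -1), 0))
  vals <- sort(unique(round(img[img > 0], 6)))
  n1 <- leafgen:::.unit3(leafgen:::.cross3(c(0.5, 0, 0.3) - c(0, 0, 0),
                                           c(0.5, 1, 0.3) - c(0, 0, 0)))
  expect_true(any(abs(vals - abs(n1[3])) < 1e-6))
})

test_that("degenerate cameras and empty models are rejected", {
  m <- toy_model(list(square_leaf(1, 0, 0, 1, 1, 0)))
  expect_error(camera_spec(eye = c(0, 0, 1), look_at = c(0, 0, 1)),
               "degenerate")
  expect_error(camera_spec(units_per_pixel = 0), "pixel scale")
  empty <- structure(list(organs = list(), leaf_count = 0L),
                     class = "plant_model")
  expect_error(render_masks(empty, unit_camera()), "empty model")
})

test_that("perspective projection scales with distance", {
  cam <- camera_spec("perspective", eye = c(0, 0, 5), look_at = c(0, 0, 0),
                     size = c(64, 64), fov = 40)
  near <- project_points_wrap(cam, rbind(c(0.5, 0, 1)))
  far <- project_points_wrap(cam, rbind(c(0.5, 0, -3)))
  # same world offset appears smaller when farther from the eye
  expect_lt(abs(far[1, 1] - 32), abs(near[1, 1] - 32))
  expect_lt(near[1, 3], far[1, 3])
})
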