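# Persistence (COCO, RLE/polygon segmentations), backgrounds, config, and
# the end-to-end generation pipeline.

test_that("RLE encoding is a lossless column-major round trip", {
  withr::local_seed(1)
  for (i in 1:10) {
    m <- random_blob_mask(sample(5:30, 1), sample(5:30, 1), sample(1:3, 1))
    r <- rle_encode(m)
    expect_identical(rle_decode(r), m)
    expect_equal(sum(r$counts), length(m))
    # even-position counts are the foreground runs
    fg_runs <- seq_along(r$counts) %% 2 == 0
    expect_equal(sum(r$counts[fg_runs]), sum(m))
  }
})

test_that("polygon and RLE encodings decode to the identical mask", {
  withr::local_seed(2)
  for (i in 1:6) {
    m <- random_blob_mask(20, 22, 2)
    via_rle <- rle_decode(rle_encode(m))
    via_poly <- polygon_decode(polygon_encode(m), nrow(m), ncol(m))
    expect_identical(via_poly, via_rle)
  }
  # a mask with a hole decodes exactly via even-odd filling
  ring <- matrix(0L, 15, 15)
  ring[4:12, 4:12] <- 1L
  ring[7:9, 7:9] <- 0L
  expect_identical(polygon_decode(polygon_encode(ring), 15, 15), ring)
})

test_that("COCO write/read round-trips masks, boxes, areas, categories", {
  withr::local_seed(3)
  dir <- withr::local_tempdir()
  records <- lapply(1:4, function(i) {
    H <- 24; W <- 24
    masks <- list()
    for (k in 1:sample(1:3, 1)) {
      masks[[as.character(k)]] <- random_blob_mask(H, W, 1)
    }
    img <- round(array(stats::runif(H * W * 3, 0, 255), c(H, W, 3)))
    ms <- structure(list(visible_masks = masks, amodal_masks = NULL,
                         label_image = NULL,
                         bboxes = lapply(masks, mask_bbox),
                         size = c(H, W), mode = "visible"),
                    class = "instance_mask_set")
    list(image_id = sprintf("im%02d", i), image = img, masks = ms)
  })
  for (seg in c("rle", "polygon")) {
    d <- file.path(dir, seg)
    path <- write_coco(records, d, segmentation = seg)
    back <- read_coco(path)
    expect_length(back, 4)
    for (i in 1:4) {
      rec <- records[[i]]
      got <- back[[match(rec$image_id,
                         vapply(back, `[[`, character(1), "image_id"))]]
      expect_identical(got$image, rec$image)
      keep <- Filter(function(k) sum(rec$masks$visible_masks[[k]]) > 0,
                     names(rec$masks$visible_masks))
      expect_length(got$masks, length(keep))
      for (j in seq_along(keep)) {
        m <- rec$masks$visible_masks[[keep[j]]]
        expect_identical(got$masks[[j]], m)
        expect_equal(got$areas[j], sum(m))
        bb <- mask_bbox(m)
        expect_equal(got$bboxes[[j]],
                     as.numeric(c(bb[1], bb[2], bb[3] - bb[1],
                                  bb[4] - bb[2])))
        expect_equal(got$categories[j], 1)
      }
    }
  }
})

test_that("empty record lists produce a valid COCO file", {
  dir <- withr::local_tempdir()
  path <- write_coco(list(), dir)
  doc <- jsonlite::read_json(path)
  expect_length(doc$annotations, 0)
  expect_equal(doc$categories[[1]]$name, "leaf")
  expect_length(read_coco(path), 0)
})

test_that("missing image files are reported by id", {
  dir <- withr::local_tempdir()
  m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L
  ms <- structure(list(visible_masks = list(`1` = m), amodal_masks = NULL,
                       label_image = NULL, bboxes = list(`1` = mask_bbox(m)),
                       size = c(8, 8), mode = "visible"),
                  class = "instance_mask_set")
  rec <- list(image_id = "lost", image = flat_background(8, 8), masks = ms)
  path <- write_coco(list(rec), dir)
  unlink(file.path(dir, "images", "lost.png"))
  expect_error(read_coco(path), "lost")
  expect_silent(read_coco(path, load_images = FALSE))
})

test_that("amodal masks go to a parallel annotation file", {
  dir <- withr::local_tempdir()
  vis <- matrix(0L, 10, 10); vis[3:5, 3:5] <- 1L
  amo <- vis; amo[3:7, 3:7] <- 1L
  ms <- structure(list(visible_masks = list(`1` = vis),
                       amodal_masks = list(`1` = amo), label_image = vis,
                       bboxes = list(`1` = mask_bbox(vis)),
                       size = c(10, 10), mode = "both"),
                  class = "instance_mask_set")
  rec <- list(image_id = "a", image = flat_background(10, 10), masks = ms)
  write_coco(list(rec), dir)
  amodal_path <- file.path(dir, "annotations.amodal.json")
  expect_true(file.exists(amodal_path))
  back <- read_coco(amodal_path)
  expect_identical(back[[1]]$masks[[1]], amo)
})

test_that("procedural backgrounds are seeded and cover the colour ramp", {
  b1 <- make_background(64, 64, seed = 9)
  expect_identical(b1, make_background(64, 64, seed = 9))
  expect_false(identical(b1, make_background(64, 64, seed = 10)))
  flat <- make_background(16, 16, background_style(amplitude = 0), seed = 1)
  expect_equal(length(unique(as.vector(flat[, , 1]))), 1)
  big <- make_background(256, 256, seed = 2)
  # distinct pixel colours from at least two ramp segments
  cols <- unique(matrix(big, ncol = 3))
  expect_gt(nrow(cols), 50)
  expect_gt(diff(range(big[, , 1])), 30)
})

test_that("generation is bit-identical under a fixed config and seed", {
  cfg <- generation_config(preset_grammar("rosette"), iterations = 8,
                           count = 1, seed = 21, image_size = c(64, 64))
  r1 <- generate_dataset(cfg)[[1]]
  r2 <- generate_dataset(cfg)[[1]]
  expect_identical(r1$image, r2$image)
  expect_identical(r1$masks$visible_masks, r2$masks$visible_masks)
  expect_identical(r1$masks$amodal_masks, r2$masks$amodal_masks)
  expect_identical(r1$provenance$record_seed, r2$provenance$record_seed)
})

test_that("records get distinct per-record seeds and implied leaf counts", {
  cfg <- generation_config(preset_grammar("rosette"), iterations = 8,
                           count = 3, seed = 2, image_size = c(64, 64))
  recs <- generate_dataset(cfg)
  seeds <- vapply(recs, function(r) r$provenance$record_seed, numeric(1))
  expect_equal(length(unique(seeds)), 3)
  # deterministic rosette: the grammar places exactly 8 leaves
  g <- read_grammar(preset_grammar("rosette"))
  implied <- sum(vapply(derive(g, 8, 0)$symbols,
                        function(x) x$name == "L", logical(1)))
  expect_equal(implied, 8)
  for (r in recs) {
    expect_equal(length(r$masks$amodal_masks), implied)
    expect_equal(r$model$leaf_count, implied)
  }
})

test_that("YAML configs resolve paths and nested styles", {
  dir <- withr::local_tempdir()
  file.copy(preset_grammar("rosette"), file.path(dir, "rosette.lsys"))
  file.copy(preset_grammar("leaf"), file.path(dir, "leaf.lsys"))
  writeLines(c("grammar: rosette.lsys",
               "iterations: 8",
               "count: 2",
               "seed: 4",
               "image_size: [48, 48]",
               "mask_mode: visible",
               "blend: feathered",
               "feather_radius: 2",
               "style:",
               "  base_color: [40, 90, 35]",
               "  noise_amplitude: 0"),
             file.path(dir, "cfg.yaml"))
  cfg <- read_generation_config(file.path(dir, "cfg.yaml"))
  expect_equal(cfg$count, 2)
  expect_equal(cfg$image_size, c(48L, 48L))
  expect_equal(cfg$style$base_color, c(40, 90, 35))
  expect_equal(cfg$composition$blend, "feathered")
  recs <- generate_dataset(cfg)
  expect_length(recs, 2)
  expect_null(recs[[1]]$masks$amodal_masks)
})
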