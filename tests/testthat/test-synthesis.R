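# Texture generation, composition, refinement pairs, and objective values.

test_that("degenerate style yields a constant base colour inside the mask", {
  mask <- as_patch(random_blob_mask(16, 16, 1))
  style <- leaf_style(base_color = c(60, 120, 50), base_jitter = 0,
                      vein_width = 0, rim_darkening = 0,
                      noise_amplitude = 0)
  tex <- procedural_texture(mask, style, seed = 1)
  inside <- mask$mask > 0
  for (ch in 1:3) {
    vals <- tex[, , ch][inside]
    expect_true(all(vals == c(60, 120, 50)[ch]))
    expect_true(all(tex[, , ch][!inside] == style$background[ch]))
  }
})

test_that("texture generation is deterministic and seed-sensitive", {
  mask <- as_patch(random_blob_mask(20, 20, 2))
  style <- leaf_style()
  expect_identical(procedural_texture(mask, style, 5),
                   procedural_texture(mask, style, 5))
  expect_false(identical(procedural_texture(mask, style, 5),
                         procedural_texture(mask, style, 6)))
  expect_error(procedural_texture(matrix(0L, 4, 4)), "empty mask")
})

test_that("rim darkening makes the centre brighter than the boundary", {
  n <- 25
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  disc <- matrix(as.integer((yy - 13)^2 + (xx - 13)^2 <= 100), n, n)
  style <- leaf_style(base_jitter = 0, vein_width = 0, rim_darkening = 1,
                      noise_amplitude = 0)
  tex <- procedural_texture(as_patch(disc), style, 0)
  g <- tex[, , 2]
  boundary <- disc == 1 & (rbind(0L, disc[-n, ]) == 0 |
                           rbind(disc[-1, ], 0L) == 0 |
                           cbind(0L, disc[, -n]) == 0 |
                           cbind(disc[, -1], 0L) == 0)
  expect_gt(g[13, 13], max(g[boundary]))
})

test_that("compose is the identity without foreground", {
  bg <- flat_background(12, 12)
  expect_identical(compose(list(), list(), bg), bg)
})

test_that("a full-frame hard paste replaces the whole image", {
  bg <- flat_background(6, 6)
  mask <- as_patch(matrix(1L, 6, 6))
  tex <- flat_background(6, 6, c(200, 100, 50))
  out <- compose(list(mask), list(tex), bg)
  expect_identical(out, tex)
})

test_that("overlap pixels take the texture pasted last in depth order", {
  bg <- flat_background(4, 4, c(0, 0, 0))
  m1 <- as_patch(matrix(1L, 2, 2), x0 = 0, y0 = 0, id = 1)
  m2 <- as_patch(matrix(1L, 2, 2), x0 = 1, y0 = 1, id = 2)
  t1 <- flat_background(2, 2, c(10, 10, 10))
  t2 <- flat_background(2, 2, c(250, 250, 250))
  out <- compose(list(m1, m2), list(t1, t2), bg,
                 composition_config(depth_order = c(1, 2)))
  expect_equal(out[2, 2, 1], 250)  # the overlap pixel, id 2 pasted last
  out_rev <- compose(list(m1, m2), list(t1, t2), bg,
                     composition_config(depth_order = c(2, 1)))
  expect_equal(out_rev[2, 2, 1], 10)
  expect_equal(out[1, 1, 1], 10)   # non-overlap pixels keep their own paste
  expect_equal(out[3, 3, 1], 250)
  expect_equal(out[4, 4, 1], 0)    # background untouched
})

test_that("background outside all masks is bit-identical after composition", {
  withr::local_seed(11)
  for (i in 1:20) {
    H <- 24; W <- 24
    bg <- array(stats::runif(H * W * 3, 0, 255), c(H, W, 3))
    n <- sample(1:4, 1)
    patches <- lapply(seq_len(n), function(k) {
      m <- random_blob_mask(8, 8, 1)
      as_patch(m, x0 = sample(0:(W - 8), 1), y0 = sample(0:(H - 8), 1),
               id = k)
    })
    textures <- lapply(patches, function(p) {
      flat_background(nrow(p$mask), ncol(p$mask), stats::runif(3, 0, 255))
    })
    blend <- sample(c("hard", "feathered"), 1)
    out <- compose(patches, textures, bg, composition_config(blend))
    covered <- matrix(FALSE, H, W)
    for (p in patches) {
      rows <- (p$bbox[2] + 1):p$bbox[4]
      cols <- (p$bbox[1] + 1):p$bbox[3]
      covered[rows, cols] <- covered[rows, cols] | (p$mask > 0)
    }
    for (ch in 1:3) {
      expect_identical(out[, , ch][!covered], bg[, , ch][!covered])
    }
  }
})

test_that("compose/crop round trip reproduces the texture on mask pixels", {
  bg <- flat_background(20, 20)
  m <- random_blob_mask(9, 9, 1)
  p <- as_patch(m, x0 = 4, y0 = 6)
  tex <- procedural_texture(p, leaf_style(), 3)
  out <- compose(list(p), list(tex), bg)
  reg <- out[(p$bbox[2] + 1):p$bbox[4], (p$bbox[1] + 1):p$bbox[3], ,
             drop = FALSE]
  sel <- m > 0
  for (ch in 1:3) {
    expect_identical(reg[, , ch][sel], tex[, , ch][sel])
  }
})

test_that("refinement pairs change exactly the archived mask pixels", {
  withr::local_seed(5)
  gen <- procedural_generator(leaf_style(), seed = 1)
  img <- flat_background(30, 30, c(120, 130, 140))
  masks <- lapply(1:3, function(k) {
    as_patch(random_blob_mask(10, 10, 1), x0 = 10 * (k - 1),
             y0 = (7 * k) %% 18, id = k)
  })
  rec <- list(image_id = "img_a", patches = masks)
  pairs <- build_refinement_pairs(list(rec), gen, list(img_a = img))
  expect_length(pairs, 1)
  expect_identical(pairs[[1]]$target, img)
  changed <- apply(abs(pairs[[1]]$input - pairs[[1]]$target), c(1, 2), sum) > 0
  covered <- matrix(FALSE, 30, 30)
  for (p in masks) {
    rows <- (p$bbox[2] + 1):p$bbox[4]; cols <- (p$bbox[1] + 1):p$bbox[3]
    covered[rows, cols] <- covered[rows, cols] | (p$mask > 0)
  }
  expect_true(all(changed <= covered))  # support within the mask union
  expect_gt(sum(changed), 0.5 * sum(covered))

  # no records: input equals target
  pairs0 <- build_refinement_pairs(
    list(list(image_id = "img_a", patches = list())), gen,
    list(img_a = img))
  expect_identical(pairs0[[1]]$input, pairs0[[1]]$target)
  expect_error(build_refinement_pairs(list(rec), gen, list()),
               "missing source image")
})

test_that("cGAN objective matches its closed form and sign bound", {
  expect_equal(cgan_loss(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  expect_error(cgan_loss(1, 0.5), "strictly inside")
  expect_error(cgan_loss(0.5, 0), "strictly inside")
  withr::local_seed(2)
  for (i in 1:20) {
    dr <- stats::runif(8, 0.01, 0.99)
    df <- stats::runif(8, 0.01, 0.99)
    expect_lte(cgan_loss(dr, df), 0)
    expect_equal(cgan_loss(sample(dr), df), cgan_loss(dr, df))
  }
  # perfect-discriminator limit approaches the supremum 0 from below
  expect_gt(cgan_loss(1 - 1e-12, 1e-12), -1e-9)
})

test_that("L1 loss is a metric with the expected values", {
  a <- array(stats::runif(48, 0, 255), c(4, 4, 3))
  expect_equal(l1_loss(a, a), 0)
  expect_equal(l1_loss(a, a + 10), 10)
  expect_equal(l1_loss(matrix(c(0, 255), 1), matrix(c(255, 0), 1)), 255)
  expect_error(l1_loss(a, a[1:2, , ]), "shape mismatch")
  withr::local_seed(8)
  for (i in 1:10) {
    x <- stats::runif(6); y <- stats::runif(6); z <- stats::runif(6)
    expect_equal(l1_loss(x, y), l1_loss(y, x))
    expect_lte(l1_loss(x, z), l1_loss(x, y) + l1_loss(y, z) + 1e-12)
  }
})

test_that("total objective applies the default weights exactly", {
  expect_equal(total_objective(0, 0), 0)
  expect_equal(total_objective(-1.3863, 10), 0.01 * -1.3863 + 10)
  expect_equal(total_objective(-5, 3, w_gan = 0), 3)
})

test_that("patch archives round-trip through disk", {
  withr::local_seed(4)
  dir <- withr::local_tempdir()
  patches <- lapply(1:3, function(k) {
    as_patch(random_blob_mask(8, 8, 1), x0 = 2 * k, y0 = k, id = k)
  })
  textures <- lapply(patches, function(p) {
    round(array(stats::runif(8 * 8 * 3, 0, 255), c(8, 8, 3)))
  })
  rec <- list(image_id = "plant01", patches = patches, textures = textures,
              scores = c(0.9, 0.8, 0.7), prompt = "leaf")
  write_patch_archive(list(rec), dir)
  back <- read_patch_archive(dir)
  expect_length(back$records, 1)
  r <- back$records[[1]]
  expect_identical(r$image_id, "plant01")
  expect_equal(r$scores, c(0.9, 0.8, 0.7))
  for (k in 1:3) {
    expect_identical(r$patches[[k]]$mask, patches[[k]]$mask)
    expect_equal(unname(r$patches[[k]]$bbox), unname(patches[[k]]$bbox))
    expect_equal(r$textures[[k]], textures[[k]])
  }
})
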