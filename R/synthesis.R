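# Mask-to-texture generation, cut-and-paste composition of plant images,
# refinement-pair construction, and the adversarial/reconstruction
# objective values used when training learned texture generators.
#
# Images are numeric H x W x 3 arrays on the [0, 255] scale throughout;
# PNG conversion happens only at I/O time.

#' Procedural leaf style
#'
#' Parameters of the deterministic procedural texture generator: a base
#' colour with per-patch jitter, a vein skeleton (midrib along the mask's
#' principal axis plus paired secondary veins), rim darkening driven by the
#' distance to the mask boundary, and per-pixel speckle noise. The patch
#' region outside the mask is filled with `background`, mirroring generated
#' patches that contain both the leaf and its surroundings; composition
#' masks that background out again.
#'
#' @param base_color mean leaf RGB, 0-255.
#' @param base_jitter half-range of the uniform per-patch colour jitter.
#' @param vein_color vein RGB.
#' @param vein_density secondary veins per pixel of midrib length.
#' @param vein_width vein half-width in pixels.
#' @param rim_darkening 0 (flat) to 1 (boundary fully dark).
#' @param noise_amplitude half-range of per-pixel speckle, 0-255.
#' @param background RGB used outside the mask.
#' @return a `leaf_style` list.
#' @export
leaf_style <- function(base_color = c(52, 110, 44), base_jitter = 18,
                       vein_color = c(150, 190, 120), vein_density = 0.08,
                       vein_width = 1, rim_darkening = 0.45,
                       noise_amplitude = 10, background = c(84, 62, 45)) {
  stopifnot(all(base_color >= 0 & base_color <= 255),
            all(vein_color >= 0 & vein_color <= 255),
            vein_density >= 0, rim_darkening >= 0, rim_darkening <= 1,
            noise_amplitude >= 0, noise_amplitude <= 255)
  structure(list(base_color = base_color, base_jitter = base_jitter,
                 vein_color = vein_color, vein_density = vein_density,
                 vein_width = vein_width, rim_darkening = rim_darkening,
                 noise_amplitude = noise_amplitude, background = background),
            class = "leaf_style")
}

# Normalized distance-to-boundary inside the mask (1 at the innermost pixel).
.mask_depth <- function(mask) {
  d <- as.matrix(EBImage::distmap(mask))
  mx <- max(d)
  if (mx > 0) d / mx else d
}

#' Generate a leaf texture from a mask patch
#'
#' Deterministic procedural stand-in for a learned mask-to-texture
#' generator: inside the mask the base colour is shaded by the normalized
#' distance to the boundary (rim darkening), a midrib plus secondary-vein
#' skeleton is drawn along the mask's principal axis, and seeded speckle
#' noise is added; outside the mask the patch is filled with the style's
#' background colour. Identical `(mask, style, seed)` always produce an
#' identical patch.
#'
#' @param mask a `mask_patch` or a 0/1 matrix.
#' @param style a [leaf_style()].
#' @param seed integer seed for jitter and speckle.
#' @return H x W x 3 numeric array, integer values in `[0, 255]`.
#' @export
procedural_texture <- function(mask, style = leaf_style(), seed = 0L) {
  m <- if (inherits(mask, "mask_patch")) mask$mask else mask
  if (!sum(m)) stop("empty mask", call. = FALSE)
  h <- nrow(m); w <- ncol(m)
  inside <- m > 0

  depth <- .mask_depth(m)
  shade <- (1 - style$rim_darkening) + style$rim_darkening * depth

  withr::with_seed(seed, {
    jitter <- stats::runif(3, -style$base_jitter, style$base_jitter)
    base <- clamp(style$base_color + jitter, 0, 255)

    vein <- matrix(FALSE, h, w)
    if (style$vein_width > 0 && any(inside)) {
      pix <- which(inside, arr.ind = TRUE)
      ctr <- colMeans(pix)
      centered <- sweep(pix, 2, ctr)
      ev <- eigen(stats::cov(centered), symmetric = TRUE)$vectors
      major <- ev[, 1]; minor <- ev[, 2]
      a <- centered %*% major  # along-midrib coordinate
      b <- centered %*% minor  # across-midrib coordinate
      vein_m <- matrix(FALSE, h, w)
      vein_m[pix[abs(b) <= style$vein_width, , drop = FALSE]] <- TRUE
      n_side <- max(0L, round(style$vein_density * diff(range(a))))
      if (n_side > 0) {
        anchors <- stats::runif(n_side, min(a), max(a))
        for (a0 in anchors) {
          # paired secondary veins leaving the midrib at ~45 degrees
          off <- abs((a - a0) - abs(b))
          vein_m[pix[off <= style$vein_width, , drop = FALSE]] <- TRUE
        }
      }
      vein <- vein_m & inside
    }

    noise <- matrix(stats::runif(h * w, -style$noise_amplitude,
                                 style$noise_amplitude), h, w)

    tex <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(style$background[ch], h, w)
      leafc <- base[ch] * shade
      leafc[vein] <- style$vein_color[ch] * shade[vein]
      plane[inside] <- leafc[inside] + noise[inside]
      tex[, , ch] <- plane
    }
  })
  round(clamp(tex, 0, 255))
}

#' Texture generator interface
#'
#' Wraps any `function(mask_patch) -> H x W x 3 array` as a named texture
#' generator, the plug-in point where a trained mask-to-image translation
#' network would slot in. [procedural_generator()] is the default.
#'
#' @param generate function taking a `mask_patch` (or 0/1 matrix) and
#'   returning an RGB array of the same height/width.
#' @param name generator name recorded in provenance.
#' @param seed seed stored for provenance; the wrapped function is expected
#'   to be deterministic given it.
#' @return a `texture_generator`.
#' @export
texture_generator <- function(generate, name, seed = 0L) {
  stopifnot(is.function(generate))
  structure(list(generate = generate, name = name, seed = seed),
            class = "texture_generator")
}

#' Default procedural texture generator
#'
#' Binds a [leaf_style()] into a [texture_generator()]. Each patch is
#' textured with a child seed split from `seed` and the patch's instance
#' id, so patches are independent but reproducible.
#'
#' @param style a [leaf_style()].
#' @param seed master seed.
#' @return a `texture_generator`.
#' @export
procedural_generator <- function(style = leaf_style(), seed = 0L) {
  force(style); force(seed)
  texture_generator(function(mask) {
    id <- if (inherits(mask, "mask_patch")) mask$instance_id else 0L
    procedural_texture(mask, style, seed = split_seed(seed, id, stream = 7L))
  }, name = "procedural", seed = seed)
}

#' Composition configuration
#'
#' @param blend `"hard"` (paste mask pixels verbatim) or `"feathered"`
#'   (alpha-blend within `feather_radius` pixels of the mask boundary;
#'   pixels outside the mask are never touched).
#' @param feather_radius feather band width in pixels.
#' @param depth_order instance ids back-to-front, or `NULL` for the given
#'   patch order.
#' @return a `composition_config`.
#' @export
composition_config <- function(blend = c("hard", "feathered"),
                               feather_radius = 1, depth_order = NULL) {
  blend <- match.arg(blend)
  stopifnot(feather_radius >= 0)
  structure(list(blend = blend, feather_radius = feather_radius,
                 depth_order = depth_order),
            class = "composition_config")
}

#' Compose a plant image from textured patches
#'
#' Cut-and-paste composition: starting from the background, each instance
#' is pasted back-to-front at its patch's bounding box; only pixels where
#' the patch mask is 1 are replaced (the generated patch contains its own
#' background, which is masked out here). In feathered mode, mask pixels
#' within the feather band of the boundary are alpha-blended instead of
#' replaced; pixels outside every mask are bit-identical to the input
#' background in both modes.
#'
#' @param patches list of `mask_patch` objects placed in the background
#'   frame via their `bbox`.
#' @param textures list of RGB arrays, one per patch, same height/width as
#'   the patch mask.
#' @param background H x W x 3 numeric array, `[0, 255]`.
#' @param cfg a [composition_config()].
#' @return composed H x W x 3 array, integer values in `[0, 255]`.
#' @export
compose <- function(patches, textures, background,
                    cfg = composition_config()) {
  if (length(patches) != length(textures)) {
    stop("mask/texture count mismatch", call. = FALSE)
  }
  canvas <- background
  H <- dim(background)[1]; W <- dim(background)[2]
  order_idx <- seq_along(patches)
  if (!is.null(cfg$depth_order)) {
    ids <- vapply(patches, `[[`, integer(1), "instance_id")
    if (!setequal(cfg$depth_order, ids)) {
      stop("depth_order must be a permutation of the patch instance ids",
           call. = FALSE)
    }
    order_idx <- match(cfg$depth_order, ids)
  }
  for (i in order_idx) {
    p <- patches[[i]]
    tex <- textures[[i]]
    bb <- p$bbox
    if (bb[1] < 0 || bb[2] < 0 || bb[3] > W || bb[4] > H) {
      stop("patch bbox outside background", call. = FALSE)
    }
    if (!all(dim(p$mask) == dim(tex)[1:2])) {
      stop("texture shape does not match its mask", call. = FALSE)
    }
    rows <- (bb[2] + 1L):bb[4]
    cols <- (bb[1] + 1L):bb[3]
    m <- p$mask > 0
    if (cfg$blend == "hard" || cfg$feather_radius == 0) {
      alpha <- matrix(as.numeric(m), nrow(p$mask))
    } else {
      d <- as.matrix(EBImage::distmap(p$mask))
      alpha <- clamp(d / cfg$feather_radius, 0, 1)
      alpha[!m] <- 0
    }
    sel <- alpha > 0
    for (ch in 1:3) {
      reg <- canvas[rows, cols, ch]
      mixed <- reg * (1 - alpha) + tex[, , ch] * alpha
      # touch only mask pixels so the background stays bit-identical
      reg[sel] <- round(clamp(mixed[sel], 0, 255))
      canvas[rows, cols, ch] <- reg
    }
  }
  canvas
}

#' Build refinement training pairs
#'
#' Constructs the self-supervised dataset for an image refiner: for each
#' source image, every extracted leaf-mask region is overwritten (hard
#' blend) with the texture generator's output for that mask, yielding an
#' aligned (leaf-replaced input, original target) pair. A refiner trained
#' on such pairs learns to map pasted textures back toward natural
#' appearance.
#'
#' @param archive a `patch_archive` (see [read_patch_archive()]) or a list
#'   of records with `image_id` and `patches` (each a `mask_patch`).
#' @param gen a [texture_generator()].
#' @param images named list of H x W x 3 arrays keyed by image id.
#' @return list of `list(input, target, image_id)` pairs.
#' @export
build_refinement_pairs <- function(archive, gen, images) {
  records <- if (inherits(archive, "patch_archive")) archive$records
             else archive
  lapply(records, function(rec) {
    img <- images[[as.character(rec$image_id)]]
    if (is.null(img)) {
      stop(sprintf("missing source image '%s'", rec$image_id), call. = FALSE)
    }
    textures <- lapply(rec$patches, gen$generate)
    input <- compose(rec$patches, textures, img,
                     composition_config("hard"))
    list(input = input, target = img, image_id = rec$image_id)
  })
}

#' Identity refiner
#'
#' The default pluggable image refiner: returns its input unchanged. A
#' trained refinement network slots in as any `function(image) -> image`
#' of the same shape.
#'
#' @param image H x W x 3 array.
#' @return `image`, unchanged.
#' @export
identity_refiner <- function(image) image

#' Conditional-GAN objective value
#'
#' `mean(log d_real) + mean(log(1 - d_fake))` over given discriminator
#' outputs; the value a discriminator attains on a batch, always <= 0 with
#' the supremum 0 approached only by a perfect discriminator. No network
#' is instantiated: the inputs are plain probability arrays.
#'
#' @param d_real,d_fake arrays of discriminator probabilities, strictly
#'   inside (0, 1).
#' @return scalar objective value.
#' @export
cgan_loss <- function(d_real, d_fake) {
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1)) {
    stop("discriminator outputs must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Mean absolute (L1) reconstruction loss
#'
#' @param a,b arrays of identical shape.
#' @return mean of `|a - b|` over all elements.
#' @export
l1_loss <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("shape mismatch", call. = FALSE)
  }
  mean(abs(a - b))
}

#' Weighted total generator objective
#'
#' The combined objective used when training mask-to-texture generators:
#' a small adversarial term plus the L1 reconstruction term, default
#' weights 0.01 and 1.
#'
#' @param cgan value of [cgan_loss()].
#' @param l1 value of [l1_loss()].
#' @param w_gan,w_l1 non-negative weights.
#' @return `w_gan * cgan + w_l1 * l1`.
#' @export
total_objective <- function(cgan, l1, w_gan = 0.01, w_l1 = 1.0) {
  stopifnot(w_gan >= 0, w_l1 >= 0)
  w_gan * cgan + w_l1 * l1
}

## ---- patch-pair archives ---------------------------------------------------

#' Write a patch-pair archive
#'
#' On-disk schema for externally produced segmenter output (mask/texture
#' patch pairs with bbox, prompt and detector score): one directory per
#' source image holding `mask_####.png`, `texture_####.png` and an
#' `index.json`. A synthetic archive with the same schema can be built
#' from this package's own patches for testing.
#'
#' @param records list of records: `image_id`, `patches` (list of
#'   `mask_patch`), optional `textures` (parallel RGB arrays), `scores`,
#'   `prompt`.
#' @param dir archive root directory.
#' @return `dir`, invisibly.
#' @export
write_patch_archive <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in records) {
    rd <- file.path(dir, as.character(rec$image_id))
    dir.create(rd, showWarnings = FALSE)
    idx <- list(image_id = rec$image_id,
                prompt = rec$prompt %||% "leaf", entries = list())
    for (i in seq_along(rec$patches)) {
      p <- rec$patches[[i]]
      png::writePNG(p$mask * 1.0, file.path(rd, sprintf("mask_%04d.png", i)))
      if (!is.null(rec$textures)) {
        png::writePNG(rec$textures[[i]] / 255,
                      file.path(rd, sprintf("texture_%04d.png", i)))
      }
      idx$entries[[i]] <- list(
        index = i, bbox = as.integer(p$bbox),
        score = (rec$scores %||% rep(1, length(rec$patches)))[i])
    }
    jsonlite::write_json(idx, file.path(rd, "index.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a patch-pair archive
#'
#' @param dir archive root written by [write_patch_archive()] or by an
#'   external extraction pipeline following the same schema.
#' @return a `patch_archive`: list with `records`, each holding
#'   `image_id`, `patches` (list of `mask_patch`), `textures` (or `NULL`),
#'   `scores`, `prompt`.
#' @export
read_patch_archive <- function(dir) {
  subdirs <- list.dirs(dir, recursive = FALSE)
  records <- lapply(subdirs, function(rd) {
    idx <- jsonlite::read_json(file.path(rd, "index.json"),
                               simplifyVector = FALSE)
    patches <- list()
    textures <- list()
    scores <- numeric()
    for (e in idx$entries) {
      i <- e$index
      m <- png::readPNG(file.path(rd, sprintf("mask_%04d.png", i)))
      if (length(dim(m)) == 3) m <- m[, , 1]
      bb <- as.integer(unlist(e$bbox))
      patches[[i]] <- structure(
        list(instance_id = i, mask = matrix(as.integer(m > 0.5), nrow(m)),
             bbox = stats::setNames(bb, c("x0", "y0", "x1", "y1")),
             pad = 0L),
        class = "mask_patch")
      tf <- file.path(rd, sprintf("texture_%04d.png", i))
      if (file.exists(tf)) {
        tx <- png::readPNG(tf)
        textures[[i]] <- round(tx[, , 1:3, drop = FALSE] * 255)
      }
      scores <- c(scores, e$score %||% 1)
    }
    list(image_id = idx$image_id, patches = patches,
         textures = if (length(textures)) textures else NULL,
         scores = scores, prompt = idx$prompt %||% "leaf")
  })
  structure(list(records = records, dir = dir), class = "patch_archive")
}
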