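# End-to-end dataset generation: grammar -> string -> model -> masks ->
# textures -> composed image, with deterministic per-record seed splitting
# and provenance sufficient to regenerate any record bit-identically.

#' Generation configuration
#'
#' @param grammar an `lsys_grammar` or a path to a grammar file.
#' @param iterations plant-grammar rewriting iterations.
#' @param count number of images to generate.
#' @param seed master seed; record `i` uses a child seed split from
#'   `(seed, i)`.
#' @param image_size `c(height, width)` pixels.
#' @param camera a [camera_spec()], or `NULL` to fit an orthographic
#'   camera per model with [auto_camera()] using `camera_view`.
#' @param camera_view `"top"` (rosettes) or `"front"` (shoots), used only
#'   when `camera` is `NULL`.
#' @param style a [leaf_style()] for the procedural texture generator;
#'   ignored when `generator` is given.
#' @param generator optional [texture_generator()] plug-in.
#' @param background H x W x 3 array, path to a PNG/JPEG, or `NULL` for a
#'   procedural background per record.
#' @param background_style a [background_style()].
#' @param mask_mode `"visible"`, `"amodal"` or `"both"`.
#' @param composition a [composition_config()]; its `depth_order` is
#'   overridden per record by back-to-front leaf depth.
#' @param pad patch padding in pixels.
#' @param min_area minimum visible-mask area for an instance patch.
#' @param width initial turtle ribbon width.
#' @param refiner pluggable image refiner `function(image) -> image`;
#'   identity by default.
#' @return a `generation_config`.
#' @export
generation_config <- function(grammar, iterations = 6L, count = 1L,
                              seed = 0L, image_size = c(512L, 512L),
                              camera = NULL, camera_view = c("top", "front"),
                              style = leaf_style(),
                              generator = NULL, background = NULL,
                              background_style = leafgen::background_style(),
                              mask_mode = c("both", "visible", "amodal"),
                              composition = composition_config(),
                              pad = 4L, min_area = 16L, width = 0.1,
                              refiner = identity_refiner) {
  mask_mode <- match.arg(mask_mode)
  camera_view <- match.arg(camera_view)
  stopifnot(count >= 1)
  if (is.character(grammar)) grammar <- read_grammar(grammar)
  stopifnot(inherits(grammar, "lsys_grammar"))
  if (is.character(background)) {
    px <- png::readPNG(background)
    background <- round(px[, , 1:3, drop = FALSE] * 255)
  }
  structure(list(grammar = grammar, iterations = as.integer(iterations),
                 count = as.integer(count), seed = seed,
                 image_size = as.integer(image_size), camera = camera,
                 camera_view = camera_view,
                 style = style, generator = generator,
                 background = background,
                 background_style = background_style,
                 mask_mode = mask_mode, composition = composition,
                 pad = as.integer(pad), min_area = as.integer(min_area),
                 width = width, refiner = refiner),
            class = "generation_config")
}

#' Read a generation configuration from YAML
#'
#' Keys mirror the arguments of [generation_config()]; `grammar` and
#' `background` are paths resolved relative to the YAML file. Recognized
#' keys: `grammar`, `iterations`, `count`, `seed`, `image_size`,
#' `mask_mode`, `camera_view`, `blend`, `feather_radius`, `pad`, `min_area`, `width`,
#' `background`, and nested `style` / `background_style` parameter maps.
#'
#' @param path YAML file.
#' @return a `generation_config`.
#' @export
read_generation_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  if (is.null(y$grammar)) stop("config is missing 'grammar'", call. = FALSE)
  style <- do.call(leaf_style, as.list(y$style %||% list()))
  bstyle <- do.call(background_style,
                    as.list(y$background_style %||% list()))
  comp <- composition_config(blend = y$blend %||% "hard",
                             feather_radius = y$feather_radius %||% 1)
  generation_config(
    grammar = file.path(base, y$grammar),
    iterations = y$iterations %||% 6L,
    count = y$count %||% 1L,
    seed = y$seed %||% 0L,
    image_size = as.integer(unlist(y$image_size %||% c(512L, 512L))),
    style = style,
    background = if (!is.null(y$background)) file.path(base, y$background),
    background_style = bstyle,
    mask_mode = y$mask_mode %||% "both",
    camera_view = y$camera_view %||% "top",
    composition = comp,
    pad = y$pad %||% 4L,
    min_area = y$min_area %||% 16L,
    width = y$width %||% 0.1)
}

#' Generate a synthetic image-mask dataset
#'
#' Runs the full pipeline for each record: hierarchical derivation,
#' turtle interpretation, mask rendering, per-instance patch cropping,
#' texturing, and back-to-front composition over the background, then the
#' pluggable refiner. Record `i` derives every stochastic stage from a
#' child seed split deterministically from `(cfg$seed, i)`, so a config
#' plus seed regenerates the dataset bit-identically.
#'
#' @param cfg a [generation_config()].
#' @return list of `dataset_record`s: `image_id`, `image` (H x W x 3,
#'   integers 0-255), `masks` (an `instance_mask_set`), `model`, and
#'   `provenance` (grammar hash, seeds, camera, style).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generation_config"))
  records <- vector("list", cfg$count)
  for (i in seq_len(cfg$count)) {
    records[[i]] <- tryCatch(
      .generate_record(cfg, i),
      error = function(e) {
        stop(sprintf("record %d: %s", i, conditionMessage(e)), call. = FALSE)
      })
  }
  records
}

.generate_record <- function(cfg, i) {
  seed_i <- split_seed(cfg$seed, i, stream = 2L)
  s <- expand_hierarchical(cfg$grammar, cfg$iterations, seed_i)
  model <- interpret(s, width = cfg$width)
  cam <- cfg$camera %||% auto_camera(model, size = cfg$image_size,
                                     view = cfg$camera_view)
  masks <- render_masks(model, cam, mode = cfg$mask_mode)
  patches <- crop_patches(masks, pad = cfg$pad, min_area = cfg$min_area,
                          source = if (cfg$mask_mode == "amodal")
                            "amodal" else "visible")
  gen <- cfg$generator %||%
    procedural_generator(cfg$style, seed = split_seed(seed_i, 1L,
                                                      stream = 3L))
  textures <- lapply(patches, gen$generate)
  background <- cfg$background %||% make_background(
    cfg$image_size[1], cfg$image_size[2], cfg$background_style,
    seed = split_seed(seed_i, 2L, stream = 4L))
  comp <- cfg$composition
  if (length(patches)) {
    ids <- vapply(patches, `[[`, integer(1), "instance_id")
    depth <- masks$leaf_depth[as.character(ids)]
    comp$depth_order <- ids[order(-depth, ids)]  # far leaves pasted first
  } else {
    comp$depth_order <- NULL
  }
  image <- compose(patches, textures, background, comp)
  image <- cfg$refiner(image)
  structure(
    list(image_id = sprintf("img_%04d", i), image = image, masks = masks,
         model = model,
         provenance = list(grammar_hash = text_hash(cfg$grammar$source),
                           iterations = cfg$iterations,
                           master_seed = cfg$seed, record_seed = seed_i,
                           record_index = i,
                           camera = cam[c("projection", "size",
                                          "units_per_pixel")],
                           generator = (cfg$generator %||%
                                          list(name = "procedural"))$name,
                           mask_mode = cfg$mask_mode)),
    class = "dataset_record")
}

#' @export
print.dataset_record <- function(x, ...) {
  cat("dataset record", x$image_id, ":",
      paste(dim(x$image)[1:2], collapse = "x"), "px,",
      length(x$masks$visible_masks %||% x$masks$amodal_masks),
      "leaf instances\n")
  invisible(x)
}

#' Path of a bundled preset grammar
#'
#' Two toy presets ship with the package: `"rosette"`, a deterministic
#' flat rosette of 8 leaves (top-down imaging, Arabidopsis-like habit),
#' and `"shoot"`, a stochastic branching shoot with leaves at branch tips.
#' They are stand-ins demonstrating the grammar dialect, not reproductions
#' of any published species grammar.
#'
#' @param name `"rosette"` or `"shoot"`; with no argument, lists the
#'   available presets.
#' @return file path (or preset names).
#' @export
preset_grammar <- function(name) {
  dir <- system.file("extdata", package = "leafgen")
  if (missing(name)) {
    return(sub("\\.lsys$", "", basename(
      list.files(dir, pattern = "\\.lsys$"))))
  }
  path <- file.path(dir, paste0(name, ".lsys"))
  if (!file.exists(path)) {
    stop(sprintf("no preset grammar '%s'", name), call. = FALSE)
  }
  path
}
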