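# Software rasterization of plant models into per-leaf instance masks.
#
# Masks are binary {0,1} integer matrices, row-major with origin at the
# top-left pixel; bounding boxes are 0-based half-open (x0, y0, x1, y1),
# matching COCO conventions downstream. Pixel (r, c) is tested at its
# centre, continuous image coordinates (c - 0.5, r - 0.5).

#' Camera specification
#'
#' @param projection `"orthographic"` (default; top-down rosette imaging)
#'   or `"perspective"`.
#' @param eye,look_at,up_hint camera position, target and roll hint in
#'   world units.
#' @param size image size as `c(height, width)` pixels.
#' @param units_per_pixel world units per pixel (orthographic only).
#' @param fov vertical field of view in degrees (perspective only).
#' @return a `camera_spec`.
#' @export
camera_spec <- function(projection = c("orthographic", "perspective"),
                        eye = c(0, 0, 10), look_at = c(0, 0, 0),
                        up_hint = c(0, 1, 0), size = c(256, 256),
                        units_per_pixel = 0.02, fov = 40) {
  projection <- match.arg(projection)
  stopifnot(length(size) == 2, all(size >= 1))
  if (sum((eye - look_at)^2) < 1e-18) {
    stop("degenerate camera: eye equals look_at", call. = FALSE)
  }
  if (projection == "orthographic" &&
      (!is.finite(units_per_pixel) || units_per_pixel <= 0)) {
    stop("degenerate camera: zero pixel scale", call. = FALSE)
  }
  f <- .unit3(look_at - eye)
  r <- .cross3(f, .unit3(up_hint))
  if (.norm3(r) < 1e-9) {
    stop("up_hint parallel to viewing direction", call. = FALSE)
  }
  r <- .unit3(r)
  u <- .cross3(r, f)
  structure(list(projection = projection, eye = as.numeric(eye),
                 look_at = as.numeric(look_at), size = as.integer(size),
                 units_per_pixel = units_per_pixel, fov = fov,
                 basis = list(right = r, up = u, forward = f)),
            class = "camera_spec")
}

#' Orthographic camera fitted to a model
#'
#' `"top"` places the camera on the +Z axis looking straight down (rosette
#' imaging); `"front"` on the -Y axis looking horizontally (shoots and
#' trees, +Z up in the image). The pixel scale is chosen so the model
#' fills the frame up to a relative margin.
#'
#' @param model a `plant_model`.
#' @param size image size `c(height, width)`.
#' @param margin fraction of the frame left empty around the model.
#' @param view `"top"` or `"front"`.
#' @return a `camera_spec`.
#' @export
auto_camera <- function(model, size = c(256, 256), margin = 0.08,
                        view = c("top", "front")) {
  view <- match.arg(view)
  bb <- model_bbox(model)
  center <- colMeans(bb)
  extent <- pmax(bb[2, ] - bb[1, ], 1e-6)
  dist <- max(extent) + 1
  if (view == "top") {
    upp <- max(extent[1] / size[2], extent[2] / size[1]) / (1 - 2 * margin)
    camera_spec("orthographic",
                eye = c(center[1], center[2], bb[2, 3] + dist),
                look_at = c(center[1], center[2], bb[1, 3]),
                up_hint = c(0, 1, 0), size = size, units_per_pixel = upp)
  } else {
    upp <- max(extent[1] / size[2], extent[3] / size[1]) / (1 - 2 * margin)
    camera_spec("orthographic",
                eye = c(center[1], bb[1, 2] - dist, center[3]),
                look_at = c(center[1], bb[2, 2], center[3]),
                up_hint = c(0, 0, 1), size = size, units_per_pixel = upp)
  }
}

#' Directional light
#'
#' @param direction 3-vector pointing from the source toward the scene;
#'   normalized internally.
#' @param ambient ambient term in `[0, 1]`.
#' @return a `light_spec`.
#' @export
light_spec <- function(direction = c(0, 0, -1), ambient = 0.2) {
  stopifnot(ambient >= 0, ambient <= 1)
  structure(list(direction = .unit3(direction), ambient = ambient),
            class = "light_spec")
}

# Project world vertices (n x 3) to continuous pixel coordinates and camera
# depth. Columns: px, py, depth.
project_points <- function(cam, V) {
  V <- matrix(V, ncol = 3)
  d <- sweep(V, 2, cam$eye)
  xc <- d %*% cam$basis$right
  yc <- d %*% cam$basis$up
  depth <- d %*% cam$basis$forward
  H <- cam$size[1]; W <- cam$size[2]
  if (cam$projection == "orthographic") {
    px <- xc / cam$units_per_pixel + W / 2
    py <- H / 2 - yc / cam$units_per_pixel
  } else {
    fpx <- (H / 2) / tan(cam$fov * pi / 360)
    px <- (xc / depth) * fpx + W / 2
    py <- H / 2 - (yc / depth) * fpx
  }
  cbind(px = as.numeric(px), py = as.numeric(py), depth = as.numeric(depth))
}

# Rasterize one projected triangle. Returns list(idx, z): linear matrix
# indices (column-major into an H x W matrix) and interpolated depths.
# Inclusive >= -tol barycentric test; orientation-independent.
.raster_triangle <- function(P, H, W, tol = 1e-9) {
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  denom <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
  if (abs(denom) < 1e-12) return(NULL)
  r0 <- max(1L, as.integer(floor(min(y) + 0.5)))
  r1 <- min(H, as.integer(ceiling(max(y) + 0.5)))
  c0 <- max(1L, as.integer(floor(min(x) + 0.5)))
  c1 <- min(W, as.integer(ceiling(max(x) + 0.5)))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  cy <- rep(rows - 0.5, times = length(cols))
  cx <- rep(cols - 0.5, each = length(rows))
  l1 <- ((y[2] - y[3]) * (cx - x[3]) + (x[3] - x[2]) * (cy - y[3])) / denom
  l2 <- ((y[3] - y[1]) * (cx - x[3]) + (x[1] - x[3]) * (cy - y[3])) / denom
  l3 <- 1 - l1 - l2
  inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
  if (!any(inside)) return(NULL)
  ridx <- rep(rows, times = length(cols))[inside]
  cidx <- rep(cols, each = length(rows))[inside]
  list(idx = ridx + (cidx - 1L) * H,
       z = l1[inside] * z[1] + l2[inside] * z[2] + l3[inside] * z[3])
}

#' Render per-leaf instance masks
#'
#' Projects every organ triangle and scanline-rasterizes it against a
#' single per-pixel z-buffer spanning all organs. The label image records
#' the frontmost leaf instance per pixel; stem and branch organs occlude
#' but label 0. Visible masks are the label-image level sets, so they are
#' pairwise disjoint and partition the leaf foreground by construction.
#' Amodal masks rasterize each leaf alone with no depth test against other
#' organs, giving the full projected extent including occluded parts.
#' Depth ties within 1e-9 are broken toward the lower instance id.
#'
#' @param model a `plant_model` with at least one organ.
#' @param cam a `camera_spec`.
#' @param mode `"visible"`, `"amodal"`, or `"both"`.
#' @return an `instance_mask_set`: `visible_masks` / `amodal_masks` (named
#'   lists of H x W 0/1 integer matrices keyed by leaf instance id),
#'   `label_image`, `bboxes` (0-based half-open `c(x0, y0, x1, y1)` tight
#'   around each visible mask), `visibility` (visible / amodal pixel
#'   counts, when both modes are rendered) and `leaf_depth` (mean camera
#'   depth per leaf, used for back-to-front composition).
#' @export
render_masks <- function(model, cam, mode = c("both", "visible", "amodal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "plant_model"), inherits(cam, "camera_spec"))
  if (!length(model$organs)) stop("empty model", call. = FALSE)
  H <- cam$size[1]; W <- cam$size[2]

  leaf_ids <- sort(vapply(
    Filter(function(o) o$organ_class == "leaf", model$organs),
    function(o) as.integer(o$instance_id), integer(1)))

  proj <- lapply(model$organs, function(o) project_points(cam, o$vertices))

  visible_masks <- NULL
  label <- NULL
  instbuf <- NULL
  if (mode %in% c("visible", "both")) {
    zbuf <- matrix(Inf, H, W)
    instbuf <- matrix(-1L, H, W)
    eps <- 1e-9
    for (oi in seq_along(model$organs)) {
      o <- model$organs[[oi]]
      P <- proj[[oi]]
      if (cam$projection == "perspective" && any(P[, 3] <= 1e-9)) next
      for (t in seq_len(nrow(o$triangles))) {
        hit <- .raster_triangle(P[o$triangles[t, ], , drop = FALSE], H, W)
        if (is.null(hit)) next
        zc <- zbuf[hit$idx]
        ic <- instbuf[hit$idx]
        closer <- hit$z < zc - eps
        tie <- abs(hit$z - zc) <= eps & (o$instance_id < ic)
        upd <- closer | tie
        if (any(upd)) {
          zbuf[hit$idx[upd]] <- hit$z[upd]
          instbuf[hit$idx[upd]] <- o$instance_id
        }
      }
    }
    label <- matrix(0L, H, W)
    for (k in leaf_ids) label[instbuf == k] <- k
    visible_masks <- stats::setNames(
      lapply(leaf_ids, function(k) matrix(as.integer(label == k), H, W)),
      as.character(leaf_ids))
  }

  amodal_masks <- NULL
  if (mode %in% c("amodal", "both")) {
    amodal_masks <- stats::setNames(vector("list", length(leaf_ids)),
                                    as.character(leaf_ids))
    for (oi in seq_along(model$organs)) {
      o <- model$organs[[oi]]
      if (o$organ_class != "leaf") next
      P <- proj[[oi]]
      if (cam$projection == "perspective" && any(P[, 3] <= 1e-9)) next
      m <- matrix(0L, H, W)
      for (t in seq_len(nrow(o$triangles))) {
        hit <- .raster_triangle(P[o$triangles[t, ], , drop = FALSE], H, W)
        if (!is.null(hit)) m[hit$idx] <- 1L
      }
      amodal_masks[[as.character(o$instance_id)]] <- m
    }
  }

  ref_masks <- visible_masks %||% amodal_masks
  bboxes <- lapply(ref_masks, mask_bbox)
  visibility <- NULL
  if (!is.null(visible_masks) && !is.null(amodal_masks)) {
    visibility <- stats::setNames(vapply(as.character(leaf_ids), function(k) {
      a <- sum(amodal_masks[[k]])
      if (a == 0) return(NA_real_)
      sum(visible_masks[[k]]) / a
    }, numeric(1)), as.character(leaf_ids))
  }
  leaf_depth <- stats::setNames(vapply(seq_along(model$organs), function(oi) {
    o <- model$organs[[oi]]
    if (o$organ_class == "leaf") mean(proj[[oi]][, 3]) else NA_real_
  }, numeric(1)), vapply(model$organs, function(o) {
    as.character(o$instance_id)
  }, character(1)))
  leaf_depth <- leaf_depth[as.character(leaf_ids)]

  structure(list(visible_masks = visible_masks, amodal_masks = amodal_masks,
                 label_image = label, bboxes = bboxes,
                 visibility = visibility, leaf_depth = leaf_depth,
                 size = c(H, W), mode = mode),
            class = "instance_mask_set")
}

#' @export
print.instance_mask_set <- function(x, ...) {
  n <- length(x$visible_masks %||% x$amodal_masks)
  cat("instance mask set:", n, "instances,",
      paste(x$size, collapse = "x"), "px, mode", x$mode, "\n")
  invisible(x)
}

#' Tight bounding box of a binary mask
#'
#' @param mask 0/1 matrix.
#' @return `c(x0, y0, x1, y1)`, 0-based half-open, or `NULL` for an empty
#'   mask.
#' @export
mask_bbox <- function(mask) {
  w <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  c(x0 = min(w[, 2]) - 1L, y0 = min(w[, 1]) - 1L,
    x1 = max(w[, 2]), y1 = max(w[, 1]))
}

#' Crop per-instance mask patches
#'
#' One patch per instance whose visible mask is non-empty and at least
#' `min_area` pixels (sub-pixel slivers produce degenerate texture patches
#' and poison AP evaluation, so they are skipped). The tight bounding box
#' is symmetrically padded and clipped to the image bounds.
#'
#' @param masks an `instance_mask_set`.
#' @param pad padding in pixels around the tight box.
#' @param min_area minimum visible pixel count for a patch to be emitted.
#' @param source crop from `"visible"` (default) or `"amodal"` masks.
#' @return list of `mask_patch` objects (`instance_id`, `mask`, `bbox`,
#'   `pad`); possibly empty.
#' @export
crop_patches <- function(masks, pad = 0L, min_area = 16L,
                         source = c("visible", "amodal")) {
  source <- match.arg(source)
  ms <- if (source == "visible") masks$visible_masks else masks$amodal_masks
  if (is.null(ms)) stop(sprintf("mask set has no %s masks", source),
                        call. = FALSE)
  H <- masks$size[1]; W <- masks$size[2]
  out <- list()
  for (k in names(ms)) {
    m <- ms[[k]]
    if (sum(m) < max(1L, min_area)) next
    bb <- mask_bbox(m)
    bb <- c(max(0L, bb[1] - pad), max(0L, bb[2] - pad),
            min(W, bb[3] + pad), min(H, bb[4] + pad))
    patch <- m[(bb[2] + 1L):bb[4], (bb[1] + 1L):bb[3], drop = FALSE]
    out[[length(out) + 1L]] <- structure(
      list(instance_id = as.integer(k), mask = patch,
           bbox = stats::setNames(as.integer(bb), c("x0", "y0", "x1", "y1")),
           pad = as.integer(pad)),
      class = "mask_patch")
  }
  out
}

#' Shaded grayscale preview of a model
#'
#' Debug visualization: two-sided Lambertian shading
#' `ambient + (1 - ambient) * |n . l|` per frontmost triangle, z-buffered
#' with the same rasterizer as the masks.
#'
#' @param model a `plant_model`.
#' @param cam a `camera_spec`.
#' @param light a `light_spec`.
#' @return H x W matrix in `[0, 1]`.
#' @export
shaded_preview <- function(model, cam, light = light_spec()) {
  H <- cam$size[1]; W <- cam$size[2]
  zbuf <- matrix(Inf, H, W)
  img <- matrix(0, H, W)
  for (o in model$organs) {
    P <- project_points(cam, o$vertices)
    for (t in seq_len(nrow(o$triangles))) {
      tri <- o$triangles[t, ]
      hit <- .raster_triangle(P[tri, , drop = FALSE], H, W)
      if (is.null(hit)) next
      v <- o$vertices[tri, , drop = FALSE]
      n <- .unit3(.cross3(v[2, ] - v[1, ], v[3, ] - v[1, ]))
      shade <- light$ambient +
        (1 - light$ambient) * abs(sum(n * light$direction))
      upd <- hit$z < zbuf[hit$idx]
      zbuf[hit$idx[upd]] <- hit$z[upd]
      img[hit$idx[upd]] <- shade
    }
  }
  img
}

#' Write an instance mask set as PNG files
#'
#' The label image is written as a 16-bit single-channel PNG; per-instance
#' masks as 8-bit PNGs with values {0, 255}.
#'
#' @param masks an `instance_mask_set`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_mask_pngs <- function(masks, dir, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(masks$label_image)) {
    lab <- EBImage::Image(t(masks$label_image) / 65535)
    EBImage::writeImage(lab, file.path(dir, paste0(prefix, "_labels.png")),
                        type = "png", bits.per.sample = 16L)
  }
  for (kind in c("visible", "amodal")) {
    ms <- masks[[paste0(kind, "_masks")]]
    if (is.null(ms)) next
    for (k in names(ms)) {
      png::writePNG(ms[[k]] * 1.0,
                    file.path(dir, sprintf("%s_%s_%s.png", prefix, kind, k)))
    }
  }
  invisible(dir)
}
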