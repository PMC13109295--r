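# COCO instance-segmentation export/import. Segmentations are stored
# either as uncompressed column-major RLE ({"size": [h, w], "counts":
# [...]}, counts alternating background/foreground starting with
# background) or as boundary polygons traced along pixel edges; both
# decode back to the exact binary mask.

#' Encode a binary mask as uncompressed COCO RLE
#'
#' @param mask 0/1 matrix.
#' @return list with `size = c(h, w)` and integer `counts` (column-major
#'   run lengths, first run counts background pixels).
#' @export
rle_encode <- function(mask) {
  v <- as.integer(as.vector(mask) > 0)  # column-major, as COCO specifies
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' Decode uncompressed COCO RLE to a binary mask
#'
#' @param rle list with `size` and `counts` as produced by [rle_encode()].
#' @return 0/1 integer matrix.
#' @export
rle_decode <- function(rle) {
  size <- as.integer(unlist(rle$size))
  counts <- as.integer(unlist(rle$counts))
  vals <- rep(rep(c(0L, 1L), length.out = length(counts)), counts)
  if (length(vals) != prod(size)) {
    stop("RLE counts do not sum to the mask size", call. = FALSE)
  }
  matrix(vals, size[1], size[2])
}

#' Trace a binary mask into boundary polygons
#'
#' Contours along the half-pixel iso-level of the (zero-padded) mask, in
#' 0-based image coordinates. Because the vertices run along pixel edges,
#' rasterizing the polygons back with an even-odd pixel-centre test
#' ([polygon_decode()]) reproduces the mask exactly, holes included.
#'
#' @param mask 0/1 matrix.
#' @return list of numeric vectors `x1,y1,x2,y2,...` (COCO polygon
#'   layout).
#' @export
polygon_encode <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- mask
  # grid coordinates of pixel centres in 0-based image space; padding ring
  # sits half a pixel outside the image
  cl <- grDevices::contourLines(x = (0:(h + 1)) - 0.5,
                                y = (0:(w + 1)) - 0.5,
                                z = padded, levels = 0.5)
  lapply(cl, function(seg) {
    # contourLines x follows matrix rows (image y), y follows columns (x)
    as.numeric(rbind(seg$y, seg$x))
  })
}

#' Rasterize COCO polygons to a binary mask
#'
#' Even-odd fill over pixel centres, the inverse of [polygon_encode()].
#'
#' @param polys list of `x1,y1,...` numeric vectors.
#' @param height,width output size.
#' @return 0/1 integer matrix.
#' @export
polygon_decode <- function(polys, height, width) {
  cx <- rep(seq_len(width) - 0.5, each = height)
  cy <- rep(seq_len(height) - 0.5, times = width)
  crossings <- integer(height * width)
  for (poly in polys) {
    poly <- as.numeric(unlist(poly))
    xs <- poly[seq(1, length(poly), by = 2)]
    ys <- poly[seq(2, length(poly), by = 2)]
    n <- length(xs)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- ys[i]; y2 <- ys[j]
      if (y1 == y2) next
      x1 <- xs[i]; x2 <- xs[j]
      hitband <- (cy >= pmin(y1, y2)) & (cy < pmax(y1, y2))
      xint <- x1 + (cy - y1) / (y2 - y1) * (x2 - x1)
      crossings <- crossings + as.integer(hitband & cx < xint)
    }
  }
  matrix(as.integer(crossings %% 2L == 1L), height, width)
}

# annotation list for one instance mask
.coco_annotation <- function(mask, ann_id, image_id, category_id,
                             segmentation, score = NULL) {
  bb <- mask_bbox(mask)
  seg <- if (segmentation == "rle") rle_encode(mask) else polygon_encode(mask)
  ann <- list(id = ann_id, image_id = image_id, category_id = category_id,
              segmentation = seg, area = sum(mask),
              bbox = c(bb[1], bb[2], bb[3] - bb[1], bb[4] - bb[2]),
              iscrowd = 0)
  if (!is.null(score)) ann$score <- score
  ann
}

#' Write dataset records as COCO instance annotations
#'
#' Writes images as PNG under `dir/images/` and a COCO JSON annotation
#' file (`annotations.json`). When records carry amodal masks, a parallel
#' `annotations.amodal.json` is written with the amodal segmentations so
#' the visible file stays standard-compliant.
#'
#' @param records list of dataset records from [generate_dataset()], or
#'   any list with `image_id`, `image` and `masks` (an
#'   `instance_mask_set`).
#' @param dir output directory.
#' @param segmentation `"rle"` (default) or `"polygon"`.
#' @return path of the visible-annotation JSON, invisibly.
#' @export
write_coco <- function(records, dir, segmentation = c("rle", "polygon")) {
  segmentation <- match.arg(segmentation)
  dir.create(file.path(dir, "images"), showWarnings = FALSE, recursive = TRUE)
  images <- list()
  anns <- list()
  amodal_anns <- list()
  ann_id <- 0L
  any_amodal <- FALSE
  for (rec in records) {
    H <- dim(rec$image)[1]; W <- dim(rec$image)[2]
    fn <- sprintf("%s.png", rec$image_id)
    png::writePNG(rec$image / 255, file.path(dir, "images", fn))
    images[[length(images) + 1L]] <-
      list(id = rec$image_id, file_name = fn, height = H, width = W)
    vis <- rec$masks$visible_masks
    amo <- rec$masks$amodal_masks
    for (k in names(vis %||% list())) {
      if (!sum(vis[[k]])) next
      ann_id <- ann_id + 1L
      anns[[length(anns) + 1L]] <- .coco_annotation(
        vis[[k]], ann_id, rec$image_id, 1L, segmentation)
      if (!is.null(amo[[k]]) && sum(amo[[k]])) {
        any_amodal <- TRUE
        amodal_anns[[length(amodal_anns) + 1L]] <- .coco_annotation(
          amo[[k]], ann_id, rec$image_id, 1L, segmentation)
      }
    }
  }
  categories <- list(list(id = 1L, name = "leaf", supercategory = "plant"))
  doc <- list(images = images, annotations = anns, categories = categories)
  path <- file.path(dir, "annotations.json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  if (any_amodal) {
    jsonlite::write_json(
      list(images = images, annotations = amodal_anns,
           categories = categories),
      file.path(dir, "annotations.amodal.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a COCO instance-annotation file
#'
#' Inverse of [write_coco()]: decodes every annotation's segmentation
#' (RLE or polygon) back to a binary mask and groups annotations by image.
#'
#' @param path COCO JSON file; images are resolved in `images/` next to
#'   it (set `load_images = FALSE` to skip pixel data).
#' @param load_images read the PNG images as well.
#' @return list of records: `image_id`, `image` (or `NULL`), `height`,
#'   `width`, `masks` (list of 0/1 matrices), `bboxes`, `areas`,
#'   `categories`, `scores`.
#' @export
read_coco <- function(path, load_images = TRUE) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  img_dir <- file.path(dirname(path), "images")
  by_image <- list()
  for (im in doc$images) {
    key <- as.character(im$id)
    image <- NULL
    if (load_images) {
      f <- file.path(img_dir, im$file_name)
      if (!file.exists(f)) {
        stop(sprintf("missing image file for image id '%s'", im$id),
             call. = FALSE)
      }
      px <- png::readPNG(f)
      image <- round(px[, , 1:3, drop = FALSE] * 255)
    }
    by_image[[key]] <- list(image_id = im$id, image = image,
                            height = im$height, width = im$width,
                            masks = list(), bboxes = list(),
                            areas = numeric(), categories = integer(),
                            scores = numeric())
  }
  for (ann in doc$annotations) {
    key <- as.character(ann$image_id)
    rec <- by_image[[key]]
    if (is.null(rec)) {
      stop(sprintf("annotation %s references unknown image id '%s'",
                   ann$id, ann$image_id), call. = FALSE)
    }
    seg <- ann$segmentation
    mask <- if (!is.null(seg$counts)) {
      rle_decode(seg)
    } else {
      polygon_decode(seg, rec$height, rec$width)
    }
    i <- length(rec$masks) + 1L
    rec$masks[[i]] <- mask
    rec$bboxes[[i]] <- as.numeric(unlist(ann$bbox))
    rec$areas[i] <- ann$area
    rec$categories[i] <- ann$category_id
    rec$scores[i] <- ann$score %||% NA_real_
    by_image[[key]] <- rec
  }
  unname(by_image)
}
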