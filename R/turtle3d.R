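# 3D turtle-graphics interpretation of derived symbol strings into labelled
# per-organ triangle meshes.
#
# Command table (classic bracketed L-system alphabet):
#   F(d)  draw forward (ribbon quad of current width), default d = step
#   f(d)  move forward without drawing
#   +(a) / -(a)  yaw left/right about U        &(a) / ^(a)  pitch about L
#   \(a) / /(a)  roll about H                  |            turn 180 about U
#   [ ]   push / pop the full turtle state
#   { . } polygon capture: '.' records the current position, '}' fan-
#         triangulates from the first captured vertex
#   !(w)  set line width                        '(c)  set colour index
#   %{ %} organ-span markers emitted by expand_hierarchical()
# Unknown symbols (bare nonterminals left in the string) are ignored.

#' Create a turtle state
#'
#' The turtle starts at the origin heading up the +Z axis with left +X and
#' up +Y (right-handed), so a top-down orthographic camera on the -Z axis
#' views a rosette the way an overhead photograph would.
#'
#' @param position 3-vector, length units.
#' @param heading,left,up orthonormal frame vectors.
#' @param step default forward distance.
#' @param width ribbon width for drawn segments (0 draws nothing).
#' @return a `turtle_state` list.
#' @export
turtle_state <- function(position = c(0, 0, 0),
                         heading = c(0, 0, 1),
                         left = c(1, 0, 0),
                         up = c(0, 1, 0),
                         step = 1, width = 0.1) {
  st <- list(position = as.numeric(position), H = .unit3(heading),
             L = .unit3(left), U = .unit3(up), step = step,
             width = width, color_index = 1L)
  stopifnot(st$step > 0, st$width >= 0)
  class(st) <- "turtle_state"
  st
}

#' Rotate the turtle frame about one of its own axes
#'
#' Applies the Rodrigues rotation of `angle` degrees about the named frame
#' axis to all three frame vectors, then re-orthonormalizes by Gram-Schmidt
#' so numerical drift cannot accumulate over long command sequences. The
#' position is unchanged.
#'
#' @param state a `turtle_state`.
#' @param axis `"H"` (roll), `"L"` (pitch) or `"U"` (yaw).
#' @param angle degrees, positive per the right-hand rule about the axis.
#' @return the rotated `turtle_state`.
#' @export
turn <- function(state, axis = c("U", "L", "H"), angle) {
  axis <- match.arg(axis)
  k <- state[[axis]]
  th <- angle * pi / 180
  ct <- cos(th); st_ <- sin(th)
  rot <- function(v) {
    v * ct + .cross3(k, v) * st_ + k * sum(k * v) * (1 - ct)
  }
  H <- rot(state$H); L <- rot(state$L); U <- rot(state$U)
  # Gram-Schmidt re-orthonormalization; U completes the right-handed triple
  H <- .unit3(H)
  L <- .unit3(L - sum(L * H) * H)
  U <- .cross3(H, L)
  state$H <- H; state$L <- L; state$U <- U
  state
}

# mesh accumulator: grows vertex/triangle lists per organ
.new_mesh_store <- function() {
  e <- new.env(parent = emptyenv())
  e$organs <- list()
  e
}

.organ_key <- function(instance_id, organ_class) {
  paste0(organ_class, "_", instance_id)
}

.store_triangle <- function(store, key, organ_class, instance_id, a, b, c) {
  area2 <- .norm3(.cross3(b - a, c - a))
  if (area2 < 1e-12) return(invisible(NULL))  # drop degenerate triangles
  org <- store$organs[[key]]
  if (is.null(org)) {
    org <- list(instance_id = instance_id, organ_class = organ_class,
                vertices = list(), triangles = list())
  }
  i0 <- length(org$vertices)
  org$vertices[[i0 + 1L]] <- a
  org$vertices[[i0 + 2L]] <- b
  org$vertices[[i0 + 3L]] <- c
  org$triangles[[length(org$triangles) + 1L]] <- c(i0 + 1L, i0 + 2L, i0 + 3L)
  store$organs[[key]] <- org
  invisible(NULL)
}

#' Interpret a symbol string into a 3D plant model
#'
#' Executes the turtle command table over the string. Geometry emitted
#' inside an organ span (`%{` ... `%}`) is appended to that organ instance's
#' mesh; geometry outside any span belongs to the stem organ (instance 0).
#' Drawn segments become quadrilateral ribbons of the current width in the
#' turtle's H-L plane; polygons captured with `{` `.` `}` are fan-
#' triangulated from the first recorded vertex.
#'
#' @param s a `symbol_string` from [derive()] or [expand_hierarchical()],
#'   or literal command text (passed through [lsys_string()]).
#' @param angle,step default turn angle (degrees) and forward distance;
#'   taken from the originating grammar when `NULL`.
#' @param width initial ribbon width.
#' @return a `plant_model`: list of organ meshes (leaf instances renumbered
#'   1..K in order of first geometry, branches after, stem id 0) and
#'   `leaf_count`.
#' @export
interpret <- function(s, angle = NULL, step = NULL, width = 0.1) {
  if (is.character(s)) s <- lsys_string(s)
  stopifnot(inherits(s, "symbol_string"))
  angle <- angle %||% attr(s, "angle") %||% 90
  step <- step %||% attr(s, "step") %||% 1

  st <- turtle_state(step = step, width = width)
  stack <- list()
  organ_stack <- list(list(id = 0L, class = "stem"))
  store <- .new_mesh_store()
  poly <- NULL  # list of captured vertices while inside { }
  poly_organ <- NULL
  class_names <- c("leaf", "branch")

  cur_organ <- function() organ_stack[[length(organ_stack)]]
  emit_quad <- function(a, b, c_, d) {
    o <- cur_organ()
    key <- .organ_key(o$id, o$class)
    .store_triangle(store, key, o$class, o$id, a, b, c_)
    .store_triangle(store, key, o$class, o$id, a, c_, d)
  }

  for (sym in s$symbols) {
    nm <- sym$name
    p1 <- if (length(sym$params) >= 1) sym$params[1] else NA_real_
    switch(nm,
      "F" = {
        d <- if (is.na(p1)) st$step else p1
        p2 <- st$position + st$H * d
        if (is.null(poly) && st$width > 0) {
          hw <- st$width / 2
          emit_quad(st$position - st$L * hw, st$position + st$L * hw,
                    p2 + st$L * hw, p2 - st$L * hw)
        }
        st$position <- p2
      },
      "f" = {
        d <- if (is.na(p1)) st$step else p1
        st$position <- st$position + st$H * d
      },
      "+" = st <- turn(st, "U", if (is.na(p1)) angle else p1),
      "-" = st <- turn(st, "U", -(if (is.na(p1)) angle else p1)),
      "&" = st <- turn(st, "L", if (is.na(p1)) angle else p1),
      "^" = st <- turn(st, "L", -(if (is.na(p1)) angle else p1)),
      "\\" = st <- turn(st, "H", if (is.na(p1)) angle else p1),
      "/" = st <- turn(st, "H", -(if (is.na(p1)) angle else p1)),
      "|" = st <- turn(st, "U", 180),
      "[" = stack[[length(stack) + 1L]] <- st,
      "]" = {
        if (!length(stack)) stop("unbalanced brackets: ']' with empty stack",
                                 call. = FALSE)
        st <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
      },
      "{" = {
        if (!is.null(poly)) stop("nested '{' polygon capture", call. = FALSE)
        poly <- list()
        poly_organ <- cur_organ()
      },
      "." = {
        if (is.null(poly)) stop("'.' outside polygon capture", call. = FALSE)
        poly[[length(poly) + 1L]] <- st$position
      },
      "}" = {
        if (is.null(poly)) stop("'}' without '{'", call. = FALSE)
        if (length(poly) < 3) stop("polygon with fewer than 3 vertices",
                                   call. = FALSE)
        key <- .organ_key(poly_organ$id, poly_organ$class)
        for (i in 2:(length(poly) - 1L)) {
          .store_triangle(store, key, poly_organ$class, poly_organ$id,
                          poly[[1]], poly[[i]], poly[[i + 1L]])
        }
        poly <- NULL
        poly_organ <- NULL
      },
      "!" = st$width <- if (is.na(p1)) st$width else p1,
      "'" = st$color_index <- if (is.na(p1)) st$color_index else as.integer(p1),
      "%{" = {
        organ_stack[[length(organ_stack) + 1L]] <-
          list(id = as.integer(sym$params[1]),
               class = class_names[sym$params[2]])
      },
      "%}" = {
        if (length(organ_stack) <= 1L) {
          stop("organ-span close marker without open", call. = FALSE)
        }
        organ_stack[[length(organ_stack)]] <- NULL
      },
      NULL  # bare nonterminals and unknown symbols: no drawing action
    )
  }
  if (length(stack)) stop("unbalanced brackets: unmatched '['", call. = FALSE)
  if (!is.null(poly)) stop("unclosed '{' polygon capture", call. = FALSE)

  model <- .finalize_model(store)
  attr(model, "final_state") <- st  # turtle state after the last command
  model
}

# Renumber leaf organs 1..K (order of first geometry emission), branches
# K+1.., stem stays 0; matrixify vertex/triangle lists.
.finalize_model <- function(store) {
  organs <- store$organs
  if (!length(organs)) {
    return(structure(list(organs = list(), leaf_count = 0L),
                     class = "plant_model"))
  }
  meshes <- lapply(organs, function(o) {
    list(instance_id = o$instance_id, organ_class = o$organ_class,
         vertices = do.call(rbind, o$vertices),
         triangles = do.call(rbind, o$triangles))
  })
  cls <- vapply(meshes, `[[`, character(1), "organ_class")
  ids <- vapply(meshes, function(o) as.numeric(o$instance_id), numeric(1))
  leaf_idx <- which(cls == "leaf")[order(ids[cls == "leaf"])]
  branch_idx <- which(cls == "branch")[order(ids[cls == "branch"])]
  stem_idx <- which(cls == "stem")
  K <- length(leaf_idx)
  for (i in seq_along(leaf_idx)) meshes[[leaf_idx[i]]]$instance_id <- i
  for (i in seq_along(branch_idx)) {
    meshes[[branch_idx[i]]]$instance_id <- K + i
  }
  for (i in stem_idx) meshes[[i]]$instance_id <- 0L
  ordered <- unname(meshes[c(leaf_idx, branch_idx, stem_idx)])
  structure(list(organs = ordered, leaf_count = K), class = "plant_model")
}

#' @export
print.plant_model <- function(x, ...) {
  ntri <- sum(vapply(x$organs, function(o) nrow(o$triangles), numeric(1)))
  cat("plant model:", length(x$organs), "organs (", x$leaf_count,
      "leaves ),", ntri, "triangles\n")
  invisible(x)
}

#' Bounding box of a plant model
#'
#' @param model a `plant_model`.
#' @return 2x3 matrix: rows are the min and max corner.
#' @export
model_bbox <- function(model) {
  V <- do.call(rbind, lapply(model$organs, `[[`, "vertices"))
  if (is.null(V)) stop("empty model has no bounding box", call. = FALSE)
  rbind(min = apply(V, 2, min), max = apply(V, 2, max))
}

#' Export a plant model as Wavefront OBJ
#'
#' One `o`/`g` group per organ instance (`leaf_1`, ..., `stem_0`) so the
#' per-organ decomposition survives inspection in external 3D tools.
#'
#' @param model a `plant_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  offset <- 0L
  for (o in model$organs) {
    writeLines(sprintf("o %s_%d", o$organ_class, o$instance_id), con)
    apply(o$vertices, 1, function(v) {
      writeLines(sprintf("v %.9g %.9g %.9g", v[1], v[2], v[3]), con)
    })
    apply(o$triangles, 1, function(tr) {
      writeLines(sprintf("f %d %d %d", tr[1] + offset, tr[2] + offset,
                         tr[3] + offset), con)
    })
    offset <- offset + nrow(o$vertices)
  }
  invisible(path)
}
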