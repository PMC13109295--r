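# Shared fixtures: tiny grammars, random geometry, and independent oracles
# used across the suite. Everything is generated in code; no binary data.

algae_grammar <- function() {
  parse_grammar("axiom: A\nA -> A B\nB -> A")
}

# Independent character-level rewriter for the algae grammar (A -> AB,
# B -> A), used as the oracle for derivation lengths and strings.
algae_brute <- function(n) {
  s <- "A"
  for (i in seq_len(n)) {
    chars <- strsplit(s, "")[[1]]
    s <- paste(vapply(chars, function(ch) {
      if (ch == "A") "AB" else "A"
    }, character(1)), collapse = "")
  }
  s
}

# Random balanced bracketed command string (no polygons; those cannot span
# brackets). Returns a single string.
random_bracketed <- function(depth = 0, rng_max_len = 6) {
  cmds <- c("F", "f", "+", "-", "&", "^", "\\", "/", "|",
            "+(17)", "-(33)", "F(0.3)", "&(70)")
  n <- sample.int(rng_max_len, 1)
  parts <- vapply(seq_len(n), function(i) {
    if (depth < 3 && stats::runif(1) < 0.25) {
      paste0("[", random_bracketed(depth + 1), "]")
    } else {
      sample(cmds, 1)
    }
  }, character(1))
  paste(parts, collapse = "")
}

expect_state_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$position - b$position)), tol)
  expect_lt(max(abs(a$H - b$H)), tol)
  expect_lt(max(abs(a$L - b$L)), tol)
  expect_lt(max(abs(a$U - b$U)), tol)
}

final_state <- function(model) attr(model, "final_state")

# Build a plant_model directly from a list of per-organ triangle soups.
# organs: list of list(instance_id, organ_class, tris = list of 3x3
# matrices (rows = vertices)).
toy_model <- function(organs) {
  K <- sum(vapply(organs, function(o) o$organ_class == "leaf", logical(1)))
  meshes <- lapply(organs, function(o) {
    V <- do.call(rbind, o$tris)
    Tm <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
    list(instance_id = o$instance_id, organ_class = o$organ_class,
         vertices = V, triangles = Tm)
  })
  structure(list(organs = meshes, leaf_count = K), class = "plant_model")
}

# A flat axis-aligned square leaf: z constant, [x0,x1] x [y0,y1].
square_leaf <- function(id, x0, y0, x1, y1, z) {
  list(instance_id = id, organ_class = "leaf",
       tris = list(rbind(c(x0, y0, z), c(x1, y0, z), c(x1, y1, z)),
                   rbind(c(x0, y0, z), c(x1, y1, z), c(x0, y1, z))))
}

# Random toy model of n_leaves random triangles in the unit cube.
random_triangle_model <- function(n_leaves, tris_per_leaf = 1) {
  organs <- lapply(seq_len(n_leaves), function(k) {
    tris <- lapply(seq_len(tris_per_leaf), function(i) {
      matrix(stats::runif(9), 3, 3)
    })
    list(instance_id = k, organ_class = "leaf", tris = tris)
  })
  toy_model(organs)
}

project_points_wrap <- function(cam, V) leafgen:::project_points(cam, V)

unit_camera <- function(size = c(16, 16)) {
  camera_spec("orthographic", eye = c(0.5, 0.5, 10),
              look_at = c(0.5, 0.5, 0), up_hint = c(0, 1, 0),
              size = size, units_per_pixel = 1 / size[1])
}

# Brute-force per-pixel ray-depth-sort labelling oracle. Loops pixels and
# triangles with scalar arithmetic; mirrors the package's documented depth
# tie convention (ties within 1e-9 go to the lower instance id) but shares
# no code with the z-buffer path.
brute_force_labels <- function(model, cam) {
  H <- cam$size[1]; W <- cam$size[2]
  tris <- list()
  for (o in model$organs) {
    P <- leafgen:::project_points(cam, o$vertices)
    for (t in seq_len(nrow(o$triangles))) {
      tris[[length(tris) + 1L]] <- list(
        P = P[o$triangles[t, ], , drop = FALSE],
        id = o$instance_id, leaf = o$organ_class == "leaf")
    }
  }
  label <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      cx <- cc - 0.5; cy <- r - 0.5
      hit_z <- numeric(); hit_id <- integer(); hit_leaf <- logical()
      for (tr in tris) {
        x <- tr$P[, 1]; y <- tr$P[, 2]; z <- tr$P[, 3]
        denom <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
        if (abs(denom) < 1e-12) next
        l1 <- ((y[2] - y[3]) * (cx - x[3]) + (x[3] - x[2]) * (cy - y[3])) / denom
        l2 <- ((y[3] - y[1]) * (cx - x[3]) + (x[1] - x[3]) * (cy - y[3])) / denom
        l3 <- 1 - l1 - l2
        if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
          hit_z <- c(hit_z, l1 * z[1] + l2 * z[2] + l3 * z[3])
          hit_id <- c(hit_id, tr$id)
          hit_leaf <- c(hit_leaf, tr$leaf)
        }
      }
      if (!length(hit_z)) next
      near <- which(hit_z <= min(hit_z) + 1e-9)
      w <- near[which.min(hit_id[near])]
      label[r, cc] <- if (hit_leaf[w]) hit_id[w] else 0L
    }
  }
  label
}

# Random blob mask: union of a few filled discs on an h x w grid.
random_blob_mask <- function(h = 24, w = 24, discs = 2) {
  m <- matrix(0L, h, w)
  for (i in seq_len(discs)) {
    cy <- stats::runif(1, 2, h - 1); cx <- stats::runif(1, 2, w - 1)
    rad <- stats::runif(1, 2, max(3, min(h, w) / 3))
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    m[(yy - cy)^2 + (xx - cx)^2 <= rad^2] <- 1L
  }
  m
}

as_patch <- function(mask, x0 = 0L, y0 = 0L, id = 1L) {
  structure(list(instance_id = as.integer(id), mask = mask,
                 bbox = stats::setNames(as.integer(
                   c(x0, y0, x0 + ncol(mask), y0 + nrow(mask))),
                   c("x0", "y0", "x1", "y1")),
                 pad = 0L),
            class = "mask_patch")
}

flat_background <- function(h, w, value = c(10, 20, 30)) {
  bg <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) bg[, , ch] <- value[ch]
  bg
}

# Maximum-cardinality bipartite matching size over pairs with IoU >= tau,
# by exhaustive recursion (feasible for <= 6 x 6 sets): the diagnostic
# oracle for the greedy matcher.
optimal_match_count <- function(pred_masks, gt_masks, tau) {
  np <- length(pred_masks); ng <- length(gt_masks)
  if (!np || !ng) return(0L)
  iou <- outer(seq_len(np), seq_len(ng),
               Vectorize(function(p, g) mask_iou(pred_masks[[p]],
                                                 gt_masks[[g]])))
  best <- 0L
  recurse <- function(p, used, count) {
    if (count + (np - p + 1L) <= best) return()
    if (p > np) { best <<- max(best, count); return() }
    for (g in seq_len(ng)) {
      if (!used[g] && iou[p, g] >= tau) {
        used[g] <- TRUE
        recurse(p + 1L, used, count + 1L)
        used[g] <- FALSE
      }
    }
    recurse(p + 1L, used, count)
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}
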