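#' @title Labelled stimulus scenes on a 16x16 degree canvas
#'
#' @description
#' Scenes are parametric collections of labelled regions (faces, eyes, bodies,
#' occluders, face-shaped noise patches, outlines, objects) placed on a square
#' canvas measured in visual degrees. Coordinates follow one convention used
#' throughout the package: x increases rightward, y increases upward, the
#' origin of *image* coordinates is the image centre, and the origin of
#' *screen* coordinates is the fixation point. A raster stores row 1 at the
#' top (y decreasing with row index).
#'
#' @name scenes
NULL

REGION_LABELS <- c("face", "eyes", "body", "occluder", "mask_cover", "object",
                   "noise_patch", "outline", "background_control")

fm_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "facemap_error", "error")))
}

#' Create a labelled scene region
#'
#' @param label Region label; one of `face`, `eyes`, `body`, `occluder`,
#'   `mask_cover`, `object`, `noise_patch`, `outline`, `background_control`.
#' @param center Region centre `c(x, y)` in image-centred degrees.
#' @param radii Semi-axes `c(rx, ry)` in degrees (ellipse) or ignored for
#'   polygons.
#' @param orientation_deg Rotation of the region about its centre, degrees
#'   clockwise from upright. Bodies must use a multiple of 45.
#' @param shape `"ellipse"` (default) or `"polygon"`.
#' @param vertices For polygons, an n x 2 matrix of (x, y) vertices.
#' @param implied_face For bodies: the point `c(x, y)` where a face ought to
#'   be, given the body's position and orientation. Required when
#'   `label == "body"`.
#' @param implied_feet Optional point where the feet land (drives the weaker
#'   end-of-body context response).
#' @param name Optional identifying name (defaults to the label); used to
#'   distinguish e.g. an object atop a body from the same object elsewhere.
#' @return An object of class `"fm_region"`.
#' @export
region <- function(label, center, radii = c(1, 1), orientation_deg = 0,
                   shape = c("ellipse", "polygon"), vertices = NULL,
                   implied_face = NULL, implied_feet = NULL, name = label) {
  shape <- match.arg(shape)
  if (!label %in% REGION_LABELS)
    fm_error("facemap_unknown_label", sprintf("unknown region label '%s'", label))
  if (label == "body") {
    if (is.null(implied_face) || !all(is.finite(implied_face)))
      fm_error("facemap_invalid_region", "a body region requires a finite implied_face point")
    if (orientation_deg %% 45 != 0)
      fm_error("facemap_invalid_region", "body orientation must be a multiple of 45 degrees")
  }
  structure(list(label = label, name = name, shape = shape,
                 center = as.numeric(center), radii = as.numeric(radii),
                 orientation_deg = orientation_deg, vertices = vertices,
                 implied_face = if (!is.null(implied_face)) as.numeric(implied_face),
                 implied_feet = if (!is.null(implied_feet)) as.numeric(implied_feet)),
            class = "fm_region")
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
}

# Per-axis half-extent bound of a region about its centre (for canvas
# containment checks). For a rotated ellipse the tight axis-aligned
# bounding-box half-widths are used.
region_extent <- function(reg) {
  if (reg$shape == "polygon") {
    apply(abs(sweep(reg$vertices, 2, reg$center)), 2, max)
  } else {
    th <- reg$orientation_deg * pi / 180
    c(sqrt((reg$radii[1] * cos(th))^2 + (reg$radii[2] * sin(th))^2),
      sqrt((reg$radii[1] * sin(th))^2 + (reg$radii[2] * cos(th))^2))
  }
}

#' Test points for membership in a region
#'
#' @param reg An `fm_region`.
#' @param pts An n x 2 matrix (or length-2 vector) of image-centred (x, y)
#'   coordinates in degrees.
#' @return Logical vector of length n.
#' @export
point_in_region <- function(reg, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  q <- sweep(pts, 2, reg$center)
  if (reg$orientation_deg != 0) q <- q %*% rot2(reg$orientation_deg)
  if (reg$shape == "ellipse") {
    (q[, 1] / reg$radii[1])^2 + (q[, 2] / reg$radii[2])^2 <= 1
  } else {
    vx <- reg$vertices[, 1] - reg$center[1]
    vy <- reg$vertices[, 2] - reg$center[2]
    apply(q, 1, function(p) point_in_polygon(p[1], p[2], vx, vy))
  }
}

# Ray-casting point-in-polygon (even-odd rule), boundary-inclusive enough for
# mask rendering at any finite resolution.
point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx); inside <- FALSE; j <- n
  for (i in seq_len(n)) {
    if (((vy[i] > y) != (vy[j] > y)) &&
        (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside <- !inside
    j <- i
  }
  inside
}

#' Create a scene specification
#'
#' @param scene_id Character identifier, unique within a set.
#' @param regions List of [region()] objects.
#' @param image_set One of the seven stimulus-set archetypes (see
#'   [make_scene_set()]).
#' @param canvas_deg Canvas side length in degrees (default 16).
#' @param inverted Logical; marks inverted face/body configurations in the
#'   upright/inverted set.
#' @param pair_id Optional identifier linking matched scene pairs (e.g. the
#'   above-body / no-body pair sharing a face-shaped footprint).
#' @return Object of class `"fm_scene"`.
#' @export
scene_spec <- function(scene_id, regions, image_set = "intact", canvas_deg = 16,
                       inverted = FALSE, pair_id = NULL) {
  half <- canvas_deg / 2
  for (reg in regions) {
    if (any(abs(reg$center) + region_extent(reg) > half + 1e-9))
      fm_error("facemap_invalid_region",
               sprintf("region '%s' of scene '%s' extends beyond the %g-degree canvas",
                       reg$name, scene_id, canvas_deg))
  }
  structure(list(scene_id = scene_id, regions = regions, image_set = image_set,
                 canvas_deg = canvas_deg, inverted = inverted, pair_id = pair_id),
            class = "fm_scene")
}

scene_regions <- function(scene, label = NULL, name = NULL) {
  keep <- vapply(scene$regions, function(r) {
    (is.null(label) || r$label %in% label) && (is.null(name) || r$name %in% name)
  }, logical(1))
  scene$regions[keep]
}

IMAGE_SETS <- c("intact", "masked", "occluded", "face_swapped",
                "face_variants_x_body", "body_orientations", "upright_inverted")

# Canonical person geometry used across archetypes. Faces are 3 degrees wide
# (footprint radius 1.5), which guarantees that any presentation grid of
# spacing <= 2 degrees places at least one node inside a face-shaped region
# (nearest-node distance is bounded by sqrt(2) < 1.5).
FACE_R <- 1.5
BODY_RX <- 1.8
BODY_RY <- 3.0

# Unit vector from body centre toward the head for a clockwise-from-up
# orientation in degrees: 0 = head up, 90 = head right.
body_axis <- function(orientation_deg) {
  th <- orientation_deg * pi / 180
  c(sin(th), cos(th))
}

person_regions <- function(face_center, with_eyes = TRUE, with_body = TRUE,
                           face_variant = "face", body_orientation = 0) {
  regs <- list()
  d <- body_axis(body_orientation)
  if (with_body) {
    body_center <- face_center - (FACE_R + BODY_RY) * d
    regs <- c(regs, list(region("body", body_center, c(BODY_RX, BODY_RY),
                                orientation_deg = body_orientation,
                                implied_face = face_center,
                                implied_feet = body_center - (BODY_RY + 0.5) * d)))
  }
  if (face_variant == "face") {
    regs <- c(regs, list(region("face", face_center, c(FACE_R, FACE_R))))
    if (with_eyes)
      regs <- c(regs, list(region("eyes", face_center + c(0, 0.35 * FACE_R),
                                  c(0.55 * FACE_R, 0.22 * FACE_R))))
  } else if (face_variant != "none") {
    regs <- c(regs, list(region(face_variant, face_center, c(FACE_R, FACE_R),
                                name = face_variant)))
  }
  regs
}

sample_face_center <- function() c(runif(1, -3, 3), runif(1, 0, 4))

#' Generate a stimulus-set archetype as parametric labelled scenes
#'
#' Seven archetypes mirror the image sets of the main experiment:
#' `intact` natural scenes (face + eyes + body + a distractor object),
#' `masked` (face covered by a mask), `occluded` (face hidden behind an
#' occluding object), `face_swapped` (the same non-face object placed once
#' above a body and once elsewhere), `face_variants_x_body` (four face
#' variants -- intact face, face-shaped noise patch, face outline, non-face
#' object -- each above a body and without the body, over an identical
#' face-shaped footprint), `body_orientations` (headless bodies at eight
#' orientations in 45-degree steps), and `upright_inverted` (matched
#' upright/inverted pairs of intact faces and face-shaped noise atop bodies).
#'
#' @param archetype One of the seven image-set names.
#' @param n_exemplars Number of distinct exemplars (people) to generate.
#' @param seed Integer seed; scene placement is fully reproducible.
#' @return A named list of [scene_spec()] objects.
#' @examples
#' length(make_scene_set("face_variants_x_body", 7, seed = 1)) # 56 scenes
#' length(make_scene_set("body_orientations", 8, seed = 1))    # 64 scenes
#' @export
make_scene_set <- function(archetype, n_exemplars, seed = 1) {
  if (!archetype %in% IMAGE_SETS)
    fm_error("facemap_unknown_archetype",
             sprintf("unknown image-set archetype '%s'", archetype))
  stopifnot(n_exemplars >= 1)
  set.seed(seed)
  scenes <- list()
  add <- function(s) scenes[[s$scene_id]] <<- s
  for (i in seq_len(n_exemplars)) {
    fc <- sample_face_center()
    id <- function(...) paste0(archetype, "_", i, ...)
    if (archetype == "intact") {
      regs <- person_regions(fc)
      regs <- c(regs, list(region("object", distractor_center(fc), c(1.2, 1.2),
                                  name = "distractor")))
      add(scene_spec(id(), regs, archetype))
    } else if (archetype == "masked") {
      regs <- person_regions(fc, face_variant = "mask_cover")
      add(scene_spec(id(), regs, archetype))
    } else if (archetype == "occluded") {
      regs <- person_regions(fc, face_variant = "none")
      regs <- c(regs, list(region("occluder", fc, c(1.6, 1.6))))
      add(scene_spec(id(), regs, archetype))
    } else if (archetype == "face_swapped") {
      regs <- person_regions(fc, face_variant = "none")
      regs <- c(regs, list(
        region("object", fc, c(FACE_R, FACE_R), name = "object_atop_body"),
        region("object", distractor_center(fc), c(FACE_R, FACE_R),
               name = "object_control")))
      add(scene_spec(id(), regs, archetype))
    } else if (archetype == "face_variants_x_body") {
      for (variant in c("face", "noise_patch", "outline", "object")) {
        for (with_body in c(TRUE, FALSE)) {
          regs <- person_regions(fc, with_eyes = FALSE, with_body = with_body,
                                 face_variant = variant)
          add(scene_spec(id("_", variant, if (with_body) "_body" else "_nobody"),
                         regs, archetype,
                         pair_id = paste0(archetype, "_", i, "_", variant)))
        }
      }
    } else if (archetype == "body_orientations") {
      # isolated body images on a uniform background: the body is centred in
      # the image, so implied-face anchors coincide across exemplars and
      # per-orientation maps can be averaged over exemplars
      bc <- c(0, 0)
      for (orient in seq(0, 315, by = 45)) {
        d <- body_axis(orient)
        regs <- list(region("body", bc, c(BODY_RX, BODY_RY),
                            orientation_deg = orient,
                            implied_face = bc + (BODY_RY + FACE_R) * d,
                            implied_feet = bc - (BODY_RY + 0.5) * d))
        add(scene_spec(id("_o", orient), regs, archetype, pair_id = id()))
      }
    } else if (archetype == "upright_inverted") {
      # both configurations must fit: the inverted body sits above the face
      fc <- c(stats::runif(1, -3, 3), stats::runif(1, -0.5, 0.5))
      for (variant in c("face", "noise_patch")) {
        for (inv in c(FALSE, TRUE)) {
          orient <- if (inv) 180 else 0
          regs <- person_regions(fc, with_eyes = FALSE, face_variant = variant,
                                 body_orientation = orient)
          add(scene_spec(id("_", variant, if (inv) "_inv" else "_upr"),
                         regs, archetype, inverted = inv,
                         pair_id = paste0(archetype, "_", i, "_", variant)))
        }
      }
    }
  }
  scenes
}

# A distractor/control location at least ~5 degrees from the face footprint,
# kept inside the canvas.
distractor_center <- function(face_center) {
  for (k in 1:50) {
    cand <- c(runif(1, -6, 6), runif(1, -6, 6))
    if (sqrt(sum((cand - face_center)^2)) > 5) return(cand)
  }
  c(-6, -6)
}

# Pixel-centre coordinate axes for a raster of a scene canvas.
raster_axes <- function(canvas_deg, px_per_deg) {
  n <- round(canvas_deg * px_per_deg)
  x <- (seq_len(n) - 0.5) / px_per_deg - canvas_deg / 2
  y <- canvas_deg / 2 - (seq_len(n) - 0.5) / px_per_deg
  list(n = n, x = x, y = y)
}

#' Render boolean region masks for a scene
#'
#' All masks share one raster; a pixel belongs to a label's mask if its centre
#' lies inside any region carrying that label. Labels absent from the scene
#' yield all-`FALSE` masks so that downstream code can index masks uniformly.
#'
#' @param scene An `fm_scene`.
#' @param px_per_deg Raster resolution in pixels per degree (default 4).
#' @return Named list of logical matrices (row 1 = top of the image), one per
#'   canonical region label.
#' @export
render_region_masks <- function(scene, px_per_deg = 4) {
  stopifnot(px_per_deg > 0)
  ax <- raster_axes(scene$canvas_deg, px_per_deg)
  # column-major stacking: entry (row i, col j) has x = ax$x[j], y = ax$y[i]
  grid_x <- matrix(rep(ax$x, each = ax$n), nrow = ax$n)
  grid_y <- matrix(rep(ax$y, times = ax$n), nrow = ax$n)
  pts <- cbind(as.vector(grid_x), as.vector(grid_y))
  masks <- setNames(vector("list", length(REGION_LABELS)), REGION_LABELS)
  for (lab in REGION_LABELS)
    masks[[lab]] <- matrix(FALSE, ax$n, ax$n)
  for (reg in scene$regions) {
    inside <- matrix(point_in_region(reg, pts), ax$n, ax$n)
    if (reg$label == "outline")  # outlines rasterize as a ring, not a disc
      inside <- inside & !matrix(point_in_region(shrink_region(reg, 0.8), pts),
                                 ax$n, ax$n)
    masks[[reg$label]] <- masks[[reg$label]] | inside
  }
  masks
}

shrink_region <- function(reg, factor) {
  reg$radii <- reg$radii * factor
  reg
}

# Brown-noise field: white Gaussian noise filtered in the Fourier domain with
# amplitude 1/f, giving a 1/f^2 power spectrum. Affinely rescaled to [0, 1]
# (affine maps do not change the spectral slope away from DC).
brown_noise_field <- function(n) {
  w <- matrix(stats::rnorm(n * n), n, n)
  fx <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  f2 <- outer(fx^2, fx^2, "+")
  amp <- 1 / sqrt(f2)
  amp[1, 1] <- 0
  field <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (n * n)
  rng <- range(field)
  if (diff(rng) == 0) return(matrix(0.5, n, n))
  (field - rng[1]) / diff(rng)
}

REGION_COLORS <- list(
  face = c(0.90, 0.75, 0.60), eyes = c(0.15, 0.10, 0.08),
  body = c(0.30, 0.40, 0.70), occluder = c(0.45, 0.28, 0.12),
  mask_cover = c(0.82, 0.82, 0.86), object = c(0.55, 0.55, 0.20),
  outline = c(0.10, 0.10, 0.10), background_control = c(0.5, 0.5, 0.5))

#' Render a scene as an RGB raster
#'
#' The background is brown noise (power spectrum proportional to 1/f^2);
#' regions are drawn as flat coloured patches, outlines as rings, and
#' `noise_patch` regions are filled with independent uniform random values in
#' each colour channel.
#'
#' @inheritParams render_region_masks
#' @param seed Integer seed; the same seed yields an identical raster.
#' @return Numeric array `n x n x 3` with values in `[0, 1]`.
#' @export
render_image <- function(scene, px_per_deg = 4, seed = 1) {
  stopifnot(px_per_deg > 0)
  set.seed(seed)
  ax <- raster_axes(scene$canvas_deg, px_per_deg)
  img <- array(0, c(ax$n, ax$n, 3))
  for (ch in 1:3) img[, , ch] <- brown_noise_field(ax$n)
  masks <- render_region_masks(scene, px_per_deg)
  draw_order <- c("body", "object", "occluder", "mask_cover", "outline",
                  "noise_patch", "face", "eyes", "background_control")
  for (lab in draw_order) {
    m <- masks[[lab]]
    if (!any(m)) next
    if (lab == "noise_patch") {
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- stats::runif(sum(m))
        img[, , ch] <- plane
      }
    } else {
      col <- REGION_COLORS[[lab]]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- col[ch]
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Build a presentation protocol over a position grid
#'
#' Every scene is shown `reps` times at every grid position, in a seeded
#' random order, three presentations per trial with 100 ms ON / 200 ms OFF.
#' Grid positions denote the offset of the image centre from fixation, so
#' position (0, 0) centres the image on `grid_center_deg`... precisely: the
#' image centre is placed at the grid position, and the grid is centred on
#' `grid_center_deg` (normally the population receptive-field centre).
#'
#' @param grid_shape Number of grid points per side (e.g. 17 or 9).
#' @param spacing_deg Grid spacing in degrees (e.g. 1 or 2).
#' @param grid_center_deg Centre of the grid, `c(x, y)` in degrees from
#'   fixation.
#' @param scenes Named list of scenes (or character vector of scene ids).
#' @param reps Repetitions of every (scene, position) pair.
#' @param seed Integer seed for the presentation order.
#' @param on_ms,off_ms Presentation timing (defaults 100 ON / 200 OFF).
#' @param iti_ms Gap after the third presentation of a trial before the next
#'   trial's first onset (default 200, giving an 1100 ms trial period).
#' @return Object of class `"fm_protocol"`: a list with the events table
#'   (`trial`, `presentation_index`, `scene_id`, `grid_x`, `grid_y`,
#'   `onset_ms`), the grid definition and timing parameters.
#' @export
make_protocol <- function(grid_shape, spacing_deg, grid_center_deg, scenes,
                          reps, seed = 1, on_ms = 100, off_ms = 200,
                          iti_ms = 200) {
  ids <- if (is.character(scenes)) scenes else names(scenes)
  if (length(ids) == 0)
    fm_error("facemap_empty_scene_list", "protocol requires at least one scene")
  stopifnot(reps >= 1, grid_shape >= 1)
  offs <- (seq_len(grid_shape) - (grid_shape + 1) / 2) * spacing_deg
  gx <- grid_center_deg[1] + offs
  gy <- grid_center_deg[2] + offs
  combos <- expand.grid(scene_id = ids, grid_x = gx, grid_y = gy,
                        stringsAsFactors = FALSE)
  events <- combos[rep(seq_len(nrow(combos)), times = reps), ]
  set.seed(seed)
  events <- events[sample.int(nrow(events)), ]
  n <- nrow(events)
  soa <- on_ms + off_ms
  trial_len <- 3 * soa + iti_ms
  events$trial <- rep(seq_len(ceiling(n / 3)), each = 3)[seq_len(n)]
  events$presentation_index <- rep(1:3, length.out = n)
  events$onset_ms <- (events$trial - 1) * trial_len +
    (events$presentation_index - 1) * soa
  rownames(events) <- NULL
  structure(list(events = events[, c("trial", "presentation_index", "scene_id",
                                     "grid_x", "grid_y", "onset_ms")],
                 grid_x = gx, grid_y = gy, grid_shape = grid_shape,
                 spacing_deg = spacing_deg, grid_center_deg = grid_center_deg,
                 reps = reps, on_ms = on_ms, off_ms = off_ms,
                 duration_ms = max(events$onset_ms) + trial_len),
            class = "fm_protocol")
}

#' Write a scene list to JSON
#' @param scenes Named list of scenes.
#' @param path Output file path.
#' @export
write_scenes_json <- function(scenes, path) {
  ser <- lapply(scenes, function(s) {
    list(scene_id = s$scene_id, image_set = s$image_set,
         canvas_deg = s$canvas_deg, inverted = s$inverted,
         pair_id = s$pair_id,
         regions = lapply(s$regions, function(r) r[!vapply(r, is.null, TRUE)]))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
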