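#' Landmark registry for the ear surface
#'
#' The pipeline tracks 18 named anatomical landmarks on every ear mesh. Three of
#' them (`cauda_helicis`, `incisura_intertragica`, `otobasion_inferius`) define
#' the boundary between the upper auricle and the lobule; the remaining fifteen
#' cover the helix, antihelix, tragus, concha and fossae so that a similarity
#' alignment and thin-plate-spline warp are well constrained over the whole
#' surface.
#'
#' @return Character vector of the 18 landmark names, in canonical order.
#' @export
ear_landmark_names <- function() {
  c(
    "cauda_helicis", "incisura_intertragica", "otobasion_inferius",
    "otobasion_superius", "helix_root", "helix_apex", "helix_posterior",
    "helix_descending", "antihelix_superior", "antihelix_inferior",
    "tragus", "antitragus", "concha_center", "concha_rim_anterior",
    "concha_rim_posterior", "triangular_fossa", "scapha", "lobule_apex"
  )
}

#' Region labels recognised on ear meshes
#' @return Character vector `c("upper_auricle", "lobule")`.
#' @export
ear_regions <- function() c("upper_auricle", "lobule")

#' Construct a triangle mesh
#'
#' The basic surface container used throughout the package: an ordered vertex
#' list in millimetres, triangle faces as 1-based vertex index triples
#' (file sidecars use 0-based indices), optional named landmarks, and optional
#' per-vertex region labels.
#'
#' @param vertices Numeric matrix, N x 3, coordinates in mm.
#' @param faces Integer matrix, F x 3, 1-based vertex indices.
#' @param landmarks Optional numeric matrix (18 x 3) with rownames equal to the
#'   configured landmark registry, or a named list of length-3 vectors.
#' @param region Optional character vector of length N with values in
#'   `ear_regions()`.
#' @param landmark_names Landmark name registry the mesh must conform to when
#'   `landmarks` is present. Defaults to [ear_landmark_names()].
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, landmarks = NULL, region = NULL,
                     landmark_names = ear_landmark_names()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns", call. = FALSE)
  if (nrow(vertices) == 0L) stop("degenerate mesh: 0 vertices", call. = FALSE)
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns", call. = FALSE)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  if (!is.null(landmarks)) {
    if (is.list(landmarks)) {
      landmarks <- do.call(rbind, landmarks)
    }
    landmarks <- as.matrix(landmarks)
    storage.mode(landmarks) <- "double"
    if (is.null(rownames(landmarks)) ||
        !setequal(rownames(landmarks), landmark_names) ||
        nrow(landmarks) != length(landmark_names)) {
      stop("landmarks must carry exactly the ", length(landmark_names),
           " configured landmark names", call. = FALSE)
    }
    landmarks <- landmarks[landmark_names, , drop = FALSE]
  }
  if (!is.null(region)) {
    region <- as.character(region)
    if (length(region) != nrow(vertices)) {
      stop("`region` must have one label per vertex", call. = FALSE)
    }
    if (!all(region %in% ear_regions())) {
      stop("region labels must be in {",
           paste(ear_regions(), collapse = ", "), "}", call. = FALSE)
    }
  }
  structure(
    list(vertices = vertices, faces = faces,
         landmarks = landmarks, region = region),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("<tri_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces), " faces",
      if (!is.null(x$landmarks)) paste0(", ", nrow(x$landmarks), " landmarks"),
      if (!is.null(x$region)) ", region-labelled",
      "\n", sep = "")
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh A `tri_mesh`.
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Bounding-box diagonal of a mesh (mm)
#' @param mesh A `tri_mesh` or an N x 3 coordinate matrix.
#' @return Length of the axis-aligned bounding-box diagonal.
#' @export
bbox_diagonal <- function(mesh) {
  v <- if (inherits(mesh, "tri_mesh")) mesh$vertices else as.matrix(mesh)
  sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
}

#' Mirror a mesh across a coordinate plane
#'
#' Negates the coordinate orthogonal to the chosen plane for all vertices and
#' landmarks, and flips face winding so outward normals are preserved. Used to
#' map right ears into the left-ear frame before joint analysis.
#'
#' @param mesh A `tri_mesh`.
#' @param plane One of `"yz"` (negate x), `"xz"` (negate y), `"xy"` (negate z).
#' @return The mirrored `tri_mesh`.
#' @export
mirror_mesh <- function(mesh, plane = c("yz", "xz", "xy")) {
  plane <- match.arg(plane)
  ax <- match(plane, c("yz", "xz", "xy"))  # axis to negate
  v <- mesh$vertices
  v[, ax] <- -v[, ax]
  lm <- mesh$landmarks
  if (!is.null(lm)) lm[, ax] <- -lm[, ax]
  f <- mesh$faces
  if (nrow(f) > 0L) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  out <- mesh
  out$vertices <- v
  out$faces <- f
  out$landmarks <- lm
  out
}

#' Subject metadata record
#'
#' @param subject_id Character id.
#' @param side `"left"` or `"right"`.
#' @param age Age in years (integer), validated against `age_limits`.
#' @param age_limits Plausible age range, default 0--120 years.
#' @return A `subject_meta` list.
#' @export
subject_meta <- function(subject_id, side = c("left", "right"), age,
                         age_limits = c(0L, 120L)) {
  side <- match.arg(side)
  age <- as.integer(age)
  if (is.na(age) || age < age_limits[1] || age > age_limits[2]) {
    stop("age out of plausible range [", age_limits[1], ", ", age_limits[2], "]",
         call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), side = side, age = age),
            class = "subject_meta")
}

# Vertex adjacency list from faces (used by smoothing/relaxation).
vertex_neighbours <- function(mesh) {
  f <- mesh$faces
  n <- n_vertices(mesh)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(n)))
}

# One pass of uniform Laplacian smoothing on vertex coordinates.
laplacian_smooth <- function(vertices, nbrs, alpha = 1) {
  out <- vertices
  for (i in seq_len(nrow(vertices))) {
    nb <- nbrs[[i]]
    if (length(nb) == 0L) next
    m <- colMeans(vertices[nb, , drop = FALSE])
    out[i, ] <- (1 - alpha) * vertices[i, ] + alpha * m
  }
  out
}

# Flatten N x 3 vertex matrix to the 3N shape vector (x1,y1,z1,x2,...).
as_shape_vector <- function(vertices) as.vector(t(vertices))

# Inverse of as_shape_vector().
as_vertex_matrix <- function(x) matrix(x, ncol = 3, byrow = TRUE)
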