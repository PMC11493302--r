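#' Template-fitting parameters
#'
#' Controls the dense-correspondence pipeline of [fit_template()]:
#' landmark similarity alignment, thin-plate-spline (TPS) warp, nearest-point
#' surface projection, and optional Laplacian relaxation blended with
#' re-projection.
#'
#' @param tps_regularization Non-negative TPS ridge parameter. `NULL` (default)
#'   means `1e-3 *` the target's bounding-box diagonal.
#' @param n_relax_iters Number of relaxation/re-projection rounds (default 0:
#'   the plain Procrustes + TPS + projection fit, which reproduces a target
#'   identical to the template exactly).
#' @param relax_weight Blend weight in `[0, 1]` given in each relaxation round
#'   to the Laplacian pull toward the warped template's differential
#'   coordinates (0 leaves projection untouched).
#' @param projection Projection rule; only `"nearest_point_on_surface"`.
#' @return A `fit_params` list.
#' @export
fit_params <- function(tps_regularization = NULL, n_relax_iters = 0,
                       relax_weight = 0.5,
                       projection = "nearest_point_on_surface") {
  if (!is.null(tps_regularization) && tps_regularization < 0) {
    stop("tps_regularization must be non-negative", call. = FALSE)
  }
  if (relax_weight < 0 || relax_weight > 1) {
    stop("relax_weight must be in [0, 1]", call. = FALSE)
  }
  projection <- match.arg(projection, "nearest_point_on_surface")
  structure(list(tps_regularization = tps_regularization,
                 n_relax_iters = as.integer(n_relax_iters),
                 relax_weight = relax_weight, projection = projection),
            class = "fit_params")
}

# Closed-form similarity alignment (rotation R, scale s, translation t)
# minimising ||s R x_i + t - y_i||^2 over paired landmark sets (Umeyama).
similarity_transform <- function(x, y, allow_scaling = TRUE) {
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  s_xy <- crossprod(yc, xc) / nrow(x)
  sv <- svd(s_xy)
  d <- sign(det(sv$u %*% t(sv$v)))
  S <- diag(c(1, 1, d))
  R <- sv$u %*% S %*% t(sv$v)
  s <- if (allow_scaling) sum(sv$d * diag(S)) / (sum(xc^2) / nrow(x)) else 1
  t_vec <- my - s * as.numeric(R %*% mx)
  list(R = R, s = s, t = t_vec,
       apply = function(p) sweep(s * p %*% t(R), 2, t_vec, `+`))
}

# 3D thin-plate-spline displacement interpolant with kernel U(r) = r and
# ridge regularisation; returns a function evaluating the warp at new points.
tps_warp <- function(src, dst, lambda = 0) {
  n <- nrow(src)
  K <- as.matrix(stats::dist(src))          # U(r) = r in 3D
  K <- K + diag(lambda, n)
  P <- cbind(1, src)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  B <- rbind(dst - src, matrix(0, 4, 3))
  coef <- solve(A, B)
  W <- coef[seq_len(n), , drop = FALSE]
  Aff <- coef[n + 1:4, , drop = FALSE]
  function(pts) {
    d2 <- outer(rowSums(pts^2), rep(1, n)) +
      outer(rep(1, nrow(pts)), rowSums(src^2)) -
      2 * pts %*% t(src)
    U <- sqrt(pmax(d2, 0))
    disp <- U %*% W + cbind(1, pts) %*% Aff
    pts + disp
  }
}

# Nearest point on a target mesh surface for each row of `pts`.
project_to_surface <- function(pts, target) {
  closest_points_on_mesh(pts, target$vertices, target$faces)
}

#' Fit the template to a target mesh (dense correspondence)
#'
#' Produces a homologous model: the template's topology deformed onto the
#' target surface. Pipeline: (1) similarity Procrustes of the template onto
#' the target using the 18 landmark pairs; (2) thin-plate-spline warp
#' interpolating the landmark displacements, applied to all template
#' vertices; (3) projection of every warped vertex to its nearest point on
#' the target surface; (4) optional rounds of Laplacian relaxation blended
#' with re-projection. `fit_residual` is the mean distance from the fitted
#' vertices to the target surface.
#'
#' @param template A [tri_mesh()] with the 18 landmarks.
#' @param target A [tri_mesh()]; landmarks taken from `target_landmarks` or
#'   from the target itself.
#' @param target_landmarks Optional 18 x 3 named landmark matrix.
#' @param params A [fit_params()].
#' @param meta Optional [subject_meta()] carried into the result.
#' @return A `homologous_model`: list with `vertices` (template order),
#'   `faces`/`region` (inherited from the template), `landmarks`, `meta`,
#'   `fit_residual` (mm).
#' @export
fit_template <- function(template, target, target_landmarks = NULL,
                         params = fit_params(), meta = NULL) {
  if (is.null(target_landmarks)) target_landmarks <- target$landmarks
  if (is.null(template$landmarks) || is.null(target_landmarks)) {
    stop("template and target must both carry the full landmark set",
         call. = FALSE)
  }
  nm <- ear_landmark_names()
  src_lm <- template$landmarks[nm, , drop = FALSE]
  dst_lm <- target_landmarks[nm, , drop = FALSE]

  sim <- similarity_transform(src_lm, dst_lm, allow_scaling = TRUE)
  v <- sim$apply(template$vertices)
  lm1 <- sim$apply(src_lm)

  lambda <- params$tps_regularization
  if (is.null(lambda)) lambda <- 1e-3 * bbox_diagonal(target)
  warp <- tps_warp(lm1, dst_lm, lambda = lambda)
  v <- warp(v)
  if (any(!is.finite(v))) stop("non-finite coordinates after TPS warp",
                               call. = FALSE)

  warped <- v
  proj <- project_to_surface(v, target)
  v <- proj$points
  if (params$n_relax_iters > 0) {
    # Laplacian relaxation toward the warped template's differential
    # coordinates: each vertex is pulled to (neighbour mean + reference
    # offset), blended with its current position, then re-projected. The
    # warped template is the attractor, so the template's local triangle
    # structure is restored rather than smoothed away.
    nbrs <- vertex_neighbours(template)
    w <- params$relax_weight
    nbr_mean <- function(x) {
      t(vapply(nbrs, function(nb) colMeans(x[nb, , drop = FALSE]), numeric(3)))
    }
    dref <- warped - nbr_mean(warped)
    for (it in seq_len(params$n_relax_iters)) {
      vr <- nbr_mean(v) + dref
      v <- project_to_surface((1 - w) * v + w * vr, target)$points
    }
  }
  residual <- mean(project_to_surface(v, target)$distances)

  structure(
    list(vertices = v, faces = template$faces, region = template$region,
         landmarks = dst_lm, meta = meta, fit_residual = residual),
    class = "homologous_model"
  )
}

#' @export
print.homologous_model <- function(x, ...) {
  cat("<homologous_model> ", nrow(x$vertices), " vertices, fit residual ",
      signif(x$fit_residual, 3), " mm\n", sep = "")
  invisible(x)
}

# Coerce a homologous model (or subject) to a tri_mesh.
as_tri_mesh <- function(x) {
  if (inherits(x, "tri_mesh")) return(x)
  tri_mesh(x$vertices, x$faces, region = x$region)
}

#' Split a homologous model into upper-auricle and lobule sub-models
#'
#' Partitions the vertices by region label (the lobule is the area bounded by
#' the cauda helicis, the lower incisura intertragica and the otobasion
#' inferius). Faces straddling the boundary go to the region holding two of
#' their three vertices. Sub-model vertex order is the template's restricted
#' order, hence identical across all subjects.
#'
#' @param model A `homologous_model` (or region-labelled [tri_mesh()]).
#' @return List with `upper_auricle` and `lobule` sub-models; each carries an
#'   `index_map` attribute (template vertex indices, in order).
#' @export
split_regions <- function(model) {
  region <- model$region
  if (is.null(region)) stop("region labels are required", call. = FALSE)
  out <- lapply(ear_regions(), function(lab) {
    idx <- which(region == lab)
    remap <- integer(length(region))
    remap[idx] <- seq_along(idx)
    fl <- model$faces
    votes <- matrix(region[fl] == lab, ncol = 3)
    keep <- rowSums(votes) >= 2
    faces <- fl[keep, , drop = FALSE]
    # a straddling face references one vertex of the other region; the vertex
    # sets must partition the model, so pin that corner to the face's
    # lowest-index in-region vertex (a boundary sliver, same map for every
    # subject because labels come from the shared template)
    if (nrow(faces) > 0L) {
      fvotes <- votes[keep, , drop = FALSE]
      for (r in which(rowSums(fvotes) == 2L)) {
        inside <- faces[r, fvotes[r, ]]
        faces[r, !fvotes[r, ]] <- min(inside)
      }
    }
    sub <- list(
      vertices = model$vertices[idx, , drop = FALSE],
      faces = matrix(remap[faces], ncol = 3),
      region = rep(lab, length(idx)),
      meta = model$meta,
      fit_residual = model$fit_residual
    )
    class(sub) <- "homologous_model"
    attr(sub, "index_map") <- idx
    sub
  })
  stats::setNames(out, ear_regions())
}
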