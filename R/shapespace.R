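#' Generalized Procrustes alignment of homologous models
#'
#' Standardises size and posture of every model to match the evolving sample
#' mean: each model is translated to the origin, (optionally) scaled to the
#' common centroid size, and rotated onto the current mean; the mean is then
#' recomputed and the loop repeats until the mean moves by less than
#' `1e-8 * bbox diagonal` or 100 iterations.
#'
#' @param models List of `homologous_model`s (or `tri_mesh`es) sharing the
#'   template topology.
#' @param allow_scaling Standardise centroid size as well as pose (default
#'   `TRUE`, removing ear-size variation before PCA).
#' @return List with `models` (aligned copies, mm, mean centroid at origin),
#'   `mean_shape` (N x 3 matrix), `iterations`, `converged`.
#' @export
generalized_procrustes <- function(models, allow_scaling = TRUE) {
  if (length(models) < 2L) stop("need at least 2 models", call. = FALSE)
  confs <- lapply(models, function(m) m$vertices)
  nv <- nrow(confs[[1]])
  if (!all(vapply(confs, nrow, integer(1)) == nv)) {
    stop("models must share topology", call. = FALSE)
  }
  cs <- function(x) sqrt(sum(scale(x, scale = FALSE)^2))  # centroid size
  confs <- lapply(confs, function(x) scale(x, scale = FALSE))
  target_size <- mean(vapply(confs, cs, numeric(1)))
  if (allow_scaling) {
    confs <- lapply(confs, function(x) x * target_size / cs(x))
  }
  mean_shape <- confs[[1]]
  tol <- 1e-8 * bbox_diagonal(mean_shape)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(100L)) {
    iterations <- it
    confs <- lapply(confs, function(x) {
      tr <- similarity_transform(x, mean_shape, allow_scaling = FALSE)
      out <- tr$apply(x)
      if (allow_scaling) out <- out * target_size / cs(out)
      out
    })
    new_mean <- Reduce(`+`, confs) / length(confs)
    new_mean <- scale(new_mean, scale = FALSE)
    if (allow_scaling) new_mean <- new_mean * target_size / cs(new_mean)
    delta <- max(abs(new_mean - mean_shape))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  aligned <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    m$vertices <- unclass(confs[[i]])
    attr(m$vertices, "scaled:center") <- NULL
    m
  })
  list(models = aligned, mean_shape = {
    ms <- unclass(mean_shape); attr(ms, "scaled:center") <- NULL; ms
  }, iterations = iterations, converged = converged)
}

#' Coordinate PCA over aligned homologous models
#'
#' PCA of the n x 3N matrix of vertex coordinate vectors via singular value
#' decomposition of the centered data (never the explicit 3N x 3N covariance;
#' n is far smaller than 3N). Eigenvalues use the population convention
#' (divisor n) so that the standard deviation of a component is `sqrt(EV)`;
#' set `divisor = "n-1"` for the sample convention. Contribution ratios are
#' percentages of the full trace, and components are "displayed" when their
#' CR meets `display_cr_threshold` (1% by default, mirroring shape-PCA
#' software that hides minor components).
#'
#' @param aligned List of aligned models (from [generalized_procrustes()]), or
#'   a list with a `models` field.
#' @param display_cr_threshold Display cutoff in percent (default 1.0).
#' @param divisor `"n"` (default) or `"n-1"` eigenvalue normalisation.
#' @return A `shape_model`: mean shape, eigenvalues (descending), orthonormal
#'   eigenvectors (3N x m), per-PC contribution ratio `cr` and cumulative
#'   `ccr` (%), per-specimen `scores`, `total_variance`, `n_displayed`,
#'   `faces`/`region` topology carried from the first model.
#' @export
fit_shape_pca <- function(aligned, display_cr_threshold = 1.0,
                          divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  if (!is.null(aligned$models)) aligned <- aligned$models
  n <- length(aligned)
  if (n < 2L) stop("need at least 2 specimens", call. = FALSE)
  X <- do.call(rbind, lapply(aligned, function(m) as_shape_vector(m$vertices)))
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  sv <- svd(Xc, nu = n, nv = min(n, ncol(Xc)))
  denom <- if (divisor == "n") n else n - 1L
  ev <- sv$d^2 / denom
  keep <- seq_len(min(n, ncol(Xc)))
  ev <- ev[keep]
  vecs <- sv$v[, keep, drop = FALSE]
  # deterministic eigenvector sign: largest-|component| entry positive
  for (k in seq_along(ev)) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  scores <- Xc %*% vecs
  total_variance <- sum(sv$d^2) / denom
  cr <- 100 * ev / total_variance
  structure(
    list(
      mean_shape = mean_shape,
      eigenvalues = ev,
      eigenvectors = vecs,
      cr = cr,
      ccr = cumsum(cr),
      scores = scores,
      total_variance = total_variance,
      display_cr_threshold = display_cr_threshold,
      n_displayed = sum(cr >= display_cr_threshold),
      n_specimens = n,
      divisor = divisor,
      faces = aligned[[1]]$faces,
      region = aligned[[1]]$region
    ),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat("<shape_model> ", x$n_specimens, " specimens, ",
      length(x$mean_shape) / 3, " vertices, ", x$n_displayed,
      " displayed PCs (CR >= ", x$display_cr_threshold, "%)\n", sep = "")
  invisible(x)
}

#' Synthesize a mesh from PC scores
#'
#' Reconstructs `mean + sum_k score_k * eigenvector_k` as a mesh with the
#' model's topology. Shapes at `+/- 3 * sqrt(EV_k)` visualise the morphological
#' change carried by component k.
#'
#' @param model A `shape_model`.
#' @param scores Numeric vector of scores. Either named/indexed by PC number
#'   (`c("1" = 50)`), or positional over the leading PCs.
#' @return A [tri_mesh()].
#' @export
synthesize <- function(model, scores) {
  m <- length(model$eigenvalues)
  idx <- if (!is.null(names(scores))) as.integer(names(scores)) else
    seq_along(scores)
  if (anyNA(idx) || any(idx < 1L) || any(idx > m)) {
    stop("unknown PC index in `scores`", call. = FALSE)
  }
  vec <- model$mean_shape
  if (length(scores)) {
    vec <- vec + as.numeric(model$eigenvectors[, idx, drop = FALSE] %*%
                              as.numeric(scores))
  }
  tri_mesh(as_vertex_matrix(vec), model$faces, region = model$region)
}

#' Project a mesh into a shape model's score space
#'
#' @param model A `shape_model`.
#' @param mesh A [tri_mesh()] (or model) with the model's topology.
#' @return Numeric vector of scores on all retained PCs.
#' @export
project_scores <- function(model, mesh) {
  v <- if (inherits(mesh, "tri_mesh") || inherits(mesh, "homologous_model")) {
    as_shape_vector(mesh$vertices)
  } else as.numeric(mesh)
  as.numeric(crossprod(model$eigenvectors, v - model$mean_shape))
}

#' Correlation between PC scores and a covariate
#'
#' Pearson correlation of each displayed component's scores with per-specimen
#' age (or any covariate), as shape-PCA result tables report alongside EV and
#' CR columns.
#'
#' @param model A `shape_model`.
#' @param ages Numeric vector, one value per specimen.
#' @return Tibble with `pc` and `r` (NA when the covariate has zero variance).
#' @export
score_covariate_correlation <- function(model, ages) {
  if (length(ages) != model$n_specimens) {
    stop("`ages` must have one value per specimen", call. = FALSE)
  }
  kk <- seq_len(model$n_displayed)
  r <- if (stats::sd(ages) == 0) rep(NA_real_, length(kk)) else
    vapply(kk, function(k) stats::cor(model$scores[, k], ages), numeric(1))
  tibble::tibble(pc = kk, r = r)
}

#' Contribution-ratio table from an eigenvalue spectrum
#'
#' Computes CR and CCR percentages for a (descending) eigenvalue vector
#' against a total variance that may include undisplayed components, as
#' published PCA tables do.
#'
#' @param eigenvalues Numeric vector, descending.
#' @param total_variance Total variance (sum of all eigenvalues including
#'   undisplayed ones); defaults to `sum(eigenvalues)`.
#' @return Tibble with `pc`, `ev`, `cr`, `ccr` (percent, full precision).
#' @export
contribution_table <- function(eigenvalues, total_variance = sum(eigenvalues)) {
  cr <- 100 * eigenvalues / total_variance
  tibble::tibble(pc = seq_along(eigenvalues), ev = eigenvalues,
                 cr = cr, ccr = cumsum(cr))
}

#' Tidy a shape model into its PC table
#'
#' One row per displayed component: eigenvalue, contribution ratio, cumulative
#' contribution ratio (percent), and, when `ages` is given, the Pearson
#' correlation of the scores with age. `rounded = TRUE` formats CR/CCR at 0.1%
#' and R at 0.01, the conventional precision of published shape-PCA tables.
#'
#' @param x A `shape_model`.
#' @param ages Optional covariate vector (one per specimen).
#' @param all Include undisplayed components too.
#' @param rounded Round CR/CCR to 0.1 and R to 0.01.
#' @param ... Unused.
#' @return A tibble with columns `pc`, `ev`, `cr`, `ccr` (and `r`).
#' @export
tidy.shape_model <- function(x, ages = NULL, all = FALSE, rounded = FALSE, ...) {
  kk <- seq_len(if (all) length(x$eigenvalues) else x$n_displayed)
  out <- tibble::tibble(pc = kk, ev = x$eigenvalues[kk],
                        cr = x$cr[kk], ccr = x$ccr[kk])
  if (!is.null(ages)) {
    rr <- score_covariate_correlation(x, ages)
    out$r <- rr$r[match(out$pc, rr$pc)]
  }
  if (rounded) {
    out$cr <- round(out$cr, 1)
    out$ccr <- round(out$ccr, 1)
    if ("r" %in% names(out)) out$r <- round(out$r, 2)
  }
  out
}

#' One-row summary of a shape model
#' @param x A `shape_model`.
#' @param ... Unused.
#' @return Tibble with specimen count, vertex count, displayed-PC count,
#'   total variance and displayed CCR.
#' @export
glance.shape_model <- function(x, ...) {
  tibble::tibble(
    n_specimens = x$n_specimens,
    n_vertices = length(x$mean_shape) / 3,
    n_displayed = x$n_displayed,
    total_variance = x$total_variance,
    ccr_displayed = if (x$n_displayed) x$ccr[x$n_displayed] else 0
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Persist / load a shape model as a directory of text artifacts
#'
#' Writes a manifest JSON (counts, total variance, display threshold,
#' divisor) plus columnar CSVs: the PC table (EV/CR/CCR), the mean shape,
#' the eigenvectors and the per-specimen scores. `read_shape_model()`
#' restores a `shape_model` that synthesizes and projects identically.
#'
#' @param model A `shape_model`.
#' @param dir Directory to create/write.
#' @return `write_shape_model()` the directory (invisibly);
#'   `read_shape_model()` the restored `shape_model`.
#' @export
write_shape_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    n_specimens = model$n_specimens,
    n_vertices = length(model$mean_shape) / 3,
    n_components = length(model$eigenvalues),
    n_displayed = model$n_displayed,
    total_variance = model$total_variance,
    display_cr_threshold = model$display_cr_threshold,
    divisor = model$divisor
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(tidy(model, all = TRUE), file.path(dir, "components.csv"))
  readr::write_csv(tibble::tibble(mean = model$mean_shape),
                   file.path(dir, "mean_shape.csv"))
  ev <- tibble::as_tibble(model$eigenvectors, .name_repair = ~ paste0("pc", seq_along(.x)))
  readr::write_csv(ev, file.path(dir, "eigenvectors.csv"))
  sc <- tibble::as_tibble(model$scores, .name_repair = ~ paste0("pc", seq_along(.x)))
  readr::write_csv(sc, file.path(dir, "scores.csv"))
  if (!is.null(model$faces)) {
    readr::write_csv(tibble::as_tibble(model$faces,
                                       .name_repair = ~ c("v1", "v2", "v3")),
                     file.path(dir, "faces.csv"))
  }
  if (!is.null(model$region)) {
    readr::write_csv(tibble::tibble(region = model$region),
                     file.path(dir, "region.csv"))
  }
  invisible(dir)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  comp <- readr::read_csv(file.path(dir, "components.csv"),
                          show_col_types = FALSE)
  vecs <- as.matrix(readr::read_csv(file.path(dir, "eigenvectors.csv"),
                                    show_col_types = FALSE))
  dimnames(vecs) <- NULL
  scores <- as.matrix(readr::read_csv(file.path(dir, "scores.csv"),
                                      show_col_types = FALSE))
  dimnames(scores) <- NULL
  faces_path <- file.path(dir, "faces.csv")
  faces <- if (file.exists(faces_path)) {
    f <- as.matrix(readr::read_csv(faces_path, show_col_types = FALSE))
    dimnames(f) <- NULL
    storage.mode(f) <- "integer"
    f
  } else matrix(integer(0), 0, 3)
  region_path <- file.path(dir, "region.csv")
  region <- if (file.exists(region_path)) {
    readr::read_csv(region_path, show_col_types = FALSE)$region
  } else NULL
  structure(
    list(
      mean_shape = readr::read_csv(file.path(dir, "mean_shape.csv"),
                                   show_col_types = FALSE)$mean,
      eigenvalues = comp$ev,
      eigenvectors = vecs,
      cr = comp$cr,
      ccr = comp$ccr,
      scores = scores,
      total_variance = manifest$total_variance,
      display_cr_threshold = manifest$display_cr_threshold,
      n_displayed = manifest$n_displayed,
      n_specimens = manifest$n_specimens,
      divisor = manifest$divisor,
      faces = faces,
      region = region
    ),
    class = "shape_model"
  )
}
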