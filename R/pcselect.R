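#' Distance between vertices (DBV) of two corresponded meshes
#'
#' The per-vertex Euclidean distance between corresponding vertices,
#' summarised by its mean (the convention used for image determination) or
#' maximum. A pseudo-metric on corresponded meshes: symmetric, non-negative,
#' zero iff the meshes are vertex-wise equal, and (for the mean statistic)
#' satisfying the triangle inequality.
#'
#' @param meshA,meshB Meshes (or models) with identical vertex count and
#'   correspondence.
#' @param statistic `"mean"` (default) or `"max"`.
#' @return DBV in mm.
#' @export
dbv <- function(meshA, meshB, statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  a <- if (is.matrix(meshA)) meshA else meshA$vertices
  b <- if (is.matrix(meshB)) meshB else meshB$vertices
  if (nrow(a) != nrow(b)) stop("vertex counts differ", call. = FALSE)
  d <- sqrt(rowSums((a - b)^2))
  if (statistic == "mean") mean(d) else max(d)
}

#' Select components by eigenvalue-magnitude threshold
#'
#' Returns the largest m such that `EV_m >= threshold` for a descending
#' eigenvalue spectrum (0 when even the first falls below). On published ear
#' PCA tables the thresholds 500 (upper auricle) and 100 (lobule) both cross
#' between PC6 and PC7.
#'
#' @param eigenvalues Descending numeric vector.
#' @param threshold Positive cutoff on eigenvalue magnitude.
#' @return Integer count m.
#' @export
ev_threshold_select <- function(eigenvalues, threshold) {
  if (is.unsorted(rev(eigenvalues))) {
    stop("eigenvalues must be non-increasing", call. = FALSE)
  }
  ok <- which(eigenvalues >= threshold)
  if (length(ok)) max(ok) else 0L
}

#' Scree-elbow component count
#'
#' Locates the component immediately before the eigenvalue curve turns from
#' steep to smooth: the interior index k maximising the second difference
#' `EV_(k-1) - 2 EV_k + EV_(k+1)` marks the turn, and `k - 1` is returned.
#' Ties break to the smallest k. Spectra without a marked elbow (e.g. smooth
#' geometric decay) still return the largest-second-difference index; the rule
#' is always defined.
#'
#' @param eigenvalues Descending numeric vector of length >= 3.
#' @return Integer count m >= 1.
#' @export
scree_elbow <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (p < 3L) stop("need at least 3 eigenvalues", call. = FALSE)
  k <- 2:(p - 1L)
  d2 <- eigenvalues[k - 1L] - 2 * eigenvalues[k] + eigenvalues[k + 1L]
  elbow <- k[which.max(d2)]          # which.max takes the first on ties
  max(elbow - 1L, 1L)
}

#' Per-PC DBV of the +/- 3 SD shape pair
#'
#' For each component k, the DBV between the shapes synthesized at
#' `-3 sqrt(EV_k)` and `+3 sqrt(EV_k)`; for the mean statistic this equals
#' `6 sqrt(EV_k) * mean_i ||phi_k,i||` in closed form. The slope of this
#' curve over k is one of the three component-selection criteria.
#'
#' @param model A `shape_model`.
#' @param upto Number of leading components (default: displayed PCs).
#' @param statistic `"mean"` or `"max"`.
#' @return Tibble `pc`, `dbv` (mm), with attribute `statistic`.
#' @export
dbv_per_pc <- function(model, upto = model$n_displayed,
                       statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  if (upto > length(model$eigenvalues)) {
    stop("`upto` exceeds available PCs", call. = FALSE)
  }
  vals <- vapply(seq_len(upto), function(k) {
    sdk <- sqrt(model$eigenvalues[k])
    lo <- synthesize(model, stats::setNames(-3 * sdk, k))
    hi <- synthesize(model, stats::setNames(+3 * sdk, k))
    dbv(lo, hi, statistic)
  }, numeric(1))
  out <- tibble::tibble(pc = seq_len(upto), dbv = vals)
  attr(out, "statistic") <- statistic
  out
}

#' Displacement mask of a component's shape change
#'
#' Per-vertex displacement between the mean shape and the `+3 SD` shape of a
#' component, thresholded into the "changed area" (the red regions of
#' superimposition renderings). The default threshold is the 75th percentile
#' of that component's per-vertex displacements; an absolute mm cutoff can be
#' supplied instead.
#'
#' @param model A `shape_model`.
#' @param pc Component index.
#' @param displacement_threshold Absolute mm cutoff, or `NULL` for the
#'   75th-percentile rule.
#' @return List with `displacement` (per-vertex mm), `mask` (logical),
#'   `threshold` (mm).
#' @export
shape_change_mask <- function(model, pc, displacement_threshold = NULL) {
  sdk <- sqrt(model$eigenvalues[pc])
  hi <- synthesize(model, stats::setNames(3 * sdk, pc))
  mean_mesh <- as_vertex_matrix(model$mean_shape)
  disp <- sqrt(rowSums((hi$vertices - mean_mesh)^2))
  thr <- displacement_threshold %||% stats::quantile(disp, 0.75, names = FALSE)
  list(displacement = disp, mask = disp >= thr, threshold = thr)
}

#' Dice overlap of two models' shape-change areas
#'
#' Compares where component `pc` moves the surface in two shape models fitted
#' on (sub)cohorts sharing the template topology: Dice = 2|A n B|/(|A|+|B|)
#' of the displacement masks. The comparison is also run against the
#' sign-flipped component and the larger Dice kept, absorbing eigenvector
#' sign ambiguity (displacement magnitudes are sign-invariant, so this is a
#' safeguard, not a correction). Two empty masks count as perfect agreement.
#'
#' @param modelA,modelB `shape_model`s with shared topology.
#' @param pc Component index (in both models).
#' @param displacement_threshold Passed to [shape_change_mask()].
#' @return Dice coefficient in `[0, 1]`.
#' @export
shape_change_overlap <- function(modelA, modelB, pc,
                                 displacement_threshold = NULL) {
  a <- shape_change_mask(modelA, pc, displacement_threshold)$mask
  dice_of <- function(mb) {
    if (!any(a) && !any(mb)) return(1)
    2 * sum(a & mb) / (sum(a) + sum(mb))
  }
  b <- shape_change_mask(modelB, pc, displacement_threshold)
  flipped <- modelB
  flipped$eigenvectors[, pc] <- -flipped$eigenvectors[, pc]
  bf <- shape_change_mask(flipped, pc, displacement_threshold)
  max(dice_of(b$mask), dice_of(bf$mask))
}

# Age strata used for stratified subset draws (seven bands).
age_bands <- function() {
  list(c(17, 29), c(30, 39), c(40, 49), c(50, 59),
       c(60, 69), c(70, 79), c(80, 93))
}

#' Nested age-stratified subset sweep
#'
#' Draws nested, age-stratified subsets of the cohort at the requested sizes,
#' fits the full shape-space per subset (GPA + PCA) and reports the three
#' component-selection criteria side by side: displayed-PC counts,
#' EV-threshold counts, scree-elbow counts, per-PC DBV slopes, and Dice
#' agreement of the leading components' shape-change areas between
#' consecutive subset sizes. Default sizes follow the published design
#' (123, 242, 300, 363 models plus the full set).
#'
#' @param models List of homologous models (with `meta$age`).
#' @param sizes Integer subset sizes; `NA` or values equal to the cohort size
#'   mean the full cohort. Default `c(123, 242, 300, 363, n)` clipped to n.
#' @param seed Integer seed for the stratified draw.
#' @param ev_threshold Threshold for [ev_threshold_select()].
#' @param n_pcs_dice Leading components compared across sizes with Dice.
#' @param allow_scaling Passed to [generalized_procrustes()].
#' @return List with `summary` (tibble: size, n_displayed, m_ev_threshold,
#'   m_scree, dice columns), `dbv` (tibble: size, pc, dbv), `models` (named
#'   list of `shape_model`s), `subsets` (index lists, nested).
#' @export
subset_sweep <- function(models, sizes = NULL, seed = 1, ev_threshold = NULL,
                         n_pcs_dice = 5, allow_scaling = TRUE) {
  n <- length(models)
  if (is.null(sizes)) {
    sizes <- pmin(c(123, 242, 300, 363, n), n)  # default design, clipped
  }
  sizes <- sizes[!is.na(sizes)]
  if (any(sizes > n)) stop("subset size exceeds cohort size", call. = FALSE)
  sizes <- sort(unique(sizes))
  ages <- vapply(models, function(m) m$meta$age, numeric(1))
  band_of <- vapply(ages, function(a) {
    which(vapply(age_bands(), function(b) a >= b[1] && a <= b[2], logical(1)))[1]
  }, numeric(1))
  # per-band random order; nested subsets are prefixes of a global order that
  # cycles through bands proportionally
  ord <- local_rng(seed)(function() {
    by_band <- split(seq_len(n), band_of)
    by_band <- lapply(by_band, sample)
    # interleave: take from the band with the largest remaining share
    counts <- lengths(by_band)
    taken <- integer(length(by_band))
    out <- integer(0)
    for (i in seq_len(n)) {
      frac <- (taken + 1) / counts
      b <- which.min(frac)
      taken[b] <- taken[b] + 1L
      out <- c(out, by_band[[b]][taken[b]])
    }
    out
  })
  subsets <- lapply(sizes, function(s) sort(ord[seq_len(s)]))
  names(subsets) <- as.character(sizes)

  fits <- lapply(subsets, function(idx) {
    gpa <- generalized_procrustes(models[idx], allow_scaling = allow_scaling)
    fit_shape_pca(gpa)
  })

  dbv_tbl <- purrr::map2_dfr(fits, sizes, function(f, s) {
    d <- dbv_per_pc(f, upto = min(f$n_displayed, 10L))
    d$size <- s
    d
  })
  summary <- tibble::tibble(
    size = sizes,
    n_displayed = vapply(fits, function(f) f$n_displayed, numeric(1)),
    m_ev_threshold = if (is.null(ev_threshold)) NA_real_ else
      vapply(fits, function(f)
        as.numeric(ev_threshold_select(f$eigenvalues, ev_threshold)),
        numeric(1)),
    m_scree = vapply(fits, function(f)
      as.numeric(scree_elbow(f$eigenvalues)), numeric(1))
  )
  if (length(fits) > 1L) {
    dice <- vapply(seq_len(length(fits) - 1L), function(i) {
      kk <- seq_len(min(n_pcs_dice, fits[[i]]$n_displayed,
                        fits[[i + 1]]$n_displayed))
      mean(vapply(kk, function(k)
        shape_change_overlap(fits[[i]], fits[[i + 1]], k), numeric(1)))
    }, numeric(1))
    summary$dice_with_next <- c(dice, NA_real_)
  }
  list(summary = summary, dbv = dbv_tbl, models = fits, subsets = subsets)
}
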