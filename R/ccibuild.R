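#' Synthesize composite images (CIs) from a shape model
#'
#' Builds the CI battery over the first k components at a fixed score
#' amplitude: two single-PC shapes (`-a`, `+a`) per component, plus all four
#' sign combinations for every unordered pair of components, i.e.
#' `2k + 4 * choose(k, 2)` meshes (50 for k = 5, 72 for k = 6). Ordering is
#' deterministic: singles by PC then sign (-, +), pairs lexicographic with
#' sign pairs (-,-), (-,+), (+,-), (+,+).
#'
#' @param model A `shape_model`.
#' @param k Number of leading components (must not exceed displayed PCs).
#' @param amplitude Positive raw score amplitude (no `sqrt(EV)` scaling; CI
#'   amplitudes are absolute score values read off the biplots).
#' @return A `ci_set`: list of composite images, each
#'   `list(mesh, provenance)` where provenance is a tibble of (pc, amplitude).
#' @export
make_composite_images <- function(model, k, amplitude) {
  if (k > model$n_displayed) {
    stop("k exceeds the model's displayed PCs", call. = FALSE)
  }
  if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
  cis <- list()
  add <- function(pcs, amps) {
    mesh <- synthesize(model, stats::setNames(amps, pcs))
    cis[[length(cis) + 1L]] <<- list(
      mesh = mesh,
      provenance = tibble::tibble(pc = pcs, amplitude = amps)
    )
  }
  for (j in seq_len(k)) for (s in c(-1, 1)) add(j, s * amplitude)
  if (k >= 2L) {
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      for (sa in c(-1, 1)) for (sb in c(-1, 1)) {
        add(c(a, b), c(sa, sb) * amplitude)
      }
    }
  }
  structure(cis, class = "ci_set", amplitude = amplitude, k = k)
}

#' Second-stage PCA over composite images
#'
#' PCA of the CI meshes themselves (no re-alignment: CIs are synthesized in
#' the common model frame). Its scree spectrum drives the choice of how many
#' prototype axes the final criterion images keep.
#'
#' @param cis A `ci_set` (or list of objects with a `mesh` field).
#' @param display_cr_threshold Display cutoff in percent.
#' @return A `shape_model` fitted to the CI meshes.
#' @export
second_stage_pca <- function(cis, display_cr_threshold = 1.0) {
  meshes <- lapply(cis, function(ci) if (!is.null(ci$mesh)) ci$mesh else ci)
  fit_shape_pca(meshes, display_cr_threshold = display_cr_threshold)
}

#' Derive classification criterion images (CCIs)
#'
#' Synthesizes the final prototypes from the second-stage model: the two
#' shapes at `+/- cci_amplitude` on each of the first `n_pcs` components,
#' labelled with Roman numerals in deterministic order (PC1-, PC1+, PC2-,
#' ...), giving `2 * n_pcs` criterion images (10 for the upper auricle at
#' `n_pcs = 5`, amplitude 100; 12 for the lobule at `n_pcs = 6`, amplitude
#' 30).
#'
#' @param ci_model A `shape_model` from [second_stage_pca()].
#' @param n_pcs Components kept (<= displayed PCs of `ci_model`).
#' @param cci_amplitude Positive raw score amplitude.
#' @param region `"upper_auricle"` or `"lobule"`.
#' @param threshold Classification DBV cutoff in mm (`NA` until calibrated,
#'   see [calibrate_threshold()]).
#' @return A `cci_set`: list with `region`, `ccis` (label, mesh, provenance),
#'   `cci_amplitude`, `n_pcs`, `threshold`.
#' @export
derive_ccis <- function(ci_model, n_pcs, cci_amplitude, region = "upper_auricle",
                        threshold = NA_real_) {
  region <- match.arg(region, ear_regions())
  if (cci_amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
  if (n_pcs > ci_model$n_displayed) {
    stop("n_pcs exceeds the model's displayed PCs", call. = FALSE)
  }
  ccis <- list()
  lab <- 0L
  for (j in seq_len(n_pcs)) for (s in c(-1, 1)) {
    lab <- lab + 1L
    ccis[[lab]] <- list(
      label = as.character(utils::as.roman(lab)),
      mesh = synthesize(ci_model, stats::setNames(s * cci_amplitude, j)),
      provenance = tibble::tibble(pc = j, amplitude = s * cci_amplitude)
    )
  }
  structure(
    list(region = region, ccis = ccis, n_pcs = as.integer(n_pcs),
         cci_amplitude = cci_amplitude, threshold = threshold,
         mean_shape = ci_model$mean_shape),
    class = "cci_set"
  )
}

#' @export
print.cci_set <- function(x, ...) {
  cat("<cci_set> ", length(x$ccis), " criterion images (", x$region,
      "), threshold ",
      if (is.na(x$threshold)) "uncalibrated" else
        paste0(signif(x$threshold, 4), " mm"),
      "\n", sep = "")
  invisible(x)
}

#' Labels of a CCI set
#' @param ccis A `cci_set`.
#' @return Character vector of Roman-numeral labels, in order.
#' @export
cci_labels <- function(ccis) {
  vapply(ccis$ccis, function(c3) c3$label, character(1))
}

# Exact min-cost assignment (Hungarian objective) by bitmask dynamic
# programming; cost is an n x n matrix, n <= ~16.
min_cost_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 16L)
  full <- bitwShiftL(1L, n) - 1L
  best <- rep(Inf, full + 1L)
  parent <- matrix(NA_integer_, nrow = full + 1L, ncol = 2L)
  best[1L] <- 0
  for (mask in 0:(full - 1L)) {
    if (!is.finite(best[mask + 1L])) next
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L)  # row index
    for (j in 0:(n - 1L)) {
      if (bitwAnd(mask, bitwShiftL(1L, j)) > 0L) next
      nm <- bitwOr(mask, bitwShiftL(1L, j))
      cand <- best[mask + 1L] + cost[i + 1L, j + 1L]
      if (cand < best[nm + 1L]) {
        best[nm + 1L] <- cand
        parent[nm + 1L, ] <- c(mask, j + 1L)
      }
    }
  }
  assign <- integer(n)
  mask <- full
  while (mask > 0L) {
    pm <- parent[mask + 1L, ]
    i <- sum(bitwAnd(pm[1], bitwShiftL(1L, 0:(n - 1L))) > 0L) + 1L
    assign[i] <- pm[2]
    mask <- pm[1]
  }
  assign
}

#' Distance between two CCI sets
#'
#' Mean DBV between corresponding criterion images of two sets after optimal
#' matching (exact min-cost assignment on the full DBV matrix), which absorbs
#' PC order and sign instability between independently fitted models. Used to
#' measure how stable the prototypes are across cohort subsets.
#'
#' @param setA,setB `cci_set`s with equal CCI counts and shared topology.
#' @return List with `pairs` (tibble: label_a, label_b, dbv) and `summary`
#'   (tibble: min, max, mean over matched pairs, mm).
#' @export
cci_set_distance <- function(setA, setB) {
  na <- length(setA$ccis); nb <- length(setB$ccis)
  if (na != nb) stop("CCI counts differ", call. = FALSE)
  cost <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cost[i, j] <- dbv(setA$ccis[[i]]$mesh, setB$ccis[[j]]$mesh)
  }
  assign <- min_cost_assignment(cost)
  d <- cost[cbind(seq_len(na), assign)]
  list(
    pairs = tibble::tibble(
      label_a = cci_labels(setA),
      label_b = cci_labels(setB)[assign],
      dbv = d
    ),
    summary = tibble::tibble(min = min(d), max = max(d), mean = mean(d))
  )
}
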