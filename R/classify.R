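#' Sentinel label for meshes beyond the threshold of every CCI
#' @export
OUT_OF_CLASSIFICATION <- "out_of_classification"

#' Classify one mesh against a CCI set
#'
#' Computes the mean DBV between the mesh and every criterion image and
#' assigns the label with the minimum DBV when that minimum is within the
#' set's threshold; otherwise the mesh is out of classification. Ties on the
#' minimum break by label order. All labels under the threshold are reported
#' (ordered by DBV) so multi-match cases remain auditable: the assignment is
#' always the DBV minimiser, and any visual override among under-threshold
#' candidates is left to the analyst.
#'
#' @param mesh A region sub-model (topology matching the CCIs).
#' @param ccis A `cci_set` with a calibrated `threshold`.
#' @return A `classification_result`: list with `dbv_by_cci` (named vector),
#'   `assigned`, `under_threshold_labels`, `rank_of_assigned`, `region`, and
#'   the subject's `meta` when present.
#' @export
classify_one <- function(mesh, ccis) {
  nv <- nrow(mesh$vertices)
  nv_cci <- nrow(ccis$ccis[[1]]$mesh$vertices)
  if (nv != nv_cci) {
    stop("mesh topology does not match the CCI set (", nv, " vs ", nv_cci,
         " vertices)", call. = FALSE)
  }
  labels <- cci_labels(ccis)
  d <- vapply(ccis$ccis, function(c3) dbv(mesh, c3$mesh), numeric(1))
  names(d) <- labels
  ord <- order(d)                      # stable: ties keep label order
  thr <- ccis$threshold
  under <- labels[ord][d[ord] <= thr]
  assigned <- if (length(under)) under[1] else OUT_OF_CLASSIFICATION
  structure(
    list(
      dbv_by_cci = d,
      assigned = assigned,
      under_threshold_labels = under,
      rank_of_assigned = if (identical(assigned, OUT_OF_CLASSIFICATION))
        NA_integer_ else 1L,
      region = ccis$region,
      meta = mesh$meta
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> assigned: ", x$assigned,
      " (min DBV ", signif(min(x$dbv_by_cci), 4), " mm, ",
      length(x$under_threshold_labels), " under threshold)\n", sep = "")
  invisible(x)
}

#' Calibrate the classification threshold
#'
#' The DBV cutoff separating classifiable from out-of-classification meshes
#' is not a published constant; it is calibrated as the q-th percentile of
#' the cohort's minimum DBV to its nearest criterion image, so that about q%
#' of the calibration cohort falls under the threshold.
#'
#' @param meshes List of region sub-models.
#' @param ccis A `cci_set` (threshold ignored).
#' @param q Percentile (default 90).
#' @return The `cci_set` with `threshold` set (also attribute
#'   `threshold_quantile`).
#' @export
calibrate_threshold <- function(meshes, ccis, q = 90) {
  mins <- vapply(meshes, function(m) {
    min(vapply(ccis$ccis, function(c3) dbv(m, c3$mesh), numeric(1)))
  }, numeric(1))
  ccis$threshold <- stats::quantile(mins, q / 100, names = FALSE)
  attr(ccis, "threshold_quantile") <- q
  ccis
}

#' Classify a cohort and summarise per region
#'
#' Splits each homologous model into its upper-auricle and lobule sub-models,
#' classifies both against the matching CCI set, and tabulates the four
#' headline statistics per region: meshes under/over the threshold,
#' multi-match cases (two or more labels under the threshold), and asymmetry
#' - computed only over subjects contributing both sides, flagged when the
#' left and right assignments differ (out-of-classification differs from
#' every label).
#'
#' @param models List of `homologous_model`s (full ears, with `meta`).
#' @param ccis_upper,ccis_lobule Calibrated `cci_set`s.
#' @return A `cohort_classification`: list with `results` (tibble: one row
#'   per mesh and region), `summary` (list of per-region
#'   `cohort_summary` lists).
#' @export
classify_cohort <- function(models, ccis_upper, ccis_lobule) {
  if (!length(models)) stop("empty cohort", call. = FALSE)
  sets <- list(upper_auricle = ccis_upper, lobule = ccis_lobule)
  rows <- list()
  for (m in models) {
    subs <- split_regions(m)
    for (reg in ear_regions()) {
      res <- classify_one(subs[[reg]], sets[[reg]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = m$meta$subject_id,
        side = m$meta$side,
        region = reg,
        assigned = res$assigned,
        min_dbv = min(res$dbv_by_cci),
        n_under_threshold = length(res$under_threshold_labels),
        under_threshold_labels =
          paste(res$under_threshold_labels, collapse = ",")
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summaries <- lapply(ear_regions(), function(reg) {
    summarise_region_results(dplyr::filter(results, .data$region == reg),
                             cci_labels(sets[[reg]]), reg)
  })
  names(summaries) <- ear_regions()
  structure(list(results = results, summary = summaries),
            class = "cohort_classification")
}

#' Tidy cohort classification into a four-row-per-region table
#'
#' Mirrors the headline layout of cohort CCI verification tables: counts and
#' percentages for under threshold, over threshold, multiple classification
#' model detection, and asymmetrical (over bilateral subjects).
#'
#' @param x A `cohort_classification`.
#' @param ... Unused.
#' @return Tibble with `region`, `statistic`, `n`, `denominator`, `percent`.
#' @export
tidy.cohort_classification <- function(x, ...) {
  purrr::map_dfr(x$summary, function(s) {
    tibble::tibble(
      region = s$region,
      statistic = c("under_threshold", "over_threshold", "multi_match",
                    "asymmetrical"),
      n = c(s$n_under_threshold, s$n_over_threshold, s$n_multi_match,
            s$n_asymmetric),
      denominator = c(s$n_total, s$n_total, s$n_total,
                      s$n_bilateral_subjects),
      percent = 100 * .data$n / .data$denominator
    )
  })
}

#' @export
glance.cohort_classification <- function(x, ...) {
  purrr::map_dfr(x$summary, function(s) {
    tibble::tibble(
      region = s$region, n_total = s$n_total,
      pct_under = 100 * s$n_under_threshold / s$n_total,
      pct_multi = 100 * s$n_multi_match / s$n_total,
      pct_asymmetric = if (s$n_bilateral_subjects)
        100 * s$n_asymmetric / s$n_bilateral_subjects else NA_real_
    )
  })
}

#' Per-CCI assignment frequencies
#'
#' The share of classified (under-threshold) meshes assigned to each
#' criterion image; fractions sum to one.
#'
#' @param summary A `cohort_classification`, or one region's summary list.
#' @param region Region to extract when a `cohort_classification` is given.
#' @return Tibble with `label`, `n`, `fraction`.
#' @export
assignment_frequencies <- function(summary, region = "upper_auricle") {
  s <- if (inherits(summary, "cohort_classification")) {
    summary$summary[[match.arg(region, ear_regions())]]
  } else summary
  tibble::tibble(
    label = s$assignment_labels,
    n = s$assignment_counts,
    fraction = s$assignment_counts / sum(s$assignment_counts)
  )
}
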