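models <- small_homologous_cohort(n = 40, K = 3, mode_sd = c(6, 4, 2),
                                  seed = 103)
gpa <- generalized_procrustes(models)
model <- fit_shape_pca(gpa)
cm <- second_stage_pca(make_composite_images(model, 3, 50))
ccis <- derive_ccis(cm, 3, 50)
ccis <- calibrate_threshold(gpa$models, ccis, q = 90)

test_that("each CCI self-classifies with zero DBV and rank 1", {
  for (j in seq_along(ccis$ccis)) {
    res <- classify_one(ccis$ccis[[j]]$mesh, ccis)
    expect_equal(res$assigned, ccis$ccis[[j]]$label)
    expect_equal(unname(res$dbv_by_cci[res$assigned]), 0)
    expect_equal(res$rank_of_assigned, 1L)
    expect_equal(res$under_threshold_labels[1], res$assigned)
  }
})

test_that("a mesh beyond the threshold of every CCI is out of classification", {
  far <- ccis$ccis[[1]]$mesh
  far$vertices <- far$vertices + 10 * ccis$threshold
  res <- classify_one(far, ccis)
  expect_equal(res$assigned, OUT_OF_CLASSIFICATION)
  expect_length(res$under_threshold_labels, 0)
  expect_true(is.na(res$rank_of_assigned))
})

test_that("per-CCI DBVs match a brute-force loop and sort under threshold", {
  m <- gpa$models[[7]]
  res <- classify_one(m, ccis)
  loop <- vapply(ccis$ccis, function(c3)
    mean(sqrt(rowSums((m$vertices - c3$mesh$vertices)^2))), numeric(1))
  expect_lt(max(abs(res$dbv_by_cci - loop)), 1e-12)
  u <- res$dbv_by_cci[res$under_threshold_labels]
  expect_true(all(diff(u) >= 0))
  expect_error(classify_one(tetra_mesh(), ccis), "topology")
})

test_that("lowering the threshold never increases the under-threshold count", {
  thresholds <- seq(0, 2 * ccis$threshold, length.out = 8)
  counts <- vapply(thresholds, function(t) {
    cc <- ccis; cc$threshold <- t
    sum(vapply(gpa$models, function(m)
      classify_one(m, cc)$assigned != OUT_OF_CLASSIFICATION, logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("percentile calibration puts about q% of the cohort under threshold", {
  frac <- mean(vapply(gpa$models, function(m)
    classify_one(m, ccis)$assigned != OUT_OF_CLASSIFICATION, logical(1)))
  expect_gte(frac, 0.87)
  expect_lte(frac, 0.93)
})

test_that("classification is invariant to CCI list order up to tie-breaking", {
  m <- gpa$models[[3]]
  res <- classify_one(m, ccis)
  perm <- rev(seq_along(ccis$ccis))
  shuffled <- ccis
  shuffled$ccis <- ccis$ccis[perm]
  res2 <- classify_one(m, shuffled)
  expect_equal(res2$assigned, res$assigned)
  expect_equal(res2$dbv_by_cci[names(res$dbv_by_cci)], res$dbv_by_cci)
})

test_that("cohort summary counts, frequencies and asymmetry follow the rules", {
  tpl <- make_template(0, seed = 1)
  spec <- population_spec(n_subjects = 12,
                          side_plan = c(both = 8, left = 3, right = 1),
                          n_modes = 3, mode_sd = c(6, 4, 2),
                          vertex_noise_sd = 0.1, seed = 107)
  coh <- sample_population(spec, tpl)
  hom <- cohort_to_homologous(coh)
  splits <- lapply(hom, split_regions)
  sets <- lapply(ear_regions(), function(reg) {
    subs <- lapply(splits, function(s) s[[reg]])
    g <- generalized_procrustes(subs)
    m <- fit_shape_pca(g)
    cmr <- second_stage_pca(make_composite_images(m, min(3, m$n_displayed), 50))
    cc <- derive_ccis(cmr, min(3, cmr$n_displayed), 50, region = reg)
    calibrate_threshold(g$models, cc, q = 90)
  })
  names(sets) <- ear_regions()
  # align per region, then stitch the aligned sub-regions back into full
  # models so classify_cohort's internal split reproduces them
  aligned <- lapply(ear_regions(), function(reg) {
    generalized_procrustes(lapply(splits, function(s) s[[reg]]))$models
  })
  names(aligned) <- ear_regions()
  stitched <- lapply(seq_along(hom), function(i) {
    m <- hom[[i]]
    for (reg in ear_regions()) {
      idx <- attr(splits[[i]][[reg]], "index_map")
      m$vertices[idx, ] <- aligned[[reg]][[i]]$vertices
    }
    m
  })
  res <- classify_cohort(stitched, sets$upper_auricle, sets$lobule)
  tab <- tidy(res)
  expect_setequal(unique(tab$statistic),
                  c("under_threshold", "over_threshold", "multi_match",
                    "asymmetrical"))
  s <- res$summary$upper_auricle
  expect_equal(s$n_under_threshold + s$n_over_threshold, s$n_total)
  expect_equal(sum(s$assignment_counts), s$n_under_threshold)
  # asymmetry denominator counts only bilateral subjects
  expect_equal(s$n_bilateral_subjects, 8)

  f <- assignment_frequencies(res, "lobule")
  if (sum(f$n) > 0) expect_lt(abs(sum(f$fraction) - 1), 1e-12)
})

test_that("assignment frequencies degenerate correctly", {
  s <- list(assignment_labels = c("I", "II", "III"),
            assignment_counts = c(10L, 0L, 0L))
  f <- assignment_frequencies(s)
  expect_equal(f$fraction, c(1, 0, 0))
})

test_that("a balanced synthetic cohort spreads assignments across CCIs", {
  frac <- assignment_frequencies(local({
    labels <- vapply(gpa$models, function(m) classify_one(m, ccis)$assigned,
                     character(1))
    keep <- labels != OUT_OF_CLASSIFICATION
    freq <- table(factor(labels[keep], levels = cci_labels(ccis)))
    list(assignment_labels = names(freq), assignment_counts = as.integer(freq))
  }))
  nonzero <- frac$fraction[frac$fraction > 0]
  expect_gte(length(nonzero), 3)
  expect_lt(max(nonzero) / min(nonzero), 8)
})
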