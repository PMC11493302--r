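test_that("DBV is the stated statistic of per-vertex distances", {
  a <- random_mesh(50, seed = 1)
  b <- random_mesh(50, seed = 2)
  expect_equal(dbv(a, a), 0)
  shifted <- a
  shifted$vertices <- sweep(a$vertices, 2, c(3, 0, 0), `+`)
  expect_equal(dbv(a, shifted), 3)
  expect_equal(dbv(a, shifted, "max"), 3)
  # brute-force per-vertex loop oracle
  loop <- mean(vapply(seq_len(50), function(i)
    sqrt(sum((a$vertices[i, ] - b$vertices[i, ])^2)), numeric(1)))
  expect_lt(abs(dbv(a, b) - loop), 1e-12)
  expect_error(dbv(a, random_mesh(40)), "vertex counts differ")
})

test_that("mean DBV is a pseudo-metric on corresponded meshes", {
  set.seed(77)
  meshes <- lapply(1:3, function(i) random_mesh(30, seed = i + 10))
  a <- meshes[[1]]; b <- meshes[[2]]; c3 <- meshes[[3]]
  expect_equal(dbv(a, b), dbv(b, a))
  expect_gte(dbv(a, b), 0)
  expect_lte(dbv(a, c3), dbv(a, b) + dbv(b, c3) + 1e-12)
  same <- a
  expect_identical(dbv(a, same), 0)
})

test_that("EV-magnitude selection crosses at PC6 on the published 414-model spectra", {
  upper <- reference_ev_table("upper_auricle")
  lobule <- reference_ev_table("lobule")
  expect_equal(ev_threshold_select(upper$ev, 500), 6)
  expect_equal(ev_threshold_select(lobule$ev, 100), 6)
  expect_equal(ev_threshold_select(upper$ev, upper$ev[1] + 1), 0)
  # monotone: a larger threshold never keeps more components
  thresholds <- c(50, 100, 300, 500, 1000, 2000)
  counts <- vapply(thresholds, function(t)
    as.numeric(ev_threshold_select(upper$ev, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(ev_threshold_select(c(1, 5, 2), 1), "non-increasing")
})

test_that("the scree elbow sits immediately before the steep-to-smooth turn", {
  expect_equal(scree_elbow(c(100, 90, 10, 9, 8)), 2)
  # exhaustive check of the rule on the same spectrum
  ev <- c(100, 90, 10, 9, 8)
  k <- 2:4
  d2 <- ev[k - 1] - 2 * ev[k] + ev[k + 1]
  expect_equal(scree_elbow(ev), k[which.max(d2)] - 1L)
  # smooth geometric decay still returns the defined index
  geo <- 100 * 0.5^(0:7)
  expect_equal(scree_elbow(geo), 1L)
  expect_error(scree_elbow(c(2, 1)), "at least 3")
  # spiked spectrum: K = 4 signal EVs over a noise floor
  set.seed(5)
  spiked <- c(c(400, 300, 220, 150), sort(runif(10, 1, 4), decreasing = TRUE))
  expect_equal(scree_elbow(spiked), 4L)
})

test_that("per-PC DBV of the ±3 SD pair matches its closed form", {
  models <- small_homologous_cohort(n = 12, seed = 71)
  m <- fit_shape_pca(generalized_procrustes(models))
  rep <- dbv_per_pc(m, upto = 4)
  for (k in 1:4) {
    phi <- matrix(m$eigenvectors[, k], ncol = 3, byrow = TRUE)
    closed <- 6 * sqrt(m$eigenvalues[k]) * mean(sqrt(rowSums(phi^2)))
    expect_lt(abs(rep$dbv[k] - closed), 1e-9)
  }
  # homogeneity: doubling all EVs doubles every per-PC DBV
  m2 <- m; m2$eigenvalues <- 4 * m$eigenvalues   # EV scales as amplitude^2
  expect_equal(dbv_per_pc(m2, upto = 4)$dbv, 2 * rep$dbv, tolerance = 1e-9)
  # zero-variance component moves nothing
  m0 <- m; m0$eigenvalues[2] <- 0
  expect_equal(dbv_per_pc(m0, upto = 2)$dbv[2], 0)
})

test_that("shape-change overlap is Dice on displacement masks", {
  models <- small_homologous_cohort(n = 20, seed = 73)
  m <- fit_shape_pca(generalized_procrustes(models))
  expect_equal(shape_change_overlap(m, m, 1), 1)
  # sign flip of the other model's PC is absorbed
  flipped <- m
  flipped$eigenvectors[, 1] <- -flipped$eigenvectors[, 1]
  expect_equal(shape_change_overlap(m, flipped, 1), 1)

  # disjoint single-vertex masks -> 0; empty masks -> 1 (via the mask rule)
  msk <- shape_change_mask(m, 1)
  expect_true(all(msk$displacement[msk$mask] >= msk$threshold))
  a <- c(TRUE, rep(FALSE, 9)); b <- c(rep(FALSE, 9), TRUE)
  dice <- function(x, y) if (!any(x) && !any(y)) 1 else
    2 * sum(x & y) / (sum(x) + sum(y))
  expect_equal(dice(a, b), 0)
  expect_equal(dice(logical(10), logical(10)), 1)
})

test_that("leading shape-change areas are stable across overlapping subsets", {
  models <- small_homologous_cohort(n = 80, K = 3, mode_sd = c(6, 4, 2),
                                    noise = 0.1, seed = 79)
  sub300 <- models[1:60]       # overlapping nested subsets, desk scale
  sub363 <- models[1:72]
  m1 <- fit_shape_pca(generalized_procrustes(sub300))
  m2 <- fit_shape_pca(generalized_procrustes(sub363))
  expect_gte(shape_change_overlap(m1, m2, 1), 0.8)
})

test_that("subset sweep draws nested age-stratified subsets and reports criteria", {
  models <- small_homologous_cohort(n = 60, seed = 83)
  sw <- subset_sweep(models, sizes = c(24, 40, 60), seed = 2,
                     ev_threshold = 1)
  expect_equal(sw$summary$size, c(24, 40, 60))
  expect_true(all(sw$subsets[["24"]] %in% sw$subsets[["40"]]))
  expect_true(all(sw$subsets[["40"]] %in% sw$subsets[["60"]]))
  expect_true(all(c("n_displayed", "m_ev_threshold", "m_scree",
                    "dice_with_next") %in% names(sw$summary)))
  # the full-cohort entry equals the direct pipeline
  direct <- fit_shape_pca(generalized_procrustes(models))
  expect_equal(sw$models[["60"]]$eigenvalues, direct$eigenvalues,
               tolerance = 1e-9)
  expect_error(subset_sweep(models, sizes = 61), "exceeds")
  # age strata are respected: subset age-band shares track the cohort's
  ages <- vapply(models, function(m) m$meta$age, numeric(1))
  band <- findInterval(ages, c(17, 30, 40, 50, 60, 70, 80))
  sub <- sw$subsets[["40"]]
  share_all <- table(factor(band, 1:7)) / length(band)
  share_sub <- table(factor(band[sub], 1:7)) / length(sub)
  expect_lt(max(abs(share_all - share_sub)), 0.08)
})
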