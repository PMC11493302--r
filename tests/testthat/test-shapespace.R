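tpl <- make_template(0, seed = 1)

test_that("GPA leaves mutually aligned copies fixed and undoes similarity transforms", {
  base <- cohort_to_homologous(sample_population(
    population_spec(n_subjects = 1, side_plan = c(both = 0, left = 1, right = 0),
                    n_modes = 2, mode_sd = c(4, 2), seed = 5), tpl))[[1]]
  copies <- replicate(4, base, simplify = FALSE)
  out <- generalized_procrustes(copies)
  centred <- scale(base$vertices, scale = FALSE)
  for (m in out$models) expect_lt(max(abs(m$vertices - centred)), 1e-9)

  set.seed(31)
  moved <- lapply(1:5, function(i) {
    m <- base
    m$vertices <- sweep(runif(1, 0.7, 1.4) *
                          base$vertices %*% t(rotation_matrix(rnorm(3), runif(1, 0, 1))),
                        2, rnorm(3, sd = 20), `+`)
    m
  })
  al <- generalized_procrustes(moved, allow_scaling = TRUE)
  ref <- al$models[[1]]$vertices
  for (m in al$models) expect_lt(max(abs(m$vertices - ref)), 1e-6)
  expect_error(generalized_procrustes(copies[1]), "at least 2")
})

test_that("GPA converges on a 50-subject synthetic cohort", {
  models <- small_homologous_cohort(n = 50, seed = 41)
  out <- generalized_procrustes(models)
  expect_true(out$converged)
  expect_lte(out$iterations, 100)
  expect_lt(max(abs(colMeans(out$mean_shape))), 1e-6)
})

test_that("GPA agrees with an independent pairwise Procrustes superimposition", {
  skip_if_not_installed("vegan")
  models <- small_homologous_cohort(n = 6, seed = 43)
  out <- generalized_procrustes(models, allow_scaling = TRUE)
  # aligning raw model i onto the GPA mean with vegan must reproduce the
  # package's aligned coordinates
  pv <- vegan::procrustes(out$mean_shape, models[[3]]$vertices,
                          scale = TRUE, symmetric = FALSE)
  cs <- function(x) sqrt(sum(scale(x, scale = FALSE)^2))
  fitted <- pv$Yrot * cs(out$mean_shape) / cs(pv$Yrot)
  expect_lt(dbv(fitted, out$models[[3]]$vertices), 1e-6)
})

test_that("shape PCA matches a dense covariance eigendecomposition", {
  set.seed(8)
  n <- 5; nvert <- 4
  confs <- lapply(1:n, function(i) {
    list(vertices = matrix(rnorm(nvert * 3), ncol = 3),
         faces = matrix(integer(0), 0, 3), region = NULL)
  })
  model <- fit_shape_pca(confs, display_cr_threshold = 0)
  X <- do.call(rbind, lapply(confs, function(m) as.vector(t(m$vertices))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / n                     # population covariance, 3N x 3N
  ev_dense <- sort(eigen(C, symmetric = TRUE)$values, decreasing = TRUE)
  expect_lt(max(abs(model$eigenvalues - ev_dense[seq_along(model$eigenvalues)])),
            1e-9)
  # scores reproduce centred data through the eigenbasis
  expect_lt(max(abs(model$scores %*% t(model$eigenvectors) - Xc)), 1e-9)
  expect_lt(max(abs(crossprod(model$eigenvectors) -
                      diag(ncol(model$eigenvectors)))), 1e-8)
  expect_lt(max(abs(colMeans(model$scores))), 1e-6)
})

test_that("two specimens give a single informative component", {
  models <- small_homologous_cohort(n = 2, seed = 3)
  m <- fit_shape_pca(models)
  expect_lt(m$eigenvalues[2] / m$eigenvalues[1], 1e-12)
  expect_equal(m$cr[1], 100, tolerance = 1e-9)
  expect_error(fit_shape_pca(models[1]), "at least 2")
})

test_that("the display threshold filters components exactly at CR >= cutoff", {
  models <- small_homologous_cohort(n = 15, seed = 19)
  m <- fit_shape_pca(models, display_cr_threshold = 1.0)
  expect_equal(m$n_displayed, sum(m$cr >= 1.0))
  m5 <- fit_shape_pca(models, display_cr_threshold = 5.0)
  expect_equal(m5$n_displayed, sum(m$cr >= 5.0))
})

test_that("synthesis is linear in scores and inverts projection", {
  models <- small_homologous_cohort(n = 12, seed = 29)
  m <- fit_shape_pca(models)
  expect_equal(as.vector(t(synthesize(m, numeric(0))$vertices)), m$mean_shape)
  sd1 <- sqrt(m$eigenvalues[1])
  mesh <- synthesize(m, c("1" = 3 * sd1))
  sc <- project_scores(m, mesh)
  expect_lt(abs(sc[1] - 3 * sd1), 1e-9)
  expect_lt(max(abs(sc[-1])), 1e-9)

  a <- c("1" = 10, "3" = -4); b <- c("1" = 2, "3" = 7)
  lhs <- synthesize(m, a)$vertices + synthesize(m, b)$vertices -
    matrix(m$mean_shape, ncol = 3, byrow = TRUE)
  rhs <- synthesize(m, c("1" = 12, "3" = 3))$vertices
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(synthesize(m, c("999" = 1)), "unknown PC")
})

test_that("each aligned specimen is reconstructed from its full score vector", {
  models <- small_homologous_cohort(n = 8, seed = 37)
  gpa <- generalized_procrustes(models)
  m <- fit_shape_pca(gpa)
  for (i in c(1, 5)) {
    rec <- m$mean_shape + as.numeric(m$eigenvectors %*% m$scores[i, ])
    expect_lt(max(abs(rec - as.vector(t(gpa$models[[i]]$vertices)))), 1e-6)
  }
})

test_that("uniform rescaling scales EVs by c^2 and leaves CR/CCR unchanged", {
  models <- small_homologous_cohort(n = 10, seed = 53)
  m1 <- fit_shape_pca(generalized_procrustes(models))
  scaled <- lapply(models, function(m) { m$vertices <- 2.5 * m$vertices; m })
  m2 <- fit_shape_pca(generalized_procrustes(scaled))
  k <- seq_len(5)
  expect_equal(m2$eigenvalues[k], 2.5^2 * m1$eigenvalues[k], tolerance = 1e-6)
  expect_equal(m2$cr[k], m1$cr[k], tolerance = 1e-6)
  expect_equal(m2$ccr[k], m1$ccr[k], tolerance = 1e-6)
})

test_that("score-age correlations flag the injected mode and nothing else", {
  spec <- population_spec(n_subjects = 200,
                          side_plan = c(both = 0, left = 200, right = 0),
                          n_modes = 3, mode_sd = c(6, 4, 2),
                          vertex_noise_sd = 0.1,
                          age_linked_mode = list(mode = 2, r = 0.5), seed = 61)
  coh <- sample_population(spec, tpl)
  models <- cohort_to_homologous(coh)
  m <- fit_shape_pca(generalized_procrustes(models, allow_scaling = FALSE))
  ages <- cohort_manifest(coh)$age
  rr <- score_covariate_correlation(m, ages)
  top <- rr$r[1:3]
  hit <- which(abs(top) >= 0.4 & abs(top) <= 0.6)
  expect_length(hit, 1)
  expect_lt(max(abs(top[-hit])), 0.2)

  # degenerate covariate
  expect_true(all(is.na(score_covariate_correlation(m, rep(50, 200))$r)))
  expect_error(score_covariate_correlation(m, 1:3), "one value per specimen")
})

test_that("tidy/glance expose the PC table at table precision", {
  models <- small_homologous_cohort(n = 10, seed = 67)
  m <- fit_shape_pca(generalized_procrustes(models))
  tab <- tidy(m, rounded = TRUE)
  expect_named(tab, c("pc", "ev", "cr", "ccr"))
  expect_equal(tab$cr, round(m$cr[seq_len(m$n_displayed)], 1))
  expect_true(all(diff(tab$ccr) >= -1e-9))
  g <- glance(m)
  expect_equal(g$n_specimens, 10)
  # displayed CCR ties out with the displayed EV share of total variance
  expect_equal(g$ccr_displayed,
               100 * sum(m$eigenvalues[seq_len(m$n_displayed)]) /
                 m$total_variance,
               tolerance = 1e-9)
})

test_that("a shape model round-trips through its directory form", {
  models <- small_homologous_cohort(n = 8, seed = 131)
  m <- fit_shape_pca(generalized_procrustes(models))
  d <- withr::local_tempdir()
  write_shape_model(m, d)
  back <- read_shape_model(d)
  expect_equal(back$eigenvalues, m$eigenvalues, tolerance = 1e-12)
  expect_equal(back$mean_shape, m$mean_shape, tolerance = 1e-12)
  expect_equal(back$n_displayed, m$n_displayed)
  sc <- c("1" = 3 * sqrt(m$eigenvalues[1]))
  expect_lt(dbv(synthesize(back, sc), synthesize(m, sc)), 1e-9)
})
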