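test_that("template generation is deterministic and region-partitioned", {
  a <- make_template(0, seed = 3)
  b <- make_template(0, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$vertices, make_template(0, seed = 4)$vertices))
  expect_true(all(table(a$region) > 0))
  expect_equal(length(a$region), n_vertices(a))
  expect_setequal(rownames(a$landmarks), ear_landmark_names())
})

test_that("full-resolution template matches the reference vertex/polygon budget", {
  tpl <- make_template(3, seed = 1)
  expect_equal(n_vertices(tpl), 5507)
  expect_equal(n_faces(tpl), 16521)
  expect_true(all(tpl$faces >= 1) && all(tpl$faces <= 5507))
  expect_true(all(table(tpl$region) > 0))
})

test_that("ground-truth modes are orthonormal, smooth fields", {
  tpl <- make_template(0, seed = 1)
  K <- 4
  phi <- make_modes(tpl, K, seed = 2)
  expect_equal(dim(phi), c(3 * n_vertices(tpl), K))
  expect_lt(max(abs(crossprod(phi) - diag(K))), 1e-8)
  expect_equal(sqrt(sum(make_modes(tpl, 1, seed = 2)^2)), 1)
  expect_error(make_modes(tpl, 3 * n_vertices(tpl) + 1), "exceeds")

  # roughness (mean neighbour difference) decreases as smoothness increases
  nb <- lapply(seq_len(n_vertices(tpl)), function(i) {
    f <- tpl$faces
    unique(setdiff(as.vector(f[rowSums(f == i) > 0, ]), i))
  })
  roughness <- function(field) {
    v <- matrix(field, ncol = 3, byrow = TRUE)
    mean(vapply(seq_along(nb), function(i) {
      if (!length(nb[[i]])) return(0)
      mean(sqrt(rowSums((v[nb[[i]], , drop = FALSE] -
                           matrix(v[i, ], length(nb[[i]]), 3, byrow = TRUE))^2)))
    }, numeric(1)))
  }
  r <- vapply(c(2, 8, 20), function(s)
    roughness(make_modes(tpl, 1, smoothness = s, seed = 7)[, 1]), numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("degenerate spec reproduces the template on both sides", {
  tpl <- make_template(0, seed = 1)
  spec <- population_spec(n_subjects = 4, side_plan = c(both = 2, left = 1, right = 1),
                          n_modes = 2, mode_sd = c(0, 0), vertex_noise_sd = 0,
                          asymmetry_sd = 0, seed = 5)
  coh <- sample_population(spec, tpl)
  for (s in coh) {
    mesh <- s$mesh
    if (s$meta$side == "right") mesh <- mirror_mesh(mesh, "yz")
    expect_lt(max(abs(mesh$vertices - tpl$vertices)), 1e-12)
  }
})

test_that("latent scores match the requested spread and age linkage", {
  tpl <- make_template(0, seed = 1)
  sds <- c(6, 4, 2)
  spec <- population_spec(n_subjects = 1000,
                          side_plan = c(both = 0, left = 1000, right = 0),
                          n_modes = 3, mode_sd = sds, vertex_noise_sd = 0,
                          seed = 9)
  coh <- sample_population(spec, tpl)
  z <- do.call(rbind, lapply(coh, function(s) s$true_scores))
  expect_true(all(abs(apply(z, 2, var) / sds^2 - 1) < 0.10))

  spec2 <- population_spec(n_subjects = 500,
                           side_plan = c(both = 0, left = 500, right = 0),
                           n_modes = 3, mode_sd = sds,
                           age_linked_mode = list(mode = 2, r = 0.5), seed = 9)
  coh2 <- sample_population(spec2, tpl)
  z2 <- do.call(rbind, lapply(coh2, function(s) s$true_scores))
  ages <- cohort_manifest(coh2)$age
  expect_lt(abs(cor(z2[, 2], ages) - 0.5), 0.08)
  expect_error(
    population_spec(n_modes = 1, mode_sd = 1,
                    age_linked_mode = list(mode = 1, r = 1.2)),
    "\\|r\\| < 1")
})

test_that("the default cohort plan yields 218 left + 196 right = 414 meshes", {
  spec <- population_spec()
  expect_equal(sum(spec$side_plan), 228)
  # counts follow from the plan without sampling meshes
  n_left <- spec$side_plan[["both"]] + spec$side_plan[["left"]]
  n_right <- spec$side_plan[["both"]] + spec$side_plan[["right"]]
  expect_equal(n_left, 218)
  expect_equal(n_right, 196)
  expect_equal(n_left + n_right, 414)
})

test_that("identical spec and seed reproduce the cohort exactly", {
  tpl <- make_template(0, seed = 1)
  spec <- population_spec(n_subjects = 6, side_plan = c(both = 3, left = 2, right = 1),
                          n_modes = 2, mode_sd = c(3, 1), seed = 21)
  expect_identical(sample_population(spec, tpl), sample_population(spec, tpl))
})

test_that("PCA on noise-free samples recovers the true mode subspace", {
  tpl <- make_template(0, seed = 1)
  K <- 3
  spec <- population_spec(n_subjects = 40, side_plan = c(both = 0, left = 40, right = 0),
                          n_modes = K, mode_sd = c(6, 4, 2),
                          vertex_noise_sd = 0, seed = 13)
  coh <- sample_population(spec, tpl)
  X <- do.call(rbind, lapply(coh, function(s) as.vector(t(s$mesh$vertices))))
  Xc <- sweep(X, 2, colMeans(X))
  V <- svd(Xc)$v[, 1:K]
  expect_lt(max_principal_angle(V, attr(coh, "modes")), 5)
})

test_that("resampled cohorts permute vertex order but keep landmarks", {
  tpl <- make_template(0, seed = 1)
  spec <- population_spec(n_subjects = 2, side_plan = c(both = 0, left = 2, right = 0),
                          n_modes = 2, mode_sd = c(0, 0), vertex_noise_sd = 0,
                          correspondence_jitter = "resample", seed = 2)
  coh <- sample_population(spec, tpl)
  m <- coh[[1]]$mesh
  expect_false(isTRUE(all.equal(m$vertices, tpl$vertices)))
  expect_equal(sort(as.vector(m$vertices)), sort(as.vector(tpl$vertices)))
  expect_lt(max(abs(m$landmarks - tpl$landmarks)), 1e-12)
  expect_error(cohort_to_homologous(coh), "resampled")
})

test_that("write_cohort persists meshes and a manifest", {
  tpl <- make_template(0, seed = 1)
  spec <- population_spec(n_subjects = 2, side_plan = c(both = 1, left = 1, right = 0),
                          n_modes = 2, mode_sd = c(2, 1), seed = 4)
  coh <- sample_population(spec, tpl)
  d <- withr::local_tempdir()
  man <- write_cohort(coh, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(all(file.exists(file.path(d, man$mesh))))
  back <- read_mesh(file.path(d, man$mesh[1]))
  expect_lt(max(abs(back$vertices - coh[[1]]$mesh$vertices)), 1e-5)
})
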