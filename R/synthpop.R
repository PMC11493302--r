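#' Ground-truth deformation modes for the synthetic cohort
#'
#' Draws `K` random vertex displacement fields, smooths them over the mesh
#' adjacency graph (bandlimiting them over the surface), and orthonormalises
#' the result. These orthonormal fields play the role of the population's true
#' shape components: downstream PCA should recover their span.
#'
#' @param template A [tri_mesh()].
#' @param K Number of modes (1 to 3N).
#' @param smoothness Non-negative integer: rounds of Laplacian smoothing
#'   applied to each raw field before orthonormalisation. Default 10.
#' @param seed Integer seed; output is fully determined by it.
#' @return A 3N x K matrix with orthonormal columns (unit 3N vectors).
#' @export
make_modes <- function(template, K, smoothness = 10, seed = 1) {
  n <- n_vertices(template)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > 3 * n) stop("K exceeds 3N degrees of freedom", call. = FALSE)
  nbrs <- vertex_neighbours(template)
  raw <- local_rng(seed)(function() matrix(stats::rnorm(3 * n * K), ncol = K))
  for (k in seq_len(K)) {
    f <- as_vertex_matrix(raw[, k])
    for (s in seq_len(smoothness)) f <- laplacian_smooth(f, nbrs)
    raw[, k] <- as_shape_vector(f)
  }
  q <- qr.Q(qr(raw))[, seq_len(K), drop = FALSE]
  # deterministic sign: largest-|entry| component positive
  for (k in seq_len(K)) {
    j <- which.max(abs(q[, k]))
    if (q[j, k] < 0) q[, k] <- -q[, k]
  }
  q
}

#' Specification of a synthetic ear cohort
#'
#' The defaults emulate the study conditions of a forensic CT ear cohort:
#' 228 male subjects of which 186 contribute both ears, 32 the left only and
#' 10 the right only (218 left + 196 right = 414 meshes), ages uniform over
#' 17--93 years, six smooth orthonormal deformation modes with mm-scale
#' standard deviations, small per-vertex measurement noise and a small
#' left/right asymmetry perturbation.
#'
#' @param n_subjects Number of subjects.
#' @param side_plan Named integer vector `c(both =, left =, right =)` whose sum
#'   is `n_subjects`: how many subjects contribute both ears / left only /
#'   right only.
#' @param n_modes Number K of ground-truth deformation modes.
#' @param mode_sd Length-K positive vector of latent-score standard deviations
#'   (mm scale).
#' @param age_range Integer `c(min, max)` years; ages drawn uniformly.
#' @param age_linked_mode Optional `list(mode =, r =)`: that mode's scores are
#'   constructed to have Pearson correlation `r` with age (|r| < 1).
#' @param asymmetry_sd Per-vertex mm sd of the extra perturbation applied to a
#'   subject's right ear relative to the left.
#' @param vertex_noise_sd Per-coordinate mm sd of i.i.d. vertex noise.
#' @param correspondence_jitter `"none"` keeps every target in template vertex
#'   order; `"resample"` randomly permutes each target's vertex order (faces
#'   remapped) so targets no longer share the template ordering and must be
#'   re-corresponded by template fitting.
#' @param seed Integer seed; the cohort is fully determined by the spec.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_subjects = 228,
                            side_plan = c(both = 186, left = 32, right = 10),
                            n_modes = 6,
                            mode_sd = c(6, 5, 4, 3, 2.5, 2),
                            age_range = c(17L, 93L),
                            age_linked_mode = NULL,
                            asymmetry_sd = 0.3,
                            vertex_noise_sd = 0.15,
                            correspondence_jitter = c("none", "resample"),
                            seed = 1) {
  correspondence_jitter <- match.arg(correspondence_jitter)
  side_plan <- side_plan[c("both", "left", "right")]
  if (anyNA(side_plan) || sum(side_plan) != n_subjects) {
    stop("side_plan must be named c(both=, left=, right=) summing to n_subjects",
         call. = FALSE)
  }
  if (length(mode_sd) != n_modes || any(mode_sd < 0)) {
    stop("mode_sd must be length n_modes and non-negative", call. = FALSE)
  }
  if (!is.null(age_linked_mode)) {
    if (abs(age_linked_mode$r) >= 1 || age_linked_mode$mode > n_modes) {
      stop("age_linked_mode requires |r| < 1 and a valid mode index",
           call. = FALSE)
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), side_plan = side_plan,
         n_modes = as.integer(n_modes), mode_sd = as.numeric(mode_sd),
         age_range = as.integer(age_range), age_linked_mode = age_linked_mode,
         asymmetry_sd = asymmetry_sd, vertex_noise_sd = vertex_noise_sd,
         correspondence_jitter = correspondence_jitter,
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' Sample a synthetic ear cohort
#'
#' Each subject's left-ear shape is `template + sum_k z_k * phi_k + noise`,
#' with latent scores `z_k ~ N(0, mode_sd_k^2)` shared between that subject's
#' two sides. Right ears additionally receive an asymmetry perturbation and
#' are mirrored across the yz plane (so the raw cohort contains native right
#' ears, as CT reconstruction would produce). When an age-linked mode is
#' requested, that mode's scores are built from the standardised ages so the
#' empirical Pearson correlation equals the requested value.
#'
#' @param spec A [population_spec()].
#' @param template A [tri_mesh()] from [make_template()].
#' @param modes Optional 3N x K mode matrix; by default
#'   `make_modes(template, spec$n_modes, seed = spec$seed)`.
#' @return A `synthetic_cohort`: list of subjects, each with `meta`
#'   ([subject_meta()]), `mesh` ([tri_mesh()]), `true_scores` (length K) and
#'   `true_region_labels`. Attribute `modes` stores the mode matrix.
#' @export
sample_population <- function(spec, template, modes = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(modes)) {
    modes <- make_modes(template, spec$n_modes, seed = spec$seed)
  }
  n <- spec$n_subjects
  K <- spec$n_modes
  nverts <- n_vertices(template)
  lm_idx <- attr(template, "landmark_vertices")
  if (is.null(lm_idx)) stop("template must carry landmark vertex indices",
                            call. = FALSE)

  draws <- local_rng(spec$seed + 1L)(function() {
    ages <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
    z <- matrix(stats::rnorm(n * K), nrow = n)
    list(
      ages = ages, z = z,
      asym = matrix(stats::rnorm(n * 3 * nverts), nrow = n),
      noise_seed = sample.int(2^31 - 2L, 1L),
      perm_seed = sample.int(2^31 - 2L, 1L)
    )
  })
  ages <- draws$ages
  z <- draws$z
  if (!is.null(spec$age_linked_mode)) {
    if (stats::sd(ages) == 0) stop("cannot link scores to constant age",
                                   call. = FALSE)
    j <- spec$age_linked_mode$mode
    r <- spec$age_linked_mode$r
    a_std <- as.numeric(scale(ages))
    e <- stats::residuals(stats::lm(z[, j] ~ a_std))
    e_std <- as.numeric(scale(e))
    z[, j] <- r * a_std + sqrt(1 - r^2) * e_std
  }
  z <- sweep(z, 2, spec$mode_sd, `*`)

  sides_of <- c(rep(list(c("left", "right")), spec$side_plan["both"]),
                rep(list("left"), spec$side_plan["left"]),
                rep(list("right"), spec$side_plan["right"]))

  base_vec <- as_shape_vector(template$vertices)
  subjects <- list()
  noise_rng <- local_rng(draws$noise_seed)
  perm_rng <- local_rng(draws$perm_seed)
  n_meshes <- sum(lengths(sides_of))
  noise <- noise_rng(function()
    matrix(stats::rnorm(n_meshes * 3 * nverts, sd = max(spec$vertex_noise_sd, 0)),
           nrow = n_meshes))
  if (spec$vertex_noise_sd == 0) noise[] <- 0
  perms <- perm_rng(function()
    lapply(seq_len(n_meshes), function(i) sample.int(nverts)))

  mesh_i <- 0L
  for (i in seq_len(n)) {
    shape_left <- base_vec + as.numeric(modes %*% z[i, ])
    for (side in sides_of[[i]]) {
      mesh_i <- mesh_i + 1L
      vec <- shape_left
      if (side == "right") {
        vec <- vec + spec$asymmetry_sd * draws$asym[i, ]
      }
      vec <- vec + noise[mesh_i, ]
      verts <- as_vertex_matrix(vec)
      lm <- verts[lm_idx, , drop = FALSE]
      rownames(lm) <- names(lm_idx)
      region <- template$region
      faces <- template$faces
      if (spec$correspondence_jitter == "resample") {
        p <- perms[[mesh_i]]                  # p[new] = old
        inv <- integer(nverts); inv[p] <- seq_len(nverts)
        verts <- verts[p, , drop = FALSE]
        faces <- matrix(inv[faces], ncol = 3)
        region <- region[p]
      }
      mesh <- tri_mesh(verts, faces, landmarks = lm, region = region)
      if (side == "right") mesh <- mirror_mesh(mesh, "yz")
      subjects[[length(subjects) + 1L]] <- list(
        meta = subject_meta(sprintf("S%04d", i), side, ages[i]),
        mesh = mesh,
        true_scores = z[i, ],
        true_region_labels = region
      )
    }
  }
  structure(subjects, class = "synthetic_cohort", modes = modes, spec = spec)
}

#' Cohort manifest as a tibble
#'
#' @param cohort A `synthetic_cohort` from [sample_population()], or any list
#'   of subjects/models carrying a `meta` field.
#' @return A tibble with one row per mesh: `subject_id`, `side`, `age`.
#' @export
cohort_manifest <- function(cohort) {
  tibble::tibble(
    subject_id = vapply(cohort, function(s) s$meta$subject_id, character(1)),
    side = vapply(cohort, function(s) s$meta$side, character(1)),
    age = vapply(cohort, function(s) s$meta$age, integer(1))
  )
}

#' Write a synthetic cohort to disk
#'
#' Writes one PLY mesh (+ landmark sidecar) per subject-side and a manifest
#' CSV (`subject_id`, `side`, `age`, `mesh`, true scores).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  man$mesh <- sprintf("%s_%s.ply", man$subject_id, man$side)
  scores <- do.call(rbind, lapply(cohort, function(s) s$true_scores))
  colnames(scores) <- paste0("true_score_", seq_len(ncol(scores)))
  man <- dplyr::bind_cols(man, tibble::as_tibble(scores))
  for (i in seq_along(cohort)) {
    write_mesh(cohort[[i]]$mesh, file.path(dir, man$mesh[i]), format = "ply")
  }
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  invisible(man)
}

#' Convert template-ordered synthetic subjects to homologous models
#'
#' When a cohort was generated without correspondence jitter its meshes are
#' already in template vertex order, so dense correspondence is known by
#' construction and template fitting is unnecessary: this converter mirrors
#' right ears into the left frame and wraps each mesh as a homologous model
#' with zero fit residual.
#'
#' @param cohort A `synthetic_cohort` from [sample_population()] (generated
#'   with `correspondence_jitter = "none"`).
#' @return List of `homologous_model`s.
#' @export
cohort_to_homologous <- function(cohort) {
  spec <- attr(cohort, "spec")
  if (!is.null(spec) && spec$correspondence_jitter != "none") {
    stop("cohort was resampled; use fit_template() for correspondence",
         call. = FALSE)
  }
  lapply(cohort, function(s) {
    mesh <- s$mesh
    if (s$meta$side == "right") mesh <- mirror_mesh(mesh, "yz")
    structure(
      list(vertices = mesh$vertices, faces = mesh$faces,
           region = mesh$region, landmarks = mesh$landmarks,
           meta = s$meta, fit_residual = 0),
      class = "homologous_model"
    )
  })
}
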