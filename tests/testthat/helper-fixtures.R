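# Shared fixtures, built in code at test time.

# Regular tetrahedron: minimal closed triangle mesh.
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  tri_mesh(v, f)
}

# Small irregular mesh with a seeded vertex cloud (for brute-force oracles).
random_mesh <- function(n = 50, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * 3, sd = 10), ncol = 3)
  f <- t(utils::combn(min(n, 6), 3))  # a few faces over the first vertices
  tri_mesh(v, f)
}

# Template plus landmark-carrying copy under a known similarity transform.
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transform_mesh <- function(mesh, s = 1, R = diag(3), t = c(0, 0, 0)) {
  out <- mesh
  out$vertices <- sweep(s * mesh$vertices %*% t(R), 2, t, `+`)
  if (!is.null(mesh$landmarks)) {
    out$landmarks <- sweep(s * mesh$landmarks %*% t(R), 2, t, `+`)
  }
  out
}

# Small template-ordered cohort converted straight to homologous models.
small_homologous_cohort <- function(n = 20, K = 3, mode_sd = c(5, 3, 2),
                                    noise = 0.1, seed = 11, template = NULL,
                                    ...) {
  template <- template %||% make_template(0, seed = 1)
  spec <- population_spec(
    n_subjects = n,
    side_plan = c(both = 0, left = n, right = 0),
    n_modes = K, mode_sd = mode_sd, vertex_noise_sd = noise,
    asymmetry_sd = 0, seed = seed, ...
  )
  cohort_to_homologous(sample_population(spec, template))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest principal angle (degrees) between the column spans of A and B.
max_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(sv)))) * 180 / pi
}
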