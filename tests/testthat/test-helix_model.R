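test_that("centroid is the arithmetic mean of rows", {
  expect_equal(backbone_centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(backbone_centroid(rbind(c(5, -1, 2))), c(5, -1, 2))
  expect_error(backbone_centroid(matrix(numeric(0), 0, 3)),
               class = "helixforce_error_validation")
})

test_that("centroid of a full-turn ideal helix lies on the true axis", {
  # 18 residues at 100 deg/residue span exactly five full turns of phase,
  # so the radial components cancel
  gen <- generate_ideal_helix(ideal_helix_spec(n_residues = 18L,
                                               axis_direction = c(1, 0, 0)))
  ctr <- backbone_centroid(gen$truth$ca)
  expect_lt(max(abs(ctr[2:3])), 1e-9)
})

test_that("principal axis recovers collinear directions with N-to-C sign", {
  M <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  ax <- principal_axis(M)
  expect_equal(ax$direction, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(principal_axis(M[4:1, ])$direction, c(-1, 0, 0), tolerance = 1e-12)
  # covariance reconstructs from its SVD factors
  d <- ax$decomposition
  recon <- d$left_singular_vectors %*% diag(d$singular_values) %*%
    t(d$right_singular_vectors)
  expect_lt(max(abs(recon - d$covariance)), 1e-9)
  expect_true(all(diff(d$singular_values) <= 0) && all(d$singular_values >= 0))
})

test_that("principal axis rejects degenerate inputs", {
  expect_error(principal_axis(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))),
               class = "helixforce_error_degenerate")
  expect_error(principal_axis(rbind(c(0, 0, 0), c(1, 0, 0))),
               class = "helixforce_error_validation")
})

test_that("fitted axis matches an oblique generator axis and a brute-force oracle", {
  axis_true <- c(1, 1, 1) / sqrt(3)
  gen <- generate_ideal_helix(ideal_helix_spec(n_residues = 18L,
                                               axis_direction = axis_true))
  d_svd <- principal_axis(gen$truth$ca)$direction
  # finite-length tilt of a short discrete helix: ~2.2 deg at 18 residues,
  # shrinking with length (the SVD axis is the exact variance maximiser;
  # the tilt is a property of the estimand, not the estimator)
  expect_equal(angle_between_deg(d_svd, axis_true), 2.2232, tolerance = 1e-3)
  d_bf <- brute_force_axis(gen$truth$ca)
  expect_lt(angle_between_deg(d_svd, d_bf), 0.05)

  gen72 <- generate_ideal_helix(ideal_helix_spec(n_residues = 72L,
                                                 axis_direction = axis_true))
  expect_lt(angle_between_deg(principal_axis(gen72$truth$ca)$direction, axis_true), 0.2)
})

test_that("axis endpoints are orthogonal projections of the terminal residues", {
  ends <- axis_endpoints(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, -1, 0))
  expect_equal(ends$axis_start, c(0, 0, 0))
  expect_equal(ends$axis_end, c(2, 0, 0))
  # a point already on the axis projects to itself
  on_axis <- axis_endpoints(c(1, 0, 0), c(1, 0, 0), c(3, 0, 0), c(5, 0, 0))
  expect_equal(on_axis$axis_start, c(3, 0, 0))
})

test_that("perpendicular foot and parameter behave like the line equation", {
  r <- point_on_axis(c(0, 0, 0), c(2, 0, 0), c(1, 5, 0))
  expect_equal(r$foot, c(1, 0, 0)); expect_equal(r$t, 0.5)
  r0 <- point_on_axis(c(0, 0, 0), c(2, 0, 0), c(0, 0, 0))
  expect_equal(r0$foot, c(0, 0, 0)); expect_equal(r0$t, 0)
  r2 <- point_on_axis(c(0, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_equal(r2$t, 1.5); expect_equal(r2$foot, c(3, 0, 0))
  # perpendicularity of the residual
  q <- c(0.3, 1.7, -2.2)
  rq <- point_on_axis(c(0, 0, 0), c(2, 0, 0), q)
  expect_lt(abs(sum((rq$foot - q) * c(1, 0, 0))), 1e-9)
  expect_error(point_on_axis(c(1, 1, 1), c(1, 1, 1), q),
               class = "helixforce_error_degenerate")
})

test_that("radius is the mean true Euclidean distance to the axis", {
  M <- rbind(c(0, 1, 0), c(1, -1, 0), c(2, 0, 1), c(3, 0, -1))
  r <- backbone_radius(M, c(0, 0, 0), c(3, 0, 0))
  expect_equal(r$radial_distances, rep(1, 4))
  expect_equal(r$radius, 1)
  r2 <- backbone_radius(rbind(c(1.5, 0, 0)), c(0, 0, 0), c(3, 0, 0))
  expect_equal(r2$radial_distances, 0)
})

test_that("sidechain spheres take the mean position and mean spread", {
  s <- sidechain_sphere(rbind(c(0, 0, 0), c(2, 0, 0)), c(9, 9, 9))
  expect_equal(s$center, c(1, 0, 0)); expect_equal(s$sphere_radius, 1)
  s1 <- sidechain_sphere(rbind(c(4, 4, 4)), c(0, 0, 0))
  expect_equal(s1$center, c(4, 4, 4)); expect_equal(s1$sphere_radius, 0)
  # glycine: centre falls back to the C-alpha
  s0 <- sidechain_sphere(matrix(numeric(0), 0, 3), c(1, 2, 3))
  expect_equal(s0$center, c(1, 2, 3)); expect_equal(s0$atom_count, 0L)
  # regular tetrahedron with circumradius 1.5: all vertices equidistant
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v <- v / sqrt(3) * 1.5
  st <- sidechain_sphere(sweep(v, 2, c(2, -1, 0), `+`), c(0, 0, 0))
  expect_equal(st$center, c(2, -1, 0), tolerance = 1e-12)
  expect_equal(st$sphere_radius, 1.5, tolerance = 1e-12)
})

test_that("a full model fit reproduces the generator geometry", {
  fit <- fit_ideal(ideal_helix_spec(n_residues = 18L))
  g <- fit$model$geometry
  expect_equal(g$n_residues, 18L)
  # values computed from the generator ground truth (finite-length tilt
  # shifts them slightly off the nominal 2.3 / 25.5)
  expect_equal(g$radius, 2.2717, tolerance = 1e-3)
  expect_equal(g$axis_length, 25.6175, tolerance = 1e-3)
  expect_equal(g$radius, mean(g$radial_distances))
  expect_equal(sqrt(sum(g$direction^2)), 1, tolerance = 1e-9)
  # collinearity of start, centroid, end
  v1 <- g$centroid - g$axis_start
  v2 <- g$axis_end - g$axis_start
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  expect_lt(sqrt(sum(cr^2)) / sqrt(sum(v2^2)), 1e-6)
  # orientation: axis runs N to C
  expect_gt(sum(g$direction * (g$backbone_positions[18, ] - g$backbone_positions[1, ])), 0)
  expect_equal(nrow(fit$model$sidechains), 18L)
})

test_that("frame reference skips leading glycines; all-glycine fails", {
  seq_gly_first <- c("GLY", "LYS", rep("ALA", 8))
  fit <- fit_ideal(ideal_helix_spec(n_residues = 10L, sequence = seq_gly_first))
  # the frame y-axis must point toward the LYS (residue 2) sidechain centre
  sc <- fit$model$sidechains
  s1 <- c(sc$center_x[2], sc$center_y[2], sc$center_z[2])
  g <- fit$model$geometry
  foot <- point_on_axis(g$axis_start, g$axis_end, s1)$foot
  y_ref <- (s1 - foot)
  y_ref <- y_ref - sum(y_ref * g$direction) * g$direction
  y_ref <- y_ref / sqrt(sum(y_ref^2))
  expect_equal(fit$model$local_frame$rotation[, 2], y_ref, tolerance = 1e-9)

  gen <- generate_ideal_helix(ideal_helix_spec(n_residues = 6L, sequence = "GLY"))
  groups <- group_residues(gen$atoms, gen$annotation)
  expect_error(build_helix_model(groups), class = "helixforce_error_degenerate")
})

test_that("fewer than four residues cannot be fitted", {
  gen <- generate_ideal_helix(ideal_helix_spec(n_residues = 4L))
  groups <- group_residues(gen$atoms, gen$annotation)
  expect_error(build_helix_model(groups[1:3, ]), class = "helixforce_error_validation")
})

test_that("fit is equivariant under rigid motion and scale", {
  spec <- ideal_helix_spec(n_residues = 14L, jitter_sd = 0.1, seed = 21L)
  gen <- generate_ideal_helix(spec)
  base <- build_helix_model(group_residues(gen$atoms, gen$annotation))
  for (seed in 1:5) {
    T <- random_rigid_transform(seed)
    moved <- build_helix_model(group_residues(transform_atoms(gen$atoms, T),
                                              gen$annotation))
    expect_lt(max(abs(moved$geometry$centroid -
                        ht_apply(T, base$geometry$centroid))), 1e-9)
    expect_lt(max(abs(moved$geometry$direction -
                        as.numeric(T$rotation %*% base$geometry$direction))), 1e-9)
    expect_lt(max(abs(moved$geometry$radial_distances -
                        base$geometry$radial_distances)), 1e-9)
    expect_equal(moved$geometry$radius, base$geometry$radius, tolerance = 1e-12)
  }
  # scaling all coordinates scales the radius
  scaled <- gen$atoms
  scaled$x <- scaled$x * 2.5; scaled$y <- scaled$y * 2.5; scaled$z <- scaled$z * 2.5
  ms <- build_helix_model(group_residues(scaled, gen$annotation))
  expect_equal(ms$geometry$radius, 2.5 * base$geometry$radius, tolerance = 1e-12)
})

test_that("SVD radius agrees with a brute-force axis search on small instances", {
  for (seed in c(2L, 7L)) {
    gen <- generate_ideal_helix(ideal_helix_spec(n_residues = 12L,
                                                 jitter_sd = 0.15, seed = seed))
    M <- gen$truth$ca + 0  # fitted from jittered parse below
    m <- build_helix_model(group_residues(gen$atoms, gen$annotation))
    M <- m$geometry$backbone_positions
    d_bf <- brute_force_axis(M)
    ctr <- colMeans(M)
    ends <- axis_endpoints(ctr, d_bf, M[1, ], M[nrow(M), ])
    r_bf <- backbone_radius(M, ends$axis_start, ends$axis_end)$radius
    expect_equal(m$geometry$radius, r_bf, tolerance = 1e-6)
  }
})

test_that("model documents round-trip through serialization", {
  spec <- ideal_helix_spec(n_residues = 10L, jitter_sd = 0.05, seed = 4L,
                           sequence = c("GLY", rep(c("LYS", "ASP", "ALA"), 3)))
  fit <- fit_ideal(spec)
  f <- tempfile(fileext = ".json")
  write_helix_model(fit$model, f)
  back <- read_helix_model(f)
  expect_equal(back$geometry$backbone_positions, fit$model$geometry$backbone_positions)
  expect_equal(back$geometry$radius, fit$model$geometry$radius)
  expect_equal(back$sidechains$residue_name, fit$model$sidechains$residue_name)
  expect_equal(as.matrix(back$local_frame), as.matrix(fit$model$local_frame),
               tolerance = 1e-12)
  expect_equal(nrow(back$sidechains$atom_positions[[1]]), 0L)  # glycine
})

test_that("tidy and glance views expose the fitted quantities", {
  fit <- fit_ideal(ideal_helix_spec(n_residues = 8L))
  td <- tidy(fit$model)
  expect_equal(nrow(td), 8L)
  expect_true(all(c("axial_position", "radial_distance", "sphere_radius") %in% names(td)))
  gl <- glance(fit$model)
  expect_equal(gl$n_residues, 8L)
  expect_equal(gl$radius, fit$model$geometry$radius)
})
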