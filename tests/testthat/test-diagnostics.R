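test_that("radial profiles report the fitted axial/radial pairs", {
  fit <- fit_ideal(ideal_helix_spec(n_residues = 18L))
  prof <- radial_profile(fit$model)
  expect_equal(nrow(prof), 18L)
  expect_equal(prof$axial_position, fit$model$geometry$axial_params)
  expect_equal(prof$radial_distance, fit$model$geometry$radial_distances)
  # the construction has constant width about the TRUE axis; about the
  # fitted (slightly tilted) axis the distances oscillate symmetrically,
  # so the skew stays near zero even though the spread does not vanish
  expect_lt(abs(skew_regression(prof)$skew_angle), 0.1)
  true_l <- sqrt(fit$gen$truth$ca[, 2]^2 + fit$gen$truth$ca[, 3]^2)
  expect_lt(max(true_l) - min(true_l), 1e-9)
})

test_that("skew regression recovers constructed slopes exactly", {
  flat <- tibble::tibble(helix_id = 1L, axial_position = 0:9,
                         radial_distance = 2.3)
  sk <- skew_regression(flat)
  expect_equal(sk$slope, 0, tolerance = 1e-12)
  expect_equal(sk$skew_angle, 0, tolerance = 1e-12)
  expect_equal(sk$mean_radius, 2.3)

  cone <- tibble::tibble(helix_id = 2L, axial_position = seq(0, 20, by = 2),
                         radial_distance = 1 + 0.1 * seq(0, 20, by = 2))
  skc <- skew_regression(cone)
  expect_equal(skc$slope, 0.1, tolerance = 1e-12)
  expect_equal(skc$skew_angle, atan(0.1) * 180 / pi, tolerance = 1e-12)

  shrink <- cone
  shrink$radial_distance <- rev(shrink$radial_distance)
  expect_lt(skew_regression(shrink)$skew_angle, 0)

  expect_error(skew_regression(flat[1:2, ]), class = "helixforce_error_validation")
})

test_that("skew is invariant under rigid motion of the helix", {
  gen <- generate_ideal_helix(ideal_helix_spec(n_residues = 12L,
                                               jitter_sd = 0.15, seed = 23L))
  base <- skew_regression(build_helix_model(group_residues(gen$atoms, gen$annotation)))
  for (seed in 1:3) {
    T <- random_rigid_transform(seed)
    moved <- build_helix_model(group_residues(transform_atoms(gen$atoms, T),
                                              gen$annotation))
    expect_equal(skew_regression(moved)$skew_angle, base$skew_angle,
                 tolerance = 1e-9)
  }
})

test_that("skew distributions summarise per-helix angles exactly", {
  models <- purrr::map(1:6, function(s) {
    fit_ideal(ideal_helix_spec(n_residues = 12L, jitter_sd = 0.1, seed = s))$model
  })
  dist <- skew_distribution(models)
  a <- dist$angles$skew_angle
  expect_equal(dist$summary$median, stats::median(a))
  expect_equal(dist$summary$mean, mean(a))
  expect_equal(dist$summary$sd, stats::sd(a))
  expect_equal(dist$summary$n, 6L)

  one <- skew_distribution(models[1])
  expect_equal(one$summary$median, one$summary$mean)
  expect_identical(one$summary$sd, 0)
  expect_equal(one$summary$n, 1L)

  expect_error(skew_distribution(list()), class = "helixforce_error_validation")
})

test_that("constant-width helices give near-zero skew across seeds", {
  angles <- vapply(1:20, function(s) {
    fit <- fit_ideal(ideal_helix_spec(n_residues = 36L, seed = s,
                                      axis_direction = withr::with_seed(s, stats::rnorm(3))))
    skew_regression(fit$model)$skew_angle
  }, numeric(1))
  expect_lt(mean(abs(angles)), 0.1)
})

test_that("radial histograms pool distances and moment-match a normal", {
  m1 <- fit_ideal(ideal_helix_spec(n_residues = 10L, seed = 1L))$model
  m2 <- fit_ideal(ideal_helix_spec(n_residues = 12L, seed = 2L))$model
  h <- radial_histogram(list(m1, m2), bin_width = 0.05)
  pooled <- c(m1$geometry$radial_distances, m2$geometry$radial_distances)
  expect_equal(h$n, 22L)
  expect_equal(sum(h$bins$count), 22L)
  expect_equal(h$mean, mean(pooled))
  expect_equal(h$sd, stats::sd(pooled))

  # degenerate: identical values occupy a single bin, sd 0
  fake <- list(list(geometry = list(radial_distances = rep(2, 5))))
  hd <- radial_histogram(fake)
  expect_equal(sum(hd$bins$count > 0), 1L)
  expect_equal(hd$sd, 0)

  expect_error(radial_histogram(list(list(geometry = list(radial_distances = 1)))),
               class = "helixforce_error_validation")
})

test_that("histogram sd tracks the generator jitter on a large pool", {
  models <- purrr::map(1:18, function(s) {
    fit_ideal(ideal_helix_spec(n_residues = 30L, jitter_sd = 0.2, seed = 100L + s))$model
  })
  h <- radial_histogram(models)
  expect_equal(h$n, 540L)
  # radial jitter projects the 3-d Gaussian noise into the transverse plane;
  # the pooled sd should sit near the per-coordinate sd
  expect_lt(abs(h$sd - 0.2), 0.05)
})

test_that("sidechain shape pooling is pose-invariant", {
  spec <- ideal_helix_spec(n_residues = 8L, sequence = "ASP",
                           atoms_per_sidechain = 4L, cluster_sd = 0.3, seed = 31L)
  gen <- generate_ideal_helix(spec)
  m <- build_helix_model(group_residues(gen$atoms, gen$annotation))
  base <- sidechain_shape_stats(list(m), "ASP")
  # duplicate the helix in a different global pose: stats unchanged, n doubled
  T <- random_rigid_transform(7)
  m2 <- build_helix_model(group_residues(transform_atoms(gen$atoms, T), gen$annotation))
  both <- sidechain_shape_stats(list(m, m2), "ASP")
  expect_equal(both$n_instances, 2L * base$n_instances)
  expect_equal(both$mean_distance, base$mean_distance, tolerance = 1e-9)
  expect_equal(both$median, base$median, tolerance = 1e-9)
  expect_true(both$q1 <= both$median && both$median <= both$q3)
})

test_that("single-atom sidechains collapse to a point after normalisation", {
  # zero jitter, one atom per sidechain: every instance normalises to the
  # same point on the reference axis, so the pooled cloud is degenerate
  spec <- ideal_helix_spec(n_residues = 4L, atoms_per_sidechain = 1L, seed = 2L)
  m <- fit_ideal(spec)$model
  s <- sidechain_shape_stats(list(m), "ALA")
  expect_equal(s$n_atoms, 4L)
  expect_equal(s$mean_distance, 0, tolerance = 1e-9)
  expect_equal(s$q3, 0, tolerance = 1e-9)
})

test_that("shape statistics track the generator cluster spread", {
  models <- purrr::map(1:6, function(s) {
    fit_ideal(ideal_helix_spec(n_residues = 10L, sequence = "ASP",
                               atoms_per_sidechain = 6L, cluster_sd = 0.3,
                               seed = 300L + s))$model
  })
  s <- sidechain_shape_stats(models, "ASP")
  expect_equal(s$n_instances, 60L)
  # expected mean distance of a centred 3-d Gaussian cloud from its centroid
  # is near sd * sqrt(8/pi) ~ 0.48 for sd 0.3; pooling across instances adds
  # the centroid-alignment spread, so check the generator scale loosely
  expect_lt(abs(s$mean_distance - 0.3 * sqrt(8 / pi)), 0.1)

  expect_error(sidechain_shape_stats(models, "GLY"),
               class = "helixforce_error_validation")
  expect_error(sidechain_shape_stats(models, "TRP"),
               class = "helixforce_error_validation")
})

test_that("diagnostic plots build without evaluation errors", {
  m <- fit_ideal(ideal_helix_spec(n_residues = 12L, jitter_sd = 0.1, seed = 41L))$model
  expect_s3_class(plot_radial_profile(m), "ggplot")
  expect_s3_class(autoplot(m), "ggplot")
  h <- radial_histogram(list(m))
  expect_s3_class(plot_radial_histogram(h), "ggplot")
})
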