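# Approximation-validation diagnostics: how well do real helices match the
# straight, constant-width cylinder and the sidechain-sphere summaries?
# Radial profiles and skew-angle regression quantify the first; pooled
# pose-normalised sidechain clouds quantify the second.

#' Radial-distance profile along a fitted helix
#'
#' @param model A `helix_model`.
#' @return Tibble: `helix_id`, `residue_seq`, `axial_position` (Angstrom
#'   along the axis from its start) and `radial_distance` (Angstrom).
#' @export
radial_profile <- function(model) {
  g <- model$geometry
  tibble(
    helix_id = model$helix_id,
    residue_seq = model$sidechains$residue_seq,
    axial_position = g$axial_params,
    radial_distance = g$radial_distances
  )
}

#' Skew-angle regression of helix width along its length
#'
#' Fits an ordinary least-squares line of radial distance on axial position
#' (both in Angstrom). The skew angle is `atan(slope)` in degrees: the angle
#' between the fitted line and the constant mean-radius line. Near zero
#' means the helix width is constant along its length, supporting the
#' fixed-radius cylinder approximation.
#'
#' @param x A `helix_model` or a profile tibble from [radial_profile()].
#' @return One-row tibble: `helix_id`, `slope` (Angstrom per Angstrom),
#'   `intercept` (Angstrom), `skew_angle` (degrees), `mean_radius`
#'   (Angstrom), `n`.
#' @export
skew_regression <- function(x) {
  profile <- if (inherits(x, "helix_model")) radial_profile(x) else as_tibble(x)
  if (nrow(profile) < 3L) {
    hf_abort("skew regression needs at least 3 residues", "helixforce_error_validation")
  }
  fit <- stats::lm(radial_distance ~ axial_position, data = profile)
  slope <- unname(stats::coef(fit)[2])
  tibble(
    helix_id = profile$helix_id[1],
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    skew_angle = atan(slope) * 180 / pi,
    mean_radius = mean(profile$radial_distance),
    n = nrow(profile)
  )
}

#' Distribution of skew angles across helices
#'
#' @param models List of `helix_model`s (at least one).
#' @return List of class `skew_distribution`: `angles` tibble (per helix)
#'   and `summary` one-row tibble with `median`, `mean`, `sd` (degrees) and
#'   `n`. With a single helix the standard deviation is reported as 0 and
#'   flagged via `n = 1`.
#' @export
skew_distribution <- function(models) {
  if (length(models) == 0L) {
    hf_abort("skew distribution needs at least one helix", "helixforce_error_validation")
  }
  angles <- purrr::map_dfr(models, skew_regression)
  a <- angles$skew_angle
  structure(
    list(
      angles = angles,
      summary = tibble(
        median = stats::median(a),
        mean = mean(a),
        sd = if (length(a) > 1L) stats::sd(a) else 0,
        n = length(a)
      )
    ),
    class = "skew_distribution"
  )
}

#' @export
print.skew_distribution <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<skew_distribution> %d helices: median %.4f deg, mean %.4f deg, sd %.4f deg\n",
    s$n, s$median, s$mean, s$sd
  ))
  invisible(x)
}

#' Histogram of pooled radial distances with a moment-matched normal fit
#'
#' Pools the per-residue radial distances of the given helices, bins them at
#' a fixed width, and fits a normal distribution by moment matching (sample
#' mean and standard deviation).
#'
#' @param models List of `helix_model`s.
#' @param bin_width Bin width, Angstrom.
#' @return List of class `radial_histogram`: `bins` tibble (`midpoint`,
#'   `count`), `mean`, `sd`, `n`, `bin_width`.
#' @export
radial_histogram <- function(models, bin_width = 0.05) {
  pooled <- unlist(lapply(models, function(m) m$geometry$radial_distances))
  if (length(pooled) < 2L) {
    hf_abort("radial histogram needs at least 2 pooled distances", "helixforce_error_validation")
  }
  lo <- floor(min(pooled) / bin_width) * bin_width
  hi <- ceiling(max(pooled) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width  # all values identical: one bin
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  structure(
    list(
      bins = tibble(midpoint = h$mids, count = h$counts),
      mean = mean(pooled),
      sd = stats::sd(pooled),
      n = length(pooled),
      bin_width = bin_width
    ),
    class = "radial_histogram"
  )
}

# Minimal rotation mapping unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # opposite: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit3(cross3(a, p))
    return(2 * tcrossprod(ax) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Pooled shape statistics of one sidechain type
#'
#' Every instance of the residue type across the given helices is
#' pose-normalised: atoms are translated so the C-alpha sits at the origin,
#' then rotated so the C-alpha-to-centroid direction maps onto a fixed
#' reference axis (+x). The rotation about that axis is left free, which is
#' irrelevant for distance statistics. All transformed atoms are pooled and
#' distances measured from the pooled-set centroid.
#'
#' @param models List of `helix_model`s.
#' @param residue_name 3-letter code (not `"GLY"`, which has no sidechain
#'   atoms).
#' @return List of class `sidechain_shape_stats`: `residue_name`,
#'   `pooled_distances`, `mean_distance`, `median`, `q1`, `q3`,
#'   `n_instances`, `n_atoms`, `pooled_positions`.
#' @export
sidechain_shape_stats <- function(models, residue_name) {
  if (identical(residue_name, "GLY")) {
    hf_abort("glycine has no sidechain atoms", "helixforce_error_validation")
  }
  clouds <- list()
  n_inst <- 0L
  for (m in models) {
    sc <- m$sidechains
    idx <- which(sc$residue_name == residue_name & sc$atom_count >= 1L)
    for (i in idx) {
      atoms <- sc$atom_positions[[i]]
      ca <- c(sc$ca_x[i], sc$ca_y[i], sc$ca_z[i])
      centred <- sweep(atoms, 2, ca)
      v <- c(sc$center_x[i], sc$center_y[i], sc$center_z[i]) - ca
      if (sqrt(sum(v^2)) > 1e-9) {
        R <- rotation_between(v, c(1, 0, 0))
        centred <- centred %*% t(R)
      }
      n_inst <- n_inst + 1L
      clouds[[n_inst]] <- centred
    }
  }
  if (n_inst == 0L) {
    hf_abort(paste0("no instances of residue ", residue_name, " with sidechain atoms"),
             "helixforce_error_validation")
  }
  pooled <- do.call(rbind, clouds)
  ctr <- colMeans(pooled)
  d <- sqrt(rowSums(sweep(pooled, 2, ctr)^2))
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  structure(
    list(
      residue_name = residue_name,
      pooled_distances = d,
      mean_distance = mean(d),
      median = q[2], q1 = q[1], q3 = q[3],
      n_instances = n_inst,
      n_atoms = nrow(pooled),
      pooled_positions = pooled
    ),
    class = "sidechain_shape_stats"
  )
}

#' @export
print.sidechain_shape_stats <- function(x, ...) {
  cat(sprintf(
    "<sidechain_shape_stats> %s: %d instances, %d atoms; mean %.3f A, median %.3f A [q1 %.3f, q3 %.3f]\n",
    x$residue_name, x$n_instances, x$n_atoms, x$mean_distance, x$median, x$q1, x$q3
  ))
  invisible(x)
}

#' Plot the radial-distance profile of a helix
#'
#' Shows the per-residue distance from the fitted axis, the constant mean
#' radius, and the skew regression line whose angle to the mean line
#' measures how much the helix width drifts along its length.
#'
#' @param model A `helix_model`.
#' @return A ggplot.
#' @export
plot_radial_profile <- function(model) {
  prof <- radial_profile(model)
  sk <- skew_regression(prof)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$axial_position, y = .data$radial_distance)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = sk$mean_radius, colour = "darkgreen") +
    ggplot2::geom_abline(slope = sk$slope, intercept = sk$intercept, colour = "red") +
    ggplot2::labs(
      x = "axial position (Å)", y = "radial distance (Å)",
      title = sprintf("helix %d: mean radius %.2f Å, skew %.3f°",
                      prof$helix_id[1], sk$mean_radius, sk$skew_angle)
    )
}

#' @rdname plot_radial_profile
#' @param object A `helix_model`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.helix_model <- function(object, ...) plot_radial_profile(object)

#' Plot a pooled radial-distance histogram with its normal fit
#'
#' @param h A `radial_histogram`.
#' @return A ggplot.
#' @export
plot_radial_histogram <- function(h) {
  dens_scale <- h$n * h$bin_width
  ggplot2::ggplot(h$bins, ggplot2::aes(x = .data$midpoint, y = .data$count)) +
    ggplot2::geom_col(width = h$bin_width, fill = "grey70", colour = "grey30") +
    ggplot2::stat_function(
      fun = function(x) dens_scale * stats::dnorm(x, h$mean, h$sd),
      colour = "red"
    ) +
    ggplot2::labs(x = "radial distance (Å)", y = "count",
                  title = sprintf("pooled radii: mean %.3f Å, sd %.3f Å", h$mean, h$sd))
}
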