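# Coarse-grained helix fit: centroid + principal axis (SVD of the covariance
# of the zero-mean C-alpha trace), axis endpoints by orthogonal projection of
# the terminal residues, mean radial distance as the cylinder radius, and one
# mean-position / mean-spread sphere per sidechain.

#' Centroid of backbone positions
#'
#' @param M Numeric n-by-3 matrix of backbone (C-alpha) positions, Angstrom.
#' @return Length-3 numeric vector, the arithmetic mean of the rows.
#' @export
backbone_centroid <- function(M) {
  M <- as_positions(M)
  if (nrow(M) == 0L) hf_abort("no backbone positions", "helixforce_error_validation")
  colMeans(M)
}

as_positions <- function(M) {
  M <- as.matrix(M)
  if (ncol(M) != 3L) hf_abort("positions must be n-by-3", "helixforce_error_validation")
  storage.mode(M) <- "double"
  if (nrow(M) > 0L && any(!is.finite(M))) {
    hf_abort("positions must be finite", "helixforce_error_validation")
  }
  M
}

#' Principal axis of a point set by SVD
#'
#' Forms the variance-covariance matrix `S = t(B) B / (n - 1)` of the
#' zero-mean positions `B` and takes the singular vector of `S` with the
#' largest singular value. The sign is fixed so the axis points from the
#' first toward the last row (`direction . (b_n - b_1) > 0`), i.e. N-to-C
#' along an annotated helix.
#'
#' @param M Numeric n-by-3 matrix of positions (n >= 3, not all coincident).
#' @return List with `direction` (unit 3-vector) and `decomposition` (list:
#'   `covariance`, `left_singular_vectors`, `singular_values`,
#'   `right_singular_vectors`).
#' @export
principal_axis <- function(M) {
  M <- as_positions(M)
  n <- nrow(M)
  if (n < 3L) hf_abort("principal axis needs at least 3 points", "helixforce_error_validation")
  ctr <- colMeans(M)
  B <- sweep(M, 2, ctr)
  if (max(abs(B)) < 1e-9) {
    hf_abort("all points coincident; axis undefined", "helixforce_error_degenerate")
  }
  S <- crossprod(B) / (n - 1)
  dec <- svd(S)
  d <- dec$u[, 1]
  span <- M[n, ] - M[1, ]
  if (sum(d * span) < 0) d <- -d
  list(
    direction = d,
    decomposition = list(
      covariance = S,
      left_singular_vectors = dec$u,
      singular_values = dec$d,
      right_singular_vectors = dec$v
    )
  )
}

#' Axis endpoints from the terminal backbone positions
#'
#' The start and end of the backbone axis segment are the orthogonal
#' projections of the first and last backbone positions onto the fitted line
#' through the centroid, so start, centroid and end are collinear and the
#' segment runs N-to-C.
#'
#' @param centroid 3D centroid of the backbone positions.
#' @param direction Unit axis direction.
#' @param b_first,b_last First and last backbone positions.
#' @return List with `axis_start` and `axis_end` (3D points).
#' @export
axis_endpoints <- function(centroid, direction, b_first, b_last) {
  proj <- function(b) centroid + sum((b - centroid) * direction) * direction
  list(axis_start = proj(b_first), axis_end = proj(b_last))
}

#' Foot of the perpendicular from a point to the axis segment's line
#'
#' @param axis_start,axis_end Distinct 3D points defining the axis line.
#' @param query 3D point.
#' @return List with `foot` (3D point on the line) and `t` (scalar position:
#'   0 at `axis_start`, 1 at `axis_end`; may fall outside `[0, 1]`).
#' @export
point_on_axis <- function(axis_start, axis_end, query) {
  seg <- axis_end - axis_start
  len <- sqrt(sum(seg^2))
  if (len < 1e-12) hf_abort("zero-length axis", "helixforce_error_degenerate")
  d_hat <- seg / len
  t <- sum((query - axis_start) * d_hat) / len
  list(foot = axis_start + t * seg, t = t)
}

#' Backbone radius as the mean perpendicular distance to the axis
#'
#' @param M n-by-3 backbone positions.
#' @param axis_start,axis_end Axis segment endpoints.
#' @return List with `radius` (mean of the per-row distances) and
#'   `radial_distances` (per-row Euclidean distances, Angstrom).
#' @export
backbone_radius <- function(M, axis_start, axis_end) {
  M <- as_positions(M)
  l <- vapply(seq_len(nrow(M)), function(i) {
    foot <- point_on_axis(axis_start, axis_end, M[i, ])$foot
    sqrt(sum((M[i, ] - foot)^2))
  }, numeric(1))
  list(radius = mean(l), radial_distances = l)
}

#' Sidechain sphere approximation
#'
#' A sidechain is summarised as a sphere centred at the mean heavy-atom
#' position, with radius the mean distance from that centre to the atoms.
#' An empty atom set (glycine) yields a zero-radius sphere at the C-alpha.
#'
#' @param atom_positions m-by-3 matrix of sidechain heavy-atom positions (may
#'   have zero rows).
#' @param ca_position The residue's C-alpha position (sphere centre fallback).
#' @return List with `center`, `sphere_radius`, `atom_count`,
#'   `atom_positions`.
#' @export
sidechain_sphere <- function(atom_positions, ca_position) {
  P <- as_positions(atom_positions)
  m <- nrow(P)
  if (m == 0L) {
    return(list(center = as.numeric(ca_position), sphere_radius = 0,
                atom_count = 0L, atom_positions = P))
  }
  center <- colMeans(P)
  r <- if (m == 1L) 0 else mean(sqrt(rowSums(sweep(P, 2, center)^2)))
  list(center = center, sphere_radius = r, atom_count = m, atom_positions = P)
}

#' Fit the coarse-grained model of one helix
#'
#' Assembles the C-alpha trace in residue order, fits the cylinder geometry
#' (centroid, SVD principal axis, projected endpoints, mean radius), builds
#' one sidechain sphere per residue, and attaches the helix-local coordinate
#' frame (x along the axis, y toward the first non-glycine sidechain, origin
#' at the axis start).
#'
#' @param residues Nested residue tibble from [group_residues()].
#' @param helix_id Integer id carried into the model.
#' @return An object of class `helix_model` with components `geometry`
#'   (list), `sidechains` (tibble), `local_frame`
#'   ([homogeneous_transform()]), `helix_id`.
#' @export
build_helix_model <- function(residues, helix_id = 1L) {
  n <- nrow(residues)
  if (n < 4L) {
    hf_abort("helix model needs at least 4 residues", "helixforce_error_validation")
  }
  ca <- t(vapply(residues$backbone_atoms, function(bb) {
    row <- bb[bb$atom_name == "CA", , drop = FALSE]
    c(row$x[1], row$y[1], row$z[1])
  }, numeric(3)))

  ctr <- backbone_centroid(ca)
  ax <- principal_axis(ca)
  ends <- axis_endpoints(ctr, ax$direction, ca[1, ], ca[n, ])
  axis_len <- sqrt(sum((ends$axis_end - ends$axis_start)^2))
  feet <- lapply(seq_len(n), function(i) point_on_axis(ends$axis_start, ends$axis_end, ca[i, ]))
  t_frac <- vapply(feet, `[[`, numeric(1), "t")
  l <- vapply(seq_len(n), function(i) sqrt(sum((ca[i, ] - feet[[i]]$foot)^2)), numeric(1))

  spheres <- purrr::map(seq_len(n), function(i) {
    sc <- residues$sidechain_atoms[[i]]
    sidechain_sphere(cbind(sc$x, sc$y, sc$z), ca[i, ])
  })
  sidechains <- tibble(
    residue_seq = residues$residue_seq,
    residue_name = residues$residue_name,
    center_x = vapply(spheres, function(s) s$center[1], numeric(1)),
    center_y = vapply(spheres, function(s) s$center[2], numeric(1)),
    center_z = vapply(spheres, function(s) s$center[3], numeric(1)),
    sphere_radius = vapply(spheres, `[[`, numeric(1), "sphere_radius"),
    atom_count = vapply(spheres, `[[`, integer(1), "atom_count"),
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    atom_positions = purrr::map(spheres, "atom_positions")
  )

  geometry <- list(
    backbone_positions = ca,
    centroid = ctr,
    direction = ax$direction,
    decomposition = ax$decomposition,
    axis_start = ends$axis_start,
    axis_end = ends$axis_end,
    axis_length = axis_len,
    axial_params = t_frac * axis_len,  # Angstrom along the axis from axis_start
    radial_distances = l,
    radius = mean(l),
    n_residues = n
  )

  ref <- first_significant_sidechain(sidechains)
  frame <- build_helix_frame(geometry, ref, helix_id = helix_id)

  structure(
    list(geometry = geometry, sidechains = sidechains,
         local_frame = frame, helix_id = as.integer(helix_id)),
    class = "helix_model"
  )
}

# First non-glycine sidechain (lowest residue_seq) used as the frame's
# y-axis reference; all-glycine helices have no valid reference.
first_significant_sidechain <- function(sidechains) {
  idx <- which(sidechains$residue_name != "GLY" & sidechains$atom_count >= 1L)
  if (length(idx) == 0L) {
    hf_abort("no significant (non-glycine) sidechain to anchor the local frame",
             "helixforce_error_degenerate")
  }
  i <- idx[which.min(sidechains$residue_seq[idx])]
  c(sidechains$center_x[i], sidechains$center_y[i], sidechains$center_z[i])
}

#' @export
print.helix_model <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "<helix_model> id %d: %d residues, radius %.3f A, axis length %.2f A\n",
    x$helix_id, g$n_residues, g$radius, g$axis_length
  ))
  invisible(x)
}

#' Per-residue tidy view of a fitted helix model
#'
#' @param x A `helix_model`.
#' @param ... Unused.
#' @return Tibble with one row per residue: axial position and radial
#'   distance of the C-alpha, and the sidechain sphere centre / radius /
#'   atom count.
#' @exportS3Method generics::tidy
tidy.helix_model <- function(x, ...) {
  g <- x$geometry
  dplyr::bind_cols(
    tibble(
      helix_id = x$helix_id,
      axial_position = g$axial_params,
      radial_distance = g$radial_distances
    ),
    x$sidechains[, c("residue_seq", "residue_name", "center_x", "center_y",
                     "center_z", "sphere_radius", "atom_count")]
  )
}

#' One-row summary of a fitted helix model
#'
#' @param x A `helix_model`.
#' @param ... Unused.
#' @return One-row tibble: `helix_id`, `n_residues`, `radius`,
#'   `axis_length`.
#' @exportS3Method generics::glance
glance.helix_model <- function(x, ...) {
  g <- x$geometry
  tibble(
    helix_id = x$helix_id,
    n_residues = g$n_residues,
    radius = g$radius,
    axis_length = g$axis_length
  )
}

#' Serialize a helix model to a structured-text (JSON) document
#'
#' @param model A `helix_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_helix_model <- function(model, path) {
  g <- model$geometry
  sc <- model$sidechains
  doc <- list(
    helix_id = model$helix_id,
    geometry = list(
      backbone_positions = unclass(g$backbone_positions),
      centroid = g$centroid, direction = g$direction,
      axis_start = g$axis_start, axis_end = g$axis_end,
      axial_params = g$axial_params, radial_distances = g$radial_distances,
      radius = g$radius, n_residues = g$n_residues
    ),
    sidechains = list(
      residue_seq = sc$residue_seq, residue_name = sc$residue_name,
      center = cbind(sc$center_x, sc$center_y, sc$center_z),
      sphere_radius = sc$sphere_radius, atom_count = sc$atom_count,
      ca = cbind(sc$ca_x, sc$ca_y, sc$ca_z),
      atom_positions = sc$atom_positions
    ),
    local_frame = list(
      rotation = unclass(model$local_frame$rotation),
      translation = model$local_frame$translation,
      from_frame = model$local_frame$from_frame,
      to_frame = model$local_frame$to_frame
    )
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a helix model document written by [write_helix_model()]
#'
#' @param path Path to the JSON document.
#' @return A `helix_model`.
#' @export
read_helix_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- doc$geometry
  geometry <- list(
    backbone_positions = as_positions(g$backbone_positions),
    centroid = as.numeric(g$centroid),
    direction = as.numeric(g$direction),
    decomposition = NULL,
    axis_start = as.numeric(g$axis_start),
    axis_end = as.numeric(g$axis_end),
    axis_length = sqrt(sum((as.numeric(g$axis_end) - as.numeric(g$axis_start))^2)),
    axial_params = as.numeric(g$axial_params),
    radial_distances = as.numeric(g$radial_distances),
    radius = as.numeric(g$radius),
    n_residues = as.integer(g$n_residues)
  )
  sc <- doc$sidechains
  center <- as_positions(sc$center)
  ca <- as_positions(sc$ca)
  ap <- sc$atom_positions
  # jsonlite simplification: a list of equal-shape matrices comes back as a
  # 3-d array; a 1-row matrix as a bare length-3 vector; empty as list()
  if (is.array(ap) && length(dim(ap)) == 3L) {
    ap <- lapply(seq_len(dim(ap)[1]), function(i) ap[i, , , drop = TRUE])
  }
  norm_cloud <- function(p) {
    if (is.null(p) || length(p) == 0L) return(matrix(numeric(0), 0, 3))
    if (is.null(dim(p)) && length(p) == 3L) p <- matrix(p, 1, 3)
    as_positions(p)
  }
  sidechains <- tibble(
    residue_seq = as.integer(sc$residue_seq),
    residue_name = as.character(sc$residue_name),
    center_x = center[, 1], center_y = center[, 2], center_z = center[, 3],
    sphere_radius = as.numeric(sc$sphere_radius),
    atom_count = as.integer(sc$atom_count),
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    atom_positions = lapply(ap, norm_cloud)
  )
  lf <- doc$local_frame
  frame <- homogeneous_transform(
    rotation = as_positions(lf$rotation),
    translation = as.numeric(lf$translation),
    from_frame = lf$from_frame, to_frame = lf$to_frame
  )
  structure(
    list(geometry = geometry, sidechains = sidechains,
         local_frame = frame, helix_id = as.integer(doc$helix_id)),
    class = "helix_model"
  )
}
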