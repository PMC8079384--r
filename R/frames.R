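# Homogeneous-transform algebra (Craig convention): a 4x4 rigid transform
# maps coordinates in its source frame to its target frame. Frame names are
# carried on every transform and checked at composition time, which catches
# transform-direction mistakes early.

#' Construct a homogeneous rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1; columns
#'   are the source frame's basis vectors expressed in the target frame).
#' @param translation 3D origin of the source frame in the target frame.
#' @param from_frame,to_frame Frame names; applying the transform maps
#'   `from_frame` coordinates to `to_frame` coordinates.
#' @return An object of class `homogeneous_transform`.
#' @export
homogeneous_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                  from_frame = "local", to_frame = "PDB") {
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3L, 3L))) {
    hf_abort("rotation must be 3x3", "helixforce_error_validation")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    hf_abort("rotation must be orthonormal with determinant +1",
             "helixforce_error_validation")
  }
  structure(
    list(rotation = R, translation = as.numeric(translation),
         from_frame = from_frame, to_frame = to_frame),
    class = "homogeneous_transform"
  )
}

#' @export
as.matrix.homogeneous_transform <- function(x, ...) {
  rbind(cbind(x$rotation, x$translation), c(0, 0, 0, 1))
}

#' @export
print.homogeneous_transform <- function(x, ...) {
  cat(sprintf("<homogeneous_transform> %s -> %s\n", x$from_frame, x$to_frame))
  print(round(as.matrix(x), 6))
  invisible(x)
}

#' Compose two homogeneous transforms
#'
#' `ht_compose(A, B)` is the transform applying `B` first, then `A`; the
#' frame chain must be compatible (`A$from_frame == B$to_frame`).
#'
#' @param A,B `homogeneous_transform` objects.
#' @return The composite transform, mapping `B$from_frame` to `A$to_frame`.
#' @export
ht_compose <- function(A, B) {
  if (!identical(A$from_frame, B$to_frame)) {
    hf_abort(
      sprintf("frame mismatch in composition: '%s' -> '%s' then '%s' -> '%s'",
              B$from_frame, B$to_frame, A$from_frame, A$to_frame),
      "helixforce_error_frame_mismatch"
    )
  }
  homogeneous_transform(
    rotation = A$rotation %*% B$rotation,
    translation = as.numeric(A$rotation %*% B$translation) + A$translation,
    from_frame = B$from_frame, to_frame = A$to_frame
  )
}

#' Invert a homogeneous transform
#'
#' @param T A `homogeneous_transform`.
#' @return The inverse transform with the frame names swapped.
#' @export
ht_invert <- function(T) {
  Rt <- t(T$rotation)
  homogeneous_transform(
    rotation = Rt, translation = as.numeric(-Rt %*% T$translation),
    from_frame = T$to_frame, to_frame = T$from_frame
  )
}

#' Apply a transform to points
#'
#' @param T A `homogeneous_transform`.
#' @param points n-by-3 matrix (or length-3 vector) of coordinates in
#'   `T$from_frame`.
#' @return Coordinates in `T$to_frame`, same shape as the input.
#' @export
ht_apply <- function(T, points) {
  if (is.null(dim(points))) {
    return(as.numeric(T$rotation %*% points) + T$translation)
  }
  P <- as_positions(points)
  sweep(P %*% t(T$rotation), 2, T$translation, `+`)
}

# Rotate only (directions, not points).
ht_rotate <- function(T, v) as.numeric(T$rotation %*% v)

#' Build the local coordinate frame of a fitted helix
#'
#' The frame's x-axis runs along the fitted helix axis (N to C), the y-axis
#' points from the axis toward the first significant (non-glycine) sidechain
#' centre, orthogonalised against x so the rotation is exactly orthonormal,
#' and z completes the right-handed triad. The origin sits at the axis start.
#' The returned transform maps helix-local coordinates to the parent (PDB)
#' frame.
#'
#' @param geometry Geometry list of a `helix_model` (needs `direction`,
#'   `axis_start`, `axis_end`).
#' @param sidechain_center 3D centre of the first significant sidechain.
#' @param helix_id Integer used in the frame name (`"helix<id>"`).
#' @param to_frame Parent frame name (default `"PDB"`).
#' @return A `homogeneous_transform` from `helix<id>` to `to_frame`.
#' @export
build_helix_frame <- function(geometry, sidechain_center, helix_id = 1L,
                              to_frame = "PDB") {
  x_hat <- unit3(geometry$direction)
  foot <- point_on_axis(geometry$axis_start, geometry$axis_end, sidechain_center)$foot
  y0 <- sidechain_center - foot
  if (sqrt(sum(y0^2)) < 1e-6) {
    hf_abort("sidechain centre lies on the helix axis; frame undefined",
             "helixforce_error_degenerate")
  }
  y0 <- y0 - sum(y0 * x_hat) * x_hat  # Gram-Schmidt: exact orthogonality
  y_hat <- unit3(y0)
  z_hat <- cross3(x_hat, y_hat)
  homogeneous_transform(
    rotation = cbind(x_hat, y_hat, z_hat, deparse.level = 0),
    translation = geometry$axis_start,
    from_frame = paste0("helix", helix_id), to_frame = to_frame
  )
}

# Re-express every coordinate of a helix model through transform T
# (T$from_frame must be the frame the model currently lives in).
transform_helix_model <- function(model, T) {
  g <- model$geometry
  g$backbone_positions <- ht_apply(T, g$backbone_positions)
  g$centroid <- ht_apply(T, g$centroid)
  g$axis_start <- ht_apply(T, g$axis_start)
  g$axis_end <- ht_apply(T, g$axis_end)
  g$direction <- ht_rotate(T, g$direction)
  g$decomposition <- NULL  # covariance no longer matches the stored frame
  sc <- model$sidechains
  ctr <- ht_apply(T, cbind(sc$center_x, sc$center_y, sc$center_z))
  ca <- ht_apply(T, cbind(sc$ca_x, sc$ca_y, sc$ca_z))
  sc$center_x <- ctr[, 1]; sc$center_y <- ctr[, 2]; sc$center_z <- ctr[, 3]
  sc$ca_x <- ca[, 1]; sc$ca_y <- ca[, 2]; sc$ca_z <- ca[, 3]
  sc$atom_positions <- lapply(sc$atom_positions, function(p) {
    if (nrow(p) == 0L) p else ht_apply(T, p)
  })
  model$geometry <- g
  model$sidechains <- sc
  model$local_frame <- ht_compose(T, model$local_frame)
  model
}

#' Place a helix bundle in the simulation (SIM) frame
#'
#' The SIM frame is anchored to the first helix: the transform from the first
#' helix's local frame to SIM is the identity, so the first axis start maps
#' to the SIM origin and its axis lies along SIM x. Every helix is
#' re-expressed in SIM coordinates by the same rigid motion, so all relative
#' geometry recorded in the source structure is preserved exactly.
#'
#' @param models List of `helix_model` objects fitted from one structure
#'   (at least 2).
#' @return An object of class `bundle_layout`: list with `models` (helices in
#'   SIM coordinates) and `sim_anchor` (the PDB -> SIM transform used).
#' @export
place_bundle <- function(models) {
  if (length(models) < 2L) {
    hf_abort("a bundle needs at least 2 helices", "helixforce_error_validation")
  }
  anchor <- ht_invert(models[[1]]$local_frame)  # PDB -> helix1 == SIM
  anchor$to_frame <- "SIM"
  placed <- lapply(models, transform_helix_model, T = anchor)
  for (i in seq_along(placed)) placed[[i]]$local_frame$to_frame <- "SIM"
  structure(list(models = placed, sim_anchor = anchor), class = "bundle_layout")
}

#' @export
print.bundle_layout <- function(x, ...) {
  cat(sprintf("<bundle_layout> %d helices in SIM frame\n", length(x$models)))
  for (m in x$models) print(m)
  invisible(x)
}

#' Relative transform between two helix frames
#'
#' Returns the transform expressing helix-2-local coordinates in helix 1's
#' local frame, derived through their common parent frame. This is the
#' product of the chain through any intermediate linker frame; only the
#' product is observable, so only the product is represented.
#'
#' @param frame_h1,frame_h2 `homogeneous_transform`s with a common
#'   `to_frame`.
#' @return The transform from `frame_h2$from_frame` to `frame_h1$from_frame`.
#' @export
derive_linker_transform <- function(frame_h1, frame_h2) {
  if (!identical(frame_h1$to_frame, frame_h2$to_frame)) {
    hf_abort(
      sprintf("frames have different parents: '%s' vs '%s'",
              frame_h1$to_frame, frame_h2$to_frame),
      "helixforce_error_frame_mismatch"
    )
  }
  ht_compose(ht_invert(frame_h1), frame_h2)
}
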