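# Static electrostatics: integer point charges at sidechain sphere centres,
# pairwise Coulomb forces between helices, and the signed scalar net force
# for a bundle (negative = net attraction, positive = net repulsion).

#' Physical constants for the Coulomb calculation
#'
#' @param coulomb_constant Coulomb's constant \eqn{k_e = 1/(4\pi\epsilon_0)},
#'   N m^2 C^-2 (CODATA).
#' @param elementary_charge Elementary charge, C (CODATA exact).
#' @param relative_permittivity Dimensionless medium permittivity
#'   \eqn{\epsilon_r}; default 1 (vacuum, no solvent screening).
#' @return A list of constants used by [coulomb_force()].
#' @export
physical_constants <- function(coulomb_constant = 8.9875517873681764e9,
                               elementary_charge = 1.602176634e-19,
                               relative_permittivity = 1) {
  consts <- list(
    coulomb_constant = coulomb_constant,
    elementary_charge = elementary_charge,
    relative_permittivity = relative_permittivity,
    angstrom_to_metre = 1e-10,
    newton_to_piconewton = 1e12
  )
  if (any(unlist(consts) <= 0)) {
    hf_abort("all physical constants must be positive", "helixforce_error_validation")
  }
  consts
}

#' Integer sidechain charge table at a given pH
#'
#' At the physiological pH of 7.2 the ionisable sidechains round to integer
#' charges: aspartate and glutamate -1, lysine and arginine +1, everything
#' else (including histidine, whose pK_a of about 6 leaves it mostly neutral
#' at 7.2, plus cysteine and tyrosine) 0. The table can be overridden per
#' residue, e.g. `overrides = c(HIS = 1)` to force protonated histidine.
#'
#' @param pH Solution pH (informational; the default table encodes 7.2).
#' @param overrides Named integer vector of per-residue charge overrides,
#'   values in `{-1, 0, +1}`.
#' @return Tibble with columns `residue_name`, `charge`, and attribute `pH`.
#' @export
charge_table <- function(pH = 7.2, overrides = NULL) {
  if (pH <= 0) hf_abort("pH must be positive", "helixforce_error_validation")
  charge <- stats::setNames(rep(0L, length(STANDARD_RESIDUES)), STANDARD_RESIDUES)
  charge[c("ASP", "GLU")] <- -1L
  charge[c("LYS", "ARG")] <- 1L
  if (!is.null(overrides)) {
    if (!all(names(overrides) %in% STANDARD_RESIDUES)) {
      hf_abort("charge override for unknown residue name", "helixforce_error_validation")
    }
    if (!all(overrides %in% c(-1L, 0L, 1L))) {
      hf_abort("charges must be integers in {-1, 0, +1}", "helixforce_error_validation")
    }
    charge[names(overrides)] <- as.integer(overrides)
  }
  tbl <- tibble(residue_name = names(charge), charge = unname(charge))
  attr(tbl, "pH") <- pH
  tbl
}

#' Assign integer charges to every sidechain in a bundle
#'
#' Adds a `charge` column to each helix's sidechain table by residue name.
#' The whole charge of a residue sits at its sidechain sphere centre.
#'
#' @param layout A `bundle_layout` (or plain list of `helix_model`s).
#' @param table Charge table from [charge_table()].
#' @return The input with charged sidechain tables.
#' @export
assign_charges <- function(layout, table = charge_table()) {
  models <- if (inherits(layout, "bundle_layout")) layout$models else layout
  models <- lapply(models, function(m) {
    unknown <- setdiff(unique(m$sidechains$residue_name), table$residue_name)
    if (length(unknown) > 0L) {
      hf_abort(paste0("no charge defined for residue name(s): ",
                      paste(unknown, collapse = ", ")),
               "helixforce_error_validation")
    }
    m$sidechains <- dplyr::left_join(m$sidechains, table, by = "residue_name")
    # glycine has no sidechain atoms, hence no charge carrier
    m$sidechains$charge[m$sidechains$atom_count == 0L] <- 0L
    m
  })
  if (inherits(layout, "bundle_layout")) {
    layout$models <- models
    layout
  } else {
    models
  }
}

#' Tidy table of charged sidechain sites in a bundle
#'
#' @param layout A charged `bundle_layout` (after [assign_charges()]).
#' @return Tibble: `helix_id`, `residue_seq`, `residue_name`, `x`, `y`, `z`
#'   (sphere centre, SIM frame), `charge`.
#' @export
sidechain_charges <- function(layout) {
  models <- if (inherits(layout, "bundle_layout")) layout$models else layout
  purrr::map_dfr(models, function(m) {
    sc <- m$sidechains
    if (!"charge" %in% names(sc)) {
      hf_abort("sidechains carry no charges; call assign_charges() first",
               "helixforce_error_validation")
    }
    tibble(
      helix_id = m$helix_id, residue_seq = sc$residue_seq,
      residue_name = sc$residue_name,
      x = sc$center_x, y = sc$center_y, z = sc$center_z,
      charge = sc$charge
    )
  })
}

#' Coulomb force between two point charges
#'
#' \eqn{F = k_e q_1 q_2 / (\epsilon_r r^2)} with charges in units of the
#' elementary charge and the separation in Angstrom, returned in piconewton.
#' Positive values are repulsive, negative attractive.
#'
#' @param q1,q2 Integer charges (elementary-charge units); vectorised.
#' @param distance Separation, Angstrom; must be positive.
#' @param constants List from [physical_constants()].
#' @return Signed force in pN.
#' @export
coulomb_force <- function(q1, q2, distance, constants = physical_constants()) {
  if (any(distance <= 0)) {
    hf_abort("distance must be positive", "helixforce_error_validation")
  }
  e <- constants$elementary_charge
  r_m <- distance * constants$angstrom_to_metre
  f_n <- constants$coulomb_constant * (q1 * e) * (q2 * e) /
    (constants$relative_permittivity * r_m^2)
  f_n * constants$newton_to_piconewton
}

#' Net static electrostatic force of a helix bundle
#'
#' For every unordered pair of helices, Coulomb's law is applied to every
#' cross pair of charged sidechain sites (intra-helix pairs excluded; pairs
#' with a zero charge product contribute nothing and are omitted). The net
#' force is the signed scalar sum over all pairs, in a fixed summation order
#' (helix pair, then site index in each helix) so totals are bit
#' reproducible. A per-helix 3D force vector sum is also reported for
#' inspection; the headline number is the scalar sum.
#'
#' @param layout A charged `bundle_layout`, or a tidy charge table as from
#'   [sidechain_charges()].
#' @param constants List from [physical_constants()].
#' @param bundle_id Label carried into the result.
#' @return Object of class `bundle_force_result`: `per_pair` tibble,
#'   `per_helix_pair_totals` tibble, `net_force` (pN),
#'   `per_helix_vectors` tibble.
#' @export
bundle_static_force <- function(layout, constants = physical_constants(),
                                bundle_id = "bundle") {
  sites <- if (inherits(layout, "bundle_layout")) sidechain_charges(layout) else as_tibble(layout)
  ids <- sort(unique(sites$helix_id))
  if (length(ids) < 2L) {
    hf_abort("a bundle needs at least 2 helices", "helixforce_error_validation")
  }

  pair_rows <- list()
  k <- 0L
  for (ai in seq_along(ids)[-length(ids)]) {
    for (bi in seq.int(ai + 1L, length(ids))) {
      a <- sites[sites$helix_id == ids[ai] & sites$charge != 0L, , drop = FALSE]
      b <- sites[sites$helix_id == ids[bi] & sites$charge != 0L, , drop = FALSE]
      if (nrow(a) == 0L || nrow(b) == 0L) next
      for (i in seq_len(nrow(a))) {
        dx <- b$x - a$x[i]; dy <- b$y - a$y[i]; dz <- b$z - a$z[i]
        d <- sqrt(dx^2 + dy^2 + dz^2)
        if (any(d < 1e-6)) {
          j <- which(d < 1e-6)[1]
          hf_abort(
            sprintf("coincident charged sidechain centres: helix %d residue %d vs helix %d residue %d",
                    ids[ai], a$residue_seq[i], ids[bi], b$residue_seq[j]),
            "helixforce_error_degenerate"
          )
        }
        f <- coulomb_force(a$charge[i], b$charge, d, constants)
        k <- k + 1L
        pair_rows[[k]] <- tibble(
          helix_a = ids[ai], helix_b = ids[bi],
          residue_a = a$residue_seq[i], residue_b = b$residue_seq,
          charge_a = a$charge[i], charge_b = b$charge,
          distance = d, force = f,
          # unit vector a -> b scaled by force gives the vector force ON b
          fx = f * dx / d, fy = f * dy / d, fz = f * dz / d
        )
      }
    }
  }

  per_pair <- if (k == 0L) {
    tibble(
      helix_a = integer(), helix_b = integer(), residue_a = integer(),
      residue_b = integer(), charge_a = integer(), charge_b = integer(),
      distance = double(), force = double(),
      fx = double(), fy = double(), fz = double()
    )
  } else {
    bind_rows(pair_rows)
  }

  totals <- per_pair |>
    group_by(.data$helix_a, .data$helix_b) |>
    summarise(total_force = sum(.data$force), n_pairs = dplyr::n(), .groups = "drop")

  # per-helix vector sum: force on each helix from all others
  vec_on <- function(id) {
    on_b <- per_pair[per_pair$helix_b == id, , drop = FALSE]
    on_a <- per_pair[per_pair$helix_a == id, , drop = FALSE]
    c(sum(on_b$fx) - sum(on_a$fx),
      sum(on_b$fy) - sum(on_a$fy),
      sum(on_b$fz) - sum(on_a$fz))
  }
  vecs <- purrr::map_dfr(ids, function(id) {
    v <- vec_on(id)
    tibble(helix_id = id, fx = v[1], fy = v[2], fz = v[3],
           magnitude = sqrt(sum(v^2)))
  })

  structure(
    list(
      bundle_id = bundle_id,
      per_pair = per_pair,
      per_helix_pair_totals = totals,
      net_force = sum(per_pair$force),
      per_helix_vectors = vecs,
      constants = constants
    ),
    class = "bundle_force_result"
  )
}

#' @export
print.bundle_force_result <- function(x, ...) {
  cat(sprintf(
    "<bundle_force_result> %s: net static force %s pN (%s) over %d charge pairs\n",
    x$bundle_id, signif(x$net_force, 3),
    if (x$net_force < 0) "attractive" else "repulsive",
    nrow(x$per_pair)
  ))
  invisible(x)
}

#' Per-pair tidy view of a bundle force result
#'
#' @param x A `bundle_force_result`.
#' @param ... Unused.
#' @return The per-pair tibble (one row per charged cross pair).
#' @exportS3Method generics::tidy
tidy.bundle_force_result <- function(x, ...) x$per_pair

#' One-row summary of a bundle force result
#'
#' @param x A `bundle_force_result`.
#' @param ... Unused.
#' @return One-row tibble: `bundle_id`, `net_force` (pN), `n_charge_pairs`,
#'   `n_helix_pairs`, `attractive` flag.
#' @exportS3Method generics::glance
glance.bundle_force_result <- function(x, ...) {
  tibble(
    bundle_id = x$bundle_id,
    net_force = x$net_force,
    n_charge_pairs = nrow(x$per_pair),
    n_helix_pairs = nrow(x$per_helix_pair_totals),
    attractive = x$net_force < 0
  )
}

#' Plot per-helix-pair force totals
#'
#' @param object A `bundle_force_result`.
#' @param ... Unused.
#' @return A ggplot: signed total force per helix pair, attraction below
#'   zero.
#' @exportS3Method ggplot2::autoplot
autoplot.bundle_force_result <- function(object, ...) {
  df <- object$per_helix_pair_totals |>
    mutate(pair = paste0(.data$helix_a, "-", .data$helix_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$total_force,
                                   fill = .data$total_force < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "helix pair", y = "total Coulomb force (pN)",
      title = paste0(object$bundle_id, ": net ", signif(object$net_force, 3), " pN")
    )
}
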