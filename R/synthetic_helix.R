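# Ideal-helix generation: parametric alpha-helices with known geometry and
# charges, so every downstream stage (parsing, fitting, frames, forces,
# diagnostics) can be exercised without external structure files.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) hf_abort("zero-length vector cannot be normalised", "helixforce_error_degenerate")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal pair (u, v) perpendicular to unit axis a with u x v = a,
# so increasing phase winds right-handed about the axis.
axis_basis <- function(a) {
  e <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- unit3(cross3(e, a))
  v <- cross3(a, u)
  list(u = u, v = v)
}

# Fixed heavy-atom name pools per residue type; generic fallback for others.
SIDECHAIN_NAME_POOL <- list(
  ALA = c("CB"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")
)
GENERIC_POOL <- c("CB", "CG", "CD", "CE", "CZ", "CH", "CI", "CJ", "CK", "CL")

#' Specify an ideal (straight, rigid) alpha-helix
#'
#' Defaults follow canonical alpha-helix geometry: 1.5 Angstrom rise and 100
#' degree twist per residue about the axis, with the C-alpha trace on a
#' cylinder of radius 2.3 Angstrom. Sidechain centroids sit
#' `sidechain_distance` radially outward from each C-alpha. `jitter_sd` adds
#' i.i.d. Gaussian noise (per coordinate) to C-alpha placements and sidechain
#' centroids; `cluster_sd` sets the spread of the atoms within one sidechain
#' cluster about its centroid.
#'
#' @param n_residues Number of residues (at least 4; the axis fit is
#'   ill-conditioned below that).
#' @param rise_per_residue Axial rise per residue, Angstrom.
#' @param twist_per_residue Turn per residue, degrees (positive =
#'   right-handed).
#' @param backbone_radius Radius of the C-alpha cylinder, Angstrom.
#' @param axis_direction Unit 3-vector of the helix axis (normalised
#'   internally).
#' @param origin 3D point the axis passes through at residue 1, Angstrom.
#' @param sequence Character vector of 3-letter residue codes (recycled if a
#'   single code); defaults to all-`"ALA"`.
#' @param sidechain_distance Radial offset of the sidechain centroid from the
#'   C-alpha, Angstrom.
#' @param atoms_per_sidechain Atoms per sidechain cluster (glycine gets none).
#' @param jitter_sd Gaussian placement noise, Angstrom (0 = exact geometry).
#' @param cluster_sd Within-sidechain atom spread, Angstrom.
#' @param seed Integer seed making generation reproducible.
#' @param chain_id Chain letter for the emitted atoms.
#' @param helix_id Integer id for the matching annotation.
#' @param start_seq First residue sequence number.
#' @return An object of class `ideal_helix_spec`.
#' @export
ideal_helix_spec <- function(n_residues = 18L,
                             rise_per_residue = 1.5,
                             twist_per_residue = 100,
                             backbone_radius = 2.3,
                             axis_direction = c(1, 0, 0),
                             origin = c(0, 0, 0),
                             sequence = "ALA",
                             sidechain_distance = 2.5,
                             atoms_per_sidechain = 3L,
                             jitter_sd = 0,
                             cluster_sd = 0.3,
                             seed = 1L,
                             chain_id = "A",
                             helix_id = 1L,
                             start_seq = 1L) {
  if (n_residues < 4L) {
    hf_abort("n_residues must be at least 4 (axis fit undefined below)", "helixforce_error_validation")
  }
  if (length(sequence) == 1L) sequence <- rep(sequence, n_residues)
  if (length(sequence) != n_residues) {
    hf_abort("length(sequence) must equal n_residues", "helixforce_error_validation")
  }
  if (!all(sequence %in% STANDARD_RESIDUES)) {
    hf_abort("sequence contains nonstandard residue codes", "helixforce_error_validation")
  }
  if (atoms_per_sidechain < 1L) {
    hf_abort("atoms_per_sidechain must be >= 1", "helixforce_error_validation")
  }
  spec <- list(
    n_residues = as.integer(n_residues),
    rise_per_residue = rise_per_residue,
    twist_per_residue = twist_per_residue,
    backbone_radius = backbone_radius,
    axis_direction = unit3(axis_direction),
    origin = as.numeric(origin),
    sequence = sequence,
    sidechain_distance = sidechain_distance,
    atoms_per_sidechain = as.integer(atoms_per_sidechain),
    jitter_sd = jitter_sd,
    cluster_sd = cluster_sd,
    seed = as.integer(seed),
    chain_id = chain_id,
    helix_id = as.integer(helix_id),
    start_seq = as.integer(start_seq)
  )
  structure(spec, class = "ideal_helix_spec")
}

sidechain_atom_names <- function(residue_name, m) {
  pool <- SIDECHAIN_NAME_POOL[[residue_name]]
  if (is.null(pool)) pool <- GENERIC_POOL
  pool <- c(pool, GENERIC_POOL, paste0("X", seq_len(m)))
  pool[seq_len(m)]
}

#' Generate an ideal alpha-helix as atom records
#'
#' Places C-alpha atoms on the parametric helix defined by the spec, adds
#' `N`, `C`, `O` backbone atoms at fixed chemically plausible offsets, and a
#' seeded atom cluster per sidechain whose centroid sits the spec's radial
#' distance outward from the C-alpha (exactly, before jitter). Glycine
#' residues get no sidechain atoms. The output parses through
#' [group_residues()] unchanged.
#'
#' @param spec An [ideal_helix_spec()].
#' @return A list with `atoms` (atom tibble as from [read_structure()]),
#'   `annotation` (one-row annotation tibble), and `truth` (list with the true
#'   `axis`, `origin`, `radius`, and exact `ca` positions before jitter).
#' @export
generate_ideal_helix <- function(spec) {
  stopifnot(inherits(spec, "ideal_helix_spec"))
  withr::local_seed(spec$seed)

  a <- spec$axis_direction
  basis <- axis_basis(a)
  u <- basis$u
  v <- basis$v
  theta <- spec$twist_per_residue * pi / 180
  n <- spec$n_residues

  rows <- vector("list", n)
  ca_true <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    k <- i - 1L
    radial <- cos(k * theta) * u + sin(k * theta) * v
    tangent <- -sin(k * theta) * u + cos(k * theta) * v
    ca0 <- spec$origin + a * spec$rise_per_residue * k + spec$backbone_radius * radial
    ca_true[i, ] <- ca0
    ca <- ca0 + jitter3(spec$jitter_sd)

    # fixed offsets in the local (axial, tangential, radial) frame; magnitudes
    # roughly bond-length scale, exact stereochemistry out of scope
    n_pos <- ca + (-0.9) * a + (-0.9) * tangent + (-0.4) * radial
    c_pos <- ca + 0.9 * a + 0.9 * tangent + (-0.4) * radial
    o_pos <- c_pos + 0.3 * a + 0.2 * tangent + (-1.15) * radial

    rname <- spec$sequence[i]
    rseq <- spec$start_seq + k
    res_rows <- tibble(
      atom_name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      residue_name = rname,
      residue_seq = rseq,
      chain_id = spec$chain_id,
      x = c(n_pos[1], ca[1], c_pos[1], o_pos[1]),
      y = c(n_pos[2], ca[2], c_pos[2], o_pos[2]),
      z = c(n_pos[3], ca[3], c_pos[3], o_pos[3]),
      model_index = 1L
    )

    if (rname != "GLY") {
      m <- spec$atoms_per_sidechain
      centroid <- ca + spec$sidechain_distance * radial + jitter3(spec$jitter_sd)
      if (m == 1L) {
        pos <- matrix(centroid, 1, 3, byrow = TRUE)
      } else {
        off <- matrix(stats::rnorm(3 * m, sd = spec$cluster_sd), m, 3)
        off <- sweep(off, 2, colMeans(off))  # recentre: centroid is exact
        pos <- sweep(off, 2, centroid, `+`)
      }
      nm <- sidechain_atom_names(rname, m)
      res_rows <- bind_rows(res_rows, tibble(
        atom_name = nm,
        element = substr(sub("^[0-9]+", "", nm), 1, 1),
        residue_name = rname,
        residue_seq = rseq,
        chain_id = spec$chain_id,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        model_index = 1L
      ))
    }
    rows[[i]] <- res_rows
  }

  list(
    atoms = bind_rows(rows),
    annotation = tibble(
      helix_id = spec$helix_id,
      chain_id = spec$chain_id,
      start_seq = spec$start_seq,
      end_seq = spec$start_seq + n - 1L
    ),
    truth = list(
      axis = a, origin = spec$origin, radius = spec$backbone_radius,
      ca = ca_true
    )
  )
}

jitter3 <- function(sd) {
  if (sd <= 0) return(c(0, 0, 0))
  stats::rnorm(3, sd = sd)
}

charge_to_residue <- function(q) {
  if (!all(q %in% c(-1L, 0L, 1L))) {
    hf_abort("requested charges must be in {-1, 0, +1}", "helixforce_error_validation")
  }
  c(`-1` = "ASP", `0` = "ALA", `1` = "LYS")[as.character(q)]
}

#' Generate a parallel pair of helices with specified per-residue charges
#'
#' Builds two ideal helices with identical phase, the second a pure
#' translation of the first by `separation` along the inter-axis direction,
#' so corresponding sidechain centroids are exactly `separation` apart.
#' Residue types encode the requested charges under the default pH 7.2 table
#' (`LYS` for +1, `ASP` for -1, `ALA` for 0); charge vectors shorter than 4
#' are padded with neutral alanines to keep the axis fit well-posed.
#'
#' @param separation Inter-axis (and matching inter-centroid) distance,
#'   Angstrom; must be positive.
#' @param charges_a,charges_b Integer charges in `{-1, 0, +1}` per residue of
#'   helix A / helix B.
#' @param seed Integer seed.
#' @param n_residues Number of residues per helix (padded minimum 4).
#' @return A list with `atoms` (both chains), `annotations` (two rows), and
#'   the two specs.
#' @export
generate_charged_pair <- function(separation, charges_a, charges_b,
                                  seed = 1L, n_residues = NULL) {
  if (separation <= 0) {
    hf_abort("separation must be positive", "helixforce_error_validation")
  }
  n <- max(length(charges_a), length(charges_b), 4L, n_residues %||% 0L)
  pad <- function(q) c(as.integer(q), rep(0L, n - length(q)))
  seq_a <- unname(charge_to_residue(pad(charges_a)))
  seq_b <- unname(charge_to_residue(pad(charges_b)))

  base <- function(sequence, origin, chain, id, seed) {
    ideal_helix_spec(
      n_residues = n, sequence = sequence, origin = origin,
      axis_direction = c(1, 0, 0), atoms_per_sidechain = 1L,
      jitter_sd = 0, seed = seed, chain_id = chain, helix_id = id
    )
  }
  spec_a <- base(seq_a, c(0, 0, 0), "A", 1L, seed)
  spec_b <- base(seq_b, c(0, separation, 0), "B", 2L, seed + 1L)
  gen_a <- generate_ideal_helix(spec_a)
  gen_b <- generate_ideal_helix(spec_b)
  list(
    atoms = bind_rows(gen_a$atoms, gen_b$atoms),
    annotations = bind_rows(gen_a$annotation, gen_b$annotation),
    spec_a = spec_a, spec_b = spec_b
  )
}

#' Write an atom tibble as fixed-column PDB ATOM records
#'
#' Emits a minimal single-model PDB file (ATOM records plus `END`) that
#' [read_structure()] parses back identically, so synthetic fixtures exercise
#' the real parser.
#'
#' @param atoms Atom tibble (columns as produced by the generator / parser).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(atoms, path) {
  # PDB atom-name column convention: names shorter than 4 chars start in
  # column 14 when the element symbol is a single character
  fmt_name <- function(nm) {
    ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), fmt_name(atoms$atom_name), atoms$residue_name,
    atoms$chain_id, atoms$residue_seq, atoms$x, atoms$y, atoms$z,
    atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a helix annotation table as CSV
#'
#' @param annotations Annotation tibble (`helix_id`, `chain_id`, `start_seq`,
#'   `end_seq`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_helix_annotations <- function(annotations, path) {
  readr::write_csv(validate_annotations(annotations), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
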