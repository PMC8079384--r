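# Pipeline entry points: configuration, the model/force/diagnose/synth runs,
# and file reporting. A thin Rscript wrapper over these lives in
# inst/cli/helixforce.R for shell use; the functions here are the tested
# surface.

#' Configuration for a pipeline run
#'
#' @param structure_path Path to the PDB structure file.
#' @param annotation_path Path to the helix-annotation CSV.
#' @param model_index Which PDB `MODEL` to read (default 1).
#' @param chain_id Optional chain restriction for [read_structure()];
#'   annotations still select their own chains.
#' @param charge_table_overrides Named integer vector of charge overrides
#'   (see [charge_table()]).
#' @param pH Solution pH recorded with the charge table.
#' @param relative_permittivity Medium permittivity (default 1, vacuum).
#' @param output_dir Directory for written reports (created if missing).
#' @param seed Integer seed for the synthetic subcommand.
#' @param bundle_id Label used in force reports.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(structure_path = NULL,
                       annotation_path = NULL,
                       model_index = 1L,
                       chain_id = NULL,
                       charge_table_overrides = NULL,
                       pH = 7.2,
                       relative_permittivity = 1,
                       output_dir = tempdir(),
                       seed = 1L,
                       bundle_id = "bundle") {
  if (pH <= 0) hf_abort("pH must be positive", "helixforce_error_validation")
  if (relative_permittivity <= 0) {
    hf_abort("relative_permittivity must be positive", "helixforce_error_validation")
  }
  structure(
    list(
      structure_path = structure_path, annotation_path = annotation_path,
      model_index = as.integer(model_index), chain_id = chain_id,
      charge_table_overrides = charge_table_overrides, pH = pH,
      relative_permittivity = relative_permittivity,
      output_dir = output_dir, seed = as.integer(seed), bundle_id = bundle_id
    ),
    class = "run_config"
  )
}

load_models <- function(config) {
  if (is.null(config$structure_path) || is.null(config$annotation_path)) {
    hf_abort("run requires structure_path and annotation_path", "helixforce_error_validation")
  }
  atoms <- read_structure(config$structure_path, config$model_index, config$chain_id)
  anns <- read_helix_annotations(config$annotation_path)
  lapply(seq_len(nrow(anns)), function(i) {
    ann <- anns[i, ]
    build_helix_model(group_residues(atoms, ann), helix_id = ann$helix_id)
  })
}

#' Fit and write helix models for an annotated structure
#'
#' Reads the structure and annotations, fits one coarse-grained model per
#' annotated helix, writes a JSON model document per helix plus a summary
#' table (`model_summary.csv`) to the output directory.
#'
#' @param config A [run_config()].
#' @return The list of `helix_model`s, invisibly; the summary tibble is
#'   attached as attribute `summary`.
#' @export
run_model <- function(config) {
  models <- load_models(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (m in models) {
    write_helix_model(m, file.path(config$output_dir,
                                   sprintf("helix_%d_model.json", m$helix_id)))
  }
  summary <- purrr::map_dfr(models, glance)
  readr::write_csv(summary, file.path(config$output_dir, "model_summary.csv"))
  attr(models, "summary") <- summary
  invisible(models)
}

#' Compute and write the static electrostatic force of a bundle
#'
#' Runs the full pipeline: parse, fit, place in the SIM frame, assign
#' integer charges at the configured pH, and sum the inter-helix Coulomb
#' pair forces. Writes `net_force.csv` (one row per bundle: id, signed net
#' force in pN to 3 significant figures, pair counts) and
#' `pair_forces.csv` (per charge pair detail).
#'
#' @param config A [run_config()].
#' @return The `bundle_force_result`, invisibly.
#' @export
run_force <- function(config) {
  models <- load_models(config)
  if (length(models) < 2L) {
    hf_abort("force run needs at least 2 annotated helices", "helixforce_error_validation")
  }
  layout <- place_bundle(models)
  layout <- assign_charges(layout, charge_table(config$pH, config$charge_table_overrides))
  consts <- physical_constants(relative_permittivity = config$relative_permittivity)
  result <- bundle_static_force(layout, consts, bundle_id = config$bundle_id)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  net_row <- glance(result) |>
    mutate(net_force = signif(.data$net_force, 3))
  readr::write_csv(net_row, file.path(config$output_dir, "net_force.csv"))
  readr::write_csv(result$per_pair, file.path(config$output_dir, "pair_forces.csv"))
  invisible(result)
}

#' Compute and write approximation diagnostics for annotated helices
#'
#' Writes the per-helix skew table (`skew.csv`), the skew-angle distribution
#' summary (`skew_distribution.csv`), the pooled radial histogram
#' (`radial_histogram.csv`), and pooled sidechain shape statistics per
#' residue type present (`sidechain_shapes.csv`).
#'
#' @param config A [run_config()].
#' @param bin_width Histogram bin width, Angstrom.
#' @return A list with the computed objects, invisibly.
#' @export
run_diagnose <- function(config, bin_width = 0.05) {
  models <- load_models(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  dist <- skew_distribution(models)
  readr::write_csv(dist$angles, file.path(config$output_dir, "skew.csv"))
  readr::write_csv(dist$summary, file.path(config$output_dir, "skew_distribution.csv"))

  hist <- radial_histogram(models, bin_width = bin_width)
  readr::write_csv(hist$bins, file.path(config$output_dir, "radial_histogram.csv"))

  types <- sort(unique(unlist(lapply(models, function(m) {
    sc <- m$sidechains
    sc$residue_name[sc$atom_count >= 1L & sc$residue_name != "GLY"]
  }))))
  shapes <- purrr::map_dfr(types, function(rn) {
    s <- sidechain_shape_stats(models, rn)
    tibble(
      residue_name = rn, mean_distance = s$mean_distance, median = s$median,
      q1 = s$q1, q3 = s$q3, n_instances = s$n_instances, n_atoms = s$n_atoms
    )
  })
  readr::write_csv(shapes, file.path(config$output_dir, "sidechain_shapes.csv"))

  invisible(list(skew = dist, histogram = hist, shapes = shapes))
}

#' Generate and write a synthetic structure plus annotations
#'
#' Produces a deterministic (per seed) ideal two-helix charged pair as a PDB
#' file and annotation CSV in the output directory, ready for [run_model()]
#' and [run_force()].
#'
#' @param config A [run_config()]; `seed` and `output_dir` are used.
#' @param separation Inter-axis distance of the pair, Angstrom.
#' @param charges_a,charges_b Integer per-residue charges (see
#'   [generate_charged_pair()]).
#' @return List with `structure_path` and `annotation_path`, invisibly.
#' @export
run_synth <- function(config, separation = 10,
                      charges_a = c(1L, -1L, 1L, 0L),
                      charges_b = c(-1L, 1L, 0L, 1L)) {
  pair <- generate_charged_pair(separation, charges_a, charges_b, seed = config$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(config$output_dir, "synthetic_pair.pdb")
  ap <- file.path(config$output_dir, "synthetic_pair_annotations.csv")
  write_structure_pdb(pair$atoms, sp)
  write_helix_annotations(pair$annotations, ap)
  invisible(list(structure_path = sp, annotation_path = ap))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
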