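#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort .data
#' @importFrom dplyr filter mutate arrange group_by ungroup summarise bind_rows
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# Names treated as backbone for the backbone/sidechain split.
BACKBONE_ATOM_NAMES <- c("N", "CA", "C", "O")

# Standard 20 amino-acid three-letter codes.
STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

hf_abort <- function(message, class, ...) {
  abort(message, class = c(class, "helixforce_error"), ...)
}

#' Read ATOM records from a PDB file
#'
#' Parses fixed-column `ATOM` records into a tibble of heavy-atom coordinates.
#' `HETATM` records (waters, ligands), hydrogens and alternate locations other
#' than blank or `'A'` are excluded, so the result is a single-conformer,
#' heavy-atom view of the structure. Multi-model (NMR) files are gated on
#' `model_index`; files without `MODEL` records are treated as model 1.
#' Residues carrying insertion codes are rejected rather than silently merged.
#'
#' @param path Path to a PDB file.
#' @param model_index Which `MODEL` to read (default 1, the first model).
#' @param chain_id Optional single chain identifier; `NULL` keeps all chains.
#' @return A tibble with one row per accepted atom: `atom_name`, `element`,
#'   `residue_name`, `residue_seq`, `chain_id`, `x`, `y`, `z` (Angstrom, PDB
#'   global frame) and `model_index`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(paste0(
#'   "ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
#'   "  1.00  0.00           C"), pdb)
#' read_structure(pdb)
#' @export
read_structure <- function(path, model_index = 1L, chain_id = NULL) {
  if (!file.exists(path)) {
    hf_abort(paste0("PDB file not found: ", path), "helixforce_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_of <- cumsum(startsWith(rec, "MODEL "))
  model_of[model_of == 0L] <- 1L

  keep <- which(rec == "ATOM  " & model_of == model_index)
  atoms <- parse_atom_lines(lines[keep], model_index)

  if (!is.null(chain_id)) {
    atoms <- filter(atoms, .data$chain_id == !!chain_id)
  }
  if (nrow(atoms) == 0L) {
    hf_abort(
      sprintf(
        "no ATOM records for model %d%s in %s",
        model_index,
        if (is.null(chain_id)) "" else paste0(", chain '", chain_id, "'"),
        path
      ),
      "helixforce_error_empty_selection"
    )
  }
  atoms
}

parse_atom_lines <- function(lines, model_index) {
  if (length(lines) == 0L) {
    return(tibble(
      atom_name = character(), element = character(),
      residue_name = character(), residue_seq = integer(),
      chain_id = character(), x = double(), y = double(), z = double(),
      model_index = integer()
    ))
  }
  fld <- function(a, b) trimws(substr(lines, a, b))
  atom_name <- fld(13, 16)
  alt_loc <- substr(lines, 17, 17)
  residue_name <- fld(18, 20)
  chain <- substr(lines, 22, 22)
  residue_seq <- fld(23, 26)
  icode <- substr(lines, 27, 27)
  x <- as.numeric(fld(31, 38))
  y <- as.numeric(fld(39, 46))
  z <- as.numeric(fld(47, 54))
  element <- toupper(fld(77, 78))
  # Older files leave the element columns blank; fall back to the atom name,
  # stripping any leading digit (e.g. "1HB"-style hydrogen names).
  blank <- element == ""
  element[blank] <- substr(sub("^[0-9]+", "", atom_name[blank]), 1, 1)

  keep <- alt_loc %in% c(" ", "A") & !(element %in% c("H", "D"))
  bad_icode <- icode != " " & keep
  if (any(bad_icode)) {
    hf_abort(
      paste0(
        "residue insertion codes are not supported (residue ",
        residue_name[bad_icode][1], " ", residue_seq[bad_icode][1],
        icode[bad_icode][1], ")"
      ),
      "helixforce_error_validation"
    )
  }
  if (any(!is.finite(x[keep]) | !is.finite(y[keep]) | !is.finite(z[keep]))) {
    hf_abort("non-finite coordinates in ATOM records", "helixforce_error_validation")
  }
  tibble(
    atom_name = atom_name[keep],
    element = element[keep],
    residue_name = residue_name[keep],
    residue_seq = as.integer(residue_seq[keep]),
    chain_id = chain[keep],
    x = x[keep], y = y[keep], z = z[keep],
    model_index = as.integer(model_index)
  )
}

#' Read a helix annotation table
#'
#' Helix annotations give the residue span of each alpha-helix in a bundle,
#' as determined upstream (e.g. from a secondary-structure overlay). The file
#' is plain CSV with header `helix_id,chain_id,start_seq,end_seq`; lines
#' beginning with `#` are comments. Spans are inclusive PDB residue numbers.
#'
#' @param path Path to the annotation CSV.
#' @return A tibble of annotations sorted by `helix_id`.
#' @export
read_helix_annotations <- function(path) {
  if (!file.exists(path)) {
    hf_abort(paste0("annotation file not found: ", path), "helixforce_error_io")
  }
  ann <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      helix_id = readr::col_integer(),
      chain_id = readr::col_character(),
      start_seq = readr::col_integer(),
      end_seq = readr::col_integer()
    )
  )
  validate_annotations(as_tibble(ann))
}

validate_annotations <- function(ann) {
  required <- c("helix_id", "chain_id", "start_seq", "end_seq")
  if (!all(required %in% names(ann))) {
    hf_abort(
      paste0("annotation table must have columns: ", paste(required, collapse = ", ")),
      "helixforce_error_validation"
    )
  }
  bad <- ann$start_seq > ann$end_seq
  if (any(bad)) {
    hf_abort(
      sprintf("helix %d has start_seq > end_seq (%d > %d)",
              ann$helix_id[bad][1], ann$start_seq[bad][1], ann$end_seq[bad][1]),
      "helixforce_error_validation"
    )
  }
  if (anyDuplicated(ann$helix_id)) {
    hf_abort("duplicate helix_id in annotations", "helixforce_error_validation")
  }
  # no overlap on the same chain
  ann <- arrange(ann, .data$helix_id)
  for (ch in unique(ann$chain_id)) {
    sub <- ann[ann$chain_id == ch, , drop = FALSE]
    sub <- sub[order(sub$start_seq), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start_seq[-1] <= sub$end_seq[-nrow(sub)])) {
      hf_abort(
        paste0("overlapping helix annotations on chain ", ch),
        "helixforce_error_validation"
      )
    }
  }
  ann
}

#' Group atoms of one annotated helix into residues
#'
#' Slices the atom table to the annotation's chain and residue span and splits
#' each residue into backbone (`N`, `CA`, `C`, `O`) and sidechain (all other
#' heavy) atoms. Glycine yields an empty sidechain set. Every residue in the
#' span must be present with exactly one `CA`; nonstandard residues inside the
#' span are an error.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param annotation One annotation row (tibble or list with `helix_id`,
#'   `chain_id`, `start_seq`, `end_seq`).
#' @return A nested tibble with one row per residue, ordered by `residue_seq`:
#'   `residue_seq`, `residue_name`, and list-columns `backbone_atoms`,
#'   `sidechain_atoms` holding atom tibbles.
#' @export
group_residues <- function(atoms, annotation) {
  ann <- as.list(annotation)
  sel <- filter(
    atoms,
    .data$chain_id == ann$chain_id,
    .data$residue_seq >= ann$start_seq,
    .data$residue_seq <= ann$end_seq
  )
  seqs <- seq.int(ann$start_seq, ann$end_seq)
  groups <- lapply(seqs, function(s) {
    res <- filter(sel, .data$residue_seq == s)
    if (nrow(res) == 0L) {
      hf_abort(
        sprintf("residue %d (chain %s) missing from annotated helix %d",
                s, ann$chain_id, ann$helix_id),
        "helixforce_error_missing_residue"
      )
    }
    rname <- res$residue_name[1]
    if (!rname %in% STANDARD_RESIDUES) {
      hf_abort(
        sprintf("nonstandard residue %s at %d inside annotated helix %d",
                rname, s, ann$helix_id),
        "helixforce_error_validation"
      )
    }
    is_bb <- res$atom_name %in% BACKBONE_ATOM_NAMES
    if (sum(res$atom_name == "CA") != 1L) {
      hf_abort(
        sprintf("residue %s %d (chain %s) has %d CA atoms; expected exactly 1",
                rname, s, ann$chain_id, sum(res$atom_name == "CA")),
        "helixforce_error_missing_ca"
      )
    }
    tibble(
      residue_seq = s,
      residue_name = rname,
      backbone_atoms = list(res[is_bb, , drop = FALSE]),
      sidechain_atoms = list(res[!is_bb, , drop = FALSE])
    )
  })
  bind_rows(groups)
}
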