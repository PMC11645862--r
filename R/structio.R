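#' Read a structure coordinate file
#'
#' Parses a PDB or mmCIF file into a [structure_model()]. Hydrogens (and
#' deuterium) are dropped; alternate conformers are reduced to the
#' highest-occupancy one (ties resolved in favour of altloc "A"); chain
#' order follows the file.
#'
#' @param path path to a coordinate file.
#' @param format `"pdb"`, `"cif"`/`"mmcif"`, or `"auto"` (by extension;
#'   `.cif`/`.mmcif` are mmCIF, anything else PDB).
#' @param model_id identifier for the returned model; defaults to the file
#'   base name.
#' @return A `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif", "mmcif"),
                           model_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    fs_stop("fs_unreadable", "file does not exist: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "mmcif") format <- "cif"

  parsed <- tryCatch(suppressWarnings(suppressMessages(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))),
    error = function(e)
      fs_stop("fs_unreadable", "could not parse %s as %s: %s",
              path, format, conditionMessage(e)))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L)
    fs_stop("fs_unreadable", "no atom records in %s", path)

  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- guess_element(a$elety, a$resid)
  elem <- toupper(trimws(elem))
  blank <- is.na(elem) | !nzchar(elem)
  elem[blank] <- guess_element(a$elety[blank], a$resid[blank])

  chain <- as.character(a$chain)
  chain[is.na(chain) | !nzchar(chain)] <- "A"

  atoms <- data.frame(
    chain = chain, resnum = as.integer(a$resno),
    resname = trimws(a$resid), atom = trimws(a$elety), element = elem,
    x = a$x, y = a$y, z = a$z,
    bfactor = if (is.null(a$b)) 0 else as.numeric(a$b),
    occ = if (is.null(a$o)) 1 else as.numeric(a$o),
    alt = if (is.null(a$alt)) NA_character_ else as.character(a$alt),
    stringsAsFactors = FALSE)
  atoms <- atoms[!is_hydrogen(atoms$element), , drop = FALSE]
  if (nrow(atoms) == 0L)
    fs_stop("fs_unreadable", "no heavy atoms in %s", path)

  # altloc: keep the highest-occupancy conformer per atom; ties -> altloc A
  has_alt <- !is.na(atoms$alt) & nzchar(atoms$alt)
  if (any(has_alt)) {
    atoms$occ[is.na(atoms$occ)] <- 1
    key <- paste(atoms$chain, atoms$resnum, atoms$atom, sep = "\r")
    altrank <- ifelse(has_alt, match(atoms$alt, LETTERS, nomatch = 99L), 0L)
    ord <- order(key, -atoms$occ, altrank)
    keep_rows <- ord[!duplicated(key[ord])]
    atoms <- atoms[sort(keep_rows), , drop = FALSE]
  }
  atoms$occ <- NULL
  atoms$alt <- NULL

  structure_model(atoms,
                 model_id = model_id %||%
                   tools::file_path_sans_ext(basename(path)),
                 source_path = path)
}

#' Write a structure coordinate file
#'
#' Writes a `StructureModel` as PDB (via bio3d) or mmCIF (a minimal
#' `atom_site` loop). [read_structure()] inverts the operation; PDB
#' coordinates are stored at 1e-3 Angstrom precision.
#'
#' @param model a `StructureModel`.
#' @param path output path.
#' @param format `"pdb"`, `"cif"`/`"mmcif"`, or `"auto"` (by extension).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path,
                            format = c("auto", "pdb", "cif", "mmcif")) {
  if (!inherits(model, "StructureModel"))
    fs_stop("fs_bad_argument", "model must be a StructureModel")
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "mmcif") format <- "cif"
  a <- model$atoms
  ok <- tryCatch({
    if (format == "pdb") {
      bio3d::write.pdb(file = path,
                       xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                       resno = a$resnum, resid = a$resname,
                       eleno = seq_len(nrow(a)), elety = a$atom,
                       chain = a$chain, o = rep(1, nrow(a)), b = a$bfactor,
                       elesy = a$element)
    } else {
      write_mmcif(model, path)
    }
    TRUE
  }, error = function(e)
    fs_stop("fs_unwritable", "could not write %s: %s", path,
            conditionMessage(e)))
  invisible(path)
}

# Minimal mmCIF atom_site writer (enough for round-tripping heavy-atom
# coordinate models; bio3d::read.cif reads it back).
write_mmcif <- function(model, path) {
  a <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("data_%s", gsub("[^A-Za-z0-9_]", "_", model$model_id)),
    "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"), con)
  ent <- match(a$chain, unique(a$chain))
  writeLines(sprintf(
    "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 %.2f %d %s %s %s 1",
    seq_len(nrow(a)), a$element, a$atom, a$resname, a$chain, ent, a$resnum,
    a$x, a$y, a$z, a$bfactor, a$resnum, a$resname, a$chain, a$atom), con)
  writeLines("#", con)
}

# Accepted key names in confidence JSON files.
PLDDT_KEYS <- c("plddt", "pLDDT", "plddts")
PAE_KEYS <- c("pae", "predicted_aligned_error", "PAE")

#' Read prediction-confidence annotations for a model
#'
#' Two JSON dialects are supported:
#' * `scores_json` — a combined scores file holding both a per-residue pLDDT
#'   array (key `plddt`, `pLDDT` or `plddts`) and a square PAE matrix (key
#'   `pae`, `PAE` or `predicted_aligned_error`);
#' * `pae_json` — a PAE-only file (key `predicted_aligned_error` or `pae`,
#'   possibly wrapped in a one-element array as in AFDB downloads), with
#'   pLDDT taken from the coordinate file's B-factor column (per-residue
#'   mean). `bfactor_plddt` is accepted as a synonym for this dialect.
#'
#' `"auto"` picks `scores_json` when a pLDDT key is present, else `pae_json`.
#'
#' @param path path to a confidence JSON file.
#' @param model the `StructureModel` the annotations belong to.
#' @param dialect one of `"auto"`, `"scores_json"`, `"pae_json"`,
#'   `"bfactor_plddt"`.
#' @return A `ConfidenceBundle` whose index map follows the model's chain
#'   order (see [build_residue_index()]).
#' @export
read_confidence <- function(path, model,
                            dialect = c("auto", "scores_json", "pae_json",
                                        "bfactor_plddt")) {
  dialect <- match.arg(dialect)
  if (dialect == "bfactor_plddt") dialect <- "pae_json"
  if (!file.exists(path))
    fs_stop("fs_unreadable", "file does not exist: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    fs_stop("fs_unreadable", "could not parse JSON %s: %s",
                            path, conditionMessage(e)))
  # AFDB-style files wrap the scores object in a one-element array
  if (is.data.frame(obj)) obj <- as.list(obj[1L, , drop = FALSE])
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L)
    obj <- obj[[1L]]

  pick <- function(keys) {
    hit <- intersect(keys, names(obj))
    if (length(hit)) obj[[hit[1L]]] else NULL
  }
  pae <- pick(PAE_KEYS)
  if (is.null(pae))
    fs_stop("fs_bad_confidence",
            "no PAE matrix found in %s (accepted keys: %s)", path,
            paste(PAE_KEYS, collapse = ", "))
  if (is.list(pae) && !is.matrix(pae)) pae <- do.call(rbind, pae)
  if (is.list(pae) && is.matrix(pae)) pae <- apply(pae, c(1, 2), as.numeric)

  if (dialect == "auto")
    dialect <- if (!is.null(pick(PLDDT_KEYS))) "scores_json" else "pae_json"
  plddt <- if (dialect == "scores_json") {
    p <- pick(PLDDT_KEYS)
    if (is.null(p))
      fs_stop("fs_bad_confidence",
              "no pLDDT array found in %s (accepted keys: %s)", path,
              paste(PLDDT_KEYS, collapse = ", "))
    as.numeric(p)
  } else {
    plddt_from_bfactor(model)
  }
  confidence_bundle(plddt, pae, build_residue_index(model))
}

# Per-residue pLDDT from B-factors (mean over the residue's atoms).
plddt_from_bfactor <- function(model) {
  a <- model$atoms
  key <- factor(paste(a$chain, a$resnum, sep = "\r"),
                levels = unique(paste(a$chain, a$resnum, sep = "\r")))
  as.numeric(tapply(a$bfactor, key, mean))
}

#' Write prediction-confidence annotations
#'
#' Inverse of [read_confidence()]. The `scores_json` dialect stores pLDDT
#' and PAE; the `pae_json` dialect stores the PAE matrix only (pLDDT is
#' expected to travel in the coordinate file's B-factor column).
#'
#' @param bundle a `ConfidenceBundle`.
#' @param path output path.
#' @param dialect `"scores_json"` or `"pae_json"`.
#' @return Invisibly, `path`.
#' @export
write_confidence <- function(bundle, path,
                             dialect = c("scores_json", "pae_json")) {
  dialect <- match.arg(dialect)
  obj <- if (dialect == "scores_json")
    list(plddt = bundle$plddt, pae = bundle$pae)
  else
    list(predicted_aligned_error = bundle$pae,
         max_predicted_aligned_error = max(bundle$pae))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Stamp per-residue pLDDT into a model's B-factor column
#'
#' Prediction pipelines conventionally store pLDDT in the B-factor field of
#' the deposited coordinates; this helper applies a bundle's pLDDT vector to
#' every atom of the corresponding residue so the `pae_json` dialect can
#' recover it.
#'
#' @param model a `StructureModel`.
#' @param bundle a matching `ConfidenceBundle`.
#' @return The model with updated B-factors.
#' @export
set_bfactor_plddt <- function(model, bundle) {
  idx <- bundle$index
  gi <- global_index(idx, model$atoms$chain, model$atoms$resnum)
  model$atoms$bfactor <- bundle$plddt[gi + 1L]
  model
}
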