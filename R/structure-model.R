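#' Structure model container
#'
#' A `StructureModel` holds the heavy-atom coordinates of one predicted or
#' experimental model as a flat atom table organised by chain and residue,
#' the representation shared by every downstream stage (contact extraction,
#' superposition, clash census). Atom records are kept in file order;
#' hydrogens are expected to have been dropped at parse time.
#'
#' @param atoms data.frame with columns `chain` (character), `resnum`
#'   (integer, author numbering), `resname` (3-letter code), `atom`
#'   (atom name, unique within a residue), `element`, `x`, `y`, `z`
#'   (Angstrom) and optionally `bfactor` (used to carry per-residue pLDDT).
#' @param model_id character scalar identifying the model.
#' @param source_path file of origin, or `NA` for in-memory models.
#' @param metadata free-form named list (e.g. prediction run settings).
#'
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms, model_id = "model",
                            source_path = NA_character_,
                            metadata = list()) {
  required <- c("chain", "resnum", "resname", "atom", "element",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    fs_stop("fs_bad_argument", "atoms is missing columns: %s",
            paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L)
    fs_stop("fs_empty_model", "a StructureModel must contain at least one atom")
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  atoms$chain <- as.character(atoms$chain)
  atoms$resnum <- as.integer(atoms$resnum)
  rownames(atoms) <- NULL

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    fs_stop("fs_bad_coordinates", "non-finite atom coordinates")

  # chain blocks must be contiguous in file order; a chain id that reappears
  # after another chain has started is a duplicate chain id
  blocks <- rle(atoms$chain)$values
  if (anyDuplicated(blocks))
    fs_stop("fs_duplicate_chain", "duplicate chain id(s): %s",
            paste(unique(blocks[duplicated(blocks)]), collapse = ", "))

  # residues strictly ordered by residue number within each chain
  for (ch in blocks) {
    rn <- unique(atoms$resnum[atoms$chain == ch])
    if (any(diff(rn) <= 0L))
      fs_stop("fs_unordered_residues",
              "residue numbers in chain '%s' are not strictly increasing", ch)
  }

  # atom names unique within a residue
  key <- paste(atoms$chain, atoms$resnum, atoms$atom, sep = "\r")
  if (anyDuplicated(key))
    fs_stop("fs_duplicate_atom",
            "duplicate atom name within a residue (e.g. %s)",
            sub("\r", " ", key[duplicated(key)][1L]))

  structure(list(model_id = model_id, atoms = atoms,
                 source_path = source_path, metadata = metadata),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  idx <- residue_table(x)
  cat(sprintf("StructureModel '%s': %d chain(s), %d residue(s), %d atom(s)\n",
              x$model_id, length(chain_ids(x)), nrow(idx), nrow(x$atoms)))
  for (ch in chain_ids(x)) {
    sub <- idx[idx$chain == ch, ]
    cat(sprintf("  chain %s: %d residues (%d..%d), %s\n", ch, nrow(sub),
                min(sub$resnum), max(sub$resnum), chain_kind(x, ch)))
  }
  invisible(x)
}

#' Chain identifiers of a model, in file order
#' @param model a `StructureModel`.
#' @return Character vector of chain ids.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Entity kind of a chain (protein, nucleic or other) by majority residue name
#' @param model a `StructureModel`.
#' @param chain chain id.
#' @return One of `"protein"`, `"nucleic"`, `"other"`.
#' @export
chain_kind <- function(model, chain) {
  res <- residue_table(model)
  kinds <- residue_kind(res$resname[res$chain == chain])
  if (!length(kinds)) fs_stop("fs_unknown_chain", "no such chain: %s", chain)
  names(sort(table(kinds), decreasing = TRUE))[1L]
}

# one row per residue, in file order, with 0-based global index `gi`
residue_table <- function(model) {
  a <- model$atoms
  first <- !duplicated(paste(a$chain, a$resnum, sep = "\r"))
  out <- data.frame(chain = a$chain[first], resnum = a$resnum[first],
                    resname = a$resname[first], stringsAsFactors = FALSE)
  out$gi <- seq_len(nrow(out)) - 1L
  out
}

#' Total residue count of a model
#' @param model a `StructureModel`.
#' @return Integer.
#' @export
n_residues <- function(model) nrow(residue_table(model))

#' Global residue index of a model
#'
#' Residues are numbered 0-based in file chain order; each chain occupies a
#' half-open contiguous range of the global index. This is the indexing
#' convention used to address rows/columns of the PAE matrix.
#'
#' @param model a `StructureModel`.
#' @return A `ResidueIndex`: list with `ranges` (one row per chain: `chain`,
#'   `start`, `end` half-open, `n`) and `table` (one row per residue:
#'   `gi`, `chain`, `resnum`).
#' @export
build_residue_index <- function(model) {
  tab <- residue_table(model)
  ranges <- do.call(rbind, lapply(chain_ids(model), function(ch) {
    gi <- tab$gi[tab$chain == ch]
    data.frame(chain = ch, start = min(gi), end = max(gi) + 1L,
               n = length(gi), stringsAsFactors = FALSE)
  }))
  structure(list(ranges = ranges,
                 table = tab[, c("gi", "chain", "resnum")],
                 key = paste(tab$chain, tab$resnum, sep = "\r")),
            class = "ResidueIndex")
}

#' Look up global residue indices for (chain, resnum) pairs
#' @param index a `ResidueIndex`.
#' @param chain,resnum equal-length vectors addressing residues.
#' @return Integer vector of 0-based global indices.
#' @export
global_index <- function(index, chain, resnum) {
  key <- index$key %||% paste(index$table$chain, index$table$resnum,
                              sep = "\r")
  m <- match(paste(chain, resnum, sep = "\r"), key)
  if (anyNA(m))
    fs_stop("fs_unknown_residue", "residue(s) not in index: %s",
            paste(paste(chain, resnum)[is.na(m)], collapse = ", "))
  index$table$gi[m]
}

#' Look up (chain, resnum) for global residue indices
#' @param index a `ResidueIndex`.
#' @param gi integer vector of 0-based global indices.
#' @return data.frame with columns `chain`, `resnum`.
#' @export
residue_at <- function(index, gi) {
  m <- match(gi, index$table$gi)
  if (anyNA(m))
    fs_stop("fs_unknown_residue", "global index out of range: %s",
            paste(gi[is.na(m)], collapse = ", "))
  index$table[m, c("chain", "resnum")]
}

#' Confidence bundle: per-residue pLDDT plus pairwise PAE matrix
#'
#' Couples a model's prediction-confidence annotations to its residue index:
#' a pLDDT vector on the 0-100 scale and a square predicted-aligned-error
#' (PAE) matrix in Angstrom addressed by the 0-based global residue index.
#' PAE is directional and need not be symmetric: entry (i, j) is the expected
#' error of residue j when aligned on residue i.
#'
#' @param plddt numeric vector, one value in \[0, 100\] per residue.
#' @param pae square numeric matrix of non-negative errors (Angstrom).
#' @param index the model's `ResidueIndex` (see [build_residue_index()]).
#' @return An object of class `ConfidenceBundle`.
#' @export
confidence_bundle <- function(plddt, pae, index) {
  n <- nrow(index$table)
  pae <- as.matrix(pae)
  if (length(plddt) != n)
    fs_stop("fs_length_mismatch",
            "pLDDT length (%d) != model residue count (%d)",
            length(plddt), n)
  if (nrow(pae) != ncol(pae))
    fs_stop("fs_bad_pae", "PAE matrix is not square (%d x %d)",
            nrow(pae), ncol(pae))
  if (nrow(pae) != n)
    fs_stop("fs_length_mismatch",
            "PAE side (%d) != model residue count (%d)", nrow(pae), n)
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100))
    fs_stop("fs_bad_plddt", "pLDDT values must be finite and in [0, 100]")
  if (any(!is.finite(pae)) || any(pae < 0))
    fs_stop("fs_bad_pae", "PAE values must be finite and >= 0")
  dimnames(pae) <- NULL
  structure(list(plddt = as.numeric(plddt), pae = pae, index = index),
            class = "ConfidenceBundle")
}

#' @export
print.ConfidenceBundle <- function(x, ...) {
  cat(sprintf(
    "ConfidenceBundle: %d residues; mean pLDDT %.1f; mean PAE %.1f A\n",
    length(x$plddt), mean(x$plddt), mean(x$pae)))
  invisible(x)
}
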