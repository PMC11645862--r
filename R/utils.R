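# Internal helpers shared across modules.

fs_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fs_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    fs_stop("fs_bad_argument", "seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Element symbol from a PDB atom name when no explicit element is available.
TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CL", "BR", "SE", "NA",
                         "CA", "CU", "NI", "CO", "CD", "HG", "IOD")

guess_element <- function(atom_name, resname = NULL) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  # Metal/ion residues use the full name; polymer atoms start with the element.
  out <- substr(nm, 1L, 1L)
  ion <- !is.null(resname) & nm == toupper(resname) & nm %in% TWO_LETTER_ELEMENTS
  out[ion] <- nm[ion]
  out
}

is_hydrogen <- function(element) toupper(element) %in% c("H", "D")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
NUC3 <- c("DA", "DC", "DG", "DT", "DI", "DU", "A", "C", "G", "U", "I")

residue_kind <- function(resname) {
  ifelse(toupper(resname) %in% AA3, "protein",
         ifelse(toupper(resname) %in% NUC3, "nucleic", "other"))
}
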