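#' Contact-extraction parameters
#'
#' The confident inter-chain contact rule: two residues from different
#' chains are a contact when their minimum heavy-atom distance is strictly
#' below `distance_cutoff`, both residues have pLDDT strictly above
#' `plddt_min`, and the combined inter-residue PAE is strictly below
#' `pae_max`. Defaults are the 5 Angstrom / 50 / 15 Angstrom rule.
#'
#' PAE is directional, so the two values PAE(i, j) and PAE(j, i) are
#' combined per `pae_combine`: `"min"` (default; permissive), `"mean"`, or
#' `"both_must_pass"` (both directions must clear the ceiling; the recorded
#' combined value is then the maximum).
#'
#' @param distance_cutoff residue distance cutoff in Angstrom (default 5).
#' @param plddt_min pLDDT floor, 0-100 scale (default 50).
#' @param pae_max PAE ceiling in Angstrom (default 15).
#' @param pae_combine how to combine the two PAE directions.
#' @param atom_rule `"any_heavy"` (minimum over all heavy-atom pairs,
#'   default) or `"cbeta"` (beta-carbon distance, alpha-carbon for glycine).
#' @return An object of class `ContactParams`.
#' @export
contact_params <- function(distance_cutoff = 5, plddt_min = 50, pae_max = 15,
                           pae_combine = c("min", "mean", "both_must_pass"),
                           atom_rule = c("any_heavy", "cbeta")) {
  pae_combine <- match.arg(pae_combine)
  atom_rule <- match.arg(atom_rule)
  if (distance_cutoff <= 0 || plddt_min <= 0 || pae_max <= 0)
    fs_stop("fs_bad_argument", "all thresholds must be positive")
  structure(list(distance_cutoff = distance_cutoff, plddt_min = plddt_min,
                 pae_max = pae_max, pae_combine = pae_combine,
                 atom_rule = atom_rule),
            class = "ContactParams")
}

params_equal <- function(a, b) {
  identical(a$distance_cutoff, b$distance_cutoff) &&
    identical(a$plddt_min, b$plddt_min) &&
    identical(a$pae_max, b$pae_max) &&
    identical(a$pae_combine, b$pae_combine) &&
    identical(a$atom_rule, b$atom_rule)
}

# Representative atom per residue under the cbeta rule: CB, CA for glycine
# (or when no CB exists), else the residue's first atom.
representative_atoms <- function(atoms) {
  key <- factor(paste(atoms$chain, atoms$resnum, sep = "\r"),
                levels = unique(paste(atoms$chain, atoms$resnum, sep = "\r")))
  pick <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    nm <- atoms$atom[i]
    if ("CB" %in% nm && atoms$resname[i[1L]] != "GLY") i[match("CB", nm)]
    else if ("CA" %in% nm) i[match("CA", nm)]
    else i[1L]
  }), use.names = FALSE)
  atoms[sort(pick), , drop = FALSE]
}

# Minimum inter-residue distances between two chains' atom sets.
# Returns list(gi_a, gi_b, dist) for residue pairs under `cutoff`;
# `nres` is the total residue count (for numeric pair keys).
min_residue_distances <- function(A, B, gi_a, gi_b, cutoff, nres) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  hit <- which(d2 < cutoff^2)
  if (!length(hit)) return(NULL)
  ia <- (hit - 1L) %% nrow(d2) + 1L
  jb <- (hit - 1L) %/% nrow(d2) + 1L
  ga <- gi_a[ia]; gb <- gi_b[jb]
  key <- as.numeric(ga) * nres + gb
  dv <- pmax(d2[hit], 0)
  o <- order(key, dv)
  f <- !duplicated(key[o])
  list(gi_a = ga[o][f], gi_b = gb[o][f], dist = sqrt(dv[o][f]))
}

#' Extract confident inter-chain contacts
#'
#' Applies the three-part contact rule of [contact_params()] to every
#' inter-chain residue pair of a model and returns the surviving pairs with
#' their distances and confidence values. Contacts are stored canonically:
#' `residue_a` precedes `residue_b` by (chain id, residue number), so each
#' contact has exactly one representation and the result is independent of
#' chain order in the file.
#'
#' @param model a `StructureModel` with at least two chains.
#' @param conf the matching `ConfidenceBundle`.
#' @param params a `ContactParams`.
#' @return An object of class `ContactSet`: list with `model_id`, `params`
#'   and `contacts`, a data.frame with columns `chain_a`, `resnum_a`,
#'   `chain_b`, `resnum_b`, `min_distance`, `plddt_a`, `plddt_b`, `pae_ab`,
#'   `pae_ba`, `pae` (the combined value).
#' @export
extract_contacts <- function(model, conf, params = contact_params()) {
  chains <- chain_ids(model)
  if (length(chains) < 2L)
    fs_stop("fs_single_chain",
            "no inter-chain interface possible: model has a single chain")
  if (length(conf$plddt) != n_residues(model))
    fs_stop("fs_length_mismatch",
            "confidence bundle does not match model residue count")

  atoms <- model$atoms
  if (params$atom_rule == "cbeta") atoms <- representative_atoms(atoms)
  idx <- conf$index
  tab <- idx$table  # row r holds global index r - 1
  gi_atoms <- global_index(idx, atoms$chain, atoms$resnum)
  nres <- nrow(tab)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])

  ga <- integer(); gb <- integer(); dist <- numeric()
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (i >= j) next
    sel_a <- atoms$chain == chains[i]; sel_b <- atoms$chain == chains[j]
    hits <- min_residue_distances(xyz[sel_a, , drop = FALSE],
                                  xyz[sel_b, , drop = FALSE],
                                  gi_atoms[sel_a], gi_atoms[sel_b],
                                  params$distance_cutoff, nres)
    if (!is.null(hits)) {
      ga <- c(ga, hits$gi_a); gb <- c(gb, hits$gi_b)
      dist <- c(dist, hits$dist)
    }
  }

  chain_a <- tab$chain[ga + 1L]; resnum_a <- tab$resnum[ga + 1L]
  chain_b <- tab$chain[gb + 1L]; resnum_b <- tab$resnum[gb + 1L]
  plddt_a <- conf$plddt[ga + 1L]; plddt_b <- conf$plddt[gb + 1L]
  pae_ab <- conf$pae[cbind(ga + 1L, gb + 1L)]
  pae_ba <- conf$pae[cbind(gb + 1L, ga + 1L)]

  # canonical representation: residue_a < residue_b by (chain id, resnum)
  swap <- chain_a > chain_b | (chain_a == chain_b & resnum_a > resnum_b)
  if (any(swap)) {
    sw <- function(a, b) {
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp; list(a, b)
    }
    s <- sw(chain_a, chain_b); chain_a <- s[[1L]]; chain_b <- s[[2L]]
    s <- sw(resnum_a, resnum_b); resnum_a <- s[[1L]]; resnum_b <- s[[2L]]
    s <- sw(plddt_a, plddt_b); plddt_a <- s[[1L]]; plddt_b <- s[[2L]]
    s <- sw(pae_ab, pae_ba); pae_ab <- s[[1L]]; pae_ba <- s[[2L]]
  }
  pae <- combine_pae(pae_ab, pae_ba, params$pae_combine)
  keep <- plddt_a > params$plddt_min & plddt_b > params$plddt_min &
    if (params$pae_combine == "both_must_pass")
      pae_ab < params$pae_max & pae_ba < params$pae_max
    else pae < params$pae_max
  keep <- which(keep)
  o <- keep[order(chain_a[keep], resnum_a[keep], chain_b[keep],
                  resnum_b[keep])]
  contacts <- data.frame(
    chain_a = chain_a[o], resnum_a = resnum_a[o],
    chain_b = chain_b[o], resnum_b = resnum_b[o],
    min_distance = dist[o], plddt_a = plddt_a[o], plddt_b = plddt_b[o],
    pae_ab = pae_ab[o], pae_ba = pae_ba[o], pae = pae[o],
    stringsAsFactors = FALSE)
  structure(list(model_id = model$model_id, params = params,
                 contacts = contacts),
            class = "ContactSet")
}

combine_pae <- function(pae_ab, pae_ba, rule) {
  switch(rule,
         min = pmin(pae_ab, pae_ba),
         mean = (pae_ab + pae_ba) / 2,
         both_must_pass = pmax(pae_ab, pae_ba))
}

#' @export
print.ContactSet <- function(x, ...) {
  cat(sprintf("ContactSet '%s': %d confident contact(s)\n", x$model_id,
              nrow(x$contacts)))
  cat(sprintf("  rule: d < %g A, pLDDT > %g, PAE(%s) < %g A, atoms: %s\n",
              x$params$distance_cutoff, x$params$plddt_min,
              x$params$pae_combine, x$params$pae_max, x$params$atom_rule))
  invisible(x)
}

contact_keys <- function(cs) {
  k <- cs$contacts
  if (!nrow(k)) return(character())
  paste(k$chain_a, k$resnum_a, k$chain_b, k$resnum_b, sep = "\r")
}

#' Interface summary statistics of a contact set
#'
#' Summarises a `ContactSet` as the contact count, the average interface
#' pLDDT and the average interface PAE, all computed over the confident
#' contacts only. The pLDDT average is by default over per-contact
#' residue-pair means (a residue participating in several contacts is
#' counted once per contact); `plddt_average = "unique_residues"` averages
#' each interface residue once instead.
#'
#' @param contacts a `ContactSet`.
#' @param plddt_average `"per_contact"` (default) or `"unique_residues"`.
#' @return List with `n_contacts`, `avg_plddt`, `avg_pae` (`NA` for an
#'   empty set, whose averages are undefined).
#' @export
interface_stats <- function(contacts,
                            plddt_average = c("per_contact",
                                              "unique_residues")) {
  plddt_average <- match.arg(plddt_average)
  k <- contacts$contacts
  if (nrow(k) == 0L)
    return(list(n_contacts = 0L, avg_plddt = NA_real_, avg_pae = NA_real_))
  avg_plddt <- if (plddt_average == "per_contact")
    mean((k$plddt_a + k$plddt_b) / 2)
  else {
    key <- c(paste(k$chain_a, k$resnum_a), paste(k$chain_b, k$resnum_b))
    val <- c(k$plddt_a, k$plddt_b)
    mean(val[!duplicated(key)])
  }
  list(n_contacts = nrow(k), avg_plddt = avg_plddt, avg_pae = mean(k$pae))
}

#' Ensemble model-agreement score (avg_models)
#'
#' Agreement statistic over an ensemble of M independently predicted models
#' of the same pair: over the union U of confident contacts observed in any
#' model, the mean fraction of models containing each contact,
#' \deqn{\mathrm{avg\_models} = \frac{1}{|U|}\sum_{c \in U} n_c / M,}
#' where \eqn{n_c} counts the models containing contact c. Ranges from 0
#' (worst; defined value for an empty union) to 1 (best: every contact in
#' every model).
#'
#' @param contact_sets list of `ContactSet`s, one per model, produced with
#'   identical parameters.
#' @return Numeric scalar in \[0, 1\].
#' @export
avg_models_score <- function(contact_sets) {
  if (!length(contact_sets))
    fs_stop("fs_bad_argument", "need at least one contact set")
  p0 <- contact_sets[[1L]]$params
  for (cs in contact_sets[-1L])
    if (!params_equal(cs$params, p0))
      fs_stop("fs_params_mismatch",
              "contact sets were extracted with different parameters")
  M <- length(contact_sets)
  keys <- unlist(lapply(contact_sets, contact_keys))
  if (!length(keys)) return(0)
  counts <- table(keys)
  mean(as.numeric(counts) / M)
}

# Published pDockQ sigmoid coefficients (Bryant, Pozzati & Elofsson 2022,
# Nat Commun 13:1265, reference implementation pdockq.py).
PDOCKQ_COEF <- c(L = 0.724, x0 = 152.611, k = 0.052, b = 0.018)

#' pDockQ sigmoid
#'
#' Evaluates the published pDockQ calibration curve
#' \deqn{pDockQ(x) = \frac{0.724}{1 + e^{-0.052 (x - 152.611)}} + 0.018}
#' at `x` = mean interface pLDDT times the natural log of the interface
#' contact count.
#'
#' @param x numeric vector.
#' @return Numeric vector of scores.
#' @export
pdockq_sigmoid <- function(x) {
  PDOCKQ_COEF[["L"]] /
    (1 + exp(-PDOCKQ_COEF[["k"]] * (x - PDOCKQ_COEF[["x0"]]))) +
    PDOCKQ_COEF[["b"]]
}

#' pDockQ interface-accuracy estimate
#'
#' Computes pDockQ with its own published contact definition, deliberately
#' independent of the confident-contact rule: interface contacts are
#' beta-carbon pairs (alpha-carbon for glycine) from different chains within
#' 8 Angstrom; the interface pLDDT is averaged over the unique interface
#' residues; the score is [pdockq_sigmoid()] of
#' (mean interface pLDDT) * ln(contact count). An interface with zero
#' contacts scores exactly 0.
#'
#' @param model a `StructureModel` with at least two chains.
#' @param conf the matching `ConfidenceBundle`.
#' @param dist_cutoff contact cutoff in Angstrom (published value 8).
#' @return Numeric scalar.
#' @export
pdockq <- function(model, conf, dist_cutoff = 8) {
  if (length(chain_ids(model)) < 2L)
    fs_stop("fs_single_chain",
            "no inter-chain interface possible: model has a single chain")
  atoms <- representative_atoms(model$atoms)
  idx <- conf$index
  gi <- global_index(idx, atoms$chain, atoms$resnum)
  chains <- chain_ids(model)
  n_contacts <- 0L
  if_res <- integer()
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (i >= j) next
    sa <- atoms$chain == chains[i]; sb <- atoms$chain == chains[j]
    A <- as.matrix(atoms[sa, c("x", "y", "z")])
    B <- as.matrix(atoms[sb, c("x", "y", "z")])
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    hit <- which(d2 <= dist_cutoff^2, arr.ind = TRUE)
    n_contacts <- n_contacts + nrow(hit)
    if_res <- c(if_res, gi[sa][hit[, 1L]], gi[sb][hit[, 2L]])
  }
  if (n_contacts == 0L) return(0)
  mean_plddt <- mean(conf$plddt[unique(if_res) + 1L])
  unname(pdockq_sigmoid(mean_plddt * log(n_contacts)))
}

#' Published confidence thresholds
#'
#' The decision table for calling an interface prediction confident:
#' average interface pLDDT above 70, ensemble agreement (avg_models) above
#' 0.5, pDockQ above 0.23, and external classifier score above 0.5. All
#' comparisons are strict.
#'
#' @param avg_plddt,avg_models,pdockq,classifier threshold values.
#' @return Named list of thresholds.
#' @export
threshold_table <- function(avg_plddt = 70, avg_models = 0.5,
                            pdockq = 0.23, classifier = 0.5) {
  list(avg_plddt = avg_plddt, avg_models = avg_models, pdockq = pdockq,
       classifier = classifier)
}

#' Confidence calls for an interface-metrics record
#'
#' One boolean flag per criterion, using a strict ">" comparison at each
#' threshold, so a value exactly at a threshold is not confident. A metric
#' that is undefined (`NA`, e.g. average pLDDT of a zero-contact interface)
#' or absent (no external classifier registered) yields `FALSE`.
#'
#' @param metrics an `InterfaceMetrics` record (see [score_pair()]) or a
#'   named list with any of `avg_plddt`, `avg_models`, `pdockq`,
#'   `classifier`.
#' @param thresholds a [threshold_table()].
#' @return Named logical vector.
#' @export
confidence_calls <- function(metrics, thresholds = threshold_table()) {
  flag <- function(value, thr)
    !is.null(value) && !is.na(value) && value > thr
  c(avg_plddt = flag(metrics$avg_plddt, thresholds$avg_plddt),
    avg_models = flag(metrics$avg_models, thresholds$avg_models),
    pdockq = flag(metrics$pdockq, thresholds$pdockq),
    classifier = flag(metrics$classifier, thresholds$classifier))
}

#' Score one candidate pair from its model ensemble
#'
#' Runs the full per-pair analysis: per-model confident contacts and
#' interface statistics, the ensemble agreement score over all models, and
#' pDockQ. Single-model statistics (contact count, average interface pLDDT
#' and PAE, pDockQ) are reported for the representative model, chosen
#' deterministically as the model with the highest own average interface
#' pLDDT (ties broken by lowest model position).
#'
#' @param models list of `StructureModel`s of the same pair (M >= 1).
#' @param confs list of matching `ConfidenceBundle`s, same length.
#' @param params a [contact_params()].
#' @param pair_id identifier for the pair; defaults to the first model's id.
#' @param classifier optional external scorer: a function
#'   `function(metrics, models, confs)` returning a score in \[0, 1\]
#'   (e.g. a wrapper around a trained interaction classifier). `NULL` (the
#'   default) leaves the classifier field `NA`.
#' @param thresholds a [threshold_table()] for the confidence flags.
#' @return An object of class `InterfaceMetrics`: list with `pair_id`,
#'   `n_models`, `n_contacts_per_model`, `n_contacts`, `avg_plddt`,
#'   `avg_pae`, `avg_models`, `pdockq`, `classifier`, `top_model`, `flags`,
#'   and `contact_sets` (the per-model `ContactSet`s).
#' @export
score_pair <- function(models, confs, params = contact_params(),
                       pair_id = NULL, classifier = NULL,
                       thresholds = threshold_table()) {
  if (!length(models) || length(models) != length(confs))
    fs_stop("fs_bad_argument",
            "models and confs must be non-empty lists of equal length")
  contact_sets <- Map(extract_contacts, models, confs,
                      MoreArgs = list(params = params))
  stats <- lapply(contact_sets, interface_stats)
  own_plddt <- vapply(stats, function(s)
    ifelse(is.na(s$avg_plddt), -Inf, s$avg_plddt), numeric(1L))
  top <- which.max(own_plddt)  # ties -> lowest position
  metrics <- structure(list(
    pair_id = pair_id %||% models[[1L]]$model_id,
    n_models = length(models),
    n_contacts_per_model = vapply(stats, `[[`, integer(1L), "n_contacts"),
    n_contacts = stats[[top]]$n_contacts,
    avg_plddt = stats[[top]]$avg_plddt,
    avg_pae = stats[[top]]$avg_pae,
    avg_models = avg_models_score(contact_sets),
    pdockq = pdockq(models[[top]], confs[[top]]),
    classifier = NA_real_,
    top_model = top,
    contact_sets = contact_sets), class = "InterfaceMetrics")
  if (!is.null(classifier)) {
    score <- classifier(metrics, models, confs)
    if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
        score < 0 || score > 1)
      fs_stop("fs_bad_classifier",
              "external classifier must return a single score in [0, 1]")
    metrics$classifier <- as.numeric(score)
  }
  metrics$flags <- confidence_calls(metrics, thresholds)
  metrics
}

#' @export
print.InterfaceMetrics <- function(x, ...) {
  cat(sprintf("InterfaceMetrics '%s' (M = %d models)\n", x$pair_id,
              x$n_models))
  cat(sprintf(
    "  n_contacts %d | avg pLDDT %s | avg PAE %s | avg_models %.3f | pDockQ %.3f\n",
    x$n_contacts,
    ifelse(is.na(x$avg_plddt), "NA", sprintf("%.1f", x$avg_plddt)),
    ifelse(is.na(x$avg_pae), "NA", sprintf("%.1f", x$avg_pae)),
    x$avg_models, x$pdockq))
  conf <- names(x$flags)[x$flags]
  cat("  confident by:", if (length(conf)) paste(conf, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Export a metrics record (or several) as a one-row-per-pair data.frame
#'
#' Fixed column order used by the TSV reports:
#' pair_id, n_models, n_contacts, avg_plddt, avg_pae, avg_models, pdockq,
#' classifier, then one logical flag column per confidence criterion.
#'
#' @param metrics an `InterfaceMetrics` or list of them.
#' @return data.frame.
#' @export
metrics_row <- function(metrics) {
  if (inherits(metrics, "InterfaceMetrics")) metrics <- list(metrics)
  do.call(rbind, lapply(metrics, function(m) data.frame(
    pair_id = m$pair_id, n_models = m$n_models, n_contacts = m$n_contacts,
    avg_plddt = m$avg_plddt, avg_pae = m$avg_pae,
    avg_models = m$avg_models, pdockq = m$pdockq,
    classifier = m$classifier,
    flag_avg_plddt = m$flags[["avg_plddt"]],
    flag_avg_models = m$flags[["avg_models"]],
    flag_pdockq = m$flags[["pdockq"]],
    flag_classifier = m$flags[["classifier"]],
    stringsAsFactors = FALSE)))
}

#' Write a contact list as TSV
#'
#' Contacts are written in canonical order (residue_a before residue_b by
#' chain id and residue number) with the thresholds that produced them in
#' a `#`-prefixed header line.
#'
#' @param contacts a `ContactSet`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_contacts_tsv <- function(contacts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- contacts$params
  writeLines(sprintf(
    "# model_id=%s distance_cutoff=%g plddt_min=%g pae_max=%g pae_combine=%s atom_rule=%s",
    contacts$model_id, p$distance_cutoff, p$plddt_min, p$pae_max,
    p$pae_combine, p$atom_rule), con)
  utils::write.table(contacts$contacts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
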