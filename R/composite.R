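# Rigid-body superposition and composite-model assembly: anchor a mobile
# model onto a reference via a shared chain, chain several such placements,
# census steric clashes between components, and measure named-atom
# distances in the assembled coordinate frame.

#' van der Waals radii by element (Angstrom)
#'
#' Standard element radii (Bondi, J Phys Chem 68:441, 1964; Mantina et al.
#' 2009 for metals), used by the default "major clash" rule. Elements not
#' listed fall back to 1.7 (carbon).
#'
#' @format Named numeric vector, element symbol to radius in Angstrom.
#' @export
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
               ZN = 1.39, MG = 1.73, FE = 1.94, MN = 1.93, CU = 1.40,
               NI = 1.63, CO = 1.72, CA = 2.31, "NA" = 2.27, K = 2.75)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising the RMSD of
#' `mobile %*% R + t` against `ref` over paired points. The SVD solution is
#' reflection-corrected: when the raw orthogonal optimum is improper, the
#' sign of the smallest singular component is flipped, so the result is
#' always a rigid-body motion (det(R) = +1) even for mirror-image inputs.
#'
#' @param ref,mobile n x 3 matrices of paired coordinates (n >= 3, not all
#'   collinear).
#' @return A `RigidTransform`: list with `rotation` (3 x 3, applied on the
#'   right of row-vector coordinates), `translation` (length 3), `rmsd`
#'   (Angstrom, residual after the fit) and `n_matched`.
#' @export
superpose <- function(ref, mobile) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (ncol(ref) != 3L || ncol(mobile) != 3L)
    fs_stop("fs_bad_argument", "coordinate sets must be n x 3 matrices")
  n <- nrow(ref)
  if (n != nrow(mobile))
    fs_stop("fs_bad_argument", "coordinate sets differ in length")
  if (n < 3L)
    fs_stop("fs_degenerate", "need at least 3 paired points, got %d", n)
  cref <- colMeans(ref); cmob <- colMeans(mobile)
  A <- sweep(ref, 2L, cref); B <- sweep(mobile, 2L, cmob)
  # collinear (or coincident) point sets leave the rotation underdetermined
  if (svd(A, nu = 0, nv = 0)$d[2L] < 1e-8 ||
      svd(B, nu = 0, nv = 0)$d[2L] < 1e-8)
    fs_stop("fs_degenerate", "degenerate (collinear) coordinate set")
  s <- svd(crossprod(B, A))           # t(B) %*% A = U D V'
  d <- sign(det(tcrossprod(s$u, s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cref - as.numeric(cmob %*% R)
  fitted <- B %*% R
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n_matched = n),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("RigidTransform: %d matched atoms, rmsd %.4f A, det(R) = %+.6f\n",
              x$n_matched, x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a model
#' @param transform a `RigidTransform`.
#' @param x an n x 3 coordinate matrix or a `StructureModel`.
#' @return Object of the same type with transformed coordinates.
#' @export
transform_apply <- function(transform, x) {
  if (inherits(x, "StructureModel")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    xyz <- transform_apply(transform, xyz)
    x$atoms$x <- xyz[, 1L]; x$atoms$y <- xyz[, 2L]; x$atoms$z <- xyz[, 3L]
    return(x)
  }
  sweep(as.matrix(x) %*% transform$rotation, 2L, -transform$translation)
}

#' Compose two rigid transforms (apply `first`, then `second`)
#' @param first,second `RigidTransform`s.
#' @return The composed `RigidTransform` (rmsd/n_matched from `second`).
#' @export
transform_compose <- function(first, second) {
  structure(list(
    rotation = first$rotation %*% second$rotation,
    translation = as.numeric(first$translation %*% second$rotation) +
      second$translation,
    rmsd = second$rmsd, n_matched = second$n_matched),
    class = "RigidTransform")
}

#' Anchor-chain pairing for a superposition
#'
#' Names the shared chain through which a mobile model is aligned onto a
#' reference: residues are paired by residue-number intersection (or an
#' explicit `pairs` table), and the fit uses alpha-carbons (default) or the
#' four backbone atoms of each paired residue.
#'
#' @param ref_chain,mobile_chain chain ids in the reference and mobile
#'   models.
#' @param atom_rule `"alpha_carbon"` or `"backbone"` (N, CA, C, O).
#' @param pairs optional data.frame with columns `ref_resnum`,
#'   `mobile_resnum` giving an explicit one-to-one residue pairing.
#' @return Object of class `ChainPairing`.
#' @export
chain_pairing <- function(ref_chain, mobile_chain = ref_chain,
                          atom_rule = c("alpha_carbon", "backbone"),
                          pairs = NULL) {
  atom_rule <- match.arg(atom_rule)
  if (!is.null(pairs)) {
    if (anyDuplicated(pairs$ref_resnum) ||
        anyDuplicated(pairs$mobile_resnum))
      fs_stop("fs_bad_argument", "explicit pairing must be one-to-one")
  }
  structure(list(ref_chain = ref_chain, mobile_chain = mobile_chain,
                 atom_rule = atom_rule, pairs = pairs),
            class = "ChainPairing")
}

anchor_coords <- function(model, chain, resnums, atom_rule) {
  wanted <- if (atom_rule == "alpha_carbon") "CA" else c("N", "CA", "C", "O")
  a <- model$atoms[model$atoms$chain == chain &
                     model$atoms$resnum %in% resnums &
                     model$atoms$atom %in% wanted, , drop = FALSE]
  a[order(a$resnum, match(a$atom, wanted)), , drop = FALSE]
}

#' Align a mobile model onto a reference via a shared chain
#'
#' Fits the rigid transform on the paired anchor-chain atoms only, then
#' applies it to every atom of the mobile model.
#'
#' @param reference,mobile `StructureModel`s.
#' @param pairing a [chain_pairing()] resolvable in both models.
#' @return List with `transform` (the anchor fit, including anchor rmsd and
#'   `n_matched`) and `model` (the transformed mobile model).
#' @export
align_via_chain <- function(reference, mobile, pairing) {
  for (side in list(c("reference", pairing$ref_chain),
                    c("mobile", pairing$mobile_chain))) {
    mdl <- if (side[1L] == "reference") reference else mobile
    if (!side[2L] %in% chain_ids(mdl))
      fs_stop("fs_unknown_chain", "chain '%s' absent from %s model",
              side[2L], side[1L])
  }
  if (is.null(pairing$pairs)) {
    ref_res <- residue_table(reference)
    mob_res <- residue_table(mobile)
    shared <- intersect(
      ref_res$resnum[ref_res$chain == pairing$ref_chain],
      mob_res$resnum[mob_res$chain == pairing$mobile_chain])
    pairs <- data.frame(ref_resnum = sort(shared),
                        mobile_resnum = sort(shared))
  } else pairs <- pairing$pairs

  ra <- anchor_coords(reference, pairing$ref_chain, pairs$ref_resnum,
                      pairing$atom_rule)
  ma <- anchor_coords(mobile, pairing$mobile_chain, pairs$mobile_resnum,
                      pairing$atom_rule)
  # keep only residues contributing the same atoms on both sides
  key_r <- paste(ra$resnum, ra$atom); key_m <- paste(
    pairs$ref_resnum[match(ma$resnum, pairs$mobile_resnum)], ma$atom)
  ra <- ra[key_r %in% key_m, , drop = FALSE]
  ma <- ma[key_m %in% key_r, , drop = FALSE]
  if (nrow(ra) < 3L)
    fs_stop("fs_degenerate",
            "fewer than 3 matched anchor atoms between '%s' and '%s'",
            pairing$ref_chain, pairing$mobile_chain)
  tf <- superpose(as.matrix(ra[, c("x", "y", "z")]),
                  as.matrix(ma[, c("x", "y", "z")]))
  list(transform = tf, model = transform_apply(tf, mobile))
}

#' Assemble a composite model by sequential anchored superposition
#'
#' Starting from a base model, each step aligns a mobile component onto the
#' current assembly via a shared chain and adds it. A step's reference is
#' the base (`reference = "base"`) or any previously placed component (by
#' name). Chain ids colliding with ones already present are suffixed
#' (`_2`, `_3`, ...) and the mapping recorded per component.
#'
#' @param base the reference `StructureModel`.
#' @param steps list of steps, each a list with `mobile` (a
#'   `StructureModel`), `pairing` (a [chain_pairing()]), optionally
#'   `reference` (component name, default `"base"`) and `name` (component
#'   name, default the mobile's `model_id`).
#' @return A `CompositeModel`: list with `base` and `components`, each
#'   component a list of `name`, `model` (placed), `transform`,
#'   `pairing`, `reference`, `chain_map`.
#' @export
assemble <- function(base, steps = list()) {
  comp <- structure(list(base = base, components = list()),
                    class = "CompositeModel")
  for (k in seq_along(steps)) {
    step <- steps[[k]]
    ref_name <- step$reference %||% "base"
    ref_model <- if (identical(ref_name, "base")) comp$base
    else {
      hit <- which(vapply(comp$components, `[[`, "", "name") == ref_name)
      if (!length(hit))
        fs_stop("fs_unknown_component",
                "step %d references unplaced component '%s'", k, ref_name)
      comp$components[[hit]]$model
    }
    fit <- align_via_chain(ref_model, step$mobile, step$pairing)
    placed <- fit$model
    taken <- c(chain_ids(comp$base),
               unlist(lapply(comp$components,
                             function(cc) chain_ids(cc$model))))
    chain_map <- stats::setNames(chain_ids(placed), chain_ids(placed))
    for (ch in names(chain_map)) {
      new <- ch; suffix <- 1L
      while (new %in% taken) { suffix <- suffix + 1L
        new <- sprintf("%s_%d", ch, suffix) }
      chain_map[ch] <- new
      taken <- c(taken, new)
    }
    placed$atoms$chain <- unname(chain_map[placed$atoms$chain])
    comp$components[[length(comp$components) + 1L]] <- list(
      name = step$name %||% step$mobile$model_id, model = placed,
      transform = fit$transform, pairing = step$pairing,
      reference = ref_name, chain_map = chain_map)
  }
  names(comp$components) <- vapply(comp$components, `[[`, "", "name")
  comp
}

#' @export
print.CompositeModel <- function(x, ...) {
  cat(sprintf("CompositeModel: base '%s' + %d placed component(s)\n",
              x$base$model_id, length(x$components)))
  for (cc in x$components)
    cat(sprintf("  %s onto %s via %s->%s (anchor rmsd %.4f A, n = %d)\n",
                cc$name, cc$reference, cc$pairing$mobile_chain,
                cc$pairing$ref_chain, cc$transform$rmsd,
                cc$transform$n_matched))
  invisible(x)
}

composite_atoms <- function(composite) {
  parts <- c(list(cbind(component = "base", composite$base$atoms)),
             lapply(composite$components, function(cc)
               cbind(component = cc$name, cc$model$atoms)))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

clash_threshold <- function(rule, elem_a, elem_b, vdw_slack, fixed_cutoff) {
  if (rule == "vdw") vdw_radius(elem_a) + vdw_radius(elem_b) - vdw_slack
  else rep(fixed_cutoff, length(elem_a))
}

#' Steric clash census of a composite model
#'
#' Enumerates inter-component heavy-atom pairs violating a steric rule.
#' The default "major clash" rule flags pairs closer than the sum of the
#' two van der Waals radii minus `vdw_slack` (1.5 Angstrom); a fixed
#' distance rule (`rule = "fixed"`, default 2 Angstrom) is selectable.
#' Atom pairs within one component are never tested, anchor chains are
#' skipped (each placed component's anchor chain is by construction
#' superposed on its reference's, so those overlaps are not clashes), and
#' further component pairs can be excluded explicitly. Search uses a
#' spatial grid (cell lists); results equal the naive all-pairs census.
#'
#' @param composite a `CompositeModel` with >= 1 placed component.
#' @param rule `"vdw"` or `"fixed"`.
#' @param vdw_slack slack subtracted from the radius sum (Angstrom).
#' @param fixed_cutoff cutoff for the fixed rule (Angstrom).
#' @param exclude list of length-2 character vectors naming component
#'   pairs to skip (use `"base"` for the base model).
#' @return A `ClashReport`: list with `clashes` (data.frame: components,
#'   chains, residues, atoms, `distance`, `overlap`), `counts` (per
#'   component pair), and `rule` metadata.
#' @export
clash_census <- function(composite, rule = c("vdw", "fixed"),
                         vdw_slack = 1.5, fixed_cutoff = 2.0,
                         exclude = list()) {
  rule <- match.arg(rule)
  atoms <- composite_atoms(composite)
  # drop anchor chains of placed components (and the chains they pair to)
  drop <- rep(FALSE, nrow(atoms))
  for (cc in composite$components) {
    drop <- drop | (atoms$component == cc$name &
                      atoms$chain == cc$chain_map[[cc$pairing$mobile_chain]])
  }
  atoms <- atoms[!drop, , drop = FALSE]

  excluded_pair <- function(a, b) any(vapply(exclude, function(p)
    setequal(p, c(a, b)), logical(1L)))

  max_thr <- if (rule == "vdw") 2 * max(vdw_radius(atoms$element)) -
    vdw_slack else fixed_cutoff
  cell <- max(max_thr, 0.1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  gidx <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / cell)
  cell_key <- paste(gidx[, 1L], gidx[, 2L], gidx[, 3L])
  cells <- split(seq_len(nrow(atoms)), cell_key)
  coords_of <- function(key) cells[[key]]

  # candidate atom pairs from neighbouring cells
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pair_i <- integer(); pair_j <- integer()
  keys <- names(cells)
  keymat <- do.call(rbind, lapply(strsplit(keys, " ", fixed = TRUE),
                                  as.integer))
  keyenv <- new.env(hash = TRUE, size = length(keys))
  for (k in seq_along(keys)) assign(keys[k], k, envir = keyenv)
  for (k in seq_along(keys)) {
    here <- cells[[k]]
    for (o in seq_len(nrow(offsets))) {
      nb_key <- paste(keymat[k, 1L] + offsets[o, 1L],
                      keymat[k, 2L] + offsets[o, 2L],
                      keymat[k, 3L] + offsets[o, 3L])
      nb_id <- keyenv[[nb_key]]
      if (is.null(nb_id) || nb_id < k) next
      there <- cells[[nb_id]]
      if (nb_id == k) {
        if (length(here) > 1L) {
          cmb <- utils::combn(here, 2L)
          pair_i <- c(pair_i, cmb[1L, ]); pair_j <- c(pair_j, cmb[2L, ])
        }
      } else {
        g <- expand.grid(i = here, j = there)
        pair_i <- c(pair_i, g$i); pair_j <- c(pair_j, g$j)
      }
    }
  }
  keep <- atoms$component[pair_i] != atoms$component[pair_j]
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  if (length(pair_i)) {
    excl <- vapply(seq_along(pair_i), function(k)
      excluded_pair(atoms$component[pair_i[k]],
                    atoms$component[pair_j[k]]), logical(1L))
    pair_i <- pair_i[!excl]; pair_j <- pair_j[!excl]
  }

  if (length(pair_i)) {
    d <- sqrt(rowSums((xyz[pair_i, , drop = FALSE] -
                         xyz[pair_j, , drop = FALSE])^2))
    thr <- clash_threshold(rule, atoms$element[pair_i],
                           atoms$element[pair_j], vdw_slack, fixed_cutoff)
    hit <- d < thr
  } else hit <- logical()

  mk_side <- function(ii, suf) {
    out <- atoms[ii, c("component", "chain", "resnum", "atom"), drop = FALSE]
    names(out) <- paste0(c("component_", "chain_", "resnum_", "atom_"), suf)
    out
  }
  clashes <- if (any(hit)) {
    i <- pair_i[hit]; j <- pair_j[hit]
    # canonical order: component_a <= component_b alphabetically
    flip <- atoms$component[i] > atoms$component[j]
    tmp <- i[flip]; i[flip] <- j[flip]; j[flip] <- tmp
    cbind(mk_side(i, "a"), mk_side(j, "b"),
          data.frame(distance = d[hit], overlap = (thr - d)[hit]))
  } else cbind(mk_side(integer(), "a"), mk_side(integer(), "b"),
               data.frame(distance = numeric(), overlap = numeric()))
  ord <- order(clashes$component_a, clashes$component_b, clashes$chain_a,
               clashes$resnum_a, clashes$atom_a, clashes$chain_b,
               clashes$resnum_b, clashes$atom_b)
  clashes <- clashes[ord, , drop = FALSE]
  rownames(clashes) <- NULL
  counts <- if (nrow(clashes))
    stats::aggregate(list(n_clashes = clashes$distance),
                     by = list(component_a = clashes$component_a,
                               component_b = clashes$component_b), length)
  else data.frame(component_a = character(), component_b = character(),
                  n_clashes = integer())
  structure(list(clashes = clashes, counts = counts,
                 rule = list(rule = rule, vdw_slack = vdw_slack,
                             fixed_cutoff = fixed_cutoff)),
            class = "ClashReport")
}

#' @export
print.ClashReport <- function(x, ...) {
  cat(sprintf("ClashReport (%s rule): %d clashing atom pair(s)\n",
              x$rule$rule, nrow(x$clashes)))
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' Write a clash report as TSV
#' @param report a `ClashReport`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_clashes_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rule=%s vdw_slack=%g fixed_cutoff=%g",
                     report$rule$rule, report$rule$vdw_slack,
                     report$rule$fixed_cutoff), con)
  utils::write.table(report$clashes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Measure a named-atom distance in a composite model
#'
#' Euclidean distance in Angstrom between two uniquely addressed atoms
#' after all placement transforms (e.g. strand-end separations in an
#' assembled multi-component model).
#'
#' @param composite a `CompositeModel`.
#' @param selector_a,selector_b lists with `component` (`"base"` or a
#'   component name), `chain`, `resnum`, `atom`.
#' @return Numeric distance in Angstrom.
#' @export
measure_distance <- function(composite, selector_a, selector_b) {
  atoms <- composite_atoms(composite)
  resolve <- function(sel) {
    hit <- atoms$component == (sel$component %||% "base") &
      atoms$chain == sel$chain & atoms$resnum == sel$resnum &
      atoms$atom == sel$atom
    if (sum(hit) != 1L)
      fs_stop("fs_bad_selector",
              "selector %s/%s/%s/%s resolves to %d atom(s)",
              sel$component %||% "base", sel$chain, sel$resnum, sel$atom,
              sum(hit))
    as.numeric(atoms[hit, c("x", "y", "z")])
  }
  sqrt(sum((resolve(selector_a) - resolve(selector_b))^2))
}

#' Flatten a composite model into a single StructureModel
#'
#' Concatenates the base and all placed components (chain ids already
#' disambiguated) so the assembly can be written with [write_structure()].
#'
#' @param composite a `CompositeModel`.
#' @param model_id id for the flattened model.
#' @return A `StructureModel`.
#' @export
flatten_composite <- function(composite, model_id = "composite") {
  atoms <- composite_atoms(composite)
  atoms$component <- NULL
  structure_model(atoms, model_id = model_id,
                  metadata = list(
                    components = c("base",
                                   names(composite$components))))
}
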