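# Independent reference implementations ("oracles") used to cross-check the
# package: deliberately naive, loop-based, and coded without reference to
# the implementation they verify.

# All-pairs brute-force confident-contact filter: loops over every
# inter-chain residue pair, takes the min atom-atom distance by explicit
# expansion, and applies the three threshold rules one by one.
oracle_contacts <- function(model, conf, params = contact_params()) {
  stopifnot(params$atom_rule == "any_heavy")
  atoms <- model$atoms
  idx <- build_residue_index(model)
  res <- idx$table
  coords <- lapply(seq_len(nrow(res)), function(r) {
    sel <- atoms$chain == res$chain[r] & atoms$resnum == res$resnum[r]
    as.matrix(atoms[sel, c("x", "y", "z")])
  })
  out <- list()
  for (i in seq_len(nrow(res) - 1L)) for (j in (i + 1L):nrow(res)) {
    if (res$chain[i] == res$chain[j]) next
    A <- coords[[i]]; B <- coords[[j]]
    dmin <- Inf
    for (ai in seq_len(nrow(A))) for (bi in seq_len(nrow(B)))
      dmin <- min(dmin, sqrt(sum((A[ai, ] - B[bi, ])^2)))
    if (dmin >= params$distance_cutoff) next
    if (conf$plddt[i] <= params$plddt_min) next
    if (conf$plddt[j] <= params$plddt_min) next
    p_ij <- conf$pae[i, j]; p_ji <- conf$pae[j, i]
    pass <- switch(params$pae_combine,
                   min = min(p_ij, p_ji) < params$pae_max,
                   mean = (p_ij + p_ji) / 2 < params$pae_max,
                   both_must_pass = p_ij < params$pae_max &&
                     p_ji < params$pae_max)
    if (!pass) next
    # canonical order: a before b by (chain, resnum)
    a <- i; b <- j
    if (res$chain[a] > res$chain[b] ||
        (res$chain[a] == res$chain[b] && res$resnum[a] > res$resnum[b])) {
      a <- j; b <- i
    }
    out[[length(out) + 1L]] <- data.frame(
      chain_a = res$chain[a], resnum_a = res$resnum[a],
      chain_b = res$chain[b], resnum_b = res$resnum[b],
      min_distance = dmin, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain_a = character(), resnum_a = integer(),
                      chain_b = character(), resnum_b = integer(),
                      min_distance = numeric()))
  out <- do.call(rbind, out)
  out[order(out$chain_a, out$resnum_a, out$chain_b, out$resnum_b), ,
      drop = FALSE]
}

contact_pair_strings <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$chain_a, df$resnum_a, df$chain_b, df$resnum_b))
}

# Independent pDockQ evaluation: own representative-atom selection and
# double-loop contact count, direct formula evaluation.
oracle_pdockq <- function(model, conf, cutoff = 8) {
  atoms <- model$atoms
  idx <- build_residue_index(model)
  res <- idx$table
  rep_xyz <- matrix(NA_real_, nrow(res), 3L)
  for (r in seq_len(nrow(res))) {
    sel <- atoms[atoms$chain == res$chain[r] &
                   atoms$resnum == res$resnum[r], , drop = FALSE]
    row <- if ("CB" %in% sel$atom && sel$resname[1L] != "GLY")
      sel[sel$atom == "CB", ]
    else if ("CA" %in% sel$atom) sel[sel$atom == "CA", ]
    else sel[1L, ]
    rep_xyz[r, ] <- as.numeric(row[1L, c("x", "y", "z")])
  }
  n_contacts <- 0L
  iface <- logical(nrow(res))
  for (i in seq_len(nrow(res) - 1L)) for (j in (i + 1L):nrow(res)) {
    if (res$chain[i] == res$chain[j]) next
    if (sqrt(sum((rep_xyz[i, ] - rep_xyz[j, ])^2)) <= cutoff) {
      n_contacts <- n_contacts + 1L
      iface[i] <- TRUE; iface[j] <- TRUE
    }
  }
  if (n_contacts == 0L) return(0)
  x <- mean(conf$plddt[iface]) * log(n_contacts)
  0.724 / (1 + exp(-0.052 * (x - 152.611))) + 0.018
}

# Naive all-pairs clash census over a composite's atoms (anchor chains of
# placed components excluded, mirroring the census contract).
oracle_clashes <- function(composite, rule = "vdw", vdw_slack = 1.5,
                           fixed_cutoff = 2.0) {
  atoms <- foldscreen:::composite_atoms(composite)
  for (cc in composite$components) {
    anchor <- cc$chain_map[[cc$pairing$mobile_chain]]
    atoms <- atoms[!(atoms$component == cc$name & atoms$chain == anchor), ,
                   drop = FALSE]
  }
  radius <- function(e) {
    r <- foldscreen::VDW_RADII[toupper(e)]
    ifelse(is.na(r), 1.7, r)
  }
  n <- nrow(atoms)
  hits <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (atoms$component[i] == atoms$component[j]) next
    d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                (atoms$z[i] - atoms$z[j])^2)
    thr <- if (rule == "vdw")
      radius(atoms$element[i]) + radius(atoms$element[j]) - vdw_slack
    else fixed_cutoff
    if (d < thr)
      hits[[length(hits) + 1L]] <-
        sort(c(paste(atoms$component[i], atoms$chain[i], atoms$resnum[i],
                     atoms$atom[i]),
               paste(atoms$component[j], atoms$chain[j], atoms$resnum[j],
                     atoms$atom[j])))
  }
  sort(vapply(hits, paste, "", collapse = " | "))
}

clash_pair_strings <- function(report) {
  k <- report$clashes
  if (!nrow(k)) return(character())
  sort(vapply(seq_len(nrow(k)), function(i) paste(
    sort(c(paste(k$component_a[i], k$chain_a[i], k$resnum_a[i], k$atom_a[i]),
           paste(k$component_b[i], k$chain_b[i], k$resnum_b[i],
                 k$atom_b[i]))), collapse = " | "), ""))
}

# Uniform random proper rotation (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L, 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Apply a random (or given) rigid displacement to a model's coordinates.
displaced <- function(model, R = random_rotation(),
                      t = stats::rnorm(3, sd = 12)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% R, 2L, -t)
  model$atoms$x <- xyz[, 1L]; model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

# Small hand-built helical-ish test model with arbitrary chains.
toy_model <- function(chains = c(A = 4L, B = 4L), spacing = 3.8,
                      offset = 10, model_id = "toy") {
  rows <- list()
  for (k in seq_along(chains)) {
    ch <- names(chains)[k]
    for (r in seq_len(chains[k])) {
      # wobble depends on resnum only, keeping CA atoms non-collinear
      base <- c((r - 1) * spacing, (k - 1) * offset + 0.3 * sin(1.7 * r),
                0.4 * cos(1.3 * r))
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resnum = r, resname = "ALA",
        atom = c("N", "CA", "CB"), element = c("N", "C", "C"),
        x = base[1L] + c(-1.2, 0, 0.4), y = base[2L] + c(0.2, 0, 0.6),
        z = base[3L] + c(0, 0, 1.2), stringsAsFactors = FALSE)
    }
  }
  structure_model(do.call(rbind, rows), model_id = model_id)
}
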