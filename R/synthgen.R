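# Synthetic fixtures: two-chain (plus spectator-chain) complexes with a
# planted interface, confidence annotations with controllable quality, and
# M-model ensembles with controllable contact reproducibility. Geometry is
# an idealised coarse trace (one CA and, except glycine, one CB per
# residue); only inter-residue distances and confidence values matter to
# the analyses under test.

RESIDUE_SPACING <- 7    # CA-CA spacing along a chain trace, Angstrom
CHAIN_SEPARATION <- 25  # baseline inter-chain separation, Angstrom
CB_OFFSET <- 1.5        # CB displacement from CA, Angstrom

#' Specification of a synthetic two-chain interface fixture
#'
#' @param n_res_a,n_res_b residues in chains A and B.
#' @param n_true_contacts number of planted inter-chain contacts; each pairs
#'   residue i of A with residue i of B for a planted index i. Must not
#'   exceed `min(n_res_a, n_res_b)`.
#' @param contact_range target min-distance range in Angstrom for planted
#'   pairs (default 3.5-4.5); must lie inside (0, 5).
#' @param backbone_style `"extended"` (straight trace) or `"helical"`
#'   (coiled trace; stylised, not stereochemical).
#' @param n_extra_chains spectator chains placed far from the interface
#'   (for k-chain fixtures).
#' @param seed RNG seed; fixtures are byte-identical per seed.
#' @return Object of class `InterfaceSpec`.
#' @export
interface_spec <- function(n_res_a = 60, n_res_b = 60, n_true_contacts = 20,
                           contact_range = c(3.5, 4.5),
                           backbone_style = c("extended", "helical"),
                           n_extra_chains = 0, seed = 1) {
  backbone_style <- match.arg(backbone_style)
  if (n_true_contacts > min(n_res_a, n_res_b))
    fs_stop("fs_bad_argument",
            "n_true_contacts exceeds the shorter chain length")
  if (contact_range[1L] <= 0 || contact_range[2L] >= 5 ||
      contact_range[1L] > contact_range[2L])
    fs_stop("fs_bad_argument",
            "contact_range must be increasing and inside (0, 5)")
  structure(list(n_res_a = n_res_a, n_res_b = n_res_b,
                 n_true_contacts = n_true_contacts,
                 contact_range = contact_range,
                 backbone_style = backbone_style,
                 n_extra_chains = n_extra_chains, seed = seed),
            class = "InterfaceSpec")
}

#' Specification of synthetic confidence annotations
#'
#' Interface residues / planted residue pairs draw their pLDDT and PAE from
#' the `interface_*` distributions, everything else from the `background_*`
#' ones; draws are independent normals, clipped to the legal ranges
#' (pLDDT to \[0, 100\], PAE to \[0, 31.75\]) and rounded to 2 decimals
#' (the precision of prediction-score files). PAE is drawn independently in
#' each direction, so generated matrices are asymmetric like real ones.
#'
#' Defaults emulate a confidently predicted interface on an otherwise
#' moderately confident model: interface pLDDT 90 (sd 4) vs background 65
#' (sd 8); interface PAE 4 (sd 1.5) vs background 24 (sd 4) Angstrom.
#'
#' @param interface_plddt_mean,interface_plddt_sd interface pLDDT moments.
#' @param background_plddt_mean,background_plddt_sd background pLDDT moments.
#' @param interface_pae_mean,interface_pae_sd interface PAE moments (A).
#' @param background_pae_mean,background_pae_sd background PAE moments (A).
#' @param seed RNG seed.
#' @return Object of class `ConfidenceSpec`.
#' @export
confidence_spec <- function(interface_plddt_mean = 90,
                            interface_plddt_sd = 4,
                            background_plddt_mean = 65,
                            background_plddt_sd = 8,
                            interface_pae_mean = 4, interface_pae_sd = 1.5,
                            background_pae_mean = 24, background_pae_sd = 4,
                            seed = 1) {
  if (interface_plddt_mean < 0 || interface_plddt_mean > 100 ||
      background_plddt_mean < 0 || background_plddt_mean > 100)
    fs_stop("fs_bad_argument", "pLDDT means must be in [0, 100]")
  if (min(interface_plddt_sd, background_plddt_sd, interface_pae_sd,
          background_pae_sd) < 0)
    fs_stop("fs_bad_argument", "standard deviations must be >= 0")
  if (interface_pae_mean < 0 || background_pae_mean < 0)
    fs_stop("fs_bad_argument", "PAE means must be >= 0")
  structure(list(interface_plddt_mean = interface_plddt_mean,
                 interface_plddt_sd = interface_plddt_sd,
                 background_plddt_mean = background_plddt_mean,
                 background_plddt_sd = background_plddt_sd,
                 interface_pae_mean = interface_pae_mean,
                 interface_pae_sd = interface_pae_sd,
                 background_pae_mean = background_pae_mean,
                 background_pae_sd = background_pae_sd, seed = seed),
            class = "ConfidenceSpec")
}

#' Specification of a synthetic model ensemble
#'
#' @param n_models ensemble size M (default 5, the usual number of
#'   independently trained multimer prediction models).
#' @param reproducibility probability p that each true contact is rendered
#'   confident in each model, independently.
#' @param decoy_rate expected number of spurious (per-model-only) contacts
#'   planted per model (Poisson).
#' @param seed RNG seed.
#' @return Object of class `EnsembleSpec`.
#' @export
ensemble_spec <- function(n_models = 5, reproducibility = 0.9,
                          decoy_rate = 0, seed = 1) {
  if (n_models < 1) fs_stop("fs_bad_argument", "n_models must be >= 1")
  if (reproducibility < 0 || reproducibility > 1)
    fs_stop("fs_bad_argument", "reproducibility must be in [0, 1]")
  if (decoy_rate < 0) fs_stop("fs_bad_argument", "decoy_rate must be >= 0")
  structure(list(n_models = as.integer(n_models),
                 reproducibility = reproducibility,
                 decoy_rate = decoy_rate, seed = seed),
            class = "EnsembleSpec")
}

# coarse CA trace for one chain: x spaced RESIDUE_SPACING apart, plus a
# style-dependent (y, z) profile
chain_trace <- function(n, style) {
  x <- RESIDUE_SPACING * (seq_len(n) - 1L)
  if (style == "extended") {
    cbind(x = x, y = rep(0, n), z = stats::runif(n, -0.3, 0.3))
  } else {
    phi <- 1.745 * seq_len(n)  # ~100 degrees per residue
    cbind(x = x, y = cos(phi), z = sin(phi))
  }
}

res_atoms <- function(chain, resnum, resname, ca) {
  atoms <- data.frame(chain = chain, resnum = resnum, resname = resname,
                      atom = "CA", element = "C",
                      x = ca[, 1L], y = ca[, 2L], z = ca[, 3L],
                      stringsAsFactors = FALSE)
  has_cb <- resname != "GLY"
  if (any(has_cb)) {
    cb <- atoms[has_cb, ]
    cb$atom <- "CB"
    cb$z <- cb$z + CB_OFFSET
    atoms <- rbind(atoms, cb)
  }
  atoms[order(atoms$resnum, atoms$atom), ]
}

#' Generate a two-chain model with a planted interface
#'
#' Builds a deterministic coarse-trace complex in which exactly the planted
#' residue pairs (i of chain A with i of chain B, for randomly chosen
#' planted indices) have a minimum heavy-atom distance inside
#' `spec$contact_range`, and every other inter-chain residue pair is at
#' least 2 Angstrom beyond the 5 Angstrom contact cutoff. The planted
#' contact list is stored in `model$metadata$planted_contacts`.
#'
#' @param spec an [interface_spec()].
#' @return A `StructureModel` (chains `"A"`, `"B"`, then spectator chains).
#' @export
make_interface_pair <- function(spec) {
  with_seed(spec$seed, {
    resnames_a <- sample(AA3, spec$n_res_a, replace = TRUE)
    resnames_b <- sample(AA3, spec$n_res_b, replace = TRUE)
    ca_a <- chain_trace(spec$n_res_a, spec$backbone_style)
    ca_b <- chain_trace(spec$n_res_b, spec$backbone_style)
    ca_b[, "y"] <- ca_b[, "y"] + CHAIN_SEPARATION

    planted_idx <- sort(sample.int(min(spec$n_res_a, spec$n_res_b),
                                   spec$n_true_contacts))
    d <- stats::runif(spec$n_true_contacts,
                      spec$contact_range[1L], spec$contact_range[2L])
    # drop the contacted B residue onto its A partner at the target distance
    ca_b[planted_idx, ] <- ca_a[planted_idx, ]
    ca_b[planted_idx, "y"] <- ca_b[planted_idx, "y"] + d

    atoms <- rbind(res_atoms("A", seq_len(spec$n_res_a), resnames_a, ca_a),
                   res_atoms("B", seq_len(spec$n_res_b), resnames_b, ca_b))
    if (spec$n_extra_chains > 0) {
      for (k in seq_len(spec$n_extra_chains)) {
        n_k <- max(5L, round(spec$n_res_a / 2))
        ca_k <- chain_trace(n_k, spec$backbone_style)
        ca_k[, "y"] <- ca_k[, "y"] - CHAIN_SEPARATION * k
        atoms <- rbind(atoms, res_atoms(LETTERS[2L + k], seq_len(n_k),
                                        sample(AA3, n_k, replace = TRUE),
                                        ca_k))
      }
    }
    planted <- data.frame(chain_a = rep("A", spec$n_true_contacts),
                          resnum_a = planted_idx,
                          chain_b = rep("B", spec$n_true_contacts),
                          resnum_b = planted_idx,
                          distance = d, stringsAsFactors = FALSE)
    structure_model(atoms, model_id = sprintf("synth_seed%d", spec$seed),
                    metadata = list(planted_contacts = planted,
                                    interface_spec = unclass(spec)))
  })
}

#' Generate confidence annotations for a synthetic model
#'
#' Draws pLDDT and PAE from the interface vs background distributions of a
#' [confidence_spec()]: residues participating in `planted` pairs get
#' interface-quality pLDDT, planted residue pairs get interface-quality PAE
#' in both directions (drawn independently), and everything else gets
#' background values.
#'
#' @param model a `StructureModel`.
#' @param spec a [confidence_spec()].
#' @param planted data.frame of planted pairs (`chain_a`, `resnum_a`,
#'   `chain_b`, `resnum_b`); defaults to the model's
#'   `metadata$planted_contacts`.
#' @param index optional precomputed [build_residue_index()] of `model`.
#' @return A `ConfidenceBundle`.
#' @export
make_confidence <- function(model, spec = confidence_spec(),
                            planted = NULL, index = NULL) {
  planted <- planted %||% model$metadata$planted_contacts %||%
    data.frame(chain_a = character(), resnum_a = integer(),
               chain_b = character(), resnum_b = integer())
  idx <- index %||% build_residue_index(model)
  with_seed(spec$seed, draw_confidence(spec, planted, idx))
}

# unseeded core of make_confidence; callers manage the RNG stream
draw_confidence <- function(spec, planted, idx) {
  n <- nrow(idx$table)
  gi_a <- if (nrow(planted)) global_index(idx, planted$chain_a,
                                          planted$resnum_a) else integer()
  gi_b <- if (nrow(planted)) global_index(idx, planted$chain_b,
                                          planted$resnum_b) else integer()
  at_interface <- rep(FALSE, n)
  at_interface[c(gi_a, gi_b) + 1L] <- TRUE
  plddt <- stats::rnorm(n, spec$background_plddt_mean,
                        spec$background_plddt_sd)
  plddt[at_interface] <- stats::rnorm(sum(at_interface),
                                      spec$interface_plddt_mean,
                                      spec$interface_plddt_sd)
  plddt <- round(pmin(pmax(plddt, 0), 100), 2L)
  pae <- matrix(stats::rnorm(n * n, spec$background_pae_mean,
                             spec$background_pae_sd), n, n)
  if (length(gi_a)) {
    pae[cbind(gi_a + 1L, gi_b + 1L)] <-
      stats::rnorm(length(gi_a), spec$interface_pae_mean,
                   spec$interface_pae_sd)
    pae[cbind(gi_b + 1L, gi_a + 1L)] <-
      stats::rnorm(length(gi_b), spec$interface_pae_mean,
                   spec$interface_pae_sd)
  }
  diag(pae) <- 0
  pae <- round(pmin(pmax(pae, 0), 31.75), 2L)
  confidence_bundle(plddt, pae, idx)
}

#' Generate an M-model ensemble with controllable contact reproducibility
#'
#' All models share the planted geometry of `ispec` (every true contact is
#' geometrically present in every model); reproducibility is imposed through
#' the confidence annotations: each true contact is rendered confident in
#' each model independently with probability `espec$reproducibility`. A
#' non-reproduced contact gets background PAE in both directions, left-
#' truncated at `pae_ceiling` so that "not reproduced" is definitive rather
#' than subject to lucky background draws. Additionally,
#' `Poisson(espec$decoy_rate)` spurious contacts per model are planted
#' geometrically and rendered confident in that model only.
#'
#' The ensemble is deterministic given the three spec seeds: geometry comes
#' from `ispec$seed`, while per-model presence, decoys and confidence draws
#' all come from a single stream seeded with `espec$seed` (the
#' distributional parameters of `cspec` apply; its own seed is not used
#' here).
#'
#' @param ispec an [interface_spec()] for the shared pair.
#' @param cspec a [confidence_spec()].
#' @param espec an [ensemble_spec()].
#' @param pae_ceiling the PAE ceiling (Angstrom) of the contact rule the
#'   fixture is built for (default 15, the published rule).
#' @return List of M elements, each `list(model, conf)`, with the true
#'   planted contact list in `attr(, "true_contacts")`.
#' @export
make_ensemble <- function(ispec = interface_spec(),
                          cspec = confidence_spec(),
                          espec = ensemble_spec(), pae_ceiling = 15) {
  base <- make_interface_pair(ispec)
  true <- base$metadata$planted_contacts
  index <- build_residue_index(base)
  idx_b <- index$table
  free_b <- setdiff(idx_b$resnum[idx_b$chain == "B"], true$resnum_b)
  free_a <- setdiff(idx_b$resnum[idx_b$chain == "A"], true$resnum_a)

  out <- with_seed(espec$seed, lapply(seq_len(espec$n_models), function(m) {
    present <- if (nrow(true))
      stats::runif(nrow(true)) < espec$reproducibility else logical()
    n_decoy <- min(stats::rpois(1L, espec$decoy_rate),
                   length(free_a), length(free_b))
    model <- base
    model$model_id <- sprintf("%s_m%d", base$model_id, m)
    decoys <- NULL
    if (n_decoy > 0) {
      da <- sample(free_a, n_decoy)
      db <- sample(free_b, n_decoy)
      dd <- stats::runif(n_decoy, ispec$contact_range[1L],
                         ispec$contact_range[2L])
      # relocate each decoy B residue onto its A partner
      for (k in seq_len(n_decoy)) {
        src <- model$atoms$chain == "A" & model$atoms$resnum == da[k] &
          model$atoms$atom == "CA"
        tgt <- model$atoms$chain == "B" & model$atoms$resnum == db[k]
        ca <- unlist(model$atoms[src, c("x", "y", "z")])
        shift <- model$atoms$atom[tgt] == "CB"
        model$atoms$x[tgt] <- ca[1L]
        model$atoms$y[tgt] <- ca[2L] + dd[k]
        model$atoms$z[tgt] <- ca[3L] + ifelse(shift, CB_OFFSET, 0)
      }
      decoys <- data.frame(chain_a = rep("A", n_decoy), resnum_a = da,
                           chain_b = rep("B", n_decoy), resnum_b = db,
                           distance = dd, stringsAsFactors = FALSE)
    }
    confident <- rbind(true[present, c("chain_a", "resnum_a", "chain_b",
                                       "resnum_b")],
                       if (!is.null(decoys))
                         decoys[, c("chain_a", "resnum_a", "chain_b",
                                    "resnum_b")])
    conf <- draw_confidence(cspec, confident, index)
    # absent true contacts must not pass the PAE filter by chance
    absent <- true[!present, , drop = FALSE]
    if (nrow(absent)) {
      idx <- conf$index
      ga <- global_index(idx, absent$chain_a, absent$resnum_a)
      gb <- global_index(idx, absent$chain_b, absent$resnum_b)
      trunc_draw <- function(k) round(pmin(31.75, pmax(
        stats::rnorm(k, cspec$background_pae_mean, cspec$background_pae_sd),
        pae_ceiling + 0.25)), 2L)
      conf$pae[cbind(ga + 1L, gb + 1L)] <- trunc_draw(length(ga))
      conf$pae[cbind(gb + 1L, ga + 1L)] <- trunc_draw(length(gb))
    }
    model$metadata$planted_contacts <- confident
    list(model = model, conf = conf)
  }))
  attr(out, "true_contacts") <- true
  out
}
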