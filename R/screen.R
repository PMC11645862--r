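#' Screen manifest: the candidate list of a many-pair interaction screen
#'
#' A manifest names the bait, the candidate pairs, and for each pair the M
#' model/confidence inputs. Entries reference either files on disk
#' (`model_paths` / `conf_paths`, `;`-separated within a pair) or, for
#' in-memory screens, pre-built objects in the `objects` list
#' (`objects[[pair_id]] = list(models = <list>, confs = <list>)`).
#'
#' @param entries data.frame with columns `pair_id`, and either
#'   `model_paths` + `conf_paths` or nothing (when `objects` supplies all
#'   pairs).
#' @param bait_id identifier of the bait protein.
#' @param params a [contact_params()] applied to every pair.
#' @param ranking_key one of `"avg_models"`, `"avg_plddt"`, `"pdockq"`,
#'   `"classifier"`.
#' @param objects optional named list of in-memory inputs (see above).
#' @param conf_dialect confidence-file dialect passed to
#'   [read_confidence()].
#' @return Object of class `ScreenManifest`.
#' @export
screen_manifest <- function(entries, bait_id = "bait",
                            params = contact_params(),
                            ranking_key = c("avg_models", "avg_plddt",
                                            "pdockq", "classifier"),
                            objects = NULL, conf_dialect = "auto") {
  ranking_key <- match.arg(ranking_key)
  if (is.null(entries$pair_id) || nrow(entries) == 0L)
    fs_stop("fs_empty_manifest", "manifest has no entries")
  if (anyDuplicated(entries$pair_id))
    fs_stop("fs_bad_manifest", "duplicate pair_id(s): %s",
            paste(unique(entries$pair_id[duplicated(entries$pair_id)]),
                  collapse = ", "))
  has_paths <- !is.null(entries$model_paths)
  for (i in seq_len(nrow(entries))) {
    pid <- entries$pair_id[i]
    n_models <- if (!is.null(objects[[pid]]))
      length(objects[[pid]]$models)
    else if (has_paths)
      length(strsplit(entries$model_paths[i], ";", fixed = TRUE)[[1L]])
    else 0L
    if (n_models < 1L)
      fs_stop("fs_bad_manifest", "entry '%s' has no models", pid)
  }
  structure(list(bait_id = bait_id, entries = entries, params = params,
                 ranking_key = ranking_key, objects = objects,
                 conf_dialect = conf_dialect),
            class = "ScreenManifest")
}

#' Read a screen manifest from TSV
#'
#' Expected columns: `pair_id`, `model_paths`, `conf_paths` (paths
#' `;`-separated within an entry, relative paths resolved against the
#' manifest's directory).
#'
#' @param path manifest TSV.
#' @inheritParams screen_manifest
#' @return A `ScreenManifest`.
#' @export
read_manifest <- function(path, params = contact_params(),
                          ranking_key = "avg_models",
                          conf_dialect = "auto") {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(path))
  fix <- function(paths) vapply(strsplit(paths, ";", fixed = TRUE),
    function(p) paste(ifelse(grepl("^/", p), p, file.path(base, p)),
                      collapse = ";"), "")
  entries$model_paths <- fix(entries$model_paths)
  entries$conf_paths <- fix(entries$conf_paths)
  screen_manifest(entries, bait_id = attr(entries, "bait_id") %||% "bait",
                  params = params, ranking_key = ranking_key,
                  conf_dialect = conf_dialect)
}

load_entry <- function(manifest, i) {
  pid <- manifest$entries$pair_id[i]
  obj <- manifest$objects[[pid]]
  if (!is.null(obj)) return(obj)
  mp <- strsplit(manifest$entries$model_paths[i], ";", fixed = TRUE)[[1L]]
  cp <- strsplit(manifest$entries$conf_paths[i], ";", fixed = TRUE)[[1L]]
  if (length(mp) != length(cp))
    fs_stop("fs_bad_manifest",
            "entry '%s': %d model paths but %d confidence paths",
            pid, length(mp), length(cp))
  models <- lapply(mp, read_structure)
  confs <- Map(function(p, m) read_confidence(p, m, manifest$conf_dialect),
               cp, models)
  list(models = models, confs = unname(confs))
}

#' Run a many-pair interaction screen
#'
#' Scores every manifest entry with [score_pair()] and ranks the resulting
#' metrics by the manifest's ranking key. Entries that fail (unreadable
#' files, mismatched confidence, ...) are recorded with their failure
#' reason and excluded from the ranking rather than aborting the screen.
#'
#' @param manifest a [screen_manifest()].
#' @param classifier optional external scorer passed to [score_pair()].
#' @param thresholds a [threshold_table()].
#' @param progress emit one `message()` per pair.
#' @return A `ScreenResult`: list with `rows` (ranked data.frame, see
#'   [metrics_row()], plus a `rank` column), `metrics` (named list of
#'   `InterfaceMetrics`), `failures` (data.frame `pair_id`, `reason`),
#'   `ranking_key`, `params`, and `run_info` (timestamp, package version).
#' @export
run_screen <- function(manifest, classifier = NULL,
                       thresholds = threshold_table(), progress = FALSE) {
  if (!inherits(manifest, "ScreenManifest"))
    fs_stop("fs_bad_argument", "manifest must be a ScreenManifest")
  n <- nrow(manifest$entries)
  metrics <- list()
  failures <- data.frame(pair_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pid <- manifest$entries$pair_id[i]
    if (progress) message(sprintf("[%d/%d] %s", i, n, pid))
    res <- tryCatch({
      inp <- load_entry(manifest, i)
      score_pair(inp$models, inp$confs, params = manifest$params,
                 pair_id = pid, classifier = classifier,
                 thresholds = thresholds)
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures <- rbind(failures, data.frame(
        pair_id = pid, reason = conditionMessage(res),
        stringsAsFactors = FALSE))
    else metrics[[pid]] <- res
  }
  if (!length(metrics))
    fs_stop("fs_screen_failed", "every screen entry failed")
  rank_rows(metrics, manifest$ranking_key,
            bait_id = manifest$bait_id, params = manifest$params,
            failures = failures)
}

#' Rank per-pair interface metrics
#'
#' Sorts pairs in descending order of the chosen metric; ties are broken by
#' `pair_id` ascending, so rankings are deterministic and re-ranking an
#' already-ranked result is idempotent. `NA` values of `avg_plddt`,
#' `avg_pae` or `pdockq` arising from zero-contact interfaces are a defined
#' "no measurable interface" outcome and sort below every number. Ranking
#' by `"classifier"` requires a classifier score on every pair; pairs
#' without one are an error.
#'
#' @param metrics list of `InterfaceMetrics` (or a `ScreenResult` to
#'   re-rank).
#' @param key ranking key: `"avg_models"`, `"avg_plddt"`, `"pdockq"` or
#'   `"classifier"`.
#' @param bait_id,params,failures run metadata carried into the result.
#' @return A `ScreenResult` (see [run_screen()]); `rows$rank` is `1..n`
#'   with no gaps.
#' @export
rank_rows <- function(metrics, key = c("avg_models", "avg_plddt", "pdockq",
                                       "classifier"),
                      bait_id = "bait", params = NULL, failures = NULL) {
  key <- match.arg(key)
  if (inherits(metrics, "ScreenResult")) {
    bait_id <- metrics$bait_id
    params <- metrics$params
    failures <- metrics$failures
    metrics <- metrics$metrics
  }
  if (!length(metrics)) fs_stop("fs_bad_argument", "no metrics to rank")
  rows <- metrics_row(metrics)
  if (key == "classifier" && anyNA(rows$classifier))
    fs_stop("fs_missing_key",
            "classifier scores missing for pair(s): %s",
            paste(rows$pair_id[is.na(rows$classifier)], collapse = ", "))
  val <- rows[[key]]
  val[is.na(val)] <- -Inf
  ord <- order(-val, rows$pair_id)
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  structure(list(rows = rows, metrics = metrics[rows$pair_id],
                 failures = failures %||%
                   data.frame(pair_id = character(), reason = character()),
                 ranking_key = key, bait_id = bait_id, params = params,
                 run_info = list(
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package = "foldscreen",
                   version = as.character(utils::packageVersion("foldscreen")))),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("ScreenResult: %d ranked pair(s) by %s (bait: %s)\n",
              nrow(x$rows), x$ranking_key, x$bait_id))
  print(utils::head(x$rows[, c("rank", "pair_id", "n_contacts",
                               "avg_plddt", "avg_pae", "avg_models",
                               "pdockq")], 10L))
  if (nrow(x$failures))
    cat(sprintf("  %d failed entr%s (see $failures)\n", nrow(x$failures),
                ifelse(nrow(x$failures) == 1L, "y", "ies")))
  invisible(x)
}

#' Write a ranked screen result as TSV (+ metadata sidecar)
#'
#' Writes the ranked table to `path` and a machine-readable JSON sidecar
#' (`<path>.meta.json`) recording the run configuration: contact
#' parameters, ranking key, bait, timestamp, package version and failures.
#'
#' @param result a `ScreenResult`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_screen_tsv <- function(result, path) {
  utils::write.table(result$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(bait_id = result$bait_id, ranking_key = result$ranking_key,
               params = unclass(result$params), run_info = result$run_info,
               failures = result$failures)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic screen with planted true interactors
#'
#' Builds `n_decoys` non-interacting candidate pairs and `n_true` strong
#' interactors, each as an M-model ensemble, and returns a ready-to-run
#' [screen_manifest()]. True pairs use `true_*` specs (planted interface,
#' confident annotations, high reproducibility); decoys have no planted
#' interface and only rare, mediocre, per-model spurious contacts.
#'
#' With `materialize = "files"` (the default) every model is written as a
#' PDB with pLDDT in the B-factor column plus a scores-JSON confidence
#' file, and the manifest references those files; `"memory"` skips the disk
#' round-trip and stores the objects in the manifest, which is what the
#' large repeated-seed simulations use.
#'
#' @param n_decoys,n_true candidate counts (defaults 100 and 5).
#' @param dir output directory for `materialize = "files"`.
#' @param seed screen-level seed; per-pair seeds are derived from it.
#' @param materialize `"files"` or `"memory"`.
#' @param true_ispec,true_cspec,true_espec specs for true interactors
#'   (defaults: 40+40 residues, 20 planted contacts, confident annotations,
#'   reproducibility 0.9).
#' @param decoy_ispec,decoy_cspec,decoy_espec specs for decoys (defaults:
#'   no planted contacts; 0.5 spurious contacts per model with mediocre
#'   confidence, pLDDT ~60 and PAE ~11).
#' @param params contact parameters recorded in the manifest.
#' @param ranking_key manifest ranking key.
#' @return A `ScreenManifest` with attribute `"true_pairs"` naming the
#'   planted true pair ids.
#' @export
make_screen <- function(n_decoys = 100, n_true = 5, dir = NULL, seed = 1,
                        materialize = c("files", "memory"),
                        true_ispec = interface_spec(n_res_a = 40,
                                                    n_res_b = 40,
                                                    n_true_contacts = 20),
                        true_cspec = confidence_spec(),
                        true_espec = ensemble_spec(reproducibility = 0.9),
                        decoy_ispec = interface_spec(n_res_a = 40,
                                                     n_res_b = 40,
                                                     n_true_contacts = 0),
                        decoy_cspec = confidence_spec(
                          interface_plddt_mean = 60, interface_plddt_sd = 3,
                          interface_pae_mean = 11, interface_pae_sd = 1),
                        decoy_espec = ensemble_spec(reproducibility = 0,
                                                    decoy_rate = 0.5),
                        params = contact_params(),
                        ranking_key = "avg_models") {
  materialize <- match.arg(materialize)
  if (materialize == "files") {
    if (is.null(dir)) fs_stop("fs_bad_argument",
                              "dir is required for materialize = 'files'")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir))
      fs_stop("fs_unwritable", "cannot create directory %s", dir)
  }
  ids <- c(sprintf("true_%03d", seq_len(n_true)),
           sprintf("decoy_%03d", seq_len(n_decoys)))
  is_true <- c(rep(TRUE, n_true), rep(FALSE, n_decoys))
  pair_seeds <- with_seed(seed, sample.int(2^20, length(ids)))

  objects <- list()
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    ispec <- if (is_true[k]) true_ispec else decoy_ispec
    cspec <- if (is_true[k]) true_cspec else decoy_cspec
    espec <- if (is_true[k]) true_espec else decoy_espec
    ispec$seed <- pair_seeds[k]
    cspec$seed <- pair_seeds[k] + 1L
    espec$seed <- pair_seeds[k] + 2L
    ens <- make_ensemble(ispec, cspec, espec)
    if (materialize == "memory") {
      objects[[ids[k]]] <- list(models = lapply(ens, `[[`, "model"),
                                confs = lapply(ens, `[[`, "conf"))
      rows[[k]] <- data.frame(pair_id = ids[k], stringsAsFactors = FALSE)
    } else {
      mp <- cp <- character(length(ens))
      for (m in seq_along(ens)) {
        stem <- file.path(dir, sprintf("%s_model%d", ids[k], m))
        mod <- set_bfactor_plddt(ens[[m]]$model, ens[[m]]$conf)
        write_structure(mod, paste0(stem, ".pdb"))
        write_confidence(ens[[m]]$conf, paste0(stem, ".json"))
        mp[m] <- paste0(stem, ".pdb")
        cp[m] <- paste0(stem, ".json")
      }
      rows[[k]] <- data.frame(pair_id = ids[k],
                              model_paths = paste(mp, collapse = ";"),
                              conf_paths = paste(cp, collapse = ";"),
                              stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  if (materialize == "files")
    utils::write.table(entries, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest <- screen_manifest(entries, bait_id = "synthetic_bait",
                              params = params, ranking_key = ranking_key,
                              objects = if (length(objects)) objects)
  attr(manifest, "true_pairs") <- ids[is_true]
  manifest
}
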