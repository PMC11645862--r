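#' Run configuration for pipeline invocations
#'
#' Bundles everything a reproducible run needs: contact parameters, the
#' confidence threshold table, the ranking key, the clash rule, and the
#' seed. The configuration is validated on construction and serialised
#' verbatim into every output's metadata sidecar.
#'
#' @param params a [contact_params()].
#' @param thresholds a [threshold_table()].
#' @param ranking_key screen ranking key.
#' @param clash_rule `"vdw"` or `"fixed"`.
#' @param vdw_slack,fixed_cutoff clash-rule parameters (Angstrom).
#' @param seed integer seed for generators.
#' @param log_level `"quiet"` or `"progress"`.
#' @return Object of class `RunConfig`.
#' @export
run_config <- function(params = contact_params(),
                       thresholds = threshold_table(),
                       ranking_key = c("avg_models", "avg_plddt", "pdockq",
                                       "classifier"),
                       clash_rule = c("vdw", "fixed"), vdw_slack = 1.5,
                       fixed_cutoff = 2.0, seed = 1,
                       log_level = c("quiet", "progress")) {
  ranking_key <- match.arg(ranking_key)
  clash_rule <- match.arg(clash_rule)
  log_level <- match.arg(log_level)
  if (!inherits(params, "ContactParams"))
    fs_stop("fs_bad_argument", "params must be a ContactParams")
  for (nm in c("avg_plddt", "avg_models", "pdockq", "classifier"))
    if (is.null(thresholds[[nm]]) || !is.numeric(thresholds[[nm]]))
      fs_stop("fs_bad_argument", "thresholds is missing '%s'", nm)
  structure(list(params = params, thresholds = thresholds,
                 ranking_key = ranking_key, clash_rule = clash_rule,
                 vdw_slack = vdw_slack, fixed_cutoff = fixed_cutoff,
                 seed = as.integer(seed), log_level = log_level),
            class = "RunConfig")
}

#' Read a run configuration from JSON
#' @param path JSON file with (a subset of) the [run_config()] fields.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  p <- obj$params %||% list()
  params <- contact_params(
    distance_cutoff = p$distance_cutoff %||% 5,
    plddt_min = p$plddt_min %||% 50,
    pae_max = p$pae_max %||% 15,
    pae_combine = p$pae_combine %||% "min",
    atom_rule = p$atom_rule %||% "any_heavy")
  th <- obj$thresholds %||% list()
  run_config(params = params,
             thresholds = threshold_table(
               avg_plddt = th$avg_plddt %||% 70,
               avg_models = th$avg_models %||% 0.5,
               pdockq = th$pdockq %||% 0.23,
               classifier = th$classifier %||% 0.5),
             ranking_key = obj$ranking_key %||% "avg_models",
             clash_rule = obj$clash_rule %||% "vdw",
             vdw_slack = obj$vdw_slack %||% 1.5,
             fixed_cutoff = obj$fixed_cutoff %||% 2.0,
             seed = obj$seed %||% 1,
             log_level = obj$log_level %||% "quiet")
}

#' Write a run configuration sidecar
#' @param config a `RunConfig`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$params <- unclass(out$params)
  out$package <- "foldscreen"
  out$version <- as.character(utils::packageVersion("foldscreen"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
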