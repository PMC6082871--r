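#' Read and write force-clamp trajectories
#'
#' Trajectories are stored as a TSV of the sampled channels (`time_s`,
#' `force_pN`, `extension_nm`, `segment_id`, `segment_label`) plus a JSON
#' sidecar (`<stem>.json`) carrying the protocol, compound name, seed,
#' ground-truth events and simulator configuration. The round trip is
#' lossless at full double precision; diff-friendly text formats are used
#' because trajectories are small (at most ~60 s at 1 kHz).
#'
#' @param trajectory An `fc_trajectory`.
#' @param path TSV file path; the sidecar path is derived from it.
#' @param compound_table Parameter table used to resolve the sidecar's
#'   compound name on read.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the reconstructed `fc_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  # format doubles at 17 significant digits so the text round trip is exact
  out <- as_tibble(trajectory)
  out <- mutate(out, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)
  ))
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  sidecar <- list(
    compound_name = attr(trajectory, "compound_name"),
    seed = attr(trajectory, "seed"),
    protocol = as.data.frame(attr(trajectory, "protocol")),
    true_events = as.data.frame(attr(trajectory, "true_events")),
    config = unclass(attr(trajectory, "config")),
    units = list(
      time_s = "s", force_pN = "pN", extension_nm = "nm", size_nm = "nm"
    )
  )
  qo <- attr(trajectory, "quench_outcomes")
  if (!is.null(qo)) sidecar$quench_outcomes <- as.data.frame(qo)
  jsonlite::write_json(
    sidecar, sidecar_path(path),
    auto_unbox = TRUE, digits = I(17), null = "null"
  )
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, compound_table = forcequench::compound_table()) {
  tbl <- as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  req <- c("time_s", "force_pN", "extension_nm", "segment_id", "segment_label")
  missing <- setdiff(req, names(tbl))
  if (length(missing)) {
    abort(paste0("trajectory TSV is missing columns: ", paste(missing, collapse = ", ")))
  }
  dt <- diff(tbl$time_s)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-9) {
    abort("non-uniform or non-increasing time axis")
  }
  sp <- sidecar_path(path)
  if (!file.exists(sp)) abort(paste0("missing JSON sidecar: ", sp))
  side <- jsonlite::fromJSON(sp)
  compound <- as_compound(get_compound(side$compound_name, compound_table))
  protocol <- new_protocol(
    side$protocol$force_pN, side$protocol$duration_s, side$protocol$label
  )
  cfg <- do.call(sim_config, side$config)
  extra <- list()
  if (!is.null(side$quench_outcomes)) {
    extra$quench_outcomes <- as_tibble(side$quench_outcomes)
  }
  new_trajectory(
    tbl$time_s, tbl$force_pN, tbl$segment_id, tbl$segment_label,
    tbl$extension_nm,
    true_events = as_tibble(side$true_events),
    protocol = protocol, compound = compound,
    seed = as.integer(side$seed), config = cfg, extra = extra
  )
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write a run manifest
#'
#' Records what a cohort run consisted of: a digest of the resolved
#' configuration, the root seed, the per-trajectory output paths and the
#' package version, so a run is reconstructible from the manifest alone.
#'
#' @param manifest Tibble of per-trajectory records (from
#'   [generate_cohort()]).
#' @param config The `fc_sim_config` used.
#' @param dir Output directory.
#' @return The manifest file path, invisibly.
#' @export
write_manifest <- function(manifest, config, dir) {
  out <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("forcequench")),
    config = unclass(config),
    trajectories = as.data.frame(manifest)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
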