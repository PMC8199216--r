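#' Read an analysis configuration (YAML or JSON)
#'
#' The configuration declares the ligand, the interaction channels
#' (kind, label, participant selectors) and any cutoff overrides, plus
#' optional superposition selections for the RMSD trace. Format is
#' chosen by extension (`.yml`/`.yaml` vs `.json`).
#'
#' Schema (YAML shown):
#' \preformatted{
#' compound: A366-like
#' ligand: "LIG 1 *"
#' cutoffs:            # optional overrides of interaction_spec() defaults
#'   salt_bridge_cutoff: 4.0
#' superposition:      # optional; defaults shown
#'   fit: "* * N,CA,C,O"
#'   report: ligand-heavy
#' channels:
#'   - kind: salt_bridge
#'     label: amidine-Asp184 salt bridge
#'     anion_oxygens: "ASP 184 OD1,OD2"
#'     cation_nitrogens: "LIG 1 NH1,NH2"
#'   - kind: cation_pi
#'     label: pyrrolidinium-Phe141 cation-pi
#'     cation: "LIG 1 NP"
#'     rings: ["PHE 141 CG,CD1,CE1,CZ,CE2,CD2"]
#' }
#' The special report selector `ligand-heavy` means all non-hydrogen
#' atoms matched by the `ligand` selector.
#'
#' @param path config file path.
#' @return list of class `analysis_config` with elements `compound`,
#'   `ligand`, `spec` (an [interaction_spec()]), `channels` (list of
#'   [channel()]), `fit_selector`, `report_selector`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_input("read_analysis_config: no such file: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  as_analysis_config(raw)
}

as_analysis_config <- function(raw) {
  if (is.null(raw$channels) || !length(raw$channels))
    stop_config("analysis config: no channels declared")
  spec <- do.call(interaction_spec, as.list(raw$cutoffs %||% list()))
  channels <- lapply(raw$channels, function(cd) {
    cd <- as.list(cd)
    if (is.null(cd$kind) || is.null(cd$label))
      stop_config("analysis config: every channel needs 'kind' and 'label'")
    do.call(channel, c(list(kind = cd$kind, label = cd$label),
                       cd[setdiff(names(cd), c("kind", "label"))]))
  })
  structure(list(compound = raw$compound %||% "compound",
                 ligand = raw$ligand %||% "LIG * *",
                 spec = spec,
                 channels = channels,
                 fit_selector = raw$superposition$fit %||% "* * N,CA,C,O",
                 report_selector = raw$superposition$report %||% "ligand-heavy"),
            class = "analysis_config")
}

#' Write an analysis configuration
#'
#' @param config an `analysis_config` (or the raw list form).
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  raw <- if (inherits(config, "analysis_config")) {
    list(compound = config$compound,
         ligand = config$ligand,
         cutoffs = unclass(config$spec),
         superposition = list(fit = config$fit_selector,
                              report = config$report_selector),
         channels = lapply(config$channels, function(ch)
           c(list(kind = ch$kind, label = ch$label), ch$roles)))
  } else config
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(raw, path)
  invisible(path)
}

#' Default analysis configuration for the toy complex
#'
#' Convenience wrapper producing the `analysis_config` matching
#' [make_toy_complex()], used by the simulate-then-analyze round trip.
#'
#' @param tpl a [make_toy_complex()] template.
#' @param compound compound label.
#' @return an `analysis_config`.
#' @export
toy_analysis_config <- function(tpl = make_toy_complex(),
                                compound = "toy-compound") {
  structure(list(compound = compound,
                 ligand = "LIG 1 *",
                 spec = tpl$spec,
                 channels = tpl$channels,
                 fit_selector = "* * N,CA,C,O",
                 report_selector = "ligand-heavy"),
            class = "analysis_config")
}

# Resolve the fit/report selectors of a config against a trajectory.
# "ligand-heavy": non-hydrogen atoms of the ligand selection. The fit
# selector must not match ligand atoms (backbone names never do here).
resolve_config_selections <- function(traj, config) {
  lig <- resolve_selection(traj, config$ligand)
  fit <- setdiff(resolve_selection(traj, config$fit_selector), lig)
  if (length(fit) < 3L)
    stop_config("analysis config: fit selection resolves to %d atoms (need >= 3)",
                length(fit))
  rep_idx <- if (identical(config$report_selector, "ligand-heavy")) {
    lig[traj$atoms$element[lig] != "H"]
  } else resolve_selection(traj, config$report_selector)
  if (length(rep_idx) < 1L)
    stop_config("analysis config: report selection is empty")
  list(fit = fit, report = rep_idx, ligand = lig)
}
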