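#' Pipeline entry points with run manifests
#'
#' The four orchestration steps behind the command-line interface:
#' analyze a trajectory, simulate one, fit an assay plate, and run the
#' score-discrimination statistics. Every run writes a `manifest.json`
#' next to its outputs recording input paths and digests, the cutoffs
#' actually applied, the package version, the seed and a timestamp, so
#' no default is silent.
#'
#' @name pipeline
NULL

write_manifest <- function(out_dir, inputs, extra = list()) {
  digests <- lapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  manifest <- c(list(package = "plifr",
                     version = as.character(utils::packageVersion("plifr")),
                     inputs = inputs, input_md5 = digests,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_input("cannot create output directory %s", out_dir)
  out_dir
}

#' Analyze a trajectory: occupancies and RMSD trace
#'
#' Reads a multi-model PDB trajectory and an analysis config, evaluates
#' every declared channel on every frame, and writes `occupancy.csv`,
#' `rmsd_trace.csv`, the per-frame `events.csv` and a manifest to
#' `out_dir`.
#'
#' @param traj_path multi-model PDB path.
#' @param config_path analysis config (YAML/JSON) path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `occupancy` (an [occupancy()]
#'   report), `rmsd` (an [rmsd_trace()]) and the output paths.
#' @export
run_analyze <- function(traj_path, config_path, out_dir) {
  traj <- read_multimodel_pdb(traj_path)
  config <- read_analysis_config(config_path)
  ensure_out_dir(out_dir)
  em <- build_event_matrix(traj, config$channels, config$spec)
  occ <- occupancy(em, compound = config$compound)
  sel <- resolve_config_selections(traj, config)
  tr <- rmsd_trace(traj, sel$fit, sel$report)
  paths <- c(occupancy = file.path(out_dir, "occupancy.csv"),
             rmsd = file.path(out_dir, "rmsd_trace.csv"),
             events = file.path(out_dir, "events.csv"))
  write_report(occ, paths[["occupancy"]])
  write_report(tr, paths[["rmsd"]])
  utils::write.csv(as.data.frame(unclass(em)[, , drop = FALSE]),
                   paths[["events"]], row.names = FALSE)
  write_manifest(out_dir,
                 inputs = list(trajectory = traj_path, config = config_path),
                 extra = list(cutoffs = unclass(config$spec),
                              compound = config$compound,
                              n_frames = n_frames(traj),
                              channels = vapply(config$channels,
                                                function(ch) ch$label,
                                                character(1)),
                              fit_selector = config$fit_selector,
                              report_selector = config$report_selector))
  invisible(list(occupancy = occ, rmsd = tr, paths = paths))
}

#' Simulate a trajectory and write it with its matching config
#'
#' Builds the toy complex, simulates `n_frames` with the plan's planted
#' occupancies, and writes `trajectory.pdb`, `config.yml`, the realized
#' per-frame states (`states.csv`) and a manifest. Running
#' [run_analyze()] on the outputs recovers the planted occupancies.
#'
#' @param plan a [channel_plan()], or path to a YAML/JSON file with
#'   fields `probs`, `jitter_sd`, `jitter_rot_deg`.
#' @param n_frames frames to simulate.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return invisibly, list with the `trajectory`, the realized `states`
#'   matrix and the output paths.
#' @export
run_simulate <- function(plan = channel_plan(), n_frames = 1000L, seed = 1L,
                         out_dir) {
  if (is.character(plan)) {
    raw <- if (grepl("\\.json$", plan, TRUE)) jsonlite::fromJSON(plan)
           else yaml::read_yaml(plan)
    plan <- channel_plan(probs = unlist(raw$probs),
                         jitter_sd = raw$jitter_sd %||% 0.3,
                         jitter_rot_deg = raw$jitter_rot_deg %||% 2)
  }
  ensure_out_dir(out_dir)
  tpl <- make_toy_complex()
  traj <- simulate_trajectory(tpl, plan, n_frames = n_frames, seed = seed)
  paths <- c(trajectory = file.path(out_dir, "trajectory.pdb"),
             config = file.path(out_dir, "config.yml"),
             states = file.path(out_dir, "states.csv"))
  write_multimodel_pdb(traj, paths[["trajectory"]])
  write_analysis_config(toy_analysis_config(tpl), paths[["config"]])
  utils::write.csv(as.data.frame(attr(traj, "states")), paths[["states"]],
                   row.names = FALSE)
  write_manifest(out_dir, inputs = list(),
                 extra = list(seed = seed, n_frames = n_frames,
                              planted = as.list(plan$probs),
                              jitter_sd = plan$jitter_sd,
                              jitter_rot_deg = plan$jitter_rot_deg))
  invisible(list(trajectory = traj, states = attr(traj, "states"),
                 paths = paths))
}

# Assay CSV -> per-compound inhibition table. Two schemas:
#  (a) compound, concentration, replicate, inhibition
#  (b) compound, concentration, replicate, i_s, i_p [, g][, well_type]
#      where well_type in {sample, negative, positive}; control rows
#      supply P_neg / P_pos and need no concentration.
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop_input("read_assay_csv: no such file: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!("compound" %in% names(d))) d$compound <- "cmpd"
  if ("inhibition" %in% names(d)) {
    if (!all(c("concentration") %in% names(d)))
      stop_input("read_assay_csv: need a 'concentration' column")
    return(d[, intersect(c("compound", "concentration", "replicate",
                           "inhibition"), names(d))])
  }
  if (!all(c("i_s", "i_p") %in% names(d)))
    stop_input("read_assay_csv: need either an 'inhibition' column or 'i_s'/'i_p' columns")
  g <- if ("g" %in% names(d)) d$g else 1
  d$mp <- polarization_mP(d$i_s, d$i_p, g = if (length(unique(g)) == 1L) unique(g) else 1)
  if (!("well_type" %in% names(d)))
    stop_input("read_assay_csv: intensity input needs a 'well_type' column (sample/negative/positive)")
  out <- do.call(rbind, lapply(split(d, d$compound), function(dd) {
    p_neg <- mean(dd$mp[dd$well_type == "negative"])
    p_pos <- mean(dd$mp[dd$well_type == "positive"])
    if (!is.finite(p_neg) || !is.finite(p_pos))
      stop_input("read_assay_csv: compound '%s' lacks negative/positive control wells",
                 dd$compound[1L])
    s <- dd[dd$well_type == "sample", , drop = FALSE]
    data.frame(compound = s$compound, concentration = s$concentration,
               replicate = s$replicate %||% seq_len(nrow(s)),
               inhibition = percent_inhibition(s$mp, p_neg, p_pos),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit dose-response curves for every compound on a plate
#'
#' Reads an assay CSV (pre-computed inhibition, or raw S/P intensities
#' with control wells), fits the variable-slope sigmoidal model per
#' compound and writes `fits.csv`, per-compound JSON fit reports and a
#' manifest. Non-convergent or degenerate compounds are flagged in the
#' output and the run continues.
#'
#' @param csv_path assay CSV path.
#' @param out_dir output directory.
#' @param average_replicates passed to [fit_4pl()].
#' @return invisibly, list of `fit_4pl` objects (or `NULL` for
#'   degenerate compounds) named by compound, plus the summary table.
#' @export
run_assay <- function(csv_path, out_dir, average_replicates = FALSE) {
  d <- read_assay_csv(csv_path)
  ensure_out_dir(out_dir)
  fits <- list(); rows <- list()
  for (cmp in unique(d$compound)) {
    dd <- d[d$compound == cmp, , drop = FALSE]
    fit <- tryCatch(fit_4pl(dd$concentration, dd$inhibition,
                            average_replicates = average_replicates),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("run_assay: compound '%s' not fitted: %s",
                      cmp, conditionMessage(fit)))
      fits[[cmp]] <- NULL
      rows[[cmp]] <- data.frame(compound = cmp, ic50 = NA_real_,
                                hill = NA_real_, top = NA_real_,
                                bottom = NA_real_, converged = FALSE,
                                note = conditionMessage(fit))
    } else {
      fits[[cmp]] <- fit
      co <- fit$coefficients
      rows[[cmp]] <- data.frame(compound = cmp, ic50 = co[["ic50"]],
                                hill = co[["hill"]], top = co[["top"]],
                                bottom = co[["bottom"]],
                                converged = fit$converged, note = "")
      write_report(fit, file.path(out_dir, paste0("fit_", cmp, ".json")))
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  utils::write.csv(tab, file.path(out_dir, "fits.csv"), row.names = FALSE)
  write_manifest(out_dir, inputs = list(assay_csv = csv_path),
                 extra = list(average_replicates = average_replicates,
                              model = "4PL variable slope",
                              initialization = "top/bottom from data range, IC50 from half-response concentration, hill = 1"))
  invisible(list(fits = fits, table = tab))
}

#' Score discrimination statistics per score kind
#'
#' Reads a scores CSV (`compound, score, kind, activity`), computes
#' group statistics and single-threshold separation per score kind,
#' ranks the kinds, and writes `group_stats.csv`, `ranking.csv` and a
#' manifest. A kind missing one of the activity groups is skipped with
#' a warning.
#'
#' @param csv_path scores CSV path.
#' @param out_dir output directory.
#' @return invisibly, list with `stats` (per-kind `group_stats`),
#'   `separation` (per-kind), and `ranking` (when >= 2 kinds survive).
#' @export
run_discriminate <- function(csv_path, out_dir) {
  if (!file.exists(csv_path)) stop_input("run_discriminate: no such file: %s", csv_path)
  d <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("compound", "score", "activity")
  if (!all(need %in% names(d)))
    stop_input("run_discriminate: CSV needs columns %s", paste(need, collapse = ", "))
  if (!("kind" %in% names(d))) d$kind <- "score"
  ensure_out_dir(out_dir)
  kinds <- unique(d$kind)
  stats_l <- list(); sep_l <- list(); gs_rows <- list()
  for (k in kinds) {
    tab <- tryCatch(score_table(d$compound[d$kind == k], d$score[d$kind == k],
                                d$activity[d$kind == k], kind = k),
                    error = function(e) e)
    ok <- !inherits(tab, "error") &&
      all(c("active", "inactive") %in% tab$activity)
    if (!ok) {
      warning(sprintf("run_discriminate: kind '%s' skipped (%s)", k,
                      if (inherits(tab, "error")) conditionMessage(tab)
                      else "needs both activity groups"))
      next
    }
    gs <- group_summary(tab)
    stats_l[[k]] <- gs
    sep_l[[k]] <- separation_assessment(tab)
    gs_rows[[k]] <- cbind(kind = k, as.data.frame(gs),
                          gap = attr(gs, "gap"))
  }
  if (!length(stats_l))
    stop_input("run_discriminate: no score kind had both activity groups")
  utils::write.csv(do.call(rbind, c(gs_rows, make.row.names = FALSE)),
                   file.path(out_dir, "group_stats.csv"), row.names = FALSE)
  ranking <- NULL
  if (length(stats_l) >= 2L) {
    ranking <- compare_score_kinds(d[d$kind %in% names(stats_l), ])
    utils::write.csv(as.data.frame(ranking),
                     file.path(out_dir, "ranking.csv"), row.names = FALSE)
  }
  write_manifest(out_dir, inputs = list(scores_csv = csv_path),
                 extra = list(quartile_method = "type 7",
                              kinds = names(stats_l)))
  invisible(list(stats = stats_l, separation = sep_l, ranking = ranking))
}

#' Heat map across several analyzed compounds
#'
#' Convenience step for multi-compound studies: stack per-compound
#' occupancy reports into the heat-map matrix and write it as CSV (the
#' canonical artifact; rendering is cosmetic).
#'
#' @param reports named list of [occupancy()] reports.
#' @param path output CSV path.
#' @return the [heatmap_matrix()], invisibly.
#' @export
write_heatmap <- function(reports, path) {
  hm <- heatmap_matrix(reports)
  write_report(hm, path)
  invisible(hm)
}
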