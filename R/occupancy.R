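#' Event matrix: per-frame booleans for every channel
#'
#' Evaluates every channel on every frame of the trajectory and returns
#' the frames x channels boolean event matrix from which occupancies are
#' computed.
#'
#' @param traj a [trajectory()].
#' @param channels list of [channel()] objects (labels must be unique).
#' @param spec an [interaction_spec()].
#' @return logical matrix `n_frames x n_channels` of class
#'   `event_matrix`, columns named by channel label, with the spec
#'   attached as attribute `spec`.
#' @export
build_event_matrix <- function(traj, channels, spec = interaction_spec()) {
  labels <- vapply(channels, function(ch) ch$label, character(1))
  if (anyDuplicated(labels))
    stop_config("build_event_matrix: duplicate channel label '%s'",
                labels[duplicated(labels)][1L])
  m <- matrix(logical(0), nrow = n_frames(traj), ncol = length(channels))
  if (length(channels))
    m <- vapply(channels, function(ch) evaluate_channel(traj, ch, spec),
                logical(n_frames(traj)))
  if (is.null(dim(m))) m <- matrix(m, nrow = n_frames(traj))
  dimnames(m) <- list(NULL, labels)
  structure(m, class = c("event_matrix", class(m)), spec = spec)
}

#' Per-channel occupancy report
#'
#' Occupancy of a channel is the percent of trajectory frames in which
#' its geometric criteria are satisfied: `100 * event_count /
#' frame_count`, computed exactly from integer counts (no intermediate
#' rounding); formatting to one decimal happens only at print time.
#'
#' @param matrix an `event_matrix` from [build_event_matrix()].
#' @param compound optional compound label carried into reports.
#' @param spec the [interaction_spec()] the events were detected with;
#'   taken from the event matrix when present.
#' @return data.frame of class `occupancy_report` with columns
#'   `channel`, `events`, `frames`, `occupancy_pct`; the detection spec
#'   is attached as attribute `spec`, the compound label as `compound`.
#' @export
occupancy <- function(matrix, compound = NULL,
                      spec = attr(matrix, "spec", exact = TRUE)) {
  if (nrow(matrix) < 1L)
    stop_data("occupancy: zero frames; occupancy is undefined")
  events <- as.integer(colSums(matrix))
  rep <- data.frame(channel = colnames(matrix) %||% character(0),
                    events = events,
                    frames = rep.int(nrow(matrix), length(events)),
                    occupancy_pct = 100 * events / nrow(matrix),
                    stringsAsFactors = FALSE)
  structure(rep, class = c("occupancy_report", "data.frame"),
            spec = spec, compound = compound)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occupancy_report <- function(x, ...) {
  cmp <- attr(x, "compound")
  cat(sprintf("Interaction occupancies%s (%d frames):\n",
              if (!is.null(cmp)) paste0(" for ", cmp) else "",
              if (nrow(x)) x$frames[1L] else 0L))
  if (nrow(x) == 0L) { cat("  (no channels)\n"); return(invisible(x)) }
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-28s %6.1f %%  (%d/%d frames)\n",
                x$channel[i], x$occupancy_pct[i], x$events[i], x$frames[i]))
  invisible(x)
}

#' Heat-map matrix of occupancies across compounds
#'
#' Stacks per-compound occupancy reports into a compounds x channels
#' percentage matrix, the tabular analogue of an interaction-occupancy
#' heat map. A channel missing from a compound's report yields `NA`
#' (an empty cell, deliberately distinct from an observed 0 %).
#'
#' @param reports named list of [occupancy()] reports; names (or the
#'   reports' `compound` attributes) are the row labels.
#' @return numeric matrix of class `occupancy_heatmap`, rows =
#'   compounds, columns = union of channel labels in input order.
#' @export
heatmap_matrix <- function(reports) {
  labels <- names(reports)
  if (is.null(labels))
    labels <- vapply(reports, function(r) attr(r, "compound") %||% NA_character_,
                     character(1))
  if (anyDuplicated(labels) || any(is.na(labels)))
    stop_config("heatmap_matrix: compound labels must be present and unique")
  chans <- unique(unlist(lapply(reports, function(r) r$channel)))
  m <- matrix(NA_real_, nrow = length(reports), ncol = length(chans),
              dimnames = list(labels, chans))
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    m[i, r$channel] <- r$occupancy_pct
  }
  structure(m, class = c("occupancy_heatmap", class(m)))
}

#' @export
print.occupancy_heatmap <- function(x, ...) {
  cat(sprintf("Occupancy heat map: %d compound(s) x %d channel(s) [%%]\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), 1))
  invisible(x)
}

#' @export
plot.occupancy_heatmap <- function(x, main = "Interaction occupancy (%)", ...) {
  m <- unclass(x)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  zlim = c(0, 100), axes = FALSE, xlab = "", ylab = "",
                  main = main, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 1, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}

#' Per-frame RMSD trace with superposition
#'
#' For every frame: superpose the fit selection onto the reference frame
#' (Kabsch), apply the fitted transform to the report selection, and
#' record the RMSD of the report selection against its reference-frame
#' coordinates. The default protocol fits on protein backbone atoms
#' (N, CA, C, O) and reports ligand heavy atoms, the usual way
#' ligand-stability traces are drawn for MD runs; both selections are
#' configurable.
#'
#' @param traj a [trajectory()].
#' @param fit_idx atom indices used for superposition.
#' @param report_idx atom indices whose RMSD is reported.
#' @param reference_frame reference frame index (default 1, the first
#'   frame).
#' @return numeric vector of length `n_frames(traj)` of class
#'   `rmsd_trace` (Angstrom).
#' @export
rmsd_trace <- function(traj, fit_idx, report_idx, reference_frame = 1L) {
  if (reference_frame < 1L || reference_frame > n_frames(traj))
    stop_input("rmsd_trace: reference frame %d out of range", reference_frame)
  ref <- traj$xyz[, , reference_frame]
  ref_fit <- ref[fit_idx, , drop = FALSE]
  ref_rep <- ref[report_idx, , drop = FALSE]
  out <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$xyz[, , f]
    k <- kabsch_superpose(fr[fit_idx, , drop = FALSE], ref_fit)
    moved <- fr[report_idx, , drop = FALSE] %*% k$rotation
    moved <- sweep(moved, 2L, k$translation, FUN = "+")
    out[f] <- rmsd_coords(moved, ref_rep)
  }
  structure(out, class = "rmsd_trace")
}

#' @export
print.rmsd_trace <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("RMSD trace: %d frames, mean %.3f A, max %.3f A\n",
              length(v), mean(v), max(v)))
  invisible(x)
}

#' @export
plot.rmsd_trace <- function(x, xlab = "frame", ylab = "RMSD (A)",
                            type = "l", ...) {
  graphics::plot(seq_along(x), unclass(x), xlab = xlab, ylab = ylab,
                 type = type, ...)
  invisible(x)
}
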