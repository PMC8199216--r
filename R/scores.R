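#' Per-compound score table with activity labels
#'
#' Container for docking-score or binding-free-energy tables: one row
#' per compound with a score (kcal/mol, more negative = better
#' predicted binding), an activity label and a score-kind tag (e.g.
#' `"DS"`, `"DS_intra_hbond"`, `"MMGBSA"`). Activity labels are inputs
#' (actives are the compounds with a determined IC50), never inferred
#' from the scores themselves.
#'
#' @param compound character, unique per score kind.
#' @param score numeric, kcal/mol.
#' @param activity `"active"` or `"inactive"`.
#' @param kind score-kind tag (scalar or per-row).
#' @return data.frame of class `score_table`.
#' @export
score_table <- function(compound, score, activity, kind = "score") {
  activity <- as.character(activity)
  if (!all(activity %in% c("active", "inactive")))
    stop_data("score_table: activity must be 'active' or 'inactive'")
  tab <- data.frame(compound = as.character(compound),
                    score = as.numeric(score),
                    activity = activity,
                    kind = as.character(kind),
                    stringsAsFactors = FALSE)
  dup <- duplicated(tab[, c("compound", "kind")])
  if (any(dup))
    stop_data("score_table: duplicate compound '%s' within kind '%s'",
              tab$compound[dup][1L], tab$kind[dup][1L])
  structure(tab, class = c("score_table", "data.frame"))
}

#' Per-group distribution summary and mean gap
#'
#' Five-number summaries (box-plot statistics) per activity group plus
#' the gap between the group means, the quantity used to judge whether
#' a scoring method discriminates actives from inactives. Quartiles use
#' linear interpolation between order statistics (the common "type 7"
#' convention); whiskers are Tukey's: the most extreme points within
#' 1.5 x IQR of the quartiles.
#'
#' @param table a [score_table()] holding one score kind.
#' @return object of class `group_stats`: data.frame with one row per
#'   group (`n`, `mean`, `min`, `q1`, `median`, `q3`, `max`,
#'   `whisker_lo`, `whisker_hi`) plus attributes `gap`
#'   (`|mean_active - mean_inactive|`), `kind` and `quartile_method`.
#' @export
group_summary <- function(table) {
  for (g in c("active", "inactive"))
    if (!any(table$activity == g))
      stop_data("group_summary: group '%s' is empty", g)
  rows <- lapply(c("active", "inactive"), function(g) {
    x <- table$score[table$activity == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    data.frame(group = g, n = length(x), mean = mean(x),
               min = min(x), q1 = q[1L], median = q[2L], q3 = q[3L],
               max = max(x),
               whisker_lo = min(x[x >= q[1L] - 1.5 * iqr]),
               whisker_hi = max(x[x <= q[3L] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("group_stats", "data.frame"),
            gap = abs(out$mean[1L] - out$mean[2L]),
            kind = table$kind[1L], quartile_method = "type 7")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("Score-group statistics [%s]:\n", attr(x, "kind")))
  print.data.frame(cbind(x[, "group", drop = FALSE],
                         round(x[, -1L], 3)), row.names = FALSE)
  cat(sprintf("mean gap |active - inactive|: %.3f\n", attr(x, "gap")))
  invisible(x)
}

#' Best single-threshold separation of actives from inactives
#'
#' Exhaustively scans the midpoints between adjacent sorted scores
#' (plus thresholds below and above all scores) for the cut that
#' misclassifies the fewest compounds, classifying as active the side
#' of the threshold holding the active-group mean. Ties between equally
#' good thresholds are broken toward the more negative threshold. The
#' overlap flag is true iff no threshold classifies perfectly.
#'
#' @param table a [score_table()].
#' @return list of class `separation`: `threshold`, `misclassified`,
#'   `overlap`, `direction` (`"active_below"` or `"active_above"`),
#'   `n`.
#' @export
separation_assessment <- function(table) {
  act <- table$score[table$activity == "active"]
  ina <- table$score[table$activity == "inactive"]
  if (!length(act) || !length(ina))
    stop_data("separation_assessment: both activity groups must be non-empty")
  dir_below <- mean(act) <= mean(ina)   # actives on the more negative side?
  s <- sort(unique(table$score))
  cand <- c(s[1L] - 1, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2,
            s[length(s)] + 1)
  mis <- vapply(cand, function(thr) {
    if (dir_below) sum(act > thr) + sum(ina <= thr)
    else sum(act < thr) + sum(ina >= thr)
  }, numeric(1))
  best <- min(mis)
  thr <- min(cand[mis == best])         # ties -> more negative threshold
  structure(list(threshold = thr, misclassified = as.integer(best),
                 overlap = best > 0,
                 direction = if (dir_below) "active_below" else "active_above",
                 n = nrow(table)),
            class = "separation")
}

#' @export
print.separation <- function(x, ...) {
  cat(sprintf("Single-threshold separation: threshold %.4g (%s), %d/%d misclassified%s\n",
              x$threshold, x$direction, x$misclassified, x$n,
              if (x$overlap) " [groups overlap]" else " [fully separated]"))
  invisible(x)
}

#' Rank scoring methods by discriminatory power
#'
#' Computes group statistics and the best single-threshold separation
#' for each score kind and ranks the kinds by (misclassifications
#' ascending, mean gap descending). Exact ties keep input order and are
#' flagged.
#'
#' @param tables list of [score_table()] objects (or one table whose
#'   `kind` column distinguishes the methods).
#' @return data.frame of class `score_comparison`, one row per kind in
#'   rank order, with the per-kind `group_stats` attached as attribute
#'   `stats`.
#' @export
compare_score_kinds <- function(tables) {
  if (is.data.frame(tables))
    tables <- split(tables, factor(tables$kind, levels = unique(tables$kind)))
  if (length(tables) < 2L)
    stop_data("compare_score_kinds: need >= 2 score kinds, got %d", length(tables))
  rows <- lapply(tables, function(tab) {
    gs <- group_summary(tab)
    sep <- separation_assessment(tab)
    data.frame(kind = attr(gs, "kind"),
               gap = attr(gs, "gap"),
               misclassified = sep$misclassified,
               overlap = sep$overlap,
               threshold = sep$threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  ord <- order(out$misclassified, -out$gap, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out$tied_with_next <- c(out$misclassified[-nrow(out)] == out$misclassified[-1L] &
                            out$gap[-nrow(out)] == out$gap[-1L], FALSE)
  structure(out, class = c("score_comparison", "data.frame"),
            stats = lapply(tables, group_summary)[ord])
}

#' @export
print.score_comparison <- function(x, ...) {
  cat("Score-kind discrimination ranking:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
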