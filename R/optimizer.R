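#' Run the stringency grid
#'
#' Scans occurrence levels from the strictest (all donors) down to the
#' configured minimum. At every level the genes are selected, focus
#' networks built and scored, structuring metrics computed, the sharing
#' matrix against the previous (stricter) level assembled, and -- when gene
#' sets are supplied -- per-set hit counts and enrichment scores recorded.
#'
#' @param ev_tab An [ev_table()].
#' @param kg A [knowledge_graph()].
#' @param genesets Optional named list of gene sets.
#' @param config A [run_config()].
#' @return A `stringency_grid`: list with `levels` (integer k values,
#'   strict first), `rows` (per level: `selection`, `networks`, `metrics`,
#'   `sharing` vs previous level, `genesets`), `records` (the occurrence
#'   table) and `n_donors`.
#' @export
run_grid <- function(ev_tab, kg, genesets = NULL, config = run_config()) {
  n <- n_donors(ev_tab)
  levels <- config$occurrence_levels %||% seq(n, max(2L, ceiling(n / 2)))
  levels <- sort(unique(pmin(levels, n)), decreasing = TRUE)
  if (length(levels) < 1L) stop("no occurrence levels to scan")
  records <- count_occurrence(ev_tab, config$ev_threshold,
                              config$p_threshold)
  rows <- list()
  prev_networks <- NULL
  for (k in levels) {
    sel <- select_by_occurrence(records, k)
    if (length(sel$gene_ids) == 0L) {
      stop("no genes selected at level ", k, "/", n)
    }
    networks <- tryCatch(
      build_networks(sel$gene_ids, kg, config$network_max_size),
      error = function(e) stop("level ", k, "/", n, ": ",
                               conditionMessage(e)))
    metrics <- compute_metrics(networks, length(sel$gene_ids),
                               config$major_network_min_focus,
                               level = sel$level)
    sharing <- if (!is.null(prev_networks)) {
      cross_level_sharing(prev_networks, networks, top_k = 1L)
    }
    gs <- if (!is.null(genesets)) {
      bg <- config$background_size %||% kg$background_size
      score_genesets(sel, genesets, bg)
    }
    rows[[as.character(k)]] <- list(k = k, selection = sel,
                                    networks = networks, metrics = metrics,
                                    sharing = sharing, genesets = gs)
    prev_networks <- networks
    stage_log("run_grid", level = sel$level,
              genes = length(sel$gene_ids),
              networks = length(networks),
              common_pct = metrics$common_pct)
  }
  structure(list(levels = levels, rows = rows, records = records,
                 n_donors = n),
            class = "stringency_grid")
}

#' @export
print.stringency_grid <- function(x, ...) {
  cat("stringency_grid over levels",
      paste(x$levels, x$n_donors, sep = "/", collapse = ", "), "\n")
  print(grid_metrics(x))
  invisible(x)
}

#' Collect the per-level metrics table of a grid
#' @param grid A `stringency_grid`.
#' @return Data.frame with one `stringency_metrics` row per level.
#' @export
grid_metrics <- function(grid) {
  out <- do.call(rbind, lapply(grid$rows, `[[`, "metrics"))
  row.names(out) <- NULL
  out
}

#' Recommend the occurrence stringency threshold
#'
#' Applies the two decision rules to a [run_grid()] result.
#'
#' Rule A (structuring peak): pick the level whose networks have the
#' highest percentage of common genes -- the point of maximal structuring;
#' ties go to the strictest level.
#'
#' Rule B (best-score continuity): walk from the strictest level; as long
#' as the top network's focus genes land their plurality share in the next
#' level's top network, the stringency may still be too high. The first
#' time the plurality falls outside the top network the level has become
#' too loose, and the preceding (stricter) level is returned. The rule
#' presumes the walk starts in the too-strict regime, so a break is only
#' meaningful after continuity has been observed at least once: if the
#' very first transition already breaks -- the top-network lineage was
#' never established -- or if the walk never breaks, Rule B is undefined.
#'
#' Rule B, the stated stopping criterion, wins when defined; otherwise
#' Rule A decides. Disagreement between defined rules is reported in the
#' rationale.
#'
#' @param grid A `stringency_grid` with at least two levels.
#' @return A `threshold_recommendation`: list with `chosen_level` (integer
#'   k), `rule_a`, `rule_b` (k or NA), `label` and `rationale`.
#' @export
choose_threshold <- function(grid) {
  if (length(grid$levels) < 2L) stop("need at least two grid levels")
  metrics <- grid_metrics(grid)
  common <- metrics$common_pct
  rule_a <- grid$levels[which.max(common)] # first max = strictest on ties

  rule_b <- NA_integer_
  seen_continuity <- FALSE
  for (i in seq_len(length(grid$levels) - 1L)) {
    strict <- grid$rows[[as.character(grid$levels[i])]]
    loose <- grid$rows[[as.character(grid$levels[i + 1L])]]
    share <- cross_level_sharing(strict$networks, loose$networks,
                                 top_k = 1L)[1L, ]
    plurality <- which.max(share) # earlier (better-ranked) network on ties
    if (plurality != 1L) {
      if (seen_continuity) rule_b <- grid$levels[i]
      break
    }
    seen_continuity <- TRUE
  }
  chosen <- if (!is.na(rule_b)) rule_b else rule_a
  rationale <- if (is.na(rule_b)) {
    "best-score continuity never broke; structuring peak (Rule A) decides"
  } else if (rule_b == rule_a) {
    "structuring peak and best-score continuity agree"
  } else {
    sprintf(paste("rules disagree: structuring peak at %d/%d,",
                  "best-score continuity at %d/%d; continuity rule wins"),
            rule_a, grid$n_donors, rule_b, grid$n_donors)
  }
  if (!is.na(rule_b) && rule_b != rule_a) {
    warning("threshold rules disagree: ", rationale)
  }
  structure(list(chosen_level = chosen,
                 rule_a = rule_a,
                 rule_b = rule_b,
                 label = sprintf(">=%d/%d", chosen, grid$n_donors),
                 rationale = rationale),
            class = "threshold_recommendation")
}

#' @export
print.threshold_recommendation <- function(x, ...) {
  cat("recommended stringency:", x$label, "--", x$rationale, "\n")
  invisible(x)
}
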