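#' Combined significance of an EV occurrence
#'
#' Two combinations of the per-donor significance level are reported for a
#' gene exceeding the EV threshold in k of n donors in the same direction:
#' the product bound `p_threshold^k` (attained when every consensus donor
#' sits exactly at the threshold) and the binomial tail
#' P(X >= k), X ~ Binomial(n, p_threshold). The binomial tail is the
#' default ranking key.
#'
#' @param k Number of concordant donors (vectorized).
#' @param n Total donors.
#' @param p_threshold Per-donor one-sided significance level.
#' @return Data.frame with columns `product_bound` and `binomial_tail`.
#' @export
combined_p <- function(k, n, p_threshold) {
  if (any(k < 0) || any(k > n) || n < 1) stop("need 0 <= k <= n, n >= 1")
  if (!(p_threshold > 0 && p_threshold < 1)) {
    stop("p_threshold must lie in (0, 1)")
  }
  data.frame(product_bound = p_threshold^k,
             binomial_tail = pbinom(k - 1, n, p_threshold,
                                    lower.tail = FALSE))
}

#' Count per-gene EV occurrences across donors
#'
#' A donor counts toward a gene's occurrence only if its EV meets the
#' threshold *and* varies in the consensus direction: up- and
#' down-exceedances are tallied separately and the larger tally wins
#' (mixed-direction exceedances are never pooled).
#'
#' @param ev_tab An [ev_table()].
#' @param ev_threshold Per-donor EV cut (> 0).
#' @param p_threshold Per-donor significance level used for the combined
#'   p-values; defaults to `ev_to_p(ev_threshold)`.
#' @return Data.frame with one row per gene: `gene_id`, `n_up`, `n_down`,
#'   `occurrence`, `consensus_direction`, `summary_ev` (median EV over the
#'   consensus donors), `summary_ev_all` (median signed EV over all
#'   donors), `combined_p_product`, `combined_p_binomial`. Attribute
#'   `n_donors` carries n.
#' @export
count_occurrence <- function(ev_tab, ev_threshold,
                             p_threshold = ev_to_p(ev_threshold)) {
  if (!is.data.frame(ev_tab) || nrow(ev_tab) == 0L) stop("empty EV table")
  if (ev_threshold <= 0) stop("ev_threshold must be > 0")
  n <- n_donors(ev_tab) %||% length(unique(ev_tab$donor_id))
  grp <- split(seq_len(nrow(ev_tab)), ev_tab$gene_id)
  rows <- lapply(grp, function(i) {
    ev <- ev_tab$ev[i]
    dir <- ev_tab$direction[i]
    hit <- ev >= ev_threshold
    n_up <- sum(hit & dir > 0)
    n_down <- sum(hit & dir < 0)
    occurrence <- max(n_up, n_down)
    consensus <- if (n_up >= n_down) 1L else -1L
    cons_idx <- hit & (if (consensus > 0) dir > 0 else dir < 0)
    summary_ev <- if (occurrence > 0) median(ev[cons_idx]) else NA_real_
    c(n_up = n_up, n_down = n_down, occurrence = occurrence,
      consensus_direction = consensus, summary_ev = summary_ev,
      summary_ev_all = median(ev * dir))
  })
  m <- do.call(rbind, rows)
  cp <- combined_p(m[, "occurrence"], n, p_threshold)
  out <- data.frame(gene_id = names(grp),
                    n_up = as.integer(m[, "n_up"]),
                    n_down = as.integer(m[, "n_down"]),
                    occurrence = as.integer(m[, "occurrence"]),
                    consensus_direction = as.integer(m[, "consensus_direction"]),
                    summary_ev = m[, "summary_ev"],
                    summary_ev_all = m[, "summary_ev_all"],
                    combined_p_product = cp$product_bound,
                    combined_p_binomial = cp$binomial_tail,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_donors") <- n
  attr(out, "ev_threshold") <- ev_threshold
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Select genes by occurrence level
#'
#' Keeps the genes whose occurrence is at least `k_min`. Selections are
#' nested: the genes selected at k+1 are a subset of those at k.
#'
#' @param records Output of [count_occurrence()].
#' @param k_min Minimum number of concordant donors (1..n).
#' @return A `gene_selection`: list with `level` (label "k/n"), `k_min`,
#'   `n_donors`, `ev_threshold`, `gene_ids` and `table` (the selected rows,
#'   with `summary_ev_all` as the per-gene summary expression used
#'   downstream).
#' @export
select_by_occurrence <- function(records, k_min) {
  n <- attr(records, "n_donors")
  if (k_min < 1L || k_min > n) stop("k_min must lie in 1..n_donors")
  sel <- records[records$occurrence >= k_min, , drop = FALSE]
  label <- if (k_min == n) sprintf("%d/%d", k_min, n) else
    sprintf(">=%d/%d", k_min, n)
  structure(list(level = label, k_min = as.integer(k_min),
                 n_donors = n,
                 ev_threshold = attr(records, "ev_threshold"),
                 gene_ids = sel$gene_id,
                 table = sel),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat("gene_selection level", x$level, ":", length(x$gene_ids),
      "genes at EV >=", signif(x$ev_threshold %||% NA_real_, 4), "\n")
  invisible(x)
}

#' Select genes by cohort-averaged EV (baseline approach)
#'
#' The classical alternative to occurrence counting: average the signed EV
#' over all donors and select genes whose absolute average meets the EV
#' value corresponding to `p_cut`. Provided as the comparison baseline; it
#' misses genes with moderate but consistent variation and is dominated by
#' a few extreme donors.
#'
#' @param ev_tab An [ev_table()].
#' @param p_cut One-sided p-value cut (e.g. 0.01 for EV 2.33).
#' @param stat Averaging statistic, `"mean"` or `"median"`.
#' @return A `gene_selection` with `table` columns `gene_id`,
#'   `avg_signed_ev`, `direction`.
#' @export
select_by_mean <- function(ev_tab, p_cut, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!(p_cut > 0 && p_cut < 1)) stop("p_cut must lie in (0, 1)")
  cut <- p_to_ev(min(p_cut, 0.5))
  f <- if (stat == "mean") mean else median
  grp <- split(seq_len(nrow(ev_tab)), ev_tab$gene_id)
  avg <- vapply(grp, function(i) f(ev_tab$ev[i] * ev_tab$direction[i]),
                numeric(1L))
  keep <- abs(avg) >= cut
  tab <- data.frame(gene_id = names(grp)[keep],
                    avg_signed_ev = avg[keep],
                    direction = ifelse(avg[keep] >= 0, 1L, -1L),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(level = paste0(stat, " p<=", p_cut),
                 k_min = NA_integer_,
                 n_donors = n_donors(ev_tab),
                 ev_threshold = cut,
                 gene_ids = tab$gene_id,
                 table = tab),
            class = "gene_selection")
}
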