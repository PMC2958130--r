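#' Pairwise overlap of per-donor gene selections
#'
#' Every unordered donor pair is compared by the size of the intersection
#' of their selected gene sets, normalized by the mean set size (default),
#' the smaller set, or the union (Jaccard), expressed in percent.
#'
#' @param selections Named list of character vectors, one per donor.
#' @param metric `"mean"`, `"min"` or `"jaccard"`.
#' @return List with `matrix` (symmetric percent matrix, NA diagonal) and
#'   `average` (mean over pairs; pairs involving an empty selection are
#'   excluded with a warning).
#' @export
pairwise_overlap <- function(selections, metric = c("mean", "min", "jaccard")) {
  metric <- match.arg(metric)
  nd <- length(selections)
  if (nd < 2L) stop("need at least two donors")
  if (is.null(names(selections))) {
    names(selections) <- paste0("D", seq_len(nd))
  }
  empty <- vapply(selections, length, 0L) == 0L
  if (any(empty)) {
    warning("empty selection for donor(s) ",
            paste(names(selections)[empty], collapse = ", "),
            "; their pairs are excluded from the average")
  }
  m <- matrix(NA_real_, nd, nd, dimnames = list(names(selections),
                                                names(selections)))
  vals <- numeric(0)
  for (i in seq_len(nd - 1L)) {
    for (j in (i + 1L):nd) {
      if (empty[i] || empty[j]) next
      a <- unique(selections[[i]])
      b <- unique(selections[[j]])
      inter <- length(intersect(a, b))
      denom <- switch(metric,
                      mean = (length(a) + length(b)) / 2,
                      min = min(length(a), length(b)),
                      jaccard = length(union(a, b)))
      ov <- 100 * inter / denom
      m[i, j] <- m[j, i] <- ov
      vals <- c(vals, ov)
    }
  }
  list(matrix = m,
       average = if (length(vals)) mean(vals) else NA_real_)
}

#' Decompose inter-donor variability
#'
#' The total variability between two donors is the complement of their
#' average selection overlap; subtracting an assumed technical component
#' (assay reproducibility) leaves the biological, inter-individual part,
#' floored at zero.
#'
#' @param avg_overlap Average pairwise overlap, percent.
#' @param technical Technical variability, percent (default 20).
#' @return List with `total` and `biological`, percent.
#' @export
decompose_variability <- function(avg_overlap, technical = 20) {
  if (avg_overlap < 0 || avg_overlap > 100 || technical < 0 ||
      technical > 100) {
    stop("percent inputs must lie in [0, 100]")
  }
  total <- 100 - avg_overlap
  list(total = total, biological = max(0, total - technical))
}

#' Project expected gene counts across occurrence levels
#'
#' Under the geometric attrition model, each step up in occurrence
#' stringency retains a fraction `1 - total_variability` of the genes:
#' expected = round(n_observed * (1 - v)^delta_k), rounded half away from
#' zero.
#'
#' @param n_observed Observed gene count at the reference level.
#' @param total_variability Total inter-donor variability as a fraction in
#'   \[0, 1).
#' @param delta_k Number of occurrence steps above the reference level
#'   (vectorized, >= 0).
#' @return Integer expected count(s).
#' @export
project_counts <- function(n_observed, total_variability, delta_k) {
  if (total_variability < 0 || total_variability >= 1) {
    stop("total_variability must lie in [0, 1)")
  }
  if (any(delta_k < 0)) stop("delta_k must be >= 0")
  x <- n_observed * (1 - total_variability)^delta_k
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Per-donor high-stringency gene selections
#'
#' The per-donor gene sets entering the variability analysis: genes whose
#' EV meets the value corresponding to `p_cut` in that donor (either
#' direction).
#'
#' @param ev_tab An [ev_table()].
#' @param p_cut One-sided p-value cut (default 0.01, EV 2.33).
#' @return Named list of character vectors, one per donor.
#' @export
donor_selections <- function(ev_tab, p_cut = 0.01) {
  cut <- p_to_ev(min(p_cut, 0.5))
  donors <- attr(ev_tab, "donors") %||% unique(ev_tab$donor_id)
  sel <- lapply(donors, function(d) {
    rows <- ev_tab$donor_id == d & ev_tab$ev >= cut
    unique(ev_tab$gene_id[rows])
  })
  names(sel) <- donors
  sel
}

#' Full inter-individual variability report
#'
#' Runs [pairwise_overlap()] on the per-donor high-stringency selections,
#' decomposes the complement into technical and biological components, and
#' projects expected gene counts from the observed count at the reference
#' occurrence level up to the strictest level.
#'
#' @param ev_tab An [ev_table()].
#' @param p_cut Per-donor selection cut (default 0.01).
#' @param technical Technical variability percent (default 20).
#' @param metric Overlap metric (default `"mean"`).
#' @param n_observed Observed gene count at the reference occurrence level
#'   (typically the size of the selection at the chosen stringency); when
#'   `NULL`, no projections are produced.
#' @param reference_k Reference occurrence level for the projection.
#' @return A `variability_report`: list with `overlap_matrix`,
#'   `avg_overlap`, `total`, `technical`, `biological`, `projections`
#'   (data.frame `k`, `delta_k`, `expected`).
#' @export
variability_report <- function(ev_tab, p_cut = 0.01, technical = 20,
                               metric = "mean", n_observed = NULL,
                               reference_k = NULL) {
  sel <- donor_selections(ev_tab, p_cut)
  ov <- pairwise_overlap(sel, metric)
  dec <- decompose_variability(ov$average, technical)
  n <- n_donors(ev_tab)
  reference_k <- reference_k %||% max(2L, ceiling(2 * n / 3))
  projections <- NULL
  if (!is.null(n_observed)) {
    ks <- reference_k:n
    projections <- data.frame(k = ks, delta_k = ks - reference_k,
                              expected = project_counts(
                                n_observed, dec$total / 100,
                                ks - reference_k))
  }
  structure(list(overlap_matrix = ov$matrix,
                 avg_overlap = ov$average,
                 total = dec$total,
                 technical = technical,
                 biological = dec$biological,
                 projections = projections),
            class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat("variability_report: avg overlap", round(x$avg_overlap, 1),
      "% -> total", round(x$total, 1), "% = technical", x$technical,
      "% + biological", round(x$biological, 1), "%\n")
  if (!is.null(x$projections)) print(x$projections)
  invisible(x)
}
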