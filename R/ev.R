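#' Box-Cox power transformation
#'
#' @param v Positive values.
#' @param lambda Power parameter; 0 means natural log.
#' @param shift Additive shift applied before transforming.
#' @return Transformed values.
#' @export
boxcox_transform <- function(v, lambda, shift = 0) {
  v <- v + shift
  if (any(v <= 0)) stop("Box-Cox transform requires positive values")
  if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
}

#' Fit the Box-Cox power parameter
#'
#' Maximizes the profile log-likelihood of the one-parameter Box-Cox family
#' over lambda in \[-2, 2\]: for a candidate lambda the transformed values are
#' assumed Gaussian, giving ll(lambda) = -n/2 log(sigma2_hat(lambda)) +
#' (lambda - 1) sum(log v). Values are shifted by +1 when zeros are present;
#' the shift is recorded on the result.
#'
#' @param values Intensity values, positive after the automatic shift.
#' @return Numeric `lambda` with attribute `shift`.
#' @export
fit_boxcox <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("need at least 10 values to fit Box-Cox")
  shift <- if (any(values == 0)) 1 else 0
  v <- values + shift
  if (any(v <= 0)) stop("non-positive values remain after shift")
  if (var(v) == 0) stop("constant input: Box-Cox fit is undefined")
  slv <- sum(log(v))
  n <- length(v)
  ll <- function(lambda) {
    y <- if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
    s2 <- mean((y - mean(y))^2)
    -n / 2 * log(s2) + (lambda - 1) * slv
  }
  opt <- optimize(ll, interval = c(-2, 2), maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  attr(lambda, "shift") <- shift
  lambda
}

#' Fit the dispersion model for one donor
#'
#' On the Box-Cox scale, each probe yields a mean intensity
#' A = (y_test + y_ref)/2 and a difference M = y_test - y_ref. A is binned
#' into `max(20, n/500)` equal-count windows; cubic smoothing splines
#' (smoothness by generalized cross-validation) are fitted to the windowed
#' median of M (the center curve) and to the windowed robust SD of M
#' (1.4826 * MAD, the spread curve). Because the bands must describe the
#' genes devoid of significant variation, the fit is iterated: probes
#' deviating by more than `outlier_ev` fitted spreads are set aside and
#' the windows and splines are refitted on the remainder until the
#' exclusion set stabilizes (at most `max_iter` rounds). This keeps
#' strongly regulated genes from hijacking the bands where they crowd the
#' intensity extremes. The spread curve is clamped below at 10% of its
#' median so that EV never divides by a vanishing spread.
#'
#' @param pairs Intensity pairs for one donor (see
#'   [read_intensity_table()]); flagged probes are excluded.
#' @param lambda Box-Cox parameter from [fit_boxcox()] (its `shift`
#'   attribute, if any, is honoured).
#' @param outlier_ev EV above which a probe is excluded from the refit
#'   (default 2, outside the central ~95% band).
#' @param max_iter Maximum refinement rounds (default 5).
#' @return An object of class `dispersion_model`.
#' @export
fit_dispersion <- function(pairs, lambda, outlier_ev = 2, max_iter = 5L) {
  shift <- attr(lambda, "shift") %||% 0
  keep <- !pairs$flagged
  pairs <- pairs[keep, , drop = FALSE]
  n <- nrow(pairs)
  if (n < 200L) stop("need at least 200 unflagged pairs to fit dispersion")
  y_ref <- boxcox_transform(pairs$intensity_ref, lambda, shift)
  y_test <- boxcox_transform(pairs$intensity_test, lambda, shift)
  A <- (y_test + y_ref) / 2
  M <- y_test - y_ref

  # consistency factor for the MAD of a normal sample truncated at +-t sd:
  # median(|Z| : |Z| < t) = qnorm(1/2 + (2 pnorm(t) - 1)/4), so the usual
  # 1.4826 constant under-estimates the null spread after band trimming
  trunc_correction <- function(t) {
    qnorm(0.75) / qnorm(0.5 + (2 * pnorm(t) - 1) / 4)
  }

  fit_pass <- function(A, M, correction = 1) {
    n <- length(A)
    n_win <- max(20L, floor(n / 500))
    if (n < n_win * 5L) stop("too few pairs for ", n_win, " windows")
    ord <- order(A)
    idx <- split(ord, cut(seq_len(n), breaks = n_win, labels = FALSE))
    mid <- vapply(idx, function(i) median(A[i]), numeric(1L))
    ctr <- vapply(idx, function(i) median(M[i]), numeric(1L))
    spr <- vapply(idx, function(i) mad(M[i]) * correction, numeric(1L))
    # center the abscissa and quantize the spline inputs (1e-9, far below
    # any meaningful signal) so the fit -- including the GCV smoothness
    # selection, which can amplify last-bit perturbations -- is exactly
    # invariant under translations of A, e.g. global intensity rescaling
    # at lambda = 0
    a_offset <- mean(mid)
    # windows have equal counts, so the sampling noise of both the median
    # and the MAD scales with the local spread: weight inversely
    w <- 1 / (round(spr, 12) + 1e-8)^2
    w <- w / mean(w)
    center_fit <- smooth.spline(round(mid - a_offset, 9), round(ctr, 12),
                                w = w)
    spread_fit <- smooth.spline(round(mid - a_offset, 9), round(spr, 12),
                                w = w)
    # clamp at 10% of the median spread; essentially noise-free data falls
    # back to a tiny absolute floor so EV never divides by zero
    floor_val <- max(0.1 * median(predict(spread_fit, mid - a_offset)$y),
                     1e-8)
    structure(list(lambda = as.numeric(lambda), shift = shift,
                   center_fit = center_fit, spread_fit = spread_fit,
                   a_offset = a_offset,
                   spread_floor = floor_val,
                   fit_domain = range(A),
                   windows = data.frame(mid = mid, center = ctr,
                                        spread = spr)),
              class = "dispersion_model")
  }

  model <- fit_pass(A, M)
  ok <- rep(TRUE, length(A))
  for (it in seq_len(max_iter)) {
    ev_it <- abs(M - center_curve(model, A)) / spread_curve(model, A)
    ok_new <- ev_it < outlier_ev
    if (sum(ok_new) < 200L || identical(ok_new, ok)) break
    ok <- ok_new
    model <- fit_pass(A[ok], M[ok], trunc_correction(outlier_ev))
  }
  if (any(spread_curve(model, model$windows$mid) <= 0)) {
    stop("internal error: non-positive spread after clamping")
  }
  stage_log("fit_dispersion", n = n, windows = nrow(model$windows),
            excluded = sum(!ok), lambda = signif(model$lambda, 4))
  model
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("dispersion_model: lambda", signif(x$lambda, 4),
      "| windows", nrow(x$windows),
      "| A domain [", signif(x$fit_domain[1L], 4), ",",
      signif(x$fit_domain[2L], 4), "]\n")
  invisible(x)
}

clamp_domain <- function(model, a) {
  pmin(pmax(a, model$fit_domain[1L]), model$fit_domain[2L])
}

#' Evaluate the center curve of a dispersion model
#' @param model A `dispersion_model`.
#' @param a Mean intensities (Box-Cox scale); values outside the fit domain
#'   use the nearest boundary.
#' @return Expected difference at `a`.
#' @export
center_curve <- function(model, a) {
  predict(model$center_fit, clamp_domain(model, a) - model$a_offset)$y
}

#' Evaluate the spread curve of a dispersion model
#' @inheritParams center_curve
#' @return Standard deviation of the difference at `a`, clamped below.
#' @export
spread_curve <- function(model, a) {
  pmax(predict(model$spread_fit, clamp_domain(model, a) - model$a_offset)$y,
       model$spread_floor)
}

#' Map an EV score to its one-sided p-value
#'
#' EV and p are linked by the one-sided standard-normal upper tail:
#' p = P(Z >= ev). The printed threshold pairs of the method (p = 0.1 at
#' EV 1.28, p = 0.01 at EV 2.32) are the two-decimal truncations of the
#' normal quantiles 1.2816 and 2.3263.
#'
#' @param ev Non-negative EV score(s).
#' @return One-sided p-value(s) in (0, 0.5].
#' @export
ev_to_p <- function(ev) {
  if (any(!is.finite(ev)) || any(ev < 0)) stop("ev must be finite and >= 0")
  pnorm(ev, lower.tail = FALSE)
}

#' Map a one-sided p-value to its EV score
#' @param p One-sided p-value(s) in (0, 0.5].
#' @return EV score(s) >= 0.
#' @export
p_to_ev <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 0.5)) {
    stop("p must lie in (0, 0.5]")
  }
  qnorm(p, lower.tail = FALSE)
}

#' Two-decimal display truncation of an EV value
#'
#' Thresholds are reported truncated (not rounded) to two decimals, so the
#' quantile 2.3263 prints as 2.32.
#'
#' @param ev EV value(s).
#' @return Truncated value(s).
#' @export
ev_display <- function(ev) floor(ev * 100) / 100

#' Compute per-probe EV records for one donor
#'
#' Positions every unflagged probe in the dispersion space: ev =
#' |M - center(A)| / spread(A), direction = sign(M - center(A)) (a tie at
#' the center breaks to +1), p = one-sided normal upper tail of ev.
#'
#' @param pairs Intensity pairs for one donor.
#' @param model The donor's [fit_dispersion()] model.
#' @return Data.frame with columns `gene_id`, `donor_id`, `ev`, `p`,
#'   `direction`.
#' @export
compute_ev <- function(pairs, model) {
  all_genes <- unique(pairs$gene_id)
  keep <- !pairs$flagged
  dropped <- setdiff(all_genes, unique(pairs$gene_id[keep]))
  if (length(dropped)) {
    warning(length(dropped), " gene(s) with only flagged probes omitted: ",
            paste(head(dropped, 5L), collapse = ", "))
  }
  pairs <- pairs[keep, , drop = FALSE]
  y_ref <- boxcox_transform(pairs$intensity_ref, model$lambda, model$shift)
  y_test <- boxcox_transform(pairs$intensity_test, model$lambda, model$shift)
  A <- (y_test + y_ref) / 2
  M <- y_test - y_ref
  dev <- M - center_curve(model, A)
  spr <- spread_curve(model, A)
  ev <- abs(dev) / spr
  direction <- ifelse(dev >= 0, 1L, -1L)
  data.frame(gene_id = pairs$gene_id,
             donor_id = pairs$donor_id,
             ev = ev,
             p = ev_to_p(ev),
             direction = direction,
             stringsAsFactors = FALSE)
}

#' Aggregate replicate probes to gene level
#'
#' Replicate probes for the same gene collapse to a single record: EV is
#' the replicate median; direction is the majority sign, ties broken by the
#' sign of the summed signed EV and then to +1. A homogeneity summary over
#' genes with >= 2 replicates reports the per-gene relative spread,
#' 100 * mean(|EV_i - median(EV)|) / median(EV) (genes whose median EV is 0
#' are excluded from the summary).
#'
#' @param records Per-probe records from [compute_ev()] for one donor.
#' @return List with `records` (one row per gene: `gene_id`, `donor_id`,
#'   `ev`, `p`, `direction`) and `homogeneity` (`mean`, `median`, `sd` of
#'   the relative spreads, and `n_replicated`).
#' @export
aggregate_replicates <- function(records) {
  stopifnot(nrow(records) >= 1L)
  grp <- split(seq_len(nrow(records)), records$gene_id)
  agg <- lapply(grp, function(i) {
    evs <- records$ev[i]
    dirs <- records$direction[i]
    med <- median(evs)
    n_up <- sum(dirs > 0)
    n_dn <- sum(dirs < 0)
    dir <- if (n_up > n_dn) 1L else if (n_dn > n_up) -1L else {
      s <- sum(evs * dirs)
      if (s >= 0) 1L else -1L
    }
    spread <- if (length(i) >= 2L && med > 0) {
      100 * mean(abs(evs - med)) / med
    } else NA_real_
    c(ev = med, direction = dir, spread = spread, nrep = length(i))
  })
  m <- do.call(rbind, agg)
  out <- data.frame(gene_id = names(grp),
                    donor_id = records$donor_id[vapply(grp, `[`, 0L, 1L)],
                    ev = m[, "ev"],
                    p = ev_to_p(m[, "ev"]),
                    direction = as.integer(m[, "direction"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  spreads <- m[, "spread"][m[, "nrep"] >= 2 & !is.na(m[, "spread"])]
  homog <- list(mean = if (length(spreads)) mean(spreads) else NA_real_,
                median = if (length(spreads)) median(spreads) else NA_real_,
                sd = if (length(spreads) > 1L) sd(spreads) else NA_real_,
                n_replicated = length(spreads))
  list(records = out, homogeneity = homog)
}

#' Build a donor-by-gene EV table from raw intensity tables
#'
#' Runs the full per-donor chain -- Box-Cox fit on the donor's pooled
#' intensities, dispersion-band fit, per-probe EV, replicate aggregation --
#' and assembles one record per (gene, donor) over the common gene universe
#' (genes quantified in every donor).
#'
#' @param donor_tables Named list of per-donor intensity pair tables.
#' @return An `ev_table`: data.frame of `gene_id`, `donor_id`, `ev`, `p`,
#'   `direction` with attributes `n_donors`, `donors`, `homogeneity` and
#'   `models`.
#' @export
ev_table <- function(donor_tables) {
  stopifnot(length(donor_tables) >= 1L)
  if (is.null(names(donor_tables)) || any(!nzchar(names(donor_tables)))) {
    names(donor_tables) <- paste0("D", seq_along(donor_tables))
  }
  per <- lapply(names(donor_tables), function(d) {
    pairs <- donor_tables[[d]]
    pairs$donor_id <- d
    lambda <- fit_boxcox(c(pairs$intensity_ref[!pairs$flagged],
                           pairs$intensity_test[!pairs$flagged]))
    model <- fit_dispersion(pairs, lambda)
    agg <- aggregate_replicates(compute_ev(pairs, model))
    list(records = agg$records, homogeneity = agg$homogeneity, model = model)
  })
  names(per) <- names(donor_tables)
  universe <- Reduce(intersect, lapply(per, function(x) x$records$gene_id))
  recs <- do.call(rbind, lapply(per, function(x) {
    r <- x$records
    r[r$gene_id %in% universe, , drop = FALSE]
  }))
  row.names(recs) <- NULL
  stage_log("ev_table", donors = length(per), genes = length(universe))
  structure(recs,
            n_donors = length(per),
            donors = names(per),
            homogeneity = lapply(per, `[[`, "homogeneity"),
            models = lapply(per, `[[`, "model"),
            class = c("ev_table", "data.frame"))
}

n_donors <- function(ev_tab) attr(ev_tab, "n_donors")
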