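# grid-search oracle for the Box-Cox profile log-likelihood
boxcox_grid_oracle <- function(v, grid = seq(-2, 2, by = 0.01)) {
  slv <- sum(log(v))
  n <- length(v)
  ll <- vapply(grid, function(lambda) {
    y <- if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
    -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * slv
  }, numeric(1))
  grid[which.max(ll)]
}

test_that("fit_boxcox recovers the transform family", {
  set.seed(101)
  v_lnorm <- rlnorm(5000, meanlog = 6, sdlog = 0.8)
  lam <- fit_boxcox(v_lnorm)
  expect_lt(abs(lam - 0), 0.1)
  expect_lt(abs(lam - boxcox_grid_oracle(v_lnorm)), 0.011)

  v_norm <- rnorm(5000, 50, 5)
  lam2 <- fit_boxcox(v_norm)
  expect_lt(abs(lam2 - 1), 0.15)
  expect_lt(abs(lam2 - boxcox_grid_oracle(v_norm)), 0.011)

  expect_error(fit_boxcox(rep(3, 100)), "constant")
  expect_error(fit_boxcox(rlnorm(5)), "at least 10")
  expect_error(fit_boxcox(c(-1, rlnorm(20))), "non-positive")
})

test_that("fit_boxcox shifts by one when zeros are present", {
  set.seed(5)
  v <- c(0, rlnorm(999, 5, 0.5))
  lam <- fit_boxcox(v)
  expect_equal(attr(lam, "shift"), 1)
})

test_that("fit_dispersion recovers an intensity-dependent spread", {
  set.seed(202)
  n <- 10000
  A <- runif(n, 2, 10)
  sigma <- function(a) 0.5 + 1 / (1 + a)
  M <- rnorm(n, 0, sigma(A))
  model <- quietly(fit_dispersion(pairs_from_am(A, M), lambda1()))
  mids <- model$windows$mid
  rel_err <- abs(spread_curve(model, mids) - sigma(mids)) / sigma(mids)
  expect_lt(max(rel_err), 0.10)
  # symmetric null data: center close to zero everywhere
  expect_lt(max(abs(center_curve(model, mids))), 0.05)
})

test_that("fit_dispersion handles the noise-free degenerate case", {
  A <- seq(1, 10, length.out = 500)
  model <- quietly(fit_dispersion(pairs_from_am(A, rep(0.3, 500)),
                                  lambda1()))
  mids <- model$windows$mid
  expect_equal(center_curve(model, mids), rep(0.3, length(mids)),
               tolerance = 1e-6)
  expect_true(all(spread_curve(model, mids) == model$spread_floor))
  expect_gt(model$spread_floor, 0)
})

test_that("fit_dispersion enforces its preconditions", {
  expect_error(quietly(fit_dispersion(pairs_from_am(runif(100, 2, 5),
                                                    rnorm(100)),
                                      lambda1())),
               "at least 200")
})

test_that("compute_ev positions genes in the dispersion space", {
  set.seed(303)
  A <- runif(5000, 2, 10)
  M <- rnorm(5000, 0, 0.5)
  model <- quietly(fit_dispersion(pairs_from_am(A, M), lambda1()))
  # plant probes exactly on the band multiples of the fitted curves
  a0 <- 6
  ctr <- center_curve(model, a0)
  spr <- spread_curve(model, a0)
  z01 <- qnorm(0.01, lower.tail = FALSE) # 2.3263...
  probe <- pairs_from_am(rep(a0, 3),
                         c(ctr + 1.28 * spr, ctr, ctr + z01 * spr),
                         gene_id = c("ON_BAND", "AT_CENTER", "AT_P01"))
  ev <- compute_ev(probe, model)
  expect_equal(ev$ev[1], 1.28, tolerance = 1e-6)
  expect_equal(ev$p[1], 0.10, tolerance = 0.005)
  expect_lt(ev$ev[2], 1e-10)
  expect_equal(ev$p[2], 0.5)
  expect_equal(ev$p[3], 0.01, tolerance = 1e-6)

  # a probe exactly at the center: direction tie breaks to +1
  flat <- quietly(fit_dispersion(pairs_from_am(seq(1, 10, length.out = 500),
                                               rep(0, 500)), lambda1()))
  at0 <- compute_ev(pairs_from_am(5, 0, gene_id = "TIE"), flat)
  expect_equal(at0$ev, 0)
  expect_equal(at0$direction, 1L)
})

test_that("genes outside the fit domain use boundary curve values", {
  set.seed(7)
  A <- runif(2000, 3, 8)
  model <- quietly(fit_dispersion(pairs_from_am(A, rnorm(2000, 0, 0.3)),
                                  lambda1()))
  expect_equal(spread_curve(model, 100), spread_curve(model, 8))
  expect_equal(center_curve(model, -50), center_curve(model, 3))
})

test_that("ev_to_p and p_to_ev are exact inverses and match display pairs", {
  p <- 10^seq(log10(1e-8), log10(0.5), length.out = 200)
  expect_equal(ev_to_p(p_to_ev(p)), p, tolerance = 1e-10)
  expect_equal(ev_display(p_to_ev(0.1)), 1.28)
  expect_equal(ev_display(p_to_ev(0.01)), 2.32)
  expect_equal(ev_to_p(p_to_ev(0.05)), 0.05, tolerance = 1e-12)
  # monotone: p strictly decreasing in ev
  ev <- seq(0, 6, by = 0.05)
  expect_true(all(diff(ev_to_p(ev)) < 0))
  expect_error(p_to_ev(0.6), "0.5")
  expect_error(p_to_ev(0), "0.5")
  expect_error(ev_to_p(-1), ">= 0")
})

test_that("aggregate_replicates medians, votes and summarizes spread", {
  rec <- data.frame(gene_id = c("A", "A", "A", "B", "B", "C"),
                    donor_id = "D1",
                    ev = c(2, 2, 2, 1, 3, 1.7),
                    p = ev_to_p(c(2, 2, 2, 1, 3, 1.7)),
                    direction = c(1L, 1L, -1L, 1L, 1L, -1L))
  out <- aggregate_replicates(rec)
  a <- out$records[out$records$gene_id == "A", ]
  b <- out$records[out$records$gene_id == "B", ]
  expect_equal(a$ev, 2)          # median of {2,2,2}
  expect_equal(a$direction, 1L)  # majority sign
  expect_equal(b$ev, 2)          # median of {1,3}
  # relative spreads: A -> 0%, B -> 100*mean(|{1,3}-2|)/2 = 50%
  expect_equal(out$homogeneity$n_replicated, 2L)
  expect_equal(out$homogeneity$mean, mean(c(0, 50)))
  expect_equal(out$homogeneity$median, median(c(0, 50)))
  # single-probe gene passes through untouched
  expect_equal(out$records$ev[out$records$gene_id == "C"], 1.7)
})

test_that("replicate direction ties fall back to summed signed EV", {
  rec <- data.frame(gene_id = "A", donor_id = "D1",
                    ev = c(1, 3), p = ev_to_p(c(1, 3)),
                    direction = c(1L, -1L))
  expect_equal(aggregate_replicates(rec)$records$direction, -1L)
  rec$ev <- c(2, 2)
  expect_equal(aggregate_replicates(rec)$records$direction, 1L)
})

test_that("EV is scale equivariant on the log scale", {
  set.seed(9)
  v_ref <- rlnorm(3000, 6, 0.8)
  v_test <- v_ref * exp(rnorm(3000, 0, 0.3))
  mk <- function(scale) {
    data.frame(gene_id = sprintf("G%04d", seq_along(v_ref)),
               donor_id = "D1",
               intensity_ref = v_ref * scale,
               intensity_test = v_test * scale,
               flagged = FALSE)
  }
  lam0 <- 0; attr(lam0, "shift") <- 0
  ev_a <- compute_ev(mk(1), quietly(fit_dispersion(mk(1), lam0)))
  ev_b <- compute_ev(mk(7.3), quietly(fit_dispersion(mk(7.3), lam0)))
  expect_lt(max(abs(ev_a$ev - ev_b$ev)), 1e-6)
})

test_that("ev_table intersects donors onto a common gene universe", {
  set.seed(21)
  mk_tab <- function(genes) {
    A <- runif(length(genes), 3, 9)
    p <- pairs_from_am(A, rnorm(length(genes), 0, 0.4), gene_id = genes)
    p$intensity_ref <- exp(p$intensity_ref / 2)
    p$intensity_test <- exp(p$intensity_test / 2)
    p
  }
  g_all <- sprintf("G%04d", 1:500)
  tabs <- list(D1 = mk_tab(g_all), D2 = mk_tab(g_all[1:450]))
  evt <- quietly(ev_table(tabs))
  expect_equal(attr(evt, "n_donors"), 2L)
  expect_setequal(unique(evt$gene_id), g_all[1:450])
  expect_equal(nrow(evt), 900L) # one record per gene per donor
})
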