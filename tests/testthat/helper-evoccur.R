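# shared fixtures, built in code

quietly <- function(expr) suppressMessages(expr)

# intensity pairs whose Box-Cox(lambda = 1) A/M coordinates are prescribed:
# y = v - 1, so ref = A - M/2 + 1, test = A + M/2 + 1
pairs_from_am <- function(A, M, gene_id = sprintf("G%05d", seq_along(A)),
                          donor_id = "D1") {
  data.frame(gene_id = gene_id, donor_id = donor_id,
             intensity_ref = A - M / 2 + 1,
             intensity_test = A + M / 2 + 1,
             flagged = FALSE, stringsAsFactors = FALSE)
}

lambda1 <- function() {
  l <- 1
  attr(l, "shift") <- 0
  l
}

# hand-built EV table (one row per gene x donor) with the attributes the
# occurrence module relies on
mock_ev_table <- function(ev_mat, dir_mat = NULL) {
  n_genes <- nrow(ev_mat)
  nd <- ncol(ev_mat)
  if (is.null(dir_mat)) dir_mat <- matrix(1L, n_genes, nd)
  genes <- rownames(ev_mat) %||% sprintf("G%03d", seq_len(n_genes))
  donors <- paste0("D", seq_len(nd))
  df <- data.frame(gene_id = rep(genes, times = nd),
                   donor_id = rep(donors, each = n_genes),
                   ev = as.vector(ev_mat),
                   p = evoccur::ev_to_p(as.vector(ev_mat)),
                   direction = as.integer(as.vector(dir_mat)),
                   stringsAsFactors = FALSE)
  structure(df, n_donors = nd, donors = donors,
            class = c("ev_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mock network list in ranked order, for metric / rule tests
mock_networks <- function(...) {
  nets <- list(...)
  for (i in seq_along(nets)) {
    nets[[i]]$rank <- i
    nets[[i]]$id <- i
    if (is.null(nets[[i]]$score)) nets[[i]]$score <- 10 - i
    class(nets[[i]]) <- "gene_network"
  }
  nets
}

# small seeded cohort + graph for structural tests
small_world <- function(seed, n_genes = 600L, ...) {
  spec <- cohort_spec(n_genes = n_genes, seed = seed, ...)
  cohort <- quietly(generate_cohort(spec))
  gg <- quietly(generate_graph(cohort$truth, seed = seed))
  evt <- quietly(ev_table(cohort$tables))
  list(cohort = cohort, gg = gg, evt = evt)
}
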