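#' Specification of a synthetic paired-expression cohort
#'
#' Describes the stated world the generators emulate: a cohort of donors
#' assayed in two paired conditions on a two-channel array, with
#' log-intensity baselines, intensity-dependent (decreasing) noise, a
#' fraction of truly responsive genes, and per-donor response
#' heterogeneity -- each responsive gene responds in a given donor
#' independently with probability `response_prob`.
#'
#' Defaults mirror the validation design the method was built around: 6
#' donors, 10% responsive genes, effect size 3 local spreads, response
#' probability 0.7. `effect_size` is measured in multiples of the local
#' standard deviation of the paired log-difference (the spread the EV
#' statistic standardizes by), so a responding gene has expected EV close
#' to `effect_size`.
#'
#' @param n_genes Number of genes.
#' @param n_donors Number of donors.
#' @param frac_de Fraction of truly responsive (DE) genes.
#' @param response_prob Probability a DE gene responds in a given donor.
#' @param effect_size Shift in multiples of the local difference spread.
#' @param baseline_mean,baseline_sd Normal parameters of the per-gene log
#'   baseline intensity.
#' @param noise_base,noise_amp Per-channel log-scale noise SD at baseline b
#'   is `noise_base + noise_amp / max(b, 1)` -- decreasing with intensity,
#'   the heteroscedasticity that motivates the variance-stabilizing
#'   machinery.
#' @param replicate_probes Probes per gene (replicates share the gene
#'   signal with independent noise).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 2000L, n_donors = 6L, frac_de = 0.1,
                        response_prob = 0.7, effect_size = 3,
                        baseline_mean = 6, baseline_sd = 1,
                        noise_base = 0.15, noise_amp = 1.5,
                        replicate_probes = 1L, seed = 20101020L) {
  if (!(frac_de > 0 && frac_de < 1)) stop("frac_de must lie in (0, 1)")
  if (!(response_prob > 0 && response_prob <= 1)) {
    stop("response_prob must lie in (0, 1]")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  # effect_size 0 gives a null cohort (DE labels without signal), used for
  # false-positive calibration
  if (n_genes < 50L || n_donors < 2L) stop("infeasible cohort size")
  if (replicate_probes < 1L) stop("replicate_probes must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_donors = as.integer(n_donors),
                 frac_de = frac_de, response_prob = response_prob,
                 effect_size = effect_size,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_base = noise_base, noise_amp = noise_amp,
                 replicate_probes = as.integer(replicate_probes),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

noise_sd <- function(spec, b) spec$noise_base + spec$noise_amp / pmax(b, 1)

#' Generate a synthetic paired-expression cohort
#'
#' For gene g with log baseline b_g, the unstimulated channel is
#' exp(b_g + e) and the stimulated channel exp(b_g + delta + e'), with
#' independent noise e, e' ~ N(0, sd(b_g)) per probe, and delta =
#' direction * effect_size * sqrt(2) * sd(b_g) when the gene responds in
#' that donor (so delta equals `effect_size` local spreads of the paired
#' difference), zero otherwise. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `tables` (named list of
#'   per-donor intensity pair data.frames), and `truth` (list with `genes`
#'   -- data.frame `gene_id`, `is_de`, `direction`, `module` (NA until a
#'   graph is generated) -- and `responded`, a DE-gene by donor logical
#'   matrix).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  gene_id <- sprintf("G%05d", seq_len(ng))
  n_de <- round(spec$frac_de * ng)
  de_idx <- sort(sample.int(ng, n_de))
  is_de <- seq_len(ng) %in% de_idx
  direction <- integer(ng)
  direction[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
  b <- rnorm(ng, spec$baseline_mean, spec$baseline_sd)
  sdv <- noise_sd(spec, b)
  responded <- matrix(runif(n_de * spec$n_donors) < spec$response_prob,
                      nrow = n_de,
                      dimnames = list(gene_id[de_idx],
                                      paste0("D", seq_len(spec$n_donors))))
  rep_id <- rep(seq_len(ng), each = spec$replicate_probes)
  tables <- list()
  for (d in seq_len(spec$n_donors)) {
    delta <- numeric(ng)
    resp <- de_idx[responded[, d]]
    delta[resp] <- direction[resp] * spec$effect_size * sqrt(2) * sdv[resp]
    e_ref <- rnorm(length(rep_id), 0, sdv[rep_id])
    e_test <- rnorm(length(rep_id), 0, sdv[rep_id])
    tables[[paste0("D", d)]] <- data.frame(
      gene_id = gene_id[rep_id],
      donor_id = paste0("D", d),
      intensity_ref = exp(b[rep_id] + e_ref),
      intensity_test = exp(b[rep_id] + delta[rep_id] + e_test),
      flagged = FALSE,
      stringsAsFactors = FALSE)
  }
  truth <- list(genes = data.frame(gene_id = gene_id, is_de = is_de,
                                   direction = direction,
                                   module = NA_integer_,
                                   stringsAsFactors = FALSE),
                responded = responded)
  stage_log("generate_cohort", genes = ng, donors = spec$n_donors,
            de = n_de, seed = spec$seed)
  structure(list(tables = tables, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Generate a module-structured interaction graph
#'
#' Emulates a knowledge base in which the truly responsive genes cluster
#' into functional modules: DE genes are partitioned into `n_modules`
#' equal-sized modules, each wired as a hub-dominated scale-free backbone
#' (preferential attachment, `pa_m` edges per gene, power `pa_power`) plus
#' a uniform overlay of density `intra_p`; modules are joined by sparse
#' inter-module edges (`inter_p`) and by `linker_genes` non-assayed hub
#' genes each bridging two modules. Non-DE genes receive a random edge
#' with probability `attach_p`, reflecting that a knowledge base annotates
#' interactions for many genes outside the response modules -- these genes
#' are sparsely connected and, when falsely selected, tend to form small
#' networks unlinked to the modules.
#'
#' @param truth Truth component of a [generate_cohort()] result.
#' @param n_modules Number of DE modules.
#' @param intra_p Within-module overlay edge probability.
#' @param inter_p Between-module edge probability (< `intra_p`).
#' @param linker_genes Number of bridging linker genes.
#' @param attach_p Probability a non-DE gene gets a random edge.
#' @param pa_m Preferential-attachment edges per gene in the module
#'   backbone.
#' @param pa_power Preferential-attachment power (hub strength).
#' @param seed Integer seed.
#' @return List with `kg` (a [knowledge_graph()] whose background is the
#'   full gene universe), `modules` (named module id per DE gene) and
#'   `truth` with module ids filled in.
#' @export
generate_graph <- function(truth, n_modules = 3L, intra_p = 0.02,
                           inter_p = 0.002, linker_genes = 30L,
                           attach_p = 0.5, pa_m = 3L, pa_power = 1.2,
                           seed = 20101020L) {
  if (!(intra_p > inter_p)) stop("intra_p must exceed inter_p")
  set.seed(seed)
  genes <- truth$genes
  de <- genes$gene_id[genes$is_de]
  nonde <- genes$gene_id[!genes$is_de]
  if (length(de) < n_modules) stop("fewer DE genes than modules")
  module <- sample(rep_len(seq_len(n_modules), length(de)))
  names(module) <- de
  edges <- list()
  add_pairs <- function(a, b, p) {
    # Bernoulli(p) over all unordered pairs between vectors a and b
    grid <- expand.grid(x = a, y = b, stringsAsFactors = FALSE)
    if (identical(a, b)) grid <- grid[grid$x < grid$y, , drop = FALSE]
    keep <- runif(nrow(grid)) < p
    grid[keep, , drop = FALSE]
  }
  for (m in seq_len(n_modules)) {
    gm <- sample(de[module == m]) # random order feeds the PA backbone
    if (length(gm) > pa_m) {
      pa <- igraph::sample_pa(length(gm), power = pa_power, m = pa_m,
                              directed = FALSE)
      el <- igraph::as_edgelist(pa)
      edges[[length(edges) + 1L]] <-
        data.frame(x = gm[el[, 1L]], y = gm[el[, 2L]],
                   stringsAsFactors = FALSE)
    }
    edges[[length(edges) + 1L]] <- add_pairs(sort(gm), sort(gm), intra_p)
  }
  if (inter_p > 0 && n_modules > 1L) {
    for (m1 in seq_len(n_modules - 1L)) {
      for (m2 in (m1 + 1L):n_modules) {
        edges[[length(edges) + 1L]] <-
          add_pairs(de[module == m1], de[module == m2], inter_p)
      }
    }
  }
  if (linker_genes > 0L && n_modules > 1L) {
    for (l in seq_len(linker_genes)) {
      lid <- sprintf("LNK%03d", l)
      mods <- sample(seq_len(n_modules), 2L)
      targets <- c(sample(de[module == mods[1L]],
                          min(2L, sum(module == mods[1L]))),
                   sample(de[module == mods[2L]],
                          min(2L, sum(module == mods[2L]))))
      edges[[length(edges) + 1L]] <-
        data.frame(x = lid, y = targets, stringsAsFactors = FALSE)
    }
  }
  attach <- nonde[runif(length(nonde)) < attach_p]
  if (length(attach)) {
    partners <- sample(genes$gene_id, length(attach), replace = TRUE)
    ok <- partners != attach
    edges[[length(edges) + 1L]] <-
      data.frame(x = attach[ok], y = partners[ok],
                 stringsAsFactors = FALSE)
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::E(g)$interaction <- "direct"
  kg <- knowledge_graph(g, background_size = max(nrow(genes),
                                                 igraph::vcount(g)))
  truth$genes$module[match(de, truth$genes$gene_id)] <- module
  stage_log("generate_graph", nodes = igraph::vcount(kg$graph),
            edges = igraph::ecount(kg$graph), modules = n_modules)
  list(kg = kg, modules = module, truth = truth)
}

#' Generate synthetic gene sets
#'
#' Half of the sets are enriched for DE genes (a fraction `hit_fraction`
#' of their members is drawn from the DE genes), the rest are uniform
#' background draws.
#'
#' @param truth Truth component of a [generate_cohort()] result.
#' @param n_sets Number of sets.
#' @param set_size Genes per set.
#' @param hit_fraction Fraction of DE members in enriched sets (0, 1].
#' @param seed Integer seed.
#' @return Named list of character vectors with attribute `enriched`
#'   (logical per set).
#' @export
generate_genesets <- function(truth, n_sets = 10L, set_size = 50L,
                              hit_fraction = 0.5, seed = 20101020L) {
  if (!(hit_fraction > 0 && hit_fraction <= 1)) {
    stop("hit_fraction must lie in (0, 1]")
  }
  set.seed(seed)
  genes <- truth$genes
  de <- genes$gene_id[genes$is_de]
  n_enriched <- ceiling(n_sets / 2)
  sets <- list()
  enriched <- logical(n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_enriched) {
      n_hit <- min(round(hit_fraction * set_size), length(de))
      members <- c(sample(de, n_hit),
                   sample(genes$gene_id[!genes$is_de], set_size - n_hit))
      enriched[i] <- TRUE
    } else {
      members <- sample(genes$gene_id, set_size)
    }
    sets[[sprintf("SET%02d", i)]] <- unique(members)
  }
  attr(sets, "enriched") <- enriched
  sets
}
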