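#' Build focus-gene networks on a knowledge graph
#'
#' Deterministic greedy replacement for the proprietary network algorithms
#' of commercial pathway tools, reproducing their observable behaviour: a
#' hard cap on network size (default 35 genes), non-focus "linker" genes
#' recruited for connectivity, overlapping networks, and trivial two-node
#' networks around isolated focus genes.
#'
#' Construction: until every focus gene with at least one interaction is
#' covered, seed a new network at the uncovered focus gene with the most
#' focus genes within graph distance 2 (ties broken lexicographically).
#' Grow by repeatedly adding, among the neighbours of the current members,
#' the gene (focus or linker) that brings the most not-yet-covered focus
#' genes within reach -- the candidate itself or its direct neighbours,
#' so every addition keeps an uncovered focus gene within distance 2.
#' "Covered" counts focus genes in any previously built network and those
#' already absorbed by the current one. Ties break by connectivity into
#' the current members and then lexicographically. Growth stops at
#' `max_size` or when no candidate brings a new focus gene within reach.
#' A network that would remain a singleton recruits its best-connected
#' partner, giving the two-node pattern. Hub genes -- including focus
#' genes already covered elsewhere -- are recruited into several networks
#' for connectivity, which is what makes networks share genes.
#'
#' @param focus_genes Character vector of selected (focus) genes.
#' @param kg A [knowledge_graph()].
#' @param max_size Maximum genes per network (>= 2).
#' @return List of `gene_network` objects sorted by rank: each has
#'   `id`, `members`, `focus`, `score`, `rank`.
#' @export
build_networks <- function(focus_genes, kg, max_size = 35L) {
  if (length(focus_genes) == 0L) stop("empty focus gene set")
  if (max_size < 2L) stop("max_size must be >= 2")
  g <- kg$graph
  nodes <- igraph::V(g)$name
  focus_genes <- unique(focus_genes)
  n_focus_total <- length(focus_genes)
  focus_in <- intersect(focus_genes, nodes)
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, function(v) nodes[as.integer(v)])
  names(adj) <- nodes
  is_focus <- structure(nodes %in% focus_in, names = nodes)

  # focus genes reachable from f within distance 2 (used for seeding order)
  seed_score <- vapply(focus_in, function(f) {
    nb <- adj[[f]]
    nb2 <- unique(c(nb, unlist(adj[nb], use.names = FALSE)))
    sum(is_focus[setdiff(nb2, f)])
  }, numeric(1L))

  covered <- character(0)
  eligible <- focus_in[deg[focus_in] >= 1L]
  networks <- list()
  while (length(uncov <- setdiff(eligible, covered)) > 0L) {
    sc <- seed_score[uncov]
    seed <- sort(uncov[sc == max(sc)])[1L]
    members <- seed
    cov_local <- union(covered, seed)
    pick_best <- function(cand, gain) {
      best <- cand[gain == max(gain)]
      if (length(best) > 1L) {
        into <- vapply(best, function(c_) sum(adj[[c_]] %in% members),
                       numeric(1L))
        best <- best[into == max(into)]
      }
      sort(best)[1L]
    }
    repeat {
      if (length(members) >= max_size) break
      cand <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                      members)
      if (length(cand) == 0L) break
      gain <- vapply(cand, function(c_) {
        reach <- setdiff(unique(c(c_, adj[[c_]])), c(members, cov_local))
        sum(is_focus[reach])
      }, numeric(1L))
      if (max(gain) == 0) break
      add <- pick_best(cand, gain)
      if (is_focus[add] && !(add %in% cov_local)) {
        cov_local <- c(cov_local, add)
      }
      members <- c(members, add)
    }
    if (length(members) == 1L && deg[seed] >= 1L) {
      nb <- adj[[seed]]
      into <- deg[nb]
      members <- c(members, sort(nb[into == max(into)])[1L])
    }
    focus_m <- intersect(members, focus_in)
    covered <- union(covered, focus_m)
    networks[[length(networks) + 1L]] <-
      list(members = sort(members), focus = sort(focus_m))
  }
  for (i in seq_along(networks)) {
    networks[[i]]$score <- score_network(networks[[i]], kg, n_focus_total)
  }
  networks <- rank_networks(networks)
  stage_log("build_networks", focus_in = length(focus_in),
            networks = length(networks))
  networks
}

# total order: score desc, focus count desc, lexicographic smallest member
rank_networks <- function(networks) {
  key <- order(-vapply(networks, `[[`, 0, "score"),
               -vapply(networks, function(n) length(n$focus), 0),
               vapply(networks, function(n) n$members[1L], ""))
  networks <- networks[key]
  for (i in seq_along(networks)) {
    networks[[i]]$rank <- i
    networks[[i]]$id <- i
    class(networks[[i]]) <- "gene_network"
  }
  networks
}

#' Score a network by focus-gene enrichment
#'
#' The score is the negative base-10 logarithm of the hypergeometric
#' upper-tail probability of drawing at least `|focus|` focus genes in
#' `|members|` draws from a background of `background_size` genes
#' containing `n_focus_total` focus genes. A score of 2 therefore means a
#' 1-in-100 chance that the focus genes assemble in the network at random.
#'
#' @param network A `gene_network` (or list with `members`, `focus`).
#' @param kg The [knowledge_graph()] providing `background_size`.
#' @param n_focus_total Total number of focus genes in the analysis.
#' @return Non-negative score, -log10 p.
#' @export
score_network <- function(network, kg, n_focus_total) {
  k <- length(network$focus)
  m <- length(network$members)
  if (k > m) stop("focus count exceeds member count")
  if (n_focus_total < k) stop("n_focus_total must be >= |focus|")
  bg <- kg$background_size
  p <- phyper(k - 1, n_focus_total, bg - n_focus_total, m,
              lower.tail = FALSE)
  max(0, -log10(p))
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network #", x$rank, ": ", length(x$members), " genes (",
      length(x$focus), " focus), score ", signif(x$score, 3), "\n", sep = "")
  invisible(x)
}

#' Structuring metrics from raw counts
#'
#' Pure arithmetic used by [compute_metrics()]: the percentage of
#' network-eligible genes found in at least two networks (the structuring
#' signal), and the main-network specific-gene count and percentage
#' (main-network size minus the common genes it contains, over eligible).
#'
#' @param genes_output Genes selected at this stringency level.
#' @param eligible Focus genes placed in at least one network.
#' @param common Genes found in at least two networks.
#' @param main_size Genes in the main (top-scoring) network.
#' @param common_in_main Common genes that belong to the main network.
#' @param best_score Score of the main network.
#' @param level Stringency level label.
#' @return A `stringency_metrics` (one-row data.frame).
#' @export
structuring_metrics <- function(genes_output, eligible, common, main_size,
                                common_in_main = common, best_score = NA_real_,
                                level = NA_character_) {
  if (common > eligible) stop("common genes cannot exceed eligible genes")
  specific <- main_size - common_in_main
  out <- data.frame(level = level,
                    genes_output = as.integer(genes_output),
                    eligible = as.integer(eligible),
                    common = as.integer(common),
                    common_pct = round(100 * common / eligible, 2),
                    main_size = as.integer(main_size),
                    specific = as.integer(specific),
                    specific_pct = round(100 * specific / eligible, 2),
                    best_score = best_score,
                    stringsAsFactors = FALSE)
  class(out) <- c("stringency_metrics", "data.frame")
  out
}

#' Structuring metrics of a network list
#'
#' Computes, for one stringency level, the table of metrics used for
#' threshold selection: eligible focus genes, genes common to two or more
#' networks, the main-network size and its specific genes, and the best
#' score. The "main network" is the meta-network component containing the
#' top-scoring network -- all networks chained to it by shared genes -- and
#' its size is counted in eligible (focus) genes, mirroring how the
#' dominant interconnected structure is tallied.
#'
#' @param networks Output of [build_networks()].
#' @param genes_output Number of genes selected at this level.
#' @param major_min_focus Focus count for the major-network flag.
#' @param level Level label for the output row.
#' @return A `stringency_metrics` row.
#' @export
compute_metrics <- function(networks, genes_output,
                            major_min_focus = 15L, level = NA_character_) {
  if (length(networks) == 0L) stop("need at least one network")
  focus_all <- unlist(lapply(networks, `[[`, "focus"), use.names = FALSE)
  eligible_set <- unique(focus_all)
  membership <- table(unlist(lapply(networks, function(n)
    unique(intersect(n$members, eligible_set))), use.names = FALSE))
  common_set <- names(membership)[membership >= 2L]
  meta <- meta_network(networks, major_min_focus)
  top_component <- meta$components[[which(vapply(
    meta$components, function(ids) 1L %in% ids, logical(1L)))]]
  main_members <- intersect(
    unique(unlist(lapply(networks[top_component], `[[`, "members"),
                  use.names = FALSE)),
    eligible_set)
  common_in_main <- length(intersect(common_set, main_members))
  structuring_metrics(genes_output = genes_output,
                      eligible = length(eligible_set),
                      common = length(common_set),
                      main_size = length(main_members),
                      common_in_main = common_in_main,
                      best_score = networks[[1L]]$score,
                      level = level)
}

#' Meta-network of overlapping networks
#'
#' Two networks are linked when they share at least one gene; the edge
#' weight is the number of shared genes. Networks with at least
#' `major_min_focus` focus genes are flagged major. Connected components of
#' this graph are the meta-networks.
#'
#' @param networks Output of [build_networks()].
#' @param major_min_focus Major-network focus threshold.
#' @return List with `edges` (data.frame `net_a`, `net_b`, `shared`),
#'   `major` (logical per network) and `components` (list of integer
#'   vectors of network ranks).
#' @export
meta_network <- function(networks, major_min_focus = 15L) {
  if (length(networks) == 0L) stop("need at least one network")
  n <- length(networks)
  edges <- data.frame(net_a = integer(0), net_b = integer(0),
                      shared = integer(0))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        shared <- length(intersect(networks[[i]]$members,
                                   networks[[j]]$members))
        if (shared >= 1L) {
          edges <- rbind(edges, data.frame(net_a = i, net_b = j,
                                           shared = shared))
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, 1:2] else data.frame(from = integer(0), to = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)
  components <- split(as.integer(igraph::V(g)$name), comp$membership)
  names(components) <- NULL
  major <- vapply(networks, function(x) length(x$focus) >= major_min_focus,
                  logical(1L))
  list(edges = edges, major = major, components = components)
}

#' Focus-gene sharing between consecutive stringency levels
#'
#' For each of the `top_k` best networks at the stricter level, the
#' percentage of its focus genes found among the members of each network at
#' the looser level. Rows follow the strict ranking, columns the loose
#' ranking; entries are percentages rounded to one decimal.
#'
#' @param strict_networks Networks at the stricter level (ranked).
#' @param loose_networks Networks at the looser level (ranked).
#' @param top_k Number of strict networks to trace (default 1).
#' @return Numeric matrix, `top_k` rows by `length(loose_networks)` columns.
#' @export
cross_level_sharing <- function(strict_networks, loose_networks,
                                top_k = 1L) {
  if (length(strict_networks) == 0L || length(loose_networks) == 0L) {
    stop("both network lists must be non-empty")
  }
  top_k <- min(top_k, length(strict_networks))
  m <- matrix(0, nrow = top_k, ncol = length(loose_networks),
              dimnames = list(paste0("strict_", seq_len(top_k)),
                              paste0("loose_", seq_along(loose_networks))))
  for (r in seq_len(top_k)) {
    fr <- strict_networks[[r]]$focus
    if (length(fr) == 0L) next
    for (c_ in seq_along(loose_networks)) {
      m[r, c_] <- round(
        100 * length(intersect(fr, loose_networks[[c_]]$members)) /
          length(fr), 1)
    }
  }
  m
}

#' Score gene sets against a selection
#'
#' One-sided Fisher exact enrichment of each gene set in the selected
#' genes, against a background of `background_size` assayable genes; the
#' score is -log10 p, zero when no enrichment is possible.
#'
#' @param selection A `gene_selection` (or character vector of genes).
#' @param genesets Named list of character vectors (see [read_gmt()]).
#' @param background_size Number of assayable genes.
#' @return Data.frame: `set`, `set_size`, `hits`, `p`, `score`.
#' @export
score_genesets <- function(selection, genesets, background_size) {
  genes <- if (inherits(selection, "gene_selection")) selection$gene_ids
           else as.character(selection)
  if (length(genesets) == 0L) stop("no gene sets supplied")
  m <- length(genes)
  rows <- lapply(names(genesets), function(nm) {
    set <- unique(genesets[[nm]])
    k <- length(intersect(genes, set))
    K <- length(set)
    if (background_size < K || background_size < m) {
      stop("background_size smaller than a gene set or the selection")
    }
    p <- phyper(k - 1, K, background_size - K, m, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, hits = k, p = p,
               score = max(0, -log10(p)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Write a network list as a long-format TSV
#' @param networks Output of [build_networks()].
#' @param path Output TSV path.
#' @export
write_networks <- function(networks, path) {
  rows <- do.call(rbind, lapply(networks, function(nw) {
    data.frame(network_id = nw$rank, member = nw$members,
               is_focus = as.integer(nw$members %in% nw$focus),
               score = nw$score)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
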