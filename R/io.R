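#' Read a paired intensity table for one donor
#'
#' Reads a tab-separated table of background-subtracted fluorescence
#' intensities for one donor, with one row per probe. The expected header is
#' `gene_id`, `ref`, `test` and an optional `flag` column (0/1); `#` lines
#' are comments. Duplicate `gene_id` rows are retained as replicate probes.
#'
#' @param path Path to a TSV file.
#' @param donor_id Donor identifier attached to every record.
#' @return A data.frame with columns `gene_id`, `donor_id`,
#'   `intensity_ref`, `intensity_test`, `flagged`.
#' @export
read_intensity_table <- function(path, donor_id) {
  stopifnot(is.character(donor_id), length(donor_id) == 1L, nzchar(donor_id))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("gene_id", "ref", "test")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("intensity table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("ref", "test")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric ", col, " intensity at data line ", bad[1L],
             " of ", path, ": '", v[bad[1L]], "'")
      }
      df[[col]] <- num
    }
  }
  bad <- which(!is.finite(df$ref) | !is.finite(df$test))
  if (length(bad)) {
    stop("non-finite intensity at data line ", bad[1L], " of ", path)
  }
  if (any(!nzchar(df$gene_id))) stop("empty gene_id in ", path)
  flagged <- if ("flag" %in% names(df)) as.numeric(df$flag) != 0 else
    rep(FALSE, nrow(df))
  out <- data.frame(gene_id = as.character(df$gene_id),
                    donor_id = donor_id,
                    intensity_ref = df$ref,
                    intensity_test = df$test,
                    flagged = flagged,
                    stringsAsFactors = FALSE)
  stage_log("read_intensity_table", donor = donor_id, rows_in = nrow(df),
            flagged = sum(flagged))
  out
}

#' Write a paired intensity table
#'
#' @param pairs Data.frame as returned by [read_intensity_table()].
#' @param path Output TSV path.
#' @export
write_intensity_table <- function(pairs, path) {
  out <- data.frame(gene_id = pairs$gene_id,
                    ref = pairs$intensity_ref,
                    test = pairs$intensity_test,
                    flag = as.integer(pairs$flagged))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a knowledge graph
#'
#' A knowledge graph is an undirected simple graph of gene interactions, a
#' desk-scale stand-in for a curated interaction knowledge base. Each edge
#' carries an `interaction` tag (`direct` or `indirect`). `background_size`
#' is the number of assayable genes used as the enrichment background; it
#' may exceed the number of nodes because most assayed genes have no curated
#' interaction.
#'
#' @param graph An [igraph::graph] object (undirected, simple).
#' @param background_size Number of genes in the assay background.
#' @return An object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(graph, background_size = igraph::vcount(graph)) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph)
  graph <- igraph::simplify(graph, edge.attr.comb = "first")
  if (background_size < igraph::vcount(graph)) {
    stop("background_size must be at least the number of graph nodes")
  }
  structure(list(graph = graph, background_size = background_size),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("knowledge_graph:", igraph::vcount(x$graph), "genes,",
      igraph::ecount(x$graph), "interactions; background",
      x$background_size, "genes\n")
  invisible(x)
}

#' Read an interaction edge list
#'
#' TSV columns `gene_a`, `gene_b` and optional `interaction`
#' (`direct`/`indirect`, default `direct`). Self-loops are dropped with a
#' warning and duplicated edges collapse to a single undirected edge.
#'
#' @param path TSV path.
#' @param background_size Optional background size; defaults to the node count.
#' @return A [knowledge_graph()].
#' @export
read_edge_list <- function(path, background_size = NULL) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty edge list: ", path)
  need <- c("gene_a", "gene_b")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns gene_a, gene_b")
  }
  interaction <- if ("interaction" %in% names(df)) df$interaction else
    rep("direct", nrow(df))
  bad <- setdiff(unique(interaction), c("direct", "indirect"))
  if (length(bad)) {
    stop("unknown interaction label(s): ", paste(bad, collapse = ", "))
  }
  loops <- df$gene_a == df$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from ", path)
    df <- df[!loops, , drop = FALSE]
    interaction <- interaction[!loops]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = df$gene_a, to = df$gene_b, interaction = interaction),
    directed = FALSE)
  kg <- knowledge_graph(g, background_size %||% igraph::vcount(g))
  stage_log("read_edge_list", nodes = igraph::vcount(kg$graph),
            edges = igraph::ecount(kg$graph))
  kg
}

#' Write a knowledge graph as an edge list
#' @param kg A [knowledge_graph()].
#' @param path Output TSV path.
#' @export
write_edge_list <- function(kg, path) {
  el <- igraph::as_data_frame(kg$graph, what = "edges")
  names(el)[1:2] <- c("gene_a", "gene_b")
  if (!"interaction" %in% names(el)) el$interaction <- "direct"
  write.table(el[, c("gene_a", "gene_b", "interaction")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, fields `name`, `description`, then member
#' genes. Duplicate members within a set are de-duplicated.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields")
    }
    sets[[fields[1L]]] <- unique(fields[-(1:2)])
  }
  stage_log("read_gmt", sets = length(sets))
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable thresholds of the pipeline. Defaults follow the
#' method's canonical operating point: per-donor significance `p_threshold`
#' 0.1 (EV 1.28), occurrence levels from all donors down to half, a 35-gene
#' network cap, and a major-network focus threshold of 15.
#'
#' @param ev_threshold Per-donor EV cut; if `NULL`, derived from
#'   `p_threshold` via [p_to_ev()].
#' @param p_threshold Per-donor one-sided significance level.
#' @param occurrence_levels Integer vector of occurrence levels k (out of n
#'   donors) to scan, strictest first.
#' @param network_max_size Maximum genes per network.
#' @param major_network_min_focus Focus-gene count above which a network is
#'   called major.
#' @param overlap_metric Pairwise donor overlap normalization:
#'   `"mean"`, `"min"` or `"jaccard"`.
#' @param technical_variability Assumed technical variability, percent.
#' @param background_size Enrichment background; `NULL` = graph node count.
#' @param seed Integer seed used by every randomized operation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(ev_threshold = NULL,
                       p_threshold = 0.1,
                       occurrence_levels = NULL,
                       network_max_size = 35L,
                       major_network_min_focus = 15L,
                       overlap_metric = c("mean", "min", "jaccard"),
                       technical_variability = 20,
                       background_size = NULL,
                       seed = 20101020L) {
  overlap_metric <- match.arg(overlap_metric)
  if (!(p_threshold > 0 && p_threshold < 1)) {
    stop("p_threshold must lie in (0, 1)")
  }
  if (is.null(ev_threshold)) ev_threshold <- p_to_ev(min(p_threshold, 0.5))
  if (network_max_size < 2L) stop("network_max_size must be >= 2")
  if (!is.null(occurrence_levels)) {
    occurrence_levels <- as.integer(occurrence_levels)
    if (any(occurrence_levels < 1L)) stop("occurrence levels must be >= 1")
  }
  structure(list(ev_threshold = ev_threshold,
                 p_threshold = p_threshold,
                 occurrence_levels = occurrence_levels,
                 network_max_size = as.integer(network_max_size),
                 major_network_min_focus = as.integer(major_network_min_focus),
                 overlap_metric = overlap_metric,
                 technical_variability = technical_variability,
                 background_size = background_size,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' The YAML file mirrors the fields of [run_config()]; absent fields take
#' their defaults.
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
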