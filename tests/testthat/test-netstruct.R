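# brute-force hypergeometric upper tail by pmf summation
hyper_tail_oracle <- function(k, total_focus, bg, m) {
  sum(vapply(k:min(m, total_focus), function(j)
    dhyper(j, total_focus, bg - total_focus, m), numeric(1)))
}

clique_edges <- function(genes) {
  t(combn(genes, 2))
}

test_that("build_networks separates disconnected components", {
  g1 <- sprintf("A%02d", 1:10)
  g2 <- sprintf("B%02d", 1:10)
  el <- rbind(clique_edges(g1), clique_edges(g2))
  kg <- knowledge_graph(igraph::graph_from_edgelist(el, directed = FALSE),
                        background_size = 100)
  focus <- c(g1[1:5], g2[1:5])
  nets <- quietly(build_networks(focus, kg, max_size = 35))
  expect_length(nets, 2L)
  expect_length(intersect(nets[[1]]$members, nets[[2]]$members), 0L)
  expect_setequal(unlist(lapply(nets, `[[`, "focus")), focus)
})

test_that("build_networks covers a large connected module with overlap", {
  set.seed(42)
  g <- igraph::sample_pa(40, power = 1.2, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%02d", 1:40)
  kg <- knowledge_graph(g, background_size = 500)
  focus <- igraph::V(g)$name
  nets <- quietly(build_networks(focus, kg, max_size = 35))
  expect_gte(length(nets), 2L)
  # full coverage of the connected focus set
  expect_setequal(unlist(lapply(nets, `[[`, "focus")), focus)
  # networks share at least one gene
  shared <- length(intersect(nets[[1]]$members, nets[[2]]$members))
  expect_gte(shared, 1L)
  expect_true(all(vapply(nets, function(n) length(n$members), 0L) <= 35))
})

test_that("an isolated focus gene forms a two-node network", {
  el <- rbind(c("LONER", "PARTNER"), clique_edges(sprintf("C%02d", 1:6)))
  kg <- knowledge_graph(igraph::graph_from_edgelist(el, directed = FALSE),
                        background_size = 100)
  nets <- quietly(build_networks(c("LONER", sprintf("C%02d", 1:3)), kg))
  two <- Filter(function(n) "LONER" %in% n$members, nets)
  expect_length(two, 1L)
  expect_setequal(two[[1]]$members, c("LONER", "PARTNER"))
  expect_equal(length(two[[1]]$focus), 1L)
})

test_that("build_networks is deterministic and validates input", {
  set.seed(1)
  g <- igraph::sample_gnp(60, 0.1)
  igraph::V(g)$name <- sprintf("D%02d", 1:60)
  kg <- knowledge_graph(g, background_size = 200)
  focus <- sprintf("D%02d", 1:20)
  n1 <- quietly(build_networks(focus, kg))
  n2 <- quietly(build_networks(focus, kg))
  expect_identical(n1, n2)
  expect_error(quietly(build_networks(character(0), kg)), "empty")
  expect_error(quietly(build_networks(focus, kg, max_size = 1)), "max_size")
})

test_that("score_network agrees with the brute-force hypergeometric oracle", {
  kg <- list(background_size = 1000)
  # the spec instance: 35 members, 10 focus, background 1000, 100 focus total
  nw <- list(members = sprintf("M%02d", 1:35), focus = sprintf("M%02d", 1:10))
  expect_equal(score_network(nw, kg, 100),
               -log10(hyper_tail_oracle(10, 100, 1000, 35)),
               tolerance = 1e-9)
  set.seed(99)
  for (i in 1:100) {
    m <- sample(2:35, 1)
    k <- sample(0:m, 1)
    total <- sample(k:200, 1)
    bg <- 1000 + sample(0:500, 1)
    nw <- list(members = paste0("g", seq_len(m)),
               focus = if (k > 0) paste0("g", seq_len(k)) else character(0))
    p_oracle <- if (k == 0) 1 else hyper_tail_oracle(k, total, bg, m)
    expect_equal(10^(-score_network(nw, kg_bg <- list(background_size = bg),
                                    total)),
                 p_oracle, tolerance = 1e-9)
  }
  # no enrichment possible: p = 1, score 0
  nw0 <- list(members = c("a", "b"), focus = character(0))
  expect_equal(score_network(nw0, kg, 10), 0)
  expect_error(score_network(list(members = "a", focus = c("a", "b")),
                             kg, 10), "exceeds")
})

test_that("structuring metrics reproduce the printed arithmetic", {
  m <- structuring_metrics(genes_output = 300, eligible = 202, common = 63,
                           main_size = 193, common_in_main = 63,
                           best_score = 38, level = ">=4/6")
  expect_equal(m$common_pct, 31.19)
  expect_equal(m$specific, 130L)
  expect_equal(m$specific_pct, 64.36)
  expect_error(structuring_metrics(10, 5, 6, 5), "common")
})

test_that("compute_metrics counts common and main-component genes", {
  # two overlapping networks plus one singleton pair
  nets <- mock_networks(
    list(members = c("A", "B", "C", "L1"), focus = c("A", "B", "C")),
    list(members = c("C", "D", "L1"), focus = c("C", "D")),
    list(members = c("X", "L2"), focus = "X"))
  m <- compute_metrics(nets, genes_output = 10, level = "t")
  expect_equal(m$eligible, 5L)       # A B C D X
  expect_equal(m$common, 1L)         # C in two networks
  expect_equal(m$common_pct, 20)
  expect_equal(m$main_size, 4L)      # focus genes in the top component
  expect_equal(m$specific, 3L)
  expect_equal(m$best_score, nets[[1]]$score)

  single <- mock_networks(list(members = c("A", "B"), focus = c("A", "B")))
  ms <- compute_metrics(single, genes_output = 2)
  expect_equal(ms$common, 0L)
  expect_equal(ms$common_pct, 0)
  expect_equal(ms$specific, ms$main_size)
})

test_that("meta_network links networks by shared genes", {
  nets <- mock_networks(
    list(members = c("A", "B", "C"), focus = c("A", "B")),
    list(members = c("B", "C", "D"), focus = "D"),
    list(members = c("X", "Y"), focus = "X"))
  meta <- meta_network(nets)
  expect_equal(nrow(meta$edges), 1L)
  expect_equal(meta$edges$shared, 2L)
  comp_sizes <- sort(vapply(meta$components, length, 0L))
  expect_equal(comp_sizes, c(1L, 2L))

  # a chain of 13 pairwise-linked networks forms one component
  chain <- do.call(mock_networks, lapply(1:13, function(i) {
    list(members = c(paste0("g", i), paste0("g", i + 1)),
         focus = paste0("g", i))
  }))
  expect_length(meta_network(chain)$components, 1L)
  expect_length(meta_network(chain)$components[[1]], 13L)

  # no sharing: every network its own component
  loners <- mock_networks(
    list(members = c("A", "B"), focus = "A"),
    list(members = c("C", "D"), focus = "C"))
  expect_length(meta_network(loners)$components, 2L)
})

test_that("cross_level_sharing reproduces focus-share percentages", {
  strict <- mock_networks(
    list(members = paste0("f", 1:23), focus = paste0("f", 1:23)))
  loose <- mock_networks(
    list(members = c(paste0("f", 1:13), paste0("x", 1:10)),
         focus = paste0("f", 1:13)),
    list(members = paste0("f", 14:23), focus = paste0("f", 14:23)))
  sh <- cross_level_sharing(strict, loose)
  expect_equal(sh[1, 1], 56.5) # 13/23
  expect_equal(sh[1, 2], 43.5)

  subset_case <- cross_level_sharing(
    mock_networks(list(members = c("a", "b"), focus = c("a", "b"))),
    mock_networks(list(members = c("a", "b", "c"), focus = "c")))
  expect_equal(subset_case[1, 1], 100)

  disjoint <- cross_level_sharing(
    mock_networks(list(members = "a", focus = "a")),
    mock_networks(list(members = "z", focus = "z")))
  expect_equal(disjoint[1, 1], 0)
  expect_error(cross_level_sharing(list(), loose), "non-empty")
})

test_that("score_genesets matches exact hypergeometric enrichment", {
  sel <- paste0("g", 1:10)
  sets <- list(PERFECT = paste0("g", 1:10),
               MISS = paste0("z", 1:10))
  out <- score_genesets(sel, sets, background_size = 1000)
  expect_equal(out$p[1], hyper_tail_oracle(10, 10, 1000, 10),
               tolerance = 1e-12)
  expect_equal(out$score[1], -log10(out$p[1]))
  # disjoint set: no enrichment, score 0
  expect_equal(out$p[2], 1)
  expect_equal(out$score[2], 0)
  # set equal to the whole background: p = 1, score 0
  whole <- list(ALL = paste0("g", 1:50))
  out2 <- score_genesets(paste0("g", 1:10), whole, background_size = 50)
  expect_equal(out2$p, 1)
  expect_equal(out2$score, 0)
})
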