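edge_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  readr::write_lines(c("protein1 protein2 combined_score", lines), path)
  path
}

test_that("STRING loading filters on score and collapses orientations", {
  path <- edge_file(c("A B 400", "B A 400", "A C 399", "C D 500", "D C 700"))
  edges <- load_string_edges(path)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$score[edges$a == "A" & edges$b == "B"], 400)
  # max score kept when orientations disagree
  expect_equal(edges$score[edges$a == "C" & edges$b == "D"], 700)
  expect_false(any(edges$a == "A" & edges$b == "C"))
})

test_that("protein-to-gene mapping drops unmapped proteins and keeps max score", {
  path <- edge_file(c("p1 p2 500", "p3 p2 600", "p9 p1 800"))
  id_map <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
                          gene_id = c("G1", "G2", "G1"))
  edges <- load_string_edges(path, id_map = id_map)
  # p1-p2 and p3-p2 both collapse onto G1-G2; p9 is unmapped
  expect_equal(nrow(edges), 1)
  expect_equal(edges$score, 600)
  expect_equal(attr(edges, "report")$n_unmapped, 1L)
})

test_that("tissue network keeps only expressed nodes and their edges", {
  edges <- tibble::tibble(a = c("A", "A", "B"), b = c("B", "C", "C"),
                          score = c(500L, 600L, 700L))
  expr <- tibble::tibble(gene_id = c("A", "B", "C", "D"), tpm = c(5, 3, 0, 2))
  net <- build_cs_ppi(edges, expr, "fetal")
  expect_equal(net$nodes$gene_id, c("A", "B", "D"))
  expect_equal(nrow(net$edges), 1)  # only A-B survives; C is unexpressed
  expect_equal(glance(net)$n_edges, 1)
  # a protein absent from the expression table is removed too
  expect_false("E" %in% net$nodes$gene_id)
})

test_that("induced subnetworks never gain edges", {
  edges <- tibble::tibble(a = c("A", "A", "B"), b = c("B", "C", "C"),
                          score = c(500L, 600L, 700L))
  expr <- tibble::tibble(gene_id = c("A", "B", "C"), tpm = c(1, 1, 1))
  net <- build_cs_ppi(edges, expr, "t")
  sub <- extract_subnetwork(net, c("A", "B"))
  expect_equal(nrow(sub$edges), 1)
  expect_equal(sub$edges$a, "A")
  empty <- extract_subnetwork(net, "Z")
  expect_equal(nrow(empty$nodes), 0)
  expect_lte(nrow(sub$edges), nrow(net$edges))
})

two_clique_net <- function() {
  cl1 <- t(utils::combn(paste0("a", 1:4), 2))
  cl2 <- t(utils::combn(paste0("b", 1:4), 2))
  edges <- tibble::tibble(
    a = c(cl1[, 1], cl2[, 1], "a4"),
    b = c(cl1[, 2], cl2[, 2], "b1"),
    score = 500L
  )
  expr <- tibble::tibble(gene_id = c(paste0("a", 1:4), paste0("b", 1:4)), tpm = 1)
  build_cs_ppi(edges, expr, "t")
}

test_that("Louvain recovers two bridged cliques and reports true modularity", {
  net <- two_clique_net()
  part <- louvain_cluster(net, seed = 3)
  mem <- tidy(part)
  expect_equal(length(unique(mem$module)), 2)
  expect_equal(length(unique(mem$module[startsWith(mem$gene_id, "a")])), 1)
  expect_equal(length(unique(mem$module[startsWith(mem$gene_id, "b")])), 1)
  # reported modularity equals independent recomputation from the definition
  q_ref <- modularity_from_edges(net$edges, net$nodes$gene_id,
                                 mem$module[match(net$nodes$gene_id, mem$gene_id)])
  expect_equal(part$modularity, q_ref, tolerance = 1e-10)
  # and equals the exhaustive maximum over all partitions of the 8 nodes
  expect_equal(part$modularity,
               max_modularity_exhaustive(net$edges, net$nodes$gene_id),
               tolerance = 1e-10)
})

test_that("identical seeds give identical partitions; empty networks error", {
  net <- two_clique_net()
  a <- louvain_cluster(net, seed = 11)
  b <- louvain_cluster(net, seed = 11)
  expect_equal(tidy(a), tidy(b))
  empty <- build_cs_ppi(tibble::tibble(a = character(), b = character(),
                                       score = integer()),
                        tibble::tibble(gene_id = character(), tpm = numeric()),
                        "t")
  expect_error(louvain_cluster(empty), "empty")
})

test_that("well-separated planted modules are recovered at high ARI", {
  genes <- sprintf("g%02d", 1:20)
  ok <- 0
  for (s in 1:100) {
    sim <- simulate_ppi(
      genes,
      list(sizes = c(10L, 10L), p_within = 0.9, p_between = 0.02),
      seed = s
    )
    expr <- tibble::tibble(gene_id = genes, tpm = 1)
    net <- build_cs_ppi(sim$edges, expr, "t")
    part <- louvain_cluster(net, seed = s)
    mem <- tidy(part)
    truth <- sim$truth$module[match(mem$gene_id, sim$truth$gene_id)]
    if (ari(mem$module, truth) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("hypergeometric ORA equals the exact combinatorial sum", {
  universe <- sprintf("u%03d", 1:100)
  modules <- tibble::tibble(gene_id = universe[1:5], module = 1L)
  # pathway of 10 genes overlapping the module in exactly 3
  pathways <- list(pw = c(universe[1:3], universe[50:56]))
  res <- ora_pathways(modules, pathways, universe)
  expect_equal(res$k, 3)
  expect_equal(res$p, hyper_upper_sum(3, 10, 100, 5), tolerance = 1e-12)
  # module contained in a pathway equal to the universe: certain event
  res2 <- ora_pathways(modules, list(all = universe), universe)
  expect_equal(res2$p, 1)
  # zero overlap: upper tail at 0 is 1
  res3 <- ora_pathways(modules, list(none = universe[90:99]), universe)
  expect_equal(res3$p, 1)
})

test_that("ORA matches the exact sum across a parameter sweep", {
  set.seed(60)
  for (rep in 1:20) {
    N <- sample(20:200, 1)
    universe <- sprintf("x%04d", seq_len(N))
    n <- sample(3:15, 1)
    K <- sample(3:15, 1)
    k <- sample(0:min(n, K), 1)
    modules <- tibble::tibble(gene_id = universe[1:n], module = 1L)
    pw <- c(universe[seq_len(k)],
            if (K > k) universe[(n + 1):(n + K - k)] else character(0))
    res <- ora_pathways(modules, list(pw = pw), universe)
    expect_equal(res$p, hyper_upper_sum(k, K, N, n), tolerance = 1e-10)
  }
})
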