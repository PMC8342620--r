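#' Load a STRING-style protein-protein interaction edge list
#'
#' Reads "protein.links"-style text (`protein1 protein2 combined_score`,
#' whitespace-delimited, optional header), drops edges below `min_score`
#' (default 400, the medium-confidence STRING cut), collapses the two stored
#' orientations of each pair to one undirected edge, and optionally maps
#' protein ids to gene ids. When several protein pairs collapse onto one gene
#' pair the maximum score is kept. Self edges after mapping are dropped.
#'
#' @param path Edge-list file.
#' @param min_score Minimum combined score, inclusive (default 400).
#' @param id_map Optional tibble `protein_id`, `gene_id`; unmapped proteins
#'   are dropped and counted in `attr(, "report")`.
#' @return Tibble `a`, `b`, `score` with `a < b` lexicographically.
#' @export
load_string_edges <- function(path, min_score = 400, id_map = NULL) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("protein", first, ignore.case = TRUE)
  tbl <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tbl) < 3) abort("edge list needs 3 columns: protein1 protein2 score")
  tbl <- tbl[, 1:3]
  names(tbl) <- c("a", "b", "score")
  if (!is.numeric(tbl$score) || any(tbl$score != round(tbl$score))) {
    abort("combined scores must be integers")
  }
  tbl <- as_tibble(tbl)
  tbl <- filter(tbl, .data$score >= min_score)
  n_unmapped <- 0L
  if (!is.null(id_map)) {
    assert_cols(id_map, c("protein_id", "gene_id"))
    ga <- id_map$gene_id[match(tbl$a, id_map$protein_id)]
    gb <- id_map$gene_id[match(tbl$b, id_map$protein_id)]
    mapped <- !is.na(ga) & !is.na(gb)
    n_unmapped <- sum(!mapped)
    tbl <- tibble(a = ga[mapped], b = gb[mapped], score = tbl$score[mapped])
  }
  out <- tbl |>
    mutate(lo = pmin(.data$a, .data$b), hi = pmax(.data$a, .data$b)) |>
    filter(.data$lo != .data$hi) |>
    group_by(a = .data$lo, b = .data$hi) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    arrange(.data$a, .data$b)
  attr(out, "report") <- list(n_unmapped = n_unmapped)
  out
}

#' Build a tissue-specific (expression-filtered) PPI network
#'
#' A node survives only if it is expressed in the tissue (TPM strictly
#' greater than zero); proteins absent from the expression table are removed;
#' an edge survives only if both endpoints do.
#'
#' @param edges Undirected edge tibble from [load_string_edges()].
#' @param expression Tibble `gene_id`, `tpm` for the tissue (one row per
#'   gene; typically median or mean TPM across samples).
#' @param tissue Tissue label.
#' @return A `cs_ppi` object: list with `nodes` (tibble `gene_id`, `tpm`),
#'   `edges`, `tissue`.
#' @export
build_cs_ppi <- function(edges, expression, tissue) {
  assert_cols(edges, c("a", "b", "score"))
  assert_cols(expression, c("gene_id", "tpm"))
  nodes <- filter(expression, !is.na(.data$tpm), .data$tpm > 0)
  keep <- edges$a %in% nodes$gene_id & edges$b %in% nodes$gene_id
  net <- structure(
    list(
      nodes = select(nodes, "gene_id", "tpm"),
      edges = edges[keep, , drop = FALSE],
      tissue = tissue
    ),
    class = "cs_ppi"
  )
  net
}

#' @export
print.cs_ppi <- function(x, ...) {
  cat(sprintf(
    "<cs_ppi> %s: %d expressed proteins, %d interactions\n",
    x$tissue, nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cs_ppi <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.cs_ppi <- function(x, ...) {
  tibble(tissue = x$tissue, n_nodes = nrow(x$nodes), n_edges = nrow(x$edges))
}

#' Induced subnetwork on a gene set
#'
#' @param network A `cs_ppi` object.
#' @param gene_set Character vector of gene ids.
#' @return A `cs_ppi` restricted to `gene_set` (nodes kept even when
#'   isolated, so module detection sees singletons).
#' @export
extract_subnetwork <- function(network, gene_set) {
  stopifnot(inherits(network, "cs_ppi"))
  nodes <- filter(network$nodes, .data$gene_id %in% gene_set)
  edges <- filter(network$edges, .data$a %in% nodes$gene_id, .data$b %in% nodes$gene_id)
  structure(list(nodes = nodes, edges = edges, tissue = network$tissue),
            class = "cs_ppi")
}

#' Louvain community detection
#'
#' Greedy modularity optimization (Louvain) on the unweighted network, with
#' the node order fixed by the seed so repeated runs are identical.
#' Singleton components form their own modules.
#'
#' @param network A `cs_ppi` object with at least one node.
#' @param seed RNG seed controlling tie-breaking.
#' @param resolution Resolution parameter (default 1.0; larger favours more,
#'   smaller modules).
#' @return A `module_partition`: list with `membership` (tibble `gene_id`,
#'   `module`), `modularity`, `seed`, `resolution`.
#' @export
louvain_cluster <- function(network, seed = 1L, resolution = 1.0) {
  stopifnot(inherits(network, "cs_ppi"))
  if (nrow(network$nodes) == 0) abort("empty network")
  g <- igraph::graph_from_data_frame(
    network$edges[, c("a", "b")],
    directed = FALSE,
    vertices = network$nodes$gene_id
  )
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  membership <- tibble(
    gene_id = igraph::V(g)$name,
    module = as.integer(igraph::membership(comm))
  )
  structure(
    list(
      membership = membership,
      modularity = igraph::modularity(g, igraph::membership(comm)),
      seed = seed,
      resolution = resolution
    ),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf(
    "<module_partition> %d nodes in %d modules, modularity %.4f\n",
    nrow(x$membership), length(unique(x$membership$module)), x$modularity
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.module_partition <- function(x, ...) x$membership

#' @exportS3Method generics::glance
glance.module_partition <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$membership),
    n_modules = length(unique(x$membership$module)),
    modularity = x$modularity,
    seed = x$seed,
    resolution = x$resolution
  )
}

#' Hypergeometric pathway over-representation analysis
#'
#' For each (module, pathway) cell the upper-tail hypergeometric p value
#' `P(X >= k)` is computed with universe size `N`, pathway size `K` (after
#' intersection with the universe), and module size `n`. Benjamini-Hochberg
#' adjustment is applied across the full module x pathway grid.
#'
#' @param modules Tibble `gene_id`, `module` (e.g. `tidy()` of a
#'   [louvain_cluster()] result); gene ids must lie in the universe.
#' @param pathways Named list of character vectors (pathway gene sets).
#' @param universe Character vector: the statistical domain (all annotated
#'   genes).
#' @return Tibble `module`, `pathway`, `k`, `n`, `K`, `N`, `p`, `q`.
#' @export
ora_pathways <- function(modules, pathways, universe) {
  assert_cols(modules, c("gene_id", "module"))
  universe <- unique(universe)
  if (!all(modules$gene_id %in% universe)) {
    abort("all module genes must belong to the universe")
  }
  N <- length(universe)
  grid <- tidyr::expand_grid(
    module = sort(unique(modules$module)),
    pathway = names(pathways)
  )
  res <- purrr::pmap(grid, function(module, pathway) {
    mg <- unique(modules$gene_id[modules$module == module])
    pg <- intersect(unique(pathways[[pathway]]), universe)
    k <- length(intersect(mg, pg))
    # upper tail including k itself
    p <- phyper(k - 1, length(pg), N - length(pg), length(mg), lower.tail = FALSE)
    tibble(module = module, pathway = pathway, k = k,
           n = length(mg), K = length(pg), N = N, p = p)
  })
  out <- bind_rows(res)
  out$q <- adjust_fdr(out$p)
  arrange(out, .data$p)
}
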