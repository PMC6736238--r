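# Shared toy objects and independent oracles used across test files.

toy_expression <- function() {
  data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
             wt_rpkm = c(2, 4, 1, 10, 5),
             mut_rpkm = c(2, 1, 3, 40, 25),
             stringsAsFactors = FALSE)
}

# five genes whose ratios are exactly {1, 2, 3, 4, 5}
ratio_ladder <- function() {
  data.frame(gene_id = paste0("r", 1:5),
             wt_rpkm = rep(1, 5), mut_rpkm = 1:5,
             stringsAsFactors = FALSE)
}

edges_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(source = r[[1]], target = r[[2]], edge_type = r[[3]],
               sign = if (length(r) > 3) r[[4]] else "unknown",
               stringsAsFactors = FALSE)))
}

# a small embryonic interaction web used by the cascade tests
toy_db <- function(edges = NULL, stages = NULL) {
  if (is.null(stages))
    stages <- list(a = "early embryo", b = "embryo", c = "embryo",
                   d = "larva", q = "early embryo")
  if (is.null(edges)) edges <- genecascades:::empty_interactions()
  annotation_db(
    tf_genes = c("a", "b"),
    stages = stages,
    phenotypes = list(q = "embryonic lethal", a = "embryonic lethal",
                      b = "sterile"),
    interactions = edges
  )
}

classification_of <- function(stable = character(), fluctuating = character(),
                              boundary = character(),
                              undefined = character()) {
  structure(list(stable = stable, fluctuating = fluctuating,
                 boundary = boundary, undefined = undefined,
                 n_total = length(c(stable, fluctuating, boundary,
                                    undefined))),
            class = "fluctuation_classification")
}

# independent sort-and-interpolate quantile oracle (linear interpolation
# between order statistics, the type-7 convention)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, n)] - x[lo + 1])
}

# exhaustive binomial upper-tail oracle
oracle_binom_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# independent reachability oracle over the stage-filtered traversal graph
oracle_cascade_nodes <- function(root, db, allowed_stages) {
  stage_ok <- function(g)
    length(intersect(gene_stages(db, g), allowed_stages)) > 0
  e <- db$interactions
  arcs <- rbind(
    e[e$edge_type == "regulatory", c("source", "target")],
    e[e$edge_type != "regulatory", c("source", "target")],
    stats::setNames(e[e$edge_type != "regulatory", c("target", "source")],
                    c("source", "target")))
  genes <- unique(c(root, arcs$source, arcs$target))
  ok <- genes[vapply(genes, stage_ok, logical(1))]
  ok <- union(ok, root)
  arcs <- arcs[arcs$source %in% ok & arcs$target %in% ok, , drop = FALSE]
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = data.frame(name = ok))
  sort(names(igraph::subcomponent(g, root, mode = "out")))
}

# random stage-labeled interaction graph for property tests
random_graph_db <- function(n_nodes, n_edges, p_embryonic = 0.7) {
  genes <- sprintf("n%02d", seq_len(n_nodes))
  stages <- lapply(genes, function(g)
    if (stats::runif(1) < p_embryonic) sample(c("early embryo", "embryo"), 1)
    else "larva")
  names(stages) <- genes
  src <- sample(genes, n_edges, replace = TRUE)
  tgt <- sample(genes, n_edges, replace = TRUE)
  type <- sample(c("regulatory", "genetic", "physical"), n_edges,
                 replace = TRUE, prob = c(0.6, 0.2, 0.2))
  sign <- ifelse(type == "regulatory",
                 sample(c("positive", "negative"), n_edges, replace = TRUE),
                 "unknown")
  annotation_db(stages = stages,
                interactions = data.frame(source = src, target = tgt,
                                          edge_type = type, sign = sign,
                                          stringsAsFactors = FALSE))
}
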