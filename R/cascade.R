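#' Default life-stage vocabulary for cascade expansion
#'
#' Only genes annotated as expressed in early embryos or in embryos are
#' accepted as downstream cascade members.
#'
#' @export
DEFAULT_STAGES <- c("early embryo", "embryo")

#' Predict direct targets of a translational-regulator query gene
#'
#' A candidate gene is a predicted direct target when all four criteria
#' hold: (1) its mRNA level does not fluctuate between wild type and the
#' query mutant (it is in the stable class — the query regulates its
#' targets translationally, so target mRNA levels are unchanged); (2) it
#' is a transcription factor (so it can have downstream genes); (3) it is
#' expressed at the same time as the query gene (non-empty life-stage
#' overlap); (4) its mutant phenotype resembles the query's (at least
#' `min_phenotype_overlap` shared phenotype terms). The query gene itself
#' is never returned.
#'
#' @param query_gene query gene identifier; must have at least one stage
#'   term in `annotations` (criterion 3 is unevaluable otherwise).
#' @param classification a [classify_genes()] result.
#' @param annotations an [annotation_db()].
#' @param min_phenotype_overlap minimum number of shared phenotype terms;
#'   default 1.
#' @param criteria which of the four criteria to apply; dropping one is
#'   meant for filter-ablation studies, not routine use.
#' @return Lexicographically sorted character vector of target gene ids.
#' @export
find_direct_targets <- function(query_gene, classification, annotations,
                                min_phenotype_overlap = 1,
                                criteria = c("stability", "tf", "stage",
                                             "phenotype")) {
  stopifnot(inherits(classification, "fluctuation_classification"),
            inherits(annotations, "annotation_db"))
  criteria <- match.arg(criteria, several.ok = TRUE)
  q_stages <- gene_stages(annotations, query_gene)
  if ("stage" %in% criteria && length(q_stages) == 0)
    stop(sprintf("query gene '%s' has no life-stage annotation; cannot test simultaneous expression", query_gene))
  q_phen <- gene_phenotypes(annotations, query_gene)
  candidates <- if ("stability" %in% criteria) classification$stable
                else unlist(classification[c("stable", "fluctuating",
                                             "boundary", "undefined")],
                            use.names = FALSE)
  if ("tf" %in% criteria) candidates <- intersect(candidates,
                                                  annotations$tf_genes)
  candidates <- setdiff(candidates, query_gene)
  hits <- vapply(candidates, function(g) {
    (!("stage" %in% criteria) ||
       length(intersect(gene_stages(annotations, g), q_stages)) > 0) &&
      (!("phenotype" %in% criteria) ||
         length(intersect(gene_phenotypes(annotations, g), q_phen)) >=
           min_phenotype_overlap)
  }, logical(1))
  sort(candidates[hits])
}

neighbor_candidates <- function(edges, node) {
  reg_out <- edges$target[edges$edge_type == "regulatory" & edges$source == node]
  undirected <- edges$edge_type %in% c("genetic", "physical")
  partners <- c(edges$target[undirected & edges$source == node],
                edges$source[undirected & edges$target == node])
  unique(c(reg_out, partners))
}

#' Expand a direct target into a gene cascade
#'
#' Breadth-first fixpoint from the root target: from each accepted node,
#' the candidates are the targets of its outgoing regulatory edges plus the
#' partners of its genetic and physical edges (undirected). A candidate is
#' accepted iff it is annotated with at least one stage term in
#' `allowed_stages`. A visited set guarantees termination on cyclic
#' graphs; expansion repeats until no gene is left to extract. All edges
#' whose endpoints are both accepted (including cycle-closing edges) are
#' retained in the cascade. Each node gets a stage tier: `early_embryo`
#' when annotated with the term `"early embryo"`, `embryo` otherwise.
#'
#' @param root_target root gene identifier; must itself pass the stage
#'   filter.
#' @param annotations an [annotation_db()].
#' @param allowed_stages accepted life-stage terms; default
#'   [DEFAULT_STAGES].
#' @param query_gene optional query gene identifier recorded on the
#'   cascade.
#' @param cascade_id identifier; defaults to `"<query>_to_<root>"`.
#' @return Object of class `cascade`: list with `cascade_id`,
#'   `query_gene`, `root_target`, `nodes` (sorted character vector),
#'   `tiers` (named character vector over nodes), `edges` (data.frame
#'   restricted to the nodes), `bottom_genes`.
#' @export
expand_cascade <- function(root_target, annotations,
                           allowed_stages = DEFAULT_STAGES,
                           query_gene = NA_character_,
                           cascade_id = NULL) {
  stopifnot(inherits(annotations, "annotation_db"))
  stage_ok <- function(g)
    length(intersect(gene_stages(annotations, g), allowed_stages)) > 0
  if (!stage_ok(root_target))
    stop(sprintf("root target '%s' has no stage term among: %s",
                 root_target, paste(allowed_stages, collapse = ", ")))
  edges <- annotations$interactions
  visited <- character()
  queue <- root_target
  while (length(queue) > 0) {
    node <- queue[1]
    queue <- queue[-1]
    if (node %in% visited) next
    visited <- c(visited, node)
    cands <- neighbor_candidates(edges, node)
    cands <- cands[!(cands %in% visited) & !(cands %in% queue)]
    accepted <- cands[vapply(cands, stage_ok, logical(1))]
    queue <- c(queue, sort(accepted))
  }
  nodes <- sort(visited)
  keep <- edges$source %in% nodes & edges$target %in% nodes
  sub_edges <- edges[keep, , drop = FALSE]
  sub_edges <- sub_edges[order(sub_edges$source, sub_edges$target,
                               sub_edges$edge_type, sub_edges$sign), ,
                         drop = FALSE]
  rownames(sub_edges) <- NULL
  tiers <- vapply(nodes, function(g) {
    if ("early embryo" %in% gene_stages(annotations, g)) "early_embryo"
    else "embryo"
  }, character(1))
  cc <- structure(
    list(cascade_id = if (is.null(cascade_id))
           paste0(if (is.na(query_gene)) "cascade" else query_gene,
                  "_to_", root_target)
         else cascade_id,
         query_gene = query_gene, root_target = root_target,
         nodes = nodes, tiers = tiers, edges = sub_edges,
         bottom_genes = character()),
    class = "cascade"
  )
  cc$bottom_genes <- find_bottom_genes(cc)
  cc
}

#' @export
print.cascade <- function(x, ...) {
  cat(sprintf("<cascade %s> root %s: %d nodes, %d edges, %d bottom genes\n",
              x$cascade_id, x$root_target, length(x$nodes), nrow(x$edges),
              length(x$bottom_genes)))
  invisible(x)
}

reg_adjacency <- function(cascade) {
  reg <- cascade$edges[cascade$edges$edge_type == "regulatory", , drop = FALSE]
  # self-loops carry no downstream meaning for leaf detection
  reg[reg$source != reg$target, , drop = FALSE]
}

reachable_from <- function(node, adj) {
  seen <- character()
  queue <- node
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, adj$target[adj$source == v])
  }
  setdiff(seen, node)
}

#' Bottom genes of a cascade
#'
#' The bottom genes are the nodes with zero outgoing regulatory edges
#' within the cascade; their protein domains define the cascade's
#' predicted function. When every node has regulatory out-degree > 0 (a
#' pure regulatory cycle), the nodes of the terminal strongly-connected
#' components are returned instead (a node is terminal-SCC when everything
#' it reaches via regulatory edges reaches back).
#'
#' @param cascade a [cascade] object.
#' @return Sorted character vector of gene ids.
#' @export
find_bottom_genes <- function(cascade) {
  stopifnot(inherits(cascade, "cascade"))
  nodes <- cascade$nodes
  if (length(nodes) == 0) stop("cascade has no nodes")
  adj <- reg_adjacency(cascade)
  outdeg <- vapply(nodes, function(v) sum(adj$source == v), integer(1))
  leaves <- nodes[outdeg == 0]
  if (length(leaves) > 0) return(sort(leaves))
  # all-cycle fallback: terminal strongly-connected components
  reach <- lapply(nodes, reachable_from, adj = adj)
  names(reach) <- nodes
  terminal <- vapply(nodes, function(u) {
    all(vapply(reach[[u]], function(v) u %in% reach[[v]], logical(1)))
  }, logical(1))
  sort(nodes[terminal])
}

#' Build every cascade of a query gene
#'
#' Predicts the direct targets with [find_direct_targets()] and expands
#' each into a cascade with [expand_cascade()]. One cascade per direct
#' target; ids and ordering are deterministic (targets sorted
#' lexicographically).
#'
#' @inheritParams find_direct_targets
#' @param allowed_stages accepted life-stage terms for downstream
#'   expansion.
#' @return List of [cascade] objects, one per direct target.
#' @export
build_all_cascades <- function(query_gene, classification, annotations,
                               allowed_stages = DEFAULT_STAGES,
                               min_phenotype_overlap = 1) {
  targets <- find_direct_targets(query_gene, classification, annotations,
                                 min_phenotype_overlap = min_phenotype_overlap)
  lapply(targets, function(tg)
    expand_cascade(tg, annotations, allowed_stages = allowed_stages,
                   query_gene = query_gene))
}
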