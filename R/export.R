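#' Export cascades as Cytoscape-compatible network files
#'
#' Writes three files to `out_dir`:
#' \describe{
#'   \item{network.sif}{simple interaction format, tab-separated
#'     `source<TAB>label<TAB>target`; the label is `positive`/`negative`
#'     for signed regulatory edges (unsigned regulatory edges are labeled
#'     `regulatory`), `genetic`, or `physical`. A synthetic
#'     `direct_target` line links the query node to each cascade root.}
#'   \item{nodes.tsv}{`gene_id`, `role` (`query`, `direct_target`,
#'     `downstream`), `tier` (`early_embryo`/`embryo`; empty for the query
#'     node, which need not be a cascade member).}
#'   \item{edges.tsv}{`source`, `target`, `edge_type`, `sign` — the
#'     attributes SIF cannot carry.}
#' }
#' Node coloring by tier and edge coloring by sign are applied in
#' Cytoscape from the attribute tables. Ordering is deterministic; two
#' identical exports are byte-identical.
#'
#' @param cascades list of [cascade] objects sharing one query gene.
#' @param query_gene the query gene identifier.
#' @param out_dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_cytoscape <- function(cascades, query_gene, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  qg <- vapply(cascades, function(cc) cc$query_gene, character(1))
  if (length(qg) > 0 && any(!is.na(qg) & qg != query_gene))
    stop("all cascades must share the query gene '", query_gene, "'")

  roles <- stats::setNames("query", query_gene)
  tiers <- stats::setNames("", query_gene)
  edge_rows <- list()
  for (cc in cascades) {
    for (g in cc$nodes) {
      r <- if (g == cc$root_target) "direct_target" else "downstream"
      # role precedence: query > direct_target > downstream
      if (is.na(roles[g]) || (roles[g] == "downstream" && r == "direct_target"))
        roles[g] <- r
      if (is.na(tiers[g]) || tiers[g] == "") tiers[g] <- cc$tiers[[g]]
    }
    e <- cc$edges
    edge_rows[[length(edge_rows) + 1L]] <-
      rbind(data.frame(source = query_gene, target = cc$root_target,
                       edge_type = "direct_target", sign = "unknown",
                       stringsAsFactors = FALSE),
            e[, c("source", "target", "edge_type", "sign"), drop = FALSE])
  }
  edges <- if (length(edge_rows) > 0) do.call(rbind, edge_rows)
           else data.frame(source = character(), target = character(),
                           edge_type = character(), sign = character(),
                           stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$source, edges$target, edges$edge_type,
                       edges$sign), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(gene_id = names(roles), role = unname(roles),
                      tier = unname(tiers), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL

  sif_label <- ifelse(edges$edge_type == "regulatory" & edges$sign != "unknown",
                      edges$sign, edges$edge_type)
  sif <- paste(edges$source, sif_label, edges$target, sep = "\t")

  f_sif <- file.path(out_dir, "network.sif")
  f_nodes <- file.path(out_dir, "nodes.tsv")
  f_edges <- file.path(out_dir, "edges.tsv")
  writeLines(sif, f_sif)
  write_tsv(nodes, f_nodes)
  write_tsv(edges, f_edges)
  invisible(c(f_sif, f_nodes, f_edges))
}

#' Re-import a Cytoscape export
#'
#' Parses the `network.sif`, `nodes.tsv`, and `edges.tsv` written by
#' [export_cytoscape()] back into node and edge tables; export followed by
#' re-import preserves the node set, edge multiset, roles, tiers, and
#' labels exactly.
#'
#' @param dir directory containing the export.
#' @return List with `nodes` (data.frame `gene_id`, `role`, `tier`),
#'   `edges` (data.frame `source`, `target`, `edge_type`, `sign`), and
#'   `sif` (data.frame `source`, `label`, `target`).
#' @export
read_cytoscape_export <- function(dir) {
  nodes <- read_tsv_checked(file.path(dir, "nodes.tsv"),
                            c("gene_id", "role", "tier"), "nodes")
  nodes$tier[is.na(nodes$tier)] <- ""
  edges <- read_tsv_checked(file.path(dir, "edges.tsv"),
                            c("source", "target", "edge_type", "sign"),
                            "edges")
  sif_lines <- readLines(file.path(dir, "network.sif"))
  sif_lines <- sif_lines[nzchar(sif_lines)]
  parts <- strsplit(sif_lines, "\t", fixed = TRUE)
  sif <- if (length(parts) == 0)
    data.frame(source = character(), label = character(),
               target = character(), stringsAsFactors = FALSE)
  else
    data.frame(source = vapply(parts, `[`, "", 1),
               label = vapply(parts, `[`, "", 2),
               target = vapply(parts, `[`, "", 3),
               stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, sif = sif)
}
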