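read_tsv_checked <- function(path, required, table_name) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", table_name, path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s (%s): missing required column(s): %s",
                 table_name, path, paste(missing, collapse = ", ")))
  df
}

#' Read a wild-type vs. mutant expression table
#'
#' The table is UTF-8, tab-separated, with a mandatory header row and
#' columns `gene_id`, `wt_rpkm`, `mut_rpkm`. Expression levels are RPKM and
#' must be non-negative; gene identifiers are opaque case-sensitive strings,
#' unique within one table.
#'
#' @param path path to the expression table.
#' @return data.frame with columns `gene_id` (character), `wt_rpkm`,
#'   `mut_rpkm` (numeric), one row per gene in file order.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "wt_rpkm", "mut_rpkm"),
                         "expression table")
  out <- data.frame(gene_id = df$gene_id,
                    wt_rpkm = suppressWarnings(as.numeric(df$wt_rpkm)),
                    mut_rpkm = suppressWarnings(as.numeric(df$mut_rpkm)),
                    stringsAsFactors = FALSE)
  # line numbers reported 1-based including the header line
  for (col in c("wt_rpkm", "mut_rpkm")) {
    bad <- which(is.na(out[[col]]) | out[[col]] < 0)
    if (length(bad) > 0)
      stop(sprintf("expression table (%s): unparseable or negative %s at line %d",
                   path, col, bad[1] + 1L))
  }
  blank <- which(!nzchar(out$gene_id))
  if (length(blank) > 0)
    stop(sprintf("expression table (%s): empty gene_id at line %d",
                 path, blank[1] + 1L))
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup) > 0)
    stop(sprintf("expression table (%s): duplicate gene_id(s): %s",
                 path, paste(dup, collapse = ", ")))
  out
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]; write-then-read round-trips the
#' table exactly.
#'
#' @param expression data.frame with columns `gene_id`, `wt_rpkm`, `mut_rpkm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  write_tsv(expression[, c("gene_id", "wt_rpkm", "mut_rpkm")], path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
}

rows_to_setmap <- function(df, key, value) {
  if (nrow(df) == 0) return(list())
  blank <- !nzchar(df[[key]])
  if (any(blank)) stop("empty gene identifier at line ", which(blank)[1] + 1L)
  split(df[[value]], df[[key]])
}

#' Read annotation extracts into an annotation bundle
#'
#' Each table is optional; an omitted table yields an empty structure (the
#' resulting lookups return the empty set). All files are UTF-8,
#' tab-separated, with header rows:
#' \describe{
#'   \item{tf_list}{column `gene_id`; one transcription factor per row.}
#'   \item{stages}{columns `gene_id`, `stage`; multi-row genes merge into a set.}
#'   \item{phenotypes}{columns `gene_id`, `phenotype`.}
#'   \item{interactions}{columns `source`, `target`, `edge_type`, `sign`;
#'     `sign` may be omitted (defaults to `unknown`).}
#'   \item{gene_domains}{columns `gene_id`, `domain_acc`.}
#'   \item{domain_categories}{columns `domain_acc`, `category`.}
#' }
#'
#' @param paths named list/vector of file paths; recognised names as above.
#' @return An [annotation_db()].
#' @export
read_annotations <- function(paths = list()) {
  paths <- as.list(paths)
  known <- c("tf_list", "stages", "phenotypes", "interactions",
             "gene_domains", "domain_categories")
  unknown <- setdiff(names(paths), known)
  if (length(unknown) > 0)
    stop("unknown annotation table name(s): ", paste(unknown, collapse = ", "))

  tf_genes <- character()
  if (!is.null(paths$tf_list)) {
    df <- read_tsv_checked(paths$tf_list, "gene_id", "tf_list")
    tf_genes <- df$gene_id
  }
  stages <- list()
  if (!is.null(paths$stages)) {
    df <- read_tsv_checked(paths$stages, c("gene_id", "stage"), "stages")
    stages <- rows_to_setmap(df, "gene_id", "stage")
  }
  phenotypes <- list()
  if (!is.null(paths$phenotypes)) {
    df <- read_tsv_checked(paths$phenotypes, c("gene_id", "phenotype"),
                           "phenotypes")
    phenotypes <- rows_to_setmap(df, "gene_id", "phenotype")
  }
  interactions <- empty_interactions()
  if (!is.null(paths$interactions)) {
    df <- read_tsv_checked(paths$interactions,
                           c("source", "target", "edge_type"), "interactions")
    if (is.null(df$sign)) df$sign <- "unknown"
    df$sign[!nzchar(df$sign)] <- "unknown"
    interactions <- df[, c("source", "target", "edge_type", "sign")]
  }
  domains <- list()
  if (!is.null(paths$gene_domains)) {
    df <- read_tsv_checked(paths$gene_domains, c("gene_id", "domain_acc"),
                           "gene_domains")
    domains <- rows_to_setmap(df, "gene_id", "domain_acc")
  }
  domain_categories <- character()
  if (!is.null(paths$domain_categories)) {
    df <- read_tsv_checked(paths$domain_categories,
                           c("domain_acc", "category"), "domain_categories")
    df <- df[!duplicated(df$domain_acc), , drop = FALSE]
    domain_categories <- stats::setNames(df$category, df$domain_acc)
  }
  annotation_db(tf_genes = tf_genes, stages = stages, phenotypes = phenotypes,
                interactions = interactions, domains = domains,
                domain_categories = domain_categories)
}

#' Read annotation tables from a directory of conventionally named files
#'
#' Looks for `tf_list.tsv`, `stages.tsv`, `phenotypes.tsv`,
#' `interactions.tsv`, `gene_domains.tsv`, `domain_categories.tsv`; any
#' file may be absent.
#'
#' @param dir directory containing the annotation tables.
#' @return An [annotation_db()].
#' @export
read_annotations_dir <- function(dir) {
  known <- c("tf_list", "stages", "phenotypes", "interactions",
             "gene_domains", "domain_categories")
  paths <- list()
  for (nm in known) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(p)) paths[[nm]] <- p
  }
  read_annotations(paths)
}

#' Write cascade summary and membership tables
#'
#' Writes `cascade_summary.tsv` (one row per cascade: id, query gene, root
#' target, node count, comma-joined bottom genes) and
#' `cascade_members.tsv` (long format: cascade id, gene, role, stage tier).
#' Row order is deterministic: cascade id, then gene id, lexicographic.
#'
#' @param cascades list of [cascade] objects (may be empty).
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_cascade_tables <- function(cascades, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  summary_df <- cascade_summary(cascades)
  members_df <- cascade_members(cascades)
  f1 <- file.path(out_dir, "cascade_summary.tsv")
  f2 <- file.path(out_dir, "cascade_members.tsv")
  write_tsv(summary_df, f1)
  write_tsv(members_df, f2)
  invisible(c(f1, f2))
}

#' Tabulate cascades
#'
#' @param cascades list of [cascade] objects.
#' @return `cascade_summary()`: one row per cascade; `cascade_members()`:
#'   one row per (cascade, gene) with the gene's role (`direct_target` or
#'   `downstream`) and stage tier.
#' @export
cascade_summary <- function(cascades) {
  if (length(cascades) == 0)
    return(data.frame(cascade_id = character(), query_gene = character(),
                      root_target = character(), n_nodes = integer(),
                      bottom_genes = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(cascades, function(cc) {
    data.frame(cascade_id = cc$cascade_id, query_gene = cc$query_gene,
               root_target = cc$root_target, n_nodes = length(cc$nodes),
               bottom_genes = paste(sort(cc$bottom_genes), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  df[order(df$cascade_id), , drop = FALSE]
}

#' @rdname cascade_summary
#' @export
cascade_members <- function(cascades) {
  if (length(cascades) == 0)
    return(data.frame(cascade_id = character(), gene_id = character(),
                      role = character(), tier = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(cascades, function(cc) {
    genes <- sort(cc$nodes)
    data.frame(cascade_id = cc$cascade_id, gene_id = genes,
               role = ifelse(genes == cc$root_target, "direct_target",
                             "downstream"),
               tier = unname(cc$tiers[genes]), stringsAsFactors = FALSE)
  }))
  df <- df[order(df$cascade_id, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
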