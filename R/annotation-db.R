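#' Edge types and regulation signs recognised in interaction tables
#'
#' Regulatory edges are directed (source regulates target) and may carry a
#' positive or negative sign; genetic and physical edges are undirected and
#' must have sign `"unknown"`.
#'
#' @name interaction-vocabulary
#' @keywords internal
EDGE_TYPES <- c("regulatory", "genetic", "physical")

#' @rdname interaction-vocabulary
#' @keywords internal
EDGE_SIGNS <- c("positive", "negative", "unknown")

empty_interactions <- function() {
  data.frame(source = character(), target = character(),
             edge_type = character(), sign = character(),
             stringsAsFactors = FALSE)
}

#' Construct an annotation bundle
#'
#' Bundles the flat-file annotation extracts the cascade builder consumes:
#' the transcription-factor gene set, gene-to-life-stage terms,
#' gene-to-phenotype terms, typed interaction edges, gene-to-domain
#' accessions, and the domain-to-functional-category map. Genes absent from
#' a mapping are treated as annotated with the empty set; lookups never
#' error.
#'
#' @param tf_genes character vector of transcription-factor gene ids.
#' @param stages named list: gene id -> character vector of life-stage terms
#'   (e.g. `"early embryo"`, `"embryo"`).
#' @param phenotypes named list: gene id -> character vector of phenotype
#'   terms.
#' @param interactions data.frame with columns `source`, `target`,
#'   `edge_type` (one of `regulatory`, `genetic`, `physical`) and `sign`
#'   (one of `positive`, `negative`, `unknown`).
#' @param domains named list: gene id -> character vector of domain
#'   accessions.
#' @param domain_categories named character vector: domain accession ->
#'   functional-category label.
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(tf_genes = character(),
                          stages = list(),
                          phenotypes = list(),
                          interactions = empty_interactions(),
                          domains = list(),
                          domain_categories = character()) {
  stopifnot(is.character(tf_genes), is.list(stages), is.list(phenotypes),
            is.data.frame(interactions), is.list(domains))
  for (nm in c("stages", "phenotypes", "domains")) {
    m <- get(nm)
    if (length(m) > 0 && (is.null(names(m)) || any(!nzchar(names(m)))))
      stop(sprintf("every key of '%s' must be a non-empty gene identifier", nm))
  }
  need <- c("source", "target", "edge_type", "sign")
  if (!all(need %in% names(interactions)))
    stop("interactions table must have columns: ", paste(need, collapse = ", "))
  interactions <- interactions[, need, drop = FALSE]
  if (nrow(interactions) > 0) {
    bad_type <- setdiff(unique(interactions$edge_type), EDGE_TYPES)
    if (length(bad_type) > 0)
      stop("unknown edge_type token(s): ", paste(bad_type, collapse = ", "))
    bad_sign <- setdiff(unique(interactions$sign), EDGE_SIGNS)
    if (length(bad_sign) > 0)
      stop("unknown sign token(s): ", paste(bad_sign, collapse = ", "))
    signed_nonreg <- interactions$edge_type != "regulatory" &
      interactions$sign != "unknown"
    if (any(signed_nonreg))
      stop("sign given on non-regulatory edge (rows ",
           paste(which(signed_nonreg), collapse = ", "), ")")
  }
  structure(
    list(tf_genes = unique(tf_genes),
         stages = lapply(stages, function(x) sort(unique(as.character(x)))),
         phenotypes = lapply(phenotypes, function(x) sort(unique(as.character(x)))),
         interactions = interactions,
         domains = lapply(domains, function(x) sort(unique(as.character(x)))),
         domain_categories = domain_categories),
    class = "annotation_db"
  )
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("<annotation_db>\n")
  cat("  transcription factors:", length(x$tf_genes), "\n")
  cat("  genes with stage terms:", length(x$stages), "\n")
  cat("  genes with phenotypes:", length(x$phenotypes), "\n")
  cat("  interaction edges:", nrow(x$interactions), "\n")
  cat("  genes with domains:", length(x$domains), "\n")
  cat("  domain categories:", length(x$domain_categories), "\n")
  invisible(x)
}

set_lookup <- function(mapping, gene) {
  v <- mapping[[gene]]
  if (is.null(v)) character() else v
}

#' Annotation lookups with an empty-set default
#'
#' @param db an [annotation_db()].
#' @param gene a single gene identifier.
#' @return Character vector of terms; `character(0)` for unannotated genes.
#' @export
gene_stages <- function(db, gene) set_lookup(db$stages, gene)

#' @rdname gene_stages
#' @export
gene_phenotypes <- function(db, gene) set_lookup(db$phenotypes, gene)

#' @rdname gene_stages
#' @export
gene_domains <- function(db, gene) set_lookup(db$domains, gene)

#' @rdname gene_stages
#' @export
is_tf <- function(db, gene) gene %in% db$tf_genes
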