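#' Fixed reporting order for functional categories
#'
#' Categories not in this list are appended alphabetically, then
#' `"Others"`, then `"Unknown"`.
#'
#' @export
CATEGORY_ORDER <- c("Transcription", "Signal transduction", "Development",
                    "Cell cycle", "Cell division", "DNA replication",
                    "Transport")

binom_upper_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

hyper_upper_tail <- function(k, n, K, N_bg) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, m = K, n = N_bg - K, k = n, lower.tail = FALSE)
}

#' Domain over-representation among cascade bottom genes
#'
#' For each domain accession carried by at least one bottom gene (or each
#' domain in `candidate_domains` when given), tests whether the domain is
#' over-represented among the n bottom genes that carry any domain
#' annotation, relative to its background frequency. The default test is
#' the classic binomial over-representation tail: with k bottom genes
#' carrying the domain, K of N_bg background genes carrying it, and
#' p0 = K / N_bg, the p-value is P(X >= k) for X ~ Binomial(n, p0).
#' `test = "fisher"` uses the hypergeometric (Fisher one-sided) tail
#' instead.
#'
#' @param bottom_genes character vector of bottom gene ids.
#' @param annotations an [annotation_db()] supplying gene-to-domain
#'   annotations.
#' @param background character vector of background gene ids (the genes of
#'   the input expression table); must contain `bottom_genes`. Only
#'   background genes with at least one domain annotation enter N_bg.
#' @param test `"binomial"` (default) or `"fisher"`.
#' @param candidate_domains optional accession vector; defaults to the
#'   domains present among the bottom genes.
#' @return data.frame with columns `domain_acc`, `k`, `n`, `K`, `N_bg`,
#'   `p_value` and a list column `genes` (the bottom genes hit), sorted by
#'   p-value then accession. Empty `bottom_genes` yield zero rows.
#' @export
domain_enrichment <- function(bottom_genes, annotations, background,
                              test = c("binomial", "fisher"),
                              candidate_domains = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(annotations, "annotation_db"))
  if (!all(bottom_genes %in% background))
    stop("background must contain every bottom gene")
  empty <- data.frame(domain_acc = character(), k = integer(), n = integer(),
                      K = integer(), N_bg = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  empty$genes <- list()
  if (length(bottom_genes) == 0) return(empty)

  bg_dom <- annotations$domains[intersect(names(annotations$domains), background)]
  bg_dom <- bg_dom[lengths(bg_dom) > 0]
  N_bg <- length(bg_dom)
  if (N_bg == 0) stop("no background gene carries a domain annotation")
  bot_dom <- bg_dom[intersect(names(bg_dom), bottom_genes)]
  n <- length(bot_dom)
  if (is.null(candidate_domains))
    candidate_domains <- sort(unique(unlist(bot_dom, use.names = FALSE)))
  if (length(candidate_domains) == 0) return(empty)

  rows <- lapply(sort(unique(candidate_domains)), function(acc) {
    hits <- names(bot_dom)[vapply(bot_dom, function(d) acc %in% d, logical(1))]
    K <- sum(vapply(bg_dom, function(d) acc %in% d, logical(1)))
    k <- length(hits)
    p <- switch(test,
                binomial = binom_upper_tail(k, n, K / N_bg),
                fisher = hyper_upper_tail(k, n, K, N_bg))
    out <- data.frame(domain_acc = acc, k = k, n = n, K = K, N_bg = N_bg,
                      p_value = p, stringsAsFactors = FALSE)
    out$genes <- list(sort(hits))
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p_value, res$domain_acc), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Discard cascades whose bottom genes carry transcription-related domains
#'
#' A cascade whose significantly enriched bottom-gene domains (p < alpha)
#' include a transcription-related domain is removed: such a cascade would
#' function only after the early embryo stage. The removed cascades and
#' their triggering accessions are recorded in the `"removed"` attribute
#' of the result.
#'
#' @param cascades list of [cascade] objects.
#' @param enrichments named list: cascade id -> [domain_enrichment()]
#'   result.
#' @param transcription_domains character vector of transcription-related
#'   domain accessions (user-supplied; empty set retains everything).
#' @param alpha significance level; default 0.05.
#' @return The retained cascades, with attribute `removed`: data.frame
#'   (`cascade_id`, `domain_acc`).
#' @export
filter_transcription_cascades <- function(cascades, enrichments,
                                          transcription_domains,
                                          alpha = 0.05) {
  removed <- data.frame(cascade_id = character(), domain_acc = character(),
                        stringsAsFactors = FALSE)
  keep <- vapply(cascades, function(cc) {
    enr <- enrichments[[cc$cascade_id]]
    if (is.null(enr) || nrow(enr) == 0) return(TRUE)
    sig <- enr$domain_acc[enr$p_value < alpha]
    trig <- intersect(sig, transcription_domains)
    if (length(trig) > 0) {
      removed <<- rbind(removed,
                        data.frame(cascade_id = cc$cascade_id,
                                   domain_acc = sort(trig)[1],
                                   stringsAsFactors = FALSE))
      return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- cascades[keep]
  attr(out, "removed") <- removed
  out
}

#' Functional-category scores of enriched domains
#'
#' Significant domains (p < alpha) are grouped by functional category via
#' `category_map`; a category's score is the number of distinct bottom
#' genes hit by its domains. Domains absent from the map are tallied under
#' `"Unknown"`; categories scoring below `min_score` are folded into
#' `"Others"`. Output order: [CATEGORY_ORDER], other categories
#' alphabetically, then `"Others"`, then `"Unknown"`.
#'
#' @param enrichments a [domain_enrichment()] result (rows from several
#'   cascades may be concatenated).
#' @param category_map named character vector: domain accession ->
#'   category label.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param min_score categories scoring below this are folded into
#'   `"Others"`; default 1.
#' @return data.frame `category`, `score`.
#' @export
categorize_domains <- function(enrichments, category_map, alpha = 0.05,
                               min_score = 1) {
  stopifnot(alpha > 0, alpha < 1)
  empty <- data.frame(category = character(), score = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(enrichments) == 0) return(empty)
  sig <- enrichments[enrichments$p_value < alpha, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  cat_of <- function(acc) {
    v <- unname(category_map[acc])
    if (is.na(v) || is.null(v)) "Unknown" else v
  }
  sig$category <- vapply(sig$domain_acc, cat_of, character(1))
  genes_by_cat <- lapply(split(sig$genes, sig$category),
                         function(gl) unique(unlist(gl, use.names = FALSE)))
  scores <- vapply(genes_by_cat, length, integer(1))
  fold <- scores < min_score & !(names(scores) %in% c("Others", "Unknown"))
  if (any(fold)) {
    others_genes <- unique(unlist(genes_by_cat[fold], use.names = FALSE))
    genes_by_cat <- genes_by_cat[!fold]
    genes_by_cat[["Others"]] <- unique(c(genes_by_cat[["Others"]], others_genes))
    scores <- vapply(genes_by_cat, length, integer(1))
  }
  cats <- names(scores)
  extra <- sort(setdiff(cats, c(CATEGORY_ORDER, "Others", "Unknown")))
  ordering <- c(intersect(CATEGORY_ORDER, cats), extra,
                intersect(c("Others", "Unknown"), cats))
  data.frame(category = ordering, score = unname(scores[ordering]),
             stringsAsFactors = FALSE)
}
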