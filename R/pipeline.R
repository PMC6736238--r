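#' Configuration of an end-to-end run
#'
#' @param expression path to the expression table
#'   ([read_expression_table()] format).
#' @param annotations_dir directory of annotation tables
#'   ([read_annotations_dir()] naming convention).
#' @param query_gene query gene identifier.
#' @param out_dir output directory.
#' @param quartile_type quartile convention (see [fluctuation_stats()]).
#' @param pseudocount pseudocount for ratio computation; default 0 (off).
#' @param allowed_stages life-stage vocabulary for cascade expansion.
#' @param min_phenotype_overlap minimum shared phenotype terms for direct
#'   targets.
#' @param enrichment_test `"binomial"` or `"fisher"`.
#' @param alpha significance level in (0, 1).
#' @param transcription_domains accessions of transcription-related
#'   domains; cascades whose significant bottom-gene domains hit this set
#'   are discarded when `transcription_filter` is on.
#' @param transcription_filter apply the transcription-domain cascade
#'   filter; default TRUE (a no-op when `transcription_domains` is empty).
#' @return Object of class `run_config`.
#' @export
run_config <- function(expression, annotations_dir, query_gene, out_dir,
                       quartile_type = 7, pseudocount = 0,
                       allowed_stages = DEFAULT_STAGES,
                       min_phenotype_overlap = 1,
                       enrichment_test = c("binomial", "fisher"),
                       alpha = 0.05,
                       transcription_domains = character(),
                       transcription_filter = TRUE) {
  enrichment_test <- match.arg(enrichment_test)
  stopifnot(alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full cascade-prediction pipeline
#'
#' Executes classification, direct-target prediction, cascade expansion,
#' domain enrichment, category scoring, and Cytoscape export, writing all
#' result tables plus a `manifest.json` (configuration echo, package
#' version, and stage-by-stage counts) to the output directory. The
#' pipeline is a pure function of its inputs and configuration: repeated
#' runs produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`stats`,
#'   `classification`, `targets`, `cascades`, `retained_cascades`,
#'   `enrichments`, `categories`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$expression))
    stop("expression file not found: ", config$expression)
  if (!dir.exists(config$annotations_dir))
    stop("annotations directory not found: ", config$annotations_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  expression <- read_expression_table(config$expression)
  annotations <- read_annotations_dir(config$annotations_dir)

  ratios <- compute_ratios(expression, pseudocount = config$pseudocount)
  stats <- fluctuation_stats(ratios, quartile_type = config$quartile_type)
  classification <- classify_genes(ratios, stats)
  cls_table <- classification_table(ratios, classification)
  write_tsv(cls_table, file.path(config$out_dir, "classification.tsv"))
  write_tsv(data.frame(
    statistic = c("n_total", "n_defined", "median", "quartile_dev",
                  "lower_bound", "upper_bound", "lower_bound_log2",
                  "upper_bound_log2"),
    value = c(stats$n_total, stats$n_defined, stats$median,
              stats$quartile_dev, stats$lower_bound, stats$upper_bound,
              stats$lower_bound_log2, stats$upper_bound_log2)),
    file.path(config$out_dir, "fluctuation_stats.tsv"))

  cascades <- build_all_cascades(
    config$query_gene, classification, annotations,
    allowed_stages = config$allowed_stages,
    min_phenotype_overlap = config$min_phenotype_overlap)
  targets <- vapply(cascades, function(cc) cc$root_target, character(1))
  write_cascade_tables(cascades, config$out_dir)

  background <- expression$gene_id
  enrichments <- stats::setNames(
    lapply(cascades, function(cc)
      domain_enrichment(cc$bottom_genes, annotations, background,
                        test = config$enrichment_test)),
    vapply(cascades, function(cc) cc$cascade_id, character(1)))
  enr_flat <- do.call(rbind, c(lapply(names(enrichments), function(id) {
    e <- enrichments[[id]]
    if (nrow(e) == 0) return(NULL)
    cbind(data.frame(cascade_id = id, stringsAsFactors = FALSE), e)
  }), list(make.row.names = FALSE)))
  enr_out <- if (is.null(enr_flat))
    data.frame(cascade_id = character(), domain_acc = character(),
               k = integer(), n = integer(), K = integer(),
               N_bg = integer(), p_value = numeric(), genes = character())
  else {
    out <- enr_flat
    out$genes <- vapply(out$genes, paste, "", collapse = ",")
    out
  }
  write_tsv(enr_out, file.path(config$out_dir, "enrichment.tsv"))

  retained <- if (config$transcription_filter)
    filter_transcription_cascades(cascades, enrichments,
                                  config$transcription_domains,
                                  alpha = config$alpha)
  else structure(cascades, removed = data.frame(cascade_id = character(),
                                                domain_acc = character()))
  removed <- attr(retained, "removed")
  write_tsv(removed, file.path(config$out_dir, "filtered_cascades.tsv"))

  # category scoring runs on the pre-filter enrichment set: the
  # transcription filter asks whether a cascade acts after the early
  # embryo stage, while the category table describes what all predicted
  # cascades do
  all_enr <- if (is.null(enr_flat))
    domain_enrichment(character(), annotations, background)
  else enr_flat
  categories <- categorize_domains(all_enr, annotations$domain_categories,
                                   alpha = config$alpha)
  write_tsv(categories, file.path(config$out_dir, "category_scores.tsv"))

  export_cytoscape(retained, config$query_gene, config$out_dir)

  manifest <- list(
    package = "genecascades",
    version = as.character(utils::packageVersion("genecascades")),
    config = list(
      expression = config$expression,
      annotations_dir = config$annotations_dir,
      query_gene = config$query_gene,
      quartile_type = config$quartile_type,
      pseudocount = config$pseudocount,
      allowed_stages = config$allowed_stages,
      min_phenotype_overlap = config$min_phenotype_overlap,
      enrichment_test = config$enrichment_test,
      alpha = config$alpha,
      transcription_filter = config$transcription_filter,
      n_transcription_domains = length(config$transcription_domains)),
    counts = list(
      genes_input = nrow(expression),
      genes_defined_ratio = stats$n_defined,
      genes_stable = length(classification$stable),
      genes_fluctuating = length(classification$fluctuating),
      genes_boundary = length(classification$boundary),
      genes_undefined = length(classification$undefined),
      direct_targets = length(targets),
      cascades = length(cascades),
      cascades_retained = length(retained),
      cascades_removed = nrow(removed),
      bottom_genes = length(unique(unlist(lapply(cascades,
                                                 `[[`, "bottom_genes")))),
      enriched_domains = if (is.null(enr_flat)) 0L
        else length(unique(enr_flat$domain_acc[enr_flat$p_value <
                                                 config$alpha]))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(stats = stats, classification = classification,
                 targets = targets, cascades = cascades,
                 retained_cascades = retained, enrichments = enrichments,
                 categories = categories, manifest = manifest))
}
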