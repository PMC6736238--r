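#' Specification of a synthetic benchmark dataset
#'
#' Describes a seeded synthetic dataset with planted ground truth: a query
#' gene, `n_direct_targets` planted direct targets that satisfy all four
#' target criteria by construction, one decoy per criterion that violates
#' exactly that criterion, per-target downstream trees of regulatory edges
#' over embryo-annotated genes (plus one physically interacting partner
#' and one stage-blocked neighbor per target), and background genes whose
#' mutant/wild-type ratios follow a log-normal distribution.
#'
#' @param n_genes total number of genes in the expression table (including
#'   query, targets, decoys, and downstream genes).
#' @param n_direct_targets number of planted direct targets.
#' @param cascade_depth number of regulatory levels below each target.
#' @param branching number of independent branches per target.
#' @param frac_tf fraction of genes flagged as transcription factors.
#' @param stable_noise_sd standard deviation of log2 ratios for
#'   planted-stable genes (targets and stable decoys).
#' @param fluct_shift absolute log2-ratio displacement of planted
#'   fluctuating genes.
#' @param frac_embryonic fraction of background genes annotated with an
#'   embryonic stage term.
#' @param seed integer seed; identical seeds give identical fixtures.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 200, n_direct_targets = 3,
                         cascade_depth = 4, branching = 2,
                         frac_tf = 0.15, stable_noise_sd = 0.05,
                         fluct_shift = 2.0, frac_embryonic = 0.7,
                         seed = 1) {
  stopifnot(n_genes > 0, n_direct_targets > 0, cascade_depth > 0,
            branching > 0, frac_tf >= 0, frac_tf <= 1,
            stable_noise_sd >= 0, fluct_shift >= 0,
            frac_embryonic >= 0, frac_embryonic <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

QUERY_PHENOTYPES <- c("embryonic lethal", "polarity defect")

#' Generate a synthetic dataset with planted cascades
#'
#' Builds an expression table, an annotation bundle, and the planted
#' ground truth described by a [fixture_spec()]. Planted direct targets
#' are transcription factors sharing a life stage and phenotype terms with
#' the query gene, with ratios drawn tightly around the background ratio
#' median (strictly inside the median +/- quartile-deviation band by
#' construction, which is asserted before returning). Four decoys violate
#' exactly one criterion each (`stability`, `tf`, `stage`, `phenotype`).
#' Each target roots a tree of positive regulatory edges over
#' embryo-annotated genes; the leaf of the first branch additionally has a
#' physically interacting embryonic partner (reached by undirected
#' traversal, itself a bottom gene) and each target has a larva-only
#' neighbor that the stage filter must exclude. Bottom genes carry domain
#' accessions drawn from a small catalog mapped to functional categories.
#'
#' @param spec a [fixture_spec()].
#' @return List with elements `expression` (data.frame `gene_id`,
#'   `wt_rpkm`, `mut_rpkm`), `annotations` ([annotation_db()]), `truth`
#'   (list: `query_gene`, `direct_targets`, `cascade_membership`,
#'   `bottom_genes`, `decoys`, `blocked`), `category_map`, and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_t <- spec$n_direct_targets
  tree_n <- 1 + spec$branching * spec$cascade_depth
  per_target <- tree_n + 2  # + physical partner + stage-blocked neighbor
  n_planted <- 1 + n_t * per_target + 4  # query + cascades + decoys
  n_bg <- spec$n_genes - n_planted
  if (n_bg < 20)
    stop(sprintf("infeasible spec: %d genes cannot hold %d planted genes plus a background of at least 20",
                 spec$n_genes, n_planted))
  n_tf <- round(spec$frac_tf * spec$n_genes)
  if (n_t + 3 > n_tf)
    stop(sprintf("infeasible spec: %d targets + 3 TF decoys exceed the TF budget %d (n_genes * frac_tf)",
                 n_t, n_tf))

  set.seed(spec$seed)
  query <- "qry-1"
  targets <- sprintf("tgt-%d", seq_len(n_t))
  decoys <- c(stability = "dcy-stability", tf = "dcy-tf",
              stage = "dcy-stage", phenotype = "dcy-phenotype")
  bg <- sprintf("syn-%03d", seq_len(n_bg))

  stages <- list()
  phenotypes <- list()
  domains <- list()
  tf_genes <- character()
  edges <- list()
  add_edge <- function(s, t, type, sign = "unknown")
    edges[[length(edges) + 1L]] <<- data.frame(source = s, target = t,
                                               edge_type = type, sign = sign,
                                               stringsAsFactors = FALSE)

  stages[[query]] <- "early embryo"
  phenotypes[[query]] <- QUERY_PHENOTYPES

  # domain catalog: accessions and the functional categories they map to
  catalog <- c(DOMSIG1 = "Signal transduction", DOMSIG2 = "Signal transduction",
               DOMDEV1 = "Development", DOMCYC1 = "Cell cycle",
               DOMREP1 = "DNA replication", DOMTRA1 = "Transport")
  unmapped_dom <- "DOMX999"  # deliberately absent from the category map

  membership <- list()
  bottoms <- list()
  cascade_genes <- character()
  for (ti in seq_len(n_t)) {
    tg <- targets[ti]
    tf_genes <- c(tf_genes, tg)
    stages[[tg]] <- c("early embryo", "embryo")
    phenotypes[[tg]] <- QUERY_PHENOTYPES[1]
    members <- tg
    bot <- character()
    for (br in seq_len(spec$branching)) {
      chain <- sprintf("dwn-%d-%d-%d", ti, br, seq_len(spec$cascade_depth))
      parent <- tg
      for (g in chain) {
        add_edge(parent, g, "regulatory",
                 if (stats::runif(1) < 0.8) "positive" else "negative")
        stages[[g]] <- if (stats::runif(1) < 0.5) "early embryo" else "embryo"
        parent <- g
      }
      members <- c(members, chain)
      bot <- c(bot, chain[length(chain)])
      if (br == 1) {
        phy <- sprintf("phy-%d", ti)
        add_edge(chain[length(chain)], phy, "physical")
        stages[[phy]] <- "embryo"
        members <- c(members, phy)
        bot <- c(bot, phy)
      }
    }
    blocked <- sprintf("blk-%d", ti)
    add_edge(tg, blocked, "regulatory", "positive")
    stages[[blocked]] <- "larva"
    membership[[tg]] <- sort(members)
    bottoms[[tg]] <- sort(bot)
    cascade_genes <- c(cascade_genes, members, blocked)
    # every bottom gene of a cascade shares one signature accession, so
    # the cascade's function is recoverable by enrichment; the first
    # bottom gene also carries the accession missing from the category map
    sig_acc <- names(catalog)[((ti - 1) %% length(catalog)) + 1]
    for (bi in seq_along(bot)) {
      domains[[bot[bi]]] <- if (bi == 1) c(sig_acc, unmapped_dom) else sig_acc
    }
  }

  # decoys: each violates exactly one target criterion
  tf_genes <- c(tf_genes, decoys[["stability"]], decoys[["stage"]],
                decoys[["phenotype"]])
  for (d in decoys) phenotypes[[d]] <- QUERY_PHENOTYPES[1]
  phenotypes[[decoys[["phenotype"]]]] <- "larval arrest"
  for (d in decoys) stages[[d]] <- "early embryo"
  stages[[decoys[["stage"]]]] <- "larva"

  # background: TFs up to the budget, embryonic fraction, no phenotype
  # overlap with the query, log-normal ratio noise with a fluctuating tail
  n_bg_tf <- n_tf - (n_t + 3)
  tf_genes <- c(tf_genes, bg[seq_len(min(n_bg_tf, length(bg)))])
  emb <- stats::runif(n_bg) < spec$frac_embryonic
  for (i in seq_len(n_bg)) {
    stages[[bg[i]]] <- if (emb[i]) {
      if (stats::runif(1) < 0.4) "early embryo" else "embryo"
    } else "larva"
  }
  # a few background-only undirected edges so the parsers see edges that
  # belong to no cascade
  for (i in seq_len(min(10, n_bg %/% 2))) {
    add_edge(bg[2 * i - 1], bg[2 * i],
             if (i %% 2 == 0) "genetic" else "physical")
  }
  # background domain annotations give the enrichment test its background
  for (i in seq_len(n_bg)) {
    if (i %% 3 == 0)
      domains[[bg[i]]] <- names(catalog)[(i %% length(catalog)) + 1]
  }

  # expression levels
  all_genes <- c(query, targets, unname(decoys),
                 setdiff(cascade_genes, c(targets)), bg)
  all_genes <- unique(all_genes)
  stopifnot(length(all_genes) == spec$n_genes)
  n_all <- length(all_genes)
  wt <- round(stats::rlnorm(n_all, meanlog = log(50), sdlog = 1), 3)
  names(wt) <- all_genes

  bg_log2 <- stats::rnorm(n_bg, 0, 0.6)
  n_fluct_bg <- max(1L, round(0.15 * n_bg))
  fluct_idx <- seq_len(n_fluct_bg)  # first genes of the shuffled-free id order
  bg_log2[fluct_idx] <- sign(stats::rnorm(n_fluct_bg)) *
    (spec$fluct_shift + abs(stats::rnorm(n_fluct_bg, 0, 0.3)))
  log2r <- stats::setNames(rep(NA_real_, n_all), all_genes)
  log2r[bg] <- bg_log2
  # planted-stable genes sit in the inner band of the background ratios
  inner <- stats::quantile(2^bg_log2[-fluct_idx], c(0.45, 0.55), type = 7)
  planted_stable <- c(targets, decoys[["tf"]], decoys[["stage"]],
                      decoys[["phenotype"]])
  for (g in planted_stable) {
    r <- 2^stats::rnorm(1, 0, spec$stable_noise_sd)
    log2r[g] <- log2(min(max(r, inner[1]), inner[2]))
  }
  log2r[decoys[["stability"]]] <- spec$fluct_shift + 0.5
  log2r[query] <- -(spec$fluct_shift + 1)  # deleted in the mutant
  downstream <- setdiff(cascade_genes, targets)
  log2r[downstream] <- stats::rnorm(length(downstream), 0, 0.4)

  mut <- round(wt * 2^log2r, 3)
  expression <- data.frame(gene_id = all_genes, wt_rpkm = unname(wt),
                           mut_rpkm = unname(mut), stringsAsFactors = FALSE)

  ann <- annotation_db(
    tf_genes = tf_genes, stages = stages, phenotypes = phenotypes,
    interactions = do.call(rbind, edges), domains = domains,
    domain_categories = catalog
  )

  # construction guarantee: planted targets classify stable, the
  # stability decoy fluctuating
  ratios <- compute_ratios(expression)
  cls <- classify_genes(ratios, fluctuation_stats(ratios))
  if (!all(planted_stable %in% cls$stable) ||
      !(decoys[["stability"]] %in% cls$fluctuating))
    stop("infeasible spec: planted genes do not classify as constructed; widen the background or shrink stable_noise_sd")

  list(expression = expression, annotations = ann,
       truth = list(query_gene = query,
                    direct_targets = sort(targets),
                    cascade_membership = membership,
                    bottom_genes = bottoms,
                    decoys = decoys,
                    blocked = sprintf("blk-%d", seq_len(n_t))),
       category_map = catalog, spec = spec)
}

#' Write a fixture to disk in the tool's input formats
#'
#' Writes `expression.tsv` plus the six annotation tables read by
#' [read_annotations_dir()], and `ground_truth.tsv` (columns `gene_id`,
#' `role`, `target`) recording the planted targets, cascade members,
#' bottom genes, and decoys.
#'
#' @param fixture result of [generate_fixture()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(fixture, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(fixture$expression, file.path(out_dir, "expression.tsv"))
  ann <- fixture$annotations
  write_tsv(data.frame(gene_id = sort(ann$tf_genes)),
            file.path(out_dir, "tf_list.tsv"))
  setmap_to_rows <- function(m, value_col) {
    keys <- sort(names(m))
    df <- do.call(rbind, lapply(keys, function(k)
      data.frame(gene_id = k, value = m[[k]], stringsAsFactors = FALSE)))
    if (is.null(df)) df <- data.frame(gene_id = character(),
                                      value = character())
    names(df)[2] <- value_col
    df
  }
  write_tsv(setmap_to_rows(ann$stages, "stage"),
            file.path(out_dir, "stages.tsv"))
  write_tsv(setmap_to_rows(ann$phenotypes, "phenotype"),
            file.path(out_dir, "phenotypes.tsv"))
  inter <- ann$interactions
  inter <- inter[order(inter$source, inter$target, inter$edge_type), ]
  write_tsv(inter, file.path(out_dir, "interactions.tsv"))
  write_tsv(setmap_to_rows(ann$domains, "domain_acc"),
            file.path(out_dir, "gene_domains.tsv"))
  write_tsv(data.frame(domain_acc = names(ann$domain_categories),
                       category = unname(ann$domain_categories),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "domain_categories.tsv"))
  tr <- fixture$truth
  gt <- rbind(
    data.frame(gene_id = tr$query_gene, role = "query", target = "",
               stringsAsFactors = FALSE),
    data.frame(gene_id = tr$direct_targets, role = "direct_target",
               target = tr$direct_targets, stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(tr$cascade_membership), function(tg)
      data.frame(gene_id = setdiff(tr$cascade_membership[[tg]], tg),
                 role = "member", target = tg, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(names(tr$bottom_genes), function(tg)
      data.frame(gene_id = tr$bottom_genes[[tg]], role = "bottom",
                 target = tg, stringsAsFactors = FALSE))),
    data.frame(gene_id = unname(tr$decoys),
               role = paste0("decoy_", names(tr$decoys)), target = "",
               stringsAsFactors = FALSE)
  )
  gt <- gt[order(gt$role, gt$target, gt$gene_id), ]
  write_tsv(gt, file.path(out_dir, "ground_truth.tsv"))
  invisible(out_dir)
}
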