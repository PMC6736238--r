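#' Mutant/wild-type expression ratios
#'
#' For each gene the change rate is the ratio of the mutant expression
#' level to the wild-type level, R = mut/wt. The ratio is undefined (NA)
#' when the wild-type level is zero, unless a pseudocount is supplied, in
#' which case R = (mut + pseudocount) / (wt + pseudocount) is always
#' defined. `log2_ratio` is defined only when the ratio is defined and
#' strictly positive.
#'
#' @param records data.frame with columns `gene_id`, `wt_rpkm`, `mut_rpkm`
#'   (as returned by [read_expression_table()]).
#' @param pseudocount non-negative value added to both levels before the
#'   division; default 0 (off).
#' @return data.frame with columns `gene_id`, `ratio`, `log2_ratio`; NA
#'   marks an undefined value.
#' @export
compute_ratios <- function(records, pseudocount = 0) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("expression records must be a non-empty data.frame")
  stopifnot(all(c("gene_id", "wt_rpkm", "mut_rpkm") %in% names(records)),
            pseudocount >= 0)
  wt <- records$wt_rpkm + pseudocount
  mut <- records$mut_rpkm + pseudocount
  ratio <- ifelse(wt > 0, mut / wt, NA_real_)
  log2_ratio <- ifelse(!is.na(ratio) & ratio > 0, log2(ratio), NA_real_)
  data.frame(gene_id = records$gene_id, ratio = ratio,
             log2_ratio = log2_ratio, stringsAsFactors = FALSE)
}

#' Median and quartile deviation of the ratio distribution
#'
#' Computes, over the genes whose ratio is defined, the median M and the
#' quartile deviation Q = (Q3 - Q1) / 2 (semi-interquartile range), and the
#' classification bounds M - Q and M + Q. Bounds are additionally reported
#' on the log2 scale, the scale on which ratio distributions are usually
#' plotted; a non-positive lower bound maps to `-Inf`.
#'
#' @param ratios data.frame from [compute_ratios()].
#' @param quartile_type quartile convention, passed to
#'   [stats::quantile()] `type`; default 7 (linear interpolation between
#'   order statistics).
#' @return Object of class `fluctuation_stats` with fields `n_total`,
#'   `n_defined`, `median`, `quartile_dev`, `lower_bound`, `upper_bound`,
#'   `lower_bound_log2`, `upper_bound_log2`, `quartile_type`.
#' @export
fluctuation_stats <- function(ratios, quartile_type = 7) {
  stopifnot(is.data.frame(ratios), "ratio" %in% names(ratios))
  r <- ratios$ratio[!is.na(ratios$ratio)]
  if (length(r) < 4)
    stop("need at least 4 defined ratios to estimate quartiles (got ",
         length(r), ")")
  qs <- stats::quantile(r, probs = c(0.25, 0.5, 0.75),
                        type = quartile_type, names = FALSE)
  m <- qs[2]
  q <- (qs[3] - qs[1]) / 2
  lower <- m - q
  upper <- m + q
  structure(
    list(n_total = nrow(ratios), n_defined = length(r),
         median = m, quartile_dev = q,
         lower_bound = lower, upper_bound = upper,
         lower_bound_log2 = if (lower > 0) log2(lower) else -Inf,
         upper_bound_log2 = if (upper > 0) log2(upper) else -Inf,
         quartile_type = quartile_type),
    class = "fluctuation_stats"
  )
}

#' @export
print.fluctuation_stats <- function(x, ...) {
  cat("<fluctuation_stats>\n")
  cat(sprintf("  genes: %d (%d with defined ratio)\n", x$n_total, x$n_defined))
  cat(sprintf("  median M = %.4f, quartile deviation Q = %.4f\n",
              x$median, x$quartile_dev))
  cat(sprintf("  stable band (ratio): %.4f .. %.4f\n",
              x$lower_bound, x$upper_bound))
  cat(sprintf("  stable band (log2):  %.4f .. %.4f\n",
              x$lower_bound_log2, x$upper_bound_log2))
  invisible(x)
}

#' Classify genes by expression-ratio fluctuation
#'
#' A gene is *fluctuating* when its ratio lies strictly outside the band
#' (R < M - Q or R > M + Q), *stable* when strictly inside
#' (M - Q < R < M + Q), *boundary* when exactly equal to a bound (both
#' defining inequalities are strict, so such genes satisfy neither), and
#' *undefined* when the ratio itself is undefined. The four classes
#' partition the input gene set.
#'
#' @param ratios data.frame from [compute_ratios()].
#' @param stats a [fluctuation_stats()] computed from the same ratios.
#' @return Object of class `fluctuation_classification`: a list of
#'   character vectors `stable`, `fluctuating`, `boundary`, `undefined`
#'   plus `n_total`.
#' @export
classify_genes <- function(ratios, stats) {
  stopifnot(inherits(stats, "fluctuation_stats"),
            is.data.frame(ratios),
            all(c("gene_id", "ratio") %in% names(ratios)))
  r <- ratios$ratio
  g <- ratios$gene_id
  undef <- is.na(r)
  stable <- !undef & r > stats$lower_bound & r < stats$upper_bound
  fluct <- !undef & (r < stats$lower_bound | r > stats$upper_bound)
  boundary <- !undef & !stable & !fluct
  structure(
    list(stable = sort(g[stable]), fluctuating = sort(g[fluct]),
         boundary = sort(g[boundary]), undefined = sort(g[undef]),
         n_total = length(g)),
    class = "fluctuation_classification"
  )
}

#' @export
print.fluctuation_classification <- function(x, ...) {
  cat("<fluctuation_classification>\n")
  cat(sprintf("  stable: %d  fluctuating: %d  boundary: %d  undefined: %d  (total %d)\n",
              length(x$stable), length(x$fluctuating), length(x$boundary),
              length(x$undefined), x$n_total))
  invisible(x)
}

#' Per-gene classification table
#'
#' @param ratios data.frame from [compute_ratios()].
#' @param classification a [classify_genes()] result.
#' @return data.frame `gene_id`, `ratio`, `log2_ratio`, `class`.
#' @export
classification_table <- function(ratios, classification) {
  cls <- rep(NA_character_, nrow(ratios))
  for (label in c("stable", "fluctuating", "boundary", "undefined"))
    cls[ratios$gene_id %in% classification[[label]]] <- label
  data.frame(gene_id = ratios$gene_id, ratio = ratios$ratio,
             log2_ratio = ratios$log2_ratio, class = cls,
             stringsAsFactors = FALSE)
}
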