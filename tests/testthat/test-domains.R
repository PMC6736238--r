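enrichment_db <- function(domains) {
  annotation_db(domains = domains)
}

test_that("binomial tail matches the exhaustive-summation oracle", {
  # n = 5 bottom genes, 3 carry the domain; 3 of the 20 background genes
  # carry DOM1, so p0 = 0.15
  doms <- c(
    list(b1 = "DOM1", b2 = "DOM1", b3 = "DOM1", b4 = "OTHER", b5 = "OTHER"),
    stats::setNames(rep(list("FILLER"), 15), paste0("f", 1:15))
  )
  db <- enrichment_db(doms)
  bottom <- paste0("b", 1:5)
  res <- domain_enrichment(bottom, db, names(doms))
  row <- res[res$domain_acc == "DOM1", ]
  expect_identical(row$k, 3L)
  expect_identical(row$n, 5L)
  expect_identical(row$K, 3L)
  expect_identical(row$N_bg, 20L)
  expect_equal(row$p_value, oracle_binom_tail(3, 5, 3 / 20),
               tolerance = 1e-12)
  expect_identical(sort(row$genes[[1]]), c("b1", "b2", "b3"))
})

test_that("degenerate tails are exactly one", {
  db <- enrichment_db(list(b1 = "DOM1", b2 = "DOM1", f1 = "DOM1",
                           f2 = "DOM1"))
  # k = 0 for a candidate domain nobody at the bottom carries
  res <- domain_enrichment(c("b1", "b2"), db, c("b1", "b2", "f1", "f2"),
                           candidate_domains = c("DOM1", "ABSENT"))
  expect_equal(res$p_value[res$domain_acc == "ABSENT"], 1)
  # k = n with p0 = 1 (every background gene carries the domain)
  expect_equal(res$p_value[res$domain_acc == "DOM1"], 1)
})

test_that("empty bottom sets give empty results; empty background errors", {
  db <- enrichment_db(list(g1 = "DOM1"))
  expect_identical(nrow(domain_enrichment(character(), db, "g1")), 0L)
  db_none <- enrichment_db(list())
  expect_error(domain_enrichment("g1", db_none, "g1"), "background")
  expect_error(domain_enrichment("g2", db, "g1"), "must contain")
})

test_that("the binomial tail is monotone non-increasing in k", {
  set.seed(17)
  for (p0 in runif(5, 0.05, 0.95)) {
    for (n in c(3, 10, 25)) {
      p <- vapply(0:n, genecascades:::binom_upper_tail, numeric(1),
                  n = n, p0 = p0)
      expect_true(all(diff(p) <= 1e-15))
    }
  }
})

test_that("the Fisher alternative matches the one-sided exact test", {
  doms <- c(list(b1 = "DOM1", b2 = "DOM1", b3 = "OTHER"),
            stats::setNames(rep(list(c("DOM1", "FILLER")), 4),
                            paste0("f", 1:4)),
            stats::setNames(rep(list("FILLER"), 13), paste0("g", 1:13)))
  db <- enrichment_db(doms)
  res <- domain_enrichment(c("b1", "b2", "b3"), db, names(doms),
                           test = "fisher")
  row <- res[res$domain_acc == "DOM1", ]
  ft <- fisher.test(matrix(c(row$k, row$n - row$k,
                             row$K - row$k,
                             row$N_bg - row$n - row$K + row$k), 2),
                    alternative = "greater")
  expect_equal(row$p_value, ft$p.value, tolerance = 1e-12)
})

test_that("transcription-domain cascades are removed and logged", {
  cc <- function(id) structure(list(cascade_id = id), class = "cascade")
  enr <- function(acc, p) {
    e <- data.frame(domain_acc = acc, k = 2L, n = 3L, K = 2L, N_bg = 30L,
                    p_value = p, stringsAsFactors = FALSE)
    e$genes <- list("x")
    e
  }
  cascades <- list(cc("c1"), cc("c2"), cc("c3"))
  enrichments <- list(c1 = enr("TRXDOM", 0.001),
                      c2 = enr("TRXDOM", 0.5),   # not significant
                      c3 = enr("SIGDOM", 0.001))
  kept <- filter_transcription_cascades(cascades, enrichments, "TRXDOM")
  expect_identical(vapply(kept, `[[`, "", "cascade_id"), c("c2", "c3"))
  removed <- attr(kept, "removed")
  expect_identical(removed$cascade_id, "c1")
  expect_identical(removed$domain_acc, "TRXDOM")

  # an empty transcription-domain set is the neutral element
  all_kept <- filter_transcription_cascades(cascades, enrichments,
                                            character(0))
  expect_length(all_kept, 3L)
  # a cascade with no enrichment rows is vacuously retained
  expect_length(filter_transcription_cascades(list(cc("c4")),
                                              list(c4 = enr("X", 1)[0, ]),
                                              "TRXDOM"), 1L)
})

test_that("category scores count distinct genes of significant domains", {
  mk_enr <- function(acc, p, genes) {
    e <- data.frame(domain_acc = acc, k = length(genes), n = 5L, K = 2L,
                    N_bg = 50L, p_value = p, stringsAsFactors = FALSE)
    e$genes <- list(genes)
    e
  }
  enr <- rbind(mk_enr("D1", 0.01, c("g1", "g2")),
               mk_enr("D2", 0.02, c("g2", "g3")),
               mk_enr("D3", 0.20, c("g4", "g5", "g6")),  # not significant
               mk_enr("D9", 0.01, "g7"))                 # unmapped
  cmap <- c(D1 = "Signal transduction", D2 = "Signal transduction",
            D3 = "Transport")
  res <- categorize_domains(enr, cmap, alpha = 0.05)
  # two significant domains map to one category hitting 3 distinct genes
  expect_identical(res$score[res$category == "Signal transduction"], 3L)
  expect_identical(res$score[res$category == "Unknown"], 1L)
  expect_false("Transport" %in% res$category)
  # fixed reporting order: named categories first, Unknown last
  expect_identical(res$category, c("Signal transduction", "Unknown"))

  expect_identical(nrow(categorize_domains(enr[0, ], cmap)), 0L)
  expect_identical(nrow(categorize_domains(mk_enr("D3", 0.9, "g1"), cmap)),
                   0L)
})

test_that("low-scoring categories fold into Others", {
  mk_enr <- function(acc, p, genes) {
    e <- data.frame(domain_acc = acc, k = length(genes), n = 5L, K = 2L,
                    N_bg = 50L, p_value = p, stringsAsFactors = FALSE)
    e$genes <- list(genes)
    e
  }
  enr <- rbind(mk_enr("D1", 0.01, c("g1", "g2", "g3")),
               mk_enr("D2", 0.01, "g4"))
  cmap <- c(D1 = "Development", D2 = "Transport")
  res <- categorize_domains(enr, cmap, min_score = 2)
  expect_identical(res$category, c("Development", "Others"))
  expect_identical(res$score[res$category == "Others"], 1L)
  # total gene tally is conserved by the fold
  expect_identical(sum(res$score), 4L)
})
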