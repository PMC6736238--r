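test_that("direct targets must pass all four criteria", {
  # five genes: only 'a' is a stable TF sharing a stage and a phenotype
  # with the query
  db <- toy_db()
  cls <- classification_of(stable = c("a", "b", "c"), fluctuating = "d")
  expect_identical(find_direct_targets("q", cls, db), "a")

  # exhaustive check: every single-criterion ablation of 'a' empties the
  # result
  db_no_tf <- toy_db()
  db_no_tf$tf_genes <- "b"
  expect_identical(find_direct_targets("q", cls, db_no_tf), character(0))
  cls_fluct_a <- classification_of(stable = c("b", "c"),
                                   fluctuating = c("a", "d"))
  expect_identical(find_direct_targets("q", cls_fluct_a, db), character(0))
  db_late <- toy_db(stages = list(a = "larva", b = "embryo", c = "embryo",
                                  d = "larva", q = "early embryo"))
  expect_identical(find_direct_targets("q", cls, db_late), character(0))
  db_phen <- toy_db()
  db_phen$phenotypes$a <- "sterile"
  expect_identical(find_direct_targets("q", cls, db_phen), character(0))
})

test_that("an empty transcription-factor set yields no targets", {
  db <- toy_db()
  db$tf_genes <- character(0)
  cls <- classification_of(stable = c("a", "b", "c", "d"))
  expect_identical(find_direct_targets("q", cls, db), character(0))
})

test_that("the query gene is excluded even when it passes every criterion", {
  db <- toy_db()
  db$tf_genes <- c(db$tf_genes, "q")
  cls <- classification_of(stable = c("a", "q"))
  expect_identical(find_direct_targets("q", cls, db), "a")
})

test_that("a query without stage terms is an error", {
  db <- toy_db()
  cls <- classification_of(stable = "a")
  expect_error(find_direct_targets("nostage", cls, db),
               "no life-stage annotation")
})

test_that("phenotype overlap threshold is configurable", {
  db <- toy_db()
  db$stages$b <- "early embryo"  # put 'b' in the query stage
  db$phenotypes$q <- c("embryonic lethal", "polarity defect")
  db$phenotypes$a <- c("embryonic lethal", "polarity defect")
  db$phenotypes$b <- "embryonic lethal"
  cls <- classification_of(stable = c("a", "b"))
  expect_setequal(find_direct_targets("q", cls, db,
                                      min_phenotype_overlap = 1), c("a", "b"))
  expect_identical(find_direct_targets("q", cls, db,
                                       min_phenotype_overlap = 2), "a")
})

test_that("an isolated root is its own cascade and bottom gene", {
  cc <- expand_cascade("a", toy_db())
  expect_identical(cc$nodes, "a")
  expect_identical(cc$bottom_genes, "a")
  expect_identical(nrow(cc$edges), 0L)
})

test_that("expansion terminates on cycles and keeps cycle-closing edges", {
  db <- toy_db(edges_df(list("a", "b", "regulatory", "positive"),
                        list("b", "c", "regulatory", "positive"),
                        list("c", "a", "regulatory", "negative")))
  cc <- expand_cascade("a", db)
  expect_identical(cc$nodes, c("a", "b", "c"))
  expect_identical(nrow(cc$edges), 3L)
})

test_that("candidates without an embryonic stage term are excluded", {
  db <- toy_db(edges_df(list("a", "b", "regulatory", "positive"),
                        list("a", "d", "regulatory", "positive")))
  cc <- expand_cascade("a", db)
  expect_false("d" %in% cc$nodes)
  expect_false("d" %in% cc$edges$target)
  expect_error(expand_cascade("d", db), "no stage term")
})

test_that("genetic and physical edges are traversed in both directions", {
  db <- toy_db(edges_df(list("b", "a", "physical"),
                        list("c", "b", "genetic")))
  cc <- expand_cascade("a", db)
  expect_identical(cc$nodes, c("a", "b", "c"))
})

test_that("regulatory edges are traversed source to target only", {
  db <- toy_db(edges_df(list("b", "a", "regulatory", "positive")))
  cc <- expand_cascade("a", db)
  expect_identical(cc$nodes, "a")
})

test_that("node tiers follow the early-embryo annotation", {
  db <- toy_db(edges_df(list("a", "b", "regulatory", "positive")))
  cc <- expand_cascade("a", db)
  expect_identical(unname(cc$tiers[c("a", "b")]),
                   c("early_embryo", "embryo"))
})

test_that("bottom genes are the regulatory leaves", {
  mk <- function(...) {
    db <- toy_db(edges_df(...),
                 stages = list(a = "embryo", b = "embryo", c = "embryo"))
    expand_cascade("a", db)
  }
  expect_identical(mk(list("a", "b", "regulatory", "positive"),
                      list("b", "c", "regulatory", "positive"))$bottom_genes,
                   "c")
  expect_identical(mk(list("a", "b", "regulatory", "positive"),
                      list("a", "c", "regulatory", "positive"))$bottom_genes,
                   c("b", "c"))
  # cycle with a tail: brute-force over out-degrees says only 'c' is a leaf
  expect_identical(mk(list("a", "b", "regulatory", "positive"),
                      list("b", "a", "regulatory", "positive"),
                      list("a", "c", "regulatory", "positive"))$bottom_genes,
                   "c")
})

test_that("a pure regulatory cycle falls back to its terminal component", {
  db <- toy_db(edges_df(list("a", "b", "regulatory", "positive"),
                        list("b", "a", "regulatory", "positive")),
               stages = list(a = "embryo", b = "embryo"))
  cc <- expand_cascade("a", db)
  expect_identical(cc$bottom_genes, c("a", "b"))

  # two-cycle graph: a<->b feeds c<->d; only the terminal cycle is bottom
  db2 <- toy_db(edges_df(list("a", "b", "regulatory", "positive"),
                         list("b", "a", "regulatory", "positive"),
                         list("b", "c", "regulatory", "positive"),
                         list("c", "d", "regulatory", "positive"),
                         list("d", "c", "regulatory", "positive")),
                stages = list(a = "embryo", b = "embryo", c = "embryo",
                              d = "embryo"))
  cc2 <- expand_cascade("a", db2)
  expect_identical(cc2$bottom_genes, c("c", "d"))
})

test_that("expansion matches a transitive-closure oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(123)
  for (rep in 1:60) {
    db <- random_graph_db(n_nodes = sample(4:12, 1),
                          n_edges = sample(3:24, 1))
    roots <- names(db$stages)[vapply(names(db$stages), function(g)
      length(intersect(db$stages[[g]], DEFAULT_STAGES)) > 0, logical(1))]
    if (length(roots) == 0) next
    root <- sample(roots, 1)
    cc <- expand_cascade(root, db)
    expect_identical(cc$nodes, oracle_cascade_nodes(root, db, DEFAULT_STAGES))
  }
})

test_that("expansion terminates on large random graphs", {
  set.seed(321)
  db <- random_graph_db(n_nodes = 400, n_edges = 10000)
  roots <- names(db$stages)[vapply(names(db$stages), function(g)
    length(intersect(db$stages[[g]], DEFAULT_STAGES)) > 0, logical(1))]
  cc <- expand_cascade(roots[1], db)
  expect_true(length(cc$nodes) <= 400)
  expect_true(all(cc$edges$source %in% cc$nodes))
})

test_that("enlarging the stage vocabulary never removes nodes", {
  set.seed(55)
  for (rep in 1:20) {
    db <- random_graph_db(n_nodes = 10, n_edges = 18, p_embryonic = 0.5)
    roots <- names(db$stages)[vapply(names(db$stages), function(g)
      "embryo" %in% db$stages[[g]] || "early embryo" %in% db$stages[[g]],
      logical(1))]
    if (length(roots) == 0) next
    small <- expand_cascade(roots[1], db, allowed_stages = DEFAULT_STAGES)
    big <- expand_cascade(roots[1], db,
                          allowed_stages = c(DEFAULT_STAGES, "larva"))
    expect_true(all(small$nodes %in% big$nodes))
  }
})

test_that("one cascade per direct target, in deterministic order", {
  db <- toy_db(edges_df(list("a", "c", "regulatory", "positive")))
  db$phenotypes$b <- "embryonic lethal"
  db$stages$b <- "early embryo"  # so 'b' shares a stage with the query
  cls <- classification_of(stable = c("a", "b", "c"))
  ccs <- build_all_cascades("q", cls, db)
  expect_length(ccs, 2L)
  expect_identical(vapply(ccs, `[[`, "", "root_target"), c("a", "b"))
  expect_identical(vapply(ccs, `[[`, "", "cascade_id"),
                   c("q_to_a", "q_to_b"))
  ccs2 <- build_all_cascades("q", cls, db)
  expect_identical(ccs, ccs2)

  cls_none <- classification_of(fluctuating = c("a", "b", "c"))
  expect_length(build_all_cascades("q", cls_none, db), 0L)
})
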