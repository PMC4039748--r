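test_that("the exact test matches closed forms and the standard implementation", {
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_equal(fisher_exact(1, 1, 1, 1, "greater"), 5 / 6) # P(a >= 1)
  expect_equal(fisher_exact(5, 0, 0, 5), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact(5, 0, 0, 5, "greater"), 1 / choose(10, 5), tolerance = 1e-12)
  expect_error(fisher_exact(-1, 2, 3, 4), "nonnegative")

  set.seed(31)
  for (i in 1:100) {
    t <- sample(0:15, 4, replace = TRUE)
    if (sum(t) == 0) next
    # cross-check against stats::fisher.test, an independent implementation
    ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE))
    expect_equal(fisher_exact(t[1], t[2], t[3], t[4]), ft$p.value, tolerance = 1e-9)
    gt <- stats::fisher.test(matrix(t, 2, byrow = TRUE), alternative = "greater")
    expect_equal(fisher_exact(t[1], t[2], t[3], t[4], "greater"), gt$p.value,
      tolerance = 1e-9
    )
    # upper tail identity: 1 - cdf(a - 1) of the hypergeometric
    expect_lt(
      abs(fisher_exact(t[1], t[2], t[3], t[4], "greater") -
        (1 - phyper(t[1] - 1, t[1] + t[3], t[2] + t[4], t[1] + t[2]))),
      1e-10
    )
  }
})

test_that("TOP enrichment builds the group-vs-rest tables over the 1-8 universe", {
  cl <- classification_with_sizes(c(20, 15, 5, 10, 5, 5, 10, 5, 100))
  status <- tibble::tibble(
    gene_id = cl$gene_id,
    # plant motifs in most of group 1, few elsewhere
    top_bearing = ifelse(cl$group_id == 1, cl$group_id <= 1 &
      seq_len(nrow(cl)) %% 5 != 0, seq_len(nrow(cl)) %% 25 == 0)
  )
  res <- top_enrichment(cl, status)
  expect_equal(nrow(res), 8)
  universe_n <- sum(cl$group_id <= 8)
  # margins: every table resolves to the same universe
  expect_true(all(res$a + res$b + res$c + res$d == universe_n))
  g1 <- res[res$group_id == 1, ]
  expect_equal(g1$a + g1$b, 20) # group size within the universe
  expect_equal(g1$p_value, fisher_exact(g1$a, g1$b, g1$c, g1$d))
  expect_true(g1$significant)

  # genes without UTR status are excluded with a message
  status2 <- status[-(1:3), ]
  expect_message(res2 <- top_enrichment(cl, status2), "Excluding 3 gene")
  expect_equal(res2$a[1] + res2$b[1], 17)

  # all genes TOP-bearing: both columns collapse, p = 1
  all_top <- dplyr::mutate(status, top_bearing = TRUE)
  res3 <- top_enrichment(cl, all_top)
  expect_true(all(res3$b == 0 & res3$d == 0))
  expect_true(all(res3$p_value == 1))

  # an empty group yields p = 1 with a warning
  cl0 <- classification_with_sizes(c(20, 15, 5, 10, 5, 5, 10, 0, 100))
  status0 <- tibble::tibble(gene_id = cl0$gene_id, top_bearing = FALSE)
  expect_warning(res0 <- top_enrichment(cl0, status0), "group 8 has no genes")
  expect_equal(res0$p_value[res0$group_id == 8], 1)
})

test_that("GO enrichment counts propagated genes against the reference list", {
  cl <- classification_with_sizes(c(10, 10, 0, 0, 0, 0, 0, 0, 30))
  grp1 <- cl$gene_id[cl$group_id == 1]
  grp2 <- cl$gene_id[cl$group_id == 2]
  terms <- tibble::tibble(
    term_id = c("GO:root", "GO:grp1", "GO:other"),
    name = c("root", "planted", "other"),
    namespace = "BP",
    parents = list(character(), "GO:root", "GO:root")
  )
  ann <- tibble::tibble(
    gene_id = c(grp1, grp2), # group 9 genes are unannotated
    term_id = c(rep("GO:grp1", 10), rep("GO:other", 10))
  )
  onto <- gene_ontology(terms, ann)
  res <- go_enrichment(cl, onto, namespace = "BP")
  # universe: annotated genes of groups 1-8 only
  expect_true(all(res$a + res$b + res$c + res$d == 20))
  g1 <- res[res$group_id == 1, ]
  # the term annotated to exactly the group reaches the minimal p: 1/C(|U|,|g|)
  planted <- g1[g1$term_id == "GO:grp1", ]
  expect_equal(planted$a, 10)
  expect_equal(planted$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_true(planted$significant)
  # the root term covers the whole universe: p = 1
  expect_equal(g1$p_value[g1$term_id == "GO:root"], 1)
  # output is sorted by p within group, ties by term id
  expect_equal(g1$term_id[1], "GO:grp1")
  # child-term counts never exceed an ancestor's for the same group
  expect_gte(
    g1$a[g1$term_id == "GO:root"],
    g1$a[g1$term_id == "GO:grp1"]
  )
  # raw p-values: no multiple-testing adjustment is applied
  expect_equal(
    res$p_value,
    fisher_exact(res$a, res$b, res$c, res$d, "greater")
  )
  # boundary: significance uses p <= alpha
  expect_true(all(res$significant == (res$p_value <= 0.05)))
  expect_error(
    go_enrichment(cl, onto, namespace = "MF"),
    "No testable terms|Empty universe"
  )
})

test_that("planted GO enrichment ranks the enriched terms near the top", {
  hits <- 0
  runs <- 20
  for (seed in seq_len(runs)) {
    cl <- classification_with_sizes(c(60, 0, 0, 0, 0, 0, 0, 0, 440))
    target <- cl$gene_id[cl$group_id == 1]
    sim <- simulate_ontology(cl$gene_id, 40,
      enriched_term_fraction = 0.1,
      target_genes = target, seed = seed,
      background_prob = 0.05, enrichment_factor = 5
    )
    res <- go_enrichment(cl, sim$ontology, namespace = "BP", groups = c(1, 9))
    res1 <- res[res$group_id == 1, ]
    planted <- res1$term_id %in% sim$enriched_terms
    # planted terms rank above the background terms on average
    if (mean(rank(res1$p_value)[planted]) <
      mean(rank(res1$p_value)[!planted])) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / runs, 0.9)
})
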