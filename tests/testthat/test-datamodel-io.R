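test_that("expression TSV round-trips and validates its design", {
  tmp <- withr::local_tempdir()
  sim <- simulate_expression(sim_config(n_genes = 40, n_spikeins = 5, seed = 11))
  ep <- file.path(tmp, "expr.tsv")
  mp <- file.path(tmp, "meta.tsv")
  write_expression_table(sim$data, ep, mp)
  back <- read_expression_table(ep, mp)
  expect_equal(back$expression, sim$data$expression, tolerance = 1e-12)
  expect_equal(back$samples, sim$data$samples)

  # a tiny hand-built table reads to the expected shape
  writeLines(c(
    "gene_id\ts1\ts2\ts3\ts4\ts5\ts6\ts7\ts8",
    paste(c("gA", 1:8), collapse = "\t"),
    paste(c("gB", 8:1), collapse = "\t")
  ), file.path(tmp, "small.tsv"))
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    fraction = rep(c("polysomal", "nonpolysomal"), each = 4),
    time_h = rep(c(0, 0, 6, 6), 2),
    replicate = rep(1:2, 4)
  )
  readr::write_tsv(meta, file.path(tmp, "small_meta.tsv"))
  small <- read_expression_table(file.path(tmp, "small.tsv"), file.path(tmp, "small_meta.tsv"))
  expect_equal(nrow(small$expression), 2)
  expect_equal(nrow(small$samples), 8)
  expect_false(any(small$expression$spikein))
})

test_that("malformed expression inputs fail with pointed messages", {
  tmp <- withr::local_tempdir()
  sim <- simulate_expression(sim_config(n_genes = 5, n_spikeins = 2, replicates = 2, seed = 2))
  ep <- file.path(tmp, "expr.tsv")
  mp <- file.path(tmp, "meta.tsv")
  write_expression_table(sim$data, ep, mp)

  # metadata missing one declared sample column
  meta <- sim$data$samples[-3, ]
  readr::write_tsv(meta, file.path(tmp, "short_meta.tsv"))
  expect_error(
    read_expression_table(ep, file.path(tmp, "short_meta.tsv")),
    sim$data$samples$sample_id[3]
  )

  # non-numeric cell reported with row and column
  lines <- readLines(ep)
  lines[3] <- sub("(\t[-0-9.e]+)$", "\toops", lines[3])
  writeLines(lines, file.path(tmp, "bad.tsv"))
  expect_error(
    read_expression_table(file.path(tmp, "bad.tsv"), mp),
    "non-numeric value 'oops' at row 2"
  )

  # duplicate gene ids
  dup <- sim$data$expression[c(1, 1, 2), ]
  expect_error(expr_set(dup, sim$data$samples), "Duplicate gene ids")

  # single replicate in a populated cell
  one_rep <- sim$data$samples
  expect_error(
    expr_set(
      sim$data$expression[, c("gene_id", "spikein", one_rep$sample_id[-2])],
      one_rep[-2, ]
    ),
    "fewer than 2 replicates"
  )
})

test_that("FASTA reading enforces the UTR alphabet and tags", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "utr.fa")
  writeLines(c(
    ">NM_025587 gene=Rps21", "ctcctgaaa",
    ">plain_header", "ACGU"
  ), fa)
  utrs <- read_utr_fasta(fa)
  expect_equal(utrs$refseq_id, c("NM_025587", "plain_header"))
  expect_equal(utrs$gene_id, c("Rps21", "plain_header"))
  expect_match(utrs$sequence[1], "^CTCCTG")
  expect_equal(utrs$sequence[2], "ACGT") # U -> T, case folded
  expect_equal(utrs$length, c(9L, 4L))

  writeLines(c(">x", "ACGN"), fa)
  expect_error(read_utr_fasta(fa), "outside the A/C/G/T/U alphabet")
  writeLines(c(">x", "", ">y", "ACGT"), fa)
  expect_error(read_utr_fasta(fa), "Empty sequence")

  # write -> read round-trip
  out <- tibble::tibble(
    gene_id = c("a", "b"), refseq_id = c("NM_1", "NM_2"),
    sequence = c("ACGT", "CTTTG"), length = c(4L, 5L)
  )
  write_utr_fasta(out, fa)
  expect_equal(read_utr_fasta(fa), out)
})

test_that("ontology reading, cycle detection and true-path propagation work", {
  tmp <- withr::local_tempdir()
  obo <- file.path(tmp, "toy.obo")
  ann <- file.path(tmp, "ann.tsv")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:a", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:b", "name: mid", "namespace: biological_process",
    "is_a: GO:a ! root", "",
    "[Term]", "id: GO:c", "name: leaf", "namespace: biological_process",
    "is_a: GO:b", "",
    "[Term]", "id: GO:old", "name: gone", "is_obsolete: true", ""
  ), obo)
  readr::write_tsv(
    tibble::tibble(gene_id = c("g1", "g2"), term_id = c("GO:c", "GO:zzz")),
    ann
  )
  expect_message(onto <- read_ontology(obo, ann), "Dropped 1 annotation")
  expect_equal(nrow(onto$terms), 3) # obsolete term dropped
  expect_equal(onto$terms$namespace, rep("BP", 3))
  # true-path rule: the gene reaches every ancestor
  expect_equal(onto$propagated[["GO:a"]], "g1")
  expect_equal(onto$propagated[["GO:b"]], "g1")
  expect_equal(onto$propagated[["GO:c"]], "g1")
  expect_equal(onto$n_dropped_annotations, 1L)

  # ontology round-trip through OBO + TSV
  write_ontology(onto, obo, ann)
  back <- read_ontology(obo, ann)
  expect_equal(back$terms, onto$terms)
  expect_equal(back$propagated, onto$propagated)

  cyc <- tibble::tibble(
    term_id = c("t1", "t2"), name = c("a", "b"), namespace = "BP",
    parents = list("t2", "t1")
  )
  expect_error(
    gene_ontology(cyc, tibble::tibble(gene_id = character(), term_id = character())),
    "Cycle in is_a graph"
  )
  expect_error(
    gene_ontology(
      tibble::tibble(term_id = "t1", name = "a", namespace = "BP", parents = list("nope")),
      tibble::tibble(gene_id = character(), term_id = character())
    ),
    "Unresolved parent"
  )
})

test_that("propagation equals the ancestor-closure oracle and is idempotent", {
  for (seed in 1:3) {
    genes <- sprintf("g%02d", 1:30)
    onto <- simulate_ontology(genes, 50,
      enriched_term_fraction = 0, seed = seed,
      background_prob = 0.08
    )$ontology
    expect_equal(onto$propagated, propagation_oracle(onto))
    expect_equal(propagate_annotations(onto), onto$propagated)
    # monotone containment along is_a
    for (i in seq_len(nrow(onto$terms))) {
      for (p in onto$terms$parents[[i]]) {
        expect_true(all(
          onto$propagated[[onto$terms$term_id[i]]] %in% onto$propagated[[p]]
        ))
      }
    }
  }
})
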