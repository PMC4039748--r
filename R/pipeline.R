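#' Configuration of an end-to-end pipeline run
#'
#' Either point the pipeline at existing input files (expression +
#' metadata TSV, optional UTR FASTA and ontology OBO/annotation TSV) or
#' let it generate seeded synthetic inputs. Stages whose inputs are absent
#' are skipped with a logged notice.
#'
#' @param out_dir Output directory (created if missing).
#' @param expression_path,metadata_path,spikein_path Input TSVs for
#'   [read_expression_table()]; leave `NULL` to simulate.
#' @param fasta_path 5'UTR FASTA for the TOP stages (`NULL` to use
#'   simulated UTRs when simulating, otherwise the TOP stages are
#'   skipped).
#' @param obo_path,annotation_path Ontology inputs for the GO stage.
#' @param sim A [sim_config()] used when no expression input is given.
#' @param normalize Run spike-in normalization (default `TRUE`).
#' @param rule A [significance_rule()].
#' @param min_pyrimidines TOP scanner threshold.
#' @param top_alternative,go_alternative Sidedness of the two enrichment
#'   tests.
#' @param go_namespaces Namespaces to test in the GO stage.
#' @param seed Integer seed recorded in every output header and used for
#'   the synthetic generators.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            expression_path = NULL, metadata_path = NULL,
                            spikein_path = NULL, fasta_path = NULL,
                            obo_path = NULL, annotation_path = NULL,
                            sim = sim_config(),
                            normalize = TRUE,
                            rule = significance_rule(),
                            min_pyrimidines = 3,
                            top_alternative = "two.sided",
                            go_alternative = "greater",
                            go_namespaces = "BP",
                            seed = 1) {
  for (p in c(expression_path, metadata_path, spikein_path, fasta_path,
              obo_path, annotation_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("Input path does not exist: ", p))
    }
  }
  structure(
    list(
      out_dir = out_dir,
      expression_path = expression_path, metadata_path = metadata_path,
      spikein_path = spikein_path, fasta_path = fasta_path,
      obo_path = obo_path, annotation_path = annotation_path,
      sim = sim, normalize = normalize, rule = rule,
      min_pyrimidines = min_pyrimidines,
      top_alternative = top_alternative, go_alternative = go_alternative,
      go_namespaces = go_namespaces,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

pipeline_log <- function(...) {
  message("[polyeff] ", ...)
}

# TSV with a reproducibility header comment; read back with comment = "#"
write_stage_tsv <- function(x, path, header) {
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or file reading),
#' spike-in normalization, the TC/TL moderated-t analysis, nine-group
#' classification with group sizes and marginals, the TOP motif scan, and
#' the TOP and GO enrichment tests. Every output TSV carries a header
#' comment with the package version, the configuration hash and the seed;
#' identical configurations reproduce identical outputs. A stage failure
#' aborts the run naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`data`, `fit`, `classified`, `group_sizes`, `marginals`,
#'   `top_hits`, `top_status`, `top_enrichment`, `go_enrichment`,
#'   `files`).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   out_dir = tempfile("polyeff_run_"),
#'   sim = sim_config(n_genes = 300, seed = 7), seed = 7
#' )
#' res <- run_pipeline(cfg)
#' res$marginals
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  header <- paste0(
    "# polyeff ", as.character(utils::packageVersion("polyeff")),
    "; config_hash=", hash, "; seed=", config$seed
  )
  files <- character()
  out <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
    pipeline_log(
      name, " done in ",
      format(difftime(Sys.time(), t0, units = "secs"), digits = 3)
    )
    res
  }

  simulated <- is.null(config$expression_path)
  truth <- NULL
  utrs <- NULL
  if (simulated) {
    sim <- stage("simulate", {
      cfg <- config$sim
      cfg$seed <- config$seed
      simulate_expression(cfg)
    })
    es <- sim$data
    truth <- sim$truth
    utrs <- simulate_utrs(truth, seed = config$seed + 1L,
                          min_pyrimidines = config$min_pyrimidines)
    write_expression_table(es, out("expression.tsv"), out("samples.tsv"),
                           header = header)
    write_stage_tsv(truth, out("truth.tsv"), header)
    write_utr_fasta(utrs, out("utrs.fa"))
    files <- c(files, out("expression.tsv"), out("samples.tsv"),
               out("truth.tsv"), out("utrs.fa"))
  } else {
    es <- stage("read", read_expression_table(
      config$expression_path, config$metadata_path, config$spikein_path
    ))
    if (!is.null(config$fasta_path)) {
      utrs <- stage("read-fasta", read_utr_fasta(config$fasta_path))
    }
  }

  norm_report <- NULL
  if (config$normalize) {
    norm <- stage("normalize", normalize_spikein(es))
    es <- norm$data
    norm_report <- norm$report
    files <- c(files, write_stage_tsv(
      norm_report, out("normalization_report.tsv"), header
    ))
  } else {
    pipeline_log("normalize skipped by configuration")
  }

  fit <- stage("analyze", analyze_efficiency(es))
  files <- c(files, write_stage_tsv(tidy(fit), out("efficiency.tsv"), header))

  classified <- stage("classify", classify_regulation(
    filter(tidy(fit), !.data$spikein), config$rule
  ))
  group_sizes <- regulation_summary(classified)
  marginals <- regulation_marginals(classified)
  files <- c(
    files,
    write_stage_tsv(
      select(classified, "gene_id", "tc", "tl", "tc_status", "tl_status",
             "group_id", "group_name", "net_effect"),
      out("classification.tsv"), header
    ),
    write_stage_tsv(group_sizes, out("group_sizes.tsv"), header),
    write_stage_tsv(marginals, out("marginals.tsv"), header)
  )

  top_hits <- NULL
  top_status <- NULL
  top_enr <- NULL
  if (!is.null(utrs)) {
    top_hits <- stage("scan-top", scan_top(
      utrs, min_pyrimidines = config$min_pyrimidines
    ))
    top_status <- summarize_top(utrs, min_pyrimidines = config$min_pyrimidines)
    top_enr <- stage("enrich-top", top_enrichment(
      classified, top_status, alternative = config$top_alternative
    ))
    files <- c(
      files,
      write_stage_tsv(top_hits, out("top_hits.tsv"), header),
      write_stage_tsv(top_status, out("top_status.tsv"), header),
      write_stage_tsv(top_enr, out("top_enrichment.tsv"), header)
    )
  } else {
    pipeline_log("scan-top/enrich-top skipped: no UTR sequences available")
  }

  go_enr <- NULL
  ontology <- NULL
  if (simulated) {
    ontology <- stage("simulate-ontology", {
      target <- classified$gene_id[classified$group_id == 1L]
      simulate_ontology(
        genes = truth$gene_id[!truth$spikein], n_terms = 50,
        enriched_term_fraction = 0.1, target_genes = target,
        seed = config$seed + 2L
      )$ontology
    })
    write_ontology(ontology, out("ontology.obo"), out("annotations.tsv"),
                   header = header)
    files <- c(files, out("ontology.obo"), out("annotations.tsv"))
  } else if (!is.null(config$obo_path) && !is.null(config$annotation_path)) {
    ontology <- stage("read-ontology", read_ontology(
      config$obo_path, config$annotation_path
    ))
  }
  if (!is.null(ontology)) {
    go_enr <- stage("enrich-go", bind_rows(lapply(
      intersect(config$go_namespaces, unique(ontology$terms$namespace)),
      function(ns) {
        go_enrichment(classified, ontology,
          namespace = ns,
          alternative = config$go_alternative
        )
      }
    )))
    files <- c(files, write_stage_tsv(go_enr, out("go_enrichment.tsv"), header))
  } else {
    pipeline_log("enrich-go skipped: no ontology available")
  }

  report <- c(
    header,
    paste0("genes: ", nrow(classified), "  samples: ", fit$n_samples),
    paste0(
      "prior: d0 = ", format(fit$prior$d0, digits = 4),
      ", s0_sq = ", format(fit$prior$s0_sq, digits = 4)
    ),
    "",
    "group sizes:",
    paste0(
      "  ", format(group_sizes$group_name, width = 28),
      group_sizes$n
    ),
    "",
    "marginals:",
    paste0("  ", format(marginals$marginal, width = 28), marginals$n),
    if (!is.null(top_enr)) c(
      "",
      "TOP-bearing genes per group:",
      paste0(
        "  ", format(top_enr$group_name, width = 28), top_enr$a,
        "  (p = ", signif(top_enr$p_value, 3), ")"
      )
    ),
    if (!is.null(go_enr)) c(
      "",
      "top GO terms per group (by p):",
      {
        top3 <- dplyr::slice_min(group_by(go_enr, .data$group_id),
          .data$p_value, n = 3, with_ties = FALSE
        )
        paste0(
          "  ", format(top3$group_name, width = 28), top3$term_id,
          "  p = ", signif(top3$p_value, 3)
        )
      }
    )
  )
  writeLines(report, out("report.txt"))
  files <- c(files, out("report.txt"))
  pipeline_log("report written to ", out("report.txt"))

  invisible(list(
    data = es, truth = truth, fit = fit, classified = classified,
    group_sizes = group_sizes, marginals = marginals,
    normalization = norm_report,
    top_hits = top_hits, top_status = top_status, top_enrichment = top_enr,
    go_enrichment = go_enr, ontology = ontology, files = files
  ))
}
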