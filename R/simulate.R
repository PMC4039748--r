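#' Configuration of the synthetic expression generator
#'
#' Collects the parameters of the simulated two-fraction, two-timepoint
#' log2-intensity design. Defaults emulate the study conditions of an
#' early-adipogenesis polysome-profiling experiment: group proportions
#' follow the nine-group classification of such a time course, planted
#' effect magnitudes straddle the |log2FC| > 1 calling threshold, and the
#' gene-wise variances follow the scaled inverse-chi-square prior the
#' moderated t-test assumes.
#'
#' @param n_genes Number of non-control genes.
#' @param n_spikeins Number of spike-in control probes (zero effects).
#' @param replicates Replicates per fraction x time cell (>= 2).
#' @param group_proportions Nine nonnegative weights summing to 1, in
#'   regulation-group order 1-9 (see [regulation_groups()]); genes are
#'   assigned by largest-remainder rounding.
#' @param effect_low,effect_high Uniform range of nonzero TC/TL effect
#'   magnitudes (log2 units).
#' @param d0,s0_sq Prior degrees of freedom and prior variance of the
#'   gene-wise variance distribution `s0_sq * d0 / chisq(d0)` (log2^2);
#'   `d0 = Inf` makes all variances equal `s0_sq`.
#' @param array_offset_sd Standard deviation (log2) of the additive
#'   per-sample offset applied to every probe, spike-ins included.
#' @param top_probability_by_group Nine probabilities that a gene of each
#'   group carries a 5'TOP motif.
#' @param baseline_range Range of baseline log2 intensities.
#' @param seed Integer seed; identical configurations reproduce identical
#'   data.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_spikeins = 50,
                       replicates = 3,
                       group_proportions = c(813, 754, 25, 660, 10, 87, 358, 37, 2536) / 5280,
                       effect_low = 1.25,
                       effect_high = 3,
                       d0 = 4,
                       s0_sq = 0.05,
                       array_offset_sd = 0.3,
                       top_probability_by_group = c(0.5, rep(0.05, 8)),
                       baseline_range = c(6, 12),
                       seed = 1) {
  stopifnot(
    n_genes >= 1, n_spikeins >= 1, replicates >= 2,
    length(group_proportions) == 9, all(group_proportions >= 0),
    abs(sum(group_proportions) - 1) < 1e-9,
    effect_low >= 0, effect_high >= effect_low,
    d0 > 0, s0_sq > 0, array_offset_sd >= 0,
    length(top_probability_by_group) == 9,
    all(top_probability_by_group >= 0 & top_probability_by_group <= 1)
  )
  structure(
    list(
      n_genes = as.integer(n_genes), n_spikeins = as.integer(n_spikeins),
      replicates = as.integer(replicates),
      group_proportions = group_proportions,
      effect_low = effect_low, effect_high = effect_high,
      d0 = d0, s0_sq = s0_sq, array_offset_sd = array_offset_sd,
      top_probability_by_group = top_probability_by_group,
      baseline_range = baseline_range,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# largest-remainder apportionment of n items to weights
largest_remainder <- function(n, weights) {
  weights <- weights / sum(weights)
  quota <- n * weights
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Simulate a two-fraction, two-timepoint expression dataset
#'
#' Generates log2 intensities for `replicates` arrays in each of the four
#' design cells (polysomal/non-polysomal x 0 h/6 h). Each gene draws a
#' regulation group; its condition means are built so that the population
#' TC and TL equal the drawn effects: relative to the 0 h baseline, the
#' polysomal 6 h mean is shifted by `TC + TL/2` and the non-polysomal 6 h
#' mean by `TC - TL/2`. Gene-wise variances follow
#' `s0_sq * d0 / chisq(d0)`; replicate values are normal around the cell
#' mean; every sample additionally receives one additive offset (applied
#' to all probes, spike-ins included) that spike-in normalization can
#' remove. Spike-in probes have zero TC and TL by construction.
#'
#' @param config A [sim_config()].
#' @return List with elements `data` (an [expr_set]) and `truth`, a tibble
#'   with one row per probe: `gene_id`, `spikein`, `group_id`,
#'   `group_name`, `tc_true`, `tl_true`, `sigma_sq`, `top_flag`, plus the
#'   per-sample `offsets` tibble.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  counts <- largest_remainder(n, config$group_proportions)
  group_id <- sample(rep.int(1:9, counts))
  groups <- regulation_groups()
  tc_sign <- c(up = 1, unchanged = 0, down = -1)[groups$tc_status][group_id]
  tl_sign <- c(up = 1, unchanged = 0, down = -1)[groups$tl_status][group_id]
  mag <- function(sign) {
    ifelse(sign == 0, 0, sign * runif(n, config$effect_low, config$effect_high))
  }
  tc_true <- mag(tc_sign)
  tl_true <- mag(tl_sign)
  top_flag <- rbinom(n, 1, config$top_probability_by_group[group_id]) == 1

  n_all <- n + config$n_spikeins
  gene_id <- c(
    sprintf("gene_%05d", seq_len(n)),
    sprintf("spike_%03d", seq_len(config$n_spikeins))
  )
  spikein <- c(rep(FALSE, n), rep(TRUE, config$n_spikeins))
  tc_all <- c(tc_true, rep(0, config$n_spikeins))
  tl_all <- c(tl_true, rep(0, config$n_spikeins))
  sigma_sq <- if (is.infinite(config$d0)) {
    rep(config$s0_sq, n_all)
  } else {
    config$s0_sq * config$d0 / rchisq(n_all, config$d0)
  }
  baseline <- runif(n_all, config$baseline_range[1], config$baseline_range[2])

  samples <- tidyr::expand_grid(
    fraction = c("polysomal", "nonpolysomal"),
    time_h = c(0, 6),
    replicate = seq_len(config$replicates)
  )
  samples <- mutate(samples,
    sample_id = paste0(
      ifelse(.data$fraction == "polysomal", "p", "np"),
      .data$time_h, "_r", .data$replicate
    )
  ) |> select("sample_id", "fraction", "time_h", "replicate")
  offsets <- rnorm(nrow(samples), 0, config$array_offset_sd)

  # population cell means: 0 h = baseline; 6 h shifted by TC +- TL/2
  shift6 <- ifelse(samples$fraction == "polysomal", 1, -1)
  values <- matrix(NA_real_, n_all, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline +
      (samples$time_h[j] == 6) * (tc_all + shift6[j] * tl_all / 2)
    values[, j] <- rnorm(n_all, mu, sqrt(sigma_sq)) + offsets[j]
  }
  expression <- bind_cols(
    tibble(gene_id = gene_id, spikein = spikein),
    as_tibble(setNames(as.data.frame(values), samples$sample_id))
  )
  group_all <- c(group_id, rep(9L, config$n_spikeins))
  truth <- tibble(
    gene_id = gene_id, spikein = spikein,
    group_id = group_all,
    group_name = groups$group_name[group_all],
    tc_true = tc_all, tl_true = tl_all,
    sigma_sq = sigma_sq,
    top_flag = c(top_flag, rep(FALSE, config$n_spikeins))
  )
  list(
    data = expr_set(expression, samples),
    truth = truth,
    offsets = tibble(sample_id = samples$sample_id, offset = offsets)
  )
}

#' Simulate 5'UTR sequences with planted TOP motifs
#'
#' TOP-flagged genes receive a 5'-anchored motif: `C`, then 3-12 random
#' pyrimidines, then `G`, followed by a random 20-200 nt tail. Non-flagged
#' genes receive a random sequence, re-drawn until position 1 does not
#' open a TOP motif.
#'
#' @param truth Truth tibble from [simulate_expression()] (columns
#'   `gene_id`, `top_flag`; spike-ins are skipped).
#' @param seed Integer seed.
#' @param min_pyrimidines Scanner threshold the planted motifs must meet.
#' @return Tibble of UTR records (`gene_id`, `refseq_id`, `sequence`,
#'   `length`).
#' @export
simulate_utrs <- function(truth, seed = 1, min_pyrimidines = 3) {
  set.seed(seed)
  genes <- filter(truth, !.data$spikein)
  rand_seq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  sequence <- purrr::map_chr(seq_len(nrow(genes)), function(i) {
    if (genes$top_flag[i]) {
      run <- paste(sample(c("C", "T"), sample(3:12, 1), replace = TRUE),
        collapse = ""
      )
      paste0("C", run, "G", rand_seq(sample(20:200, 1)))
    } else {
      repeat {
        s <- rand_seq(sample(24:214, 1))
        if (nrow(scan_top(s, min_pyrimidines = min_pyrimidines)) == 0) {
          return(s)
        }
      }
    }
  })
  tibble(
    gene_id = genes$gene_id,
    refseq_id = sprintf("SYN_%05d", seq_len(nrow(genes))),
    sequence = sequence,
    length = nchar(sequence)
  )
}

#' Simulate a toy gene ontology with planted enrichment
#'
#' Builds a random rooted DAG of `n_terms` terms (each non-root term picks
#' one or two parents among earlier terms) and random direct annotations:
#' every gene-term pair is annotated with `background_prob`; a designated
#' fraction of terms is enriched, annotating `target_genes` with
#' `background_prob * enrichment_factor` instead.
#'
#' @param genes Character vector of gene ids.
#' @param n_terms Number of terms (>= 2).
#' @param enriched_term_fraction Fraction of non-root terms that are
#'   enriched in the target genes.
#' @param target_genes Genes with elevated annotation odds at enriched
#'   terms (default none).
#' @param seed Integer seed.
#' @param background_prob Per gene-term direct annotation probability.
#' @param enrichment_factor Odds multiplier at enriched terms.
#' @param namespace Namespace assigned to all terms (`"BP"` or `"MF"`).
#' @return List with elements `ontology` (a [gene_ontology]) and
#'   `enriched_terms` (character vector of planted term ids).
#' @export
simulate_ontology <- function(genes, n_terms, enriched_term_fraction = 0.1,
                              target_genes = character(), seed = 1,
                              background_prob = 0.05, enrichment_factor = 5,
                              namespace = "BP") {
  stopifnot(length(genes) >= 1, n_terms >= 2)
  set.seed(seed)
  term_id <- sprintf("GO:SIM%04d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  parents[[1]] <- character()
  for (i in 2:n_terms) {
    k <- sample(1:2, 1)
    parents[[i]] <- term_id[sample.int(i - 1, min(k, i - 1))]
  }
  terms <- tibble(
    term_id = term_id,
    name = paste("simulated term", seq_len(n_terms)),
    namespace = namespace,
    parents = parents
  )
  n_enriched <- round(enriched_term_fraction * (n_terms - 1))
  enriched <- if (n_enriched > 0) {
    sample(term_id[-1], n_enriched)
  } else {
    character()
  }
  prob <- matrix(background_prob, length(genes), n_terms)
  if (length(target_genes) && length(enriched)) {
    prob[
      genes %in% target_genes,
      term_id %in% enriched
    ] <- min(1, background_prob * enrichment_factor)
  }
  hit <- matrix(runif(length(prob)) < prob, nrow(prob))
  idx <- which(hit, arr.ind = TRUE)
  annotations <- tibble(
    gene_id = genes[idx[, 1]],
    term_id = term_id[idx[, 2]]
  )
  list(
    ontology = gene_ontology(terms, annotations),
    enriched_terms = sort(enriched)
  )
}
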