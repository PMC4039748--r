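#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact hypergeometric test on the table
#' \preformatted{            has feature   lacks feature
#'   in group        a             b
#'   out group       c             d}
#' Probabilities are hypergeometric densities (log-gamma factorials via
#' `dhyper`). The two-sided p-value sums the probabilities of all tables
#' with the same margins whose probability does not exceed the observed
#' one times `1 + 1e-7` (a relative guard against floating-point ties);
#' `"greater"` is the upper tail of `a`, i.e. `1 - cdf(a - 1)`.
#'
#' @param a,b,c,d Nonnegative integer counts (vectorized).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return Numeric vector of p-values.
#' @examples
#' fisher_exact(5, 0, 0, 5) # 2 / choose(10, 5)
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- cbind(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Contingency counts must be nonnegative integers.")
  }
  purrr::pmap_dbl(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c), d = as.numeric(d)),
    fisher_exact_one,
    alternative = alternative
  )
}

fisher_exact_one <- function(a, b, c, d, alternative) {
  m <- a + c # feature total
  n_ <- b + d # non-feature total
  k <- a + b # group size
  if (m + n_ == 0) {
    abort("Empty contingency table.")
  }
  if (alternative == "greater") {
    return(phyper(a - 1, m, n_, k, lower.tail = FALSE))
  }
  support <- max(0, k - n_):min(k, m)
  dens <- dhyper(support, m, n_, k)
  obs <- dhyper(a, m, n_, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

odds_ratio <- function(a, b, c, d) {
  ifelse(b * c == 0, ifelse(a * d > 0, Inf, NaN), (a * d) / (b * c))
}

#' Group-wise TOP motif overrepresentation
#'
#' Tests, for each regulation group among the groups of interest, whether
#' TOP-motif-bearing genes occur preferentially in that group compared
#' with the remaining groups of interest, with Fisher's exact test on the
#' 2x2 table of TOP-bearing status by group membership. Genes without an
#' available UTR sequence are excluded from the universe (their number is
#' reported in a message).
#'
#' @param classified Output of [classify_regulation()].
#' @param top_status Tibble from [summarize_top()] (`gene_id`,
#'   `top_bearing`).
#' @param alternative Sidedness of [fisher_exact()]; two-sided by default
#'   (odds ratio different from one).
#' @param groups Integer vector of group ids forming the universe;
#'   defaults to the eight groups with at least one significant effect
#'   (`1:8`).
#' @param alpha Significance level; a group is called significant when
#'   `p < alpha` (strict). Default 0.05.
#' @return Tibble with one row per tested group: `group_id`, `group_name`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `significant`. Empty
#'   groups get `p_value = 1` with a warning.
#' @export
top_enrichment <- function(classified, top_status,
                           alternative = c("two.sided", "greater"),
                           groups = 1:8, alpha = 0.05) {
  alternative <- match.arg(alternative)
  univ <- filter(classified, .data$group_id %in% groups)
  univ <- left_join(
    select(univ, "gene_id", "group_id", "group_name"),
    select(top_status, "gene_id", "top_bearing"),
    by = "gene_id"
  )
  n_missing <- sum(is.na(univ$top_bearing))
  if (n_missing > 0) {
    inform(paste0(
      "Excluding ", n_missing, " gene(s) without UTR sequence from the TOP universe."
    ))
    univ <- filter(univ, !is.na(.data$top_bearing))
  }
  out <- purrr::map(sort(unique(groups)), function(g) {
    in_g <- univ$group_id == g
    a <- sum(in_g & univ$top_bearing)
    b <- sum(in_g & !univ$top_bearing)
    c_ <- sum(!in_g & univ$top_bearing)
    d <- sum(!in_g & !univ$top_bearing)
    if (a + b == 0) {
      warn(paste0("Regulation group ", g, " has no genes; p set to 1."))
      p <- 1
    } else {
      p <- fisher_exact(a, b, c_, d, alternative)
    }
    tibble(
      group_id = g, a = a, b = b, c = c_, d = d,
      odds_ratio = odds_ratio(a, b, c_, d), p_value = p
    )
  })
  out <- bind_rows(out)
  out <- left_join(out, select(regulation_groups(), "group_id", "group_name"),
    by = "group_id"
  )
  select(
    mutate(out, significant = .data$p_value < alpha),
    "group_id", "group_name", "a", "b", "c", "d",
    "odds_ratio", "p_value", "significant"
  )
}

#' Group-wise GO term overrepresentation
#'
#' Classic gene-count Fisher's exact test per GO term: for every term of
#' the requested namespace with at least one annotated gene in the
#' universe, tests whether the genes of a regulation group are
#' overrepresented among the term's (true-path propagated) genes relative
#' to the reference gene list. The reference list (universe) defaults to
#' the genes of the groups of interest that carry at least one annotation
#' in the namespace. p-values are one-sided (`greater`) by default and are
#' not adjusted for multiple testing; a term is significant when
#' `p <= alpha`.
#'
#' @param classified Output of [classify_regulation()].
#' @param ontology A [gene_ontology].
#' @param namespace `"BP"` or `"MF"`.
#' @param groups Group ids to test and from which the default universe is
#'   built (default `1:8`).
#' @param universe Optional explicit reference gene list; it is
#'   intersected with the annotated genes of the namespace.
#' @param alternative Sidedness of [fisher_exact()]; `"greater"` by
#'   default (overrepresentation).
#' @param alpha Significance level; `p <= alpha` is significant
#'   (default 0.05).
#' @return Tibble with one row per (group, term), sorted by `p_value`
#'   ascending (ties by term id) within group: `group_id`, `group_name`,
#'   `term_id`, `term_name`, `namespace`, `annotated` (universe genes of
#'   the term), `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `significant`.
#' @export
go_enrichment <- function(classified, ontology,
                          namespace = c("BP", "MF"),
                          groups = 1:8, universe = NULL,
                          alternative = c("greater", "two.sided"),
                          alpha = 0.05) {
  namespace <- match.arg(namespace)
  alternative <- match.arg(alternative)
  stopifnot(inherits(ontology, "gene_ontology"))
  terms <- filter(ontology$terms, .data$namespace == !!namespace)
  prop <- ontology$propagated[terms$term_id]
  annotated_genes <- unique(unlist(prop))
  grouped <- filter(classified, .data$group_id %in% groups)
  if (is.null(universe)) {
    universe <- unique(grouped$gene_id)
  }
  universe <- intersect(universe, annotated_genes)
  if (!length(universe)) {
    abort("Empty universe: no grouped gene carries an annotation in this namespace.")
  }
  gene_sets <- split(grouped$gene_id, grouped$group_id)
  out <- purrr::map(sort(unique(groups)), function(g) {
    grp <- intersect(gene_sets[[as.character(g)]] %||% character(), universe)
    rows <- purrr::map(seq_len(nrow(terms)), function(i) {
      term_genes <- intersect(prop[[i]], universe)
      if (!length(term_genes)) {
        return(NULL) # terms with no annotated universe gene are skipped
      }
      a <- length(intersect(grp, term_genes))
      b <- length(grp) - a
      c_ <- length(term_genes) - a
      d <- length(universe) - length(grp) - c_
      tibble(
        group_id = g, term_id = terms$term_id[i],
        term_name = terms$name[i], namespace = namespace,
        annotated = length(term_genes),
        a = a, b = b, c = c_, d = d
      )
    })
    bind_rows(rows)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    abort("No testable terms in this namespace.")
  }
  out <- mutate(out,
    odds_ratio = odds_ratio(.data$a, .data$b, .data$c, .data$d),
    p_value = fisher_exact(.data$a, .data$b, .data$c, .data$d, alternative),
    significant = .data$p_value <= alpha
  )
  out <- left_join(out, select(regulation_groups(), "group_id", "group_name"),
    by = "group_id"
  )
  out <- arrange(out, .data$group_id, .data$p_value, .data$term_id)
  select(
    out, "group_id", "group_name", "term_id", "term_name", "namespace",
    "annotated", "a", "b", "c", "d", "odds_ratio", "p_value", "significant"
  )
}

#' Bar chart of enrichment results
#'
#' @param object Tibble from [top_enrichment()] or [go_enrichment()].
#' @param n_terms For GO results, number of top terms per group to show.
#' @param ... Unused.
#' @return A ggplot of -log10 p-values.
#' @export
plot_enrichment <- function(object, n_terms = 10, ...) {
  if ("term_id" %in% names(object)) {
    shown <- dplyr::slice_min(group_by(object, .data$group_id),
      .data$p_value,
      n = n_terms, with_ties = FALSE
    )
    shown <- ungroup(shown)
    p <- ggplot2::ggplot(shown, ggplot2::aes(
      x = -log10(.data$p_value),
      y = stats::reorder(.data$term_name, -.data$p_value),
      fill = .data$significant
    )) +
      ggplot2::facet_wrap(~ .data$group_name, scales = "free_y") +
      ggplot2::labs(y = "GO term")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(
      x = -log10(.data$p_value),
      y = stats::reorder(.data$group_name, -.data$p_value),
      fill = .data$significant
    )) +
      ggplot2::labs(y = "regulation group")
  }
  p +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "-log10 p") +
    ggplot2::theme_minimal()
}
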