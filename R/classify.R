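#' Significance rule for calling regulation
#'
#' A gene's TC (or TL) is called up- or down-regulated when its fdr falls
#' below `fdr_max` (strict) and, where the fold-change rule applies, its
#' absolute log2 effect exceeds `lfc_min` (strict). `apply_lfc_to` controls
#' which effects the fold-change rule gates: `"both"` (default), only TC,
#' or neither (fdr-only calling). Both variants are first-class because
#' borderline cases (e.g. an effect of 0.41 with fdr 0.06) must be callable
#' under either reading of the thresholds.
#'
#' @param fdr_max Maximum fdr, in (0, 1]; default 0.05.
#' @param lfc_min Minimum absolute log2 effect; default 1.
#' @param apply_lfc_to One of `"both"`, `"TC_only"`, `"neither"`.
#' @return A list of class `significance_rule`.
#' @export
significance_rule <- function(fdr_max = 0.05, lfc_min = 1,
                              apply_lfc_to = c("both", "TC_only", "neither")) {
  stopifnot(fdr_max > 0, fdr_max <= 1, lfc_min >= 0)
  structure(
    list(
      fdr_max = fdr_max, lfc_min = lfc_min,
      apply_lfc_to = match.arg(apply_lfc_to)
    ),
    class = "significance_rule"
  )
}

# group numbering of the nine-way TC x TL cross
regulation_groups <- function() {
  tibble(
    group_id = 1:9,
    tc_status = c(
      "up", "up", "up", "unchanged", "unchanged",
      "down", "down", "down", "unchanged"
    ),
    tl_status = c(
      "up", "unchanged", "down", "up", "down",
      "up", "unchanged", "down", "unchanged"
    ),
    group_name = paste0(
      "TC:", c(
        "up", "up", "up", "unchanged", "unchanged",
        "down", "down", "down", "unchanged"
      ),
      "/TL:", c(
        "up", "unchanged", "down", "up", "down",
        "up", "unchanged", "down", "unchanged"
      )
    )
  )
}

call_status <- function(effect, fdr, rule, lfc_applies) {
  fdr_ok <- !is.na(fdr) & fdr < rule$fdr_max
  lfc_ok <- if (lfc_applies) abs(effect) > rule$lfc_min else TRUE
  dplyr::case_when(
    fdr_ok & lfc_ok & effect > 0 ~ "up",
    fdr_ok & lfc_ok & effect < 0 ~ "down",
    .default = "unchanged"
  )
}

#' Classify genes into the nine TC x TL regulation groups
#'
#' Crosses the per-effect regulation calls into the nine-group taxonomy
#' (group 1 = TC:up/TL:up ... group 9 = TC:unchanged/TL:unchanged) and
#' appends the net-effect score `TC + TL`, a summary of the combined
#' transcriptional and translational change.
#'
#' @param records Tibble with columns `gene_id`, `tc`, `tl`, `fdr_tc`,
#'   `fdr_tl` — typically `tidy()` of an [analyze_efficiency()] fit.
#' @param rule A [significance_rule()].
#' @return The input tibble with columns `tc_status`, `tl_status`
#'   (`"up"`, `"unchanged"`, `"down"`), `group_id`, `group_name` and
#'   `net_effect` appended. The nine groups partition the gene list.
#' @examples
#' records <- tibble::tibble(
#'   gene_id = c("a", "b"), tc = c(1.5, 0.2), tl = c(-2, 0.1),
#'   fdr_tc = c(0.01, 0.8), fdr_tl = c(0.001, 0.9)
#' )
#' classify_regulation(records)
#' @export
classify_regulation <- function(records, rule = significance_rule()) {
  stopifnot(inherits(rule, "significance_rule"))
  need <- c("gene_id", "tc", "tl", "fdr_tc", "fdr_tl")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("`records` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  lfc_tc <- rule$apply_lfc_to %in% c("both", "TC_only")
  lfc_tl <- rule$apply_lfc_to == "both"
  out <- mutate(records,
    tc_status = call_status(.data$tc, .data$fdr_tc, rule, lfc_tc),
    tl_status = call_status(.data$tl, .data$fdr_tl, rule, lfc_tl),
    net_effect = net_effect(.data$tc, .data$tl)
  )
  left_join(out, regulation_groups(), by = c("tc_status", "tl_status"))
}

#' Net regulation effect
#'
#' The sum `TC + TL`, an estimate of the combined influence of changed
#' transcription and changed translation on a gene's protein output.
#'
#' @param tc,tl Numeric vectors of log2 efficiencies.
#' @return `tc + tl`.
#' @export
net_effect <- function(tc, tl) {
  tc + tl
}

#' Group sizes of a regulation classification
#'
#' @param classified Output of [classify_regulation()].
#' @return Tibble with one row per group 1-9 (`group_id`, `group_name`,
#'   `n`), including empty groups; sizes sum to the number of genes.
#' @export
regulation_summary <- function(classified) {
  counts <- count(classified, .data$group_id)
  out <- left_join(regulation_groups(), counts, by = "group_id")
  mutate(
    select(out, "group_id", "group_name", "n"),
    n = tidyr::replace_na(.data$n, 0L)
  )
}

#' Marginal counts of a regulation classification
#'
#' Collapses the nine groups into the six headline marginals: genes
#' up-/down-regulated at the transcriptional level, up-/down-regulated at
#' the translational level, and the purely transcriptional (TC significant,
#' TL unchanged) and purely translational (TL significant, TC unchanged)
#' sets. Each marginal is a sum of group sizes.
#'
#' @param classified Output of [classify_regulation()].
#' @return Tibble with columns `marginal` and `n`.
#' @export
regulation_marginals <- function(classified) {
  tc <- classified$tc_status
  tl <- classified$tl_status
  tibble(
    marginal = c(
      "tc_up", "tc_down", "tl_up", "tl_down",
      "only_transcriptional", "only_translational"
    ),
    n = c(
      sum(tc == "up"), sum(tc == "down"),
      sum(tl == "up"), sum(tl == "down"),
      sum(tc != "unchanged" & tl == "unchanged"),
      sum(tl != "unchanged" & tc == "unchanged")
    )
  )
}

#' TC-TL scatter of a classified gene table
#'
#' @param object Output of [classify_regulation()].
#' @param ... Unused.
#' @return A ggplot: TL against TC, coloured by regulation group.
#' @export
plot_regulation <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$tc, y = .data$tl, colour = .data$group_name)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(
      x = "transcription efficiency (log2)",
      y = "translation efficiency (log2)",
      colour = "group"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot eff_fit
#' @export
autoplot.eff_fit <- function(object, rule = significance_rule(), ...) {
  plot_regulation(classify_regulation(tidy(object), rule))
}
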