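#' Per-gene condition means and pooled residual variance
#'
#' Summarises an expression dataset by the four design-cell means per gene
#' (polysomal/non-polysomal x 0 h/6 h) and the pooled within-cell residual
#' variance of the saturated four-cell model.
#'
#' @param es An [expr_set] with all four design cells populated (each with
#'   at least two replicates).
#' @return Tibble with columns `gene_id`, `spikein`, `p0`, `p6`, `np0`,
#'   `np6` (log2 condition means), `s_sq` (pooled residual variance, log2
#'   squared) and `df` (residual degrees of freedom, `n_samples - 4`).
#' @details `s_sq` is the within-cell sum of squares divided by
#'   `n_samples - 4`; it is the gene-wise variance fed to the
#'   empirical-Bayes prior in [analyze_efficiency()].
#' @export
condition_means <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  cells <- count(es$samples, .data$fraction, .data$time_h)
  if (nrow(cells) < 4L) {
    abort("All four fraction x time design cells are required.")
  }
  m <- expr_matrix(es)
  cell_of <- paste0(
    ifelse(es$samples$fraction == "polysomal", "p", "np"),
    es$samples$time_h
  )
  cell_means <- matrix(
    NA_real_, nrow(m), 4,
    dimnames = list(NULL, c("p0", "p6", "np0", "np6"))
  )
  for (cl in colnames(cell_means)) {
    cell_means[, cl] <- rowMeans(m[, cell_of == cl, drop = FALSE])
  }
  sse <- rowSums((m - cell_means[, cell_of, drop = FALSE])^2)
  df <- ncol(m) - 4L
  tibble(
    gene_id = es$expression$gene_id,
    spikein = es$expression$spikein,
    p0 = cell_means[, "p0"], p6 = cell_means[, "p6"],
    np0 = cell_means[, "np0"], np6 = cell_means[, "np6"],
    s_sq = unname(sse) / df,
    df = df
  )
}

#' Transcription and translation efficiencies
#'
#' Adds the two per-gene effect estimates to a condition-means table:
#' translation efficiency `TL = (p6 - p0) - (np6 - np0)`, the difference of
#' the time-related log2 fold changes of the polysomal and non-polysomal
#' fractions, and transcription efficiency
#' `TC = (p6 + np6)/2 - (p0 + np0)/2`, the change of the total (mean of the
#' two fractions) log2 abundance. Positive values mean up-regulation.
#'
#' The two definitions imply the reconstruction identities
#' `p6 - p0 = TC + TL/2` and `np6 - np0 = TC - TL/2`.
#'
#' @param means Tibble from [condition_means()] (any tibble with `p0`,
#'   `p6`, `np0`, `np6` columns works).
#' @return The input with `tc` and `tl` columns appended.
#' @export
efficiencies <- function(means) {
  mutate(means,
    tc = (.data$p6 + .data$np6) / 2 - (.data$p0 + .data$np0) / 2,
    tl = (.data$p6 - .data$p0) - (.data$np6 - .data$np0)
  )
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior
#' (hyperparameters `d0`, `s0_sq`) to gene-wise residual variances, via the
#' log-variance transform `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`:
#' `d0` solves `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` by
#' monotone Newton/bisection on the strictly decreasing trigamma, and
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the dispersion
#' of `e_g` does not exceed its sampling expectation, the prior is
#' degenerate: `d0 = Inf`, `s0_sq = exp(mean(e))`.
#'
#' Zero variances carry no information under the log transform and are
#' excluded from the moments; an all-zero input is an error.
#'
#' @param s_sq Numeric vector of gene-wise variances (log2 squared).
#' @param df Residual degrees of freedom, scalar or per-gene vector.
#' @return List with elements `d0` and `s0_sq`.
#' @export
estimate_prior <- function(s_sq, df) {
  stopifnot(length(s_sq) >= 1, all(df >= 1))
  df <- rep_len(df, length(s_sq))
  pos <- s_sq > 0
  if (!any(pos)) {
    abort("All gene-wise variances are zero; the variance prior is undefined.")
  }
  e <- log(s_sq[pos]) - digamma(df[pos] / 2) + log(df[pos] / 2)
  e_mean <- mean(e)
  e_var <- var(e) - mean(trigamma(df[pos] / 2))
  if (!is.finite(e_var) || e_var <= 0) {
    return(list(d0 = Inf, s0_sq = exp(e_mean)))
  }
  d0 <- 2 * trigamma_inverse(e_var)
  list(d0 = d0, s0_sq = exp(e_mean + digamma(d0 / 2) - log(d0 / 2)))
}

# Solve trigamma(y) = x for y > 0. trigamma is strictly decreasing, so
# Newton iteration on the transformed variable is globally convergent;
# bisection-style clamping guards the positivity constraint.
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) {
    return(1 / sqrt(x))
  }
  if (x < 1e-6) {
    return(1 / x)
  }
  y <- 0.5 + 1 / x
  for (i in 1:100) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (y <= 0) y <- .Machine$double.eps
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated t-statistic for one contrast
#'
#' Shrinks the gene-wise residual variance toward the prior,
#' `s2_post = (d0 * s0_sq + df * s_sq) / (d0 + df)`, and forms
#' `t = effect / sqrt(s2_post * contrast_scale)` with `d0 + df` degrees of
#' freedom (standard normal when `d0` is infinite). `contrast_scale` is the
#' variance multiplier of the contrast, `sum(c_i^2) / r` for cell-mean
#' coefficients `c_i` and `r` replicates per cell: `4/r` for TL
#' (coefficients +-1) and `1/r` for TC (coefficients +-1/2).
#'
#' @param effect Numeric vector of contrast estimates (log2).
#' @param s_sq Gene-wise residual variances.
#' @param df Residual degrees of freedom (scalar or vector).
#' @param prior List with `d0`, `s0_sq`, as from [estimate_prior()].
#' @param contrast_scale Unitless variance multiplier of the contrast.
#' @return Tibble with columns `t`, `p` (two-sided), `df_total`.
#' @export
moderated_t <- function(effect, s_sq, df, prior, contrast_scale) {
  stopifnot(contrast_scale > 0, prior$d0 >= 0, prior$s0_sq > 0)
  df <- rep_len(df, length(effect))
  if (is.infinite(prior$d0)) {
    s2_post <- rep_len(prior$s0_sq, length(effect))
    df_total <- rep_len(Inf, length(effect))
  } else {
    s2_post <- (prior$d0 * prior$s0_sq + df * s_sq) / (prior$d0 + df)
    df_total <- prior$d0 + df
  }
  degenerate <- s2_post == 0
  if (any(degenerate)) {
    warn("Zero posterior variance for some genes; their p-values are set to 0.")
  }
  t_stat <- effect / sqrt(s2_post * contrast_scale)
  p <- ifelse(is.infinite(df_total),
    2 * pnorm(-abs(t_stat)),
    2 * pt(-abs(t_stat), df_total)
  )
  p[degenerate] <- ifelse(effect[degenerate] == 0, 1, 0)
  t_stat[degenerate & effect == 0] <- 0
  tibble(t = t_stat, p = p, df_total = df_total)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment: for ordered p-values, `fdr_(i) = min_{j >= i}
#' p_(j) * n / j`, capped at 1 and returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values (fdr), same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Fit transcription and translation efficiencies with moderated tests
#'
#' The main per-gene analysis: condition means and pooled variances
#' ([condition_means()]), TC/TL effects ([efficiencies()]), an
#' empirical-Bayes variance prior estimated across genes
#' ([estimate_prior()]), moderated t-tests of TC and TL against zero
#' ([moderated_t()]), and Benjamini-Hochberg fdr per effect
#' ([bh_adjust()]). Spike-in probes are excluded from prior estimation and
#' from the fdr computation but are reported with their statistics.
#'
#' @param es An [expr_set] covering all four design cells.
#' @param prior Optional list `(d0, s0_sq)` to use instead of estimating
#'   the prior from the data.
#' @return An object of class `eff_fit`. Use [tidy()] for the per-gene
#'   table (`gene_id`, `tc`, `tl`, `t_tc`, `t_tl`, `p_tc`, `p_tl`,
#'   `fdr_tc`, `fdr_tl`), [glance()] for the fit summary, and
#'   [autoplot()] for a TC-TL scatter.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 200, seed = 1))
#' fit <- analyze_efficiency(normalize_spikein(sim$data)$data)
#' tidy(fit)
#' glance(fit)
#' @export
analyze_efficiency <- function(es, prior = NULL) {
  means <- efficiencies(condition_means(es))
  use <- !means$spikein
  if (is.null(prior)) {
    prior <- estimate_prior(means$s_sq[use], means$df[use])
  }
  # variance multiplier sum c_i^2 / r_i over the four cell means
  reps <- count(es$samples, .data$fraction, .data$time_h)$n
  scale_tl <- sum(1 / reps)        # coefficients +-1
  scale_tc <- sum(0.25 / reps)     # coefficients +-1/2
  test_tc <- moderated_t(means$tc, means$s_sq, means$df, prior, scale_tc)
  test_tl <- moderated_t(means$tl, means$s_sq, means$df, prior, scale_tl)
  table <- tibble(
    gene_id = means$gene_id,
    spikein = means$spikein,
    tc = means$tc, tl = means$tl,
    t_tc = test_tc$t, t_tl = test_tl$t,
    p_tc = test_tc$p, p_tl = test_tl$p,
    fdr_tc = NA_real_, fdr_tl = NA_real_
  )
  table$fdr_tc[use] <- bh_adjust(table$p_tc[use])
  table$fdr_tl[use] <- bh_adjust(table$p_tl[use])
  structure(
    list(
      table = table, means = means, prior = prior,
      contrast_scales = c(tc = scale_tc, tl = scale_tl),
      n_samples = nrow(es$samples)
    ),
    class = "eff_fit"
  )
}

#' @export
print.eff_fit <- function(x, ...) {
  cat("<eff_fit> ", nrow(x$table), " genes, ", x$n_samples, " samples\n",
    "  prior: d0 = ", format(x$prior$d0, digits = 4),
    ", s0_sq = ", format(x$prior$s0_sq, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname analyze_efficiency
#' @param x An `eff_fit` object.
#' @param ... Unused.
#' @method tidy eff_fit
#' @export
tidy.eff_fit <- function(x, ...) {
  x$table
}

#' @rdname analyze_efficiency
#' @method glance eff_fit
#' @export
glance.eff_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_spikeins = sum(x$table$spikein),
    n_samples = x$n_samples,
    df_residual = x$means$df[1],
    d0 = x$prior$d0,
    s0_sq = x$prior$s0_sq
  )
}
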