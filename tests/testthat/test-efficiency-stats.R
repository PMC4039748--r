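test_that("condition means and pooled variance follow the four-cell model", {
  es <- expr_set_from_cells(list(
    p0 = rbind(c(1, 1)), p6 = rbind(c(2, 2)),
    np0 = rbind(c(0, 0)), np6 = rbind(c(0, 0))
  ))
  cm <- condition_means(es)
  expect_equal(unlist(cm[1, c("p0", "p6", "np0", "np6")], use.names = FALSE), c(1, 2, 0, 0))
  expect_equal(cm$s_sq, 0)
  expect_equal(cm$df, 4L)

  # shift equivariance
  set.seed(1)
  cells <- list(
    p0 = matrix(rnorm(150), 50), p6 = matrix(rnorm(150), 50),
    np0 = matrix(rnorm(150), 50), np6 = matrix(rnorm(150), 50)
  )
  cm1 <- condition_means(expr_set_from_cells(cells))
  cm2 <- condition_means(expr_set_from_cells(lapply(cells, `+`, 2.5)))
  expect_equal(cm2$p0, cm1$p0 + 2.5)
  expect_equal(cm2$np6, cm1$np6 + 2.5)
  expect_equal(cm2$s_sq, cm1$s_sq, tolerance = 1e-12)

  # pooled variance equals a direct sum-of-squares computation
  sse <- sapply(seq_len(50), function(g) {
    sum(sapply(cells, function(x) sum((x[g, ] - mean(x[g, ]))^2)))
  })
  expect_equal(cm1$s_sq, sse / (12 - 4), tolerance = 1e-12)
})

test_that("TC and TL formulas and their reconstruction identity hold", {
  one <- function(p0, p6, np0, np6) {
    efficiencies(tibble::tibble(p0 = p0, p6 = p6, np0 = np0, np6 = np6))
  }
  expect_equal(one(1, 2, 0, 1)[, c("tc", "tl")], tibble::tibble(tc = 1, tl = 0))
  expect_equal(one(0, 2, 0, 1)[, c("tc", "tl")], tibble::tibble(tc = 1.5, tl = 1))

  set.seed(42)
  rand <- one(rnorm(200), rnorm(200), rnorm(200), rnorm(200))
  expect_equal(rand$p6 - rand$p0, rand$tc + rand$tl / 2, tolerance = 1e-12)
  expect_equal(rand$np6 - rand$np0, rand$tc - rand$tl / 2, tolerance = 1e-12)
})

test_that("prior estimation handles degenerate and heavy-tailed inputs", {
  # identical variances: no excess dispersion, infinite prior df
  same <- estimate_prior(rep(0.04, 100), df = 16)
  expect_identical(same$d0, Inf)
  expect_lt(abs(same$s0_sq - 0.04) / 0.04, 0.10)

  # heavy tail (d0 = 1) still recovered by the moment estimator
  set.seed(3)
  sigma_sq <- 0.05 * 1 / rchisq(10000, df = 1)
  s_sq <- sigma_sq * rchisq(10000, df = 8) / 8
  heavy <- estimate_prior(s_sq, df = 8)
  expect_lt(abs(heavy$d0 - 1), 0.30)

  expect_error(estimate_prior(rep(0, 5), df = 4), "variances are zero")
})

test_that("prior estimation agrees with an established variance-shrinkage fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  sigma_sq <- 0.05 * 4 / rchisq(5000, df = 4)
  s_sq <- sigma_sq * rchisq(5000, df = 8) / 8
  ours <- estimate_prior(s_sq, df = 8)
  ref <- limma::squeezeVar(s_sq, df = 8)
  expect_equal(ours$d0, ref$df.prior, tolerance = 0.02)
  expect_equal(ours$s0_sq, ref$var.prior, tolerance = 0.02)
  # posterior variances then agree too
  post <- (ours$d0 * ours$s0_sq + 8 * s_sq) / (ours$d0 + 8)
  expect_equal(post, ref$var.post, tolerance = 0.02)
})

test_that("the moderated t follows its formula chain and limits", {
  null <- moderated_t(0, 0.04, 8, list(d0 = 4, s0_sq = 0.05), 4 / 3)
  expect_equal(null$t, 0)
  expect_equal(null$p, 1)

  # hand-computed fixture: shrink, scale, then Student tail
  fix <- moderated_t(1.2, 0.04, 8, list(d0 = 4, s0_sq = 0.05), 4 / 3)
  s2_post <- (4 * 0.05 + 8 * 0.04) / 12
  t_hand <- 1.2 / sqrt(s2_post * 4 / 3)
  expect_equal(fix$t, t_hand, tolerance = 1e-12)
  expect_equal(fix$p, 2 * pt(-abs(t_hand), 12), tolerance = 1e-12)
  expect_equal(fix$df_total, 12)

  # no-moderation limit: ordinary t with the residual df
  ord <- moderated_t(0.8, 0.09, 6, list(d0 = 0, s0_sq = 1), 0.5)
  expect_equal(ord$t, 0.8 / sqrt(0.09 * 0.5), tolerance = 1e-12)
  expect_equal(ord$p, 2 * pt(-abs(ord$t), 6), tolerance = 1e-12)

  # infinite-prior limit: z statistic with variance s0_sq
  z <- moderated_t(0.8, 0.09, 6, list(d0 = Inf, s0_sq = 0.04), 0.5)
  expect_equal(z$t, 0.8 / sqrt(0.04 * 0.5), tolerance = 1e-12)
  expect_equal(z$p, 2 * pnorm(-abs(z$t)), tolerance = 1e-12)

  # degenerate: prior and sample variance both (numerically) zero
  expect_warning(
    deg <- moderated_t(c(0.5, 0), c(0, 0), 4, list(d0 = 0, s0_sq = 1), 1),
    "Zero posterior variance"
  )
  expect_equal(deg$p, c(0, 1))
  expect_equal(deg$t[2], 0)
})

test_that("BH adjustment matches the step-up definition and keeps p-order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "must lie in")

  set.seed(9)
  p <- runif(300)
  fdr <- bh_adjust(p)
  expect_true(all(fdr >= p))
  expect_true(all(diff(fdr[order(p)]) >= 0)) # monotone in p
  expect_equal(fdr, bh_oracle(p), tolerance = 1e-12)
})

test_that("the full fit ties the pieces together on simulated data", {
  sim <- simulate_expression(sim_config(n_genes = 400, seed = 12))
  fit <- analyze_efficiency(normalize_spikein(sim$data)$data)
  tab <- tidy(fit)
  expect_true(all(tab$p_tc >= 0 & tab$p_tc <= 1))
  keep <- !tab$spikein
  expect_true(all(tab$fdr_tc[keep] >= tab$p_tc[keep] - 1e-12))
  expect_true(all(tab$fdr_tl[keep] >= tab$p_tl[keep] - 1e-12))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 450)
  expect_equal(gl$df_residual, 12L - 4L)
  # a supplied prior short-circuits estimation
  fixed <- analyze_efficiency(sim$data, prior = list(d0 = Inf, s0_sq = 0.05))
  expect_identical(glance(fixed)$d0, Inf)
})
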