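make_allometry <- function(seed, n_extant = 30, n_fossil = 8, ...) {
  cfg <- sim_config(n_extant = n_extant, n_fossil = n_fossil, seed = seed, ...)
  tr <- simulate_tree(cfg)
  list(cfg = cfg, tree = tr, tab = simulate_allometry(tr, cfg))
}

test_that("identity correlation reduces PGLS to ordinary least squares", {
  s <- make_allometry(61)
  fI <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree, alpha = Inf)
  fl <- lm(log_qdot ~ log_bm + group, s$tab)
  expect_equal(coef(fI), coef(fl), tolerance = 1e-8)
  expect_equal(unname(fitted(fI)), unname(fitted(fl)), tolerance = 1e-8)
})

test_that("two points with one predictor are interpolated exactly", {
  tr <- tree_cherry()
  d <- data.frame(taxon = c("A", "B"), y = c(1, 3), x = c(0, 1))
  f <- pgls(y ~ x, d, tr, alpha = 1)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-10)
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-10)
})

test_that("PGLS coefficients match the explicit normal-equations oracle", {
  for (seed in c(5, 23)) {
    s <- make_allometry(seed, n_extant = 9, n_fossil = 3)
    a <- 0.07
    X <- model.matrix(~ log_bm + group, s$tab)
    V <- ou_correlation_matrix(s$tree, a)
    f <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree, alpha = a)
    expect_equal(unname(coef(f)),
                 unname(drop(brute_gls(X, s$tab$log_qdot, V))),
                 tolerance = 1e-8)
  }
})

test_that("PGLS agrees with nlme::gls under the corMartins structure", {
  skip_if_not_installed("nlme")
  s <- make_allometry(37)
  a <- 0.05
  dat <- s$tab
  dat$taxon <- factor(dat$taxon, levels = s$tree$tip.label)
  gfit <- nlme::gls(log_qdot ~ log_bm + group, data = dat,
                    correlation = ape::corMartins(a, s$tree, fixed = TRUE,
                                                  form = ~taxon),
                    method = "ML")
  f <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree, alpha = a)
  expect_equal(coef(f), coef(gfit), tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(logLik(gfit)), tolerance = 1e-6)
})

test_that("rank-deficient designs and unknown taxa raise informative errors", {
  s <- make_allometry(11)
  s$tab$dup <- s$tab$log_bm
  expect_error(pgls(log_qdot ~ log_bm + dup, s$tab, s$tree, alpha = 1),
               "aliased")
  bad <- s$tab
  bad$taxon[1] <- "not_in_tree"
  expect_error(pgls(log_qdot ~ log_bm, bad, s$tree, alpha = 1),
               "not_in_tree")
})

test_that("model comparison reports deltas and Wald interaction test", {
  s <- make_allometry(71, n_extant = 69, n_fossil = 19)
  f0 <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree)
  f1 <- pgls(log_qdot ~ log_bm * group, s$tab, s$tree)
  cmp <- compare_pgls(f0, f1)
  expect_length(cmp$extra_terms, 3L)
  expect_equal(cmp$delta_AIC, f1$AIC - f0$AIC)
  expect_equal(cmp$delta_BIC, f1$BIC - f0$BIC)
  expect_true(cmp$p_interaction >= 0 && cmp$p_interaction <= 1)
  # self-comparison: zero deltas, no test
  self <- compare_pgls(f0, f0)
  expect_equal(self$delta_AIC, 0)
  expect_equal(self$delta_BIC, 0)
  expect_true(is.na(self$p_interaction))
})

test_that("interaction test has near-nominal size and detects slope differences", {
  nrep <- 30
  set.seed(500)
  seeds <- sample.int(1e6, 2 * nrep)
  null_ns <- power_hit <- logical(nrep)
  for (i in seq_len(nrep)) {
    s <- make_allometry(seeds[i], n_extant = 69, n_fossil = 19)
    f0 <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree)
    f1 <- pgls(log_qdot ~ log_bm * group, s$tab, s$tree)
    null_ns[i] <- compare_pgls(f0, f1)$p_interaction > 0.05
    # truly different slope for one clade-group
    s2 <- make_allometry(seeds[nrep + i], n_extant = 69, n_fossil = 19)
    s2$tab$log_qdot <- s2$tab$log_qdot +
      ifelse(s2$tab$group == "Xenarthra_fossil", 0.3, 0) * s2$tab$log_bm
    g0 <- pgls(log_qdot ~ log_bm + group, s2$tab, s2$tree)
    g1 <- pgls(log_qdot ~ log_bm * group, s2$tab, s2$tree)
    power_hit[i] <- compare_pgls(g0, g1)$p_interaction < 0.05
  }
  expect_gte(mean(null_ns), 0.90)   # size: non-significant under the null
  expect_gte(mean(power_hit), 0.80) # power at slope difference 0.3
})

test_that("pairwise ANCOVA applies the Bonferroni rule over all six pairs", {
  s <- make_allometry(81, n_extant = 40, n_fossil = 10)
  f <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree)
  an <- pairwise_ancova(f)
  expect_equal(nrow(an), 6L)
  expect_equal(an$p_bonferroni, pmin(1, 6 * an$p_raw))
  expect_true(all(an$flow_ratio > 0))
  expect_equal(an$flow_ratio, 10^an$delta_intercept)
  # intercept differences consistent with the per-group intercepts
  gi <- group_intercepts(f)
  d12 <- gi$intercept[gi$group == an$group_a[1]] -
    gi$intercept[gi$group == an$group_b[1]]
  expect_equal(an$delta_intercept[1], d12, tolerance = 1e-10)
})

test_that("contrast z statistics are invariant to recentring the covariate", {
  s <- make_allometry(91)
  f1 <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree, alpha = 0.03)
  s$tab$log_bm_c <- s$tab$log_bm - mean(s$tab$log_bm)
  f2 <- pgls(log_qdot ~ log_bm_c + group, s$tab, s$tree, alpha = 0.03)
  expect_equal(pairwise_ancova(f1)$z, pairwise_ancova(f2)$z,
               tolerance = 1e-8)
})

test_that("flow ratios reproduce the published elevation arithmetic", {
  expect_equal(flow_ratio(-5.31, -5.77), 10^0.46, tolerance = 1e-12)
  expect_equal(round(flow_ratio(-5.31, -5.77), 2), 2.88)
  expect_equal(round(flow_ratio(-5.35, -5.77), 2), 2.63)
  expect_equal(flow_ratio(-2.2, -2.2), 1)
  expect_equal(flow_ratio(-5.31, -5.77) * flow_ratio(-5.77, -5.31), 1,
               tolerance = 1e-12)
})

test_that("OLS reference recovers exact lines and matches identity-PGLS", {
  d <- data.frame(taxon = paste0("t", 1:5),
                  log_bm = 1:5, log_qdot = 0.78 * (1:5) - 5.63)
  ols <- ols_reference(d)
  expect_equal(ols$slope, 0.78, tolerance = 1e-10)
  expect_equal(ols$intercept, -5.63, tolerance = 1e-10)
  s <- make_allometry(101)
  ols2 <- ols_reference(s$tab)
  fI <- pgls(log_qdot ~ log_bm, s$tab, s$tree, alpha = Inf)
  expect_equal(unname(coef(fI)["log_bm"]), ols2$slope, tolerance = 1e-8)
})

test_that("whitening is the identity under an identity correlation", {
  s <- make_allometry(111)
  f <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree, alpha = Inf)
  w <- residuals(f, type = "normalized")
  expect_equal(w * sqrt(f$sigma2), residuals(f), tolerance = 1e-10)
})

test_that("whitened residuals of a correct model pass Lilliefors at nominal rate", {
  s <- make_allometry(121, n_extant = 69, n_fossil = 19)
  a <- 0.02; sig <- 0.25
  V <- sig^2 * ou_correlation_matrix(s$tree, a)
  X <- model.matrix(~ log_bm + group, s$tab)
  beta <- c(-5.3, 0.74, 0.1, -0.3, 0.05)
  set.seed(314)
  nrep <- 100
  pass <- heavy_reject <- logical(nrep)
  for (i in seq_len(nrep)) {
    s$tab$y <- drop(X %*% beta) + rmvn_test(rep(0, nrow(X)), V)
    f <- pgls(y ~ log_bm + group, s$tab, s$tree, alpha = a)
    pass[i] <- whitened_residual_normality(f, nsim = 400)$p_value > 0.05
    # heavy-tailed residuals: t with 2 df, no phylogenetic structure
    s$tab$yh <- drop(X %*% beta) + 0.25 * rt(nrow(X), df = 2)
    fh <- pgls(yh ~ log_bm + group, s$tab, s$tree, alpha = a)
    heavy_reject[i] <- whitened_residual_normality(fh, nsim = 400)$p_value <= 0.05
  }
  expect_gte(mean(pass), 0.88)       # ~95% nominal acceptance
  expect_lte(mean(pass), 0.995)
  expect_gt(mean(heavy_reject), 0.5) # power against t2 tails
})

test_that("simulate/predict methods are consistent with the fit", {
  s <- make_allometry(131)
  f <- pgls(log_qdot ~ log_bm + group, s$tab, s$tree, alpha = 0.05)
  expect_equal(predict(f), fitted(f))
  nd <- data.frame(log_bm = c(2, 6), group = factor("Epitheria",
                   levels = levels(factor(s$tab$group))))
  pr <- predict(f, nd, se.fit = TRUE)
  b <- coef(f)
  expect_equal(unname(pr$fit[1] - pr$fit[2]), unname(-4 * b["log_bm"]),
               tolerance = 1e-10)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(f$n, 3L))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))
})
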