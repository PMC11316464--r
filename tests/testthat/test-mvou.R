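# small fossil-bearing tree + correlated three-trait data used throughout
mvou_fixture <- function(seed = 5, n_extant = 25, n_fossil = 6) {
  cfg <- sim_config(n_extant = n_extant, n_fossil = n_fossil, seed = seed)
  tr <- simulate_tree(cfg)
  X <- simulate_mvou_traits(tr, cfg$A, cfg$Sigma, cfg$theta, seed = seed + 1)
  list(cfg = cfg, tree = tr, X = X)
}

test_that("mvOU likelihood reduces to the univariate OU density", {
  fx <- mvou_fixture()
  x1 <- fx$X[, 1, drop = FALSE]
  a <- 1; s2 <- 0.5; z0 <- 2
  ll <- mvou_loglik(fx$tree, x1, matrix(a, 1, 1), matrix(s2, 1, 1), z0)
  D <- patristic_matrix(fx$tree); C <- shared_path_matrix(fx$tree)
  V <- s2 * exp(-a * D) * (-expm1(-2 * a * C)) / (2 * a)
  expect_equal(ll, dmvnorm_eigen(x1[, 1], rep(z0, nrow(x1)), V),
               tolerance = 1e-6)
})

test_that("diagonal A and Sigma factorise into per-trait OU likelihoods", {
  fx <- mvou_fixture()
  Ad <- diag(c(0.5, 1, 2)); Sd <- diag(c(0.3, 0.7, 1.1))
  th <- c(1, 2, 3)
  llj <- mvou_loglik(fx$tree, fx$X, Ad, Sd, th)
  lls <- sum(vapply(1:3, function(k)
    mvou_loglik(fx$tree, fx$X[, k, drop = FALSE],
                Ad[k, k, drop = FALSE], Sd[k, k, drop = FALSE], th[k]), 0))
  expect_equal(llj, lls, tolerance = 1e-6)
})

test_that("marginalising a tip's entries equals pruning the tip", {
  fx <- mvou_fixture()
  drop_tip <- rownames(fx$X)[4]
  Xna <- fx$X; Xna[drop_tip, ] <- NA
  A <- diag(c(0.2, 0.4, 0.8)); S <- fx$cfg$Sigma; th <- c(4, -2, 4)
  ll_na <- mvou_loglik(fx$tree, Xna, A, S, th)
  pruned <- ape::keep.tip(fx$tree, setdiff(fx$tree$tip.label, drop_tip))
  ll_pr <- mvou_loglik(pruned, fx$X[pruned$tip.label, ], A, S, th)
  expect_equal(ll_na, ll_pr, tolerance = 1e-8)
})

test_that("non-SPD pull or diffusion matrices are rejected", {
  fx <- mvou_fixture()
  bad <- diag(c(1, -1, 1))
  expect_error(mvou_loglik(fx$tree, fx$X, bad, diag(3), c(0, 0, 0)),
               "positive definite")
  asym <- matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  expect_error(mvou_loglik(fx$tree, fx$X, asym, diag(3), c(0, 0, 0)),
               "symmetric")
})

test_that("fitting one trait agrees with the univariate OU fit", {
  fx <- mvou_fixture(seed = 9)
  x <- fx$X[, 2, drop = FALSE]
  fm <- mvou(fx$tree, x, A_structure = "scalar")
  fu <- fit_ou(fx$tree, setNames(x[, 1], rownames(x)))
  expect_equal(fm$lnL, fu$lnL, tolerance = 1e-3)
  expect_equal(drop(fm$A), fu$parameters[["alpha"]], tolerance = 0.05)
  expect_equal(drop(fm$Sigma), fu$parameters[["sigma2"]], tolerance = 0.05)
  expect_equal(unname(fm$theta), fu$parameters[["z0"]], tolerance = 0.02)
})

test_that("imputation matches the brute-force conditional MVN on a toy tree", {
  fx <- mvou_fixture(seed = 13, n_extant = 6, n_fossil = 2)
  Xna <- fx$X
  Xna[c(2, 7), 1] <- NA
  Xna[4, 3] <- NA
  fit <- mvou(fx$tree, Xna, A_structure = "diagonal", maxit = 600)
  est <- estimate_missing(fit)
  # oracle: explicit-inverse conditioning on the same joint Gaussian
  st <- foramenflow:::node_shared_times(fit$tree, "tips")
  V <- foramenflow:::mvou_covariance(st$C, fit$A, fit$Sigma)
  y <- as.vector(Xna)
  mu <- rep(fit$theta, each = 8)
  oracle <- brute_conditional(mu, V, which(is.finite(y)),
                              y[is.finite(y)], which(!is.finite(y)))
  expect_equal(est$mean, unname(oracle$mean), tolerance = 1e-8)
  expect_equal(est$sd, unname(oracle$sd), tolerance = 1e-6)
  expect_equal(est$ci_low, est$mean - 1.96 * est$sd)
  # observed entries are returned as themselves with zero sd
  all_est <- estimate_missing(fit, include_observed = TRUE)
  obs <- all_est[all_est$observed, ]
  expect_equal(obs$sd, rep(0, nrow(obs)))
  i <- match(paste(rownames(Xna)[1], "log_mmr"),
             paste(obs$node, obs$trait))
  expect_equal(obs$mean[i], Xna[1, 1])
})

test_that("ancestral reconstruction matches the BM symmetric average and shrinks with pull", {
  tr <- tree_cherry()
  X <- matrix(c(0, 2), 2, 1, dimnames = list(c("A", "B"), "x"))
  fit <- mvou(tr, X, model = "BM")
  anc <- ancestral_states(fit)
  expect_equal(nrow(anc), 1L)          # the root
  expect_equal(anc$mean, 1, tolerance = 1e-6)
  expect_equal(anc$sd, 0, tolerance = 1e-8)

  # hand-built fits: stronger pull shrinks node means toward theta
  fx <- mvou_fixture(seed = 17)
  mk <- function(alpha) structure(list(
    A = diag(alpha, 3), Sigma = fx$cfg$Sigma, theta = fx$cfg$theta,
    model = "OU", tree = fx$tree, traits = fx$X,
    trait_names = colnames(fx$X), n = nrow(fx$X), p = 3), class = "mvou")
  dev <- function(alpha) {
    anc <- ancestral_states(mk(alpha))
    mean(abs(anc$mean - rep(fx$cfg$theta, each = nrow(anc) / 3)))
  }
  expect_lt(dev(1), dev(0.01))
})

test_that("likelihood and imputation are invariant to trait reordering", {
  fx <- mvou_fixture(seed = 23, n_extant = 10, n_fossil = 3)
  Xna <- fx$X; Xna[1:3, 1] <- NA
  A <- diag(c(0.2, 0.5, 0.9))
  S <- fx$cfg$Sigma; th <- c(4, -2, 4)
  perm <- c(2, 1, 3)
  ll1 <- mvou_loglik(fx$tree, Xna, A, S, th)
  ll2 <- mvou_loglik(fx$tree, Xna[, perm], A[perm, perm], S[perm, perm],
                     th[perm])
  expect_equal(ll1, ll2, tolerance = 1e-8)
  mk <- function(Xm, A, S, th) structure(list(
    A = A, Sigma = S, theta = th, model = "OU", tree = fx$tree,
    traits = Xm, trait_names = colnames(Xm), n = nrow(Xm), p = 3),
    class = "mvou")
  e1 <- estimate_missing(mk(Xna, A, S, th))
  e2 <- estimate_missing(mk(Xna[, perm], A[perm, perm], S[perm, perm],
                            th[perm]))
  expect_equal(e1[order(e1$node), c("mean", "sd")],
               e2[order(e2$node), c("mean", "sd")], tolerance = 1e-8)
})

test_that("AIC prefers the generating multivariate model", {
  Abm <- diag(1e-8, 2)           # effectively BM
  Aou <- diag(3, 2)              # strong pull on a unit-height tree
  S <- matrix(c(1, .6, .6, 1), 2)
  th <- c(0, 0)
  nrep <- 20
  bm_wins <- ou_wins <- 0L
  for (i in seq_len(nrep)) {
    cfg <- sim_config(n_extant = 80, n_fossil = 0, seed = 300 + i,
                      tree_height = 1)
    tr <- simulate_tree(cfg)
    Xb <- simulate_mvou_traits(tr, Abm, S, th, trait_names = c("u", "v"),
                               seed = 7000 + i)
    if (compare_mvou(tr, Xb, A_structure = "scalar",
                     maxit = 800)$best == "BM") bm_wins <- bm_wins + 1L
    Xo <- simulate_mvou_traits(tr, Aou, S, th, trait_names = c("u", "v"),
                               seed = 8000 + i)
    if (compare_mvou(tr, Xo, A_structure = "scalar",
                     maxit = 800)$best == "OU") ou_wins <- ou_wins + 1L
  }
  expect_gte(bm_wins / nrep, 0.8)
  expect_gte(ou_wins / nrep, 0.8)
})

test_that("leave-one-out predictions and R-squared behave at the extremes", {
  expect_equal(prediction_r2(1:10, 1:10), 1)
  set.seed(9)
  expect_lt(prediction_r2(rnorm(200), rnorm(200)), 0.05)
  expect_error(prediction_r2(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(prediction_r2(1:2, 1:2), "three")

  # LOO conditional means agree with explicit per-tip conditioning
  fx <- mvou_fixture(seed = 29, n_extant = 8, n_fossil = 0)
  fit <- structure(list(
    A = diag(c(0.3, 0.6, 1.2)), Sigma = fx$cfg$Sigma, theta = fx$cfg$theta,
    model = "OU", tree = fx$tree, traits = fx$X,
    trait_names = colnames(fx$X), n = 8, p = 3), class = "mvou")
  loo <- loo_estimates(fit, "log_mmr")
  st <- foramenflow:::node_shared_times(fx$tree, "tips")
  V <- foramenflow:::mvou_covariance(st$C, fit$A, fit$Sigma)
  mu <- rep(fit$theta, each = 8)
  y <- as.vector(fx$X)
  for (i in c(1, 5)) {
    oracle <- brute_conditional(mu, V, setdiff(seq_along(y), i), y[-i], i)
    j <- match(rownames(fx$X)[i], loo$node)
    expect_equal(loo$predicted[j], unname(oracle$mean), tolerance = 1e-8)
    expect_equal(loo$sd[j], unname(oracle$sd), tolerance = 1e-6)
  }
})

test_that("imputed giant-fossil MMR exceeds extant-xenarthran MMR as designed", {
  wins <- 0L
  for (i in 1:5) {
    cfg <- sim_config(seed = 400 + i)
    tr <- simulate_tree(cfg)
    tab <- simulate_allometry(tr, cfg)
    tm <- as.matrix(tab[, c("log_mmr", "log_qdot", "log_bm")])
    rownames(tm) <- tab$taxon
    fit <- mvou(tr, tm, A_structure = "scalar", maxit = 1200)
    est <- estimate_missing(fit)
    est <- est[est$trait == "log_mmr", ]
    mi_fossil <- est$mean - 0.67 * tab$log_bm[match(est$node, tab$taxon)]
    xen <- tab$group == "Xenarthra" & is.finite(tab$log_mmr)
    mi_xen <- tab$log_mmr[xen] - 0.67 * tab$log_bm[xen]
    if (mean(mi_fossil) > mean(mi_xen)) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
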