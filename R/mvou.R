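# Multivariate Ornstein-Uhlenbeck machinery.
#
# Model: p traits evolve jointly along the tree as
#   dx = -A (x - theta) dt + S dW,   Sigma = S S^T,
# with the root state fixed at the optimum theta and A symmetric positive
# definite. For two points u, v on the tree whose most recent common
# ancestor sits at depth t (root-to-node time), with depths T_u, T_v, the
# covariance in the eigenbasis of A (A = Q Lambda Q^T, St = Q^T Sigma Q) is
#   Cov(y_u^k, y_v^l) = St_kl (exp(-l_k (T_u - t) - l_l (T_v - t))
#                              - exp(-l_k T_u - l_l T_v)) / (l_k + l_l),
# which degrades gracefully to St_kl * t as l_k + l_l -> 0 (the
# multivariate-BM limit). All exponents are <= 0, so the expression is
# stable for arbitrarily strong pull. Every tip (or node) mean equals theta.

check_spd <- function(M, name, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(name, " must be symmetric", call. = FALSE)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(name, " must be positive definite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  invisible(ev)
}

# Shared root-to-MRCA times for a set of nodes ("tips" or all nodes).
node_shared_times <- function(phy, nodes = c("tips", "all")) {
  nodes <- match.arg(nodes)
  depths <- ape::node.depth.edgelength(phy)
  if (nodes == "tips") {
    C <- shared_path_matrix(phy)
    list(C = C, depths = diag(C), labels = phy$tip.label)
  } else {
    M <- ape::mrca(phy, full = TRUE)
    C <- matrix(depths[M], nrow(M), ncol(M))
    labs <- c(phy$tip.label, paste0("node_", ape::Ntip(phy) +
                                      seq_len(phy$Nnode)))
    dimnames(C) <- list(labs, labs)
    list(C = C, depths = depths, labels = labs)
  }
}

# Joint covariance of the stacked vector (trait-major: trait k occupies rows
# (k-1)*m + 1 .. k*m) for points with shared-time matrix C.
mvou_covariance <- function(C, A, Sigma) {
  p <- nrow(A); m <- nrow(C)
  Tdep <- diag(C)
  diagonal <- p == 1L || max(abs(A[row(A) != col(A)])) < 1e-14
  if (diagonal) {
    Q <- diag(1, p); lam <- diag(A); St <- Sigma
  } else {
    eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
    Q <- eg$vectors; lam <- eg$values
    St <- t(Q) %*% Sigma %*% Q
  }
  o <- lapply(seq_len(p), function(k) exp(-lam[k] * Tdep))
  G <- vector("list", p * p)
  for (k in seq_len(p)) for (l in k:p) {
    s <- lam[k] + lam[l]
    M2 <- tcrossprod(o[[k]], o[[l]])
    Gkl <- if (s > 1e-10) {
      M1 <- exp(s * C - outer(lam[k] * Tdep, lam[l] * Tdep, "+"))
      St[k, l] * (M1 - M2) / s
    } else {
      St[k, l] * M2 * C
    }
    G[[(k - 1) * p + l]] <- Gkl
    if (l != k) G[[(l - 1) * p + k]] <- t(Gkl)   # St is symmetric
  }
  V <- matrix(0, m * p, m * p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    blk <- if (diagonal) G[[(a - 1) * p + b]] else {
      acc <- matrix(0, m, m)
      for (k in seq_len(p)) for (l in seq_len(p))
        acc <- acc + Q[a, k] * Q[b, l] * G[[(k - 1) * p + l]]
      acc
    }
    V[(a - 1) * m + seq_len(m), (b - 1) * m + seq_len(m)] <- blk
  }
  V
}

# Multivariate BM analogue: Cov block (k,l) = Sigma_kl * C.
mvbm_covariance <- function(C, Sigma) {
  p <- nrow(Sigma); m <- nrow(C)
  V <- matrix(0, m * p, m * p)
  for (a in seq_len(p)) for (b in seq_len(p))
    V[(a - 1) * m + seq_len(m), (b - 1) * m + seq_len(m)] <- Sigma[a, b] * C
  V
}

check_traits <- function(phy, traits) {
  if (!is.matrix(traits)) traits <- as.matrix(traits)
  if (is.null(rownames(traits)))
    stop("trait matrix needs taxon rownames", call. = FALSE)
  miss <- setdiff(phy$tip.label, rownames(traits))
  if (length(miss)) stop("no trait rows for tips: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  traits <- traits[phy$tip.label, , drop = FALSE]
  nobs <- colSums(is.finite(traits))
  if (any(nobs < 2L))
    stop("trait(s) observed at fewer than 2 tips: ",
         paste(colnames(traits)[nobs < 2L], collapse = ", "), call. = FALSE)
  traits
}

#' Log-likelihood of a multivariate OU model at the tips
#'
#' Gaussian log-likelihood of the observed entries of an n x p trait matrix
#' under the multivariate OU tip distribution on a (possibly
#' non-ultrametric) tree, root fixed at the optimum `theta`. Missing
#' entries (`NA`) are marginalised by deleting their rows/columns from the
#' joint covariance — exact for a Gaussian.
#'
#' @param phy a `phylo` tree.
#' @param traits n x p numeric matrix, rownames = taxa, `NA` for missing.
#' @param A p x p symmetric positive-definite pull matrix.
#' @param Sigma p x p symmetric positive-definite diffusion matrix.
#' @param theta length-p optimum (= root state).
#' @return the log-likelihood (scalar).
#' @export
mvou_loglik <- function(phy, traits, A, Sigma, theta) {
  phy <- validate_phylo(phy)
  traits <- check_traits(phy, traits)
  p <- ncol(traits)
  check_spd(A, "A"); check_spd(Sigma, "Sigma")
  stopifnot(length(theta) == p)
  st <- node_shared_times(phy, "tips")
  V <- mvou_covariance(st$C, A, Sigma)
  y <- as.vector(traits)                       # trait-major stacking
  obs <- which(is.finite(y))
  mu <- rep(theta, each = nrow(traits))
  R <- chol(V[obs, obs])
  r <- forwardsolve(t(R), y[obs] - mu[obs])
  -length(obs) / 2 * log(2 * pi) - sum(log(diag(R))) - sum(r^2) / 2
}

# --- parameterisations -------------------------------------------------

# Lower-triangular log-Cholesky <-> SPD matrix.
par_to_spd <- function(par, p, diag_only = FALSE, fix_first = FALSE) {
  L <- matrix(0, p, p)
  if (diag_only) {
    diag(L) <- exp(par)
  } else {
    nd <- if (fix_first) p - 1L else p
    d <- if (fix_first) c(0, par[seq_len(nd)]) else par[seq_len(nd)]
    diag(L) <- exp(d)
    L[lower.tri(L)] <- par[-seq_len(nd)]
  }
  L %*% t(L)
}

n_par_spd <- function(p, diag_only = FALSE, fix_first = FALSE) {
  if (diag_only) p else (if (fix_first) p - 1L else p) + p * (p - 1L) / 2L
}

# Moment-based starting values: per-trait univariate fits for scales, raw
# cross-trait correlations for the diffusion shape.
mvou_init <- function(phy, traits) {
  p <- ncol(traits)
  rates <- vapply(seq_len(p), function(k) {
    x <- traits[, k]
    ok <- is.finite(x)
    sub <- ape::keep.tip(phy, rownames(traits)[ok])
    f <- tryCatch(fit_bm(sub, x[ok]), error = function(e) NULL)
    if (is.null(f) || !is.finite(f$parameters[["sigma2"]]) ||
        f$parameters[["sigma2"]] <= 0)
      stats::var(x[ok]) / max(tip_depths(phy)) else f$parameters[["sigma2"]]
  }, 0)
  Cor <- suppressWarnings(stats::cor(traits, use = "pairwise.complete.obs"))
  Cor[!is.finite(Cor)] <- 0; diag(Cor) <- 1
  Cor <- Cor * 0.9 + diag(p) * 0.1          # pull toward PD
  Sigma0 <- diag(sqrt(rates), p) %*% Cor %*% diag(sqrt(rates), p)
  list(Sigma = (Sigma0 + t(Sigma0)) / 2,
       alpha = 1 / max(tip_depths(phy)),
       theta = colMeans(traits, na.rm = TRUE))
}

# Profile lnL given a unit-scale covariance V0: theta by GLS, overall scale
# analytically. Returns -Inf on numerical failure (optimizer-safe).
profile_eval <- function(V0, yobs, Xobs) {
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(list(lnL = -Inf))
  N <- length(yobs)
  Wy <- forwardsolve(t(R), yobs)
  WX <- forwardsolve(t(R), Xobs)
  qrW <- qr(WX)
  theta <- qr.coef(qrW, Wy)
  r <- Wy - drop(WX %*% theta)
  q <- sum(r^2)
  cstar <- q / N
  if (!is.finite(cstar) || cstar <= 0) return(list(lnL = -Inf))
  lnL <- -N / 2 * log(2 * pi) - N / 2 * log(cstar) -
    sum(log(diag(R))) - N / 2
  list(lnL = lnL, theta = theta, scale = cstar)
}

#' Fit a multivariate OU (or BM) model to several traits on a tree
#'
#' Maximum likelihood for the joint evolution of p continuous traits under
#' a multivariate OU process with symmetric positive-definite pull matrix
#' `A` and diffusion `Sigma`, root fixed at the optimum `theta`; or under
#' multivariate BM (`model = "BM"`, the no-pull analogue). `theta` and the
#' overall scale of `Sigma` are profiled analytically; the remaining
#' parameters are log-Cholesky parameterised and optimised by Nelder-Mead.
#' Arbitrary tip-by-trait missingness is handled by exact Gaussian
#' marginalisation, which is what makes the model usable for fossil tips
#' lacking MMR but retaining flow and body-mass values.
#'
#' @param phy a `phylo` tree.
#' @param traits n x p matrix, rownames = taxa, `NA` for missing entries.
#' @param model `"OU"` (default) or `"BM"`.
#' @param A_structure `"symmetric"` (default), `"diagonal"` (independent
#'   per-trait pull rates) or `"scalar"` (one shared pull rate). The
#'   restricted forms are considerably faster and often adequate when
#'   trait coupling enters through `Sigma`.
#' @param maxit Nelder-Mead iteration cap (default 2000).
#' @param init optional list with starting `A`, `Sigma`.
#' @return an object of class `mvou`: `A`, `Sigma`, `theta`, `lnL`, `k`,
#'   `AIC`, `model`, `convergence` (0 = converged), `counts`, `tree`,
#'   `traits`, `trait_names`.
#' @seealso [estimate_missing()], [ancestral_states()], [compare_mvou()]
#' @export
mvou <- function(phy, traits, model = c("OU", "BM"),
                 A_structure = c("symmetric", "diagonal", "scalar"),
                 maxit = 2000L, init = NULL) {
  model <- match.arg(model)
  A_structure <- match.arg(A_structure)
  phy <- validate_phylo(phy)
  traits <- check_traits(phy, traits)
  n <- nrow(traits); p <- ncol(traits)
  tnames <- colnames(traits) %||% paste0("trait", seq_len(p))
  colnames(traits) <- tnames
  st <- node_shared_times(phy, "tips")
  y <- as.vector(traits)
  obs <- which(is.finite(y))
  X <- matrix(0, n * p, p)
  for (k in seq_len(p)) X[(k - 1) * n + seq_len(n), k] <- 1
  Xobs <- X[obs, , drop = FALSE]
  yobs <- y[obs]

  ini <- mvou_init(phy, traits)
  if (!is.null(init$Sigma)) ini$Sigma <- init$Sigma
  Ls <- t(chol(ini$Sigma))
  # Sigma parameterised with its first diagonal fixed (scale is profiled).
  sig_par <- c(log(diag(Ls)[-1] / diag(Ls)[1]),
               (Ls / diag(Ls)[1])[lower.tri(Ls)])

  if (model == "OU") {
    A0 <- if (!is.null(init$A)) init$A else diag(ini$alpha, p)
    La <- t(chol(A0))
    a_par <- switch(A_structure,
                    scalar = log(mean(diag(A0))),
                    diagonal = log(diag(A0)),
                    symmetric = c(log(diag(La)), La[lower.tri(La)]))
    n_a <- length(a_par)
    par0 <- c(a_par, sig_par)
    build <- function(par) {
      A <- switch(A_structure,
                  scalar = diag(exp(par[1L]), p),
                  diagonal = diag(exp(par[seq_len(n_a)]), p),
                  symmetric = par_to_spd(par[seq_len(n_a)], p))
      Sigma0 <- par_to_spd(par[-seq_len(n_a)], p, fix_first = TRUE)
      list(A = A, Sigma0 = Sigma0)
    }
    negll <- function(par) {
      if (length(par) && (any(!is.finite(par)) || max(abs(par)) > 30))
        return(1e10)
      pr <- build(par)
      V0 <- mvou_covariance(st$C, pr$A, pr$Sigma0)
      ev <- profile_eval(V0[obs, obs], yobs, Xobs)
      if (!is.finite(ev$lnL)) 1e10 else -ev$lnL
    }
  } else {
    par0 <- sig_par
    build <- function(par) list(A = NULL,
                                Sigma0 = par_to_spd(par, p, fix_first = TRUE))
    negll <- function(par) {
      if (length(par) && (any(!is.finite(par)) || max(abs(par)) > 30))
        return(1e10)
      V0 <- mvbm_covariance(st$C, build(par)$Sigma0)
      ev <- profile_eval(V0[obs, obs], yobs, Xobs)
      if (!is.finite(ev$lnL)) 1e10 else -ev$lnL
    }
  }

  opt <- if (length(par0) == 0L) {
    list(par = par0, value = negll(par0), convergence = 0L,
         counts = c(`function` = 1L, gradient = NA))
  } else if (length(par0) == 1L) {
    stats::optim(par0, negll, method = "Brent", lower = -30, upper = 30,
                 control = list(maxit = maxit))
  } else {
    stats::optim(par0, negll, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8))
  }
  if (opt$value >= 1e10)
    stop("mvOU optimisation failed: no finite likelihood reached; ",
         "best parameters ", paste(signif(opt$par, 3), collapse = ", "),
         call. = FALSE)
  pr <- build(opt$par)
  V0 <- if (model == "OU") mvou_covariance(st$C, pr$A, pr$Sigma0)
        else mvbm_covariance(st$C, pr$Sigma0)
  ev <- profile_eval(V0[obs, obs], yobs, Xobs)
  Sigma <- ev$scale * pr$Sigma0
  theta <- stats::setNames(as.numeric(ev$theta), tnames)
  k <- p + n_par_spd(p) +                       # theta + Sigma (incl. scale)
    if (model == "OU") switch(A_structure, scalar = 1L, diagonal = p,
                              symmetric = n_par_spd(p)) else 0L
  structure(list(
    A = if (model == "OU") structure(pr$A, dimnames = list(tnames, tnames)),
    Sigma = structure(Sigma, dimnames = list(tnames, tnames)),
    theta = theta, lnL = ev$lnL, k = k, AIC = 2 * k - 2 * ev$lnL,
    model = model, A_structure = if (model == "OU") A_structure,
    convergence = opt$convergence, counts = opt$counts,
    tree = phy, traits = traits, trait_names = tnames, n = n, p = p
  ), class = "mvou")
}

#' @export
print.mvou <- function(x, ...) {
  cat(sprintf("Multivariate %s fit: %d traits, %d tips, %d observed entries\n",
              x$model, x$p, x$n, sum(is.finite(x$traits))))
  if (!is.null(x$A)) { cat("Pull matrix A:\n"); print(signif(x$A, 4)) }
  cat("Diffusion Sigma:\n"); print(signif(x$Sigma, 4))
  cat("Optimum/root theta:\n"); print(signif(x$theta, 6))
  cat(sprintf("lnL = %.4f, k = %d, AIC = %.4f (convergence %d)\n",
              x$lnL, x$k, x$AIC, x$convergence))
  invisible(x)
}

#' @export
logLik.mvou <- function(object, ...) {
  structure(object$lnL, df = object$k,
            nobs = sum(is.finite(object$traits)), class = "logLik")
}

#' @export
coef.mvou <- function(object, ...) {
  list(A = object$A, Sigma = object$Sigma, theta = object$theta)
}

#' Compare multivariate OU and BM fits on the same data
#'
#' @param phy,traits as in [mvou()].
#' @param ... passed on to [mvou()].
#' @return list with both fits and `delta_AIC` (BM minus OU; positive
#'   favours OU).
#' @export
compare_mvou <- function(phy, traits, ...) {
  fou <- mvou(phy, traits, model = "OU", ...)
  fbm <- mvou(phy, traits, model = "BM", ...)
  list(OU = fou, BM = fbm, delta_AIC = fbm$AIC - fou$AIC,
       best = if (fou$AIC <= fbm$AIC) "OU" else "BM")
}

# Joint covariance + mean for the fitted model over a node set.
fit_covariance <- function(fit, nodes = "tips") {
  st <- node_shared_times(fit$tree, nodes)
  V <- if (fit$model == "OU") mvou_covariance(st$C, fit$A, fit$Sigma)
       else mvbm_covariance(st$C, fit$Sigma)
  m <- length(st$depths)
  mu <- rep(fit$theta, each = m)
  lab <- rep(st$labels, times = fit$p)
  trait <- rep(fit$trait_names, each = m)
  list(V = V, mu = mu, labels = lab, trait = trait, m = m)
}

conditional_rows <- function(V, mu, obs_idx, y_obs, want_idx) {
  Voo <- V[obs_idx, obs_idx]
  R <- chol(Voo + diag(1e-12 * mean(diag(Voo)), length(obs_idx)))
  d <- y_obs - mu[obs_idx]
  Kd <- backsolve(R, forwardsolve(t(R), d))
  Vwo <- V[want_idx, obs_idx, drop = FALSE]
  mean_w <- mu[want_idx] + drop(Vwo %*% Kd)
  # var = diag(Vww) - diag(Vwo Voo^-1 Vow)
  Wt <- forwardsolve(t(R), t(Vwo))
  var_w <- pmax(0, diag(V)[want_idx] - colSums(Wt^2))
  list(mean = mean_w, sd = sqrt(var_w))
}

#' Impute missing tip values under a fitted multivariate model
#'
#' Exact conditional-MVN imputation: each missing tip-by-trait entry gets
#' the conditional mean and variance given every observed entry, under the
#' joint Gaussian implied by the fitted parameters. 95% intervals are
#' `mean +/- 1.96 sd`, conditional on the parameter point estimates
#' (parameter uncertainty is not propagated).
#'
#' @param fit an `mvou` fit.
#' @param include_observed also return rows for observed entries (mean =
#'   observation, sd = 0). Default `FALSE`.
#' @return data.frame: `node` (tip label), `trait`, `mean`, `sd`,
#'   `ci_low`, `ci_high`, `observed`.
#' @export
estimate_missing <- function(fit, include_observed = FALSE) {
  fc <- fit_covariance(fit, "tips")
  y <- as.vector(fit$traits)
  obs <- which(is.finite(y))
  mis <- which(!is.finite(y))
  out <- NULL
  if (length(mis)) {
    cr <- conditional_rows(fc$V, fc$mu, obs, y[obs], mis)
    out <- data.frame(node = fc$labels[mis], trait = fc$trait[mis],
                      mean = cr$mean, sd = cr$sd,
                      ci_low = cr$mean - 1.96 * cr$sd,
                      ci_high = cr$mean + 1.96 * cr$sd,
                      observed = FALSE, stringsAsFactors = FALSE)
  }
  if (include_observed) {
    ob <- data.frame(node = fc$labels[obs], trait = fc$trait[obs],
                     mean = y[obs], sd = 0, ci_low = y[obs],
                     ci_high = y[obs], observed = TRUE,
                     stringsAsFactors = FALSE)
    out <- rbind(out, ob)
  }
  rownames(out) <- NULL
  out
}

#' Ancestral state reconstruction under a fitted multivariate model
#'
#' Conditional means and 95% intervals for every internal node and trait,
#' given all observed tip entries, under the joint Gaussian implied by the
#' fitted parameters. The root is fixed at the optimum (sd 0).
#'
#' @param fit an `mvou` fit.
#' @return data.frame: `node` (`node_<k>` in ape numbering), `trait`,
#'   `mean`, `sd`, `ci_low`, `ci_high`.
#' @export
ancestral_states <- function(fit) {
  fc <- fit_covariance(fit, "all")
  m <- fc$m; n <- fit$n; p <- fit$p
  # positions of tip entries within the all-nodes stacking
  tip_pos <- as.vector(outer(seq_len(n), (seq_len(p) - 1) * m, "+"))
  y <- as.vector(fit$traits)
  obs_tip <- which(is.finite(y))
  obs <- tip_pos[obs_tip]
  internal <- setdiff(seq_len(m * p), tip_pos)
  cr <- conditional_rows(fc$V, fc$mu, obs, y[obs_tip], internal)
  data.frame(node = fc$labels[internal], trait = fc$trait[internal],
             mean = cr$mean, sd = cr$sd,
             ci_low = cr$mean - 1.96 * cr$sd,
             ci_high = cr$mean + 1.96 * cr$sd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Leave-one-out predictions for observed entries of one trait
#'
#' For every tip where `trait` is observed, the conditional mean of that
#' entry given all *other* observed entries — the honest way to score the
#' model's predictive capacity on taxa that have data. Computed from a
#' single precision matrix (no refitting).
#'
#' @param fit an `mvou` fit.
#' @param trait trait name (default the first trait).
#' @return data.frame: `node`, `observed`, `predicted`, `sd`.
#' @export
loo_estimates <- function(fit, trait = fit$trait_names[1L]) {
  k <- match(trait, fit$trait_names)
  if (is.na(k)) stop("unknown trait: ", trait, call. = FALSE)
  fc <- fit_covariance(fit, "tips")
  y <- as.vector(fit$traits)
  obs <- which(is.finite(y))
  Voo <- fc$V[obs, obs]
  P <- chol2inv(chol(Voo + diag(1e-12 * mean(diag(Voo)), length(obs))))
  d <- y[obs] - fc$mu[obs]
  Pd <- drop(P %*% d)
  # conditional of obs entry i given the rest: mu_i + d_i - Pd_i / P_ii
  cond_mean <- fc$mu[obs] + d - Pd / diag(P)
  cond_sd <- sqrt(1 / diag(P))
  sel <- fc$trait[obs] == trait
  data.frame(node = fc$labels[obs][sel], observed = y[obs][sel],
             predicted = cond_mean[sel], sd = cond_sd[sel],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Observed-versus-predicted R-squared
#'
#' Squared Pearson correlation between observed and estimated values, the
#' conventional summary of imputation quality.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 3).
#' @return R-squared in [0, 1].
#' @export
prediction_r2 <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  if (sum(ok) < 3L) stop("need at least three pairs", call. = FALSE)
  if (stats::sd(observed[ok]) == 0 || stats::sd(predicted[ok]) == 0)
    stop("zero variance: R-squared undefined", call. = FALSE)
  stats::cor(observed[ok], predicted[ok])^2
}
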