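#' Phylogenetic generalized least squares with an OU correlation structure
#'
#' Fits a linear model whose residuals are correlated across taxa according
#' to the Martins-Hansen (OU-derived) structure
#' `cor(i, j) = exp(-alpha * d_ij)` with `d_ij` the patristic distance
#' between tips. The GLS estimator is
#' \deqn{\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y}
#' with `V` the OU correlation matrix; the residual scale `sigma2` is
#' profiled by ML, and `alpha` is either supplied fixed or profiled by ML
#' over `log(alpha)` in [-10, 10] with a deterministic multi-start search
#' (one extra start is centred at the univariate-OU estimate for the
#' response). Fitting is by ML, not REML, so AIC/BIC are comparable across
#' models that differ in their fixed effects.
#'
#' `alpha = Inf` requests the identity correlation, in which case the fit is
#' ordinary least squares.
#'
#' @param formula model formula, e.g. `log_qdot ~ log_bm + group`.
#' @param data data.frame with one row per taxon; taxa are taken from a
#'   `taxon` column if present, else from `rownames(data)`. All taxa must be
#'   tips of `tree` (exact string match after whitespace trimming).
#' @param tree a `phylo` tree; pruned to the taxa in `data`.
#' @param alpha `"ML"` (default: profile by ML), a fixed non-negative rate,
#'   or `Inf` for the identity correlation (OLS).
#' @param normalize_height passed to [ou_correlation_matrix()].
#' @return an object of class `pgls`: list with `coefficients`, `vcov`,
#'   `sigma2`, `alpha`, `alpha_estimated`, `logLik`, `k`, `AIC`, `BIC`, `n`,
#'   `fitted.values`, `residuals`, `formula`, `model` (model frame), `tree`,
#'   `V` (correlation matrix), `xlevels`, `terms`, `call`.
#' @examples
#' cfg <- sim_config(n_extant = 24, n_fossil = 6, seed = 7)
#' tr  <- simulate_tree(cfg)
#' tab <- simulate_allometry(tr, cfg)
#' fit <- pgls(log_qdot ~ log_bm + group, tab, tr)
#' summary(fit)
#' @export
pgls <- function(formula, data, tree, alpha = "ML", normalize_height = FALSE) {
  cl <- match.call()
  tree <- validate_phylo(tree)
  taxa <- if ("taxon" %in% names(data)) trimws(as.character(data$taxon))
          else trimws(rownames(data))
  if (anyDuplicated(taxa)) stop("duplicate taxa in data", call. = FALSE)
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("taxa missing from tree: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (length(taxa) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, taxa)
  rownames(data) <- taxa
  data <- data[tree$tip.label, , drop = FALSE]

  mf <- stats::model.frame(formula, data)
  if (any(!vapply(mf, function(v) all(is.finite(v) | is.factor(v) |
                                        is.character(v)), TRUE)))
    stop("non-finite values in model variables", call. = FALSE)
  trm <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(trm, mf)
  if (qr(X)$rank < ncol(X)) {
    qx <- qr(X)
    aliased <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n <- length(y); p <- ncol(X)

  fit_at <- function(a) {
    V <- if (is.infinite(a)) diag(n)
         else ou_correlation_matrix(tree, a, normalize_height)
    R <- tryCatch(chol(V), error = function(e)
      stop("correlation matrix not positive definite at alpha = ", a,
           call. = FALSE))
    Wy <- forwardsolve(t(R), y)
    WX <- forwardsolve(t(R), X)
    qrW <- qr(WX)
    beta <- stats::setNames(qr.coef(qrW, Wy), colnames(X))
    r <- y - drop(X %*% beta)
    Wr <- Wy - drop(WX %*% beta)
    s2 <- sum(Wr^2) / n
    logdet <- 2 * sum(log(diag(R)))
    lnL <- -n / 2 * (log(2 * pi) + log(s2) + 1) - logdet / 2
    XtViX_inv <- chol2inv(qr.R(qrW))
    dimnames(XtViX_inv) <- list(colnames(X), colnames(X))
    list(V = V, beta = beta, resid = r, s2 = s2, lnL = lnL,
         vcov = s2 * XtViX_inv)
  }

  if (identical(alpha, "ML")) {
    obj <- function(la) -fit_at(exp(la))$lnL
    cuts <- seq(-10, 10, length.out = 6)
    best <- NULL
    for (i in seq_len(5)) {
      o <- stats::optimize(obj, c(cuts[i], cuts[i + 1]), tol = 1e-8)
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    init <- tryCatch(fit_ou(tree, stats::setNames(y, tree$tip.label))$parameters[["alpha"]],
                     error = function(e) NULL)
    if (!is.null(init) && init > 0) {
      li <- log(init)
      o <- stats::optimize(obj, c(max(-10, li - 1.5), min(10, li + 1.5)),
                           tol = 1e-8)
      if (o$objective < best$objective) best <- o
    }
    a_hat <- exp(best$minimum)
    alpha_estimated <- TRUE
  } else {
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
    a_hat <- alpha
    alpha_estimated <- FALSE
  }
  ft <- fit_at(a_hat)
  k <- p + 1L + as.integer(alpha_estimated)   # beta, sigma2, (alpha)
  structure(list(
    coefficients = ft$beta, vcov = ft$vcov, sigma2 = ft$s2,
    alpha = a_hat, alpha_estimated = alpha_estimated,
    logLik = ft$lnL, k = k, AIC = 2 * k - 2 * ft$lnL,
    BIC = k * log(n) - 2 * ft$lnL, n = n,
    fitted.values = drop(X %*% ft$beta), residuals = ft$resid,
    formula = formula, model = mf, tree = tree, V = ft$V,
    xlevels = stats::.getXlevels(trm, mf), terms = trm, call = cl
  ), class = "pgls")
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$vcov

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
nobs.pgls <- function(object, ...) object$n

#' Residuals of a PGLS fit
#'
#' @param object a `pgls` fit.
#' @param type `"response"` for raw residuals, `"normalized"` for residuals
#'   whitened by the inverse Cholesky factor of `sigma2 * V` (iid standard
#'   normal under the model).
#' @param ... unused.
#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "response") return(r)
  L <- t(chol(object$sigma2 * object$V))
  stats::setNames(drop(forwardsolve(L, r)), names(r))
}

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
predict.pgls <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) {
    if (!se.fit) return(object$fitted.values)
    X <- stats::model.matrix(object$terms, object$model)
  } else {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata,
                             xlev = object$xlevels)
  }
  mu <- drop(X %*% object$coefficients)
  if (!se.fit) return(mu)
  se <- sqrt(rowSums((X %*% object$vcov) * X))
  list(fit = mu, se.fit = se)
}

#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  L <- t(chol(object$sigma2 * object$V))
  n <- object$n
  out <- replicate(nsim, object$fitted.values + drop(L %*% stats::rnorm(n)))
  as.data.frame(out)
}

#' @export
print.pgls <- function(x, ...) {
  cat("Phylogenetic GLS (OU/Martins-Hansen correlation)\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, alpha = %.6g%s, sigma2 = %.6g\n", x$n, x$alpha,
              if (x$alpha_estimated) " (ML)" else " (fixed)", x$sigma2))
  cat("Coefficients:\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("logLik = %.4f, AIC = %.4f, BIC = %.4f\n", x$logLik, x$AIC, x$BIC))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(call = object$call, coefficients = tab, alpha = object$alpha,
              alpha_estimated = object$alpha_estimated,
              sigma2 = object$sigma2, logLik = object$logLik,
              AIC = object$AIC, BIC = object$BIC, n = object$n)
  class(out) <- "summary.pgls"
  out
}

#' @export
print.summary.pgls <- function(x, ...) {
  cat("Phylogenetic GLS fit\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nalpha = %.6g%s, sigma2 = %.6g, n = %d\n", x$alpha,
              if (x$alpha_estimated) " (ML)" else " (fixed)", x$sigma2, x$n))
  cat(sprintf("logLik = %.4f, AIC = %.4f, BIC = %.4f\n", x$logLik, x$AIC, x$BIC))
  invisible(x)
}

#' @export
plot.pgls <- function(x, covariate = NULL, group = NULL, ...) {
  mf <- x$model
  num <- vapply(mf, is.numeric, TRUE)
  num[1L] <- FALSE
  if (is.null(covariate)) covariate <- names(mf)[num][1L]
  y <- stats::model.response(mf)
  xc <- mf[[covariate]]
  fac <- vapply(mf, function(v) is.factor(v) || is.character(v), TRUE)
  gname <- if (!is.null(group)) group else names(mf)[fac][1L]
  col <- if (!is.na(gname) && length(gname))
    as.integer(factor(mf[[gname]])) else 1L
  graphics::plot(xc, y, col = col, pch = 19,
                 xlab = covariate, ylab = names(mf)[1L], ...)
  o <- order(xc)
  for (g in unique(col)) {
    idx <- which(col == g)
    graphics::lines(xc[idx][order(xc[idx])],
                    x$fitted.values[idx][order(xc[idx])], col = g)
  }
  invisible(x)
}
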