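#' Compare nested PGLS fixed-effect structures
#'
#' Reports the AIC/BIC differences between a common-slope model and a model
#' with group-by-covariate interaction, and a joint Wald test of the extra
#' (interaction) coefficients. The conventional reading: keep the simpler
#' model when the interaction is non-significant at 0.05 and BIC favours it;
#' the deltas are reported verbatim rather than reduced to a hard rule.
#'
#' @param fit_reduced the simpler (e.g. common-slope) `pgls` fit.
#' @param fit_full the richer (e.g. interaction) `pgls` fit; must be fitted
#'   to the same taxa and nest `fit_reduced` by coefficient names.
#' @return a list: `delta_AIC`, `delta_BIC` (full minus reduced; positive
#'   favours the reduced model), `wald_chisq`, `df`, `p_interaction`,
#'   `extra_terms`, `preferred` (by the convention above).
#' @export
compare_pgls <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "pgls"), inherits(fit_full, "pgls"))
  if (fit_reduced$n != fit_full$n)
    stop("fits have different numbers of taxa", call. = FALSE)
  extra <- setdiff(names(coef(fit_full)), names(coef(fit_reduced)))
  dAIC <- fit_full$AIC - fit_reduced$AIC
  dBIC <- fit_full$BIC - fit_reduced$BIC
  if (!length(extra))
    return(list(delta_AIC = dAIC, delta_BIC = dBIC, wald_chisq = NA_real_,
                df = 0L, p_interaction = NA_real_, extra_terms = character(),
                preferred = "reduced"))
  b <- coef(fit_full)[extra]
  Vb <- fit_full$vcov[extra, extra, drop = FALSE]
  W <- drop(t(b) %*% solve(Vb, b))
  df <- length(extra)
  p <- stats::pchisq(W, df, lower.tail = FALSE)
  list(delta_AIC = dAIC, delta_BIC = dBIC, wald_chisq = W, df = df,
       p_interaction = p, extra_terms = extra,
       preferred = if (p > 0.05 && dBIC > 0) "reduced" else "full")
}

group_design_rows <- function(fit, group) {
  mf <- fit$model
  if (!group %in% names(mf))
    stop("no grouping variable '", group, "' in the model", call. = FALSE)
  lev <- levels(factor(mf[[group]]))
  if (length(lev) < 2L) stop("need at least two groups", call. = FALSE)
  nd <- mf[rep(1L, length(lev)), , drop = FALSE]
  for (v in names(nd)) if (is.numeric(nd[[v]])) nd[[v]] <- 0
  nd[[group]] <- factor(lev, levels = fit$xlevels[[group]] %||% lev)
  L <- stats::model.matrix(stats::delete.response(fit$terms), nd,
                           xlev = fit$xlevels)
  rownames(L) <- lev
  L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-group regression intercepts from a common-slope PGLS fit
#'
#' Evaluates each group's intercept (the fitted value at covariate zero),
#' giving the Table-of-equations view `log_qdot = b * log_bm + a_g`.
#'
#' @param fit a `pgls` fit containing a grouping factor.
#' @param group name of the grouping variable.
#' @return data.frame with `group`, `intercept`, `se`.
#' @export
group_intercepts <- function(fit, group = "group") {
  L <- group_design_rows(fit, group)
  a <- drop(L %*% coef(fit))
  se <- sqrt(rowSums((L %*% fit$vcov) * L))
  data.frame(group = rownames(L), intercept = a, se = se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Phylogenetic ANCOVA: pairwise intercept (elevation) contrasts
#'
#' For every pair of groups in a common-slope PGLS fit, computes the
#' intercept difference, its standard error from the coefficient
#' covariance, a normal z statistic, the two-sided p-value, the
#' Bonferroni-adjusted p (multiplied by the number of pairs, capped at 1)
#' and the flow ratio `10^Delta` — the ratio of the two groups' predicted
#' flows at equal body mass when the response is log10 flow.
#'
#' @param fit a common-slope `pgls` fit.
#' @param group name of the grouping variable (default `"group"`).
#' @return data.frame with one row per pair: `group_a`, `group_b`,
#'   `delta_intercept`, `se`, `z`, `p_raw`, `p_bonferroni`, `flow_ratio`.
#' @export
pairwise_ancova <- function(fit, group = "group") {
  L <- group_design_rows(fit, group)
  lev <- rownames(L)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(i) {
    ca <- L[pairs[1, i], ] - L[pairs[2, i], ]
    d <- sum(ca * coef(fit))
    se <- sqrt(drop(t(ca) %*% fit$vcov %*% ca))
    z <- d / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               delta_intercept = d, se = se, z = z, p_raw = p,
               p_bonferroni = min(1, m * p), flow_ratio = 10^d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flow ratio between two groups at equal body mass
#'
#' For intercepts on the log10 scale, `10^(a - b)` is the ratio of the two
#' groups' predicted flows at any shared body mass under a common slope.
#'
#' @param intercept_a,intercept_b log10-scale intercepts.
#' @return `10^(intercept_a - intercept_b)`.
#' @examples
#' flow_ratio(-5.31, -5.77)  # ~2.88x higher flow in the first group
#' @export
flow_ratio <- function(intercept_a, intercept_b) 10^(intercept_a - intercept_b)

#' Ordinary least squares reference line
#'
#' The phylogeny-free regression of `log10(qdot)` on `log10(Bm)` across all
#' taxa, conventionally plotted alongside PGLS results for comparison with
#' earlier foramen studies.
#'
#' @param data data.frame of taxon traits.
#' @param response,predictor column names (defaults `log_qdot`, `log_bm`).
#' @return list with `slope`, `intercept`, and the underlying `lm` fit.
#' @export
ols_reference <- function(data, response = "log_qdot", predictor = "log_bm") {
  if (nrow(data) < 3L) stop("need at least three taxa", call. = FALSE)
  f <- stats::reformulate(predictor, response)
  fit <- stats::lm(f, data = data)
  list(slope = unname(coef(fit)[predictor]),
       intercept = unname(coef(fit)["(Intercept)"]), fit = fit)
}

# Lilliefors (KS with estimated mean/sd) statistic, matching the
# conventional definition (sample sd with divisor n-1).
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  Dplus <- max(seq_len(n) / n - p)
  Dminus <- max(p - (seq_len(n) - 1) / n)
  max(Dplus, Dminus)
}

#' Normality of phylogenetically whitened residuals
#'
#' GLS residuals are correlated by construction; before a normality test
#' they are transformed by the inverse Cholesky factor of the residual
#' covariance, `u = L^{-1}(y - Xb)` with `sigma2 V = L L^T`, which makes
#' them iid standard normal under the model. Normality of `u` is then
#' assessed with the Lilliefors statistic (Kolmogorov-Smirnov with
#' estimated mean and sd) and a seeded Monte-Carlo p-value.
#'
#' @param fit a `pgls` fit.
#' @param nsim number of null Monte-Carlo replicates (default 10000).
#' @param seed optional RNG seed for the null replicates.
#' @return list with `statistic`, `p_value`, `nsim`, and the whitened
#'   residuals `whitened`.
#' @export
whitened_residual_normality <- function(fit, nsim = 10000L, seed = NULL) {
  u <- residuals(fit, type = "normalized")
  D <- lilliefors_stat(u)
  if (!is.null(seed)) set.seed(seed)
  n <- length(u)
  Dnull <- vapply(seq_len(nsim),
                  function(i) lilliefors_stat(stats::rnorm(n)), 0)
  p <- (1 + sum(Dnull >= D)) / (nsim + 1)
  list(statistic = D, p_value = p, nsim = nsim, whitened = u)
}
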