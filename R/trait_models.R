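# Gaussian GLS machinery shared by the evolutionary-model fits: profile the
# mean (z0) and the scale (sigma^2) analytically given a correlation-shaped
# matrix W, so only alpha is ever optimised numerically.

gls_profile_loglik <- function(x, W, tip_labels = NULL) {
  n <- length(x)
  R <- tryCatch(chol(W), error = function(e) {
    pair <- which(W == max(W) & upper.tri(W), arr.ind = TRUE)
    hint <- if (length(pair) && !is.null(tip_labels))
      paste0(" (check tips ", tip_labels[pair[1, 1]], ", ",
             tip_labels[pair[1, 2]], ")") else ""
    stop("phylogenetic covariance is singular", hint, call. = FALSE)
  })
  logdet <- 2 * sum(log(diag(R)))
  one <- rep(1, n)
  Wi_x <- backsolve(R, forwardsolve(t(R), x))
  Wi_1 <- backsolve(R, forwardsolve(t(R), one))
  z0 <- sum(Wi_x) / sum(Wi_1)
  r <- x - z0
  s2 <- sum(r * backsolve(R, forwardsolve(t(R), r))) / n
  degenerate <- s2 < .Machine$double.eps * max(1, mean(x)^2)
  lnL <- if (degenerate) Inf else
    -n / 2 * log(2 * pi) - n / 2 * log(s2) - logdet / 2 - n / 2
  list(z0 = z0, sigma2 = s2, lnL = lnL, degenerate = degenerate)
}

new_evomodel <- function(model, parameters, lnL, k, n, note = NULL) {
  structure(list(model = model, parameters = parameters, lnL = lnL, k = k,
                 AIC = 2 * k - 2 * lnL, n = n, note = note),
            class = "evomodel")
}

match_trait <- function(phy, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != ape::Ntip(phy))
      stop("trait length differs from tip count and is unnamed", call. = FALSE)
    names(trait) <- phy$tip.label
    return(trait)
  }
  miss <- setdiff(phy$tip.label, names(trait))
  if (length(miss)) stop("no trait value for tips: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x <- trait[phy$tip.label]
  if (anyNA(x)) stop("non-finite trait values", call. = FALSE)
  x
}

#' Fit Brownian motion to a continuous trait
#'
#' Maximum likelihood under `x ~ MVN(z0 * 1, sigma2 * C)` with `C` the
#' shared-path matrix of the tree; `z0` (root state) and `sigma2` (rate) have
#' closed-form GLS/profile estimates. Works on non-ultrametric trees.
#'
#' @param phy a `phylo` tree.
#' @param trait numeric vector of tip values, named by taxon (or in tip
#'   order if unnamed).
#' @return an object of class `evomodel` with elements `model`,
#'   `parameters` (`sigma2`, `z0`), `lnL`, `k` (= 2), `AIC`, `n`.
#' @export
fit_bm <- function(phy, trait) {
  phy <- validate_phylo(phy)
  x <- match_trait(phy, trait)
  C <- shared_path_matrix(phy)
  p <- gls_profile_loglik(x, C, phy$tip.label)
  note <- if (p$degenerate) "degenerate: trait variance at zero boundary"
  new_evomodel("BM", c(sigma2 = p$sigma2, z0 = p$z0),
               if (p$degenerate) NA_real_ else p$lnL, 2L, length(x), note)
}

# OU correlation-shaped tip covariance (unit sigma^2): on a possibly
# non-ultrametric tree with the root fixed at the optimum,
#   Cov(i,j)/sigma^2 = exp(-a d_ij) (1 - exp(-2 a t_ij)) / (2 a)
# where d_ij is patristic distance and t_ij the root-to-MRCA time.
# The a -> 0 limit is the BM shared-path matrix.
ou_shape <- function(alpha, D, C) {
  if (alpha == 0) return(C)
  exp(-alpha * D) * (-expm1(-2 * alpha * C)) / (2 * alpha)
}

#' Fit a single-optimum Ornstein-Uhlenbeck model
#'
#' ML over (`alpha`, `sigma2`, `z0`) for an OU process whose root state is
#' fixed at the optimum, on a possibly non-ultrametric tree: fossil tips
#' accumulate stationary variance only over their own depth. `z0` and
#' `sigma2` are profiled analytically; `alpha` is found by a deterministic
#' multi-start bounded search on `log(alpha)` in [-10, 10] (per unit branch
#' time) unless supplied fixed.
#'
#' @param phy a `phylo` tree.
#' @param trait tip values as in [fit_bm()].
#' @param alpha `NULL` (estimate, default) or a fixed non-negative rate.
#' @param n_starts number of multi-start intervals across the `log(alpha)`
#'   range (default 5).
#' @return an `evomodel` with parameters `alpha`, `sigma2`, `z0` and `k = 3`.
#' @export
fit_ou <- function(phy, trait, alpha = NULL, n_starts = 5L) {
  phy <- validate_phylo(phy)
  x <- match_trait(phy, trait)
  D <- patristic_matrix(phy)
  C <- shared_path_matrix(phy)
  obj <- function(la) {
    p <- gls_profile_loglik(x, ou_shape(exp(la), D, C), phy$tip.label)
    if (!is.finite(p$lnL)) 1e10 else -p$lnL
  }
  if (!is.null(alpha)) {
    if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
    a_hat <- alpha
  } else {
    lo <- -10; hi <- 10
    cuts <- seq(lo, hi, length.out = n_starts + 1L)
    best <- NULL
    for (i in seq_len(n_starts)) {
      o <- stats::optimize(obj, c(cuts[i], cuts[i + 1L]), tol = 1e-8)
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    if (!is.finite(best$objective))
      stop("OU optimisation failed to find a finite likelihood; best log-alpha ",
           signif(best$minimum, 4), call. = FALSE)
    a_hat <- exp(best$minimum)
  }
  p <- gls_profile_loglik(x, ou_shape(a_hat, D, C), phy$tip.label)
  note <- if (p$degenerate) "degenerate: trait variance at zero boundary"
  new_evomodel("OU", c(alpha = a_hat, sigma2 = p$sigma2, z0 = p$z0),
               if (p$degenerate) NA_real_ else p$lnL, 3L, length(x), note)
}

#' Fit white noise (no phylogenetic signal)
#'
#' iid Normal maximum likelihood: mean = sample mean, variance = ML variance
#' (divisor n). Tree-independent by construction.
#'
#' @param trait numeric tip values (n >= 2).
#' @return an `evomodel` with parameters `sigma2`, `z0` and `k = 2`.
#' @export
fit_wn <- function(trait) {
  x <- as.numeric(trait)
  n <- length(x)
  if (n < 2L) stop("need at least two values", call. = FALSE)
  m <- mean(x)
  s2 <- sum((x - m)^2) / n
  if (s2 == 0)
    return(new_evomodel("WN", c(sigma2 = 0, z0 = m), NA_real_, 2L, n,
                        "degenerate: zero variance"))
  lnL <- -(n / 2) * (log(2 * pi * s2) + 1)
  new_evomodel("WN", c(sigma2 = s2, z0 = m), lnL, 2L, n)
}

#' Akaike weights across a set of fitted models
#'
#' `w_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2))` with
#' `Delta_m = AIC_m - min(AIC)`.
#'
#' @param fits a list of `evomodel` objects, or a numeric vector of AIC
#'   values (optionally named).
#' @return named numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(fits) {
  aic <- if (is.numeric(fits)) fits
         else vapply(fits, function(f) f$AIC, 0)
  if (is.null(names(aic)) && is.list(fits))
    names(aic) <- vapply(fits, function(f) f$model, "")
  if (length(aic) < 2L) stop("need at least two models", call. = FALSE)
  d <- aic - min(aic, na.rm = TRUE)
  w <- exp(-d / 2)
  w[is.na(w)] <- 0
  w / sum(w)
}

#' Fit BM, OU and WN and select by Akaike weight
#'
#' @param phy a `phylo` tree.
#' @param trait tip values as in [fit_bm()].
#' @return a list with `fits` (named list of `evomodel`), `table`
#'   (data.frame of model, k, lnL, AIC, weight) and `best` (model name with
#'   the highest weight).
#' @export
compare_evomodels <- function(phy, trait) {
  fits <- list(BM = fit_bm(phy, trait),
               OU = fit_ou(phy, trait),
               WN = fit_wn(match_trait(validate_phylo(phy), trait)))
  w <- akaike_weights(fits)
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, function(f) f$k, 0L),
                    lnL = vapply(fits, function(f) f$lnL, 0),
                    AIC = vapply(fits, function(f) f$AIC, 0),
                    weight = as.numeric(w))
  rownames(tab) <- NULL
  list(fits = fits, table = tab, best = tab$model[which.max(tab$weight)])
}

#' @export
print.evomodel <- function(x, ...) {
  cat(sprintf("%s model fit (n = %d)\n", x$model, x$n))
  print(signif(x$parameters, 6))
  cat(sprintf("lnL = %.4f, k = %d, AIC = %.4f\n", x$lnL, x$k, x$AIC))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
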