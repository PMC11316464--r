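#' Run the full foramen-to-metabolic-rate analysis pipeline
#'
#' One call executing the analysis graph end to end: aggregate specimens to
#' taxon flow values; fit BM/OU/WN to log10 mass and log10 flow and select
#' the PGLS correlation structure by Akaike weight; fit common-slope and
#' interaction PGLS models and compare them; test whitened-residual
#' normality; run the pairwise phylogenetic ANCOVA with flow ratios; fit
#' the multivariate OU model of (MMR, flow, mass) against its BM analogue;
#' impute missing MMR at fossil tips and reconstruct ancestral states; and
#' score observed-versus-predicted MMR by leave-one-out. Every stochastic
#' stage consumes the configured seed, so reruns are identical.
#'
#' @param specimens specimen data.frame (see [read_specimens()]), or `NULL`
#'   if `taxa` already carries flow values.
#' @param taxa taxon data.frame with `taxon`, `group`, `bm` (g); optional
#'   `mmr` (mL O2 h^-1) or `log_mmr`; optional `qdot`/`log_qdot` if
#'   `specimens` is `NULL`.
#' @param tree a `phylo` tree (or newick path handed to [read_phylo()]).
#' @param index `"qdot"` (default) to analyse the polynomial flow rate, or
#'   `"qi"` to replicate the analyses on the legacy index.
#' @param seed seed for the residual-normality Monte Carlo.
#' @param nsim_lilliefors null replicates for the Lilliefors p-value.
#' @param mvou_A_structure pull-matrix structure for the multivariate fit.
#' @return an object of class `pipeline_report` (a list of per-stage
#'   results; see `print` method).
#' @export
run_pipeline <- function(specimens, taxa, tree, index = c("qdot", "qi"),
                         seed = 1L, nsim_lilliefors = 10000L,
                         mvou_A_structure = "diagonal") {
  index <- match.arg(index)
  if (is.character(tree)) tree <- read_phylo(tree)
  tree <- validate_phylo(tree)
  stage <- "aggregate"
  rep_out <- list(schema = "foramenflow-report-1", seed = seed,
                  index = index)
  tryCatch({
    taxa$taxon <- trimws(as.character(taxa$taxon))
    if (!is.null(specimens)) {
      agg <- aggregate_taxa(specimens)
      taxa <- merge(taxa, agg, by = "taxon")
    }
    flow_col <- if (index == "qdot") {
      if ("qdot_cm3_s" %in% names(taxa)) "qdot_cm3_s" else "qdot"
    } else "qi"
    if (!flow_col %in% names(taxa))
      stop("no '", flow_col, "' column after aggregation")
    taxa$log_flow <- log10(taxa[[flow_col]])
    taxa$log_bm <- log10(taxa$bm)
    if (!"log_mmr" %in% names(taxa))
      taxa$log_mmr <- if ("mmr" %in% names(taxa)) log10(taxa$mmr)
                      else NA_real_
    keep <- intersect(taxa$taxon, tree$tip.label)
    dropped <- setdiff(taxa$taxon, keep)
    taxa <- taxa[taxa$taxon %in% keep, , drop = FALSE]
    tree_p <- ape::keep.tip(tree, keep)
    rep_out$data <- list(n_taxa = nrow(taxa), dropped_taxa = dropped,
                         tree = tree_check(tree_p))

    stage <- "evolutionary_models"
    xb <- stats::setNames(taxa$log_bm, taxa$taxon)
    xq <- stats::setNames(taxa$log_flow, taxa$taxon)
    mb <- compare_evomodels(tree_p, xb)
    mq <- compare_evomodels(tree_p, xq)
    rep_out$model_selection <- list(log_bm = mb$table, log_flow = mq$table,
                                    best_bm = mb$best, best_flow = mq$best)
    use_identity <- mq$best == "WN"

    stage <- "pgls"
    taxa$group <- factor(taxa$group)
    alpha_arg <- if (use_identity) Inf else "ML"
    fit0 <- pgls(log_flow ~ log_bm + group, taxa, tree_p, alpha = alpha_arg)
    fit1 <- pgls(log_flow ~ log_bm * group, taxa, tree_p, alpha = alpha_arg)
    cmp <- compare_pgls(fit0, fit1)
    eq <- group_intercepts(fit0, "group")
    eq$slope <- unname(coef(fit0)["log_bm"])
    rep_out$pgls <- list(
      correlation = if (use_identity) "identity" else "OU",
      alpha = fit0$alpha, common_slope = eq$slope[1],
      equations = eq[, c("group", "slope", "intercept", "se")],
      model_comparison = cmp)

    stage <- "residual_normality"
    norm <- whitened_residual_normality(fit0, nsim = nsim_lilliefors,
                                        seed = seed)
    rep_out$residual_normality <- norm[c("statistic", "p_value", "nsim")]

    stage <- "ancova"
    rep_out$ancova <- pairwise_ancova(fit0, "group")
    rep_out$ols <- ols_reference(taxa, "log_flow", "log_bm")[c("slope",
                                                               "intercept")]

    stage <- "mvou"
    tm <- as.matrix(taxa[, c("log_mmr", "log_flow", "log_bm")])
    rownames(tm) <- taxa$taxon
    n_mmr <- sum(is.finite(tm[, "log_mmr"]))
    if (n_mmr >= 3L) {
      cmpm <- compare_mvou(tree_p, tm, A_structure = mvou_A_structure)
      fit_m <- cmpm[[cmpm$best]]
      rep_out$mvou <- list(delta_AIC_bm_minus_ou = cmpm$delta_AIC,
                           best = cmpm$best, A = fit_m$A,
                           Sigma = fit_m$Sigma, theta = fit_m$theta,
                           lnL = fit_m$lnL)
      stage <- "mmr_estimates"
      imp <- estimate_missing(fit_m, include_observed = TRUE)
      imp <- imp[imp$trait == "log_mmr", , drop = FALSE]
      anc <- ancestral_states(fit_m)
      loo <- loo_estimates(fit_m, "log_mmr")
      r2 <- if (nrow(loo) >= 3L)
        tryCatch(prediction_r2(loo$observed, loo$predicted),
                 error = function(e) NA_real_) else NA_real_
      rep_out$mmr <- list(tip_estimates = imp,
                          ancestral = anc[anc$trait == "log_mmr", ],
                          loo = loo, r2_observed_vs_predicted = r2)
    } else {
      rep_out$mvou <- list(skipped = "fewer than 3 taxa with observed MMR")
    }
    structure(rep_out, class = "pipeline_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("foramenflow pipeline report (seed", x$seed, ", index", x$index, ")\n")
  cat(sprintf("  taxa: %d; tree: %d tips (%d extinct)\n",
              x$data$n_taxa, x$data$tree$n_tips, x$data$tree$n_extinct))
  cat("  best evolutionary model  log_bm:", x$model_selection$best_bm,
      " log_flow:", x$model_selection$best_flow, "\n")
  cat(sprintf("  PGLS (%s correlation, alpha = %.4g): common slope %.4f\n",
              x$pgls$correlation, x$pgls$alpha, x$pgls$common_slope))
  eq <- x$pgls$equations
  for (i in seq_len(nrow(eq)))
    cat(sprintf("    %-24s log_flow = %.3f*log_bm %+.3f\n",
                eq$group[i], eq$slope[i], eq$intercept[i]))
  cmp <- x$pgls$model_comparison
  cat(sprintf("  interaction: p = %.4f, dAIC = %.2f, dBIC = %.2f -> %s\n",
              cmp$p_interaction, cmp$delta_AIC, cmp$delta_BIC,
              cmp$preferred))
  cat(sprintf("  whitened-residual Lilliefors p = %.4f\n",
              x$residual_normality$p_value))
  an <- x$ancova
  for (i in seq_len(nrow(an)))
    cat(sprintf("    %s vs %s: z = %+.2f, p_adj = %.4f, ratio = %.2f\n",
                an$group_a[i], an$group_b[i], an$z[i], an$p_bonferroni[i],
                an$flow_ratio[i]))
  if (!is.null(x$mvou$best)) {
    cat(sprintf("  multivariate fit: %s preferred (dAIC BM-OU = %.2f)\n",
                x$mvou$best, x$mvou$delta_AIC_bm_minus_ou))
    if (!is.null(x$mmr))
      cat(sprintf("  MMR leave-one-out R^2 = %.3f; %d tip estimates, %d nodes\n",
                  x$mmr$r2_observed_vs_predicted,
                  nrow(x$mmr$tip_estimates), nrow(x$mmr$ancestral)))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (full report), `equations.csv` and `contrasts.csv`
#' (the Table-1-shaped summaries), per-tip and per-node MMR estimate CSVs,
#' and an annotated newick whose internal node labels carry the ancestral
#' MMR means.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @param tree the (pruned) analysis tree, required for the annotated
#'   newick; omit to skip it.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, tree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$pgls$equations,
                   file.path(dir, "equations.csv"), row.names = FALSE)
  utils::write.csv(report$ancova, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  if (!is.null(report$mmr)) {
    utils::write.csv(report$mmr$tip_estimates,
                     file.path(dir, "mmr_tips.csv"), row.names = FALSE)
    utils::write.csv(report$mmr$ancestral,
                     file.path(dir, "mmr_nodes.csv"), row.names = FALSE)
    if (!is.null(tree)) {
      anc <- report$mmr$ancestral
      lab <- anc$mean[match(paste0("node_", ape::Ntip(tree) +
                                     seq_len(tree$Nnode)), anc$node)]
      tree$node.label <- sprintf("%.4f", lab)
      ape::write.tree(tree, file.path(dir, "mmr_annotated.nwk"))
    }
  }
  json <- report
  class(json) <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
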