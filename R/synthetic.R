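#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator with defaults that
#' emulate the design of the empirical study: an 88-tip mammal tree (69
#' extant, 19 fossil tips cut short of the present), log10 body mass
#' evolving by Brownian motion, log10 flow following a common-slope
#' group-intercept allometry (slope 0.74; group intercepts -5.31 Epitheria,
#' -5.47 non-placentals, -5.77 extant Xenarthra, -5.35 fossil giant
#' xenarthrans) with OU-correlated residuals, and log10 MMR coupled to both
#' through a multivariate OU model. Fossil tips lack MMR.
#'
#' @param n_extant,n_fossil tip counts (defaults 69 and 19).
#' @param birth pure-birth speciation rate used to grow the tree shape.
#' @param tree_height root-to-present depth the tree is rescaled to, Ma.
#' @param fossil_depth_range fossil tips end between these fractions of
#'   tree height before the present (default 0.01–0.6).
#' @param slope common allometric slope of log10 flow on log10 mass.
#' @param intercepts named per-group intercepts (log10 cm^3 s^-1).
#' @param ou_alpha,ou_sigma OU rate (1/Ma) and stationary sd (log10 units)
#'   of the allometry residuals.
#' @param bm_root,bm_sigma2 root state and BM rate of log10 body mass (g).
#' @param A,Sigma,theta multivariate OU pull, diffusion and optimum for
#'   (log10 MMR, log10 flow, log10 mass); defaults couple MMR strongly to
#'   the other two.
#' @param mmr_observed_frac fraction of *extant* tips with observed MMR
#'   (fossil tips never have it).
#' @param specimens_per_taxon femora sampled per taxon.
#' @param noise_sd specimen-level measurement noise sd on log10 lumen
#'   radius (mm).
#' @param two_foramen_prob probability a specimen carries two foramina.
#' @param occupancy arterial lumen occupancy of the foramen area.
#' @param length_intercept,length_noise_sd log-linear femur-length model:
#'   `log10 L = log10(Bm)/3 + length_intercept + N(0, length_noise_sd)`.
#' @param seed mandatory RNG seed; each stage derives its own substream.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_extant = 69L, n_fossil = 19L, birth = 0.1,
                       tree_height = 180,
                       fossil_depth_range = c(0.01, 0.6),
                       slope = 0.74,
                       intercepts = c(Epitheria = -5.31,
                                      `Prototheria+Metatheria` = -5.47,
                                      Xenarthra = -5.77,
                                      Xenarthra_fossil = -5.35),
                       ou_alpha = 0.02, ou_sigma = 0.25,
                       bm_root = 4, bm_sigma2 = 0.01,
                       A = diag(0.01, 3),
                       Sigma = NULL, theta = c(4.7, -2.35, 4),
                       mmr_observed_frac = 1,
                       specimens_per_taxon = 2L, noise_sd = 0.05,
                       two_foramen_prob = 0.04, occupancy = 0.20,
                       length_intercept = 0.77, length_noise_sd = 0.03,
                       seed = 1L) {
  if (is.null(Sigma)) {
    # stationary sds (1.2, 1.5, 1.3) log10 units with strong correlations
    sds <- c(1.2, 1.5, 1.3)
    R <- matrix(c(1, .9, .85,
                  .9, 1, .9,
                  .85, .9, 1), 3, 3)
    Sstat <- diag(sds) %*% R %*% diag(sds)
    Sigma <- 2 * A %*% Sstat        # Sigma = 2 alpha * stationary cov
    Sigma <- (Sigma + t(Sigma)) / 2
  }
  stopifnot(n_extant >= 2L, n_fossil >= 0L, birth > 0, tree_height > 0,
            ou_sigma > 0, bm_sigma2 > 0, length(seed) == 1L)
  structure(list(n_extant = as.integer(n_extant),
                 n_fossil = as.integer(n_fossil), birth = birth,
                 tree_height = tree_height,
                 fossil_depth_range = fossil_depth_range, slope = slope,
                 intercepts = intercepts, ou_alpha = ou_alpha,
                 ou_sigma = ou_sigma, bm_root = bm_root,
                 bm_sigma2 = bm_sigma2, A = A, Sigma = Sigma, theta = theta,
                 mmr_observed_frac = mmr_observed_frac,
                 specimens_per_taxon = as.integer(specimens_per_taxon),
                 noise_sd = noise_sd, two_foramen_prob = two_foramen_prob,
                 occupancy = occupancy, length_intercept = length_intercept,
                 length_noise_sd = length_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# correlated MVN draw given a covariance
rmvn_chol <- function(mu, V) {
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  drop(mu + ev$vectors %*% (sqrt(ev$values) * stats::rnorm(length(mu))))
}

#' Simulate a time-scaled tree with fossil tips
#'
#' Grows a pure-birth tree with `n_extant + n_fossil` tips, rescales it to
#' `tree_height`, then truncates `n_fossil` terminal branches inside one
#' clade so those tips end before the present — the non-ultrametric shape
#' that fossil taxa grafted onto a molecular timetree produce. Fossil tips
#' are labelled `fossil_*`, extant tips `taxon_*`. Deterministic under the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return a `phylo` tree.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_extant + config$n_fossil
  phy <- ape::rphylo(n, birth = config$birth, death = 0)
  phy$edge.length <- phy$edge.length * config$tree_height /
    max(ape::node.depth.edgelength(phy))
  phy$tip.label <- paste0("taxon_", seq_len(n))
  if (config$n_fossil > 0L) {
    fos <- pick_fossil_tips(phy, config$n_fossil)
    depths <- tip_depths(phy)
    h <- max(depths)
    u <- stats::runif(length(fos), config$fossil_depth_range[1],
                      config$fossil_depth_range[2])
    for (i in seq_along(fos)) {
      tip <- which(phy$tip.label == fos[i])
      e <- which(phy$edge[, 2] == tip)
      cut <- min(u[i] * h, phy$edge.length[e] - 1e-6 * h)
      if (cut > 0) phy$edge.length[e] <- phy$edge.length[e] - cut
    }
    phy$tip.label[phy$tip.label %in% fos] <-
      paste0("fossil_", seq_along(fos))
  }
  phy
}

# choose fossil tips from within one clade so fossil status and phylogeny
# are confounded, as in the real design
pick_fossil_tips <- function(phy, n_fossil) {
  n <- ape::Ntip(phy)
  sizes <- vapply((n + 1L):(n + phy$Nnode), function(nd)
    length(tip_indices(phy, nd)), 0L)
  # keep at least two extant members in the fossil-bearing clade so the
  # extant-xenarthran group is always estimable
  cand <- which(sizes >= n_fossil + 2L & sizes <= max(n_fossil + 2L,
                                                      floor(2 * n / 3)))
  if (!length(cand)) cand <- which(sizes >= n_fossil + 2L)
  if (!length(cand)) cand <- which(sizes >= n_fossil + 1L)
  node <- n + sample(cand, 1L)
  tips <- phy$tip.label[tip_indices(phy, node)]
  sample(tips, n_fossil)
}

tip_indices <- function(phy, node) {
  n <- ape::Ntip(phy)
  if (node <= n) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, tip_indices, phy = phy))
}

#' Assign taxa to metabolic groups by clade
#'
#' Fossil tips form the `Xenarthra_fossil` group; the extant members of the
#' smallest clade containing all fossils become `Xenarthra`; one further
#' clade among the remaining tips is painted `Prototheria+Metatheria`; the
#' rest are `Epitheria`. Clade-based painting confounds group with
#' phylogeny on purpose — that is the structure the real data have, and the
#' regime the comparative methods must cope with.
#'
#' @param phy a tree from [simulate_tree()].
#' @param config a [sim_config()].
#' @return named character vector of group labels, one per tip.
#' @export
assign_groups <- function(phy, config) {
  set.seed(config$seed + 1000L)
  n <- ape::Ntip(phy)
  lab <- phy$tip.label
  grp <- stats::setNames(rep("Epitheria", n), lab)
  fossils <- grep("^fossil_", lab, value = TRUE)
  grp[fossils] <- "Xenarthra_fossil"
  if (length(fossils) >= 2L) {
    anc <- ape::getMRCA(phy, fossils)
    clade <- lab[tip_indices(phy, anc)]
    grp[setdiff(clade, fossils)] <- "Xenarthra"
  } else if (length(fossils) == 1L) {
    # sister tips of the lone fossil
    anc <- phy$edge[phy$edge[, 2] == which(lab == fossils), 1]
    clade <- lab[tip_indices(phy, anc)]
    grp[setdiff(clade, fossils)] <- "Xenarthra"
  }
  free <- names(grp)[grp == "Epitheria"]
  target <- max(2L, round(length(free) * 0.3))
  sizes <- vapply((n + 1L):(n + phy$Nnode), function(nd) {
    tips <- lab[tip_indices(phy, nd)]
    if (all(tips %in% free)) length(tips) else 0L
  }, 0L)
  ok <- which(sizes >= 2L & sizes <= length(free) - 2L)
  if (length(ok)) {
    pick <- ok[which.min(abs(sizes[ok] - target))]
    grp[lab[tip_indices(phy, n + pick)]] <- "Prototheria+Metatheria"
  } else if (length(free) >= 4L) {
    grp[sample(free, target)] <- "Prototheria+Metatheria"
  }
  grp
}

#' Simulate taxon traits under the group allometry
#'
#' log10 body mass evolves by Brownian motion on the tree; log10 flow is
#' `slope * log_bm + a_group + eps` with `eps` multivariate normal with OU
#' correlation; log10 MMR is drawn from the multivariate-OU conditional
#' given flow and mass, so all three traits carry the assumed joint
#' structure. MMR is reported observed for extant tips only (subsampled by
#' `mmr_observed_frac`); the generating truth is kept in `log_mmr_true`.
#'
#' @param phy tree from [simulate_tree()].
#' @param config a [sim_config()].
#' @param groups optional named group vector; default [assign_groups()].
#' @return data.frame: `taxon`, `group`, `log_bm`, `log_qdot`, `log_mmr`
#'   (NA where unobserved), `log_mmr_true`, `bm`, `qdot`.
#' @export
simulate_allometry <- function(phy, config, groups = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(groups)) groups <- assign_groups(phy, config)
  groups <- groups[phy$tip.label]
  miss <- setdiff(unique(groups), names(config$intercepts))
  if (length(miss)) stop("no intercept configured for group(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  set.seed(config$seed + 2000L)
  n <- ape::Ntip(phy)
  C <- shared_path_matrix(phy)
  log_bm <- rmvn_chol(rep(config$bm_root, n), config$bm_sigma2 * C)
  R <- ou_correlation_matrix(phy, config$ou_alpha)
  eps <- rmvn_chol(rep(0, n), config$ou_sigma^2 * R)
  log_qdot <- config$slope * log_bm + config$intercepts[groups] + eps
  log_mmr_true <- draw_mmr_conditional(phy, log_qdot, log_bm, config)
  log_mmr <- log_mmr_true
  fossil <- grepl("^fossil_", phy$tip.label)
  log_mmr[fossil] <- NA_real_
  if (config$mmr_observed_frac < 1) {
    ext <- which(!fossil)
    drop_n <- round((1 - config$mmr_observed_frac) * length(ext))
    if (drop_n > 0L) log_mmr[sample(ext, drop_n)] <- NA_real_
  }
  data.frame(taxon = phy$tip.label, group = unname(groups),
             log_bm = unname(log_bm), log_qdot = unname(log_qdot),
             log_mmr = unname(log_mmr), log_mmr_true = unname(log_mmr_true),
             bm = 10^unname(log_bm), qdot = 10^unname(log_qdot),
             stringsAsFactors = FALSE)
}

# conditional draw of trait 1 (MMR) given traits 2..3 under the configured
# multivariate OU joint covariance
draw_mmr_conditional <- function(phy, log_qdot, log_bm, config) {
  n <- ape::Ntip(phy)
  st <- node_shared_times(phy, "tips")
  V <- mvou_covariance(st$C, config$A, config$Sigma)
  i1 <- seq_len(n)
  i23 <- (n + 1L):(3L * n)
  obs <- c(log_qdot, log_bm) - rep(config$theta[2:3], each = n)
  V22 <- V[i23, i23]
  Rch <- chol(V22 + diag(1e-10 * mean(diag(V22)), 2L * n))
  K <- backsolve(Rch, forwardsolve(t(Rch), obs))
  mu <- config$theta[1] + drop(V[i1, i23] %*% K)
  W <- forwardsolve(t(Rch), t(V[i1, i23, drop = FALSE]))
  Vc <- V[i1, i1] - crossprod(W)
  rmvn_chol(mu, Vc)
}

#' Simulate traits directly under a multivariate OU model
#'
#' Exact joint draw of all p traits at the tips (root fixed at `theta`),
#' used for model-recovery experiments where the fitted model must be
#' well-specified.
#'
#' @param phy a `phylo` tree.
#' @param A,Sigma,theta model parameters (see [mvou()]).
#' @param trait_names column names (default `c("log_mmr","log_qdot","log_bm")`
#'   truncated/extended to p).
#' @param seed RNG seed.
#' @return n x p matrix with taxon rownames.
#' @export
simulate_mvou_traits <- function(phy, A, Sigma, theta,
                                 trait_names = NULL, seed = 1L) {
  set.seed(seed)
  phy <- validate_phylo(phy)
  n <- ape::Ntip(phy)
  p <- length(theta)
  st <- node_shared_times(phy, "tips")
  V <- mvou_covariance(st$C, A, Sigma)
  y <- rmvn_chol(rep(theta, each = n), V)
  out <- matrix(y, n, p)
  rownames(out) <- phy$tip.label
  colnames(out) <- if (!is.null(trait_names)) trait_names
                   else c("log_mmr", "log_qdot", "log_bm")[seq_len(p)]
  out
}

#' Emit a specimen table consistent with taxon flow values
#'
#' For each taxon, draws `specimens_per_taxon` femora. Each specimen's
#' lumen radius is the taxon value `inverse_qdot(qdot)` perturbed by
#' log-normal measurement noise, converted back to foramen minor
#' diameter(s) by exactly inverting the occupancy and circular-area rules;
#' occasionally a specimen carries two foramina that split the area. Femur
#' length follows geometric similarity, `log10 L = log10(Bm)/3 + c`, with
#' noise. With `noise_sd = 0` and one specimen per taxon the measurement
#' chain reproduces the input flow exactly.
#'
#' @param table taxon table from [simulate_allometry()] (needs `taxon`,
#'   `qdot`, `bm`).
#' @param config a [sim_config()].
#' @return specimen data.frame with the columns [read_specimens()] expects
#'   plus the parsed `diameters` list column.
#' @export
emit_specimens <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3000L)
  rows <- list()
  for (i in seq_len(nrow(table))) {
    r0 <- inverse_qdot(table$qdot[i])
    L <- 10^(log10(table$bm[i]) / 3 + config$length_intercept +
               stats::rnorm(1, 0, config$length_noise_sd))
    for (k in seq_len(config$specimens_per_taxon)) {
      r <- r0 * 10^stats::rnorm(1, 0, config$noise_sd)
      area <- pi * r^2 / config$occupancy
      areas <- if (stats::runif(1) < config$two_foramen_prob) {
        f <- stats::runif(1, 0.3, 0.7)
        c(f, 1 - f) * area
      } else area
      d <- 2 * sqrt(areas / pi)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = table$taxon[i],
        specimen_id = paste0(table$taxon[i], "_s", k),
        foramen_minor_diameters_mm = paste(format(d, digits = 17),
                                           collapse = ";"),
        femur_length_mm = L, adult = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$diameters <- lapply(strsplit(out$foramen_minor_diameters_mm, ";"),
                          as.numeric)
  out
}

#' Generate a complete synthetic study bundle
#'
#' Tree, taxon table and specimen table with consistent structure, plus the
#' generating truth, optionally written to disk as plain-text files
#' (`tree.nwk`, `taxa.csv`, `specimens.csv`, `truth.json`).
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `tree`, `taxa`, `specimens`, `truth` (generating
#'   parameters), `config`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  tree <- simulate_tree(config)
  taxa <- simulate_allometry(tree, config)
  specimens <- emit_specimens(taxa, config)
  truth <- list(slope = config$slope, intercepts = as.list(config$intercepts),
                ou_alpha = config$ou_alpha, ou_sigma = config$ou_sigma,
                bm_root = config$bm_root, bm_sigma2 = config$bm_sigma2,
                theta = config$theta, seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    utils::write.csv(taxa, file.path(out_dir, "taxa.csv"), row.names = FALSE)
    sp <- specimens[, setdiff(names(specimens), "diameters")]
    utils::write.csv(sp, file.path(out_dir, "specimens.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tree = tree, taxa = taxa, specimens = specimens, truth = truth,
       config = config)
}
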