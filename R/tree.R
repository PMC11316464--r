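#' Read and validate a time-scaled phylogeny
#'
#' Reads a newick tree (from a file path or a literal newick string) into an
#' [ape::phylo] object and validates it for comparative analysis: the tree
#' must be rooted, every edge must carry a non-negative branch length, and
#' tip labels must be unique. Trees may be non-ultrametric — fossil tips
#' whose root-to-tip depth falls short of the maximum are the normal case in
#' palaeontological datasets, not an error.
#'
#' Tip labels are trimmed of surrounding whitespace so that exact-string
#' matching against trait tables is robust to sloppy newick export.
#'
#' @param source path to a newick file, or a character string that itself is
#'   newick (detected by the presence of a `(`).
#' @return an object of class `phylo`.
#' @examples
#' tr <- read_phylo("((A:1,B:1):1,C:2):0;")
#' tree_check(tr)
#' @export
read_phylo <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  phy <- if (grepl("(", source, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = source),
             error = function(e) stop("malformed newick: ", conditionMessage(e),
                                      call. = FALSE))
  } else {
    if (!file.exists(source)) stop("no such tree file: ", source, call. = FALSE)
    ape::read.tree(source)
  }
  if (is.null(phy)) stop("malformed newick: parser returned no tree", call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  validate_phylo(phy)
}

#' @keywords internal
validate_phylo <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths; time-scaled branch lengths are required",
         call. = FALSE)
  if (anyNA(phy$edge.length))
    stop("missing branch length on ", sum(is.na(phy$edge.length)), " edge(s)",
         call. = FALSE)
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  phy$tip.label <- trimws(phy$tip.label)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  term <- phy$edge[, 2] <= ape::Ntip(phy)
  if (any(phy$edge.length[term] == 0))
    warning("zero-length terminal branch(es): tips ",
            paste(phy$tip.label[phy$edge[term, 2][phy$edge.length[term] == 0]],
                  collapse = ", "),
            " are perfectly correlated with their sister under BM")
  phy
}

#' Root-to-tip depths
#'
#' @param phy a `phylo` tree.
#' @return named numeric vector of root-to-tip path lengths (time units).
#' @export
tip_depths <- function(phy) {
  d <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  names(d) <- phy$tip.label
  d
}

#' Summarise a tree for comparative analysis
#'
#' Reports tip count, which tips are extinct (root-to-tip depth below the
#' maximum depth by more than `tol`), and whether the tree is ultrametric at
#' that tolerance.
#'
#' @param phy a `phylo` tree.
#' @param tol depth tolerance (same units as branch lengths).
#' @return a list with `n_tips`, `n_extinct`, `extinct_tips`, `ultrametric`,
#'   `height` (maximum depth).
#' @export
tree_check <- function(phy, tol = 1e-6) {
  phy <- validate_phylo(phy)
  d <- tip_depths(phy)
  ext <- names(d)[d < max(d) - tol]
  list(n_tips = length(d), n_extinct = length(ext), extinct_tips = ext,
       ultrametric = length(ext) == 0L, height = max(d))
}

#' Shared-path (Brownian motion) covariance matrix
#'
#' Entry (i, j) is the total branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip depths.
#' Under Brownian motion with unit rate this is the expected tip covariance,
#' the "phylogenetic covariance matrix" of comparative methods. Valid for
#' non-ultrametric trees, where the diagonal is unequal.
#'
#' @param phy a `phylo` tree.
#' @return an n x n symmetric matrix with tip labels as dimnames.
#' @seealso [ou_correlation_matrix()] for the OU correlation used in PGLS.
#' @export
shared_path_matrix <- function(phy) {
  phy <- validate_phylo(phy)
  C <- ape::vcv.phylo(phy)
  C[phy$tip.label, phy$tip.label, drop = FALSE]
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param phy a `phylo` tree.
#' @return an n x n symmetric matrix with zero diagonal.
#' @export
patristic_matrix <- function(phy) {
  phy <- validate_phylo(phy)
  D <- ape::cophenetic.phylo(phy)
  D[phy$tip.label, phy$tip.label, drop = FALSE]
}

#' Ornstein-Uhlenbeck (Martins-Hansen) tip correlation matrix
#'
#' The OU-derived correlation structure used for PGLS ("corMartins"
#' convention): entry (i, j) is `exp(-alpha * d_ij)` with `d_ij` the
#' patristic distance between tips i and j, and unit diagonal. `alpha = 0`
#' gives a matrix of ones (no decay); large `alpha` approaches the identity
#' (phylogenetic independence).
#'
#' Branch lengths are taken in their own time units (typically Ma), so
#' `alpha` has units of 1/time. Set `normalize_height = TRUE` to rescale the
#' tree to unit height first, in which case `alpha` is per unit tree height.
#'
#' @param phy a `phylo` tree.
#' @param alpha non-negative OU rate.
#' @param normalize_height rescale branch lengths so the maximum root-to-tip
#'   depth is 1 before applying `alpha`. Default `FALSE`.
#' @return an n x n correlation matrix with tip labels as dimnames.
#' @export
ou_correlation_matrix <- function(phy, alpha, normalize_height = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  D <- patristic_matrix(phy)
  if (normalize_height) D <- D / max(tip_depths(phy))
  exp(-alpha * D)
}
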