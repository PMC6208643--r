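#' Simulate a pure-birth (Yule) phylogeny rescaled to unit height
#'
#' Simulates a rooted, binary, ultrametric tree under a pure-birth process
#' and rescales its root-to-tip height to exactly 1, so that node depths are
#' comparable across simulations and lie in \[0, 1\] (the domain required by
#' [delta_transform()]).
#'
#' The birth rate is fixed at 1; it is irrelevant after height rescaling.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @return An [ape::phylo] object with `n_tips` tips, height 1.
#' @examples
#' tr <- sim_yule_tree(10, seed = 1)
#' max(ape::node.depth.edgelength(tr)) # 1
#' @export
sim_yule_tree <- function(n_tips, seed = NULL) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || is.na(n_tips) ||
      n_tips < 2 || n_tips != round(n_tips)) {
    stop("`n_tips` must be a single integer >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(as.integer(n_tips), birth = 1, death = 0)
  rescale_tree_height(tr)
}

#' Rescale a tree to unit height
#'
#' Divides all branch lengths by the maximum root-to-tip depth.
#'
#' @param tree A phylo object with branch lengths.
#' @return The tree with height 1.
#' @export
rescale_tree_height <- function(tree) {
  check_phylo(tree)
  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Pagel's delta branch-length transformation
#'
#' Raises every node depth of a unit-height ultrametric tree to the power
#' `delta`: a node at depth-from-root d moves to d^delta. `delta < 1`
#' concentrates divergence near the root (stronger phylogenetic signal in
#' traits subsequently evolved on the tree), `delta > 1` concentrates it near
#' the tips (weaker signal). Topology and tip labels are unchanged; because
#' d^delta maps \[0, 1\] onto \[0, 1\], the output is again ultrametric with
#' height 1 and no post-hoc rescaling is applied.
#'
#' @param tree A unit-height ultrametric phylo object.
#' @param delta Positive real exponent.
#' @return The transformed phylo object.
#' @export
delta_transform <- function(tree, delta) {
  check_phylo(tree)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0) {
    stop("`delta` must be a single positive number")
  }
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth)
  if (abs(h - 1) > 1e-8) {
    stop("`tree` must have height 1 (see rescale_tree_height)")
  }
  newdepth <- pmin(depth, 1)^delta
  tree$edge.length <- newdepth[tree$edge[, 2L]] - newdepth[tree$edge[, 1L]]
  tree
}

#' Simulate Brownian-motion traits on a tree
#'
#' Evolves `n_traits` independent continuous traits by Brownian motion along
#' the branches, root state 0 and rate `sigma2` (variance accrued per unit
#' branch length). Tip values are jointly multivariate normal with covariance
#' `sigma2` times the shared-path-length matrix of the tree.
#'
#' @param tree A phylo object with branch lengths.
#' @param n_traits Number of independent traits (default 1).
#' @param sigma2 Brownian rate, trait-units^2 per unit time (default 1; all
#'   downstream statistics are scale-invariant).
#' @param seed Optional integer seed.
#' @return Numeric matrix, tips x traits, rownames = tip labels.
#' @export
sim_bm_traits <- function(tree, n_traits = 1L, sigma2 = 1, seed = NULL) {
  check_phylo(tree)
  if (!n_traits %in% c(1L, 2L, 4L) && !(is.numeric(n_traits) && n_traits >= 1)) {
    stop("`n_traits` must be a positive integer")
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 < 0) {
    stop("`sigma2` must be a nonnegative number")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- vapply(
    seq_len(n_traits),
    function(j) {
      ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2), root.value = 0)
    },
    numeric(length(tree$tip.label))
  )
  x <- matrix(x, nrow = length(tree$tip.label), ncol = n_traits,
              dimnames = list(tree$tip.label, paste0("trait", seq_len(n_traits))))
  x
}

#' Simulate a host trait with tunable phylogenetic signal
#'
#' Applies [delta_transform()] to the (unit-height) host tree, evolves
#' Brownian traits on the transformed tree, and measures the realized
#' phylogenetic signal of each trait with [blomberg_k()] computed on the
#' ORIGINAL, untransformed tree -- the tree all downstream phylogenetic
#' distances are taken from, so K describes signal relative to that tree.
#'
#' @inheritParams sim_bm_traits
#' @param delta Positive delta exponent (e.g. from the grid
#'   0.01, 0.1, 1, 10, 1000: small delta = strong signal).
#' @return A list with elements `traits` (tips x traits matrix), `k` (numeric
#'   vector of per-trait Blomberg K on the original tree) and `k_mean`
#'   (their mean, used for binning replicates when several traits filter
#'   jointly).
#' @export
sim_host_traits <- function(tree, delta, n_traits = 1L, sigma2 = 1, seed = NULL) {
  rescaled <- delta_transform(tree, delta)
  traits <- sim_bm_traits(rescaled, n_traits = n_traits, sigma2 = sigma2,
                          seed = seed)
  k <- blomberg_k(tree, traits)
  list(traits = traits, k = k, k_mean = mean(k))
}

#' Blomberg's K phylogenetic signal statistic
#'
#' K compares the observed ratio of the non-phylogenetic to the phylogenetic
#' mean squared error of a trait to its expectation under Brownian motion:
#' with C the shared-path-length (Brownian covariance) matrix and a-hat the
#' GLS estimate of the root state,
#' \deqn{K = \frac{[MSE_0/MSE]_{obs}}{(\mathrm{tr}\,C - n / \mathbf{1}'C^{-1}\mathbf{1}) / (n-1)}}
#' where \eqn{MSE_0 = \sum_i (x_i - \hat a)^2/(n-1)} and
#' \eqn{MSE = (x - \hat a)' C^{-1} (x - \hat a)/(n-1)}.
#' K near 1 is expected under Brownian motion on the given tree; K >> 1 means
#' stronger-than-Brownian signal and K near 0 no signal.
#'
#' @param tree A phylo object (>= 4 tips).
#' @param traits Named numeric vector, or tips x traits matrix with rownames
#'   matching the tip labels.
#' @return Numeric vector of K values, one per trait.
#' @export
blomberg_k <- function(tree, traits) {
  check_phylo(tree)
  n <- length(tree$tip.label)
  if (n < 4L) stop("Blomberg K requires at least 4 tips")
  if (is.null(dim(traits))) {
    traits <- matrix(traits, ncol = 1L,
                     dimnames = list(names(traits), "trait1"))
  }
  if (is.null(rownames(traits)) || !setequal(rownames(traits), tree$tip.label)) {
    stop("trait rownames must match the tree tip labels")
  }
  traits <- traits[tree$tip.label, , drop = FALSE]
  C <- ape::vcv(tree)
  Cinv <- solve(C)
  ones <- rep(1, n)
  denom_exp <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  apply(traits, 2L, function(x) {
    if (stats::var(x) == 0) stop("Blomberg K is undefined for a constant trait")
    a_hat <- sum(Cinv %*% x) / sum(Cinv)
    r <- x - a_hat
    mse0 <- sum(r^2) / (n - 1)
    mse <- drop(crossprod(r, Cinv %*% r)) / (n - 1)
    (mse0 / mse) / denom_exp
  })
}

#' Rescale microbial trait preferences into the host-trait range
#'
#' Per trait dimension, applies the affine min-max map taking the range of
#' the microbial values onto the range of the host values, so that microbial
#' niche preferences span exactly the realized host trait space. Order is
#' preserved. A constant microbial column (zero range) is mapped to the
#' midpoint of the host range.
#'
#' @param microbe_traits Tips x traits matrix of microbial preferences.
#' @param host_traits Tips x traits matrix of host trait values (same number
#'   of columns; nonzero range per column).
#' @return Rescaled microbial trait matrix (same shape and dimnames).
#' @export
rescale_microbe_traits <- function(microbe_traits, host_traits) {
  microbe_traits <- as.matrix(microbe_traits)
  host_traits <- as.matrix(host_traits)
  if (ncol(microbe_traits) != ncol(host_traits)) {
    stop("host and microbe trait tables must have the same number of traits")
  }
  if (nrow(microbe_traits) == 0L || nrow(host_traits) == 0L) {
    stop("trait tables must be non-empty")
  }
  out <- microbe_traits
  for (j in seq_len(ncol(out))) {
    hr <- range(host_traits[, j])
    if (diff(hr) == 0) stop("host trait range is zero; cannot rescale")
    mr <- range(microbe_traits[, j])
    if (diff(mr) == 0) {
      out[, j] <- mean(hr)
    } else {
      out[, j] <- hr[1L] + (microbe_traits[, j] - mr[1L]) / diff(mr) * diff(hr)
    }
  }
  out
}

# shared validation for phylo inputs
check_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape \"phylo\" object")
  if (is.null(tree$edge.length)) stop("`tree` must have branch lengths")
  invisible(tree)
}
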