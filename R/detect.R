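#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle vectors of the two
#' matrices, with a one-sided permutation p-value obtained by jointly
#' permuting rows and columns of `d2`:
#' `p = (#{permuted r >= observed r} + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 Symmetric distance matrices with matching labels (if `d2`
#'   carries dimnames it is reordered to match `d1`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param method Label stored in the result (internal use).
#' @return A `phylosym_test` object with fields `statistic` (Pearson r),
#'   `p_value`, `n_perm` and `null_model = "matrix_permutation"`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL,
                        method = "mantel") {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 4L) stop("Mantel test requires at least 4 labels")
  if (!all(dim(d1) == dim(d2))) stop("distance matrices must have equal size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2))) {
      stop("distance matrix labels do not match")
    }
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  lt <- lower.tri(d1)
  x <- d1[lt]
  y <- d2[lt]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("a distance matrix has zero variance in its lower triangle")
  }
  r_obs <- stats::cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  ij <- which(lt, arr.ind = TRUE)
  xc <- x - mean(x)
  denom <- sqrt(sum(xc^2) * sum((y - mean(y))^2))
  perms <- vapply(seq_len(n_perm), function(k) sample.int(n), integer(n))
  pi_ <- matrix(perms[ij[, 1L], ], nrow = nrow(ij))
  pj_ <- matrix(perms[ij[, 2L], ], nrow = nrow(ij))
  yperm <- matrix(d2[(pj_ - 1L) * n + pi_], nrow = nrow(ij))
  # permutation leaves the multiset of y values unchanged, so only the
  # cross-product term varies
  r_perm <- colSums(yperm * xc) / denom
  # tolerance so that permutations tied with the observed statistic count
  # as >= despite floating-point noise (matters for tiny label sets)
  p <- (sum(r_perm >= r_obs - sqrt(.Machine$double.eps)) + 1) / (n_perm + 1)
  new_phylosym_test(method = method, statistic = r_obs, p_value = p,
                    n_perm = n_perm, null_model = "matrix_permutation",
                    n = n, null_stats = r_perm)
}

#' Mantel test of host trait distance against community dissimilarity
#'
#' The sanity check for trait-driven filtering: `d1` is the Euclidean
#' distance between host trait vectors (absolute difference for a single
#' trait), `d2` the microbiota dissimilarity matrix.
#'
#' @param host_traits Hosts x traits matrix (rownames = host labels) or
#'   named vector.
#' @param d Community distance matrix over the same hosts.
#' @inheritParams mantel_test
#' @return A `phylosym_test` object (method `"trait_mantel"`).
#' @export
trait_mantel <- function(host_traits, d, n_perm = 999L, seed = NULL) {
  if (is.null(dim(host_traits))) {
    host_traits <- matrix(host_traits, ncol = 1L,
                          dimnames = list(names(host_traits), "trait1"))
  }
  d1 <- as.matrix(stats::dist(host_traits))
  mantel_test(d1, d, n_perm = n_perm, seed = seed, method = "trait_mantel")
}

#' UPGMA dendrogram of a distance matrix
#'
#' Average-linkage agglomerative clustering; merge heights equal half the
#' average inter-cluster distance, so the returned tree is ultrametric.
#'
#' @param d Symmetric distance matrix or `dist` object (>= 2 labels).
#' @return An ultrametric phylo object over the matrix labels.
#' @export
upgma <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 2L) stop("UPGMA requires at least 2 labels")
  ape::as.phylo(stats::hclust(d, method = "average"))
}

#' Normalized Robinson-Foulds distance between two rooted trees
#'
#' Size of the symmetric difference of the two trees' non-trivial clade sets
#' (descendant tip sets of internal nodes, excluding the root), divided by
#' the maximum `2(n - 2)` attainable by rooted binary trees. 0 means
#' identical topologies; 1 means no shared non-trivial clade. Branch lengths
#' are ignored.
#'
#' @param t1,t2 Rooted phylo objects with identical tip label sets
#'   (>= 4 tips).
#' @return Normalized RF distance in \[0, 1\].
#' @export
normalized_rf <- function(t1, t2) {
  if (!inherits(t1, "phylo") || !inherits(t2, "phylo")) {
    stop("inputs must be phylo objects")
  }
  labs <- t1$tip.label
  if (!setequal(labs, t2$tip.label)) stop("trees must share the same tip labels")
  n <- length(labs)
  if (n < 4L) stop("normalized RF requires at least 4 tips")
  k1 <- clade_keys(t1, labs)
  k2 <- clade_keys(t2, labs)
  shared <- sum(k1 %in% k2)
  (length(k1) + length(k2) - 2L * shared) / (2 * (n - 2))
}

# Non-trivial clades of a rooted tree as canonical string keys of sorted tip
# indices in the reference label ordering `labs`. Root (all tips) and
# singletons excluded.
clade_keys <- function(tree, labs) {
  idx <- match(tree$tip.label, labs)
  sets <- clade_index_sets(tree, idx)
  vapply(sets, function(s) paste(s, collapse = ","), character(1L))
}

# List of sorted tip-index sets for each non-trivial, non-root clade.
# `idx` maps the tree's own tip numbering into the reference ordering.
clade_index_sets <- function(tree, idx) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  acc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) acc[[i]] <- idx[i]
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    acc[[par]] <- c(acc[[par]], acc[[child]])
  }
  internal <- acc[(ntip + 1L):(ntip + tree$Nnode)]
  keep <- vapply(internal, function(s) length(s) > 1L && length(s) < ntip,
                 logical(1L))
  lapply(internal[keep], sort)
}

#' Dendrogram congruence test for phylosymbiosis
#'
#' Builds the UPGMA dendrogram of the community distance matrix, measures
#' its topological congruence with the host phylogeny by the normalized
#' Robinson-Foulds distance, and assesses significance with a one-sided
#' permutation null: either shuffling the host tree's tip labels
#' (`"tip_shuffle"`) or drawing fresh pure-birth topologies on the same
#' labels (`"random_trees"`).
#' `p = (#{null nRF <= observed} + 1) / (n_perm + 1)` -- low nRF indicates
#' phylosymbiosis.
#'
#' @param host_tree Host phylogeny (phylo).
#' @param d Community distance matrix over the host labels.
#' @param n_perm Number of null draws (default 999).
#' @param null_model `"tip_shuffle"` or `"random_trees"`.
#' @param seed Optional integer seed.
#' @return A `phylosym_test` object with `statistic` = observed normalized
#'   RF.
#' @export
dendrogram_test <- function(host_tree, d, n_perm = 999L,
                            null_model = c("tip_shuffle", "random_trees"),
                            seed = NULL) {
  null_model <- match.arg(null_model)
  check_phylo(host_tree)
  d <- as.matrix(d)
  labs <- host_tree$tip.label
  if (!is.null(rownames(d))) {
    if (!setequal(rownames(d), labs)) stop("distance labels must match host tips")
  }
  n <- length(labs)
  if (n < 4L) stop("dendrogram test requires at least 4 hosts")
  if (n > 52L) stop("dendrogram test supports at most 52 hosts")
  dend <- upgma(d)
  # clades encoded as exact numeric bitmasks: key(S) = sum over tips in S of
  # 2^(tip - 1); order-free and collision-free for n <= 52
  pw <- 2^(seq_len(n) - 1)
  dend_sets <- clade_index_sets(dend, match(dend$tip.label, labs))
  dend_keys <- vapply(dend_sets, function(s) sum(pw[s]), numeric(1L))
  host_sets <- clade_index_sets(host_tree, match(host_tree$tip.label, labs))
  H <- matrix(0, nrow = length(host_sets), ncol = n)
  for (i in seq_along(host_sets)) H[i, host_sets[[i]]] <- 1
  maxrf <- 2 * (n - 2)
  nrf_of_keys <- function(keys) {
    shared <- sum(keys %in% dend_keys)
    (length(keys) + length(dend_keys) - 2L * shared) / maxrf
  }
  obs <- nrf_of_keys(drop(H %*% pw))
  if (!is.null(seed)) set.seed(seed)
  null_stats <- if (null_model == "tip_shuffle") {
    # under a label permutation sigma, key(S) becomes sum of 2^(sigma - 1)
    # over S: one small matrix product per draw
    PW <- vapply(seq_len(n_perm), function(k) pw[sample.int(n)], numeric(n))
    K <- H %*% PW
    shared <- colSums(matrix(K %in% dend_keys, nrow = nrow(H)))
    (nrow(H) + length(dend_keys) - 2 * shared) / maxrf
  } else {
    vapply(seq_len(n_perm), function(k) {
      nrf_of_keys(random_join_keys(n, pw))
    }, numeric(1L))
  }
  p <- (sum(null_stats <= obs) + 1) / (n_perm + 1)
  new_phylosym_test(method = "dendrogram", statistic = obs, p_value = p,
                    n_perm = n_perm, null_model = null_model, n = n,
                    null_stats = null_stats)
}

# Bitmask keys of the non-trivial clades of a random rooted binary topology
# on n labelled tips, generated by sequential uniform pair-merging (the
# tree-shape distribution of this process coincides with the pure-birth /
# coalescent one). Merging two groups just adds their keys.
random_join_keys <- function(n, pw) {
  keys <- pw
  out <- numeric(n - 2L)
  k <- 0L
  m <- n
  while (m > 1L) {
    pick <- sample.int(m, 2L)
    merged <- keys[pick[1L]] + keys[pick[2L]]
    keys[pick[1L]] <- merged
    keys <- keys[-pick[2L]]
    m <- m - 1L
    if (m > 1L) {
      k <- k + 1L
      out[k] <- merged
    }
  }
  out[seq_len(k)]
}

#' Patristic (cophenetic) distances between tips
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree A phylo object with branch lengths.
#' @return Symmetric matrix with zero diagonal, labelled by tip.
#' @export
cophenetic_distances <- function(tree) {
  check_phylo(tree)
  ape::cophenetic.phylo(tree)
}

#' Test for phylosymbiosis in a host-microbiota data set
#'
#' The main user-facing entry point. Given a host phylogeny, a hosts x
#' microbes abundance table and (for UniFrac metrics) a microbial phylogeny,
#' computes the chosen beta-diversity matrix and applies the chosen
#' detection procedure:
#' \describe{
#'   \item{`"mantel"`}{Pearson correlation between host cophenetic distance
#'     and community dissimilarity, permutation null on the community
#'     matrix.}
#'   \item{`"dendrogram"`}{Normalized Robinson-Foulds distance between the
#'     host tree and the UPGMA dendrogram of the community dissimilarities,
#'     tip-shuffle (or random-trees) null.}
#'   \item{`"trait_mantel"`}{Pearson correlation between host *trait*
#'     distance and community dissimilarity (requires `host_traits`); the
#'     positive control when a measured trait drives filtering.}
#' }
#'
#' @param host_tree Host phylogeny (phylo; tips = rownames of `table`).
#' @param table Hosts x microbes abundance matrix.
#' @param method `"mantel"`, `"dendrogram"` or `"trait_mantel"`.
#' @param metric Beta-diversity metric passed to [distance_matrix()].
#' @param microbe_tree Microbial phylogeny (required for UniFrac metrics).
#' @param host_traits Hosts x traits matrix, required for
#'   `method = "trait_mantel"`.
#' @param n_perm Number of permutations (default 999).
#' @param null_model Null model for the dendrogram method.
#' @param seed Optional integer seed.
#' @return A `phylosym_test` object.
#' @examples
#' tr <- sim_yule_tree(10, seed = 1)
#' mt <- sim_yule_tree(40, seed = 2)
#' ht <- sim_host_traits(tr, delta = 0.1, seed = 3)
#' mp <- rescale_microbe_traits(sim_bm_traits(mt, seed = 4), ht$traits)
#' tab <- assemble_system(ht$traits, mp, assembly_params(), seed = 5)
#' phylosymbiosis_test(tr, tab, method = "mantel", metric = "wunifrac",
#'                     microbe_tree = mt, n_perm = 99, seed = 6)
#' @export
phylosymbiosis_test <- function(host_tree, table,
                                method = c("mantel", "dendrogram",
                                           "trait_mantel"),
                                metric = c("wunifrac", "uunifrac", "jaccard",
                                           "braycurtis"),
                                microbe_tree = NULL, host_traits = NULL,
                                n_perm = 999L,
                                null_model = c("tip_shuffle", "random_trees"),
                                seed = NULL) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  check_phylo(host_tree)
  table <- as.matrix(table)
  if (!setequal(rownames(table), host_tree$tip.label)) {
    stop("table rownames must match the host tree tip labels")
  }
  d <- distance_matrix(table, metric = metric, tree = microbe_tree)
  res <- switch(
    method,
    mantel = mantel_test(cophenetic_distances(host_tree), d,
                         n_perm = n_perm, seed = seed),
    dendrogram = dendrogram_test(host_tree, d, n_perm = n_perm,
                                 null_model = match.arg(null_model),
                                 seed = seed),
    trait_mantel = {
      if (is.null(host_traits)) {
        stop("`host_traits` is required for the trait Mantel test")
      }
      trait_mantel(host_traits, d, n_perm = n_perm, seed = seed)
    }
  )
  res$metric <- metric
  res
}

new_phylosym_test <- function(method, statistic, p_value, n_perm, null_model,
                              n, null_stats = NULL, metric = NA_character_) {
  structure(
    list(method = method, metric = metric, statistic = statistic,
         p_value = p_value, n_perm = as.integer(n_perm),
         null_model = null_model, n = as.integer(n),
         null_stats = null_stats),
    class = "phylosym_test"
  )
}

#' @export
print.phylosym_test <- function(x, ...) {
  statname <- if (x$method == "dendrogram") "normalized RF" else "Pearson r"
  cat("Phylosymbiosis test\n")
  cat(sprintf("  method: %s%s\n", x$method,
              if (!is.na(x$metric)) paste0(" (", x$metric, ")") else ""))
  cat(sprintf("  %s = %.4f\n", statname, x$statistic))
  cat(sprintf("  p = %.4g  (%d permutations, %s null, one-sided)\n",
              x$p_value, x$n_perm, x$null_model))
  invisible(x)
}

#' @export
summary.phylosym_test <- function(object, alpha = 0.05, ...) {
  out <- object
  out$alpha <- alpha
  out$significant <- object$p_value < alpha
  class(out) <- c("summary.phylosym_test", "phylosym_test")
  out
}

#' @export
print.summary.phylosym_test <- function(x, ...) {
  NextMethod()
  cat(sprintf("  significant at alpha = %g: %s\n", x$alpha,
              if (x$significant) "yes" else "no"))
  if (!is.null(x$null_stats)) {
    q <- stats::quantile(x$null_stats, c(0.025, 0.5, 0.975))
    cat(sprintf("  null statistic quantiles: 2.5%% %.3f | median %.3f | 97.5%% %.3f\n",
                q[1L], q[2L], q[3L]))
  }
  invisible(x)
}
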