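#' Jaccard dissimilarity between two communities
#'
#' Presence/absence overlap: `1 - |A intersect B| / |A union B|` where A, B
#' are the sets of taxa with nonzero abundance.
#'
#' @param a,b Nonnegative abundance vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
beta_jaccard <- function(a, b) {
  check_pair(a, b)
  pa <- a > 0
  pb <- b > 0
  1 - sum(pa & pb) / sum(pa | pb)
}

#' Bray-Curtis dissimilarity between two communities
#'
#' `sum |a_i - b_i| / sum (a_i + b_i)`.
#'
#' @inheritParams beta_jaccard
#' @return Dissimilarity in \[0, 1\].
#' @export
beta_bray_curtis <- function(a, b) {
  check_pair(a, b)
  sum(abs(a - b)) / sum(a + b)
}

#' UniFrac dissimilarity between two communities
#'
#' Phylogenetically weighted overlap on the microbial tree. The unweighted
#' form is the branch length unique to either community's tip set divided by
#' the branch length spanned by their union (a branch is "in" a community if
#' any descendant tip is present; branches absent from both are excluded
#' from numerator and denominator). The weighted form is normalized:
#' `sum_b len_b |A_b - B_b| / sum_b len_b (A_b + B_b)` with `A_b` the
#' fraction of community A's individuals descending from branch b, so both
#' variants lie in \[0, 1\].
#'
#' @inheritParams beta_jaccard
#' @param tree Phylo object whose tips cover all taxa with nonzero
#'   abundance; vectors must be named by tip label (tips absent from a
#'   vector count as absent taxa).
#' @param weighted Logical: abundance-weighted (normalized) or
#'   presence/absence form.
#' @return Dissimilarity in \[0, 1\].
#' @export
unifrac <- function(a, b, tree, weighted = FALSE) {
  check_pair(a, b)
  prof <- unifrac_profile(tree)
  av <- align_to_tips(a, tree)
  bv <- align_to_tips(b, tree)
  if (weighted) {
    Aa <- drop(prof$incidence %*% (av / sum(av)))
    Ab <- drop(prof$incidence %*% (bv / sum(bv)))
    sum(prof$lengths * abs(Aa - Ab)) / sum(prof$lengths * (Aa + Ab))
  } else {
    pa <- drop(prof$incidence %*% (av > 0)) > 0
    pb <- drop(prof$incidence %*% (bv > 0)) > 0
    sum(prof$lengths[xor(pa, pb)]) / sum(prof$lengths[pa | pb])
  }
}

#' All pairwise community dissimilarities
#'
#' Computes the full symmetric distance matrix over the hosts (rows) of a
#' community table under one of the four metrics. Jaccard and Bray-Curtis go
#' through [vegan::vegdist()]; the UniFrac variants share one per-edge
#' abundance profile across all pairs.
#'
#' @param table Hosts x microbes abundance matrix (rownames = host labels).
#' @param metric One of `"jaccard"`, `"braycurtis"`, `"wunifrac"`,
#'   `"uunifrac"`.
#' @param tree Microbial phylogeny; required for the UniFrac metrics.
#' @return Symmetric numeric matrix with zero diagonal and host labels.
#' @export
distance_matrix <- function(table,
                            metric = c("wunifrac", "uunifrac", "jaccard",
                                       "braycurtis"),
                            tree = NULL) {
  metric <- match.arg(metric)
  table <- as.matrix(table)
  n <- nrow(table)
  labs <- rownames(table)
  if (metric %in% c("wunifrac", "uunifrac")) {
    if (is.null(tree)) stop("a microbial tree is required for UniFrac metrics")
    prof <- unifrac_profile(tree)
    tipmat <- matrix(0, nrow = n, ncol = length(tree$tip.label),
                     dimnames = list(labs, tree$tip.label))
    common <- intersect(colnames(table), tree$tip.label)
    missing <- setdiff(colnames(table)[colSums(table) > 0], tree$tip.label)
    if (length(missing)) {
      stop("taxa with nonzero abundance are missing from the tree: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    tipmat[, common] <- table[, common]
    if (metric == "wunifrac") {
      B <- prof$incidence %*% t(tipmat / rowSums(tipmat))  # edges x hosts
      D <- matrix(0, n, n, dimnames = list(labs, labs))
      for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
          dif <- abs(B[, i] - B[, j])
          tot <- B[, i] + B[, j]
          D[i, j] <- D[j, i] <- sum(prof$lengths * dif) / sum(prof$lengths * tot)
        }
      }
    } else {
      P <- (prof$incidence %*% t(tipmat > 0)) > 0  # edges x hosts, presence
      D <- matrix(0, n, n, dimnames = list(labs, labs))
      for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
          uniq <- xor(P[, i], P[, j])
          un <- P[, i] | P[, j]
          D[i, j] <- D[j, i] <- sum(prof$lengths[uniq]) / sum(prof$lengths[un])
        }
      }
    }
    D
  } else {
    method <- if (metric == "jaccard") "jaccard" else "bray"
    d <- vegan::vegdist(table, method = method, binary = metric == "jaccard")
    as.matrix(d)
  }
}

# Per-edge descendant-tip incidence and branch lengths for a tree.
# incidence is an (edges x tips) 0/1 matrix; lengths the matching branch
# lengths. The root carries no edge.
unifrac_profile <- function(tree) {
  check_phylo(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- matrix(FALSE, nrow = ntip + nnode, ncol = ntip)
  sets[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    sets[par, ] <- sets[par, ] | sets[child, ]
  }
  incidence <- sets[tree$edge[, 2L], , drop = FALSE]
  colnames(incidence) <- tree$tip.label
  list(incidence = incidence * 1, lengths = tree$edge.length)
}

align_to_tips <- function(x, tree) {
  if (is.null(names(x))) stop("abundance vectors must be named by tip label")
  missing <- setdiff(names(x)[x > 0], tree$tip.label)
  if (length(missing)) {
    stop("taxa with nonzero abundance are missing from the tree: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  out <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  keep <- intersect(names(x), tree$tip.label)
  out[keep] <- x[keep]
  if (sum(out) == 0) stop("community is empty")
  out
}

check_pair <- function(a, b) {
  if (length(a) != length(b)) stop("communities must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be nonnegative")
  if (sum(a) == 0 && sum(b) == 0) stop("both communities are empty")
  invisible(NULL)
}
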