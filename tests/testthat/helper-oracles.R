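# Independent oracles used across the test files. Each reimplements a
# quantity by a different route than the package (dense matrices, explicit
# enumeration, per-edge walks) so agreement is evidence, not tautology.

# Blomberg K by explicit GLS arithmetic on a caller-supplied covariance
# matrix (no tree machinery at all).
gls_k_oracle <- function(C, x) {
  n <- length(x)
  Cinv <- solve(C)
  a <- sum(Cinv %*% x) / sum(Cinv)
  r <- x - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(t(r) %*% Cinv %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  (mse0 / mse) / expected
}

# Brownian covariance matrix built from first principles: shared path length
# = depth of the most recent common ancestor of each tip pair.
bm_cov_oracle <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  n <- length(tree$tip.label)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m <- if (i == j) i else ape::getMRCA(tree, c(i, j))
      C[i, j] <- depth[m]
      if (i == j) C[i, j] <- depth[i]
    }
  }
  C
}

# All permutations of 1..n (n small), as a list: insert the value n at
# every position of every permutation of 1..(n-1).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# Exact Mantel p-value by full enumeration of all n! joint row/column
# relabelings of d2 (the identity counts itself, so p >= 1/n!).
mantel_exact_oracle <- function(d1, d2) {
  n <- nrow(d1)
  lt <- lower.tri(d1)
  x <- d1[lt]
  r_obs <- stats::cor(x, d2[lt])
  rs <- vapply(all_perms(n), function(p) {
    stats::cor(x, d2[p, p][lt])
  }, numeric(1))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# Normalized rooted RF by explicit clade "frozensets": sorted tip-label
# strings, compared as character sets.
nrf_clade_oracle <- function(t1, t2) {
  clades <- function(tr) {
    n <- length(tr$tip.label)
    out <- character(0)
    for (node in (n + 1L):(n + tr$Nnode)) {
      tips <- ape::extract.clade(tr, node)$tip.label
      if (length(tips) > 1L && length(tips) < n) {
        out <- c(out, paste(sort(tips), collapse = "|"))
      }
    }
    out
  }
  c1 <- clades(t1)
  c2 <- clades(t2)
  n <- length(t1$tip.label)
  (length(setdiff(c1, c2)) + length(setdiff(c2, c1))) / (2 * (n - 2))
}

# Patristic distances by breadth-first edge walk over an explicit adjacency
# list (no ape distance code).
cophenetic_walk_oracle <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nn)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1L]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][k, 2L]
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist[seq_len(n)]
  }
  D
}

# A fixed small ultrametric tree used in several hand-worked cases:
# 4 tips, both cherries splitting at depth 0.5, height 1.
balanced4 <- function() {
  ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
}

# 3-tip tree of the worked UniFrac examples: pendant edges 0.5 each,
# internal edge (ancestor of x,y) 0.5.
unifrac3 <- function() {
  ape::read.tree(text = "((x:0.5,y:0.5):0.5,z:0.5);")
}
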