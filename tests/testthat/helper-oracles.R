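# Independent oracles: everything here evaluates the same quantities as the
# package by a different route (dense linear algebra, explicit recursions,
# exhaustive enumeration) and must never call the implementation paths it
# checks.

# dense multivariate-normal log density from an explicit covariance matrix
dense_mvn_loglik <- function(x, mu, V) {
  n <- length(x)
  ev <- eigen(V, symmetric = TRUE)
  stopifnot(all(ev$values > 0))
  z <- crossprod(ev$vectors, x - mu)
  -0.5 * n * log(2 * pi) - 0.5 * sum(log(ev$values)) -
    0.5 * sum(z^2 / ev$values)
}

# OU tip covariance by recursion down the tree: node variances accumulate
# per segment, pairwise covariance decays from the MRCA
oracle_ou_cov <- function(tree, alpha, sigma2) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  v <- rep(NA_real_, nn)
  v[ntip + 1L] <- 0
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(cw$edge))) {
    p <- cw$edge[i, 1L]; ch <- cw$edge[i, 2L]; t <- cw$edge.length[i]
    v[ch] <- exp(-2 * alpha * t) * v[p] +
      sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * t))
  }
  mr <- ape::mrca(tree)
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    a <- if (i == j) i else mr[i, j]
    V[i, j] <- v[a] * exp(-alpha * (depth[i] - depth[a])) *
      exp(-alpha * (depth[j] - depth[a]))
  }
  V
}

# expected tip values under the root-regime convention, by explicit
# root-to-tip path integration per tip (plain loops, no aggregation tricks)
oracle_ou_mean <- function(tree, painting, alpha, thetas) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  parent_edge <- rep(NA_integer_, ntip + tree$Nnode)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  mu <- numeric(ntip)
  for (i in seq_len(ntip)) {
    Ti <- depth[i]
    m <- thetas[[painting$root_regime]] * exp(-alpha * Ti)
    node <- i
    while (!is.na(parent_edge[node])) {
      e <- parent_edge[node]
      t0 <- depth[tree$edge[e, 1L]]; t1 <- depth[tree$edge[e, 2L]]
      th <- thetas[[painting$edge_regime[e]]]
      m <- m + th * (exp(-alpha * (Ti - t1)) - exp(-alpha * (Ti - t0)))
      node <- tree$edge[e, 1L]
    }
    mu[i] <- m
  }
  setNames(mu, tree$tip.label)
}

# exhaustive cherry enumeration for the sister-pruning rule
oracle_prune <- function(tree, masses, ratio, protected) {
  ntip <- ape::Ntip(tree)
  drop <- character(0)
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1L] == v, 2L]
    if (length(kids) == 2L && all(kids <= ntip)) {
      lab <- tree$tip.label[kids]
      if (!any(lab %in% protected) &&
          min(masses[lab]) / max(masses[lab]) > ratio)
        drop <- c(drop, lab[2L])
    }
  }
  drop
}

# random non-ultrametric chronogram for oracle sweeps
random_chronogram <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

random_two_regime <- function(tree, seed) {
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  internal <- unique(tree$edge[, 1L])
  internal <- internal[internal != ntip + 1L]
  node <- if (length(internal)) sample(internal, 1L) else
    sample(seq_len(ntip), 1L)
  painting_from_shifts(tree, which(tree$edge[, 2L] == node), "shifted",
                       root_label = "base")
}

paper_anchors <- function() {
  list(hylobatid_tips = c("Hylobates_lar", "Symphalangus_syndactylus",
                          "Nomascus_leucogenys", "Hoolock_hoolock"),
       hominoid_tips = c("Homo_sapiens", "Hylobates_lar"),
       pan_tips = c("Pan_troglodytes", "Pan_paniscus"),
       stem_fossils = c("Proconsul_africanus", "Proconsul_major",
                        "Ekembo_heseloni", "Ekembo_nyanzae"))
}
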