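#' Precompute tree geometry for repeated OU likelihood evaluation
#'
#' Collects the quantities the Hansen-model likelihood needs that depend
#' only on the tree: root-to-tip path lengths, shared path times (depth of
#' each pair's MRCA measured from the root), and the flattened list of
#' root-to-tip path segments with their start/end depths.  Fitting and the
#' stepwise search reuse one cache across hundreds of likelihood calls; the
#' cache also memoizes per-alpha Cholesky factors.
#'
#' @param tree a `phylo` chronogram.
#' @return a `tree_cache` environment.
#' @export
tree_cache <- function(tree) {
  validate_chronogram(tree)
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)  # distance from root
  Tt <- depth[seq_len(ntip)]

  # shared path time matrix: depth of MRCA(i, j) from the root
  mr <- ape::mrca(tree)
  Ta <- matrix(depth[mr], ntip, ntip,
               dimnames = list(tree$tip.label, tree$tip.label))
  diag(Ta) <- Tt

  # per-tip root-to-tip path segments, flattened over (tip, edge)
  n_all <- ntip + tree$Nnode
  parent_edge <- rep(NA_integer_, n_all)
  parent_edge[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  seg_tip <- integer(0); seg_edge <- integer(0)
  paths <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    es <- integer(0)
    node <- i
    while (!is.na(parent_edge[node])) {
      es <- c(es, parent_edge[node])
      node <- tree$edge[parent_edge[node], 1L]
    }
    paths[[i]] <- rev(es)
    seg_tip <- c(seg_tip, rep.int(i, length(es)))
    seg_edge <- c(seg_edge, es)
  }
  seg_t0 <- depth[tree$edge[seg_edge, 1L]]  # segment start depth
  seg_t1 <- depth[tree$edge[seg_edge, 2L]]  # segment end depth

  # postorder index of each edge, for deterministic tie-breaking
  po <- ape::reorder.phylo(tree, "postorder")
  po_index <- match(paste(tree$edge[, 1L], tree$edge[, 2L]),
                    paste(po$edge[, 1L], po$edge[, 2L]))

  env <- new.env(parent = emptyenv())
  env$tree <- tree
  env$ntip <- ntip
  env$tip_depth <- Tt
  env$Ta <- Ta
  env$seg_tip <- seg_tip
  env$seg_edge <- seg_edge
  env$seg_t0 <- seg_t0
  env$seg_t1 <- seg_t1
  env$po_index <- po_index
  env$chol_memo <- new.env(parent = emptyenv())
  env$contrib_memo <- new.env(parent = emptyenv())
  class(env) <- "tree_cache"
  env
}

as_cache <- function(tree, cache = NULL) {
  if (is.null(cache)) tree_cache(tree) else cache
}

# segment contributions for a whole alpha grid at once (nseg x K), cached;
# shared by every candidate painting during a search step
contrib_grid <- function(cache, alphas) {
  key <- sprintf("g%d_%.17g_%.17g", length(alphas), alphas[1L],
                 alphas[length(alphas)])
  hit <- cache$contrib_memo[[key]]
  if (!is.null(hit)) return(hit)
  Ti <- cache$tip_depth[cache$seg_tip]
  CT <- exp(-outer(Ti - cache$seg_t1, alphas)) -
    exp(-outer(Ti - cache$seg_t0, alphas))
  cache$contrib_memo[[key]] <- CT
  CT
}

root_weight_grid <- function(cache, alphas) {
  key <- sprintf("rw%d_%.17g_%.17g", length(alphas), alphas[1L],
                 alphas[length(alphas)])
  hit <- cache$contrib_memo[[key]]
  if (!is.null(hit)) return(hit)
  RW <- exp(-outer(cache$tip_depth, alphas))
  cache$contrib_memo[[key]] <- RW
  RW
}

# exp(-a(T_i - t_end)) - exp(-a(T_i - t_start)) for every path segment,
# memoized per alpha (identical across candidate paintings in the search)
segment_contrib <- function(cache, alpha) {
  key <- sprintf("%.17g", alpha)
  hit <- cache$contrib_memo[[key]]
  if (!is.null(hit)) return(hit)
  Ti <- cache$tip_depth[cache$seg_tip]
  ct <- exp(-alpha * (Ti - cache$seg_t1)) - exp(-alpha * (Ti - cache$seg_t0))
  cache$contrib_memo[[key]] <- ct
  ct
}

#' Hansen model weight matrix
#'
#' Entry (i, r) is the weight of regime r's optimum in the expected trait
#' value of tip i: the sum over the root-to-tip path segments spent in
#' regime r of `exp(-a (T_i - t_end)) - exp(-a (T_i - t_start))`, with the
#' residual root weight `exp(-a T_i)` assigned to the root regime's column
#' (the root state is pinned to the root regime's optimum).  Rows sum to 1.
#'
#' @param tree a `phylo` chronogram.
#' @param painting a `regime_painting`.
#' @param alpha rate of adaptation, 1/Ma; must be > 0.
#' @param cache optional [tree_cache()].
#' @return numeric matrix, tips by regimes (columns in sorted label order).
#' @export
ou_weight_matrix <- function(tree, painting, alpha, cache = NULL) {
  if (alpha <= 0)
    stop("alpha must be > 0; for alpha = 0 use the Brownian-motion model")
  cache <- as_cache(tree, cache)
  labs <- regime_labels(painting)
  ct <- segment_contrib(cache, alpha)
  reg <- match(painting$edge_regime[cache$seg_edge], labs)
  W <- matrix(0, cache$ntip, length(labs),
              dimnames = list(cache$tree$tip.label, labs))
  agg <- rowsum(ct, group = (reg - 1L) * cache$ntip + cache$seg_tip)
  pos <- as.integer(rownames(agg))
  W[cbind((pos - 1L) %% cache$ntip + 1L, (pos - 1L) %/% cache$ntip + 1L)] <-
    agg[, 1L]
  rcol <- match(painting$root_regime, labs)
  W[, rcol] <- W[, rcol] + exp(-alpha * cache$tip_depth)
  W[W < 1e-250] <- 0  # flush subnormals: they break LAPACK's QR
  W
}

#' Tip covariance matrix of the OU process
#'
#' For tips i, j with root-to-tip times T_i, T_j and shared path time t_a
#' (depth of their MRCA from the root),
#' `Cov(i, j) = sigma2/(2 alpha) * exp(-alpha (T_i + T_j - 2 t_a)) *
#' (1 - exp(-2 alpha t_a))`.  Valid on non-ultrametric trees; the
#' covariance does not depend on the painting.
#'
#' @param tree a `phylo` chronogram.
#' @param alpha rate of adaptation, 1/Ma (> 0).
#' @param sigma2 intensity of stochastic fluctuations, trait^2/Ma (> 0).
#' @param cache optional [tree_cache()].
#' @return symmetric positive-definite matrix, tips by tips.
#' @export
ou_covariance <- function(tree, alpha, sigma2, cache = NULL) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  cache <- as_cache(tree, cache)
  Ti <- cache$tip_depth
  Tsum <- outer(Ti, Ti, "+")
  V <- sigma2 / (2 * alpha) * exp(-alpha * (Tsum - 2 * cache$Ta)) *
    (1 - exp(-2 * alpha * cache$Ta))
  dimnames(V) <- dimnames(cache$Ta)
  V
}

#' Brownian-motion tip covariance
#'
#' `Cov(i, j) = sigma2 * t_a`, the shared path time scaled by the rate.
#'
#' @inheritParams ou_covariance
#' @return covariance matrix, tips by tips.
#' @export
bm_covariance <- function(tree, sigma2, cache = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  cache <- as_cache(tree, cache)
  sigma2 * cache$Ta
}

# Cholesky with a memo per (kind, alpha); covariance is evaluated at unit
# sigma2 so one factor serves every sigma2.
chol_unit_cov <- function(cache, alpha = NULL, bm = FALSE) {
  key <- if (bm) "bm" else sprintf("ou%.17g", alpha)
  hit <- cache$chol_memo[[key]]
  if (!is.null(hit)) return(hit)
  V <- if (bm) cache$Ta else
    ou_covariance(cache$tree, alpha, 1, cache = cache)
  L <- tryCatch(chol(V), error = function(e) {
    V2 <- V + diag(1e-10 * max(diag(V)), nrow(V))
    tryCatch(chol(V2), error = function(e2)
      stop("covariance not positive definite (condition number ~ ",
           format(kappa(V)), ")"))
  })
  cache$chol_memo[[key]] <- L
  L
}

# Multivariate-normal log density given the upper Cholesky factor of the
# unit-sigma2 covariance.
mvn_loglik_chol <- function(x, mean, L, sigma2) {
  n <- length(x)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * n * log(2 * pi * sigma2) - sum(log(diag(L))) -
    0.5 * sum(z^2) / sigma2
}

#' Exact log-likelihood of the multi-optimum OU model
#'
#' The tip traits are multivariate normal with mean `W(alpha) %*% theta`
#' (root state pinned to the root regime's optimum) and covariance from
#' [ou_covariance()].
#'
#' @param tree a `phylo` chronogram.
#' @param painting a `regime_painting`.
#' @param traits named numeric vector of tip trait values (natural-log kg),
#'   covering exactly the tree's tips.
#' @param params list with `alpha`, `sigma2`, and named `thetas` keyed by
#'   the painting's regime labels.
#' @param cache optional [tree_cache()].
#' @return log-likelihood in nats.
#' @export
ou_loglik <- function(tree, painting, traits, params, cache = NULL) {
  cache <- as_cache(tree, cache)
  x <- check_traits(cache$tree, traits)
  labs <- regime_labels(painting)
  if (!all(labs %in% names(params$thetas)))
    stop("thetas must be keyed by the painting's regime labels")
  W <- ou_weight_matrix(cache$tree, painting, params$alpha, cache)
  mu <- drop(W %*% params$thetas[labs])
  L <- chol_unit_cov(cache, alpha = params$alpha)
  mvn_loglik_chol(x, mu, L, params$sigma2)
}

#' Log-likelihood of Brownian motion
#'
#' @param tree a `phylo` chronogram.
#' @param traits named numeric vector of tip values.
#' @param sigma2 BM rate (> 0).
#' @param root_state trait value at the root.
#' @param cache optional [tree_cache()].
#' @return log-likelihood in nats.
#' @export
bm_loglik <- function(tree, traits, sigma2, root_state, cache = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  cache <- as_cache(tree, cache)
  x <- check_traits(cache$tree, traits)
  L <- chol_unit_cov(cache, bm = TRUE)
  mvn_loglik_chol(x, rep(root_state, length(x)), L, sigma2)
}

# order traits to tip order; error on mismatch
check_traits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be named by tip label")
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing))
    stop("traits missing for species: ", paste(missing, collapse = ", "))
  x <- traits[tree$tip.label]
  if (any(!is.finite(x))) stop("non-finite trait values")
  x
}
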