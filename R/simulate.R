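#' Simulate a trait under a multi-regime OU process
#'
#' Exact simulation via the OU transition density, applied edge by edge in
#' preorder (child order as stored): along an edge of length t in regime r,
#' `child ~ Normal(theta_r + (parent - theta_r) exp(-alpha t),
#' sigma2/(2 alpha) (1 - exp(-2 alpha t)))`.  The root takes `root_state`.
#' One RNG stream is seeded per call and the caller's RNG state restored.
#'
#' @param tree a `phylo` chronogram.
#' @param painting a `regime_painting`.
#' @param params list with `alpha` (> 0), `sigma2` (> 0), named `thetas`.
#' @param root_state trait value at the root (log kg).
#' @param seed integer seed; same seed, same vector.
#' @return named numeric vector of tip trait values.
#' @export
simulate_ou <- function(tree, painting, params, root_state, seed) {
  if (params$alpha <= 0)
    stop("alpha must be > 0; use simulate_bm for alpha = 0")
  if (params$sigma2 <= 0) stop("sigma2 must be > 0")
  labs <- regime_labels(painting)
  if (!all(labs %in% names(params$thetas)))
    stop("thetas must cover the painting's regime labels")
  validate_chronogram(tree)
  a <- params$alpha; s2 <- params$sigma2
  with_local_seed(seed, {
    tree_cw <- ape::reorder.phylo(tree, "cladewise")
    ord <- match(paste(tree_cw$edge[, 1L], tree_cw$edge[, 2L]),
                 paste(tree$edge[, 1L], tree$edge[, 2L]))
    state <- rep(NA_real_, ape::Ntip(tree) + tree$Nnode)
    state[ape::Ntip(tree) + 1L] <- root_state
    for (i in seq_len(nrow(tree_cw$edge))) {
      e <- ord[i]
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      t <- tree$edge.length[e]
      th <- params$thetas[[painting$edge_regime[e]]]
      m <- th + (state[p] - th) * exp(-a * t)
      v <- s2 / (2 * a) * (1 - exp(-2 * a * t))
      state[ch] <- rnorm(1L, m, sqrt(v))
    }
    setNames(state[seq_len(ape::Ntip(tree))], tree$tip.label)
  })
}

#' Simulate a trait under Brownian motion
#'
#' Edge increments are independent `Normal(0, sigma2 t)`.
#'
#' @param tree a `phylo` chronogram.
#' @param sigma2 BM rate (> 0).
#' @param root_state trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_bm <- function(tree, sigma2, root_state, seed) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  validate_chronogram(tree)
  with_local_seed(seed, {
    tree_cw <- ape::reorder.phylo(tree, "cladewise")
    ord <- match(paste(tree_cw$edge[, 1L], tree_cw$edge[, 2L]),
                 paste(tree$edge[, 1L], tree$edge[, 2L]))
    state <- rep(NA_real_, ape::Ntip(tree) + tree$Nnode)
    state[ape::Ntip(tree) + 1L] <- root_state
    for (i in seq_len(nrow(tree_cw$edge))) {
      e <- ord[i]
      state[tree$edge[e, 2L]] <- state[tree$edge[e, 1L]] +
        rnorm(1L, 0, sqrt(sigma2 * tree$edge.length[e]))
    }
    setNames(state[seq_len(ape::Ntip(tree))], tree$tip.label)
  })
}

#' Random pure-birth chronogram
#'
#' Pure-birth topology (the simplest stationary tree shape, with no claim
#' of realism) rescaled to a chosen crown age.
#'
#' @param n number of tips.
#' @param crown_age crown age in Ma.
#' @param seed integer seed.
#' @param tip_prefix prefix for generated tip labels.
#' @return a `phylo` chronogram.
#' @export
sim_pure_birth <- function(n, crown_age, seed, tip_prefix = "t") {
  tr <- with_local_seed(seed, ape::rphylo(n, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * crown_age / depth
  tr$tip.label <- paste0(tip_prefix, seq_len(n))
  tr
}
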