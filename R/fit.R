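#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik log-likelihood, nats.
#' @param k number of estimated parameters.
#' @param n number of tips.
#' @return AICc, dimensionless.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1 (n = ", n,
                       ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Phylogenetic half-life
#'
#' `t_1/2 = ln 2 / alpha`: the expected time for a maladapted lineage to
#' evolve half the distance to its optimum.  Infinite at `alpha = 0`, where
#' there is no pull toward the optimum and evolution is Brownian.
#'
#' @param alpha rate of adaptation, 1/Ma (>= 0).
#' @return half-life in Ma.
#' @export
half_life <- function(alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (alpha == 0) return(Inf)
  log(2) / alpha
}

default_fit_control <- function() {
  list(alpha_bounds = c(1e-6, 1e3),  # half-lives ~7e5 Ma down to ~7e-4 Ma
       n_grid = 64L,
       refine = TRUE,
       log_alpha_tol = 1e-8,
       sigma2_floor = 1e-12)
}

# transformed traits L^-T x, memoized per alpha for a fixed trait vector
# (the stepwise search evaluates hundreds of candidate paintings against
# the same data; L and x do not depend on the painting)
xt_at_alpha <- function(cache, x, alpha) {
  key <- sprintf("%.17g", alpha)
  hit <- cache$xt_memo[[key]]
  if (!is.null(hit) && identical(hit$x, x)) return(hit)
  L <- chol_unit_cov(cache, alpha = alpha)
  out <- list(x = x, xt = backsolve(L, x, transpose = TRUE),
              L = L, logdet = sum(log(diag(L))))
  cache$xt_memo[[key]] <- out
  out
}

# GLS profile step at fixed alpha: thetas by generalized least squares with
# the weight matrix as design, sigma2 in closed form from the residuals
# (ML 1/n denominator).  Returns the profile log-likelihood and estimates.
profile_at_alpha <- function(cache, painting, x, alpha) {
  labs <- regime_labels(painting)
  W <- ou_weight_matrix(cache$tree, painting, alpha, cache)
  tx <- xt_at_alpha(cache, x, alpha)
  n <- length(x)
  Wt <- backsolve(tx$L, W, transpose = TRUE)  # L^-T W
  fit <- stats::.lm.fit(Wt, tx$xt)
  if (fit$rank == length(labs) && all(is.finite(fit$residuals))) {
    theta <- numeric(length(labs))
    theta[fit$pivot] <- fit$coefficients
  } else {
    # near-unidentifiable optimum (a regime weight column underflowing at
    # extreme alpha): pivoted least squares, dropped optima reported as 0
    fit <- stats::lm.fit(Wt, tx$xt)
    theta <- fit$coefficients
    theta[is.na(theta)] <- 0
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, 1e-12)  # floor keeps degenerate data comparable
  ll <- -0.5 * n * (log(2 * pi) + 1 + log(sigma2)) - tx$logdet
  list(loglik = ll, alpha = alpha, sigma2 = sigma2,
       thetas = setNames(theta, labs),
       rank_deficient = fit$rank < length(labs))
}

# profile log-likelihood over a whole alpha grid in one pass, sharing the
# per-alpha Cholesky factors and transformed traits across candidates and
# the per-painting segment aggregation across alphas
profile_grid <- function(cache, painting, x, alphas) {
  labs <- regime_labels(painting)
  p <- length(labs)
  n <- cache$ntip
  reg <- match(painting$edge_regime[cache$seg_edge], labs)
  group <- (reg - 1L) * n + cache$seg_tip
  rcol <- match(painting$root_regime, labs)
  CT <- contrib_grid(cache, alphas)          # nseg x K
  AGG <- rowsum(CT, group)                   # combos x K
  pos <- as.integer(rownames(AGG))
  idx <- (pos - 1L) %% n + 1L + ((pos - 1L) %/% n) * n  # linear index
  rootcol <- (rcol - 1L) * n + seq_len(n)
  RW <- root_weight_grid(cache, alphas)      # n x K
  lls <- numeric(length(alphas))
  W <- matrix(0, n, p)
  for (k in seq_along(alphas)) {
    W[] <- 0
    W[idx] <- AGG[, k]
    W[rootcol] <- W[rootcol] + RW[, k]
    W[W < 1e-250] <- 0  # flush subnormals: they break LAPACK's QR
    tx <- xt_at_alpha(cache, x, alphas[k])
    Wt <- backsolve(tx$L, W, transpose = TRUE)
    fit <- stats::.lm.fit(Wt, tx$xt)
    rss <- sum(fit$residuals^2)
    if (!is.finite(rss))  # underflowing weight column: pivoted fallback
      rss <- sum(stats::lm.fit(Wt, tx$xt)$residuals^2)
    lls[k] <- -0.5 * n * (log(2 * pi) + 1 + log(max(rss / n, 1e-12))) -
      tx$logdet
  }
  lls
}

new_ou_fit <- function(model, params, loglik, n, k, painting = NULL,
                       notes = character()) {
  structure(list(model = model, params = params, loglik = loglik,
                 n = n, k = k, aicc = aicc(loglik, k, n),
                 half_life = half_life(params$alpha),
                 painting = painting, notes = notes),
            class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, k = %d, logL = %.4f, AICc = %.4f\n",
              x$model, x$n, x$k, x$loglik, x$aicc))
  cat(sprintf("  alpha = %.6g /Ma (t1/2 = %.4g Ma), sigma2 = %.6g\n",
              x$params$alpha, x$half_life, x$params$sigma2))
  if (length(x$params$thetas)) {
    cat("  optima (log scale / kg):\n")
    for (r in names(x$params$thetas))
      cat(sprintf("    %-12s %8.4f  (%.2f kg)\n", r, x$params$thetas[r],
                  exp(x$params$thetas[r])))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Maximum-likelihood fit of a multi-optimum OU model
#'
#' Profiles the likelihood over the rate of adaptation alpha on a
#' log-spaced grid, then refines the optimum by bounded scalar optimization
#' in log alpha.  At each alpha the optima are the generalized least
#' squares solution with the Hansen weight matrix as design, and sigma2 has
#' its closed-form ML (1/n) value from the GLS residuals.  Parameter count
#' is k = p + 2 for p regimes (alpha, sigma2, p optima; the root state is
#' pinned to the root regime's optimum and not counted separately).
#'
#' @param tree a `phylo` chronogram.
#' @param painting a `regime_painting`.
#' @param traits named numeric vector (natural-log kg).
#' @param control list overriding elements of the default search control:
#'   `alpha_bounds` (default `c(1e-6, 1e3)` per Ma), `n_grid` (64),
#'   `refine` (TRUE), `log_alpha_tol` (1e-8).
#' @param cache optional [tree_cache()].
#' @return an `ou_fit` with elements `params` (alpha, sigma2, thetas),
#'   `loglik`, `n`, `k`, `aicc`, `half_life`, `painting`, `notes`.
#' @export
fit_ou <- function(tree, painting, traits, control = list(), cache = NULL) {
  ctl <- utils::modifyList(default_fit_control(), control)
  cache <- as_cache(tree, cache)
  x <- check_traits(cache$tree, traits)
  p <- length(regime_labels(painting))
  k <- p + 2L
  n <- length(x)
  if (n <= k + 1) stop("too few tips for painting: n = ", n, ", k = ", k)

  grid <- exp(seq(log(ctl$alpha_bounds[1]), log(ctl$alpha_bounds[2]),
                  length.out = ctl$n_grid))
  lls <- profile_grid(cache, painting, x, grid)
  best_i <- which.max(lls)
  best <- profile_at_alpha(cache, painting, x, grid[best_i])

  notes <- character()
  if (ctl$refine) {
    lo <- grid[max(1L, best_i - 1L)]
    hi <- grid[min(length(grid), best_i + 1L)]
    opt <- stats::optimize(
      function(la) profile_at_alpha(cache, painting, x, exp(la))$loglik,
      lower = log(lo), upper = log(hi), maximum = TRUE,
      tol = ctl$log_alpha_tol)
    cand <- profile_at_alpha(cache, painting, x, exp(opt$maximum))
    if (cand$loglik > best$loglik) best <- cand
  }
  if (best$alpha <= ctl$alpha_bounds[1] * 1.01 ||
      best$alpha >= ctl$alpha_bounds[2] * 0.99)
    notes <- c(notes, "alpha at search bound (flat likelihood)")
  if (best$sigma2 <= ctl$sigma2_floor) {
    best$sigma2 <- ctl$sigma2_floor
    notes <- c(notes, "degenerate: sigma2 at lower bound")
  }
  if (best$rank_deficient)
    notes <- c(notes, "weight matrix rank deficient: some optima not identifiable")

  new_ou_fit("OU", list(alpha = best$alpha, sigma2 = best$sigma2,
                        thetas = best$thetas),
             best$loglik, n, k, painting = painting, notes = notes)
}

#' Maximum-likelihood Brownian-motion fit
#'
#' GLS with the BM covariance: the root state is the GLS mean and sigma2
#' the ML (1/n) residual variance.  k = 2 (sigma2, root state).
#'
#' @param tree a `phylo` chronogram.
#' @param traits named numeric vector.
#' @param cache optional [tree_cache()].
#' @return an `ou_fit` with `model = "BM"`, `params$alpha = 0`,
#'   `params$root_state`, infinite half-life.
#' @export
fit_bm <- function(tree, traits, cache = NULL) {
  cache <- as_cache(tree, cache)
  x <- check_traits(cache$tree, traits)
  n <- length(x)
  L <- chol_unit_cov(cache, bm = TRUE)
  ones <- backsolve(L, rep(1, n), transpose = TRUE)
  xt <- backsolve(L, x, transpose = TRUE)
  root <- sum(ones * xt) / sum(ones^2)
  rss <- sum((xt - root * ones)^2)
  sigma2 <- max(rss / n, 1e-12)
  ll <- -0.5 * n * (log(2 * pi) + 1 + log(sigma2)) - sum(log(diag(L)))
  notes <- if (rss / n <= 1e-12) "degenerate: sigma2 at lower bound"
           else character()
  new_ou_fit("BM", list(alpha = 0, sigma2 = sigma2, root_state = root,
                        thetas = numeric(0)),
             ll, n, 2L, notes = notes)
}

#' AICc comparison table across fitted models
#'
#' @param fits named list of `ou_fit` objects on the same data.
#' @return a `model_comparison` data.frame with columns `model`, `loglik`,
#'   `k`, `aicc`, `delta_aicc`, `half_life`, sorted by AICc ascending
#'   (ties broken by model name).
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L)
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be a named list")
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("fits are on mismatched tip sets (n = ",
         paste(unique(ns), collapse = ", "), ")")
  tab <- data.frame(
    model = names(fits),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    half_life = vapply(fits, `[[`, numeric(1), "half_life"),
    row.names = NULL)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$aicc, tab$model), ]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Comparison table from bare AICc values
#'
#' Convenience for worked examples on published AICc tables: wraps numeric
#' AICc values as degenerate fits so [compare_models()] arithmetic (delta
#' AICc, ordering) can be applied to printed values.
#'
#' @param aicc_values named numeric vector of AICc scores.
#' @return a `model_comparison` data.frame (loglik, k, half_life are NA).
#' @export
compare_aicc_values <- function(aicc_values) {
  stopifnot(is.numeric(aicc_values), !is.null(names(aicc_values)))
  tab <- data.frame(model = names(aicc_values),
                    loglik = NA_real_, k = NA_real_,
                    aicc = unname(aicc_values),
                    half_life = NA_real_)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$aicc, tab$model), ]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, digits = 2, ...) {
  cat("Model comparison (AICc):\n")
  out <- data.frame(model = x$model,
                    AICc = round(x$aicc, digits),
                    dAICc = round(x$delta_aicc, digits),
                    t_half = signif(x$half_life, 3))
  print.data.frame(out, row.names = FALSE)
  invisible(x)
}
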