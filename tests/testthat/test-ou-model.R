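test_that("weight matrix limits: single regime, alpha to 0, alpha large", {
  tr <- random_chronogram(10, seed = 1)
  ca <- tree_cache(tr)
  W1 <- ou_weight_matrix(tr, ou1_painting(tr), 0.7, ca)
  expect_equal(unname(W1[, 1L]), rep(1, 10))

  p2 <- random_two_regime(tr, seed = 2)
  W0 <- ou_weight_matrix(tr, p2, 1e-8, ca)
  expect_equal(unname(W0[, p2$root_regime]), rep(1, 10), tolerance = 1e-6)

  Winf <- ou_weight_matrix(tr, p2, 1e3, ca)
  pend <- vapply(seq_len(10), function(i)
    p2$edge_regime[which(tr$edge[, 2L] == i)], character(1))
  expect_equal(unname(Winf[cbind(seq_len(10), match(pend, colnames(Winf)))]),
               rep(1, 10), tolerance = 1e-10)
  expect_error(ou_weight_matrix(tr, p2, 0), "Brownian")
})

test_that("weight rows sum to one for any alpha and painting", {
  for (s in 1:5) {
    tr <- random_chronogram(15, seed = 300 + s)
    p <- random_two_regime(tr, seed = 400 + s)
    for (a in c(1e-6, 1e-2, 0.5, 3, 50, 1e3)) {
      W <- ou_weight_matrix(tr, p, a)
      expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
    }
  }
})

test_that("weight matrix matches per-tip path integration oracle", {
  for (s in 1:5) {
    tr <- random_chronogram(8, seed = 500 + s)
    p <- random_two_regime(tr, seed = 600 + s)
    th <- c(base = 0.4, shifted = 2.1)
    for (a in c(0.05, 0.9, 7)) {
      W <- ou_weight_matrix(tr, p, a)
      mu <- drop(W %*% th[colnames(W)])
      expect_equal(unname(mu), unname(oracle_ou_mean(tr, p, a, th)),
                   tolerance = 1e-12)
    }
  }
})

test_that("OU covariance has the closed form on a star tree", {
  star <- ape::stree(4, "star")
  star$edge.length <- rep(1, 4)
  V <- ou_covariance(star, alpha = 1, sigma2 = 2)
  expect_equal(unname(diag(V)), rep(1 - exp(-2), 4))
  expect_equal(max(abs(V[upper.tri(V)])), 0)
})

test_that("OU covariance approaches the BM covariance as alpha vanishes", {
  tr <- random_chronogram(10, seed = 11)
  V <- ou_covariance(tr, alpha = 1e-8, sigma2 = 0.5)
  expect_equal(V, bm_covariance(tr, 0.5), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("OU covariance equals the segment-recursion oracle", {
  for (s in 1:6) {
    tr <- random_chronogram(8, seed = 700 + s)
    a <- exp(runif(1, log(0.05), log(5)))
    s2 <- runif(1, 0.1, 2)
    expect_equal(ou_covariance(tr, a, s2), oracle_ou_cov(tr, a, s2),
                 tolerance = 1e-10)
  }
})

test_that("BM covariance matches the shared-path-time oracle", {
  tr <- random_chronogram(9, seed = 21)
  expect_equal(bm_covariance(tr, 1.7), 1.7 * ape::vcv(tr),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("log-likelihoods agree with dense MVN evaluation", {
  for (s in 1:10) {
    n <- sample(4:8, 1)
    tr <- random_chronogram(n, seed = 800 + s)
    p <- random_two_regime(tr, seed = 900 + s)
    a <- exp(runif(1, log(0.05), log(5))); s2 <- runif(1, 0.2, 2)
    th <- c(base = rnorm(1), shifted = rnorm(1))
    x <- setNames(rnorm(n), tr$tip.label)
    ll <- ou_loglik(tr, p, x, list(alpha = a, sigma2 = s2, thetas = th))
    mu <- oracle_ou_mean(tr, p, a, th)
    V <- oracle_ou_cov(tr, a, s2)
    expect_equal(ll, dense_mvn_loglik(x[tr$tip.label], mu, V),
                 tolerance = 1e-9)

    root <- rnorm(1)
    llb <- bm_loglik(tr, x, s2, root)
    expect_equal(llb, dense_mvn_loglik(x[tr$tip.label],
                                       rep(root, n), s2 * ape::vcv(tr)),
                 tolerance = 1e-9)
  }
})

test_that("univariate closed form holds on a two-tip star", {
  tr <- read_newick("(A:3,B:3);")
  x <- c(A = 0.7, B = -0.2)
  a <- 0.8; s2 <- 0.4; th <- 1.1
  v <- s2 / (2 * a) * (1 - exp(-2 * a * 3))
  m <- th  # weights sum to 1 within a single regime
  ll <- ou_loglik(tr, ou1_painting(tr, "z"), x,
                  list(alpha = a, sigma2 = s2, thetas = c(z = th)))
  expect_equal(ll, sum(dnorm(x, m, sqrt(v), log = TRUE)), tolerance = 1e-12)
  llb <- bm_loglik(tr, x, s2, th)
  expect_equal(llb, sum(dnorm(x, th, sqrt(s2 * 3), log = TRUE)),
               tolerance = 1e-12)
})

test_that("OU likelihood is continuous into the BM limit", {
  for (s in 1:5) {
    tr <- random_chronogram(10, seed = 950 + s)
    x <- setNames(rnorm(10), tr$tip.label)
    root <- rnorm(1); s2 <- runif(1, 0.2, 1.5)
    ll_ou <- ou_loglik(tr, ou1_painting(tr, "r"), x,
                       list(alpha = 1e-8, sigma2 = s2, thetas = c(r = root)))
    expect_lt(abs(ll_ou - bm_loglik(tr, x, s2, root)), 1e-3)
  }
})

test_that("stationary variance bounds every tip variance", {
  tr <- random_chronogram(12, seed = 31)
  a <- 0.6; s2 <- 0.9
  V <- ou_covariance(tr, a, s2)
  expect_true(all(diag(V) <= s2 / (2 * a) + 1e-12))
})

test_that("likelihood is invariant to tip order and BM to time rescaling", {
  tr <- random_chronogram(8, seed = 41)
  p <- random_two_regime(tr, seed = 42)
  x <- setNames(rnorm(8), tr$tip.label)
  pars <- list(alpha = 0.7, sigma2 = 0.5,
               thetas = c(base = 0, shifted = 1))
  expect_equal(ou_loglik(tr, p, x, pars),
               ou_loglik(tr, p, x[sample(names(x))], pars))
  # doubling branch lengths with halved rate leaves BM likelihood unchanged
  tr2 <- tr; tr2$edge.length <- 2 * tr$edge.length
  expect_equal(bm_loglik(tr, x, 0.8, 0.1), bm_loglik(tr2, x, 0.4, 0.1),
               tolerance = 1e-10)
})
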