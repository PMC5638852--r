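test_that("AICc arithmetic, limit and error guard", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(-10, 3, 1e9), 20 + 6, tolerance = 1e-6)
  expect_error(aicc(0, 5, 6), "n > k")
})

test_that("AICc prefers the smaller model when the gain is under a nat", {
  base <- aicc(-50, 3, 40)
  richer <- aicc(-50 + 0.9, 4, 40)
  expect_lt(base, richer)
})

test_that("half-life definition and round trip", {
  expect_equal(half_life(log(2)), 1.0)
  expect_identical(half_life(0), Inf)
  expect_equal(half_life(log(2) / 0.88), 0.88, tolerance = 1e-12)
  expect_error(half_life(-1), ">= 0")
})

test_that("BM fit: star-tree root state is the tip mean; degenerate flag", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(2, 6)
  x <- setNames(rnorm(6, 3), star$tip.label)
  f <- fit_bm(star, x)
  expect_equal(f$params$root_state, mean(x), tolerance = 1e-10)
  expect_equal(f$k, 2L)
  g <- fit_bm(star, setNames(rep(1.5, 6), star$tip.label))
  expect_match(paste(g$notes, collapse = " "), "degenerate")
})

test_that("BM fit matches a dense numerical maximum-likelihood oracle", {
  tr <- random_chronogram(7, seed = 51)
  set.seed(52)
  x <- setNames(rnorm(7, 1, 0.8), tr$tip.label)
  f <- fit_bm(tr, x)
  V0 <- ape::vcv(tr)
  nll <- function(par) -dense_mvn_loglik(x[rownames(V0)],
                                         rep(par[2], 7), exp(par[1]) * V0)
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(f$loglik, -opt$value, tolerance = 1e-4)
  expect_equal(f$params$sigma2, exp(opt$par[1]), tolerance = 1e-3)
  expect_equal(f$params$root_state, opt$par[2], tolerance = 1e-3)
})

test_that("OU fit recovers optima simulated tightly around two regimes", {
  tr <- sim_pure_birth(64, 70, seed = 61)
  p <- random_two_regime(tr, seed = 62)
  truth <- list(alpha = 5, sigma2 = 0.05, thetas = c(base = 0, shifted = 1))
  x <- simulate_ou(tr, p, truth, 0, seed = 63)
  f <- fit_ou(tr, p, x)
  expect_lt(max(abs(f$params$thetas[names(truth$thetas)] - truth$thetas)),
            0.1)
})

test_that("identical traits give a degenerate flagged OU fit", {
  tr <- random_chronogram(10, seed = 71)
  x <- setNames(rep(0.3, 10), tr$tip.label)
  f <- fit_ou(tr, ou1_painting(tr), x)
  expect_match(paste(f$notes, collapse = " "), "degenerate|bound")
})

test_that("single-regime fit equals the OU1 fit after a full merge", {
  tr <- random_chronogram(12, seed = 81)
  set.seed(82)
  x <- setNames(rnorm(12), tr$tip.label)
  p2 <- random_two_regime(tr, seed = 83)
  merged <- merge_regimes(p2, "shifted", "base")
  f1 <- fit_ou(tr, ou1_painting(tr, "base"), x)
  f2 <- fit_ou(tr, merged, x)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$aicc, f2$aicc, tolerance = 1e-8)
})

test_that("a richer nested painting never fits worse", {
  for (s in 1:5) {
    tr <- random_chronogram(16, seed = 90 + s)
    set.seed(190 + s)
    x <- setNames(rnorm(16, 0, 0.6), tr$tip.label)
    p2 <- random_two_regime(tr, seed = 290 + s)
    f1 <- fit_ou(tr, ou1_painting(tr, "base"), x)
    f2 <- fit_ou(tr, p2, x)
    expect_gte(f2$loglik, f1$loglik - 1e-6)
  }
})

test_that("theta bias shrinks from 32 to 128 tips", {
  alpha <- log(2); s2 <- 2 * alpha * 0.3^2
  bias_at <- function(n, reps) {
    errs <- numeric(reps)
    for (r in seq_len(reps)) {
      tr <- sim_pure_birth(n, 70, seed = 7000 + n + r)
      p <- random_two_regime(tr, seed = 8000 + n + r)
      x <- simulate_ou(tr, p, list(alpha = alpha, sigma2 = s2,
                                   thetas = c(base = 0, shifted = 1)),
                       0, seed = 9000 + n + r)
      f <- fit_ou(tr, p, x)
      errs[r] <- f$params$thetas[["shifted"]] - 1
    }
    abs(mean(errs))
  }
  expect_lt(bias_at(128, 25), bias_at(32, 25))
})

test_that("model comparison reproduces published-style delta AICc tables", {
  cmp <- compare_aicc_values(c(BM = 1998.35, OU1 = 1968.73,
                               Anc_Pan = 1714.99, Surface = 1671.37))
  expect_identical(cmp$model, c("Surface", "Anc_Pan", "OU1", "BM"))
  expect_equal(cmp$delta_aicc, c(0, 43.62, 297.36, 326.98),
               tolerance = 1e-9)
})

test_that("model comparison sorts, zeroes the best row, breaks ties by name", {
  tr <- random_chronogram(10, seed = 99)
  set.seed(100)
  x <- setNames(rnorm(10), tr$tip.label)
  f1 <- fit_bm(tr, x)
  f2 <- fit_ou(tr, ou1_painting(tr), x)
  cmp <- compare_models(list(OU1 = f2, BM = f1))
  expect_equal(min(cmp$delta_aicc), 0)
  expect_equal(sum(cmp$delta_aicc == 0), 1L)
  expect_true(!is.unsorted(cmp$aicc))
  tie <- compare_aicc_values(c(b_model = 5, a_model = 5))
  expect_identical(tie$model, c("a_model", "b_model"))
  expect_equal(tie$delta_aicc, c(0, 0))
  # mismatched tip sets refuse comparison
  tr2 <- random_chronogram(8, seed = 101)
  set.seed(102)
  f3 <- fit_bm(tr2, setNames(rnorm(8), tr2$tip.label))
  expect_error(compare_models(list(a = f1, b = f3)), "mismatched")
})
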