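test_that("Wald ratios follow the first-order construction", {
  h <- h_set(bx = 1, by = 0.2, sy = 0.05)
  w <- wald_ratios(h)
  expect_equal(w$ratio, 0.2)
  expect_equal(w$se, 0.05)

  h <- h_set(bx = -0.5, by = 0.1, sy = 0.05)
  w <- wald_ratios(h)
  expect_equal(w$ratio, -0.2)
  expect_equal(w$se, 0.1)

  h <- h_set(bx = c(0.4, -0.8, 1.2), by = c(0.1, -0.3, 0.5),
             sy = c(0.02, 0.05, 0.08))
  w <- wald_ratios(h)
  expect_equal(w$ratio, c(0.1, -0.3, 0.5) / c(0.4, -0.8, 1.2))
  expect_equal(w$se, c(0.02, 0.05, 0.08) / c(0.4, 0.8, 1.2))
  expect_equal(w$weight, 1 / w$se^2)

  expect_error(wald_ratios(h_set(bx = c(1, 0), by = c(0.1, 0.1), sy = 0.05)),
               "rs002")
})

test_that("IVW equals the closed-form weighted mean and degenerates correctly", {
  # single SNP: the Wald ratio itself
  est1 <- mr_ivw(h_set(bx = 2, by = 0.4, sy = 0.1))
  expect_equal(est1$beta, 0.2)
  expect_equal(est1$se, 0.05)
  expect_equal(est1$method, "Wald ratio")

  # homogeneous ratios: Q = 0, random-effects SE equals fixed SE
  h <- h_set(bx = c(1, 2, 4), by = 0.2 * c(1, 2, 4), sy = c(0.1, 0.1, 0.2))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.2)
  expect_equal(est$extras$Q, 0)
  expect_equal(est$se, est$extras$se_fixed)

  # stated toy: weights (100, 100, 25), weighted mean = 40/225
  h <- h_set(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.4), sy = c(0.1, 0.1, 0.2))
  est <- mr_ivw(h)
  expect_equal(est$beta, 40 / 225)
  expect_equal(est$extras$se_fixed, 1 / sqrt(225))
})

test_that("Egger matches an independent weighted-least-squares fit", {
  # exact line: slope and intercept recovered with zero residual Q
  bx <- c(0.2, 0.5, 0.9)
  h <- h_set(bx = bx, by = 0.05 + 0.2 * bx, sy = c(0.03, 0.04, 0.05))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  expect_equal(est$extras$intercept, 0.05, tolerance = 1e-12)
  expect_lt(est$extras$Q, 1e-20)

  # 4-SNP toy vs lm() normal equations
  bx <- c(0.3, 0.6, 0.8, 1.1)
  by <- c(0.08, 0.10, 0.22, 0.25)
  sy <- c(0.02, 0.05, 0.04, 0.03)
  h <- h_set(bx = bx, by = by, sy = sy)
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  est <- mr_egger(h)
  expect_equal(est$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(est$extras$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  # SE inflation floored at 1: se >= unscaled WLS se
  XtWX <- crossprod(cbind(1, bx), (1 / sy^2) * cbind(1, bx))
  expect_gte(est$se, sqrt(solve(XtWX)[2, 2]) - 1e-12)

  expect_error(mr_egger(h_set(bx = c(1, 2), by = c(0.1, 0.2), sy = 0.1)),
               ">=3")
  expect_error(mr_egger(h_set(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3), sy = 0.1)),
               "singular")
})

test_that("Egger orients instruments so exposure effects are positive", {
  bx <- c(0.2, 0.5, 0.9, 0.4)
  by <- 0.03 + 0.3 * bx + c(0.01, -0.02, 0.005, 0)
  sy <- rep(0.04, 4)
  h1 <- h_set(bx = bx, by = by, sy = sy)
  h2 <- h1
  h2$beta_exp[2] <- -h2$beta_exp[2]
  h2$beta_out[2] <- -h2$beta_out[2]
  e1 <- mr_egger(h1); e2 <- mr_egger(h2)
  expect_equal(e2$beta, e1$beta)
  expect_equal(e2$extras$intercept, e1$extras$intercept)
})

test_that("median estimators match sorting/grid oracles", {
  h <- h_set(bx = rep(1, 5), by = c(3, 1, 2, 5, 4), sy = rep(0.1, 5))
  est <- mr_simple_median(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 3)   # sort-and-pick oracle

  # equal weights reduce the weighted median to the simple median
  h <- h_set(bx = rep(1, 3), by = c(1, 2, 3), sy = rep(0.1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 2)

  # stated weights (0.2, 0.3, 0.5) on ratios (1, 2, 4):
  # interpolation formula gives 2.75; check it minimizes the weighted
  # absolute deviation on a fine grid (the WAD minimum is flat here)
  w <- c(0.2, 0.3, 0.5)
  sy <- 1 / sqrt(w)          # ratios have unit exposure effect
  h <- h_set(bx = rep(1, 3), by = c(1, 2, 4), sy = sy)
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2 + (4 - 2) * (0.5 - 0.35) / (0.75 - 0.35))
  wad <- function(b) sum(w * abs(c(1, 2, 4) - b))
  grid <- seq(0, 5, by = 1e-3)
  expect_lte(wad(est$beta), min(vapply(grid, wad, numeric(1))) + 1e-9)

  # dominant weight pulls the estimate to that SNP's ratio
  h <- h_set(bx = rep(1, 3), by = c(1, 2, 4), sy = c(1, 1, 0.001))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 4,
               tolerance = 1e-5)
})

test_that("penalization leaves homogeneous sets untouched and tames outliers", {
  # homogeneous: every per-SNP Q is far below chi-square significance, so
  # the penalty is inactive and the estimate equals the weighted median
  h <- h_set(bx = rep(1, 7), by = 0.3 + seq(-3, 3) * 1e-3,
             sy = c(0.05, 0.06, 0.04, 0.05, 0.07, 0.05, 0.06))
  pw <- mr_penalized_weighted_median(h, n_boot = 50, seed = 2)
  wm <- mr_weighted_median(h, n_boot = 50, seed = 2)
  expect_equal(pw$beta, wm$beta)

  # one gross outlier with a large weight: penalized estimate is closer
  # to the consensus of the other four SNPs
  h <- h_set(bx = rep(1, 5), by = c(0.20, 0.21, 0.19, 0.20, 1.5),
             sy = c(0.05, 0.05, 0.05, 0.05, 0.02))
  pw <- mr_penalized_weighted_median(h, n_boot = 50, seed = 3)
  wm <- mr_weighted_median(h, n_boot = 50, seed = 3)
  expect_lt(abs(pw$beta - 0.2), abs(wm$beta - 0.2))

  expect_error(mr_penalized_weighted_median(h, penalty_k = 0), "zero")
})

test_that("mode estimators find the dense cluster and match a dense-grid argmax", {
  # two clusters: estimate must sit in the dense one
  h <- h_set(bx = rep(1, 4), by = c(0.2, 0.21, 0.19, 0.8), sy = rep(0.05, 4))
  est <- mr_simple_mode(h, n_boot = 100, seed = 1)
  expect_lt(abs(est$beta - 0.2), 0.05)

  # dense-grid KDE argmax oracle
  ratios <- c(0.2, 0.21, 0.19, 0.8)
  s <- min(sd(ratios), mad(ratios))
  hbw <- 0.9 * s * 4^(-1 / 5)
  fine <- seq(min(ratios) - 3 * hbw, max(ratios) + 3 * hbw, length.out = 20001)
  dens <- vapply(fine, function(x) sum(dnorm((x - ratios) / hbw)), numeric(1))
  oracle <- fine[which.max(dens)]
  coarse_step <- (diff(range(ratios)) + 6 * hbw) / 511
  expect_lt(abs(est$beta - oracle), coarse_step)

  # all ratios identical: the common ratio, no density evaluation needed
  h <- h_set(bx = c(1, 2, 4), by = 0.3 * c(1, 2, 4), sy = rep(0.1, 3))
  expect_equal(mr_simple_mode(h, n_boot = 50, seed = 1)$beta, 0.3)

  # weighted mode with all mass on one SNP
  h <- h_set(bx = rep(1, 3), by = c(0.1, 0.5, 0.9), sy = c(1, 1e-4, 1))
  expect_equal(mr_weighted_mode(h, n_boot = 50, seed = 1)$beta, 0.5,
               tolerance = 1e-2)
})

test_that("maximum likelihood matches its limits and a profile grid search", {
  # single SNP: Wald ratio
  est <- mr_maximum_likelihood(h_set(bx = 2, by = 0.4, sy = 0.1))
  expect_equal(est$beta, 0.2)

  # no exposure-side error: agrees with fixed-effect IVW
  h <- h_set(bx = c(0.4, 0.7, 1.1), by = c(0.09, 0.13, 0.24),
             sy = c(0.02, 0.03, 0.04), sx = rep(1e-8, 3))
  ml <- mr_maximum_likelihood(h)
  w <- wald_ratios(h)
  ivw_fixed <- sum(w$weight * w$ratio) / sum(w$weight)
  expect_equal(ml$beta, ivw_fixed, tolerance = 1e-4)

  # 3-SNP toy with real exposure error vs profile-likelihood grid search
  h <- h_set(bx = c(0.4, 0.7, 1.1), by = c(0.09, 0.13, 0.24),
             sy = c(0.02, 0.03, 0.04), sx = c(0.05, 0.06, 0.04))
  ml <- mr_maximum_likelihood(h)
  nll <- function(theta) 0.5 * sum((h$beta_out - theta * h$beta_exp)^2 /
                                     (h$se_out^2 + theta^2 * h$se_exp^2))
  grid <- seq(-1, 1, by = 1e-4)
  oracle <- grid[which.min(vapply(grid, nll, numeric(1)))]
  expect_lt(abs(ml$beta - oracle), 1e-4)
})

test_that("log effects convert to odds ratios at 5-decimal precision", {
  expect_equal(beta_to_or(0), 1)
  expect_equal(beta_to_or(0.32490), 1.38389)
  expect_equal(beta_to_or(0.00360), 1.00361)
  expect_equal(beta_to_or(log(2)), 2)
})

test_that("all eight estimators return the common ratio when ratios are identical", {
  theta <- 0.37
  bx <- c(0.3, 0.6, 1.0, 1.4)
  h <- h_set(bx = bx, by = theta * bx, sy = rep(0.05, 4))
  est <- mr_all(h, n_boot = 50, seed = 9)
  expect_equal(nrow(est), 8)
  expect_equal(est$beta, rep(theta, 8), tolerance = 1e-6)
})

test_that("estimates are invariant to SNP reordering", {
  h <- random_h(8, seed = 21)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  hp <- h[perm, , drop = FALSE]
  attributes(hp) <- attributes(h)
  hp[] <- h[perm, ]
  for (fn in list(mr_ivw, mr_egger, mr_maximum_likelihood)) {
    expect_equal(fn(hp)$beta, fn(h)$beta, tolerance = 1e-10)
    expect_equal(fn(hp)$se, fn(h)$se, tolerance = 1e-10)
  }
  expect_equal(mr_weighted_median(hp, n_boot = 2, seed = 1)$beta,
               mr_weighted_median(h, n_boot = 2, seed = 1)$beta)
  expect_equal(mr_simple_mode(hp, n_boot = 2, seed = 1)$beta,
               mr_simple_mode(h, n_boot = 2, seed = 1)$beta)
})

test_that("negating all outcome effects negates every estimate, SEs unchanged", {
  for (seed in c(3, 14)) {
    h <- random_h(6, seed = seed)
    hn <- h
    hn$beta_out <- -hn$beta_out
    expect_equal(mr_ivw(hn)$beta, -mr_ivw(h)$beta)
    expect_equal(mr_ivw(hn)$se, mr_ivw(h)$se)
    expect_equal(mr_egger(hn)$beta, -mr_egger(h)$beta)
    expect_equal(mr_egger(hn)$se, mr_egger(h)$se)
    expect_equal(mr_simple_median(hn, n_boot = 2, seed = 1)$beta,
                 -mr_simple_median(h, n_boot = 2, seed = 1)$beta)
    expect_equal(mr_weighted_median(hn, n_boot = 2, seed = 1)$beta,
                 -mr_weighted_median(h, n_boot = 2, seed = 1)$beta)
    expect_equal(mr_simple_mode(hn, n_boot = 2, seed = 1)$beta,
                 -mr_simple_mode(h, n_boot = 2, seed = 1)$beta,
                 tolerance = 1e-12)
    ml <- mr_maximum_likelihood(h); mln <- mr_maximum_likelihood(hn)
    expect_equal(mln$beta, -ml$beta, tolerance = 1e-6)
    expect_equal(mln$se, ml$se, tolerance = 1e-4)
  }
})

test_that("random-effects IVW SE never drops below the fixed-effect SE", {
  for (seed in 1:15) {
    h <- random_h(sample(2:12, 1), seed = seed)
    est <- mr_ivw(h)
    expect_gte(est$se, est$extras$se_fixed)
  }
})

test_that("bootstrap-based estimates are reproducible under a fixed seed", {
  h <- random_h(6, seed = 8)
  a <- mr_weighted_median(h, n_boot = 100, seed = 42)
  b <- mr_weighted_median(h, n_boot = 100, seed = 42)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(h, n_boot = 100, seed = 43)
  expect_false(identical(a$se, c_$se))
})

test_that("estimators converge to the true effect as per-SNP noise shrinks", {
  theta <- 0.4
  fit_all <- function(noise, seed) {
    h <- consistent_pair(30, theta = theta, noise = noise, seed = seed)
    mr_all(h, n_boot = 30, seed = seed)$beta
  }
  coarse <- fit_all(0.05, seed = 100)
  fine <- fit_all(0.002, seed = 100)
  expect_true(all(abs(fine - theta) < 0.01))
  expect_lt(mean(abs(fine - theta)), mean(abs(coarse - theta)))
})
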