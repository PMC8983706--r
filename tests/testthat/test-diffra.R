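test_that("BH adjustment matches hand step-up and handles NAs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)                  # single p unchanged
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_oracle(p))
  pna <- c(p[1:10], NA, p[11:20])
  adj <- bh_adjust(pna)
  expect_true(is.na(adj[11]))
  expect_equal(adj[-11], bh_oracle(pna[-11]))
  # fdr is monotone in p
  expect_true(all(diff(adj[-11][order(pna[-11])]) >= -1e-12))
  expect_true(all(adj >= pna, na.rm = TRUE))
})

test_that("NB GLM recovers closed-form and saturated fits", {
  y <- c(4, 4, 4, 4)
  X <- matrix(1, 4, 1)
  fit <- fit_nb_glm(y, X, alpha = 0.1)
  expect_equal(unname(fit$beta), log(4), tolerance = 1e-7)
  expect_equal(fit$loglik, sum(dnbinom(y, mu = 4, size = 10, log = TRUE)),
               tolerance = 1e-8)

  # saturated 2x2 interaction model reproduces the observed cell means
  set.seed(21)
  for (i in 1:5) {
    cells <- matrix(rpois(4, c(20, 80, 40, 10)) + 1, 2)
    y <- rep(as.vector(cells), each = 3) + rep(c(-1, 0, 1), 4)
    cond <- rep(rep(c(0, 1), each = 3), 2)
    type <- rep(c(0, 1), each = 6)
    X <- cbind(1, cond, type, cond * type)
    fit <- fit_nb_glm(y, X, alpha = 0.05)
    obs_means <- tapply(y, interaction(cond, type), mean)
    fit_means <- tapply(fit$mu, interaction(cond, type), mean)
    expect_equal(unname(fit_means), unname(obs_means), tolerance = 1e-6)
  }
})

test_that("alpha = 0 reduces exactly to Poisson regression", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    off <- rnorm(n, sd = 0.2)
    y <- rpois(n, exp(drop(X %*% c(2, 0.5, -0.3)) + off))
    fit <- fit_nb_glm(y, X, offset = off, alpha = 0)
    ref <- glm(y ~ X - 1 + offset(off), family = poisson())
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  }
})

test_that("maximized log-likelihood matches a direct-optimization oracle", {
  set.seed(41)
  worst <- 0
  for (i in 1:20) {
    cond <- rep(c(0, 1), each = 3)
    type <- rep(c(0, 0, 1, 1, 1, 0))
    X <- cbind(1, cond, type, cond * type)
    if (qr(X)$rank < 4) X <- X[, 1:3]
    mu0 <- exp(2 + rnorm(1))
    y <- rnbinom(6, mu = mu0 * exp(0.5 * cond - 0.3 * type), size = 5)
    if (all(y == 0)) next
    alpha <- runif(1, 0.01, 0.5)
    fit <- fit_nb_glm(y, X, alpha = alpha)
    oracle <- optim(rep(0, ncol(X)), function(b)
      -nb_loglik(y, exp(pmin(drop(X %*% b), 30)), alpha),
      method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    worst <- max(worst, abs(fit$loglik - (-oracle$value)))
    expect_gte(fit$loglik, -oracle$value - 1e-4)
  }
  expect_lt(worst, 1e-4)
})

test_that("LRT statistic and p behave at the boundary and the 5% point", {
  # identical full/reduced likelihood: stat clipped at zero, p = 1
  y <- rep(5, 8)
  des <- design_spec(rep(c("DMSO", "drug"), each = 4),
                     rep(c("total", "ribo"), 4), "DMSO")
  res <- lrt_interaction(y, des, alpha = 0.1)
  expect_gte(res$stat, 0)
  expect_lt(res$stat, 1e-6)
  expect_gt(res$pvalue, 0.99)
  # chi-square(1) tail oracle at the classic 5% critical value
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
})

test_that("dispersion estimation recovers Poisson, constant-alpha and floors", {
  set.seed(51)
  n <- 12
  X <- cbind(1, rep(c(0, 1), each = 6))
  mu <- exp(runif(400, log(100), log(1000)))
  # Poisson data: dispersions collapse toward the floor
  cnt_p <- t(sapply(mu, function(m) rpois(n, m)))
  dp <- estimate_dispersions(cnt_p, X)
  expect_lte(median(dp$alpha_final, na.rm = TRUE), 0.01)

  # NB data with alpha = 0.1 everywhere: trend recovers it
  cnt_nb <- t(sapply(mu, function(m) rnbinom(n, mu = m, size = 10)))
  dn <- estimate_dispersions(cnt_nb, X)
  expect_gte(median(dn$alpha_final, na.rm = TRUE), 0.05)
  expect_lte(median(dn$alpha_final, na.rm = TRUE), 0.2)

  # constant genes: zero variance pins the gene at the floor
  cnt_c <- matrix(7, 5, n)
  dc <- estimate_dispersions(cnt_c, X)
  expect_equal(unname(dc$alpha_final), rep(1e-8, 5))

  # all-zero gene is excluded (NA)
  cnt_z <- rbind(cnt_p[1:3, ], 0)
  dz <- estimate_dispersions(cnt_z, X)
  expect_true(is.na(dz$alpha_final[4]))
})

test_that("swapping ribo and total labels flips every lfcRA sign exactly", {
  s <- tiny_sim(seed = 61, n_coding = 80, n_ncrna = 0, n_spikein = 0,
                n_top_canonical = 10, n_top_candidate = 0,
                effect_map = list(drugA = list(set = "TOP_canonical", lfc = -1)),
                depth_mean = 8e4)
  res <- differential_ra(s$pc, s$meta, "drugA", anno = s$anno)
  swapped <- paired_counts(s$pc$total, s$pc$ribo)
  res_sw <- differential_ra(swapped, s$meta, "drugA", anno = s$anno)
  ok <- !is.na(res$lfcRA) & !is.na(res_sw$lfcRA)
  expect_gt(mean(ok), 0.9)
  expect_equal(res_sw$lfcRA[ok], -res$lfcRA[ok], tolerance = 1e-6)
  expect_equal(res_sw$stat[ok], res$stat[ok], tolerance = 1e-5)
})

test_that("differential RA controls false discoveries on a null plate", {
  s <- tiny_sim(seed = 71, n_coding = 300, n_ncrna = 0, n_spikein = 0,
                n_top_canonical = 0, n_top_candidate = 0, depth_mean = 2e5)
  res <- differential_ra(s$pc, s$meta, "drugA", anno = s$anno)
  expect_lte(mean(res$fdr < 0.05, na.rm = TRUE), 0.05)
  expect_true(all(res$fdr >= res$pvalue - 1e-12, na.rm = TRUE))
  expect_true(all(res$stat >= 0, na.rm = TRUE))
})

test_that("degenerate designs are rejected with clear errors", {
  s <- tiny_sim(seed = 81)
  expect_error(differential_ra(s$pc, s$meta, "absent"), "absent")
  expect_error(design_spec(rep("DMSO", 4), rep(c("total", "ribo"), 2), "DMSO"),
               "exactly one")
  expect_error(fit_nb_glm(c(1, 2, 3), cbind(1, c(1, 1, 1))), "rank deficient")
})
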