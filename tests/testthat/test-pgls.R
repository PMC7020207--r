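test_that("phylogenetic covariance holds shared path lengths", {
  tr <- three_taxon_tree()
  V <- phylo_vcv(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(diag(V)), c(2, 2, 2))
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  # a root cherry shares no path: diagonal covariance
  ch <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_vcv(ch)), diag(2))
  expect_error(phylo_vcv(tr, species = c("A", "Z")), "missing.*Z")
})

test_that("pagel transforms scale off-diagonals and depth powers", {
  V <- phylo_vcv(three_taxon_tree())
  expect_equal(pagel_transform(V, 1, 1), V)  # identity
  V0 <- pagel_transform(V, 0)
  expect_equal(unname(V0), diag(diag(V)))    # star equivalence
  V5 <- pagel_transform(V, 0.5)
  expect_equal(V5["A", "B"], 0.5)
  expect_equal(unname(diag(V5)), unname(diag(V)))
  # delta on a unit-normalized ultrametric tree: elementwise power
  Vd <- pagel_transform(V, 1, 2)
  expect_equal(Vd["A", "B"], (1 / 2)^2)
  expect_equal(unname(diag(Vd)), rep(1, 3))
  expect_error(pagel_transform(V, 1.2), "lambda")
  expect_error(pagel_transform(V, 1, -1), "delta")
})

test_that("GLS with identity covariance reduces exactly to OLS", {
  set.seed(10)
  n <- 30
  d <- data.frame(species = paste0("t", 1:n), x = rnorm(n))
  d$y <- 1 + 2 * d$x + rnorm(n)
  star <- ape::read.tree(text = paste0("(",
    paste(sprintf("t%d:1", 1:n), collapse = ","), ");"))
  fit <- pgls(y ~ x, d, star, lambda = 1)  # star tree: V = I
  ols <- lm(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-10)
  expect_equal(fit$adj_r2, summary(ols)$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit$fstatistic, unname(summary(ols)$fstatistic[1]),
               tolerance = 1e-10)
  # exact linear data: perfect fit
  d$y <- 2 + 3 * d$x
  perfect <- pgls(y ~ x, d, star)
  expect_equal(unname(coef(perfect)), c(2, 3), tolerance = 1e-9)
  expect_equal(max(abs(perfect$residuals)), 0, tolerance = 1e-9)
  expect_equal(perfect$adj_r2, 1, tolerance = 1e-9)
})

test_that("three-taxon fit matches the explicit matrix-algebra solution", {
  tr <- three_taxon_tree()
  d <- data.frame(species = c("A", "B", "C"), y = c(1.2, 0.7, -0.4),
                  x = c(0.5, -0.2, 0.1))
  fit <- pgls(y ~ x, d, tr, lambda = 1)
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3)  # hand-counted paths
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% solve(V) %*% X) %*% t(X) %*% solve(V) %*% d$y
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-10)
  # residual GLS orthogonality: X' V^-1 e = 0
  e <- d$y - X %*% beta
  expect_equal(drop(t(X) %*% solve(V) %*% e), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(drop(t(fit$X) %*% solve(V) %*%
                             unclass(fit$residuals))),
               c(0, 0), tolerance = 1e-10)
})

test_that("fits agree with the nlme/ape reference implementation", {
  skip_if_not_installed("nlme")
  tr <- sim_tree(60, seed = 7)
  d <- sim_brownian_traits(tr, lambda = 0.6, beta = c(1, 0.8), seed = 8)
  fit <- pgls(y ~ x1, d, tr, lambda = "ML")
  ref <- nlme::gls(y ~ x1, data = d,
                   correlation = ape::corPagel(0.5, tr, form = ~species),
                   method = "ML")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$lambda,
               unname(coef(ref$modelStruct$corStruct)), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  # fixed lambda: exact agreement of coefficients and standard errors
  fit5 <- pgls(y ~ x1, d, tr, lambda = 0.5)
  ref5 <- nlme::gls(y ~ x1, data = d,
                    correlation = ape::corPagel(0.5, tr, form = ~species,
                                                fixed = TRUE),
                    method = "ML")
  expect_equal(unname(coef(fit5)), unname(coef(ref5)), tolerance = 1e-10)
  expect_equal(unname(fit5$se), unname(sqrt(diag(vcov(ref5)))),
               tolerance = 1e-8)
})

test_that("scale of the covariance does not affect inference", {
  tr <- sim_tree(25, seed = 15)
  d <- sim_brownian_traits(tr, lambda = 0.8, beta = c(0, 1), seed = 16)
  V <- phylo_vcv(tr, species = d$species)
  f1 <- weedshift:::.gls_core(d$y, cbind(1, d$x1), V)
  f2 <- weedshift:::.gls_core(d$y, cbind(1, d$x1), 7.3 * V)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$tval, f2$tval, tolerance = 1e-10)
  expect_equal(f1$pval, f2$pval, tolerance = 1e-10)
})

test_that("ML at fixed parameter values equals the fixed fit", {
  tr <- sim_tree(30, seed = 17)
  d <- sim_brownian_traits(tr, lambda = 0.5, beta = c(0, 1), seed = 18)
  ml <- pgls(y ~ x1, d, tr, lambda = "ML")
  fixed <- pgls(y ~ x1, d, tr, lambda = ml$lambda)
  expect_identical(coef(ml), coef(fixed))
  expect_identical(fixed$loglik, ml$loglik)
  # ML optimum beats a fixed 21-point grid audit
  grid_ll <- vapply(seq(0, 1, length.out = 21), function(l)
    pgls(y ~ x1, d, tr, lambda = l)$loglik, numeric(1))
  expect_gte(ml$loglik + 1e-8, max(grid_ll))
})

test_that("likelihood-ratio test behaves at the boundary and under signal", {
  tr <- sim_tree(40, seed = 19)
  d <- sim_brownian_traits(tr, lambda = 0, beta = c(0, 1), seed = 20)
  f0 <- pgls(y ~ x1, d, tr, lambda = 0)
  lrt0 <- lambda_lrt(f0)
  expect_equal(unname(lrt0$statistic), 0, tolerance = 1e-9)
  expect_equal(lrt0$p.value, 1)
  d1 <- sim_brownian_traits(tr, lambda = 1, beta = c(0, 1), seed = 21)
  lrt1 <- lambda_lrt(pgls(y ~ x1, d1, tr, lambda = "ML"))
  expect_gte(unname(lrt1$statistic), 0)
})

test_that("pgls methods are coherent", {
  tr <- sim_tree(30, seed = 23)
  d <- sim_brownian_traits(tr, lambda = 0.7, beta = c(1, 2), seed = 24)
  fit <- pgls(y ~ x1, d, tr, lambda = "ML")
  expect_equal(unname(fitted(fit) + residuals(fit)), d$y)
  expect_equal(unname(predict(fit, d)), unname(fitted(fit)))
  expect_equal(nobs(fit), 30)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(30, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  # normalized residuals are decorrelated: unit variance scale
  rn <- residuals(fit, type = "normalized")
  expect_equal(length(rn), 30)
  expect_output(print(summary(fit)), "lambda")
})
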