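test_that("all-quantitative tables reduce to correlation PCA", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40, 6) %*% diag(c(3, 2, 1, 1, 0.5, 0.2))
  X[, 2] <- X[, 1] * 0.6 + X[, 2]
  td <- data.frame(species = sprintf("s%02d", 1:40), X)
  ord <- hill_smith(td, n_axes = 6)
  expect_equal(ord$eig, eigen(cor(X), symmetric = TRUE)$values,
               tolerance = 1e-8)
  expect_equal(ord$total_inertia, 6, tolerance = 1e-10)
  expect_equal(sum(ord$pct_inertia), 100, tolerance = 1e-10)
  # design equals the z-scored matrix (population sd)
  des <- build_mixed_design(td)
  Z <- scale(X) * sqrt(40 / 39)
  expect_equal(des$Z, Z, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("qualitative traits expand to frequency-weighted indicators", {
  td <- data.frame(species = paste0("s", 1:10),
                   q = rnorm(10),
                   bin = rep(c("yes", "no"), c(3, 7)))
  des <- build_mixed_design(td)
  expect_equal(ncol(des$Z), 3)  # 1 quantitative + 2 indicator columns
  p <- 0.3
  expect_equal(unname(des$Z[1, "bin.yes"]), (1 - p) / sqrt(p))
  expect_equal(unname(des$Z[10, "bin.yes"]), -p / sqrt(p))
  # binary trait contributes 2 - 1 = 1 to the inertia
  ord <- hill_smith(td, n_axes = 2)
  expect_equal(ord$total_inertia, 2, tolerance = 1e-10)
  # mixed schema column count: 11 quantitative + 13 qualitative levels
  tt <- sim_trait_table(95, seed = 32)
  expect_equal(nrow(hill_smith(tt, n_axes = 6)$contributions), 24)
  expect_error(build_mixed_design(data.frame(species = c("a", "b"),
                                             q = c(1, 1))), "constant")
})

test_that("eigenvalue sum conserves the design inertia on mixed tables", {
  for (seed in 1:5) {
    tt <- sim_trait_table(30, seed = 40 + seed)
    ord <- hill_smith(tt, n_axes = 4)
    sch <- trait_schema()
    expected <- length(sch$quantitative) +
      sum(vapply(names(sch$qualitative), function(q)
        length(unique(tt[[q]])) - 1L, integer(1)))
    expect_equal(ord$total_inertia, expected, tolerance = 1e-8)
    expect_true(all(diff(ord$eig) <= 1e-10))  # nonincreasing
    expect_equal(colSums(abs(ord$contributions)),
                 structure(rep(100, 4), names = colnames(ord$contributions)),
                 tolerance = 1e-8)
  }
})

test_that("scores respect duplication, row order and sign conventions", {
  tt <- sim_trait_table(20, seed = 51)
  ord <- hill_smith(tt, n_axes = 3)
  # duplicated trait rows (fresh species ids) get identical scores
  dup <- rbind(tt, transform(tt[3, ], species = "dupsp"))
  od <- hill_smith(dup, n_axes = 3)
  expect_equal(unname(od$row_scores["sp003", ]),
               unname(od$row_scores["dupsp", ]), tolerance = 1e-10)
  # row permutation leaves per-species scores unchanged
  perm <- tt[sample(nrow(tt)), ]
  op <- hill_smith(perm, n_axes = 3)
  expect_equal(op$row_scores[rownames(ord$row_scores), ],
               ord$row_scores, tolerance = 1e-8)
  # orientation: the dominant loading of each axis is positive
  for (k in 1:3)
    expect_gt(max(ord$col_scores[, k]), abs(min(ord$col_scores[, k])) - 1e-12)
  # negating a quantitative column flips its loadings/contributions only
  tt2 <- tt; tt2$sla <- -tt2$sla
  o2 <- hill_smith(tt2, n_axes = 3)
  expect_equal(o2$eig, ord$eig, tolerance = 1e-10)
  expect_equal(abs(o2$contributions["sla", ]),
               abs(ord$contributions["sla", ]), tolerance = 1e-8)
})

test_that("single and orthogonal designs place all inertia as expected", {
  td1 <- data.frame(species = paste0("s", 1:12), q = rnorm(12))
  o1 <- hill_smith(td1, n_axes = 1)
  expect_equal(unname(o1$contributions[1, 1]), 100, tolerance = 1e-10)
  # two exactly uncorrelated variables: one axis each, 100% contribution
  td2 <- data.frame(species = paste0("s", 1:4),
                    x = c(1, -1, 1, -1), y = c(1, 1, -1, -1))
  o2 <- hill_smith(td2, n_axes = 2)
  expect_equal(sort(abs(as.vector(o2$contributions))),
               c(0, 0, 100, 100), tolerance = 1e-8)
})

test_that("axis scores join cleanly and reproduce single-trait PGLS", {
  tt <- sim_trait_table(40, seed = 61)
  tr <- sim_tree(40, seed = 62)
  ord <- hill_smith(tt, n_axes = 6)
  ax <- axis_scores(ord, axes = 1:6)
  expect_equal(names(ax), c("species", paste0("Axis", 1:6)))
  expect_error(axis_scores(ord, axes = 9), "unknown axis")
  # a one-variable ordination's axis is the z-scored trait, so PGLS on
  # the axis reproduces the single-trait PGLS up to scale
  one <- data.frame(species = tt$species, sla = tt$sla)
  oa <- axis_scores(hill_smith(one, n_axes = 1))
  d <- sim_brownian_traits(tr, lambda = 0.5, beta = 0, seed = 63)
  d$axis <- oa$Axis1[match(d$species, oa$species)]
  d$sla <- tt$sla[match(d$species, tt$species)]
  f_axis <- pgls(y ~ axis, d, tr, lambda = 0.5)
  f_trait <- pgls(y ~ sla, d, tr, lambda = 0.5)
  expect_equal(unname(f_axis$tval[2]), unname(f_trait$tval[2]),
               tolerance = 1e-8)
  expect_equal(unname(f_axis$pval[2]), unname(f_trait$pval[2]),
               tolerance = 1e-8)
})
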