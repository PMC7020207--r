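test_that("midpoint mean abundance reproduces hand arithmetic", {
  expect_equal(mean_local_abundance(0, 0, 0, 4), 1.5)
  expect_equal(mean_local_abundance(0, 0, 1, 1), 75.5)
  # (2*11.5 + 35.5 + 75.5 + 6*1.5) / 10
  expect_equal(mean_local_abundance(2, 1, 1, 10), 14.3)
})

test_that("mean abundance is bounded, scale-invariant, and signals N = 0", {
  set.seed(42)
  for (i in 1:200) {
    N <- sample(1:50, 1)
    n3 <- sample(0:N, 1)
    n4 <- sample(0:(N - n3), 1)
    n5 <- sample(0:(N - n3 - n4), 1)
    n345 <- c(n3, n4, n5)
    a <- mean_local_abundance(n345[1], n345[2], n345[3], N)
    expect_gte(a, 1.5)
    expect_lte(a, 75.5)
    k <- sample(2:5, 1)  # linearity under integer scaling of all counts
    expect_equal(mean_local_abundance(k * n345[1], k * n345[2],
                                      k * n345[3], k * N), a)
  }
  expect_error(mean_local_abundance(0, 0, 0, 0), "undefined")
  expect_error(mean_local_abundance(3, 0, 0, 2), "exceed")
})

test_that("change index matches closed form and its symmetries", {
  expect_equal(change_index(5, 5), 0)
  expect_equal(change_index(0, 3), 1)
  expect_equal(change_index(3, 0), -1)
  expect_equal(change_index(26.5, 39.1), 0.192, tolerance = 5e-3)
  set.seed(7)
  a <- runif(100, 0, 50); b <- runif(100, 0, 50)
  ch <- change_index(a, b)
  expect_true(all(ch >= -1 & ch <= 1))
  expect_equal(change_index(b, a), -ch)  # antisymmetry under period swap
  # strictly increasing in the new value
  expect_true(all(diff(change_index(10, c(1, 5, 10, 20, 40))) > 0))
  expect_error(change_index(0, 0), "undefined")
})

test_that("regional frequency counts distinct fields under the plot filter", {
  s <- tiny_survey()
  f <- regional_frequency(s, period = "P2000s")
  expect_equal(unname(f["chealb"]), 1.0)   # present in all 3 fields
  expect_equal(unname(f["echcru"]), 1 / 3)
  # a field visited twice counts once
  s2 <- rbind(s, data.frame(field_id = "f1", year = 2005L,
                            period = "P2000s", region = "East",
                            crop = "maize", plot = "control",
                            species = "chealb", score = "2",
                            stringsAsFactors = FALSE))
  expect_equal(unname(regional_frequency(s2)["chealb"]), 1.0)
  # species present only in treated plots is absent from control output
  s3 <- rbind(s, data.frame(field_id = "f2", year = 2003L,
                            period = "P2000s", region = "East",
                            crop = "maize", plot = "treated",
                            species = "setpum", score = "4",
                            stringsAsFactors = FALSE))
  expect_false("setpum" %in% names(regional_frequency(s3, plot = "control")))
  expect_error(regional_frequency(s, period = "P1970s"), "empty")
})

test_that("field-level aggregation keeps the maximum class per field", {
  s <- tiny_survey()
  s <- rbind(s, data.frame(field_id = "f3", year = 2004L,
                           period = "P2000s", region = "East",
                           crop = "maize", plot = "control",
                           species = "chealb", score = "4",
                           stringsAsFactors = FALSE))
  ss <- species_summary(s)
  row <- ss[ss$species == "chealb", ]
  expect_equal(row$N, 3)       # three distinct fields
  expect_equal(row$n4, 1)      # f3's max class is 4, not 1
  expect_equal(row$A, (11.5 + 75.5 + 35.5) / 3)
})

test_that("fidelity partitions midpoint individuals across crops", {
  mk <- function(crop, species, score, field)
    data.frame(field_id = field, year = 2002L, period = "P2000s",
               region = "East", crop = crop, plot = "control",
               species = species, score = score, stringsAsFactors = FALSE)
  s <- rbind(mk("maize", "only_maize", "3", "m1"),
             mk("maize", "split", "2", "m1"),
             mk("wheat", "split", "2", "w1"),
             mk("wheat", "only_wheat", "5", "w1"))
  fid <- crop_fidelity(s, "maize")
  expect_equal(unname(fid["only_maize"]), 100)
  expect_equal(unname(fid["split"]), 50)  # identical profile in both crops
  expect_equal(unname(fid["only_wheat"]), 0)
  # hand arithmetic: 1.5 in maize vs 1.5 + 2 * 11.5 elsewhere
  s2 <- rbind(mk("maize", "sp", "1", "m1"),
              mk("wheat", "sp", "1", "w1"),
              mk("wheat", "sp", "3", "w2"),
              mk("barley", "sp", "3", "b1"))
  expect_equal(unname(crop_fidelity(s2, "maize")["sp"]),
               100 * 1.5 / (1.5 + 1.5 + 11.5 + 11.5))
  # partition property: fidelities over all crops sum to 100
  tot <- crop_fidelity(s, "maize") + crop_fidelity(s, "wheat")
  expect_equal(unname(tot), rep(100, 3))
  expect_error(crop_fidelity(s, "maize", species = "absent"), "undefined")
})

test_that("density discretization respects the class boundaries", {
  expect_equal(density_to_class(1 / 2000), "+")  # singleton in the plot
  expect_equal(density_to_class(c(0.01, 0.99)), c("1", "1"))
  expect_equal(density_to_class(c(1, 2, 2.99)), c("2", "2", "2"))
  expect_equal(density_to_class(c(3, 12, 20)), c("3", "3", "3"))
  expect_equal(density_to_class(c(20.001, 35, 50)), c("4", "4", "4"))
  expect_equal(density_to_class(c(50.001, 1000)), c("5", "5"))
  set.seed(1)
  d <- runif(500, 3, 20)
  expect_true(all(density_to_class(d) == "3"))
  d <- runif(500, 20.0001, 50)
  expect_true(all(density_to_class(d) == "4"))
  d <- runif(500, 50.0001, 500)
  expect_true(all(density_to_class(d) == "5"))
})
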