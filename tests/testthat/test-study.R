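test_that("the run plan is scenarios x geometries plus one pretreatment each", {
  hr <- hr_scenarios()
  plan <- enumerate_runs(hr, paste0("G", 1:5))
  expect_identical(sum(plan$deployment != "pretreatment"), 80L)
  expect_identical(sum(plan$deployment == "pretreatment"), 5L)
  plan1 <- enumerate_runs(hr, "G1")
  expect_identical(sum(plan1$deployment != "pretreatment"), 16L)
  expect_identical(sum(plan1$deployment == "pretreatment"), 1L)
  expect_identical(nrow(enumerate_runs(hr, character(0))), 0L)
  bad <- rbind(hr, hr[1, ])
  expect_error(enumerate_runs(bad, "G1"), "duplicate")
})

test_that("power-law fitting recovers exact and noisy relationships", {
  lc <- c(5, 12, 30, 70, 140, 186)
  fit <- fit_power_law(lc, 0.1 * lc^0.3)
  expect_equal(fit$a, 0.1, tolerance = 1e-9)
  expect_equal(fit$b, 0.3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- fit_power_law(lc, rep(0.4, 6))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0, tolerance = 1e-12)
  set.seed(42)
  noisy <- 0.1 * lc^0.3 * exp(rnorm(6, sd = 0.05))
  expect_equal(fit_power_law(lc, noisy)$b, 0.3, tolerance = 0.1)
  expect_error(fit_power_law(c(-1, 2, 3), c(0.1, 0.2, 0.3)), "positive")
  expect_warning(fit_power_law(lc, c(-0.1, 0.1, 0.2, 0.3, 0.4, 0.5)), "excluded")
})

test_that("Welch's test from summaries reproduces published group contrasts", {
  w1 <- welch_from_summaries(51.9, 11.8, 20, 60.3, 9.5, 15)
  expect_gt(w1$p_value, 0.024); expect_lt(w1$p_value, 0.028)
  w2 <- welch_from_summaries(25.7, 9.4, 20, 27.5, 8.8, 25)
  expect_gt(w2$p_value, 0.50); expect_lt(w2$p_value, 0.53)
  expect_equal(welch_from_summaries(10, 2, 5, 10, 3, 8)$p_value, 1)
  expect_error(welch_from_summaries(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("group statistics agree with the summary-based Welch test", {
  set.seed(7)
  mk <- function(dev, dep, n, mu, sdv) {
    data.frame(device = dev, deployment = dep, amvr = rnorm(n, mu, sdv) / 100)
  }
  res <- rbind(mk("PED", "nominal", 20, 52, 12), mk("P64", "nominal", 15, 60, 9),
               mk("PED", "oversized", 20, 26, 9), mk("P64", "oversized", 25, 27, 9))
  gs <- group_stats(res)
  for (dep in c("nominal", "oversized")) {
    sub <- res[res$deployment == dep, ]
    g1 <- 100 * sub$amvr[sub$device == "P64"]
    g2 <- 100 * sub$amvr[sub$device == "PED"]
    w <- welch_from_summaries(mean(g1), sd(g1), length(g1),
                              mean(g2), sd(g2), length(g2))
    expect_equal(gs$tests[[dep]]$p_value, w$p_value, tolerance = 1e-3)
  }
  # identical groups give p = 1
  same <- rbind(mk("PED", "nominal", 10, 50, 5), mk("P64", "nominal", 10, 50, 5))
  same$amvr <- rep(same$amvr[1:10], 2)
  expect_equal(group_stats(same)$tests$nominal$p_value, 1)
})

test_that("threshold classification is inclusive at the boundary", {
  res <- data.frame(device = "PED", deployment = "nominal",
                    amvr = c(0.35, 0.349, 0, 0.6))
  tc <- threshold_classification(res)
  expect_identical(tc$runs$pass, c(TRUE, FALSE, FALSE, TRUE))
  allz <- data.frame(device = "PED", deployment = "nominal", amvr = rep(0, 4))
  expect_true(all(!threshold_classification(allz)$runs$pass))
  set.seed(11)
  mixed <- data.frame(device = "PED", deployment = "nominal",
                      amvr = runif(50))
  tc2 <- threshold_classification(mixed, 0.4)
  expect_identical(sum(tc2$runs$pass), sum(mixed$amvr >= 0.4))
})
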