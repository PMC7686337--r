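test_that("fixed-effects pooling reproduces hand-evaluated examples", {
  p <- pool_fixed(c(0, 2), c(1, 1))
  expect_equal(p$estimate, 1)
  expect_equal(p$se, 1 / sqrt(2))

  p2 <- pool_fixed(c(0, 1), c(1, 0.5))
  expect_equal(p2$estimate, 0.8)       # (0*1 + 1*4) / 5

  p3 <- pool_fixed(c(1, 1, 1), c(0.3, 1, 2))
  expect_equal(p3$estimate, 1)
  expect_equal(p3$Q, 0)
  expect_equal(p3$i2, 0)

  expect_warning(p1 <- pool_fixed(2, 0.5), "single estimate")
  expect_equal(p1$estimate, 2)
  expect_true(is.na(p1$Q))
})

test_that("heterogeneity matches the Higgins definition and class boundaries", {
  # construct k = 6 with Q = 10 -> I2 = 50%, moderate
  est <- c(rep(0, 5), sqrt(10 * 1.2))
  w <- rep(1, 6); pooled <- sum(est) / 6
  Q <- sum((est - pooled)^2)
  h <- heterogeneity(est, rep(1, 6))
  expect_equal(h$Q, Q, tolerance = 1e-12)
  expect_equal(h$i2, max(0, 100 * (Q - 5) / Q), tolerance = 1e-12)
  # floor: Q < k-1 gives exactly 0
  expect_equal(heterogeneity(c(1, 1.01, 0.99), c(1, 1, 1))$i2, 0)
  # class boundaries at 50 and 75 (I2 = 50 is moderate, not low)
  mk <- function(i2_target, k = 6) {
    # k estimates with Q solving I2 = 100 (Q - (k-1))/Q
    Q <- (k - 1) / (1 - i2_target / 100)
    x <- c(rep(0, k - 1), sqrt(Q * k / (k - 1)))
    heterogeneity(x, rep(1, k))
  }
  expect_equal(mk(50)$i2, 50, tolerance = 1e-9)
  expect_equal(mk(50 + 1e-6)$class, "moderate")
  expect_equal(mk(74.9)$class, "moderate")
  expect_equal(mk(75 + 1e-6)$class, "high")
  expect_equal(mk(20)$class, "low")
})

test_that("pooling matches brute-force formula evaluation to 1e-10", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:20, 1)
    est <- rnorm(k)
    se <- runif(k, 0.1, 2)
    p <- pool_fixed(est, se)
    w <- 1 / se^2
    expect_equal(p$estimate, sum(w * est) / sum(w), tolerance = 1e-10)
    expect_equal(p$se, sqrt(1 / sum(w)), tolerance = 1e-10)
    Q <- sum(w * (est - sum(w * est) / sum(w))^2)
    expect_equal(p$Q, Q, tolerance = 1e-10)
    expect_equal(p$i2, max(0, 100 * (Q - (k - 1)) / Q), tolerance = 1e-10)
    expect_equal(p$p, pchisq(Q, k - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("pooling agrees with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  set.seed(12)
  est <- rnorm(8, 0.5, 0.3)
  se <- runif(8, 0.1, 0.5)
  ours <- pool_fixed(est, se)
  ref <- metafor::rma(yi = est, sei = se, method = "FE")
  expect_equal(ours$estimate, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se, ref$se, tolerance = 1e-8)
  expect_equal(ours$Q, ref$QE, tolerance = 1e-8)
})

test_that("rescaling all SEs by c preserves the estimate and scales the SE", {
  set.seed(3)
  est <- rnorm(5); se <- runif(5, 0.2, 1)
  a <- pool_fixed(est, se)
  b <- pool_fixed(est, 3 * se)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(b$se, 3 * a$se, tolerance = 1e-12)
})

test_that("build_pooled_tables pools logistic terms on the log scale and exponentiates", {
  fits <- data.frame(
    site = rep(c("a", "b", "c"), 2),
    stratum = "all", outcome = "sarcopenia",
    term = rep(c("sexmale", "age"), each = 3),
    estimate = c(1.0, 1.1, 0.9, 0.12, 0.10, 0.14),
    se = rep(0.2, 6), n = 100, flagged = FALSE,
    stringsAsFactors = FALSE)
  out <- build_pooled_tables(fits)
  m <- out[out$term == "sexmale", ]
  expect_equal(m$estimate, 1.0, tolerance = 1e-12)
  expect_equal(m$or, exp(1.0))
  expect_equal(m$or_low, exp(m$ci_low))
  expect_equal(m$k, 3)
  # identical fits across sites pool to the common value with I2 = 0
  same <- fits; same$estimate <- rep(c(1, 0.1), each = 3)
  out2 <- build_pooled_tables(same)
  expect_equal(out2$i2, c(0, 0))
  # flagged sites are excluded from the pool
  fits$flagged[1] <- TRUE
  out3 <- suppressMessages(build_pooled_tables(fits))
  expect_equal(out3$k[out3$term == "sexmale"], 2)
  # dropping a site moves the pool to the re-derived inverse-variance mean
  sub <- fits[fits$term == "sexmale" & !fits$flagged, ]
  expect_equal(out3$estimate[out3$term == "sexmale"],
               sum(sub$estimate / sub$se^2) / sum(1 / sub$se^2),
               tolerance = 1e-12)
})

test_that("terms in fewer than two sites pass through unpooled", {
  fits <- data.frame(site = "a", stratum = "all", outcome = "smi",
                     term = "age", estimate = 0.1, se = 0.02, n = 50,
                     flagged = FALSE, stringsAsFactors = FALSE)
  out <- build_pooled_tables(fits)
  expect_false(out$pooled)
  expect_true(is.na(out$i2))
})
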