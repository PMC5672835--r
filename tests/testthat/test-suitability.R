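test_that("niche fitting recovers mean and covariance and rejects degeneracy", {
  set.seed(71)
  X <- matrix(rnorm(20000), ncol = 2)
  m <- fit_niche(X)
  expect_equal(unname(m$mu), c(0, 0), tolerance = 0.05)
  expect_equal(unname(diag(m$sigma)), c(1, 1), tolerance = 0.05)
  expect_lt(abs(m$sigma[1, 2]), 0.05)

  ## row order is irrelevant
  m2 <- fit_niche(X[sample(nrow(X)), ])
  expect_equal(m2$mu, m$mu)
  expect_equal(m2$sigma, m$sigma)

  expect_error(fit_niche(matrix(1, 10, 2)), "singular")
  dup <- cbind(rnorm(50), 0)
  dup[, 2] <- 2 * dup[, 1]          # exact collinearity
  expect_error(fit_niche(dup), "singular")
  expect_message(fit_niche(rbind(dup, c(0, 0.1)) + rnorm(102, 0, 1e-9),
                           ridge = 1e-3), "ridge")
})

test_that("suitability is the chi-square survival of Mahalanobis distance", {
  rut <- structure(
    data.frame(ru_id = 1:3, x = 0, y = 0, v = c(0, 2, 5)),
    class = c("ru_table", "data.frame"),
    prop_cols = character(), cont_cols = "v")
  model <- structure(list(mu = c(v = 0), sigma = matrix(1, 1, 1), p = 1L,
                          n = 100L, condition = 1), class = "niche_model")
  sm <- suitability_map(rut, model)
  expect_equal(sm$d2, c(0, 4, 25))
  expect_equal(sm$suitability[1], 1)
  expect_equal(sm$suitability[2], pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(sm$suitability[2], 0.0455, tolerance = 1e-3)
  ## suitability strictly decreases with distance
  expect_true(all(diff(sm$suitability) < 0))
})

test_that("Fi curve normalizes, ratios, and thresholds correctly", {
  ## two effective classes with E = (0.5, 0.5), P = (0.2, 0.8)
  cells <- c(rep(0.51, 50), rep(0.99, 50))
  pts <- c(rep(0.51, 20), rep(0.99, 80))
  fc <- fi_curve(cells, pts, n_classes = 20)
  expect_equal(fc$classes$F, c(0.4, 1.6))
  expect_equal(sum(fc$classes$E), 1)
  expect_equal(sum(fc$classes$P), 1)
  expect_equal(fc$threshold, 0.95)

  ## uniform evaluation points give F close to 1 everywhere
  set.seed(72)
  cs <- runif(20000)
  fu <- fi_curve(cs, sample(cs, 5000), n_classes = 10)
  expect_true(all(abs(fu$classes$F - 1) < 0.15))

  ## threshold is the first upcrossing that stays above 1
  fcx <- fi_curve(c(rep(0.11, 25), rep(0.31, 25), rep(0.51, 25),
                    rep(0.71, 25)),
                  c(rep(0.11, 5), rep(0.31, 40), rep(0.51, 15),
                    rep(0.71, 40)),
                  n_classes = 10)
  ## F = (0.2, 1.6, 0.6, 1.6): class at 0.30 crosses 1 but dips after, so
  ## the sustained threshold is at 0.70
  expect_equal(fcx$classes$F, c(0.2, 1.6, 0.6, 1.6))
  expect_equal(fcx$threshold, 0.7)

  expect_error(fi_curve(cs, NA_real_), "no evaluation points")
})

test_that("Boyce index ranks the Fi curve", {
  up <- structure(list(classes = data.frame(F = c(0.2, 0.5, 1.1, 1.9),
                                            class = 1:4)),
                  class = "fi_curve")
  b <- boyce_index(up)
  expect_equal(b$spearman, 1)
  down <- up; down$classes$F <- rev(up$classes$F)
  expect_equal(boyce_index(down)$spearman, -1)
  two <- structure(list(classes = data.frame(F = c(0.4, 1.6), class = 1:2)),
                   class = "fi_curve")
  expect_equal(boyce_index(two)$spearman, 1)
  flat <- up; flat$classes$F <- rep(1, 4)
  expect_message(bf <- boyce_index(flat), "constant")
  expect_true(is.na(bf$spearman))
})

test_that("reclassification is monotone in the threshold and zone-aware", {
  set.seed(73)
  suit <- runif(500)
  zone <- rep(1:2, each = 250)
  r0 <- reclassify_suitability(suit, 0, zone)
  expect_equal(r0$percent_suitable, 100)
  r1 <- reclassify_suitability(suit, 1 + 1e-9, zone)
  expect_equal(r1$percent_suitable, 0)
  ths <- seq(0, 1, by = 0.1)
  pct <- vapply(ths, function(t)
    reclassify_suitability(suit, t)$percent_suitable, 0)
  expect_true(all(diff(pct) <= 0))
  rz <- reclassify_suitability(suit, 0.5, zone)
  expect_equal(nrow(rz$by_zone), 2L)
  expect_equal(mean(rz$by_zone$percent_suitable),
               rz$percent_suitable, tolerance = 1)
})
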