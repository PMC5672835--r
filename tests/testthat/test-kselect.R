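test_that("standardization centres, scales, and is idempotent", {
  set.seed(51)
  X <- cbind(a = rnorm(200, 10, 2), b = runif(200))
  z <- toy_z(X)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  ## value 14 in a column with mean 10, sd 2 -> 2 standard units
  expect_equal(unname((14 - attr(z, "center")["a"]) / attr(z, "scale")["a"]),
               (14 - mean(X[, "a"])) / sd(X[, "a"]))
  z2 <- toy_z(as.matrix(as.data.frame(z)))
  expect_equal(unname(z2[, ]), unname(z[, ]), tolerance = 1e-12)

  expect_warning(toy_z(cbind(a = rnorm(10), k = rep(1, 10))), "constant")
  expect_error(toy_z(cbind(k = rep(1, 10))), "constant")
})

test_that("marginality is the used-minus-available mean difference", {
  X <- cbind(v = c(-1, -1, 1, 1))
  z <- toy_z(X)
  ## sd of (-1,-1,1,1) is 2/sqrt(3); used mean 1 maps to sqrt(3)/2... work in
  ## raw units via a two-value column standardized to +-1 exactly
  Xb <- cbind(v = c(-1, 1))
  zb <- toy_z(rbind(Xb, Xb))          # {-1, 1} duplicated, sd-scaled
  m0 <- marginality(1:4, 1:4, zb)
  expect_equal(unname(m0$m), 0)
  expect_equal(m0$norm2, 0)

  ## used only the +1 RUs: m = standardized(+1) - 0
  m1 <- marginality(c(2, 4), 1:4, zb)
  expect_equal(m1$norm2, unname(zb[2, 1]^2))
  expect_gt(m1$norm2, 0)

  ## duplicating every available RU leaves the marginality unchanged
  m2 <- marginality(c(2, 4), c(1:4, 1:4), zb)
  expect_equal(m1$m, m2$m)

  expect_error(marginality(c(1, 9), 1:4, zb), "outside availability")
})

test_that("K-select eigenanalysis matches the 2-animal orthogonal fixture", {
  marg <- list(structure(list(m = c(2, 0), norm2 = 4, n_used = 10,
                              animal_id = "a"), class = "marginality"),
               structure(list(m = c(0, 1), norm2 = 1, n_used = 10,
                              animal_id = "b"), class = "marginality"))
  ks <- kselect(marg)
  expect_equal(ks$eigenvalues, c(2, 0.5))
  expect_equal(sum(ks$eigenvalues), mean(c(4, 1)))
  expect_equal(abs(ks$loadings[, 1]), c(1, 0))
  expect_equal(unname(abs(ks$scores[, 1])), c(2, 0))

  ## single animal: first eigenvalue is the squared marginality
  ks1 <- kselect(marg[1])
  expect_equal(ks1$eigenvalues[1], 4)
  expect_equal(ks1$eigenvalues[2], 0)
})

test_that("eigenvalues are rotation invariant; their sum conserves marginality", {
  set.seed(52)
  for (rep in 1:8) {
    K <- sample(2:6, 1); p <- sample(2:5, 1)
    M <- matrix(rnorm(K * p), K, p)
    w <- rgamma(K, 1); w <- w / sum(w)
    marg <- lapply(seq_len(K), function(k)
      structure(list(m = M[k, ], norm2 = sum(M[k, ]^2), n_used = 5,
                     animal_id = k), class = "marginality"))
    ks <- kselect(marg, w)
    expect_equal(sum(ks$eigenvalues), sum(w * rowSums(M^2)),
                 tolerance = 1e-10)
    expect_true(all(diff(ks$eigenvalues) <= 1e-12))

    Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
    margR <- lapply(seq_len(K), function(k)
      structure(list(m = as.vector(M[k, ] %*% Q), norm2 = sum(M[k, ]^2),
                     n_used = 5, animal_id = k), class = "marginality"))
    expect_equal(kselect(margR, w)$eigenvalues, ks$eigenvalues,
                 tolerance = 1e-9)
  }
})

test_that("randomization p-values use the add-one estimator with tie = exceed", {
  set.seed(53)
  X <- cbind(a = rnorm(60), b = rnorm(60))
  z <- toy_z(X)
  m <- marginality(1:10, 1:60, z)
  ## N = 1: whatever the draw, p is 0.5 or 1
  r1 <- marginality_randomization(m, 1:60, z, N = 1, seed = 99)
  expect_true(r1$p_value %in% c(0.5, 1))
  expect_equal(r1$p_value,
               (1 + sum(r1$null >= m$norm2)) / 2)
  ## extreme selector: observed above every randomized value
  top <- order(z[, "a"], decreasing = TRUE)[1:5]
  mx <- marginality(top, 1:60, z)
  rx <- marginality_randomization(mx, 1:60, z, N = 500, seed = 100)
  expect_equal(rx$p_value, 1 / 501)
  expect_error(marginality_randomization(m, 1:5, z), "fewer used")
})

test_that("first-eigenvalue test reduces to the marginality test for K = 1", {
  set.seed(54)
  X <- cbind(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  z <- toy_z(X)
  m <- marginality(1:12, 1:80, z, animal_id = "solo")
  pm <- marginality_randomization(m, 1:80, z, N = 300, seed = 7)
  pe <- first_eigenvalue_test(list(m), list(1:80), z, N = 300, seed = 7)
  expect_equal(pe$observed, m$norm2)
  expect_equal(pe$p_value, pm$p_value)
  expect_equal(pe$null, pm$null)
})

test_that("Bonferroni per-test levels follow alpha over K", {
  expect_equal(bonferroni_alpha(6), 0.05 / 6)
  expect_equal(bonferroni_alpha(8), 0.05 / 8)
  expect_equal(bonferroni_alpha(4, alpha = 0.1), 0.025)
  expect_error(bonferroni_alpha(0))
})
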