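test_that("aggregation counts class proportions and averages within blocks", {
  cover <- raster_grid(matrix(c(1, 1, 1,
                                2, 2, 2,
                                1, 1, 1), 3, 3, byrow = TRUE), 30,
                       categorical = TRUE)
  elev <- raster_grid(matrix(300, 3, 3), 30)
  agg <- aggregate_to_ru(cover, list(elevation = elev), factor = 3)
  rut <- agg$rut
  expect_equal(nrow(rut), 1L)
  expect_equal(rut$prop_1, 6 / 9)
  expect_equal(rut$prop_2, 3 / 9)
  expect_equal(rut$elevation, 300)
  expect_equal(rut$dominant, 1)
})

test_that("factor 1 aggregation reproduces the fine grid row for row", {
  set.seed(21)
  vals <- matrix(sample(1:3, 25, replace = TRUE), 5, 5)
  elev <- matrix(rnorm(25, 300, 20), 5, 5)
  agg <- aggregate_to_ru(raster_grid(vals, 30, categorical = TRUE),
                         list(elevation = raster_grid(elev, 30)), factor = 1)
  expect_equal(nrow(agg$rut), 25L)
  expect_equal(agg$rut$elevation, as.vector(t(elev)))
  expect_equal(agg$rut$dominant, as.vector(t(vals)))
})

test_that("class proportions sum to one in every RU", {
  set.seed(22)
  cover <- raster_grid(matrix(sample(1:5, 30 * 30, replace = TRUE), 30, 30),
                       30, categorical = TRUE)
  rut <- aggregate_to_ru(cover, factor = 3)$rut
  sums <- rowSums(rut[, attr(rut, "prop_cols")])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("block mean aggregation is idempotent under replication", {
  set.seed(23)
  fine <- matrix(rnorm(18 * 18), 18, 18)
  cover <- raster_grid(matrix(1L, 18, 18), 30, categorical = TRUE)
  agg1 <- aggregate_to_ru(cover, list(v = raster_grid(fine, 30)), factor = 3)
  coarse <- agg1$stack$v$values
  ## disaggregate by replication, re-aggregate: must reproduce the means
  repl <- coarse[rep(seq_len(6), each = 3), rep(seq_len(6), each = 3)]
  agg2 <- aggregate_to_ru(raster_grid(matrix(1L, 18, 18), 30,
                                      categorical = TRUE),
                          list(v = raster_grid(repl, 30)), factor = 3)
  expect_equal(agg2$stack$v$values, coarse)
})

test_that("trailing rows are dropped with a warning; mixed cell sizes error", {
  cover <- raster_grid(matrix(1:2, 7, 8), 30, categorical = TRUE)
  expect_warning(aggregate_to_ru(cover, factor = 3), "trailing")
  expect_error(
    aggregate_to_ru(raster_grid(matrix(1, 6, 6), 30, categorical = TRUE),
                    list(e = raster_grid(matrix(0, 6, 6), 10))),
    "cell sizes")
})

test_that("RUs with a nodata majority are dropped, minorities tolerated", {
  vals <- matrix(1L, 6, 3)
  vals[1:2, 1:3] <- NA   # 6/9 nodata in the first block -> dropped
  vals[4, 1] <- NA       # 1/9 nodata in the second block -> kept
  cover <- raster_grid(vals, 30, categorical = TRUE)
  rut <- aggregate_to_ru(cover, factor = 3)$rut
  expect_equal(nrow(rut), 1L)
  expect_equal(rut$ru_id, 2L)
})

test_that("correlation screening flags strong pairs and excludes constants", {
  set.seed(24)
  n <- 10000
  x <- rnorm(n)
  rut <- structure(
    data.frame(ru_id = 1:n, x = 0, y = 0,
               a = x, neg = -x, indep = rnorm(n), const = 5),
    class = c("ru_table", "data.frame"),
    prop_cols = character(), cont_cols = c("a", "neg", "indep", "const"))
  expect_warning(scr <- pearson_screen(rut), "constant")
  expect_equal(scr$constant, "const")
  expect_equal(diag(scr$r), c(a = 1, neg = 1, indep = 1))
  expect_equal(scr$r["a", "neg"], -1)
  expect_lt(abs(scr$r["a", "indep"]), 0.05)
  expect_true(any(scr$flagged$var1 == "a" & scr$flagged$var2 == "neg"))
})

test_that("EGV PCA has unit-norm loadings and calibrated eigenvalues", {
  set.seed(25)
  x <- rnorm(200)
  rut2 <- structure(
    data.frame(ru_id = 1:200, x = 0, y = 0, a = x, b = 2 * x + 3),
    class = c("ru_table", "data.frame"),
    prop_cols = character(), cont_cols = c("a", "b"))
  p2 <- pca_egv(rut2)
  expect_equal(p2$percent[1], 100)            # perfectly correlated pair
  expect_equal(sum(p2$percent), 100)

  iso <- matrix(rnorm(20000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  rut_iso <- structure(
    data.frame(ru_id = 1:10000, x = 0, y = 0, iso),
    class = c("ru_table", "data.frame"),
    prop_cols = character(), cont_cols = c("a", "b"))
  pi_ <- pca_egv(rut_iso)
  expect_lt(pi_$eigenvalues[1] / pi_$eigenvalues[2], 1.05)
  expect_equal(unname(colSums(pi_$loadings^2)), c(1, 1))
})

test_that("kappa agrees with hand-computed confusion matrices", {
  expect_equal(kappa_accuracy(diag(c(10, 20, 30))),
               list(accuracy = 1, kappa = 1))
  km <- kappa_accuracy(matrix(c(40, 5, 10, 45), 2, 2))
  expect_equal(km$accuracy, 0.85)
  expect_equal(km$kappa, 0.70)
  expect_equal(kappa_accuracy(matrix(25, 2, 2))$kappa, 0)
  expect_error(kappa_accuracy(matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE)),
               "undefined")
})
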