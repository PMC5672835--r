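test_that("the generator is deterministic and validates its config", {
  cfg <- small_config(seed = 5)
  s1 <- generate_landscape(cfg)
  s2 <- generate_landscape(cfg)
  expect_identical(s1$cover$values, s2$cover$values)
  expect_identical(s1$continuous$elevation$values,
                   s2$continuous$elevation$values)
  t1 <- generate_telemetry(cfg, s1)
  t2 <- generate_telemetry(cfg, s2)
  expect_identical(t1$telemetry, t2$telemetry)

  expect_error(small_config(n_cover_classes = 1), "at least 2")
  expect_error(small_config(patch_smoothing = 0), "positive")
  expect_error(synthetic_config(grid_rows = 20, grid_cols = 20), "30 x 30")
  expect_error(small_config(home_range_radii = 5000), "outside the landscape")
  ## near-infinite smoothing: a single class swallows the grid -> rejected
  expect_error(generate_landscape(
    synthetic_config(seed = 2, grid_rows = 30, grid_cols = 30,
                     n_animals = 1, patch_smoothing = 1e6,
                     home_range_radii = 200)), "degenerate landscape")
})

test_that("landscape layers are co-registered with sane value ranges", {
  cfg <- small_config(seed = 6)
  s <- generate_landscape(cfg)
  dims <- vapply(c(list(s$cover), s$continuous, list(s$zone)),
                 function(g) dim(g$values), integer(2))
  expect_true(all(dims == dims[, 1]))
  expect_true(all(s$cover$values %in% seq_len(cfg$n_cover_classes + 2L)))
  expect_gte(length(unique(as.vector(s$cover$values))), 2L)
  expect_true(all(s$continuous$dist_water$values >= 0))
  ## distance is zero exactly on water cells
  expect_true(all((s$continuous$dist_water$values == 0) ==
                    (s$cover$values == cfg$n_cover_classes + 1L)))
  expect_true(all(s$zone$values %in% 1:2))
})

test_that("relocations stay inside each animal's home-range disc", {
  cfg <- small_config(seed = 7)
  synth <- generate_telemetry(cfg)
  tel <- synth$telemetry
  half_diag <- attr(synth$rut, "cell_size") * sqrt(2) / 2
  for (k in seq_len(cfg$n_animals)) {
    id <- sprintf("A%02d", k)
    pts <- tel[tel$animal_id == id, c("x", "y")]
    d <- sqrt((pts$x - cfg$home_range_centres[k, 1])^2 +
                (pts$y - cfg$home_range_centres[k, 2])^2)
    ## sampled RU centres are inside the disc; points are uniform in the
    ## RU cell, so they can overshoot by at most the cell half-diagonal
    expect_true(all(d <= cfg$home_range_radii[k] + half_diag))
  }
  expect_error(generate_telemetry(small_config(home_range_radii = 90)),
               "< 10")
})

test_that("a null sampler uses resource units proportionally to availability", {
  beta0 <- matrix(0, 2, 16)
  cfg <- small_config(seed = 8, n_animals = 2, points = 1250,
                      selection_coefficients = beta0)
  synth <- generate_telemetry(cfg)
  rut <- synth$rut
  for (k in 1:2) {
    id <- sprintf("A%02d", k)
    disc <- which((rut$x - cfg$home_range_centres[k, 1])^2 +
                    (rut$y - cfg$home_range_centres[k, 2])^2 <=
                    cfg$home_range_radii[k]^2)
    used <- synth$truth$points$ru_id[synth$truth$points$animal_id == id]
    counts <- table(factor(used, levels = rut$ru_id[disc]))
    gof <- suppressWarnings(
      chisq.test(as.numeric(counts),
                 p = rep(1 / length(disc), length(disc))))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("strong selection concentrates points in rich resource units", {
  beta <- matrix(0, 1, 16, dimnames = list(NULL, NULL))
  beta[1, 2] <- 4          # strong selection on the class-2 proportion
  cfg <- small_config(seed = 9, n_animals = 1, points = 1000,
                      selection_coefficients = beta)
  synth <- generate_telemetry(cfg)
  rut <- synth$rut
  disc <- which((rut$x - cfg$home_range_centres[1, 1])^2 +
                  (rut$y - cfg$home_range_centres[1, 2])^2 <=
                  cfg$home_range_radii[1]^2)
  med <- median(rut$prop_2[disc])
  used <- synth$truth$points$ru_id
  frac_above <- mean(rut$prop_2[match(used, rut$ru_id)] > med)
  expect_gt(frac_above, 0.8)
})

test_that("the sampler depends on coefficients only through named matching", {
  cfg <- small_config(seed = 10)
  perm <- sample(16)
  b_perm <- lapply(cfg$selection_coefficients, function(b)
    b[, perm, drop = FALSE])
  cfg_perm <- small_config(seed = 10, selection_coefficients = b_perm)
  t1 <- generate_telemetry(cfg)
  t2 <- generate_telemetry(cfg_perm)
  expect_identical(t1$telemetry, t2$telemetry)
})

test_that("per-animal child seeds make single-animal regeneration stable", {
  ctr <- rbind(c(700, 700), c(2000, 2000), c(700, 2000))
  cfg3 <- small_config(seed = 12, n_animals = 3,
                       home_range_centres = ctr, home_range_radii = 450)
  cfg1 <- small_config(seed = 12, n_animals = 1,
                       home_range_centres = ctr[1, , drop = FALSE],
                       home_range_radii = 450)
  t3 <- generate_telemetry(cfg3)
  t1 <- generate_telemetry(cfg1)
  a1 <- t3$telemetry[t3$telemetry$animal_id == "A01", ]
  rownames(a1) <- NULL
  expect_equal(a1[, c("period", "x", "y")],
               t1$telemetry[, c("period", "x", "y")])
})

test_that("config YAML round trip preserves the study conditions", {
  cfg <- small_config(seed = 13)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$home_range_centres, cfg$home_range_centres,
               ignore_attr = TRUE)
  expect_equal(cfg2$selection_coefficients$settled,
               cfg$selection_coefficients$settled, ignore_attr = TRUE)
  t1 <- generate_telemetry(cfg)
  t2 <- generate_telemetry(cfg2)
  expect_identical(t1$telemetry, t2$telemetry)
})
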