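## separable Gaussian smoothing with edge replication
gauss_smooth <- function(M, sigma) {
  ## kernel support beyond the grid extent adds nothing
  half <- min(max(1L, as.integer(ceiling(3 * sigma))), max(dim(M)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_cols <- function(A) {
    P <- A[c(rep(1L, half), seq_len(nrow(A)), rep(nrow(A), half)), ,
           drop = FALSE]
    F <- stats::filter(P, k, sides = 2)
    as.matrix(F)[(half + 1L):(half + nrow(A)), , drop = FALSE]
  }
  t(smooth_cols(t(smooth_cols(M))))
}

rescale01 <- function(m) (m - min(m)) / (max(m) - min(m))

#' Configuration of a synthetic landscape-and-telemetry study
#'
#' Defines the conditions a synthetic study is generated under: a patchy
#' multi-class cover landscape on a 30 m grid with continuous layers
#' (elevation, slope, an NDVI-like greenness index, distances to water,
#' settlements and a core zone), and a radio-collared population whose
#' relocations are drawn by an exponential (log-linear) resource-selection
#' sampler with known coefficients. The defaults emulate a reserve-scale
#' telemetry study: 9 animals with an exploratory and a settled period,
#' roughly 11,000 relocations in total, 16 eco-geographical variables of
#' which the cover-class proportions lie in `[0, 1]`, and selection
#' concentrated on a few cover classes (stronger and habitat-focused once
#' settled, weaker and water-oriented while exploring).
#'
#' @param seed integer root seed; per-animal child seeds are derived as
#'   `seed + 9973 * animal_index`, so a single animal can be regenerated
#'   stably.
#' @param grid_rows,grid_cols fine-grid dimensions (>= 30 each).
#' @param cell_size fine cell edge (m), default 30.
#' @param n_cover_classes number of cover classes (>= 2), default 10.
#' @param patch_smoothing Gaussian smoothing radius in cells controlling
#'   cover patch size (> 0).
#' @param n_animals number of animals (>= 1).
#' @param points_per_animal_per_period relocations per animal per period at
#'   an even period mix.
#' @param period_mix fraction of each animal's relocations labelled
#'   exploratory.
#' @param selection_coefficients either a single animal x EGV matrix used in
#'   both periods or `list(exploratory =, settled =)`; columns follow
#'   `prop_1..prop_K, elevation, slope, ndvi, dist_water, dist_settlement,
#'   dist_core`. `NULL` uses the defaults described above.
#' @param home_range_centres animal x 2 matrix of disc centres (m); default a
#'   regular layout keeping every disc inside the landscape.
#' @param home_range_radii per-animal disc radii (m), recycled.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             grid_rows = 180L, grid_cols = 180L,
                             cell_size = 30,
                             n_cover_classes = 10L,
                             patch_smoothing = 6,
                             n_animals = 9L,
                             points_per_animal_per_period = 615L,
                             period_mix = 0.5,
                             selection_coefficients = NULL,
                             home_range_centres = NULL,
                             home_range_radii = 650) {
  if (grid_rows < 30L || grid_cols < 30L)
    stop("grid must be at least 30 x 30 fine cells")
  if (n_cover_classes < 2L)
    stop("degenerate config: need at least 2 cover classes")
  if (!is.numeric(patch_smoothing) || patch_smoothing <= 0)
    stop("degenerate config: `patch_smoothing` must be positive")
  if (n_animals < 1L) stop("need at least one animal")
  if (period_mix < 0 || period_mix > 1) stop("`period_mix` must be in [0, 1]")

  p <- n_cover_classes + 6L
  egv_names <- c(paste0("prop_", seq_len(n_cover_classes)),
                 "elevation", "slope", "ndvi",
                 "dist_water", "dist_settlement", "dist_core")

  if (is.null(selection_coefficients)) {
    b_settled <- matrix(0, n_animals, p, dimnames = list(NULL, egv_names))
    b_settled[, "prop_2"] <- 2
    b_settled[, "dist_settlement"] <- 0.5
    b_settled[, "dist_water"] <- -0.5
    b_expl <- matrix(0, n_animals, p, dimnames = list(NULL, egv_names))
    b_expl[, "prop_1"] <- 1
    b_expl[, "dist_water"] <- -0.5
    selection_coefficients <- list(exploratory = b_expl, settled = b_settled)
  }
  if (is.matrix(selection_coefficients))
    selection_coefficients <- list(exploratory = selection_coefficients,
                                   settled = selection_coefficients)
  for (nm in names(selection_coefficients)) {
    b <- selection_coefficients[[nm]]
    if (nrow(b) != n_animals || ncol(b) != p)
      stop("`selection_coefficients` must be animal x EGV (",
           n_animals, " x ", p, ")")
    if (is.null(colnames(b)))
      colnames(selection_coefficients[[nm]]) <- egv_names
  }

  width <- grid_cols * cell_size
  height <- grid_rows * cell_size
  home_range_radii <- rep_len(home_range_radii, n_animals)
  if (is.null(home_range_centres)) {
    ncol_hr <- ceiling(sqrt(n_animals))
    nrow_hr <- ceiling(n_animals / ncol_hr)
    gx <- seq(0, 1, length.out = ncol_hr + 2L)[-c(1L, ncol_hr + 2L)]
    gy <- seq(0, 1, length.out = nrow_hr + 2L)[-c(1L, nrow_hr + 2L)]
    pts <- expand.grid(x = gx, y = gy)[seq_len(n_animals), ]
    home_range_centres <- cbind(pts$x * width, pts$y * height)
  }
  home_range_centres <- as.matrix(home_range_centres)
  inside <- home_range_centres[, 1] - home_range_radii >= 0 &
    home_range_centres[, 1] + home_range_radii <= width &
    home_range_centres[, 2] - home_range_radii >= 0 &
    home_range_centres[, 2] + home_range_radii <= height
  if (!all(inside))
    stop("home-range disc(s) extend outside the landscape: animal(s) ",
         paste(which(!inside), collapse = ", "))

  structure(list(seed = as.integer(seed), grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols), cell_size = cell_size,
                 n_cover_classes = as.integer(n_cover_classes),
                 patch_smoothing = patch_smoothing,
                 n_animals = as.integer(n_animals),
                 points_per_animal_per_period =
                   as.integer(points_per_animal_per_period),
                 period_mix = period_mix,
                 selection_coefficients = selection_coefficients,
                 home_range_centres = home_range_centres,
                 home_range_radii = home_range_radii,
                 egv_names = egv_names),
            class = "synthetic_config")
}

#' Generate a synthetic landscape and EGV stack
#'
#' Builds, deterministically from the config seed: a patchy categorical cover
#' raster (argmax over per-class smoothed Gaussian noise fields; regenerated,
#' then rejected with an error, if a single class swallows the whole grid); a
#' smooth elevation surface (166-546 m) with its gradient-magnitude slope
#' (degrees); an NDVI-like index (-0.19 to 0.5); Euclidean-distance layers to
#' a meandering river plus scattered waterholes, to settlement cells, and to
#' a central core zone (0 inside the core); and a core/buffer zone raster.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_landscape`: list with `cover`
#'   (categorical [raster_grid]), `continuous` (named list of continuous
#'   layers), `zone` (1 = core, 2 = buffer) and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  cell <- config$cell_size
  K <- config$n_cover_classes
  set.seed(config$seed)

  cover_vals <- NULL
  for (attempt in seq_len(20L)) {
    fields <- lapply(seq_len(K), function(k)
      gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                   config$patch_smoothing))
    cv <- matrix(0L, nr, nc)
    best <- matrix(-Inf, nr, nc)
    for (k in seq_len(K)) {
      sel <- fields[[k]] > best
      cv[sel] <- k
      best[sel] <- fields[[k]][sel]
    }
    ## every class must be represented: downstream use-availability designs
    ## need availability of each tracked cover type
    if (length(unique(as.vector(cv))) == K) { cover_vals <- cv; break }
  }
  if (is.null(cover_vals))
    stop("degenerate landscape: cover class(es) absent (in the limit a ",
         "single class covers 100% of cells when smoothing is too large ",
         "for the grid)")

  elev <- raster_grid(166 + 380 * rescale01(
    gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                 3 * config$patch_smoothing)), cell)
  ## slope (degrees) from central differences of elevation
  ev <- elev$values
  gx <- (ev[, c(2:nc, nc)] - ev[, c(1, 1:(nc - 1))]) / (2 * cell)
  gy <- (ev[c(2:nr, nr), ] - ev[c(1, 1:(nr - 1)), ]) / (2 * cell)
  slope <- raster_grid(atan(sqrt(gx^2 + gy^2)) * 180 / pi, cell)
  ndvi <- raster_grid(-0.19 + 0.69 * rescale01(
    gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                 2 * config$patch_smoothing)), cell)

  ## river: a west-to-east meandering corridor (3 cells wide), plus
  ## waterholes; mapped both as a distance layer and as its own cover class
  water <- matrix(0, nr, nc)
  r <- sample.int(nr, 1L)
  for (j in seq_len(nc)) {
    r <- min(max(r + sample(c(-1L, 0L, 1L), 1L), 2L), nr - 1L)
    water[(r - 1L):(r + 1L), j] <- 1
  }
  for (h in seq_len(3L)) {
    hr <- sample(2:(nr - 1L), 1L); hc <- sample(2:(nc - 1L), 1L)
    water[(hr - 1L):(hr + 1L), (hc - 1L):(hc + 1L)] <- 1
  }
  dist_water <- distance_layer(raster_grid(water, cell))

  ## settlements: a few village blobs, likewise a class of their own
  settle <- matrix(0, nr, nc)
  for (s in seq_len(4L)) {
    sr <- sample(3:(nr - 2L), 1L); sc <- sample(3:(nc - 2L), 1L)
    settle[(sr - 2L):(sr + 2L), (sc - 2L):(sc + 2L)] <- 1
  }
  settle[water == 1] <- 0          # villages are not in the river
  dist_settlement <- distance_layer(raster_grid(settle, cell))

  ## water and settlement override the vegetation classes; they are mapped
  ## cover types but not proportion EGVs, so the EGV proportions are not
  ## exactly compositional (their sum is 1 minus the water/settlement share)
  cover_vals[water == 1] <- K + 1L
  cover_vals[settle == 1] <- K + 2L
  cover <- raster_grid(cover_vals, cell, categorical = TRUE)

  ## core zone: central disc covering ~30% of the short axis radius-wise
  cx <- nc * cell / 2; cy <- nr * cell / 2
  core_r <- 0.35 * min(nr, nc) * cell
  ctr <- cell_centres(cover)
  core <- matrix(as.numeric((ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2 <= core_r^2),
                 nr, nc, byrow = TRUE)
  dist_core <- distance_layer(raster_grid(core, cell))
  zone <- raster_grid(2 - core, cell, categorical = TRUE)  # 1 core, 2 buffer

  structure(list(cover = cover,
                 continuous = list(elevation = elev, slope = slope,
                                   ndvi = ndvi, dist_water = dist_water,
                                   dist_settlement = dist_settlement,
                                   dist_core = dist_core),
                 zone = zone, config = config),
            class = "synthetic_landscape")
}

#' Generate telemetry by an exponential resource-selection sampler
#'
#' Aggregates the landscape to resource units, standardizes the EGVs, and,
#' for each animal and period, draws used RUs from the RUs whose centres lie
#' inside the animal's home-range disc with probability proportional to
#' `exp(sum_v beta_v z_v)`; each relocation is then placed uniformly inside
#' its RU cell. The selection coefficients may differ between the exploratory
#' and the settled period. All randomness descends from per-animal child
#' seeds, so regenerating one animal is stable.
#'
#' @param config a [synthetic_config()].
#' @param landscape the matching [generate_landscape()] result (regenerated
#'   from the config when omitted).
#' @param factor RU aggregation factor (default 3: 30 m cells to 90 m RUs).
#'
#' @return An object of class `synthetic_telemetry`: list with `telemetry`
#'   (data.frame: `animal_id`, `period`, `x`, `y`, `timestamp`, `sex`),
#'   `truth` (the beta matrices actually used, per-animal discs, per-point
#'   sampled RU id, the root seed), `rut` and `stack` (the RU aggregation
#'   the sampler worked on), `z` (standardized EGV matrix).
#' @export
generate_telemetry <- function(config, landscape = NULL, factor = 3L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(landscape)) landscape <- generate_landscape(config)
  agg <- aggregate_to_ru(landscape$cover, landscape$continuous,
                         factor = factor, zone = landscape$zone,
                         egv_classes = seq_len(config$n_cover_classes))
  rut <- agg$rut
  z <- standardize_egv(rut)
  present <- colnames(z)
  beta <- lapply(config$selection_coefficients, function(b)
    b[, present, drop = FALSE])

  sexes <- rep_len(c("F", "F", "M", "F", "F", "F", "M", "M", "F"),
                   config$n_animals)
  rows <- list(); truth_rows <- list()
  for (k in seq_len(config$n_animals)) {
    set.seed(config$seed + 9973L * k)
    ctr <- config$home_range_centres[k, ]
    rad <- config$home_range_radii[k]
    disc <- which((rut$x - ctr[1])^2 + (rut$y - ctr[2])^2 <= rad^2)
    if (length(disc) < 10L)
      stop(sprintf("animal %d: home-range disc contains only %d RUs (< 10)",
                   k, length(disc)))
    n_exp <- round(2 * config$points_per_animal_per_period * config$period_mix)
    n_set <- 2 * config$points_per_animal_per_period - n_exp
    for (period in c("exploratory", "settled")) {
      n_pts <- if (period == "exploratory") n_exp else n_set
      if (n_pts == 0L) next
      eta <- as.vector(z[disc, , drop = FALSE] %*% beta[[period]][k, ])
      pr <- exp(eta - max(eta))
      draw <- disc[sample.int(length(disc), n_pts, replace = TRUE,
                              prob = pr / sum(pr))]
      half <- attr(rut, "cell_size") / 2
      px <- rut$x[draw] - half + stats::runif(n_pts) * 2 * half
      py <- rut$y[draw] - half + stats::runif(n_pts) * 2 * half
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("A%02d", k), period = period, x = px, y = py,
        timestamp = format(as.POSIXct("2010-01-01", tz = "UTC") +
                             3600 * seq_len(n_pts), "%Y-%m-%dT%H:%M:%SZ"),
        sex = sexes[k])
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        animal_id = sprintf("A%02d", k), period = period,
        ru_id = rut$ru_id[draw])
    }
  }
  telemetry <- do.call(rbind, rows)
  rownames(telemetry) <- NULL
  structure(list(
    telemetry = telemetry,
    truth = list(beta = beta,
                 discs = data.frame(animal_id = sprintf("A%02d",
                                                        seq_len(config$n_animals)),
                                    x = config$home_range_centres[, 1],
                                    y = config$home_range_centres[, 2],
                                    radius = config$home_range_radii),
                 points = do.call(rbind, truth_rows),
                 seed = config$seed),
    rut = rut, stack = agg$stack, z = z),
    class = "synthetic_telemetry")
}

#' Read or write telemetry CSV
#'
#' Delimited text with header `animal_id,period,x,y,timestamp,sex`.
#'
#' @param telemetry telemetry data.frame.
#' @param path file path.
#' @export
write_telemetry <- function(telemetry, path) {
  utils::write.csv(telemetry, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_telemetry
#' @export
read_telemetry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "period", "x", "y")
  if (!all(need %in% names(df)))
    stop("telemetry file must have columns ", paste(need, collapse = ", "))
  df
}

#' Write a synthetic config as YAML
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$selection_coefficients <- lapply(cfg$selection_coefficients,
                                       function(b) apply(b, 1L, as.list,
                                                         simplify = FALSE))
  cfg$home_range_centres <- apply(cfg$home_range_centres, 1L, as.numeric,
                                  simplify = FALSE)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  b <- lapply(cfg$selection_coefficients, function(rows)
    do.call(rbind, lapply(rows, function(r) unlist(r))))
  ctr <- do.call(rbind, lapply(cfg$home_range_centres, as.numeric))
  synthetic_config(seed = cfg$seed, grid_rows = cfg$grid_rows,
                   grid_cols = cfg$grid_cols, cell_size = cfg$cell_size,
                   n_cover_classes = cfg$n_cover_classes,
                   patch_smoothing = cfg$patch_smoothing,
                   n_animals = cfg$n_animals,
                   points_per_animal_per_period =
                     cfg$points_per_animal_per_period,
                   period_mix = cfg$period_mix,
                   selection_coefficients = b,
                   home_range_centres = ctr,
                   home_range_radii = cfg$home_range_radii)
}
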