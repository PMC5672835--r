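# small, fast synthetic study used across tests
small_config <- function(seed = 11, n_animals = 3L, points = 120L,
                         patch_smoothing = 4, home_range_radii = 500, ...) {
  synthetic_config(seed = seed, grid_rows = 90L, grid_cols = 90L,
                   n_animals = n_animals,
                   points_per_animal_per_period = points,
                   patch_smoothing = patch_smoothing,
                   home_range_radii = home_range_radii, ...)
}

# RU table from a cover raster whose factor x factor blocks are uniform,
# giving RUs with known dominant classes laid out row-major
block_rut <- function(block_classes, factor = 3L, cell = 30,
                      elevation = NULL) {
  bc <- as.matrix(block_classes)
  cover <- raster_grid(bc[rep(seq_len(nrow(bc)), each = factor),
                          rep(seq_len(ncol(bc)), each = factor)],
                       cell, categorical = TRUE)
  cont <- list()
  if (!is.null(elevation)) {
    el <- as.matrix(elevation)
    cont$elevation <- raster_grid(el[rep(seq_len(nrow(el)), each = factor),
                                     rep(seq_len(ncol(el)), each = factor)],
                                  cell)
  }
  aggregate_to_ru(cover, cont, factor = factor)
}

# standardized EGV table over n "RUs" with given raw columns (for direct
# K-select tests without a landscape)
toy_z <- function(X) {
  rut <- structure(data.frame(ru_id = seq_len(nrow(X)), x = 0, y = 0, X),
                   class = c("ru_table", "data.frame"),
                   prop_cols = character(), cont_cols = colnames(X))
  standardize_egv(rut)
}
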