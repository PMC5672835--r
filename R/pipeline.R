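#' Write / read an RU table as CSV (plus a small JSON sidecar of grid
#' metadata, so the table can be rebuilt with its class universe and grain)
#'
#' @param rut RU table.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @export
write_ru_table <- function(rut, path) {
  utils::write.csv(as.data.frame(rut), path, row.names = FALSE, quote = FALSE)
  meta <- list(classes = attr(rut, "classes"),
               prop_cols = attr(rut, "prop_cols"),
               cont_cols = attr(rut, "cont_cols"),
               cell_size = attr(rut, "cell_size"),
               n_rows = attr(rut, "n_rows"), n_cols = attr(rut, "n_cols"),
               xmin = attr(rut, "xmin"), ymax = attr(rut, "ymax"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ru_table
#' @export
read_ru_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(df, class = c("ru_table", "data.frame"),
            classes = meta$classes, prop_cols = meta$prop_cols,
            cont_cols = meta$cont_cols, cell_size = meta$cell_size,
            n_rows = meta$n_rows, n_cols = meta$n_cols,
            xmin = meta$xmin, ymax = meta$ymax)
}

pipeline_stages <- c("simulate", "egv", "homerange", "ratios", "kselect",
                     "thin", "suitability", "evaluate")

need_file <- function(outdir, file, stage, needed_by) {
  path <- file.path(outdir, file)
  if (!file.exists(path))
    stop(sprintf("stage '%s' requires '%s' produced by stage '%s'; run that stage first",
                 needed_by, file, stage))
  path
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates simulate -> egv -> homerange -> ratios -> kselect -> thin ->
#' suitability -> evaluate, writing each stage's outputs under `outdir` and a
#' run manifest (`manifest.json`) with the config hash, seed, package
#' version and per-file checksums. Later stages read the files earlier
#' stages wrote, so a subset of stages can be re-run against an existing
#' output directory; a missing input aborts with an error naming the stage
#' that produces it. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created if needed).
#' @param stages subset of the pipeline stages to run, in order.
#' @param seed optional integer overriding the config seed.
#' @param randomization_n randomizations for the K-select tests.
#' @param thin_tolerance,thin_min_points thinning controls.
#' @param n_classes number of Fi suitability classes.
#' @param niche_ridge ridge passed to [fit_niche()] (0 = none; the pipeline
#'   defaults to a light 1e-4 because cover-class proportions are exactly
#'   compositional inside home ranges that contain no water or settlement
#'   cells, making the covariance singular). EGVs that are constant at the
#'   fitting locations are always dropped from the niche model with a
#'   message: they carry no covariance information.
#' @param holdout fraction of thinned locations held out for evaluation
#'   (0 = evaluate on the fitting locations, mirroring a presence-only
#'   workflow without an independent sample).
#' @param alpha family-wise level for selection-ratio intervals.
#'
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir, stages = pipeline_stages,
                         seed = NULL, randomization_n = 1000L,
                         thin_tolerance = 0.05, thin_min_points = 20L,
                         n_classes = 20L, holdout = 0, alpha = 0.05,
                         niche_ridge = 1e-4) {
  stopifnot(inherits(config, "synthetic_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  if (!is.null(seed)) {
    cfg <- unclass(config); cfg$seed <- as.integer(seed)
    config <- do.call(synthetic_config,
                      cfg[setdiff(names(cfg), "egv_names")])
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("habselect")),
                   r_version = R.version.string,
                   stages = stages, files = list())
  add <- function(files) {
    for (f in files)
      manifest$files[[f]] <<- unname(tools::md5sum(file.path(outdir, f)))
  }

  if ("simulate" %in% stages) {
    scape <- generate_landscape(config)
    synth <- generate_telemetry(config, scape)
    write_asc(scape$cover, file.path(outdir, "cover.asc"))
    for (nm in names(scape$continuous))
      write_asc(scape$continuous[[nm]], file.path(outdir, paste0(nm, ".asc")))
    write_asc(scape$zone, file.path(outdir, "zone.asc"))
    write_telemetry(synth$telemetry, file.path(outdir, "telemetry.csv"))
    utils::write.csv(synth$truth$points, file.path(outdir, "truth_points.csv"),
                     row.names = FALSE, quote = FALSE)
    for (pd in names(synth$truth$beta))
      utils::write.csv(synth$truth$beta[[pd]],
                       file.path(outdir, paste0("truth_beta_", pd, ".csv")),
                       row.names = FALSE, quote = FALSE)
    write_config(config, file.path(outdir, "config.yaml"))
    add(c("cover.asc", paste0(names(scape$continuous), ".asc"), "zone.asc",
          "telemetry.csv", "truth_points.csv",
          paste0("truth_beta_", names(synth$truth$beta), ".csv"),
          "config.yaml"))
  }

  if ("egv" %in% stages) {
    cover <- read_asc(need_file(outdir, "cover.asc", "simulate", "egv"),
                      categorical = TRUE)
    cont_names <- c("elevation", "slope", "ndvi", "dist_water",
                    "dist_settlement", "dist_core")
    continuous <- lapply(cont_names, function(nm)
      read_asc(need_file(outdir, paste0(nm, ".asc"), "simulate", "egv")))
    names(continuous) <- cont_names
    zone <- read_asc(file.path(outdir, "zone.asc"), categorical = TRUE)
    agg <- aggregate_to_ru(cover, continuous, factor = 3L, zone = zone,
                           egv_classes = seq_len(config$n_cover_classes))
    write_ru_table(agg$rut, file.path(outdir, "ru_table.csv"))
    scr <- pearson_screen(agg$rut)
    utils::write.csv(round(scr$r, 10), file.path(outdir, "correlation.csv"))
    pca <- pca_egv(agg$rut)
    utils::write.csv(data.frame(axis = seq_along(pca$eigenvalues),
                                eigenvalue = pca$eigenvalues,
                                percent = pca$percent),
                     file.path(outdir, "pca_eigenvalues.csv"),
                     row.names = FALSE, quote = FALSE)
    add(c("ru_table.csv", "ru_table.csv.meta.json", "correlation.csv",
          "pca_eigenvalues.csv"))
  }

  if (any(c("homerange", "ratios", "kselect", "thin", "suitability",
            "evaluate") %in% stages)) {
    rut <- read_ru_table(need_file(outdir, "ru_table.csv", "egv",
                                   stages[stages != "simulate"][1]))
    tel <- read_telemetry(need_file(outdir, "telemetry.csv", "simulate",
                                    stages[stages != "simulate"][1]))
    grid_tpl <- raster_grid(
      matrix(NA_real_, attr(rut, "n_rows"), attr(rut, "n_cols")),
      cell_size = attr(rut, "cell_size"),
      xmin = attr(rut, "xmin"), ymax = attr(rut, "ymax"))
  }

  if ("homerange" %in% stages) {
    polys <- list(); avail_rows <- list(); used_rows <- list()
    ru_rows <- list()
    for (id in unique(tel$animal_id)) for (pd in unique(tel$period)) {
      pts <- tel[tel$animal_id == id & tel$period == pd, c("x", "y")]
      if (nrow(pts) < 3L) next
      hr <- mcp(pts, animal_id = id, period = pd)
      polys[[paste(id, pd)]] <- hr
      us <- used_units(pts, rut, grid_tpl)
      av <- hr_availability(rut, hr, used_ru_ids = us$ru_ids)
      avail_rows[[paste(id, pd)]] <- data.frame(
        animal_id = id, period = pd, category = names(av$pi),
        pi = as.numeric(av$pi), area_m2 = hr$area)
      used_rows[[paste(id, pd)]] <- data.frame(
        animal_id = id, period = pd, category = names(us$u),
        u = as.numeric(us$u))
      ru_rows[[paste(id, pd)]] <- rbind(
        data.frame(animal_id = id, period = pd, role = "available",
                   ru_id = av$ru_ids),
        data.frame(animal_id = id, period = pd, role = "used",
                   ru_id = us$ru_ids))
    }
    write_geojson(polys, file.path(outdir, "mcp.geojson"))
    utils::write.csv(do.call(rbind, avail_rows),
                     file.path(outdir, "availability.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, used_rows),
                     file.path(outdir, "used.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, ru_rows),
                     file.path(outdir, "animal_rus.csv"),
                     row.names = FALSE, quote = FALSE)
    add(c("mcp.geojson", "availability.csv", "used.csv", "animal_rus.csv"))
  }

  if ("ratios" %in% stages) {
    av <- utils::read.csv(need_file(outdir, "availability.csv", "homerange",
                                    "ratios"), stringsAsFactors = FALSE)
    us <- utils::read.csv(need_file(outdir, "used.csv", "homerange",
                                    "ratios"), stringsAsFactors = FALSE)
    out <- list()
    for (pd in unique(av$period)) {
      ids <- unique(av$animal_id[av$period == pd])
      u_list <- lapply(ids, function(id) {
        s <- us[us$animal_id == id & us$period == pd, ]
        stats::setNames(s$u, s$category)
      })
      pi_list <- lapply(ids, function(id) {
        s <- av[av$animal_id == id & av$period == pd, ]
        stats::setNames(s$pi, s$category)
      })
      gt <- global_selection_ratios(u_list, pi_list, alpha = alpha,
                                    animal_ids = ids)
      tb <- gt$table
      tb$period <- pd; tb$chi2 <- gt$chi2; tb$df <- gt$df
      tb$p_value <- gt$p_value
      out[[pd]] <- tb
    }
    utils::write.csv(do.call(rbind, out),
                     file.path(outdir, "selection_ratios.csv"),
                     row.names = FALSE, quote = TRUE)
    add("selection_ratios.csv")
  }

  if ("kselect" %in% stages) {
    aru <- utils::read.csv(need_file(outdir, "animal_rus.csv", "homerange",
                                     "kselect"), stringsAsFactors = FALSE)
    z <- standardize_egv(rut)
    res <- list(); pvals <- list()
    for (pd in unique(aru$period)) {
      sub <- aru[aru$period == pd, ]
      ids <- unique(sub$animal_id)
      marg <- list(); avail <- list()
      for (id in ids) {
        ## the RU is the analysis unit: the used sample is the set of
        ## distinct visited RUs, matching the without-replacement null
        used <- unique(sub$ru_id[sub$animal_id == id & sub$role == "used"])
        avl <- sub$ru_id[sub$animal_id == id & sub$role == "available"]
        marg[[id]] <- marginality(used, avl, z, animal_id = id, period = pd)
        avail[[id]] <- avl
      }
      ks <- kselect(marg)
      res[[pd]] <- data.frame(period = pd, axis = seq_along(ks$eigenvalues),
                              eigenvalue = ks$eigenvalues,
                              percent = ks$percent)
      set.seed(config$seed + 271L)
      pv <- vapply(ids, function(id)
        marginality_randomization(marg[[id]], avail[[id]], z,
                                  N = randomization_n)$p_value, 0)
      ev1 <- first_eigenvalue_test(marg, avail, z, N = randomization_n)
      pvals[[pd]] <- data.frame(
        period = pd, animal_id = c(ids, "(first eigenvalue)"),
        observed = c(vapply(marg, `[[`, 0, "norm2"), ks$eigenvalues[1]),
        p_value = c(pv, ev1$p_value),
        bonferroni_alpha = bonferroni_alpha(length(ids)))
    }
    utils::write.csv(do.call(rbind, res),
                     file.path(outdir, "kselect_eigenvalues.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, pvals),
                     file.path(outdir, "kselect_pvalues.csv"),
                     row.names = FALSE, quote = TRUE)
    add(c("kselect_eigenvalues.csv", "kselect_pvalues.csv"))
  }

  if ("thin" %in% stages) {
    av <- utils::read.csv(need_file(outdir, "availability.csv", "homerange",
                                    "thin"), stringsAsFactors = FALSE)
    keep <- rep(FALSE, nrow(tel))
    reports <- list()
    settled <- tel$period == "settled"
    for (id in unique(tel$animal_id[settled])) {
      sel <- which(settled & tel$animal_id == id)
      area <- av$area_m2[av$animal_id == id & av$period == "settled"][1]
      th <- thin_to_random(tel[sel, c("x", "y")], area,
                           tolerance = thin_tolerance,
                           min_points = thin_min_points, animal_id = id)
      kept_orig <- sel[attr(dedupe(tel[sel, c("x", "y")]), "kept")[th$retained]]
      keep[kept_orig] <- TRUE
      reports[[id]] <- list(animal_id = id, final_R = th$R,
                            converged = th$converged,
                            n_retained = length(th$retained),
                            n_removed = length(th$removed),
                            R_trajectory = th$R_trajectory)
    }
    tel$retained <- keep
    write_telemetry(tel, file.path(outdir, "telemetry_thinned.csv"))
    jsonlite::write_json(unname(reports), file.path(outdir, "thinning.json"),
                         auto_unbox = TRUE, digits = NA)
    add(c("telemetry_thinned.csv", "thinning.json"))
  }

  if (any(c("suitability", "evaluate") %in% stages)) {
    telt <- utils::read.csv(need_file(outdir, "telemetry_thinned.csv", "thin",
                                      "suitability"),
                            stringsAsFactors = FALSE)
    pts <- telt[telt$retained & telt$period == "settled", c("x", "y")]
    set.seed(config$seed + 653L)
    n_fit <- nrow(pts)
    eval_idx <- seq_len(n_fit)
    if (holdout > 0) {
      eval_idx <- sample.int(n_fit, max(1L, round(holdout * n_fit)))
      fit_idx <- setdiff(seq_len(n_fit), eval_idx)
    } else fit_idx <- eval_idx
    cols <- egv_columns(rut)
    loc <- locate_cells(grid_tpl, as.matrix(pts))
    ridx <- match(loc$cell, rut$ru_id)
    Xfit <- as.matrix(rut[ridx[fit_idx], cols])
    keep_egv <- apply(Xfit, 2L, stats::sd) > 0
    if (!all(keep_egv))
      message("dropping EGV(s) constant at the fitting locations: ",
              paste(cols[!keep_egv], collapse = ", "))
    rut_fit <- rut
    attr(rut_fit, "prop_cols") <- intersect(attr(rut, "prop_cols"),
                                            cols[keep_egv])
    attr(rut_fit, "cont_cols") <- intersect(attr(rut, "cont_cols"),
                                            cols[keep_egv])
    model <- fit_niche(Xfit[, keep_egv, drop = FALSE], ridge = niche_ridge)
    sm <- suitability_map(rut_fit, model, grid = grid_tpl)
    write_asc(sm$d2_raster, file.path(outdir, "d2.asc"))
    write_asc(sm$suitability_raster, file.path(outdir, "suitability.asc"))
    curve <- fi_curve(sm$suitability, sm$suitability[ridx[eval_idx]],
                      n_classes = n_classes)
    utils::write.csv(curve$classes, file.path(outdir, "fi_curve.csv"),
                     row.names = FALSE, quote = FALSE)
    recl <- reclassify_suitability(sm$suitability, curve$threshold,
                                   zone = rut$zone)
    binmap <- sm$suitability_raster
    binmap$values[] <- NA_real_
    binmap$values[!is.na(sm$suitability_raster$values)] <-
      as.numeric(sm$suitability_raster$values[
        !is.na(sm$suitability_raster$values)] >= curve$threshold)
    write_asc(binmap, file.path(outdir, "suitable_binary.asc"))
    utils::write.csv(recl$by_zone, file.path(outdir, "zone_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    add(c("d2.asc", "suitability.asc", "fi_curve.csv",
          "suitable_binary.asc", "zone_summary.csv"))
  }

  if ("evaluate" %in% stages) {
    bi <- boyce_index(curve)
    jsonlite::write_json(list(
      boyce_spearman = bi$spearman,
      adj_r_squared = bi$adj_r_squared,
      threshold = curve$threshold,
      percent_suitable = recl$percent_suitable,
      by_zone = recl$by_zone,
      holdout = holdout), file.path(outdir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA)
    add("evaluation.json")
  }

  cfg_path <- file.path(outdir, "config.yaml")
  if (file.exists(cfg_path))
    manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
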