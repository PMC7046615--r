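#' Pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()]:
#' synthetic-landscape settings, the true suitability models of the
#' simulated species, the ensemble design at both scales, graph and
#' connectivity conventions, and the mandatory seed. `x` may be a named
#' list overriding any subset of the defaults, or the path of a YAML file
#' with the same structure.
#'
#' @param x Named list of overrides, or a YAML file path.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(
    seed = 1L,
    scenarios = c("current", "rcp26_2050", "rcp85_2100"),
    synthetic = list(coarse_shape = c(64L, 64L), fine_factor = 4L,
                     n_climate_vars = 3L, n_landcover_vars = 3L,
                     autocorr_range = 8, n_ponds = 80L,
                     trend_magnitudes = list(rcp26_2050 = 0.75,
                                             rcp85_2100 = 2.5),
                     n_presences = 300L, fine_cell_size = 50),
    species = list(
      # strong low-prevalence responses emulate a rare, habitat-specialist
      # newt; coefficient sums are negative so additive warming shifts
      # reduce suitability (species_a more exposed than species_b)
      species_a = list(
        climate = c(clim1 = -6, clim2 = 4, clim3 = -2.5),
        climate_intercept = -8,
        landcover = c(lc1 = 2.5, dist_pond = -0.008),
        landcover_intercept = 1),
      species_b = list(
        climate = c(clim1 = -3, clim2 = -2.5, clim3 = 4),
        climate_intercept = -6,
        landcover = c(lc2 = 2.5, dist_pond = -0.008),
        landcover_intercept = 1)),
    enm = list(learners = c("glm", "rf"),
               climate = list(n_pa = 500L, n_sets = 2L, n_runs = 2L,
                              pa_method = "random"),
               landcover = list(n_pa = 500L, n_sets = 2L, n_runs = 2L,
                                pa_method = "disk", min_dist = 50),
               split_fraction = 0.7, tss_cutoff = 0.7, thin_dist = 50),
    graph = list(dispersal_dist = 1000, percentile = 0.1),
    moran = list(n_perm = 199L))
  cfg <- utils::modifyList(defaults, x)
  if (is.null(cfg$seed)) stop("`seed` is mandatory", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  if (!"current" %in% cfg$scenarios)
    stop("scenarios must include 'current'", call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

sample_from_surface <- function(surface, n, seed, species) {
  p <- as.vector(surface$values)
  p[is.na(p)] <- 0
  if (n > 0 && sum(p) <= 0)
    stop("sampling impossible: suitability is zero everywhere",
         call. = FALSE)
  cells <- with_seed(seed, sample.int(length(p), n, replace = TRUE,
                                      prob = p))
  cc <- cell_centers(surface, cells)
  data.frame(species = species, x = cc$x, y = cc$y, cell = cc$cell)
}

#' Run the five-step pipeline end to end
#'
#' For every species: (1) climate-only ensemble on the coarse grid,
#' projected to every scenario with MESS transferability checks; (2)
#' land-cover-only ensemble on the fine grid (disk pseudo-absences); (3)
#' HSI = disaggregated climate suitability x current land-cover
#' suitability, with the Moran's I residual diagnostic; (4) binarization at
#' the 10th percentile of training presences, habitat patches, resistance
#' surface, least-cost landscape graph, interaction flux and its
#' interpolation; then (5) z-normalization, two-species combination and
#' current/future difference maps. Every surface and table is written under
#' `out_dir` and listed in a machine-readable manifest; a scenario without
#' habitat patches is recorded as a "no graph" outcome and the run
#' continues.
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pondscape_")) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  art <- function(p) { paths <<- c(paths, p); p }
  scfg <- do.call(synthetic_config, c(cfg$synthetic, list(seed = cfg$seed)))

  clim <- generate_climate_grids(scfg)
  lc <- generate_landcover_layers(scfg)
  scenarios <- intersect(cfg$scenarios, names(clim))
  fine <- lc$frame
  clim_fine <- lapply(clim, function(vars)
    lapply(vars, disaggregate, fine_frame = fine))
  write_geojson(lc$ponds, art(file.path(out_dir, "ponds.geojson")))
  if (length(lc$habitat_patches))
    write_geojson(lc$habitat_patches,
                  art(file.path(out_dir, "habitat_patches.geojson")))

  summaries <- list()
  norm_maps <- list()  # [[scenario]][[species]]
  sp_offset <- 0L
  for (sp in names(cfg$species)) {
    sp_cfg <- cfg$species[[sp]]
    sp_offset <- sp_offset + 101L
    clim_truth <- true_suitability_model(unlist(sp_cfg$climate),
                                         sp_cfg$climate_intercept)
    lc_truth <- true_suitability_model(unlist(sp_cfg$landcover),
                                       sp_cfg$landcover_intercept)
    truth_fine <- combine_suitability(
      disaggregate(true_suitability(clim_truth, clim$current),
                   fine_frame = fine),
      true_suitability(lc_truth, lc$covariates))
    occ <- sample_from_surface(truth_fine$raster, scfg$n_presences,
                               seed = cfg$seed + sp_offset, species = sp)
    write_occurrences(occ, art(file.path(out_dir,
                                         paste0(sp, "_occurrences.csv"))))
    occ_thin <- thin_occurrences(occ, cfg$enm$thin_dist)

    # step 1: climate-only ensemble (coarse grid)
    e1 <- cfg$enm$climate
    ens_clim <- run_enm(clim$current, occ_thin,
                        learners = cfg$enm$learners, n_pa = e1$n_pa,
                        n_sets = e1$n_sets, n_runs = e1$n_runs,
                        pa_method = e1$pa_method,
                        split_fraction = cfg$enm$split_fraction,
                        tss_cutoff = cfg$enm$tss_cutoff,
                        seed = cfg$seed + sp_offset + 1L)
    utils::write.csv(ens_clim$ledger,
                     art(file.path(out_dir, paste0(sp, "_climate_models.csv"))),
                     row.names = FALSE)
    write_asc(ens_clim$cv_surface,
              art(file.path(out_dir, paste0(sp, "_climate_cv.asc"))))
    envelope <- reference_envelope(ens_clim$calibration)
    rc <- do.call(rbind, lapply(names(clim$current), function(v)
      cbind(variable = v, response_curve(ens_clim, v))))
    utils::write.csv(rc, art(file.path(out_dir,
                                       paste0(sp, "_climate_response_curves.csv"))),
                     row.names = FALSE)

    # step 2: land-cover-only ensemble (fine grid)
    e2 <- cfg$enm$landcover
    ens_lc <- run_enm(lc$covariates, occ_thin,
                      learners = cfg$enm$learners, n_pa = e2$n_pa,
                      n_sets = e2$n_sets, n_runs = e2$n_runs,
                      pa_method = e2$pa_method, pa_min_dist = e2$min_dist,
                      split_fraction = cfg$enm$split_fraction,
                      tss_cutoff = cfg$enm$tss_cutoff,
                      seed = cfg$seed + sp_offset + 2L)
    utils::write.csv(ens_lc$ledger,
                     art(file.path(out_dir, paste0(sp, "_landcover_models.csv"))),
                     row.names = FALSE)
    lc_surface <- ens_lc$mean_surface
    write_asc(lc_surface, art(file.path(out_dir,
                                        paste0(sp, "_landcover_mean.asc"))))

    sp_sum <- list(
      n_occurrences = nrow(occ), n_thinned = nrow(occ_thin),
      n_models_climate = length(ens_clim$members),
      n_models_landcover = length(ens_lc$members),
      climate_tss = mean(ens_clim$ledger$tss[ens_clim$passing]),
      climate_auc = mean(ens_clim$ledger$auc[ens_clim$passing]),
      landcover_tss = mean(ens_lc$ledger$tss[ens_lc$passing]),
      landcover_auc = mean(ens_lc$ledger$auc[ens_lc$passing]),
      truth_spearman = stats::cor(
        as.vector(project_ensemble(ens_clim, clim$current)$values),
        as.vector(true_suitability(clim_truth, clim$current)$values),
        method = "spearman", use = "complete.obs"),
      scenarios = list())

    threshold <- NULL
    for (scen in scenarios) {
      clim_surf <- project_ensemble(ens_clim, clim[[scen]])
      mess <- mess_surface(clim[[scen]], envelope)
      write_asc(mess, art(file.path(out_dir,
                                    paste0(sp, "_", scen, "_mess.asc"))))
      hsi <- combine_suitability(disaggregate(clim_surf, fine_frame = fine),
                                 lc_surface, species = sp, scenario = scen)
      write_asc(hsi$raster, art(file.path(out_dir,
                                          paste0(sp, "_", scen, "_hsi.asc"))))
      if (scen == "current")
        threshold <- binarization_threshold(hsi, occ_thin,
                                            cfg$graph$percentile)
      graph <- build_graph(hsi, dispersal_dist = cfg$graph$dispersal_dist,
                           threshold = threshold)
      write_graph_json(graph, art(file.path(out_dir,
                                            paste0(sp, "_", scen, "_graph.json"))))
      scen_sum <- list(
        suitable_area_km2 = suitable_area(hsi, threshold),
        threshold = threshold,
        n_patches = length(graph$patches),
        mess_negative_fraction = mean(mess$values < 0, na.rm = TRUE),
        no_graph = graph$no_graph)
      if (scen == "current") {
        mor <- tryCatch(
          hsi_residual_moran(hsi, occ_thin, n_perm = cfg$moran$n_perm,
                             seed = cfg$seed + sp_offset + 3L),
          error = function(e) NULL)
        if (!is.null(mor))
          scen_sum$moran <- list(i = mor$i, p_value = mor$p_value)
      }
      if (!graph$no_graph) {
        write_asc(graph$resistance,
                  art(file.path(out_dir,
                                paste0(sp, "_", scen, "_resistance.asc"))))
        ifr <- interaction_flux(graph)
        pt <- patch_table(graph)
        pt$if_value <- ifr$if_values
        utils::write.csv(pt, art(file.path(out_dir,
                                           paste0(sp, "_", scen, "_patches.csv"))),
                         row.names = FALSE)
        utils::write.csv(graph$edges,
                         art(file.path(out_dir,
                                       paste0(sp, "_", scen, "_edges.csv"))),
                         row.names = FALSE)
        imap <- interpolate_metric(ifr, species = sp, scenario = scen)
        write_asc(imap$raster, art(file.path(out_dir,
                                             paste0(sp, "_", scen, "_if.asc"))))
        scen_sum$mean_if <- mean(ifr$if_values)
        nm <- tryCatch(normalize_map(imap), error = function(e) NULL)
        if (!is.null(nm)) {
          if (is.null(norm_maps[[scen]])) norm_maps[[scen]] <- list()
          norm_maps[[scen]][[sp]] <- nm
          write_asc(nm$raster,
                    art(file.path(out_dir,
                                  paste0(sp, "_", scen, "_if_norm.asc"))))
        }
      }
      sp_sum$scenarios[[scen]] <- scen_sum
    }
    summaries[[sp]] <- sp_sum
  }

  # step 5: cross-species combination and scenario deltas
  combined <- list()
  for (scen in names(norm_maps)) {
    if (length(norm_maps[[scen]]) == length(cfg$species)) {
      cm <- combine_species(unname(norm_maps[[scen]]))
      combined[[scen]] <- cm
      write_asc(cm$raster, art(file.path(out_dir,
                                         paste0("combined_", scen, "_if.asc"))))
    }
  }
  for (scen in setdiff(names(combined), "current")) {
    if (!is.null(combined$current)) {
      dm <- delta_map(combined[[scen]], combined$current)
      write_asc(dm, art(file.path(out_dir,
                                  paste0("delta_", scen, "_vs_current.asc"))))
    }
  }

  prj <- paste0(tools::file_path_sans_ext(
    paths[grepl("\\.asc$", paths)]), ".prj")
  all_paths <- c(paths, prj)
  manifest <- list(
    config = unclass(cfg),
    scenarios = scenarios,
    artifacts = data.frame(
      path = basename(all_paths),
      md5 = unname(tools::md5sum(all_paths))),
    combined_scenarios = names(combined),
    summaries = summaries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, force = TRUE)
  invisible(manifest)
}
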