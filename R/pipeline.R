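#' Default pipeline configuration
#'
#' Returns the full configuration list [run_pipeline()] consumes, with every
#' constant the pipeline uses surfaced: grid resolution 0.083 degrees, PCA
#' variance target 95%, the 3-occurrence modelling floor, the 2-km
#' municipality-seat filter, the 50% protected-cell rule, 10,000
#' randomizations, and the additive-benefit exponent 0.25. The `synthetic`
#' block describes the generated study system (a 40 x 40 landscape, 19
#' collinear layers, 25 species with range sizes from about 1% to 20% of the
#' landscape and occurrence counts spread across the AUC-test classes, 6
#' biomes, 13% protected-area coverage). Supply `paths` instead of
#' `synthetic` to run on files (occurrences/seats CSV, ESRI ASCII rasters).
#'
#' @param ... Named overrides merged (shallowly per block) into the defaults.
#' @return A nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    synthetic = list(
      nrows = 40, ncols = 40, n_layers = 19, autocorr_scale = 5,
      noise_sd = 0.05, n_species = 25,
      range_quantiles = c(0.00125, 0.0025, 0.00625, 0.0125, 0.025, 0.05,
                          0.1, 0.2),
      n_occurrences = c(6, 10, 14, 20, 28, 38, 50, 62, 74),
      snap_fraction = 0.1, n_biomes = 6, cu_coverage = 0.13,
      placement = "random", partial_band = 0.1
    ),
    paths = NULL,
    grid = list(resolution = 0.083, cell_area_km2 = 85),
    pca = list(target_cumvar = 0.95),
    sdm = list(background_n = 10000, regularization = 1, k_folds = 5),
    thresholds = list(min_occurrences = 3, proximity_km = 2,
                      protection_cutoff = 0.5),
    nullmodels = list(n_rand = 10000, class_width = 15,
                      first_class = c(4, 15)),
    prioritization = list(z = 0.25, batch = 1)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    base <- pipeline_config()
    for (nm in names(config)) {
      if (is.list(base[[nm]]) && is.list(config[[nm]])) {
        base[[nm]][names(config[[nm]])] <- config[[nm]]
      } else {
        base[[nm]] <- config[[nm]]
      }
    }
    config <- base
  }
  config
}

#' Run the full gap-analysis pipeline
#'
#' Executes every stage end-to-end and writes all outputs under `outdir`:
#' cleaned occurrences with a drop report, PCA axes and variance table,
#' per-species suitability and binarized rasters with the evaluation table,
#' the community matrix, the diversity maps, the AUC-versus-occurrence-count
#' Monte Carlo table, the per-biome diversity randomization, the
#' conservation-importance map, the protected-cell randomization, the gap
#' table with its logistic fit, and a JSON manifest recording the seed, the
#' configuration and every metadata convention (p-value denominators,
#' benefit exponent, tie-breaks). All randomness derives from `seed`; a
#' re-run with the same configuration and seed reproduces every file
#' byte-for-byte. A stage failure aborts with the stage name; an INCOMPLETE
#' marker file is left next to any partial outputs.
#'
#' @param config A configuration list from [pipeline_config()] or a YAML file
#'   path with the same structure.
#' @param seed Master integer seed.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1, outdir) {
  config <- read_pipeline_config(config)
  if (missing(outdir) || is.null(outdir)) {
    stop("`outdir` is required.", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  incomplete <- file.path(outdir, "INCOMPLETE")
  file.create(incomplete)
  stage <- function(name, expr) {
    message("[aquagap] ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()

  ## ---- inputs -------------------------------------------------------------
  if (!is.null(config$paths)) {
    inp <- stage("load inputs", {
      occ <- load_occurrences(config$paths$occurrences)
      seats <- readr::read_csv(config$paths$seats, show_col_types = FALSE)
      layers <- lapply(config$paths$env_layers, read_esri_ascii)
      grid <- layers[[1]]$grid
      grid$cell_area_km2 <- config$grid$cell_area_km2
      stack <- grid_cells(grid)
      for (i in seq_along(layers)) {
        stack[[sprintf("env_%02d", i)]] <- layers[[i]]$values
      }
      attr(stack, "grid") <- grid
      masks <- grid_cells(grid)[c("cell_id", "row", "col")]
      masks$biome <- sprintf("biome_%d",
                             read_esri_ascii(config$paths$biome)$values)
      masks$protection <- read_esri_ascii(config$paths$protection)$values
      list(occ = occ, seats = seats, stack = stack, grid = grid,
           masks = masks, truth = NULL)
    })
  } else {
    inp <- stage("generate synthetic inputs", {
      sc <- config$synthetic
      grid <- grid_spec(resolution = config$grid$resolution,
                        nrows = sc$nrows, ncols = sc$ncols,
                        cell_area_km2 = config$grid$cell_area_km2)
      land <- make_landscape(seed + 1, nrows = sc$nrows, ncols = sc$ncols,
                             n_layers = sc$n_layers,
                             autocorr_scale = sc$autocorr_scale,
                             noise_sd = sc$noise_sd, grid = grid)
      occ <- make_species(seed + 2, land, n_species = sc$n_species,
                          range_quantiles = sc$range_quantiles,
                          n_occurrences = sc$n_occurrences,
                          snap_fraction = sc$snap_fraction,
                          min_km = config$thresholds$proximity_km)
      truth <- synthetic_truth(occ)
      attr(occ, "report") <- tibble::tibble(
        n_read = nrow(occ), n_kept = nrow(occ),
        n_invalid_coordinate = 0L, n_missing_species = 0L)
      list(occ = occ, seats = attr(land, "seats"), stack = land,
           grid = grid, masks = NULL, truth = truth)
    })
  }
  grid <- inp$grid
  res$truth <- inp$truth

  ## ---- occurrence cleaning ------------------------------------------------
  res$occurrences <- stage("clean occurrences", {
    kept <- filter_municipality_proximity(inp$occ, inp$seats,
                                          min_km = config$thresholds$proximity_km)
    prox_report <- drop_report(kept)
    kept <- filter_min_records(kept,
                               min_n = config$thresholds$min_occurrences)
    species_report <- drop_report(kept)
    presences <- assign_to_cells(kept, grid)
    readr::write_csv(kept[c("species", "lon", "lat")],
                     file.path(outdir, "occurrences_clean.csv"))
    readr::write_csv(
      dplyr::bind_cols(drop_report(inp$occ), prox_report,
                       tibble::tibble(
                         n_species_in = nrow(species_report),
                         n_species_excluded = sum(!species_report$kept))),
      file.path(outdir, "occurrence_drop_report.csv"))
    readr::write_csv(species_report,
                     file.path(outdir, "species_record_counts.csv"))
    list(records = kept, presences = presences,
         species_report = species_report)
  })

  ## ---- environmental features --------------------------------------------
  res$pca <- stage("PCA of environmental stack", {
    std <- standardize_stack(inp$stack)
    pca <- pca_reduce(std, target_cumvar = config$pca$target_cumvar)
    readr::write_csv(tidy(pca), file.path(outdir, "pca_variance.csv"))
    for (j in seq_len(pca$n_retained)) {
      write_esri_ascii(pca$axes[[paste0("axis_", j)]], grid,
                       file.path(outdir, sprintf("pca_axis_%02d.asc", j)))
    }
    pca
  })
  axes <- res$pca$axes

  ## ---- species distribution models ---------------------------------------
  res$sdm <- stage("fit and evaluate SDMs", {
    bg_n <- min(config$sdm$background_n, n_cells(grid))
    background <- sample_background(grid, bg_n, seed = seed + 4)
    by_sp <- split(res$occurrences$presences$cell_id,
                   res$occurrences$presences$species)
    # the occurrence floor is a records rule; modelling additionally needs
    # >= 3 distinct occupied cells
    modellable <- lengths(by_sp) >= 3
    if (any(!modellable)) {
      readr::write_csv(
        tibble::tibble(species = names(by_sp)[!modellable],
                       n_cells = lengths(by_sp)[!modellable]),
        file.path(outdir, "species_too_few_cells.csv"))
    }
    by_sp <- by_sp[modellable]
    record_counts <- table(res$occurrences$records$species)
    sp_ids <- names(by_sp)
    evals <- vector("list", length(sp_ids))
    preds <- vector("list", length(sp_ids))
    for (i in seq_along(sp_ids)) {
      sp <- sp_ids[i]
      ev <- evaluate_sdm(axes, by_sp[[sp]], background,
                         k_folds = config$sdm$k_folds,
                         seed = seed + 100 + i,
                         regularization = config$sdm$regularization,
                         species = sp)
      suit <- attr(ev, "suitability")
      bin <- binarize(suit, ev$threshold)
      write_esri_ascii(suit$suitability, grid,
                       file.path(outdir, sprintf("suitability_%s.asc", sp)))
      write_esri_ascii(bin$presence, grid,
                       file.path(outdir, sprintf("binary_%s.asc", sp)))
      ev$n_records <- as.integer(record_counts[[sp]])
      evals[[i]] <- ev
      preds[[i]] <- tibble::tibble(species = sp, cell_id = bin$cell_id,
                                   presence = bin$presence)
    }
    evaluation <- dplyr::bind_rows(evals)
    readr::write_csv(evaluation, file.path(outdir, "evaluation.csv"))
    list(evaluation = evaluation,
         predictions = dplyr::bind_rows(preds), background = background)
  })

  ## ---- community matrix and diversity ------------------------------------
  res$community <- stage("community matrix", {
    cm <- community_matrix(res$sdm$predictions, grid)
    readr::write_csv(tibble::as_tibble(cm),
                     file.path(outdir, "community_matrix.csv"))
    cm
  })
  res$diversity <- stage("diversity maps", {
    dm <- diversity_maps(res$community)
    readr::write_csv(dm, file.path(outdir, "diversity_maps.csv"))
    write_esri_ascii(dm$richness, grid, file.path(outdir, "richness.asc"))
    for (comp in c("beta_total", "beta_turnover", "beta_nestedness")) {
      write_esri_ascii(dm[[comp]], grid,
                       file.path(outdir, paste0(comp, ".asc")))
    }
    dm
  })

  ## ---- prioritization -----------------------------------------------------
  res$importance <- stage("greedy prioritization", {
    imp <- rank_cells(res$community, z = config$prioritization$z,
                      batch = config$prioritization$batch)
    readr::write_csv(imp, file.path(outdir, "importance.csv"))
    write_esri_ascii(imp$importance, grid, file.path(outdir, "importance.asc"))
    imp
  })

  ## ---- masks (synthetic mode generates them here, so importance-aware
  ##      placements can see the importance map) ----------------------------
  masks <- inp$masks
  if (is.null(masks)) {
    masks <- stage("generate masks", {
      sc <- config$synthetic
      imp_vec <- numeric(n_cells(grid))
      imp_vec[res$importance$cell_id + 1] <- res$importance$importance
      make_masks(seed + 3, grid, n_biomes = sc$n_biomes,
                 cu_coverage = sc$cu_coverage, placement = sc$placement,
                 importance = if (sc$placement != "random") imp_vec,
                 partial_band = sc$partial_band)
    })
  }
  res$masks <- masks
  stage("write masks", {
    biome_num <- as.integer(factor(masks$biome))
    write_esri_ascii(biome_num, grid, file.path(outdir, "biomes.asc"))
    write_esri_ascii(masks$protection, grid,
                     file.path(outdir, "protection.asc"))
  })

  ## ---- null models --------------------------------------------------------
  n_rand <- config$nullmodels$n_rand
  res$auc_test <- stage("AUC-versus-occurrences Monte Carlo test", {
    ev <- res$sdm$evaluation
    eligible <- ev[ev$n_records >= config$nullmodels$first_class[1], ]
    tab <- auc_class_test(eligible, auc, n_records,
                          class_width = config$nullmodels$class_width,
                          first_class = config$nullmodels$first_class,
                          n_rand = n_rand, seed = seed + 6)
    readr::write_csv(tab, file.path(outdir, "auc_class_test.csv"))
    tab
  })
  res$biome_test <- stage("biome diversity randomization", {
    cells <- dplyr::inner_join(res$diversity, masks,
                               by = c("cell_id", "row", "col"))
    tabs <- purrr::map_dfr(c("richness", "beta_total"), function(m) {
      dplyr::mutate(
        biome_randomization(cells, dplyr::all_of(m), biome,
                            n_rand = n_rand, seed = seed + 7),
        metric = m, .before = 1)
    })
    readr::write_csv(tabs, file.path(outdir, "biome_randomization.csv"))
    tabs
  })
  res$protection_test <- stage("protected-cell randomization", {
    cells <- dplyr::inner_join(res$importance, masks,
                               by = c("cell_id", "row", "col"))
    tab <- protection_randomization(cells, importance, protection,
                                    biome = biome,
                                    cutoff = config$thresholds$protection_cutoff,
                                    n_rand = n_rand, seed = seed + 8,
                                    scope = "per_biome")
    readr::write_csv(tab, file.path(outdir, "protection_randomization.csv"))
    tab
  })

  ## ---- gap analysis -------------------------------------------------------
  res$gap <- stage("gap analysis", {
    prot_vec <- masks$protection[match(res$community$cell_id,
                                       masks$cell_id)]
    protected <- protected_cells(prot_vec,
                                 cutoff = config$thresholds$protection_cutoff)
    status <- species_protection_status(res$community, protected)
    readr::write_csv(status, file.path(outdir, "gap_table.csv"))
    if (length(unique(status$protected)) < 2) {
      # every modelled species shares one status: the regression is
      # undefined; record that instead of aborting a finished landscape
      readr::write_csv(
        tibble::tibble(n = nrow(status), chi_square = NA_real_, df = 1L,
                       p_value = NA_real_, separation = NA,
                       intercept = NA_real_, slope = NA_real_,
                       threshold_cells = NA_real_, threshold_km2 = NA_real_,
                       prob = 0.5, defined = FALSE,
                       note = "all species share one protection status"),
        file.path(outdir, "logistic_fit.csv"))
      list(status = status, fit = NULL, threshold = NULL)
    } else {
      fit <- fit_protection_logistic(status, range_cells, protected)
      thr <- protection_threshold(fit, prob = 0.5,
                                  cell_area_km2 = grid$cell_area_km2)
      readr::write_csv(
        dplyr::bind_cols(glance(fit),
                         tibble::tibble(intercept = fit$intercept,
                                        slope = fit$slope), thr),
        file.path(outdir, "logistic_fit.csv"))
      list(status = status, fit = fit, threshold = thr)
    }
  })

  ## ---- manifest -----------------------------------------------------------
  stage("manifest", {
    manifest <- list(
      package = "aquagap",
      version = as.character(utils::packageVersion("aquagap")),
      seed = seed,
      config = config,
      conventions = list(
        p_denominator_cell_tests = "(n_rand + 1), count of randoms >= observed",
        p_denominator_auc_class_test = "n_rand, count of randoms >= control mean",
        comparison_rule = ">= (greater or equal) in all tests",
        sampling = "without replacement within a draw",
        benefit_exponent_z = config$prioritization$z,
        prioritization_tie_break = "lower current richness, then lower cell id",
        max_tss_tie_break = "higher threshold (more restricted range)",
        protection_rule = ">= 50% coverage counts as protected",
        threshold_rule = "smallest integer cell count with fitted P >= 0.5"
      ),
      outputs = sort(setdiff(list.files(outdir), "INCOMPLETE"))
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  file.remove(incomplete)
  invisible(res)
}
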