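# End-to-end orchestration: terrain -> flowlines -> occurrences ->
# covariates -> maxent -> evaluation -> habitat -> gap report, plus the
# config-driven command-line interface.

#' Default pipeline parameters
#'
#' Tuning knobs of the full pipeline with their field-standard defaults:
#' 60-m cells, 120-m focal radius, flow-accumulation threshold 300 cells,
#' headwater orders 1-2, 300-m occurrence snapping, 10,000 background
#' points from landform classes 6-10 with road-bias decay 500 m, LQH(P)
#' features with regularization multiplier 1, ESS threshold, 500-m
#' terrestrial buffer.
#'
#' @param accum_threshold flow-accumulation threshold (cells).
#' @param focal_radius covariate focal radius (m).
#' @param snap_dist occurrence snapping radius (m).
#' @param n_background background points.
#' @param road_tau road-bias decay length (m).
#' @param classes maxent feature classes.
#' @param n_hinge hinge knots per variable.
#' @param rm regularization multiplier.
#' @param k_folds cross-validation folds.
#' @param select_model run AICc model selection over `rm_grid`/`class_grid`
#'   instead of a single fit.
#' @param rm_grid,class_grid the selection grid (when `select_model`).
#' @param terrestrial_radius terrestrial habitat buffer (m).
#' @return a named list of parameters.
#' @export
pipeline_params <- function(accum_threshold = 300, focal_radius = 120,
                            snap_dist = 300, n_background = 10000,
                            road_tau = 500, classes = c("L", "Q", "H"),
                            n_hinge = 10, rm = 1, k_folds = 10,
                            select_model = FALSE,
                            rm_grid = c(0.5, 1, 2),
                            class_grid = list("L", c("L", "Q"),
                                              c("L", "Q", "H")),
                            terrestrial_radius = 500) {
  as.list(environment())
}

#' Run the full habitat-modeling pipeline on a synthetic world
#'
#' Stages: (1) D8 flow and headwater flowlines, cleaned by the five-rule
#' cascade (a high-accumulation extraction serves as the reference network
#' the way a coarse national hydrography layer would); (2) occurrence
#' cleaning, downslope snapping, and per-reach thinning; (3) the 12-layer
#' covariate stack; (4) bias-matched background and the maxent fit with
#' k-fold cross-validation; (5) evaluation report; (6) habitat refinement
#' cascade and terrestrial extension; (7) gap analysis.
#'
#' @param world an `rh_world` (from [generate_world()] or [world_read()]).
#' @param occurrences occurrence data.frame; defaults to sampling from the
#'   world's truth.
#' @param seed RNG seed governing all pipeline randomness.
#' @param params a [pipeline_params()] list.
#' @param through last stage to run: `"terrain"`, `"occurrences"`,
#'   `"covariates"`, `"fit"`, `"evaluate"`, `"delineate"`, `"gap"`.
#' @param verbose log per-stage progress and filter counts.
#' @return list of stage outputs (those up to `through`).
#' @export
run_pipeline <- function(world, occurrences = NULL, seed = 1,
                         params = pipeline_params(), through = "gap",
                         verbose = FALSE) {
  stages <- c("terrain", "occurrences", "covariates", "fit", "evaluate",
              "delineate", "gap")
  through <- match.arg(through, stages)
  want <- function(s) match(s, stages) <= match(through, stages)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list(world = world, params = params, seed = seed)

  # --- terrain and flowlines ----------------------------------------------
  fl <- world$flow %||% d8_flow(world$dem)
  net_raw <- extract_flowlines(fl$accumulation, fl$direction,
                               threshold = params$accum_threshold)
  reference <- extract_flowlines(fl$accumulation, fl$direction,
                                 threshold = 4 * params$accum_threshold,
                                 keep_orders = 1:9)
  ww <- grid_mask(world$landcover, lc_legend()[["woody_wetlands"]])
  net <- clean_flowlines(net_raw, world$waterbodies, reference,
                         world$landform, ww)
  say("flowlines: %d raw -> %d cleaned segments", length(net_raw$segments),
      length(net$segments))
  out$flow <- fl; out$net_raw <- net_raw; out$net <- net
  if (!want("occurrences")) return(out)

  # --- occurrences ---------------------------------------------------------
  if (is.null(occurrences))
    occurrences <- sample_occurrences(world, seed = fan_seed(seed, 1))
  study <- mask_create(!is.na(world$dem$values), template = world$dem)
  records <- occ_pipeline(occurrences, study, net, world$dem,
                          max_dist = params$snap_dist,
                          seed = fan_seed(seed, 2), verbose = verbose)
  kept <- occ_retained(records)
  say("occurrences: %d retained on %d reaches", nrow(kept),
      length(unique(kept$reach_id)))
  out$records <- records
  if (!want("covariates")) return(out)

  # --- covariates ----------------------------------------------------------
  stack <- build_stack(world$dem, world$landcover, world$canopy,
                       world$soils, world$climate, net, world$watersheds,
                       radius = params$focal_radius,
                       landform = world$landform)
  out$stack <- stack
  if (!want("fit")) return(out)

  # --- background + model --------------------------------------------------
  bg <- sample_background(params$n_background, world$landform,
                          world$roads_dist, tau = params$road_tau,
                          seed = fan_seed(seed, 3))
  pres_cells <- cell_at(world$dem, kept$x, kept$y)
  pres_data <- stack_extract(stack, cells = pres_cells)
  bg_data <- stack_extract(stack, cells = bg$cells)
  okp <- stats::complete.cases(pres_data)
  okb <- stats::complete.cases(bg_data)
  pres_data <- pres_data[okp, , drop = FALSE]
  bg_data <- bg_data[okb, , drop = FALSE]
  say("model data: %d presences, %d background", nrow(pres_data),
      nrow(bg_data))
  if (params$select_model) {
    sel <- select_model(pres_data, bg_data, rm_grid = params$rm_grid,
                        class_grid = params$class_grid,
                        n_hinge = params$n_hinge)
    model <- sel$model
    out$selection <- sel$records
    classes <- strsplit(sel$records$classes[sel$best], "")[[1]]
    rm_use <- sel$records$rm[sel$best]
  } else {
    fs <- make_features(rbind(pres_data, bg_data), nrow(pres_data),
                        classes = params$classes, n_hinge = params$n_hinge)
    model <- fit_maxent(fs, pres_data, bg_data, rm = params$rm)
    classes <- params$classes
    rm_use <- params$rm
  }
  out$background <- bg; out$pres_data <- pres_data; out$bg_data <- bg_data
  out$model <- model
  if (!want("evaluate")) return(out)

  # --- cross-validation and evaluation ------------------------------------
  k <- min(params$k_folds, nrow(pres_data))
  cv <- crossvalidate(pres_data, bg_data, k = k, seed = fan_seed(seed, 4),
                      classes = classes, n_hinge = params$n_hinge,
                      rm = rm_use)
  eval <- evaluation_report(cv, model, pres_data, bg_data,
                            seed = fan_seed(seed, 5))
  say("evaluation: test AUC %.3f (%s), TSS %.2f, SEDI %.2f",
      eval$auc_test_mean, eval$auc_class, eval$tss, eval$sedi)
  out$cv <- cv; out$evaluation <- eval
  if (!want("delineate")) return(out)

  # --- habitat delineation -------------------------------------------------
  suit_map <- predict_map(model, stack)
  habitat <- delineate_habitat(suit_map, eval$threshold_ess,
                               world$landcover, world$canopy,
                               terrestrial_radius = params$terrestrial_radius)
  say("habitat: breeding %.2f + terrestrial %.2f = %.2f km^2",
      habitat$areas_km2$breeding, habitat$areas_km2$terrestrial,
      habitat$areas_km2$combined)
  out$suitability <- suit_map; out$habitat <- habitat
  if (!want("gap")) return(out)

  # --- gap analysis --------------------------------------------------------
  out$gap <- gap_summary(habitat, world$protected, world$sleuth,
                         world$landcover, world$plantations, world$regions)
  out
}

#' Read a written world bundle back from disk
#'
#' Inverse of [world_write()] (flow routing is recomputed on demand).
#'
#' @param dir bundle directory.
#' @return an `rh_world`.
#' @export
world_read <- function(dir) {
  rg <- function(name, kind = "continuous")
    grid_read_asc(file.path(dir, paste0(name, ".asc")), kind = kind)
  cfgj <- jsonlite::read_json(file.path(dir, "world_config.json"),
                              simplifyVector = TRUE)
  cfg <- cfgj$config
  cfg$beta <- unlist(cfgj$beta)
  class(cfg) <- "wd_config"
  roads <- rg("roads", "mask")
  carved <- rg("carved", "mask")
  structure(list(
    config = cfg, dem = rg("dem"),
    landcover = rg("landcover", "categorical"), canopy = rg("canopy"),
    soils = list(conductivity = rg("soil_conductivity"),
                 ph = rg("soil_ph"), pct_sand = rg("soil_pct_sand")),
    climate = list(temp_march = rg("temp_march"),
                   precip_march = rg("precip_march")),
    roads = roads, roads_dist = distance_to(roads),
    protected = rg("protected", "mask"),
    plantations = rg("plantations", "mask"),
    waterbodies = rg("waterbodies", "mask"),
    watersheds = rg("watersheds", "categorical"),
    regions = rg("regions", "categorical"), sleuth = rg("sleuth"),
    landform = rg("landform", "categorical"), flow = NULL,
    truth = list(carved = carved, suitability = rg("true_suitability"))),
    class = "rh_world")
}

#' Write the main pipeline outputs to a directory
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @export
pipeline_write <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$net))
    flownet_write_csv(result$net, file.path(dir, "flowlines.csv"),
                      cells_json = file.path(dir, "flowline_cells.json"))
  if (!is.null(result$records))
    occ_write_csv(result$records, file.path(dir, "occurrences_processed.csv"))
  if (!is.null(result$model))
    maxent_write_json(result$model, file.path(dir, "model.json"))
  if (!is.null(result$evaluation))
    jsonlite::write_json(unclass(result$evaluation),
                         file.path(dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(result$suitability))
    grid_write_asc(result$suitability, file.path(dir, "suitability.asc"))
  if (!is.null(result$habitat)) {
    grid_write_asc(result$habitat$breeding, file.path(dir, "breeding.asc"))
    grid_write_asc(result$habitat$terrestrial,
                   file.path(dir, "terrestrial.asc"))
    grid_write_asc(result$habitat$combined, file.path(dir, "combined.asc"))
    jsonlite::write_json(result$habitat$areas_km2,
                         file.path(dir, "habitat_areas.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$gap)) gap_write(result$gap, file.path(dir, "gap"))
  invisible(dir)
}

read_cli_config <- function(path) {
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Command-line entry point
#'
#' `ravinehab <subcommand> <config.(yaml|json)>` with subcommands `synth`,
#' `terrain`, `occ`, `covariates`, `fit`, `evaluate`, `delineate`, `gap`,
#' `all`.  The config must provide `seed` and `out_dir`; `size` and any
#' [pipeline_params()] field are optional.  `synth` writes the world bundle
#' into `out_dir/world`; later stages regenerate the same world from the
#' config seed (or read `out_dir/world` when present) and write their
#' artifacts under `out_dir`.
#'
#' @param args character vector (default: the command line).
#' @return invisibly, the stage result.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: ravinehab <synth|terrain|occ|covariates|fit|",
                 "evaluate|delineate|gap|all> <config.yaml|config.json>")
  if (length(args) < 2) stop(usage, call. = FALSE)
  cmd <- args[1]
  cfg <- read_cli_config(args[2])
  if (is.null(cfg$seed) || is.null(cfg$out_dir))
    stop("config must set seed and out_dir", call. = FALSE)
  par <- pipeline_params()
  for (nm in intersect(names(cfg), names(par))) par[[nm]] <- cfg[[nm]]
  wdir <- file.path(cfg$out_dir, "world")
  world <- if (file.exists(file.path(wdir, "world_config.json")))
    world_read(wdir)
  else generate_world(world_config(size = cfg$size %||% 400,
                                   seed = cfg$seed))
  if (cmd == "synth") {
    occ <- sample_occurrences(world)
    world_write(world, wdir, occurrences = occ)
    message("world bundle written to ", wdir)
    return(invisible(world))
  }
  through <- switch(cmd, terrain = "terrain", occ = "occurrences",
                    covariates = "covariates", fit = "fit",
                    evaluate = "evaluate", delineate = "delineate",
                    gap = "gap", all = "gap", stop(usage, call. = FALSE))
  occurrences <- NULL
  occ_path <- file.path(wdir, "occurrences.csv")
  if (file.exists(occ_path)) occurrences <- occ_read_csv(occ_path)
  res <- run_pipeline(world, occurrences = occurrences, seed = cfg$seed,
                      params = par, through = through, verbose = TRUE)
  pipeline_write(res, cfg$out_dir)
  message("artifacts written to ", cfg$out_dir)
  invisible(res)
}

#' Parameter-recovery experiment on a synthetic landscape
#'
#' Generates a world whose true suitability is logistic in focal slope and
#' subwatershed percent agriculture only, draws presences proportional to
#' that truth over the valley landforms (classes 6-10), samples a uniform
#' background from the same domain, fits the maxent model, and reports the
#' held-out AUC and permutation importance.  Recovery means the held-out
#' AUC clears 0.85 and the two generating variables rank first and second
#' in importance.
#'
#' @param seed master seed (world, presences, background, folds).
#' @param size world edge in cells.
#' @param n_presence presences drawn.
#' @param n_background background points.
#' @param beta true coefficients (slope and percent agriculture only).
#' @param k_folds cross-validation folds.
#' @param n_hinge hinge knots per variable.
#' @return list with `auc_test`, `importance` (sorted), `top2`,
#'   `top2_expected`, `recovered` (logical), `world`.
#' @export
recovery_experiment <- function(seed, size = 400, n_presence = 180,
                                n_background = 4000,
                                beta = c(intercept = 1, slope = 1.6,
                                         tpi = 0, pct_agriculture = -0.8,
                                         temp = 0),
                                k_folds = 5, n_hinge = 8) {
  world <- generate_world(world_config(size = size, seed = seed,
                                       beta = beta))
  suit <- world$truth$suitability$values
  elig <- which(world$landform$values %in% 6:10)
  pres_idx <- with_seed(fan_seed(seed, 21),
                        sample(elig, n_presence,
                               prob = pmax(suit[elig], 1e-9)))
  bg <- sample_background(n_background, world$landform, world$roads_dist,
                          tau = Inf, seed = fan_seed(seed, 22))
  # the carved ravine network stands in for the cleaned flowlines so the
  # full 12-layer stack can be built without re-deriving hydrology
  cells <- which(world$truth$carved$member, arr.ind = TRUE)
  net <- structure(list(segments = list(list(cells = cells, length_m = 0,
                                             sinuosity = 1, strahler = 1L,
                                             downstream = NA_integer_)),
                        cell_size = world$dem$cell_size, origin_x = 0,
                        origin_y = nrow(suit) * world$dem$cell_size,
                        dim = dim(suit)), class = "rh_flownet")
  stack <- build_stack(world$dem, world$landcover, world$canopy,
                       world$soils, world$climate, net, world$watersheds,
                       landform = world$landform)
  nr <- nrow(suit)
  pres_cells <- cbind(((pres_idx - 1) %% nr) + 1,
                      ((pres_idx - 1) %/% nr) + 1)
  pres <- stack_extract(stack, cells = pres_cells)
  bgd <- stack_extract(stack, cells = bg$cells)
  pres <- pres[stats::complete.cases(pres), , drop = FALSE]
  bgd <- bgd[stats::complete.cases(bgd), , drop = FALSE]
  cv <- crossvalidate(pres, bgd, k = k_folds, seed = fan_seed(seed, 23),
                      classes = c("L", "Q", "H"), n_hinge = n_hinge)
  fs <- make_features(rbind(pres, bgd), nrow(pres),
                      classes = c("L", "Q", "H"), n_hinge = n_hinge)
  model <- fit_maxent(fs, pres, bgd)
  imp <- sort(permutation_importance(model, pres, bgd,
                                     seed = fan_seed(seed, 24)),
              decreasing = TRUE)
  top2 <- names(imp)[1:2]
  expected <- c("slope", "pct_agriculture")
  list(auc_test = mean(cv$test_auc, na.rm = TRUE), importance = imp,
       top2 = top2, top2_expected = expected,
       recovered = mean(cv$test_auc, na.rm = TRUE) >= 0.85 &&
         setequal(top2, expected),
       model = model, world = world)
}

#' End-to-end recovery of suitable ravine habitat
#'
#' Runs the complete pipeline on a default-truth world (suitability in
#' slope, TPI, percent agriculture, and temperature) and measures the share
#' of truly suitable carved ravine cells (truth > `suit_cut`) captured by
#' the delineated breeding habitat.
#'
#' @param seed master seed.
#' @param size world edge in cells.
#' @param suit_cut truth threshold defining "truly suitable" (default 0.7).
#' @param params pipeline parameters; the default adapts the accumulation
#'   threshold (25 cells) and background size to the synthetic domain.
#' @return list with `overlap`, `auc_test`, `habitat`, `result`.
#' @export
endtoend_recovery <- function(seed, size = 400, suit_cut = 0.7,
                              params = pipeline_params(
                                accum_threshold = 25, n_background = 4000,
                                k_folds = 10)) {
  world <- generate_world(world_config(size = size, seed = seed))
  res <- run_pipeline(world, seed = fan_seed(seed, 31), params = params)
  truly <- world$truth$suitability$values > suit_cut &
    world$truth$carved$member
  overlap <- if (any(truly)) mean(res$habitat$breeding$member[truly])
  else NA_real_
  list(overlap = overlap, auc_test = res$evaluation$auc_test_mean,
       habitat = res$habitat, result = res)
}
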