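#' End-to-end run configuration
#'
#' Bundles the sub-configurations of every stage. All randomness flows from
#' the single root `seed`, split into per-stage streams, so stages are
#' reproducible in isolation.
#'
#' @param scene A [scene_config()].
#' @param train A [train_config()].
#' @param assessment List with `samples_per_class` (accuracy-assessment
#'   sample drawn stratified by the *predicted* map), `ci_multiplier` and
#'   `kappa_basis`.
#' @param association List with `alpha`, `rs_threshold`, `k` (CV folds),
#'   `n_samples` (size of the presence/absence table) and `ntree`.
#' @param seed Root seed; overrides the sub-config seeds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scene = scene_config(),
                       train = train_config(),
                       assessment = list(samples_per_class = 100L,
                                         ci_multiplier = 1.96,
                                         kappa_basis = "counts"),
                       association = list(alpha = 0.0005,
                                          rs_threshold = 0.7, k = 10L,
                                          n_samples = 600L, ntree = 300L),
                       seed = 1L) {
  scene$seed <- as.integer(seed)
  train$seed <- stage_seed(seed, "train")
  structure(list(scene = validate_scene_config(scene), train = train,
                 assessment = assessment, association = association,
                 seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(name, manifest_env, code) {
  t0 <- proc.time()[["elapsed"]]
  manifest_env$stages[[name]] <- list(name = name, files = character(0))
  message(sprintf("[pinyon] stage %-12s start (config %s)",
                  name, manifest_env$config_hash))
  result <- tryCatch(code, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  el <- proc.time()[["elapsed"]] - t0
  manifest_env$stages[[name]]$elapsed_s <- round(el, 3)
  message(sprintf("[pinyon] stage %-12s done in %.2fs", name, el))
  result
}

record_files <- function(manifest_env, stage, paths) {
  manifest_env$stages[[stage]]$files <-
    c(manifest_env$stages[[stage]]$files, paths)
  invisible(paths)
}

#' Run the full synthetic mapping pipeline
#'
#' Executes generate -> terrain/covariates/cover -> spectra + NDVI stack ->
#' classifier training and whole-scene prediction -> design-based accuracy
#' and area assessment -> presence/absence association, writing every
#' intermediate product to `output_dir` (grids as ESRI ASCII, tables as
#' CSV, reports as JSON) and returning a manifest. A failure in any stage
#' aborts with a stage-tagged error; files written before the failure are
#' retained for debugging. Reruns with the same config and seed reproduce
#' identical reports.
#'
#' @param config A [run_config()].
#' @param output_dir Directory for stage outputs (created if needed).
#' @param stages Which stages to run: `"all"` runs everything;
#'   `"assessment"` stops after the accuracy/area report (skipping the
#'   association stage).
#' @return A list of class `run_manifest`: per-stage wall time and files,
#'   the config hash, and the in-memory stage results (`dem`, `terrain`,
#'   `cover`, `stack`, `model`, `map`, `accuracy_report`, `association`).
#' @export
run_pipeline <- function(config, output_dir,
                         stages = c("all", "assessment")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(output_dir, "config.json")
  jsonlite::write_json(unclass_rapply(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  env <- new.env()
  env$stages <- list()
  env$config_hash <- unname(tools::md5sum(cfg_path))
  sc <- config$scene

  dem <- run_stage("generate", env, generate_dem(sc))
  record_files(env, "generate",
               write_grid(dem, file.path(output_dir, "dem.asc")))

  terrain <- run_stage("terrain", env, compute_terrain(dem))
  for (nm in c("slope", "tri", "vrm")) {
    record_files(env, "terrain",
                 write_grid(terrain[[nm]],
                            file.path(output_dir, paste0(nm, ".asc"))))
  }

  covariates <- run_stage("covariates", env, generate_covariates(dem, sc))
  cover <- run_stage("cover", env,
                     generate_cover_truth(dem, terrain, covariates, sc))
  record_files(env, "cover",
               write_grid(cover, file.path(output_dir, "cover_truth.asc")))

  stack <- run_stage("spectra", env, {
    bands <- generate_spectra(cover, sc)
    f <- sc$coarse_band_factor
    if (f > 1L && nrow(dem$values) %% f == 0L &&
        ncol(dem$values) %% f == 0L) {
      coarse20 <- c("B5", "B6", "B7", "B8A", "B11", "B12")
      for (b in coarse20) {
        bands[[b]] <- resample_to_fine(aggregate_to_coarse(bands[[b]], f),
                                       f, method = "bilinear")
      }
    }
    ndvi <- compute_ndvi(bands$B8, bands$B4)
    stack_scene(bands, ndvi)
  })

  fitted <- run_stage("classify", env, {
    train_samples <- sample_reference(cover, sc)
    model <- fit_bpnn(stack, train_samples, config$train,
                      classes = sc$class_names)
    map <- predict_map(model, stack)
    record_files(env, "classify",
                 write_grid(map$class,
                            file.path(output_dir, "cover_predicted.asc")))
    utils::write.csv(train_samples,
                     file.path(output_dir, "training_sample.csv"),
                     row.names = FALSE)
    record_files(env, "classify",
                 file.path(output_dir, "training_sample.csv"))
    list(model = model, map = map)
  })

  report <- run_stage("assess", env, {
    amap <- fitted$map$class
    cell_ha <- (amap$cell_size^2) / 1e4
    counts_map <- tabulate(amap$values[!is.na(amap$values)],
                           nbins = length(sc$class_names))
    mapped_areas <- stats::setNames(counts_map * cell_ha, sc$class_names)
    asc <- sc
    asc$seed <- stage_seed(config$seed, "assess")
    val <- sample_reference(amap, asc,
                            counts = config$assessment$samples_per_class)
    names(val)[names(val) == "true_class"] <- "mapped_class"
    val$true_class <- cover$levels[cover$values[cbind(val$row, val$col)]]
    em <- build_error_matrix(val, mapped_areas)
    rep <- area_report(em,
                       ci_multiplier = config$assessment$ci_multiplier,
                       kappa_basis = config$assessment$kappa_basis)
    path <- file.path(output_dir, "area_report.json")
    jsonlite::write_json(area_report_json(rep), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    record_files(env, "assess", path)
    rep
  })

  assoc <- NULL
  if (stages == "all") {
    assoc <- run_stage("associate", env, {
      tab <- build_env_samples(dem, terrain, covariates, cover, sc,
                               n = config$association$n_samples,
                               seed = stage_seed(config$seed, "associate"))
      utils::write.csv(tab, file.path(output_dir, "env_samples.csv"),
                       row.names = FALSE)
      record_files(env, "associate",
                   file.path(output_dir, "env_samples.csv"))
      scr <- screen_variables(tab, alpha = config$association$alpha,
                              rs_threshold = config$association$rs_threshold)
      fit <- if (length(scr$retained)) {
        fit_logistic(tab, scr$retained)
      } else NULL
      cv <- if (length(scr$retained)) {
        random_forest_cv(tab, scr$retained, k = config$association$k,
                         seed = stage_seed(config$seed, "associate"),
                         ntree = config$association$ntree)
      } else NULL
      list(screening = scr, logistic = fit, cv = cv)
    })
  }

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("pinyon")),
    config_hash = env$config_hash, seed = config$seed,
    output_dir = output_dir, stages = env$stages,
    dem = dem, terrain = terrain, covariates = covariates, cover = cover,
    stack = stack, model = fitted$model, map = fitted$map,
    accuracy_report = report, association = assoc),
    class = "run_manifest")
  mpath <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(list(package_version = manifest$package_version,
                            config_hash = manifest$config_hash,
                            seed = manifest$seed,
                            stages = env$stages),
                       mpath, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, config %s\n", x$seed, x$config_hash))
  for (s in x$stages) {
    cat(sprintf("  %-12s %6.2fs  %s\n", s$name, s$elapsed_s,
                paste(basename(s$files %||% character(0)),
                      collapse = ", ")))
  }
  cat(sprintf("  overall accuracy %.4f; pine area %.1f ha\n",
              x$accuracy_report$overall,
              x$accuracy_report$areas$area_ha[1]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON-friendly view of an area_report
area_report_json <- function(rep) {
  list(classes = rep$error_matrix$class_names,
       counts = unname(apply(rep$error_matrix$counts, 1, as.list)),
       mapped_areas = as.list(rep$error_matrix$mapped_areas),
       proportions = unname(apply(rep$proportions, 1, as.list)),
       column_totals = as.numeric(rep$column_totals),
       areas = rep$areas, overall = rep$overall,
       users = as.list(rep$users), producers = as.list(rep$producers),
       kappa = rep$kappa, kappa_basis = rep$kappa_basis,
       ci_multiplier = rep$ci_multiplier)
}

unclass_rapply <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_rapply))
  x
}

# Draw a presence/absence covariate table from the pine-eligible zone.
build_env_samples <- function(dem, terrain, covariates, cover, sc, n,
                              seed) {
  z <- dem$values
  eligible <- which(!is.na(z) & z >= sc$pine_floor &
                      !is.na(cover$values))
  if (length(eligible) < n) {
    stop("not enough pine-eligible cells for the association sample",
         call. = FALSE)
  }
  cells <- withr::with_seed(as.integer(seed), sample(eligible, n))
  data.frame(
    presence = as.integer(cover$values[cells] == 1),
    TRI = terrain$tri$values[cells],
    VRM = terrain$vrm$values[cells],
    S = terrain$slope$values[cells],
    E = z[cells],
    MTWM = covariates$MTWM$values[cells],
    noise1 = covariates$noise1$values[cells],
    noise2 = covariates$noise2$values[cells])
}
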