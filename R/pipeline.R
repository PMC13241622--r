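#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config accepted by [run_pipeline()]:
#' `mode` ("synthetic" or "real"), `seed`, and sections `scene`,
#' `emission`, `design`, `render`, `analysis` (plus `inputs` for real
#' data). Every named constant of the analysis (0.75 mask fraction,
#' 900 nm^2 floor, 150 nm CRU threshold, 5 nm pixels) is an explicit key.
#'
#' @return Configuration list.
#' @export
default_config <- function() {
  list(mode = "synthetic",
       seed = 1L,
       scene = unclass(scene_config()),
       emission = unclass(emission_config()),
       design = list(n_animals_per_group = 5L, cells_per_animal = 6L,
                     animal_sd = 0.08),
       render = list(pixel_size_nm = 5, sigma_render_nm = 12),
       analysis = unclass(analysis_config()),
       inputs = NULL)
}

.merge_config <- function(base, user, path, problems) {
  for (key in names(user)) {
    if (!key %in% names(base)) {
      problems$msgs <- c(problems$msgs,
                         sprintf("unknown config key '%s%s'", path, key))
    } else if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) {
        problems$msgs <- c(problems$msgs,
                           sprintf("config key '%s%s' must be a section", path, key))
      } else {
        base[[key]] <- .merge_config(base[[key]], user[[key]],
                                     paste0(path, key, "."), problems)
      }
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Merges user values (a YAML file path or a list) over
#' [default_config()], then validates every section, reporting all
#' problems at once. Unknown keys are rejected so typos cannot silently
#' revert a threshold to its default.
#'
#' @param config YAML file path, a list of overrides, or `NULL` for the
#'   defaults.
#' @return Validated configuration list with `scene`, `emission` and
#'   `analysis` replaced by their constructed, validated objects.
#' @export
load_config <- function(config = NULL) {
  if (is.character(config)) {
    nc_check(file.exists(config), sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  nc_check(is.null(config) || is.list(config), "config must be a list or a YAML path")
  problems <- new.env()
  problems$msgs <- character()
  # 'inputs' is free-form (list of per-cell file records), merged as a leaf
  cfg <- .merge_config(default_config(), config %||% list(), "", problems)
  build <- function(ctor, args, section) {
    tryCatch(do.call(ctor, args),
             error = function(e) {
               problems$msgs <- c(problems$msgs,
                                  sprintf("in section '%s': %s", section,
                                          conditionMessage(e)))
               NULL
             })
  }
  cfg$scene <- build(scene_config, cfg$scene, "scene")
  cfg$emission <- build(emission_config, cfg$emission, "emission")
  cfg$analysis <- build(analysis_config, cfg$analysis, "analysis")
  if (!cfg$mode %in% c("synthetic", "real"))
    problems$msgs <- c(problems$msgs, "mode must be 'synthetic' or 'real'")
  if (cfg$mode == "real" && is.null(cfg$inputs))
    problems$msgs <- c(problems$msgs, "mode 'real' requires an 'inputs' section")
  with(cfg$design, {
    if (n_animals_per_group < 1) problems$msgs <- c(problems$msgs,
      "design.n_animals_per_group must be >= 1")
    if (cells_per_animal < 1) problems$msgs <- c(problems$msgs,
      "design.cells_per_animal must be >= 1")
    if (animal_sd < 0) problems$msgs <- c(problems$msgs,
      "design.animal_sd must be >= 0")
  })
  if (cfg$render$pixel_size_nm <= 0)
    problems$msgs <- c(problems$msgs, "render.pixel_size_nm must be positive")
  if (cfg$render$sigma_render_nm < 0)
    problems$msgs <- c(problems$msgs, "render.sigma_render_nm must be >= 0")
  if (!is.null(cfg$analysis) &&
      !isTRUE(all.equal(cfg$render$pixel_size_nm, cfg$analysis$pixel_size_nm)))
    problems$msgs <- c(problems$msgs,
                       "render.pixel_size_nm and analysis.pixel_size_nm must agree")
  if (length(problems$msgs))
    nc_stop(paste0("invalid configuration:\n  - ",
                   paste(problems$msgs, collapse = "\n  - ")))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze one cell image
#'
#' Full per-cell analysis: segmentation, per-cluster metrics (area,
#' channels, NND), CRU grouping and both per-cell summaries.
#'
#' @param image a [rendered_image()].
#' @param roi a [roi_mask()].
#' @param config an [analysis_config()].
#' @return List with `clusters` (per-cluster table including `nnd_nm`),
#'   `crus` (per-CRU table), and `summary` (one row combining
#'   [cell_summary()] and [cru_summary()]).
#' @export
analyze_cell <- function(image, roi, config = analysis_config()) {
  cs <- segment_image(image, roi, config)
  D <- cluster_pair_distances(cs)
  clusters <- data.table::copy(cs$clusters)
  clusters$nnd_nm <- edge_to_edge_nnd(cs, D)
  crus <- group_crus(cs, D = D)
  list(clusters = clusters,
       crus = crus$crus,
       summary = cbind(cell_summary(cs, D = D), cru_summary(crus)))
}

.pipeline_metrics <- c("mean_area_nm2", "mean_channels", "mean_nnd_nm",
                       "density_per_um2", "mean_clusters_per_cru_all",
                       "mean_channels_per_cru", "frac_isolated")

#' Run the full pipeline
#'
#' Orchestrates simulate (or load) -> segment -> metrics -> CRU ->
#' group comparison as one reproducible run. In synthetic mode a nested
#' two-group dataset is generated from the config; in real mode
#' `inputs` lists per-cell records
#' (`image`, `include`, `exclude`, `animal_id`, `group`, `cell_id`).
#' Result tables and a JSON run manifest (config snapshot, seed, package
#' version, stage timings, output hashes) are written to `out_dir` when
#' given.
#'
#' @param config YAML path, override list, or `NULL` for defaults.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed overrides `config$seed`.
#' @return List with `cells` (per-cell summary table), `clusters`,
#'   `crus`, `comparisons` (per-metric group comparison table),
#'   `comparison_objects`, and `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  acfg <- cfg$analysis
  if (cfg$mode == "synthetic") {
    dataset <- make_two_group_dataset(
      cfg$scene, cfg$emission,
      n_animals_per_group = cfg$design$n_animals_per_group,
      cells_per_animal = cfg$design$cells_per_animal,
      animal_sd = cfg$design$animal_sd,
      pixel_size_nm = cfg$render$pixel_size_nm,
      sigma_render_nm = cfg$render$sigma_render_nm,
      seed = cfg$seed,
      cell_fun = function(image, roi, scene) analyze_cell(image, roi, acfg))
    cells <- lapply(dataset, function(r)
      c(list(animal_id = r$animal_id, group = r$group, cell_id = r$cell_id),
        r$data))
  } else {
    cells <- lapply(cfg$inputs, function(inp) {
      for (key in c("image", "include", "animal_id", "group", "cell_id"))
        nc_check(!is.null(inp[[key]]),
                 sprintf("real-mode input record lacks '%s'", key))
      img <- read_rendered_image(inp$image, acfg$pixel_size_nm)
      roi <- read_roi_mask(inp$include, inp$exclude, dim(img))
      c(list(animal_id = inp$animal_id, group = inp$group,
             cell_id = inp$cell_id),
        analyze_cell(img, roi, acfg))
    })
  }
  timings$analyze <- proc.time()[["elapsed"]] - t0
  key_cols <- function(r) data.table::data.table(
    animal_id = r$animal_id, group = r$group, cell_id = r$cell_id)
  cell_tab <- data.table::rbindlist(lapply(cells, function(r)
    cbind(key_cols(r), r$summary)))
  cluster_tab <- data.table::rbindlist(lapply(cells, function(r)
    if (nrow(r$clusters)) cbind(key_cols(r), r$clusters) else NULL))
  cru_tab <- data.table::rbindlist(lapply(cells, function(r)
    if (nrow(r$crus)) cbind(key_cols(r), r$crus) else NULL))
  t1 <- proc.time()[["elapsed"]]
  comps <- lapply(.pipeline_metrics, function(m)
    tryCatch(compare_groups(cell_tab, m), error = function(e) NULL))
  names(comps) <- .pipeline_metrics
  comps <- Filter(Negate(is.null), comps)
  comp_tab <- data.table::rbindlist(lapply(comps, as.data.frame))
  timings$compare <- proc.time()[["elapsed"]] - t1
  manifest <- list(package = "nanocluster",
                   version = as.character(utils::packageVersion("nanocluster")),
                   seed = cfg$seed,
                   config = .config_snapshot(cfg),
                   timings = timings,
                   n_cells = nrow(cell_tab),
                   outputs = list())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(per_cell = "per_cell.csv", per_cluster = "per_cluster.csv",
               per_cru = "per_cru.csv", comparisons = "comparisons.csv")
    tabs <- list(cell_tab, cluster_tab, cru_tab, comp_tab)
    for (i in seq_along(paths)) {
      fp <- file.path(out_dir, paths[i])
      data.table::fwrite(tabs[[i]], fp)
      manifest$outputs[[names(paths)[i]]] <-
        list(path = paths[[i]], md5 = unname(tools::md5sum(fp)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cells = cell_tab, clusters = cluster_tab, crus = cru_tab,
       comparisons = comp_tab, comparison_objects = comps,
       manifest = manifest)
}

.config_snapshot <- function(cfg) {
  cfg$scene <- unclass(cfg$scene)
  cfg$emission <- unclass(cfg$emission)
  cfg$analysis <- unclass(cfg$analysis)
  cfg
}
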