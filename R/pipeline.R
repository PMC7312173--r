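# pipeline_cli: end-to-end orchestration from a single YAML config, with
# stage markers (config-hash gated) so completed stages are never recomputed.

default_config <- function() {
  list(
    run_dir = "slidedamage_run",
    seed = 1L,
    pixel_size = 0.5,
    fast_axis = "cols",
    channels = list(dapi = NULL, gh2ax = NULL),
    cohort = list(role = "treated", incubation_h = NA, control_table = NULL),
    simulate = NULL,
    segmentation = list(sigma = 1, min_area = 30, window = 1024,
                        method = "seeded_watershed"),
    qc = list(tile = 512, density_threshold = 10, focus_threshold = NULL),
    correction = list(lowess_span = 0.3, block_mm = 1, pct = c(2, 4),
                      flatten_gh2ax = TRUE, min_nuclei = 500),
    features = list(fourier_k = 16, shells = 4, levels = 64, granularity = 16),
    classify = list(model = NULL, train_synthetic = FALSE, n_per_class = 500),
    damage_map = list(enable = FALSE, center_x_um = NULL, center_y_um = NULL,
                      diameter_mm = 18, bin_mm = 0.25, stat = "DR",
                      phases = list("all"), threshold = 75, scale = NULL)
  )
}

#' Read and validate a run configuration
#'
#' @param path YAML file, or a list already in config shape.
#' @return validated config list (defaults filled in).
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- modifyList(default_config(), user)
  if (cfg$pixel_size <= 0) stop("config: pixel_size must be positive")
  if (!cfg$fast_axis %in% c("rows", "cols"))
    stop("config: fast_axis must be 'rows' or 'cols'")
  if (isTRUE(cfg$damage_map$enable)) {
    if (is.null(cfg$damage_map$center_x_um) || is.null(cfg$damage_map$center_y_um))
      stop("config: damage_map is enabled but treatment center ",
           "(damage_map.center_x_um / center_y_um) is missing")
  }
  if (is.null(cfg$simulate) &&
      (is.null(cfg$channels$dapi) || is.null(cfg$channels$gh2ax)))
    stop("config: channel paths are required unless simulate: is given")
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg, f)
  unname(tools::md5sum(f))
}

stage_done <- function(run_dir, stage, hash) {
  f <- file.path(run_dir, sprintf(".done_%s.json", stage))
  file.exists(f) && identical(jsonlite::read_json(f)$hash, hash)
}

mark_done <- function(run_dir, stage, hash, info = list()) {
  jsonlite::write_json(c(list(stage = stage, hash = hash,
                              time = format(Sys.time())), info),
                       file.path(run_dir, sprintf(".done_%s.json", stage)),
                       auto_unbox = TRUE)
}

log_line <- function(run_dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  cat(msg, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

#' Run the whole pipeline (or selected stages)
#'
#' Stages, in the fixed order: \code{simulate} (optional), \code{segment},
#' \code{correct}, \code{features}, \code{classify}, \code{damage_map}.
#' Each stage's outputs are written before the next begins; a completed
#' stage with an unchanged config hash is skipped on rerun. Any stage error
#' aborts with the stage name.
#'
#' @param config path to a YAML config or a config list
#'   (\code{\link{read_run_config}}).
#' @param stages subset of stages to run (dependencies must already have
#'   outputs in the run directory).
#' @return run directory path, invisibly.
#' @export
run_pipeline <- function(config, stages = c("simulate", "segment", "correct",
                                            "features", "classify",
                                            "damage_map")) {
  cfg <- read_run_config(config)
  rd <- cfg$run_dir
  dir.create(rd, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  yaml::write_yaml(cfg, file.path(rd, "config_snapshot.yaml"))
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    if (stage_done(rd, name, hash)) {
      log_line(rd, "stage ", name, ": up to date, skipping")
      return(invisible(NULL))
    }
    log_line(rd, "stage ", name, ": start")
    info <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    mark_done(rd, name, hash, info %||% list())
    log_line(rd, "stage ", name, ": done")
  }

  paths <- list(dapi = cfg$channels$dapi %||% file.path(rd, "dapi.tif"),
                gh2ax = cfg$channels$gh2ax %||% file.path(rd, "gh2ax.tif"))

  run_stage("simulate", function() {
    if (is.null(cfg$simulate)) return(list(skipped = TRUE))
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim_args$pixel_size <- sim_args$pixel_size %||% cfg$pixel_size
    if (is.list(sim_args$phase_mix))         # YAML round trip yields a list
      sim_args$phase_mix <- unlist(sim_args$phase_mix)
    if (!is.null(sim_args$artifacts) && !inherits(sim_args$artifacts, "artifact_spec"))
      sim_args$artifacts <- do.call(artifact_spec, sim_args$artifacts)
    sim <- do.call(generate_slide, sim_args)
    write_slide(sim$dapi, paths$dapi)
    write_slide(sim$gh2ax, paths$gh2ax)
    write_ground_truth(sim$truth, file.path(rd, "truth"))
    list(n_nuclei = nrow(sim$truth$nuclei))
  })

  load_channels <- function() {
    list(dapi = read_slide(paths$dapi, "DAPI", cfg$pixel_size, cfg$fast_axis),
         gh2ax = read_slide(paths$gh2ax, "gH2AX", cfg$pixel_size, cfg$fast_axis))
  }

  run_stage("segment", function() {
    ch <- load_channels()
    sg <- cfg$segmentation
    lab <- segment_nuclei(ch$dapi, sigma = sg$sigma, min_area = sg$min_area,
                          adaptive_window = sg$window)
    lab <- partition_overlaps(lab, ch$dapi, method = sg$method)
    write_label_map(lab, file.path(rd, "labels.tif"))
    list(n_labels = max(lab))
  })

  run_stage("correct", function() {
    ch <- load_channels()
    lab <- read_label_map(file.path(rd, "labels.tif"))
    co <- cfg$correction
    cor <- correct_slide(ch$dapi, ch$gh2ax, lab, span = co$lowess_span,
                         block_mm = co$block_mm,
                         percentile_band = unlist(co$pct) / 100,
                         flatten_gh2ax = isTRUE(co$flatten_gh2ax),
                         min_nuclei = co$min_nuclei %||% 500L)
    write_nucleus_table(cor$records, file.path(rd, "records_corrected.csv"))
    write_slide(cor$dapi, file.path(rd, "dapi_corrected.tif"), "float32")
    write_slide(cor$gh2ax, file.path(rd, "gh2ax_corrected.tif"), "float32")
    yaml::write_yaml(list(stripe_factors_dapi = cor$model$stripe_factors_dapi,
                          gain_curve = cor$model$gain_curve[c("center_um", "g1", "g2")]),
                     file.path(rd, "correction_model.yaml"))
    list(n_records = nrow(cor$records))
  })

  run_stage("features", function() {
    lab <- read_label_map(file.path(rd, "labels.tif"))
    dapi <- read_slide(file.path(rd, "dapi_corrected.tif"), "DAPI",
                       cfg$pixel_size, cfg$fast_axis)
    gh <- read_slide(file.path(rd, "gh2ax_corrected.tif"), "gH2AX",
                     cfg$pixel_size, cfg$fast_axis)
    qc <- qc_mask(dapi, lab, tile = cfg$qc$tile,
                  density_threshold = cfg$qc$density_threshold,
                  focus_threshold = cfg$qc$focus_threshold)
    fe <- cfg$features
    feats <- extract_features(lab, dapi, gh, K = fe$fourier_k, S = fe$shells,
                              levels = fe$levels, G = fe$granularity, qc = qc)
    rec <- read_nucleus_table(file.path(rd, "records_corrected.csv"))
    # corrected (band-anchored / baseline-flattened) intensities win
    for (cn in c("i_dapi", "i_gh2ax", "i_dapi_raw", "i_gh2ax_raw"))
      if (cn %in% names(rec)) feats[[cn]] <- rec[[cn]][match(feats$nucleus_id,
                                                             rec$nucleus_id)]
    write_nucleus_table(feats, file.path(rd, "features.csv"))
    list(n_records = nrow(feats), n_masked = sum(!feats$qc_pass))
  })

  run_stage("classify", function() {
    feats <- read_nucleus_table(file.path(rd, "features.csv"))
    nn <- if (!is.null(cfg$classify$model)) {
      load_model(cfg$classify$model)
    } else if (isTRUE(cfg$classify$train_synthetic)) {
      fx <- balanced_training_fixture(n_per_class = cfg$classify$n_per_class,
                                      seed = cfg$seed,
                                      pixel_size = cfg$pixel_size)
      train_mitosis_classifier(fx$records, fx$labels, seed = cfg$seed)
    } else stop("classify: supply classify.model or set classify.train_synthetic")
    cl <- classify_cells(feats, nn, seed = cfg$seed)
    write_nucleus_table(cl$records, file.path(rd, "records_classified.csv"))
    save_model(nn, file.path(rd, "mitosis_classifier.json"))
    save_model(cl$mog, file.path(rd, "interphase_mog.json"))
    list(n_interphase = sum(cl$records$nn_class == 1L, na.rm = TRUE))
  })

  run_stage("damage_map", function() {
    if (!isTRUE(cfg$damage_map$enable)) return(list(skipped = TRUE))
    dm <- cfg$damage_map
    f_class <- file.path(rd, "records_classified.csv")
    rec <- read_nucleus_table(
      if (file.exists(f_class)) f_class else file.path(rd, "features.csv"))
    scale <- dm$scale %||% calibrate_damage_scale(rec$i_gh2ax, rec$i_dapi)
    rec$damage <- damage_value(rec$i_gh2ax, rec$i_dapi, scale)
    if (!is.null(cfg$cohort$control_table)) {
      ctl <- read_nucleus_table(cfg$cohort$control_table)
      ctl_damage <- damage_value(ctl$i_gh2ax, ctl$i_dapi, scale)
      rec$damage <- subtract_control_baseline(rec$damage, ctl_damage)
    }
    center <- c(dm$center_x_um, dm$center_y_um)
    for (ph in unlist(dm$phases)) {
      map <- build_damage_map(rec, center, diameter_mm = dm$diameter_mm,
                              bin_mm = dm$bin_mm, statistic = dm$stat,
                              phase_filter = ph, threshold = dm$threshold)
      export_damage_map(map,
                        file.path(rd, sprintf("map_%s_%s.csv", dm$stat, ph)),
                        file.path(rd, sprintf("map_%s_%s.png", dm$stat, ph)))
    }
    write_nucleus_table(rec, file.path(rd, "records_damage.csv"))
    list(scale = scale)
  })

  invisible(rd)
}

#' Balanced five-class synthetic training fixture
#'
#' Generates \code{n_per_class} nuclei of each of the five mitosis classes
#' with the generator's class-distinct morphologies (no slide artifacts),
#' extracts the full feature set from the ground-truth label map, and
#' returns records plus labels. The interphase class draws its nuclei from
#' the G1/S/G2 mix in proportion to time spent in each phase.
#'
#' @param n_per_class nuclei per class (the training set of record: 500).
#' @param seed integer seed.
#' @param pixel_size micrometres per pixel.
#' @return list: \code{records} (feature table), \code{labels} (integer 1..5),
#'   \code{truth} (generator ground truth).
#' @export
balanced_training_fixture <- function(n_per_class = 500L, seed = 1L,
                                      pixel_size = 0.5) {
  n <- ceiling(5 * n_per_class * 1.15)   # headroom so every class reaches n_per_class
  mix <- c(G1 = 0.6, S = 0.1, G2 = 0.3) / 5
  mix <- c(mix, M2 = 0.2, M3 = 0.2, M4 = 0.2, M5 = 0.2)
  art <- artifact_spec(background = list(enable = FALSE),
                       stripes = list(enable = FALSE),
                       gain_drift = list(enable = FALSE),
                       noise = list(shot = 0.3, read = 2))
  sim <- generate_slide(n, phase_mix = mix, artifacts = art,
                        confluence = 0.12, pixel_size = pixel_size,
                        seed = seed, sep_frac = 1.15)
  dapi <- sim$dapi
  feats <- extract_features(sim$truth$labels, dapi)
  cls <- c(G1 = 1L, S = 1L, G2 = 1L, M2 = 2L, M3 = 3L, M4 = 4L, M5 = 5L)
  labels <- unname(cls[sim$truth$nuclei$phase])
  # rebalance: exactly n_per_class per class where available
  keep <- integer(0)
  set.seed(child_seed(seed, 9L))
  for (k in 1:5) {
    ik <- which(labels == k)
    keep <- c(keep, if (length(ik) > n_per_class) sample(ik, n_per_class) else ik)
  }
  list(records = feats[keep, , drop = FALSE], labels = labels[keep],
       truth = sim$truth)
}
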