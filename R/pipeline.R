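# Config-driven pipeline: simulate -> trace -> analyze -> topology, with
# deterministic seeding and manifest-stamped, inspectable outputs.

# Default configuration tree; also the schema (unknown keys are errors).
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "afmwlc-run",
    stages = c("simulate", "trace", "analyze"),
    condition = list(n_molecules = 10L, lp_nm = 56, contour_nm = 328,
                     height_nm = 0.6, closed = FALSE, label = "bare-dna"),
    render = list(pixel_nm = 2, noise_sd_nm = 0.05, ridge_sigma_nm = 2,
                  tip_sigma_nm = 2, background_particles = 0L,
                  image_rows = 512L, image_cols = 512L),
    trace = list(step_nm = 8, min_len_nm = 50),
    analyze = list(max_sep_nm = 160, fit_min_nm = 8, fit_max_nm = 120),
    topology = list(compact_height_nm = 1.2, plectoneme_factor = 1.6))
}

merge_checked <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- merge_checked(defaults[[k]], as.list(user[[k]]),
                                     paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks it against the schema
#' (unknown keys are errors — fail closed), fills defaults, and validates
#' parameter ranges.
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated config list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    yaml::read_yaml(config)
  } else as.list(config)
  cfg <- merge_checked(default_config(), user)
  with(cfg, {
    if (render$pixel_nm <= 0) stop("render.pixel_nm must be > 0", call. = FALSE)
    if (trace$step_nm <= 0) stop("trace.step_nm must be > 0", call. = FALSE)
    if (condition$n_molecules < 1)
      stop("condition.n_molecules must be >= 1", call. = FALSE)
    if (condition$lp_nm <= 0 || condition$contour_nm <= 0 ||
        condition$height_nm <= 0)
      stop("condition lengths must be positive", call. = FALSE)
    bad <- setdiff(stages, c("simulate", "trace", "analyze", "topology"))
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  })
  structure(cfg, class = "run_config")
}

# Small deterministic FNV-1a hash of the scientific configuration (hex
# string) for manifests; the output location does not alter the science,
# so identical runs into different directories hash identically.
config_hash <- function(cfg) {
  c2 <- unclass(cfg)
  c2$out_dir <- NULL
  s <- jsonlite::toJSON(c2, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647  # stays exact in doubles
  sprintf("%08x", h)
}

#' Run the simulate / trace / analyze / topology pipeline
#'
#' Executes the requested stages into `out_dir`, writing inspectable
#' artifacts: float TIFF images with YAML sidecars and a ground-truth CSV +
#' JSON manifest (`simulate/`), a traces CSV and per-image class counts
#' (`trace/`), the pooled correlation curve and persistence-length fit
#' (`analyze/`), and per-molecule topology rows plus aggregates
#' (`topology/`). Every stage directory carries a `manifest.json` with the
#' package version, master seed and config hash; no stage mutates another
#' stage's outputs. All randomness derives from the single master seed, so
#' a rerun with the same config is byte-identical.
#'
#' @param config a [validate_config()] result, a path to a YAML config, or
#'   a named list.
#' @return invisibly, a list with the per-stage summary report.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "afmwlc",
                   version = as.character(utils::packageVersion("afmwlc")),
                   seed = cfg$seed, config_hash = config_hash(cfg))
  report <- list(manifest = manifest)
  params <- render_params(
    pixel_nm = cfg$render$pixel_nm, noise_sd_nm = cfg$render$noise_sd_nm,
    ridge_sigma_nm = cfg$render$ridge_sigma_nm,
    tip_sigma_nm = cfg$render$tip_sigma_nm,
    background_particles = cfg$render$background_particles,
    image_shape = c(cfg$render$image_rows, cfg$render$image_cols))
  cond <- afm_condition(cfg$condition$n_molecules, cfg$condition$lp_nm,
                        cfg$condition$contour_nm, cfg$condition$height_nm,
                        cfg$condition$closed, cfg$condition$label)
  stage_dir <- function(s) {
    d <- file.path(cfg$out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ensemble <- NULL
  if ("simulate" %in% cfg$stages) {
    d <- stage_dir("simulate")
    run_stage("simulate", function() {
      ensemble <<- make_condition_ensemble(cond, cfg$seed, params)
      for (i in seq_along(ensemble))
        write_afm_tiff(ensemble[[i]]$image,
                       file.path(d, sprintf("mol%03d.tif", i)),
                       seed = cfg$seed)
      write_ground_truth(lapply(ensemble, `[[`, "polymer"),
                         file.path(d, "ground_truth.csv"),
                         file.path(d, "ground_truth.json"))
      write_report_json(manifest, file.path(d, "manifest.json"))
    })
    report$simulate <- list(n_molecules = length(ensemble))
  }

  traces <- NULL
  if ("trace" %in% cfg$stages) {
    d <- stage_dir("trace")
    run_stage("trace", function() {
      if (is.null(ensemble))
        ensemble <<- make_condition_ensemble(cond, cfg$seed, params)
      traces <<- list()
      counts <- c(linear = 0L, circular = 0L, compact = 0L, reject = 0L)
      for (i in seq_along(ensemble)) {
        regions <- segment_molecules(
          ensemble[[i]]$image, min_len_nm = cfg$trace$min_len_nm,
          height_band = c(cond$height_nm, cond$height_nm),
          compact_height_nm = cfg$topology$compact_height_nm)
        for (rg in regions) {
          counts[rg$class_hint] <- counts[rg$class_hint] + 1L
          if (rg$class_hint %in% c("linear", "circular")) {
            tr <- tryCatch(
              trace_backbone(ensemble[[i]]$image, rg, cfg$trace$step_nm),
              error = function(e) NULL)
            if (!is.null(tr)) {
              tr$molecule_id <- sprintf("mol%03d", i)
              traces[[length(traces) + 1L]] <<- tr
            }
          } else {
            warning(sprintf("image %d: %s molecule excluded", i,
                            rg$class_hint), call. = FALSE)
          }
        }
      }
      write_traces_csv(traces, file.path(d, "traces.csv"))
      write_report_json(c(manifest, list(class_counts = as.list(counts),
                                         n_traced = length(traces))),
                        file.path(d, "report.json"))
    })
    report$trace <- list(n_traced = length(traces))
  }

  if ("analyze" %in% cfg$stages) {
    d <- stage_dir("analyze")
    run_stage("analyze", function() {
      if (is.null(traces))
        traces <<- read_traces_csv(file.path(cfg$out_dir, "trace",
                                             "traces.csv"))
      curve <- tangent_correlation(traces, cfg$analyze$max_sep_nm)
      fit <- fit_persistence_length(
        curve, c(cfg$analyze$fit_min_nm, cfg$analyze$fit_max_nm))
      cls <- contour_length_stats(traces)
      utils::write.csv(
        data.frame(sep_nm = curve$sep_nm, mean_corr = curve$mean_corr,
                   n_pairs = curve$n_pairs, se = curve$se),
        file.path(d, "correlation.csv"), row.names = FALSE)
      rep_an <- c(manifest, list(
        lp_nm = fit$lp, lp_se_nm = fit$lp_se,
        fit_range_nm = fit$fit_range, residual_rms = fit$residual_rms,
        n_molecules = fit$n_molecules,
        contour_mean_nm = cls$mean_nm, contour_sd_nm = cls$sd_nm))
      write_report_json(rep_an, file.path(d, "report.json"))
      report$analyze <<- rep_an
    })
  }

  if ("topology" %in% cfg$stages) {
    d <- stage_dir("topology")
    run_stage("topology", function() {
      if (is.null(ensemble))
        ensemble <<- make_condition_ensemble(cond, cfg$seed, params)
      rows <- list()
      for (i in seq_along(ensemble)) {
        regions <- segment_molecules(
          ensemble[[i]]$image, min_len_nm = cfg$trace$min_len_nm,
          height_band = c(cond$height_nm, cond$height_nm),
          compact_height_nm = cfg$topology$compact_height_nm)
        for (rg in regions) {
          tp <- tryCatch(
            classify_topology(ensemble[[i]]$image, rg,
                              single_height_nm = cond$height_nm,
                              compact_height_nm = cfg$topology$compact_height_nm,
                              plectoneme_factor = cfg$topology$plectoneme_factor,
                              step_nm = cfg$trace$step_nm),
            error = function(e) NULL)
          if (!is.null(tp))
            rows[[length(rows) + 1L]] <- data.frame(
              image = i, molecule_id = tp$molecule_id, class = tp$class,
              contour_nm = tp$contour_nm, axis_nm = tp$axis_nm,
              axis_ratio = tp$axis_ratio, n_branches = tp$n_branches)
        }
      }
      df <- do.call(rbind, rows)
      utils::write.csv(df, file.path(d, "topology.csv"), row.names = FALSE)
      agg <- c(manifest, list(
        class_counts = as.list(table(df$class)),
        mean_contour_nm = mean(df$contour_nm, na.rm = TRUE),
        mean_axis_nm = mean(df$axis_nm, na.rm = TRUE),
        mean_axis_ratio = mean(df$axis_ratio, na.rm = TRUE)))
      write_report_json(agg, file.path(d, "report.json"))
      report$topology <<- agg
    })
  }
  invisible(report)
}
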