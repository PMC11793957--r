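# End-to-end orchestration: simulate (or load) -> preprocess -> fit ->
# dispersion -> describe, with all outputs written as CSV/JSON and a
# manifest recording seed, configuration and file checksums.

drop_models <- function(x) {
  # strip fitted lmer objects before JSON serialisation
  if (inherits(x, "data.frame")) return(x)
  if (is.list(x)) {
    x$model <- NULL
    x$fits <- NULL
    x <- lapply(x, function(el) if (is.list(el)) drop_models(el) else el)
  }
  x
}

write_json_out <- function(x, path) {
  jsonlite::write_json(drop_models(unclass(x)), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE,
                       force = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Chains panel generation (or a user-supplied panel with the documented
#' raw schema), preprocessing, the polynomial model comparison and
#' segmented changepoint search on each resource variable, the
#' variance-heterogeneity analyses, and the descriptive tables. Every
#' stage's output is written under `out_dir` and a manifest (seed,
#' configuration, package version, per-file MD5 checksums) is written as
#' `manifest.json`. Runs are reproducible: a fixed seed and configuration
#' give identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling all randomness.
#' @param config A [panel_config()] for the generator.
#' @param panel Optional raw panel data frame; when supplied the generator
#'   is skipped and `config` is ignored.
#' @param resources Resource variables to analyse.
#' @param max_degree Highest polynomial degree compared.
#' @param grid_step Percentile step of the changepoint grid.
#' @param min_side Minimum observations per changepoint side.
#' @param pmin,pmax Percentile range of the variance sweep.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = panel_config(),
                         panel = NULL,
                         resources = c("objective_resources",
                                       "subjective_resources"),
                         max_degree = 5, grid_step = 0.5, min_side = 20,
                         pmin = 1, pmax = 50) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  out_path <- function(f) file.path(out_dir, f)

  panel <- stage("simulate", {
    if (is.null(panel)) panel <- generate_panel(config, seed = seed)
    write.csv(panel, out_path("panel.csv"), row.names = FALSE)
    panel
  })
  files <- c(files, "panel.csv")

  proc <- stage("preprocess", {
    p <- preprocess_panel(panel)
    write.csv(p, out_path("processed.csv"), row.names = FALSE)
    p
  })
  files <- c(files, "processed.csv")

  diagnostics <- stage("diagnostics", validate_generator(panel))
  write_json_out(diagnostics, out_path("diagnostics.json"))
  files <- c(files, "diagnostics.json")

  for (rv in resources) {
    short <- sub("_resources", "", rv)
    stage(paste0("fit-poly-", short), {
      cmp <- compare_polynomials(proc, rv, max_degree = max_degree)
      write_json_out(list(table = cmp$table,
                          selected_degree = cmp$selected_degree,
                          inflection = lapply(cmp$fits, function(f)
                            if (is.null(f)) NULL else f$inflection_points)),
                     out_path(sprintf("poly_%s.json", short)))
    })
    files <- c(files, sprintf("poly_%s.json", short))
    stage(paste0("fit-segmented-", short), {
      seg <- fit_segmented_mixed(proc, rv, grid = "percentile",
                                 step = grid_step, min_side = min_side)
      write.csv(seg$profile, out_path(sprintf("profile_%s.csv", short)),
                row.names = FALSE)
      seg$profile <- NULL
      write_json_out(seg, out_path(sprintf("segmented_%s.json", short)))
    })
    files <- c(files, sprintf("profile_%s.csv", short),
               sprintf("segmented_%s.json", short))
  }

  stage("dispersion", {
    disp <- list(
      p2_family = p2_family_tests(proc),
      icc_risk_count = icc(proc, "risk_count"),
      cronbach_alpha = cronbach_alpha(panel[paste0("subj_item_", 1:3)]),
      stability = lapply(setNames(resources, resources), function(rv) {
        s <- within_person_stability(proc, rv)
        s$participants <- NULL
        s
      })
    )
    write_json_out(disp, out_path("dispersion.json"))
    for (rv in resources) {
      short <- sub("_resources", "", rv)
      sw <- variance_sweep(proc, rv, pmin = pmin, pmax = pmax)
      write.csv(sw, out_path(sprintf("sweep_%s.csv", short)),
                row.names = FALSE)
    }
  })
  files <- c(files, "dispersion.json",
             sprintf("sweep_%s.csv", sub("_resources", "", resources)))

  stage("describe", {
    write.csv(extreme_prevalence_table(proc),
              out_path("extreme_prevalence.csv"), row.names = FALSE)
    write.csv(mean_resources_by_count(proc),
              out_path("resources_by_count.csv"), row.names = FALSE)
    write.csv(strain_group_summary(proc),
              out_path("strain_summary.csv"), row.names = FALSE)
    write.csv(discounting_contrast(proc),
              out_path("discounting_contrast.csv"), row.names = FALSE)
    write.csv(consistency_by_resources(proc),
              out_path("consistency.csv"), row.names = FALSE)
  })
  files <- c(files, "extreme_prevalence.csv", "resources_by_count.csv",
             "strain_summary.csv", "discounting_contrast.csv",
             "consistency.csv")

  files <- unique(files)
  manifest <- list(
    package = "thresholdrisk",
    version = as.character(packageVersion("thresholdrisk")),
    seed = seed,
    config = unclass(config)[!vapply(config, is.list, logical(1))],
    resources = resources,
    options = list(max_degree = max_degree, grid_step = grid_step,
                   min_side = min_side, pmin = pmin, pmax = pmax),
    files = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
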