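#' Assemble a pipeline run configuration
#'
#' Collects everything a reproducible end-to-end run needs: paths, the
#' simulation configuration, analysis parameters, statistics settings and
#' the master seed. Can be loaded from a YAML file whose keys mirror the
#' argument names (nested \code{simulation}, \code{analysis},
#' \code{statistics} sections).
#'
#' @param mode one of \code{"simulate"}, \code{"analyze"}, \code{"stats"},
#'   \code{"all"}.
#' @param out_dir output directory (created on run).
#' @param seed master seed; every stage derives its randomness from it.
#' @param layout plate layout data.frame, or path to its CSV.
#' @param effects named list of planted effect multipliers per treatment
#'   (simulate modes only).
#' @param sim_config a \code{\link{simulation_config}}.
#' @param params an \code{\link{analysis_params}}.
#' @param fields_per_well imaged fields per well (simulate modes).
#' @param replicate_cv,well_cv simulator variability (see
#'   \code{\link{simulate_screen}}).
#' @param scope,min_per_well,min_total,validate_k statistics settings.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(mode = "all", out_dir = "hcsnano_run", seed = 1L,
                       layout = NULL, effects = NULL,
                       sim_config = simulation_config(),
                       params = analysis_params(), fields_per_well = 1L,
                       replicate_cv = 0.05, well_cv = 0.05,
                       scope = "plate_replicate", min_per_well = 50,
                       min_total = 150, validate_k = 2L) {
  mode <- match.arg(mode, c("simulate", "analyze", "stats", "all"))
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 layout = layout, effects = effects,
                 sim_config = sim_config, params = params,
                 fields_per_well = as.integer(fields_per_well),
                 replicate_cv = replicate_cv, well_cv = well_cv,
                 scope = scope, min_per_well = min_per_well,
                 min_total = min_total, validate_k = as.integer(validate_k)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; top-level keys as in \code{\link{run_config}},
#'   with \code{simulation} and \code{analysis} sections passed to
#'   \code{\link{simulation_config}} and \code{\link{analysis_params}}.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, y$simulation %||% list())
  gates <- if (!is.null(y$analysis$gates))
    do.call(qc_gates, y$analysis$gates) else qc_gates()
  apars <- y$analysis %||% list()
  apars$gates <- gates
  par <- do.call(analysis_params, apars)
  run_config(mode = y$mode %||% "all",
             out_dir = y$out_dir %||% "hcsnano_run",
             seed = y$seed %||% 1L, layout = y$layout,
             effects = y$effects, sim_config = sim, params = par,
             fields_per_well = y$fields_per_well %||% 1L,
             replicate_cv = y$replicate_cv %||% 0.05,
             well_cv = y$well_cv %||% 0.05,
             scope = y$scope %||% "plate_replicate",
             min_per_well = y$min_per_well %||% 50,
             min_total = y$min_total %||% 150,
             validate_k = y$validate_k %||% 2L)
}

resolve_run_layout <- function(config) {
  lay <- config$layout
  if (is.character(lay)) {
    if (!file.exists(lay)) stop("missing layout file: ", lay, call. = FALSE)
    lay <- utils::read.csv(lay, stringsAsFactors = FALSE)
  }
  if (is.null(lay)) stop("a plate layout is required", call. = FALSE)
  validate_layout(lay)
}

write_table <- function(df, dir, name) {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE)
  p
}

#' Run the screen pipeline
#'
#' Orchestrates simulation, image analysis and screen statistics with a
#' single master seed. Partial modes consume the CSV outputs of earlier
#' stages from \code{out_dir}, so \code{simulate} + \code{analyze} +
#' \code{stats} run separately reproduce an \code{all} run exactly. All
#' result tables are written as CSV, together with a JSON run manifest
#' recording the seed, a configuration digest and per-stage row counts.
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, a results bundle: list with (depending on mode)
#'   \code{manifest}, \code{wells}, \code{cells}, \code{treatments},
#'   \code{validation}, \code{controls}, \code{control_readouts}, plus
#'   \code{paths} of the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mode <- config$mode
  out <- list(paths = character(0))
  if (mode %in% c("simulate", "all"))
    out <- pipeline_simulate(config, out)
  if (mode %in% c("analyze", "all"))
    out <- pipeline_analyze(config, out)
  if (mode %in% c("stats", "all"))
    out <- pipeline_stats(config, out)
  out$paths["run_manifest"] <- write_run_manifest(config, out)
  message(sprintf("[hcsnano] %s run complete in %s", mode, config$out_dir))
  invisible(out)
}

pipeline_simulate <- function(config, out) {
  layout <- resolve_run_layout(config)
  if (is.null(config$effects))
    stop("simulate mode needs an 'effects' map", call. = FALSE)
  scr <- simulate_screen(layout, config$effects, config$sim_config,
                         fields_per_well = config$fields_per_well,
                         seed = derive_seed(config$seed, "simulate"),
                         dir = file.path(config$out_dir, "images"),
                         replicate_cv = config$replicate_cv,
                         well_cv = config$well_cv)
  out$manifest <- scr$manifest
  out$truth_wells <- scr$truth_wells
  out$layout <- layout
  out$paths["layout"] <- write_table(layout, config$out_dir, "layout.csv")
  out$paths["image_manifest"] <-
    write_table(scr$manifest, config$out_dir, "image_manifest.csv")
  out$paths["truth_wells"] <-
    write_table(scr$truth_wells, config$out_dir, "truth_wells.csv")
  out
}

pipeline_analyze <- function(config, out) {
  if (is.null(out$manifest)) {
    p <- file.path(config$out_dir, "image_manifest.csv")
    if (!file.exists(p)) stop("missing image manifest: ", p, call. = FALSE)
    out$manifest <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  if (is.null(out$layout)) {
    lp <- file.path(config$out_dir, "layout.csv")
    out$layout <- if (file.exists(lp))
      utils::read.csv(lp, stringsAsFactors = FALSE)
    else resolve_run_layout(config)
  }
  known <- unique(out$layout$treatment_id)
  bad <- setdiff(unique(out$manifest$treatment_id), known)
  if (length(bad))
    stop("treatment(s) in images but absent from layout: ",
         paste(bad, collapse = ", "), call. = FALSE)
  man <- out$manifest
  key <- paste(man$plate_id, man$well_id, man$replicate_id)
  wells <- list(); cells <- list()
  for (k in unique(key)) {
    rows <- man[key == k, ]
    recs <- list()
    for (j in seq_len(nrow(rows))) {
      fld <- read_field_tiff(dirname(rows$nuclei[j]), rows$plate_id[j],
                             sprintf("%s_R%d", rows$well_id[j],
                                     rows$replicate_id[j]),
                             rows$field_id[j])
      ana <- analyze_field(fld, config$params)
      r <- ana$records
      if (nrow(r)) {
        r$plate_id <- rows$plate_id[j]; r$well_id <- rows$well_id[j]
        r$replicate_id <- rows$replicate_id[j]; r$field_id <- rows$field_id[j]
      }
      recs[[j]] <- r
    }
    pooled <- do.call(rbind, recs)
    wr <- well_ratio(pooled)
    wells[[k]] <- data.frame(
      plate_id = rows$plate_id[1], well_id = rows$well_id[1],
      replicate_id = rows$replicate_id[1],
      treatment_id = rows$treatment_id[1], gene = rows$gene[1],
      sirna_id = rows$sirna_id[1],
      is_negative_control = rows$is_negative_control[1], wr)
    cells[[k]] <- pooled
  }
  out$wells <- do.call(rbind, wells); rownames(out$wells) <- NULL
  out$cells <- do.call(rbind, cells); rownames(out$cells) <- NULL
  out$paths["wells"] <- write_table(out$wells, config$out_dir, "wells.csv")
  out$paths["cells"] <- write_table(out$cells, config$out_dir, "cells.csv")
  out
}

pipeline_stats <- function(config, out) {
  # always consume the written well table so staged and all-mode runs see
  # bit-identical inputs (CSV round-trips doubles at 15 significant digits)
  p <- file.path(config$out_dir, "wells.csv")
  if (file.exists(p)) {
    out$wells <- utils::read.csv(p, stringsAsFactors = FALSE)
  } else if (is.null(out$wells)) {
    stop("missing well table: ", p, call. = FALSE)
  }
  res <- screen_statistics(out$wells, scope = config$scope,
                           min_per_well = config$min_per_well,
                           min_total = config$min_total)
  out$wells <- res$wells   # now carries normalized_ratio
  out$treatments <- res$treatments
  out$controls <- res$controls
  out$validation <- validate_screen(res$treatments, k = config$validate_k)
  out$control_readouts <- control_readouts(out$wells)
  out$paths["treatment_results"] <-
    write_table(res$treatments, config$out_dir, "treatment_results.csv")
  out$paths["validation"] <-
    write_table(out$validation, config$out_dir, "validation.csv")
  out$paths["controls"] <-
    write_table(out$controls, config$out_dir, "controls.csv")
  out$paths["control_readouts"] <-
    write_table(out$control_readouts, config$out_dir,
                "control_readouts.csv")
  out
}

config_digest <- function(config) {
  x <- config[setdiff(names(config), c("layout"))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(utils::capture.output(utils::str(x, digits.d = 10)), tf)
  unname(tools::md5sum(tf))
}

write_run_manifest <- function(config, out) {
  counts <- list()
  for (nm in c("manifest", "wells", "cells", "treatments", "validation"))
    if (!is.null(out[[nm]])) counts[[nm]] <- nrow(out[[nm]])
  man <- list(package = "hcsnano",
              version = as.character(utils::packageVersion("hcsnano")),
              mode = config$mode, seed = config$seed,
              config_md5 = config_digest(config), rows = counts)
  p <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(man, p, auto_unbox = TRUE, pretty = TRUE)
  p
}

#' Summarize a results bundle as text
#'
#' Prints the screen summary: viable/total treatments, phenotype counts,
#' and the hit list (decrease phenotypes) sorted by ascending normalized
#' ratio with validation status when available.
#'
#' @param results a results bundle from \code{\link{run_pipeline}} (or a
#'   directory containing \code{treatment_results.csv}).
#' @param max_hits show at most this many hits.
#' @return invisibly, the hit-list data.frame.
#' @export
report_screen <- function(results, max_hits = 25L) {
  if (is.character(results)) {
    p <- file.path(results, "treatment_results.csv")
    if (!file.exists(p)) stop("missing results: ", p, call. = FALSE)
    results <- list(treatments = utils::read.csv(p, stringsAsFactors = FALSE))
    vp <- file.path(dirname(p), "validation.csv")
    if (file.exists(vp))
      results$validation <- utils::read.csv(vp, stringsAsFactors = FALSE)
  }
  tr <- results$treatments
  if (is.null(tr) || !nrow(tr)) {
    warning("empty results: nothing to report")
    cat("0 treatments; 0 viable.\n")
    return(invisible(data.frame()))
  }
  nv <- sum(tr$viable)
  cat(sprintf("%d treatments; %d viable.\n", nrow(tr), nv))
  cat("Phenotypes:",
      paste(sprintf("%s=%d", names(table(tr$phenotype)),
                    as.integer(table(tr$phenotype))), collapse = ", "),
      "\n")
  hits <- tr[tr$viable &
               tr$phenotype %in% c("strong_decrease", "mild_decrease"), ]
  hits <- hits[order(hits$normalized_ratio_mean), ]
  if (!is.null(results$validation))
    hits$validated <- results$validation$validated[
      match(hits$gene, results$validation$gene)]
  if (nrow(hits)) {
    cat(sprintf("%d decrease hits (lowest ratios first):\n", nrow(hits)))
    show <- utils::head(hits, max_hits)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %-16s ratio %.3f +/- %s  %s%s\n",
                  show$treatment_id[i], show$normalized_ratio_mean[i],
                  ifelse(is.na(show$normalized_ratio_sem[i]), "NA",
                         sprintf("%.3f", show$normalized_ratio_sem[i])),
                  show$phenotype[i],
                  if (!is.null(show$validated))
                    ifelse(isTRUE(show$validated[i]), " [validated]", "")
                  else ""))
  } else cat("No decrease hits.\n")
  invisible(hits)
}
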