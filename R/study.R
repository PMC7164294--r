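# End-to-end study driver: fit the normative model, compute per-patient and
# group-mean effect maps for every interval, run the pointwise tests at every
# cutoff, and export colormaps, region summaries and a run manifest. These
# functions (plus write_study()/simulate_study()) are the package's pipeline
# interface; inst/cli/growthmorph.R wraps them for shell use.

#' Study analysis configuration
#'
#' Defaults mirror the emulated study's printed choices: significance level
#' 0.05, clinical cutoffs 0 / 0.5 / 1.5 mm, the three intervals T1-T2,
#' T2-T3, T1-T3, symmetric null p0 = 0.5, kernel bandwidth 1 year.
#'
#' @param bandwidth kernel regression bandwidth in years.
#' @param cutoffs exceedance cutoffs in mm (>= 0).
#' @param alpha pointwise significance level.
#' @param p0 null exceedance probability.
#' @param intervals list of `c(from, to)` timepoint label pairs.
#' @param robust a `robust_config` for all superimpositions.
#' @param colormap_limit diverging-colormap saturation (mm).
#' @param seed integer seed recorded in the manifest.
#' @return object of class `study_config`.
#' @export
study_config <- function(bandwidth = 1.0,
                         cutoffs = c(0, 0.5, 1.5),
                         alpha = 0.05,
                         p0 = 0.5,
                         intervals = list(c("T1", "T2"), c("T2", "T3"),
                                          c("T1", "T3")),
                         robust = robust_config(),
                         colormap_limit = 2.0,
                         seed = 1L) {
  stopifnot(all(cutoffs >= 0), alpha > 0, alpha < 1, p0 > 0, p0 < 1,
            bandwidth > 0)
  structure(list(bandwidth = bandwidth, cutoffs = cutoffs, alpha = alpha,
                 p0 = p0, intervals = intervals, robust = robust,
                 colormap_limit = colormap_limit, seed = as.integer(seed)),
            class = "study_config")
}

.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else x
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(.strip_classes(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

.log_info <- function(...) message("[growthmorph] ", sprintf(...))

#' Run the full analysis pipeline on a study
#'
#' Fits the normative growth model (both sexes pooled for alignment, teeth
#' zero-weighted), computes each patient's treatment-effect map and the group
#' mean for every configured interval, runs the pointwise binomial exceedance
#' test at every configured cutoff, and writes PLY colormaps, CSV region
#' summaries and a JSON run manifest into `out_dir`.
#'
#' @param study a study list as returned by [simulate_study()] or
#'   [read_study()]: elements `template`, `mask`, `normative`, `patients`.
#' @param out_dir output directory (created).
#' @param config a `study_config`.
#' @return invisibly a list with `model`, `effects` (per interval, list of
#'   `effect_map`s), `group_means`, `tests` (per interval x cutoff),
#'   `region_summaries`, `manifest`.
#' @export
run_study <- function(study, out_dir, config = study_config()) {
  if (length(study$patients) == 0L) {
    stop("study contains no patients", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bw <- study$mask$base_weights
  stage <- "fit-growth"
  .log_info("fitting growth model on %d normative observations",
            length(study$normative))
  model <- fit_growth_model(study$normative, bw, h = config$bandwidth,
                            config = config$robust)
  not_converged <- character(0)
  effects <- list()
  group_means <- list()
  tests <- list()
  region_rows <- list()
  test_rows <- list()
  for (iv in config$intervals) {
    key <- paste(iv, collapse = "-")
    stage <- paste0("effect:", key)
    effects[[key]] <- lapply(study$patients, function(p) {
      em <- tryCatch(
        treatment_effect(p, model, iv[1], iv[2], bw, config$robust),
        error = function(e) {
          stop(sprintf("stage %s failed for patient %s: %s", stage,
                       p$patient_id, conditionMessage(e)), call. = FALSE)
        })
      ali <- attr(em$components$observed, "alignment")
      if (!is.null(ali) && !ali$converged) {
        not_converged <<- c(not_converged, paste(p$patient_id, key))
      }
      em
    })
    gm <- group_mean_effect(effects[[key]])
    group_means[[key]] <- gm
    path <- file.path(out_dir, sprintf("effect_group_mean_%s.ply", key))
    write_effect_map(gm, study$template, path, config$colormap_limit)
    .log_info("wrote %s", path)
    rs <- summarize_regions(gm, study$mask)
    rs$interval <- key
    region_rows[[key]] <- rs
    for (delta in config$cutoffs) {
      stage <- sprintf("test:%s:delta=%g", key, delta)
      tr <- pointwise_test(effects[[key]], delta, config$p0, config$alpha)
      tests[[key]][[sprintf("delta_%g", delta)]] <- tr
      path <- file.path(out_dir,
                        sprintf("significance_%s_delta%g.ply", key, delta))
      write_significance_map(tr, study$template, path)
      .log_info("wrote %s", path)
      ts <- summarize_test_regions(tr, study$mask)
      ts$interval <- key
      ts$delta <- delta
      test_rows[[paste(key, delta)]] <- ts
    }
  }
  region_summary <- do.call(rbind, region_rows)
  test_summary <- do.call(rbind, test_rows)
  rownames(region_summary) <- NULL
  rownames(test_summary) <- NULL
  p1 <- file.path(out_dir, "region_summary.csv")
  utils::write.csv(region_summary, p1, row.names = FALSE, quote = FALSE)
  .log_info("wrote %s", p1)
  p2 <- file.path(out_dir, "test_summary.csv")
  utils::write.csv(test_summary, p2, row.names = FALSE, quote = FALSE)
  .log_info("wrote %s", p2)
  manifest <- list(
    package_version = as.character(utils::packageVersion("growthmorph")),
    config = .strip_classes(config),
    config_hash = .config_hash(config),
    seed = config$seed,
    n_normative = length(study$normative),
    n_patients = length(study$patients),
    n_vertices = n_vertices(study$template),
    non_converged_alignments = as.list(not_converged))
  p3 <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p3, auto_unbox = TRUE, digits = NA)
  .log_info("wrote %s", p3)
  invisible(list(model = model, effects = effects,
                 group_means = group_means, tests = tests,
                 region_summaries = region_summary,
                 test_summaries = test_summary, manifest = manifest))
}

#' Human-readable summary of a results directory
#'
#' One markdown section per interval: region means of the group-mean effect,
#' exceedance proportions above each cutoff, and per-region
#' significant-vertex fractions.
#'
#' @param results_dir directory written by [run_study()].
#' @return character vector of markdown lines (also printed invisibly
#'   usable via `writeLines`).
#' @export
study_report <- function(results_dir) {
  rs_path <- file.path(results_dir, "region_summary.csv")
  ts_path <- file.path(results_dir, "test_summary.csv")
  if (!file.exists(rs_path) || !file.exists(ts_path)) {
    stop("no results found in ", results_dir, call. = FALSE)
  }
  rs <- utils::read.csv(rs_path, stringsAsFactors = FALSE)
  ts <- utils::read.csv(ts_path, stringsAsFactors = FALSE)
  if (nrow(rs) == 0L) stop("empty region summary", call. = FALSE)
  manifest <- jsonlite::read_json(file.path(results_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- c("# Treatment-effect study report", "",
           sprintf("- patients: %d; normative observations: %d; vertices: %d",
                   manifest$n_patients, manifest$n_normative,
                   manifest$n_vertices),
           sprintf("- cutoffs (mm): %s; alpha = %g",
                   paste(manifest$config$cutoffs, collapse = ", "),
                   manifest$config$alpha), "")
  for (iv in unique(rs$interval)) {
    out <- c(out, sprintf("## Interval %s", iv), "",
             "Group-mean effect by region (mm):", "")
    sub <- rs[rs$interval == iv, ]
    out <- c(out, sprintf("- %s: mean %.2f (sd %.2f, range %.2f to %.2f)",
                          sub$region, sub$mean, sub$sd, sub$min, sub$max),
             "")
    tsub <- ts[ts$interval == iv, ]
    for (d in unique(tsub$delta)) {
      dd <- tsub[tsub$delta == d, ]
      out <- c(out, sprintf("Cutoff %g mm:", d),
               sprintf(
                 "- %s: %.0f%% of patients exceed on average; %.0f%% of vertices significant",
                 dd$region, 100 * dd$mean_proportion,
                 100 * dd$frac_significant),
               "")
    }
  }
  out
}
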