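# End-to-end session and cohort drivers over files: NIfTI in, maps +
# regional CSV + QC JSON out. Registration is out of scope: the atlas must
# already live on the series grid (phantoms are generated in atlas space).

#' Default run configuration
#'
#' @param dt,te acquisition timing, seconds
#' @param n_baseline pre-bolus frames for the baseline estimate
#' @param k relaxivity constant of the signal model
#' @param n_aif,ttp_quantile,mtt_quantile,require_peak_ratio AIF search
#'   parameters (see \code{\link{select_aif_voxels}})
#' @param mode,truncation,pad_length,quadrature,flow_scale deconvolution
#'   parameters (see \code{\link{compute_maps}})
#' @param q FDR level for cohort tables
#' @param equal_var pooled-variance across-group tests
#' @return a named list of defaults, overridable per call
#' @export
default_run_config <- function(dt = 1.5, te = 0.03, n_baseline = 8L, k = 1,
                               n_aif = 10L, ttp_quantile = 0.1,
                               mtt_quantile = 0.2, require_peak_ratio = 1.5,
                               mode = "circulant", truncation = NULL,
                               pad_length = NULL,
                               quadrature = "trapezoid",
                               flow_scale = dsc_flow_scale(),
                               q = 0.2, equal_var = TRUE) {
  list(dt = dt, te = te, n_baseline = n_baseline, k = k, n_aif = n_aif,
       ttp_quantile = ttp_quantile, mtt_quantile = mtt_quantile,
       require_peak_ratio = require_peak_ratio, mode = mode,
       truncation = truncation, pad_length = pad_length,
       quadrature = quadrature, flow_scale = flow_scale, q = q,
       equal_var = equal_var)
}

#' Read a run configuration from YAML or JSON
#' @param path file path; unknown keys are rejected
#' @return config list merged over \code{\link{default_run_config}}
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- default_run_config()
  extra <- setdiff(names(cfg), c(names(base), "series", "atlas", "manifest",
                                 "surgical_side", "out_dir", "roi_mask"))
  if (length(extra)) stopf("unknown config keys: %s", paste(extra, collapse = ", "))
  utils::modifyList(base, cfg)
}

read_volume <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  v <- RNifti::readNifti(path)
  structure(as.array(v), affine = RNifti::xform(v))
}

check_affines <- function(a, b, tol = 1e-4) {
  if (is.null(a) || is.null(b)) return(invisible(TRUE))
  if (max(abs(a - b)) > tol)
    stopf("series and atlas affines differ by more than %g", tol)
  invisible(TRUE)
}

#' Analyse one session in memory
#'
#' The computational core of \code{\link{run_session}}: baseline and mask,
#' concentration conversion, automatic AIF selection, deconvolution maps,
#' regional means and relative values. Fails with the stage name on error.
#'
#' @param series a \code{\link{perfusion_series}}
#' @param atlas a \code{\link{territory_atlas}} on the same grid
#' @param surgical_side "left" or "right"
#' @param config list from \code{\link{default_run_config}}
#' @param roi_mask optional AIF search restriction
#' @return list: maps, regional means, relative values, aif, qc
#' @export
analyze_session <- function(series, atlas, surgical_side,
                            config = default_run_config(),
                            roi_mask = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (!identical(dim(series$data)[1:3], dim(atlas$labels)))
    stopf("series grid %s does not match atlas grid %s",
          paste(dim(series$data)[1:3], collapse = "x"),
          paste(dim(atlas$labels), collapse = "x"))
  baseline <- stage("baseline", estimate_baseline(series, config$n_baseline))
  conc <- stage("concentration",
                signal_to_concentration(series, baseline, k = config$k))
  features <- stage("aif-features", compute_curve_features(conc))
  aif <- stage("aif-selection",
               select_aif_voxels(conc, features, n_aif = config$n_aif,
                                 ttp_quantile = config$ttp_quantile,
                                 mtt_quantile = config$mtt_quantile,
                                 roi_mask = roi_mask,
                                 require_peak_ratio = config$require_peak_ratio))
  maps <- stage("deconvolution",
                compute_maps(conc, aif, mode = config$mode,
                             truncation = config$truncation,
                             pad_length = config$pad_length,
                             quadrature = config$quadrature,
                             flow_scale = config$flow_scale))
  means <- stage("regional-means", regional_means(maps, atlas))
  rel <- stage("relative-values", relative_parameters(means, surgical_side))
  list(maps = maps, regional_means = means, relative = rel, aif = aif,
       qc = list(concentration = conc$qc, deconvolution = maps$qc,
                 aif_voxels = aif$voxel_ids,
                 aif_thresholds = aif$thresholds_used))
}

#' Run one session from files
#'
#' Reads the 4D series and atlas (NIfTI-1, .nii or .nii.gz), requires
#' matching grids and affines (tolerance 1e-4), runs
#' \code{\link{analyze_session}} and writes CBF/CBV/MTT maps (NIfTI),
#' regional and relative CSVs, and an AIF QC JSON (selected voxel
#' coordinates for the manual-check audit) into \code{out_dir}. Outputs
#' are deterministic functions of the inputs and config.
#'
#' @param config list with at least \code{series}, \code{atlas},
#'   \code{surgical_side}, \code{out_dir}, merged over
#'   \code{\link{default_run_config}} (or a YAML/JSON path)
#' @return the \code{\link{analyze_session}} result, invisibly
#' @export
run_session <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_run_config(), config)
  for (key in c("series", "atlas", "surgical_side", "out_dir"))
    if (is.null(config[[key]])) stopf("config is missing '%s'", key)
  svol <- read_volume(config$series, "series")
  avol <- read_volume(config$atlas, "atlas")
  check_affines(attr(svol, "affine"), attr(avol, "affine"))
  series <- perfusion_series(unclass(svol)[, , , , drop = FALSE],
                             dt = config$dt, te = config$te,
                             affine = attr(svol, "affine"))
  dict_path <- sub("\\.nii(\\.gz)?$", "_dictionary.csv", config$atlas)
  dict <- if (file.exists(dict_path))
    utils::read.csv(dict_path, stringsAsFactors = FALSE)
  else build_phantom_atlas(dim(avol))$dictionary
  atlas <- territory_atlas(array(as.integer(round(avol)), dim = dim(avol)),
                           dict)
  res <- analyze_session(series, atlas, config$surgical_side, config)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  for (p in c("cbf", "cbv", "mtt"))
    RNifti::writeNifti(RNifti::asNifti(res$maps[[p]]), out(paste0(p, ".nii.gz")))
  utils::write.csv(res$regional_means, out("regional_means.csv"),
                   row.names = FALSE)
  utils::write.csv(res$relative, out("relative_values.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(aif_voxels = res$qc$aif_voxels,
                            thresholds = res$qc$aif_thresholds,
                            concentration = res$qc$concentration,
                            deconvolution = res$qc$deconvolution),
                       out("aif_qc.json"), auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("session: %s", config$series),
               sprintf("surgical_side: %s", config$surgical_side),
               sprintf("mode: %s truncation: %s", config$mode,
                       format(res$maps$qc$truncation)),
               sprintf("flagged voxels: %d", res$maps$qc$n_flagged)),
             out("run.log"))
  invisible(res)
}

#' Write a simulated cohort to disk
#'
#' Materialises every session of a \code{dsc_cohort} as NIfTI plus the
#' shared atlas (with its label dictionary CSV), the manifest CSV and a
#' ground-truth sidecar JSON, in the layout \code{\link{run_cohort}}
#' consumes.
#'
#' @param cohort_obj a \code{dsc_cohort}
#' @param dir output directory
#' @return the manifest with file paths, invisibly
#' @export
write_cohort <- function(cohort_obj, dir) {
  stopifnot(inherits(cohort_obj, "dsc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(cohort_obj$atlas$labels + 0), atlas_path)
  utils::write.csv(cohort_obj$atlas$dictionary,
                   file.path(dir, "atlas_dictionary.csv"), row.names = FALSE)
  manifest <- cohort_obj$manifest
  manifest$series <- NA_character_
  sidecar <- list()
  for (i in seq_len(nrow(manifest))) {
    ses <- cohort_session(cohort_obj, manifest$subject_id[i],
                          manifest$session[i])
    f <- file.path(dir, sprintf("%s_%s.nii.gz", manifest$subject_id[i],
                                manifest$session[i]))
    RNifti::writeNifti(RNifti::asNifti(ses$series$data), f)
    manifest$series[i] <- f
    sidecar[[paste(manifest$subject_id[i], manifest$session[i], sep = "_")]] <-
      ses$truths[c("label", "territory", "side", "cbf", "cbv", "mtt", "delay")]
  }
  manifest$atlas <- atlas_path
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}

#' Run a full cohort from a manifest
#'
#' Every subject must have a pre and an intra session. Each session is
#' analysed with \code{\link{analyze_session}}; the per-session relative
#' values are assembled into the long summary table and compared with
#' \code{\link{build_comparison_tables}}. Writes the three parameter
#' tables as CSV plus a machine-readable statistics JSON.
#'
#' @param config list (or YAML/JSON path) with \code{manifest} (CSV path:
#'   subject_id, group, surgical_side, session, series, atlas) and
#'   \code{out_dir}, over \code{\link{default_run_config}}
#' @return the \code{cohort_result}, invisibly
#' @export
run_cohort <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_run_config(), config)
  for (key in c("manifest", "out_dir"))
    if (is.null(config[[key]])) stopf("config is missing '%s'", key)
  if (!file.exists(config$manifest))
    stopf("manifest file not found: %s", config$manifest)
  manifest <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
  for (s in unique(manifest$subject_id)) {
    ses <- manifest$session[manifest$subject_id == s]
    if (!all(c("pre", "intra") %in% ses))
      stopf("subject '%s' is missing a %s session", s,
            setdiff(c("pre", "intra"), ses)[1])
  }
  summaries <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    scfg <- utils::modifyList(config, list(series = row$series,
                                           atlas = row$atlas,
                                           surgical_side = row$surgical_side))
    svol <- read_volume(row$series, "series")
    avol <- read_volume(row$atlas, "atlas")
    check_affines(attr(svol, "affine"), attr(avol, "affine"))
    series <- perfusion_series(unclass(svol)[, , , , drop = FALSE],
                               dt = config$dt, te = config$te)
    dict_path <- file.path(dirname(row$atlas), "atlas_dictionary.csv")
    dict <- if (file.exists(dict_path))
      utils::read.csv(dict_path, stringsAsFactors = FALSE)
    else build_phantom_atlas(dim(avol))$dictionary
    atlas <- territory_atlas(array(as.integer(round(avol)), dim = dim(avol)),
                             dict)
    res <- analyze_session(series, atlas, row$surgical_side, config)
    rel <- res$relative
    rel$subject_id <- row$subject_id
    rel$group <- row$group
    rel$surgical_side <- row$surgical_side
    rel$session <- row$session
    summaries[[i]] <- rel
  }
  summaries <- do.call(rbind, summaries)
  result <- build_comparison_tables(summaries, q = config$q,
                                    equal_var = config$equal_var)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(result$tables))
    utils::write.csv(result$tables[[p]],
                     file.path(config$out_dir,
                               sprintf("table_relative_%s.csv", p)),
                     row.names = FALSE)
  utils::write.csv(summaries, file.path(config$out_dir, "session_summaries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(q = result$q, stats = result$stats),
                       file.path(config$out_dir, "statistics.json"),
                       dataframe = "rows", digits = NA)
  invisible(result)
}
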