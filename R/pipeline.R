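# End-to-end federated orchestration: per-study analysis, masking,
# stratified pooling and effect estimation, with a provenance manifest.

.file_md5 <- function(paths) {
  vapply(paths, function(p) as.character(tools::md5sum(p)), "")
}

#' Run the full federated analysis pipeline
#'
#' Executes, per cohort: zero imputation, landmark exclusion and the
#' compositional Cox fit; masks the sleep coordinate of waking-day
#' studies; pools per requested stratum with heterogeneity statistics;
#' and, for each stratum pool, emits a coefficient/unit-HR table plus any
#' requested substitution solutions.  Alternatively, pre-fitted exchange
#' files (or a coefficient set) can be supplied for an effects-only run.
#'
#' @param config A list (or path to a JSON file) with entries:
#'   \describe{
#'     \item{cohorts}{list of `list(path, study, device)` CSV inputs
#'       (or ready-made `cohort` objects).}
#'     \item{fits}{alternatively, paths to [write_study_fit()] JSON
#'       files.}
#'     \item{landmark_years}{landmark cutoff, default 2.}
#'     \item{mask_variance}{default 1e6.}
#'     \item{strata}{character subset of `c("all", "wrist", "hip")`.}
#'     \item{reference}{named part vector for effect estimation,
#'       e.g. `c(mvpa = 2, lipa = 229, sb = 729)`.}
#'     \item{substitutions}{optional list of
#'       `list(target_hr, mode, ref)` requests.}
#'   }
#' @param out_dir Optional directory; when given, fits, pools, tables and
#'   the manifest are written there as JSON/CSV.
#' @return List with `fits`, `pools`, `unit_hr`, `substitutions`,
#'   `heterogeneity`, and `manifest` (inputs with checksums, config
#'   snapshot, package version, timestamp, accumulated warnings).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  if (length(config) == 0 ||
      (is.null(config$cohorts) && is.null(config$fits) &&
       is.null(config$pooled)))
    stop("usage: config must list `cohorts` (CSV), `fits` (JSON) or a ",
         "`pooled` model for an effects-only run")
  landmark_years <- config$landmark_years %||% 2
  mask_variance <- config$mask_variance %||% 1e6
  strata <- config$strata %||% c("all", "wrist", "hip")
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  input_files <- character(0)

  fits <- list()
  if (!is.null(config$cohorts)) {
    for (cc in config$cohorts) {
      ch <- if (inherits(cc, "cohort")) cc
      else {
        input_files <- c(input_files, cc$path)
        read_cohort(cc$path, study = cc$study %||% basename(cc$path),
                    device = cc$device %||% "hip")
      }
      withCallingHandlers({
        comp <- compositions(ch)
        if (any(comp == 0))
          ch$data[ch$parts] <- as.data.frame(impute_zeros(comp))
        ch <- suppressMessages(landmark_filter(ch, landmark_years))
        fits[[ch$study]] <- fit_compositional_cox(ch)
      }, warning = function(w) {
        note(paste0(ch$study, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    }
  }
  if (!is.null(config$fits)) {
    for (fp in config$fits) {
      input_files <- c(input_files, fp)
      f <- read_study_fit(fp)
      fits[[f$study]] <- f
    }
  }

  pools_external <- list()
  if (!is.null(config$pooled)) {
    pm <- config$pooled
    if (is.character(pm)) {
      input_files <- c(input_files, pm)
      pm <- read_pooled_model(pm)
    }
    pools_external[[pm$stratum %||% "external"]] <- pm
  }

  masked <- lapply(fits, function(f)
    if (isTRUE(f$measures_sleep) || "z1" %in% names(f$gamma)) f
    else mask_missing_sleep(f, mask_variance))

  pools <- pools_external
  for (s in if (length(fits)) strata else character(0)) {
    sel <- if (s == "all") masked
           else Filter(function(f) identical(f$device, s),
                       if (s == "wrist") masked else fits)
    if (length(sel) == 0) next
    pools[[s]] <- withCallingHandlers(
      pool_random_effects(unname(sel), stratum = s),
      warning = function(w) {
        note(paste0("pool ", s, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  unit_hr <- lapply(pools, unit_hazard_ratios)
  het <- lapply(pools, function(p) p$het)

  subs <- list()
  if (!is.null(config$substitutions)) {
    for (i in seq_along(config$substitutions)) {
      rq <- config$substitutions[[i]]
      pool <- pools[[rq$stratum %||% "hip"]]
      ref <- close_composition(unlist(rq$ref))
      subs[[i]] <- c(list(mode = rq$mode,
                          target_hr = rq$target_hr %||% 0.9),
                     solve_reallocation(pool, ref,
                                        rq$target_hr %||% 0.9, rq$mode))
    }
  }

  manifest <- list(
    inputs = if (length(input_files))
      data.frame(file = input_files, md5 = .file_md5(input_files))
      else NULL,
    config = config[setdiff(names(config), "cohorts")],
    package_version = as.character(utils::packageVersion("codasurv")),
    timestamp = format(Sys.time(), tz = "UTC"),
    warnings = warnings_log)

  res <- list(fits = fits, pools = pools, unit_hr = unit_hr,
              heterogeneity = het, substitutions = subs,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(fits))
      if (!is.null(fits[[nm]]$fit))
        write_study_fit(fits[[nm]], file.path(out_dir,
                                              paste0("fit_", nm, ".json")))
    for (nm in names(pools))
      write_pooled_model(pools[[nm]],
                         file.path(out_dir, paste0("pool_", nm, ".json")))
    for (nm in names(unit_hr))
      utils::write.csv(unit_hr[[nm]],
                       file.path(out_dir, paste0("unit_hr_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
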