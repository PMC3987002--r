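# Descriptive statistics, table I/O and end-to-end pipeline orchestration.

#' Descriptive statistics for a participant sample
#'
#' Percent ANA positive, percent male, and median age for one sample,
#' with configurable rounding: the convention for these summaries is one
#' decimal for the full study sample and nearest integer for small strip
#' subsamples.
#'
#' @param participants data frame with columns ana (0/1) and, optionally,
#'   gendernum (1 = male) and CurAge.
#' @param digits decimal places for the percentages (0 or 1, default 1).
#' @return list of class `descriptive_summary`: n, pct_ana_positive,
#'   pct_male, median_age.
#' @export
descriptive_stats <- function(participants, digits = 1) {
  n <- nrow(participants)
  if (n == 0L) stop("empty participant table", call. = FALSE)
  pct <- function(x) round(100 * sum(x) / length(x), digits)
  structure(list(
    n = n,
    pct_ana_positive = pct(participants$ana),
    pct_male = if ("gendernum" %in% names(participants))
      pct(participants$gendernum) else NA_real_,
    median_age = if ("CurAge" %in% names(participants))
      median(participants$CurAge) else NA_real_),
    class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat(sprintf("n = %d | %% ANA positive = %s | %% male = %s | median age = %s\n",
              x$n, format(x$pct_ana_positive),
              format(x$pct_male), format(x$median_age)))
  invisible(x)
}

#' Write sites as GeoJSON points
#'
#' @param sites data frame with site_id, lon, lat and further columns
#'   (written as properties).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_geojson <- function(sites, path) {
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    props <- as.list(sites[i, setdiff(names(sites), c("lon", "lat")),
                           drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sites$lon[i], sites$lat[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> exposures -> PCA -> spike-and-slab selection,
#' and optionally Kriging validation of the strip, writing every table to
#' `out_dir` as comma-separated files plus a JSON log of the
#' configuration, seeds and thresholds.  All randomness flows from the
#' config's master seed, so a fixed config regenerates the bundle
#' identically.
#'
#' @param config a [sim_config()] object (or path to a YAML/JSON config).
#' @param out_dir output directory (created if needed); NULL to skip
#'   writing.
#' @param address_class address class analysed.
#' @param power distance-weighting power (1 or 2).
#' @param media media for the exposure matrix.
#' @param design "pcs" to model retained PCA scores, "chemicals" for the
#'   raw distance-weighted chemicals.
#' @param pca_threshold cumulative-variance retention threshold.
#' @param with_strip run the Kriging validation stage (skipped, with a
#'   log entry, when FALSE or when the config has no strip sites).
#' @param strip_chemicals strip metals to krige and offer to selection.
#' @param buffer_km strip eligibility buffer.
#' @param n_iter,burnin,thin,chains,seed_offset MCMC settings for the
#'   selection fits (kept modest here; raise for production runs).
#' @return list of class `pipeline_report` with the simulated study, PCA,
#'   selection summary, optional validation results, and the log.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         address_class = "first", power = 1,
                         media = c("soil", "groundwater"),
                         design = c("pcs", "chemicals"),
                         pca_threshold = 0.80,
                         with_strip = TRUE,
                         strip_chemicals = c("Pb", "Cu", "Cr"),
                         buffer_km = 1.0,
                         n_iter = 3000, burnin = 1000, thin = 2,
                         chains = 1, seed_offset = 101L) {
  design <- match.arg(design)
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  log <- list(seed = config$seed, address_class = address_class,
              power = power, media = media, design = design,
              pca_threshold = pca_threshold,
              thresholds = list(include = 0.5, report = 0.25),
              hyper = unclass(nmig_hyperparams()),
              mcmc = list(n_iter = n_iter, burnin = burnin, thin = thin,
                          chains = chains),
              stages = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  study <- stage("simulate", simulate_study(config,
                                            address_class = address_class,
                                            power = power))
  log$stages <- c(log$stages, "simulate")
  expo <- stage("exposures",
                build_exposure_matrix(study$addresses, study$measurements,
                                      address_class = address_class,
                                      media = media, p = power))
  log$stages <- c(log$stages, "exposures")

  pca <- stage("pca", correlation_pca(expo))
  ret <- retain_components(pca, pca_threshold)
  loadings <- loading_report(pca, ret$k)
  log$stages <- c(log$stages, "pca")

  pers <- study$participants[, setdiff(names(study$participants),
                                       c("participant_id", "ana"))]
  terms <- list()
  if (design == "pcs") {
    for (j in seq_len(ret$k))
      terms[[length(terms) + 1L]] <- term_linear(paste0("PC", j),
                                                 ret$scores[, j])
  } else {
    for (j in seq_len(ncol(expo)))
      terms[[length(terms) + 1L]] <- term_linear(colnames(expo)[j],
                                                 expo[, j])
  }
  for (nm in names(pers)) {
    if (sd(pers[[nm]]) > 0)
      terms[[length(terms) + 1L]] <- term_linear(nm, pers[[nm]])
  }
  sel <- stage("select",
               fit_ssvs_logistic(study$participants$ana, terms,
                                 n_iter = n_iter, burnin = burnin,
                                 thin = thin, chains = chains,
                                 seed = (config$seed + seed_offset) %%
                                   .Machine$integer.max))
  sel_summary <- inclusion_summary(sel)
  log$stages <- c(log$stages, "select")

  validation <- NULL
  if (isTRUE(with_strip) && config$n_strip_sites > 0) {
    validation <- stage("validate", {
      strip_sites <- study$sites[study$sites$medium == "strip", ]
      elig <- buffer_filter(
        study$addresses[study$addresses$address_class == address_class, ],
        strip_sites, radius_km = buffer_km)
      if (nrow(elig) < 5) {
        list(skipped = paste("only", nrow(elig),
                             "eligible addresses; validation skipped"))
      } else {
        strip_meas <- study$measurements[
          study$measurements$medium == "strip" &
          study$measurements$chemical %in% strip_chemicals, ]
        kriged <- lapply(split(strip_meas, strip_meas$chemical), function(mm) {
          km <- fit_kriging(mm, n_iter = 2000, burnin = 800, thin = 4,
                            seed = (config$seed + seed_offset + 7L) %%
                              .Machine$integer.max)
          krige_predict(km, elig, max_draws = 100)
        })
        idx <- match(elig$participant_id, study$participants$participant_id)
        tsf <- two_stage_fit(study$participants$ana[idx], kriged,
                             personal = pers[idx, , drop = FALSE],
                             n_iter = n_iter, burnin = burnin, thin = thin,
                             chains = chains,
                             seed = (config$seed + seed_offset + 13L) %%
                               .Machine$integer.max)
        list(eligible = elig, kriged = kriged, fit = tsf,
             descriptive = descriptive_stats(study$participants[idx, ],
                                             digits = 0))
      }
    })
    log$stages <- c(log$stages, "validate")
  } else {
    log$stages <- c(log$stages, "validate:skipped (no strip section)")
  }

  report <- structure(list(study = study, exposures = expo, pca = pca,
                           retained = ret, loadings = loadings,
                           selection = sel, selection_summary = sel_summary,
                           validation = validation,
                           descriptive = descriptive_stats(study$participants),
                           log = log),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' Emits the simulated tables, PCA loadings/scores, selection summary and
#' (when present) validation summary as comma-separated files, the sites
#' as GeoJSON, and the run log as JSON.  Every table round-trips through
#' `read.csv` unchanged.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) write.csv(x, file.path(out_dir, f),
                                   row.names = FALSE)
  wcsv(report$study$measurements, "site_measurements.csv")
  wcsv(report$study$addresses, "addresses.csv")
  wcsv(report$study$participants, "participants.csv")
  expo_df <- data.frame(participant_id = rownames(report$exposures),
                        as.data.frame(unclass(report$exposures)[, ,
                                                                drop = FALSE]),
                        check.names = FALSE)
  wcsv(expo_df, "exposure_matrix.csv")
  wcsv(data.frame(component = seq_along(report$pca$eigenvalues),
                  eigenvalue = report$pca$eigenvalues,
                  variance_fraction = report$pca$variance_fractions),
       "pca_variance.csv")
  load_df <- do.call(rbind, lapply(names(report$loadings), function(nm)
    if (nrow(report$loadings[[nm]]))
      cbind(component = nm, report$loadings[[nm]])))
  if (!is.null(load_df)) wcsv(load_df, "pca_loadings.csv")
  wcsv(as.data.frame(report$selection_summary), "selection_summary.csv")
  if (!is.null(report$validation$fit))
    wcsv(as.data.frame(report$validation$fit$summary),
         "validation_summary.csv")
  write_sites_geojson(report$study$sites, file.path(out_dir, "sites.geojson"))
  jsonlite::write_json(report$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (stages:", paste(x$log$stages, collapse = " -> "),
      ")\n\nFull sample descriptives: ")
  print(x$descriptive)
  cat("\nPCA: k =", x$retained$k, "component(s) retained\n")
  print(x$loadings)
  cat("\nSelection (full sample):\n")
  print(x$selection_summary)
  if (!is.null(x$validation$fit)) {
    cat("\nValidation strip (", nrow(x$validation$eligible),
        "eligible addresses):\n")
    print(x$validation$fit$summary)
  } else if (!is.null(x$validation$skipped)) {
    cat("\nValidation:", x$validation$skipped, "\n")
  }
  invisible(x)
}
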