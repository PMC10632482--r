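# Config-driven orchestration of the analysis stages over a synthetic or
# file-based cohort. Tidy CSV is the interchange format between stages; a
# JSON manifest records version, config fingerprint, seed and per-stage row
# counts so every output table is reproducible from the manifest alone.

.pipeline_stages <- c("simulate", "scenith", "binning", "seahorse", "flux",
                      "survival")

#' Build a pipeline run configuration
#'
#' @param seed master seed (mandatory).
#' @param outdir output directory for result tables and the manifest.
#' @param cohort synthetic-cohort config from [syntheticCohortConfig()];
#'   defaults to the study conditions with the given seed.
#' @param scenith list of SCENITH options: `clamp`, `min_dynamic_range`.
#' @param binning list: `scope` (`"cohort"`/`"sample"`).
#' @param survival_opts list: `endpoint` (`"OS"`/`"PFS"`), `bounds`
#'   (maxstat quantile window), `n_perm` (permutation reps, 0 = skip).
#' @param aggregators Seahorse aggregator config
#'   ([seahorseAggregators()]).
#' @return config list of class `immunomet_run_config`.
#' @export
runConfig <- function(seed, outdir = tempfile("immunomet_run_"),
                      cohort = syntheticCohortConfig(seed),
                      scenith = list(clamp = TRUE, min_dynamic_range = 0.2),
                      binning = list(scope = "cohort"),
                      survival_opts = list(endpoint = "OS",
                                           bounds = c(0.1, 0.9), n_perm = 0),
                      aggregators = seahorseAggregators()) {
  if (missing(seed)) stop("config error: seed is mandatory")
  cfg <- list(seed = as.integer(seed), outdir = outdir, cohort = cohort,
              scenith = scenith, binning = binning,
              survival_opts = survival_opts, aggregators = aggregators)
  class(cfg) <- "immunomet_run_config"
  cfg
}

#' Validate a run configuration
#'
#' @param config from [runConfig()] or a YAML file parsed into the same
#'   shape.
#' @return TRUE invisibly; errors describe the offending field.
#' @export
validateRunConfig <- function(config) {
  if (is.null(config$seed)) stop("config error: missing seed")
  if (!config$binning$scope %in% c("cohort", "sample"))
    stop("config error: binning scope must be cohort or sample")
  if (!config$survival_opts$endpoint %in% c("OS", "PFS"))
    stop("config error: endpoint must be OS or PFS")
  validateSyntheticConfig(config$cohort)
  invisible(TRUE)
}

.write_table <- function(df, outdir, name) {
  path <- file.path(outdir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  nrow(df)
}

#' Run the immuno-metabolic pipeline
#'
#' Executes the requested stages in dependency order on a synthetic cohort
#' generated from the config, writing tidy CSV result tables and a JSON
#' manifest to `config$outdir`. A stage failure is isolated and recorded;
#' requesting a stage whose upstream output is absent names the missing
#' dependency. Identical config + seed reproduces byte-identical tables.
#'
#' @param config from [runConfig()].
#' @param stages subset of
#'   `simulate, scenith, binning, seahorse, flux, survival`.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
runPipeline <- function(config, stages = .pipeline_stages) {
  validateRunConfig(config)
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  counts <- list()
  failures <- list()
  cohort <- NULL

  need_cohort <- function(stage) {
    if (is.null(cohort))
      stop("stage '", stage, "' requires the 'simulate' stage output ",
           "(missing upstream: simulate)")
    cohort
  }

  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures[[stage]] <<- conditionMessage(res)
      message("stage ", stage, " FAILED (", round(dt, 2), "s): ",
              conditionMessage(res))
    } else {
      message("stage ", stage, " done (", round(dt, 2), "s)")
    }
    res
  }

  for (stage in stages) {
    if (stage == "simulate") {
      res <- run_stage(stage, function() generateCohort(config$cohort))
      if (!inherits(res, "error")) {
        cohort <- res
        counts$simulate <- nrow(eventData(cohort$events))
      }
    } else if (stage == "scenith") {
      res <- run_stage(stage, function() {
        ch <- need_cohort(stage)
        panels <- summarisePanel(ch$events)
        prof <- profileCohort(panels,
                              clamp = config$scenith$clamp,
                              min_dynamic_range =
                                config$scenith$min_dynamic_range)
        n_clamped <- sum(grepl("clamped", prof$qc_flags))
        if (n_clamped) warning(n_clamped, " clamped profile(s)")
        list(panels = panels, profiles = prof)
      })
      if (!inherits(res, "error")) {
        results$scenith <- res
        counts$scenith <- .write_table(res$profiles, config$outdir,
                                       "scenith_profiles")
        .write_table(res$panels, config$outdir, "scenith_panels")
      }
    } else if (stage == "binning") {
      res <- run_stage(stage, function() {
        ch <- need_cohort(stage)
        asg <- assignOligomycinQuantiles(ch$events,
                                         scope = config$binning$scope)
        props <- binProportionsByGroup(asg, ch$groups)
        cmp <- perBinMarkerComparison(
          ch$events, asg,
          markers = names(config$cohort$markers),
          groups = ch$groups, reference_group = "HD")
        list(assignment = asg, proportions = props, comparisons = cmp)
      })
      if (!inherits(res, "error")) {
        results$binning <- res
        counts$binning <- .write_table(res$assignment, config$outdir,
                                       "bin_assignment")
        .write_table(res$proportions, config$outdir, "bin_proportions")
        .write_table(res$comparisons, config$outdir, "bin_marker_tests")
      }
    } else if (stage == "seahorse") {
      res <- run_stage(stage, function() {
        ch <- need_cohort(stage)
        rows <- lapply(names(ch$seahorse), function(g) {
          tr <- ch$seahorse[[g]]
          idx <- computeSeahorseIndices(tr$control, tr$palmitate_etomoxir,
                                        aggregators = config$aggregators)
          cbind(group = g, idx)
        })
        do.call(rbind, rows)
      })
      if (!inherits(res, "error")) {
        if (any(unlist(res[vapply(res, is.numeric, logical(1))]) < 0,
                na.rm = TRUE))
          warning("negative Seahorse index in output")
        results$seahorse <- res
        counts$seahorse <- .write_table(res, config$outdir,
                                        "seahorse_indices")
      }
    } else if (stage == "flux") {
      res <- run_stage(stage, function() {
        ch <- need_cohort(stage)
        rows <- lapply(names(ch$supernatant), function(g) {
          sp <- ch$supernatant[[g]]
          fl <- intervalFluxes(sp$series, sp$media_changes)
          fr <- glucoseToLactateFraction(fl$total_glucose_consumed,
                                         fl$total_lactate_produced)
          data.frame(group = g,
                     total_glucose_consumed = fl$total_glucose_consumed,
                     total_lactate_produced = fl$total_lactate_produced,
                     fraction_stoich = fr$fraction_stoich,
                     ratio_raw = fr$ratio_raw)
        })
        do.call(rbind, rows)
      })
      if (!inherits(res, "error")) {
        results$flux <- res
        counts$flux <- .write_table(res, config$outdir, "supernatant_flux")
      }
    } else if (stage == "survival") {
      res <- run_stage(stage, function() {
        ch <- need_cohort(stage)
        survivalAssociationTable(
          ch$survival, covariates = "mitochondrial_dependence",
          endpoint = config$survival_opts$endpoint,
          bounds = config$survival_opts$bounds)
      })
      if (!inherits(res, "error")) {
        results$survival <- res
        counts$survival <- .write_table(res, config$outdir,
                                        "survival_associations")
        .write_table(need_cohort(stage)$survival, config$outdir,
                     "survival_records")
      }
    }
  }

  manifest <- list(
    package = "immunomet",
    version = as.character(utils::packageVersion("immunomet")),
    seed = config$seed,
    config_hash = fnvHash(paste(deparse(config[setdiff(names(config),
                                                       "outdir")]),
                                collapse = "")),
    stages = stages,
    row_counts = counts,
    failures = failures)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, manifest = manifest,
                 outdir = config$outdir))
}
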