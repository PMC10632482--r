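# Seeded synthetic cohort generator.
#
# Emulates the data structure of a DC-vaccine immuno-metabolism study: a
# small melanoma cohort split into good/bad clinical-outcome groups plus
# healthy donors, with per-cell SCENITH cytometry events, Seahorse kinetic
# traces, supernatant glucose/lactate series and proportional-hazards
# survival. The inhibitor-effect model is the simplest one consistent with
# the SCENITH formulas: with ground-truth dependence d_i for pathway i and
# background (residual DGO) fraction b, the expected puromycin level under
# inhibitor i is C * (1 - d_i * (1 - b)), with d_DGO = 1. Per-cell
# intensities are log-normal (positive, right-skewed, median equal to the
# expected level), so population medians recover the configured truth.

#' Configuration for a synthetic immuno-metabolic cohort
#'
#' All study conditions live here: group sizes, ground-truth metabolic
#' dependence vectors, noise levels, marker-to-metabolism couplings,
#' Seahorse segment plateaus, supernatant kinetics and the survival model.
#' The seed is mandatory; every generator output is a pure function of
#' (config, seed).
#'
#' @param seed master integer seed (mandatory, split into named
#'   sub-streams).
#' @param n_good,n_bad,n_hd patients per clinical group (defaults 13/17/3).
#' @param cells_per_condition cells per inhibitor condition per sample.
#' @param dependence named list of group -> c(g, m, f, q) ground-truth
#'   glucose/mitochondrial/FAO/glutaminolysis dependence fractions in
#'   \[0, 1\].
#' @param control_mean control-condition median puromycin MFI.
#' @param sigma log-normal noise sigma for per-cell intensities.
#' @param background residual translation fraction under full (DGO) block.
#' @param latent_sd log-scale spread of the per-cell latent glycolytic
#'   state expressed under oligomycin.
#' @param markers named list marker -> coupling coefficient of log-intensity
#'   to the latent glycolytic state (0 = uncoupled).
#' @param marker_mean baseline marker median intensity.
#' @param seahorse list per group: `segments` (named OCR/ECAR plateau means
#'   for pre_oligo, post_oligomycin, post_FCCP, post_RA), `noise_sd`,
#'   `n_per_segment`, `fao_drop` (post-FCCP OCR deficit of the paired
#'   palmitate+etomoxir well).
#' @param supernatant list per group: daily glucose consumption and lactate
#'   production rates (mM/day), observation days, media-change day and
#'   fresh glucose (mM).
#' @param survival list: `baseline_hazard` (events/month), `hr_high`
#'   (hazard ratio for subjects above `threshold` on mitochondrial
#'   dependence %), `threshold`, `censoring_rate`.
#' @return validated config list of class `immunomet_config`.
#' @export
syntheticCohortConfig <- function(
    seed,
    n_good = 13, n_bad = 17, n_hd = 3,
    cells_per_condition = 1000,
    dependence = list(
      good = c(g = 0.55, m = 0.844, f = 0.25, q = 0.30),
      bad  = c(g = 0.60, m = 0.764, f = 0.20, q = 0.23),
      HD   = c(g = 0.50, m = 0.88,  f = 0.25, q = 0.35)),
    control_mean = 1000,
    sigma = 0.35,
    background = 0.05,
    latent_sd = 0.3,
    markers = list(HLA_DR = 0, CD86 = -0.3, ILT3 = 0.5),
    marker_mean = 500,
    seahorse = list(
      good = list(segments = list(
        ocr = c(pre_oligo = 100, post_oligomycin = 30, post_FCCP = 160,
                post_RA = 10),
        ecar = c(pre_oligo = 20, post_oligomycin = 35, post_FCCP = 30,
                 post_RA = 5)),
        noise_sd = 5, n_per_segment = 3, fao_drop = 40),
      bad = list(segments = list(
        ocr = c(pre_oligo = 80, post_oligomycin = 28, post_FCCP = 120,
                post_RA = 10),
        ecar = c(pre_oligo = 28, post_oligomycin = 45, post_FCCP = 40,
                 post_RA = 5)),
        noise_sd = 5, n_per_segment = 3, fao_drop = 25)),
    supernatant = list(
      good = list(glucose_rate = 1.0, lactate_rate = 1.5),
      bad  = list(glucose_rate = 1.4, lactate_rate = 2.4),
      days = c(0, 3, 5, 6), media_change_day = 3, fresh_glucose = 11,
      noise_sd = 0.2),
    survival = list(baseline_hazard = 0.04, hr_high = 0.35,
                    threshold = 80, censoring_rate = 0.2)) {
  if (missing(seed)) stop("seed is mandatory (no implicit entropy)")
  cfg <- list(seed = as.integer(seed), n_good = n_good, n_bad = n_bad,
              n_hd = n_hd, cells_per_condition = cells_per_condition,
              dependence = dependence, control_mean = control_mean,
              sigma = sigma, background = background, latent_sd = latent_sd,
              markers = markers, marker_mean = marker_mean,
              seahorse = seahorse, supernatant = supernatant,
              survival = survival)
  validateSyntheticConfig(cfg)
  class(cfg) <- "immunomet_config"
  cfg
}

#' Validate a synthetic cohort configuration
#'
#' Fails before any sampling happens when dependence fractions leave
#' \[0, 1\], probabilities are invalid, or the survival model is
#' degenerate.
#'
#' @param cfg config list from [syntheticCohortConfig()].
#' @return TRUE invisibly, or an error.
#' @export
validateSyntheticConfig <- function(cfg) {
  for (grp in names(cfg$dependence)) {
    d <- cfg$dependence[[grp]]
    if (length(d) != 4 || any(d < 0 | d > 1))
      stop("dependence vector for group '", grp,
           "' must be 4 fractions in [0, 1]")
  }
  if (cfg$background < 0 || cfg$background >= 1)
    stop("background fraction must lie in [0, 1)")
  if (cfg$sigma < 0) stop("sigma must be >= 0")
  if (cfg$survival$hr_high <= 0) stop("hazard ratio must be > 0")
  if (cfg$survival$censoring_rate < 0 || cfg$survival$censoring_rate > 1)
    stop("censoring rate must lie in [0, 1]")
  if (cfg$survival$baseline_hazard <= 0)
    stop("baseline hazard must be > 0")
  invisible(TRUE)
}

.expected_mfi <- function(C, dep, background, condition) {
  # Harringtonine arrests elongation outright, so its expected signal sits
  # below even the combined metabolic block: it must satisfy the QC anchor
  # H <= all other conditions that it exists to check.
  if (condition == "H") return(C * background * 0.8)
  d <- switch(condition,
              "C" = 0, "2DG" = dep[["g"]], "O" = dep[["m"]],
              "Eto" = dep[["f"]], "Tele" = dep[["q"]], "DGO" = 1)
  C * (1 - d * (1 - background))
}

#' Generate per-cell SCENITH events for one sample
#'
#' Draws log-normal per-cell puromycin intensities around the
#' condition-expected level for every inhibitor condition, plus
#' marker intensities whose log-means are shifted by their coupling to the
#' per-cell latent glycolytic state (the state also feeds puromycin under
#' oligomycin, so marker-coupled structure is recoverable from the
#' oligomycin quantile bins). Harringtonine (H) cells are generated at the
#' full-arrest level as a translation-arrest anchor.
#'
#' @param cfg config from [syntheticCohortConfig()].
#' @param group one of the configured groups (`good`, `bad`, `HD`).
#' @param sample_id sample identifier.
#' @param seed optional override; defaults to a sub-stream of
#'   `cfg$seed` keyed by `"cells"` and the sample id.
#' @return an [EventTable-class] covering conditions C, 2DG, O, Eto, Tele,
#'   DGO, H with channels `puromycin` + configured markers.
#' @export
generateCellEvents <- function(cfg, group, sample_id, seed = NULL) {
  validateSyntheticConfig(cfg)
  dep <- cfg$dependence[[group]]
  if (is.null(dep)) stop("unknown group: ", group)
  if (is.null(seed))
    seed <- streamSeed(cfg$seed, paste0("cells:", sample_id))
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  n <- cfg$cells_per_condition
  conditions <- c("C", "2DG", "O", "Eto", "Tele", "DGO", "H")
  blocks <- lapply(conditions, function(cond) {
    expected <- .expected_mfi(cfg$control_mean, dep, cfg$background, cond)
    s <- stats::rnorm(n)  # latent glycolytic state, N(0, 1)
    if (expected > 0) {
      mu <- log(expected)
      if (cond == "O") mu <- mu + cfg$latent_sd * s
      puro <- stats::rlnorm(n, meanlog = mu, sdlog = cfg$sigma)
    } else {
      puro <- rep(0, n)  # complete translation arrest (b = 0 limit)
    }
    df <- data.frame(sample_id = sample_id, condition = cond,
                     population = "mDC", viability_pass = TRUE,
                     puromycin = puro)
    for (mk in names(cfg$markers)) {
      df[[mk]] <- stats::rlnorm(
        n, meanlog = log(cfg$marker_mean) + cfg$markers[[mk]] * s,
        sdlog = cfg$sigma)
    }
    df
  })
  EventTable(do.call(rbind, blocks), puromycinChannel = "puromycin")
}

#' Generate a Seahorse stress-test trace (with paired FAO well)
#'
#' Plateau segments at the configured group means plus Gaussian noise,
#' measured every 30 minutes with the oligomycin / FCCP /
#' rotenone-antimycin A injection schedule. The paired palmitate+etomoxir
#' trace is identical except its post-FCCP OCR plateau sits `fao_drop`
#' below the control's, so the exogenous-FAO contrast recovers `fao_drop`
#' in the noiseless case.
#'
#' @inheritParams generateCellEvents
#' @param well well id stem.
#' @param noise_sd override the configured noise SD (set 0 for noiseless).
#' @return list with `control` and `palmitate_etomoxir`
#'   [SeahorseTrace-class] objects.
#' @export
generateSeahorseTrace <- function(cfg, group, well = "A1", seed = NULL,
                                  noise_sd = NULL) {
  validateSyntheticConfig(cfg)
  sh <- cfg$seahorse[[group]]
  if (is.null(sh)) stop("no Seahorse config for group: ", group)
  if (is.null(seed))
    seed <- streamSeed(cfg$seed, paste0("seahorse:", group, ":", well))
  if (is.null(noise_sd)) noise_sd <- sh$noise_sd
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  k <- sh$n_per_segment
  nt <- 4 * k
  time <- seq(0, by = 30, length.out = nt)
  seg <- rep(c("pre_oligo", "post_oligomycin", "post_FCCP", "post_RA"),
             each = k)
  inj_times <- time[c(k, 2 * k, 3 * k)] + 15
  injections <- data.frame(
    label = c("oligomycin", "FCCP", "rotenone/antimycinA"),
    time = inj_times)

  mk_trace <- function(cond, fccp_ocr) {
    ocr_mean <- unname(sh$segments$ocr[seg])
    ocr_mean[seg == "post_FCCP"] <- fccp_ocr
    ecar_mean <- unname(sh$segments$ecar[seg])
    SeahorseTrace(well = paste0(well, if (cond != "control") "-FAO"),
                  time = time,
                  ocr = ocr_mean + stats::rnorm(nt, 0, noise_sd),
                  ecar = ecar_mean + stats::rnorm(nt, 0, noise_sd),
                  injections = injections, condition = cond)
  }
  list(control = mk_trace("control", sh$segments$ocr[["post_FCCP"]]),
       palmitate_etomoxir = mk_trace(
         "palmitate+etomoxir",
         sh$segments$ocr[["post_FCCP"]] - sh$fao_drop))
}

#' Generate a supernatant glucose/lactate series
#'
#' Piecewise-linear glucose decline and lactate rise at the group's
#' configured rates, with a media change (fresh glucose, zero lactate)
#' at the configured day. Observations carry Gaussian measurement noise
#' truncated at zero.
#'
#' @inheritParams generateCellEvents
#' @return list with `series` (data.frame day/glucose/lactate) and
#'   `media_changes` (data.frame day/fresh_glucose/fresh_lactate).
#' @export
generateSupernatantSeries <- function(cfg, group, sample_id = group,
                                      seed = NULL) {
  validateSyntheticConfig(cfg)
  sp <- cfg$supernatant
  rates <- sp[[group]]
  if (is.null(rates)) stop("no supernatant config for group: ", group)
  if (is.null(seed))
    seed <- streamSeed(cfg$seed, paste0("supernatant:", sample_id))
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  days <- sp$days
  glucose <- numeric(length(days))
  lactate <- numeric(length(days))
  g <- sp$fresh_glucose; l <- 0
  prev_day <- days[1]
  for (i in seq_along(days)) {
    dt <- days[i] - prev_day
    g <- max(g - rates$glucose_rate * dt, 0)
    l <- l + rates$lactate_rate * dt
    glucose[i] <- max(g + stats::rnorm(1, 0, sp$noise_sd), 0)
    lactate[i] <- max(l + stats::rnorm(1, 0, sp$noise_sd), 0)
    prev_day <- days[i]
    if (days[i] == sp$media_change_day) {
      g <- sp$fresh_glucose
      l <- 0
    }
  }
  list(series = data.frame(day = days, glucose = glucose, lactate = lactate),
       media_changes = data.frame(day = sp$media_change_day,
                                  fresh_glucose = sp$fresh_glucose,
                                  fresh_lactate = 0))
}

#' Generate a proportional-hazards survival cohort
#'
#' Per-patient mitochondrial dependence is drawn around the group's
#' ground-truth value; event times are exponential with the hazard
#' multiplied by `hr_high` for patients whose dependence exceeds the
#' configured threshold. Censoring is independent exponential, calibrated
#' to the target censoring rate (rate 1 censors everyone). Identical
#' config + seed gives identical output.
#'
#' @inheritParams generateCellEvents
#' @param covariate_sd SD of the per-patient dependence draw (percent
#'   points, default 6).
#' @return data.frame of `SurvivalRecord` rows: patient, outcome_group,
#'   os_months, os_event, pfs_months, pfs_event, mitochondrial_dependence,
#'   high_mito.
#' @export
generateSurvivalCohort <- function(cfg, seed = NULL, covariate_sd = 6) {
  validateSyntheticConfig(cfg)
  if (is.null(seed)) seed <- streamSeed(cfg$seed, "survival")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sv <- cfg$survival

  groups <- c(rep("good", cfg$n_good), rep("bad", cfg$n_bad))
  n <- length(groups)
  truth <- vapply(groups, function(g) cfg$dependence[[g]][["m"]] * 100,
                  numeric(1))
  mito <- pmin(pmax(stats::rnorm(n, truth, covariate_sd), 0), 100)
  high <- mito > sv$threshold
  hazard <- sv$baseline_hazard * ifelse(high, sv$hr_high, 1)

  draw_endpoint <- function(hz) {
    t_event <- stats::rexp(n, hz)
    if (sv$censoring_rate >= 1) {
      list(time = t_event, event = rep(0L, n))
    } else if (sv$censoring_rate <= 0) {
      list(time = t_event, event = rep(1L, n))
    } else {
      # exponential censoring with P(censor) = mu / (lambda + mu)
      mu <- mean(hz) * sv$censoring_rate / (1 - sv$censoring_rate)
      t_cens <- stats::rexp(n, mu)
      list(time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
    }
  }
  os <- draw_endpoint(hazard)
  pfs <- draw_endpoint(hazard * 1.5)
  data.frame(patient = sprintf("P%03d", seq_len(n)),
             outcome_group = groups,
             os_months = os$time, os_event = os$event,
             pfs_months = pfs$time, pfs_event = pfs$event,
             mitochondrial_dependence = mito,
             high_mito = as.integer(high))
}

#' Generate the full synthetic cohort
#'
#' One call producing everything the pipeline stages consume: per-sample
#' cell events (all inhibitor conditions), sample-to-group mapping,
#' Seahorse trace pairs, supernatant series and the survival table.
#'
#' @param cfg config from [syntheticCohortConfig()].
#' @return list with `events` (one combined [EventTable-class]), `groups`
#'   (named vector sample -> group), `seahorse`, `supernatant`, `survival`.
#' @export
generateCohort <- function(cfg) {
  validateSyntheticConfig(cfg)
  labels <- c(rep("good", cfg$n_good), rep("bad", cfg$n_bad),
              rep("HD", cfg$n_hd))
  ids <- sprintf("S%03d", seq_along(labels))
  evs <- lapply(seq_along(ids), function(i)
    generateCellEvents(cfg, labels[i], ids[i]))
  combined <- EventTable(do.call(rbind, lapply(evs, eventData)),
                         puromycinChannel = "puromycin")
  groups <- stats::setNames(labels, ids)
  seah <- lapply(stats::setNames(nm = names(cfg$seahorse)), function(g)
    generateSeahorseTrace(cfg, g, well = paste0("W_", g)))
  supn <- lapply(stats::setNames(nm = setdiff(names(cfg$supernatant),
                                              c("days", "media_change_day",
                                                "fresh_glucose",
                                                "noise_sd"))),
                 function(g) generateSupernatantSeries(cfg, g))
  list(events = combined, groups = groups, seahorse = seah,
       supernatant = supn, survival = generateSurvivalCohort(cfg))
}
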