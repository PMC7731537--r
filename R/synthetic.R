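#' Configuration for a synthetic tracer-infusion cohort
#'
#' Captures, as explicit parameters, the statistical structure the analysis
#' assumes for a glutamine-infusion SIRM study: plateau plasma enrichments
#' of a few percent, per-subject anaplerotic fractional contributions with
#' a multiplicative CD138+/CD138- effect that differs by disease group,
#' substantial between-subject heterogeneity, and bone-marrow plasma
#' concentrations that scale with marrow plasma-cell percentage (BMPC).
#' Every default is a modeling choice of this package, not a measured
#' value; all are overridable.
#'
#' @param n_volunteer,n_mgus,n_mm subjects per group.
#' @param tracer_name `"u13c5"` or `"5c13"` (see [tracer_spec()]).
#' @param metabolites enrichment panel (default: the five first-turn
#'   readouts glutamate, citrate, fumarate, malate, aspartate).
#' @param enrichment_range named list of plateau plasma glutamine
#'   enrichment ranges per group (uniform draw).
#' @param f_base mean anaplerotic fraction in CD138- cells.
#' @param effect_ratio named list per group: multiplicative CD138+/CD138-
#'   effect, a named vector with a `.default` entry plus optional
#'   per-metabolite overrides (default: MM 1.5 for all metabolites, MGUS 1
#'   except aspartate 1.3, volunteers 1).
#' @param subject_cv between-subject lognormal CV of the anaplerotic
#'   fraction (shared by both sorted fractions of a subject).
#' @param fraction_cv within-subject, per-fraction lognormal CV.
#' @param additive_sigma SIM additive Gaussian noise, as a fraction of the
#'   per-(sample, metabolite) total ion intensity.
#' @param multiplicative_cv SIM per-channel multiplicative noise CV.
#' @param enrichment_measurement_cv CV of the measured plasma enrichment
#'   around its true plateau.
#' @param bmpc_range named list of BMPC\% ranges per group (uniform draw).
#' @param concentration_model named list per analyte:
#'   `c(intercept, slope, cv)` giving concentration (umol/L) =
#'   intercept + slope * BMPC\% with lognormal noise of that CV. Negative
#'   slopes model depletion (glutamine consumed by the tumor compartment).
#' @param platform_cv CV of the LC-MS re-measurement around the GC-MS
#'   value, for concordance checks.
#' @param missingness per-(sample, metabolite) probability of a missing
#'   measurement (default 0).
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_volunteer = 7, n_mgus = 11, n_mm = 12,
                          tracer_name = "u13c5",
                          metabolites = c("glutamate", "citrate", "fumarate",
                                          "malate", "aspartate"),
                          enrichment_range = list(volunteer = c(0.04, 0.10),
                                                  MGUS = c(0.03, 0.07),
                                                  MM = c(0.03, 0.07)),
                          f_base = 0.15,
                          effect_ratio = list(
                            volunteer = c(.default = 1),
                            MGUS = c(.default = 1, aspartate = 1.3),
                            MM = c(.default = 1.5)),
                          subject_cv = 0.4, fraction_cv = 0.15,
                          additive_sigma = 1e-4, multiplicative_cv = 0.01,
                          enrichment_measurement_cv = 0.02,
                          bmpc_range = list(volunteer = c(0.5, 3),
                                            MGUS = c(1, 9),
                                            MM = c(10, 60)),
                          concentration_model = list(
                            glutamate = c(intercept = 55, slope = 1.2,
                                          cv = 0.15),
                            aspartate = c(intercept = 8, slope = 0.3,
                                          cv = 0.15),
                            glutamine = c(intercept = 480, slope = -2.5,
                                          cv = 0.15)),
                          platform_cv = 0.05,
                          missingness = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  for (rng in enrichment_range)
    if (any(rng <= 0) || any(rng >= 1))
      stop("enrichment ranges must lie in (0, 1)")
  if (f_base <= 0 || f_base >= 1) stop("f_base must lie in (0, 1)")
  structure(as.list(environment()), class = "cohort_config")
}

# lognormal multiplier with mean 1 and the given CV
lnorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

ratio_for <- function(effect, metabolite) {
  if (metabolite %in% names(effect)) unname(effect[[metabolite]])
  else unname(effect[[".default"]])
}

#' Generate a synthetic tracer-infusion cohort
#'
#' Draws a cohort under a [cohort_config()] and emits the same tidy tables
#' the analysis pipeline consumes, plus a truth table recording every
#' latent parameter for recovery tests. Raw SIM intensities are produced by
#' the forward model: idealized first-turn MID ([ideal_mid()]) convolved
#' with natural abundance (the columns of [build_correction_matrix()]),
#' scaled to an ion-count total, with multiplicative and additive noise.
#'
#' @param config a [cohort_config()].
#' @param fragments fragment catalog ([read_fragment_catalog()] default).
#' @param isotopes an [isotope_table()].
#' @param atom_maps a [load_atom_maps()] result.
#' @return list of data.frames: `metadata` (subject, group, fraction,
#'   sample_id, bmpc_percent), `intensities` (tidy SIM table),
#'   `plasma_enrichment` (per sample, measured), `concentrations`
#'   (per subject x analyte x platform, umol/L), `truth` (latent
#'   anaplerotic fractions and true enrichments).
#' @export
generate_cohort <- function(config,
                            fragments = read_fragment_catalog(),
                            isotopes = isotope_table(),
                            atom_maps = load_atom_maps()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- rep(c("volunteer", "MGUS", "MM"),
                c(config$n_volunteer, config$n_mgus, config$n_mm))
  subjects <- sprintf("S%02d", seq_along(groups))
  shifts <- propagate_first_turn(tracer_spec(config$tracer_name),
                                 atom_maps)
  mats <- lapply(config$metabolites, function(m)
    build_correction_matrix(fragments[[m]], isotopes))
  names(mats) <- config$metabolites

  meta <- list(); inten <- list(); plasma <- list(); truth <- list()
  conc <- list()
  for (i in seq_along(subjects)) {
    g <- groups[i]
    e_true <- runif(1, config$enrichment_range[[g]][1],
                    config$enrichment_range[[g]][2])
    bmpc <- runif(1, config$bmpc_range[[g]][1], config$bmpc_range[[g]][2])
    subj_mult <- lnorm_mult(1, config$subject_cv)
    for (fr in c("CD138+", "CD138-")) {
      sid <- paste0(subjects[i], ifelse(fr == "CD138+", "_pos", "_neg"))
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = subjects[i], group = g, fraction = fr,
        sample_id = sid, bmpc_percent = bmpc)
      e_meas <- e_true * (1 + rnorm(1, 0, config$enrichment_measurement_cv))
      plasma[[length(plasma) + 1L]] <- data.frame(
        sample_id = sid, subject_id = subjects[i], enrichment = e_meas)
      tracer <- tracer_spec(config$tracer_name, enrichment = e_true)
      for (met in config$metabolites) {
        if (config$missingness > 0 && runif(1) < config$missingness) next
        ratio <- if (fr == "CD138+")
          ratio_for(config$effect_ratio[[g]], met) else 1
        f <- min(config$f_base * ratio * subj_mult *
                   lnorm_mult(1, config$fraction_cv), 0.95)
        mid <- ideal_mid(tracer, met, f, atom_maps)
        expected <- as.numeric(mats[[met]] %*% mid)
        total <- rlnorm(1, log(1e6), 0.3)
        raw <- total * expected *
          (1 + rnorm(length(expected), 0, config$multiplicative_cv)) +
          rnorm(length(expected), 0, config$additive_sigma * total)
        raw <- pmax(raw, 0)
        inten[[length(inten) + 1L]] <- data.frame(
          sample_id = sid, metabolite = met,
          channel = paste0("M", seq_along(raw) - 1L), intensity = raw)
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = subjects[i], sample_id = sid, group = g,
          fraction = fr, metabolite = met, f_true = f, e_true = e_true,
          shift = shifts[[met]],
          backbone_carbons = length(mid) - 1L)
      }
    }
    for (an in names(config$concentration_model)) {
      cm <- config$concentration_model[[an]]
      base <- max(cm[["intercept"]] + cm[["slope"]] * bmpc, 5)
      gc_val <- base * lnorm_mult(1, cm[["cv"]])
      lc_val <- gc_val * (1 + rnorm(1, 0, config$platform_cv))
      conc[[length(conc) + 1L]] <- data.frame(
        subject_id = subjects[i], group = g, analyte = an,
        bmpc_percent = bmpc,
        platform = c("GC-MS", "LC-MS"),
        concentration = c(gc_val, lc_val), units = "umol/L")
    }
  }
  list(metadata = do.call(rbind, meta),
       intensities = do.call(rbind, inten),
       plasma_enrichment = do.call(rbind, plasma),
       concentrations = do.call(rbind, conc),
       truth = do.call(rbind, truth))
}

#' Recover anaplerotic fractions from precursor-normalized enrichments
#'
#' Inverts the first-turn forward model: with a single-turn shift `s` out of
#' `n` backbone carbons, MPE = f * e * s / n, so
#' f = relative_enrichment * n / s. Metabolites with shift 0 carry no
#' information and return `NA`.
#'
#' @param rel output of [normalize_to_precursor()].
#' @param tracer_name tracer used for the cohort.
#' @param atom_maps a [load_atom_maps()] result.
#' @param fragments fragment catalog supplying backbone carbon counts.
#' @return `rel` with an added `f_hat` column.
#' @export
recover_anaplerotic_fraction <- function(rel, tracer_name = "u13c5",
                                         atom_maps = load_atom_maps(),
                                         fragments =
                                           read_fragment_catalog()) {
  shifts <- propagate_first_turn(tracer_spec(tracer_name), atom_maps)
  s <- shifts[rel$metabolite]
  n <- vapply(rel$metabolite, function(m)
    fragments[[m]]$backbone_carbons, integer(1))
  rel$f_hat <- ifelse(s > 0, rel$relative_enrichment * n / s, NA_real_)
  rel
}

#' Plasma tracer-enrichment time course during an infusion
#'
#' Emulates the bolus-plus-continuous-infusion protocol: a rapid rise to
#' the subject's plateau within the first `rise_time` minutes, then a flat
#' plateau with optional multiplicative jitter.
#'
#' @param plateau plateau enrichment fraction.
#' @param n_timepoints number of sampling times (>= 2), evenly spaced over
#'   \[0, `t_end`\].
#' @param t_end infusion duration in minutes (default 60).
#' @param rise_time minutes to reach plateau (default 15).
#' @param jitter_cv multiplicative CV of plateau samples (default 0).
#' @return data.frame `time_min`, `enrichment`.
#' @export
generate_enrichment_timecourse <- function(plateau, n_timepoints = 13,
                                           t_end = 60, rise_time = 15,
                                           jitter_cv = 0) {
  if (n_timepoints < 2L) stop("need at least 2 timepoints")
  tm <- seq(0, t_end, length.out = n_timepoints)
  e <- plateau * pmin(tm / rise_time, 1)
  if (jitter_cv > 0)
    e <- e * (1 + rnorm(n_timepoints, 0, jitter_cv))
  data.frame(time_min = tm, enrichment = pmax(e, 0))
}
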