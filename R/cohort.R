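#' Configuration for the synthetic morphometry cohort generator
#'
#' Defines a two-group cohort of per-subject, per-region gray-matter (GM)
#' voxel-value samples with a known statistical structure: regions belong to
#' communities that share distribution-family parameters (so within-community
#' similarity is high), patients receive a location shift of the dominant
#' mixture component in a chosen set of effect nodes, and clinical covariates
#' emulate a pediatric spinal muscular atrophy cohort (ages, sex ratio,
#' disease duration, HFMSE motor score on the 0-66 scale).
#'
#' @param n_per_group subjects per group (patients and controls); default 38.
#' @param n_regions number of parcellation regions (default 116; an
#'   83-region alternative mirrors a coarser atlas).
#' @param voxel_range integer range of voxels per region; each region draws
#'   a fixed count from this range.
#' @param n_communities number of region communities sharing distribution
#'   parameters.
#' @param effect_nodes character vector of region ids (or integer indices)
#'   receiving the patient-group effect.
#' @param effect_size standardized mean shift, in units of `subject_sd`,
#'   applied to the dominant mixture component of each effect node in
#'   patients. 0 disables the effect.
#' @param subject_sd between-subject SD of per-region location offsets
#'   (unitless GM volume fraction scale).
#' @param clinical_spec list of clinical distribution settings; see
#'   [default_clinical_spec()].
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 38L, n_regions = 116L,
                          voxel_range = c(100L, 300L), n_communities = 6L,
                          effect_nodes = character(), effect_size = 0,
                          subject_sd = 0.01,
                          clinical_spec = default_clinical_spec(),
                          seed = 1L) {
  stopifnot(n_per_group >= 2, n_regions >= 2, n_communities >= 1,
            length(voxel_range) == 2, voxel_range[1] >= 10,
            voxel_range[2] >= voxel_range[1],
            effect_size >= 0, subject_sd > 0)
  region_ids <- region_names(n_regions)
  if (is.numeric(effect_nodes)) effect_nodes <- region_ids[effect_nodes]
  unknown <- setdiff(effect_nodes, region_ids)
  if (length(unknown)) {
    stop("effect node id(s) outside the parcellation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    n_regions = as.integer(n_regions),
    voxel_range = as.integer(voxel_range),
    n_communities = as.integer(n_communities),
    effect_nodes = effect_nodes,
    effect_size = effect_size,
    subject_sd = subject_sd,
    clinical_spec = clinical_spec,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Default clinical covariate distributions
#'
#' Truncated-normal parameters for age (patients 10.37 +/- 3.81 years on
#' 5-17; controls 10.30 +/- 3.54 on 6-20), age of onset (2.55 +/- 2.59 on
#' 0.5-12), disease duration (7.78 +/- 3.61 on 2-16.5), a 24:14 male:female
#' ratio, and the HFMSE link (score = round(66 * logistic(-a * exposure +
#' noise)) clipped to 0-66, where exposure is each patient's standardized
#' realized effect magnitude).
#'
#' @param hfmse_slope slope `a` of the HFMSE logistic link on the
#'   standardized exposure.
#' @param hfmse_noise_sd SD of the logistic-scale noise; larger values widen
#'   the score spread.
#' @return list of clinical settings.
#' @export
default_clinical_spec <- function(hfmse_slope = 2, hfmse_noise_sd = 0.9) {
  list(
    age_patient = list(mean = 10.37, sd = 3.81, range = c(5, 17)),
    age_control = list(mean = 10.30, sd = 3.54, range = c(6, 20)),
    male_fraction = 24 / 38,
    onset = list(mean = 2.55, sd = 2.59, range = c(0.5, 12)),
    duration = list(mean = 7.78, sd = 3.61, range = c(2, 16.5)),
    hfmse_slope = hfmse_slope,
    hfmse_noise_sd = hfmse_noise_sd
  )
}

region_names <- function(n_regions) sprintf("R%03d", seq_len(n_regions))

#' Generate a synthetic two-group morphometry cohort
#'
#' Regional GM values are drawn from two-component Gaussian mixtures whose
#' parameters are shared within region communities (plus small per-region
#' jitter), giving non-trivial distribution shapes and high within-community
#' similarity. Every subject gets region-level location offsets with SD
#' `subject_sd`; patients additionally shift the dominant mixture component
#' of each effect node by `effect_size * subject_sd` times a subject- and
#' node-specific positive multiplier, with a fixed alternating sign per
#' effect node, so effect nodes diverge from every other region (including
#' each other) and the realized effect magnitude varies across patients.
#' Each patient's exposure is the mean absolute realized shift; HFMSE
#' declines with exposure through a noisy logistic link, making the
#' clinical association recoverable.
#'
#' @param config a [cohort_config()].
#' @return list with class `morph_cohort`: `subjects` (list of per-subject
#'   records with `subject_id`, `group`, `region_values`), `clinical`
#'   (data.frame), `regions`, `communities`, and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_reg <- config$n_regions
  regions <- region_names(n_reg)
  comm <- sort(rep_len(seq_len(config$n_communities), n_reg))

  # Communities share the location of the dominant mixture component;
  # shape parameters (mode separation, widths, weight) vary per region.
  # Locations are kept close relative to the component widths so that
  # cross-community similarity stays moderate rather than vanishing --
  # real morphological similarity values span a broad 0.2-0.9 range and
  # regional GM distributions overlap heavily -- while within-community
  # similarity remains higher on average.
  c_mu1 <- stats::runif(config$n_communities, 0.435, 0.465)
  mu1 <- c_mu1[comm] + stats::rnorm(n_reg, 0, 0.010)
  mu2 <- mu1 + stats::runif(n_reg, 0.12, 0.22)
  s1  <- stats::runif(n_reg, 0.04, 0.10)
  s2  <- stats::runif(n_reg, 0.07, 0.13)
  w   <- stats::runif(n_reg, 0.50, 0.70)

  vox_choices <- seq(config$voxel_range[1], config$voxel_range[2])
  n_vox <- vox_choices[sample.int(length(vox_choices), n_reg, replace = TRUE)]
  eff_idx <- match(config$effect_nodes, regions)

  n <- config$n_per_group
  groups <- rep(c("patient", "control"), each = n)
  ids <- sprintf("S%03d", seq_along(groups))

  # Each effect node gets a fixed shift direction (alternating sign) so
  # effect nodes also diverge from one another, not only from the rest;
  # per-subject magnitude multipliers make the realized exposure vary
  # across patients, which the HFMSE link depends on.
  eff_sign <- rep_len(c(1, -1), length(eff_idx))

  subjects <- vector("list", length(ids))
  exposure <- numeric(length(ids))
  for (s in seq_along(ids)) {
    offs <- stats::rnorm(n_reg, 0, config$subject_sd)
    # shared severity multiplier per subject, mild per-node variation
    sev <- abs(stats::rnorm(1, 1, 0.4))
    mult <- sev * abs(stats::rnorm(max(length(eff_idx), 1L), 1, 0.15))
    shift <- numeric(n_reg)
    if (groups[s] == "patient" && length(eff_idx) && config$effect_size > 0) {
      shift[eff_idx] <- config$effect_size * config$subject_sd *
        mult[seq_along(eff_idx)] * eff_sign
      exposure[s] <- mean(abs(shift[eff_idx]))
    }
    vals <- vector("list", n_reg)
    for (r in seq_len(n_reg)) {
      m <- n_vox[r]
      z1 <- stats::rbinom(1, m, w[r])
      # effect applies to the dominant (first) component only
      v <- c(stats::rnorm(z1, mu1[r] + offs[r] + shift[r], s1[r]),
             stats::rnorm(m - z1, mu2[r] + offs[r], s2[r]))
      vals[[r]] <- pmax(v, 1e-6)
    }
    names(vals) <- regions
    subjects[[s]] <- list(subject_id = ids[s], group = groups[s],
                          region_values = vals)
  }
  names(subjects) <- ids

  clinical <- generate_clinical(ids, groups, exposure, config)
  structure(list(subjects = subjects, clinical = clinical,
                 regions = regions, communities = comm, config = config),
            class = "morph_cohort")
}

generate_clinical <- function(ids, groups, exposure, config) {
  cs <- config$clinical_spec
  pat <- groups == "patient"
  n_p <- sum(pat); n_c <- sum(!pat)

  age <- numeric(length(ids))
  age[pat] <- rtruncnorm(n_p, cs$age_patient$mean, cs$age_patient$sd,
                         cs$age_patient$range[1], cs$age_patient$range[2])
  age[!pat] <- rtruncnorm(n_c, cs$age_control$mean, cs$age_control$sd,
                          cs$age_control$range[1], cs$age_control$range[2])

  sex_block <- function(n) {
    n_m <- round(cs$male_fraction * n)
    sample(rep(c("M", "F"), c(n_m, n - n_m)))
  }
  sex <- character(length(ids))
  sex[pat] <- sex_block(n_p)
  sex[!pat] <- sex_block(n_c)

  onset <- duration <- hfmse <- rep(NA_real_, length(ids))
  onset[pat] <- rtruncnorm(n_p, cs$onset$mean, cs$onset$sd,
                           cs$onset$range[1], cs$onset$range[2])
  duration[pat] <- rtruncnorm(n_p, cs$duration$mean, cs$duration$sd,
                              cs$duration$range[1], cs$duration$range[2])

  expo <- exposure[pat]
  z <- if (stats::sd(expo) > 0) as.numeric(scale(expo)) else rep(0, n_p)
  lin <- -cs$hfmse_slope * z + stats::rnorm(n_p, 0, cs$hfmse_noise_sd)
  hfmse[pat] <- pmin(pmax(round(66 * stats::plogis(lin)), 0), 66)

  data.frame(subject_id = ids, group = groups, age = age, sex = sex,
             onset = onset, duration = duration, hfmse = hfmse,
             exposure = exposure, stringsAsFactors = FALSE)
}

#' @export
print.morph_cohort <- function(x, ...) {
  cat(sprintf("<morph_cohort> %d subjects (%d patients / %d controls), %d regions\n",
              length(x$subjects), sum(x$clinical$group == "patient"),
              sum(x$clinical$group == "control"), length(x$regions)))
  invisible(x)
}

#' Export a cohort to long-format TSV files
#'
#' Writes `cohort.tsv` (columns `subject_id`, `region_id`, `value`; one row
#' per voxel) and `clinical.tsv` into `path`. Files round-trip losslessly
#' through [read_cohort_table()] and [read_clinical_table()].
#'
#' @param cohort a `morph_cohort` or a bare list of subject records.
#' @param clinical clinical data.frame; defaults to `cohort$clinical`.
#' @param path output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
export_cohort <- function(cohort, clinical = NULL, path) {
  subjects <- if (inherits(cohort, "morph_cohort")) cohort$subjects else cohort
  clinical <- clinical %||%
    (if (inherits(cohort, "morph_cohort")) cohort$clinical else NULL)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(path, "cohort.tsv")
  clinical_path <- file.path(path, "clinical.tsv")

  if (length(subjects)) {
    tabs <- lapply(subjects, function(s) {
      nv <- lengths(s$region_values)
      data.table::data.table(
        subject_id = s$subject_id,
        region_id = rep(names(s$region_values), nv),
        value = unlist(s$region_values, use.names = FALSE))
    })
    data.table::fwrite(data.table::rbindlist(tabs), cohort_path, sep = "\t")
  } else {
    writeLines("subject_id\tregion_id\tvalue", cohort_path)
  }

  if (!is.null(clinical) && nrow(clinical)) {
    data.table::fwrite(clinical, clinical_path, sep = "\t")
  } else {
    writeLines(paste(c("subject_id", "group", "age", "sex", "onset",
                       "duration", "hfmse"), collapse = "\t"), clinical_path)
  }
  invisible(c(cohort = cohort_path, clinical = clinical_path))
}
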