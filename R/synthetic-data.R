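#' Define a synthetic group profile
#'
#' A profile parameterizes the latent pair-intensity model from which a
#' group's connectomes are drawn: a block (module) structure on the parcels,
#' connection probabilities within and between modules, a within/between
#' mean-weight contrast that concentrates strong connections inside modules,
#' a gamma weight-concentration (sharpness of streamline allocation), a
#' hub-degree structure (`degree_spread`) with an assortative tilt
#' (`hub_tilt` < 0: hubs prefer non-hubs, the disassortative regime of
#' healthy biological networks), and a target weighted-graph (support)
#' density with between-subject SD. Group effects are planted on these
#' latent intensities, never on metric values directly — the metrics are
#' emergent.
#'
#' @param label Group label (one of HC/CIS/RR/SP/PP or any string).
#' @param n_modules Number of latent modules (>= 1).
#' @param p_within,p_between Connection probabilities inside/between modules
#'   (within >= between); jointly rescaled per subject to hit the drawn
#'   target density.
#' @param weight_contrast Mean weight ratio of within- vs between-module
#'   connections (>= 1 for modular profiles).
#' @param weight_concentration Gamma shape of pair weights (larger = less
#'   weight dispersion).
#' @param hub_tilt Log-intensity boost for hub-hub and periphery-periphery
#'   pairs (positive = assortative, negative = disassortative).
#' @param degree_spread Log-intensity half-gap between hub and non-hub
#'   nodes (>= 0; controls degree heterogeneity).
#' @param target_density Mean support density of the weighted graph.
#' @param density_sd Between-subject SD of the support density.
#' @param subject_sigma Log-normal SD of per-subject pair-intensity jitter.
#' @return A `group_profile` list.
#' @export
group_profile <- function(label, n_modules = 4, p_within = 0.75,
                          p_between = 0.52, weight_contrast = 2,
                          weight_concentration = 1.5, hub_tilt = -0.5,
                          degree_spread = 0.6, target_density = 0.58,
                          density_sd = 0.055, subject_sigma = 0.35) {
  if (p_within < 0 || p_within > 1 || p_between < 0 || p_between > 1) {
    abort("Connection probabilities must lie in [0, 1].",
          class = "connectoms_invalid_input")
  }
  if (p_within < p_between) {
    abort("`p_within` must be >= `p_between` for a modular profile.",
          class = "connectoms_invalid_input")
  }
  if (n_modules < 1 || weight_contrast <= 0 || weight_concentration <= 0 ||
      degree_spread < 0 || target_density <= 0 || target_density > 1 ||
      density_sd < 0 || subject_sigma < 0) {
    abort("Invalid profile parameter (see ?group_profile for domains).",
          class = "connectoms_invalid_input")
  }
  structure(
    list(label = label, n_modules = as.integer(n_modules),
         p_within = p_within, p_between = p_between,
         weight_contrast = weight_contrast,
         weight_concentration = weight_concentration,
         hub_tilt = hub_tilt, degree_spread = degree_spread,
         target_density = target_density, density_sd = density_sd,
         subject_sigma = subject_sigma),
    class = "group_profile"
  )
}

# Latent block labels (contiguous, near-equal) plus a fixed node-propensity
# profile: normal quantiles interleaved so every block spans the full hub /
# periphery range. `z` scales log-intensity (degree heterogeneity); its sign
# splits nodes into the hub / non-hub classes used by the assortative tilt.
latent_structure <- function(q, n_modules) {
  block <- sort(rep_len(seq_len(n_modules), q))
  z <- numeric(q)
  z[order(rep_len(seq_len(n_modules), q))] <- stats::qnorm(stats::ppoints(q))
  list(block = block, z = z, hub = ifelse(z >= 0, 1, -1))
}

#' Draw one synthetic connectome
#'
#' Draws a latent support (within/between-module connection indicators at a
#' subject-specific density), assigns gamma-distributed pair intensities
#' with the profile's modular contrast, hub propensity and assortative tilt,
#' jitters them by a subject-level log-normal factor, and finally allocates
#' `f` streamlines multinomially over the supported pairs. The result is a
#' symmetric, zero-diagonal integer count matrix whose upper triangle sums
#' to `f`.
#'
#' @param profile A [group_profile()].
#' @param q Number of parcels (default 84).
#' @param f Streamlines per subject (default 500,000).
#' @param seed RNG seed (caller's RNG state is preserved).
#' @return A [connectivity_matrix()].
#' @export
sample_connectome <- function(profile, q = 84, f = 500000, seed = 1L) {
  stopifnot(inherits(profile, "group_profile"))
  if (q < 2 || f < 1) {
    abort("Need q >= 2 and f >= 1.", class = "connectoms_invalid_input")
  }
  with_local_seed(seed, {
    lat <- latent_structure(q, profile$n_modules)
    ut <- which(upper.tri(matrix(0, q, q)), arr.ind = TRUE)
    i <- ut[, 1]; j <- ut[, 2]
    same_block <- lat$block[i] == lat$block[j]
    # subject-specific support density, probabilities rescaled to match
    dens <- min(0.95, max(0.05,
                          rnorm(1, profile$target_density, profile$density_sd)))
    frac_within <- mean(same_block)
    implied <- frac_within * profile$p_within +
      (1 - frac_within) * profile$p_between
    sc <- dens / implied
    pw <- min(1, profile$p_within * sc)
    pb <- min(1, profile$p_between * sc)
    support <- stats::runif(length(i)) < ifelse(same_block, pw, pb)
    if (!any(support)) support[1] <- TRUE
    # latent intensities: modular contrast x hub propensity x tilt x jitter
    shape <- profile$weight_concentration
    lam <- rgamma(length(i), shape = shape, rate = shape) *
      ifelse(same_block, profile$weight_contrast, 1) *
      exp(profile$degree_spread * (lat$z[i] + lat$z[j])) *
      exp(profile$hub_tilt * lat$hub[i] * lat$hub[j]) *
      rlnorm(length(i), 0, profile$subject_sigma)
    lam[!support] <- 0
    counts <- as.numeric(rmultinom(1, size = f, prob = lam))
    m <- matrix(0, q, q)
    m[cbind(i, j)] <- counts
    m[cbind(j, i)] <- counts
    connectivity_matrix(m)
  })
}

#' Preset group profiles for the five subject groups
#'
#' Five profiles calibrated so that, on simulated cohorts at the default
#' group sizes, the direction of the group differences in the six metrics
#' matches the pattern reported for MS clinical courses: lower density in
#' the progressive courses (SP strongest), higher (less negative)
#' assortativity in SP and PP, lower modularity in CIS and higher in RR,
#' lower global efficiency and higher characteristic path length in all
#' patient groups, and negative assortativity in HC.
#'
#' @return Named list of five [group_profile()] objects
#'   (`HC`, `CIS`, `RR`, `SP`, `PP`).
#' @export
preset_profiles <- function() {
  list(
    HC = group_profile("HC"),
    CIS = group_profile("CIS", weight_contrast = 1.5, degree_spread = 1.15),
    RR = group_profile("RR", weight_contrast = 3.3, degree_spread = 1.05,
                       target_density = 0.56),
    SP = group_profile("SP", weight_contrast = 2.4, degree_spread = 0.95,
                       hub_tilt = 0.3, target_density = 0.52,
                       density_sd = 0.05),
    PP = group_profile("PP", weight_contrast = 2.3, degree_spread = 0.9,
                       hub_tilt = 0.15, target_density = 0.53,
                       density_sd = 0.075)
  )
}

#' Configure a synthetic cohort
#'
#' Defaults mirror the study conditions: 84 parcels, 500,000 streamlines per
#' subject, and group sizes HC 24, CIS 12, RR 24, SP 24, PP 17.
#'
#' @param q Number of parcels.
#' @param f Streamlines per subject.
#' @param n_per_group Named integer vector of subjects per group; names must
#'   match the supplied profiles.
#' @param profiles Named list of [group_profile()] objects.
#' @param seed Master seed; all subject seeds are derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(q = 84, f = 500000,
                          n_per_group = c(HC = 24, CIS = 12, RR = 24,
                                          SP = 24, PP = 17),
                          profiles = preset_profiles(), seed = 1L) {
  if (q < 2 || f < 1 || any(n_per_group < 1)) {
    abort("Need q >= 2, f >= 1, and group sizes >= 1.",
          class = "connectoms_invalid_input")
  }
  missing <- setdiff(names(n_per_group), names(profiles))
  if (length(missing) > 0) {
    abort(sprintf("No profile supplied for group(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "connectoms_invalid_input")
  }
  structure(list(q = q, f = f, n_per_group = n_per_group,
                 profiles = profiles, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample a full synthetic cohort
#'
#' Draws every group's subjects i.i.d. from its profile, with per-subject
#' child seeds derived deterministically from the master seed: the same
#' configuration always yields the identical cohort.
#'
#' @param config A [cohort_config()].
#' @return Cohort tibble: `subject_id`, `group` (factor over the configured
#'   groups in HC/CIS/RR/SP/PP order), `matrix` list-column of
#'   [connectivity_matrix()] objects.
#' @export
#'
#' @examples
#' cohort <- sample_cohort(cohort_config(
#'   q = 24, f = 5000, n_per_group = c(HC = 2, RR = 2), seed = 42
#' ))
#' cohort
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n_total <- length(groups)
  child_seeds <- with_local_seed(config$seed,
                                 sample.int(.Machine$integer.max - 1, n_total))
  ids <- unlist(purrr::map(names(config$n_per_group), function(g) {
    sprintf("%s%03d", g, seq_len(config$n_per_group[[g]]))
  }))
  lvls <- GROUP_LEVELS[GROUP_LEVELS %in% names(config$n_per_group)]
  if (length(lvls) == 0) lvls <- unique(groups)
  tibble(
    subject_id = ids,
    group = factor(groups, levels = lvls),
    matrix = purrr::map2(groups, child_seeds, function(g, s) {
      sample_connectome(config$profiles[[g]], q = config$q, f = config$f,
                        seed = s)
    })
  )
}

#' Write a cohort to disk as matrix files plus a manifest
#'
#' One tab-delimited matrix file per subject and a `manifest.csv`
#' (`subject_id`, `group`, `path`) that [read_cohort_manifest()] round-trips.
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(cohort$subject_id, ".tsv")
  purrr::walk2(cohort$matrix, files, function(m, f) {
    write_connectivity_matrix(m, file.path(dir, f))
  })
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(
    tibble(subject_id = cohort$subject_id,
           group = as.character(cohort$group), path = files),
    manifest
  )
  invisible(manifest)
}
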