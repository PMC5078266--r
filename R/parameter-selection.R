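#' Default threshold grid
#'
#' Thresholds from 0.05 to 1 in steps of 0.05 — the grid scanned when
#' choosing the binarization threshold.
#'
#' @return Numeric vector of 20 thresholds.
#' @export
default_tau_grid <- function() {
  round(seq(0.05, 1, by = 0.05), 10)
}

#' Default streamline-count grid
#'
#' 1000 to 10,000 every 1000, 10,000 to 100,000 every 10,000, and 100,000 to
#' 1,000,000 every 100,000 (28 distinct values) — the grid scanned when
#' choosing the tractography streamline count.
#'
#' @return Increasing integer vector of 28 fiber counts.
#' @export
default_fiber_grid <- function() {
  sort(unique(c(seq(1e3, 1e4, by = 1e3),
                seq(1e4, 1e5, by = 1e4),
                seq(1e5, 1e6, by = 1e5))))
}

#' Coefficient-of-variation curves across thresholds
#'
#' For every threshold in `tau_grid`, computes the five binarized-graph
#' metrics (`r`, `T`, `Eg`, `Q`, `CPL`) for each subject and their
#' across-subject coefficient of variation `CV = sd / |mean|`. Undefined
#' metric values are excluded from the CV with a count kept in the result.
#' The cohort's mean weighted-graph density is recorded for the rejection
#' rule of [select_threshold()].
#'
#' @param cohort Cohort tibble (with a `matrix` list-column) or a plain list
#'   of [connectivity_matrix()] objects; at least 2 subjects.
#' @param tau_grid Strictly increasing thresholds in `[0, 1]`.
#' @param n_restarts,seed Passed to [graph_modularity()].
#' @return A `threshold_scan`: tibble with columns `tau`, `metric`, `cv`,
#'   `n_used`, `n_excluded`, and attributes `mean_density` and `tau_grid`.
#' @export
metric_cv_curve <- function(cohort, tau_grid = default_tau_grid(),
                            n_restarts = 10, seed = 1L) {
  mats <- if (is.data.frame(cohort)) cohort$matrix else cohort
  if (length(mats) < 2) {
    abort("At least 2 subjects are needed to estimate a CV.",
          class = "connectoms_insufficient_cohort")
  }
  if (is.unsorted(tau_grid, strictly = TRUE) ||
      any(tau_grid < 0 | tau_grid > 1)) {
    abort("`tau_grid` must be strictly increasing within [0, 1].",
          class = "connectoms_range_error")
  }
  graphs <- purrr::map(mats, graph_from_matrix)
  mean_density <- mean(purrr::map_dbl(graphs, graph_density))
  per_tau <- purrr::map(tau_grid, function(tau) {
    vals <- suppressWarnings(purrr::map(graphs, function(g) {
      b <- proportional_threshold(g, tau)
      if (nrow(b$edges) == 0) {
        return(setNames(rep(NA_real_, 5), BINARY_METRIC_COLS))
      }
      c(r = graph_assortativity(b),
        T = graph_transitivity(b),
        Eg = global_efficiency(b),
        Q = graph_modularity(b, n_restarts = n_restarts, seed = seed)$Q,
        CPL = as.numeric(characteristic_path_length(b)))
    }))
    vm <- do.call(rbind, vals)
    purrr::map_dfr(BINARY_METRIC_COLS, function(met) {
      v <- vm[, met]
      ok <- !is.na(v)
      mu <- mean(v[ok])
      tibble(
        tau = tau, metric = met,
        cv = if (sum(ok) < 2 || abs(mu) < 1e-12) NA_real_ else sd(v[ok]) / abs(mu),
        n_used = sum(ok), n_excluded = sum(!ok)
      )
    })
  })
  scan <- dplyr::bind_rows(per_tau)
  excl <- sum(scan$n_excluded)
  if (excl > 0) {
    warn(sprintf("%d undefined metric values excluded from CV curves.", excl))
  }
  structure(scan, class = c("threshold_scan", class(scan)),
            mean_density = mean_density, tau_grid = tau_grid)
}

#' Select the binarization threshold from a CV scan
#'
#' Two criteria: (1) inter-subject variability of the metrics should be as
#' low as possible; (2) it should be stable over the threshold range.
#' Thresholds strictly greater than the cohort's mean weighted density are
#' rejected first (above that point thresholding no longer modifies the
#' graph's topology). Among the admissible thresholds, the smallest one
#' whose mean CV (averaged over the five metrics) lies within
#' `stability_tol` (relative) of the minimum mean CV is returned.
#'
#' @param scan A `threshold_scan` from [metric_cv_curve()].
#' @param stability_tol Relative tolerance defining the CV plateau
#'   (default 0.10).
#' @return The selected threshold, with attributes `mean_cv` (its mean CV)
#'   and `admissible` (the candidate thresholds).
#' @export
select_threshold <- function(scan, stability_tol = 0.10) {
  stopifnot(inherits(scan, "threshold_scan"))
  dens <- attr(scan, "mean_density")
  mean_cv <- scan |>
    dplyr::group_by(.data$tau) |>
    dplyr::summarise(mean_cv = mean(.data$cv, na.rm = TRUE), .groups = "drop")
  adm <- mean_cv[mean_cv$tau <= dens & is.finite(mean_cv$mean_cv), ]
  if (nrow(adm) == 0) {
    abort("No admissible threshold at or below the cohort mean density.",
          class = "connectoms_selection_failure")
  }
  lo <- min(adm$mean_cv)
  stable <- adm[adm$mean_cv <= lo * (1 + stability_tol), ]
  tau <- min(stable$tau)
  structure(tau,
            mean_cv = stable$mean_cv[stable$tau == tau],
            admissible = adm$tau)
}

#' Density as a function of the number of sampled streamlines
#'
#' Emulates the tractography streamline-count scan: for each fiber count `f`
#' in the grid, `n_subjects` connectivity matrices are drawn by distributing
#' `f` streamlines multinomially over node pairs in proportion to the base
#' weights, and the mean and SD of the weighted-graph density are recorded.
#' Density saturates at the base support density once every positive pair is
#' hit.
#'
#' @param base_weights A [connectivity_matrix()] with at least one positive
#'   entry, defining relative pair intensities.
#' @param f_grid Increasing positive fiber counts.
#' @param n_subjects Replicates per fiber count (default 20).
#' @param seed RNG seed.
#' @return A `fiber_scan` tibble: `f`, `mean_density`, `sd_density`.
#' @export
density_vs_fibers <- function(base_weights, f_grid = default_fiber_grid(),
                              n_subjects = 20, seed = 1L) {
  if (!inherits(base_weights, "connectivity_matrix")) {
    base_weights <- connectivity_matrix(base_weights)
  }
  q <- nrow(base_weights)
  w <- base_weights[upper.tri(base_weights)]
  if (sum(w) <= 0) {
    abort("`base_weights` must have at least one positive pair.",
          class = "connectoms_invalid_input")
  }
  n_pairs <- (q^2 - q) / 2
  scan <- with_local_seed(seed, {
    purrr::map_dfr(f_grid, function(f) {
      dens <- purrr::map_dbl(seq_len(n_subjects), function(s) {
        counts <- rmultinom(1, size = f, prob = w)
        sum(counts > 0) / n_pairs
      })
      tibble(f = f, mean_density = mean(dens), sd_density = sd(dens))
    })
  })
  structure(scan, class = c("fiber_scan", class(scan)))
}

#' Maximum spherical harmonics order for a diffusion acquisition
#'
#' The largest even order `h` whose number of coefficients stays below the
#' number of acquired diffusion directions: `(h+1)(h+2)/2 < d`. With 24
#' directions the admissible order is 4.
#'
#' @param d Number of diffusion gradient directions (>= 2).
#' @return Largest admissible even order (integer, >= 0).
#' @export
#'
#' @examples
#' max_sh_order(24) # 4
max_sh_order <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || d <= 1) {
    abort("`d` must be a single number >= 2 (no admissible order otherwise).",
          class = "connectoms_range_error")
  }
  h <- 0L
  while ((h + 3) * (h + 4) / 2 < d) h <- h + 2L
  h
}
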