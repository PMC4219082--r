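#' Specify a simulated cohort
#'
#' Defines the study conditions a labelled phantom cohort emulates: mild
#' subjects draw parenchyma around a healthy mode (29 HU), while severe,
#' delayed and deceased subjects add an edematous excess component centred
#' at the edematous tissue mode (24 HU) and concentrated inside HU 17--24,
#' worth `band_mass_shift` percentage points of expected band mass relative
#' to the mild group; the excess also moves the severe histogram peak from
#' the healthy towards the edematous mode. Delayed-edema subjects share the
#' severe generator (their initial distributions are indistinguishable from
#' overt severe edema); deceased subjects do too. Between-subject
#' variability mirrors the anatomy real cohorts vary in: the parenchymal
#' mode (`subject_mode_sd`, HU) and width, the CSF and blood mixture
#' weights (coefficients of variation `subject_csf_cv`, `subject_blood_cv`),
#' a percentage-point jitter of the in-band mass (`subject_band_sd`), and a
#' fine-grained multiplicative per-bin roughness (`subject_bin_cv`)
#' capturing textural heterogeneity (partial-volume effects, focal lesions)
#' that smooth mixtures miss.
#'
#' @param n_mild,n_severe,n_delayed,n_deceased Subject counts per group.
#' @param mild_tissue_mode,severe_tissue_mode Healthy parenchymal mode and
#'   edematous-excess centre, in HU.
#' @param band_mass_shift Target difference (percentage points) in expected
#'   HU 17--24 mass between the severe-type and mild generators.
#' @param slices_per_subject CT images per examination.
#' @param pixels_per_slice Retained intracranial pixels per image.
#' @param subject_mode_sd,subject_band_sd,subject_csf_cv,subject_blood_cv,subject_bin_cv
#'   Between-subject variability parameters.
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mild = 30L, n_severe = 30L, n_delayed = 0L,
                        n_deceased = 0L, mild_tissue_mode = 29,
                        severe_tissue_mode = 24, band_mass_shift = 8,
                        slices_per_subject = 10L, pixels_per_slice = 20000L,
                        subject_mode_sd = 0.6, subject_band_sd = 1.5,
                        subject_csf_cv = 0.25, subject_blood_cv = 0.4,
                        subject_bin_cv = 0.2, seed = 1L) {
  counts <- c(n_mild, n_severe, n_delayed, n_deceased)
  if (any(counts < 0) || sum(counts) == 0) {
    ctces_abort("Cohort needs non-negative counts and at least one subject.",
                "ctces_error_spec")
  }
  if (mild_tissue_mode < 0 || mild_tissue_mode > 79 ||
      severe_tissue_mode < 0 || severe_tissue_mode > 79) {
    ctces_abort("Tissue modes must lie in HU 0-79.", "ctces_error_spec")
  }
  structure(list(n_mild = as.integer(n_mild), n_severe = as.integer(n_severe),
                 n_delayed = as.integer(n_delayed),
                 n_deceased = as.integer(n_deceased),
                 mild_tissue_mode = mild_tissue_mode,
                 severe_tissue_mode = severe_tissue_mode,
                 band_mass_shift = band_mass_shift,
                 slices_per_subject = as.integer(slices_per_subject),
                 pixels_per_slice = as.integer(pixels_per_slice),
                 subject_mode_sd = subject_mode_sd,
                 subject_band_sd = subject_band_sd,
                 subject_csf_cv = subject_csf_cv,
                 subject_blood_cv = subject_blood_cv,
                 subject_bin_cv = subject_bin_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

band_mass <- function(pmf, band = c(17L, 24L)) {
  sum(pmf[(band[1]:band[2]) + 1L])
}

# Edematous excess component: a discrete normal centred at the edematous
# tissue mode, softly truncated to the HU 17-24 band (logistic edges) so the
# excess mass the generator injects is concentrated in the discriminative
# band rather than spread across the whole distribution.
edema_bump <- function(mode = 24, band = c(17L, 24L), edge_scale = 1.2) {
  hu <- 0:79
  soft <- stats::plogis((hu - (band[1] - 0.5)) / edge_scale) *
    stats::plogis(((band[2] + 0.5) - hu) / edge_scale)
  w <- stats::dnorm(hu, mode, 3) * soft
  w / sum(w)
}

# Move `delta` (probability) of mass into the band by blending in the bump:
# out = (pmf + q * bump) / (1 + q), with q solving band(out) = band(pmf) +
# delta. Outside the band this is a diffuse proportional down-weighting, so
# the group difference stays concentrated where the bump lives. Works for
# small negative delta too (mass drained from the band).
add_band_mass <- function(pmf, delta, bump, band = c(17L, 24L)) {
  if (delta == 0) return(pmf)
  b <- band_mass(bump, band)
  cur <- band_mass(pmf, band)
  denom <- b - cur - delta
  if (denom <= 0.05) delta <- b - cur - 0.05  # clamp: cannot exceed bump mass
  q <- delta / (b - cur - delta)
  out <- pmax(pmf + q * bump, 0) / (1 + q)
  out / sum(out)
}

# Group-level pmfs: the severe-type generator is the mild mixture plus an
# edematous excess of exactly `band_mass_shift` percentage points inside
# HU 17-24, centred at `severe_tissue_mode`; this also moves the overall
# histogram peak from the healthy mode towards the edematous one.
cohort_group_pmfs <- function(cspec) {
  mild <- tissue_mixture(mode = cspec$mild_tissue_mode)$pmf
  bump <- edema_bump(mode = cspec$severe_tissue_mode)
  severe <- add_band_mass(mild, cspec$band_mass_shift / 100, bump)
  list(mild = mild, severe = severe, bump = bump)
}

# One subject's expected HU distribution: anatomy parameters are drawn
# around the cohort's central values, then the edematous excess (zero for
# mild subjects, `band_mass_shift` for severe-type subjects, plus jitter) is
# blended in. The pinning of the band mass makes `band_mass_shift` exactly
# the expected CES difference between the groups.
subject_pmf <- function(cspec, severe_type, bump) {
  mode <- stats::rnorm(1, cspec$mild_tissue_mode, cspec$subject_mode_sd)
  width <- max(3, stats::rnorm(1, 5, 0.4))
  cw <- min(0.12 * exp(stats::rnorm(1, 0, cspec$subject_csf_cv)), 0.35)
  bw <- min(0.05 * exp(stats::rnorm(1, 0, cspec$subject_blood_cv)), 0.25)
  p <- tissue_mixture(mode = mode, tissue_sd = width,
                      csf_weight = cw, blood_weight = bw)$pmf
  rough <- exp(stats::rnorm(80, 0, cspec$subject_bin_cv))
  p <- p * rough / sum(p * rough)
  delta <- (if (severe_type) cspec$band_mass_shift else 0) +
    stats::rnorm(1, 0, cspec$subject_band_sd)
  add_band_mass(p, delta / 100, bump)
}

#' Simulate a labelled phantom cohort
#'
#' Draws, per subject, a subject-specific HU distribution (group generator
#' plus between-subject jitter) and then `slices_per_subject` multinomial
#' CT images of `pixels_per_slice` retained pixels each, averaged into a
#' series distribution exactly as the densitometry module would. This
#' distribution-level sampling is statistically equivalent to rendering full
#' phantom slices and segmenting them perfectly; set `render = TRUE` to
#' additionally rasterise full [make_series()] image stacks (slow, intended
#' for small cohorts and end-to-end pipeline checks).
#'
#' @param cspec A [cohort_spec()].
#' @param render Also render pixel-level phantom series per subject.
#' @return A list of class `phantom_cohort`: `manifest` tibble (subject_id,
#'   group, true_ces, true_mces), `distributions` (named list of series
#'   distributions), `subjects` (subjects x 80 matrix), and optionally
#'   `series` (named list of rendered series with truths).
#' @export
simulate_cohort <- function(cspec, render = FALSE) {
  stopifnot(inherits(cspec, "cohort_spec"))
  pmfs <- cohort_group_pmfs(cspec)
  groups <- c(rep("mild", cspec$n_mild), rep("severe", cspec$n_severe),
              rep("delayed", cspec$n_delayed), rep("deceased", cspec$n_deceased))
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  dists <- vector("list", n)
  series <- if (render) vector("list", n) else NULL
  true_ces <- true_mces <- numeric(n)
  # one RNG stream for the whole cohort: sequentially derived per-subject
  # seeds would correlate the first draws of neighbouring streams and break
  # group exchangeability under the null
  withr::with_seed(cspec$seed, {
    for (i in seq_len(n)) {
      sp <- subject_pmf(cspec, severe_type = groups[i] != "mild", pmfs$bump)
      true_ces[i] <- 100 * band_mass(sp, c(17L, 24L))
      true_mces[i] <- 100 * band_mass(sp, c(19L, 23L))
      slice_dists <- purrr::map(seq_len(cspec$slices_per_subject), function(k) {
        counts <- stats::rmultinom(1, cspec$pixels_per_slice, sp)[, 1]
        new_density_distribution(100 * counts / sum(counts), "slice",
                                 n_images = 1L, n_pixels = sum(counts))
      })
      dists[[i]] <- series_distribution(slice_dists)
      if (render) {
        tm <- tissue_mixture()
        tm$pmf <- sp
        tm$components <- list(list(name = "tissue", weight = 1,
                                   support = 0:79, pmf = sp))
        series[[i]] <- make_series(
          phantom_spec(grid = 256L, tissue_model = tm,
                       seed = derive_seed(cspec$seed, 100000L + i)),
          n_slices = min(cspec$slices_per_subject, 3L))
      }
    }
  })
  names(dists) <- ids
  if (render) names(series) <- ids
  structure(list(
    manifest = tibble(subject_id = ids, group = groups,
                      true_ces = true_ces, true_mces = true_mces),
    distributions = dists,
    subjects = {
      m <- t(vapply(dists, function(d) d$proportion, numeric(80)))
      colnames(m) <- 0:79
      rownames(m) <- ids
      m
    },
    series = series, spec = cspec),
    class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$group)),
                            table(x$manifest$group)), collapse = ", ")))
  invisible(x)
}
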