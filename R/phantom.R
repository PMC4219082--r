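# Seed derivation: subsets of a simulation are reproducible because every
# slice/subject gets its own seed from the master seed by a fixed counter
# scheme (kept below 2^31 - 1).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 97003 * as.numeric(k)) %% 2147483647)
}

# Discrete truncated normal pmf on an integer support.
discrete_tnorm <- function(mean, sd, support) {
  w <- stats::dnorm(support, mean, sd)
  w / sum(w)
}

#' Intracranial tissue mixture model
#'
#' Hounsfield-Unit mixture the phantoms draw intracranial pixels from, built
#' from the standard HU anatomy of the intracranial space: CSF occupies
#' roughly 0--15 HU, normal parenchyma sits below 40 HU (the mixture mode),
#' and blood products reach up to just below 80 HU. Each component is a
#' discrete truncated normal on integer HU.
#'
#' @param mode Parenchymal mode in HU (about 29 in healthy tissue; edema
#'   shifts it down).
#' @param tissue_sd Parenchymal spread in HU.
#' @param csf_weight,blood_weight Mixture weights of the CSF and blood
#'   components (parenchyma takes the remainder).
#' @return List with `pmf` (length-80 probability vector over HU 0..79) and
#'   `components` (name, weight, support, pmf per component).
#' @export
tissue_mixture <- function(mode = 29, tissue_sd = 5,
                           csf_weight = 0.12, blood_weight = 0.05) {
  stopifnot(mode >= 0, mode <= 79, csf_weight + blood_weight < 1)
  comps <- list(
    list(name = "csf", weight = csf_weight, support = 0:15,
         pmf = discrete_tnorm(8, 4, 0:15)),
    list(name = "tissue", weight = 1 - csf_weight - blood_weight,
         support = 0:79, pmf = discrete_tnorm(mode, tissue_sd, 0:79)),
    list(name = "blood", weight = blood_weight, support = 16:79,
         pmf = discrete_tnorm(55, 8, 16:79)))
  pmf <- numeric(80)
  for (cm in comps) pmf[cm$support + 1L] <- pmf[cm$support + 1L] + cm$weight * cm$pmf
  list(pmf = pmf, components = comps)
}

#' Specify a synthetic head phantom
#'
#' Describes one axial head-CT slice: an elliptical cranial shell (bone HU
#' 1000) around a tissue interior, a scalp ring outside it, and optional
#' fracture gaps, craniotomy arcs, EVD catheter, air bubble and
#' scanner-gantry arc. Geometry defaults mimic a 512 x 512 axial field of
#' view. Angles follow the ray convention: 0 degrees points towards row 1,
#' increasing towards larger columns.
#'
#' @param grid Grid size (square, pixels).
#' @param center Ellipse center (row, col); default grid center.
#' @param semi_axes Ellipse semi-axes (row, col) in pixels.
#' @param shell_thickness Cranial shell thickness in pixels (>= 2).
#' @param bone_hu,metal_hu,air_hu Fixed HU of bone, metal and air.
#' @param scalp_thickness Scalp ring thickness in pixels.
#' @param scalp_hu Integer HU range the scalp is drawn from.
#' @param tissue_model A [tissue_mixture()].
#' @param fractures Data frame with `angle_deg`, `width_px`: small shell gaps.
#' @param craniotomy Data frame with `start_deg`, `span_deg`: large defects.
#' @param evd,air_bubble,gantry Logical artifact flags.
#' @param seed Integer seed; phantoms are bit-reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = 512L, center = NULL, semi_axes = NULL,
                         shell_thickness = 6, bone_hu = 1000L,
                         metal_hu = 3000L, air_hu = -1000L,
                         scalp_thickness = 10, scalp_hu = c(30L, 60L),
                         tissue_model = tissue_mixture(),
                         fractures = NULL, craniotomy = NULL,
                         evd = FALSE, air_bubble = FALSE, gantry = FALSE,
                         seed = 1L) {
  grid <- as.integer(grid)
  center <- center %||% c((grid + 1) / 2, (grid + 1) / 2)
  semi_axes <- semi_axes %||% (c(0.39, 0.32) * grid)
  if (shell_thickness < 2) {
    ctces_abort("Shell thickness must be at least 2 px.", "ctces_error_spec")
  }
  if (any(center - semi_axes - scalp_thickness < 1) ||
      any(center + semi_axes + scalp_thickness > grid)) {
    ctces_abort("Phantom geometry must fit inside the grid.", "ctces_error_spec")
  }
  structure(list(grid = grid, center = center, semi_axes = semi_axes,
                 shell_thickness = shell_thickness, bone_hu = as.integer(bone_hu),
                 metal_hu = as.integer(metal_hu), air_hu = as.integer(air_hu),
                 scalp_thickness = scalp_thickness,
                 scalp_hu = as.integer(scalp_hu),
                 tissue_model = tissue_model,
                 fractures = fractures, craniotomy = craniotomy,
                 evd = isTRUE(evd), air_bubble = isTRUE(air_bubble),
                 gantry = isTRUE(gantry), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Pixel angle in the ray convention; radians in [0, 2*pi).
pixel_angle <- function(rr, cc, center) {
  (atan2(cc - center[2], center[1] - rr)) %% (2 * pi)
}

in_angular_window <- function(theta, start_rad, span_rad) {
  ((theta - start_rad) %% (2 * pi)) <= span_rad
}

#' Render a phantom slice with ground truth
#'
#' Deterministic for a fixed seed. The truth carries the intracranial mask,
#' a per-class label grid (background, scalp, bone, csf, tissue, blood,
#' artifact) partitioning the image, and the exact HU distribution of the
#' in-bounds intracranial pixels.
#'
#' @param spec A [phantom_spec()].
#' @return List with `slice` (a [ct_slice()]) and `truth` (list:
#'   `intracranial_mask`, `class` character matrix, `true_distribution`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  rr <- matrix(seq_len(g), g, g)
  cc <- matrix(seq_len(g), g, g, byrow = TRUE)
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  ctr <- spec$center
  s <- sqrt(((rr - ctr[1]) / a)^2 + ((cc - ctr[2]) / b)^2)
  mean_r <- mean(c(a, b))
  s_in <- 1 - spec$shell_thickness / mean_r
  s_out <- 1 + spec$scalp_thickness / mean_r
  bone <- s > s_in & s <= 1
  interior <- s <= s_in
  scalp <- s > 1 & s <= s_out
  theta <- pixel_angle(rr, cc, ctr)
  # local ellipse radius, used to convert fracture widths to angles
  r_theta <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (!is.null(spec$fractures) && nrow(spec$fractures) > 0) {
    for (i in seq_len(nrow(spec$fractures))) {
      w <- spec$fractures$width_px[i]
      if (w <= 0) next
      ang <- spec$fractures$angle_deg[i] * pi / 180
      half <- w / (2 * r_theta)
      bone[bone & in_angular_window(theta, (ang - half) %% (2 * pi), 2 * half)] <- FALSE
    }
  }
  if (!is.null(spec$craniotomy) && nrow(spec$craniotomy) > 0) {
    for (i in seq_len(nrow(spec$craniotomy))) {
      sp <- spec$craniotomy$span_deg[i]
      if (sp <= 0) next
      st <- spec$craniotomy$start_deg[i] * pi / 180
      win <- in_angular_window(theta, st, sp * pi / 180)
      bone[bone & win] <- FALSE
      scalp[scalp & win] <- FALSE  # craniotomy removes the overlying flap too
    }
  }
  px <- matrix(spec$air_hu, g, g)
  cls <- matrix("background", g, g)
  withr::with_seed(spec$seed, {
    px[scalp] <- sample(spec$scalp_hu[1]:spec$scalp_hu[2], sum(scalp),
                        replace = TRUE)
    cls[scalp] <- "scalp"
    px[bone] <- spec$bone_hu
    cls[bone] <- "bone"
    n_int <- sum(interior)
    comps <- spec$tissue_model$components
    comp_idx <- sample(seq_along(comps), n_int, replace = TRUE,
                       prob = vapply(comps, `[[`, numeric(1), "weight"))
    vals <- integer(n_int)
    for (j in seq_along(comps)) {
      sel <- comp_idx == j
      if (any(sel)) {
        vals[sel] <- sample(comps[[j]]$support, sum(sel), replace = TRUE,
                            prob = comps[[j]]$pmf)
      }
    }
    px[interior] <- vals
    cls[interior] <- vapply(comps, `[[`, character(1), "name")[comp_idx]
    if (spec$evd) {
      ang <- 30 * pi / 180
      rads <- seq(0.25, 0.85, by = 1 / mean_r) * s_in * mean_r
      for (off in c(-1, 0, 1)) {
        er <- round(ctr[1] - rads * cos(ang)) + ifelse(abs(cos(ang)) < 0.5, off, 0L)
        ec <- round(ctr[2] + rads * sin(ang)) + ifelse(abs(cos(ang)) < 0.5, 0L, off)
        ok <- er >= 1 & er <= g & ec >= 1 & ec <= g
        idx <- cbind(er[ok], ec[ok])
        sel <- interior[idx]
        px[idx[sel, , drop = FALSE]] <- spec$metal_hu
        cls[idx[sel, , drop = FALSE]] <- "artifact"
      }
    }
    if (spec$air_bubble) {
      bc <- ctr + c(0.35 * a, -0.2 * b)
      bub <- interior & ((rr - bc[1])^2 + (cc - bc[2])^2) <= 16
      px[bub] <- spec$air_hu
      cls[bub] <- "artifact"
    }
    if (spec$gantry) {
      gr <- sqrt((rr - (g + 1) / 2)^2 + (cc - (g + 1) / 2)^2)
      arc <- gr >= 0.52 * g & gr <= 0.52 * g + 5 &
        in_angular_window(pixel_angle(rr, cc, c((g + 1) / 2, (g + 1) / 2)),
                          120 * pi / 180, 120 * pi / 180) &
        cls == "background"
      px[arc] <- 200L
      cls[arc] <- "artifact"
    }
  })
  storage.mode(px) <- "integer"
  slice <- ct_slice(px, source_id = sprintf("phantom-seed-%d", spec$seed))
  inb <- interior & px >= 0L & px <= 79L
  truth <- list(intracranial_mask = interior, class = cls,
                true_distribution = distribution_from_pixels(px[inb]))
  list(slice = slice, truth = truth)
}

#' Render a phantom series
#'
#' Stacks `n_slices` phantoms with the cranial cross-section scaled along
#' the vertex-to-caudal axis (small at the vertex, full size caudally); each
#' slice draws from its own derived seed.
#'
#' @param spec A [phantom_spec()] describing the caudal (largest) slice.
#' @param n_slices Number of slices (>= 1).
#' @return List with `series` (a [ct_series()]) and `truths` (per-slice
#'   truth lists).
#' @export
make_series <- function(spec, n_slices = 5L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_slices < 1L) {
    ctces_abort("A series needs at least one slice.", "ctces_error_spec")
  }
  scale <- if (n_slices == 1L) 1 else
    seq(0.55, 1, length.out = n_slices)
  out <- purrr::map(seq_len(n_slices), function(k) {
    sk <- spec
    sk$semi_axes <- spec$semi_axes * scale[k]
    sk$seed <- derive_seed(spec$seed, k - 1L)  # slice 0 reuses the master seed
    ph <- make_phantom(sk)
    ph$slice$slice_index <- k - 1L
    ph
  })
  list(series = ct_series(purrr::map(out, "slice"),
                          subject_id = sprintf("phantom-%d", spec$seed)),
       truths = purrr::map(out, "truth"))
}
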