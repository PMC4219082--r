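#' Segmentation configuration
#'
#' Tunable parameters of the artifact-elimination pipeline. Defaults: cranial
#' bone is any pixel at or above 150 HU (far above the 0--79 intracranial
#' range, far below metal); 720 rays (0.5 degree resolution) probe the shell
#' for discontinuities; angular gaps up to 15 degrees are treated as
#' fractures and bridged locally, wider ones as craniotomy-scale defects and
#' closed by mirror symmetry; interiors under 100 px are considered too small
#' for stable proportion estimates and excluded from series averaging.
#'
#' @param bone_threshold HU at or above which a pixel counts as cranial bone.
#' @param ray_count Number of rays cast from the centroid for gap detection.
#' @param max_gap_deg Largest angular gap (degrees) sealed as a fracture.
#' @param min_interior_px Smallest interior (pixels) kept in series averages.
#' @param hu_lo,hu_hi Inclusive HU boundary condition for retained pixels.
#' @param background_hu Fill value for eliminated pixels.
#' @param body_threshold HU above which a pixel belongs to a solid object
#'   (used when removing gantry/head-rest components).
#' @return A list of class `segment_config`.
#' @export
segment_config <- function(bone_threshold = 150, ray_count = 720L,
                           max_gap_deg = 15, min_interior_px = 100L,
                           hu_lo = 0L, hu_hi = 79L,
                           background_hu = -1024L, body_threshold = -500) {
  structure(list(bone_threshold = bone_threshold,
                 ray_count = as.integer(ray_count),
                 max_gap_deg = max_gap_deg,
                 min_interior_px = as.integer(min_interior_px),
                 hu_lo = as.integer(hu_lo), hu_hi = as.integer(hu_hi),
                 background_hu = as.integer(background_hu),
                 body_threshold = body_threshold),
            class = "segment_config")
}

#' Detect the cranial shell
#'
#' Thresholds the slice at `bone_threshold` and keeps the connected
#' components (8-connected) forming the cranial shell. Components touching
#' the grid border (gantry ring, head rest) are excluded; among the rest, a
#' fractured or craniotomised shell may consist of several arcs, so every
#' component lying at shell radius from the estimated shell center is kept.
#' Metal artifacts (EVD, ICP probes) form clusters deep inside the shell
#' radius and are rejected; an empty mask is a valid result meaning no
#' cranium is present.
#'
#' @param slice A [ct_slice()].
#' @param bone_threshold HU threshold for bone.
#' @return Logical matrix marking cranial-bone pixels.
#' @export
detect_cranium <- function(slice, bone_threshold = 150) {
  stopifnot(inherits(slice, "ct_slice"))
  mask <- slice$pixels >= bone_threshold
  if (!any(mask)) return(mask)
  lab <- label_components(mask, 8L)
  nlab <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nlab)
  border <- vapply(seq_len(nlab), function(i) touches_border(lab == i),
                   logical(1))
  cand <- which(!border)
  if (length(cand) == 0L) return(mask & FALSE)
  if (length(cand) == 1L) return(lab == cand)
  union_mask <- matrix(lab %in% cand, nrow(mask), ncol(mask))
  center <- shell_center(union_mask, mask_centroid(union_mask))
  nr <- nrow(mask)
  radius_of <- function(idx) {
    sqrt((((idx - 1L) %% nr) + 1L - center[1])^2 +
           (((idx - 1L) %/% nr) + 1L - center[2])^2)
  }
  mean_radius <- vapply(cand, function(i) mean(radius_of(which(lab == i))),
                        numeric(1))
  r_ref <- mean_radius[which.max(sizes[cand])]  # largest arc is always shell
  keep <- cand[mean_radius >= 0.75 * r_ref]
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Remove scanner-gantry and head-rest components
#'
#' Any solid connected component (above `body_threshold` HU, 8-connected)
#' that touches the grid border and is disjoint from the cranial component is
#' part of the scanner, not the patient, and is replaced with background HU.
#' The operation is idempotent.
#'
#' @param slice A [ct_slice()].
#' @param bone_mask Cranial mask from [detect_cranium()].
#' @param background_hu Fill value for removed pixels.
#' @param body_threshold Solid-object HU threshold.
#' @return A new [ct_slice()] with gantry pixels blanked.
#' @export
remove_gantry <- function(slice, bone_mask, background_hu = -1024L,
                          body_threshold = -500) {
  stopifnot(inherits(slice, "ct_slice"))
  solid <- slice$pixels > body_threshold
  if (!any(solid)) return(slice)
  lab <- label_components(solid, 8L)
  nlab <- max(lab)
  cranial_ids <- unique(lab[bone_mask & lab > 0L])
  px <- slice$pixels
  for (i in seq_len(nlab)) {
    if (i %in% cranial_ids) next
    comp <- lab == i
    if (touches_border(comp)) px[comp] <- as.integer(background_hu)
  }
  out <- slice
  out$pixels <- px
  out
}

#' Coordinate the cranial structure into quadrants
#'
#' Places the origin at the centroid of the cranial interior (the bone pixels
#' themselves when the shell is still open) and splits the grid into four
#' quadrants by the image-aligned axes through it. The quadrants anchor the
#' fracture search and the mirror symmetry used for craniotomy sealing.
#'
#' @param slice A [ct_slice()].
#' @param bone_mask Cranial mask from [detect_cranium()].
#' @return A `quadrant_frame` with fields `centroid` (row, col) and grid size.
#' @export
assign_quadrants <- function(slice, bone_mask) {
  if (!any(bone_mask)) {
    ctces_abort("No cranium detected; cannot assign quadrants.",
                "ctces_error_no_cranium")
  }
  interior <- enclosed_interior(bone_mask)
  if (any(interior)) {
    # jagged shell edges can trap single-pixel pockets; only a substantial
    # largest component counts as the true interior
    lab <- label_components(interior, 4L)
    main <- which.max(tabulate(lab[lab > 0L], max(lab)))
    interior <- lab == main
    if (sum(interior) < 100L) interior[] <- FALSE
  }
  centroid <- if (any(interior)) mask_centroid(interior)
    else shell_center(bone_mask, mask_centroid(bone_mask))
  structure(list(centroid = centroid,
                 nrow = nrow(bone_mask), ncol = ncol(bone_mask)),
            class = "quadrant_frame")
}

#' @rdname assign_quadrants
#' @param frame A `quadrant_frame`.
#' @param row,col Pixel coordinates (vectorised, 1-based).
#' @return `quadrant_of()`: integer quadrant 1--4 for each pixel (1 = upper
#'   right, counter-clockwise), a partition of the grid.
#' @export
quadrant_of <- function(frame, row, col) {
  up <- row < frame$centroid[1]
  right <- col >= frame$centroid[2]
  ifelse(up & right, 1L, ifelse(up & !right, 2L, ifelse(!up & !right, 3L, 4L)))
}

# Center of an open (fractured/craniotomised) shell. The raw pixel centroid
# is biased away from missing arcs, which would skew the mirror axes used
# for axisymmetric sealing; instead the center is refined by averaging
# midpoints of diameters whose two first-hit points both exist -- an
# unbiased, linearly convergent estimator for a symmetric shell.
shell_center <- function(mask, start, n_iter = 30L, n_rays = 360L,
                         tol = 0.05) {
  ctr <- start
  half <- n_rays %/% 2L
  for (it in seq_len(n_iter)) {
    rays <- cast_rays(mask, ctr, n_rays)
    j <- which(rays$hit[1:half] & rays$hit[(1:half) + half])
    if (length(j) < 10L) break
    th <- rays$theta[j]
    r1 <- rays$radius[j]; r2 <- rays$radius[j + half]
    new_ctr <- c(ctr[1] - mean((r1 - r2) * cos(th)) / 2,
                 ctr[2] + mean((r1 - r2) * sin(th)) / 2)
    done <- sqrt(sum((new_ctr - ctr)^2)) < tol
    ctr <- new_ctr
    if (done) break
  }
  ctr
}

# Cast `n_rays` rays from the centroid and record, per ray, whether any mask
# pixel is met and the first-hit radius. Angle convention: theta = 0 points
# towards row 1 ("up"), increasing towards larger columns.
cast_rays <- function(mask, centroid, n_rays = 720L, step = 0.5) {
  nr <- nrow(mask); nc <- ncol(mask)
  theta <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  rmax <- sqrt(max(centroid[1] - 1, nr - centroid[1])^2 +
                 max(centroid[2] - 1, nc - centroid[2])^2)
  radii <- seq(step, rmax, by = step)
  rr <- round(centroid[1] - outer(radii, cos(theta)))
  cc <- round(centroid[2] + outer(radii, sin(theta)))
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  hitm <- matrix(FALSE, length(radii), n_rays)
  hitm[ok] <- mask[(cc[ok] - 1) * nr + rr[ok]]
  hit <- colSums(hitm) > 0L
  radius <- rep(NA_real_, n_rays)
  if (any(hit)) {
    radius[hit] <- radii[apply(hitm[, hit, drop = FALSE], 2, which.max)]
  }
  list(theta = theta, hit = hit, radius = radius, n = n_rays)
}

# Maximal circular runs of rays meeting no mask pixel, as lists of ray indices.
gap_runs <- function(hit) {
  n <- length(hit)
  if (all(hit)) return(list())
  if (!any(hit)) return(list(seq_len(n)))
  s <- which(hit)[1]
  idx <- ((seq_len(n) + s - 2L) %% n) + 1L  # rotation starting at a hit ray
  r <- rle(hit[idx])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(!r$values), function(k) idx[starts[k]:ends[k]])
}

# Rasterise pseudo-cranial pixels along an angular window. `theta`/`radius`
# are parallel vectors of control points; angles are supersampled 3x and
# radii carried radially with the given thickness so the resulting band is
# tight against 4-connected leaks.
rasterize_band <- function(nr, nc, centroid, theta, radius, thickness = 3) {
  if (length(theta) >= 2L) {
    tfine <- seq(1, length(theta), by = 1 / 3)
    th <- stats::approx(seq_along(theta), theta, xout = tfine)$y
    rad <- stats::approx(seq_along(theta), radius, xout = tfine)$y
  } else {
    th <- theta; rad <- radius
  }
  offs <- seq(-(thickness - 1) / 2, (thickness - 1) / 2, by = 0.5)
  rads <- as.vector(outer(rad, offs, `+`))
  ths <- rep(th, times = length(offs))
  keep <- rads > 0
  rr <- round(centroid[1] - rads[keep] * cos(ths[keep]))
  cc <- round(centroid[2] + rads[keep] * sin(ths[keep]))
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  out <- matrix(FALSE, nr, nc)
  out[cbind(rr[ok], cc[ok])] <- TRUE
  out
}

interior_from_centroid <- function(sealed, centroid) {
  seed <- (round(centroid[2]) - 1L) * nrow(sealed) + round(centroid[1])
  flood_fill4(!sealed, seed)
}

is_closed_shell <- function(sealed, centroid) {
  reg <- interior_from_centroid(sealed, centroid)
  any(reg) && !touches_border(reg)
}

new_cranial_shell <- function(bone, pseudo, frame, ray_count) {
  pseudo <- pseudo & !bone
  sealed <- bone | pseudo
  structure(list(bone_mask = bone, pseudo_mask = pseudo, sealed_mask = sealed,
                 frame = frame, ray_count = ray_count,
                 closed = is_closed_shell(sealed, frame$centroid)),
            class = "cranial_shell")
}

# Pinhole fractures narrower than the ray resolution can evade the angular
# scan while still leaking a 4-connected path. Morphological closing with
# growing structuring elements plugs them; the added pixels are
# pseudo-cranial like any other seal. No-op on closed shells, and a wide
# craniotomy arc is untouched (closing cannot bridge it).
plug_pinholes <- function(shell) {
  if (shell$closed) return(shell)
  base <- shell
  for (sz in c(3L, 5L, 7L)) {
    closed_mask <- EBImage::closing(shell$sealed_mask * 1,
                                    EBImage::makeBrush(sz, "box")) > 0
    pseudo <- shell$pseudo_mask | (closed_mask & !shell$sealed_mask)
    cand <- new_cranial_shell(shell$bone_mask, pseudo, shell$frame,
                              shell$ray_count)
    if (cand$closed) return(cand)
    if (sz == 3L) base <- cand  # keep small plugs even when a wide arc stays open
  }
  base
}

#' Seal fracture gaps with pseudo-cranial pixels
#'
#' Probes the shell with rays from the centroid; a fracture is a maximal
#' angular run of rays meeting no cranial pixel. Runs no wider than
#' `max_gap_deg` are bridged with temporary pseudo-cranial pixels whose radii
#' interpolate between the intact shell on either side. Wider defects
#' (craniotomies) are left for [seal_large_defects()]. Pseudo-cranial pixels
#' never overlap bone and never enter any HU statistic.
#'
#' @param bone_mask Cranial mask from [detect_cranium()].
#' @param frame A `quadrant_frame` from [assign_quadrants()].
#' @param max_gap_deg Largest angular gap sealed here.
#' @param ray_count Number of probe rays.
#' @return A `cranial_shell` with `bone_mask`, `pseudo_mask`, `sealed_mask`
#'   and a `closed` flag.
#' @export
seal_fractures <- function(bone_mask, frame, max_gap_deg = 15,
                           ray_count = 720L) {
  if (!any(bone_mask)) {
    ctces_abort("Cannot seal an empty shell.", "ctces_error_no_cranium")
  }
  nr <- nrow(bone_mask); nc <- ncol(bone_mask)
  rays <- cast_rays(bone_mask, frame$centroid, ray_count)
  runs <- gap_runs(rays$hit)
  pseudo <- matrix(FALSE, nr, nc)
  deg_per_ray <- 360 / ray_count
  for (run in runs) {
    if (length(run) * deg_per_ray > max_gap_deg) next
    before <- ((run[1] - 2L) %% ray_count) + 1L
    after <- ((run[length(run)] %% ray_count)) + 1L
    if (!rays$hit[before] || !rays$hit[after]) next
    k <- seq_along(run)
    # unwrap angles across the run so interpolation crosses 0 correctly
    th0 <- rays$theta[before]
    th <- th0 + k * deg_per_ray * pi / 180
    rad <- rays$radius[before] +
      (rays$radius[after] - rays$radius[before]) * k / (length(run) + 1)
    pseudo <- pseudo | rasterize_band(nr, nc, frame$centroid,
                                      c(th0, th, th0 + (length(run) + 1) *
                                          deg_per_ray * pi / 180),
                                      c(rays$radius[before], rad,
                                        rays$radius[after]))
  }
  plug_pinholes(new_cranial_shell(bone_mask, pseudo, frame, ray_count))
}

#' Seal craniotomy-scale defects by pseudo-axisymmetry
#'
#' For every ray from the centroid that still meets no cranial (or
#' pseudo-cranial) pixel, a pseudo-cranial pixel is generated at the radius
#' found on the ray mirrored across the vertical axis of the quadrant frame
#' (the anatomical midline), falling back to the horizontal axis when the
#' mirror ray is itself open. If both mirrors are open the cranium is
#' unsealable and an error of class `ctces_error_unsealable` is raised.
#' Already-closed shells pass through unchanged.
#'
#' @param shell A `cranial_shell` from [seal_fractures()].
#' @param frame The `quadrant_frame` used for mirroring.
#' @return A closed `cranial_shell`.
#' @export
seal_large_defects <- function(shell, frame) {
  stopifnot(inherits(shell, "cranial_shell"))
  n <- shell$ray_count
  nr <- nrow(shell$sealed_mask); nc <- ncol(shell$sealed_mask)
  rays <- cast_rays(shell$sealed_mask, frame$centroid, n)
  runs <- gap_runs(rays$hit)
  if (length(runs) == 0L && shell$closed) return(shell)
  # rays within 2 of a gap can graze a defect edge and report an unreliable
  # radius; exclude them as mirror sources
  unreliable <- logical(n)
  for (run in runs) {
    grow <- unique(((c(outer(run - 1L, -2:2, `+`)) %% n) + 1L))
    unreliable[grow] <- TRUE
  }
  usable <- rays$hit & !unreliable
  radius <- rays$radius
  for (run in runs) {
    for (j in run) {
      jv <- ((n - (j - 1L)) %% n) + 1L          # mirror across vertical axis
      jh <- ((n %/% 2L - (j - 1L)) %% n) + 1L   # mirror across horizontal axis
      radius[j] <- if (usable[jv]) rays$radius[jv]
        else if (usable[jh]) rays$radius[jh]
        else ctces_abort(
          "Defect and its mirror image are both open; cranium is unsealable.",
          "ctces_error_unsealable")
    }
  }
  pseudo <- shell$pseudo_mask
  for (run in runs) {
    before <- ((run[1] - 2L) %% n) + 1L
    after <- ((run[length(run)] %% n)) + 1L
    ext <- c(before, run, after)
    th <- rays$theta[before] + (seq_along(ext) - 1L) * 2 * pi / n
    pseudo <- pseudo | rasterize_band(nr, nc, frame$centroid, th, radius[ext])
  }
  out <- plug_pinholes(new_cranial_shell(shell$bone_mask, pseudo, frame, n))
  # rasterisation can leave residual holes; thicken pseudo pixels until
  # watertight
  tries <- 0L
  while (!out$closed && tries < 3L) {
    pseudo <- dilate3(out$pseudo_mask) & !shell$bone_mask
    out <- plug_pinholes(new_cranial_shell(shell$bone_mask, pseudo, frame, n))
    tries <- tries + 1L
  }
  if (!out$closed) {
    ctces_abort("Shell could not be closed after sealing.",
                "ctces_error_unsealable")
  }
  out
}

#' Extract the intracranial region
#'
#' Flood-fills (4-connected) from the centroid inside the sealed shell; the
#' reached region is the intracranial mask. Extracranial soft tissue (scalp)
#' is excluded by position even where its HU overlaps brain tissue. The mask
#' never intersects bone or pseudo-cranial pixels.
#'
#' @param slice A [ct_slice()] (unused pixel-wise; kept for the stage
#'   signature and grid checks).
#' @param shell A closed `cranial_shell`.
#' @return Logical intracranial mask.
#' @export
extract_intracranial <- function(slice, shell) {
  stopifnot(inherits(shell, "cranial_shell"))
  if (!shell$closed) {
    ctces_abort("Shell is open; seal fractures and defects first.",
                "ctces_error_open_shell")
  }
  interior_from_centroid(shell$sealed_mask, shell$frame$centroid)
}

#' Apply the intracranial HU boundary condition
#'
#' Keeps only masked pixels whose HU lies in `[lo, hi]` (default 0--79, the
#' range of parenchyma, CSF and blood); air cells, calcifications and metal
#' inside the cranium are dropped from the retained multiset.
#'
#' @param slice A [ct_slice()].
#' @param mask Logical intracranial mask.
#' @param lo,hi Inclusive HU bounds.
#' @return A `ct_segmentation` with fields `intracranial_mask` (in-bounds
#'   pixels only), `region_mask` (the full intracranial region),
#'   `retained_pixels` (integer HU multiset) and `stages`.
#' @export
apply_hu_bounds <- function(slice, mask, lo = 0L, hi = 79L) {
  stopifnot(inherits(slice, "ct_slice"), identical(dim(mask), dim(slice$pixels)))
  inb <- mask & slice$pixels >= lo & slice$pixels <= hi
  retained <- as.integer(slice$pixels[inb])
  if (length(retained) == 0L) {
    ctces_abort("No intracranial pixels within HU bounds.",
                "ctces_error_empty_region")
  }
  structure(list(intracranial_mask = inb, region_mask = mask,
                 retained_pixels = retained,
                 hu_lo = as.integer(lo), hu_hi = as.integer(hi),
                 slice_index = slice$slice_index, stages = list()),
            class = "ct_segmentation")
}

#' @export
print.ct_segmentation <- function(x, ...) {
  cat(sprintf("<ct_segmentation> slice %d: %d retained px in HU [%d, %d]\n",
              x$slice_index, length(x$retained_pixels), x$hu_lo, x$hu_hi))
  invisible(x)
}

#' Segment one slice end to end
#'
#' Runs the six artifact-elimination stages in sequence: cranium detection,
#' gantry removal, quadrant coordination, fracture sealing, craniotomy
#' sealing by mirror symmetry, convex-tissue elimination and the HU boundary
#' condition. Per-stage diagnostic masks are recorded under `$stages`.
#'
#' @param slice A [ct_slice()].
#' @param config A [segment_config()].
#' @return A `ct_segmentation`.
#' @export
segment_slice <- function(slice, config = segment_config()) {
  bone <- detect_cranium(slice, config$bone_threshold)
  if (!any(bone)) {
    ctces_abort("No cranium in slice; nothing to segment.",
                c("ctces_error_empty_region", "ctces_error_no_cranium"))
  }
  cleaned <- remove_gantry(slice, bone, config$background_hu,
                           config$body_threshold)
  frame <- assign_quadrants(cleaned, bone)
  shell <- seal_fractures(bone, frame, config$max_gap_deg, config$ray_count)
  shell <- seal_large_defects(shell, frame)
  interior <- extract_intracranial(cleaned, shell)
  res <- apply_hu_bounds(cleaned, interior, config$hu_lo, config$hu_hi)
  res$stages <- list(bone_mask = bone, frame = frame, shell = shell,
                     removed = slice$pixels != cleaned$pixels,
                     interior_mask = interior)
  res
}

#' Segment every slice of a series
#'
#' Applies [segment_slice()] to each slice; slices that fail with an
#' empty-region/no-cranium error or whose intracranial region is smaller than
#' `min_interior_px` (unstable proportion estimates near the vertex) are
#' excluded and reported rather than aborting the series.
#'
#' @param series A [ct_series()].
#' @param config A [segment_config()].
#' @return List of class `ct_segmentation_series` with `results`, an
#'   `excluded` tibble (slice_index, reason) and the `config`.
#' @export
segment_series <- function(series, config = segment_config()) {
  stopifnot(inherits(series, "ct_series"))
  results <- list()
  excluded <- list()
  for (s in series$slices) {
    res <- tryCatch(segment_slice(s, config), ctces_error = function(e) e)
    if (inherits(res, "ctces_error")) {
      excluded[[length(excluded) + 1L]] <-
        tibble(slice_index = s$slice_index, reason = conditionMessage(res))
    } else if (sum(res$region_mask) < config$min_interior_px) {
      excluded[[length(excluded) + 1L]] <-
        tibble(slice_index = s$slice_index, reason = "interior below min_interior_px")
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  structure(list(results = results,
                 excluded = dplyr::bind_rows(excluded),
                 subject_id = series$subject_id, config = config),
            class = "ct_segmentation_series")
}
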