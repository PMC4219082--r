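# Phantoms here use a reduced 256 px grid; geometry, artifact classes and
# the sealing pipeline are identical to the full 512 px field of view.

test_that("detect_cranium recovers the shell and ignores metal and air", {
  ph <- make_phantom(small_phantom_spec(seed = 1))
  bone <- detect_cranium(ph$slice)
  expect_identical(bone, ph$truth$class == "bone")

  air <- ct_slice(matrix(-1000L, 64, 64))
  expect_false(any(detect_cranium(air)))

  ph2 <- make_phantom(small_phantom_spec(seed = 2, evd = TRUE))
  bone2 <- detect_cranium(ph2$slice)
  evd_px <- ph2$truth$class == "artifact" & ph2$slice$pixels >= 150
  expect_gt(sum(evd_px), 0)              # the metal tract is present
  expect_false(any(bone2 & evd_px))      # and excluded from the cranium
})

test_that("remove_gantry blanks border-touching scanner components only", {
  ph <- make_phantom(small_phantom_spec(seed = 3, gantry = TRUE))
  bone <- detect_cranium(ph$slice)
  cleaned <- remove_gantry(ph$slice, bone)
  gantry_px <- ph$truth$class == "artifact"
  expect_true(all(cleaned$pixels[gantry_px] == -1024L))
  head_px <- ph$truth$class %in% c("bone", "scalp", "csf", "tissue", "blood")
  expect_identical(cleaned$pixels[head_px], ph$slice$pixels[head_px])
  # idempotence and no-op cases
  expect_identical(remove_gantry(cleaned, bone)$pixels, cleaned$pixels)
  ph0 <- make_phantom(small_phantom_spec(seed = 3))
  expect_identical(remove_gantry(ph0$slice, detect_cranium(ph0$slice))$pixels,
                   ph0$slice$pixels)
})

test_that("quadrant frame centres on the cranial interior and partitions the grid", {
  ph <- make_phantom(small_phantom_spec(seed = 4))
  frame <- assign_quadrants(ph$slice, detect_cranium(ph$slice))
  expect_equal(frame$centroid, c(128.5, 128.5), tolerance = 1)

  # translation equivariance of the centroid
  off <- small_phantom_spec(seed = 4)
  off$center <- off$center + c(10, -6)
  ph2 <- make_phantom(off)
  frame2 <- assign_quadrants(ph2$slice, detect_cranium(ph2$slice))
  expect_equal(frame2$centroid, frame$centroid + c(10, -6), tolerance = 1)

  # every pixel maps to exactly one quadrant
  idx <- expand.grid(row = 1:64, col = 1:64)
  q <- quadrant_of(frame, idx$row, idx$col)
  expect_true(all(q %in% 1:4))
  expect_equal(length(q), 64 * 64)

  expect_error(assign_quadrants(ph$slice, matrix(FALSE, 256, 256)),
               class = "ctces_error_no_cranium")
})

test_that("seal_fractures bridges small gaps locally and leaves intact shells alone", {
  ph <- make_phantom(small_phantom_spec(seed = 5))
  bone <- detect_cranium(ph$slice)
  frame <- assign_quadrants(ph$slice, bone)
  sh <- seal_fractures(bone, frame)
  expect_false(any(sh$pseudo_mask))
  expect_identical(sh$sealed_mask, bone)
  expect_true(sh$closed)

  one <- make_phantom(small_phantom_spec(
    seed = 6, fractures = data.frame(angle_deg = 80, width_px = 5)))
  bone1 <- detect_cranium(one$slice)
  frame1 <- assign_quadrants(one$slice, bone1)
  sh1 <- seal_fractures(bone1, frame1)
  expect_true(sh1$closed)
  expect_gt(sum(sh1$pseudo_mask), 0)
  # pseudo pixels stay inside the gap's angular neighbourhood
  idx <- which(sh1$pseudo_mask, arr.ind = TRUE)
  ang <- (atan2(idx[, 2] - frame1$centroid[2], frame1$centroid[1] - idx[, 1]) %%
            (2 * pi)) * 180 / pi
  expect_true(all(abs(((ang - 80) + 180) %% 360 - 180) < 15))
  expect_false(any(sh1$pseudo_mask & bone1))

  two <- make_phantom(small_phantom_spec(
    seed = 7, fractures = data.frame(angle_deg = c(30, 200), width_px = c(6, 9))))
  bone2 <- detect_cranium(two$slice)
  sh2 <- seal_fractures(bone2, assign_quadrants(two$slice, bone2))
  expect_true(sh2$closed)
})

test_that("seal_large_defects mirrors craniotomy arcs and flags symmetric defects", {
  intact <- make_phantom(small_phantom_spec(seed = 8))
  cran <- make_phantom(small_phantom_spec(
    seed = 8, craniotomy = data.frame(start_deg = 60, span_deg = 60)))
  bone <- detect_cranium(cran$slice)
  frame <- assign_quadrants(cran$slice, bone)
  sh <- seal_large_defects(seal_fractures(bone, frame), frame)
  expect_true(sh$closed)
  interior <- extract_intracranial(cran$slice, sh)
  expect_lt(abs(sum(interior) - sum(intact$truth$intracranial_mask)) /
              sum(intact$truth$intracranial_mask), 0.05)

  # an already-closed shell passes through unchanged
  bone_i <- detect_cranium(intact$slice)
  frame_i <- assign_quadrants(intact$slice, bone_i)
  sh_i <- seal_fractures(bone_i, frame_i)
  expect_identical(seal_large_defects(sh_i, frame_i)$sealed_mask, sh_i$sealed_mask)

  # mirror-symmetric double defect is unsealable
  sym <- make_phantom(small_phantom_spec(
    seed = 9, craniotomy = data.frame(start_deg = c(60, 240),
                                      span_deg = c(60, 60))))
  bone_s <- detect_cranium(sym$slice)
  frame_s <- assign_quadrants(sym$slice, bone_s)
  expect_error(seal_large_defects(seal_fractures(bone_s, frame_s), frame_s),
               class = "ctces_error_unsealable")
})

test_that("extract_intracranial excludes scalp by position, not by HU", {
  ph <- make_phantom(small_phantom_spec(seed = 10))
  bone <- detect_cranium(ph$slice)
  frame <- assign_quadrants(ph$slice, bone)
  sh <- seal_fractures(bone, frame)
  interior <- extract_intracranial(ph$slice, sh)
  expect_false(any(interior & ph$truth$class == "scalp"))
  expect_true(all(interior[ph$truth$class == "tissue"]))
  expect_false(any(interior & sh$sealed_mask))

  open_shell <- sh
  open_shell$closed <- FALSE
  expect_error(extract_intracranial(ph$slice, open_shell),
               class = "ctces_error_open_shell")
})

test_that("apply_hu_bounds drops out-of-range pixels and matches a loop oracle", {
  ph <- make_phantom(small_phantom_spec(seed = 11, air_bubble = TRUE, evd = TRUE))
  seg <- segment_slice(ph$slice)
  expect_true(all(seg$retained_pixels >= 0 & seg$retained_pixels <= 79))
  # no air (-1000) or metal (3000) survives the boundary condition
  expect_false(any(seg$retained_pixels < 0 | seg$retained_pixels > 79))

  n_inbounds <- 0L
  px <- ph$slice$pixels
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (seg$region_mask[i, j] && px[i, j] >= 0L && px[i, j] <= 79L) {
      n_inbounds <- n_inbounds + 1L
    }
  }
  expect_identical(length(seg$retained_pixels), n_inbounds)

  flat <- ct_slice(matrix(30L, 16, 16))
  mask <- matrix(TRUE, 16, 16)
  expect_length(apply_hu_bounds(flat, mask)$retained_pixels, 256L)
  airy <- ct_slice(matrix(-1000L, 16, 16))
  expect_error(apply_hu_bounds(airy, mask), class = "ctces_error_empty_region")
})

test_that("segment_slice equals its stage composition and handles degenerate input", {
  ph <- make_phantom(small_phantom_spec(seed = 12))
  auto <- segment_slice(ph$slice)
  bone <- detect_cranium(ph$slice)
  cleaned <- remove_gantry(ph$slice, bone)
  frame <- assign_quadrants(cleaned, bone)
  sh <- seal_large_defects(seal_fractures(bone, frame), frame)
  manual <- apply_hu_bounds(cleaned, extract_intracranial(cleaned, sh))
  expect_identical(sort(auto$retained_pixels), sort(manual$retained_pixels))
  expect_identical(auto$intracranial_mask, manual$intracranial_mask)

  expect_error(segment_slice(ct_slice(matrix(-1000L, 64, 64))),
               class = "ctces_error_empty_region")
})

test_that("artifact-free phantom segmentation reproduces the ground truth exactly", {
  ph <- make_phantom(small_phantom_spec(seed = 13))
  seg <- segment_slice(ph$slice)
  expect_identical(seg$region_mask, ph$truth$intracranial_mask)
  truth_px <- ph$slice$pixels[ph$truth$intracranial_mask]
  truth_px <- truth_px[truth_px >= 0L & truth_px <= 79L]
  expect_identical(sort(seg$retained_pixels), sort(as.integer(truth_px)))
})

test_that("segmentation is idempotent on an already-segmented slice", {
  ph <- make_phantom(small_phantom_spec(seed = 14))
  seg <- segment_slice(ph$slice)
  px <- matrix(-1024L, 256, 256)
  keep <- seg$stages$bone_mask | seg$region_mask
  px[keep] <- ph$slice$pixels[keep]
  again <- segment_slice(ct_slice(px))
  expect_identical(sort(again$retained_pixels), sort(seg$retained_pixels))
})

test_that("translation of the phantom translates masks and preserves the HU multiset", {
  base <- small_phantom_spec(seed = 15,
                             fractures = data.frame(angle_deg = 120, width_px = 8))
  moved <- base
  moved$center <- base$center + c(7, -9)
  a <- make_phantom(base)
  b <- make_phantom(moved)
  sa <- segment_slice(a$slice)
  sb <- segment_slice(b$slice)
  expect_identical(sort(sa$retained_pixels), sort(sb$retained_pixels))
  shifted <- matrix(FALSE, 256, 256)
  shifted[8:256, 1:(256 - 9)] <- sa$region_mask[1:249, 10:256]
  expect_identical(sb$region_mask, shifted)
})

test_that("mask recovery across defect and artifact combinations stays high", {
  dice <- vapply(1:10, function(i) {
    withr::with_seed(1000 + i, {
      fr <- data.frame(angle_deg = runif(2, 0, 360), width_px = runif(2, 0, 18))
      cr <- if (i %% 2) data.frame(start_deg = runif(1, 0, 360),
                                   span_deg = runif(1, 10, 80)) else NULL
    })
    sp <- phantom_spec(grid = 256L, seed = 1000 + i, fractures = fr,
                       craniotomy = cr, evd = i %% 3 == 0,
                       gantry = i %% 4 == 0, air_bubble = i %% 5 == 0)
    ph <- make_phantom(sp)
    seg <- segment_slice(ph$slice)
    dice_coefficient(seg$region_mask, ph$truth$intracranial_mask)
  }, numeric(1))
  expect_gte(median(dice), 0.98)
  expect_gte(min(dice), 0.95)
})

test_that("segment_series skips unusable slices instead of failing", {
  ph <- make_series(small_phantom_spec(seed = 16, grid = 128), n_slices = 3)
  blank <- ct_slice(matrix(-1000L, 128, 128), slice_index = 3L)
  ser <- ct_series(c(ph$series$slices, list(blank)))
  seg <- segment_series(ser)
  expect_length(seg$results, 3L)
  expect_equal(seg$excluded$slice_index, 3L)
})
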