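test_that("slice distributions are per-HU pixel proportions", {
  d <- distribution_from_pixels(rep(10L, 40))
  expect_equal(d$proportion[d$hu == 10], 100)
  expect_equal(sum(d$proportion), 100)

  d2 <- distribution_from_pixels(rep(c(20L, 30L), each = 10))
  expect_equal(d2$proportion[d2$hu %in% c(20, 30)], c(50, 50))

  ph <- make_phantom(small_phantom_spec(seed = 31, grid = 128))
  seg <- segment_slice(ph$slice)
  d3 <- slice_distribution(seg)
  expect_equal(d3$proportion, oracle_distribution(seg$retained_pixels))
  expect_equal(attr(d3, "n_pixels"), length(seg$retained_pixels))
  expect_error(distribution_from_pixels(integer()),
               class = "ctces_error_empty_region")
})

test_that("series averaging is the unweighted mean of per-image proportions", {
  one <- distribution_from_pixels(rep(10L, 10))
  expect_equal(series_distribution(list(one))$proportion, one$proportion)

  two <- distribution_from_pixels(rep(20L, 30))
  avg <- series_distribution(list(one, two))
  expect_equal(avg$proportion[avg$hu %in% c(10, 20)], c(50, 50))
  expect_equal(sum(avg$proportion), 100)
  expect_equal(attr(avg, "n_images"), 2L)

  # unweighted: the 30-pixel image counts no more than the 10-pixel one;
  # the pooled variant weights by pixel count instead
  pooled <- series_distribution(list(one, two), method = "pooled")
  expect_equal(pooled$proportion[pooled$hu == 20], 75)

  # permutation invariance
  ds <- lapply(1:4, random_distribution)
  expect_equal(series_distribution(ds)$proportion,
               series_distribution(rev(ds))$proportion)
  expect_error(series_distribution(list()), class = "ctces_error_empty_region")
})

test_that("group distributions average subjects and retain the subject matrix", {
  d <- random_distribution(1)
  same <- group_distribution(list(a = d, b = d, c = d))
  expect_equal(same$distribution$proportion, d$proportion)

  ds <- lapply(1:5, random_distribution)
  names(ds) <- paste0("s", 1:5)
  g <- group_distribution(ds)
  mat <- t(vapply(ds, function(x) x$proportion, numeric(80)))
  expect_equal(g$distribution$proportion, colMeans(mat))
  expect_equal(dim(g$subjects), c(5L, 80L))

  co <- simulate_cohort(cohort_spec(n_mild = 8, n_severe = 8, seed = 3,
                                    slices_per_subject = 3,
                                    pixels_per_slice = 5000))
  gm <- group_distribution(co$distributions[co$manifest$group == "mild"])
  gs <- group_distribution(co$distributions[co$manifest$group == "severe"])
  expect_gt(compute_ces(gs$distribution), compute_ces(gm$distribution))
})

test_that("band proportions are inclusive sums with nesting and additivity", {
  d <- distribution_from_pixels(rep(c(20L, 30L), each = 5))
  expect_equal(band_proportion(d, 0, 79), 100)
  expect_equal(band_proportion(d, 17, 24), 50)

  ph <- make_phantom(small_phantom_spec(seed = 32, grid = 128))
  seg <- segment_slice(ph$slice)
  ds <- slice_distribution(seg)
  expect_equal(band_proportion(ds, 17, 24),
               oracle_band_percent(seg$retained_pixels, 17, 24))

  for (s in 1:5) {
    dd <- random_distribution(s)
    expect_lte(band_proportion(dd, 19, 23), band_proportion(dd, 17, 24))
    expect_equal(band_proportion(dd, 10, 20) + band_proportion(dd, 21, 40),
                 band_proportion(dd, 10, 40))
    expect_equal(band_proportion(dd, 0, 79), 100)
  }
  expect_error(band_proportion(d, -1, 10), class = "ctces_error_bounds")
  expect_error(band_proportion(d, 24, 17), class = "ctces_error_bounds")
  expect_error(band_proportion(d, 17, 80), class = "ctces_error_bounds")
})
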