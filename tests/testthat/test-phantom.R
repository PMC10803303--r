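# Phantom generator: determinism, planted-signal geometry, centre effects,
# resampling and cohort summaries.

test_that("generate_case is deterministic and rejects oversized tumours", {
  sp <- tiny_spec(); pr <- tiny_centres()[[1]]
  a <- generate_case(sp, pr, emvi = 1, cr = 0, seed = 123)
  b <- generate_case(sp, pr, emvi = 1, cr = 0, seed = 123)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a[c("age", "sex", "cT", "cN")], b[c("age", "sex", "cT", "cN")])
  c2 <- generate_case(sp, pr, emvi = 1, cr = 0, seed = 124)
  expect_false(identical(a$image$data, c2$image$data))

  big <- phantom_spec(grid_shape = c(8, 8, 8), tumour_radius_range = c(30, 40))
  expect_error(generate_case(big, pr, 0, 0, seed = 1), "grid too small")
})

test_that("EMVI label plants protrusions outside the base ellipsoid", {
  sp <- tiny_spec(); pr <- tiny_centres()[[1]]
  for (seed in 1:6) {
    pos <- generate_case(sp, pr, emvi = 1, cr = 0, seed = seed)
    neg <- generate_case(sp, pr, emvi = 0, cr = 0, seed = seed)
    expect_gt(protrusion_voxels(pos), 0)
    expect_identical(protrusion_voxels(neg), 0L)
    expect_gt(sum(pos$mask$data), 0)
  }
})

test_that("label-signal separability: the geometric oracle reaches AUC >= 0.95", {
  cohort <- generate_cohort(200, tiny_centres(), p_emvi = 0.6, p_cr = 0.28,
                            seed = 17, spec = tiny_spec())
  pv <- vapply(cohort, protrusion_voxels, numeric(1))
  emvi <- vapply(cohort, function(x) x$emvi_label, 1L)
  expect_gte(auc_rank(pv, emvi), 0.95)
})

test_that("cohort prevalences stay within binomial 3-sigma and use all centres", {
  centres <- default_centre_profiles(9)
  cohort <- generate_cohort(120, centres, p_emvi = 0.6, p_cr = 0.28,
                            seed = 2, spec = tiny_spec())
  n <- length(cohort)
  emvi <- sum(vapply(cohort, function(x) x$emvi_label, 1L))
  cr <- sum(vapply(cohort, function(x) x$cr_label, 1L))
  expect_lt(abs(emvi - 0.6 * n), 3 * sqrt(n * 0.6 * 0.4) + 1e-9)
  expect_lt(abs(cr - 0.28 * n), 3 * sqrt(n * 0.28 * 0.72) + 1e-9)
  expect_setequal(unique(vapply(cohort, function(x) x$centre_id, "")),
                  paste0("C", 1:9))
  cohort2 <- generate_cohort(120, centres, p_emvi = 0.6, p_cr = 0.28,
                             seed = 2, spec = tiny_spec())
  expect_identical(cohort[[5]]$image$data, cohort2[[5]]$image$data)
  expect_error(generate_cohort(10, list(), seed = 1), "centre")
})

test_that("apply_centre_shift: identity profile, noise level, determinism", {
  v <- volume_image(array(runif(16^3 * 2), c(16, 16, 16, 2)), c(2, 2, 2))
  idp <- centre_profile("X", gain = 1, bias_amplitude = 0, noise_sigma = 0)
  expect_identical(apply_centre_shift(v, idp, seed = 4)$data, v$data)

  const <- volume_image(array(0.5, c(32, 32, 32)), c(2, 2, 2))
  noisy <- centre_profile("Y", gain = 1, bias_amplitude = 0, noise_sigma = 0.1)
  out <- apply_centre_shift(const, noisy, seed = 6)
  resid_sd <- sd(out$data - 0.5)
  expect_gt(resid_sd, 0.09); expect_lt(resid_sd, 0.11)

  o1 <- apply_centre_shift(v, noisy, seed = 9)
  o2 <- apply_centre_shift(v, noisy, seed = 9)
  expect_identical(o1$data, o2$data)
})

test_that("resample_to_grid: identity, constants, and linear ramps", {
  arr <- array(runif(10 * 9 * 8), c(10, 9, 8))
  v <- volume_image(arr, c(2, 2, 5))
  same <- resample_to_grid(v, c(2, 2, 5))
  expect_equal(same$data, v$data)
  expect_equal(same$spacing, v$spacing)

  const <- volume_image(array(3.7, c(8, 8, 8)), c(2, 2, 2))
  rc <- resample_to_grid(const, c(1.3, 0.9, 2.6))
  expect_equal(max(abs(rc$data - 3.7)), 0, tolerance = 1e-12)

  # ramp along x: value = world x coordinate; trilinear must keep it affine
  dims <- c(12, 6, 6)
  wx <- array(rep((seq_len(dims[1]) - 1) * 2, times = prod(dims[2:3])), dims)
  ramp <- volume_image(wx, c(2, 2, 2))
  rr <- resample_to_grid(ramp, c(0.8, 2, 2))
  expected <- (seq_len(dim(rr$data)[1]) - 1) * 0.8
  expect_lt(max(abs(rr$data[, 1, 1, 1] - expected)), 1e-6)
  expect_error(resample_to_grid(v, c(0, 1, 1)), "positive")
})

test_that("summarize_cohort reproduces printed-count percentages", {
  # EMVI 304/205 -> 60%/40%; response 368/141 -> 72%/28%; total 509
  cohort <- fake_cohort(n_emvi_pos = 304, n_emvi_neg = 205, n_cr_pos = 141)
  tab <- summarize_cohort(list(All = cohort))
  get <- function(lv) tab$All[tab$level == lv]
  expect_equal(get("EMVI+"), "304 (60%)")
  expect_equal(get("EMVI-"), "205 (40%)")
  expect_equal(get("non-CR"), "368 (72%)")
  expect_equal(get("CR"), "141 (28%)")
  expect_equal(get("n"), "509")

  # single-group percentages sum to 100 up to integer rounding
  pct <- as.numeric(sub(".*\\((\\d+)%\\)", "\\1",
                        tab$All[tab$characteristic == "sex"]))
  expect_lte(abs(sum(pct) - 100), 1)
  expect_error(summarize_cohort(list(A = list())), "empty")
})

test_that("summarize_cohort appends Kruskal-Wallis comparisons", {
  dev <- fake_cohort(60, 40, n_cr_pos = 30, seed = 2)
  ext <- fake_cohort(30, 20, n_cr_pos = 15, seed = 3)
  tab <- summarize_cohort(list(Development = dev, External = ext),
                          compare = c("Development", "External"))
  p <- tab$p_value[tab$characteristic == "age" ]
  expect_true(is.finite(p) && p >= 0 && p <= 1)
  expect_true(all(c("Development", "External") %in% names(tab)))
})
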