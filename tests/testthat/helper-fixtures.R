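# Shared fixtures, all generated in code. The tiny phantom spec keeps module
# tests fast (16^3 grids); heavier protocol-scale runs live in
# test-acceptance.R only.

tiny_spec <- function() {
  phantom_spec(grid_shape = c(16, 16, 16),
               tumour_radius_range = c(4, 6),
               emvi_protrusions = list(count = 3, length = 5, radius = 1.6))
}

tiny_centres <- function(n = 3L) default_centre_profiles(n, seed = 77L)

tiny_cohort <- function(n = 8L, seed = 5L, p_emvi = 0.5, p_cr = 0.5) {
  generate_cohort(n, tiny_centres(), p_emvi = p_emvi, p_cr = p_cr,
                  seed = seed, spec = tiny_spec())
}

# lightweight case records carrying only tabular fields (for summary and
# clinical-regression math on exact printed counts)
fake_case <- function(i, emvi, cr, centre = "C1", age = 65, sex = "M",
                      cT = "3", cN = "2") {
  structure(list(patient_id = sprintf("F%04d", i), centre_id = centre,
                 image = NULL, mask = NULL,
                 emvi_label = as.integer(emvi), cr_label = as.integer(cr),
                 age = age, sex = sex, cT = cT, cN = cN),
            class = "case_record")
}

fake_cohort <- function(n_emvi_pos, n_emvi_neg, n_cr_pos = 0L, n_cr_neg = NULL,
                        seed = 1L) {
  n <- n_emvi_pos + n_emvi_neg
  if (is.null(n_cr_neg)) n_cr_neg <- n - n_cr_pos
  stopifnot(n_cr_pos + n_cr_neg == n)
  emvi <- c(rep(1L, n_emvi_pos), rep(0L, n_emvi_neg))
  cr <- c(rep(1L, n_cr_pos), rep(0L, n_cr_neg))
  withr::with_seed(seed, {
    ages <- round(pmin(pmax(rnorm(n, 65, 11), 25), 87))
    sexes <- ifelse(runif(n) < 0.35, "F", "M")
    lapply(seq_len(n), function(i)
      fake_case(i, emvi[i], cr[i], age = ages[i], sex = sexes[i]))
  })
}

# cached small trained segmenter shared across test files (trained once)
.fixture_env <- new.env(parent = emptyenv())

tiny_seg_fit <- function() {
  if (is.null(.fixture_env$seg)) {
    cohort <- tiny_cohort(n = 30L, seed = 31L)
    cfg <- unet_config(base_channels = 4L, input_channels = 1L, seed = 9L)
    .fixture_env$seg <- list(
      fit = train_segmenter(cohort[1:10], cfg, epochs = 6L,
                            val_cases = cohort[11:14], lr = 2e-3),
      cohort = cohort, config = cfg)
  }
  .fixture_env$seg
}

# segmenter feature pyramids for the whole fixture cohort (computed once)
cls_fixture <- function() {
  if (is.null(.fixture_env$cls)) {
    fx <- tiny_seg_fit()
    cohort <- fx$cohort
    pyr <- setNames(lapply(cohort, function(cs)
      extract_features(fx$fit$model, cs$image)),
      vapply(cohort, function(x) x$patient_id, ""))
    .fixture_env$cls <- list(cohort = cohort, pyramids = pyr)
  }
  .fixture_env$cls
}
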