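# strong, intercept-free contrast config used in several tests:
# Neck/Front quarter at +2, Rump/Legs at -2 degC => delta(Rump, Neck) = -4
strong_cfg <- function(name = "horse", n = 8L, animal_sd = 0.2) {
  species_config(name, n, global_mean = 22, global_sd = 3,
                 gor_offsets = list("Neck" = 2, "Front quarter" = 2,
                                    "Rump" = -2, "Legs" = -2),
                 animal_sd = animal_sd, pixel_sd = 1)
}

strong_ds <- function(seed = 1, n = 8L) {
  generate_dataset(strong_cfg(n = n), strong_cfg("donkey", n = n),
                   layout = small_layout(), rng_seed = seed)
}

test_that("difference matrices are exactly antisymmetric with zero diagonal", {
  ds <- small_study(5)
  for (sp in c("horse", "donkey")) {
    dm <- difference_matrix(ds, sp)
    expect_true(all(dm$deltas + t(dm$deltas) == 0))
    expect_true(all(diag(dm$deltas) == 0))
  }
})

test_that("pooled deltas recover the configured GOR contrast", {
  ds <- strong_ds(3)
  dm <- difference_matrix(ds, "horse")
  s_rump <- pooled_gor_pixels(ds, "horse", default_gors()[["Rump"]])
  s_neck <- pooled_gor_pixels(ds, "horse", default_gors()[["Neck"]])
  # animal intercepts cancel between equally-weighted GORs; remaining noise
  # is pixel-level
  se <- sqrt(1 / length(s_rump$values) + 1 / length(s_neck$values))
  expect_lt(abs(dm$deltas["Rump", "Neck"] - (-4)), 3 * se)
  expect_equal(dm$deltas["Rump", "Neck"],
               sample_mean(s_rump) - sample_mean(s_neck), tolerance = 1e-12)
})

test_that("global significance flags are symmetric and detect designed contrasts", {
  ds <- strong_ds(4)
  cfg <- test_config(rng_seed = 4)
  dm <- global_significance(ds, "horse", config = cfg)
  expect_identical(dm$significant, t(dm$significant))
  expect_identical(dm$p_values, t(dm$p_values))
  expect_false(any(diag(dm$significant)))
  expect_true(dm$significant["Rump", "Neck"])
  expect_true(dm$significant["Legs", "Front quarter"])
  # pairs designed with identical offsets should rarely fire; at least the
  # exact-same-composition pair Neck / Front quarter has a tiny pooled delta
  expect_lt(abs(dm$deltas["Neck", "Front quarter"]), 0.5)
})

test_that("local counts are symmetric, bounded, and saturate on strong effects", {
  ds <- strong_ds(6)
  cfg <- test_config(rng_seed = 6)
  lc <- local_count_matrix(ds, "horse", config = cfg)
  expect_identical(lc$counts, t(lc$counts))
  expect_true(all(lc$counts >= 0 & lc$counts <= lc$n_animals))
  expect_true(all(diag(lc$counts) == 0))
  expect_equal(lc$counts["Rump", "Neck"], lc$n_animals)   # |delta| = 4, sd 1
})

test_that("widening a contrast never loses local support (same seed)", {
  mk <- function(off) {
    cfg <- species_config("horse", 6L, global_mean = 22, global_sd = 3,
                          gor_offsets = list("Rump" = -off, "Legs" = -off),
                          animal_sd = 0.2, pixel_sd = 1.5)
    generate_dataset(cfg, species_config("donkey", 1L, global_mean = 19,
                                         global_sd = 2, animal_sd = 0.2,
                                         pixel_sd = 1.5),
                     layout = tiny_layout(), rng_seed = 17)
  }
  cfg <- test_config(rng_seed = 17)
  counts <- vapply(c(0.2, 0.6, 1.5, 4), function(off) {
    local_count_matrix(mk(off), "horse", config = cfg)$counts["Rump", "Neck"]
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[4], 6)
})

test_that("stable patterns are the globally-significant, unanimously-local pairs", {
  ds <- strong_ds(8)
  cfg <- test_config(rng_seed = 8)
  dm <- global_significance(ds, "horse", config = cfg)
  lc <- local_count_matrix(ds, "horse", config = cfg)
  st <- stable_patterns(dm, lc)
  expect_true(nrow(st) >= 1)
  for (k in seq_len(nrow(st))) {
    expect_true(dm$significant[st$gor_i[k], st$gor_j[k]])
    expect_equal(lc$counts[st$gor_i[k], st$gor_j[k]], lc$n_animals)
  }
  # all-zero counts => no stable pattern
  lc0 <- lc
  lc0$counts[] <- 0L
  expect_equal(nrow(stable_patterns(dm, lc0)), 0L)
  expect_error(stable_patterns(difference_matrix(ds, "horse"), lc), "significance")
})

test_that("per-ROI species comparison recovers the study-direction contrast", {
  ds <- small_study(9)
  cfg <- test_config(rng_seed = 9)
  for (roi in c(1L, 4L, 9L)) {
    cmp <- species_roi_comparison(ds, roi, cfg)
    expect_gt(cmp$delta_t, 0)               # horses configured warmer
    expect_lt(cmp$test$p_value, 0.001)
    expect_equal(cmp$delta_t, cmp$mean_horse - cmp$mean_donkey,
                 tolerance = 1e-12)
  }
})

test_that("identical species distributions do not trigger the ROI comparison", {
  # a true pixel-level null needs animal_sd = 0: with random intercepts the
  # two pooled pixel distributions genuinely differ between finite samples
  cfg_sp <- species_config("horse", 6L, global_mean = 20, global_sd = 2,
                           animal_sd = 0)
  cfg_dk <- species_config("donkey", 6L, global_mean = 20, global_sd = 2,
                           animal_sd = 0)
  rejections <- vapply(1:10, function(s) {
    ds <- generate_dataset(cfg_sp, cfg_dk, layout = tiny_layout(), rng_seed = s)
    species_roi_comparison(ds, 5L, test_config(rng_seed = s))$test$p_value < 0.001
  }, logical(1))
  expect_lte(sum(rejections), 1L)
})

test_that("metadata comparison reproduces the configured covariate contrast", {
  ds <- small_study(10)
  hc <- compare_metadata(ds, "hair_coat_length", test_config(rng_seed = 10))
  expect_gt(hc$donkey$mean, hc$horse$mean)
  expect_lt(hc$test$p_value, 1e-4)
  sf <- compare_metadata(ds, "sf_skin_thickness", test_config(rng_seed = 10))
  expect_gt(sf$donkey$mean, sf$horse$mean)
  expect_lt(sf$test$p_value, 1e-4)

  # single-animal species is a contract violation
  small <- new_dataset(list(manual_record(id = "H.1"),
                            manual_record(id = "D.1", species = "donkey"),
                            manual_record(id = "D.2", species = "donkey")))
  expect_error(compare_metadata(small, "hair_coat_length"))
})

test_that("pattern tables are written as readable delimited text", {
  ds <- strong_ds(12, n = 4L)
  cfg <- test_config(rng_seed = 12)
  dm <- global_significance(ds, "horse", config = cfg)
  lc <- local_count_matrix(ds, "horse", config = cfg)
  dir <- withr::local_tempdir()
  files <- write_pattern_tables(dm, lc, dir)
  expect_true(all(file.exists(files)))
  back <- as.matrix(utils::read.table(files["deltas"], sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(dm$deltas), tolerance = 1e-12)
})
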