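test_that("noiseless limit puts every ROI exactly at its configured level", {
  cfg <- species_config("horse", 1L, global_mean = 22, global_sd = 1,
                        gor_offsets = list("Neck" = 1.5, "Front quarter" = 1.5,
                                           "Rump" = -2.5, "Legs" = -2.5),
                        animal_sd = 0, pixel_sd = 0)
  rec <- generate_animal(cfg, small_layout(), "H.1", seed = 1)
  # each ROI constant
  for (r in 1:15) expect_equal(sd(rec$image[rec$class_map == r]), 0)
  # offset differences survive centring: Neck ROI vs Rump ROI
  expect_equal(rec$image[rec$class_map == 1L][1] -
                 rec$image[rec$class_map == 8L][1], 1.5 - (-2.5))
  # annotated mean is exactly the configured global mean
  expect_equal(mean(rec$image[rec$class_map > 0L]), 22, tolerance = 1e-12)
})

test_that("a global cold shift moves its twin down by exactly the shift", {
  cfg <- species_config("donkey", 1L, global_mean = 19, global_sd = 2.3,
                        animal_sd = 1.2)
  lay <- small_layout()
  base <- generate_animal(cfg, lay, "D.17", seed = 44)
  cold <- generate_animal(cfg, lay, "D.17",
                          anomaly = anomaly_spec("global_cold_shift", -4),
                          seed = 44)
  ann <- base$class_map > 0L
  expect_equal(cold$image[ann], base$image[ann] - 4, tolerance = 1e-12)
  expect_true(all(cold$image[!ann] == base$image[!ann]))
})

test_that("warm patches raise only the targeted GORs", {
  cfg <- species_config("donkey", 1L, global_mean = 19, global_sd = 2.3,
                        animal_sd = 1.2)
  lay <- small_layout()
  base <- generate_animal(cfg, lay, "D.18", seed = 45)
  an <- anomaly_spec("warm_patches", 3.5, patch_gors = c("Rump", "Legs"),
                     patch_fraction = 0.5)
  patched <- generate_animal(cfg, lay, "D.18", anomaly = an, seed = 45)
  diffs <- patched$image - base$image
  patch_rois <- unique(unlist(lapply(default_gors()[c("Rump", "Legs")],
                                     `[[`, "roi_ids")))
  expect_true(all(diffs[!(base$class_map %in% patch_rois)] == 0))
  in_patch <- diffs[base$class_map %in% patch_rois]
  expect_true(all(abs(in_patch) < 1e-9 | abs(in_patch - 3.5) < 1e-9))
  expect_gt(mean(in_patch > 0), 0.3)   # about half the pixels shifted
})

test_that("generation is bit-reproducible and seed-sensitive", {
  lay <- tiny_layout()
  d1 <- generate_study_dataset(7, layout = lay)
  d2 <- generate_study_dataset(7, layout = lay)
  d3 <- generate_study_dataset(8, layout = lay)
  expect_identical(d1$records[["H.3"]]$image, d2$records[["H.3"]]$image)
  expect_identical(d1$records[["D.12"]]$image, d2$records[["D.12"]]$image)
  expect_false(identical(d1$records[["H.3"]]$image, d3$records[["H.3"]]$image))
})

test_that("a horse-like animal sits near the configured species mean", {
  p <- study_preset()
  rec <- generate_animal(p$horse_cfg, small_layout(), "H.1", seed = 46)
  vals <- rec$image[rec$class_map > 0L]
  se <- sqrt(p$horse_cfg$animal_sd^2 + stats::var(vals) / length(vals))
  expect_lt(abs(mean(vals) - 22.72), 3 * se)
})

test_that("metadata draws are positive and near their configured levels", {
  ds <- small_study(47)
  hair <- vapply(dataset_records(ds, "donkey"),
                 function(r) r$metadata$hair_coat_length, numeric(1))
  expect_true(all(hair > 0))
  expect_lt(abs(mean(hair) - 3.39), 3 * 0.46 / sqrt(16))
})

test_that("conflicting GOR offsets for a shared ROI are rejected", {
  expect_error(resolve_roi_offsets(list("Neck" = 1, "Front quarter" = 2)),
               "conflicting")
  off <- resolve_roi_offsets(list("Rump" = -2.5, "Legs" = -2.5))
  expect_equal(off[c(8, 9, 13)], c(-2.5, -2.5, -2.5))
  expect_equal(off[1], 0)
  expect_error(resolve_roi_offsets(list("Nowhere" = 1)), "unknown GOR")
})

test_that("variance balancing rejects impossible configurations", {
  cfg <- species_config("horse", 1L, global_mean = 22, global_sd = 0.5,
                        animal_sd = 1.5)   # animal_sd alone exceeds global_sd
  expect_error(generate_animal(cfg, tiny_layout(), "H.1", seed = 1),
               "balance")
})

test_that("layout invariants hold: disjoint blocks, minimum pixels, 15 ROIs", {
  lay <- layout_spec()
  expect_equal(lay$height, 240L)
  expect_equal(lay$width, 320L)
  cfg <- species_config("horse", 1L, global_mean = 20, global_sd = 1,
                        animal_sd = 0.5)
  rec <- generate_animal(cfg, small_layout(), "H.1", seed = 2)
  counts <- tabulate(rec$class_map[rec$class_map > 0L], nbins = 15)
  expect_true(all(counts >= small_layout()$min_pixels))
  expect_error(layout_spec(24, 40, margin = 0, min_pixels = 100),
               "min_pixels")
})
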