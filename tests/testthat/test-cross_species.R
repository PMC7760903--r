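# builds the four matrices for a horse/donkey config pair at test scale
pattern_pipeline <- function(horse_cfg, donkey_cfg, seed = 1,
                             layout = small_layout()) {
  ds <- generate_dataset(horse_cfg, donkey_cfg, layout = layout,
                         rng_seed = seed)
  cfg <- test_config(rng_seed = seed)
  list(ds = ds,
       hd = global_significance(ds, "horse", config = cfg),
       dd = global_significance(ds, "donkey", config = cfg),
       hl = local_count_matrix(ds, "horse", config = cfg),
       dl = local_count_matrix(ds, "donkey", config = cfg),
       cfg = cfg)
}

test_that("same-sign significant pairs class as SPS with min shared-animal count", {
  p <- study_preset()
  p$horse_cfg$n_animals <- 8L
  p$donkey_cfg$n_animals <- 8L
  pl <- pattern_pipeline(p$horse_cfg, p$donkey_cfg, seed = 21)
  pcm <- classify_patterns(pl$hd, pl$dd, pl$hl, pl$dl)

  expect_identical(pcm$classes, t(pcm$classes))
  expect_true(all(is.na(diag(pcm$classes))))
  expect_equal(pcm$classes["Rump", "Neck"], "SPS")
  expect_equal(pcm$min_shared["Rump", "Neck"],
               min(pl$hl$counts["Rump", "Neck"], pl$dl$counts["Rump", "Neck"]))
  # min_shared defined exactly on the significant classes
  sig_cls <- pcm$classes %in% c("SPS", "HWS", "HCS")
  expect_identical(which(!is.na(pcm$min_shared)),
                   which(sig_cls & !is.na(pcm$classes)))
  # wherever defined it is the minimum of the two local counts
  idx <- which(!is.na(pcm$min_shared))
  expect_equal(pcm$min_shared[idx],
               pmin(pl$hl$counts, pl$dl$counts)[idx])
})

test_that("reversed contrasts between species class as horse-warmer/colder", {
  warm <- list("Neck" = 2, "Front quarter" = 2)
  cold <- list("Neck" = -2, "Front quarter" = -2)
  h <- species_config("horse", 8L, global_mean = 22, global_sd = 3,
                      gor_offsets = warm, animal_sd = 0.2, pixel_sd = 1)
  d <- species_config("donkey", 8L, global_mean = 19, global_sd = 3,
                      gor_offsets = cold, animal_sd = 0.2, pixel_sd = 1)
  pl <- pattern_pipeline(h, d, seed = 22)
  pcm <- classify_patterns(pl$hd, pl$dd, pl$hl, pl$dl)
  # horses have Neck warmer than Trunk, donkeys the reverse; on the
  # canonical (Neck, Trunk) rendering horse delta > 0 => horse-warmer class
  expect_gt(pl$hd$deltas["Neck", "Trunk"], 0)
  expect_lt(pl$dd$deltas["Neck", "Trunk"], 0)
  expect_equal(pcm$classes["Neck", "Trunk"], "HWS")
  expect_equal(pcm$classes["Trunk", "Neck"], "HWS")   # symmetric under swap
})

test_that("taxonomy fractions cover the 45 pairs and sum to one", {
  p <- study_preset()
  p$horse_cfg$n_animals <- 8L
  p$donkey_cfg$n_animals <- 8L
  pl <- pattern_pipeline(p$horse_cfg, p$donkey_cfg, seed = 23)
  ts <- taxonomy_summary(classify_patterns(pl$hd, pl$dd, pl$hl, pl$dl))
  expect_equal(sum(ts), 1, tolerance = 1e-12)
  expect_equal(attr(ts, "n_pairs"), 45L)
  expect_named(ts, c("SPS", "SP", "HWS", "HW", "HCS", "HC"))

  # an all-SPS class matrix summarises to 100%
  all_sps <- classify_patterns(pl$hd, pl$dd, pl$hl, pl$dl)
  all_sps$classes[upper.tri(all_sps$classes) | lower.tri(all_sps$classes)] <- "SPS"
  expect_equal(unname(taxonomy_summary(all_sps)["SPS"]), 1)
})

test_that("an animal complies with a reference pattern it dominates", {
  cfg <- strong_cfg <- species_config(
    "donkey", 9L, global_mean = 19, global_sd = 3,
    gor_offsets = list("Neck" = 2, "Front quarter" = 2,
                       "Rump" = -2, "Legs" = -2),
    animal_sd = 0.1, pixel_sd = 0.8)
  ds <- generate_dataset(species_config("horse", 1L, global_mean = 22,
                                        global_sd = 2, animal_sd = 0.5),
                         cfg, layout = small_layout(), rng_seed = 24)
  tcfg <- test_config(rng_seed = 24)
  # leave-one-out reference: score D.9 against D.1..D.8
  ds_ref <- ds
  ds_ref$records[["D.9"]]$metadata$excluded <- TRUE
  ref <- global_significance(ds_ref, "donkey", config = tcfg)
  cm <- compliance_matrix(ds$records[["D.9"]], ref, config = tcfg)
  expect_identical(cm$entries, t(cm$entries))
  sig_pairs <- which(ref$significant & upper.tri(ref$significant))
  expect_true(all(cm$entries[sig_pairs] == "S"))
})

test_that("warm patches break compliance on the pairs they reverse", {
  lay <- small_layout()
  tcfg <- test_config(rng_seed = 25)
  with_anom <- generate_study_dataset(25, with_outliers = TRUE, layout = lay)
  # twin dataset: same seed, no anomalies; D.18's base pixels are identical
  p <- study_preset(with_outliers = TRUE)
  p$anomalies <- list()
  twin <- generate_dataset(p$horse_cfg, p$donkey_cfg, layout = lay,
                           rng_seed = 25)
  base18 <- twin$records[["D.18"]]
  anom18 <- with_anom$records[["D.18"]]
  expect_gt(mean(anom18$image[anom18$class_map > 0]),
            mean(base18$image[base18$class_map > 0]))

  ref <- global_significance(with_anom, "donkey", config = tcfg)
  ns_anom <- ns_count(compliance_matrix(anom18, ref, config = tcfg))
  ns_base <- ns_count(compliance_matrix(base18, ref, config = tcfg))
  expect_gt(ns_anom, ns_base)
})

test_that("mismatched GOR sets are rejected", {
  pl <- pattern_pipeline(species_config("horse", 3L, global_mean = 22,
                                        global_sd = 2, animal_sd = 0.5),
                         species_config("donkey", 3L, global_mean = 19,
                                        global_sd = 2, animal_sd = 0.5),
                         seed = 26, layout = tiny_layout())
  other <- pl$hd
  rownames(other$deltas)[1] <- "Elsewhere"
  expect_error(classify_patterns(other, pl$dd, pl$hl, pl$dl), "GOR set")
})
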