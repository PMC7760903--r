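# Synthetic thermogram generator.
#
# Emulates the statistical structure the analysis assumes: a species-level
# global temperature, per-GOR offsets (resolved to per-ROI offsets), a
# per-animal random intercept, within-ROI pixel noise (gaussian or a
# two-component mixture for multimodality), and two anomaly modes (a
# globally cold long-haired animal; warm patches from hair loss). Geometry
# is a grid of disjoint rectangles per ROI: the pattern statistics depend
# only on label sets, not on anatomical shape.

#' Species generator configuration
#'
#' Pixel temperature model:
#' `T = global_mean' + animal_intercept + roi_offset + noise`, where the
#' per-ROI offsets implied by `gor_offsets` are centred by annotated-pixel
#' weight so that the expected annotated mean equals `global_mean`, the
#' intercept is drawn once per animal from `N(0, animal_sd^2)`, and noise is
#' `N(0, pixel_sd^2)` (optionally a mean-centred two-component mixture).
#' With `pixel_sd = NULL` the within-ROI sd is balanced at generation time so
#' the total annotated-pixel sd matches `global_sd`
#' (`pixel_sd^2 = global_sd^2 - animal_sd^2 - var(offsets)`).
#'
#' @param name species label (`"horse"` or `"donkey"`).
#' @param n_animals number of animals (default 16).
#' @param global_mean,global_sd target annotated-pixel mean and sd, degC.
#' @param gor_offsets named list/vector, GOR name -> offset in degC; GORs
#'   sharing an ROI must agree on its offset (checked at generation).
#' @param animal_sd between-animal intercept sd, degC.
#' @param pixel_sd within-ROI noise sd, degC, or `NULL` to balance to
#'   `global_sd`.
#' @param pixel_noise_shape `"gaussian"` or `"two_component"` (mixture with
#'   weight `mix_weight` shifted by `mix_shift`, re-centred to mean zero).
#' @param mix_weight,mix_shift mixture parameters for `"two_component"`.
#' @param hair_coat_mean,hair_coat_sd,sf_skin_mean,sf_skin_sd metadata
#'   distributions (truncated at zero), cm and mm.
#' @return object of class `species_config`.
#' @export
species_config <- function(name, n_animals = 16L,
                           global_mean, global_sd,
                           gor_offsets = list(),
                           animal_sd = 1.5, pixel_sd = NULL,
                           pixel_noise_shape = c("gaussian", "two_component"),
                           mix_weight = 0.2, mix_shift = 2,
                           hair_coat_mean = NA, hair_coat_sd = NA,
                           sf_skin_mean = NA, sf_skin_sd = NA) {
  pixel_noise_shape <- match.arg(pixel_noise_shape)
  abort_if(n_animals < 1L, "n_animals must be >= 1")
  abort_if(animal_sd < 0 || (!is.null(pixel_sd) && pixel_sd < 0) || global_sd < 0,
           "standard deviations must be >= 0")
  structure(list(name = name, n_animals = as.integer(n_animals),
                 global_mean = global_mean, global_sd = global_sd,
                 gor_offsets = gor_offsets, animal_sd = animal_sd,
                 pixel_sd = pixel_sd, pixel_noise_shape = pixel_noise_shape,
                 mix_weight = mix_weight, mix_shift = mix_shift,
                 hair_coat_mean = hair_coat_mean, hair_coat_sd = hair_coat_sd,
                 sf_skin_mean = sf_skin_mean, sf_skin_sd = sf_skin_sd),
            class = "species_config")
}

#' Resolve per-GOR offsets to per-ROI offsets
#'
#' Offsets are specified per GOR for readability but applied per ROI. When
#' two overlapping GORs imply different offsets for a shared ROI the config
#' is rejected (explicitness over averaging). ROIs not covered by any listed
#' GOR get offset 0.
#'
#' @param gor_offsets named list/vector of GOR name -> degC.
#' @param gors the [gor_set()] interpreting the names.
#' @return numeric vector of length 15 (one offset per ROI).
#' @export
resolve_roi_offsets <- function(gor_offsets, gors = default_gors()) {
  off <- rep(NA_real_, N_ROIS)
  for (gn in names(gor_offsets)) {
    g <- gors[[gn]]
    abort_if(is.null(g), "unknown GOR name in gor_offsets: '%s'", gn)
    val <- as.numeric(gor_offsets[[gn]])
    for (r in g$roi_ids) {
      abort_if(!is.na(off[r]) && off[r] != val,
               "ROI %d receives conflicting offsets (%g vs %g) from overlapping GORs",
               r, off[r], val)
      off[r] <- val
    }
  }
  ifelse(is.na(off), 0, off)
}

#' Rectangular ROI layout
#'
#' Places the 15 ROIs as disjoint rectangular blocks on a `rows x cols` grid
#' of cells inside the image, leaving an unannotated margin between blocks.
#'
#' @param height,width image shape in pixels (default native 240 x 320).
#' @param grid_rows,grid_cols arrangement of the 15 blocks (default 3 x 5).
#' @param margin unannotated gap around each block, pixels.
#' @param min_pixels minimum pixels required per ROI (default 200).
#' @return object of class `layout_spec`: `height`, `width`, `blocks`
#'   (data.frame `roi_id`, `row0`, `col0`, `nrow`, `ncol`; 1-based,
#'   origin top-left), `min_pixels`.
#' @export
layout_spec <- function(height = 240L, width = 320L,
                        grid_rows = 3L, grid_cols = 5L,
                        margin = 4L, min_pixels = 200L) {
  abort_if(grid_rows * grid_cols < N_ROIS, "grid too small for 15 ROIs")
  cell_h <- height %/% grid_rows
  cell_w <- width %/% grid_cols
  bh <- cell_h - 2L * margin
  bw <- cell_w - 2L * margin
  abort_if(bh < 1L || bw < 1L, "margin too large for image size")
  blocks <- data.frame(roi_id = integer(0), row0 = integer(0),
                       col0 = integer(0), nrow = integer(0), ncol = integer(0))
  r <- 1L
  for (gr in seq_len(grid_rows)) {
    for (gc in seq_len(grid_cols)) {
      if (r > N_ROIS) break
      blocks <- rbind(blocks, data.frame(
        roi_id = r,
        row0 = (gr - 1L) * cell_h + margin + 1L,
        col0 = (gc - 1L) * cell_w + margin + 1L,
        nrow = bh, ncol = bw))
      r <- r + 1L
    }
  }
  abort_if(any(blocks$nrow * blocks$ncol < min_pixels),
           "ROI blocks smaller than min_pixels = %d", min_pixels)
  structure(list(height = as.integer(height), width = as.integer(width),
                 blocks = blocks, min_pixels = as.integer(min_pixels)),
            class = "layout_spec")
}

layout_class_map <- function(layout) {
  cm <- matrix(0L, layout$height, layout$width)
  for (b in seq_len(nrow(layout$blocks))) {
    blk <- layout$blocks[b, ]
    cm[blk$row0:(blk$row0 + blk$nrow - 1L),
       blk$col0:(blk$col0 + blk$ncol - 1L)] <- blk$roi_id
  }
  cm
}

#' Anomaly specification
#'
#' Two outlier modes: `"global_cold_shift"` (negative `shift` applied to
#' every annotated pixel; emulates a long-haired, globally colder animal)
#' and `"warm_patches"` (positive `shift` applied to a random fraction
#' `patch_fraction` of the pixels of each GOR in `patch_gors`; emulates warm
#' areas from patchy hair loss).
#'
#' @param kind `"global_cold_shift"` or `"warm_patches"`.
#' @param shift degC; must be negative for the cold shift, positive for
#'   warm patches.
#' @param patch_gors GOR names receiving patches (warm_patches only).
#' @param patch_fraction fraction of each patch GOR's pixels shifted.
#' @return object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind = c("global_cold_shift", "warm_patches"),
                         shift, patch_gors = character(0),
                         patch_fraction = 0.5) {
  kind <- match.arg(kind)
  abort_if(kind == "global_cold_shift" && shift >= 0,
           "global_cold_shift requires a negative shift")
  abort_if(kind == "warm_patches" && shift <= 0,
           "warm_patches requires a positive shift")
  abort_if(kind == "warm_patches" && length(patch_gors) == 0L,
           "warm_patches needs at least one patch GOR")
  abort_if(patch_fraction < 0 || patch_fraction > 1,
           "patch_fraction must be in [0, 1]")
  structure(list(kind = kind, shift = shift, patch_gors = patch_gors,
                 patch_fraction = patch_fraction),
            class = "anomaly_spec")
}

resolve_pixel_sd <- function(cfg, roi_off, weights) {
  if (!is.null(cfg$pixel_sd)) return(cfg$pixel_sd)
  wmean <- sum(weights * roi_off)
  off_var <- sum(weights * (roi_off - wmean)^2)
  resid <- cfg$global_sd^2 - cfg$animal_sd^2 - off_var
  abort_if(resid < 0,
           "cannot balance pixel_sd: animal_sd^2 + offset variance exceeds global_sd^2")
  sqrt(resid)
}

#' Generate one synthetic animal record
#'
#' See [species_config()] for the pixel model. The anomaly, if any, is
#' applied last. Metadata (hair coat, SF-Skin) are drawn from the species'
#' truncated-at-zero gaussians when configured. Fully reproducible from
#' `seed`.
#'
#' @param species_cfg a [species_config()].
#' @param layout a [layout_spec()].
#' @param animal_id label for the record.
#' @param anomaly optional [anomaly_spec()].
#' @param seed integer seed for this animal's stream.
#' @param gors [gor_set()] used to resolve `gor_offsets` and `patch_gors`.
#' @param excluded mark the record excluded from formal analysis.
#' @return an [animal_record()].
#' @export
generate_animal <- function(species_cfg, layout = layout_spec(), animal_id,
                            anomaly = NULL, seed = 1L, gors = default_gors(),
                            excluded = FALSE) {
  cm <- layout_class_map(layout)
  roi_off <- resolve_roi_offsets(species_cfg$gor_offsets, gors)
  npix <- tabulate(cm[cm > 0L], nbins = N_ROIS)
  weights <- npix / sum(npix)
  # centre offsets so the expected annotated mean equals global_mean
  roi_off <- roi_off - sum(weights * roi_off)
  psd <- resolve_pixel_sd(species_cfg, roi_off, weights)

  with_seed(seed, {
    intercept <- rnorm(1, 0, species_cfg$animal_sd)
    img <- matrix(0, layout$height, layout$width)
    n_ann <- sum(cm > 0L)
    noise <- rnorm(n_ann, 0, psd)
    if (species_cfg$pixel_noise_shape == "two_component") {
      comp <- runif(n_ann) < species_cfg$mix_weight
      noise <- noise + ifelse(comp, species_cfg$mix_shift, 0) -
        species_cfg$mix_weight * species_cfg$mix_shift
    }
    ann_idx <- which(cm > 0L)
    img[ann_idx] <- species_cfg$global_mean + intercept +
      roi_off[cm[ann_idx]] + noise
    if (!is.null(anomaly)) {
      if (anomaly$kind == "global_cold_shift") {
        img[ann_idx] <- img[ann_idx] + anomaly$shift
      } else {
        # patches are drawn from the union of the patch GORs' pixels, so a
        # pixel shared by overlapping GORs is shifted at most once
        rois <- unique(unlist(lapply(anomaly$patch_gors, function(gn) {
          g <- gors[[gn]]
          abort_if(is.null(g), "unknown patch GOR '%s'", gn)
          g$roi_ids
        })))
        gidx <- which(cm %in% rois)
        k <- floor(anomaly$patch_fraction * length(gidx))
        if (k > 0L) {
          sel <- gidx[sample.int(length(gidx), k)]
          img[sel] <- img[sel] + anomaly$shift
        }
      }
    }
    hair <- if (!is.na(species_cfg$hair_coat_mean)) {
      abs(rnorm(1, species_cfg$hair_coat_mean, species_cfg$hair_coat_sd))
    } else NA_real_
    sf <- if (!is.na(species_cfg$sf_skin_mean)) {
      abs(rnorm(1, species_cfg$sf_skin_mean, species_cfg$sf_skin_sd))
    } else NA_real_
    md <- animal_metadata(animal_id, species_cfg$name,
                          hair_coat_length = hair, sf_skin_thickness = sf,
                          excluded = excluded)
    animal_record(md, img, cm)
  })
}

#' Generate a full two-species synthetic dataset
#'
#' One record per animal, ids `H.1..H.n` and `D.1..D.n`; each animal draws
#' from its own [stream_seed()] stream so the dataset is bit-reproducible
#' from `rng_seed` and insensitive to generation order. Anomalies are
#' attached by animal id.
#'
#' @param horse_cfg,donkey_cfg [species_config()] objects.
#' @param layout a [layout_spec()].
#' @param anomalies named list: animal id -> [anomaly_spec()]; those records
#'   are marked `excluded` when `exclude_anomalous = TRUE` (default),
#'   mirroring the exclusion of atypical animals from formal analysis.
#' @param rng_seed base integer seed.
#' @param gors [gor_set()] for offset/patch resolution.
#' @param exclude_anomalous flag anomalous records as excluded.
#' @return a `thermo_dataset`.
#' @export
generate_dataset <- function(horse_cfg, donkey_cfg, layout = layout_spec(),
                             anomalies = list(), rng_seed = 1L,
                             gors = default_gors(), exclude_anomalous = TRUE) {
  gen_species <- function(cfg, prefix) {
    lapply(seq_len(cfg$n_animals), function(i) {
      id <- sprintf("%s.%d", prefix, i)
      an <- anomalies[[id]]
      generate_animal(cfg, layout, id, anomaly = an,
                      seed = stream_seed(rng_seed, "animal", id),
                      gors = gors,
                      excluded = !is.null(an) && exclude_anomalous)
    })
  }
  new_dataset(c(gen_species(horse_cfg, "H"), gen_species(donkey_cfg, "D")))
}

#' Study-like generator preset
#'
#' The default emulation of the study data: 16 horses (global mean 22.72,
#' pooled sd 2.46 degC) and 16 donkeys (18.88, 2.30 degC); Neck and Front
#' quarter 1.5 degC warm, Rump and Legs 2.5 degC cold; horse intercept sd
#' 1.5, donkey 1.2 degC (donkeys more uniform); metadata at hair coat
#' 1.78+-0.38 cm (horses) / 3.39+-0.46 cm (donkeys) and SF-Skin
#' 8.80+-0.87 mm / 12.01+-0.83 mm. With `with_outliers = TRUE`, two extra
#' excluded donkeys are appended: `D.17` (globally 4 degC colder,
#' long-haired: hair coat 7.6 cm) and `D.18` (warm patches, +3.5 degC over
#' half of Rump, Legs and Hindquarter).
#'
#' @param with_outliers append the two outlier donkeys (default `FALSE`).
#' @return list with `horse_cfg`, `donkey_cfg`, `anomalies` and
#'   `n_donkeys` handled internally by [generate_study_dataset()].
#' @export
study_preset <- function(with_outliers = FALSE) {
  offsets <- list("Neck" = 1.5, "Front quarter" = 1.5,
                  "Rump" = -2.5, "Legs" = -2.5)
  horse <- species_config("horse", 16L, global_mean = 22.72, global_sd = 2.46,
                          gor_offsets = offsets, animal_sd = 1.5,
                          hair_coat_mean = 1.78, hair_coat_sd = 0.38,
                          sf_skin_mean = 8.80, sf_skin_sd = 0.87)
  donkey_n <- if (with_outliers) 18L else 16L
  donkey <- species_config("donkey", donkey_n, global_mean = 18.88,
                           global_sd = 2.30, gor_offsets = offsets,
                           animal_sd = 1.2,
                           hair_coat_mean = 3.39, hair_coat_sd = 0.46,
                           sf_skin_mean = 12.01, sf_skin_sd = 0.83)
  anomalies <- if (with_outliers) {
    list("D.17" = anomaly_spec("global_cold_shift", shift = -4),
         "D.18" = anomaly_spec("warm_patches", shift = 3.5,
                               patch_gors = c("Rump", "Legs", "Hindquarter"),
                               patch_fraction = 0.5))
  } else list()
  list(horse_cfg = horse, donkey_cfg = donkey, anomalies = anomalies)
}

#' Generate the study-like synthetic dataset
#'
#' Convenience wrapper: [study_preset()] plus [generate_dataset()].
#'
#' @param rng_seed base integer seed.
#' @param with_outliers append outlier donkeys D.17/D.18 (excluded records).
#' @param layout a [layout_spec()] (default native 240 x 320).
#' @return a `thermo_dataset` of 16 + 16 (+2) animals.
#' @export
generate_study_dataset <- function(rng_seed = 1L, with_outliers = FALSE,
                                   layout = layout_spec()) {
  p <- study_preset(with_outliers)
  ds <- generate_dataset(p$horse_cfg, p$donkey_cfg, layout = layout,
                         anomalies = p$anomalies, rng_seed = rng_seed)
  if (with_outliers) {
    # long-haired outlier: fix its hair coat metadata to the atypical length
    ds$records[["D.17"]]$metadata$hair_coat_length <- 7.6
  }
  ds
}
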