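# Species-level pattern statistics.
#
# For a species and a GOR set G, the signed difference matrix holds
# delta(i, j) = mean(pooled pixels of GOR i) - mean(pooled pixels of GOR j),
# tested "globally" on the pooled samples and "locally" per animal. A pattern
# significant globally and for every single animal is *stable*.

pair_indices <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

pooled_samples_by_gor <- function(dataset, species, gors, include_excluded = FALSE) {
  lapply(gors, function(g) {
    s <- pooled_gor_pixels(dataset, species, g, include_excluded = include_excluded)
    abort_if(length(s$values) == 0L,
             "pooled sample empty for GOR '%s' (%s)", g$name, species)
    s
  })
}

#' Signed GOR difference matrix
#'
#' Builds the antisymmetric matrix of pooled mean-temperature differences
#' `deltas[i, j] = mean(GOR i) - mean(GOR j)` for one species, pooling each
#' GOR's pixels over all non-excluded animals. Significance flags are `NULL`
#' until filled by [global_significance()].
#'
#' @param dataset a `thermo_dataset`.
#' @param species `"horse"` or `"donkey"`.
#' @param gors a [gor_set()] (default [default_gors()]).
#' @param include_excluded pool excluded animals too (default `FALSE`).
#' @return object of class `difference_matrix`: `deltas` (named k x k
#'   matrix, degrees C), `significant` (`NULL` or logical matrix),
#'   `p_values`, `gor_means`, `species`, `gor_set`, `n_animals`.
#' @export
difference_matrix <- function(dataset, species, gors = default_gors(),
                              include_excluded = FALSE) {
  samples <- pooled_samples_by_gor(dataset, species, gors, include_excluded)
  mu <- vapply(samples, sample_mean, numeric(1))
  k <- length(gors)
  deltas <- outer(mu, mu, `-`)
  diag(deltas) <- 0
  nm <- gor_names(gors)
  dimnames(deltas) <- list(nm, nm)
  n_animals <- length(dataset_records(dataset, species = species,
                                      include_excluded = include_excluded))
  structure(list(deltas = deltas, significant = NULL, p_values = NULL,
                 gor_means = setNames(mu, nm), species = species,
                 gor_set = gors, n_animals = n_animals),
            class = "difference_matrix")
}

#' @export
print.difference_matrix <- function(x, ...) {
  cat(sprintf("<difference_matrix> %s, %d GORs, %d animals%s\n", x$species,
              nrow(x$deltas), x$n_animals,
              if (is.null(x$significant)) " (significance not tested)" else ""))
  print(round(x$deltas, 2))
  invisible(x)
}

#' Global significance of every GOR pair difference
#'
#' For each unordered GOR pair the two pooled samples are size-matched with
#' [draw_test_samples()] and tested with the one-sided MWW in the direction
#' of the observed pooled difference; both symmetric cells of `significant`
#' are set to `p < alpha`. The diagonal is `FALSE`. Each pair draws from its
#' own seeded stream, so results do not depend on evaluation order.
#'
#' @inheritParams difference_matrix
#' @param config a [test_config()].
#' @return a `difference_matrix` with `significant` and `p_values` filled
#'   (symmetric; `p_values` holds the one-sided p of the tested direction).
#' @export
global_significance <- function(dataset, species, gors = default_gors(),
                                config = test_config(),
                                include_excluded = FALSE) {
  dm <- difference_matrix(dataset, species, gors, include_excluded)
  samples <- pooled_samples_by_gor(dataset, species, gors, include_excluded)
  k <- length(gors)
  nm <- gor_names(gors)
  sig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  pv <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pairs <- pair_indices(k)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dir <- if (dm$deltas[i, j] >= 0) "x_greater" else "y_greater"
    res <- sampled_mww(samples[[i]], samples[[j]], dir, config,
                       "global", species, nm[i], nm[j])
    sig[i, j] <- sig[j, i] <- res$p_value < config$alpha
    pv[i, j] <- pv[j, i] <- res$p_value
  }
  dm$significant <- sig
  dm$p_values <- pv
  dm$config <- config
  dm
}

#' Local (per-animal) significance count matrix
#'
#' For every unordered GOR pair, runs the size-matched one-sided MWW
#' separately for each non-excluded animal of the species, in the direction
#' of the *global* pooled difference sign; `counts[i, j]` is the number of
#' animals significant at `alpha`. An animal whose own mean difference
#' opposes the global sign cannot count as support (its one-sided p is large
#' by construction). Animals with an empty GOR are skipped for pairs
#' involving it and listed in the `skipped` attribute.
#'
#' @inheritParams global_significance
#' @return object of class `local_count_matrix`: `counts` (symmetric integer
#'   matrix, zero diagonal), `n_animals`, `species`, `gor_set`.
#' @export
local_count_matrix <- function(dataset, species, gors = default_gors(),
                               config = test_config(),
                               include_excluded = FALSE) {
  dm <- difference_matrix(dataset, species, gors, include_excluded)
  recs <- dataset_records(dataset, species = species,
                          include_excluded = include_excluded)
  k <- length(gors)
  nm <- gor_names(gors)
  counts <- matrix(0L, k, k, dimnames = list(nm, nm))
  skipped <- character(0)
  per_animal <- lapply(recs, function(r) lapply(gors, function(g) gor_pixels(r, g)))
  pairs <- pair_indices(k)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dir <- if (dm$deltas[i, j] >= 0) "x_greater" else "y_greater"
    cnt <- 0L
    for (a in seq_along(recs)) {
      si <- per_animal[[a]][[i]]
      sj <- per_animal[[a]][[j]]
      if (length(si$values) == 0L || length(sj$values) == 0L) {
        skipped <- c(skipped, sprintf("%s:%s/%s", recs[[a]]$metadata$animal_id,
                                      nm[i], nm[j]))
        next
      }
      res <- sampled_mww(si, sj, dir, config,
                         "local", species, nm[i], nm[j],
                         recs[[a]]$metadata$animal_id)
      if (res$p_value < config$alpha) cnt <- cnt + 1L
    }
    counts[i, j] <- counts[j, i] <- cnt
  }
  structure(list(counts = counts, n_animals = length(recs), species = species,
                 gor_set = gors, skipped = skipped, config = config),
            class = "local_count_matrix")
}

#' @export
print.local_count_matrix <- function(x, ...) {
  cat(sprintf("<local_count_matrix> %s, %d animals\n", x$species, x$n_animals))
  print(x$counts)
  invisible(x)
}

#' Stable thermal patterns
#'
#' A pattern (GOR pair) is *stable* when it is globally significant and
#' locally significant for every one of the species' animals.
#'
#' @param diff a `difference_matrix` with significance filled (from
#'   [global_significance()]).
#' @param local a `local_count_matrix` for the same species and GOR set.
#' @return data.frame of unordered pairs (`gor_i`, `gor_j`, `delta`,
#'   `count`), one row per stable pattern.
#' @export
stable_patterns <- function(diff, local) {
  abort_if(is.null(diff$significant),
           "difference matrix has no significance flags; run global_significance()")
  abort_if(!identical(gor_names(diff$gor_set), gor_names(local$gor_set)) ||
             !identical(diff$species, local$species),
           "difference and local matrices must share species and GOR set")
  k <- nrow(diff$deltas)
  nm <- rownames(diff$deltas)
  pairs <- pair_indices(k)
  keep <- vapply(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    diff$significant[i, j] && local$counts[i, j] == local$n_animals
  }, logical(1))
  data.frame(gor_i = nm[pairs[keep, 1]], gor_j = nm[pairs[keep, 2]],
             delta = diff$deltas[pairs[keep, , drop = FALSE]],
             count = local$counts[pairs[keep, , drop = FALSE]],
             stringsAsFactors = FALSE)
}

#' Species comparison for one ROI
#'
#' Pools each species' pixels for one ROI over the non-excluded animals and
#' reports the mean difference `delta_t = mean(horses) - mean(donkeys)`
#' together with the size-matched one-sided MWW p-value (direction from the
#' observed sign).
#'
#' @param dataset a `thermo_dataset` containing both species.
#' @param roi_id integer ROI label 1..15.
#' @param config a [test_config()].
#' @return list with `roi_id`, `delta_t` (degrees C), `test` ([mww_one_sided()]
#'   result) and per-species pooled means.
#' @export
species_roi_comparison <- function(dataset, roi_id, config = test_config()) {
  pool <- function(sp) {
    recs <- dataset_records(dataset, species = sp)
    abort_if(length(recs) == 0L, "no %s records in dataset", sp)
    vals <- unlist(lapply(recs, function(r) extract_roi_pixels(r, roi_id)$values),
                   use.names = FALSE)
    s <- pixel_sample(vals %||% numeric(0), sprintf("%s(pooled)/ROI%d", sp, roi_id))
    abort_if(length(s$values) == 0L, "ROI %d absent in species %s", roi_id, sp)
    s
  }
  h <- pool("horse"); d <- pool("donkey")
  delta_t <- sample_mean(h) - sample_mean(d)
  dir <- if (delta_t >= 0) "x_greater" else "y_greater"
  res <- sampled_mww(h, d, dir, config, "roi_species", roi_id)
  list(roi_id = as.integer(roi_id), delta_t = delta_t, test = res,
       mean_horse = sample_mean(h), mean_donkey = sample_mean(d))
}

#' Species comparison of a metadata field
#'
#' One-sided MWW on the per-animal values of a metadata covariate (hair coat
#' length in cm or SF-Skin thickness in mm), direction taken from the sign of
#' the species mean difference, plus per-species mean and sd.
#'
#' @param dataset a `thermo_dataset`.
#' @param field `"hair_coat_length"` or `"sf_skin_thickness"`.
#' @param config a [test_config()].
#' @return list with `field`, `test`, and per-species `mean`/`sd`/`n`.
#' @export
compare_metadata <- function(dataset, field = c("hair_coat_length",
                                                "sf_skin_thickness"),
                             config = test_config()) {
  field <- match.arg(field)
  get_vals <- function(sp) {
    recs <- dataset_records(dataset, species = sp)
    v <- vapply(recs, function(r) r$metadata[[field]], numeric(1))
    missing <- vapply(recs, function(r) r$metadata$animal_id, character(1))[is.na(v)]
    abort_if(length(missing) > 0, "missing %s for: %s", field,
             paste(missing, collapse = ", "))
    abort_if(length(v) < 2L, "need >= 2 %s animals with %s", sp, field)
    v
  }
  h <- get_vals("horse"); d <- get_vals("donkey")
  dir <- if (mean(h) - mean(d) >= 0) "x_greater" else "y_greater"
  res <- sampled_mww(pixel_sample(h, paste0("horse/", field)),
                     pixel_sample(d, paste0("donkey/", field)),
                     dir, config, "metadata", field)
  list(field = field, test = res,
       horse = list(mean = mean(h), sd = sd(h), n = length(h)),
       donkey = list(mean = mean(d), sd = sd(d), n = length(d)))
}

#' Write pattern matrices as delimited text
#'
#' Emits the signed difference matrix (full precision), its significance
#' flags, the local count matrix and a small run log (seed, alpha, n-rule)
#' into a directory.
#'
#' @param diff a `difference_matrix` from [global_significance()].
#' @param local a `local_count_matrix`.
#' @param dir output directory.
#' @return invisibly, the vector of files written.
#' @export
write_pattern_tables <- function(diff, local, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(deltas = file.path(dir, sprintf("%s_deltas.tsv", diff$species)),
         sig = file.path(dir, sprintf("%s_significant.tsv", diff$species)),
         counts = file.path(dir, sprintf("%s_local_counts.tsv", local$species)),
         log = file.path(dir, sprintf("%s_run_log.txt", diff$species)))
  wt <- function(m, path) {
    utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  }
  wt(diff$deltas, f["deltas"])
  wt(diff$significant, f["sig"])
  wt(local$counts, f["counts"])
  cfg <- diff$config %||% test_config()
  writeLines(c(sprintf("species: %s", diff$species),
               sprintf("alpha: %g", cfg$alpha),
               sprintf("seed: %d", cfg$rng_seed),
               sprintf("n_rule: %s", cfg$n_rule),
               sprintf("n_animals: %d", local$n_animals)), f["log"])
  invisible(f)
}
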