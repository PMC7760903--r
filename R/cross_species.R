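# Cross-species pattern comparison.
#
# Each unordered GOR pair is assigned one of six classes by comparing the
# signed differences of the two species:
#   SPS / SP  same sign, globally significant in both species / not;
#   HWS / HW  opposite signs with horses on the warmer side, significant / not;
#   HCS / HC  opposite signs with horses on the colder side, significant / not.
# The orientation is canonicalised on the (i < j) rendering of the pair so the
# class matrix is symmetric. For the significant classes the minimum number
# of animals (over species) locally sharing the pattern is recorded; 16 means
# the pattern is stable in both species.

PATTERN_CLASSES <- c("SPS", "SP", "HWS", "HW", "HCS", "HC")

#' Classify GOR-pair patterns across the two species
#'
#' @param horse_diff,donkey_diff `difference_matrix` objects with
#'   significance filled ([global_significance()]), same GOR set.
#' @param horse_local,donkey_local matching `local_count_matrix` objects.
#' @return object of class `pattern_class_matrix`: `classes` (symmetric
#'   character matrix with `NA` diagonal), `min_shared` (integer matrix,
#'   defined for classes SPS/HWS/HCS), and the GOR set.
#' @export
classify_patterns <- function(horse_diff, donkey_diff, horse_local, donkey_local) {
  nm <- rownames(horse_diff$deltas)
  same_set <- function(m) identical(rownames(m), nm)
  abort_if(!same_set(donkey_diff$deltas) || !same_set(horse_local$counts) ||
             !same_set(donkey_local$counts),
           "all four matrices must be built on the same GOR set")
  abort_if(is.null(horse_diff$significant) || is.null(donkey_diff$significant),
           "difference matrices need significance flags; run global_significance()")
  k <- length(nm)
  classes <- matrix(NA_character_, k, k, dimnames = list(nm, nm))
  min_shared <- matrix(NA_integer_, k, k, dimnames = list(nm, nm))
  pairs <- pair_indices(k)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    sh <- sign(horse_diff$deltas[i, j])
    sd_ <- sign(donkey_diff$deltas[i, j])
    both_sig <- horse_diff$significant[i, j] && donkey_diff$significant[i, j]
    opposite <- sh * sd_ < 0
    cls <- if (!opposite) {
      if (both_sig) "SPS" else "SP"
    } else if (sh > 0) {              # horses warmer on the i-vs-j contrast
      if (both_sig) "HWS" else "HW"
    } else {
      if (both_sig) "HCS" else "HC"
    }
    classes[i, j] <- classes[j, i] <- cls
    if (cls %in% c("SPS", "HWS", "HCS")) {
      ms <- min(horse_local$counts[i, j], donkey_local$counts[i, j])
      min_shared[i, j] <- min_shared[j, i] <- as.integer(ms)
    }
  }
  structure(list(classes = classes, min_shared = min_shared,
                 gor_set = horse_diff$gor_set,
                 n_horses = horse_local$n_animals,
                 n_donkeys = donkey_local$n_animals),
            class = "pattern_class_matrix")
}

#' @export
print.pattern_class_matrix <- function(x, ...) {
  cat("<pattern_class_matrix>\n")
  print(x$classes, quote = FALSE, na.print = ".")
  invisible(x)
}

#' Proportion of each pattern class over the unordered GOR pairs
#'
#' @param classes a `pattern_class_matrix`.
#' @return named numeric vector of fractions over `{SPS, SP, HWS, HW, HCS,
#'   HC}`, summing to 1, with attribute `"percent"` rounded to one decimal.
#' @export
taxonomy_summary <- function(classes) {
  k <- nrow(classes$classes)
  vals <- classes$classes[upper.tri(classes$classes)]
  frac <- vapply(PATTERN_CLASSES, function(cl) mean(vals == cl), numeric(1))
  attr(frac, "percent") <- round(100 * frac, 1)
  attr(frac, "n_pairs") <- length(vals)
  frac
}

#' Compliance of one animal with a species' global pattern
#'
#' For every unordered GOR pair the entry is `"S"` when the animal's own mean
#' difference has the same sign as the reference (species-global) difference
#' *and* the size-matched one-sided MWW on the animal's two GOR samples, in
#' the reference direction, is significant at `alpha`; otherwise `"NS"`.
#' When scoring an animal of the reference species, build the reference with
#' that animal excluded (leave-one-out), e.g. by flagging it `excluded` in
#' the dataset before calling [difference_matrix()]/[global_significance()].
#' Empty GOR samples give `"NS"` with the reason recorded in `skipped`.
#'
#' @param animal an [animal_record()].
#' @param reference a `difference_matrix` for the reference species.
#' @param gors the [gor_set()] used for `reference`.
#' @param config a [test_config()].
#' @return object of class `compliance_matrix`: `entries` (symmetric
#'   character matrix of `"S"`/`"NS"`, `NA` diagonal), `animal_id`,
#'   `reference_species`, `skipped`.
#' @export
compliance_matrix <- function(animal, reference, gors = default_gors(),
                              config = test_config()) {
  abort_if(!identical(gor_names(gors), rownames(reference$deltas)),
           "GOR set does not match the reference matrix")
  k <- length(gors)
  nm <- gor_names(gors)
  entries <- matrix(NA_character_, k, k, dimnames = list(nm, nm))
  skipped <- character(0)
  own <- lapply(gors, function(g) gor_pixels(animal, g))
  pairs <- pair_indices(k)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    ref_sign <- sign(reference$deltas[i, j])
    si <- own[[i]]; sj <- own[[j]]
    if (length(si$values) == 0L || length(sj$values) == 0L) {
      entries[i, j] <- entries[j, i] <- "NS"
      skipped <- c(skipped, sprintf("%s/%s: empty GOR sample", nm[i], nm[j]))
      next
    }
    own_sign <- sign(mean(si$values) - mean(sj$values))
    ok <- FALSE
    if (ref_sign != 0 && own_sign == ref_sign) {
      dir <- if (ref_sign > 0) "x_greater" else "y_greater"
      res <- sampled_mww(si, sj, dir, config,
                         "compliance", reference$species, nm[i], nm[j],
                         animal$metadata$animal_id)
      ok <- res$p_value < config$alpha
    }
    entries[i, j] <- entries[j, i] <- if (ok) "S" else "NS"
  }
  structure(list(entries = entries, animal_id = animal$metadata$animal_id,
                 reference_species = reference$species, skipped = skipped),
            class = "compliance_matrix")
}

#' @export
print.compliance_matrix <- function(x, ...) {
  cat(sprintf("<compliance_matrix> %s vs global %s pattern (%d NS pairs)\n",
              x$animal_id, x$reference_species, ns_count(x)))
  print(x$entries, quote = FALSE, na.print = ".")
  invisible(x)
}

#' Number of non-compliant (NS) unordered pairs in a compliance matrix
#'
#' Provided as a convenience score for ranking candidate outliers; this is an
#' extension, not an automated outlier detector.
#'
#' @param compliance a `compliance_matrix`.
#' @return integer count of NS pairs (of `choose(k, 2)`).
#' @export
ns_count <- function(compliance) {
  sum(compliance$entries[upper.tri(compliance$entries)] == "NS")
}

#' Write cross-species comparison tables as delimited text
#'
#' @param classes a `pattern_class_matrix`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_comparison_tables <- function(classes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(classes = file.path(dir, "pattern_classes.tsv"),
         min_shared = file.path(dir, "min_shared.tsv"),
         summary = file.path(dir, "taxonomy_summary.tsv"))
  utils::write.table(classes$classes, f["classes"], sep = "\t", quote = FALSE,
                     col.names = NA, na = ".")
  utils::write.table(classes$min_shared, f["min_shared"], sep = "\t",
                     quote = FALSE, col.names = NA, na = ".")
  ts <- taxonomy_summary(classes)
  utils::write.table(data.frame(class = names(ts), fraction = as.numeric(ts),
                                percent = attr(ts, "percent")),
                     f["summary"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(f)
}
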