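# Shared fixtures: small layouts, hand-built records, and independent
# oracles used to cross-check the package's own code paths.

# compact layout: 15 blocks of 14 x 14 px in a 48 x 80 image
small_layout <- function() {
  layout_spec(48, 80, margin = 1, min_pixels = 100)
}

# minimal layout for replicated Monte-Carlo runs: 8 x 8 px blocks
tiny_layout <- function() {
  layout_spec(24, 40, margin = 0, min_pixels = 60)
}

# a hand-built record: constant temperature, explicit class map
manual_record <- function(value = 20, labels = NULL, id = "T.1",
                          species = "horse") {
  if (is.null(labels)) {
    labels <- matrix(0L, 6, 10)
    labels[1:3, 1:5] <- 1L
    labels[4:6, 1:5] <- 2L
    labels[1:2, 6:10] <- 3L
  }
  img <- matrix(value, nrow(labels), ncol(labels))
  animal_record(animal_metadata(id, species), img, labels)
}

# study-like dataset at test scale
small_study <- function(seed = 1, with_outliers = FALSE) {
  generate_study_dataset(seed, with_outliers = with_outliers,
                         layout = small_layout())
}

# Independent oracle: exact one-sided MWW p-value by enumerating every
# assignment of the pooled values to the two groups (no ties assumed).
mww_enum_p <- function(x, y, direction = "x_greater") {
  if (direction == "y_greater") { tmp <- x; x <- y; y <- tmp }
  vals <- c(x, y)
  m <- length(x)
  u_obs <- sum(outer(x, y, ">"))
  assignments <- utils::combn(length(vals), m)
  us <- apply(assignments, 2, function(idx) {
    sum(outer(vals[idx], vals[-idx], ">"))
  })
  mean(us >= u_obs)
}

# mean silhouette width of a 2-column embedding over labels
mean_silhouette <- function(Y, labels) {
  s <- cluster::silhouette(as.integer(factor(labels)), stats::dist(Y))
  mean(s[, 3])
}

# configured (noise-free) GOR mean offsets implied by a species config and
# layout, computed independently of the generator internals
expected_gor_offsets <- function(cfg, layout = small_layout(),
                                 gors = default_gors()) {
  roi_off <- resolve_roi_offsets(cfg$gor_offsets, gors)
  cm <- matrix(0L, layout$height, layout$width)
  for (b in seq_len(nrow(layout$blocks))) {
    blk <- layout$blocks[b, ]
    cm[blk$row0:(blk$row0 + blk$nrow - 1L),
       blk$col0:(blk$col0 + blk$ncol - 1L)] <- blk$roi_id
  }
  npix <- tabulate(cm[cm > 0L], nbins = 15)
  vapply(gors, function(g) {
    sum(roi_off[g$roi_ids] * npix[g$roi_ids]) / sum(npix[g$roi_ids])
  }, numeric(1))
}
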