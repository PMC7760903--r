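# Per-animal feature vectors and 2-D embedding.
#
# An animal is summarised by one statistic (mean, sd, excess kurtosis or
# skewness) of the temperatures in each of its 15 ROIs, optionally after
# subtracting the animal's global annotated-pixel mean. Vectors are embedded
# in 2-D with exact t-SNE; only neighbourhood structure in the embedding is
# interpretable, coordinates have no absolute meaning.

FEATURE_STATS <- c("mean", "sd", "kurtosis", "skewness")

# minimum pixels per ROI for each statistic to be defined
stat_min_n <- c(mean = 1L, sd = 2L, skewness = 3L, kurtosis = 4L)

#' Extract a per-ROI feature vector for one animal
#'
#' Computes `statistic` over each ROI's pixel temperatures (ROI order
#' 1..15). With `normalized = TRUE` the animal's global mean over all
#' annotated pixels is subtracted from every pixel first, so the transformed
#' annotated mean is exactly zero. ROIs with too few pixels for the
#' statistic (sd: 2, skewness: 3, kurtosis: 4) yield `NA` and are listed in
#' `missing`. Kurtosis is the excess convention (normal = 0).
#'
#' @param record an [animal_record()] with at least one annotated pixel.
#' @param statistic one of `"mean"`, `"sd"`, `"kurtosis"`, `"skewness"`.
#' @param normalized subtract the animal's global annotated mean first.
#' @return object of class `feature_vector`: `animal_id`, `species`,
#'   `statistic`, `normalized`, `values` (named numeric length 15),
#'   `missing` (ROI ids with undefined entries).
#' @export
extract_features <- function(record, statistic = FEATURE_STATS,
                             normalized = FALSE) {
  statistic <- match.arg(statistic)
  abort_if(sum(record$class_map > 0L) == 0L,
           "record %s has no annotated pixels", record$metadata$animal_id)
  img <- record$image
  if (normalized) img <- img - mean(img[record$class_map > 0L])
  fn <- switch(statistic,
               mean = mean,
               sd = sd,
               kurtosis = function(v) e1071::kurtosis(v),
               skewness = function(v) e1071::skewness(v))
  vals <- vapply(seq_len(N_ROIS), function(r) {
    v <- img[record$class_map == r]
    if (length(v) < stat_min_n[[statistic]]) return(NA_real_)
    fn(v)
  }, numeric(1))
  names(vals) <- paste0("ROI", seq_len(N_ROIS))
  structure(list(animal_id = record$metadata$animal_id,
                 species = record$metadata$species,
                 statistic = statistic, normalized = normalized,
                 values = vals, missing = which(is.na(vals))),
            class = "feature_vector")
}

#' Feature matrix for a whole dataset
#'
#' @param dataset a `thermo_dataset`.
#' @inheritParams extract_features
#' @param include_excluded include excluded animals (default `FALSE`).
#' @return numeric matrix (animals x 15 ROIs) with animal ids as row names
#'   and a `"species"` attribute (character vector per row).
#' @export
feature_matrix <- function(dataset, statistic = FEATURE_STATS,
                           normalized = FALSE, include_excluded = FALSE) {
  statistic <- match.arg(statistic)
  recs <- dataset_records(dataset, include_excluded = include_excluded)
  fvs <- lapply(recs, extract_features, statistic = statistic,
                normalized = normalized)
  X <- do.call(rbind, lapply(fvs, `[[`, "values"))
  rownames(X) <- vapply(fvs, `[[`, character(1), "animal_id")
  attr(X, "species") <- vapply(fvs, `[[`, character(1), "species")
  X
}

#' Embedding configuration
#'
#' @param perplexity t-SNE perplexity (default 5; must be smaller than the
#'   number of points).
#' @param rng_seed integer seed making the embedding reproducible.
#' @param max_iter gradient-descent iterations (default 600).
#' @return object of class `embed_config`.
#' @export
embed_config <- function(perplexity = 5, rng_seed = 1L, max_iter = 600L) {
  abort_if(perplexity <= 0, "perplexity must be positive")
  structure(list(perplexity = perplexity, rng_seed = as.integer(rng_seed),
                 max_iter = as.integer(max_iter)),
            class = "embed_config")
}

#' Embed feature vectors in two dimensions (exact t-SNE)
#'
#' Exact t-SNE: per-point Gaussian bandwidths found by binary search to the
#' target perplexity, then Kullback-Leibler gradient descent with momentum
#' and early exaggeration on the symmetrised affinities. With a fixed
#' `rng_seed` the output is bit-reproducible. Vectors with missing entries
#' are rejected by name (no imputation).
#'
#' @param X numeric matrix (points x features), e.g. from
#'   [feature_matrix()]; needs at least `perplexity + 2` rows.
#' @param config an [embed_config()].
#' @return numeric matrix (points x 2) with `X`'s row names and any
#'   `"species"` attribute carried through.
#' @export
embed_2d <- function(X, config = embed_config()) {
  abort_if(!is.matrix(X) || !is.numeric(X), "X must be a numeric matrix")
  bad <- rownames(X)[apply(X, 1, function(r) any(!is.finite(r)))]
  abort_if(length(bad) > 0, "vectors with missing entries: %s",
           paste(bad, collapse = ", "))
  n <- nrow(X)
  abort_if(n < config$perplexity + 2,
           "too few points (%d) for perplexity %g; use a smaller perplexity",
           n, config$perplexity)
  P <- tsne_affinities(X, config$perplexity)
  Y <- with_seed(config$rng_seed,
                 tsne_descent(P, max_iter = config$max_iter))
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("x", "y")
  attr(Y, "species") <- attr(X, "species")
  Y
}

# Symmetrised input affinities at the target perplexity.
tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:64) {
      w <- exp(-d * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        p <- w / sw
        h <- -sum(ifelse(p > 0, p * log(p), 0))   # Shannon entropy
      }
      if (abs(h - target) < 1e-7) break
      if (h > target) {                            # too spread: raise beta
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    pi_ <- exp(-d * beta)
    pi_ <- pi_ / sum(pi_)
    P[i, -i] <- pi_
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Standard t-SNE gradient descent (momentum + gains + early exaggeration).
tsne_descent <- function(P, max_iter = 600L, eta = 100,
                         exaggeration = 12, exag_iter = 150L) {
  n <- nrow(P)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Pu <- if (iter <= exag_iter) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pu - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
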