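# Rendering conventions: violet-to-red thermal maps over a fixed temperature
# range, probability-normalised histograms, and Tukey boxplot summaries.

#' Rendering configuration
#'
#' The default common colour range 8.8..30.65 degC spans the extreme
#' annotated-ROI temperatures across both species; `per_animal` mode instead
#' stretches the range to each record's own annotated min/max to highlight
#' individual patterns.
#'
#' @param t_low,t_high colour range endpoints in degrees C (`t_low < t_high`).
#' @param mode `"common_range"` or `"per_animal"`.
#' @param background colour for unannotated pixels (default black).
#' @return object of class `render_config`.
#' @export
render_config <- function(t_low = 8.8, t_high = 30.65,
                          mode = c("common_range", "per_animal"),
                          background = "black") {
  mode <- match.arg(mode)
  abort_if(t_low >= t_high, "t_low must be < t_high")
  structure(list(t_low = t_low, t_high = t_high, mode = mode,
                 background = background),
            class = "render_config")
}

#' Violet-to-red colour lookup table
#'
#' A fixed 256-entry colour table running from violet (cold) to red (warm),
#' modelled on the visible electromagnetic spectrum. It approximates the
#' conventional IRT rendering; it is not a bit-for-bit match of any camera
#' vendor's palette.
#'
#' @param n number of entries (default 256).
#' @return character vector of hex colours.
#' @export
thermal_colormap <- function(n = 256L) {
  rev(grDevices::rainbow(n, start = 0, end = 0.8))
}

#' Render a record's thermal map as an RGB raster
#'
#' Annotated pixels are mapped linearly over `[t_low, t_high]` onto the
#' violet-to-red table, clamped at the endpoints; unannotated pixels take the
#' background colour. `per_animal` mode replaces the range with the record's
#' annotated min/max.
#'
#' @param record an [animal_record()].
#' @param config a [render_config()].
#' @return numeric array `rows x cols x 3` of RGB values in `[0, 1]`, with
#'   attributes `t_low`/`t_high` (the range actually used).
#' @export
render_thermal_map <- function(record, config = render_config()) {
  lut <- t(grDevices::col2rgb(thermal_colormap()) / 255)
  bg <- as.numeric(grDevices::col2rgb(config$background) / 255)
  rng <- if (config$mode == "per_animal") {
    ann <- record$image[record$class_map > 0L]
    abort_if(length(ann) == 0L, "per_animal range undefined: no annotated pixels")
    range(ann)
  } else c(config$t_low, config$t_high)
  frac <- (record$image - rng[1]) / (rng[2] - rng[1])
  frac <- pmin(pmax(frac, 0), 1)
  idx <- 1L + as.integer(round(frac * (nrow(lut) - 1L)))
  h <- nrow(record$image); w <- ncol(record$image)
  out <- array(0, dim = c(h, w, 3))
  ann_mask <- record$class_map > 0L
  for (ch in 1:3) {
    plane <- matrix(bg[ch], h, w)
    plane[ann_mask] <- lut[idx[ann_mask], ch]
    out[, , ch] <- plane
  }
  attr(out, "t_low") <- rng[1]
  attr(out, "t_high") <- rng[2]
  out
}

#' Write a rendered thermal map to a PNG file
#'
#' @param raster array from [render_thermal_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thermal_png <- function(raster, path) {
  png::writePNG(raster, path)
  invisible(path)
}

#' Probability-normalised histogram of a pixel sample
#'
#' Bin heights are counts divided by the total count, so heights sum to 1
#' (the convention used throughout the analysis); `true_density = TRUE`
#' instead divides by total x bin width. Bins are equal-width over the sample
#' range unless explicit `breaks` are given; a zero-width range is expanded
#' by +-0.5 degC around the single value.
#'
#' @param sample a non-empty [pixel_sample()].
#' @param bins number of bins (>= 1), ignored when `breaks` given.
#' @param breaks optional explicit bin edges (ascending).
#' @param true_density divide by bin width as well (default `FALSE`).
#' @return list with `breaks`, `counts`, `heights` and `mids`.
#' @export
temperature_histogram <- function(sample, bins = 20L, breaks = NULL,
                                  true_density = FALSE) {
  v <- sample$values
  abort_if(length(v) == 0L, "empty pixel sample: %s", sample$source)
  if (is.null(breaks)) {
    abort_if(bins < 1L, "bins must be >= 1")
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  }
  abort_if(any(v < breaks[1] | v > breaks[length(breaks)]),
           "values outside the given breaks")
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  heights <- counts / sum(counts)
  if (true_density) heights <- heights / diff(breaks)
  list(breaks = breaks, counts = counts, heights = heights,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
}

#' Overlap coefficient of two samples' histograms on shared bins
#'
#' Builds both probability-normalised histograms on a common set of
#' equal-width edges spanning the union range and returns the sum of
#' per-bin minima (1 = identical binned distributions, 0 = disjoint).
#'
#' @param sample_a,sample_b [pixel_sample()] objects.
#' @param bins number of shared bins.
#' @return overlap coefficient in `[0, 1]`.
#' @export
histogram_overlap <- function(sample_a, sample_b, bins = 30L) {
  rng <- range(c(sample_a$values, sample_b$values))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  ha <- temperature_histogram(sample_a, breaks = breaks)
  hb <- temperature_histogram(sample_b, breaks = breaks)
  sum(pmin(ha$heights, hb$heights))
}

#' Boxplot summary of a pixel sample
#'
#' Quartiles use the linear-interpolation convention
#' ([stats::quantile] type 7). Whiskers sit at the Tukey fences
#' `q1 - 1.5 IQR` and `q3 + 1.5 IQR`, clipped to the most extreme observed
#' values inside the fences; values beyond the fences are outliers.
#'
#' @param sample a non-empty [pixel_sample()].
#' @return object of class `boxplot_stats`: `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
boxplot_stats <- function(sample) {
  v <- sample$values
  abort_if(length(v) == 0L, "empty pixel sample: %s", sample$source)
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lf <- q[1] - 1.5 * iqr
  uf <- q[3] + 1.5 * iqr
  inside <- v[v >= lf & v <= uf]
  structure(list(q1 = q[1], median = q[2], q3 = q[3],
                 whisker_low = min(inside), whisker_high = max(inside),
                 outliers = sort(v[v < lf | v > uf])),
            class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf("<boxplot_stats> q1 = %.2f, median = %.2f, q3 = %.2f, whiskers [%.2f, %.2f], %d outliers\n",
              x$q1, x$median, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}
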