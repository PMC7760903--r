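# Dataset containers and portable text I/O.
#
# A record pairs a thermal image (numeric grid, degrees C) with a class map
# (integer grid; ROI labels 1..15, 0 = unannotated) and animal metadata.
# The portable on-disk format is one comma-separated grid file per image and
# per class map plus a YAML manifest, so a dataset is fully reproducible from
# plain text.

N_ROIS <- 15L

#' Construct animal metadata
#'
#' @param animal_id text label, e.g. `"H.1"` or `"D.17"`.
#' @param species `"horse"` or `"donkey"`.
#' @param hair_coat_length hair coat length in cm (optional, `NA` if unknown).
#' @param sf_skin_thickness subcutaneous fat plus skin thickness in mm
#'   (optional).
#' @param excluded logical; excluded animals stay retrievable but are omitted
#'   from formal (pooled) selections by default.
#' @return an object of class `animal_metadata`.
#' @export
animal_metadata <- function(animal_id, species = c("horse", "donkey"),
                            hair_coat_length = NA_real_,
                            sf_skin_thickness = NA_real_,
                            excluded = FALSE) {
  species <- match.arg(species)
  abort_if(!is.character(animal_id) || length(animal_id) != 1L || !nzchar(animal_id),
           "animal_id must be a non-empty string")
  abort_if(!is.na(hair_coat_length) && hair_coat_length <= 0,
           "hair_coat_length must be > 0 for animal %s", animal_id)
  abort_if(!is.na(sf_skin_thickness) && sf_skin_thickness <= 0,
           "sf_skin_thickness must be > 0 for animal %s", animal_id)
  structure(list(animal_id = animal_id, species = species,
                 hair_coat_length = as.numeric(hair_coat_length),
                 sf_skin_thickness = as.numeric(sf_skin_thickness),
                 excluded = isTRUE(excluded)),
            class = "animal_metadata")
}

#' Construct an animal record (thermal image + class map + metadata)
#'
#' Validates the joint invariants: matching shapes, integer labels in 0..15,
#' finite annotated temperatures. Non-fatal findings (non-native 240 x 320
#' shape, annotated temperatures outside the -20..60 degC sanity window) are
#' collected in the record's `flags` attribute rather than raised.
#'
#' @param metadata an [animal_metadata()] object.
#' @param image numeric matrix of temperatures (degrees C), rows x cols.
#' @param class_map integer matrix of the same shape; labels 0..15.
#' @return an object of class `animal_record` with elements `metadata`,
#'   `image`, `class_map` and a character vector `flags`.
#' @export
animal_record <- function(metadata, image, class_map) {
  abort_if(!inherits(metadata, "animal_metadata"), "metadata must be animal_metadata")
  abort_if(!is.matrix(image) || !is.numeric(image),
           "image must be a numeric matrix (animal %s)", metadata$animal_id)
  abort_if(!is.matrix(class_map) || !is.numeric(class_map),
           "class_map must be a numeric/integer matrix (animal %s)", metadata$animal_id)
  abort_if(!identical(dim(image), dim(class_map)),
           "image (%d x %d) and class map (%d x %d) shapes differ for animal %s",
           nrow(image), ncol(image), nrow(class_map), ncol(class_map),
           metadata$animal_id)
  cm <- class_map
  abort_if(any(cm != round(cm)) || any(is.na(cm)),
           "class map labels must be integers for animal %s", metadata$animal_id)
  abort_if(any(cm < 0 | cm > N_ROIS),
           "class map label outside 0..%d for animal %s", N_ROIS, metadata$animal_id)
  storage.mode(cm) <- "integer"
  annotated <- image[cm > 0L]
  abort_if(length(annotated) > 0 && any(!is.finite(annotated)),
           "non-finite annotated temperature for animal %s", metadata$animal_id)
  flags <- character(0)
  if (nrow(image) != 240L || ncol(image) != 320L) {
    flags <- c(flags, sprintf("non-native shape %d x %d", nrow(image), ncol(image)))
  }
  if (length(annotated) > 0 && (min(annotated) < -20 || max(annotated) > 60)) {
    flags <- c(flags, "annotated temperatures outside sanity window [-20, 60] degC")
  }
  if (length(annotated) == 0L) flags <- c(flags, "no annotated pixels")
  structure(list(metadata = metadata, image = image, class_map = cm,
                 flags = flags),
            class = "animal_record")
}

#' @export
print.animal_record <- function(x, ...) {
  cat(sprintf("<animal_record %s (%s)%s> %d x %d, %d annotated px%s\n",
              x$metadata$animal_id, x$metadata$species,
              if (x$metadata$excluded) ", excluded" else "",
              nrow(x$image), ncol(x$image), sum(x$class_map > 0L),
              if (length(x$flags)) paste0("; flags: ", paste(x$flags, collapse = "; ")) else ""))
  invisible(x)
}

#' Construct a dataset from animal records
#'
#' @param records list of [animal_record()] objects with unique animal ids.
#' @param manifest_path optional path the dataset was loaded from.
#' @return an object of class `thermo_dataset`.
#' @export
new_dataset <- function(records, manifest_path = NA_character_) {
  abort_if(!is.list(records) ||
             !all(vapply(records, inherits, logical(1), "animal_record")),
           "records must be a list of animal_record objects")
  ids <- vapply(records, function(r) r$metadata$animal_id, character(1))
  dup <- ids[duplicated(ids)]
  abort_if(length(dup) > 0, "duplicate animal ids: %s", paste(unique(dup), collapse = ", "))
  names(records) <- ids
  structure(list(records = records, manifest_path = manifest_path),
            class = "thermo_dataset")
}

#' @export
print.thermo_dataset <- function(x, ...) {
  sp <- vapply(x$records, function(r) r$metadata$species, character(1))
  ex <- vapply(x$records, function(r) r$metadata$excluded, logical(1))
  cat(sprintf("<thermo_dataset> %d animals (%d horses, %d donkeys; %d excluded)\n",
              length(x$records), sum(sp == "horse"), sum(sp == "donkey"), sum(ex)))
  invisible(x)
}

#' Select records of a dataset
#'
#' @param dataset a `thermo_dataset`.
#' @param species optional species filter.
#' @param include_excluded include records flagged as excluded from the formal
#'   analysis (default `FALSE`).
#' @return list of `animal_record`s, in manifest order.
#' @export
dataset_records <- function(dataset, species = NULL, include_excluded = FALSE) {
  abort_if(!inherits(dataset, "thermo_dataset"), "not a thermo_dataset")
  recs <- dataset$records
  if (!is.null(species)) {
    recs <- Filter(function(r) r$metadata$species == species, recs)
  }
  if (!include_excluded) {
    recs <- Filter(function(r) !r$metadata$excluded, recs)
  }
  recs
}

# ---- portable text format ------------------------------------------------

write_grid <- function(mat, path) {
  data.table::fwrite(data.table::as.data.table(mat), path,
                     col.names = FALSE, quote = FALSE)
}

read_grid <- function(path, integer = FALSE) {
  abort_if(!file.exists(path), "missing file: %s", path)
  dt <- data.table::fread(path, header = FALSE,
                          colClasses = if (integer) "integer" else "numeric",
                          showProgress = FALSE)
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  m
}

#' Write a dataset in the portable text format
#'
#' Writes, per animal, a temperature grid file (`<id>_temp.csv`, one image row
#' per line, comma-separated) and a class map file (`<id>_class.csv`, integer
#' labels 0-15), plus a `manifest.yaml` listing every record with its
#' metadata. [load_dataset()] on the result reproduces class maps bit-exactly
#' and temperatures to full stored precision (15 significant digits).
#'
#' @param dataset a `thermo_dataset`.
#' @param directory output directory (created if needed).
#' @return the manifest file path, invisibly usable by [load_dataset()].
#' @export
save_dataset <- function(dataset, directory) {
  abort_if(!inherits(dataset, "thermo_dataset"), "not a thermo_dataset")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(directory) || file.access(directory, 2) != 0,
           "directory not writable: %s", directory)
  entries <- lapply(dataset$records, function(r) {
    id <- r$metadata$animal_id
    safe <- gsub("[^A-Za-z0-9._-]", "_", id)
    img_file <- paste0(safe, "_temp.csv")
    cls_file <- paste0(safe, "_class.csv")
    write_grid(r$image, file.path(directory, img_file))
    write_grid(r$class_map, file.path(directory, cls_file))
    e <- list(animal_id = id, species = r$metadata$species,
              image = img_file, class_map = cls_file)
    if (!is.na(r$metadata$hair_coat_length)) {
      e$hair_coat_length_cm <- r$metadata$hair_coat_length
    }
    if (!is.na(r$metadata$sf_skin_thickness)) {
      e$sf_skin_mm <- r$metadata$sf_skin_thickness
    }
    e$excluded <- r$metadata$excluded
    e
  })
  manifest <- file.path(directory, "manifest.yaml")
  yaml::write_yaml(list(animals = unname(entries)), manifest,
                   precision = 17)
  manifest
}

#' Load a dataset from a portable-format manifest
#'
#' Reads the manifest and every referenced grid file, validating all record
#' invariants. Loading is strict: a missing file, an image/class-map shape
#' mismatch or an out-of-range label is fatal and names the offending path or
#' animal; no record is ever silently dropped. Non-fatal findings are
#' attached to each record's `flags`.
#'
#' @param manifest path to a `manifest.yaml` written by [save_dataset()] (or
#'   by hand in the same layout).
#' @return a `thermo_dataset`; records follow manifest order.
#' @export
load_dataset <- function(manifest) {
  abort_if(!file.exists(manifest), "missing file: %s", manifest)
  doc <- yaml::read_yaml(manifest)
  animals <- doc$animals %||% list()
  base <- dirname(manifest)
  records <- lapply(animals, function(e) {
    abort_if(is.null(e$animal_id) || is.null(e$species) ||
               is.null(e$image) || is.null(e$class_map),
             "manifest entry missing required keys (animal_id/species/image/class_map)")
    img <- read_grid(file.path(base, e$image))
    cls <- read_grid(file.path(base, e$class_map), integer = TRUE)
    md <- animal_metadata(
      animal_id = e$animal_id, species = e$species,
      hair_coat_length = e$hair_coat_length_cm %||% NA_real_,
      sf_skin_thickness = e$sf_skin_mm %||% NA_real_,
      excluded = isTRUE(e$excluded))
    animal_record(md, img, cls)
  })
  new_dataset(records, manifest_path = manifest)
}

#' Per-record validation report
#'
#' @param dataset a `thermo_dataset`.
#' @return a data.frame with one row per record: id, species, shape, number of
#'   annotated pixels, ROI ids present, excluded flag and any validation
#'   flags.
#' @export
validation_report <- function(dataset) {
  rows <- lapply(dataset$records, function(r) {
    present <- sort(unique(r$class_map[r$class_map > 0L]))
    data.frame(animal_id = r$metadata$animal_id,
               species = r$metadata$species,
               rows = nrow(r$image), cols = ncol(r$image),
               annotated_px = sum(r$class_map > 0L),
               n_rois = length(present),
               excluded = r$metadata$excluded,
               flags = paste(r$flags, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# ---- pixel samples -------------------------------------------------------

#' Construct a pixel sample
#'
#' A pixel sample is the multiset of temperatures extracted for one
#' (animal, ROI-or-GOR) pair, or a pool of such sets. Empty samples are legal
#' and carry an `"empty"` flag.
#'
#' @param values numeric vector of temperatures (degrees C).
#' @param source human-readable descriptor of provenance.
#' @return object of class `pixel_sample`.
#' @export
pixel_sample <- function(values, source = "") {
  values <- as.numeric(values)
  structure(list(values = values, source = source,
                 flags = if (length(values) == 0L) "empty" else character(0)),
            class = "pixel_sample")
}

#' @export
print.pixel_sample <- function(x, ...) {
  cat(sprintf("<pixel_sample %s> n = %d%s\n", x$source, length(x$values),
              if (length(x$values)) sprintf(", mean = %.3f degC", mean(x$values)) else ""))
  invisible(x)
}

#' Mean temperature of a pixel sample
#'
#' The mean operator over a pixel set; defined only for non-empty samples.
#'
#' @param sample a `pixel_sample`.
#' @return mean temperature in degrees C.
#' @export
sample_mean <- function(sample) {
  abort_if(length(sample$values) == 0L,
           "mean undefined for empty pixel sample (%s)", sample$source)
  mean(sample$values)
}

#' Extract the pixel sample of one ROI from a record
#'
#' Returns the temperatures at all pixels whose class-map label equals
#' `roi_id`, in stable row-major order (origin top-left). An empty ROI is a
#' flagged, non-fatal result.
#'
#' @param record an [animal_record()].
#' @param roi_id integer ROI label in 1..15.
#' @return a [pixel_sample()].
#' @export
extract_roi_pixels <- function(record, roi_id) {
  abort_if(!inherits(record, "animal_record"), "not an animal_record")
  abort_if(length(roi_id) != 1L || is.na(roi_id) || roi_id != round(roi_id) ||
             roi_id < 1L || roi_id > N_ROIS,
           "roi_id must be an integer in 1..%d", N_ROIS)
  # transpose => row-major traversal of the image grid
  timg <- t(record$image)
  tcls <- t(record$class_map)
  pixel_sample(timg[tcls == as.integer(roi_id)],
               source = sprintf("%s/ROI%d", record$metadata$animal_id, roi_id))
}
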