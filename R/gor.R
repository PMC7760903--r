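# Groups of ROIs (GORs): the ten analysis units built from the 15 ROIs.
# GORs deliberately overlap (e.g. ROI 9 sits in Hindquarter, Rump, Ventral
# aspect and Legs); a pixel contributes to every GOR whose ROI list contains
# its label, and assembly concatenates without deduplication.

#' Construct a GOR definition
#'
#' @param gor_id integer identifier (1-based position in its set).
#' @param name GOR name.
#' @param roi_ids non-empty integer vector of member ROI labels (1..15).
#' @return object of class `gor_definition`.
#' @export
gor_definition <- function(gor_id, name, roi_ids) {
  roi_ids <- sort(unique(as.integer(roi_ids)))
  abort_if(length(roi_ids) == 0L, "GOR '%s' has no ROIs", name)
  abort_if(any(roi_ids < 1L | roi_ids > N_ROIS),
           "GOR '%s' has ROI ids outside 1..%d", name, N_ROIS)
  structure(list(gor_id = as.integer(gor_id), name = as.character(name),
                 roi_ids = roi_ids),
            class = "gor_definition")
}

#' Construct a GOR set
#'
#' @param definitions list of [gor_definition()]s with unique ids and names.
#' @return object of class `gor_set` (named list of definitions).
#' @export
gor_set <- function(definitions) {
  abort_if(!all(vapply(definitions, inherits, logical(1), "gor_definition")),
           "definitions must be gor_definition objects")
  nm <- vapply(definitions, `[[`, character(1), "name")
  ids <- vapply(definitions, `[[`, integer(1), "gor_id")
  abort_if(anyDuplicated(nm) > 0, "duplicate GOR names")
  abort_if(anyDuplicated(ids) > 0, "duplicate GOR ids")
  names(definitions) <- nm
  structure(definitions, class = "gor_set")
}

#' @export
print.gor_set <- function(x, ...) {
  cat(sprintf("<gor_set> %d GORs\n", length(x)))
  for (g in x) {
    cat(sprintf("  %2d %-14s {%s}\n", g$gor_id, g$name,
                paste(g$roi_ids, collapse = ",")))
  }
  invisible(x)
}

gor_names <- function(gors) vapply(gors, `[[`, character(1), "name")

#' The ten default groups of ROIs
#'
#' The standard anatomical GOR vocabulary: Neck, Front quarter, Trunk,
#' Hindquarter, Rump, Dorsal aspect, Ventral aspect, Abdomen, Groins and
#' Legs, with their fixed ROI memberships. This is a pure constant.
#'
#' @return a [gor_set()] of 10 definitions.
#' @export
#' @examples
#' default_gors()[["Rump"]]$roi_ids  # 8, 9
default_gors <- function() {
  defs <- list(
    gor_definition(1L,  "Neck",           c(1, 2, 3)),
    gor_definition(2L,  "Front quarter",  c(1, 2, 3, 4, 14, 15)),
    gor_definition(3L,  "Trunk",          c(5, 11)),
    gor_definition(4L,  "Hindquarter",    c(6, 7, 8, 9, 10)),
    gor_definition(5L,  "Rump",           c(8, 9)),
    gor_definition(6L,  "Dorsal aspect",  c(3, 4, 5, 6)),
    gor_definition(7L,  "Ventral aspect", c(9, 10, 11, 12, 13)),
    gor_definition(8L,  "Abdomen",        11),
    gor_definition(9L,  "Groins",         c(10, 12)),
    gor_definition(10L, "Legs",           c(9, 13))
  )
  gor_set(defs)
}

#' Read a GOR set from a YAML config file
#'
#' The config may contain a `gors:` section mapping GOR names to ROI id
#' lists; when the file or the section is absent the default set is returned.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @return a [gor_set()].
#' @export
read_gor_config <- function(path = NULL) {
  if (is.null(path)) return(default_gors())
  abort_if(!file.exists(path), "missing config file: %s", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$gors)) return(default_gors())
  defs <- mapply(function(name, rois, i) gor_definition(i, name, unlist(rois)),
                 names(doc$gors), doc$gors, seq_along(doc$gors),
                 SIMPLIFY = FALSE)
  gor_set(unname(defs))
}

#' Assemble one animal's pixel sample for a GOR
#'
#' Multiset concatenation of [extract_roi_pixels()] over the GOR's member
#' ROIs (ascending ROI order). Conserves pixels: the sample size equals the
#' sum of member-ROI sizes.
#'
#' @param record an [animal_record()].
#' @param gor a [gor_definition()].
#' @return a [pixel_sample()]; empty samples are flagged, not fatal.
#' @export
gor_pixels <- function(record, gor) {
  abort_if(!inherits(gor, "gor_definition"), "gor must be a gor_definition")
  vals <- unlist(lapply(gor$roi_ids,
                        function(r) extract_roi_pixels(record, r)$values),
                 use.names = FALSE)
  pixel_sample(vals %||% numeric(0),
               source = sprintf("%s/%s", record$metadata$animal_id, gor$name))
}

#' Pool a GOR's pixels over all animals of a species
#'
#' Multiset union over the non-excluded animals of the species; every animal
#' contributes proportionally to its pixel count (no per-animal reweighting).
#'
#' @param dataset a `thermo_dataset`.
#' @param species `"horse"` or `"donkey"`.
#' @param gor a [gor_definition()].
#' @param include_excluded also pool animals flagged excluded (default
#'   `FALSE`).
#' @return a [pixel_sample()].
#' @export
pooled_gor_pixels <- function(dataset, species, gor, include_excluded = FALSE) {
  recs <- dataset_records(dataset, species = species,
                          include_excluded = include_excluded)
  abort_if(length(recs) == 0L, "no %s records in dataset", species)
  vals <- unlist(lapply(recs, function(r) gor_pixels(r, gor)$values),
                 use.names = FALSE)
  pixel_sample(vals %||% numeric(0),
               source = sprintf("%s(pooled)/%s", species, gor$name))
}
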