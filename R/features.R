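# Per-view feature extraction and multi-view aggregation.

#' Extract the full per-view feature set
#'
#' Segments (unless a mask is supplied) and computes projected area, the 25
#' morphological descriptors and the 7 texture descriptors for a single
#' side view.
#'
#' @param image An [rgb_image()].
#' @param mask Optional precomputed [plant_mask()]; segmented with the
#'   defaults of [segment_plant()] when missing.
#' @param levels,offsets Passed to [texture_features()].
#' @return Named numeric vector of length 33 (`projected_area_px` + the
#'   frozen morphological and texture catalogues), class `view_features`.
#' @export
view_features <- function(image, mask = NULL, levels = 32L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L))) {
  if (is.null(mask)) mask <- segment_plant(image)
  out <- c(projected_area_px = as.numeric(projected_area(mask)),
           morphological_features(mask),
           texture_features(image, mask, levels = levels, offsets = offsets))
  attr(out, "degenerate") <- NULL
  class(out) <- "view_features"
  out
}

#' All 33 feature names in canonical order
#' @export
feature_catalogue <- function() {
  c("projected_area_px", morph_feature_names, texture_feature_names)
}

#' Aggregate per-view features into one plant feature vector
#'
#' @param per_view List of `view_features` vectors (>= 1), all with the
#'   identical descriptor set.
#' @param plant_id Plant identifier stored on the result.
#' @param stage Growth-stage label (e.g. `"late_tillering"`).
#' @param method `"mean"` (default) or `"max"` per-descriptor aggregation.
#' @return Named numeric vector with attributes `plant_id`, `stage` and
#'   `n_views`, class `plant_feature_vector`.
#' @export
aggregate_views <- function(per_view, plant_id = "plant", stage = "unknown",
                            method = c("mean", "max")) {
  method <- match.arg(method)
  if (length(per_view) == 0L) stop("need at least one view")
  nm <- names(per_view[[1]])
  for (v in per_view)
    if (!identical(names(v), nm)) stop("inconsistent descriptor sets across views")
  m <- do.call(rbind, lapply(per_view, as.numeric))
  agg <- if (method == "mean") colMeans(m) else apply(m, 2, max)
  names(agg) <- nm
  structure(agg, plant_id = plant_id, stage = stage,
            n_views = length(per_view), class = "plant_feature_vector")
}

#' Write a per-plant feature table as CSV
#'
#' One row per plant, one column per descriptor, header names matching the
#' frozen catalogue.
#'
#' @param vectors List of `plant_feature_vector`s.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_feature_table <- function(vectors, path) {
  df <- data.frame(
    plant_id = vapply(vectors, attr, "", which = "plant_id"),
    stage = vapply(vectors, attr, "", which = "stage"),
    n_views = vapply(vectors, attr, 0L, which = "n_views"),
    do.call(rbind, lapply(vectors, as.numeric)),
    check.names = FALSE)
  names(df)[-(1:3)] <- names(vectors[[1]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
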