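#' Default structure list for pelvic volume features
#'
#' Body external plus the five evaluated organs. The feature vector is
#' configurable because evaluation uses only the five organs.
#' @export
pelvic_structures <- function(include_body = TRUE) {
  s <- c("bladder", "rectum", "femoral_head_l", "femoral_head_r", "bone_marrow")
  if (include_body) c("body", s) else s
}

#' Per-structure volume feature vector of an atlas
#'
#' Computes the volume in cc of each requested structure, in the given order.
#'
#' @param x an [atlas()] (or a [label_map()]).
#' @param structures ordered character vector of structure names.
#' @return A `feature_vector`: list with `structure_order`, `raw_cc`, and
#'   `normalized` (NA until [normalize_features()] is applied).
#' @export
extract_features <- function(x, structures = pelvic_structures()) {
  lm <- if (inherits(x, "atlas")) x$contours else x
  id <- if (inherits(x, "atlas")) x$id else NA_character_
  raw <- vapply(structures, function(s) {
    lab <- tryCatch(label_for_structure(lm, s), error = function(e)
      stop("atlas '", id, "': missing structure '", s, "'"))
    v <- volume_of_label(lm, lab)
    if (v == 0)
      stop("atlas '", id, "': structure '", s, "' is empty")
    v
  }, numeric(1))
  feature_vector(structures, raw)
}

#' Construct a feature vector directly from known volumes
#'
#' Used for targets, whose per-structure volumes are taken as given input
#' (ground truth in synthetic experiments).
#'
#' @param structure_order ordered structure names.
#' @param raw_cc per-structure volumes in cc (same order).
#' @param normalized optional normalized values.
#' @export
feature_vector <- function(structure_order, raw_cc,
                           normalized = rep(NA_real_, length(raw_cc))) {
  stopifnot(length(structure_order) == length(raw_cc),
            length(raw_cc) == length(normalized))
  if (any(raw_cc < 0)) stop("raw volumes must be >= 0")
  structure(list(structure_order = as.character(structure_order),
                 raw_cc = unname(as.numeric(raw_cc)),
                 normalized = unname(as.numeric(normalized))),
            class = "feature_vector")
}

#' Fit a per-structure min-max volume normalizer on the atlas set
#'
#' Learns, per structure, the min and max volume over the atlases; normalized
#' values are `(v - min) / (max - min)`, so atlas values land exactly in
#' \[0, 1\]. Min-max is the only affine map achieving those bounds on the
#' fitting set.
#'
#' @param atlas_vectors list of `feature_vector`s sharing `structure_order`.
#' @return A `volume_normalizer` with per-structure `min_cc` and `max_cc`.
#' @export
fit_normalizer <- function(atlas_vectors) {
  if (length(atlas_vectors) < 2L) stop("need at least 2 atlases to normalize")
  so <- atlas_vectors[[1]]$structure_order
  for (v in atlas_vectors)
    if (!identical(v$structure_order, so)) stop("structure_order mismatch")
  raw <- do.call(rbind, lapply(atlas_vectors, function(v) v$raw_cc))
  mn <- apply(raw, 2, min)
  mx <- apply(raw, 2, max)
  degen <- mx <= mn
  if (any(degen))
    stop("degenerate feature (all volumes identical) for structure(s): ",
         paste(so[degen], collapse = ", "))
  structure(list(structure_order = so, min_cc = mn, max_cc = mx),
            class = "volume_normalizer")
}

#' Apply an atlas-fit min-max normalization to a feature vector
#'
#' The identical scaling learned from the atlas set is applied; target values
#' outside \[0, 1\] are deliberately not clamped, so out-of-range targets
#' remain distinguishable in distance ranking.
#'
#' @param v a `feature_vector`.
#' @param norm a `volume_normalizer`.
#' @return `v` with its `normalized` field filled.
#' @export
normalize_features <- function(v, norm) {
  if (!identical(v$structure_order, norm$structure_order))
    stop("structure_order mismatch between vector and normalizer")
  v$normalized <- unname((v$raw_cc - norm$min_cc) / (norm$max_cc - norm$min_cc))
  v
}

#' Invert the min-max normalization
#'
#' @param v a `feature_vector` with `normalized` filled.
#' @param norm the `volume_normalizer` used to normalize.
#' @return `v` with `raw_cc` reconstructed from `normalized`.
#' @export
denormalize_features <- function(v, norm) {
  if (!identical(v$structure_order, norm$structure_order))
    stop("structure_order mismatch between vector and normalizer")
  v$raw_cc <- unname(v$normalized * (norm$max_cc - norm$min_cc) + norm$min_cc)
  v
}

#' Tabulate feature vectors as a data frame (CSV-ready)
#'
#' One row per atlas id; raw and normalized columns per structure.
#'
#' @param vectors named list of `feature_vector`s (names are atlas ids).
#' @export
feature_table <- function(vectors) {
  so <- vectors[[1]]$structure_order
  raw <- do.call(rbind, lapply(vectors, function(v) v$raw_cc))
  nrm <- do.call(rbind, lapply(vectors, function(v) v$normalized))
  colnames(raw) <- paste0(so, "_cc")
  colnames(nrm) <- paste0(so, "_norm")
  data.frame(id = names(vectors), raw, nrm, row.names = NULL,
             check.names = FALSE)
}

# normalized values as an N x d matrix with atlas-id rownames
feature_matrix <- function(vectors) {
  m <- do.call(rbind, lapply(vectors, function(v) {
    if (anyNA(v$normalized)) stop("feature vector not normalized")
    v$normalized
  }))
  rownames(m) <- names(vectors)
  colnames(m) <- vectors[[1]]$structure_order
  m
}
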