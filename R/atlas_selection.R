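#' Ranked atlas shortlist produced by a selection strategy
#'
#' @param strategy one of `"cmas"`, `"saga"`, `"fasa"`, `"sim"`, `"random"`.
#' @param target_id target identifier.
#' @param ranked_atlases atlas ids, best first; no duplicates, never the
#'   target's own id.
#' @param scores per-atlas scalar aligned with `ranked_atlases` (Euclidean
#'   feature distance D for fasa, ascending; MI or post-registration
#'   similarity for sim/saga/cmas, descending; NULL for random).
#' @export
selection_result <- function(strategy, target_id, ranked_atlases,
                             scores = NULL) {
  strategy <- match.arg(strategy, c("cmas", "saga", "fasa", "sim", "random"))
  if (anyDuplicated(ranked_atlases))
    stop("ranked_atlases must not contain duplicates")
  if (target_id %in% ranked_atlases)
    stop("ranked_atlases must not contain the target's own id")
  if (!is.null(scores) && length(scores) != length(ranked_atlases))
    stop("scores must align with ranked_atlases")
  structure(list(strategy = strategy, target_id = as.character(target_id),
                 ranked_atlases = as.character(ranked_atlases),
                 scores = scores,
                 n_selected = length(ranked_atlases)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$strategy, " for ", x$target_id, ": ",
      paste(x$ranked_atlases, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ascending-score ranking with lexicographic atlas-id tie-break
rank_ids <- function(ids, score, n, decreasing = FALSE) {
  o <- order(if (decreasing) -score else score, ids)
  o[seq_len(n)]
}

#' Feature-distance atlas selection (FASA)
#'
#' Ranks atlases by the Euclidean distance `D = ||V_atlas - V_target||`
#' between normalized volume feature vectors and keeps the `n` atlases with
#' the lowest D (ties break to the lexicographically smaller atlas id).
#'
#' @param target_vec normalized `feature_vector` of the target.
#' @param atlas_vecs named list of normalized `feature_vector`s (atlas ids).
#' @param n shortlist size (default 5).
#' @param target_id target identifier for the result.
#' @export
select_fasa <- function(target_vec, atlas_vecs, n = 5, target_id = "target") {
  if (n > length(atlas_vecs)) stop("n exceeds the number of atlases")
  x <- feature_matrix(atlas_vecs)
  tv <- if (inherits(target_vec, "feature_vector")) target_vec$normalized
        else target_vec
  if (length(tv) != ncol(x)) stop("dimension mismatch")
  d <- sqrt(colSums((t(x) - tv)^2))
  pick <- rank_ids(rownames(x), d, n)
  selection_result("fasa", target_id, rownames(x)[pick], unname(d[pick]))
}

#' Mutual-information atlas selection (SIM)
#'
#' Rigid-registers every atlas image to the target, computes the
#' joint-histogram MI between target and rigidly aligned atlas on their
#' overlap, and keeps the `n` atlases with the highest MI. An atlas whose
#' registration fails is scored `-Inf` with a warning.
#'
#' @param target a [volume_image()].
#' @param atlases list of [atlas()] objects.
#' @param n shortlist size (default 5).
#' @param settings a [reg_settings()] list.
#' @param target_id target identifier.
#' @param cache optional environment for sharing rigid registrations.
#' @export
select_sim <- function(target, atlases, n = 5, settings = reg_settings(),
                       target_id = "target", cache = NULL) {
  if (n > length(atlases)) stop("n exceeds the number of atlases")
  ids <- vapply(atlases, function(a) a$id, character(1))
  mi <- vapply(seq_along(atlases), function(i) {
    tryCatch({
      tf <- cached(cache, paste0("rigid:", ids[i]),
                   rigid_register(target, atlases[[i]]$image, settings))
      warped <- resample_rigid(geometry_of(target), atlases[[i]]$image, tf)
      keep <- !is.na(warped)
      mi_from_samples(as.vector(target$voxels)[keep], warped[keep],
                      settings$mi_bins)
    }, error = function(e) {
      warning("registration failed for atlas '", ids[i], "': ",
              conditionMessage(e))
      -Inf
    })
  }, numeric(1))
  if (sum(is.finite(mi)) < n)
    stop("fewer than n atlases registered successfully")
  pick <- rank_ids(ids, mi, n, decreasing = TRUE)
  selection_result("sim", target_id, ids[pick], unname(mi[pick]))
}

#' Conventional register-all atlas selection (cMAS)
#'
#' Deformably registers every candidate atlas to the target, scores each by
#' the normalized cross-correlation between the target and the warped atlas
#' image, and keeps the top `n`. This register-all behaviour is what makes
#' the conventional approach expensive relative to feature-based selection.
#'
#' @inheritParams select_sim
#' @param candidates optional character vector restricting the candidate
#'   atlas ids (used by SAGA).
#' @param strategy strategy label stamped on the result (SAGA reuses this
#'   ranking within its subgroup).
#' @export
select_cmas <- function(target, atlases, n = 5, settings = reg_settings(),
                        target_id = "target", cache = NULL,
                        candidates = NULL, strategy = "cmas") {
  ids <- vapply(atlases, function(a) a$id, character(1))
  if (!is.null(candidates)) {
    keep <- ids %in% candidates
    atlases <- atlases[keep]
    ids <- ids[keep]
  }
  if (n > length(atlases)) stop("n exceeds the number of candidate atlases")
  ncc <- vapply(seq_along(atlases), function(i) {
    tryCatch({
      reg <- cached(cache, paste0("def:", ids[i]),
                    ffd_register(target, atlases[[i]]$image,
                                 settings = settings))
      sc <- attr(reg, "ncc")
      if (is.null(sc)) {
        field <- expand_ffd(reg, geometry_of(target))
        sc <- image_ncc(target, warp_image(atlases[[i]]$image, field))
        if (!is.null(cache)) {
          attr(reg, "ncc") <- sc
          assign(paste0("def:", ids[i]), reg, envir = cache)
        }
      }
      sc
    }, error = function(e) {
      warning("registration failed for atlas '", ids[i], "': ",
              conditionMessage(e))
      -Inf
    })
  }, numeric(1))
  if (sum(is.finite(ncc)) < n)
    stop("fewer than n atlases registered successfully")
  pick <- rank_ids(ids, ncc, n, decreasing = TRUE)
  selection_result(strategy, target_id, ids[pick], unname(ncc[pick]))
}

#' Subgroup-restricted atlas selection (SAGA)
#'
#' Assigns the target to its volume-feature subgroup, restricts candidates to
#' that subgroup, and ranks them by the same post-deformable-registration
#' similarity used by cMAS.
#'
#' @param target_vec normalized `feature_vector` of the target.
#' @param target the target [volume_image()].
#' @param model a fitted `subgrouping_model` covering all atlas ids.
#' @inheritParams select_cmas
#' @export
select_saga <- function(target_vec, target, model, atlases, n = 5,
                        settings = reg_settings(), target_id = "target",
                        cache = NULL) {
  ids <- vapply(atlases, function(a) a$id, character(1))
  if (!all(ids %in% names(model$assignment)))
    stop("subgrouping model does not cover all atlas ids")
  cl <- assign_subgroup(target_vec, model)
  members <- subgroup_members(model, cl)
  members <- intersect(members, ids)
  if (length(members) < n)
    stop("assigned subgroup has ", length(members), " member(s) < n = ", n,
         "; use a smaller n or a smaller k")
  select_cmas(target, atlases, n, settings, target_id, cache,
              candidates = members, strategy = "saga")
}

#' Random atlas selection baseline
#'
#' Uniform sample without replacement, seeded and reproducible.
#'
#' @param atlas_ids character vector of atlas ids.
#' @param n shortlist size.
#' @param seed integer seed.
#' @param target_id target identifier.
#' @export
select_random <- function(atlas_ids, n = 5, seed = 1, target_id = "target") {
  if (n > length(atlas_ids)) stop("n exceeds the number of atlases")
  pick <- with_local_seed(seed, sample(sort(atlas_ids), n))
  selection_result("random", target_id, pick)
}

cached <- function(cache, key, expr) {
  if (is.null(cache)) return(force(expr))
  if (!exists(key, envir = cache, inherits = FALSE))
    assign(key, force(expr), envir = cache)
  get(key, envir = cache, inherits = FALSE)
}

#' Selection overlap between two strategies across targets
#'
#' Given the two strategies' selections on the same targets (same shortlist
#' size), reports per-target intersection counts, the total number of
#' coincidences, the coincidence fraction (total intersections over the
#' total number of selections made by the two strategies together, e.g.
#' 12 of 2 x 30 x 5 = 300), per-atlas selection frequencies, and the atlases
#' never selected by either strategy.
#'
#' @param a,b named lists of [selection_result()]s keyed by target id.
#' @param atlas_ids the full atlas universe (for the never-selected set).
#' @export
selection_overlap <- function(a, b, atlas_ids = NULL) {
  if (!setequal(names(a), names(b)))
    stop("the two strategies were not run on the same targets")
  targets <- sort(names(a))
  n_per <- a[[1]]$n_selected
  for (r in c(a, b)) if (r$n_selected != n_per)
    stop("selections must share the same shortlist size n")
  per_target <- vapply(targets, function(t)
    length(intersect(a[[t]]$ranked_atlases, b[[t]]$ranked_atlases)),
    integer(1))
  total <- sum(per_target)
  total_selections <- 2 * length(targets) * n_per
  sel_a <- unlist(lapply(a, function(r) r$ranked_atlases))
  sel_b <- unlist(lapply(b, function(r) r$ranked_atlases))
  freq <- function(sel) {
    t <- table(sel)
    stats::setNames(as.integer(t), names(t))
  }
  ever <- union(sel_a, sel_b)
  list(per_target = per_target,
       total_coincidences = total,
       coincidence_fraction = total / total_selections,
       frequency_a = freq(sel_a), frequency_b = freq(sel_b),
       never_selected = if (is.null(atlas_ids)) NULL
                        else sort(setdiff(atlas_ids, ever)))
}
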