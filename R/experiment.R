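#' Experiment configuration
#'
#' @param structures ordered structure list for the volume feature vector
#'   (default: body plus the five organs).
#' @param eval_structures structures evaluated against ground truth (default:
#'   the five organs, excluding the body).
#' @param k number of atlas subgroups (default 4).
#' @param adapt_k when TRUE (default), reduce k stepwise (to no less than 2)
#'   until every subgroup has at least `n_atlases` members, honouring the
#'   constraint that the shortlist must fit inside any assigned subgroup.
#' @param n_atlases shortlist size fused per target (default 5).
#' @param folds number of cross-validation re-randomisations (default 3).
#' @param test_fraction fraction of subjects held out per fold (default 0.3).
#' @param strategies subset of c("cmas", "saga", "fasa", "sim", "random").
#' @param target_amplitude extra warp applied to each held-out subject to
#'   derive its segmentation target (mm, default 5).
#' @param seed master seed.
#' @param registration a [reg_settings()] list.
#' @export
experiment_config <- function(structures = pelvic_structures(),
                              eval_structures = pelvic_structures(FALSE),
                              k = 4, adapt_k = TRUE, n_atlases = 5,
                              folds = 3, test_fraction = 0.3,
                              strategies = c("cmas", "saga", "fasa", "sim",
                                             "random"),
                              target_amplitude = 5, seed = 1,
                              registration = reg_settings()) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  stopifnot(folds >= 1, n_atlases >= 1, k >= 2)
  list(structures = structures, eval_structures = eval_structures, k = k,
       adapt_k = adapt_k, n_atlases = n_atlases, folds = folds,
       test_fraction = test_fraction, strategies = strategies,
       target_amplitude = target_amplitude, seed = as.integer(seed),
       registration = registration)
}

#' Random atlas/test splits of a cohort
#'
#' Each fold independently re-randomises the split (the cross-validation
#' re-draws the test set rather than rotating disjoint folds).
#'
#' @param ids subject ids (or a `mas_cohort`).
#' @param test_fraction fraction held out, in (0, 1).
#' @param fold_seeds one integer seed per fold.
#' @return list of folds, each with `atlas_ids` and `test_ids` (disjoint,
#'   union = cohort).
#' @export
split_cohort <- function(ids, test_fraction, fold_seeds) {
  if (inherits(ids, "mas_cohort")) ids <- ids$manifest$id
  if (length(ids) < 5) stop("cohort must have at least 5 subjects")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_test <- round(length(ids) * test_fraction)
  lapply(fold_seeds, function(s) {
    test <- with_local_seed(s, sample(sort(ids), n_test))
    list(atlas_ids = setdiff(ids, test), test_ids = sort(test))
  })
}

fit_fold_models <- function(cohort, atlas_ids, config) {
  atlases <- cohort$atlases[atlas_ids]
  vecs <- lapply(atlases, extract_features, structures = config$structures)
  norm <- fit_normalizer(vecs)
  nvecs <- lapply(vecs, normalize_features, norm = norm)
  k <- config$k
  model <- NULL
  repeat {
    model <- fit_subgroups(nvecs, k = k, seed = config$seed)
    sizes <- tabulate(model$assignment, nbins = k)
    if (!config$adapt_k || all(sizes >= config$n_atlases) || k == 2) break
    k <- k - 1
  }
  if (any(tabulate(model$assignment, nbins = model$k) < config$n_atlases))
    warning("smallest subgroup (k = ", model$k, ") is below n_atlases; ",
            "saga may fail for some targets")
  list(normalizer = norm, vectors = nvecs, model = model)
}

#' Run the full multi-strategy segmentation experiment on a cohort
#'
#' For each fold: fits the volume normalizer and the subgrouping model on the
#' atlas split only (the test split never touches them); derives a
#' segmentation target from each held-out subject by a known warp; runs each
#' enabled selection strategy; deformably registers the shortlisted atlases
#' (registrations are cached per target, so strategies sharing candidates
#' reuse work); propagates labels; fuses by majority vote; and evaluates DSC
#' and 95HD per structure against the target's ground truth. Failures are
#' recorded per (target, strategy) and the run continues.
#'
#' @param cohort a `mas_cohort` from [generate_cohort()].
#' @param config an [experiment_config()].
#' @param progress print per-target progress lines (default FALSE).
#' @return list with `records` (evaluation data frame), `selections` (nested
#'   per fold/target/strategy), `registration_counts` (registrations each
#'   strategy requires per target), `subgroup_sizes`, `failures`, `summary`
#'   (from [summarize_records()]), and `folds`.
#' @export
run_experiment <- function(cohort, config = experiment_config(),
                           progress = FALSE) {
  stopifnot(inherits(cohort, "mas_cohort"))
  folds <- split_cohort(cohort, config$test_fraction,
                        config$seed + seq_len(config$folds) - 1L)
  records <- list()
  selections <- list()
  counts <- list()
  failures <- list()
  subgroup_sizes <- list()
  t0 <- proc.time()[3]

  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    fit <- fit_fold_models(cohort, fold$atlas_ids, config)
    atlases <- cohort$atlases[fold$atlas_ids]
    subgroup_sizes[[fi]] <- tabulate(fit$model$assignment,
                                     nbins = fit$model$k)
    for (ti in seq_along(fold$test_ids)) {
      tid <- fold$test_ids[ti]
      tgt <- make_target(cohort$atlases[[tid]], config$target_amplitude,
                         seed = config$seed + 5000L + fi * 100L + ti)
      tvec <- normalize_features(
        feature_vector(config$structures, tgt$volumes[config$structures]),
        fit$normalizer)
      cache <- new.env(parent = emptyenv())
      prop_cache <- new.env(parent = emptyenv())
      for (sg in config$strategies) {
        sel <- tryCatch(switch(sg,
          fasa = select_fasa(tvec, fit$vectors, config$n_atlases, tgt$id),
          sim = select_sim(tgt$image, atlases, config$n_atlases,
                           config$registration, tgt$id, cache),
          cmas = select_cmas(tgt$image, atlases, config$n_atlases,
                             config$registration, tgt$id, cache),
          saga = select_saga(tvec, tgt$image, fit$model, atlases,
                             config$n_atlases, config$registration, tgt$id,
                             cache),
          random = select_random(names(atlases), config$n_atlases,
                                 seed = config$seed + 7000L + fi * 100L + ti,
                                 target_id = tgt$id)),
          error = function(e) e)
        if (inherits(sel, "error")) {
          failures[[length(failures) + 1]] <-
            data.frame(fold = fi, target_id = tid, strategy = sg,
                       stage = "selection", message = conditionMessage(sel))
          next
        }
        selections[[as.character(fi)]][[tid]][[sg]] <- sel
        counts[[length(counts) + 1]] <- data.frame(
          fold = fi, target_id = tid, strategy = sg,
          registrations_required = switch(sg,
            cmas = length(atlases),
            saga = length(subgroup_members(
              fit$model, assign_subgroup(tvec, fit$model))),
            config$n_atlases))
        rec <- tryCatch(
          fuse_and_evaluate(tgt, atlases, sel, config, cache, prop_cache),
          error = function(e) e)
        if (inherits(rec, "error")) {
          failures[[length(failures) + 1]] <-
            data.frame(fold = fi, target_id = tid, strategy = sg,
                       stage = "fusion", message = conditionMessage(rec))
          next
        }
        rec$fold <- fi
        records[[length(records) + 1]] <- rec
      }
      if (progress)
        message(sprintf("fold %d target %s done (%.1f s elapsed)",
                        fi, tid, proc.time()[3] - t0))
    }
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  summary <- NULL
  if (!is.null(records) && length(unique(records$strategy)) >= 1) {
    ref <- if ("cmas" %in% records$strategy) "cmas"
           else sort(unique(records$strategy))[1]
    summary <- tryCatch(summarize_records(records, reference = ref),
                        error = function(e) NULL)
  }
  list(records = records, selections = selections,
       registration_counts = if (length(counts)) do.call(rbind, counts)
                             else NULL,
       subgroup_sizes = subgroup_sizes,
       failures = if (length(failures)) do.call(rbind, failures) else NULL,
       summary = summary, folds = folds, config = config,
       elapsed_s = proc.time()[3] - t0)
}

# propagate the selected atlases' labels through cached registrations,
# majority-vote them, and evaluate against the target's ground truth
fuse_and_evaluate <- function(tgt, atlases, sel, config, cache, prop_cache) {
  geom <- geometry_of(tgt$image)
  cand <- lapply(sel$ranked_atlases, function(aid) {
    cached(prop_cache, paste0("prop:", aid), {
      reg <- cached(cache, paste0("def:", aid),
                    ffd_register(tgt$image, atlases[[aid]]$image,
                                 settings = config$registration))
      propagate_labels(atlases[[aid]]$contours, expand_ffd(reg, geom))
    })
  })
  fused <- majority_vote(cand)
  do.call(rbind, lapply(config$eval_structures, function(st) {
    d <- tryCatch(dice(fused, tgt$labels, st), error = function(e) 0)
    h <- tryCatch(hd95(fused, tgt$labels, st), error = function(e) NA_real_)
    if (is.na(h)) {
      # empty prediction: fall back to the worst observed surface separation
      h <- max(geom$dim * geom$spacing) / 10
    }
    evaluation_record(tgt$id, sel$strategy, st, d, h)
  }))
}
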