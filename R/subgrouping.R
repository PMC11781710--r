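# run expr under a temporary RNG state, restoring the caller's state after
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Partition the atlas set into volume-feature subgroups by k-means
#'
#' Lloyd's algorithm on normalized volume feature vectors, minimising the
#' within-cluster sum of squared Euclidean distances
#' `sum_i sum_{x in C_i} ||x - mu_i||^2`. Initial centroids are k distinct
#' data points chosen by seeded sampling over atlases in lexicographic id
#' order (so the fit is invariant to input-order permutations). An empty
#' cluster arising during iteration is re-seeded from the point currently
#' farthest from its assigned centroid, keeping k fixed. The best of
#' `restarts` seeded initialisations by objective is returned.
#'
#' @param vectors named list of normalized `feature_vector`s (names = atlas
#'   ids), or an N x d numeric matrix with atlas-id rownames.
#' @param k number of subgroups, `2 <= k <= N`. Default 4.
#' @param seed integer seed; the fit is deterministic given (seed, restarts).
#' @param restarts number of seeded initialisations (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return A `subgrouping_model`: `k`, `centroids` (k x d), `assignment`
#'   (named integer vector, atlas id -> cluster index in 1..k), `objective`.
#' @export
fit_subgroups <- function(vectors, k = 4, seed = 1, restarts = 10,
                          max_iter = 300) {
  x <- if (is.matrix(vectors)) vectors else feature_matrix(vectors)
  if (is.null(rownames(x))) stop("vectors must carry atlas ids")
  if (any(!is.finite(x))) stop("feature vectors must be finite")
  n <- nrow(x)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= N (N = ", n, ")")
  ord <- order(rownames(x))   # seed-stream invariant to input permutation
  x <- x[ord, , drop = FALSE]

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_local_seed(seed + r - 1L, lloyd_once(x, k, max_iter))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(list(k = as.integer(k),
                 centroids = best$centroids,
                 assignment = stats::setNames(best$assignment, rownames(x)),
                 objective = best$objective,
                 objective_trace = best$trace,
                 structure_order = colnames(x),
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "subgrouping_model")
}

lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  uniq <- unique(x)
  init_rows <- if (nrow(uniq) >= k) uniq[sample(nrow(uniq), k), , drop = FALSE]
  else x[sample(n, k), , drop = FALSE]
  centers <- init_rows
  assign_prev <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_matrix(x, centers)
    asg <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: re-seed from the farthest point; when points
    # coincide with their centroid the tie is forced so repair terminates
    guard <- 0L
    repeat {
      empty <- setdiff(seq_len(k), unique(asg))
      if (length(empty) == 0L || guard > k) break
      guard <- guard + 1L
      far <- which.max(d2[cbind(seq_len(n), asg)])
      centers[empty[1L], ] <- x[far, ]
      d2 <- dist2_matrix(x, centers)
      asg <- max.col(-d2, ties.method = "first")
      if (!(empty[1L] %in% asg)) asg[far] <- empty[1L]
    }
    obj <- sum(d2[cbind(seq_len(n), asg)])
    if (length(trace) > 0 && obj > utils::tail(trace, 1) + 1e-9)
      stop("internal error: k-means objective increased")
    trace <- c(trace, obj)
    if (identical(asg, assign_prev)) break
    assign_prev <- asg
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[asg == j, , drop = FALSE])
  }
  d2 <- dist2_matrix(x, centers)
  obj <- sum(d2[cbind(seq_len(n), asg)])
  list(centroids = centers, assignment = asg, objective = obj, trace = trace)
}

dist2_matrix <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

#' Assign a target to its atlas subgroup
#'
#' Returns the index of the cluster whose centroid is nearest (Euclidean) to
#' the target's normalized feature vector; ties break to the lowest cluster
#' index.
#'
#' @param target a normalized `feature_vector` or a numeric vector.
#' @param model a `subgrouping_model`.
#' @return cluster index in `1..k`.
#' @export
assign_subgroup <- function(target, model) {
  v <- if (inherits(target, "feature_vector")) target$normalized else target
  if (length(v) != ncol(model$centroids))
    stop("dimension mismatch: target has ", length(v), " features, model has ",
         ncol(model$centroids))
  if (any(!is.finite(v))) stop("target vector must be finite")
  d2 <- colSums((t(model$centroids) - v)^2)
  unname(which.min(d2))  # first minimum = lowest index on ties
}

#' Atlas ids belonging to one subgroup
#' @param model a `subgrouping_model`.
#' @param cluster cluster index in `1..k`.
#' @export
subgroup_members <- function(model, cluster) {
  names(model$assignment)[model$assignment == cluster]
}

#' Serialize / restore a fitted subgrouping model as JSON
#'
#' A fitted grouping is reusable across runs: only one clustering is required
#' for the entire atlas set.
#' @param model a `subgrouping_model`.
#' @param path output path.
#' @export
write_subgroups <- function(model, path) {
  jsonlite::write_json(
    list(k = model$k, centroids = model$centroids,
         assignment = as.list(model$assignment),
         objective = model$objective,
         structure_order = model$structure_order,
         seed = model$seed, restarts = model$restarts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subgroups
#' @export
read_subgroups <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  centro <- matrix(unlist(j$centroids), nrow = j$k)
  colnames(centro) <- j$structure_order
  structure(list(k = as.integer(j$k), centroids = centro,
                 assignment = stats::setNames(as.integer(unlist(j$assignment)),
                                              names(j$assignment)),
                 objective = j$objective,
                 structure_order = j$structure_order,
                 seed = as.integer(j$seed), restarts = as.integer(j$restarts)),
            class = "subgrouping_model")
}
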