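#' Dice similarity coefficient between two binary structures
#'
#' `DSC(A, B) = 2|A ∩ B| / (|A| + |B|)`, computed in exact integer arithmetic
#' before the final division.
#'
#' @param a,b [label_map()]s on a common grid.
#' @param label label integer or structure name; default "any non-zero".
#' @return DSC in \[0, 1\].
#' @export
dice <- function(a, b, label = NULL) {
  if (!same_grid(a, b)) stop("masks must share a common grid")
  ma <- structure_mask(a, label)
  mb <- structure_mask(b, label)
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) stop("undefined metric: both masks are empty")
  2 * sum(ma & mb) / (na + nb)
}

#' 95th-percentile Hausdorff distance, in cm
#'
#' Extracts both structures' surface voxels, computes directed nearest-surface
#' distances A to B and B to A (exact anisotropic Euclidean distance
#' transform), pools both directed sets, and returns the 95th percentile
#' (linear interpolation between closest order statistics) converted to cm.
#' The pooled symmetric definition makes the metric invariant to swapping
#' `a` and `b`.
#'
#' @param a,b [label_map()]s on a common grid, both non-empty.
#' @param label label integer or structure name; default "any non-zero".
#' @param percentile percentile of the pooled distance set (default 0.95).
#' @return distance in cm.
#' @export
hd95 <- function(a, b, label = NULL, percentile = 0.95) {
  if (!same_grid(a, b)) stop("masks must share a common grid")
  ma <- structure_mask(a, label)
  mb <- structure_mask(b, label)
  if (!any(ma) || !any(mb)) stop("undefined metric: empty mask")
  sa <- surface_mask(ma)
  sb <- surface_mask(mb)
  geom <- geometry_of(a)
  dim3 <- as.integer(geom$dim)
  dt_b <- cpp_sedt(as.vector(sb), dim3, geom$spacing)
  dt_a <- cpp_sedt(as.vector(sa), dim3, geom$spacing)
  d_ab <- sqrt(dt_b[as.vector(sa)])
  d_ba <- sqrt(dt_a[as.vector(sb)])
  unname(stats::quantile(c(d_ab, d_ba), percentile, type = 7)) / 10
}

#' Two-tailed paired t-test on per-target scores
#'
#' Classic paired t on the differences with `n - 1` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, paired by target.
#' @return list with `t`, `p` (two-sided), and `df`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate: zero-variance differences, t undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' One evaluation record
#'
#' @param target_id,strategy,structure identifiers.
#' @param dsc Dice coefficient in \[0, 1\].
#' @param hd95_cm 95th-percentile Hausdorff distance in cm, >= 0.
#' @export
evaluation_record <- function(target_id, strategy, structure, dsc, hd95_cm) {
  stopifnot(dsc >= 0, dsc <= 1, hd95_cm >= 0)
  data.frame(target_id = target_id, strategy = strategy,
             structure = structure, dsc = dsc, hd95_cm = hd95_cm,
             stringsAsFactors = FALSE)
}

#' Summary table of segmentation performance
#'
#' Mean and sample standard deviation (n - 1) of DSC and 95HD per
#' (strategy, structure), plus two-tailed paired t-test p-values of every
#' strategy against a reference strategy, paired by target. Requires a
#' balanced design (every strategy evaluated on every target and structure).
#'
#' @param records data frame of rows as built by [evaluation_record()].
#' @param reference reference strategy for the paired tests (default "cmas").
#' @return list with `summary` (one row per strategy x structure) and `tests`
#'   (paired comparisons vs the reference).
#' @export
summarize_records <- function(records, reference = "cmas") {
  strategies <- sort(unique(records$strategy))
  structures <- sort(unique(records$structure))
  targets <- sort(unique(records$target_id))
  full <- expand.grid(target_id = targets, strategy = strategies,
                      structure = structures, stringsAsFactors = FALSE)
  key <- function(d) paste(d$target_id, d$strategy, d$structure)
  missing <- setdiff(key(full), key(records))
  if (length(missing) > 0)
    stop("unbalanced design; missing cells: ",
         paste(utils::head(missing, 10), collapse = "; "))
  agg <- do.call(rbind, lapply(strategies, function(sg)
    do.call(rbind, lapply(structures, function(st) {
      r <- records[records$strategy == sg & records$structure == st, ]
      data.frame(strategy = sg, structure = st,
                 dsc_mean = mean(r$dsc), dsc_sd = stats::sd(r$dsc),
                 hd95_mean = mean(r$hd95_cm), hd95_sd = stats::sd(r$hd95_cm),
                 n = nrow(r), stringsAsFactors = FALSE)
    }))))
  tests <- NULL
  if (reference %in% strategies && length(targets) >= 3) {
    tests <- do.call(rbind, lapply(setdiff(strategies, reference), function(sg)
      do.call(rbind, lapply(structures, function(st) {
        pick <- function(g) {
          r <- records[records$strategy == g & records$structure == st, ]
          r[match(targets, r$target_id), ]
        }
        rx <- pick(sg); rr <- pick(reference)
        row <- data.frame(strategy = sg, reference = reference,
                          structure = st, p_dsc = NA_real_,
                          p_hd95 = NA_real_, stringsAsFactors = FALSE)
        row$p_dsc <- tryCatch(paired_ttest(rx$dsc, rr$dsc)$p,
                              error = function(e) NA_real_)
        row$p_hd95 <- tryCatch(paired_ttest(rx$hd95_cm, rr$hd95_cm)$p,
                               error = function(e) NA_real_)
        row
      }))))
  }
  list(summary = agg, tests = tests)
}
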