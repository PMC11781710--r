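# Fixed phantom layout, in mm relative to the body centre. Chosen once so
# that all structures stay disjoint and inside the body envelope across the
# full cohort volume ranges (verified at the extreme volumes in tests).
phantom_layout <- list(
  body_semi = c(92, 90, 62),          # base body ellipsoid semi-axes
  bladder_center = c(0, -34, 6),
  bladder_ratios = c(1.0, 0.78, 0.80),
  rectum_y = 34, rectum_wiggle = 6, rectum_halfspan = 40,
  femoral_center = c(62, 6, -12),     # mirrored in x for left/right
  marrow_xy = c(43, 37), marrow_halfspan = 35)

#' Cohort volume ranges (cc)
#'
#' Bladder and rectum default to the clinical cohort ranges; femoral heads,
#' bone marrow and body span habitus-plausible ranges.
#' @export
cohort_ranges <- function() {
  list(bladder = c(70.89, 437.09), rectum = c(21.3, 115.04),
       femoral_head = c(21, 36.4), bone_marrow = c(45, 78),
       body = c(1935, 2365))
}

#' Specification of one synthetic pelvic phantom
#'
#' @param dim grid dimensions (default 96 x 96 x 64).
#' @param spacing voxel spacing in mm (default 2 mm isotropic).
#' @param volumes_cc named per-structure target volumes in cc with names
#'   `body`, `bladder`, `rectum`, `femoral_head_l`, `femoral_head_r`,
#'   `bone_marrow` (bone marrow is the combined volume of both columns).
#' @param intensities named intensity means (HU-like): `background`, `body`,
#'   `bladder`, `rectum`, `femoral_head`, `bone_marrow`.
#' @param noise_sd additive Gaussian noise standard deviation (default 8).
#' @param texture_amp amplitude (HU) of a smooth deterministic intensity
#'   modulation added before any warp (default 0). A textured phantom makes
#'   the full deformation field identifiable by intensity-based registration;
#'   with piecewise-constant regions only the boundary-normal component is
#'   observable.
#' @param deformation list with `amplitude` (max displacement, mm) and
#'   optional `params` (a deformation parameter set built by
#'   [random_deformation()]); amplitude 0 means no warp.
#' @param seed integer seed controlling noise (and the warp when
#'   `deformation$params` is absent).
#' @export
phantom_spec <- function(dim = c(96, 96, 64), spacing = c(2, 2, 2),
                         volumes_cc = c(body = 2150, bladder = 254,
                                        rectum = 68, femoral_head_l = 28,
                                        femoral_head_r = 28,
                                        bone_marrow = 60),
                         intensities = c(background = -1000, body = 40,
                                         bladder = 10, rectum = 30,
                                         femoral_head = 700,
                                         bone_marrow = 200),
                         noise_sd = 8, texture_amp = 0,
                         deformation = list(amplitude = 0, params = NULL),
                         seed = 1) {
  need <- c("body", "bladder", "rectum", "femoral_head_l", "femoral_head_r",
            "bone_marrow")
  if (!all(need %in% names(volumes_cc)))
    stop("volumes_cc must name: ", paste(need, collapse = ", "))
  if (any(volumes_cc <= 0)) stop("all volumes must be > 0")
  rg <- cohort_ranges()
  if (volumes_cc["bladder"] < rg$bladder[1] - 1e-9 ||
      volumes_cc["bladder"] > rg$bladder[2] + 1e-9)
    stop("bladder volume outside the cohort range [",
         rg$bladder[1], ", ", rg$bladder[2], "] cc")
  if (volumes_cc["rectum"] < rg$rectum[1] - 1e-9 ||
      volumes_cc["rectum"] > rg$rectum[2] + 1e-9)
    stop("rectum volume outside the cohort range [",
         rg$rectum[1], ", ", rg$rectum[2], "] cc")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 volumes_cc = volumes_cc, intensities = intensities,
                 noise_sd = noise_sd, texture_amp = texture_amp,
                 deformation = deformation,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

pelvic_label_names <- c("1" = "bladder", "2" = "rectum",
                        "3" = "femoral_head_l", "4" = "femoral_head_r",
                        "5" = "bone_marrow", "6" = "body")

# coordinate arrays (mm, relative to grid physical centre)
coord_arrays <- function(dim, spacing) {
  cen <- (dim - 1) * spacing / 2
  xv <- (seq_len(dim[1]) - 1) * spacing[1] - cen[1]
  yv <- (seq_len(dim[2]) - 1) * spacing[2] - cen[2]
  zv <- (seq_len(dim[3]) - 1) * spacing[3] - cen[3]
  list(x = array(rep(xv, times = dim[2] * dim[3]), dim),
       y = array(rep(rep(yv, each = dim[1]), times = dim[3]), dim),
       z = array(rep(zv, each = dim[1] * dim[2]), dim))
}

#' Generate one synthetic pelvic CT phantom with ground-truth contours
#'
#' Builds a CT-like phantom: soft-tissue body ellipsoid containing a bladder
#' ellipsoid, a curved rectal tube, two spherical femoral heads and two
#' bone-marrow columns, each scaled so the realized label volume matches the
#' requested volume (within voxelisation error, checked at 5% for undeformed
#' phantoms). An optional smooth deformation (sum of Gaussian radial-basis
#' bumps, amplitude-normalized) is applied to image and labels, and Gaussian
#' noise is added last. Fully deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @param id atlas identifier (default "phantom").
#' @return An [atlas()] carrying attributes `true_volumes` (measured label
#'   volumes, cc) and `deformation` (the applied parameter set or NULL).
#' @export
generate_phantom <- function(spec, id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim; sp <- spec$spacing
  lay <- phantom_layout
  vol <- spec$volumes_cc
  co <- coord_arrays(d, sp)
  s_body <- (vol[["body"]] / ellipsoid_cc(lay$body_semi))^(1 / 3)
  semi <- lay$body_semi * s_body

  # each structure is the level set of a continuous field holding exactly
  # round(volume / voxel volume) voxels, so realized volumes match requests
  # to within half a voxel at any grid resolution
  vox_cc <- prod(sp) / 1000
  top_n_mask <- function(field, target_cc, name) {
    n <- round(target_cc / vox_cc)
    if (n < 1)
      stop("structure '", name, "' smaller than one voxel at this spacing")
    th <- -sort(-field, partial = n)[n]
    m <- array(field > th, dim(field))
    short <- n - sum(m)
    if (short > 0) {
      cand <- which(field == th)
      m[cand[seq_len(short)]] <- TRUE
    }
    m
  }

  labels <- array(0L, d)
  body_field <- 1 - ((co$x / semi[1])^2 + (co$y / semi[2])^2 +
                     (co$z / semi[3])^2)
  in_body <- top_n_mask(body_field, vol[["body"]], "body")
  labels[in_body] <- 6L

  carve <- function(labels, mask, lab, name) {
    bad <- mask & labels != 6L
    if (any(bad))
      stop("unplaceable structure '", name, "': overlaps ",
           paste(unique(pelvic_label_names[as.character(
             setdiff(unique(labels[bad]), 6L))]), collapse = ", "),
           if (any(labels[bad] == 0L)) " / outside body" else "")
    labels[mask] <- lab
    labels
  }

  # bladder: ellipsoid with fixed axis ratios scaled to the requested volume
  a <- (vol[["bladder"]] * 1000 * 3 / (4 * pi) /
          prod(lay$bladder_ratios))^(1 / 3)
  ax <- a * lay$bladder_ratios
  bc <- lay$bladder_center
  field <- 1 - (((co$x - bc[1]) / ax[1])^2 + ((co$y - bc[2]) / ax[2])^2 +
                ((co$z - bc[3]) / ax[3])^2)
  labels <- carve(labels, top_n_mask(field, vol[["bladder"]], "bladder"),
                  1L, "bladder")

  # rectum: curved vertical tube, circular xy cross-section around a
  # sinusoidal centreline, hard-capped in z
  span <- 2 * lay$rectum_halfspan
  r_rect <- sqrt(vol[["rectum"]] * 1000 / (pi * span))
  cx <- lay$rectum_wiggle * sin(2 * pi * co$z / (2 * lay$rectum_halfspan))
  field <- r_rect^2 - ((co$x - cx)^2 + (co$y - lay$rectum_y)^2)
  field[abs(co$z) > lay$rectum_halfspan] <- -Inf
  labels <- carve(labels, top_n_mask(field, vol[["rectum"]], "rectum"),
                  2L, "rectum")

  # femoral heads: spheres mirrored in x
  for (side in c("l", "r")) {
    v <- vol[[paste0("femoral_head_", side)]]
    r <- (v * 1000 * 3 / (4 * pi))^(1 / 3)
    fc <- lay$femoral_center * c(if (side == "l") -1 else 1, 1, 1)
    field <- r^2 - ((co$x - fc[1])^2 + (co$y - fc[2])^2 + (co$z - fc[3])^2)
    labels <- carve(labels,
                    top_n_mask(field, v, paste0("femoral_head_", side)),
                    if (side == "l") 3L else 4L,
                    paste0("femoral_head_", side))
  }

  # bone marrow: paired vertical columns, z-capped
  mspan <- 2 * lay$marrow_halfspan
  r_mar <- sqrt(vol[["bone_marrow"]] * 1000 / (2 * pi * mspan))
  field <- r_mar^2 - pmin((co$x - lay$marrow_xy[1])^2,
                          (co$x + lay$marrow_xy[1])^2) -
           (co$y - lay$marrow_xy[2])^2
  field[abs(co$z) > lay$marrow_halfspan] <- -Inf
  labels <- carve(labels, top_n_mask(field, vol[["bone_marrow"]],
                                     "bone_marrow"), 5L, "bone_marrow")

  ints <- spec$intensities
  img <- array(ints[["background"]], d)
  img[labels == 6L] <- ints[["body"]]
  img[labels == 1L] <- ints[["bladder"]]
  img[labels == 2L] <- ints[["rectum"]]
  img[labels == 3L | labels == 4L] <- ints[["femoral_head"]]
  img[labels == 5L] <- ints[["bone_marrow"]]

  if (!is.null(spec$texture_amp) && spec$texture_amp > 0) {
    # smooth incommensurate-wavelength modulation; deforms with the anatomy
    img <- img + spec$texture_amp / 4 *
      (sin(2 * pi * co$x / 73) + sin(2 * pi * co$y / 61) +
       sin(2 * pi * co$z / 47) + sin(2 * pi * (co$x + co$y) / 103))
  }

  geom <- list(dim = d, spacing = sp, origin = c(0, 0, 0), direction = diag(3))
  vi <- volume_image(img, sp, geom$origin)
  lm <- label_map(labels, sp, geom$origin, label_names = pelvic_label_names)

  def <- spec$deformation
  applied <- NULL
  if (!is.null(def) && def$amplitude > 0) {
    applied <- def$params
    if (is.null(applied))
      applied <- with_local_seed(spec$seed + 104729L,
        random_deformation(geom, def$amplitude))
    warped <- apply_deformation(vi, lm, applied)
    vi <- warped$image
    lm <- warped$labels
  }
  if (spec$noise_sd > 0) {
    noise <- with_local_seed(spec$seed,
      array(stats::rnorm(prod(d), 0, spec$noise_sd), d))
    vi <- volume_image(vi$voxels + noise, sp, geom$origin)
  }

  measured <- vapply(names(vol), function(nm) {
    lab <- switch(nm, body = 6, bladder = 1, rectum = 2, femoral_head_l = 3,
                  femoral_head_r = 4, bone_marrow = 5)
    sum(lm$labels == lab) * prod(sp) / 1000
  }, numeric(1))
  if (is.null(applied)) {
    # the requested body volume is the whole envelope (organs included);
    # the recorded body volume is the soft-tissue region (label 6) so that
    # it matches what feature extraction recovers from the label map
    realized <- measured
    realized["body"] <- sum(lm$labels > 0L) * prod(sp) / 1000
    relerr <- abs(realized - vol) / vol
    if (any(relerr > 0.05))
      stop("realized volume off by more than 5% for: ",
           paste(names(vol)[relerr > 0.05], collapse = ", "),
           " (grid too coarse for the requested volume)")
  }
  at <- atlas(id, vi, lm)
  attr(at, "true_volumes") <- measured
  attr(at, "requested_volumes") <- vol
  attr(at, "deformation") <- applied
  at
}

ellipsoid_cc <- function(semi) 4 / 3 * pi * prod(semi) / 1000

# -- smooth deformations ------------------------------------------------------

#' Random smooth deformation (sum of Gaussian radial-basis bumps)
#'
#' `u(x) = scale * sum_j v_j exp(-||x - c_j||^2 / (2 sigma^2))`, with the
#' scale normalized so the maximum displacement over the grid equals
#' `amplitude`. With `sigma` well above the amplitude the map stays
#' diffeomorphic (displacement gradient below 1).
#'
#' @param geom grid geometry (list with `dim`, `spacing`, `origin`,
#'   `direction`) the field will be evaluated on.
#' @param amplitude maximum displacement in mm.
#' @param n_bumps number of Gaussian bumps (default 6).
#' @param sigma bump width in mm (default 35).
#' @param center_box optional 2 x 3 matrix (rows = lower/upper, mm, relative
#'   to the grid centre) restricting bump centres; default: the central 70%
#'   of the grid.
#' @return A `deformation_params` object (bump centres, vectors, sigma,
#'   scale); evaluate with [evaluate_deformation()].
#' @export
random_deformation <- function(geom, amplitude, n_bumps = 6, sigma = 35,
                               center_box = NULL) {
  ext <- (geom$dim - 1) * geom$spacing
  cen <- geom$origin + as.vector(geom$direction %*% (ext / 2))
  if (is.null(center_box))
    center_box <- rbind(-0.35 * ext, 0.35 * ext)
  centers <- sapply(1:3, function(j)
    stats::runif(n_bumps, center_box[1, j], center_box[2, j]))
  centers <- sweep(matrix(centers, ncol = 3), 2, cen, "+")
  vecs <- matrix(stats::rnorm(n_bumps * 3), ncol = 3)
  params <- structure(list(components = list(
    list(centers = centers, vectors = vecs, sigma = sigma, scale = 1))),
    class = "deformation_params")
  if (amplitude <= 0) {
    params$components[[1]]$scale <- 0
    return(params)
  }
  mx <- max_displacement(params, geom)
  params$components[[1]]$scale <- amplitude / mx
  params
}

#' Evaluate a parametric deformation at physical points
#' @param params a `deformation_params` object.
#' @param pts n x 3 matrix of physical points (mm).
#' @return n x 3 matrix of displacements (mm).
#' @export
evaluate_deformation <- function(params, pts) {
  u <- matrix(0, nrow(pts), 3)
  for (cmp in params$components) {
    if (cmp$scale == 0) next
    for (j in seq_len(nrow(cmp$centers))) {
      d2 <- (pts[, 1] - cmp$centers[j, 1])^2 +
            (pts[, 2] - cmp$centers[j, 2])^2 +
            (pts[, 3] - cmp$centers[j, 3])^2
      w <- cmp$scale * exp(-d2 / (2 * cmp$sigma^2))
      u <- u + outer(w, cmp$vectors[j, ])
    }
  }
  u
}

# combine parameter sets with coefficients: sum_i coef_i * params_i
combine_deformations <- function(params_list, coefs) {
  comps <- list()
  for (i in seq_along(params_list)) {
    if (coefs[i] == 0) next
    for (cmp in params_list[[i]]$components) {
      cmp$scale <- cmp$scale * coefs[i]
      comps <- c(comps, list(cmp))
    }
  }
  structure(list(components = comps), class = "deformation_params")
}

max_displacement <- function(params, geom, stride = 2L) {
  d <- pmax(1L, geom$dim %/% stride)
  sub <- list(dim = d, spacing = geom$spacing * stride,
              origin = geom$origin, direction = geom$direction)
  u <- evaluate_deformation(params, grid_phys(sub))
  max(sqrt(rowSums(u^2)))
}

#' Materialise a parametric deformation as a dense field
#' @param params a `deformation_params` object.
#' @param geom grid geometry list (`dim`, `spacing`, `origin`, `direction`).
#' @export
deformation_to_field <- function(params, geom) {
  u <- evaluate_deformation(params, grid_phys(geom))
  deformation_field(array(u, c(geom$dim, 3)), geom$spacing, geom$origin,
                    geom$direction)
}

# backward-warp an image and its labels through a parametric deformation
apply_deformation <- function(vi, lm, params) {
  geom <- geometry_of(vi)
  field <- deformation_to_field(params, geom)
  bg <- min(vi$voxels)
  wi <- warp_image(vi, field, "linear", fill = bg)
  wl <- propagate_labels(lm, field)
  list(image = wi, labels = wl)
}

# -- cohorts ------------------------------------------------------------------

#' Generate a synthetic pelvic cohort with controlled inter-subject variation
#'
#' Per-subject bladder and rectal volumes are drawn independently and
#' uniformly over the cohort ranges (organ filling is independent of body
#' habitus); body, femoral-head and bone-marrow volumes are driven by a
#' shared habitus latent. Each subject is additionally deformed by the sum of
#' (i) an organ-linked shared warp whose signed coefficient follows the
#' subject's bladder/rectum volume deviation from the cohort midpoint — so
#' inter-subject deformation magnitude grows with organ-volume mismatch, the
#' premise that makes selection-strategy comparisons meaningful — (ii) a
#' habitus-linked shared warp following the habitus latent, and (iii) a small
#' subject-specific random warp.
#'
#' @param n number of subjects (>= 2).
#' @param seed integer seed; the cohort is fully deterministic given it.
#' @param dim,spacing grid geometry (defaults 96 x 96 x 64 at 2 mm).
#' @param ranges volume ranges as from [cohort_ranges()].
#' @param amp_organ,amp_habitus,amp_random maximum amplitudes (mm) of the
#'   three deformation components (defaults 6, 3, 1.5).
#' @param noise_sd image noise sd (default 8).
#' @return A `mas_cohort`: list with `atlases` (list of [atlas()]),
#'   `manifest` (data frame: id, drawn + measured volumes, latent habitus,
#'   organ deformation coefficient), and `deformations` (per-subject
#'   parameter sets, evaluable with [evaluate_deformation()]).
#' @export
generate_cohort <- function(n, seed = 1, dim = c(96, 96, 64),
                            spacing = c(2, 2, 2), ranges = cohort_ranges(),
                            amp_organ = 6, amp_habitus = 3, amp_random = 1.5,
                            noise_sd = 8) {
  if (n < 2) stop("need n >= 2 subjects")
  geom <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
               origin = c(0, 0, 0), direction = diag(3))
  lay <- phantom_layout

  draws <- with_local_seed(seed, {
    g <- stats::runif(n, -1, 1)                   # habitus latent
    list(g = g,
         bladder = stats::runif(n, ranges$bladder[1], ranges$bladder[2]),
         rectum = stats::runif(n, ranges$rectum[1], ranges$rectum[2]),
         fh_eps = stats::rnorm(n, 0, 0.03),
         fh_asym = stats::rnorm(n, 0, 0.02),
         mar_eps = stats::rnorm(n, 0, 0.03),
         body_eps = stats::rnorm(n, 0, 0.02))
  })
  mid <- function(r) (r[1] + r[2]) / 2
  half <- function(r) (r[2] - r[1]) / 2
  fh_base <- mid(ranges$femoral_head); mar_base <- mid(ranges$bone_marrow)
  body_base <- mid(ranges$body)

  # shared warp bases, normalized to unit maximum displacement; the
  # organ-linked basis is broad enough (wide bumps over the pelvic region)
  # that its coefficient dominates pairwise field differences, which is what
  # makes deformation magnitude track organ-volume mismatch by construction
  organ_box <- rbind(c(-60, -70, -45), c(60, 65, 50))
  u_organ <- with_local_seed(seed + 1L,
    random_deformation(geom, 1, n_bumps = 8, sigma = 55,
                       center_box = organ_box))
  u_habitus <- with_local_seed(seed + 2L,
    random_deformation(geom, 1, n_bumps = 6, sigma = 45))

  atlases <- vector("list", n)
  deformations <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    b_dev <- (draws$bladder[i] - mid(ranges$bladder)) / half(ranges$bladder)
    r_dev <- (draws$rectum[i] - mid(ranges$rectum)) / half(ranges$rectum)
    s_organ <- 0.7 * b_dev + 0.3 * r_dev           # signed, in [-1, 1]
    g <- draws$g[i]
    fh <- fh_base * (1 + 0.22 * g + draws$fh_eps[i])
    vols <- c(body = body_base * (1 + 0.09 * g + draws$body_eps[i]),
              bladder = draws$bladder[i], rectum = draws$rectum[i],
              femoral_head_l = fh * (1 + draws$fh_asym[i]),
              femoral_head_r = fh * (1 - draws$fh_asym[i]),
              bone_marrow = mar_base * (1 + 0.22 * g + draws$mar_eps[i]))
    u_rand <- with_local_seed(seed + 1000L + i,
      random_deformation(geom, amp_random, n_bumps = 4, sigma = 30))
    params <- combine_deformations(
      list(u_organ, u_habitus, u_rand),
      c(amp_organ * s_organ, amp_habitus * g, 1))
    id <- sprintf("atlas%03d", i)
    sp <- phantom_spec(dim = geom$dim, spacing = geom$spacing,
                       volumes_cc = vols, noise_sd = noise_sd,
                       deformation = list(amplitude = 1, params = params),
                       seed = seed + 2000L + i)
    atlases[[i]] <- generate_phantom(sp, id = id)
    deformations[[i]] <- params
    tv <- attr(atlases[[i]], "true_volumes")
    rows[[i]] <- data.frame(id = id, habitus = g, organ_coef = s_organ,
                            drawn_bladder_cc = draws$bladder[i],
                            drawn_rectum_cc = draws$rectum[i],
                            t(tv), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  names(deformations) <- manifest$id
  names(atlases) <- manifest$id
  structure(list(atlases = atlases, manifest = manifest,
                 deformations = deformations, geometry = geom, seed = seed),
            class = "mas_cohort")
}

#' Pairwise volume-mismatch vs deformation-magnitude table
#'
#' For every subject pair, the absolute bladder-volume difference and the
#' mean displacement magnitude between the two subjects' deformations,
#' evaluated analytically at a random sample of grid points. Used to verify
#' that the cohort realises the volume-mismatch / deformation-difficulty
#' correlation by construction.
#'
#' @param cohort a `mas_cohort`.
#' @param n_points sample size for field evaluation (default 1500).
#' @param seed sampling seed.
#' @export
pairwise_deformation <- function(cohort, n_points = 1500, seed = 1) {
  geom <- cohort$geometry
  pts <- with_local_seed(seed, {
    ext <- (geom$dim - 1) * geom$spacing
    sapply(1:3, function(j) stats::runif(n_points, 0.15 * ext[j],
                                         0.85 * ext[j]))
  })
  pts <- sweep(matrix(pts, ncol = 3), 2, geom$origin, "+")
  us <- lapply(cohort$deformations, evaluate_deformation, pts = pts)
  n <- length(us)
  vols <- cohort$manifest$bladder
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    du <- us[[i]] - us[[j]]
    out[[length(out) + 1]] <- data.frame(
      i = cohort$manifest$id[i], j = cohort$manifest$id[j],
      bladder_diff_cc = abs(vols[i] - vols[j]),
      deformation_mm = mean(sqrt(rowSums(du^2))))
  }
  do.call(rbind, out)
}

#' Derive a segmentation target from an atlas by a known smooth warp
#'
#' Applies a seeded random deformation of the requested maximum amplitude to
#' the atlas image and ground-truth labels. The returned true volumes are the
#' exact volumes of the deformed label map, sidestepping any need to estimate
#' target ROI volumes.
#'
#' @param at an [atlas()].
#' @param amplitude maximum displacement in mm (>= 0; 0 returns the atlas
#'   unchanged).
#' @param seed integer seed.
#' @return list with `id`, `image`, `labels`, `volumes` (named cc vector) and
#'   `deformation` (parameter set, NULL when amplitude is 0).
#' @export
make_target <- function(at, amplitude, seed = 1) {
  stopifnot(inherits(at, "atlas"), amplitude >= 0)
  geom <- geometry_of(at$image)
  if (amplitude == 0) {
    img <- at$image; lab <- at$contours; params <- NULL
  } else {
    params <- with_local_seed(seed, random_deformation(geom, amplitude))
    w <- apply_deformation(at$image, at$contours, params)
    img <- w$image; lab <- w$labels
  }
  vols <- vapply(unname(pelvic_label_names), function(nm)
    volume_of_label(lab, nm), numeric(1))
  names(vols) <- unname(pelvic_label_names)
  list(id = paste0(at$id, "_target"), image = img, labels = lab,
       volumes = vols, deformation = params)
}

#' Write a cohort to disk as NIfTI pairs plus a JSON manifest
#' @param cohort a `mas_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (at in cohort$atlases) {
    write_volume(at$image, file.path(dir, paste0(at$id, "_image.nii.gz")))
    write_labels(at$contours, file.path(dir, paste0(at$id, "_labels.nii.gz")))
  }
  jsonlite::write_json(list(seed = cohort$seed,
                            manifest = cohort$manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
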