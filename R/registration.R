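#' Registration settings
#'
#' Tunable parameters of the rigid and deformable stand-in registration.
#' `rigid_levels` / `def_levels` are image downsampling factors per resolution
#' level (coarse to fine); `control_spacing` is the free-form B-spline control
#' grid spacing in mm; `lambda` weights the bending-energy regularizer against
#' the (intensity-range normalized) mean-squared-difference data term.
#'
#' @param rigid_levels integer downsampling factors for rigid registration.
#' @param rigid_maxit Nelder-Mead iteration caps per rigid level.
#' @param mi_bins histogram bins for the mutual-information metric.
#' @param def_levels downsampling factors for deformable registration.
#' @param def_maxit gradient-descent iteration caps per deformable level.
#' @param control_spacing control-point spacing in mm at the finest level
#'   (default 16); coarser levels use proportionally coarser control grids.
#' @param lambda bending-energy weight (default 1e-4).
#' @export
reg_settings <- function(rigid_levels = c(2, 1), rigid_maxit = c(150, 80),
                         mi_bins = 32,
                         def_levels = c(4, 2, 1), def_maxit = c(100, 60, 40),
                         control_spacing = 16, lambda = 1e-4) {
  list(rigid_levels = rigid_levels, rigid_maxit = rigid_maxit,
       mi_bins = mi_bins, def_levels = def_levels, def_maxit = def_maxit,
       control_spacing = control_spacing, lambda = lambda)
}

#' Rigid transform (rotation about a centre plus translation)
#'
#' Maps physical points by `p' = R (p - center) + center + t`.
#'
#' @param rotation 3x3 rotation matrix, determinant +1.
#' @param translation length-3 mm vector.
#' @param center length-3 rotation centre in mm.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation matrix must have determinant +1")
  structure(list(rotation = unname(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' Apply a rigid transform to physical points
#' @param tf a [rigid_transform()].
#' @param pts n x 3 matrix of physical points (mm).
#' @export
apply_rigid <- function(tf, pts) {
  sweep(sweep(pts, 2, tf$center, "-") %*% t(tf$rotation), 2,
        tf$center + tf$translation, "+")
}

euler_rotation <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Dense deformation vector field on a target grid
#'
#' Per-voxel displacements in mm; the mapped physical point of voxel centre
#' `x` is `x + u(x)`. The identity field has all-zero displacements.
#'
#' @param disp 4-D array `dim x 3` of displacements (mm).
#' @param spacing,origin,direction grid geometry of the target.
#' @export
deformation_field <- function(disp, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                              direction = diag(3)) {
  stopifnot(length(dim(disp)) == 4L, dim(disp)[4] == 3L)
  if (any(!is.finite(disp))) stop("displacements must be finite everywhere")
  structure(list(disp = disp, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = unname(direction)),
            class = "deformation_field")
}

field_geometry <- function(field) {
  list(dim = dim(field$disp)[1:3], spacing = field$spacing,
       origin = field$origin, direction = field$direction)
}

# displacements as an n x 3 matrix in voxel (i fastest) order
field_disp_matrix <- function(field) {
  d <- dim(field$disp)
  matrix(field$disp, nrow = prod(d[1:3]), ncol = 3)
}

#' Warp an image through a deformation field
#'
#' Samples `moving` at `x + u(x)` for every voxel centre `x` of the field's
#' grid. Points mapped outside `moving` become `fill`.
#'
#' @param moving a [volume_image()].
#' @param field a [deformation_field()] on the output grid.
#' @param method `"linear"` (images) or `"nearest"` (labels).
#' @param fill value for points mapped outside the moving image
#'   (default `NA`).
#' @return A [volume_image()] on the field's grid.
#' @export
warp_image <- function(moving, field, method = c("linear", "nearest"),
                       fill = NA_real_) {
  method <- match.arg(method)
  geom <- field_geometry(field)
  pts <- grid_phys(geom) + field_disp_matrix(field)
  vals <- sample_grid(moving$voxels, geometry_of(moving), pts, method)
  vals[is.na(vals)] <- fill
  arr <- array(vals, geom$dim)
  if (all(is.finite(arr)))
    volume_image(arr, geom$spacing, geom$origin, geom$direction)
  else structure(list(voxels = arr, spacing = geom$spacing,
                      origin = geom$origin, direction = geom$direction),
                 class = "volume_image")
}

#' Mutual information between two images from a joint histogram
#'
#' `MI = sum p(x,y) log[p(x,y) / (p(x) p(y))]`, in nats, from a joint
#' intensity histogram with `bins` equal-width bins over each image's observed
#' range. Images not on a common grid are first resampled (`b` onto `a`,
#' linear); voxels falling outside the overlap are dropped.
#'
#' @param a,b [volume_image()]s.
#' @param bins number of histogram bins (>= 8, default 32).
#' @return mutual information in nats (>= 0 up to floating error).
#' @export
mattes_mi <- function(a, b, bins = 32) {
  if (bins < 8) stop("bins must be >= 8")
  av <- as.vector(a$voxels)
  if (!same_grid(a, b)) {
    bv <- sample_grid(b$voxels, geometry_of(b), grid_phys(geometry_of(a)),
                      "linear")
  } else bv <- as.vector(b$voxels)
  keep <- !is.na(av) & !is.na(bv)
  av <- av[keep]; bv <- bv[keep]
  mi_from_samples(av, bv, bins)
}

mi_from_samples <- function(av, bv, bins, soft = FALSE) {
  ra <- range(av); rb <- range(bv)
  if (diff(ra) == 0 || diff(rb) == 0) {
    warning("constant image: zero marginal entropy, MI = 0")
    return(0)
  }
  pm <- cpp_joint_hist(av, bv, as.integer(bins),
                       ra[1], diff(ra) / bins, rb[1], diff(rb) / bins, soft)
  pm <- pm / sum(pm)
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(px, py)[nz]))
}

# downsample a volume_image by integer factor with block means
downsample_image <- function(vi, f) {
  if (f == 1) return(vi)
  arr <- cpp_block_mean(as.double(vi$voxels), as.integer(dim(vi$voxels)),
                        as.integer(f))
  # block centre offset: centre of an f-block sits (f-1)/2 voxels into it
  off <- vi$direction %*% (vi$spacing * (f - 1) / 2)
  volume_image(array(arr, dim(arr)), vi$spacing * f,
               vi$origin + as.vector(off), vi$direction)
}

resample_rigid <- function(fixed_geom, moving, tf) {
  pts <- apply_rigid(tf, grid_phys(fixed_geom))
  vals <- sample_grid(moving$voxels, geometry_of(moving), pts, "linear")
  array(vals, fixed_geom$dim)
}

#' Rigid registration by mutual-information maximisation
#'
#' Multi-resolution Nelder-Mead search over three Euler
#' angles and three translations, maximising the joint-histogram MI between
#' the fixed image and the resampled moving image. Rotation is about the fixed
#' image's physical centre. Deterministic for fixed settings.
#'
#' @param fixed,moving [volume_image()]s with overlapping fields of view.
#' @param settings a [reg_settings()] list.
#' @return A [rigid_transform()]; attribute `converged` is FALSE when the
#'   optimizer hit its iteration cap at the finest level (best-found returned
#'   with a warning).
#' @export
rigid_register <- function(fixed, moving, settings = reg_settings()) {
  center <- as.vector(fixed$origin +
    fixed$direction %*% ((grid_dim(fixed) - 1) * fixed$spacing / 2))
  # initialise translation from the intensity centre-of-mass offset
  com <- function(vi) {
    w <- as.vector(vi$voxels) - min(vi$voxels)
    if (sum(w) == 0) w <- w + 1
    colSums(grid_phys(geometry_of(vi)) * w) / sum(w)
  }
  par <- c(0, 0, 0, com(moving) - com(fixed))  # rx, ry, rz (rad), t (mm)
  conv <- TRUE
  for (li in seq_along(settings$rigid_levels)) {
    f <- settings$rigid_levels[li]
    fx <- downsample_image(fixed, f)
    mv <- downsample_image(moving, f)
    geom <- geometry_of(fx)
    # evaluate the metric on a half-voxel-offset sample grid so that no pose
    # (identity included) aligns samples with voxel centres: grid-aligned
    # poses otherwise carve a spurious notch into the MI surface
    pts <- grid_phys(geom)
    pts <- sweep(pts, 2, as.vector(geom$direction %*% (geom$spacing / 2)),
                 "+")
    fxs <- sample_grid(fx$voxels, geom, pts, "linear")
    mgeom <- geometry_of(mv)
    cost <- function(p) {
      tf <- rigid_transform(euler_rotation(p[1], p[2], p[3]), p[4:6], center)
      w <- sample_grid(mv$voxels, mgeom, apply_rigid(tf, pts), "linear")
      keep <- !is.na(w) & !is.na(fxs)
      if (sum(keep) < 32) return(0)
      # partial-volume binning keeps the cost surface smooth for the optimizer
      -mi_from_samples(fxs[keep], w[keep], settings$mi_bins, soft = TRUE)
    }
    if (li == 1L) {
      # the MI surface can hold a weak local maximum at the identity pose,
      # separated from the true basin; a coarse sweep over each rotation
      # axis seeds the simplex inside the right basin
      for (ax in 1:3) {
        sweep_vals <- seq(-10, 10, by = 1.5) * pi / 180
        cands <- vapply(sweep_vals, function(a) {
          p <- par; p[ax] <- p[ax] + a; cost(p)
        }, numeric(1))
        par[ax] <- par[ax] + sweep_vals[which.min(cands)]
      }
    }
    opt <- stats::optim(par, cost, method = "Nelder-Mead",
                        control = list(maxit = settings$rigid_maxit[li],
                                       parscale = c(0.1, 0.1, 0.1, 15, 15, 15),
                                       reltol = 1e-8))
    par <- opt$par
    if (li == length(settings$rigid_levels) && opt$convergence != 0) {
      conv <- FALSE
      warning("rigid registration: optimizer iteration cap reached; ",
              "returning best-found transform")
    }
  }
  tf <- rigid_transform(euler_rotation(par[1], par[2], par[3]), par[4:6],
                        center)
  attr(tf, "converged") <- conv
  tf
}

# -- free-form deformable registration ---------------------------------------

control_geometry <- function(fixed_geom, spacing_mm) {
  ext <- (fixed_geom$dim - 1) * fixed_geom$spacing
  n <- pmax(4L, as.integer(ceiling(ext / spacing_mm)) + 3L)
  list(dim = n, spacing = rep(spacing_mm, 3),
       origin = fixed_geom$origin -
         as.vector(fixed_geom$direction %*% rep(spacing_mm, 3)),
       direction = fixed_geom$direction)
}

# second-difference (bending-like) penalty and its gradient on the control grid
bending_penalty <- function(uc) {
  d <- dim(uc)
  pen <- 0
  grad <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 3) next
    n <- d[ax]
    idx <- function(shift) {
      s <- lapply(d, seq_len)
      s[[ax]] <- seq_len(n - 2) + shift
      s
    }
    a0 <- do.call(`[`, c(list(uc), idx(0), list(drop = FALSE)))
    a1 <- do.call(`[`, c(list(uc), idx(1), list(drop = FALSE)))
    a2 <- do.call(`[`, c(list(uc), idx(2), list(drop = FALSE)))
    d2 <- a0 - 2 * a1 + a2
    pen <- pen + sum(d2^2)
    add_at <- function(g, shift, val) {
      s <- lapply(d, seq_len)
      s[[ax]] <- seq_len(n - 2) + shift
      g_sub <- do.call(`[`, c(list(g), s, list(drop = FALSE)))
      do.call(`[<-`, c(list(g), s, list(g_sub + val)))
    }
    grad <- add_at(grad, 0, 2 * d2)
    grad <- add_at(grad, 1, -4 * d2)
    grad <- add_at(grad, 2, 2 * d2)
  }
  list(penalty = pen, grad = grad)
}

ffd_level <- function(fixed, moving, cgeom, uc, lambda, maxit) {
  geom <- geometry_of(fixed)
  fxv <- as.vector(fixed$voxels)
  nvox <- length(fxv)
  pts0 <- grid_phys(geom)
  cidx <- index_from_phys(cgeom, pts0)   # constant control-space indices
  mgeom <- geometry_of(moving)
  irange2 <- max(diff(range(fxv)), 1)^2
  cd <- cgeom$dim
  nctl <- prod(cd)

  # moving-image gradient volumes (central differences, mm^-1 units * HU)
  grad_arr <- lapply(1:3, function(ax) {
    d <- dim(moving$voxels)
    s1 <- lapply(d, seq_len); s2 <- s1
    s1[[ax]] <- pmin(s1[[ax]] + 1L, d[ax]); s2[[ax]] <- pmax(s2[[ax]] - 1L, 1L)
    num <- do.call(`[`, c(list(moving$voxels), s1)) -
           do.call(`[`, c(list(moving$voxels), s2))
    array(num / (2 * moving$spacing[ax]), d)
  })

  eval_state <- function(u) {
    disp <- vapply(1:3, function(c3)
      cpp_sample3d(as.double(u[, , , c3]), as.integer(cd), cidx, FALSE),
      numeric(nvox))
    disp[is.na(disp)] <- 0
    pts <- pts0 + disp
    w <- sample_grid(moving$voxels, mgeom, pts, "linear")
    r <- w - fxv
    r[is.na(r)] <- 0
    bp <- bending_penalty_uc(u)
    cost <- mean(r^2) / irange2 + lambda * bp$penalty / (3 * nctl)
    list(pts = pts, r = r, cost = cost, bgrad = bp$grad)
  }
  bending_penalty_uc <- function(u) {
    pen <- 0; grad <- array(0, dim(u))
    for (c3 in 1:3) {
      b <- bending_penalty(u[, , , c3, drop = TRUE])
      pen <- pen + b$penalty
      grad[, , , c3] <- b$grad
    }
    list(penalty = pen, grad = grad)
  }

  # cost and exact analytic gradient of the objective in the control
  # coefficients, shared between optim's fn and gr calls
  last <- NULL
  compute <- function(pv) {
    u <- array(pv, c(cd, 3))
    st <- eval_state(u)
    gc <- array(0, c(cd, 3))
    for (ax in 1:3) {
      gm <- sample_grid(grad_arr[[ax]], mgeom, st$pts, "linear")
      gm[is.na(gm)] <- 0
      gc[, , , ax] <- array(cpp_splat3d(2 * st$r * gm / (nvox * irange2),
                                        as.integer(cd), cidx), cd)
    }
    gc <- gc + lambda * st$bgrad / (3 * nctl)
    list(pv = pv, cost = st$cost, grad = as.vector(gc))
  }
  fn <- function(pv) {
    last <<- compute(pv)
    last$cost
  }
  gr <- function(pv) {
    if (is.null(last) || !identical(pv, last$pv)) last <<- compute(pv)
    last$grad
  }
  p0 <- as.vector(uc)
  opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  if (opt$value <= fn(p0))
    list(uc = array(opt$par, c(cd, 3)), cost = opt$value)
  else
    list(uc = uc, cost = fn(p0))
}

#' Deformable registration (free-form B-spline stand-in)
#'
#' Multi-resolution free-form deformation: per-voxel displacement is the
#' trilinear (first-order B-spline) interpolation of a control grid with
#' spacing `control_spacing` mm, optimised by adaptive gradient descent on
#' the mean-squared intensity difference plus a bending-energy regularizer
#' (valid for same-modality CT-to-CT alignment). An optional rigid transform
#' is applied first; the returned field is the total displacement
#' (rigid + deformable) on the fixed grid, so
#' `warp_image(moving, field)` aligns `moving` to `fixed`. The residual
#' mean-squared difference never exceeds that of the initialisation: if
#' optimisation fails to improve, the initial field is returned.
#'
#' @param fixed,moving [volume_image()]s.
#' @param init optional [rigid_transform()] applied before deformation.
#' @param settings a [reg_settings()] list.
#' @return A [deformation_field()] on the fixed grid; attribute `cost` holds
#'   the final normalized objective.
#' @export
deformable_register <- function(fixed, moving, init = NULL,
                                settings = reg_settings()) {
  fit <- ffd_register(fixed, moving, init, settings)
  field <- expand_ffd(fit, geometry_of(fixed))
  # optimizer contract: never worse than the initialisation
  init_field <- rigid_init_field(init, geometry_of(fixed))
  if (residual_msd(fixed, moving, field) >
      residual_msd(fixed, moving, init_field) + 1e-12) {
    warning("deformable registration did not improve on its initialisation; ",
            "returning the initial field")
    field <- if (is.null(init_field))
      deformation_field(array(0, c(grid_dim(fixed), 3)), fixed$spacing,
                        fixed$origin, fixed$direction)
    else init_field
  }
  field
}

rigid_init_field <- function(init, geom) {
  if (is.null(init)) return(NULL)
  pts <- grid_phys(geom)
  disp <- apply_rigid(init, pts) - pts
  deformation_field(array(disp, c(geom$dim, 3)), geom$spacing, geom$origin,
                    geom$direction)
}

# core fit returning compact control-grid coefficients (reused by the
# experiment runner, which caches these instead of dense fields)
ffd_register <- function(fixed, moving, init = NULL,
                         settings = reg_settings()) {
  fgeom <- geometry_of(fixed)
  nlev <- length(settings$def_levels)
  finest <- settings$def_levels[nlev]
  uc <- NULL
  cgeom <- NULL
  for (li in seq_len(nlev)) {
    f <- settings$def_levels[li]
    # coarse-to-fine control grid refinement along with the image pyramid
    cs <- settings$control_spacing * f / finest
    cgeom_l <- control_geometry(fgeom, cs)
    cpts <- grid_phys(cgeom_l)
    uc_l <- array(0, c(cgeom_l$dim, 3))
    if (is.null(uc)) {
      if (!is.null(init)) {
        # bake the rigid part into the control grid (exact for an affine
        # map under trilinear interpolation)
        cdisp <- apply_rigid(init, cpts) - cpts
        for (c3 in 1:3) uc_l[, , , c3] <- array(cdisp[, c3], cgeom_l$dim)
      }
    } else {
      cidx <- index_from_phys(cgeom, cpts)
      for (c3 in 1:3) {
        v <- cpp_sample3d(as.double(uc[, , , c3]), as.integer(cgeom$dim),
                          cidx, FALSE)
        vn <- cpp_sample3d(as.double(uc[, , , c3]), as.integer(cgeom$dim),
                           pmin(pmax(cidx, 0),
                                matrix(rep(cgeom$dim - 1, each = nrow(cidx)),
                                       ncol = 3)), FALSE)
        v[is.na(v)] <- vn[is.na(v)]
        uc_l[, , , c3] <- array(v, cgeom_l$dim)
      }
    }
    fx <- downsample_image(fixed, f)
    mv <- downsample_image(moving, f)
    lev <- ffd_level(fx, mv, cgeom_l, uc_l, settings$lambda,
                     settings$def_maxit[li])
    uc <- lev$uc
    cgeom <- cgeom_l
  }
  structure(list(uc = uc, cgeom = cgeom, init = init, settings = settings),
            class = "ffd_fit")
}

expand_ffd <- function(fit, fixed_geom) {
  nvox <- prod(fixed_geom$dim)
  cidx <- index_from_phys(fit$cgeom, grid_phys(fixed_geom))
  disp <- vapply(1:3, function(c3)
    cpp_sample3d(as.double(fit$uc[, , , c3]), as.integer(fit$cgeom$dim),
                 cidx, FALSE), numeric(nvox))
  disp[is.na(disp)] <- 0
  field <- deformation_field(array(disp, c(fixed_geom$dim, 3)),
                             fixed_geom$spacing, fixed_geom$origin,
                             fixed_geom$direction)
  field
}

# mean squared difference between fixed and moving warped by field
residual_msd <- function(fixed, moving, field = NULL) {
  if (is.null(field)) {
    w <- sample_grid(moving$voxels, geometry_of(moving),
                     grid_phys(geometry_of(fixed)), "linear")
  } else {
    w <- as.vector(warp_image(moving, field)$voxels)
  }
  r <- w - as.vector(fixed$voxels)
  mean(r[!is.na(r)]^2)
}

# normalized cross-correlation on the overlap
image_ncc <- function(fixed, warped) {
  a <- as.vector(fixed$voxels); b <- as.vector(warped$voxels)
  keep <- !is.na(a) & !is.na(b)
  if (stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0) return(0)
  stats::cor(a[keep], b[keep])
}

#' Propagate atlas labels through a deformation field
#'
#' Nearest-neighbour interpolation of the atlas label map at `x + u(x)`;
#' points mapped outside the atlas volume become background (0).
#'
#' @param atlas_contours a [label_map()] on the atlas grid.
#' @param field a [deformation_field()] on the target grid (as returned by
#'   registering the atlas image to the target).
#' @return A [label_map()] on the target grid.
#' @export
propagate_labels <- function(atlas_contours, field) {
  geom <- field_geometry(field)
  pts <- grid_phys(geom) + field_disp_matrix(field)
  vals <- sample_grid(atlas_contours$labels, geometry_of(atlas_contours),
                      pts, "nearest")
  vals[is.na(vals)] <- 0
  label_map(array(as.integer(vals), geom$dim), geom$spacing, geom$origin,
            geom$direction, label_names = atlas_contours$label_names)
}

#' Majority-vote label fusion
#'
#' Per voxel, the most frequent label across candidate segmentations;
#' background (0) counts as a vote; ties between distinct top labels resolve
#' to background.
#'
#' @param candidates list of [label_map()]s on one common grid.
#' @return The fused [label_map()].
#' @export
majority_vote <- function(candidates) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  g1 <- candidates[[1]]
  for (cnd in candidates[-1])
    if (!same_grid(g1, cnd)) stop("candidate grids must be identical")
  labs <- sort(unique(unlist(lapply(candidates, function(x)
    unique(as.vector(x$labels))))))
  d <- grid_dim(g1)
  best <- array(0L, d)
  bestc <- array(-1L, d)
  tie <- array(FALSE, d)
  for (l in labs) {
    cnt <- Reduce(`+`, lapply(candidates, function(x) x$labels == l))
    gt <- cnt > bestc
    eq <- cnt == bestc
    tie[eq] <- TRUE
    tie[gt] <- FALSE
    best[gt] <- l
    bestc[gt] <- cnt[gt]
  }
  best[tie] <- 0L
  label_map(best, g1$spacing, g1$origin, g1$direction,
            label_names = g1$label_names)
}
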