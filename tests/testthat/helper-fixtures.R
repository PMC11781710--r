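# Shared fixtures: small phantoms (coarse 4 mm grid, same physical anatomy
# as the full-resolution cohort) and tiny synthetic images/masks.

small_phantom <- function(id = "p1", noise_sd = 0, texture_amp = 0,
                          volumes = NULL, seed = 1) {
  vols <- c(body = 2150, bladder = 254, rectum = 68, femoral_head_l = 28,
            femoral_head_r = 28, bone_marrow = 60)
  if (!is.null(volumes)) vols[names(volumes)] <- volumes
  generate_phantom(
    phantom_spec(dim = c(48, 48, 32), spacing = c(4, 4, 4),
                 volumes_cc = vols, noise_sd = noise_sd,
                 texture_amp = texture_amp, seed = seed),
    id = id)
}

# label map from a logical/integer array, unit names for a single label
mask_map <- function(arr, spacing = c(1, 1, 1)) {
  label_map(array(as.integer(arr), dim(arr)), spacing,
            label_names = c("1" = "s"))
}

random_mask <- function(dim = c(16, 16, 16), n = NULL) {
  a <- array(FALSE, dim)
  if (is.null(n)) n <- sample(5:50, 1)
  idx <- cbind(sample(2:(dim[1] - 1), n, TRUE),
               sample(2:(dim[2] - 1), n, TRUE),
               sample(2:(dim[3] - 1), n, TRUE))
  a[idx] <- TRUE
  a
}

# brute-force pooled 95th-percentile surface distance oracle (cm)
hd95_bruteforce <- function(la, lb, label = 1, percentile = 0.95) {
  pa <- extract_surface_voxels(la, label)
  pb <- extract_surface_voxels(lb, label)
  directed <- function(p, q)
    apply(p, 1, function(r) sqrt(min(colSums((t(q) - r)^2))))
  pooled <- c(directed(pa, pb), directed(pb, pa))
  unname(stats::quantile(pooled, percentile, type = 7)) / 10
}

# constant-translation deformation field over a geometry
translation_field <- function(vi, t) {
  d <- dim(vi$voxels)
  deformation_field(array(rep(t, each = prod(d)), c(d, 3)),
                    vi$spacing, vi$origin, vi$direction)
}

# feature vectors from a plain matrix (rows = atlas ids)
vectors_from_matrix <- function(m, structures = NULL) {
  if (is.null(structures)) structures <- paste0("s", seq_len(ncol(m)))
  out <- lapply(seq_len(nrow(m)), function(i)
    feature_vector(structures, rep(1, ncol(m)), normalized = m[i, ]))
  names(out) <- rownames(m)
  out
}
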