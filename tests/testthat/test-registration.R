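test_that("mutual information obeys its identities", {
  at <- small_phantom(noise_sd = 4)
  fx <- at$image
  # I(X;X) = H(X) at the same binning
  av <- as.vector(fx$voxels)
  bins <- 32
  br <- range(av)
  idx <- pmin(bins, 1L + floor((av - br[1]) / diff(br) * bins))
  p <- tabulate(idx, bins) / length(av)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mattes_mi(fx, fx), h, tolerance = 1e-9)

  # symmetry
  set.seed(1)
  other <- small_phantom("p2", noise_sd = 4, volumes = c(bladder = 120), seed = 2)
  expect_lt(abs(mattes_mi(fx, other$image) - mattes_mi(other$image, fx)), 1e-9)

  # invariance to an affine intensity rescale of one image
  resc <- volume_image(fx$voxels * 3 + 100, fx$spacing, fx$origin)
  expect_equal(mattes_mi(fx, resc), h, tolerance = 1e-9)

  # MI >= 0
  expect_gte(mattes_mi(fx, other$image), 0)
})

test_that("independent noise images have near-zero MI (histogram bias bound)", {
  set.seed(42)
  a <- volume_image(array(runif(64^3), c(64, 64, 64)))
  b <- volume_image(array(runif(64^3), c(64, 64, 64)))
  # expected positive bias for independent data ~ (bins-1)^2 / (2 n)
  expect_lt(mattes_mi(a, b, bins = 32), 0.01)
})

test_that("constant images give MI 0 with a warning", {
  a <- volume_image(array(1, c(8, 8, 8)))
  b <- volume_image(array(stats::rnorm(512), c(8, 8, 8)))
  expect_warning(mi <- mattes_mi(a, b), "constant")
  expect_equal(mi, 0)
})

test_that("rigid registration recovers a pure translation", {
  at <- small_phantom(noise_sd = 0)
  fx <- at$image
  mv <- warp_image(fx, translation_field(fx, c(-10, 0, 0)), fill = -1000)
  tf <- suppressWarnings(rigid_register(fx, mv))
  # recovered within half the voxel spacing
  expect_lt(max(abs(tf$translation - c(10, 0, 0))), 0.5 * min(fx$spacing))
  expect_equal(det(tf$rotation), 1, tolerance = 1e-6)

  # moving == fixed: transform within tolerance of identity
  tf0 <- suppressWarnings(rigid_register(fx, fx))
  expect_lt(max(abs(tf0$translation)), 0.5)
  expect_lt(acos(pmin(1, (sum(diag(tf0$rotation)) - 1) / 2)) * 180 / pi, 0.5)
})

test_that("deformable registration never worsens the residual and is null at identity", {
  at <- small_phantom(noise_sd = 0)
  fx <- at$image
  fid <- deformable_register(fx, fx,
                             settings = reg_settings(def_levels = c(4, 2),
                                                     def_maxit = c(30, 15)))
  mag <- sqrt(rowSums(masel:::field_disp_matrix(fid)^2))
  expect_lt(unname(stats::quantile(mag, 0.99)), 0.1)

  set.seed(3)
  params <- random_deformation(masel:::geometry_of(fx), 6)
  tgt <- warp_image(fx, deformation_to_field(params, masel:::geometry_of(fx)),
                    fill = -1000)
  fest <- deformable_register(tgt, fx,
                              settings = reg_settings(def_levels = c(4, 2),
                                                      def_maxit = c(50, 25),
                                                      lambda = 3e-4))
  expect_lte(masel:::residual_msd(tgt, fx, fest),
             masel:::residual_msd(tgt, fx) + 1e-9)
})

test_that("label propagation through identity and translation fields", {
  at <- small_phantom()
  lm <- at$contours
  geom <- masel:::geometry_of(at$image)
  id_field <- translation_field(at$image, c(0, 0, 0))
  expect_identical(propagate_labels(lm, id_field)$labels, lm$labels)

  # pure translation of (8, 0, 0) mm at 4 mm spacing shifts labels 2 voxels
  tfield <- translation_field(at$image, c(8, 0, 0))
  shifted <- propagate_labels(lm, tfield)$labels
  d <- dim(lm$labels)
  expect_identical(shifted[1:(d[1] - 2), , ], lm$labels[3:d[1], , ])
  expect_true(all(shifted[(d[1] - 1):d[1], , ] == 0L))

  # output labels are a subset of input labels plus background
  expect_true(all(unique(as.vector(shifted)) %in%
                  c(0L, unique(as.vector(lm$labels)))))
})

test_that("majority vote implements per-voxel mode with ties to background", {
  base <- array(0L, c(4, 4, 4))
  mk <- function(v) label_map(v, label_names = c("1" = "a", "2" = "b"))
  v1 <- base; v1[1, 1, 1] <- 1L
  v2 <- base; v2[1, 1, 1] <- 1L
  v3 <- base; v3[1, 1, 1] <- 1L
  v4 <- base; v5 <- base
  fused <- majority_vote(lapply(list(v1, v2, v3, v4, v5), mk))
  expect_equal(fused$labels[1, 1, 1], 1L)  # 3 of 5 vote label 1

  # 2/2 split between labels 1 and 2 -> background
  w1 <- base; w1[2, 2, 2] <- 1L
  w2 <- base; w2[2, 2, 2] <- 1L
  w3 <- base; w3[2, 2, 2] <- 2L
  w4 <- base; w4[2, 2, 2] <- 2L
  fused <- majority_vote(lapply(list(w1, w2, w3, w4), mk))
  expect_equal(fused$labels[2, 2, 2], 0L)

  # all candidates identical -> identical output
  at <- small_phantom()
  same <- majority_vote(list(at$contours, at$contours, at$contours))
  expect_identical(same$labels, at$contours$labels)
})

test_that("majority vote equals a brute-force mode oracle and is permutation-invariant", {
  set.seed(8)
  mk <- function() {
    label_map(array(sample(0:3, 16^3, TRUE), c(16, 16, 16)),
              label_names = c("1" = "a", "2" = "b", "3" = "c"))
  }
  cands <- replicate(5, mk(), simplify = FALSE)
  fused <- majority_vote(cands)
  stacked <- sapply(cands, function(x) as.vector(x$labels))
  oracle <- apply(stacked, 1, function(v) {
    t <- table(v)
    top <- max(t)
    winners <- as.integer(names(t)[t == top])
    if (length(winners) > 1) 0L else winners
  })
  expect_identical(as.vector(fused$labels), oracle)
  perm <- majority_vote(cands[c(3, 1, 5, 2, 4)])
  expect_identical(perm$labels, fused$labels)
})

test_that("an atlas registered to itself reproduces its own contours", {
  at <- small_phantom(noise_sd = 0)
  field <- deformable_register(at$image, at$image,
                               settings = reg_settings(def_levels = c(4, 2),
                                                       def_maxit = c(20, 10)))
  prop <- propagate_labels(at$contours, field)
  expect_gt(dice(prop, at$contours, "bladder"), 0.99)
})
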