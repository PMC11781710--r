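test_that("phantom realizes requested volumes and is deterministic", {
  sp <- phantom_spec(dim = c(48, 48, 32), spacing = c(4, 4, 4),
                     volumes_cc = c(body = 2150, bladder = 200, rectum = 68,
                                    femoral_head_l = 28, femoral_head_r = 28,
                                    bone_marrow = 60), seed = 4)
  at <- generate_phantom(sp)
  tv <- attr(at, "true_volumes")
  expect_gte(tv[["bladder"]], 190)
  expect_lte(tv[["bladder"]], 210)
  for (nm in c("rectum", "femoral_head_l", "femoral_head_r", "bone_marrow"))
    expect_lt(abs(tv[[nm]] - sp$volumes_cc[[nm]]) / sp$volumes_cc[[nm]], 0.05)

  at2 <- generate_phantom(sp)
  expect_identical(at$image$voxels, at2$image$voxels)   # bit-identical
  expect_identical(at$contours$labels, at2$contours$labels)
})

test_that("phantom labels are pairwise disjoint and contained in the body", {
  at <- small_phantom()
  lab <- at$contours$labels
  # single multi-label volume: disjointness is structural; check organs
  # are strictly inside the body by dilating each organ by one voxel
  organs <- lab > 0L & lab < 6L
  shell <- masel:::surface_mask(organs)
  idx <- which(shell, arr.ind = TRUE)
  for (shift in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
    nb <- sweep(idx, 2, shift, "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= dim(lab)[1] &
            nb[, 2] >= 1 & nb[, 2] <= dim(lab)[2] &
            nb[, 3] >= 1 & nb[, 3] <= dim(lab)[3]
    expect_true(all(lab[nb[keep, , drop = FALSE]] != 0L))
  }
})

test_that("phantoms reject out-of-range and unplaceable requests", {
  expect_error(phantom_spec(volumes_cc = c(body = 2150, bladder = 500,
                                           rectum = 68, femoral_head_l = 28,
                                           femoral_head_r = 28,
                                           bone_marrow = 60)),
               "cohort range")
  expect_error(phantom_spec(volumes_cc = c(body = 2150, bladder = 254,
                                           rectum = 10, femoral_head_l = 28,
                                           femoral_head_r = 28,
                                           bone_marrow = 60)),
               "cohort range")
  # a femoral head too large for a small body cannot be placed
  sp <- phantom_spec(volumes_cc = c(body = 1500, bladder = 437,
                                    rectum = 115, femoral_head_l = 60,
                                    femoral_head_r = 60, bone_marrow = 60))
  expect_error(generate_phantom(sp), "unplaceable")
})

test_that("cohort draws respect the configured ranges and reproduce bit-identically", {
  ch <- generate_cohort(6, seed = 21, dim = c(48, 48, 32),
                        spacing = c(4, 4, 4))
  expect_length(ch$atlases, 6)
  rg <- cohort_ranges()
  expect_true(all(ch$manifest$drawn_bladder_cc >= rg$bladder[1] &
                  ch$manifest$drawn_bladder_cc <= rg$bladder[2]))
  expect_true(all(ch$manifest$drawn_rectum_cc >= rg$rectum[1] &
                  ch$manifest$drawn_rectum_cc <= rg$rectum[2]))
  ch2 <- generate_cohort(6, seed = 21, dim = c(48, 48, 32),
                         spacing = c(4, 4, 4))
  expect_identical(ch$atlases[[3]]$image$voxels, ch2$atlases[[3]]$image$voxels)
  expect_false(identical(ch$atlases[[1]]$image$voxels,
                         ch$atlases[[2]]$image$voxels))
})

test_that("feature extraction recovers generator-recorded volumes", {
  ch <- generate_cohort(3, seed = 5, dim = c(48, 48, 32), spacing = c(4, 4, 4))
  for (at in ch$atlases) {
    fv <- extract_features(at, pelvic_structures())
    tv <- attr(at, "true_volumes")
    expect_equal(fv$raw_cc, unname(tv[fv$structure_order]), tolerance = 1e-12)
  }
})

test_that("pairwise deformation magnitude correlates with bladder-volume mismatch", {
  ch <- generate_cohort(12, seed = 31, dim = c(48, 48, 32),
                        spacing = c(4, 4, 4))
  pd <- pairwise_deformation(ch, n_points = 800, seed = 1)
  expect_gt(cor(pd$bladder_diff_cc, pd$deformation_mm), 0.5)
})

test_that("make_target honours its contracts", {
  at <- small_phantom()
  t0 <- make_target(at, 0)
  expect_identical(t0$image$voxels, at$image$voxels)
  expect_identical(t0$labels$labels, at$contours$labels)

  t1 <- make_target(at, 6, seed = 9)
  # returned volumes equal volume_of_label of the returned labels
  for (nm in names(t1$volumes))
    expect_equal(t1$volumes[[nm]], volume_of_label(t1$labels, nm))
  # determinism
  t2 <- make_target(at, 6, seed = 9)
  expect_identical(t1$image$voxels, t2$image$voxels)
  expect_error(make_target(at, -1), "amplitude")
})

test_that("ground-truth overlap with the undeformed atlas decays with amplitude", {
  at <- small_phantom(noise_sd = 0)
  dscs <- vapply(c(0, 4, 8, 16), function(a) {
    tg <- make_target(at, a, seed = 13)
    dice(tg$labels, at$contours, "bladder")
  }, numeric(1))
  expect_equal(dscs[1], 1)
  expect_true(all(diff(dscs) < 0))
})

test_that("a cohort written to disk regenerates identically on read", {
  ch <- generate_cohort(2, seed = 3, dim = c(48, 48, 32), spacing = c(4, 4, 4))
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_volume(file.path(dir, "atlas001_labels.nii.gz"))
  expect_identical(back$labels$labels, ch$atlases[[1]]$contours$labels)
  img <- read_volume(file.path(dir, "atlas001_image.nii.gz"))$image
  expect_equal(img$voxels, ch$atlases[[1]]$image$voxels, tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$manifest$id, ch$manifest$id)
})
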