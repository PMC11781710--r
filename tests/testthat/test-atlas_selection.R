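test_that("select_fasa equals a full-sort oracle with id tie-breaks", {
  set.seed(1)
  m <- matrix(runif(40), 20, 2,
              dimnames = list(sprintf("a%02d", sample(20)), NULL))
  vecs <- vectors_from_matrix(m)
  tgt <- feature_vector(c("s1", "s2"), c(1, 1), normalized = runif(2))
  sel <- select_fasa(tgt, vecs, n = 5)
  d <- sqrt(colSums((t(m) - tgt$normalized)^2))
  oracle <- names(sort(d))[1:5]
  expect_identical(sel$ranked_atlases, oracle)
  expect_equal(sel$scores, unname(sort(d)[1:5]))
  expect_false(is.unsorted(sel$scores))

  # target identical to one atlas: that atlas first with D = 0
  tgt0 <- feature_vector(c("s1", "s2"), c(1, 1), normalized = m[7, ])
  sel0 <- select_fasa(tgt0, vecs, n = 3)
  expect_equal(sel0$ranked_atlases[1], rownames(m)[7])
  expect_equal(sel0$scores[1], 0)
})

test_that("select_fasa breaks exact distance ties lexicographically", {
  m <- rbind(zeta = c(0, 1), alpha = c(0, -1), mid = c(5, 5))
  vecs <- vectors_from_matrix(m)
  tgt <- feature_vector(c("s1", "s2"), c(1, 1), normalized = c(0, 0))
  sel <- select_fasa(tgt, vecs, n = 2)
  expect_identical(sel$ranked_atlases, c("alpha", "zeta"))
  expect_error(select_fasa(tgt, vecs, n = 4), "exceeds")
})

test_that("selection_result enforces its invariants", {
  expect_error(selection_result("fasa", "t", c("a", "a")), "duplicates")
  expect_error(selection_result("fasa", "t", c("t", "b")), "own id")
  expect_error(selection_result("nope", "t", "a"))
})

test_that("select_random is seeded, uniform, and a permutation at n = N", {
  ids <- sprintf("a%02d", 1:10)
  s1 <- select_random(ids, 3, seed = 42)
  s2 <- select_random(ids, 3, seed = 42)
  expect_identical(s1$ranked_atlases, s2$ranked_atlases)
  expect_setequal(select_random(ids, 10, seed = 1)$ranked_atlases, ids)

  # frequency over many draws ~ n/N within 3 sigma binomial
  draws <- 4000
  counts <- table(unlist(lapply(seq_len(draws), function(s)
    select_random(ids, 3, seed = s)$ranked_atlases)))
  p <- 3 / 10
  sigma <- sqrt(draws * p * (1 - p))
  expect_true(all(abs(counts - draws * p) < 3.5 * sigma))
})

test_that("saga restricts candidates to the assigned subgroup", {
  at <- small_phantom("a1", noise_sd = 0)
  # model with two clusters; target vector sits at centroid 2
  model <- structure(list(
    k = 2L,
    centroids = rbind(c(0, 0), c(1, 1)),
    assignment = c(a1 = 1L, a2 = 1L, a3 = 2L, a4 = 2L, a5 = 2L),
    structure_order = c("s1", "s2")), class = "subgrouping_model")
  atlases <- lapply(c("a3", "a4", "a5"), function(id)
    atlas(id, at$image, at$contours))
  names(atlases) <- c("a3", "a4", "a5")
  # include cluster-1 atlases too; they must never be selected
  atlases$a1 <- atlas("a1", at$image, at$contours)
  atlases$a2 <- atlas("a2", at$image, at$contours)
  sel <- select_saga(c(1, 1), at$image, model, atlases, n = 3,
                     settings = reg_settings(def_levels = c(8, 4),
                                             def_maxit = c(10, 5)))
  expect_setequal(sel$ranked_atlases, c("a3", "a4", "a5"))
  expect_equal(sel$strategy, "saga")
  expect_error(select_saga(c(1, 1), at$image, model, atlases, n = 4,
                           settings = reg_settings()),
               "smaller n or a smaller k")
})

test_that("cmas ranks an exact copy of the target first with similarity ~ 1", {
  at1 <- small_phantom("same", noise_sd = 0)
  at2 <- small_phantom("big", noise_sd = 0, volumes = c(bladder = 400),
                       seed = 2)
  at3 <- small_phantom("small", noise_sd = 0, volumes = c(bladder = 90),
                       seed = 3)
  atlases <- list(same = at1, big = at2, small = at3)
  sel <- select_cmas(at1$image, atlases, n = 3,
                     settings = reg_settings(def_levels = c(4, 2),
                                             def_maxit = c(20, 10)))
  expect_equal(sel$ranked_atlases[1], "same")
  expect_gt(sel$scores[1], 0.999)
  expect_false(is.unsorted(-sel$scores))   # descending similarity
})

test_that("sim ranks an exact copy of the target first by MI", {
  at1 <- small_phantom("same", noise_sd = 2)
  at2 <- small_phantom("other", noise_sd = 2, volumes = c(bladder = 400),
                       seed = 5)
  atlases <- list(same = at1, other = at2)
  # the tight iteration caps trade convergence warnings for speed here
  sel <- suppressWarnings(
    select_sim(at1$image, atlases, n = 2,
               settings = reg_settings(rigid_levels = c(4, 2),
                                       rigid_maxit = c(30, 15))))
  expect_equal(sel$ranked_atlases[1], "same")
  expect_false(is.unsorted(-sel$scores))
})

test_that("selection_overlap reports intersections, fractions, and never-selected atlases", {
  mk <- function(strategy, target, ids)
    selection_result(strategy, target, ids)
  a <- list(t1 = mk("fasa", "t1", c("a1", "a2")),
            t2 = mk("fasa", "t2", c("a3", "a4")))
  # identical selections: every patch coincides, half of all selections
  # (the denominator counts both strategies' picks, as in 12-of-300)
  b_same <- list(t1 = mk("sim", "t1", c("a1", "a2")),
                 t2 = mk("sim", "t2", c("a3", "a4")))
  expect_equal(selection_overlap(a, b_same)$coincidence_fraction, 0.5)
  expect_equal(selection_overlap(a, b_same)$total_coincidences, 4)
  b_disj <- list(t1 = mk("sim", "t1", c("a5", "a6")),
                 t2 = mk("sim", "t2", c("a7", "a8")))
  ov <- selection_overlap(a, b_disj, atlas_ids = sprintf("a%d", 1:9))
  expect_equal(ov$coincidence_fraction, 0.0)
  expect_equal(ov$never_selected, "a9")
  expect_error(selection_overlap(a, b_disj[1]), "same targets")
})

test_that("engineered 30x5 fixture reproduces a 12/300 coincidence fraction", {
  atlas_ids <- sprintf("im%02d", 1:70)
  # 30 targets x 5 selections; exactly 12 coincidences by construction:
  # targets 1..6 share two atlases with the other strategy, the rest none
  a <- list(); b <- list()
  for (t in 1:30) {
    tid <- sprintf("t%02d", t)
    base <- ((t - 1) %% 11) * 5
    pick_a <- atlas_ids[base + 1:5]
    pick_b <- if (t <= 6) c(pick_a[1:2], atlas_ids[66:68])
              else atlas_ids[61:65]
    a[[tid]] <- selection_result("fasa", tid, pick_a)
    b[[tid]] <- selection_result("sim", tid, pick_b)
  }
  ov <- selection_overlap(a, b, atlas_ids)
  expect_equal(ov$total_coincidences, 12)
  expect_equal(ov$coincidence_fraction, 12 / 300)
  expect_equal(100 * ov$coincidence_fraction, 4.0)
})
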