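test_that("dice follows 2|A n B| / (|A| + |B|)", {
  a <- array(0L, c(6, 6, 6)); b <- a
  a[1:2, 1, 1] <- 1L; a[1:2, 2, 1] <- 1L       # |A| = 4
  b[1:2, 2, 1] <- 1L; b[1:2, 3, 1] <- 1L       # |B| = 4, overlap 2
  expect_equal(dice(mask_map(a), mask_map(b)), 0.5)
  expect_equal(dice(mask_map(a), mask_map(a)), 1.0)
  disj <- array(0L, c(6, 6, 6)); disj[6, 6, 6] <- 1L
  expect_equal(dice(mask_map(a), mask_map(disj)), 0.0)
  expect_error(dice(mask_map(array(0L, c(6, 6, 6))),
                    mask_map(array(0L, c(6, 6, 6)))), "empty")
})

test_that("dice is symmetric and monotone in the overlap", {
  set.seed(1)
  a <- random_mask(); b <- random_mask()
  expect_equal(dice(mask_map(a), mask_map(b)), dice(mask_map(b), mask_map(a)))
  # growing |A n B| at fixed |A| + |B| strictly increases DSC
  a2 <- array(0L, c(8, 8, 8)); b2 <- a2
  a2[1:4, 1, 1] <- 1L
  b2[3:6, 1, 1] <- 1L                      # overlap 2
  d1 <- dice(mask_map(a2), mask_map(b2))
  b3 <- array(0L, c(8, 8, 8)); b3[2:5, 1, 1] <- 1L   # overlap 3, same sizes
  expect_gt(dice(mask_map(a2), mask_map(b3)), d1)
})

test_that("hd95: identical masks give 0, parallel plates give their separation", {
  set.seed(2)
  m <- random_mask()
  expect_equal(hd95(mask_map(m), mask_map(m)), 0)
  a <- array(0L, c(30, 30, 15)); b <- a
  a[5:24, 5:24, 5] <- 1L
  b[5:24, 5:24, 15] <- 1L   # 10 mm apart at 1 mm spacing
  expect_equal(hd95(mask_map(a), mask_map(b)), 1.0)   # cm
})

test_that("hd95 matches the all-pairs brute force and is symmetric", {
  set.seed(3)
  for (i in 1:8) {
    la <- mask_map(random_mask(), spacing = c(1.5, 2, 1))
    lb <- mask_map(random_mask(), spacing = c(1.5, 2, 1))
    got <- hd95(la, lb)
    expect_equal(got, hd95_bruteforce(la, lb), tolerance = 1e-9)
    expect_equal(got, hd95(lb, la), tolerance = 1e-12)
    # hd95 <= exact Hausdorff (100th percentile of the pooled set)
    expect_lte(got, hd95(la, lb, percentile = 1) + 1e-12)
  }
})

test_that("paired t-test matches the textbook formula", {
  x <- c(2, 4, 6, 8, 10)
  y <- c(1, 2, 3, 4, 5)           # differences 1..5
  got <- paired_ttest(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$t, 4.2426, tolerance = 1e-4)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(got$df, 4)

  swapped <- paired_ttest(y, x)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)

  expect_error(paired_ttest(x, x), "degenerate")
  expect_error(paired_ttest(1:2, 2:3), "at least 3")
  expect_error(paired_ttest(1:4, 1:5), "paired")
})

test_that("paired t-test agrees with the reference implementation on random data", {
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(4:30, 1))
    y <- x + rnorm(length(x), 0.2)
    got <- paired_ttest(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("summarize_records builds a strategies-x-structures report with paired tests", {
  recs <- expand.grid(target_id = paste0("t", 1:4),
                      strategy = c("cmas", "fasa"),
                      structure = c("bladder", "rectum"),
                      stringsAsFactors = FALSE)
  set.seed(6)
  recs$dsc <- runif(nrow(recs), 0.5, 0.9)
  recs$hd95_cm <- runif(nrow(recs), 0.2, 2)
  out <- summarize_records(recs, reference = "cmas")
  expect_equal(nrow(out$summary), 4)
  expect_setequal(out$summary$strategy, c("cmas", "fasa"))
  r <- recs[recs$strategy == "fasa" & recs$structure == "bladder", ]
  row <- out$summary[out$summary$strategy == "fasa" &
                     out$summary$structure == "bladder", ]
  expect_equal(row$dsc_mean, mean(r$dsc))
  expect_equal(row$dsc_sd, sd(r$dsc))      # sample sd, n - 1
  expect_equal(nrow(out$tests), 2)

  expect_error(summarize_records(recs[-1, ]), "missing cells")
})

test_that("single-strategy summaries use the sample standard deviation", {
  recs <- data.frame(target_id = c("t1", "t2"), strategy = "fasa",
                     structure = "bladder", dsc = c(0.8, 0.8),
                     hd95_cm = c(0.5, 0.7))
  out <- summarize_records(recs, reference = "fasa")
  expect_equal(out$summary$dsc_mean, 0.8)
  expect_equal(out$summary$dsc_sd, 0)
  recs$dsc <- c(0.6, 0.8)
  out <- summarize_records(recs, reference = "fasa")
  expect_equal(out$summary$dsc_mean, 0.7)
  expect_equal(out$summary$dsc_sd, sd(c(0.6, 0.8)))
})
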