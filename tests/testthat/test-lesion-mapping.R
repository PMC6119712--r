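rand_mask <- function(dims = c(6, 6, 6), p = 0.3) {
  array(as.integer(runif(prod(dims)) < p), dims)
}

test_that("intensity binarization uses an inclusive 100-255 window", {
  v <- array(c(99, 100, 255, 256, 0, 180), c(6, 1, 1))
  b <- binarize_normalized_map(v)
  expect_equal(as.vector(b), c(0L, 1L, 1L, 0L, 0L, 1L))
  expect_error(binarize_normalized_map(v, 200, 100), "min_thr")
})

test_that("NIfTI masks round-trip through disk", {
  set.seed(31)
  masks <- list(a = rand_mask(), b = rand_mask())
  attr(masks$a, "voxel_size") <- attr(masks$b, "voxel_size") <- c(4, 4, 4)
  dir <- tempfile("masks")
  write_lesion_masks(masks, dir)
  back <- load_lesion_masks(setNames(file.path(dir, c("a.nii.gz",
                                                      "b.nii.gz")),
                                     c("a", "b")))
  expect_equal(back$a[, , ], masks$a[, , ], ignore_attr = TRUE)
  expect_equal(back$b[, , ], masks$b[, , ], ignore_attr = TRUE)
  # all-zero volumes are valid empty masks
  zero <- array(0L, c(6, 6, 6))
  pz <- file.path(dir, "z.nii.gz")
  write_lesion_volume(zero, pz)
  expect_equal(sum(load_lesion_masks(c(z = pz))$z), 0)
  # non-binary input is rejected unless a binarize window is given
  nb <- array(0, c(6, 6, 6)); nb[1] <- 2
  pn <- file.path(dir, "n.nii.gz")
  write_lesion_volume(nb, pn)
  expect_error(load_lesion_masks(c(n = pn)), "non-binary")
  expect_equal(sum(load_lesion_masks(c(n = pn), binarize = c(100, 255))$n),
               0)
})

test_that("overlap maps count lesioned patients per voxel", {
  set.seed(32)
  single <- rand_mask()
  expect_equal(overlap_map(list(single)), single, ignore_attr = TRUE)
  a <- array(0L, c(4, 4, 1)); a[1, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 1)); b[4, 4, 1] <- 1L
  expect_equal(max(overlap_map(list(a, b))), 1)
  masks <- replicate(10, rand_mask(), simplify = FALSE)
  expect_equal(overlap_map(masks), loop_overlap(masks),
               ignore_attr = TRUE)
  expect_error(overlap_map(list()), "empty")
})

test_that("subtraction maps reproduce the worked overlap percentages", {
  dims <- c(3, 3, 1)
  mk <- function(on) {
    m <- array(0L, dims); if (on) m[2, 2, 1] <- 1L; m
  }
  five_of_seven <- c(replicate(5, mk(TRUE), simplify = FALSE),
                     replicate(2, mk(FALSE), simplify = FALSE))
  four_of_seven <- c(replicate(4, mk(TRUE), simplify = FALSE),
                     replicate(3, mk(FALSE), simplify = FALSE))
  controls <- replicate(12, mk(FALSE), simplify = FALSE)
  expect_equal(subtraction_map(five_of_seven, controls)[2, 2, 1], 71L)
  expect_equal(subtraction_map(four_of_seven, controls)[2, 2, 1], 57L)
  # identical groups cancel exactly; values stay within +/- 100
  set.seed(33)
  g <- replicate(5, rand_mask(), simplify = FALSE)
  expect_true(all(subtraction_map(g, g) == 0L))
  h <- replicate(4, rand_mask(), simplify = FALSE)
  s <- subtraction_map(g, h)
  expect_true(all(s >= -100 & s <= 100))
  # rounding conventions: toward zero vs half-up differ at -5/7
  neg <- subtraction_map(controls[1:7], five_of_seven)
  expect_equal(neg[2, 2, 1], -71L)
  expect_error(subtraction_map(list(), g), "empty")
})

test_that("coverage filter implements the 20%-of-patients rule", {
  ov <- array(0L, c(2, 2, 1))
  ov[1, 1, 1] <- 4L; ov[1, 2, 1] <- 3L; ov[2, 1, 1] <- 19L
  inc <- coverage_filter(ov, n_patients = 19, min_fraction = 0.20)
  expect_true(inc[1, 1, 1])    # 4/19 = 0.2105
  expect_false(inc[1, 2, 1])   # 3/19 = 0.158
  full <- coverage_filter(ov, n_patients = 19, min_fraction = 1.0)
  expect_true(full[2, 1, 1])
  expect_false(full[1, 1, 1])
  expect_error(coverage_filter(ov, 19, 0), "min_fraction")
  expect_error(coverage_filter(ov, 19, 1.2), "min_fraction")
})

test_that("Brunner-Munzel relative effect equals the pairwise-count oracle", {
  expect_equal(brunner_munzel(c(1, 2, 3), c(1, 2, 3))$relative_effect, 0.5)
  expect_equal(brunner_munzel(c(2, 2, 3, 4), c(2, 2, 3, 4))$statistic, 0)
  sep <- brunner_munzel(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$relative_effect, 1)
  expect_true(sep$degenerate)
  expect_equal(sep$p_value, 2 / choose(6, 3))
  set.seed(34)
  for (i in 1:20) {
    x <- sample(1:5, 6, replace = TRUE)
    y <- sample(1:5, 6, replace = TRUE)
    bm <- brunner_munzel(x, y)
    expect_equal(bm$relative_effect, pairwise_relative_effect(x, y))
    # antisymmetry under swapping the groups
    sw <- brunner_munzel(y, x)
    expect_equal(sw$relative_effect, 1 - bm$relative_effect)
    expect_equal(sw$statistic, -bm$statistic)
  }
  expect_error(brunner_munzel(1, c(1, 2)), "at least 2")
  deg <- brunner_munzel(c(2, 2, 2), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("the VLSM split statistic matches the reference Brunner-Munzel", {
  set.seed(38)
  for (i in 1:15) {
    scores <- sample(0:12, 22, replace = TRUE)
    les <- seq_len(22) %in% sample(22, sample(4:10, 1))
    codes <- match(scores, sort(unique(scores)))
    fast <- vmti:::bm_split_stat(codes, rank(scores), les,
                                 max(codes), tabulate(codes, max(codes)))
    ref <- brunner_munzel(scores[les], scores[!les])
    if (ref$degenerate) next
    expect_equal(fast, ref$statistic, tolerance = 1e-12)
  }
})

test_that("Brunner-Munzel analytic p tracks permutation enumeration", {
  # the t approximation is close to the exhaustive permutation p on
  # average, with a heavier mid-p error at the smallest sample sizes;
  # VLSM therefore calibrates by permutation (see vlsm docs)
  set.seed(35)
  devs <- sapply(1:12, function(i) {
    x <- rnorm(sample(5:8, 1))
    y <- rnorm(sample(5:8, 1)) + runif(1, -1, 1)
    bm <- brunner_munzel(x, y)
    if (bm$degenerate) return(NA_real_)
    abs(bm$p_value - bm_permutation_p(x, y))
  })
  expect_lt(median(devs, na.rm = TRUE), 0.02)
  expect_lt(max(devs, na.rm = TRUE), 0.07)
})

test_that("BH step-up matches hand evaluation and is monotone in q", {
  expect_false(any(bh_fdr(rep(1, 10), 0.05)$significant))
  expect_true(bh_fdr(0.01, 0.05)$significant)
  res <- bh_fdr(c(0.001, 0.012, 0.014, 0.20, 0.85), 0.05)
  expect_equal(res$significant, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$critical_p, 0.014)
  # agreement with the adjusted-p formulation on random inputs
  set.seed(36)
  for (i in 1:10) {
    p <- runif(50)^2
    for (q in c(0.01, 0.05, 0.2)) {
      mine <- bh_fdr(p, q)$significant
      ref <- p.adjust(p, "BH") <= q
      expect_equal(mine, ref)
    }
    # monotonicity: raising q never removes a discovery
    lo <- bh_fdr(p, 0.02)$significant
    hi <- bh_fdr(p, 0.10)$significant
    expect_true(all(hi[lo]))
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("VLSM signs z so that lower scores in lesioned patients are positive", {
  dims <- c(4, 4, 1)
  n <- 12
  masks <- lapply(1:n, function(i) {
    m <- array(0L, dims)
    m[1, 1, 1] <- as.integer(i <= 6)  # patients 1-6 lesioned here
    m[2, 2, 1] <- as.integer(i %% 2 == 0)
    m
  })
  names(masks) <- sprintf("p%02d", 1:n)
  scores <- setNames(c(1:6, 101:106), names(masks))  # lesioned score lower
  res <- vlsm(masks, scores, min_fraction = 0.2, min_per_group = 2,
              fdr_q = 0.05)
  expect_gt(res$z[1, 1, 1], 0)
  expect_true(res$included[1, 1, 1])
  expect_false(res$included[3, 3, 1])       # nobody lesioned there
  expect_true(res$n_significant <= res$n_included)
  expect_true(all(res$significant <= res$included))
  # reversed scores flip the sign
  rev_res <- vlsm(masks, setNames(rev(scores), names(masks)),
                  min_fraction = 0.2, min_per_group = 2)
  expect_lt(rev_res$z[1, 1, 1], 0)
  # determinism
  expect_identical(res$z, vlsm(masks, scores, 0.2, 2, 0.05)$z)
  expect_error(vlsm(masks, scores[1:5]), "one score per patient")
  expect_error(vlsm(masks, setNames(rep(1, n), names(masks))),
               "constant scores")
})

test_that("region summaries report per-region peaks and counts", {
  dims <- c(5, 5, 2)
  labels <- array(0L, dims)
  labels[1:2, , ] <- 1L
  labels[4:5, , ] <- 2L
  zero <- array(0, dims)
  rs0 <- region_summary(zero, labels)
  expect_equal(rs0$peak_value, c(0, 0))
  one <- zero; one[1, 2, 1] <- 3.5
  rs1 <- region_summary(one, labels)
  expect_equal(rs1$peak_value[rs1$label == 1], 3.5)
  expect_equal(rs1$n_suprathreshold, c(1L, 0L))
  expect_equal(unlist(rs1[rs1$label == 1, c("peak_x", "peak_y", "peak_z")]),
               c(peak_x = 1, peak_y = 2, peak_z = 1))
  # planted peaks in both regions vs a brute-force scan
  set.seed(37)
  m <- array(rnorm(prod(dims)), dims)
  rs <- region_summary(m, labels)
  for (lb in 1:2) {
    vals <- m[labels == lb]
    expect_equal(rs$peak_value[rs$label == lb],
                 vals[which.max(abs(vals))])
    expect_equal(rs$n_voxels[rs$label == lb], sum(labels == lb))
  }
  expect_error(region_summary(zero, labels[, , 1, drop = FALSE]),
               "grid mismatch")
})
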