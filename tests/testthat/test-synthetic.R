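test_that("rendering is deterministic and rejects invalid severities", {
  a <- render_image(0.3, subject_seed = 7, noise_sd = 0.05)
  b <- render_image(0.3, subject_seed = 7, noise_sd = 0.05)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_error(render_image(1.2, 1), "severity")
  expect_error(render_image(-0.1, 1), "severity")
})

test_that("lesion grows with severity and has the expected size at s = 0", {
  big <- render_image(0.8, subject_seed = 3, noise_sd = 0)
  small <- render_image(0.2, subject_seed = 3, noise_sd = 0)
  expect_gt(lesion_pixel_count(big), lesion_pixel_count(small))

  # at s = 0 the lesion is a disc of the configured minimum radius;
  # independent geometric count of pixels within that radius
  side <- 64; rmin <- 3
  img0 <- render_image(0, subject_seed = 5, noise_sd = 0,
                       side = side, min_radius = rmin)
  cx <- (side + 1) / 2
  d <- sqrt(outer((1:side - cx)^2, (1:side - cx)^2, `+`))
  expect_identical(lesion_pixel_count(img0), sum(d <= rmin))
})

test_that("lesion extent is strictly increasing in s (noiseless renders)", {
  set.seed(99)
  for (i in 1:20) {
    s <- sort(runif(2))
    seed <- sample.int(1000, 1)
    lo <- lesion_extent(render_image(s[1], seed, noise_sd = 0))
    hi <- lesion_extent(render_image(s[2], seed, noise_sd = 0))
    expect_lt(lo, hi)
  }
})

test_that("longitudinal renders share the subject background", {
  # same subject, different severities: pixels far from lesion and vessel
  # match exactly at noise_sd = 0
  a <- render_image(0.1, subject_seed = 11, noise_sd = 0)
  b <- render_image(0.15, subject_seed = 11, noise_sd = 0)
  corner <- 1:8
  expect_identical(a[corner, corner], b[corner, corner])
})

test_that("discretization uses half-open bins with s >= threshold", {
  sch <- ordinal_scheme(3, thresholds = c(1 / 3, 2 / 3))
  expect_identical(discretize_severity(0.1, sch), 0L)
  expect_identical(discretize_severity(0.5, sch), 1L)
  expect_identical(discretize_severity(2 / 3, sch), 2L)  # boundary: upper bin
  expect_identical(discretize_severity(c(0, 1), sch), c(0L, 2L))
  expect_error(ordinal_scheme(3, thresholds = c(0.5, 0.2)), "increasing")
  expect_error(ordinal_scheme(1), "K")
})

test_that("noiseless fine ratings hit the analytic values", {
  expect_identical(simulate_fine_ratings(0, rater_sd = 0), 1L)
  expect_identical(simulate_fine_ratings(1, rater_sd = 0), 9L)
  expect_identical(simulate_fine_ratings(0.5, rater_sd = 0), 5L)
  # deterministic given seed, stays in range
  s <- seq(0, 1, length.out = 20)
  r1 <- simulate_fine_ratings(s, rater_sd = 0.3, seed = 4)
  r2 <- simulate_fine_ratings(s, rater_sd = 0.3, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 1 & r1 <= 9))
})

test_that("dataset bookkeeping: splits, labels, ranks, determinism", {
  ds <- tiny_dataset(n = 100, seed = 5)
  man <- ds$manifest
  base <- man[man$timepoint == 0L, ]
  expect_equal(sum(base$split == "train"), 70)
  expect_equal(sum(base$split == "val"), 15)
  expect_equal(sum(base$split == "test"), 15)

  # subject-level disjointness
  per_subj <- tapply(man$split, man$subject_id,
                     function(x) length(unique(x)))
  expect_true(all(per_subj == 1L))

  # label consistency on every row
  sch <- ordinal_scheme(3)
  expect_identical(man$label, discretize_severity(man$s, sch))

  # ranks: permutation of 1..n and Spearman 1 with s
  rk <- man[!is.na(man$rank), ]
  expect_setequal(rk$rank, seq_len(nrow(rk)))
  expect_equal(spearman_rho(rk$rank, rk$s), 1)

  # determinism
  ds2 <- tiny_dataset(n = 100, seed = 5)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$images, ds2$images)
})

test_that("empirical class frequencies match the threshold design", {
  # thresholds at 1/3 and 2/3 on Uniform(0,1): each class ~ Binomial(n, 1/3)
  ds <- generate_dataset(3000, ordinal_scheme(3), seed = 8, render = FALSE,
                         longitudinal_fraction = 0)
  counts <- table(ds$manifest$label)
  for (k in 0:2) {
    ci <- stats::binom.test(counts[[as.character(k)]], 3000,
                            p = 1 / 3)$conf.int
    expect_true(ci[1] < 1 / 3 && 1 / 3 < ci[2])
  }
})

test_that("longitudinal pairs exist and stay in range", {
  ds <- tiny_dataset(n = 100, seed = 5, longitudinal_fraction = 0.4)
  man <- ds$manifest
  fup <- man[man$timepoint == 1L, ]
  expect_gt(nrow(fup), 0)
  i0 <- match(fup$subject_id, man$subject_id[man$timepoint == 0L])
  s1 <- man$s[man$timepoint == 0L][i0]
  expect_true(all(abs(fup$s - s1) <= 0.3 + 1e-12))
  expect_true(all(fup$s >= 0 & fup$s <= 1))
})

test_that("dataset round-trips through disk", {
  ds <- tiny_dataset(n = 12, seed = 2, longitudinal_fraction = 0)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_error(write_dataset(ds, dir), "force")
  back <- read_dataset(dir)
  expect_equal(back$manifest$s, ds$manifest$s)
  expect_equal(back$manifest$label, ds$manifest$label)
  # 8-bit PNG round trip: within one quantization step
  expect_lt(max(abs(back$images - ds$images)), 1 / 255 + 1e-9)
})
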