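test_that("backward cloud matches hand-derived estimators", {
  # two-point sample: every quantity has a closed form
  d <- backward_cloud(c(0, 0.2))
  en_expect <- sqrt(pi / 2) * 0.1
  expect_equal(d$ex, 0.1)
  expect_equal(d$en, en_expect)
  expect_equal(d$he, sqrt(abs(0.02 - en_expect^2)))

  # zero dispersion collapses to a crisp cloud
  crisp <- backward_cloud(rep(0.1, 10))
  expect_equal(c(crisp$ex, crisp$en, crisp$he), c(0.1, 0, 0))

  expect_error(backward_cloud(0.5), class = "cmspa_invalid_input")
  expect_error(backward_cloud(c(1, NA)), class = "cmspa_invalid_input")
  expect_error(backward_cloud(c(1, Inf)), class = "cmspa_invalid_input")
})

test_that("backward cloud is translation-equivariant in ex and he stays real", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- runif(sample(2:30, 1))
    shift <- rnorm(1, sd = 5)
    d0 <- backward_cloud(x)
    d1 <- backward_cloud(x + shift)
    expect_equal(d1$ex, d0$ex + shift)
    expect_equal(d1$en, d0$en)
    expect_equal(d1$he, d0$he)
    expect_true(is.finite(d0$he) && d0$he >= 0)
  }
})

test_that("cloud aggregation adds ex and combines en/he in quadrature", {
  agg <- aggregate_clouds(list(cloud_descriptor(0.1, 0.03, 0.004),
                               cloud_descriptor(0.2, 0.04, 0.003)))
  expect_equal(c(agg$ex, agg$en, agg$he), c(0.3, 0.05, 0.005))

  single <- cloud_descriptor(0.4, 0.02, 0.001)
  agg1 <- aggregate_clouds(list(single))
  expect_equal(agg1, single)

  # permutation invariance over random lists
  for (seed in 1:5) {
    set.seed(seed)
    descs <- lapply(1:6, function(i)
      cloud_descriptor(rnorm(1), runif(1), runif(1, 0, 0.2)))
    a <- aggregate_clouds(descs)
    b <- aggregate_clouds(sample(descs))
    expect_equal(c(a$ex, a$en, a$he), c(b$ex, b$en, b$he), tolerance = 1e-12)
  }

  expect_error(aggregate_clouds(list()), class = "cmspa_invalid_input")
})

test_that("forward cloud is seed-reproducible and handles the crisp case", {
  d <- cloud_descriptor(5, 1, 0.1)
  a <- forward_cloud(d, 200, seed = 7)
  b <- forward_cloud(d, 200, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$mu >= 0 & a$mu <= 1))

  crisp <- forward_cloud(cloud_descriptor(5, 0, 0), 10, seed = 1)
  expect_equal(crisp$x, rep(5, 10))
  expect_equal(crisp$mu, rep(1, 10))

  expect_error(forward_cloud(d, 0), class = "cmspa_invalid_input")
})

test_that("forward cloud droplet statistics converge to the descriptor", {
  d <- cloud_descriptor(5, 1, 0.1)
  drops <- forward_cloud(d, 1000, seed = 11)
  expect_lt(abs(mean(drops$x) - 5), 0.15)
  expect_lt(abs(sd(drops$x) - 1), 0.15)

  # 3-sigma coverage at larger n
  big <- forward_cloud(d, 10000, seed = 12)
  expect_gte(mean(big$x >= 2 & big$x <= 8), 0.99)

  # across seeds, empirical moments approach (ex, ~en) at n = 1e5
  huge <- forward_cloud(d, 1e5, seed = 13)
  tol <- 3 * d$en / sqrt(1e5) * 5
  expect_lt(abs(mean(huge$x) - d$ex), tol)
})

test_that("at least 99% of droplets fall inside the 3En interval when he/en <= 0.1", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- cloud_descriptor(rnorm(1), runif(1, 0.5, 2), 0)
    d <- cloud_descriptor(d$ex, d$en, runif(1, 0, 0.1 * d$en))
    drops <- forward_cloud(d, 1e4, seed = seed + 100)
    iv <- three_en_interval(d)
    expect_gte(mean(drops$x >= iv[["lo"]] & drops$x <= iv[["hi"]]), 0.99)
  }
})

test_that("confusion degree flags fog and rejects crisp clouds", {
  expect_equal(confusion_degree(cloud_descriptor(5, 1, 0.1)), 0.3)
  expect_false(is_fog(cloud_descriptor(5, 1, 0.1)))
  # he = en/3 is exactly the fog boundary
  expect_equal(confusion_degree(cloud_descriptor(0, 0.3, 0.1)), 1.0)
  expect_true(is_fog(cloud_descriptor(0, 0.3, 0.1)))
  expect_error(confusion_degree(cloud_descriptor(1, 0, 0)),
               class = "cmspa_undefined_confusion")
})

test_that("3En intervals and interval intersections behave", {
  iv <- three_en_interval(cloud_descriptor(5, 1, 0.1))
  expect_equal(unname(iv[["lo"]]), 2)
  expect_equal(unname(iv[["hi"]]), 8)
  crisp <- three_en_interval(cloud_descriptor(0.4, 0, 0))
  expect_equal(unname(crisp[["lo"]]), unname(crisp[["hi"]]))

  a <- interval(0.2510, 0.4063); b <- interval(0.2152, 0.3449)
  ov <- interval_overlap(a, b)
  expect_equal(unname(ov[["lo"]]), 0.2510)
  expect_equal(unname(ov[["hi"]]), 0.3449)
  expect_equal(overlap_length(a, b), 0.0939, tolerance = 1e-12)

  expect_null(interval_overlap(interval(0.5873, 0.8124),
                               interval(0.1156, 0.2700)))
  touch <- interval_overlap(interval(0, 1), interval(1, 2))
  expect_equal(unname(touch[["lo"]]), 1)
  expect_equal(overlap_length(interval(0, 1), interval(1, 2)), 0)

  expect_error(interval(2, 1), class = "cmspa_invalid_input")
})

test_that("descriptor validation rejects negative dispersion", {
  expect_error(cloud_descriptor(1, -0.1, 0), class = "cmspa_invalid_input")
  expect_error(cloud_descriptor(1, 0, -1), class = "cmspa_invalid_input")
  expect_silent(cloud_descriptor(3, 0, 0))
})

test_that("droplet export writes a readable x/mu table", {
  drops <- forward_cloud(cloud_descriptor(5, 1, 0.1), 50, seed = 3)
  dir <- withr::local_tempdir()
  path <- write_droplets(drops, "grade I", dir = dir)
  back <- read.csv(path)
  expect_named(back, c("x", "mu"))
  expect_equal(back$x, drops$x)
  expect_equal(back$mu, drops$mu)
})
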