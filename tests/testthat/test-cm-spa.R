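bundle <- load_fixture_bundle()

test_that("panel normalization makes every expert distribute unit mass", {
  x <- normalize_panel(bundle$panel)
  expect_equal(unname(colSums(x)), rep(1, 10), tolerance = 1e-12)
  # hand-summed expert columns of the fixture panel
  expect_equal(x["K1", "Expert1"], 6 / 79)
  expect_equal(x["K1", "Expert5"], 10 / 80)

  # a single expert with equal scores spreads mass uniformly
  eq <- judgment_panel(matrix(7, nrow = 4, ncol = 1))
  expect_equal(unname(normalize_panel(eq)[, 1]), rep(0.25, 4))

  # a zero column sum is rejected (bare-matrix path)
  expect_error(normalize_panel(matrix(0, 3, 2)), class = "cmspa_invalid_panel")
})

test_that("judgment panel validation enforces the linguistic score range", {
  expect_error(judgment_panel(matrix(c(1, 0), 2, 1)), class = "cmspa_invalid_panel")
  expect_error(judgment_panel(matrix(11, 2, 2)), class = "cmspa_invalid_panel")
  expect_error(judgment_panel(matrix(-3, 2, 2)), class = "cmspa_invalid_panel")
})

test_that("cloud weights reproduce the published per-index descriptors", {
  w <- cloud_weights(bundle$panel)
  expected <- table4_expected()
  expect_equal(w$index, rownames(expected))
  for (col in c("ex", "en", "he"))
    expect_within(w[[col]], unname(expected[, col]), tol = 1e-4, label = col)
  expect_equal(sum(w$ex), 1, tolerance = 1e-12)
  # the fixture panel produces valid clouds, never fog
  descs <- attr(w, "descriptors")
  expect_true(all(vapply(descs, confusion_degree, numeric(1)) < 1))
})

test_that("unanimous experts give crisp cloud weights proportional to the scores", {
  scores <- matrix(rep(c(8, 4, 6, 2), 3), nrow = 4,
                   dimnames = list(paste0("K", 1:4), NULL))
  w <- cloud_weights(judgment_panel(scores))
  expect_equal(w$ex, c(8, 4, 6, 2) / 20)
  expect_equal(w$en, rep(0, 4))
  expect_equal(w$he, rep(0, 4))
})

test_that("cloud-weight ex components sum to 1 for any valid panel", {
  for (seed in 1:10) {
    cfg <- synthetic_panel_config(n_experts = sample(2:20, 1),
                                  jitter = runif(1, 0, 2), seed = seed)
    w <- suppressWarnings(cloud_weights(generate_panel(cfg)))
    expect_equal(sum(w$ex), 1, tolerance = 1e-12)
    expect_true(all(w$en >= 0 & w$he >= 0))
  }
})

test_that("cloud connection degrees reproduce the published per-grade clouds", {
  w <- cloud_weights(bundle$panel)
  expected <- table8_expected()
  for (p in bundle$patients) {
    ev <- build_evaluation_matrix(bundle$scheme, p)
    ccd <- cloud_connection_degree(ev, w)
    exp_p <- expected[[p$patient_id]]
    expect_equal(ccd$grade, rownames(exp_p))
    for (col in c("ex", "en", "he"))
      expect_within(ccd[[col]], unname(exp_p[, col]), tol = 1e-4,
                    label = paste(p$patient_id, col))
    # conservation: grade ex values sum to the total weight mass
    expect_equal(sum(ccd$ex), sum(w$ex), tolerance = 1e-12)
  }
})

test_that("interpretation reproduces the published verdicts", {
  w <- cloud_weights(bundle$panel)
  verdicts <- lapply(bundle$patients, function(p)
    interpret_ccd(cloud_connection_degree(
      build_evaluation_matrix(bundle$scheme, p), w)))
  names(verdicts) <- vapply(bundle$patients, `[[`, character(1), "patient_id")

  expect_equal(verdicts[["Cheng-ming Luan"]]$primary_grade, "I")
  expect_null(verdicts[["Cheng-ming Luan"]]$secondary_grade)
  expect_equal(verdicts[["Di-he Gu"]]$primary_grade, "I")
  expect_null(verdicts[["Di-he Gu"]]$secondary_grade)
  expect_equal(verdicts[["Hong-Liu"]]$primary_grade, "I")
  expect_equal(verdicts[["Hong-Liu"]]$secondary_grade, "III")
  expect_equal(unname(verdicts[["Hong-Liu"]]$overlap_lengths["I~III"]),
               0.0939, tolerance = 1e-3)
})

test_that("interpretation handles degenerate and relabelled inputs", {
  one <- structure(data.frame(grade = grade_labels(),
                              ex = c(0, 0.5, 0, 0, 0),
                              en = c(0, 0.02, 0, 0, 0),
                              he = c(0, 0.001, 0, 0, 0)),
                   class = c("cloud_connection_degree", "data.frame"))
  v <- interpret_ccd(one)
  expect_equal(v$primary_grade, "II")
  expect_null(v$secondary_grade)

  zero <- structure(data.frame(grade = grade_labels(), ex = 0, en = 0, he = 0),
                    class = c("cloud_connection_degree", "data.frame"))
  expect_error(interpret_ccd(zero), class = "cmspa_invalid_input")

  # permuting grade labels permutes the verdict labels but nothing else
  w <- cloud_weights(bundle$panel)
  ev <- build_evaluation_matrix(bundle$scheme, bundle$patients[[3]])
  ccd <- cloud_connection_degree(ev, w)
  perm <- ccd[c(3, 1, 2, 4, 5), ]
  attr(perm, "descriptors") <- NULL
  perm$grade <- grade_labels()  # III content now labelled I, etc.
  v0 <- interpret_ccd(ccd)
  v1 <- interpret_ccd(structure(perm,
                                class = c("cloud_connection_degree", "data.frame")))
  expect_equal(v1$primary_grade, "II")     # the old grade I content
  expect_equal(v1$secondary_grade, "I")    # the old grade III content
  expect_equal(unname(sort(v1$overlap_lengths)), unname(sort(v0$overlap_lengths)))
})

test_that("synthetic panels recover the generating importance ratios", {
  means <- stats::setNames(c(9, rep(1, 9)), paste0("K", 1:10))
  cfg <- synthetic_panel_config(n_experts = 50, means = means, jitter = 0.3,
                                integer = FALSE, seed = 202)
  panel <- generate_panel(cfg)
  w <- suppressWarnings(cloud_weights(panel))  # fog flags possible at this jitter
  x <- normalize_panel(panel)
  for (k in seq_len(10)) {
    se <- stats::sd(x[k, ]) / sqrt(ncol(x))
    expect_lt(abs(w$ex[k] - means[k] / sum(means)), 3 * se + 1e-3)
  }
})
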