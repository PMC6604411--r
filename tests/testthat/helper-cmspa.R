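# Expected values frozen from the published case-study tables; comparisons
# always run against unrounded pipeline output at the tables' own precision.

table4_expected <- function() {
  m <- matrix(c(
    0.11073, 0.0217,  0.00486,
    0.12116, 0.01886, 0.00515,
    0.10537, 0.01384, 0.00412,
    0.0891,  0.01365, 0.00451,
    0.09907, 0.01335, 0.00348,
    0.10844, 0.01164, 0.00255,
    0.10733, 0.01166, 0.00280,
    0.09309, 0.01464, 0.00168,
    0.08363, 0.01205, 0.00308,
    0.08207, 0.01385, 0.00154), ncol = 3, byrow = TRUE,
    dimnames = list(paste0("K", 1:10), c("ex", "en", "he")))
  m
}

# grade assignment of each index per patient (the one-hot evaluation table)
table7_expected <- function() {
  list(
    "Cheng-ming Luan" = c(K1 = "II", K2 = "I", K3 = "I", K4 = "I", K5 = "I",
                          K6 = "I", K7 = "IV", K8 = "I", K9 = "I", K10 = "II"),
    "Di-he Gu" = c(K1 = "III", K2 = "I", K3 = "I", K4 = "II", K5 = "I",
                   K6 = "II", K7 = "V", K8 = "I", K9 = "IV", K10 = "III"),
    "Hong-Liu" = c(K1 = "V", K2 = "I", K3 = "II", K4 = "III", K5 = "I",
                   K6 = "I", K7 = "III", K8 = "II", K9 = "III", K10 = "IV"))
}

# per-grade (ex, en, he) of the cloud connection degrees, as published
table8_expected <- function() {
  list(
    "Cheng-ming Luan" = matrix(c(
      0.6999, 0.0375, 0.0097,
      0.1928, 0.0257, 0.0051,
      0,      0,      0,
      0.1073, 0.0117, 0.0028,
      0,      0,      0), ncol = 3, byrow = TRUE,
      dimnames = list(c("I", "II", "III", "IV", "V"), c("ex", "en", "he"))),
    "Di-he Gu" = matrix(c(
      0.4187, 0.0307, 0.0076,
      0.1975, 0.0179, 0.0052,
      0.1928, 0.0257, 0.0051,
      0.0836, 0.0120, 0.0031,
      0.1073, 0.0117, 0.0028), ncol = 3, byrow = TRUE,
      dimnames = list(c("I", "II", "III", "IV", "V"), c("ex", "en", "he"))),
    "Hong-Liu" = matrix(c(
      0.3287, 0.0258, 0.0067,
      0.1985, 0.0201, 0.0045,
      0.2801, 0.0216, 0.0061,
      0.0821, 0.0138, 0.0015,
      0.1107, 0.0217, 0.0049), ncol = 3, byrow = TRUE,
      dimnames = list(c("I", "II", "III", "IV", "V"), c("ex", "en", "he"))))
}

# published 3En decision intervals per patient and supported grade
published_intervals <- function() {
  list(
    "Cheng-ming Luan" = list(I = c(0.5873, 0.8124), II = c(0.1156, 0.2700),
                             IV = c(0.0723, 0.1423)),
    "Di-he Gu" = list(I = c(0.3267, 0.5107), II = c(0.1437, 0.2514),
                      III = c(0.1156, 0.2700), IV = c(0.0475, 0.1198),
                      V = c(0.0723, 0.1423)),
    "Hong-Liu" = list(I = c(0.2510, 0.4063), II = c(0.1380, 0.2589),
                      III = c(0.2152, 0.3449), IV = c(0.0405, 0.1236),
                      V = c(0.0456, 0.1758)))
}

# constant-weight connection degrees of the AHP comparison arm, as published
table10_expected <- function() {
  matrix(c(
    0.8183, 0.4531, 0.3667,
    0.1101, 0.2461, 0.1619,
    0.0000, 0.1101, 0.3614,
    0.0716, 0.1191, 0.0443,
    0.0000, 0.0716, 0.0658), ncol = 3, byrow = TRUE,
    dimnames = list(c("I", "II", "III", "IV", "V"),
                    c("Cheng-ming Luan", "Di-he Gu", "Hong-Liu")))
}

# absolute-tolerance comparison: printed tables are matched digit-wise, so
# the check is |actual - expected| <= tol, not a relative difference
expect_within <- function(actual, expected, tol, label = "") {
  diff <- max(abs(actual - expected))
  testthat::expect(diff <= tol,
                   sprintf("%s: max |actual - expected| = %.3g exceeds %.1g",
                           label, diff, tol))
  invisible(actual)
}

# random positive reciprocal matrix on the Saaty 1/9..9 scale
random_reciprocal <- function(n, seed) {
  set.seed(seed)
  m <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- sample(c(1 / (9:2), 1:9), 1)
    m[i, j] <- v
    m[j, i] <- 1 / v
  }
  m
}

# perfectly consistent reciprocal matrix generated from a weight vector
consistent_matrix <- function(w) outer(w, w, "/")
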