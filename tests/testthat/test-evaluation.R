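# Independent oracle: Fréchet distance for diagonal Gaussians decomposes into
# per-dimension closed forms (mu1-mu2)^2 + (sd1-sd2)^2.
fd_diag_oracle <- function(mu1, var1, mu2, var2) {
  sum((mu1 - mu2)^2) + sum((sqrt(var1) - sqrt(var2))^2)
}

gs <- function(mean, cov) {
  structure(list(mean = mean, cov = as.matrix(cov)), class = "gaussian_summary")
}

test_that("fit_gaussian computes column means and unbiased covariance", {
  g <- fit_gaussian(matrix(c(0, 2), ncol = 1))
  expect_equal(g$mean, 1)
  expect_equal(g$cov, matrix(2, 1, 1))  # divisor n-1

  same <- fit_gaussian(matrix(1.5, nrow = 5, ncol = 3))
  expect_equal(unname(same$cov), matrix(0, 3, 3))

  x <- matrix(rnorm(40), 10, 4)
  g1 <- fit_gaussian(x)
  g2 <- fit_gaussian(x[sample(10), ])
  expect_equal(g1$mean, g2$mean)
  expect_equal(g1$cov, g2$cov)

  expect_error(fit_gaussian(matrix(1, 1, 3)), class = "synthzoo_argument_error")
})

test_that("Fréchet distance reproduces closed forms and the diagonal oracle", {
  a <- gs(0, 1)
  expect_equal(frechet_distance(a, a), 0)
  expect_equal(frechet_distance(gs(0, 1), gs(3, 1)), 9)
  expect_equal(frechet_distance(gs(0, 1), gs(0, 4)), 1)

  set.seed(99)
  for (d in c(2, 3, 5, 10)) {
    mu1 <- rnorm(d); mu2 <- rnorm(d)
    v1 <- runif(d, 0.2, 3); v2 <- runif(d, 0.2, 3)
    fd <- frechet_distance(gs(mu1, diag(v1, d)), gs(mu2, diag(v2, d)))
    expect_equal(fd, fd_diag_oracle(mu1, v1, mu2, v2), tolerance = 1e-8)
  }
})

test_that("Fréchet distance is symmetric, non-negative, and monotone in mean shift", {
  set.seed(7)
  for (i in 1:5) {
    d <- sample(2:6, 1)
    m <- matrix(rnorm(d * (d + 5)), ncol = d)
    a <- fit_gaussian(m)
    b <- fit_gaussian(m + rnorm(length(m)))
    fab <- frechet_distance(a, b)
    expect_equal(fab, frechet_distance(b, a), tolerance = 1e-8)
    expect_gte(fab, 0)
  }
  shifts <- c(0.5, 1, 2, 4)
  fds <- vapply(shifts, function(s) frechet_distance(gs(0, 1), gs(s, 1)), numeric(1))
  expect_true(all(diff(fds) > 0))
})

test_that("Fréchet distance validates its inputs", {
  expect_error(frechet_distance(gs(c(0, 0), diag(2)), gs(0, 1)),
               class = "synthzoo_argument_error")
  asym <- gs(c(0, 0), matrix(c(1, 0.9, 0.1, 1), 2, 2))
  expect_error(frechet_distance(asym, gs(c(0, 0), diag(2))),
               class = "synthzoo_argument_error")
})

test_that("normalization maps to [0,1] with the documented degenerate rules", {
  imgs <- list(matrix(seq(0, 255, length.out = 64), 8, 8))
  norm <- normalize_images(imgs, "bitdepth")
  expect_equal(range(norm[[1]]), c(0, 1))

  const <- list(matrix(100, 4, 4), matrix(100, 4, 4))
  expect_equal(normalize_images(const, "minmax")[[1]], matrix(0, 4, 4))

  tiny <- list(matrix(0.5, 4, 4))
  expect_warning(normalize_images(tiny, "bitdepth"),
                 class = "synthzoo_normalization_warning")
})

test_that("FID is zero on identical sets, permutation-invariant, and shift-sensitive", {
  ex <- toy_feature_extractor(42, 32)
  set_a <- synth_image_set(30, seed = 1)
  expect_lt(compute_fid(set_a, set_a, ex, "bitdepth"), 1e-6)

  set_b <- synth_image_set(30, seed = 100)
  f1 <- compute_fid(set_a, set_b, ex, "bitdepth")
  f2 <- compute_fid(set_a, set_b[sample(30)], ex, "bitdepth")
  expect_equal(f1, f2, tolerance = 1e-10)

  shifted <- synth_image_set(30, seed = 100, shift = 64)
  expect_lt(f1, compute_fid(set_a, shifted, ex, "bitdepth"))

  expect_error(compute_fid(set_a[1], set_b, ex), class = "synthzoo_argument_error")
})

test_that("the real-real lower bound is seeded, reproducible, and zero for constant sets", {
  ex <- toy_feature_extractor(42, 32)
  same <- rep(list(matrix(42, 16, 16)), 8)
  expect_equal(as.numeric(fid_lower_bound(same, ex, "none", seed = 3)), 0)

  real <- synth_image_set(40, seed = 5)
  r1 <- fid_lower_bound(real, ex, "bitdepth", seed = 7)
  r2 <- fid_lower_bound(real, ex, "bitdepth", seed = 7)
  expect_identical(as.numeric(r1), as.numeric(r2))
  expect_identical(attr(r1, "n1") + attr(r1, "n2"), 40L)

  r3 <- fid_lower_bound(real, ex, "bitdepth", seed = 8)
  expect_gte(as.numeric(r3), 0)
  expect_false(identical(as.numeric(r1), as.numeric(r3)))

  expect_error(fid_lower_bound(real[1:3], ex), class = "synthzoo_argument_error")
})

test_that("rfid reproduces its limits and clamps empirical violations", {
  expect_equal(rfid(5, 5), 1)
  expect_equal(rfid(5, 0), 0)
  expect_warning(v <- rfid(1, 2), class = "synthzoo_rfid_clamp_warning")
  expect_equal(as.numeric(v), 1)
  expect_true(attr(v, "clamped"))
  expect_error(rfid(0, 1), class = "synthzoo_argument_error")
  expect_error(rfid(1, -1), class = "synthzoo_argument_error")
})

test_that("evaluate_model fills provenance and satisfies the rfid identity", {
  reg <- test_registry()
  ex <- toy_feature_extractor(42, 32)
  real <- synth_image_set(60, seed = 21)
  rep <- suppressWarnings(
    evaluate_model(reg, "00001_DCGAN_MMG_MASS", real, n_syn = 60,
                   extractor = ex, normalize = "bitdepth", seed = 9)
  )
  expect_s3_class(rep, "fid_report")
  expect_identical(rep$n_real, 60L)
  expect_identical(rep$n_syn, 60L)
  expect_true(rep$normalized)
  expect_identical(rep$extractor_id, "toy-rp-42-32")
  expect_identical(rep$seed, 9)
  if (rep$fid_rs >= rep$fid_rr) {
    expect_equal(rep$rfid, 1 - (rep$fid_rs - rep$fid_rr) / rep$fid_rs,
                 tolerance = 1e-9)
  } else {
    expect_equal(rep$rfid, 1)
  }
  expect_gte(rep$rfid, 0)
  expect_lte(rep$rfid, 1)
})

test_that("report_table tabulates reports, fits the trend, and round-trips CSV", {
  mk <- function(id, rr, rs) {
    structure(list(model_id = id, fid_rr = rr, fid_rs = rs,
                   rfid = as.numeric(rfid(rs, rr)), n_real = 10L, n_syn = 10L,
                   normalized = FALSE, extractor_id = "toy", seed = 1L),
              class = "fid_report")
  }
  out <- report_table(list(mk("00001_A_B", 1, 2), mk("00002_A_B", 2, 4)))
  expect_identical(nrow(out$table), 2L)
  expect_equal(unname(out$trend["slope"]), 2)
  expect_equal(unname(out$trend["intercept"]), 0)

  csv <- tempfile(fileext = ".csv")
  report_table(list(mk("00001_A_B", 1, 2), mk("00002_A_B", 2, 4)), csv_path = csv)
  back <- utils::read.csv(csv)
  expect_equal(back$fid_rs, c(2, 4))
  expect_equal(back$rfid, c(0.5, 0.5))
})
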