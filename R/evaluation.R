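#' Fit a multivariate Gaussian summary to a feature matrix
#'
#' Computes the column-mean vector and the unbiased (n - 1 divisor) sample
#' covariance of an n x d feature matrix — the Gaussian summary that the
#' Fréchet distance compares.
#'
#' @param features Numeric n x d matrix (n >= 2), or a `feature_matrix`.
#' @return A `gaussian_summary`: list with `mean` (length d) and `cov`
#'   (d x d symmetric matrix).
#' @export
fit_gaussian <- function(features) {
  x <- if (is.list(features) && !is.null(features$values)) features$values else features
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop_synthzoo("need at least 2 feature rows to fit a Gaussian",
                  "synthzoo_argument_error")
  }
  if (!all(is.finite(x))) {
    stop_synthzoo("feature matrix contains non-finite entries",
                  "synthzoo_argument_error")
  }
  structure(list(mean = colMeans(x), cov = stats::cov(x)),
            class = "gaussian_summary")
}

# Symmetric PSD square root via eigendecomposition; eigenvalues below zero
# (numerical noise) are clamped at zero.
sym_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# tr((A^{1/2} B A^{1/2})^{1/2}) — equals tr(sqrtm(AB)) for symmetric PSD A, B,
# but needs only symmetric eigendecompositions.
trace_sqrt_product <- function(a, b) {
  ra <- sym_sqrt(a)
  inner <- ra %*% b %*% ra
  e <- eigen((inner + t(inner)) / 2, symmetric = TRUE, only.values = TRUE)
  sum(sqrt(pmax(e$values, 0)))
}

#' Fréchet (Wasserstein-2) distance between two Gaussian summaries
#'
#' `||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, evaluated through
#' the symmetric form `tr((S_a^{1/2} S_b S_a^{1/2})^{1/2})` with clamping of
#' tiny negative eigenvalues; on numerical failure both covariances are
#' jittered with `1e-6 * I` and the computation retried. Results within
#' `1e-6` below zero are clamped to zero.
#'
#' @param a,b `gaussian_summary` objects of equal dimension.
#' @return Non-negative Fréchet distance.
#' @export
frechet_distance <- function(a, b) {
  if (length(a$mean) != length(b$mean)) {
    stop_synthzoo("gaussian summaries have mismatched dimensions",
                  "synthzoo_argument_error")
  }
  sym_tol <- 1e-8
  for (s in list(a, b)) {
    if (max(abs(s$cov - t(s$cov))) > sym_tol * max(1, max(abs(s$cov)))) {
      stop_synthzoo("covariance matrix is not symmetric", "synthzoo_argument_error")
    }
  }
  compute <- function(ca, cb) {
    sum((a$mean - b$mean)^2) + sum(diag(ca)) + sum(diag(cb)) -
      2 * trace_sqrt_product(ca, cb)
  }
  fd <- compute(a$cov, b$cov)
  if (!is.finite(fd)) {
    eps <- 1e-6
    d <- length(a$mean)
    fd <- compute(a$cov + eps * diag(d), b$cov + eps * diag(d))
    if (!is.finite(fd)) {
      stop_synthzoo("matrix square root failed even after stabilization",
                    "synthzoo_numerical_error")
    }
  }
  if (fd < 0) {
    if (fd < -1e-6) {
      stop_synthzoo(sprintf("Fréchet distance is negative beyond tolerance (%g)", fd),
                    "synthzoo_numerical_error")
    }
    fd <- 0
  }
  fd
}

#' Normalize an image set to [0, 1]
#'
#' `"bitdepth"` divides by the dtype maximum (2^bitdepth - 1; 255 for 8-bit
#' images). `"minmax"` rescales by the dataset-wide minimum and maximum; a
#' constant dataset maps to all zeros. Feeding images already in `[0, 1]`
#' through bitdepth normalization shrinks them by 255 — a documented hazard
#' for which a warning is emitted.
#'
#' @param images List of numeric image arrays.
#' @param mode `"bitdepth"` or `"minmax"`.
#' @param bitdepth Bit depth for `"bitdepth"` mode (default 8).
#' @return List of arrays with values in `[0, 1]`.
#' @export
normalize_images <- function(images, mode = c("bitdepth", "minmax"), bitdepth = 8L) {
  mode <- match.arg(mode)
  if (length(images) == 0L) return(images)
  if (mode == "bitdepth") {
    denom <- 2^bitdepth - 1
    mx <- max(vapply(images, max, numeric(1)))
    if (mx <= 1) {
      warn_synthzoo(
        "images look already scaled to [0,1]; bitdepth normalization will shrink them further",
        "synthzoo_normalization_warning"
      )
    }
    lapply(images, function(im) im / denom)
  } else {
    lo <- min(vapply(images, min, numeric(1)))
    hi <- max(vapply(images, max, numeric(1)))
    if (hi - lo <= 0) {
      lapply(images, function(im) im * 0)
    } else {
      lapply(images, function(im) (im - lo) / (hi - lo))
    }
  }
}

# Apply the optional normalization mode, then resize/channel-match to the
# extractor's expected input, then extract features.
extract_features <- function(images, extractor, normalize = "none") {
  if (isTRUE(normalize)) normalize <- "bitdepth"
  if (isFALSE(normalize) || is.null(normalize)) normalize <- "none"
  if (normalize != "none") images <- normalize_images(images, normalize)
  if (!is.null(extractor$input_size)) {
    images <- lapply(images, conform_image, size = extractor$input_size)
  }
  feats <- extractor$apply(images)
  if (is.list(feats) && !is.null(feats$values)) feats <- feats$values
  structure(list(values = feats, extractor_id = extractor$id),
            class = "feature_matrix")
}

# Resize (bilinear, antialiased, via EBImage) and replicate channels to match
# an extractor's (H, W, C) expectation.
conform_image <- function(image, size) {
  d <- image_dims(image)
  if (d[1] != size[1] || d[2] != size[2]) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_synthzoo("image resizing requires the EBImage package",
                    "synthzoo_dependency_error")
    }
    image <- EBImage::imageData(
      EBImage::resize(EBImage::Image(image), w = size[1], h = size[2],
                      filter = "bilinear", antialias = TRUE)
    )
    d <- image_dims(image)
  }
  if (length(size) >= 3L && size[3] == 3L && d[3] == 1L) {
    image <- array(rep(as.vector(to_grayscale(image)), 3L), dim = c(d[1], d[2], 3L))
  }
  image
}

#' Fréchet inception distance between two image sets
#'
#' Runs `extractor` over both sets (after optional normalization and input
#' conformation), fits a Gaussian summary to each feature matrix, and returns
#' their Fréchet distance. Deterministic for fixed inputs and extractor.
#'
#' @param set_a,set_b Lists of image arrays, each of size >= 2.
#' @param extractor A `feature_extractor` (see [toy_feature_extractor()]).
#' @param normalize `"none"`, `"bitdepth"`, or `"minmax"` (logical `TRUE`
#'   means `"bitdepth"`).
#' @return Non-negative FID value.
#' @export
compute_fid <- function(set_a, set_b, extractor, normalize = "none") {
  if (length(set_a) < 2L || length(set_b) < 2L) {
    stop_synthzoo("each image set needs at least 2 images for FID",
                  "synthzoo_argument_error")
  }
  fa <- fit_gaussian(extract_features(set_a, extractor, normalize))
  fb <- fit_gaussian(extract_features(set_b, extractor, normalize))
  frechet_distance(fa, fb)
}

#' Real–real FID lower bound
#'
#' Shuffles the real set with `seed`, splits it into two disjoint halves of
#' sizes floor(n/2) and ceiling(n/2), and returns the FID between the halves
#' — an empirical floor for any real-vs-synthetic FID on this dataset, since
#' it reflects the variation within the real data itself.
#'
#' @param real_set List of image arrays, size >= 4.
#' @inheritParams compute_fid
#' @param seed Integer seed controlling the split.
#' @return The FIDrr value, with attributes `n1`, `n2` (half sizes) and
#'   `seed`.
#' @export
fid_lower_bound <- function(real_set, extractor, normalize = "none", seed = 1L) {
  n <- length(real_set)
  if (n < 4L) {
    stop_synthzoo("need at least 4 real images to form two FID halves",
                  "synthzoo_argument_error")
  }
  perm <- with_seed(seed, sample.int(n))
  n1 <- n %/% 2L
  half1 <- real_set[perm[seq_len(n1)]]
  half2 <- real_set[perm[(n1 + 1L):n]]
  fid <- compute_fid(half1, half2, extractor, normalize)
  structure(fid, n1 = n1, n2 = n - n1, seed = seed)
}

#' FID ratio rFID
#'
#' `rfid = 1 - (fid_rs - fid_rr) / fid_rs`, the share of the real–synthetic
#' FID explained by intrinsic real-data variation. Assuming
#' `fid_rs >= fid_rr` the ratio lies in `[0, 1]`; a value near 1 means the
#' synthetic set is about as far from the real data as the real data is from
#' itself. Empirical violations of the assumption (`fid_rr > fid_rs`) are
#' clamped to 1 and flagged via the `clamped` attribute.
#'
#' @param fid_rs Real–synthetic FID (> 0).
#' @param fid_rr Real–real lower-bound FID (>= 0).
#' @return rFID in `[0, 1]`.
#' @export
rfid <- function(fid_rs, fid_rr) {
  if (!is.finite(fid_rs) || fid_rs <= 0) {
    stop_synthzoo("fid_rs must be a positive finite number", "synthzoo_argument_error")
  }
  if (!is.finite(fid_rr) || fid_rr < 0) {
    stop_synthzoo("fid_rr must be a non-negative finite number", "synthzoo_argument_error")
  }
  val <- 1 - (fid_rs - fid_rr) / fid_rs
  if (val > 1) {
    warn_synthzoo("fid_rr exceeds fid_rs; rFID clamped to 1", "synthzoo_rfid_clamp_warning")
    return(structure(1, clamped = TRUE))
  }
  val
}

#' Evaluate one registered model with FIDrr / FIDrs / rFID
#'
#' Generates `n_syn` synthetic samples from the model, computes the real–real
#' lower bound on a seeded split of `real_set`, the real–synthetic FID (the
#' synthetic draw size matching the number of available real samples by
#' default), and the rFID ratio, and returns a fully provenanced report.
#'
#' @param registry A `synthzoo_registry`.
#' @param model_id Model to evaluate.
#' @param real_set List of real image arrays (>= 4).
#' @param n_syn Number of synthetic samples; defaults to `length(real_set)`.
#' @inheritParams compute_fid
#' @param seed Integer seed driving generation and the real split.
#' @param cache_dir,extra_args Passed to [generate_samples()].
#' @return A `fid_report`: list with `fid_rr`, `fid_rs`, `rfid`, `n_real`,
#'   `n_syn`, `normalized`, `extractor_id`, `seed`, `model_id`.
#' @export
evaluate_model <- function(registry, model_id, real_set,
                           n_syn = length(real_set), extractor,
                           normalize = "none", seed = 1L,
                           cache_dir = tempfile("synthzoo-cache-"),
                           extra_args = list()) {
  items <- generate_samples(registry, model_id, n_syn, seed = seed,
                            cache_dir = cache_dir, extra_args = extra_args)
  syn_set <- lapply(items, `[[`, "image")
  fid_rr <- fid_lower_bound(real_set, extractor, normalize, seed = seed)
  fid_rs <- compute_fid(real_set, syn_set, extractor, normalize)
  structure(
    list(
      model_id = model_id,
      fid_rr = as.numeric(fid_rr),
      fid_rs = fid_rs,
      rfid = as.numeric(rfid(fid_rs, fid_rr)),
      n_real = length(real_set),
      n_syn = length(syn_set),
      normalized = !identical(normalize, "none") && !isFALSE(normalize),
      extractor_id = extractor$id,
      seed = seed
    ),
    class = "fid_report"
  )
}

#' Tabulate FID reports
#'
#' One row per report with every report field, the (FIDrr, FIDrs) scatter
#' pairs, and the least-squares trend of FIDrs on FIDrr (slope and intercept;
#' `NA` with fewer than two distinct points).
#'
#' @param reports List of `fid_report`s (>= 1).
#' @param csv_path Optional path; when given the table is also written as CSV.
#' @return List with `table` (data frame), `scatter` (fid_rr/fid_rs data
#'   frame), `trend` (named vector: slope, intercept).
#' @export
report_table <- function(reports, csv_path = NULL) {
  if (length(reports) < 1L) {
    stop_synthzoo("need at least one report", "synthzoo_argument_error")
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      model_id = r$model_id, fid_rr = r$fid_rr, fid_rs = r$fid_rs,
      rfid = r$rfid, n_real = r$n_real, n_syn = r$n_syn,
      normalized = r$normalized, extractor_id = r$extractor_id, seed = r$seed,
      stringsAsFactors = FALSE
    )
  }))
  scatter <- tab[, c("fid_rr", "fid_rs")]
  trend <- c(slope = NA_real_, intercept = NA_real_)
  if (nrow(scatter) >= 2L && stats::var(scatter$fid_rr) > 0) {
    fit <- stats::lm(fid_rs ~ fid_rr, data = scatter)
    trend <- c(slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]))
  }
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  list(table = tab, scatter = scatter, trend = trend)
}
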