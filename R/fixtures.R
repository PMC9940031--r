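# Procedural image renderers shared by the fixture model packages and
# synth_image_set(). Fixture models are closed-form syntheses from a latent
# vector, not trained networks: they exercise every interface contract
# (latent input, masks, labels, image-to-image) deterministically.

#' Render a procedural "mass patch": Gaussian blob on a noisy background
#'
#' The 16-dimensional standard-normal latent controls blob position (dims
#' 1-2), extent (3-4), amplitude (5), background level (6), and a
#' low-frequency texture field (7-16), so every latent dimension is visible
#' in the output. When `z` is omitted it is drawn from `seed` together with
#' the background noise; when `z` is given the render is a pure deterministic
#' function of `z` (no noise), as required for latent exploration.
#'
#' @param z Optional length-16 latent vector.
#' @param seed Seed used when `z` is `NULL`.
#' @param size Image side length in pixels.
#' @param shift Additive intensity offset (8-bit units), applied before
#'   clamping.
#' @return `size` x `size` numeric matrix, values in 0..255.
#' @export
render_latent_blob <- function(z = NULL, seed = NULL, size = 64L, shift = 0) {
  noise <- 0
  if (is.null(z)) {
    drawn <- with_seed(seed %||% 0L, list(z = stats::rnorm(16L),
                                          noise = stats::rnorm(size * size, 0, 6)))
    z <- drawn$z
    noise <- matrix(drawn$noise, size, size)
  }
  u <- stats::pnorm(z)
  cx <- (0.35 + 0.30 * u[1]) * size
  cy <- (0.35 + 0.30 * u[2]) * size
  sx <- (0.08 + 0.10 * u[3]) * size
  sy <- (0.08 + 0.10 * u[4]) * size
  amp <- 120 + 60 * u[5]
  bg <- 20 + 20 * u[6]
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  img <- bg + amp * exp(-((xs - cx)^2 / (2 * sx^2) + (ys - cy)^2 / (2 * sy^2)))
  for (k in 7:16) {
    f <- (k - 6) / (2 * size)
    th <- (k - 6) * pi / 10
    img <- img + 3 * z[k] * sin(2 * pi * f * (xs * cos(th) + ys * sin(th)))
  }
  pmin(pmax(img + noise + shift, 0), 255)
}

#' Render a procedural sinusoidal grating patch
#'
#' Latent dims control orientation, frequency, phase, contrast, and
#' background; used as the second class of the class-conditional fixture.
#'
#' @inheritParams render_latent_blob
#' @return `size` x `size` numeric matrix, values in 0..255.
#' @export
render_grating <- function(z = NULL, seed = NULL, size = 64L, shift = 0) {
  noise <- 0
  if (is.null(z)) {
    drawn <- with_seed(seed %||% 0L, list(z = stats::rnorm(16L),
                                          noise = stats::rnorm(size * size, 0, 6)))
    z <- drawn$z
    noise <- matrix(drawn$noise, size, size)
  }
  u <- stats::pnorm(z)
  theta <- pi * u[1]
  freq <- (2 + 6 * u[2]) / size
  phase <- 2 * pi * u[3]
  contrast <- 60 + 60 * u[4]
  bg <- 80 + 40 * u[5]
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  img <- bg + contrast * sin(2 * pi * freq * (xs * cos(theta) + ys * sin(theta)) + phase)
  pmin(pmax(img + noise + shift, 0), 255)
}

#' Render a procedural lesion image with its segmentation mask
#'
#' Latent dims control the ellipse center, axes, and intensity; the mask is
#' the binary ellipse support, spatially congruent with the image.
#'
#' @inheritParams render_latent_blob
#' @return List with `image` and `mask`, both `size` x `size` matrices in
#'   0..255.
#' @export
render_ellipse_pair <- function(z = NULL, seed = NULL, size = 64L) {
  if (is.null(z)) {
    z <- with_seed(seed %||% 0L, stats::rnorm(16L))
  }
  u <- stats::pnorm(z)
  cx <- (0.35 + 0.30 * u[1]) * size
  cy <- (0.35 + 0.30 * u[2]) * size
  ax <- (0.10 + 0.15 * u[3]) * size
  ay <- (0.10 + 0.15 * u[4]) * size
  amp <- 140 + 60 * u[5]
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  r2 <- (xs - cx)^2 / ax^2 + (ys - cy)^2 / ay^2
  inside <- r2 <= 1
  img <- 25 + amp * exp(-pmax(r2 - 0.5, 0)) * inside +
    2 * z[6] * sin(2 * pi * xs / size) + 2 * z[7] * cos(2 * pi * ys / size)
  list(image = pmin(pmax(img, 0), 255), mask = 255 * inside)
}

#' Draw a synthetic image set from the fixture "real data" distribution
#'
#' Image i is rendered from seed `seed + i - 1`, exactly the per-sample
#' seeding contract the fixture models follow, so a model sampling the same
#' distribution is distribution-matched to these sets. `shift` adds a global
#' intensity offset (8-bit units) to emulate a distribution shift;
#' `class_mix` draws the blob/grating class per image with the given
#' proportions (labels attached as the `label` attribute).
#'
#' @param n Number of images (>= 1).
#' @param size Image side length.
#' @param seed Integer seed; the set is a deterministic function of it.
#' @param shift Intensity offset added to every image.
#' @param class_mix Optional length-2 proportions for classes `c(0, 1)`.
#' @return List of `size` x `size` matrices (class `synthzoo_image_set`).
#' @export
synth_image_set <- function(n, size = 64L, seed = 1L, shift = 0, class_mix = NULL) {
  if (n < 1L) stop_synthzoo("n must be >= 1", "synthzoo_argument_error")
  imgs <- lapply(seq_len(n), function(i) {
    s <- seed + i - 1L
    if (is.null(class_mix)) {
      render_latent_blob(seed = s, size = size, shift = shift)
    } else {
      cls <- with_seed((s * 7919) %% 2000000011,
                       sample(c(0L, 1L), 1L, prob = class_mix))
      im <- if (cls == 0L) {
        render_latent_blob(seed = s, size = size, shift = shift)
      } else {
        render_grating(seed = s, size = size, shift = shift)
      }
      attr(im, "label") <- cls
      im
    }
  })
  structure(imgs, class = "synthzoo_image_set")
}

#' Deterministic toy feature extractor (seeded random projection)
#'
#' Maps an image to features by grayscale conversion, 8 x 8 average pooling,
#' and a fixed seeded Gaussian random projection of the 64 pooled values to
#' `d` dimensions. Deterministic given `(seed, d)`; registered under the id
#' `toy-rp-{seed}-{d}`. It is a genuine (if simple) feature extractor that
#' makes the whole FID stack testable without pretrained networks; pretrained
#' backbones plug in through the same contract.
#'
#' @param seed Projection seed.
#' @param d Output feature dimension.
#' @return A `feature_extractor`: list with `id`, `input_size` (`NULL`: any),
#'   `apply(images) -> n x d matrix`.
#' @export
toy_feature_extractor <- function(seed = 42L, d = 64L) {
  proj <- with_seed(seed, matrix(stats::rnorm(64L * d) / sqrt(64), 64L, d))
  structure(
    list(
      id = sprintf("toy-rp-%d-%d", as.integer(seed), as.integer(d)),
      input_size = NULL,
      apply = function(images) {
        feats <- t(vapply(images, function(im) {
          as.vector(average_pool(to_grayscale(im), 8L)) %*% proj
        }, numeric(d)))
        dimnames(feats) <- NULL
        feats
      }
    ),
    class = "feature_extractor"
  )
}

fixture_model_specs <- function() {
  list(
    list(
      id = "00001_DCGAN_MMG_MASS", kind = "noise_to_image",
      title = "Mammography mass patches (procedural blob generator)",
      modality = "mammography", output_type = "image",
      keywords = c("mammography", "patches", "mass"),
      performance = list(FID = 80.51),
      latent_dim = 16L, script = script_noise_to_image()
    ),
    list(
      id = "00002_FASTGAN_POLYP_MASK", kind = "image_plus_mask",
      title = "Endoscopic polyp images with segmentation masks (procedural)",
      modality = "endoscopy", output_type = "image_and_mask",
      keywords = c("endoscopy", "polyp", "mask"),
      performance = list(FID = 63.99),
      latent_dim = 16L, script = script_image_plus_mask()
    ),
    list(
      id = "00003_CDCGAN_MMG_CLASS", kind = "class_conditional",
      title = "Class-conditional mammography texture patches (procedural)",
      modality = "mammography", output_type = "image_and_label",
      keywords = c("mammography", "patches", "conditional"),
      performance = list(FID = 120.2, downstream = list(accuracy = 0.71)),
      latent_dim = 16L, script = script_class_conditional(),
      generate_args = list(condition = 0L)
    ),
    list(
      id = "00004_CYCLEGAN_MMG_DENSITY", kind = "image_to_image",
      title = "Mammography intensity-domain translation (procedural inverter)",
      modality = "mammography", output_type = "image",
      keywords = c("mammography", "density", "translation"),
      performance = list(downstream = list(dice = 0.62)),
      latent_dim = 0L, script = script_image_to_image()
    )
  )
}

script_noise_to_image <- function() c(
  "# Noise-to-image fixture: 16-d latent -> procedural mass patch.",
  "# Contract: sample j of a batch is derived from seed + j - 1.",
  "generate <- function(model_file, num_samples, save_images = FALSE,",
  "                     output_path = NULL, seed = NULL,",
  "                     input_latent_vector = NULL, shift = 0, ...) {",
  "  w <- jsonlite::fromJSON(model_file)",
  "  lapply(seq_len(num_samples), function(j) {",
  "    if (is.null(input_latent_vector)) {",
  "      s <- (if (is.null(seed)) sample.int(1000000L, 1L) else seed) + j - 1L",
  "      synthzoo::render_latent_blob(seed = s, size = w$size, shift = shift)",
  "    } else {",
  "      z <- if (is.matrix(input_latent_vector)) input_latent_vector[j, ]",
  "           else input_latent_vector",
  "      synthzoo::render_latent_blob(z = z, size = w$size, shift = shift)",
  "    }",
  "  })",
  "}"
)

script_image_plus_mask <- function() c(
  "# Image+mask fixture: 16-d latent -> lesion image with binary mask.",
  "generate <- function(model_file, num_samples, save_images = FALSE,",
  "                     output_path = NULL, seed = NULL,",
  "                     input_latent_vector = NULL, ...) {",
  "  w <- jsonlite::fromJSON(model_file)",
  "  lapply(seq_len(num_samples), function(j) {",
  "    if (is.null(input_latent_vector)) {",
  "      s <- (if (is.null(seed)) sample.int(1000000L, 1L) else seed) + j - 1L",
  "      synthzoo::render_ellipse_pair(seed = s, size = w$size)",
  "    } else {",
  "      z <- if (is.matrix(input_latent_vector)) input_latent_vector[j, ]",
  "           else input_latent_vector",
  "      synthzoo::render_ellipse_pair(z = z, size = w$size)",
  "    }",
  "  })",
  "}"
)

script_class_conditional <- function() c(
  "# Class-conditional fixture: condition 0 -> blob patch, 1 -> grating.",
  "generate <- function(model_file, num_samples, save_images = FALSE,",
  "                     output_path = NULL, seed = NULL, condition = 0L,",
  "                     input_latent_vector = NULL, ...) {",
  "  w <- jsonlite::fromJSON(model_file)",
  "  lapply(seq_len(num_samples), function(j) {",
  "    s <- (if (is.null(seed)) sample.int(1000000L, 1L) else seed) + j - 1L",
  "    z <- if (is.null(input_latent_vector)) NULL",
  "         else if (is.matrix(input_latent_vector)) input_latent_vector[j, ]",
  "         else input_latent_vector",
  "    im <- if (condition == 0L) {",
  "      synthzoo::render_latent_blob(z = z, seed = s, size = w$size)",
  "    } else {",
  "      synthzoo::render_grating(z = z, seed = s, size = w$size)",
  "    }",
  "    list(image = im, label = condition)",
  "  })",
  "}"
)

script_image_to_image <- function() c(
  "# Image-to-image fixture: intensity inverter. Translates images from",
  "# input_image_dir (cycled) or, absent one, procedurally drawn sources.",
  "generate <- function(model_file, num_samples, save_images = FALSE,",
  "                     output_path = NULL, seed = NULL,",
  "                     input_image_dir = NULL, ...) {",
  "  w <- jsonlite::fromJSON(model_file)",
  "  inputs <- if (!is.null(input_image_dir)) synthzoo::load_image_set(input_image_dir)",
  "  lapply(seq_len(num_samples), function(j) {",
  "    src <- if (!is.null(inputs) && length(inputs) > 0) {",
  "      inputs[[(j - 1L) %% length(inputs) + 1L]]",
  "    } else {",
  "      s <- (if (is.null(seed)) sample.int(1000000L, 1L) else seed) + j - 1L",
  "      synthzoo::render_latent_blob(seed = s, size = w$size)",
  "    }",
  "    255 - src",
  "  })",
  "}"
)

#' Build the offline fixture model zoo
#'
#' Writes four procedural model packages — one per supported generation
#' scenario (noise-to-image, image-plus-mask, class-conditional,
#' image-to-image) — plus a valid registry referencing them by local path.
#' Packages contain the entry script, a JSON weights file, a license file,
#' and a requirements manifest. Output is a deterministic function of `seed`.
#'
#' @param target_dir Writable directory for the zoo.
#' @param seed Recorded in each weights file; fixture packages are otherwise
#'   static text.
#' @return List with `registry_path` and `package_dirs`.
#' @export
build_fixture_zoo <- function(target_dir, seed = 7L) {
  ensure_dir(target_dir)
  if (file.access(target_dir, 2) != 0) {
    stop_synthzoo(sprintf("target directory not writable: %s", target_dir),
                  "synthzoo_io_error")
  }
  specs <- fixture_model_specs()
  entries <- list()
  dirs <- character(0)
  for (sp in specs) {
    pkg_dir <- file.path(target_dir, sp$id)
    ensure_dir(pkg_dir)
    writeLines(sp$script, file.path(pkg_dir, ENTRY_SCRIPT))
    jsonlite::write_json(
      list(size = 64L, latent_dim = sp$latent_dim, kind = sp$kind, seed = seed),
      file.path(pkg_dir, "weights.json"), auto_unbox = TRUE, digits = NA
    )
    writeLines(c("MIT License", "Procedural fixture model; no training data."),
               file.path(pkg_dir, "LICENSE.txt"))
    writeLines(c("jsonlite", "synthzoo"), file.path(pkg_dir, "requirements.txt"))
    entries[[sp$id]] <- list(
      execution = list(
        package_location = pkg_dir,
        package_name = sp$id,
        weights_name = "weights",
        weights_extension = ".json",
        dependencies = list("jsonlite", "stats"),
        generate_method_name = "generate",
        generate_args = sp$generate_args %||% structure(list(), names = character(0)),
        image_size = c(64L, 64L, 1L),
        latent_dim = sp$latent_dim,
        value_range = c(0, 255)
      ),
      selection = list(
        performance = sp$performance,
        keywords = as.list(sp$keywords)
      ),
      description = list(
        title = sp$title,
        modality = sp$modality,
        output_type = sp$output_type,
        training_dataset = "procedural (no training data)",
        license = "MIT",
        date = "2026-01-01",
        publication = ""
      )
    )
    dirs <- c(dirs, pkg_dir)
  }
  registry_path <- file.path(target_dir, "registry.json")
  jsonlite::write_json(entries, registry_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(registry_path = registry_path, package_dirs = dirs)
}
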