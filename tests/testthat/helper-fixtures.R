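# Shared fixture zoo, built once per test session. Tests that mutate the
# registry must work on their own copy (see fresh_registry_copy()).
test_zoo <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "synthzoo-test-zoo")
      built <- build_fixture_zoo(dir, seed = 7)
      cache <<- list(dir = dir, registry_path = built$registry_path,
                     package_dirs = built$package_dirs)
    }
    cache
  }
})

test_registry <- function() load_registry(test_zoo()$registry_path)

fresh_registry_copy <- function() {
  path <- tempfile(fileext = ".json")
  file.copy(test_zoo()$registry_path, path)
  path
}

# Write a minimal single-purpose registry JSON (no packages needed) for tests
# that only exercise metadata-level behavior.
write_mini_registry <- function(entries) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  path
}

mini_entry <- function(title = "A model", keywords = list("kw"),
                       performance = list(FID = 1), latent_dim = 16L,
                       location = "/nonexistent") {
  list(
    execution = list(package_location = location, package_name = "x",
                     weights_name = "", weights_extension = "",
                     dependencies = list("stats"),
                     generate_method_name = "generate",
                     generate_args = structure(list(), names = character(0)),
                     image_size = c(64L, 64L, 1L), latent_dim = latent_dim,
                     value_range = c(0, 255)),
    selection = list(performance = performance, keywords = keywords),
    description = list(title = title, modality = "m", output_type = "image",
                       training_dataset = "d", license = "MIT",
                       date = "2026-01-01", publication = "")
  )
}

# Create a small user model package (contribution-style) whose generate
# follows the per-sample seeding contract. `body_hook` can inject failures.
make_user_package <- function(dir = tempfile("user-pkg-"),
                              size = 64L, fail_at = NA) {
  dir.create(dir, recursive = TRUE)
  # fail_at injects a failure at the sample whose per-sample seed equals
  # base seed + fail_at - 1 (i.e. global sample fail_at under the executor's
  # seeding contract)
  lines <- c(
    "generate <- function(model_file, num_samples, save_images = FALSE,",
    "                     output_path = NULL, seed = NULL, ...) {",
    "  lapply(seq_len(num_samples), function(j) {",
    "    s <- (if (is.null(seed)) 0L else seed) + j - 1L",
    sprintf("    if (!is.na(%s) && s == %s) stop('synthetic failure')",
            deparse(fail_at), deparse(fail_at)),
    sprintf("    synthzoo::render_latent_blob(seed = s, size = %dL)", size),
    "  })",
    "}"
  )
  writeLines(lines, file.path(dir, "model.R"))
  dir
}

expect_same_images <- function(a, b) {
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
}
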