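contribution_request <- function(dir, id = "00100_YOUR_MODEL") {
  list(model_id = id, init_script_path = file.path(dir, "model.R"),
       generate_method_name = "generate", weights_name = "",
       weights_extension = "", dependencies = list("stats"))
}

test_that("validate_contribution checks id, path, importability, and generate contract", {
  dir <- make_user_package()
  expect_identical(validate_contribution(contribution_request(dir)), character(0))

  bad_id <- contribution_request(dir, id = "100_model")
  expect_match(validate_contribution(bad_id), "pattern")

  gone <- contribution_request(dir)
  gone$init_script_path <- file.path(dir, "nope", "model.R")
  expect_match(validate_contribution(gone), "not found")

  wrong_fn <- contribution_request(dir)
  wrong_fn$generate_method_name <- "synthesize"
  expect_match(validate_contribution(wrong_fn), "defines no function")

  no_out <- tempfile("pkg-"); dir.create(no_out)
  writeLines("generate <- function(model_file, num_samples) list()",
             file.path(no_out, "model.R"))
  expect_match(validate_contribution(contribution_request(no_out)),
               "output_path")
})

test_that("build_metadata_entry assembles a valid three-section entry", {
  dir <- make_user_package()
  entry <- build_metadata_entry(contribution_request(dir),
                                measured = list(FID = 12.3), latent_dim = 16L)
  expect_identical(validate_metadata(entry), character(0))
  expect_equal(entry$selection$performance$FID, 12.3)
  expect_identical(entry$description$date, format(Sys.Date(), "%Y-%m-%d"))
  expect_error(build_metadata_entry(contribution_request(dir, "bad id")),
               class = "synthzoo_state_error")
})

test_that("test_model passes well-formed packages and names failing checks", {
  dir <- make_user_package()
  entry <- build_metadata_entry(contribution_request(dir), latent_dim = 16L)
  res <- test_model(entry)
  expect_true(as.logical(res))
  expect_true(any(grepl("sample count", attr(res, "log"))))

  # declared 128x128 but the package emits 64x64
  wrong <- build_metadata_entry(contribution_request(dir),
                                image_size = c(128L, 128L, 1L), latent_dim = 16L)
  res2 <- test_model(wrong)
  expect_false(as.logical(res2))
  expect_true(any(grepl("dimensions", attr(res2, "log")) &
                    grepl("FAIL", attr(res2, "log"))))

  failing <- make_user_package(fail_at = 2L)
  entry3 <- build_metadata_entry(contribution_request(failing, "00101_FAILS_EARLY"),
                                 latent_dim = 16L)
  res3 <- test_model(entry3)
  expect_false(as.logical(res3))
  expect_match(paste(attr(res3, "log"), collapse = "\n"), "batch")
})

test_that("register_and_package appends atomically, archives, and publishes locally", {
  reg_path <- fresh_registry_copy()
  before <- load_registry(reg_path)
  dir <- make_user_package()
  entry <- build_metadata_entry(contribution_request(dir), latent_dim = 16L)
  out_dir <- tempfile()

  res <- register_and_package(entry, reg_path, dir, out_dir = out_dir)
  expect_true(res$test_passed)
  expect_true(file.exists(res$package_archive))
  expect_true(file.exists(res$notice_path))
  expect_match(res$publish_receipt, "^local:")

  after <- load_registry(reg_path)
  expect_length(after$entries, length(before$entries) + 1L)
  # append-only: prior entries are untouched
  for (id in names(before$entries)) {
    expect_equal(after$entries[[id]]$selection$performance,
                 before$entries[[id]]$selection$performance)
    expect_identical(after$entries[[id]]$description$title,
                     before$entries[[id]]$description$title)
  }
  notice <- jsonlite::fromJSON(res$notice_path)
  expect_identical(notice$model_id, "00100_YOUR_MODEL")

  # duplicate id is a conflict and leaves the registry unchanged
  bytes_before <- readBin(reg_path, "raw", file.info(reg_path)$size)
  expect_error(register_and_package(entry, reg_path, dir, out_dir = out_dir),
               class = "synthzoo_conflict_error")
  bytes_after <- readBin(reg_path, "raw", file.info(reg_path)$size)
  expect_identical(bytes_before, bytes_after)
})

test_that("a contributed model is immediately generable through the facade", {
  reg_path <- fresh_registry_copy()
  zoo <- model_zoo(reg_path)
  dir <- make_user_package()
  res <- contribute(zoo, contribution_request(dir, "00102_ROUND_TRIP"),
                    measured = list(FID = 9.9), latent_dim = 16L,
                    out_dir = tempfile())
  expect_identical(res$metadata_entry$model_id, "00102_ROUND_TRIP")
  items <- generate(zoo, "00102_ROUND_TRIP", 3L, seed = 4L)
  expect_length(items, 3L)
  expect_identical(dim(items[[1]]$image), c(64L, 64L))
  # and it is searchable/rankable like any other entry
  tab <- rank_models(zoo, metric_key = "FID", order = "ascending")
  expect_identical(tab$model_id[1], "00102_ROUND_TRIP")
})

test_that("the default publisher performs no network traffic", {
  published <- tempfile()
  p <- local_publisher(published)
  arch <- tempfile(fileext = ".tar.gz"); writeLines("x", arch)
  note <- tempfile(fileext = ".json"); writeLines("{}", note)
  receipt <- p$publish(arch, note)
  expect_true(file.exists(file.path(published, basename(arch))))
  expect_match(receipt, "^local:")
})
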