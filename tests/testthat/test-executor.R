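test_that("local package directories are used in place", {
  reg <- test_registry()
  md <- get_metadata(reg, "00001_DCGAN_MMG_MASS")
  pkg <- resolve_package(md, cache_dir = tempfile())
  expect_identical(normalizePath(pkg$root_dir),
                   normalizePath(md$execution$package_location))
  expect_true(file.exists(pkg$entry_script))
  expect_match(pkg$weights_path, "weights\\.json$")
})

test_that("archived packages are fetched once, unpacked, and cached", {
  # archive a fixture package, point a registry entry at the tarball
  src <- test_zoo()$package_dirs[1]
  tarball <- tempfile(fileext = ".tar.gz")
  old <- setwd(src); on.exit(setwd(old), add = TRUE)
  utils::tar(tarball, files = sort(list.files(".", recursive = TRUE)),
             compression = "gzip", tar = "internal")
  setwd(old)

  reg_path <- write_mini_registry(list(
    "00010_ARCHIVED_MODEL" = mini_entry(location = paste0("file://", tarball))
  ))
  reg <- load_registry(reg_path)
  md <- get_metadata(reg, "00010_ARCHIVED_MODEL")

  calls <- 0L
  spy <- function(uri) { calls <<- calls + 1L; readBin(sub("^file://", "", uri), "raw",
                                                       file.info(sub("^file://", "", uri))$size) }
  cache <- tempfile()
  pkg <- resolve_package(md, cache, fetcher = spy)
  expect_identical(calls, 1L)
  expect_true(file.exists(pkg$entry_script))
  pkg2 <- resolve_package(md, cache, fetcher = spy)
  expect_identical(calls, 1L)  # idempotent: cache reused, no refetch
  expect_identical(pkg2$root_dir, pkg$root_dir)

  md$execution$package_location <- "file:///no/such/archive.tar.gz"
  expect_error(resolve_package(md, tempfile()), class = "synthzoo_fetch_error")
})

test_that("dependency checks probe presence and drive the installer", {
  reg <- test_registry()
  md <- get_metadata(reg, "00001_DCGAN_MMG_MASS")
  rep <- check_dependencies(md)
  expect_identical(rep$missing, character(0))
  expect_setequal(rep$required, c(rep$satisfied, rep$missing))

  md$execution$dependencies <- list("stats", "no_such_pkg_xyz")
  rep2 <- check_dependencies(md)
  expect_identical(rep2$missing, "no_such_pkg_xyz")

  installed <- character(0)
  rep3 <- check_dependencies(md, install = TRUE,
                             installer = function(p) installed <<- c(installed, p))
  expect_identical(rep3$installed_now, rep2$missing)
  expect_identical(installed, "no_such_pkg_xyz")
})

test_that("generate produces the declared count and dimensions; zero is empty", {
  reg <- test_registry()
  items <- generate_samples(reg, "00001_DCGAN_MMG_MASS", 5L, seed = 7L)
  expect_length(items, 5L)
  for (it in items) expect_identical(dim(it$image), c(64L, 64L))
  expect_identical(generate_samples(reg, "00001_DCGAN_MMG_MASS", 0L), list())
  expect_error(generate_samples(reg, "00099_NO_MODEL", 1L),
               class = "synthzoo_key_error")
})

test_that("output is invariant to batch size under a fixed seed", {
  reg <- test_registry()
  a <- generate_samples(reg, "00001_DCGAN_MMG_MASS", 10L, batch_size = 3L, seed = 7L)
  b <- generate_samples(reg, "00001_DCGAN_MMG_MASS", 10L, batch_size = 10L, seed = 7L)
  expect_same_images(a, b)
  c2 <- generate_samples(reg, "00001_DCGAN_MMG_MASS", 10L, batch_size = 3L, seed = 7L)
  expect_same_images(a, c2)
})

test_that("saving to disk conserves counts, names files by index, writes a manifest", {
  reg <- test_registry()
  out <- tempfile()
  paths <- generate_samples(reg, "00002_FASTGAN_POLYP_MASK", 7L, batch_size = 3L,
                            seed = 1L, save_images = TRUE, output_path = out)
  expect_length(paths, 7L)
  expect_identical(anyDuplicated(paths), 0L)
  expect_identical(basename(paths[1]), "00002_FASTGAN_POLYP_MASK_000000.png")
  expect_true(all(file.exists(paths)))
  # masks written as siblings
  expect_true(all(file.exists(sub("\\.png$", "_mask.png", paths))))
  manifest <- jsonlite::fromJSON(file.path(out, "manifest.json"))
  expect_identical(manifest$model_id, "00002_FASTGAN_POLYP_MASK")
  expect_identical(manifest$seed, 1L)
  expect_length(manifest$files, 7L)
})

test_that("save-to-disk generation holds at most one batch in memory", {
  dir <- tempfile("probe-pkg-")
  dir.create(dir)
  log <- tempfile()
  writeLines(c(
    "generate <- function(model_file, num_samples, save_images = FALSE,",
    "                     output_path = NULL, seed = NULL, ...) {",
    sprintf("  cat(num_samples, '\\n', file = %s, append = TRUE)", deparse(log)),
    "  lapply(seq_len(num_samples), function(j) matrix(0, 8, 8))",
    "}"
  ), file.path(dir, "model.R"))
  reg <- load_registry(write_mini_registry(list(
    "00020_PROBE_MODEL" = mini_entry(location = dir)
  )))
  generate_samples(reg, "00020_PROBE_MODEL", 11L, batch_size = 4L, seed = 1L,
                   save_images = TRUE, output_path = tempfile())
  sizes <- scan(log, quiet = TRUE)
  expect_identical(as.integer(sizes), c(4L, 4L, 3L))
  expect_true(max(sizes) <= 4)
})

test_that("model failures are wrapped with model id and batch index", {
  dir <- make_user_package(fail_at = 5L)
  reg <- load_registry(write_mini_registry(list(
    "00021_FAILING_MODEL" = mini_entry(location = dir)
  )))
  err <- expect_error(
    generate_samples(reg, "00021_FAILING_MODEL", 10L, batch_size = 3L, seed = 1L),
    class = "synthzoo_execution_error"
  )
  expect_match(conditionMessage(err), "00021_FAILING_MODEL")
  expect_match(conditionMessage(err), "batch 2")
})

test_that("generate callables freeze defaults, honor overrides, stay independent", {
  reg <- test_registry()
  gen1 <- get_generate_callable(reg, "00003_CDCGAN_MMG_CLASS")
  items <- gen1(3L, seed = 2L)
  expect_length(items, 3L)
  expect_identical(unique(vapply(items, `[[`, numeric(1), "label")), 0)
  items1 <- gen1(2L, seed = 2L, condition = 1L)
  expect_identical(unique(vapply(items1, `[[`, numeric(1), "label")), 1)

  # callables for different ids are independent: interleaved use of one does
  # not disturb the other's deterministic replay
  gen2 <- get_generate_callable(reg, "00001_DCGAN_MMG_MASS")
  a1 <- gen2(2L, seed = 3L)
  b <- gen1(2L, seed = 3L, condition = 1L)
  a2 <- gen2(2L, seed = 3L)
  expect_same_images(a1, a2)
  expect_false(identical(a1[[1]]$image, b[[1]]$image))
})

test_that("batch iterators chunk finite lengths and replay under a fixed seed", {
  reg <- test_registry()
  it <- as_batch_iterator(reg, "00001_DCGAN_MMG_MASS", batch_size = 4L,
                          seed = 5L, length = 10L)
  sizes <- c()
  repeat {
    b <- it$next_batch()
    if (is.null(b)) break
    sizes <- c(sizes, length(b))
  }
  expect_identical(sizes, c(4L, 4L, 2L))

  tr <- function(item) { item$image <- item$image / 255; item }
  it2 <- as_batch_iterator(reg, "00001_DCGAN_MMG_MASS", batch_size = 3L,
                           seed = 5L, transform = tr)
  b1 <- it2$next_batch()
  expect_true(all(vapply(b1, function(x) max(x$image) <= 1 && min(x$image) >= 0,
                         logical(1))))

  it3 <- as_batch_iterator(reg, "00001_DCGAN_MMG_MASS", batch_size = 3L, seed = 5L)
  expect_equal(lapply(it3$next_batch(), `[[`, "image"),
               lapply(b1, function(x) x$image * 255))
  expect_error(as_batch_iterator(reg, "00001_DCGAN_MMG_MASS", batch_size = 0L),
               class = "synthzoo_argument_error")
})
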