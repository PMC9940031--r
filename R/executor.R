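# Filename of the entry script every model package must contain at its root.
ENTRY_SCRIPT <- "model.R"

#' Resolve a model package from its metadata
#'
#' Local directory locations are used in place (no copy). Archive locations
#' (`.zip`, `.tar`, `.tar.gz`, `.tgz`), local or via a `file://` URI, are
#' fetched with the pluggable `fetcher` and extracted under
#' `cache_dir/<model_id>`. Resolution is idempotent: a second call for the
#' same model reuses the cache without invoking the fetcher.
#'
#' @param metadata A `model_metadata` entry.
#' @param cache_dir Writable cache directory.
#' @param fetcher Function `uri -> raw bytes`; defaults to reading local
#'   files and `file://` URIs. Inject a spy to assert lazy loading, or a
#'   network client to support remote hosting.
#' @return A `model_package`: list with `root_dir`, `entry_script`,
#'   `generate_callable_name`, `weights_path`, `resolved_from`.
#' @export
resolve_package <- function(metadata, cache_dir, fetcher = NULL) {
  loc <- metadata$execution$package_location
  if (is.null(loc) || !nzchar(loc)) {
    stop_synthzoo(sprintf("model %s: execution.package_location missing",
                          metadata$model_id), "synthzoo_package_error")
  }
  fetcher <- fetcher %||% default_fetcher
  is_archive <- grepl("\\.(zip|tar|tar\\.gz|tgz)$", loc, ignore.case = TRUE)

  if (!is_archive) {
    root <- sub("^file://", "", loc)
    if (!dir.exists(root)) {
      stop_synthzoo(sprintf("model %s: package directory not found: %s",
                            metadata$model_id, root), "synthzoo_fetch_error")
    }
  } else {
    ensure_dir(cache_dir)
    root <- file.path(cache_dir, metadata$model_id)
    if (!length(find_entry_script(root))) {
      bytes <- tryCatch(fetcher(loc), error = function(e) {
        stop_synthzoo(sprintf("model %s: could not fetch %s: %s",
                              metadata$model_id, loc, conditionMessage(e)),
                      "synthzoo_fetch_error")
      })
      tmp <- tempfile(fileext = paste0(".", tools::file_ext(loc)))
      on.exit(unlink(tmp), add = TRUE)
      writeBin(bytes, tmp)
      ensure_dir(root)
      if (grepl("\\.zip$", loc, ignore.case = TRUE)) {
        utils::unzip(tmp, exdir = root)
      } else {
        utils::untar(tmp, exdir = root)
      }
    }
  }

  entry <- find_entry_script(root)
  if (!length(entry)) {
    stop_synthzoo(sprintf("model %s: package at %s has no %s entry script",
                          metadata$model_id, root, ENTRY_SCRIPT),
                  "synthzoo_package_layout_error")
  }
  pkg_root <- dirname(entry[1])

  weights <- ""
  wn <- metadata$execution$weights_name %||% ""
  we <- metadata$execution$weights_extension %||% ""
  if (nzchar(wn)) {
    wfile <- file.path(pkg_root, paste0(wn, we))
    if (file.exists(wfile)) weights <- wfile
  }

  structure(
    list(
      root_dir = pkg_root,
      entry_script = entry[1],
      generate_callable_name = metadata$execution$generate_method_name,
      weights_path = weights,
      resolved_from = loc
    ),
    class = "model_package"
  )
}

find_entry_script <- function(root) {
  if (!dir.exists(root)) return(character(0))
  hits <- list.files(root, pattern = paste0("^", ENTRY_SCRIPT, "$"),
                     recursive = TRUE, full.names = TRUE)
  hits[order(nchar(hits))]
}

default_fetcher <- function(uri) {
  path <- sub("^file://", "", uri)
  if (!file.exists(path)) stop(sprintf("unreachable location: %s", uri))
  readBin(path, "raw", n = file.info(path)$size)
}

# Source the entry script in an isolated environment and return the generate
# callable named in the metadata.
import_generate_callable <- function(pkg) {
  env <- new.env(parent = globalenv())
  sys.source(pkg$entry_script, envir = env)
  fn <- get0(pkg$generate_callable_name, envir = env, mode = "function")
  if (is.null(fn)) {
    stop_synthzoo(sprintf("entry script %s does not define function %s",
                          pkg$entry_script, deparse(pkg$generate_callable_name)),
                  "synthzoo_package_layout_error")
  }
  fn
}

#' Check (and optionally install) a model's declared dependencies
#'
#' Presence is probed by namespace availability only; version specifications
#' are carried through in the report but not enforced. With `install = TRUE`
#' the pluggable `installer` is invoked for the missing names only.
#'
#' @param metadata A `model_metadata` entry.
#' @param install Install missing dependencies via `installer`?
#' @param installer Function `name -> invisible`; defaults to an error,
#'   because unattended installation must be opted into explicitly.
#' @return A `dependency_report`: list with `required`, `satisfied`,
#'   `missing`, `installed_now` character vectors.
#' @export
check_dependencies <- function(metadata, install = FALSE, installer = NULL) {
  deps <- metadata$execution$dependencies %||% list()
  req <- vapply(deps, function(d) {
    if (is.list(d)) as.character(d$name %||% "") else as.character(d)
  }, character(1))
  ok <- vapply(req, function(p) requireNamespace(p, quietly = TRUE), logical(1))
  missing <- req[!ok]
  installed_now <- character(0)
  if (install && length(missing) > 0L) {
    if (is.null(installer)) {
      stop_synthzoo("install = TRUE requires an installer function",
                    "synthzoo_dependency_error")
    }
    for (p in missing) {
      tryCatch(installer(p), error = function(e) {
        stop_synthzoo(sprintf("failed to install dependency %s: %s",
                              p, conditionMessage(e)),
                      "synthzoo_dependency_error")
      })
      installed_now <- c(installed_now, p)
    }
  }
  structure(
    list(required = req, satisfied = req[ok], missing = missing,
         installed_now = installed_now),
    class = "dependency_report"
  )
}

# Normalize one model output to a sample item (image, mask, label, filename).
as_sample_item <- function(x, model_id, index) {
  if (is.list(x) && !is.null(x$image)) {
    item <- list(image = x$image, mask = x$mask, label = x$label)
  } else {
    item <- list(image = x, mask = NULL, label = NULL)
  }
  item$filename <- sprintf("%s_%06d.png", model_id, index)
  structure(item, class = "sample_item")
}

# Run one batch through the model callable with per-batch seed = base seed +
# global start index; the entry-point contract makes the model derive sample
# j's randomness from seed + j, which is what makes output independent of the
# chosen batch_size.
run_batch <- function(fn, pkg, model_id, n, batch_seed, args, batch_index) {
  call_args <- c(
    list(model_file = pkg$weights_path, num_samples = n,
         save_images = FALSE, output_path = NULL, seed = batch_seed),
    args
  )
  keep <- !duplicated(names(call_args))
  out <- tryCatch(
    do.call(fn, call_args[keep]),
    error = function(e) {
      stop_synthzoo(
        sprintf("model %s failed in batch %d: %s",
                model_id, batch_index, conditionMessage(e)),
        "synthzoo_execution_error", model_id = model_id, batch_index = batch_index
      )
    }
  )
  if (!is.list(out) || length(out) != n) {
    stop_synthzoo(sprintf("model %s batch %d: expected a list of %d sample(s)",
                          model_id, batch_index, n),
                  "synthzoo_execution_error")
  }
  out
}

#' Generate synthetic samples from a registered model
#'
#' Resolves and imports the model package, then produces exactly
#' `num_samples` samples in `ceiling(num_samples / batch_size)` batches. With
#' a fixed `seed` the full output is identical across runs and across
#' `batch_size` choices. When `save_images = TRUE`, images are written as
#' 8-bit PNGs named `{model_id}_{index:06d}.png` (masks as `_mask.png`
#' siblings) plus a `manifest.json` recording files, model id, and seed, and
#' only one batch of samples is held in memory at a time.
#'
#' @param registry A `synthzoo_registry`.
#' @param model_id Model id to run.
#' @param num_samples Number of samples to produce (>= 0).
#' @param batch_size Chunk size for generation (>= 1).
#' @param seed Optional integer base seed for deterministic output.
#' @param save_images Write PNGs instead of returning arrays?
#' @param output_path Output directory when `save_images = TRUE`.
#' @param extra_args Named list forwarded to the model's generate function
#'   (e.g. `input_latent_vector`, a condition label, `shift`).
#' @param cache_dir Package cache directory.
#' @param fetcher,installer Pluggable I/O hooks, see [resolve_package()] and
#'   [check_dependencies()].
#' @param install_dependencies Install missing model dependencies first?
#' @return List of `sample_item`s, or (with `save_images`) the character
#'   vector of written image paths.
#' @export
generate_samples <- function(registry, model_id, num_samples,
                             batch_size = 32L, seed = NULL,
                             save_images = FALSE, output_path = NULL,
                             extra_args = list(),
                             cache_dir = tempfile("synthzoo-cache-"),
                             fetcher = NULL, installer = NULL,
                             install_dependencies = FALSE) {
  if (num_samples < 0) {
    stop_synthzoo("num_samples must be >= 0", "synthzoo_argument_error")
  }
  if (batch_size < 1) {
    stop_synthzoo("batch_size must be >= 1", "synthzoo_argument_error")
  }
  metadata <- get_metadata(registry, model_id)
  if (install_dependencies) {
    check_dependencies(metadata, install = TRUE, installer = installer)
  }
  if (num_samples == 0L) {
    return(if (save_images) character(0) else list())
  }
  pkg <- resolve_package(metadata, cache_dir, fetcher = fetcher)
  fn <- import_generate_callable(pkg)
  base_seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  args <- utils::modifyList(as_generate_defaults(metadata), extra_args)

  if (save_images) {
    output_path <- output_path %||% file.path(tempdir(), "synthzoo-samples", model_id)
    ensure_dir(output_path)
  }

  results <- if (save_images) character(0) else vector("list", num_samples)
  starts <- seq(0L, num_samples - 1L, by = batch_size)
  for (b in seq_along(starts)) {
    start <- starts[b]
    n <- min(batch_size, num_samples - start)
    out <- run_batch(fn, pkg, model_id, n, base_seed + start, args, b)
    items <- lapply(seq_len(n), function(j) {
      as_sample_item(out[[j]], model_id, start + j - 1L)
    })
    if (save_images) {
      results <- c(results, vapply(items, function(it) {
        p <- file.path(output_path, it$filename)
        write_image(it$image, p)
        if (!is.null(it$mask)) {
          write_image(it$mask, sub("\\.png$", "_mask.png", p))
        }
        p
      }, character(1)))
    } else {
      results[start + seq_len(n)] <- items
    }
  }

  if (save_images) {
    jsonlite::write_json(
      list(model_id = model_id, seed = base_seed,
           files = basename(results)),
      file.path(output_path, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  results
}

as_generate_defaults <- function(metadata) {
  args <- metadata$execution$generate_args %||% list()
  if (!is.list(args)) args <- as.list(args)
  args
}

#' Build a reusable generate callable for one model
#'
#' The returned closure resolves and imports the package once; invoking it
#' never re-resolves. Call-time named arguments override the frozen defaults.
#'
#' @inheritParams generate_samples
#' @param frozen_defaults Named list of generate arguments fixed into the
#'   closure.
#' @return Function `(num_samples, seed = NULL, ...) -> list of sample_item`.
#' @export
get_generate_callable <- function(registry, model_id,
                                  cache_dir = tempfile("synthzoo-cache-"),
                                  frozen_defaults = list(), fetcher = NULL) {
  metadata <- get_metadata(registry, model_id)
  pkg <- resolve_package(metadata, cache_dir, fetcher = fetcher)
  fn <- import_generate_callable(pkg)
  defaults <- utils::modifyList(as_generate_defaults(metadata), frozen_defaults)
  force(model_id)
  function(num_samples, seed = NULL, ...) {
    if (num_samples == 0L) return(list())
    args <- utils::modifyList(defaults, list(...))
    base_seed <- seed %||% sample.int(.Machine$integer.max, 1L)
    out <- run_batch(fn, pkg, model_id, num_samples, base_seed, args, 1L)
    lapply(seq_len(num_samples), function(j) {
      as_sample_item(out[[j]], model_id, j - 1L)
    })
  }
}

#' Expose a model as a batch iterator for training loops
#'
#' Yields lists of `sample_item`s of size `batch_size`; infinite by default,
#' or stopping after `length` samples (last batch possibly smaller). Batches
#' are seeded from `seed` plus the running sample index, so reconstruction
#' with the same seed replays the same stream.
#'
#' @inheritParams generate_samples
#' @param transform Optional function applied to each `sample_item`.
#' @param length Optional total number of samples (finite iterator).
#' @return A `batch_iterator`: list with `next_batch()` (returns `NULL` when
#'   exhausted) and `reset()`.
#' @export
as_batch_iterator <- function(registry, model_id, batch_size = 32L,
                              seed = NULL, transform = NULL, length = NULL,
                              cache_dir = tempfile("synthzoo-cache-"),
                              fetcher = NULL) {
  if (batch_size < 1) {
    stop_synthzoo("batch_size must be >= 1", "synthzoo_argument_error")
  }
  gen <- get_generate_callable(registry, model_id, cache_dir = cache_dir,
                               fetcher = fetcher)
  base_seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  pos <- 0L
  next_batch <- function() {
    if (!is.null(length) && pos >= length) return(NULL)
    n <- if (is.null(length)) batch_size else min(batch_size, length - pos)
    items <- gen(n, seed = base_seed + pos)
    if (!is.null(transform)) items <- lapply(items, transform)
    pos <<- pos + n
    items
  }
  structure(
    list(next_batch = next_batch, reset = function() pos <<- 0L,
         batch_size = batch_size, length = length),
    class = "batch_iterator"
  )
}
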