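# Contribution workflow: validate a user's model package, assemble its
# metadata entry, smoke-test its generation capability, then register,
# archive, and hand it to a Publisher. Publishing is a pluggable contract
# whose default implementation is purely local, so the whole workflow runs
# offline; real deposition backends implement the same two functions.

#' Validate a contribution request
#'
#' Checks the model id pattern, the entry-script path (must exist and end in
#' the entry-script filename convention), that the script is sourceable, that
#' it defines the named generate method, and that the method accepts the
#' synthetic-data storage path parameter (`output_path`). Violations are
#' returned, not raised.
#'
#' @param request A list with `model_id`, `init_script_path`,
#'   `generate_method_name`, and optionally `weights_name`,
#'   `weights_extension`, `dependencies`, `extra_metadata`.
#' @return Character vector of violations; empty when the request is valid.
#' @export
validate_contribution <- function(request) {
  v <- character(0)
  if (!is_valid_model_id(request$model_id %||% "")) {
    v <- c(v, sprintf("model_id: must match pattern %s", MODEL_ID_PATTERN))
  }
  path <- request$init_script_path %||% ""
  if (!nzchar(path) || !file.exists(path)) {
    v <- c(v, sprintf("init_script_path: entry script not found at %s", deparse(path)))
    return(v)
  }
  if (basename(path) != ENTRY_SCRIPT) {
    v <- c(v, sprintf("init_script_path: entry script must be named %s", ENTRY_SCRIPT))
  }
  env <- new.env(parent = globalenv())
  src_ok <- tryCatch({ sys.source(path, envir = env); TRUE },
                     error = function(e) {
                       v <<- c(v, sprintf("init_script_path: entry script fails to source: %s",
                                          conditionMessage(e)))
                       FALSE
                     })
  if (src_ok) {
    gmn <- request$generate_method_name %||% "generate"
    fn <- get0(gmn, envir = env, mode = "function")
    if (is.null(fn)) {
      v <- c(v, sprintf("generate_method_name: entry script defines no function %s",
                        deparse(gmn)))
    } else if (!"output_path" %in% names(formals(fn))) {
      v <- c(v, "generate_method_name: generate method lacks the output_path parameter")
    }
  }
  v
}

#' Assemble a registry entry from a contribution request
#'
#' Builds the three-section metadata entry, filling description defaults
#' (date defaults to today, ISO-8601) and copying a measured performance map
#' into the selection section. The request must validate first.
#'
#' @inheritParams validate_contribution
#' @param measured Optional named performance map, e.g. `list(FID = 12.3)`.
#' @param image_size Declared output size `(H, W, C)`.
#' @param latent_dim Declared latent dimension (0 for image-to-image models).
#' @return A `model_metadata` entry with zero validation violations.
#' @export
build_metadata_entry <- function(request, measured = NULL,
                                 image_size = c(64L, 64L, 1L), latent_dim = 0L) {
  viol <- validate_contribution(request)
  if (length(viol) > 0L) {
    stop_synthzoo(paste0("contribution request is invalid:\n  ",
                         paste(viol, collapse = "\n  ")),
                  "synthzoo_state_error")
  }
  extra <- request$extra_metadata %||% list()
  desc <- utils::modifyList(
    list(
      title = paste("Contributed model", request$model_id),
      modality = "unspecified",
      output_type = "image",
      training_dataset = "unspecified",
      license = "unspecified",
      date = format(Sys.Date(), "%Y-%m-%d"),
      publication = ""
    ),
    extra$description %||% list()
  )
  sel <- list(
    performance = measured %||% (extra$selection$performance %||%
                                   structure(list(), names = character(0))),
    keywords = extra$selection$keywords %||% list()
  )
  as_model_metadata(request$model_id, list(
    execution = list(
      package_location = dirname(request$init_script_path),
      package_name = request$model_id,
      weights_name = request$weights_name %||% "",
      weights_extension = request$weights_extension %||% "",
      dependencies = as.list(request$dependencies %||% list()),
      generate_method_name = request$generate_method_name %||% "generate",
      generate_args = extra$generate_args %||% structure(list(), names = character(0)),
      image_size = as.integer(image_size),
      latent_dim = as.integer(latent_dim),
      value_range = c(0, 255)
    ),
    selection = sel,
    description = desc
  ))
}

#' End-to-end smoke test of a model's generation capability
#'
#' Resolves the package and generates 3 samples into a temporary directory,
#' checking sample count, spatial dimensions against the declared
#' `image_size`, and value range against the declared `value_range`. Every
#' check (and any captured generation failure) is recorded in the log.
#'
#' @param entry A `model_metadata` entry.
#' @param cache_dir Package cache directory.
#' @return Logical pass/fail with attribute `log` (character vector).
#' @export
test_model <- function(entry, cache_dir = tempfile("synthzoo-cache-")) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  registry <- structure(
    list(entries = stats::setNames(list(entry), entry$model_id),
         source = "<in-memory>", schema_version = "1.0"),
    class = "synthzoo_registry"
  )
  items <- tryCatch(
    generate_samples(registry, entry$model_id, 3L, seed = 1L, cache_dir = cache_dir),
    error = function(e) {
      note("generation failed: %s", conditionMessage(e))
      NULL
    }
  )
  if (is.null(items)) {
    return(structure(FALSE, log = log))
  }
  ok <- TRUE
  check <- function(cond, what) {
    note("%s: %s", what, if (cond) "ok" else "FAIL")
    ok <<- ok && cond
  }
  check(length(items) == 3L, "sample count equals 3")
  want <- as.integer(entry$execution$image_size %||% c(NA, NA, NA))
  rng <- as.numeric(entry$execution$value_range %||% c(0, 255))
  for (i in seq_along(items)) {
    d <- image_dims(items[[i]]$image)
    check(!anyNA(want) && all(d == want),
          sprintf("sample %d dimensions %s match declared %s", i,
                  paste(d, collapse = "x"), paste(want, collapse = "x")))
    mn <- min(items[[i]]$image)
    mx <- max(items[[i]]$image)
    check(mn >= rng[1] - 1e-9 && mx <= rng[2] + 1e-9,
          sprintf("sample %d values within declared range [%g, %g]", i, rng[1], rng[2]))
    if (!is.null(items[[i]]$mask)) {
      md <- image_dims(items[[i]]$mask)
      check(all(md[1:2] == d[1:2]),
            sprintf("sample %d mask spatially congruent with image", i))
    }
  }
  structure(ok, log = log)
}

#' Default filesystem publisher
#'
#' Copies the package archive and the contribution notice into a local
#' directory and returns a deterministic receipt string. Network-backed
#' deposition services implement the same `publish(archive, notice)` contract.
#'
#' @param dir Directory receiving published artifacts.
#' @return A publisher: list with `publish(archive_path, notice_path)`.
#' @export
local_publisher <- function(dir) {
  ensure_dir(dir)
  list(publish = function(archive_path, notice_path) {
    file.copy(c(archive_path, notice_path), dir, overwrite = TRUE)
    sprintf("local:%s/%s", normalizePath(dir), basename(archive_path))
  })
}

#' Register, archive, and publish a tested contribution
#'
#' Appends the entry to the registry file (append-only: a duplicate id is a
#' conflict and the registry is left untouched; a failed write is rolled
#' back), archives the model package (entry script, weights, license,
#' requirements manifest, in deterministic member order) as `.tar.gz`, emits
#' a JSON contribution notice mirroring the metadata entry, and delegates
#' publishing to the supplied publisher (default: local filesystem).
#'
#' @param entry A `model_metadata` entry whose [test_model()] run passed.
#' @param registry_path Path to the registry JSON file to append to.
#' @param package_dir Directory of the model package to archive.
#' @param out_dir Directory for the archive and notice (default: alongside
#'   the registry).
#' @param publisher A publisher contract; see [local_publisher()].
#' @param test_result Result of [test_model()]; re-run when omitted. A
#'   failing test blocks registration.
#' @return A `contribution_result`: list with `metadata_entry`,
#'   `package_archive`, `notice_path`, `test_passed`, `publish_receipt`.
#' @export
register_and_package <- function(entry, registry_path, package_dir,
                                 out_dir = NULL, publisher = NULL,
                                 test_result = NULL) {
  if (is.null(test_result)) test_result <- test_model(entry)
  if (!isTRUE(as.logical(test_result))) {
    stop_synthzoo("model failed its generation smoke test; not registering",
                  "synthzoo_state_error")
  }
  registry <- load_registry(registry_path)
  if (entry$model_id %in% names(registry$entries)) {
    stop_synthzoo(sprintf("model id %s already registered", entry$model_id),
                  "synthzoo_conflict_error")
  }
  out_dir <- out_dir %||% dirname(registry_path)
  ensure_dir(out_dir)

  # archive with deterministic member order
  members <- sort(list.files(package_dir, recursive = TRUE))
  archive <- file.path(out_dir, paste0(entry$model_id, ".tar.gz"))
  old_wd <- getwd()
  on.exit(setwd(old_wd), add = TRUE)
  setwd(package_dir)
  utils::tar(archive, files = members, compression = "gzip", tar = "internal")
  setwd(old_wd)

  notice <- file.path(out_dir, paste0(entry$model_id, "_contribution.json"))
  jsonlite::write_json(
    list(model_id = entry$model_id,
         metadata = list(execution = entry$execution, selection = entry$selection,
                         description = entry$description),
         archive = basename(archive)),
    notice, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  # append-only registry update with rollback on write failure
  backup <- paste0(registry_path, ".bak")
  file.copy(registry_path, backup, overwrite = TRUE)
  registry$entries[[entry$model_id]] <- entry
  ok <- tryCatch({ write_registry(registry, registry_path); TRUE },
                 error = function(e) FALSE)
  if (!ok) {
    file.copy(backup, registry_path, overwrite = TRUE)
    unlink(backup)
    stop_synthzoo("registry write failed; previous registry restored",
                  "synthzoo_io_error")
  }
  unlink(backup)

  publisher <- publisher %||% local_publisher(file.path(out_dir, "published"))
  receipt <- publisher$publish(archive, notice)

  structure(
    list(metadata_entry = entry, package_archive = archive,
         notice_path = notice, test_passed = TRUE, publish_receipt = receipt),
    class = "contribution_result"
  )
}
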