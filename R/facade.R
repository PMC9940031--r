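#' Create the model-zoo facade
#'
#' Single access point composing registry, search/rank, execution,
#' evaluation, exploration, and contribution. Construction performs no I/O:
#' the registry is loaded lazily on first use (and then cached), and model
#' packages are resolved only when a model is first generated from or
#' explored.
#'
#' @param registry_source Path or `file://` URI of the registry JSON file.
#' @param cache_dir Model package cache directory.
#' @param samples_dir Default output directory for saved samples.
#' @param default_batch_size Default generation chunk size.
#' @param fetcher Optional pluggable fetcher passed to the executor.
#' @return A `model_zoo` facade object.
#' @export
model_zoo <- function(registry_source,
                      cache_dir = file.path(tempdir(), "synthzoo-cache"),
                      samples_dir = file.path(tempdir(), "synthzoo-samples"),
                      default_batch_size = 32L,
                      fetcher = NULL) {
  state <- new.env(parent = emptyenv())
  state$registry <- NULL
  structure(
    list(registry_source = registry_source, cache_dir = cache_dir,
         samples_dir = samples_dir, default_batch_size = default_batch_size,
         fetcher = fetcher, state = state),
    class = "model_zoo"
  )
}

#' Access (and lazily load) the facade's registry
#'
#' @param zoo A `model_zoo`.
#' @return The cached `synthzoo_registry`, loading it on first call.
#' @export
zoo_registry <- function(zoo) {
  if (is.null(zoo$state$registry)) {
    zoo$state$registry <- load_registry(zoo$registry_source)
  }
  zoo$state$registry
}

#' @describeIn model_zoo Keyword search over the zoo's metadata.
#' @param values,operator See [find_matching_models()].
#' @export
find_model <- function(zoo, values, operator = "OR") {
  find_matching_models(zoo_registry(zoo), values, operator)
}

#' @describeIn model_zoo Rank zoo models by a performance metric.
#' @param metric_key,order,model_ids See [rank_models_by_performance()].
#' @export
rank_models <- function(zoo, metric_key = "FID", order = NULL, model_ids = NULL) {
  rank_models_by_performance(zoo_registry(zoo), model_ids = model_ids,
                             metric_key = metric_key, order = order)
}

#' @describeIn model_zoo Generate samples from one zoo model.
#' @param model_id,num_samples,batch_size,seed,save_images,output_path,extra_args
#'   See [generate_samples()].
#' @export
generate <- function(zoo, model_id, num_samples, batch_size = NULL, seed = NULL,
                     save_images = FALSE, output_path = NULL,
                     extra_args = list()) {
  generate_samples(
    zoo_registry(zoo), model_id, num_samples,
    batch_size = batch_size %||% zoo$default_batch_size, seed = seed,
    save_images = save_images,
    output_path = output_path %||% (if (save_images) file.path(zoo$samples_dir, model_id)),
    extra_args = extra_args, cache_dir = zoo$cache_dir, fetcher = zoo$fetcher
  )
}

#' Search, rank, and generate from the best-ranked match
#'
#' Composes keyword search, metric ranking, and generation: the top-ranked
#' matching model generates. Zero matches is an error and nothing is
#' generated.
#'
#' @inheritParams generate
#' @param values,operator Search query, see [find_matching_models()].
#' @param metric_key,order Ranking, see [rank_models_by_performance()].
#' @return List with `model_id` (the chosen model), `ranking` (the full rank
#'   table over matches), and `samples` (the generation result).
#' @export
find_models_rank_and_generate <- function(zoo, values, operator = "OR",
                                          metric_key = "FID", order = NULL,
                                          num_samples = 1L, seed = NULL,
                                          save_images = FALSE, output_path = NULL,
                                          extra_args = list()) {
  ranked <- find_and_rank(zoo_registry(zoo), values, operator, metric_key, order)
  if (nrow(ranked) == 0L) {
    stop_synthzoo(sprintf("no model matches query [%s] with operator %s",
                          paste(values, collapse = ", "), operator),
                  "synthzoo_no_match_error")
  }
  chosen <- ranked$model_id[1]
  message(sprintf("synthzoo: generating from top-ranked model %s (%s = %s)",
                  chosen, metric_key, format(ranked$value[1])))
  samples <- generate(zoo, chosen, num_samples, seed = seed,
                      save_images = save_images, output_path = output_path,
                      extra_args = extra_args)
  list(model_id = chosen, ranking = ranked, samples = samples)
}

#' @describeIn model_zoo Batch iterator over one zoo model (training-loop
#'   adapter).
#' @param transform,length See [as_batch_iterator()].
#' @export
get_as_batch_iterator <- function(zoo, model_id, batch_size = NULL, seed = NULL,
                                  transform = NULL, length = NULL) {
  as_batch_iterator(zoo_registry(zoo), model_id,
                    batch_size = batch_size %||% zoo$default_batch_size,
                    seed = seed, transform = transform, length = length,
                    cache_dir = zoo$cache_dir, fetcher = zoo$fetcher)
}

#' @describeIn model_zoo Initialize a latent-exploration state for one model.
#' @param group_size Latent dimensions per slider.
#' @param condition Optional condition label.
#' @export
explore <- function(zoo, model_id, group_size = 10L, seed = 1L, condition = NULL) {
  init_state(zoo_registry(zoo), model_id, group_size = group_size, seed = seed,
             condition = condition)
}

#' @describeIn model_zoo Evaluate one zoo model (FIDrr, FIDrs, rFID).
#' @param real_set,n_syn,extractor,normalize See [evaluate_model()].
#' @export
evaluate <- function(zoo, model_id, real_set, n_syn = length(real_set),
                     extractor = toy_feature_extractor(), normalize = "none",
                     seed = 1L, extra_args = list()) {
  evaluate_model(zoo_registry(zoo), model_id, real_set, n_syn = n_syn,
                 extractor = extractor, normalize = normalize, seed = seed,
                 cache_dir = zoo$cache_dir, extra_args = extra_args)
}

#' @describeIn model_zoo Contribute a model package to this zoo's registry:
#'   validate, build metadata, smoke-test, then register/archive/publish.
#' @param request,measured,image_size,latent_dim,publisher,out_dir See
#'   [validate_contribution()], [build_metadata_entry()], and
#'   [register_and_package()].
#' @export
contribute <- function(zoo, request, measured = NULL,
                       image_size = c(64L, 64L, 1L), latent_dim = 0L,
                       publisher = NULL, out_dir = NULL) {
  viol <- validate_contribution(request)
  if (length(viol) > 0L) {
    stop_synthzoo(paste0("contribution request is invalid:\n  ",
                         paste(viol, collapse = "\n  ")),
                  "synthzoo_state_error")
  }
  entry <- build_metadata_entry(request, measured = measured,
                                image_size = image_size, latent_dim = latent_dim)
  test_result <- test_model(entry, cache_dir = zoo$cache_dir)
  if (!isTRUE(as.logical(test_result))) {
    stop_synthzoo(paste0("model failed its generation smoke test:\n  ",
                         paste(attr(test_result, "log"), collapse = "\n  ")),
                  "synthzoo_state_error")
  }
  source_path <- sub("^file://", "", zoo$registry_source)
  result <- register_and_package(entry, source_path,
                                 dirname(request$init_script_path),
                                 out_dir = out_dir, publisher = publisher,
                                 test_result = test_result)
  zoo$state$registry <- NULL  # invalidate cache; registry file changed
  result
}

#' @export
print.model_zoo <- function(x, ...) {
  loaded <- !is.null(x$state$registry)
  cat(sprintf("<model_zoo: registry %s (%s), cache %s>\n",
              x$registry_source,
              if (loaded) sprintf("%d model(s) loaded", length(x$state$registry$entries))
              else "not yet loaded",
              x$cache_dir))
  invisible(x)
}
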