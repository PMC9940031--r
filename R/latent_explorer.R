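# Headless state machine for latent-space exploration. Every operation
# returns a new state; a GUI (if any) is a thin binding over these functions.

slider_groups <- function(d, n) {
  unname(split(seq_len(d), ceiling(seq_len(d) / n)))
}

recompute_sliders <- function(z, n) {
  unname(vapply(slider_groups(length(z), n), function(idx) mean(z[idx]), numeric(1)))
}

#' Initialize a latent-exploration state
#'
#' Draws a standard-normal latent vector of the model's declared dimension
#' from `seed` and groups every `group_size` consecutive dimensions into one
#' slider (ceiling(d / group_size) sliders; slider values initialize to their
#' group's mean). Models without a latent input (pure image-to-image) are
#' rejected.
#'
#' @param registry A `synthzoo_registry`.
#' @param model_id Model to explore; its metadata must declare
#'   `execution.latent_dim > 0`.
#' @param group_size Latent dimensions per slider (>= 1).
#' @param seed Seed for the initial latent draw.
#' @param condition Optional condition label forwarded at render time.
#' @return An `explorer_state`: list with `model_id`, `z`, `group_size`,
#'   `sliders`, `last_seeded_z`, `condition`, `seed`.
#' @export
init_state <- function(registry, model_id, group_size = 10L, seed = 1L,
                       condition = NULL) {
  metadata <- get_metadata(registry, model_id)
  d <- metadata$execution$latent_dim %||% 0L
  if (d < 1L) {
    stop_synthzoo(sprintf("model %s declares no latent input; exploration unsupported",
                          model_id), "synthzoo_unsupported_model_error")
  }
  if (group_size < 1L) {
    stop_synthzoo("group_size must be >= 1", "synthzoo_argument_error")
  }
  z <- with_seed(seed, stats::rnorm(d))
  structure(
    list(model_id = model_id, z = z, group_size = as.integer(group_size),
         sliders = recompute_sliders(z, group_size), last_seeded_z = z,
         condition = condition, seed = as.integer(seed)),
    class = "explorer_state"
  )
}

#' Set one slider, moving its whole latent group
#'
#' Sets every latent dimension in group `index` to `value`; all other
#' dimensions are untouched. States are immutable: a new state is returned.
#'
#' @param state An `explorer_state`.
#' @param index Slider index (1-based), `1 <= index <= ceiling(d/n)`.
#' @param value New value for the group's dimensions.
#' @return New `explorer_state`.
#' @export
set_slider <- function(state, index, value) {
  groups <- slider_groups(length(state$z), state$group_size)
  if (index < 1L || index > length(groups)) {
    stop_synthzoo(sprintf("slider index %d out of range 1..%d", index, length(groups)),
                  "synthzoo_argument_error")
  }
  state$z[groups[[index]]] <- value
  state$sliders <- recompute_sliders(state$z, state$group_size)
  state
}

#' Draw a fresh latent vector from a new seed
#'
#' Replaces `z` with a fresh standard-normal draw; the reseeded vector also
#' becomes the new reset target.
#'
#' @param state An `explorer_state`.
#' @param new_seed Integer seed for the fresh draw.
#' @return New `explorer_state`.
#' @export
reseed <- function(state, new_seed) {
  z <- with_seed(new_seed, stats::rnorm(length(state$z)))
  state$z <- z
  state$last_seeded_z <- z
  state$sliders <- recompute_sliders(z, state$group_size)
  state$seed <- as.integer(new_seed)
  state
}

#' Revert slider edits to the last seeded latent vector
#'
#' @param state An `explorer_state`.
#' @return New `explorer_state` with `z` restored to `last_seeded_z`.
#' @export
reset_state <- function(state) {
  state$z <- state$last_seeded_z
  state$sliders <- recompute_sliders(state$z, state$group_size)
  state
}

#' Render the current latent vector through the model
#'
#' Generates one sample with `input_latent_vector = state$z` (and the state's
#' condition, if set). Deterministic for a fixed state.
#'
#' @param state An `explorer_state`.
#' @param registry A `synthzoo_registry`.
#' @param cache_dir Package cache directory.
#' @param fetcher Optional fetcher passed to the executor.
#' @return A `sample_item` (with `mask` when the model emits one).
#' @export
render_state <- function(state, registry,
                         cache_dir = tempfile("synthzoo-cache-"), fetcher = NULL) {
  extra <- list(input_latent_vector = state$z)
  if (!is.null(state$condition)) extra$condition <- state$condition
  generate_samples(registry, state$model_id, 1L, seed = state$seed,
                   extra_args = extra, cache_dir = cache_dir,
                   fetcher = fetcher)[[1]]
}

#' @export
print.explorer_state <- function(x, ...) {
  cat(sprintf("<explorer state: model %s, d=%d, %d slider(s) of group size %d>\n",
              x$model_id, length(x$z), length(x$sliders), x$group_size))
  cat("sliders:", paste(sprintf("%.3f", x$sliders), collapse = " "), "\n")
  invisible(x)
}
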