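# Shared fixtures: a small separable synthetic session and a regressor
# trained on it, built once per test run and reused across files.

fixture_cache <- new.env(parent = emptyenv())

fixture_params <- function(seed = 7, overlap = 0, noise = 0.02) {
  generator_params(seed = seed, overlap = overlap, noise = noise)
}

fixture_movements <- c("hand_open", "fine_pinch")

fixture_session <- function() {
  if (is.null(fixture_cache$session)) {
    fixture_cache$session <- generate_session(
      fixture_params(), fixture_movements, n_procedures = 2)
  }
  fixture_cache$session
}

fixture_model <- function() {
  if (is.null(fixture_cache$model)) {
    recs <- unlist(lapply(fixture_session(), `[[`, "recordings"),
                   recursive = FALSE)
    fixture_cache$model <- fit_movement_regressor(
      recs, fixture_movements, train_config(seed = 1, max_epochs = 100))
  }
  fixture_cache$model
}

# a window matrix with the same values in every channel
uniform_window <- function(values, n_channels = 8) {
  matrix(rep(values, n_channels), length(values), n_channels)
}

named_cmd <- function(pinch = 0, rotation = 0, flex_ext = 0, open = 0) {
  c(pinch = pinch, rotation = rotation, flex_ext = flex_ext, open = open)
}
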