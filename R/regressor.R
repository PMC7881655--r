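# Feed-forward regressor: 32 -> 50 -> 25 -> K, tanh/tanh/linear, trained with
# minibatch Adam on an MSE loss with early stopping. Written in plain matrix
# algebra so the trained weights serialize to portable JSON.

#' Training configuration for the movement regressor
#'
#' @param batch_size Minibatch size (windows per gradient step).
#' @param validation_fraction Fraction of the training windows held out for
#'   early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param max_epochs Hard epoch cap.
#' @param learning_rate Adam step size.
#' @param seed Integer RNG seed; mandatory — weight init, the validation split
#'   and minibatch shuffling all draw from it, so training is reproducible.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64L, validation_fraction = 0.10,
                         patience = 10L, max_epochs = 500L,
                         learning_rate = 1e-3, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("train_config requires an explicit integer seed")
  }
  stopifnot(batch_size >= 1, validation_fraction >= 0, validation_fraction < 1,
            patience >= 1, max_epochs >= 1, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

# run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

mlp_forward <- function(par, X) {
  H1 <- tanh(X %*% par$W1 + matrix(par$b1, nrow(X), length(par$b1), byrow = TRUE))
  H2 <- tanh(H1 %*% par$W2 + matrix(par$b2, nrow(X), length(par$b2), byrow = TRUE))
  Y <- H2 %*% par$W3 + matrix(par$b3, nrow(X), length(par$b3), byrow = TRUE)
  list(H1 = H1, H2 = H2, Y = Y)
}

mlp_grad <- function(par, X, Y) {
  fw <- mlp_forward(par, X)
  n <- nrow(X)
  dY <- 2 * (fw$Y - Y) / (n * ncol(Y))          # d MSE / d output
  dW3 <- crossprod(fw$H2, dY)
  db3 <- colSums(dY)
  dH2 <- (dY %*% t(par$W3)) * (1 - fw$H2^2)
  dW2 <- crossprod(fw$H1, dH2)
  db2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(par$W2)) * (1 - fw$H1^2)
  dW1 <- crossprod(X, dH1)
  db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

mse <- function(par, X, Y) mean((mlp_forward(par, X)$Y - Y)^2)

#' Per-window regression targets from the reference trace
#'
#' Each window's target is a vector over the trained movements: the reference
#' force (fraction of MVC) evaluated at the window's last sample on the
#' prompted movement's output, 0 elsewhere. Rest recordings yield all-zero
#' targets; MVC baselines target their `mvc_for` movement.
#'
#' @param recording An [emg_recording()] with an aligned reference trace.
#' @param movements Character vector of trained movement labels (output order).
#' @param window_ms,step_ms Windowing as in [segment_windows()].
#' @return Numeric matrix, one row per window, one column per movement.
#' @export
make_targets <- function(recording, movements, window_ms = 128, step_ms = 50) {
  stopifnot(inherits(recording, "emg_recording"))
  mv <- if (recording$movement == "mvc") recording$mvc_for else recording$movement
  if (mv != "rest" && !mv %in% movements) {
    stop("recording movement '", mv, "' is not in the trained movement list")
  }
  W <- as.integer(round(window_ms * recording$fs / 1000))
  S <- as.integer(round(step_ms * recording$fs / 1000))
  N <- nrow(recording$signal)
  if (N < W) return(matrix(numeric(0), 0, length(movements),
                           dimnames = list(NULL, movements)))
  starts <- seq.int(0L, N - W, by = S)
  targets <- matrix(0, length(starts), length(movements),
                    dimnames = list(NULL, movements))
  if (mv != "rest") {
    targets[, mv] <- recording$reference[starts + W]
  }
  targets
}

#' Train the movement-strength regressor
#'
#' Fits the 32-50-25-K network (tanh hidden activations, linear output) by
#' minibatch Adam on a mean-squared-error loss, with early stopping on a
#' randomly held-out validation split. The returned model carries the weights
#' of the best validation epoch, the full loss history, the movement list and
#' (optionally) the frozen feature normalizer.
#'
#' @param features Numeric matrix of (normalized) feature vectors, one window
#'   per row.
#' @param targets Numeric matrix of per-window target vectors (one column per
#'   movement).
#' @param config A [train_config()].
#' @param movements Movement labels for the output columns; defaults to the
#'   column names of `targets`.
#' @param normalizer Optional `emg_normalizer` stored with the model.
#' @return An object of class `emg_regressor`.
#' @export
train_regressor <- function(features, targets, config,
                            movements = colnames(targets), normalizer = NULL) {
  stopifnot(inherits(config, "train_config"))
  X <- as.matrix(features); Y <- as.matrix(targets)
  if (nrow(X) != nrow(Y)) stop("features and targets row mismatch")
  if (is.null(movements)) movements <- paste0("out", seq_len(ncol(Y)))
  n <- nrow(X); d <- ncol(X); K <- ncol(Y)

  with_local_seed(config$seed, {
    n_val <- floor(n * config$validation_fraction)
    idx <- sample.int(n)
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[setdiff(seq_len(n), seq_len(n_val))]
    if (length(tr_idx) < 2L) {
      stop("fewer than 2 training windows remain after the validation split")
    }
    Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]; Yval <- Y[val_idx, , drop = FALSE]

    par <- list(W1 = glorot(d, 50L), b1 = numeric(50L),
                W2 = glorot(50L, 25L), b2 = numeric(25L),
                W3 = glorot(25L, K), b3 = numeric(K))
    m <- lapply(par, function(p) p * 0)
    v <- lapply(par, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
    t_step <- 0L

    val_loss <- function(p) if (n_val > 0) mse(p, Xval, Yval) else mse(p, Xtr, Ytr)
    best <- list(par = par, loss = val_loss(par), epoch = 0L)
    history <- data.frame(epoch = integer(), train_mse = numeric(),
                          val_mse = numeric())
    stall <- 0L
    ntr <- nrow(Xtr)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(ntr)
      for (start in seq(1L, ntr, by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, ntr)]
        g <- mlp_grad(par, Xtr[rows, , drop = FALSE], Ytr[rows, , drop = FALSE])
        t_step <- t_step + 1L
        for (nm in names(par)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- m[[nm]] / (1 - b1^t_step)
          vhat <- v[[nm]] / (1 - b2^t_step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      vl <- val_loss(par)
      history <- rbind(history, data.frame(
        epoch = epoch, train_mse = mse(par, Xtr, Ytr), val_mse = vl))
      if (vl < best$loss - 1e-12) {
        best <- list(par = par, loss = vl, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }

    best$par <- lapply(best$par, unname)  # keep serialization name-free
    structure(list(par = best$par,
                   layer_sizes = c(d, 50L, 25L, K),
                   activations = c("tanh", "tanh", "linear"),
                   movements = movements,
                   normalizer = normalizer,
                   config = config,
                   best_epoch = best$epoch,
                   best_val_mse = best$loss,
                   history = history),
              class = "emg_regressor")
  })
}

#' @export
print.emg_regressor <- function(x, ...) {
  cat(sprintf("<emg_regressor> %s | outputs: %s | best epoch %d (val MSE %.4g)\n",
              paste(x$layer_sizes, collapse = "-"),
              paste(x$movements, collapse = ", "),
              x$best_epoch, x$best_val_mse))
  invisible(x)
}

#' Predict nonnegative movement strengths
#'
#' Runs the forward pass and rectifies negative raw outputs to 0, giving one
#' nonnegative strength (in MVC-fraction units) per trained movement.
#'
#' @param model An `emg_regressor`.
#' @param features A normalized feature vector, or a matrix of them (one per
#'   row). If the model carries a normalizer and `features` is flagged as
#'   unnormalized, it is normalized first.
#' @return Named strength vector, or a matrix with one row per input row.
#' @export
predict_strengths <- function(model, features) {
  stopifnot(inherits(model, "emg_regressor"))
  single <- !is.matrix(features)
  X <- if (single) matrix(as.numeric(features), 1L) else as.matrix(features)
  if (ncol(X) != model$layer_sizes[1]) {
    stop("feature dimension ", ncol(X), " does not match model input ",
         model$layer_sizes[1])
  }
  if (!is.null(model$normalizer) && !isTRUE(attr(features, "normalized"))) {
    X <- apply_normalizer(model$normalizer, X)
  }
  out <- pmax(mlp_forward(model$par, X)$Y, 0)
  colnames(out) <- model$movements
  if (single) out[1L, ] else out
}

#' End-to-end model fit from recordings
#'
#' Convenience pipeline: window every recording, extract Hudgins features, fit
#' the z-normalizer on the pooled features, build reference-trace targets and
#' train the regressor.
#'
#' @param recordings List of [emg_recording()] objects (graded trials, MVC
#'   baselines and rest trials all contribute windows).
#' @param movements Trained movement labels (output order).
#' @param config A [train_config()].
#' @param window_ms,step_ms Windowing parameters.
#' @param zc_threshold,ssc_threshold Feature deadbands.
#' @return An `emg_regressor` with its normalizer attached.
#' @export
fit_movement_regressor <- function(recordings, movements, config,
                                   window_ms = 128, step_ms = 50,
                                   zc_threshold = 0, ssc_threshold = 0) {
  feats <- list(); targs <- list()
  for (rec in recordings) {
    w <- segment_windows(rec, window_ms, step_ms)
    if (length(w) == 0L) next
    feats[[length(feats) + 1L]] <- feature_matrix(w, zc_threshold, ssc_threshold)
    targs[[length(targs) + 1L]] <- make_targets(rec, movements, window_ms, step_ms)
  }
  X <- do.call(rbind, feats)
  Y <- do.call(rbind, targs)
  if (is.null(X) || nrow(X) < 2L) stop("not enough windows to train on")
  norm <- fit_normalizer(X)
  train_regressor(apply_normalizer(norm, X), Y, config,
                  movements = movements, normalizer = norm)
}
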