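#' Model and training configurations
#'
#' `model_config()` describes the recurrent fingerprint-to-concentration
#' network: a stack of LSTM layers run over the wavelength sequence, mean
#' pooling over the steps, and a linear readout with a softmax that
#' constrains predictions to the simplex. Each step's input is the
#' max-normalized amplitude, optionally paired with the min-max-normalized
#' wavelength (`input_features = 2`, the default) so that a single model
#' generalizes across wavelength grids of different length.
#'
#' `train_config()` holds the optimization recipe: AdamW (betas 0.9/0.999,
#' weight decay 1e-5) on a Huber (smooth-L1) loss, batch size 32, learning
#' rate 1e-4, 100 epochs, with an 80/20 train/validation split. These
#' defaults suit full-scale training on ~1e6 fingerprints; scaled-down runs
#' override them.
#'
#' @param hidden_size LSTM hidden width (default 128).
#' @param num_layers Number of stacked LSTM layers (default 2).
#' @param input_features 1 (amplitude only) or 2 (amplitude + normalized
#'   wavelength).
#' @param n_outputs Number of chromophores N (default 5).
#' @return A `paf_model_config` / `paf_train_config` list.
#' @export
model_config <- function(hidden_size = 128, num_layers = 2,
                         input_features = 2, n_outputs = 5) {
  stopifnot(
    hidden_size >= 1, num_layers >= 1,
    input_features %in% c(1, 2), n_outputs >= 1
  )
  structure(
    list(
      hidden_size = as.integer(hidden_size),
      num_layers = as.integer(num_layers),
      input_features = as.integer(input_features),
      n_outputs = as.integer(n_outputs)
    ),
    class = "paf_model_config"
  )
}

#' @rdname model_config
#' @param batch_size Minibatch size.
#' @param learning_rate AdamW step size.
#' @param epochs Training epochs.
#' @param weight_decay Decoupled weight decay.
#' @param betas AdamW moment decay rates.
#' @param huber_delta Huber loss transition point.
#' @param train_fraction Fraction of the dataset used for training; the
#'   remainder is held out for validation.
#' @param seed Integer seed for initialization and shuffling.
#' @export
train_config <- function(batch_size = 32, learning_rate = 1e-4, epochs = 100,
                         weight_decay = 1e-5, betas = c(0.9, 0.999),
                         huber_delta = 1, train_fraction = 0.8, seed = 1L) {
  stopifnot(
    batch_size >= 1, learning_rate > 0, epochs >= 1, weight_decay >= 0,
    length(betas) == 2, all(betas > 0 & betas < 1), huber_delta > 0,
    train_fraction > 0, train_fraction <= 1
  )
  structure(
    list(
      batch_size = as.integer(batch_size),
      learning_rate = learning_rate,
      epochs = as.integer(epochs),
      weight_decay = weight_decay,
      betas = betas,
      huber_delta = huber_delta,
      train_fraction = train_fraction,
      seed = as.integer(seed)
    ),
    class = "paf_train_config"
  )
}

#' Train the recurrent unmixing model
#'
#' Max-normalizes the fingerprints (the model-input convention: spectral
#' shape, not absolute amplitude), runs the training recipe, and returns a
#' fitted model with its per-epoch loss history. Training is deterministic
#' given the seed (initialization and minibatch shuffling use a private RNG
#' stream independent of R's).
#'
#' @param data Dataset tibble from [simulate_fingerprints()] (matrix columns
#'   `amplitudes` and `concentration`).
#' @param lib The `paf_library` the data was generated from (supplies the
#'   wavelength grid and chromophore order).
#' @param model A [model_config()].
#' @param training A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A `paf_fit` object; see [predict.paf_fit()], [tidy.paf_fit()],
#'   [glance.paf_fit()].
#' @export
paf_train <- function(data, lib, model = model_config(),
                      training = train_config(), verbose = FALSE) {
  stopifnot(inherits(lib, "paf_library"))
  if (nrow(data) == 0) abort("cannot train on an empty dataset")
  X <- normalize_max(data$amplitudes)
  Y <- as.matrix(data$concentration)
  if (ncol(Y) != model$n_outputs) {
    abort("n_outputs does not match the concentration dimension")
  }
  wl <- grid_unit_position(lib$grid)
  if (ncol(X) != length(wl)) {
    abort("fingerprint length does not match the library grid")
  }
  res <- lstm_train_cpp(
    X, wl, Y,
    hidden = model$hidden_size,
    layers = model$num_layers,
    feat = model$input_features,
    epochs = training$epochs,
    batch = training$batch_size,
    lr = training$learning_rate,
    weight_decay = training$weight_decay,
    beta1 = training$betas[1],
    beta2 = training$betas[2],
    huber_delta = training$huber_delta,
    train_fraction = training$train_fraction,
    seed = training$seed,
    verbose = verbose
  )
  if (any(!is.finite(unlist(res$history_train)))) {
    abort("training diverged: non-finite loss recorded")
  }
  structure(
    list(
      weights = res[c("layers", "Wo", "bo")],
      model = model,
      training = training,
      chromophores = lib$chromophores,
      grid = lib$grid,
      library_hash = library_hash(lib),
      history = tibble(
        epoch = seq_along(res$history_train),
        train_loss = unlist(res$history_train),
        val_loss = unlist(res$history_val)
      ),
      n_train = res$n_train,
      n_val = res$n_val
    ),
    class = "paf_fit"
  )
}

#' @export
print.paf_fit <- function(x, ...) {
  cat(sprintf(
    "<paf_fit> LSTM %d x %d hidden -> %d chromophores; %d epochs, final val loss %.3g\n",
    x$model$num_layers, x$model$hidden_size, x$model$n_outputs,
    nrow(x$history), x$history$val_loss[nrow(x$history)]
  ))
  invisible(x)
}

#' Predict concentration fractions from fingerprints
#'
#' Max-normalizes the input fingerprints and runs the fitted model. Outputs
#' lie on the simplex (softmax readout), one row per fingerprint, in input
#' order. Because normalization precedes the network, predictions are
#' invariant to positive rescaling of each fingerprint.
#'
#' @param object A `paf_fit`.
#' @param newdata Dataset tibble with an `amplitudes` matrix column, or an
#'   n x K matrix of fingerprints. With `input_features = 2` the model
#'   accepts any grid length; pass `grid` when it differs from training.
#' @param grid Optional `paf_grid` for the fingerprints (defaults to the
#'   training grid).
#' @param type `"tibble"` (one named column per chromophore) or `"matrix"`.
#' @param ... Unused.
#' @return Predicted fractions.
#' @export
predict.paf_fit <- function(object, newdata, grid = NULL,
                            type = c("tibble", "matrix"), ...) {
  type <- match.arg(type)
  A <- if (is.data.frame(newdata)) newdata$amplitudes else as.matrix(newdata)
  grid <- grid %||% attr(newdata, "grid") %||% object$grid
  K <- length(grid$wavelengths_nm)
  if (ncol(A) != K) {
    abort(sprintf(
      "fingerprint length %d does not match grid K = %d", ncol(A), K
    ))
  }
  if (object$model$input_features == 1 &&
    K != length(object$grid$wavelengths_nm)) {
    abort(paste0(
      "an amplitude-only model is tied to its training grid length; ",
      "retrain with input_features = 2 for variable-length fingerprints"
    ))
  }
  X <- normalize_max(A)
  P <- lstm_predict_cpp(
    object$weights, X, grid_unit_position(grid),
    object$model$input_features
  )
  colnames(P) <- object$chromophores
  if (type == "matrix") {
    P
  } else {
    as_tibble(as.data.frame(P))
  }
}

#' Tidy the training history of a fitted model
#'
#' @param x A `paf_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.paf_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `paf_fit`.
#' @param ... Unused.
#' @return Tibble with sizes, epochs and final losses.
#' @export
glance.paf_fit <- function(x, ...) {
  h <- x$history
  tibble(
    hidden_size = x$model$hidden_size,
    num_layers = x$model$num_layers,
    n_train = x$n_train,
    n_val = x$n_val,
    epochs = nrow(h),
    final_train_loss = h$train_loss[nrow(h)],
    final_val_loss = h$val_loss[nrow(h)]
  )
}

#' Save / load a fitted model
#'
#' A checkpoint is a single-file archive of the weights together with the
#' model and training configurations, the library hash, the seed and the
#' per-epoch loss history; reloading reproduces predictions exactly.
#'
#' @param fit A `paf_fit`.
#' @param path Checkpoint file path.
#' @return `paf_save` returns `path` invisibly; `paf_load` the restored
#'   `paf_fit`.
#' @export
paf_save <- function(fit, path) {
  stopifnot(inherits(fit, "paf_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname paf_save
#' @export
paf_load <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "paf_fit")) abort("file is not a saved paf_fit")
  fit
}
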