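# Multi-layer perceptron regressor: raw 1024-sample waveform in, the two
# per-crystal energy labels out. Architecture and scaling follow the
# package's reference design: two hidden layers of 256 rectified-linear
# units, inputs divided by 1000 and labels by 10 before optimization.
# Training plumbing (MSE loss, Adam, early stopping) is ordinary regression
# machinery; all of it is configurable.

#' ANN configuration
#'
#' The input and label scaling divisors bring the data to order one before
#' optimization, which is what makes training with a fixed Adam step size
#' effective. With waveforms in digitizer-like units a fixed pair of
#' divisors (e.g. 1000 for the inputs, 10 for the labels) does this; the
#' default `"auto"` resolves each divisor from the training split as the
#' maximum absolute value (per label column), implementing the same intent
#' for any waveform units. Resolved divisors are stored in the trained
#' model, so predictions are unit-correct either way.
#'
#' @param hidden Integer vector of hidden-layer widths (default `c(256, 256)`).
#' @param input_scale Divisor applied to waveform samples: a positive
#'   number, or `"auto"` (default).
#' @param label_scale Divisor applied to labels: a positive number, a
#'   vector with one entry per label column, or `"auto"` (default).
#' @param train_fraction Training share of the data for [split_dataset()]
#'   (default 0.8, i.e. a 4:1 train/validation split).
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Minibatch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience on validation loss (default 20);
#'   the weights of the best validation epoch are kept.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return An object of class `"ann_config"`.
#' @export
ann_config <- function(hidden = c(256L, 256L), input_scale = "auto",
                       label_scale = "auto", train_fraction = 0.8,
                       epochs = 200L, batch_size = 128L,
                       learning_rate = 1e-3, patience = 20L, seed = 1L) {
  check_scale <- function(s) {
    identical(s, "auto") || (is.numeric(s) && all(is.finite(s)) && all(s > 0))
  }
  stopifnot(length(hidden) >= 1L, all(hidden >= 1L),
            check_scale(input_scale), check_scale(label_scale),
            train_fraction > 0, train_fraction < 1,
            epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(hidden = as.integer(hidden), input_scale = input_scale,
                 label_scale = label_scale, train_fraction = train_fraction,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), seed = seed),
            class = "ann_config")
}

#' Split a dataset into training and validation parts
#'
#' Seeded random shuffle, then the first `floor(train_fraction * n)` events
#' train and the remainder validate: disjoint and exhaustive.
#'
#' @param dataset A `mixed_event_dataset` with at least 5 events.
#' @param train_fraction Training share (default 0.8, a 4:1 split).
#' @param seed Integer seed for the shuffle.
#' @return List with elements `train` and `validation` (datasets) and
#'   `train_idx`, `validation_idx` (the event indices used).
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "mixed_event_dataset"))
  n <- dataset$n_events
  if (n < 5L) stop("dataset too small to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n_train <- floor(train_fraction * n)
  if (n_train < 1L || n_train >= n) stop("degenerate split sizes")
  perm <- with_seed(seed, sample.int(n))
  idx_train <- perm[seq_len(n_train)]
  idx_val <- perm[(n_train + 1L):n]
  list(train = subset_dataset(dataset, idx_train),
       validation = subset_dataset(dataset, idx_val),
       train_idx = idx_train, validation_idx = idx_val)
}

relu <- function(z) (z > 0) * z

mlp_init <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    list(w = matrix(stats::rnorm(fan_in * dims[l + 1L], 0,
                                 sqrt(2 / fan_in)),
                    fan_in, dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

mlp_forward <- function(params, x) {
  nl <- length(params)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- x
  for (l in seq_len(nl)) {
    z <- acts[[l]] %*% params[[l]]$w
    z <- sweep(z, 2L, params[[l]]$b, `+`)
    acts[[l + 1L]] <- if (l < nl) relu(z) else z
  }
  acts
}

mlp_predict <- function(params, x) {
  mlp_forward(params, x)[[length(params) + 1L]]
}

mlp_grad <- function(params, acts, y) {
  nl <- length(params)
  n <- nrow(y)
  grads <- vector("list", nl)
  delta <- 2 * (acts[[nl + 1L]] - y) / (n * ncol(y))
  for (l in nl:1) {
    grads[[l]] <- list(w = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(params[[l]]$w)) * (acts[[l]] > 0)
    }
  }
  grads
}

#' Train the MLP energy regressor
#'
#' Minimizes the mean-squared error between the network outputs and the
#' scaled per-crystal labels with the Adam optimizer, monitoring the
#' validation loss each epoch; training stops early when the validation
#' loss has not improved for `cfg$patience` epochs and the best-epoch
#' weights are restored. Deterministic for a fixed seed within one
#' platform/BLAS-thread configuration.
#'
#' @param train,validation `mixed_event_dataset`s with labels (as returned
#'   by [split_dataset()]).
#' @param cfg An [ann_config()].
#' @param label_type `"integral"` or `"amplitude"`: which ground-truth label
#'   the network is trained to regress.
#' @return An object of class `"trained_ann"`: weights, config, label type,
#'   crystal names, per-epoch `history` (train/validation loss) and
#'   `best_epoch`.
#' @export
train_ann <- function(train, validation, cfg = ann_config(),
                      label_type = c("integral", "amplitude")) {
  label_type <- match.arg(label_type)
  stopifnot(inherits(train, "mixed_event_dataset"),
            inherits(validation, "mixed_event_dataset"),
            inherits(cfg, "ann_config"))
  if (train$n_events < 1L || validation$n_events < 1L) {
    stop("empty train or validation split")
  }
  if (is.null(train$labels[[label_type]]) ||
      is.null(validation$labels[[label_type]])) {
    stop("labels missing")
  }
  in_scale <- if (identical(cfg$input_scale, "auto")) {
    max(abs(train$waveforms))
  } else cfg$input_scale
  lab_scale <- if (identical(cfg$label_scale, "auto")) {
    apply(abs(train$labels[[label_type]]), 2L, max)
  } else cfg$label_scale
  if (any(lab_scale <= 0)) lab_scale[lab_scale <= 0] <- 1
  if (in_scale <= 0) in_scale <- 1
  scale_lab <- function(y) sweep(y, 2L, rep_len(lab_scale, ncol(y)), `/`)
  x_tr <- train$waveforms / in_scale
  y_tr <- scale_lab(train$labels[[label_type]])
  x_va <- validation$waveforms / in_scale
  y_va <- scale_lab(validation$labels[[label_type]])

  dims <- c(ncol(x_tr), cfg$hidden, ncol(y_tr))
  n <- nrow(x_tr)

  with_seed(cfg$seed, {
    params <- mlp_init(dims)
    mstate <- lapply(params, lapply, function(p) p * 0)
    vstate <- mstate
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    tstep <- 0L
    best_val <- Inf; best_params <- params; best_epoch <- 0L
    wait <- 0L
    hist_tr <- hist_va <- numeric(0)

    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- perm[s:min(s + cfg$batch_size - 1L, n)]
        xb <- x_tr[rows, , drop = FALSE]
        yb <- y_tr[rows, , drop = FALSE]
        acts <- mlp_forward(params, xb)
        loss <- mean((acts[[length(params) + 1L]] - yb)^2)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        }
        ep_loss <- ep_loss + loss * length(rows)
        grads <- mlp_grad(params, acts, yb)
        tstep <- tstep + 1L
        corr1 <- 1 - b1^tstep; corr2 <- 1 - b2^tstep
        for (l in seq_along(params)) {
          for (nm in c("w", "b")) {
            g <- grads[[l]][[nm]]
            mstate[[l]][[nm]] <- b1 * mstate[[l]][[nm]] + (1 - b1) * g
            vstate[[l]][[nm]] <- b2 * vstate[[l]][[nm]] + (1 - b2) * g^2
            params[[l]][[nm]] <- params[[l]][[nm]] -
              cfg$learning_rate * (mstate[[l]][[nm]] / corr1) /
              (sqrt(vstate[[l]][[nm]] / corr2) + eps)
          }
        }
      }
      val_loss <- mean((mlp_predict(params, x_va) - y_va)^2)
      if (!is.finite(val_loss)) {
        stop(sprintf("non-finite validation loss at epoch %d", epoch))
      }
      hist_tr <- c(hist_tr, ep_loss / n)
      hist_va <- c(hist_va, val_loss)
      if (val_loss < best_val) {
        best_val <- val_loss; best_params <- params
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }

    structure(list(weights = best_params, config = cfg,
                   input_scale = in_scale,
                   label_scale = rep_len(lab_scale, ncol(y_tr)),
                   label_type = label_type,
                   crystal_names = train$crystal_names,
                   history = data.frame(epoch = seq_along(hist_tr),
                                        train_loss = hist_tr,
                                        val_loss = hist_va),
                   best_epoch = best_epoch),
              class = "trained_ann")
  })
}

#' @export
print.trained_ann <- function(x, ...) {
  dims <- c(nrow(x$weights[[1L]]$w),
            vapply(x$weights, function(p) ncol(p$w), 1L))
  cat(sprintf(paste0("<trained_ann> %s, %s labels [%s], best epoch %d ",
                     "(val loss %.4g)\n"),
              paste(dims, collapse = "-"), x$label_type,
              paste(x$crystal_names, collapse = ", "),
              x$best_epoch, min(x$history$val_loss)))
  invisible(x)
}

#' Predict per-crystal energy labels with a trained MLP
#'
#' Applies the training-time input scaling, runs the network, and inverts
#' the label scaling, returning estimates in original label units.
#'
#' @param object A [train_ann()] model.
#' @param newdata A `mixed_event_dataset`, an `n x 1024` matrix, or a single
#'   [pulse_waveform()].
#' @param ... Unused.
#' @return `n x K` matrix of estimates with attributes `method = "ann"` and
#'   `label_type`.
#' @export
predict.trained_ann <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "mixed_event_dataset")) newdata$waveforms
  else if (inherits(newdata, "pulse_waveform")) matrix(newdata$samples, 1L)
  else if (is.matrix(newdata)) newdata
  else stop("newdata must be a dataset, matrix or pulse_waveform")
  if (ncol(x) != nrow(object$weights[[1L]]$w)) {
    stop(sprintf("waveform length %d does not match model input %d",
                 ncol(x), nrow(object$weights[[1L]]$w)))
  }
  out <- mlp_predict(object$weights, x / object$input_scale)
  out <- sweep(out, 2L, object$label_scale, `*`)
  colnames(out) <- object$crystal_names
  structure(out, method = "ann", label_type = object$label_type)
}

#' Save / load a trained MLP
#'
#' The file bundles weights, configuration (including scaling divisors),
#' label type and crystal names; a reloaded model produces bit-identical
#' predictions.
#'
#' @param model A `"trained_ann"`.
#' @param path File path.
#' @return `save_ann` returns `path` invisibly; `load_ann` the model.
#' @export
save_ann <- function(model, path) {
  stopifnot(inherits(model, "trained_ann"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ann
#' @export
load_ann <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_ann")) stop("file does not contain a trained_ann")
  model
}
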