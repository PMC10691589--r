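# Model fitting with the study's training regime: Adam on categorical
# cross-entropy (plus L2 penalties), mini-batches, early stopping on a
# monitored loss with best-weight restoration, and confusion-matrix
# evaluation.

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 256).
#' @param max_epochs Maximum number of epochs (default 200).
#' @param early_stop_patience Consecutive epochs without improvement of
#'   the monitored loss before training halts (default 14).
#' @param monitor `"val_loss"` (default) or `"train_loss"`.
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `train_control`.
#' @export
train_control <- function(batch_size = 256, max_epochs = 200,
                          early_stop_patience = 14,
                          monitor = c("val_loss", "train_loss"),
                          learning_rate = 1e-3, seed = 1) {
  monitor <- match.arg(monitor)
  check_positive(batch_size, "batch_size")
  check_positive(max_epochs, "max_epochs")
  check_positive(early_stop_patience, "early_stop_patience")
  check_positive(learning_rate, "learning_rate")
  if (early_stop_patience >= max_epochs && max_epochs > 1)
    warning("patience >= max_epochs: early stopping can never trigger",
            call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 monitor = monitor, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_control")
}

# Epoch (1-based) at which training stops for a monitored-loss history:
# the wait counter resets on strict improvement and training halts once
# it reaches `patience`. NA when the history never triggers a stop.
early_stop_epoch <- function(losses, patience) {
  best <- Inf; wait <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best) {
      best <- losses[e]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  NA_integer_
}

batched_probs <- function(spec, params, state, X, chunk = 512L) {
  N <- dim(X)[1]
  out <- matrix(0, N, spec$n_classes)
  at <- 1L
  while (at <= N) {
    idx <- at:min(N, at + chunk - 1L)
    fw <- nn_forward(spec, params, state,
                     X[idx, , , drop = FALSE], training = FALSE)
    out[idx, ] <- fw$probs
    at <- at + chunk
  }
  out
}

#' Fit a fatigue-stage classifier
#'
#' Trains one of the five architectures on a [shuffle_split()] dataset
#' with Adam, mini-batches, and early stopping on the monitored loss
#' (best-epoch weights are restored). All randomness (initialization,
#' shuffling, dropout) derives from `control$seed`, so a fit is
#' reproducible.
#'
#' @param spec A `model_spec` from one of the `build_*` constructors.
#' @param splits A `split_set`; `splits$train$combo$dim` must equal
#'   `spec$input_dim`.
#' @param control A [train_control()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `fatigue_model`: list with `spec`, `params`,
#'   `state`, `history` (data frame of per-epoch losses/accuracies),
#'   `best_epoch`, `stopped_epoch`, `control`, `classes`.
#' @export
fit_fatigue_model <- function(spec, splits, control = train_control(),
                              verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(splits, "split_set"),
            inherits(control, "train_control"))
  if (dim(splits$train$windows)[3] != spec$input_dim)
    stop_invalid("input dimension mismatch: spec expects ", spec$input_dim,
                 " channels, windows have ", dim(splits$train$windows)[3])
  Xtr <- splits$train$windows
  N <- dim(Xtr)[1]
  if (N < 1) stop_invalid("empty training split")
  Ytr <- one_hot(splits$train$labels, spec$n_classes)
  Xval <- splits$val$windows
  Yval <- one_hot(splits$val$labels, spec$n_classes)

  with_seed(control$seed, {
    ini <- init_params(spec)
    params <- ini$params; state <- ini$state
    opt <- adam_init(params)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_acc = numeric(), val_loss = numeric(),
                       val_acc = numeric())
    best <- Inf; wait <- 0L
    best_params <- params; best_state <- state; best_epoch <- 0L
    stopped <- NA_integer_
    for (epoch in seq_len(control$max_epochs)) {
      perm <- sample.int(N)
      ep_loss <- 0; ep_correct <- 0
      at <- 1L
      while (at <= N) {
        idx <- perm[at:min(N, at + control$batch_size - 1L)]
        res <- nn_loss_and_grads(spec, params, state,
                                 Xtr[idx, , , drop = FALSE],
                                 Ytr[idx, , drop = FALSE],
                                 training = TRUE)
        state <- res$state
        st <- adam_step(params, res$grads, opt,
                        lr = control$learning_rate)
        params <- st$params; opt <- st$opt
        ep_loss <- ep_loss + res$loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(res$probs) == max.col(Ytr[idx, , drop = FALSE]))
        at <- at + control$batch_size
      }
      train_loss <- ep_loss / N
      train_acc <- ep_correct / N
      if (dim(Xval)[1] > 0) {
        pv <- batched_probs(spec, params, state, Xval)
        val_loss <- cross_entropy(Yval, pv)
        val_acc <- mean(max.col(pv) == max.col(Yval))
      } else {
        if (control$monitor == "val_loss")
          stop_invalid("empty validation split with monitor = val_loss")
        val_loss <- NA_real_; val_acc <- NA_real_
      }
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = train_loss,
                                     train_acc = train_acc,
                                     val_loss = val_loss,
                                     val_acc = val_acc))
      if (verbose)
        message(sprintf(
          "epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
          epoch, train_loss, train_acc, val_loss, val_acc))
      monitored <- if (control$monitor == "val_loss") val_loss
        else train_loss
      if (monitored < best) {
        best <- monitored; wait <- 0L
        best_params <- params; best_state <- state; best_epoch <- epoch
      } else {
        wait <- wait + 1L
        if (wait >= control$early_stop_patience) {
          stopped <- epoch
          break
        }
      }
    }
    structure(list(spec = spec, params = best_params, state = best_state,
                   history = hist, best_epoch = best_epoch,
                   stopped_epoch = stopped, control = control,
                   classes = STAGES),
              class = "fatigue_model")
  })
}

#' @export
print.fatigue_model <- function(x, ...) {
  cat(sprintf("<fatigue_model> %s (%s parameters), %d epochs",
              x$spec$name,
              format(total_parameters(x$spec), big.mark = ","),
              nrow(x$history)))
  if (!is.na(x$stopped_epoch))
    cat(sprintf(" (early stop at %d, best %d)",
                x$stopped_epoch, x$best_epoch))
  cat(sprintf("\n  final val loss %.4f, val accuracy %.3f\n",
              x$history$val_loss[x$best_epoch],
              x$history$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.fatigue_model <- function(object, ...) {
  summary(object$spec)
  cat(sprintf("\nTrained %d epochs (best epoch %d), monitor %s\n",
              nrow(object$history), object$best_epoch,
              object$control$monitor))
  invisible(object$history)
}

#' @export
plot.fatigue_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss),
                    type = "l", lty = 1, col = c("steelblue", "tomato"),
                    xlab = "epoch", ylab = "loss",
                    main = paste(x$spec$name, "training history"), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "tomato"), lty = 1, bty = "n")
  invisible(x)
}

#' Predict fatigue stages for new windows
#'
#' @param object A `fatigue_model`.
#' @param newdata A `window_set` or an N x Nc x D array.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted stages, or an N x 3 probability matrix.
#' @export
predict.fatigue_model <- function(object, newdata,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "window_set")) newdata$windows else newdata
  if (length(dim(X)) != 3L || dim(X)[3] != object$spec$input_dim)
    stop_invalid("newdata must be N x ", object$spec$input_len, " x ",
                 object$spec$input_dim, " windows")
  probs <- batched_probs(object$spec, object$params, object$state, X)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

confusion_matrix <- function(truth, predicted) {
  truth <- as_stage_factor(truth)
  predicted <- as_stage_factor(predicted)
  table(truth = truth, predicted = predicted)
}

#' Evaluate a classifier on a test window set
#'
#' @param model A `fatigue_model` (or any object with a `predict` method
#'   returning stage labels).
#' @param test A non-empty `window_set`.
#' @return An object of class `eval_report`: `accuracy`, `confusion`
#'   (3 x 3, rows = true stage), `per_class_recall`, `n_test`, `history`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(test, "window_set"))
  n <- dim(test$windows)[1]
  if (n < 1) stop_invalid("empty test set")
  pred <- predict(model, test)
  conf <- confusion_matrix(test$labels, pred)
  acc <- sum(diag(conf)) / sum(conf)
  recall <- diag(conf) / pmax(rowSums(conf), 1)
  structure(list(accuracy = acc, confusion = conf,
                 per_class_recall = recall, n_test = n,
                 history = if (inherits(model, "fatigue_model"))
                   model$history else NULL),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f on %d windows\n",
              x$accuracy, x$n_test))
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
eval_report_to_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(accuracy = report$accuracy,
              confusion = unclass(as.matrix(report$confusion)),
              per_class_recall = as.numeric(report$per_class_recall),
              n_test = report$n_test)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
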