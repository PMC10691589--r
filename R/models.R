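# Declarative architecture specifications for the five classifiers, with
# exact trainable-parameter accounting, plus the attention mathematics
# (scaled dot-product scores over recurrent hidden states, context
# aggregation) and the categorical cross-entropy loss.

MODEL_NAMES <- c("S_LSTM", "D_LSTM", "CNN", "LSTM_ATTN", "LSTM_CNN")

layer_spec <- function(kind, name, ..., output_shape = NULL) {
  structure(c(list(kind = kind, name = name, output_shape = output_shape),
              list(...)),
            class = "layer_spec")
}

# Trainable parameters of one layer, from the standard counting formulas:
# LSTM 4u(d+u+1); Conv2D kh*kw*cin*cout + cout; Dense din*dout (+dout with
# bias); BatchNorm 2u (gamma, beta); everything else 0.
layer_parameters <- function(l) {
  switch(l$kind,
    LSTM = 4L * l$units * (l$input_dim + l$units + 1L),
    Conv2D = l$kernel[1] * l$kernel[2] * l$in_channels * l$filters +
      l$filters,
    Dense = l$input_dim * l$units + if (isTRUE(l$use_bias)) l$units else 0L,
    BatchNorm = 2L * l$units,
    MaxPool2D = 0L, Dropout = 0L, Flatten = 0L, Attention = 0L,
    Concat = 0L, LastHiddenState = 0L,
    stop_invalid("unknown layer kind: ", l$kind))
}

#' Total trainable parameters of a model specification
#'
#' Exact integer sum of the per-layer counting formulas; equals the number
#' of weights the instantiated network trains.
#'
#' @param spec A `model_spec`.
#' @return Integer parameter count.
#' @export
total_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$layers) == 0L) return(0L)
  sum(vapply(spec$layers, layer_parameters, numeric(1)))
}

new_model_spec <- function(name, input_len, input_dim, layers,
                           n_classes = 3L, l2_lambda = 0.01,
                           dropout_rate = 0.5) {
  structure(list(name = name, input_len = as.integer(input_len),
                 input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 l2_lambda = l2_lambda, dropout_rate = dropout_rate,
                 layers = layers),
            class = "model_spec")
}

check_input_dim <- function(input_dim) {
  if (!input_dim %in% c(3L, 6L, 9L))
    stop_invalid("input_dim must be 3 (ACC or GYR), 6 (ACC+GYR) or 9 ",
                 "(ACC+GYR+POS)")
  as.integer(input_dim)
}

# Convolutional trunk shared by the CNN model and the hybrid's CNN branch.
# Time lengths follow same-padding stride-2 (ceil(T/2)) and valid 2x1
# pooling (floor(T/2)).
cnn_trunk_layers <- function(input_len, input_dim) {
  t1 <- ceiling(input_len / 2)
  t2 <- floor(t1 / 2)
  t3 <- floor(t2 / 2)
  list(
    layer_spec("Conv2D", "conv2d", filters = 32L, kernel = c(18L, 1L),
               stride = c(2L, 1L), padding = "same", in_channels = 1L,
               activation = "relu", output_shape = c(t1, input_dim, 32L)),
    layer_spec("MaxPool2D", "max_pooling2d", pool = c(2L, 1L),
               output_shape = c(t2, input_dim, 32L)),
    layer_spec("Conv2D", "conv2d_1", filters = 64L, kernel = c(9L, 1L),
               stride = c(1L, 1L), padding = "same", in_channels = 32L,
               activation = "relu", output_shape = c(t2, input_dim, 64L)),
    layer_spec("Conv2D", "conv2d_2", filters = 128L, kernel = c(3L, 1L),
               stride = c(1L, 1L), padding = "same", in_channels = 64L,
               activation = "relu", output_shape = c(t2, input_dim, 128L)),
    layer_spec("MaxPool2D", "max_pooling2d_1", pool = c(2L, 1L),
               output_shape = c(t3, input_dim, 128L)),
    layer_spec("Conv2D", "conv2d_3", filters = 128L,
               kernel = c(1L, input_dim), stride = c(1L, 1L),
               padding = "valid", in_channels = 128L, activation = "relu",
               output_shape = c(t3, 1L, 128L)),
    layer_spec("Flatten", "flatten", output_shape = t3 * 128L))
}

#' Build the CNN architecture
#'
#' Four convolutional layers (kernels 18x1 stride 2, 9x1, 3x1, and a final
#' 1xD collapsing the channel axis) with two 2x1 max-pooling layers, a
#' flatten, and a softmax head. For 200 x 6 input the flatten width is
#' 3,200 and the total trainable parameter count is 151,843.
#'
#' @param input_len Window length in samples (default 200).
#' @param input_dim Number of input channels: 3, 6 or 9.
#' @return A `model_spec`.
#' @export
build_cnn <- function(input_len = 200, input_dim = 6) {
  input_dim <- check_input_dim(input_dim)
  trunk <- cnn_trunk_layers(input_len, input_dim)
  flat <- trunk[[length(trunk)]]$output_shape
  layers <- c(trunk, list(
    layer_spec("Dense", "dense", units = 3L, input_dim = flat,
               use_bias = TRUE, activation = "softmax", l2 = 0.01,
               output_shape = 3L)))
  new_model_spec("CNN", input_len, input_dim, layers)
}

#' Build the single-layer LSTM architecture
#'
#' LSTM (128 units, final hidden state) -> batch standardization ->
#' dropout 0.5 -> dense softmax head with L2 (0.01) regularization on the
#' head weights and output.
#'
#' @inheritParams build_cnn
#' @param units LSTM hidden width (default 128).
#' @return A `model_spec`.
#' @export
build_s_lstm <- function(input_len = 200, input_dim = 6, units = 128L) {
  input_dim <- check_input_dim(input_dim)
  layers <- list(
    layer_spec("LSTM", "lstm", units = as.integer(units),
               input_dim = input_dim, return_sequences = FALSE,
               output_shape = as.integer(units)),
    layer_spec("BatchNorm", "batch_normalization", units = as.integer(units),
               output_shape = as.integer(units)),
    layer_spec("Dropout", "dropout", rate = 0.5,
               output_shape = as.integer(units)),
    layer_spec("Dense", "dense", units = 3L, input_dim = as.integer(units),
               use_bias = TRUE, activation = "softmax", l2 = 0.01,
               activity_l2 = 0.01, output_shape = 3L))
  new_model_spec("S_LSTM", input_len, input_dim, layers)
}

#' Build the dual-layer LSTM architecture
#'
#' LSTM (128, sequences) -> dropout -> LSTM (64, final state) -> batch
#' standardization -> dropout -> softmax head as in the single-layer model.
#'
#' @inheritParams build_cnn
#' @param units Hidden widths of the two recurrent layers.
#' @return A `model_spec`.
#' @export
build_d_lstm <- function(input_len = 200, input_dim = 6,
                         units = c(128L, 64L)) {
  input_dim <- check_input_dim(input_dim)
  u1 <- as.integer(units[1]); u2 <- as.integer(units[2])
  layers <- list(
    layer_spec("LSTM", "lstm", units = u1, input_dim = input_dim,
               return_sequences = TRUE, output_shape = c(input_len, u1)),
    layer_spec("Dropout", "dropout", rate = 0.5,
               output_shape = c(input_len, u1)),
    layer_spec("LSTM", "lstm_1", units = u2, input_dim = u1,
               return_sequences = FALSE, output_shape = u2),
    layer_spec("BatchNorm", "batch_normalization", units = u2,
               output_shape = u2),
    layer_spec("Dropout", "dropout_1", rate = 0.5, output_shape = u2),
    layer_spec("Dense", "dense", units = 3L, input_dim = u2,
               use_bias = TRUE, activation = "softmax", l2 = 0.01,
               activity_l2 = 0.01, output_shape = 3L))
  new_model_spec("D_LSTM", input_len, input_dim, layers)
}

#' Build the LSTM-plus-attention architecture
#'
#' LSTM (128, sequences) -> dropout -> last hidden state as query ->
#' bias-free dense score projection -> scaled dot-product scores
#' (divisor sqrt(units)) -> softmax over the time steps -> context vector
#' -> concatenation with the query -> bias-free dense (tanh) attention
#' output projection -> softmax head. For 200 x 9 input the total
#' trainable parameter count is 120,195.
#'
#' @inheritParams build_s_lstm
#' @return A `model_spec`.
#' @export
build_lstm_attention <- function(input_len = 200, input_dim = 9,
                                 units = 128L) {
  input_dim <- check_input_dim(input_dim)
  u <- as.integer(units)
  layers <- list(
    layer_spec("LSTM", "lstm", units = u, input_dim = input_dim,
               return_sequences = TRUE, output_shape = c(input_len, u)),
    layer_spec("Dropout", "dropout", rate = 0.5,
               output_shape = c(input_len, u)),
    layer_spec("LastHiddenState", "last_hidden_state", output_shape = u),
    layer_spec("Dense", "attention_score_vec", units = u, input_dim = u,
               use_bias = FALSE, activation = "linear",
               output_shape = c(input_len, u)),
    layer_spec("Attention", "attention_score", output_shape = input_len),
    layer_spec("Attention", "attention_weight", output_shape = input_len),
    layer_spec("Attention", "context_vector", output_shape = u),
    layer_spec("Concat", "attention_output", output_shape = 2L * u),
    layer_spec("Dense", "attention_vector", units = u, input_dim = 2L * u,
               use_bias = FALSE, activation = "tanh", output_shape = u),
    layer_spec("Dense", "dense", units = 3L, input_dim = u,
               use_bias = TRUE, activation = "softmax", l2 = 0.01,
               output_shape = 3L))
  new_model_spec("LSTM_ATTN", input_len, input_dim, layers)
}

#' Build the LSTM/CNN fusion architecture
#'
#' The single-layer LSTM trunk (through its 128-unit final state, batch
#' standardization and dropout) and the CNN trunk (through its flatten)
#' run on the same input window; their feature vectors are concatenated
#' (128 + 3,200 for 6 channels) and fed to a softmax head.
#'
#' @inheritParams build_s_lstm
#' @return A `model_spec`.
#' @export
build_hybrid <- function(input_len = 200, input_dim = 6, units = 128L) {
  input_dim <- check_input_dim(input_dim)
  u <- as.integer(units)
  lstm_branch <- list(
    layer_spec("LSTM", "lstm", units = u, input_dim = input_dim,
               return_sequences = FALSE, output_shape = u),
    layer_spec("BatchNorm", "batch_normalization", units = u,
               output_shape = u),
    layer_spec("Dropout", "dropout", rate = 0.5, output_shape = u))
  cnn_branch <- cnn_trunk_layers(input_len, input_dim)
  flat <- cnn_branch[[length(cnn_branch)]]$output_shape
  for (i in seq_along(lstm_branch)) lstm_branch[[i]]$branch <- "lstm"
  for (i in seq_along(cnn_branch)) cnn_branch[[i]]$branch <- "cnn"
  layers <- c(lstm_branch, cnn_branch, list(
    layer_spec("Concat", "concatenate", output_shape = u + flat),
    layer_spec("Dense", "dense", units = 3L, input_dim = u + flat,
               use_bias = TRUE, activation = "softmax", l2 = 0.01,
               output_shape = 3L)))
  new_model_spec("LSTM_CNN", input_len, input_dim, layers)
}

#' Build any of the five architectures by name
#'
#' @param name One of `"S_LSTM"`, `"D_LSTM"`, `"CNN"`, `"LSTM_ATTN"`,
#'   `"LSTM_CNN"`.
#' @inheritParams build_cnn
#' @return A `model_spec`.
#' @export
build_model <- function(name, input_len = 200, input_dim = 6) {
  name <- match.arg(name, MODEL_NAMES)
  switch(name,
         S_LSTM = build_s_lstm(input_len, input_dim),
         D_LSTM = build_d_lstm(input_len, input_dim),
         CNN = build_cnn(input_len, input_dim),
         LSTM_ATTN = build_lstm_attention(input_len, input_dim),
         LSTM_CNN = build_hybrid(input_len, input_dim))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: input %d x %d, %d classes, %s parameters\n",
              x$name, x$input_len, x$input_dim, x$n_classes,
              format(total_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.model_spec <- function(object, ...) {
  shp <- function(s) paste0("(None, ", paste(s, collapse = ", "), ")")
  df <- data.frame(
    layer = vapply(object$layers, function(l)
      sprintf("%s (%s)", l$name, l$kind), character(1)),
    output_shape = vapply(object$layers, function(l)
      shp(l$output_shape), character(1)),
    params = vapply(object$layers, layer_parameters, numeric(1)))
  cat(sprintf("Model: %s (input %d x %d)\n", object$name,
              object$input_len, object$input_dim))
  print(df, row.names = FALSE, right = FALSE)
  cat(sprintf("Total params: %s\n",
              format(total_parameters(object), big.mark = ",")))
  invisible(df)
}

#' Serialize / restore a model specification as JSON
#'
#' @param spec A `model_spec`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string or (for the reader) a `model_spec`.
#' @export
model_spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  obj <- unclass(spec)
  obj$layers <- lapply(obj$layers, unclass)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  as.character(js)
}

#' @rdname model_spec_to_json
#' @param json JSON string or file path.
#' @export
model_spec_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  obj$layers <- lapply(obj$layers, function(l)
    structure(l, class = "layer_spec"))
  structure(obj, class = "model_spec")
}

# ---- attention mathematics ------------------------------------------------

softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Scaled dot-product attention weights over hidden states
#'
#' Scores each hidden state against the query by a (bias-free) projected
#' dot product with scaling correction, `s_n = (W h_n)' q / sqrt(u)` where
#' `u` is the query dimension, and normalizes the scores with a softmax,
#' yielding the attention distribution over the `L` time steps.
#'
#' @param H L x u matrix of hidden states (one row per time step).
#' @param q Length-u query vector (here: the last hidden state).
#' @param W Optional u x u score projection matrix; identity when `NULL`.
#' @return Length-L weight vector: positive, summing to 1.
#' @export
attention_scores <- function(H, q, W = NULL) {
  H <- as.matrix(H)
  if (nrow(H) < 1L) stop_invalid("need at least one hidden state")
  if (ncol(H) != length(q))
    stop_invalid("query length must match the hidden-state width")
  P <- if (is.null(W)) H else H %*% W
  s <- as.numeric(P %*% q) / sqrt(length(q))
  softmax_vec(s)
}

#' Attention context vector
#'
#' Aggregates the hidden states into a single context vector by the
#' attention-weighted sum `sum_n alpha_n h_n`.
#'
#' @param weights Length-L normalized attention weights.
#' @param H L x u matrix of hidden states.
#' @return Length-u context vector.
#' @export
attention_context <- function(weights, H) {
  H <- as.matrix(H)
  if (length(weights) != nrow(H))
    stop_invalid("weights must have one entry per hidden state")
  as.numeric(crossprod(H, weights))
}

#' Categorical cross-entropy
#'
#' Mean over samples of `-sum_k p_k log q_k`, with the predicted
#' probabilities clipped to `[eps, 1]` before the logarithm.
#'
#' @param p N x K matrix of true (one-hot or probability) distributions.
#' @param q N x K matrix of predicted probabilities; rows must sum to 1
#'   within 1e-6.
#' @param eps Clipping floor for `log` (default 1e-7).
#' @return Non-negative scalar loss; zero iff `p == q` one-hot.
#' @export
cross_entropy <- function(p, q, eps = 1e-7) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!all(dim(p) == dim(q)))
    stop_invalid("p and q must have identical dimensions")
  if (any(abs(rowSums(q) - 1) > 1e-6))
    stop_invalid("q rows must sum to 1")
  qs <- pmin(pmax(q, eps), 1)
  mean(-rowSums(p * log(qs)))
}

one_hot <- function(labels, n_classes = 3L) {
  li <- as.integer(labels)
  Y <- matrix(0, length(li), n_classes)
  Y[cbind(seq_along(li), li)] <- 1
  Y
}
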