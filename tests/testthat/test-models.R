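test_that("CNN layer table reproduces the published parameter counts", {
  spec <- build_cnn(200, 6)
  counts <- vapply(spec$layers, ns$layer_parameters, numeric(1))
  expect_equal(counts, c(608, 0, 18496, 24704, 0, 98432, 0, 9603))
  expect_equal(total_parameters(spec), 151843)
  # flatten width and output shapes along the trunk
  shapes <- lapply(spec$layers, function(l) l$output_shape)
  expect_equal(shapes[[1]], c(100L, 6L, 32L))
  expect_equal(shapes[[2]], c(50L, 6L, 32L))
  expect_equal(shapes[[5]], c(25L, 6L, 128L))
  expect_equal(shapes[[6]], c(25L, 1L, 128L))
  expect_equal(shapes[[7]], 3200L)
})

test_that("LSTM+attention layer table reproduces the published counts", {
  spec <- build_lstm_attention(200, 9)
  counts <- vapply(spec$layers, ns$layer_parameters, numeric(1))
  expect_equal(sum(counts), 120195)
  expect_equal(counts[counts > 0], c(70656, 16384, 32768, 387))
  # recurrent layer formula 4u(d+u+1)
  expect_equal(counts[[1]], 4 * 128 * (9 + 128 + 1))
  # bias-free projections forced by the printed counts
  expect_equal(counts[[4]], 128 * 128)
  expect_equal(counts[[9]], 256 * 128)
})

test_that("plain LSTM and hybrid specs follow the counting formulas", {
  s <- build_s_lstm(200, 9)
  expect_equal(ns$layer_parameters(s$layers[[1]]), 70656)
  expect_equal(ns$layer_parameters(s$layers[[4]]), 128 * 3 + 3)
  d <- build_d_lstm(200, 6)
  expect_equal(ns$layer_parameters(d$layers[[3]]), 4 * 64 * (128 + 64 + 1))
  h <- build_hybrid(200, 6)
  concat <- Filter(function(l) l$kind == "Concat", h$layers)[[1]]
  expect_equal(concat$output_shape, 128L + 3200L)
  head_ <- h$layers[[length(h$layers)]]
  expect_equal(ns$layer_parameters(head_), 3328 * 3 + 3)
  expect_equal(total_parameters(h),
               sum(vapply(h$layers, ns$layer_parameters, numeric(1))))
})

test_that("spec parameter totals equal instantiated trainable weights", {
  for (nm in c("S_LSTM", "D_LSTM", "CNN", "LSTM_ATTN", "LSTM_CNN")) {
    for (D in c(3, 6, 9)) {
      spec <- build_model(nm, 200, D)
      ini <- withr::with_seed(1, ns$init_params(spec))
      expect_equal(ns$engine_parameter_count(ini$params),
                   total_parameters(spec),
                   info = paste(nm, D))
    }
  }
  expect_error(build_cnn(200, 4), "input_dim")
  expect_error(build_model("MLP"), "arg")
})

test_that("empty layer list counts zero parameters", {
  empty <- ns$new_model_spec("CNN", 200, 6, list())
  expect_equal(total_parameters(empty), 0)
})

test_that("attention weights are a softmax of scaled projected dots", {
  # equal scores give uniform weights
  H <- matrix(1, 5, 4)
  w <- attention_scores(H, q = rep(0, 4))
  expect_equal(w, rep(0.2, 5))
  # hand-computed softmax: scores (0, ln 4) -> weights (0.2, 0.8)
  H2 <- matrix(c(0, log(4)), 2, 1)
  w2 <- attention_scores(H2, q = 1)        # u = 1, no scaling
  expect_equal(w2, c(0.2, 0.8), tolerance = 1e-12)
  # normalization and positivity on random instances
  for (i in 1:20) {
    L <- sample(1:10, 1); u <- sample(1:8, 1)
    H <- matrix(stats::rnorm(L * u), L, u)
    q <- stats::rnorm(u)
    W <- matrix(stats::rnorm(u * u), u, u)
    w <- attention_scores(H, q, W)
    expect_equal(sum(w), 1, tolerance = 1e-6)
    expect_true(all(w > 0))
    # closed form: softmax of (W h_n)' q / sqrt(u)
    s <- as.numeric((H %*% W) %*% q) / sqrt(u)
    expect_equal(w, exp(s - max(s)) / sum(exp(s - max(s))),
                 tolerance = 1e-9)
  }
})

test_that("scaled dot scores scale linearly in the query", {
  u <- 8; L <- 6
  H <- matrix(stats::rnorm(L * u), L, u)
  q <- stats::rnorm(u)
  raw_scores <- function(qq) as.numeric(H %*% qq) / sqrt(u)
  expect_equal(raw_scores(3 * q), 3 * raw_scores(q), tolerance = 1e-12)
})

test_that("attention context is the brute-force weighted sum", {
  # one-hot selection returns the selected row exactly
  H <- matrix(stats::rnorm(20), 5, 4)
  w <- c(0, 0, 1, 0, 0)
  expect_equal(attention_context(w, H), H[3, ])
  # uniform weights give column means
  expect_equal(attention_context(rep(0.2, 5), H), colMeans(H))
  # random instances against an explicit double loop
  for (i in 1:20) {
    L <- sample(1:10, 1); u <- sample(1:8, 1)
    H <- matrix(stats::rnorm(L * u), L, u)
    w <- attention_scores(H, stats::rnorm(u))
    ctx <- attention_context(w, H)
    brute <- rep(0, u)
    for (n in seq_len(L)) brute <- brute + w[n] * H[n, ]
    expect_equal(ctx, brute, tolerance = 1e-9)
  }
  expect_error(attention_context(c(0.5, 0.5), H), "one entry per")
})

test_that("cross-entropy reproduces worked values and its invariances", {
  p <- matrix(c(1, 0, 0), 1)
  q <- matrix(c(0.7, 0.2, 0.1), 1)
  expect_equal(cross_entropy(p, q), -log(0.7), tolerance = 1e-12)
  # zero iff perfect one-hot agreement
  expect_equal(cross_entropy(p, matrix(c(1, 0, 0), 1)), 0,
               tolerance = 1e-6)
  # permutation symmetry over samples
  P <- diag(3); Q <- matrix(c(.8, .1, .1, .2, .6, .2, .3, .3, .4), 3,
                            byrow = TRUE)
  perm <- c(3, 1, 2)
  expect_equal(cross_entropy(P, Q), cross_entropy(P[perm, ], Q[perm, ]))
  expect_gte(cross_entropy(P, Q), 0)
  expect_error(cross_entropy(P, Q[1:2, ]), "identical dimensions")
  expect_error(cross_entropy(P, Q * 2), "sum to 1")
})

test_that("model specs survive a JSON round trip", {
  spec <- build_lstm_attention(200, 9)
  js <- model_spec_to_json(spec)
  back <- model_spec_from_json(js)
  expect_equal(back$name, spec$name)
  expect_equal(back$input_dim, spec$input_dim)
  expect_equal(total_parameters(back), total_parameters(spec))
  tab <- summary(spec)
  expect_equal(nrow(tab), length(spec$layers))
  expect_equal(sum(tab$params), 120195)
})
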