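test_that("stream embeddings have the documented shapes at the published dimension", {
  model <- dia_model(model_config("paper", enc_layers = 1L, dec_layers = 1L),
                     seed = 2L)
  p <- model$params
  expect_identical(dim(embed_ms1(c(300.1, 500.2, 700.3), c(1, 2, 3), p, 512L)),
                   c(3L, 512L))
  expect_identical(dim(embed_ms1(numeric(0), numeric(0), p, 512L)),
                   c(0L, 512L))
  expect_identical(dim(project_profile(cbind(1:5, 1:5), p)), c(5L, 512L))
  arr <- array(0, dim = c(26L, 8L, 5L, 10L))
  expect_identical(dim(project_ion_array(arr, p, 64L)), c(64L, 512L))
})

test_that("MS1 embedding is sinusoid(m/z) plus a linear intensity term", {
  model <- dia_model(model_config("tiny"), seed = 2L)
  p <- model$params
  d <- model$cfg$d
  e <- embed_ms1(c(400, 400), c(1, 3), p, d)
  # equal m/z, different intensity: rows differ by the intensity term only
  expect_equal(e[2L, ] - e[1L, ], 2 * p[["ms1.int.W"]][1L, ])
})

test_that("profile projection is linear: zero input gives the bias, doubling doubles", {
  model <- dia_model(model_config("tiny"), seed = 2L)
  p <- model$params
  z <- project_profile(matrix(0, 5, 2), p)
  expect_equal(z, matrix(rep(p[["prof.b"]], each = 5), 5))
  p0 <- p; p0[["prof.b"]] <- numeric(model$cfg$d)
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(project_profile(2 * x, p0), 2 * project_profile(x, p0))
})

test_that("ion-array tokens chunk the flattened slice with zero padding", {
  arr <- array(seq_len(26 * 8 * 5 * 10), dim = c(26L, 8L, 5L, 10L))
  tok <- ion_tokens(arr, 64L)
  expect_identical(dim(tok), c(64L, 163L))
  expect_identical(as.numeric(tok)[!is.na(as.numeric(tok))][1L], 1)
  # padded tail is zero: 64*163 - 10400 = 32 trailing zeros
  expect_equal(tok[64L, (163L - 31L):163L], rep(0, 32))
  expect_equal(sum(tok), sum(arr))
})

test_that("attention-fusion weights are a softmax: nonnegative, rows sum to 1", {
  set.seed(8)
  q <- matrix(rnorm(6 * 16), 6)
  h <- matrix(rnorm(9 * 16), 9)
  Wc <- matrix(rnorm(256, sd = 0.2), 16)
  fw <- attention_fuse(q, h, Wc)
  expect_true(all(fw$weights >= 0))
  expect_equal(rowSums(fw$weights), rep(1, 6), tolerance = 1e-9)
})

test_that("zero score matrix gives uniform attention and single-context attention is identity", {
  set.seed(8)
  q <- matrix(rnorm(4 * 16), 4)
  h <- matrix(rnorm(5 * 16), 5)
  fw0 <- attention_fuse(q, h, matrix(0, 16, 16))   # tanh(0) = 0
  expect_equal(fw0$weights, matrix(1 / 5, 4, 5), tolerance = 1e-12)
  h1 <- h[1L, , drop = FALSE]
  fw1 <- attention_fuse(q, h1, matrix(rnorm(256), 16))
  expect_equal(fw1$weights, matrix(1, 4, 1))
  expect_equal(fw1$context, matrix(rep(h1, each = 4), 4))
})

test_that("1-head attention with identity projections equals plain scaled dot-product", {
  d <- 8L
  set.seed(3)
  xq <- matrix(rnorm(5 * d), 5)
  xkv <- matrix(rnorm(7 * d), 7)
  p <- diaseq:::mk_attn_params(d, "t")
  p[["t.Wq.W"]] <- diag(d); p[["t.Wk.W"]] <- diag(d)
  p[["t.Wv.W"]] <- diag(d); p[["t.Wo.W"]] <- diag(d)
  for (nm in c("t.Wq.b", "t.Wk.b", "t.Wv.b", "t.Wo.b")) p[[nm]] <- numeric(d)
  got <- diaseq:::mha_fwd(xq, xkv, p, "t", h = 1L)$y
  S <- xq %*% t(xkv) / sqrt(d)
  A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
  expect_equal(got, A %*% xkv, tolerance = 1e-6)
})

test_that("multi-head attention rows are normalized per head", {
  d <- 16L
  set.seed(4)
  p <- diaseq:::mk_attn_params(d, "m")
  fw <- diaseq:::mha_fwd(matrix(rnorm(6 * d), 6), matrix(rnorm(9 * d), 9),
                         p, "m", h = 4L)
  for (A in fw$A) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-9)
  }
})

test_that("all four fusion modes produce encoder-compatible tokens on the same context", {
  d <- 16L
  set.seed(5)
  model <- dia_model(model_config("tiny", d = d, heads = 2L,
                                  fusion_heads = 2L, ion_tokens = 4L),
                     seed = 5L)
  p <- model$params
  ms1e <- matrix(rnorm(3 * d), 3)
  profe <- matrix(rnorm(5 * d), 5)
  ione <- matrix(rnorm(4 * d), 4)
  lens <- c(concat = 12L, attention = 4L, multihead = 4L, concat_no_ms1 = 9L)
  for (mode in names(lens)) {
    fw <- fuse_streams(ms1e, profe, ione, p, mode, h = 2L)
    expect_identical(dim(fw$tokens), c(lens[[mode]], d))
    expect_true(all(is.finite(fw$tokens)))
  }
  # concat output length is the sum of stream lengths
  expect_identical(nrow(fuse_streams(ms1e, profe, ione, p, "concat")$tokens),
                   3L + 5L + 4L)
})

test_that("analytic gradients of the full model agree with finite differences in every fusion mode", {
  sim <- fix_sim_small()
  ctx <- fix_ctxs_small()[[1L]]
  for (mode in c("concat", "attention", "multihead", "concat_no_ms1")) {
    cfg <- model_config("tiny", d = 16L, heads = 2L, enc_layers = 1L,
                        dec_layers = 1L, ffn_dim = 24L, ion_tokens = 4L,
                        fusion = mode, fusion_heads = 2L, max_ms1_peaks = 4L)
    model <- dia_model(cfg, seed = 5L)
    set.seed(11)
    model$params[["out.W"]] <- matrix(rnorm(length(model$params[["out.W"]]),
                                            sd = 0.3), cfg$d)
    ex <- prepare_example(model, ctx)
    gr <- diaseq:::new_grads()
    base <- diaseq:::model_forward(model, ex, gr)$loss
    set.seed(9)
    eps <- 1e-6
    for (nm in sample(names(model$params), 15)) {
      i <- sample(length(model$params[[nm]]), 1)
      m2 <- model
      m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      num <- (diaseq:::model_forward(m2, ex)$loss - base) / eps
      ana <- if (is.null(gr[[nm]])) 0 else gr[[nm]][i]
      if (abs(num) + abs(ana) < 1e-9) next
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-3)
    }
  }
})
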