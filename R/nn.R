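# Minimal neural-network core: linear layers, layer normalization,
# multi-head scaled dot-product attention, position-wise feed-forward
# blocks, softmax cross-entropy, and Adam -- all as plain matrix code
# with hand-written reverse-mode gradients.  Parameters live in a flat
# named list of matrices/vectors; gradients accumulate in an environment
# keyed by the same names.

.LN_EPS <- 1e-5

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

new_grads <- function() new.env(parent = emptyenv())

gacc <- function(gr, name, val) {
  cur <- gr[[name]]
  gr[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

# ---- linear ---------------------------------------------------------------

linear_fwd <- function(x, W, b) {
  sweep(x %*% W, 2L, b, "+")
}

linear_bwd <- function(dy, x, W, gr, pre) {
  gacc(gr, paste0(pre, ".W"), crossprod(x, dy))
  gacc(gr, paste0(pre, ".b"), colSums(dy))
  dy %*% t(W)
}

# ---- layer norm -----------------------------------------------------------

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .LN_EPS)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g, gr, pre) {
  xhat <- cache$xhat
  gacc(gr, paste0(pre, ".g"), colSums(dy * xhat))
  gacc(gr, paste0(pre, ".b"), colSums(dy))
  dxhat <- sweep(dy, 2L, g, "*")
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# ---- multi-head attention -------------------------------------------------

mk_attn_params <- function(d, pre) {
  p <- list(glorot(d, d), glorot(d, d), glorot(d, d), glorot(d, d),
            numeric(d), numeric(d), numeric(d), numeric(d))
  names(p) <- paste0(pre, c(".Wq.W", ".Wk.W", ".Wv.W", ".Wo.W",
                            ".Wq.b", ".Wk.b", ".Wv.b", ".Wo.b"))
  p
}

#' Multi-head scaled dot-product attention (forward)
#'
#' Queries from `xq`, keys and values from `xkv`; per head,
#' `softmax(Q K^T / sqrt(d_k)) V`, heads concatenated and passed through
#' the output projection.  With `causal = TRUE`, position i may only
#' attend to positions <= i (square attention assumed).
#'
#' @param xq,xkv token matrices (rows are tokens, `d` columns)
#' @param p flat parameter list
#' @param pre parameter name prefix (e.g. `"enc1.attn"`)
#' @param h number of heads (`d` divisible by `h`)
#' @param causal apply a causal mask
#' @return list with output `y`, attention matrices `A` (one per head),
#'   and the cache consumed by the matching backward pass
#' @keywords internal
mha_fwd <- function(xq, xkv, p, pre, h, causal = FALSE) {
  d <- ncol(xq)
  dk <- d %/% h
  Q <- linear_fwd(xq,  p[[paste0(pre, ".Wq.W")]], p[[paste0(pre, ".Wq.b")]])
  K <- linear_fwd(xkv, p[[paste0(pre, ".Wk.W")]], p[[paste0(pre, ".Wk.b")]])
  V <- linear_fwd(xkv, p[[paste0(pre, ".Wv.W")]], p[[paste0(pre, ".Wv.b")]])
  Tq <- nrow(xq); Tk <- nrow(xkv)
  O <- matrix(0, Tq, d)
  A <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dk)
    if (causal) S[upper.tri(S)] <- -Inf
    A[[i]] <- softmax_rows(S)
    O[, cols] <- A[[i]] %*% V[, cols, drop = FALSE]
  }
  y <- linear_fwd(O, p[[paste0(pre, ".Wo.W")]], p[[paste0(pre, ".Wo.b")]])
  list(y = y, A = A,
       cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V, A = A, O = O,
                    h = h, dk = dk))
}

mha_bwd <- function(dy, fw, p, pre, gr) {
  cc <- fw$cache
  dO <- linear_bwd(dy, cc$O, p[[paste0(pre, ".Wo.W")]], gr, paste0(pre, ".Wo"))
  d <- ncol(cc$Q); h <- cc$h; dk <- cc$dk
  dQ <- matrix(0, nrow(cc$Q), d)
  dK <- matrix(0, nrow(cc$K), d)
  dV <- matrix(0, nrow(cc$K), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    Ai <- cc$A[[i]]
    dOi <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOi, cc$V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(Ai, dOi)
    dS <- Ai * (dA - rowSums(dA * Ai))
    dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) / sqrt(dk)
  }
  dxq  <- linear_bwd(dQ, cc$xq,  p[[paste0(pre, ".Wq.W")]], gr, paste0(pre, ".Wq"))
  dxkv <- linear_bwd(dK, cc$xkv, p[[paste0(pre, ".Wk.W")]], gr, paste0(pre, ".Wk")) +
          linear_bwd(dV, cc$xkv, p[[paste0(pre, ".Wv.W")]], gr, paste0(pre, ".Wv"))
  list(dxq = dxq, dxkv = dxkv)
}

# ---- feed-forward ---------------------------------------------------------

mk_ffn_params <- function(d, dff, pre) {
  p <- list(glorot(d, dff), numeric(dff), glorot(dff, d), numeric(d))
  names(p) <- paste0(pre, c(".W1.W", ".W1.b", ".W2.W", ".W2.b"))
  p
}

ffn_fwd <- function(x, p, pre) {
  a <- linear_fwd(x, p[[paste0(pre, ".W1.W")]], p[[paste0(pre, ".W1.b")]])
  r <- pmax(a, 0)
  list(y = linear_fwd(r, p[[paste0(pre, ".W2.W")]], p[[paste0(pre, ".W2.b")]]),
       x = x, a = a, r = r)
}

ffn_bwd <- function(dy, fw, p, pre, gr) {
  dr <- linear_bwd(dy, fw$r, p[[paste0(pre, ".W2.W")]], gr, paste0(pre, ".W2"))
  da <- dr * (fw$a > 0)
  linear_bwd(da, fw$x, p[[paste0(pre, ".W1.W")]], gr, paste0(pre, ".W1"))
}

mk_ln_params <- function(d, pre) {
  p <- list(rep(1, d), numeric(d))
  names(p) <- paste0(pre, c(".g", ".b"))
  p
}

# ---- sinusoidal encodings -------------------------------------------------

#' Sinusoidal m/z encoding
#'
#' Maps m/z values to d-dimensional vectors using sine/cosine pairs whose
#' wavelengths are geometrically spaced between `lam_min` and `lam_max`
#' Da, so both sub-Dalton offsets and whole-peptide mass differences are
#' resolvable.
#'
#' @param mz numeric vector of m/z (or mass) values
#' @param d embedding dimension (even)
#' @param lam_min,lam_max wavelength range in Da
#' @return `length(mz) x d` matrix
#' @export
sinusoid_mz <- function(mz, d, lam_min = 0.001, lam_max = 10000) {
  stopifnot(d %% 2L == 0L)
  half <- d %/% 2L
  lam <- lam_min * (lam_max / lam_min)^((seq_len(half) - 1L) / (half - 1L))
  ang <- outer(mz, 2 * pi / lam)
  cbind(sin(ang), cos(ang))
}

#' Sinusoidal position encoding
#'
#' Standard transformer position encoding: for position `pos`,
#' `sin(pos / 10000^(2i/d))` and `cos(...)` pairs.
#'
#' @param pos integer vector of 0-based positions
#' @param d embedding dimension (even)
#' @return `length(pos) x d` matrix
#' @export
sinusoid_pos <- function(pos, d) {
  stopifnot(d %% 2L == 0L)
  half <- d %/% 2L
  freq <- 1 / 10000^((seq_len(half) - 1L) / half * 2)
  ang <- outer(pos, freq)
  cbind(sin(ang), cos(ang))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, gr, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- gr[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}
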