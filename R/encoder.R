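# The spectrum encoder's input embeddings and stream fusion.  Three
# input streams -- MS1 peaks, the precursor elution profile, and the
# product-ion array slice -- are each embedded to the model dimension and
# then fused by one of three mechanisms (concatenation, standard
# attention, multi-head attention) before entering the transformer
# encoder stack.

FUSION_MODES <- c("concat", "attention", "multihead", "concat_no_ms1")

#' Embed MS1 peaks
#'
#' Each peak becomes a d-dimensional vector: a fixed sinusoidal encoding
#' of its m/z plus a learned linear embedding of its intensity,
#' element-wise added.  Zero peaks give an empty (0 x d) sequence.
#'
#' @param mz,intensity peak lists (equal length)
#' @param p parameter list holding `ms1.int.W` (1 x d) and `ms1.int.b`
#' @param d model dimension
#' @return `n x d` matrix
#' @export
embed_ms1 <- function(mz, intensity, p, d) {
  if (length(mz) == 0L) return(matrix(0, 0L, d))
  sinusoid_mz(mz, d) +
    linear_fwd(matrix(intensity, ncol = 1L), p[["ms1.int.W"]], p[["ms1.int.b"]])
}

#' Project the precursor profile
#'
#' A single learned linear map from the 2 columns (intensity, RT) of the
#' 5-point elution profile to the model dimension, applied per pair.
#'
#' @param profile `5 x 2` matrix
#' @param p parameter list holding `prof.W` (2 x d) and `prof.b`
#' @return `5 x d` matrix
#' @export
project_profile <- function(profile, p) {
  linear_fwd(profile, p[["prof.W"]], p[["prof.b"]])
}

#' Reshape and project a product-ion array slice
#'
#' The `(V, 8, 5, 10)` slice is flattened, zero-padded to a multiple of
#' the token count, cut into `n_tokens` equal chunks, and each chunk is
#' linearly mapped to the model dimension (64 tokens of 512 under the
#' default configuration).
#'
#' @param arr slice from [build_ion_array()] (or an already-reshaped
#'   `n_tokens x chunk` matrix)
#' @param p parameter list holding `ion.W` (chunk x d) and `ion.b`
#' @param n_tokens number of output tokens
#' @return `n_tokens x d` matrix
#' @export
project_ion_array <- function(arr, p, n_tokens = 64L) {
  x <- if (is.matrix(arr)) arr else ion_tokens(arr, n_tokens)
  linear_fwd(x, p[["ion.W"]], p[["ion.b"]])
}

#' Cut an ion-array slice into fixed-size token rows
#'
#' @param arr `(V, 8, 5, 10)` array
#' @param n_tokens token count
#' @return `n_tokens x chunk` matrix, `chunk = ceiling(length / n_tokens)`
#' @export
ion_tokens <- function(arr, n_tokens = 64L) {
  v <- as.numeric(arr)
  chunk <- ceiling(length(v) / n_tokens)
  length(v) <- chunk * n_tokens      # zero-pads with NA -> replace
  v[is.na(v)] <- 0
  matrix(v, nrow = n_tokens, byrow = TRUE)
}

#' Standard attention fusion (context computation)
#'
#' For each query vector `q_t` (a row of `query`), scores over the
#' context vectors `h_i` (rows of `ctx`) are `e_{t,i} = q_t . tanh(W_c
#' h_i)`, attention weights are the row-softmax of the scores, and the
#' fused context is the weighted sum `c_t = sum_i att_{t,i} h_i`.  With
#' `W_c = 0` every score is zero and the weights are uniform; with a
#' single context vector the softmax is 1 and `c_t = h_1`.
#'
#' @param query `Tq x d` query stream
#' @param ctx `N x d` context stream
#' @param Wc trainable `d x d` score matrix
#' @return list with `context` (`Tq x d`), `weights` (`Tq x N`, rows sum
#'   to 1), and a cache for the backward pass
#' @export
attention_fuse <- function(query, ctx, Wc) {
  Th <- tanh(ctx %*% Wc)
  S <- tcrossprod(query, Th)
  A <- softmax_rows(S)
  list(context = A %*% ctx, weights = A,
       cache = list(query = query, ctx = ctx, Th = Th, A = A))
}

attention_fuse_bwd <- function(dC, fw, Wc, gr) {
  cc <- fw$cache
  A <- cc$A
  dA <- tcrossprod(dC, cc$ctx)
  dctx <- crossprod(A, dC)
  dS <- A * (dA - rowSums(dA * A))
  dq <- dS %*% cc$Th
  dTh <- crossprod(dS, cc$query)
  dpre <- dTh * (1 - cc$Th * cc$Th)
  dctx <- dctx + dpre %*% t(Wc)
  gacc(gr, "fus.Wc", crossprod(cc$ctx, dpre))
  list(dquery = dq, dctx = dctx)
}

#' Fuse the embedded input streams
#'
#' * `concat`: the three token sequences are appended (with a learned
#'   stream-type marker vector added per stream) -- output length is the
#'   sum of the stream lengths.
#' * `attention`: each ion-array token attends over the MS1 + profile
#'   tokens via [attention_fuse()]; the fused output is the ion token
#'   plus its context vector (a residual, so the ion evidence itself is
#'   preserved).
#' * `multihead`: ion-array tokens are queries of a multi-head
#'   scaled-dot-product attention over all streams; again residual.
#' * `concat_no_ms1`: `concat` with the MS1 stream dropped.
#'
#' @param ms1e,profe,ione embedded streams (`n x d` matrices)
#' @param p parameter list
#' @param mode one of `"concat"`, `"attention"`, `"multihead"`,
#'   `"concat_no_ms1"`
#' @param h fusion attention heads (multihead mode)
#' @return list with `tokens`, fusion `weights` (when attention-like),
#'   and a cache
#' @export
fuse_streams <- function(ms1e, profe, ione, p, mode = "concat", h = 8L) {
  mode <- match.arg(mode, FUSION_MODES)
  if (mode %in% c("concat", "concat_no_ms1")) {
    mark <- p[["fus.mark"]]
    parts <- list()
    if (mode == "concat" && nrow(ms1e) > 0L)
      parts$ms1 <- sweep(ms1e, 2L, mark[1L, ], "+")
    parts$prof <- sweep(profe, 2L, mark[2L, ], "+")
    parts$ion <- sweep(ione, 2L, mark[3L, ], "+")
    lens <- vapply(parts, nrow, 0L)
    return(list(tokens = do.call(rbind, parts), weights = NULL,
                cache = list(mode = mode, lens = lens, has_ms1 = !is.null(parts$ms1))))
  }
  if (mode == "attention") {
    ctx <- rbind(ms1e, profe)
    fw <- attention_fuse(ione, ctx, p[["fus.Wc"]])
    return(list(tokens = ione + fw$context, weights = fw$weights,
                cache = list(mode = mode, fw = fw, n_ms1 = nrow(ms1e))))
  }
  # multihead
  kv <- rbind(ms1e, profe, ione)
  fw <- mha_fwd(ione, kv, p, "fus.attn", h)
  list(tokens = ione + fw$y, weights = fw$A,
       cache = list(mode = mode, fw = fw, n_ms1 = nrow(ms1e),
                    n_prof = nrow(profe), n_ion = nrow(ione)))
}

fuse_streams_bwd <- function(dtok, fw, p, gr, h = 8L) {
  cc <- fw$cache
  if (cc$mode %in% c("concat", "concat_no_ms1")) {
    lens <- cc$lens
    off <- 0L
    out <- list(dms1 = NULL, dprof = NULL, dion = NULL)
    nm_map <- c(ms1 = "dms1", prof = "dprof", ion = "dion")
    mark_row <- c(ms1 = 1L, prof = 2L, ion = 3L)
    for (part in names(lens)) {
      rows <- seq_len(lens[[part]]) + off
      dpart <- dtok[rows, , drop = FALSE]
      gacc(gr, "fus.mark", {
        z <- matrix(0, 3L, ncol(dtok)); z[mark_row[[part]], ] <- colSums(dpart); z
      })
      out[[nm_map[[part]]]] <- dpart
      off <- off + lens[[part]]
    }
    return(out)
  }
  if (cc$mode == "attention") {
    bw <- attention_fuse_bwd(dtok, cc$fw, p[["fus.Wc"]], gr)
    dion <- dtok + bw$dquery
    dctx <- bw$dctx
    n1 <- cc$n_ms1
    return(list(
      dms1 = if (n1 > 0L) dctx[seq_len(n1), , drop = FALSE] else NULL,
      dprof = dctx[(n1 + 1L):nrow(dctx), , drop = FALSE],
      dion = dion))
  }
  bw <- mha_bwd(dtok, cc$fw, p, "fus.attn", gr)
  dkv <- bw$dxkv
  n1 <- cc$n_ms1; np <- cc$n_prof; ni <- cc$n_ion
  dion <- dtok + bw$dxq + dkv[(n1 + np + 1L):(n1 + np + ni), , drop = FALSE]
  list(dms1 = if (n1 > 0L) dkv[seq_len(n1), , drop = FALSE] else NULL,
       dprof = dkv[(n1 + 1L):(n1 + np), , drop = FALSE],
       dion = dion)
}
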