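# The transformer encoder-decoder.  The spectrum encoder's fused token
# sequence (which, through the product-ion array, depends on the decoded
# prefix mass) is re-encoded per decoding position; the decoder runs
# causal self-attention over the prefix embedding and cross-attention in
# which position t attends the encoder memory built from the ion-array
# slice of its own prefix.  Training is teacher-forced token-level
# cross-entropy, optimized with Adam under linear learning-rate warm-up.

#' Model configuration
#'
#' The `"paper"` preset mirrors the published hyperparameters (embedding
#' size 512, 8 heads, batch 32, learning rate 5e-4, max peptide length
#' 32, 26 vocabulary slots, 64 ion-array tokens); encoder/decoder depth
#' defaults to 9 layers each (the depth used by the transformer
#' sequencing lineage this model extends).  The `"tiny"` preset is a
#' CPU-sized configuration for tests and demonstrations (d = 64, 2 + 2
#' layers, reduced 5-residue alphabet).
#'
#' @param preset `"paper"` or `"tiny"`
#' @param ... overrides for any field
#' @return list of class `model_config`
#' @export
model_config <- function(preset = c("paper", "tiny"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") {
    list(d = 512L, heads = 8L, enc_layers = 9L, dec_layers = 9L,
         ffn_dim = 1024L, max_len = 32L, ion_tokens = 64L,
         max_ms1_peaks = 128L, fusion = "concat", fusion_heads = 8L,
         lr = 5e-4, batch_size = 32L, warmup = 1000L,
         profile_rt_scale = 30, alphabet = "full", n_slots = 26L)
  } else {
    list(d = 64L, heads = 4L, enc_layers = 2L, dec_layers = 2L,
         ffn_dim = 128L, max_len = 16L, ion_tokens = 16L,
         max_ms1_peaks = 16L, fusion = "concat", fusion_heads = 4L,
         lr = 1e-3, batch_size = 8L, warmup = 20L,
         profile_rt_scale = 30, alphabet = "reduced", n_slots = NULL)
  }
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$d %% cfg$heads == 0L, cfg$max_len >= 1L)
  structure(cfg, class = "model_config")
}

#' Initialize a sequencing model
#'
#' Creates all trainable parameters (input projections, fusion
#' parameters for every mode, encoder and decoder stacks, token
#' embedding, output head).  The output head starts at zero so the
#' untrained model emits uniform next-token probabilities (initial
#' cross-entropy = log V).  Initialization is seeded and reproducible.
#'
#' @param cfg a [model_config()]
#' @param table optional [residue_table()]; defaults to the config's
#'   alphabet
#' @param seed RNG seed for parameter initialization
#' @return object of class `dia_model`
#' @export
dia_model <- function(cfg = model_config("tiny"), table = NULL, seed = 1L) {
  if (is.null(table)) {
    table <- if (is.null(cfg$n_slots)) residue_table(cfg$alphabet)
             else residue_table(cfg$alphabet, cfg$n_slots)
  }
  set.seed(seed)
  d <- cfg$d
  V <- table$n_slots
  chunk <- as.integer(ceiling(V * 8L * nrow_ms2(cfg) * ION_WINDOW / cfg$ion_tokens))
  p <- c(
    list(`ms1.int.W` = glorot(1L, d), `ms1.int.b` = numeric(d),
         `prof.W` = glorot(2L, d), `prof.b` = numeric(d),
         `ion.W` = glorot(chunk, d), `ion.b` = numeric(d),
         `fus.mark` = matrix(stats::rnorm(3L * d, sd = 0.02), 3L, d),
         `fus.Wc` = glorot(d, d),
         `tok.E` = matrix(stats::rnorm(V * d, sd = 0.02), V, d),
         `out.W` = matrix(0, d, V), `out.b` = numeric(V)),
    mk_attn_params(d, "fus.attn")
  )
  for (l in seq_len(cfg$enc_layers)) {
    pre <- sprintf("enc%d", l)
    p <- c(p, mk_ln_params(d, paste0(pre, ".ln1")),
           mk_attn_params(d, paste0(pre, ".attn")),
           mk_ln_params(d, paste0(pre, ".ln2")),
           mk_ffn_params(d, cfg$ffn_dim, paste0(pre, ".ffn")))
  }
  p <- c(p, mk_ln_params(d, "enc.lnf"))
  for (l in seq_len(cfg$dec_layers)) {
    pre <- sprintf("dec%d", l)
    p <- c(p, mk_ln_params(d, paste0(pre, ".ln1")),
           mk_attn_params(d, paste0(pre, ".self")),
           mk_ln_params(d, paste0(pre, ".ln2")),
           mk_attn_params(d, paste0(pre, ".cross")),
           mk_ln_params(d, paste0(pre, ".ln3")),
           mk_ffn_params(d, cfg$ffn_dim, paste0(pre, ".ffn")))
  }
  p <- c(p, mk_ln_params(d, "dec.lnf"))
  structure(list(cfg = cfg, table = table, params = p, chunk = chunk,
                 history = NULL),
            class = "dia_model")
}

nrow_ms2 <- function(cfg) 5L   # MS2 stack depth (fixed by the data model)

#' @export
print.dia_model <- function(x, ...) {
  cat(sprintf(
    "dia_model: d=%d, %d+%d layers, fusion=%s, vocab %d slots, %d params\n",
    x$cfg$d, x$cfg$enc_layers, x$cfg$dec_layers, x$cfg$fusion,
    x$table$n_slots, sum(vapply(x$params, length, 0L))))
  invisible(x)
}

#' Embed the precursor (mass, charge) pair
#'
#' Sinusoidal mass encoding plus sinusoidal encoding of the integer
#' charge, summed; deterministic (no trainable parameters).
#'
#' @param mass neutral precursor mass, Da (> 0)
#' @param charge integer charge (>= 1)
#' @param d embedding dimension
#' @return `1 x d` matrix
#' @export
embed_precursor <- function(mass, charge, d) {
  stopifnot(mass > 0, charge >= 1)
  sinusoid_mz(mass, d) + sinusoid_pos(as.numeric(charge), d)
}

#' Embed a decoding prefix
#'
#' Learned residue embeddings plus sinusoidal position encodings; the
#' start token occupies position 0, so an empty prefix embeds to the
#' single start row.
#'
#' @param model a [dia_model()]
#' @param prefix character vector of residue symbols (possibly empty)
#' @return `(length(prefix) + 1) x d` matrix
#' @export
embed_prefix <- function(model, prefix) {
  tab <- model$table
  ids <- c(tab$start_id,
           if (length(prefix)) match(peptide_symbols(tab, prefix), tab$symbols))
  model$params[["tok.E"]][ids, , drop = FALSE] +
    sinusoid_pos(seq_along(ids) - 1, model$cfg$d)
}

# ---- encoder stack --------------------------------------------------------

enc_layer_fwd <- function(p, x, pre, h) {
  l1 <- ln_fwd(x, p[[paste0(pre, ".ln1.g")]], p[[paste0(pre, ".ln1.b")]])
  sa <- mha_fwd(l1$y, l1$y, p, paste0(pre, ".attn"), h)
  x1 <- x + sa$y
  l2 <- ln_fwd(x1, p[[paste0(pre, ".ln2.g")]], p[[paste0(pre, ".ln2.b")]])
  ff <- ffn_fwd(l2$y, p, paste0(pre, ".ffn"))
  list(y = x1 + ff$y, l1 = l1, sa = sa, l2 = l2, ff = ff)
}

enc_layer_bwd <- function(p, dy, cc, pre, h, gr) {
  dl2y <- ffn_bwd(dy, cc$ff, p, paste0(pre, ".ffn"), gr)
  dx1 <- dy + ln_bwd(dl2y, cc$l2, p[[paste0(pre, ".ln2.g")]], gr,
                     paste0(pre, ".ln2"))
  mb <- mha_bwd(dx1, cc$sa, p, paste0(pre, ".attn"), gr)
  dx1 + ln_bwd(mb$dxq + mb$dxkv, cc$l1, p[[paste0(pre, ".ln1.g")]], gr,
               paste0(pre, ".ln1"))
}

encoder_fwd <- function(p, x, cfg) {
  caches <- vector("list", cfg$enc_layers)
  for (l in seq_len(cfg$enc_layers)) {
    caches[[l]] <- enc_layer_fwd(p, x, sprintf("enc%d", l), cfg$heads)
    x <- caches[[l]]$y
  }
  lf <- ln_fwd(x, p[["enc.lnf.g"]], p[["enc.lnf.b"]])
  list(mem = lf$y, caches = caches, lf = lf)
}

encoder_bwd <- function(p, dmem, fw, cfg, gr) {
  dx <- ln_bwd(dmem, fw$lf, p[["enc.lnf.g"]], gr, "enc.lnf")
  for (l in rev(seq_len(cfg$enc_layers))) {
    dx <- enc_layer_bwd(p, dx, fw$caches[[l]], sprintf("enc%d", l),
                        cfg$heads, gr)
  }
  dx
}

# ---- decoder --------------------------------------------------------------

# mems: list of length T (encoder memory for each decoding position)
dec_fwd <- function(p, D0, mems, cfg) {
  x <- D0
  Tn <- nrow(D0)
  caches <- vector("list", cfg$dec_layers)
  for (l in seq_len(cfg$dec_layers)) {
    pre <- sprintf("dec%d", l)
    l1 <- ln_fwd(x, p[[paste0(pre, ".ln1.g")]], p[[paste0(pre, ".ln1.b")]])
    sa <- mha_fwd(l1$y, l1$y, p, paste0(pre, ".self"), cfg$heads,
                  causal = TRUE)
    x <- x + sa$y
    l2 <- ln_fwd(x, p[[paste0(pre, ".ln2.g")]], p[[paste0(pre, ".ln2.b")]])
    crossfw <- vector("list", Tn)
    C <- matrix(0, Tn, cfg$d)
    for (t in seq_len(Tn)) {
      crossfw[[t]] <- mha_fwd(l2$y[t, , drop = FALSE], mems[[t]], p,
                              paste0(pre, ".cross"), cfg$heads)
      C[t, ] <- crossfw[[t]]$y
    }
    x <- x + C
    l3 <- ln_fwd(x, p[[paste0(pre, ".ln3.g")]], p[[paste0(pre, ".ln3.b")]])
    ff <- ffn_fwd(l3$y, p, paste0(pre, ".ffn"))
    x <- x + ff$y
    caches[[l]] <- list(l1 = l1, sa = sa, l2 = l2, cross = crossfw,
                        l3 = l3, ff = ff)
  }
  lf <- ln_fwd(x, p[["dec.lnf.g"]], p[["dec.lnf.b"]])
  logits <- linear_fwd(lf$y, p[["out.W"]], p[["out.b"]])
  list(logits = logits, caches = caches, lf = lf)
}

dec_bwd <- function(p, dlogits, fw, mems, cfg, gr) {
  Tn <- nrow(dlogits)
  dx <- linear_bwd(dlogits, fw$lf$y, p[["out.W"]], gr, "out")
  dx <- ln_bwd(dx, fw$lf, p[["dec.lnf.g"]], gr, "dec.lnf")
  dmems <- lapply(mems, function(m) matrix(0, nrow(m), cfg$d))
  for (l in rev(seq_len(cfg$dec_layers))) {
    pre <- sprintf("dec%d", l)
    cc <- fw$caches[[l]]
    dl3y <- ffn_bwd(dx, cc$ff, p, paste0(pre, ".ffn"), gr)
    dx <- dx + ln_bwd(dl3y, cc$l3, p[[paste0(pre, ".ln3.g")]], gr,
                      paste0(pre, ".ln3"))
    dl2y <- matrix(0, Tn, cfg$d)
    for (t in seq_len(Tn)) {
      cb <- mha_bwd(dx[t, , drop = FALSE], cc$cross[[t]], p,
                    paste0(pre, ".cross"), gr)
      dl2y[t, ] <- cb$dxq
      dmems[[t]] <- dmems[[t]] + cb$dxkv
    }
    dx <- dx + ln_bwd(dl2y, cc$l2, p[[paste0(pre, ".ln2.g")]], gr,
                      paste0(pre, ".ln2"))
    sb <- mha_bwd(dx, cc$sa, p, paste0(pre, ".self"), gr)
    dx <- dx + ln_bwd(sb$dxq + sb$dxkv, cc$l1, p[[paste0(pre, ".ln1.g")]],
                      gr, paste0(pre, ".ln1"))
  }
  list(dD0 = dx, dmems = dmems)
}

# ---- example preparation --------------------------------------------------

#' Prepare one labelled feature context for training
#'
#' Precomputes everything that does not depend on the parameters: the
#' capped/normalized MS1 peak list, the scaled profile inputs, the
#' ion-array token matrices for every teacher-forced position, the
#' precursor embedding, and target ids.
#'
#' @param model a [dia_model()]
#' @param ctx a labelled [assemble_context()] feature context
#' @return an opaque example list, or `NULL` if the label is missing or
#'   longer than `max_len - 1`
#' @export
prepare_example <- function(model, ctx) {
  tab <- model$table; cfg <- model$cfg
  if (is.na(ctx$peptide)) return(NULL)
  syms <- peptide_symbols(tab, ctx$peptide)
  n <- length(syms)
  if (n == 0L || n > cfg$max_len - 1L) return(NULL)
  ids <- match(syms, tab$symbols)
  ion_tok <- vector("list", n + 1L)
  for (t in seq_len(n + 1L)) {
    ion_tok[[t]] <- ion_tokens(
      build_ion_array(syms[seq_len(t - 1L)], ctx, tab), cfg$ion_tokens)
  }
  list(feature_id = ctx$feature_id, peptide = ctx$peptide,
       input_ids = c(tab$start_id, ids),
       targets = c(ids, tab$stop_id),
       ion_tok = ion_tok,
       ms1 = .prep_ms1(ctx, cfg),
       prof_in = .prep_profile(ctx, cfg),
       prec_emb = embed_precursor(ctx$mass, ctx$charge, cfg$d),
       pos_emb = sinusoid_pos(0:n, cfg$d))
}

.prep_ms1 <- function(ctx, cfg) {
  mz <- ctx$ms1_mz; int <- ctx$ms1_intensity
  if (length(mz) > cfg$max_ms1_peaks) {
    keep <- order(-int, mz)[seq_len(cfg$max_ms1_peaks)]
    mz <- mz[keep]; int <- int[keep]
    o <- order(mz); mz <- mz[o]; int <- int[o]
  }
  if (length(int) && max(int) > 0) int <- int / max(int)
  list(mz = mz, int = int)
}

.prep_profile <- function(ctx, cfg) {
  pint <- ctx$profile[, 1L]
  prt <- ctx$profile[, 2L]
  if (max(pint) > 0) pint <- pint / max(pint)
  ctr <- if (!is.null(ctx$rt_center)) ctx$rt_center else mean(prt)
  cbind(pint, (prt - ctr) / cfg$profile_rt_scale)
}

# ---- full forward / backward over one example -----------------------------

model_forward <- function(model, ex, gr = NULL) {
  p <- model$params; cfg <- model$cfg
  Tn <- length(ex$targets)
  ms1e <- embed_ms1(ex$ms1$mz, ex$ms1$int, p, cfg$d)
  profe <- project_profile(ex$prof_in, p)
  mems <- vector("list", Tn)
  fuses <- vector("list", Tn)
  encs <- vector("list", Tn)
  iones <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    iones[[t]] <- linear_fwd(ex$ion_tok[[t]], p[["ion.W"]], p[["ion.b"]])
    fuses[[t]] <- fuse_streams(ms1e, profe, iones[[t]], p, cfg$fusion,
                               cfg$fusion_heads)
    encs[[t]] <- encoder_fwd(p, fuses[[t]]$tokens, cfg)
    mems[[t]] <- encs[[t]]$mem
  }
  D0 <- p[["tok.E"]][ex$input_ids, , drop = FALSE] + ex$pos_emb
  D0[1L, ] <- D0[1L, ] + ex$prec_emb
  dec <- dec_fwd(p, D0, mems, cfg)
  probs <- softmax_rows(dec$logits)
  loss <- -mean(log(pmax(probs[cbind(seq_len(Tn), ex$targets)], 1e-12)))
  if (is.null(gr)) {
    return(list(loss = loss, logits = dec$logits))
  }
  dlogits <- probs
  dlogits[cbind(seq_len(Tn), ex$targets)] <-
    dlogits[cbind(seq_len(Tn), ex$targets)] - 1
  dlogits <- dlogits / Tn
  db <- dec_bwd(p, dlogits, dec, mems, cfg, gr)
  # token embedding gradients
  dE <- matrix(0, nrow(p[["tok.E"]]), cfg$d)
  for (i in seq_len(Tn)) {
    dE[ex$input_ids[i], ] <- dE[ex$input_ids[i], ] + db$dD0[i, ]
  }
  gacc(gr, "tok.E", dE)
  dms1_tot <- matrix(0, nrow(ms1e), cfg$d)
  dprof_tot <- matrix(0, nrow(profe), cfg$d)
  for (t in seq_len(Tn)) {
    dtok <- encoder_bwd(p, db$dmems[[t]], encs[[t]], cfg, gr)
    fb <- fuse_streams_bwd(dtok, fuses[[t]], p, gr, cfg$fusion_heads)
    if (!is.null(fb$dms1) && nrow(ms1e) > 0L) dms1_tot <- dms1_tot + fb$dms1
    dprof_tot <- dprof_tot + fb$dprof
    linear_bwd(fb$dion, ex$ion_tok[[t]], p[["ion.W"]], gr, "ion")
  }
  if (nrow(ms1e) > 0L) {
    linear_bwd(dms1_tot, matrix(ex$ms1$int, ncol = 1L), p[["ms1.int.W"]],
               gr, "ms1.int")
  }
  linear_bwd(dprof_tot, ex$prof_in, p[["prof.W"]], gr, "prof")
  list(loss = loss, logits = dec$logits)
}

#' Teacher-forced next-token logits for one prefix
#'
#' Runs the full model on `prefix` and returns the next-token logits at
#' the final position.  Mainly a reference path; decoding uses an
#' internal session with encoder-memory memoization, and the two agree
#' (causal-mask correctness).
#'
#' @param model a [dia_model()]
#' @param ctx a feature context
#' @param prefix character vector of residue symbols decoded so far
#' @return numeric vector of length V (logits)
#' @export
forward_step <- function(model, ctx, prefix = character(0)) {
  sess <- decode_session(model, ctx)
  ids <- if (length(prefix))
    match(peptide_symbols(model$table, prefix), model$table$symbols)
  else integer(0)
  session_logits(sess, ids)
}

# A decode session caches parameter-dependent, prefix-independent pieces
# and memoizes encoder memories by prefix residue mass.
decode_session <- function(model, ctx) {
  p <- model$params; cfg <- model$cfg
  e <- new.env(parent = emptyenv())
  e$model <- model; e$ctx <- ctx
  ms1 <- .prep_ms1(ctx, cfg)
  e$ms1e <- embed_ms1(ms1$mz, ms1$int, p, cfg$d)
  e$profe <- project_profile(.prep_profile(ctx, cfg), p)
  e$prec_emb <- embed_precursor(ctx$mass, ctx$charge, cfg$d)
  e$memo <- new.env(parent = emptyenv())
  e
}

session_memory <- function(sess, prefix_mass) {
  key <- sprintf("%.5f", prefix_mass)
  m <- sess$memo[[key]]
  if (!is.null(m)) return(m)
  model <- sess$model; p <- model$params; cfg <- model$cfg
  arr <- .ion_slice_mass(prefix_mass, sess$ctx, model$table)
  ione <- linear_fwd(ion_tokens(arr, cfg$ion_tokens), p[["ion.W"]],
                     p[["ion.b"]])
  fw <- fuse_streams(sess$ms1e, sess$profe, ione, p, cfg$fusion,
                     cfg$fusion_heads)
  mem <- encoder_fwd(p, fw$tokens, cfg)$mem
  sess$memo[[key]] <- mem
  mem
}

session_logits <- function(sess, prefix_ids) {
  model <- sess$model; p <- model$params; cfg <- model$cfg
  tab <- model$table
  n <- length(prefix_ids)
  masses <- c(0, cumsum(tab$mass[prefix_ids]))
  mems <- lapply(masses, function(m) session_memory(sess, m))
  ids <- c(tab$start_id, prefix_ids)
  D0 <- p[["tok.E"]][ids, , drop = FALSE] + sinusoid_pos(0:n, cfg$d)
  D0[1L, ] <- D0[1L, ] + sess$prec_emb
  dec <- dec_fwd(p, D0, mems, cfg)
  dec$logits[n + 1L, ]
}

# ion-array slice parameterized by prefix mass directly (decoding path)
.ion_slice_mass <- function(prefix_mass, ctx, table, tol = 0.5) {
  V <- table$n_slots
  nspec <- nrow(ctx$ms2_binned)
  arr <- array(0, dim = c(V, 8L, nspec, ION_WINDOW))
  total_mass <- ctx$mass - H2O_MASS
  if (prefix_mass > total_mass + tol) {
    attr(arr, "mass_exceeded") <- TRUE
    return(arr)
  }
  it <- ion_types()
  w <- ctx$w; L <- ctx$L; half <- ION_WINDOW / 2L
  cut <- prefix_mass + table$mass
  cut[!table$is_residue | cut > total_mass + 1e-9] <- NA
  for (k in seq_len(8L)) {
    mz <- if (it$series[k] == "prefix") {
      (cut - it$loss[k] + it$charge[k] * PROTON_MASS) / it$charge[k]
    } else {
      (total_mass - cut + H2O_MASS - it$loss[k] +
         it$charge[k] * PROTON_MASS) / it$charge[k]
    }
    ctr <- floor(mz / w)
    ctr[!is.na(ctr) & (ctr < 0 | ctr >= L)] <- NA
    for (v in which(!is.na(ctr))) {
      bins <- (ctr[v] - half):(ctr[v] + half - 1L)
      ok <- bins >= 0 & bins < L
      if (any(ok)) {
        arr[v, k, , which(ok)] <- ctx$ms2_binned[, bins[ok] + 1L, drop = FALSE]
      }
    }
  }
  attr(arr, "mass_exceeded") <- FALSE
  arr
}

# ---- training -------------------------------------------------------------

#' Train the model by teacher forcing
#'
#' Token-level cross-entropy against the ground-truth sequences, Adam
#' with linear learning-rate warm-up, seeded data-order shuffling.
#' Optionally evaluates greedy-decoding peptide accuracy on the training
#' set every `eval_every` epochs and stops early once `target_acc` is
#' reached.
#'
#' @param contexts list of labelled feature contexts
#' @param cfg a [model_config()]
#' @param epochs maximum epochs
#' @param seed seed for parameter init and shuffling
#' @param eval_every evaluate training peptide accuracy every this many
#'   epochs (0 = never)
#' @param target_acc early-stop threshold on training peptide accuracy
#' @param mass_tol precursor mass tolerance used in the greedy accuracy
#'   evaluation, Da
#' @param verbose print per-epoch progress
#' @return a trained [dia_model()] with a `history` data.frame
#'   (epoch, loss, train_pep_acc)
#' @export
train_model <- function(contexts, cfg = model_config("tiny"), epochs = 50L,
                        seed = 1L, eval_every = 10L, target_acc = NULL,
                        mass_tol = 0.5, verbose = FALSE) {
  if (length(contexts) == 0L) stop("empty training dataset")
  model <- dia_model(cfg, seed = seed)
  exs <- Filter(Negate(is.null), lapply(contexts, prepare_example,
                                        model = model))
  if (length(exs) == 0L) stop("no usable labelled examples")
  st <- adam_init(model$params)
  set.seed(seed + 1L)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_pep_acc = numeric(0))
  nb <- max(1L, ceiling(length(exs) / cfg$batch_size))
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(length(exs))
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[seq.int((b - 1L) * cfg$batch_size + 1L,
                         min(b * cfg$batch_size, length(exs)))]
      gr <- new_grads()
      for (i in idx) {
        ep_loss <- ep_loss + model_forward(model, exs[[i]], gr)$loss
      }
      for (nm in ls(gr)) gr[[nm]] <- gr[[nm]] / length(idx)
      step <- step + 1L
      lr_t <- cfg$lr * min(1, step / max(1L, cfg$warmup))
      up <- adam_step(model$params, gr, st, lr_t)
      model$params <- up$params
      st <- up$st
    }
    acc <- NA_real_
    if (eval_every > 0L && (ep %% eval_every == 0L || ep == epochs)) {
      acc <- peptide_accuracy(model, contexts, mass_tol = mass_tol)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / length(exs),
                                   train_pep_acc = acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %s", ep,
                      ep_loss / length(exs),
                      ifelse(is.na(acc), "-", sprintf("%.2f", acc))))
    if (!is.null(target_acc) && !is.na(acc) && acc >= target_acc) break
  }
  model$history <- hist
  model
}

#' Greedy-decoding peptide accuracy on labelled contexts
#'
#' @param model a trained [dia_model()]
#' @param contexts labelled feature contexts
#' @param mass_tol precursor mass tolerance, Da
#' @return fraction of contexts whose greedy (beam k = 1) decode equals
#'   the label exactly
#' @export
peptide_accuracy <- function(model, contexts, mass_tol = 0.5) {
  hits <- vapply(contexts, function(ctx) {
    if (is.na(ctx$peptide)) return(NA)
    preds <- beam_search(ctx, model,
                         beam_config(k = 1L, max_len = model$cfg$max_len,
                                     mass_tol = mass_tol))
    length(preds) > 0L && identical(preds[[1L]]$peptide, ctx$peptide)
  }, TRUE)
  mean(hits, na.rm = TRUE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: configuration, parameters, residue
#' table and training history in one RDS file.
#'
#' @param model a [dia_model()]
#' @param path checkpoint path
#' @return `load_model` returns the model
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "dia_model")
}
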