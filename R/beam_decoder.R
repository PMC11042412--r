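# Beam-search inference with precursor-mass filtering and confidence
# scoring.

#' Beam-search configuration
#'
#' @param k beam width (default 20)
#' @param max_len maximum residue sequence length (default 32)
#' @param mass_tol precursor mass tolerance (default 0.1)
#' @param tol_unit `"Da"` (absolute) or `"ppm"` (relative to the
#'   precursor neutral mass)
#' @param confidence `"mean"` (length-normalized sum of per-residue
#'   log-probabilities, the default) or `"sum"`
#' @return list of class `beam_config`
#' @export
beam_config <- function(k = 20L, max_len = 32L, mass_tol = 0.1,
                        tol_unit = c("Da", "ppm"),
                        confidence = c("mean", "sum")) {
  stopifnot(k >= 1L, mass_tol > 0)
  structure(list(k = as.integer(k), max_len = as.integer(max_len),
                 mass_tol = mass_tol, tol_unit = match.arg(tol_unit),
                 confidence = match.arg(confidence)),
            class = "beam_config")
}

#' Next-token log-probabilities for a decoding prefix
#'
#' Generic scorer interface used by [beam_search()]: trained models
#' dispatch to the transformer forward pass; tests can supply hand-built
#' scorers (any object with a `step_logprobs` method returning a
#' length-V vector of log-probabilities over the vocabulary slots).
#'
#' @param scorer model or mock scorer
#' @param prefix_ids integer vector of vocabulary slot ids decoded so far
#' @param ctx feature context
#' @param session opaque per-decode state created by the scorer
#' @return numeric length-V log-probability vector
#' @export
step_logprobs <- function(scorer, prefix_ids, ctx, session = NULL) {
  UseMethod("step_logprobs")
}

#' @export
step_logprobs.dia_model <- function(scorer, prefix_ids, ctx, session = NULL) {
  logits <- session_logits(session, prefix_ids)
  logits - log(sum(exp(logits - max(logits)))) - max(logits)
}

#' @export
step_logprobs.function <- function(scorer, prefix_ids, ctx, session = NULL) {
  scorer(prefix_ids)
}

.open_session <- function(scorer, ctx) {
  if (inherits(scorer, "dia_model")) decode_session(scorer, ctx) else NULL
}

#' Confidence score of a prediction
#'
#' The length-normalized sum (mean) of the per-residue
#' log-probabilities; an empty sequence has no defined score.
#'
#' @param logps per-residue log-probabilities
#' @param method `"mean"` or `"sum"`
#' @return scalar confidence
#' @export
prediction_score <- function(logps, method = "mean") {
  if (length(logps) == 0L) stop("confidence undefined for an empty sequence")
  if (method == "mean") mean(logps) else sum(logps)
}

#' Beam-search decoding under a precursor-mass constraint
#'
#' Iteratively expands the `k` highest cumulative-log-probability
#' hypotheses.  A branch whose running residue mass already exceeds the
#' precursor's residue-mass budget plus the tolerance is terminated and
#' discarded during expansion; a hypothesis finishes when the stop token
#' is emitted (or the maximum length forces it), and is kept only if its
#' full peptide mass lies within the tolerance of the precursor neutral
#' mass (both sides).  Finished hypotheses are ranked by confidence
#' (mean per-residue log-probability); equal scores are ordered by
#' lexicographic sequence for determinism.  Beam width 1 is exactly
#' greedy decoding.
#'
#' @param ctx a [assemble_context()] feature context
#' @param scorer a trained [dia_model()] or any [step_logprobs()] scorer
#' @param cfg a [beam_config()]
#' @param table residue table (defaults to the model's)
#' @return list of predictions, best first; each has `peptide`,
#'   `symbols`, `logps`, `confidence`, `feature_id`.  Empty list when no
#'   hypothesis survives the mass filter.
#' @export
beam_search <- function(ctx, scorer, cfg = beam_config(),
                        table = if (inherits(scorer, "dia_model"))
                          scorer$table else residue_table()) {
  tol <- if (cfg$tol_unit == "ppm") ctx$mass * cfg$mass_tol * 1e-6
         else cfg$mass_tol
  budget <- ctx$mass - H2O_MASS      # residue-mass budget
  res_ids <- which(table$is_residue)
  banned <- which(!table$is_residue & seq_len(table$n_slots) != table$stop_id)
  session <- .open_session(scorer, ctx)

  active <- list(list(seq = integer(0), logps = numeric(0), cum = 0, mass = 0))
  finished <- list()
  seq_key <- function(ids) paste(sprintf("%03d", ids), collapse = "")

  while (length(active) > 0L) {
    cand <- list()
    for (hyp in active) {
      lp <- step_logprobs(scorer, hyp$seq, ctx, session)
      lp[banned] <- -Inf
      at_max <- length(hyp$seq) >= cfg$max_len
      for (tok in seq_along(lp)) {
        if (!is.finite(lp[tok])) next
        if (tok == table$stop_id) {
          # stop competes for a beam slot; if selected, the hypothesis
          # terminates (and survives only if the full mass fits)
          if (length(hyp$seq) == 0L) next
          cand[[length(cand) + 1L]] <- list(
            seq = hyp$seq, logps = hyp$logps,
            cum = hyp$cum + lp[tok], mass = hyp$mass, done = TRUE)
        } else {
          if (at_max) next
          nm <- hyp$mass + table$mass[tok]
          if (nm > budget + tol) next           # early mass pruning
          cand[[length(cand) + 1L]] <- list(
            seq = c(hyp$seq, tok), logps = c(hyp$logps, lp[tok]),
            cum = hyp$cum + lp[tok], mass = nm, done = FALSE)
        }
      }
    }
    if (length(cand) == 0L) break
    cums <- vapply(cand, `[[`, 0, "cum")
    keys <- vapply(cand, function(h) seq_key(h$seq), "")
    sel <- cand[order(-cums, keys)[seq_len(min(cfg$k, length(cand)))]]
    active <- list()
    for (h in sel) {
      if (h$done) {
        if (abs((h$mass + H2O_MASS) - ctx$mass) <= tol) {
          finished[[length(finished) + 1L]] <- list(
            seq = h$seq, logps = h$logps,
            confidence = prediction_score(h$logps, cfg$confidence))
        }
      } else {
        active[[length(active) + 1L]] <- h
      }
    }
  }
  if (length(finished) == 0L) {
    message(sprintf("feature %s: no hypothesis within the precursor mass tolerance",
                    ctx$feature_id))
    return(list())
  }
  confs <- vapply(finished, `[[`, 0, "confidence")
  keys <- vapply(finished, function(h) seq_key(h$seq), "")
  finished <- finished[order(-confs, keys)]
  lapply(finished, function(h) {
    syms <- table$symbols[h$seq]
    structure(list(feature_id = ctx$feature_id,
                   peptide = paste(syms, collapse = ""),
                   symbols = syms, logps = unname(h$logps),
                   confidence = h$confidence),
              class = "peptide_prediction")
  })
}

#' @export
print.peptide_prediction <- function(x, ...) {
  cat(sprintf("%s  %s  conf=%.4f\n", x$feature_id, x$peptide, x$confidence))
  invisible(x)
}

#' Decode a set of features and tabulate predictions
#'
#' Runs [beam_search()] on each context and keeps the top prediction per
#' feature (features with no surviving hypothesis are omitted).
#'
#' @param model a trained [dia_model()]
#' @param contexts list of feature contexts
#' @param cfg a [beam_config()]
#' @return data.frame: feature_id, peptide, confidence, aa_scores
#'   (comma-joined per-residue log-probabilities), precursor_mz, charge
#' @export
predict_features <- function(model, contexts, cfg = beam_config()) {
  rows <- lapply(contexts, function(ctx) {
    preds <- beam_search(ctx, model, cfg)
    if (length(preds) == 0L) return(NULL)
    p <- preds[[1L]]
    data.frame(feature_id = p$feature_id, peptide = p$peptide,
               confidence = p$confidence,
               aa_scores = paste(sprintf("%.6f", p$logps), collapse = ","),
               precursor_mz = (ctx$mass + ctx$charge * PROTON_MASS) / ctx$charge,
               charge = ctx$charge, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(feature_id = character(0), peptide = character(0),
                      confidence = numeric(0), aa_scores = character(0),
                      precursor_mz = numeric(0), charge = integer(0)))
  }
  do.call(rbind, rows)
}

#' Write / read the predictions TSV
#'
#' @param df predictions data.frame from [predict_features()]
#' @param path TSV path
#' @export
write_predictions <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(feature_id = "character",
                                   peptide = "character"))
}
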