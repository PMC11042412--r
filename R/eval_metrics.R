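# Mass-based evaluation of predictions: residue matching on the prefix
# mass ladder, amino-acid precision/recall, peptide precision, and
# confidence-ranked precision-coverage curves with AUC.

#' Count mass-matched residues between prediction and truth
#'
#' The two prefix-mass ladders are aligned greedily left-to-right:
#' predicted residue j matches truth residue i when their cumulative
#' prefix masses differ by less than `prefix_tol` (0.5 Da) AND their
#' residue masses differ by less than `residue_tol` (0.1 Da); on a
#' failed residue check the pointer with the smaller prefix mass
#' advances.  Each residue is matched at most once.  Isobaric
#' substitutions (Leu/Ile) therefore count as matches.
#'
#' @param table a [residue_table()]
#' @param pred,truth peptide strings or symbol vectors
#' @param prefix_tol,residue_tol tolerances in Da
#' @return integer matched-residue count
#' @export
match_residues <- function(table, pred, truth, prefix_tol = 0.5,
                           residue_tol = 0.1) {
  ps <- peptide_symbols(table, pred)
  ts <- peptide_symbols(table, truth)
  if (length(ps) == 0L || length(ts) == 0L) return(0L)
  pm <- cumsum(residue_mass(table, ps))
  tm <- cumsum(residue_mass(table, ts))
  rp <- residue_mass(table, ps)
  rt <- residue_mass(table, ts)
  i <- 1L; j <- 1L; matched <- 0L
  while (i <= length(ts) && j <= length(ps)) {
    if (abs(pm[j] - tm[i]) < prefix_tol) {
      if (abs(rp[j] - rt[i]) < residue_tol) matched <- matched + 1L
      i <- i + 1L; j <- j + 1L
    } else if (tm[i] < pm[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  matched
}

#' Aggregate residue matches into an evaluation report
#'
#' Amino-acid precision is total matched residues over total predicted
#' residues; recall is matched over total truth residues; peptide
#' precision is the fraction of truths whose prediction matches every
#' residue with equal lengths.  Missing predictions (unsequenced
#' features) contribute zero matches and zero predicted length.
#'
#' @param table a [residue_table()]
#' @param pairs list of `list(pred = <string or NA>, truth = <string>)`
#' @return object of class `eval_report` (fields `aa_precision`,
#'   `aa_recall`, `peptide_precision`, `n_truth`, `n_predicted`,
#'   `no_predictions` flag)
#' @export
aggregate_eval <- function(table, pairs) {
  m_tot <- 0L; p_tot <- 0L; t_tot <- 0L; pep_ok <- 0L
  for (pr in pairs) {
    ts <- peptide_symbols(table, pr$truth)
    t_tot <- t_tot + length(ts)
    if (is.null(pr$pred) || is.na(pr$pred)) next
    ps <- peptide_symbols(table, pr$pred)
    m <- match_residues(table, pr$pred, pr$truth)
    m_tot <- m_tot + m
    p_tot <- p_tot + length(ps)
    if (m == length(ts) && length(ps) == length(ts)) pep_ok <- pep_ok + 1L
  }
  structure(list(
    aa_precision = if (p_tot > 0L) m_tot / p_tot else 0,
    aa_recall = if (t_tot > 0L) m_tot / t_tot else 0,
    peptide_precision = if (length(pairs)) pep_ok / length(pairs) else 0,
    n_truth = length(pairs),
    n_predicted = sum(vapply(pairs, function(pr)
      !is.null(pr$pred) && !is.na(pr$pred), TRUE)),
    no_predictions = p_tot == 0L
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: aa precision %.3f, aa recall %.3f, peptide precision %.3f (%d/%d predicted)\n",
    x$aa_precision, x$aa_recall, x$peptide_precision, x$n_predicted,
    x$n_truth))
  if (!is.null(x$auc)) cat(sprintf("  coverage %.3f, AUC %.4f\n",
                                   x$coverage, x$auc))
  invisible(x)
}

.peptide_correct <- function(table, pred, truth) {
  ts <- peptide_symbols(table, truth)
  ps <- peptide_symbols(table, pred)
  length(ps) == length(ts) &&
    match_residues(table, pred, truth) == length(ts)
}

#' Precision-coverage curve and AUC
#'
#' Predictions are ranked by confidence (descending; ties broken stably
#' by feature id).  At rank r, coverage is the rank divided by the truth
#' count and precision is the fraction of the top-r predictions that are
#' fully correct.  The
#' AUC is the trapezoidal integral of precision over coverage from 0 to
#' the achieved maximum coverage (no extrapolation to 1).
#'
#' @param table a [residue_table()]
#' @param preds data.frame with `feature_id`, `peptide`, `confidence`
#' @param truths named character vector: feature id -> truth peptide
#' @return list with `curve` (data.frame coverage/precision per rank)
#'   and `auc`
#' @export
precision_coverage <- function(table, preds, truths) {
  n_truth <- length(truths)
  if (nrow(preds) == 0L || n_truth == 0L) {
    return(list(curve = data.frame(coverage = numeric(0),
                                   precision = numeric(0)), auc = 0))
  }
  o <- order(-preds$confidence, preds$feature_id)
  preds <- preds[o, , drop = FALSE]
  correct <- vapply(seq_len(nrow(preds)), function(r) {
    tid <- preds$feature_id[r]
    !is.na(truths[tid]) && .peptide_correct(table, preds$peptide[r],
                                            truths[[tid]])
  }, TRUE)
  r <- seq_along(correct)
  curve <- data.frame(coverage = r / n_truth,
                      precision = cumsum(correct) / r)
  auc <- sum(diff(c(0, curve$coverage)) *
             (c(curve$precision[1L], utils::head(curve$precision, -1L)) +
              curve$precision) / 2)
  list(curve = curve, auc = auc)
}

#' Evaluate a prediction table against labelled features
#'
#' Combines [aggregate_eval()] and [precision_coverage()] into one
#' report.
#'
#' @param table a [residue_table()]
#' @param preds predictions data.frame (see [predict_features()])
#' @param truths named character vector (feature id -> truth peptide),
#'   e.g. from a labelled feature table
#' @return `eval_report` with curve and AUC attached
#' @export
evaluate_predictions <- function(table, preds, truths) {
  pairs <- lapply(names(truths), function(fid) {
    hit <- match(fid, preds$feature_id)
    list(pred = if (is.na(hit)) NA_character_ else preds$peptide[hit],
         truth = truths[[fid]])
  })
  rep <- aggregate_eval(table, pairs)
  pc <- precision_coverage(table, preds, truths)
  rep$curve <- pc$curve
  rep$auc <- pc$auc
  rep$coverage <- if (nrow(pc$curve)) max(pc$curve$coverage) else 0
  rep
}

#' Write an evaluation report
#'
#' The scalar metrics go to a JSON file and the precision-coverage
#' curve to a CSV next to it.
#'
#' @param report an `eval_report`
#' @param path output JSON path (`<path>.curve.csv` holds the curve)
#' @export
write_eval_report <- function(report, path) {
  scalars <- report[c("aa_precision", "aa_recall", "peptide_precision",
                      "coverage", "auc", "n_truth", "n_predicted")]
  jsonlite::write_json(scalars[!vapply(scalars, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$curve)) {
    utils::write.csv(report$curve, paste0(path, ".curve.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Truth labels from a feature list
#'
#' @param features list of [precursor_feature()]
#' @return named character vector (feature id -> peptide), labelled
#'   features only
#' @export
feature_truths <- function(features) {
  labs <- vapply(features, `[[`, "", "peptide")
  names(labs) <- vapply(features, `[[`, "", "feature_id")
  labs[!is.na(labs)]
}
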