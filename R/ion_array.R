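# The product-ion intensity array: for a decoding position (a prefix) and
# every candidate vocabulary slot, locate all 8 theoretical product ions
# in each of the 5 binned MS2 spectra and extract a 10-bin intensity
# window around each location.

ION_WINDOW <- 10L

#' Bin index of a candidate's product ion
#'
#' Given the cumulative residue mass of the decoded prefix, appending
#' `candidate` yields a cleavage whose product-ion m/z maps to bin
#' `floor(mz / w)` (0-based).  Massless candidates (special tokens) and
#' ions falling outside `[0, L)` return `NA`.
#'
#' @param prefix_mass cumulative residue mass of the prefix, Da
#' @param candidate candidate residue symbol
#' @param total_mass sum of all residue masses of the precursor (no
#'   water), Da
#' @param ion one row of [ion_types()] or an ion name
#' @param table a [residue_table()]
#' @param w,L binning grid
#' @return 0-based bin index, or `NA` when out of range / massless
#' @export
ion_bin_index <- function(prefix_mass, candidate, total_mass, ion,
                          table = residue_table(),
                          w = DEFAULT_BIN_WIDTH, L = DEFAULT_N_BINS) {
  rm <- table$mass[candidate]
  if (is.na(rm)) stop("unknown candidate symbol: ", candidate)
  if (rm == 0) return(NA_integer_)
  cut <- prefix_mass + rm
  if (cut > total_mass + 1e-9) return(NA_integer_)
  idx <- floor(fragment_mz(cut, total_mass, ion) / w)
  if (idx < 0 || idx >= L) NA_integer_ else as.integer(idx)
}

#' Extract a 10-bin intensity window around a bin index
#'
#' Offsets cover bins `center - 5` to `center + 4` (a size-10 window
#' cannot be symmetric; the left-heavy convention is fixed), so the
#' center bin sits at 0-based offset 5.  Out-of-range bins and an `NA`
#' center give zeros.
#'
#' @param v binned intensity vector
#' @param center 0-based bin index (or `NA`)
#' @param size window size (even), default 10
#' @return numeric vector of length `size`
#' @export
extract_window <- function(v, center, size = ION_WINDOW) {
  stopifnot(size > 0L, size %% 2L == 0L)
  if (is.na(center)) return(numeric(size))
  idx <- (center - size / 2L):(center + size / 2L - 1L)   # 0-based bins
  out <- numeric(size)
  ok <- idx >= 0L & idx < length(v)
  out[ok] <- v[idx[ok] + 1L]
  out
}

#' Build the product-ion array slice for the next decoding position
#'
#' For every (candidate slot, ion type, spectrum) triple, the theoretical
#' product ion of `prefix + candidate` is located in the binned MS2
#' spectrum and a 10-bin window around it is extracted.  The slice has
#' dimensions `(V, 8, 5, 10)`: candidate slots, ion types, spectra,
#' window offsets.  Massless slots and out-of-range ions contribute
#' zeros.  When the prefix residue mass already exceeds the precursor's
#' residue-mass budget (plus `tol`), the slice is all-zero and flagged
#' with attribute `mass_exceeded` — decoding uses this as termination
#' support.
#'
#' @param prefix character vector of decoded residue symbols (may be
#'   empty)
#' @param ctx a [assemble_context()] feature context
#' @param table a [residue_table()]
#' @param tol mass slack for the exceeded-flag check, Da
#' @return numeric array `(V, 8, 5, 10)` with attribute `mass_exceeded`
#' @export
build_ion_array <- function(prefix, ctx, table = residue_table(), tol = 0.5) {
  prefix_mass <- if (length(prefix))
    sum(residue_mass(table, peptide_symbols(table, prefix))) else 0
  .ion_slice_mass(prefix_mass, ctx, table, tol)
}

#' Model-free greedy mass-ladder readout
#'
#' A sanity oracle requiring no trained model: at each teacher-forced
#' position (prefix = the true residues so far), score every residue
#' candidate by the summed intensity of its ion-array windows over all 8
#' ion types and 5 spectra, and take the argmax.  Three refinements make
#' the readout deterministic and robust to the classic b/y mirror
#' ambiguity, where a wrong candidate whose cut mass plus a true cut
#' mass equals the precursor mass sees all eight of its ions coincide
#' with mirrored true peaks (exactly so for compositions like S+2A =
#' P+2G+H2O): window offsets are weighted by proximity to the center
#' bin, where a correct candidate's fragment falls exactly; each ion
#' type's window is weighted by its expected relative intensity
#' ([ion_weights()]), a matched filter under which a mirror reading --
#' which sees strong y evidence in its b window and weak b evidence in
#' its y window -- always scores strictly below the true reading; exact
#' residual ties are broken by looking one rung ahead; and mass closure
#' decides the final rung (whose cleavage has no interior fragment).
#' On noise-free, singly-isolated simulated data with a non-isobaric
#' alphabet this recovers nearly all residues; separating co-isolated
#' precursors of very different abundance is beyond any model-free
#' readout and is what the learned model is for.
#'
#' @param ctx a feature context with a known `peptide` label
#' @param table a [residue_table()]
#' @return logical vector: per-position, did the argmax candidate equal
#'   the true residue
#' @export
ladder_readout <- function(ctx, table = residue_table()) {
  truth <- peptide_symbols(table, ctx$peptide)
  n <- length(truth)
  hits <- logical(n)
  res_ids <- which(table$is_residue)
  res_mass <- table$mass[res_ids]
  total <- ctx$mass - H2O_MASS
  prefix_mass <- 0
  # multiplier: center-weighted window kernel (center bin at 0-based
  # offset 5) times the matched-filter ion-type template
  kern <- 1 / (1 + abs(seq_len(ION_WINDOW) - 1L - ION_WINDOW / 2L))
  V <- table$n_slots
  nspec <- nrow(ctx$ms2_binned)
  mult <- array(1, dim = c(V, 8L, nspec, ION_WINDOW))
  for (k in seq_len(8L)) mult[, k, , ] <- ion_weights()[k]
  for (o in seq_len(ION_WINDOW)) mult[, , , o] <- mult[, , , o] * kern[o]
  kscore <- function(pm) {
    arr <- .ion_slice_mass(pm, ctx, table)
    apply(arr * mult, 1L, sum)[res_ids]
  }
  for (t in seq_len(n)) {
    remaining <- total - prefix_mass - res_mass
    if (any(abs(remaining) < 0.05)) {
      # a candidate closes the residue budget: only possible at the final
      # rung, where mass closure is the decisive evidence
      best <- res_ids[which.min(abs(remaining))]
    } else {
      score <- kscore(prefix_mass)
      tied <- which(score >= max(score) - 1e-9)
      if (max(score) > 0 && length(tied) > 1L) {
        # mirror ties: the true rung has a strong continuation, an
        # off-ladder mirror does not -- look one rung ahead
        la <- vapply(tied, function(ci) max(kscore(prefix_mass + res_mass[ci])),
                     0)
        best <- res_ids[tied[which.max(la)]]
      } else {
        best <- res_ids[which.max(score)]
      }
    }
    hits[t] <- identical(table$symbols[best], truth[t])
    prefix_mass <- prefix_mass + table$mass[[truth[t]]]
  }
  hits
}
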