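# Assembly of the spectrum-encoder inputs for one precursor feature:
# a 5-point precursor elution profile, 5 associated (binned, normalized)
# MS2 spectra, and the MS1 scan nearest the retention-time center.

#' Select the 5 elution-profile points nearest the RT center
#'
#' The five profile samples whose retention times lie closest to the
#' feature's RT center, ordered by RT.  Features with fewer than five
#' samples are padded with zero-intensity points at the RT center.
#'
#' @param f a [precursor_feature()]
#' @param n_points profile length (default 5)
#' @return `n_points x 2` matrix with columns `intensity`, `rt`
#' @export
build_precursor_profile <- function(f, n_points = 5L) {
  k <- length(f$profile_intensity)
  if (k == 0L) {
    sel_i <- numeric(0); sel_rt <- numeric(0)
  } else {
    ord <- order(abs(f$profile_rt - f$rt_center), f$profile_rt)
    take <- ord[seq_len(min(n_points, k))]
    take <- take[order(f$profile_rt[take])]
    sel_i <- f$profile_intensity[take]; sel_rt <- f$profile_rt[take]
  }
  pad <- n_points - length(sel_i)
  if (pad > 0L) {
    sel_i <- c(sel_i, rep(0, pad))
    sel_rt <- c(sel_rt, rep(f$rt_center, pad))
  }
  cbind(intensity = sel_i, rt = sel_rt)
}

#' Select the 5 MS2 spectra covering a feature
#'
#' Candidates are MS2 spectra whose isolation window contains the feature
#' m/z (half-open `[low, high)`) and whose retention time falls inside the
#' feature's RT range.  Of those, the five with RT nearest the RT center
#' are kept (ties broken by ascending scan id) and returned ordered by RT.
#' A shortage is padded with `NULL` placeholders, which downstream binning
#' turns into all-zero spectra.
#'
#' @param f a [precursor_feature()]
#' @param all_ms2 list of MS2 spectra
#' @param n_spectra number to select (default 5)
#' @return list of length `n_spectra` (entries may be `NULL` pads)
#' @export
select_ms2 <- function(f, all_ms2, n_spectra = 5L) {
  ok <- vapply(all_ms2, function(s) {
    s$window_low <= f$mz && f$mz < s$window_high &&
      s$rt >= f$rt_start - 1e-9 && s$rt <= f$rt_end + 1e-9
  }, TRUE)
  cand <- all_ms2[ok]
  if (length(cand) == 0L) {
    warning(sprintf("feature %s: no qualifying MS2 spectra; using zero pads",
                    f$feature_id))
    return(vector("list", n_spectra))
  }
  rts   <- vapply(cand, `[[`, 0, "rt")
  scans <- vapply(cand, `[[`, 0L, "scan")
  ord <- order(abs(rts - f$rt_center), scans)
  take <- ord[seq_len(min(n_spectra, length(cand)))]
  take <- take[order(rts[take], scans[take])]
  out <- cand[take]
  length(out) <- n_spectra   # pad with NULL
  out
}

#' Select the MS1 spectrum nearest the RT center
#'
#' @param f a [precursor_feature()]
#' @param all_ms1 list of MS1 spectra
#' @return the MS1 spectrum minimizing `|rt - rt_center|` (ties broken by
#'   the smaller scan id); an empty MS1 spectrum when `all_ms1` is empty
#' @export
select_ms1 <- function(f, all_ms1) {
  if (length(all_ms1) == 0L)
    return(new_ms1_spectrum(0L, f$rt_center, numeric(0), numeric(0)))
  rts   <- vapply(all_ms1, `[[`, 0, "rt")
  scans <- vapply(all_ms1, `[[`, 0L, "scan")
  all_ms1[[order(abs(rts - f$rt_center), scans)[1L]]]
}

#' Assemble the encoder input context for one feature
#'
#' Bundles the three spectrum-encoder inputs: the 5-point precursor
#' profile, the 5 selected MS2 spectra binned on the (w, L) grid and
#' max-normalized per spectrum, and the peak list of the nearest MS1
#' scan.  The precursor neutral mass is `mz * z - z * proton`.
#'
#' @param f a [precursor_feature()]
#' @param run spectra as returned by [read_mgf()] (elements `ms1`, `ms2`)
#' @param w,L binning grid (see [bin_spectrum()])
#' @param n_spectra,n_profile stack sizes (defaults 5)
#' @return object of class `feature_context` with fields `feature_id`,
#'   `profile` (5 x 2), `ms2_binned` (5 x L, normalized), `ms1_mz`,
#'   `ms1_intensity`, `mass`, `charge`, `peptide`
#' @export
assemble_context <- function(f, run, w = DEFAULT_BIN_WIDTH,
                             L = DEFAULT_N_BINS,
                             n_spectra = 5L, n_profile = 5L) {
  sel <- select_ms2(f, run$ms2, n_spectra)
  stack <- matrix(0, nrow = n_spectra, ncol = L)
  for (i in seq_len(n_spectra)) {
    if (!is.null(sel[[i]])) stack[i, ] <- bin_spectrum(sel[[i]], w, L)
  }
  stack <- normalize_binned(stack)
  ms1 <- select_ms1(f, if (is.null(run$ms1)) list() else run$ms1)
  structure(
    list(feature_id = f$feature_id,
         profile = build_precursor_profile(f, n_profile),
         ms2_binned = stack,
         ms1_mz = ms1$mz, ms1_intensity = ms1$intensity,
         mass = precursor_neutral_mass(f), charge = f$z,
         rt_center = f$rt_center,
         w = w, L = as.integer(L), peptide = f$peptide),
    class = "feature_context"
  )
}

#' @export
print.feature_context <- function(x, ...) {
  cat(sprintf(
    "feature_context %s: mass %.4f (z=%d), %d MS1 peaks, MS2 stack %d x %d\n",
    x$feature_id, x$mass, x$charge, length(x$ms1_mz),
    nrow(x$ms2_binned), ncol(x$ms2_binned)))
  invisible(x)
}
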