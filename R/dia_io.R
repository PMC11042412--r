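# Spectrum and feature-table I/O, plus discretization of MS2 spectra into
# fixed-length binned intensity vectors.
#
# On-disk formats: MGF for spectra (TITLE, PEPMASS, CHARGE, RTINSECONDS,
# plus MSLEVEL and WINDOWLOW/WINDOWHIGH keys for DIA isolation windows,
# which standard MGF readers ignore), and a comma-separated feature table
# with columns feature_id, mz, z, rt_center, rt_start, rt_end, profile
# (semicolon-joined intensity:rt pairs) and an optional peptide label.

DEFAULT_BIN_WIDTH <- 0.01
DEFAULT_N_BINS    <- 150000L

new_ms2_spectrum <- function(scan, rt, window_low, window_high, mz, intensity,
                             run_id = "run0") {
  o <- order(mz)
  structure(
    list(scan = as.integer(scan), rt = rt,
         window_low = window_low, window_high = window_high,
         mz = mz[o], intensity = intensity[o], run_id = run_id),
    class = "ms2_spectrum"
  )
}

new_ms1_spectrum <- function(scan, rt, mz, intensity, run_id = "run0") {
  o <- order(mz)
  structure(
    list(scan = as.integer(scan), rt = rt, mz = mz[o], intensity = intensity[o],
         n = length(mz), run_id = run_id),
    class = "ms1_spectrum"
  )
}

#' A detected precursor feature
#'
#' One precursor: m/z, charge, retention-time center and range, its
#' elution profile as (intensity, RT) pairs, and an optional ground-truth
#' peptide label.
#'
#' @param feature_id identifier string
#' @param mz precursor m/z
#' @param z charge state (>= 1)
#' @param rt_center,rt_start,rt_end retention times in seconds,
#'   `rt_start <= rt_center <= rt_end`
#' @param profile_intensity,profile_rt elution profile samples
#' @param peptide optional label peptide string (`NA` when unlabelled)
#' @return object of class `precursor_feature`
#' @export
precursor_feature <- function(feature_id, mz, z, rt_center, rt_start, rt_end,
                              profile_intensity = numeric(0),
                              profile_rt = numeric(0), peptide = NA_character_) {
  stopifnot(rt_start <= rt_center + 1e-9, rt_center <= rt_end + 1e-9, z >= 1)
  structure(
    list(feature_id = as.character(feature_id), mz = mz, z = as.integer(z),
         rt_center = rt_center, rt_start = rt_start, rt_end = rt_end,
         profile_intensity = profile_intensity, profile_rt = profile_rt,
         peptide = peptide),
    class = "precursor_feature"
  )
}

#' Neutral mass of a precursor feature
#'
#' `mz * z - z * proton`.
#' @param f a [precursor_feature()]
#' @return neutral monoisotopic mass, Da
#' @export
precursor_neutral_mass <- function(f) {
  f$mz * f$z - f$z * PROTON_MASS
}

.fmt_num <- function(x) {
  # fixed formatting so identical data give byte-identical files
  sub("\\.?0+$", "", sprintf("%.6f", x))
}

#' Write spectra to an MGF file
#'
#' Writes MS2 (and optionally MS1) spectra as standard MGF ion blocks.
#' MS1 blocks carry `MSLEVEL=1`; MS2 blocks carry the isolation window as
#' `WINDOWLOW`/`WINDOWHIGH` keys and the window center as `PEPMASS`.
#' Numeric formatting is fixed, so equal inputs produce byte-identical
#' files.
#'
#' @param ms2 list of MS2 spectra
#' @param path output file
#' @param ms1 optional list of MS1 spectra
#' @return `path`, invisibly
#' @export
write_mgf <- function(ms2, path, ms1 = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  emit <- function(lines) writeLines(lines, con)
  for (s in ms1) {
    emit(c("BEGIN IONS",
           sprintf("TITLE=scan=%d", s$scan),
           "MSLEVEL=1",
           sprintf("SCANS=%d", s$scan),
           sprintf("RTINSECONDS=%s", .fmt_num(s$rt)),
           if (length(s$mz)) paste(.fmt_num(s$mz), .fmt_num(s$intensity)),
           "END IONS"))
  }
  for (s in ms2) {
    emit(c("BEGIN IONS",
           sprintf("TITLE=scan=%d", s$scan),
           "MSLEVEL=2",
           sprintf("SCANS=%d", s$scan),
           sprintf("PEPMASS=%s", .fmt_num((s$window_low + s$window_high) / 2)),
           sprintf("RTINSECONDS=%s", .fmt_num(s$rt)),
           sprintf("WINDOWLOW=%s", .fmt_num(s$window_low)),
           sprintf("WINDOWHIGH=%s", .fmt_num(s$window_high)),
           if (length(s$mz)) paste(.fmt_num(s$mz), .fmt_num(s$intensity)),
           "END IONS"))
  }
  invisible(path)
}

#' Read an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks into MS2 spectra; blocks flagged
#' `MSLEVEL=1` become MS1 spectra when `include_ms1 = TRUE`.  Retention
#' times are taken from `RTINSECONDS` (or `RTINMINUTES`, converted);
#' isolation windows from `WINDOWLOW`/`WINDOWHIGH`, else inferred as
#' `PEPMASS` +/- `window_halfwidth`.
#'
#' @param path MGF file
#' @param include_ms1 also return MS1-flagged blocks
#' @param window_halfwidth fallback isolation half-window (m/z) when the
#'   file does not state window bounds
#' @return list with elements `ms2` and (when requested) `ms1`
#' @export
read_mgf <- function(path, include_ms1 = TRUE, window_halfwidth = 6) {
  lines <- readLines(path)
  ms1 <- list(); ms2 <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (line == "") { i <- i + 1L; next }
    if (line != "BEGIN IONS")
      stop(sprintf("MGF parse error at line %d: expected BEGIN IONS", i))
    hdr <- list(); mz <- numeric(0); int <- numeric(0)
    i <- i + 1L
    repeat {
      if (i > n) stop(sprintf("MGF parse error: unterminated block at line %d", i))
      line <- trimws(lines[[i]])
      if (line == "END IONS") { i <- i + 1L; break }
      if (grepl("=", line, fixed = TRUE)) {
        kv <- regmatches(line, regexpr("=", line, fixed = TRUE), invert = TRUE)[[1L]]
        hdr[[toupper(kv[1L])]] <- kv[2L]
      } else if (line != "") {
        parts <- strsplit(line, "[ \t]+")[[1L]]
        v <- suppressWarnings(as.numeric(parts[1:2]))
        if (anyNA(v))
          stop(sprintf("MGF parse error at line %d: bad peak line '%s'", i, line))
        mz <- c(mz, v[1L]); int <- c(int, v[2L])
      }
      i <- i + 1L
    }
    scan <- if (!is.null(hdr$SCANS)) as.integer(hdr$SCANS) else length(ms1) + length(ms2) + 1L
    rt <- if (!is.null(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS)
          else if (!is.null(hdr$RTINMINUTES)) 60 * as.numeric(hdr$RTINMINUTES)
          else NA_real_
    level <- if (!is.null(hdr$MSLEVEL)) as.integer(hdr$MSLEVEL) else 2L
    if (level == 1L) {
      ms1[[length(ms1) + 1L]] <- new_ms1_spectrum(scan, rt, mz, int)
    } else {
      if (!is.null(hdr$WINDOWLOW)) {
        lo <- as.numeric(hdr$WINDOWLOW); hi <- as.numeric(hdr$WINDOWHIGH)
      } else {
        pm <- if (!is.null(hdr$PEPMASS))
          as.numeric(strsplit(hdr$PEPMASS, "[ \t]+")[[1L]][1L]) else NA_real_
        lo <- pm - window_halfwidth; hi <- pm + window_halfwidth
      }
      ms2[[length(ms2) + 1L]] <- new_ms2_spectrum(scan, rt, lo, hi, mz, int)
    }
  }
  if (include_ms1) list(ms1 = ms1, ms2 = ms2) else list(ms2 = ms2)
}

#' Write a precursor feature table
#'
#' @param features list of [precursor_feature()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(features, path) {
  rows <- vapply(features, function(f) {
    prof <- if (length(f$profile_intensity))
      paste(sprintf("%s:%s", .fmt_num(f$profile_intensity),
                    .fmt_num(f$profile_rt)), collapse = ";")
    else ""
    paste(f$feature_id, .fmt_num(f$mz), f$z, .fmt_num(f$rt_center),
          .fmt_num(f$rt_start), .fmt_num(f$rt_end), prof,
          if (is.na(f$peptide)) "" else f$peptide, sep = ",")
  }, "")
  writeLines(c("feature_id,mz,z,rt_center,rt_start,rt_end,profile,peptide",
               rows), path)
  invisible(path)
}

#' Read a precursor feature table
#'
#' Mandatory columns: feature_id, mz, z, rt_center, rt_start, rt_end,
#' profile.  The optional peptide column supplies ground-truth labels;
#' when present and non-empty, the label's neutral mass is checked against
#' the stated m/z and charge, and an inconsistency beyond
#' `mass_check_tol` is reported as a warning (the feature is kept).
#'
#' @param path CSV path
#' @param table [residue_table()] used to validate labels
#' @param mass_check_tol label-vs-m/z consistency tolerance, Da
#' @return list of [precursor_feature()]
#' @export
read_feature_table <- function(path, table = residue_table(),
                               mass_check_tol = 0.1) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("feature_id", "mz", "z", "rt_center", "rt_start", "rt_end", "profile")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("feature table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  has_pep <- "peptide" %in% names(df)
  lapply(seq_len(nrow(df)), function(r) {
    prof_i <- numeric(0); prof_rt <- numeric(0)
    if (nzchar(df$profile[r])) {
      pairs <- strsplit(strsplit(df$profile[r], ";", fixed = TRUE)[[1L]],
                        ":", fixed = TRUE)
      prof_i  <- as.numeric(vapply(pairs, `[`, "", 1L))
      prof_rt <- as.numeric(vapply(pairs, `[`, "", 2L))
    }
    pep <- if (has_pep && nzchar(df$peptide[r])) df$peptide[r] else NA_character_
    f <- precursor_feature(df$feature_id[r], as.numeric(df$mz[r]),
                           as.integer(df$z[r]), as.numeric(df$rt_center[r]),
                           as.numeric(df$rt_start[r]), as.numeric(df$rt_end[r]),
                           prof_i, prof_rt, pep)
    if (!is.na(pep)) {
      dm <- abs(peptide_mass(table, pep) - precursor_neutral_mass(f))
      if (dm > mass_check_tol)
        warning(sprintf(
          "feature %s: label '%s' mass differs from stated m/z by %.4f Da",
          f$feature_id, pep, dm))
    }
    f
  })
}

#' Discretize an MS2 spectrum into a fixed-length intensity vector
#'
#' Each peak maps to bin `floor(mz / w)` (0-based); peaks colliding in one
#' bin are aggregated by max, and peaks at or beyond `L * w` are dropped.
#' The default grid (w = 0.01 Da, L = 150,000 bins) spans m/z 0-1500.
#'
#' @param s an MS2 spectrum (or any list with `mz` and `intensity`)
#' @param w bin width, Da
#' @param L number of bins
#' @return numeric vector of length `L` with attributes `w` and `L`
#' @export
bin_spectrum <- function(s, w = DEFAULT_BIN_WIDTH, L = DEFAULT_N_BINS) {
  stopifnot(w > 0, L > 0)
  v <- numeric(L)
  if (length(s$mz)) {
    idx <- floor(s$mz / w)
    keep <- idx >= 0 & idx < L
    if (any(keep)) {
      agg <- tapply(s$intensity[keep], idx[keep], max)
      v[as.integer(names(agg)) + 1L] <- as.numeric(agg)
    }
  }
  attr(v, "w") <- w
  attr(v, "L") <- as.integer(L)
  v
}

#' Normalize a stack of binned spectra
#'
#' Divides each spectrum (row) by its own maximum so values lie between
#' 0 and 1; all-zero spectra are left unchanged.
#'
#' @param m matrix (spectra in rows) or a single binned vector
#' @return object of the same shape
#' @export
normalize_binned <- function(m) {
  if (is.null(dim(m))) {
    mx <- max(m)
    return(if (mx > 0) m / mx else m)
  }
  mx <- apply(m, 1L, max)
  mx[mx == 0] <- 1
  m / mx
}
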