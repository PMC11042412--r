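# Synthetic multiplexed-DIA generator: samples peptides, assigns
# charges, retention times and Gaussian elution profiles, groups
# co-isolated precursors per isolation window, and writes MS1/MS2 MGF
# spectra plus a labelled precursor feature table with full ground
# truth -- so every pipeline stage is testable without external data.

#' Simulation configuration
#'
#' Defaults describe a small but realistic DIA run: 12 m/z isolation
#' windows, three co-isolated precursors per window cluster, 6 s
#' Gaussian elution peaks sampled on a 3 s scan cycle over a 300 s
#' gradient, a 100-fold precursor intensity dynamic range, 50 uniform
#' noise peaks per MS2 scan and a 0.9 per-scan fragment detection
#' probability.  Fragments are planted at exact theoretical m/z unless
#' `mz_jitter` is set.
#'
#' @param seed RNG seed; fixed seed gives byte-identical outputs
#' @param n_peptides number of unique peptides to sample
#' @param length_range peptide length range (inclusive)
#' @param alphabet `"full"`, `"reduced"` (G/A/S/P/V, whose pairwise mass
#'   gaps all exceed 1 Da), or a named mass vector
#' @param window_width isolation window width, m/z
#' @param mz_grid_min anchor of the isolation-window grid, m/z
#' @param co_isolation_depth precursors co-eluting per window cluster
#' @param sigma_rt elution peak width (Gaussian sigma), s
#' @param rt_span gradient length, s
#' @param cycle_time scan cycle, s
#' @param noise_peaks uniform noise peaks per MS2 scan
#' @param detect_prob per-scan fragment detection probability
#' @param base_intensity minimum precursor amplitude (arbitrary units)
#' @param dynamic_range amplitude spread (log-uniform over
#'   `[base, base * dynamic_range]`)
#' @param mz_jitter fragment m/z jitter sigma, Da (0 = exact)
#' @param charges candidate precursor charges
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_peptides = 50L, length_range = c(7L, 16L),
                       alphabet = "full", window_width = 12,
                       mz_grid_min = 200, co_isolation_depth = 3L,
                       sigma_rt = 6, rt_span = 300, cycle_time = 3,
                       noise_peaks = 50L, detect_prob = 0.9,
                       base_intensity = 1e4, dynamic_range = 100,
                       mz_jitter = 0, charges = c(2L, 3L)) {
  stopifnot(co_isolation_depth >= 1L, window_width > 0, sigma_rt > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Sample unique peptides
#'
#' Residues uniform over the alphabet, lengths uniform over the range,
#' duplicates removed; peptides whose doubly-protonated m/z would exceed
#' the binnable range (1490) are rejected.  Deterministic per seed.
#'
#' @param cfg a [sim_config()]
#' @return character vector of peptide strings (fewer than requested,
#'   with a warning, if the alphabet is exhausted)
#' @export
sample_peptides <- function(cfg) {
  set.seed(cfg$seed)
  tab <- residue_table(cfg$alphabet)
  res <- tab$symbols[tab$is_residue]
  out <- character(0)
  lens <- cfg$length_range[1L]:cfg$length_range[2L]
  for (attempt in seq_len(200L * cfg$n_peptides)) {
    if (length(out) >= cfg$n_peptides) break
    len <- lens[sample.int(length(lens), 1L)]
    pep <- paste(sample(res, len, replace = TRUE), collapse = "")
    if (pep %in% out) next
    if ((peptide_mass(tab, pep) + 2 * PROTON_MASS) / 2 > 1490) next
    out <- c(out, pep)
  }
  if (length(out) < cfg$n_peptides)
    warning(sprintf("alphabet exhausted: %d of %d unique peptides sampled",
                    length(out), cfg$n_peptides))
  out
}

# Relative intensity of the 8 ion types (order of ion_types()): y-family
# ions are stronger than their b counterparts, as in HCD spectra.  The
# asymmetry matters: it is what physically distinguishes a peptide from
# its mass-mirrored (reversed-ladder) reading.
.ION_WEIGHTS <- c(b = 0.5, y = 1, `b(2+)` = 0.15, `y(2+)` = 0.3,
                  `b-H2O` = 0.1, `y-H2O` = 0.2, `b-NH3` = 0.1, `y-NH3` = 0.2)

#' Relative ion-type intensity template
#'
#' The expected relative intensities of the eight product-ion types used
#' by the simulator (and as the matched-filter template of
#' [ladder_readout()]).
#' @return named numeric vector in [ion_types()] order
#' @export
ion_weights <- function() .ION_WEIGHTS

#' Simulate a DIA run
#'
#' Each peptide receives a charge, an amplitude, and a Gaussian elution
#' profile; peptides falling in the same isolation window are grouped
#' into clusters of `co_isolation_depth` that share an RT apex, so
#' their fragments genuinely multiplex in the same MS2 scans.  Every
#' scan cycle emits one MS1 scan (precursor peaks of all currently
#' eluting features) and one MS2 scan per active isolation window
#' (b/y-family fragments of all co-eluting precursors of that window,
#' scaled by the elution profile, plus uniform noise peaks).
#'
#' @param peptides character vector from [sample_peptides()]
#' @param cfg a [sim_config()]
#' @param dir optional output directory; when given, writes `run.mgf`,
#'   `features.csv` and `manifest.json`
#' @return list with `ms1`, `ms2`, `features`, `ground_truth` (per
#'   feature: peptide, charge, planted fragment bins), `table`, and
#'   `paths` (when written)
#' @export
simulate_run <- function(peptides, cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed + 1000L)
  tab <- residue_table(cfg$alphabet)
  n <- length(peptides)
  z <- cfg$charges[sample.int(length(cfg$charges), n, replace = TRUE)]
  mass <- vapply(peptides, peptide_mass, 0, table = tab)
  mz <- (mass + z * PROTON_MASS) / z
  win <- floor((mz - cfg$mz_grid_min) / cfg$window_width)
  amp <- cfg$base_intensity * cfg$dynamic_range^stats::runif(n)

  # Cluster features per window into co-isolation groups of size `depth`
  # (members share an elution apex, so their fragments multiplex), and
  # spread the clusters of each window across the gradient so that
  # distinct clusters of the same window do not co-elute.
  cluster <- integer(n)
  cluster_win <- integer(0)
  nc <- 0L
  for (w in unique(win)) {
    idx <- which(win == w)[order(mz[win == w])]
    grp <- split(idx, ceiling(seq_along(idx) / cfg$co_isolation_depth))
    for (g in grp) {
      nc <- nc + 1L
      cluster[g] <- nc
      cluster_win[nc] <- w
    }
  }
  margin <- 4 * cfg$sigma_rt
  cluster_rt <- numeric(nc)
  for (w in unique(cluster_win)) {
    cl <- which(cluster_win == w)
    m <- length(cl)
    centers <- margin + (seq_len(m) - 0.5) / m * (cfg$rt_span - 2 * margin)
    cluster_rt[cl] <- centers[sample.int(m)]
  }
  rt_center <- cluster_rt[cluster] +
    stats::runif(n, -cfg$sigma_rt / 2, cfg$sigma_rt / 2)
  rt_start <- pmax(0, rt_center - 3 * cfg$sigma_rt)
  rt_end <- pmin(cfg$rt_span, rt_center + 3 * cfg$sigma_rt)

  elution <- function(i, t) amp[i] * exp(-(t - rt_center[i])^2 /
                                         (2 * cfg$sigma_rt^2))

  # theoretical fragments per feature
  frag <- lapply(seq_len(n), function(i) {
    syms <- peptide_symbols(tab, peptides[i])
    pm <- cumsum(residue_mass(tab, syms))
    total <- sum(residue_mass(tab, syms))
    it <- ion_types()
    cuts <- pm[-length(pm)]
    if (length(cuts) == 0L) return(data.frame(mz = numeric(0), wgt = numeric(0)))
    do.call(rbind, lapply(seq_len(nrow(it)), function(k) {
      data.frame(mz = fragment_mz(cuts, total, it[k, ]),
                 wgt = unname(.ION_WEIGHTS[k]))
    }))
  })

  scan_t <- seq(0, cfg$rt_span, by = cfg$cycle_time)
  active_windows <- sort(unique(win))
  ms1 <- list(); ms2 <- list()
  scan_id <- 0L
  for (t in scan_t) {
    live <- which(t >= rt_start & t <= rt_end)
    scan_id <- scan_id + 1L
    ms1[[length(ms1) + 1L]] <- new_ms1_spectrum(
      scan_id, t, mz[live], vapply(live, elution, 0, t = t))
    for (w in active_windows) {
      scan_id <- scan_id + 1L
      tw <- t + 1e-3 * (w - active_windows[1L] + 1L)
      lo <- cfg$mz_grid_min + w * cfg$window_width
      hi <- lo + cfg$window_width
      fmz <- numeric(0); fint <- numeric(0)
      for (i in which(win == w & tw >= rt_start & tw <= rt_end)) {
        fr <- frag[[i]]
        keep <- stats::runif(nrow(fr)) <= cfg$detect_prob
        if (!any(keep)) next
        jit <- if (cfg$mz_jitter > 0)
          stats::rnorm(sum(keep), 0, cfg$mz_jitter) else 0
        fmz <- c(fmz, fr$mz[keep] + jit)
        fint <- c(fint, fr$wgt[keep] * elution(i, tw))
      }
      if (cfg$noise_peaks > 0L) {
        fmz <- c(fmz, stats::runif(cfg$noise_peaks, 100, 1495))
        fint <- c(fint, cfg$base_intensity *
                    10^stats::runif(cfg$noise_peaks, -3, -1.3))
      }
      ok <- fmz > 0 & fmz < 1500
      ms2[[length(ms2) + 1L]] <- new_ms2_spectrum(scan_id, tw, lo, hi,
                                                  fmz[ok], fint[ok])
    }
  }

  features <- lapply(seq_len(n), function(i) {
    ts <- scan_t[scan_t >= rt_start[i] & scan_t <= rt_end[i]]
    precursor_feature(sprintf("F%03d", i), mz[i], z[i], rt_center[i],
                      rt_start[i], rt_end[i],
                      vapply(ts, function(t) elution(i, t), 0), ts,
                      peptide = peptides[i])
  })
  ground_truth <- lapply(seq_len(n), function(i) {
    list(feature_id = sprintf("F%03d", i), peptide = peptides[i],
         charge = z[i],
         planted_bins = sort(unique(floor(frag[[i]]$mz / DEFAULT_BIN_WIDTH))))
  })
  names(ground_truth) <- vapply(ground_truth, `[[`, "", "feature_id")

  out <- list(ms1 = ms1, ms2 = ms2, features = features,
              ground_truth = ground_truth, table = tab, cfg = cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(mgf = file.path(dir, "run.mgf"),
                  features = file.path(dir, "features.csv"),
                  manifest = file.path(dir, "manifest.json"))
    write_mgf(ms2, paths$mgf, ms1 = ms1)
    write_feature_table(features, paths$features)
    jsonlite::write_json(unclass(cfg), paths$manifest, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}

#' Sample peptides and simulate in one call
#'
#' @param cfg a [sim_config()]
#' @param dir optional output directory (see [simulate_run()])
#' @return see [simulate_run()]
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  simulate_run(sample_peptides(cfg), cfg, dir)
}

#' Assemble contexts for all simulated features
#'
#' Convenience wrapper: [assemble_context()] over every feature of a
#' simulation result.
#'
#' @param sim result of [simulate_run()]
#' @param w,L binning grid
#' @return list of feature contexts (labelled)
#' @export
sim_contexts <- function(sim, w = DEFAULT_BIN_WIDTH, L = DEFAULT_N_BINS) {
  run <- list(ms1 = sim$ms1, ms2 = sim$ms2)
  lapply(sim$features, function(f) assemble_context(f, run, w = w, L = L))
}
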