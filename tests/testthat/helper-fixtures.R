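# Shared fixtures, memoized so expensive objects (simulations, trained
# models) are built once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# small clean run: singly-isolated, noise-free, reduced alphabet
fix_sim_small <- function() memo("sim_small", {
  simulate_dataset(sim_config(seed = 11L, n_peptides = 8L,
                              length_range = c(5L, 7L),
                              alphabet = "reduced", noise_peaks = 0L,
                              detect_prob = 1, co_isolation_depth = 1L,
                              rt_span = 400))
})

fix_ctxs_small <- function() memo("ctxs_small", sim_contexts(fix_sim_small()))

# the overfit study set: 32 noise-free features, length 7-10, reduced
# alphabet, default co-isolation depth
fix_sim32 <- function() memo("sim32", {
  simulate_dataset(sim_config(seed = 1L, n_peptides = 32L,
                              length_range = c(7L, 10L),
                              alphabet = "reduced", noise_peaks = 0L,
                              detect_prob = 1, rt_span = 300))
})

fix_ctxs32 <- function() memo("ctxs32", sim_contexts(fix_sim32()))

# tiny concat model trained to the overfit target on the 32-feature set
fix_trained <- function() memo("trained", {
  suppressMessages(train_model(fix_ctxs32(), model_config("tiny"),
                               epochs = 200L, seed = 1L, eval_every = 10L,
                               target_acc = 0.9))
})

# an untrained tiny model with a non-degenerate output head (for decode
# and gradient tests that need non-uniform logits)
fix_rand_model <- function() memo("rand_model", {
  m <- dia_model(model_config("tiny"), seed = 3L)
  set.seed(4L)
  m$params[["out.W"]] <- matrix(stats::rnorm(length(m$params[["out.W"]]),
                                             sd = 0.3), m$cfg$d)
  m
})

# hand-built minimal feature context on the default bin grid
make_ctx <- function(peaks_per_spec, mass, charge = 2L,
                     w = 0.01, L = 150000L, peptide = NA_character_) {
  stack <- matrix(0, 5L, L)
  for (s in seq_along(peaks_per_spec)) {
    for (p in peaks_per_spec[[s]]) stack[s, p$bin + 1L] <- p$int
  }
  structure(list(feature_id = "T1", profile = cbind(intensity = rep(1, 5),
                                                    rt = 1:5),
                 ms2_binned = stack, ms1_mz = numeric(0),
                 ms1_intensity = numeric(0), mass = mass, charge = charge,
                 rt_center = 3, w = w, L = L, peptide = peptide),
            class = "feature_context")
}

# exhaustive dynamic-programming alignment oracle for residue matching
oracle_match <- function(table, pred, truth, prefix_tol = 0.5,
                         residue_tol = 0.1) {
  ps <- peptide_symbols(table, pred)
  ts <- peptide_symbols(table, truth)
  np <- length(ps); nt <- length(ts)
  if (np == 0L || nt == 0L) return(0L)
  pm <- cumsum(residue_mass(table, ps))
  tm <- cumsum(residue_mass(table, ts))
  rp <- residue_mass(table, ps)
  rt <- residue_mass(table, ts)
  f <- matrix(0L, nt + 1L, np + 1L)
  for (i in seq_len(nt)) {
    for (j in seq_len(np)) {
      ok <- abs(pm[j] - tm[i]) < prefix_tol && abs(rp[j] - rt[i]) < residue_tol
      f[i + 1L, j + 1L] <- max(f[i, j + 1L], f[i + 1L, j],
                               f[i, j] + as.integer(ok))
    }
  }
  f[nt + 1L, np + 1L]
}

# hand-built 3-step mock scorer over the reduced vocabulary (8 slots:
# G A S P V <start> <stop> <pad>); greedy is deliberately suboptimal
# (picks "A" then stop), beam width 2 finds "GV"
mock_scorer <- function() {
  lp <- function(x) log(x / sum(x))
  function(prefix_ids) {
    n <- length(prefix_ids)
    if (n == 0L) {
      # G  A  S  P  V  start stop pad
      lp(c(0.45, 0.50, 0.01, 0.01, 0.01, 1e-9, 0.02, 1e-9))
    } else if (identical(prefix_ids, 2L)) {          # after "A"
      lp(c(0.02, 0.02, 0.02, 0.02, 0.02, 1e-9, 0.90, 1e-9))
    } else if (identical(prefix_ids, 1L)) {          # after "G"
      lp(c(0.02, 0.02, 0.02, 0.02, 0.90, 1e-9, 0.02, 1e-9))
    } else if (n < 3L) {
      lp(c(rep(0.0125, 5), 1e-9, 0.9375, 1e-9))
    } else {
      lp(c(rep(1e-9, 5), 1e-9, 1, 1e-9))             # force stop
    }
  }
}

mock_ctx <- function(mass = 500) {
  list(feature_id = "MOCK", mass = mass, charge = 2L)
}
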