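test_that("peptide sampling is deterministic, unique, and warns on exhausted alphabets", {
  cfg <- sim_config(seed = 9L, n_peptides = 30L, length_range = c(6L, 9L),
                    alphabet = "reduced")
  p1 <- sample_peptides(cfg)
  p2 <- sample_peptides(cfg)
  expect_identical(p1, p2)
  expect_identical(anyDuplicated(p1), 0L)
  expect_length(p1, 30L)
  # only 25 length-2 sequences exist over 5 residues
  cfg2 <- sim_config(seed = 9L, n_peptides = 100L, length_range = c(2L, 2L),
                     alphabet = "reduced")
  expect_warning(p3 <- sample_peptides(cfg2), "exhausted")
  expect_length(p3, 25L)
})

test_that("simulated features are mass-consistent and fully labelled", {
  sim <- fix_sim_small()
  tab <- sim$table
  for (f in sim$features) {
    expect_false(is.na(f$peptide))
    expect_lt(abs(precursor_neutral_mass(f) - peptide_mass(tab, f$peptide)),
              1e-4)
    expect_true(f$rt_start <= f$rt_center && f$rt_center <= f$rt_end)
    expect_true(all(f$profile_rt >= f$rt_start & f$profile_rt <= f$rt_end))
  }
  expect_identical(sort(names(sim$ground_truth)),
                   sort(vapply(sim$features, `[[`, "", "feature_id")))
})

test_that("at depth 1 with no noise each MS2 scan holds one peptide's fragments", {
  sim <- fix_sim_small()   # depth 1, noise-free
  tab <- sim$table
  bins_of <- lapply(sim$ground_truth, `[[`, "planted_bins")
  checked <- 0L
  for (s in sim$ms2) {
    if (length(s$mz) == 0L) next
    obs <- floor(s$mz / 0.01)
    owners <- names(bins_of)[vapply(bins_of, function(b) any(obs %in% b), TRUE)]
    # every non-empty scan's peaks belong to peptides in this window; the
    # scan must be fully explained by a single co-eluting feature
    feats <- Filter(function(f) s$window_low <= f$mz && f$mz < s$window_high &&
                      s$rt >= f$rt_start && s$rt <= f$rt_end, sim$features)
    expect_lte(length(feats), 1L)
    if (length(feats) == 1L) {
      expect_true(all(obs %in% bins_of[[feats[[1L]]$feature_id]]))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("at depth 3 a multiplexed MS2 scan is the union of its cluster's fragments", {
  sim <- fix_sim32()   # depth 3, noise-free
  bins_of <- lapply(sim$ground_truth, `[[`, "planted_bins")
  multiplexed <- 0L
  for (s in sim$ms2) {
    if (length(s$mz) == 0L) next
    feats <- Filter(function(f) s$window_low <= f$mz && f$mz < s$window_high &&
                      s$rt >= f$rt_start && s$rt <= f$rt_end, sim$features)
    if (length(feats) < 2L) next
    multiplexed <- multiplexed + 1L
    union_bins <- sort(unique(unlist(
      lapply(feats, function(f) bins_of[[f$feature_id]]))))
    obs <- floor(s$mz / 0.01)
    expect_true(all(obs %in% union_bins))
  }
  expect_gt(multiplexed, 5L)   # co-isolation actually happens
})

test_that("fixture files round-trip: labels and profiles survive write/read", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(seed = 21L, n_peptides = 6L,
                                     alphabet = "reduced",
                                     length_range = c(5L, 7L),
                                     rt_span = 100), dir = dir)
  expect_true(all(file.exists(unlist(sim$paths))))
  feats <- read_feature_table(sim$paths$features, sim$table)
  expect_identical(vapply(feats, `[[`, "", "peptide"),
                   vapply(sim$features, `[[`, "", "peptide"))
  manifest <- jsonlite::read_json(sim$paths$manifest)
  expect_equal(manifest$seed, 21L)
})

test_that("identical configurations give byte-identical fixture files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 33L, n_peptides = 5L, alphabet = "reduced",
                    length_range = c(5L, 6L), rt_span = 80)
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in c("run.mgf", "features.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
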