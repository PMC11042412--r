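test_that("identical sequences match fully and isobaric Leu/Ile count as matches", {
  tab <- residue_table()
  expect_identical(match_residues(tab, "PEPTIDE", "PEPTIDE"), 7L)
  expect_identical(match_residues(tab, "LES", "IES"), 3L)    # L/I isobaric
  # N vs GG shifts the ladder: N(114.043) vs G(57.021) fails both checks
  expect_identical(match_residues(tab, "NG", "GGG"),
                   oracle_match(tab, "NG", "GGG"))
})

test_that("greedy ladder alignment agrees with the exhaustive alignment oracle", {
  tab <- residue_table("reduced")
  res <- tab$symbols[tab$is_residue]
  seqs <- unlist(lapply(1:3, function(n) {
    grid <- do.call(expand.grid, c(rep(list(res), n),
                                   list(stringsAsFactors = FALSE)))
    apply(grid, 1L, paste, collapse = "")
  }))
  # all pairs of lengths 1..3 (155 x 155), both orientations implicitly
  for (a in seqs) {
    for (b in seqs) {
      expect_identical(match_residues(tab, a, b), oracle_match(tab, a, b))
    }
  }
})

test_that("greedy alignment agrees with the oracle and is symmetric on longer random pairs", {
  tab <- residue_table("reduced")
  res <- tab$symbols[tab$is_residue]
  set.seed(12)
  for (r in 1:400) {
    a <- paste(sample(res, sample(4:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(res, sample(4:6, 1), replace = TRUE), collapse = "")
    m <- match_residues(tab, a, b)
    expect_identical(m, oracle_match(tab, a, b))
    expect_identical(m, match_residues(tab, b, a))   # tolerance symmetry
  }
})

test_that("aggregate metrics: perfect, absent, and mixed predictions", {
  tab <- residue_table()
  perfect <- list(list(pred = "PETIDE", truth = "PETIDE"),
                  list(pred = "GASP", truth = "GASP"))
  r <- aggregate_eval(tab, perfect)
  expect_equal(r$aa_precision, 1)
  expect_equal(r$aa_recall, 1)
  expect_equal(r$peptide_precision, 1)
  none <- list(list(pred = NA, truth = "GASP"),
               list(pred = NA, truth = "PETIDE"))
  r0 <- aggregate_eval(tab, none)
  expect_equal(r0$aa_recall, 0)
  expect_equal(r0$peptide_precision, 0)
  expect_true(r0$no_predictions)
  mixed <- list(list(pred = "GASP", truth = "GASP"),
                list(pred = NA, truth = "SPAG"))
  rm <- aggregate_eval(tab, mixed)
  expect_equal(rm$aa_recall, 0.5)
  expect_equal(rm$peptide_precision, 0.5)
  # removing a correct prediction never increases recall
  expect_lte(rm$aa_recall, r$aa_recall)
  for (x in list(r, r0, rm)) {
    expect_true(all(unlist(x[c("aa_precision", "aa_recall",
                               "peptide_precision")]) >= 0))
    expect_true(all(unlist(x[c("aa_precision", "aa_recall",
                               "peptide_precision")]) <= 1))
  }
})

test_that("precision-coverage curves follow the cumulative oracle and AUC integrates to max coverage", {
  tab <- residue_table("reduced")
  truths <- c(F1 = "GASP", F2 = "VVSA", F3 = "PGSA", F4 = "AASG")
  # all correct: flat curve at 1, AUC = max coverage
  preds <- data.frame(feature_id = names(truths), peptide = unname(truths),
                      confidence = c(-0.1, -0.2, -0.3, -0.4))
  pc <- precision_coverage(tab, preds, truths)
  expect_equal(pc$curve$precision, rep(1, 4))
  expect_equal(pc$auc, 1)
  # single correct prediction: curve [(1/4, 1)], AUC 1/4
  pc1 <- precision_coverage(tab, preds[1L, ], truths)
  expect_equal(pc1$curve$coverage, 0.25)
  expect_equal(pc1$auc, 0.25)
  # alternating correct/incorrect with equal confidences: cumulative oracle
  preds2 <- data.frame(feature_id = names(truths),
                       peptide = c("GASP", "GGGG", "PGSA", "GGGG"),
                       confidence = rep(-0.5, 4))
  pc2 <- precision_coverage(tab, preds2, truths)
  correct <- c(TRUE, FALSE, TRUE, FALSE)    # stable order by feature id
  expect_equal(pc2$curve$precision, cumsum(correct) / seq_along(correct))
  expect_true(all(diff(pc2$curve$coverage) > 0))
})

test_that("end-to-end evaluation report writes scalars and curve", {
  tab <- residue_table("reduced")
  truths <- c(F1 = "GASP", F2 = "VVSA")
  preds <- data.frame(feature_id = c("F1", "F2"),
                      peptide = c("GASP", "VVSA"),
                      confidence = c(-0.1, -0.2))
  rep <- evaluate_predictions(tab, preds, truths)
  expect_equal(rep$peptide_precision, 1)
  expect_equal(rep$auc, 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, f)
  got <- jsonlite::read_json(f)
  expect_equal(got$aa_precision, 1)
  expect_true(file.exists(paste0(f, ".curve.csv")))
  expect_identical(nrow(utils::read.csv(paste0(f, ".curve.csv"))), 2L)
})
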