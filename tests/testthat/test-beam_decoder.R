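# reference greedy decoder over the step_logprobs interface, with the
# same mass rules as beam_search
greedy_ref <- function(scorer, ctx, table, max_len = 16L, mass_tol = 1e6) {
  budget <- ctx$mass - 18.010565
  banned <- which(!table$is_residue & seq_len(table$n_slots) != table$stop_id)
  seq <- integer(0); logps <- numeric(0); mass <- 0
  session <- diaseq:::.open_session(scorer, ctx)
  repeat {
    lp <- step_logprobs(scorer, seq, ctx, session)
    lp[banned] <- -Inf
    if (length(seq) >= max_len) {
      tok <- table$stop_id
    } else {
      ok <- rep(TRUE, length(lp))
      for (tk in which(table$is_residue))
        if (mass + table$mass[tk] > budget + mass_tol) ok[tk] <- FALSE
      if (length(seq) == 0L) ok[table$stop_id] <- FALSE
      lp[!ok] <- -Inf
      tok <- which.max(lp)
    }
    if (tok == table$stop_id) {
      if (abs(mass + 18.010565 - ctx$mass) <= mass_tol)
        return(list(seq = seq, conf = mean(logps)))
      return(NULL)
    }
    seq <- c(seq, tok); logps <- c(logps, lp[tok])
    mass <- mass + table$mass[tok]
  }
}

test_that("beam width 1 equals greedy decoding on the mock scorer", {
  tab <- residue_table("reduced")
  ctx <- mock_ctx()
  g <- greedy_ref(mock_scorer(), ctx, tab)
  b <- beam_search(ctx, mock_scorer(), beam_config(k = 1L, max_len = 16L,
                                                   mass_tol = 1e6), tab)
  expect_identical(tab$symbols[g$seq], b[[1L]]$symbols)
  expect_equal(g$conf, b[[1L]]$confidence)
  expect_identical(b[[1L]]$peptide, "A")   # greedy is deliberately shortsighted
})

test_that("beam width 2 on the mock scorer matches exhaustive enumeration", {
  tab <- residue_table("reduced")
  ctx <- mock_ctx()
  scorer <- mock_scorer()
  res_ids <- which(tab$is_residue)
  # enumerate every residue sequence of length <= 3 and its confidence
  best <- NULL
  for (n in 1:3) {
    grid <- do.call(expand.grid, rep(list(res_ids), n))
    for (r in seq_len(nrow(grid))) {
      ids <- as.integer(grid[r, ])
      logps <- vapply(seq_len(n), function(t)
        scorer(ids[seq_len(t - 1L)])[ids[t]], 0)
      conf <- mean(logps)
      if (is.null(best) || conf > best$conf)
        best <- list(ids = ids, conf = conf)
    }
  }
  b <- beam_search(ctx, scorer, beam_config(k = 2L, max_len = 3L,
                                            mass_tol = 1e6), tab)
  expect_identical(b[[1L]]$symbols, tab$symbols[best$ids])
  expect_equal(b[[1L]]$confidence, best$conf)
  expect_identical(b[[1L]]$peptide, "GV")
  # beam monotonicity on the mock: widening the beam cannot hurt
  b1 <- beam_search(ctx, scorer, beam_config(k = 1L, max_len = 3L,
                                             mass_tol = 1e6), tab)
  expect_gte(b[[1L]]$confidence, b1[[1L]]$confidence)
})

test_that("beam width 1 equals greedy decoding on a real model", {
  model <- fix_trained()
  for (ctx in fix_ctxs32()[c(1L, 5L)]) {
    g <- greedy_ref(model, ctx, model$table, max_len = model$cfg$max_len,
                    mass_tol = 0.5)
    b <- beam_search(ctx, model, beam_config(k = 1L, max_len = model$cfg$max_len,
                                             mass_tol = 0.5))
    if (is.null(g)) {
      expect_length(b, 0L)
    } else {
      expect_identical(g$seq, match(b[[1L]]$symbols, model$table$symbols))
      expect_equal(g$conf, b[[1L]]$confidence)
    }
  }
})

test_that("every emitted peptide satisfies the precursor mass tolerance", {
  model <- fix_trained()
  tol <- 0.1
  cfgb <- beam_config(k = 5L, max_len = model$cfg$max_len, mass_tol = tol)
  n_checked <- 0L
  for (ctx in fix_ctxs32()[1:6]) {
    preds <- suppressMessages(beam_search(ctx, model, cfgb))
    for (p in preds) {
      expect_lte(abs(peptide_mass(model$table, p$peptide) - ctx$mass), tol)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 0L)
})

test_that("confidence is the mean per-residue log-probability", {
  expect_equal(prediction_score(log(c(1, 1, 1))), 0)
  expect_equal(prediction_score(rep(-log(8), 4)), -log(8))
  expect_error(prediction_score(numeric(0)), "empty")
  # ranking by mean equals ranking by sum for equal lengths
  set.seed(6)
  a <- matrix(log(runif(30)), 10)
  expect_identical(order(rowMeans(a)), order(rowSums(a)))
})

test_that("equal-score hypotheses are ordered lexicographically", {
  tab <- residue_table("reduced")
  # two symmetric outcomes with identical probabilities
  scorer <- function(prefix_ids) {
    lp <- function(x) log(x / sum(x))
    if (length(prefix_ids) == 0L) lp(c(0.5, 0.5, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9))
    else lp(c(1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1, 1e-9))
  }
  b <- beam_search(mock_ctx(), scorer, beam_config(k = 2L, max_len = 1L,
                                                   mass_tol = 1e6), tab)
  expect_identical(vapply(b, `[[`, "", "peptide")[1:2], c("G", "A"))
})

test_that("an unreachable mass window yields an empty prediction with a message", {
  model <- fix_rand_model()
  ctx <- fix_ctxs_small()[[1L]]
  ctx$mass <- 50   # below a single residue: nothing can finish
  expect_message(preds <- beam_search(ctx, model,
                                      beam_config(k = 2L, max_len = 4L,
                                                  mass_tol = 1e-4)),
                 "no hypothesis")
  expect_length(preds, 0L)
})

test_that("prediction tables round-trip through TSV", {
  model <- fix_trained()
  preds <- suppressMessages(predict_features(model, fix_ctxs32()[1:4],
                                             beam_config(k = 5L, max_len = 16L,
                                                         mass_tol = 0.1)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(preds, f)
  got <- read_predictions(f)
  expect_identical(got$peptide, preds$peptide)
  expect_equal(got$confidence, preds$confidence, tolerance = 1e-12)
})
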