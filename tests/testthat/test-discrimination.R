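# the published verdict grid (rank x window), frozen for reproduction tests
published_verdicts <- matrix(
  c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,
    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
    FALSE, FALSE, FALSE, TRUE,  TRUE,  TRUE,
    TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,
    TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,
    TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,
    FALSE, TRUE,  FALSE, FALSE, TRUE,  FALSE,
    FALSE, FALSE, TRUE,  TRUE,  FALSE, FALSE,
    FALSE, TRUE,  TRUE,  TRUE,  TRUE,  TRUE,
    FALSE, TRUE,  TRUE,  TRUE,  TRUE,  TRUE,
    TRUE,  TRUE,  FALSE, TRUE,  TRUE,  TRUE,
    TRUE,  FALSE, TRUE,  TRUE,  TRUE,  TRUE),
  nrow = 12, byrow = TRUE,
  dimnames = list(rank = 1:12, window = si_windows()))

test_that("paired contrasts match the closed-form paired t", {
  y <- c(2.2, -1.3, 0.7)
  ct <- paired_contrast(y + c(1, 2, 3), y)
  expect_equal(ct$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(ct$df, 2)
  expect_equal(ct$p_raw, 2 * pt(2 / (1 / sqrt(3)), 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(ct$p_raw, 4), 0.0742)
  expect_equal(ct$direction, "si_higher")
  # identical scores: t = 0, p = 1, no direction
  same <- paired_contrast(y, y)
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
  expect_equal(same$direction, "none")
  # constant non-zero differences are degenerate
  expect_warning(dg <- paired_contrast(y + 2, y), "degenerate")
  expect_true(dg$degenerate)
  expect_equal(dg$p_raw, 0)
})

test_that("BH adjustment agrees with the brute-force step-up", {
  set.seed(21)
  for (k in 1:60) {
    m <- sample(1:200, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 6), 1))
    rec <- data.frame(window = sample(letters[1:3], m, replace = TRUE),
                      p_raw = p)
    out <- apply_fdr(rec, family = "all")
    oracle <- brute_force_bh(p)
    expect_equal(out$p_adj, oracle$p_adj, tolerance = 1e-12)
    expect_identical(out$significant, oracle$reject)
  }
  # worked example of the step-up
  ex <- apply_fdr(data.frame(p_raw = c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(ex$p_adj, rep(0.04, 4))
  expect_true(all(ex$significant))
  expect_equal(apply_fdr(data.frame(p_raw = 0.2))$p_adj, 0.2)
  expect_true(all(apply_fdr(data.frame(p_raw = rep(0, 5)))$significant))
  expect_error(apply_fdr(data.frame(p_raw = numeric(0))), "empty")
})

test_that("per-window FDR families are corrected independently", {
  rec <- data.frame(window = rep(c("a", "b"), each = 3),
                    p_raw = c(0.01, 0.02, 0.03, 0.2, 0.5, 0.9))
  out <- apply_fdr(rec, family = "per_window")
  expect_equal(out$p_adj[1:3], p.adjust(rec$p_raw[1:3], "BH"))
  expect_equal(out$p_adj[4:6], p.adjust(rec$p_raw[4:6], "BH"))
})

test_that("shrinking a raw p never de-selects a significant contrast", {
  set.seed(8)
  for (k in 1:20) {
    p <- runif(30)
    base <- apply_fdr(data.frame(p_raw = p))$significant
    i <- sample(30, 1)
    p2 <- p; p2[i] <- p[i] * runif(1)
    after <- apply_fdr(data.frame(p_raw = p2))$significant
    expect_true(all(after[base]))
  }
})

test_that("discrimination criteria match the hand-enumerated truth table", {
  # states: ns = not significant, hi = significant si_higher,
  #         lo = significant si_lower
  cases <- expand.grid(hp = c("ns", "hi", "lo"), lp = c("ns", "hi", "lo"),
                       stringsAsFactors = FALSE)
  # criterion 1 (HP-ranked): needs a significant win over LP and no
  # significant loss to HP
  expected1 <- c(ns.ns = FALSE, hi.ns = FALSE, lo.ns = FALSE,
                 ns.hi = TRUE,  hi.hi = TRUE,  lo.hi = FALSE,
                 ns.lo = FALSE, hi.lo = FALSE, lo.lo = FALSE)
  # criterion 2 (LP-ranked): needs a significant loss to HP and no
  # significant win over LP
  expected2 <- c(ns.ns = FALSE, hi.ns = FALSE, lo.ns = TRUE,
                 ns.hi = FALSE, hi.hi = FALSE, lo.hi = FALSE,
                 ns.lo = FALSE, hi.lo = FALSE, lo.lo = TRUE)
  as_args <- function(state) switch(state,
    ns = list(sig = FALSE, dir = "none"),
    hi = list(sig = TRUE, dir = "si_higher"),
    lo = list(sig = TRUE, dir = "si_lower"))
  for (r in seq_len(nrow(cases))) {
    hp <- as_args(cases$hp[r]); lp <- as_args(cases$lp[r])
    key <- paste(cases$hp[r], cases$lp[r], sep = ".")
    expect_identical(evaluate_criteria(3, hp$sig, hp$dir, lp$sig, lp$dir),
                     unname(expected1[key]), label = paste("crit1", key))
    expect_identical(evaluate_criteria(9, hp$sig, hp$dir, lp$sig, lp$dir),
                     unname(expected2[key]), label = paste("crit2", key))
  }
})

test_that("the published table evaluates to the published verdict grid", {
  ev <- evaluate_published_table()
  expect_identical(unname(ev$verdicts), unname(published_verdicts))
  # the worked example: item 5 in 400-800 fulfils criterion 1
  expect_true(ev$verdicts["5", "400-800"])
  # item 9 in the N200 window is significantly above LP, violating y <= LP
  expect_false(ev$verdicts["9", "n200"])
  expect_equal(ev$accuracy$n_true, 51)
  expect_equal(ev$accuracy$by_window_true,
               c("n200" = 6, "400-800" = 8, "800-1200" = 8,
                 "1200-1600" = 10, "1600-2000" = 10, "2000-3000" = 9))
  expect_equal(ev$accuracy$psw_800_3000, 37 / 48)
  expect_equal(ev$accuracy$excluding_true, 43)
  expect_equal(ev$accuracy$excluding_total, 60)
})

test_that("the packaged table fixture is a valid complete grid", {
  fx <- load_published_table()
  expect_equal(nrow(fx), 72)
  expect_setequal(unique(fx$window), si_windows())
  expect_true(all(fx$p_lp[fx$sig_lp] < 0.05))
  expect_true(all(fx$p_hp[fx$sig_hp] < 0.05))
  # corrupted fixtures are refused
  bad <- fx; bad$sig_lp[3] <- TRUE; bad$p_lp[3] <- 0.5
  tmp <- tempfile(fileext = ".csv")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_published_table(tmp), "significance flag")
})

test_that("group reference scores use leave-one-out only within the group", {
  # constant traces per item make window means trivial to predict
  n_t <- 60
  times <- seq(-200, 3000, length.out = n_t)
  consts <- c(10, 20, 30, 40, 50, 60)   # items 1-3 HP, 4-6 LP
  tr <- array(0, dim = c(4, 6, n_t))    # 4 participants
  for (i in 1:6) tr[, i, ] <- consts[i]
  traces <- list(anterior = tr, posterior = tr, times = times)
  profile <- profile_from_counts(matrix(rep(6:1, 4), 4, 6, byrow = TRUE))
  sc <- si_component_scores(traces, profile, windows = "400-800")
  expect_equal(unname(sc$si[1, , 1]), consts)
  # item 2 is HP: its HP reference averages items 1 and 3
  expect_equal(unname(sc$hp_ref[1, 2, 1]), mean(consts[c(1, 3)]))
  # item 2 against LP uses the full LP group
  expect_equal(unname(sc$lp_ref[1, 2, 1]), mean(consts[4:6]))
  # item 5 is LP: LP reference leaves item 5 out
  expect_equal(unname(sc$lp_ref[1, 5, 1]), mean(consts[c(4, 6)]))
  expect_equal(unname(sc$hp_ref[1, 5, 1]), mean(consts[1:3]))
})

test_that("accuracy aggregation counts verdicts and exclusions", {
  all_true <- matrix(TRUE, 12, 6,
                     dimnames = list(rank = 1:12, window = si_windows()))
  acc <- aggregate_accuracy(all_true)
  expect_equal(acc$overall, 1)
  expect_true(all(acc$by_window == 1))
  acc2 <- aggregate_accuracy(published_verdicts, exclude_ranks = c(6, 7))
  expect_equal(acc2$excluding, 43 / 60)
  expect_error(aggregate_accuracy(published_verdicts, exclude_ranks = 1:12),
               "remove all items")
})
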