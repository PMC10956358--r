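test_that("ranked_screen orders best-first with stable ties", {
  s <- ranked_screen(c("a", "b", "c", "d"), c(1, 3, 3, 2),
                     c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(s$entries$id, c("b", "c", "d", "a"))
  expect_equal(s$n_actives, 2)
  expect_equal(s$n_decoys, 2)
})

test_that("roc_auc equals the brute-force pairwise count on 50 lists", {
  s <- perfect_screen_22_28()
  expect_equal(roc_auc(s), 1)
  rev_s <- screen_from_pattern(rep(c(FALSE, TRUE), c(6, 22)))
  expect_equal(roc_auc(rev_s), 0)
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(10:40, 1)
    # quantized scores force ties
    scores <- round(rnorm(n), 1)
    active <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(active) || all(active)) next
    s <- ranked_screen(paste0("l", 1:n), scores, active)
    expect_equal(roc_auc(s), bruteforce_auc(s))
  }
  expect_error(roc_auc(screen_from_pattern(rep(TRUE, 5))), "decoy")
})

test_that("roc_auc of a tie-free list and its reverse sum to 1", {
  for (seed in 1:10) {
    set.seed(seed)
    active <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(active) || all(active)) next
    scores <- sample(seq_len(20))
    fwd <- ranked_screen(paste0("l", 1:20), scores, active)
    bwd <- ranked_screen(paste0("l", 1:20), -scores, active)
    expect_equal(roc_auc(fwd) + roc_auc(bwd), 1)
  }
})

test_that("BEDROC is 1 for the perfect 22/28 ranking at alpha 160.9", {
  br <- bedroc_rie(perfect_screen_22_28(), alpha = 160.9)
  expect_equal(br$bedroc, 1, tolerance = 1e-12)
  # all actives last: essentially zero
  worst <- screen_from_pattern(rep(c(FALSE, TRUE), c(6, 22)))
  expect_lte(bedroc_rie(worst, 160.9)$bedroc, 0.01)
  expect_error(bedroc_rie(perfect_screen_22_28(), alpha = 0), "alpha")
})

test_that("BEDROC stays in [0, 1] and regression-pins decoy appending", {
  for (seed in 1:25) {
    set.seed(seed)
    pat <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(pat) || all(pat)) next
    b <- bedroc_rie(screen_from_pattern(pat), 20)$bedroc
    expect_gte(b, 0)
    expect_lte(b, 1)
  }
  # exact-value regression: appending decoys below the last active changes
  # BEDROC only slightly at this alpha (finite-N effect, pinned here)
  base <- screen_from_pattern(c(TRUE, TRUE, FALSE, TRUE, FALSE))
  grown <- screen_from_pattern(c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 11)))
  expect_equal(bedroc_rie(base, 20)$bedroc, 0.9996766, tolerance = 1e-6)
  expect_equal(bedroc_rie(grown, 20)$bedroc, 0.9616169, tolerance = 1e-6)
})

test_that("mean RIE over random shufflings is the uniform expectation 1", {
  rie <- numeric(2000)
  for (i in seq_len(2000)) {
    set.seed(i)
    rie[i] <- bedroc_rie(screen_from_pattern(
      sample(rep(c(TRUE, FALSE), c(22, 6)))), 160.9)$rie
  }
  expect_equal(mean(rie), 1, tolerance = 0.05)
})

test_that("enrichment factors follow the counting definition", {
  # 22 actives among 35 ligands, exactly 7 in the top ceil(0.2*35) = 7 slots
  pat <- c(rep(TRUE, 7), rep(c(FALSE, TRUE), c(13, 15)))
  s <- screen_from_pattern(pat)       # 22 actives, 13 decoys, N = 35
  expect_equal(s$n_actives, 22)
  expect_equal(sum(s$entries$active[1:7]), 7)
  expect_equal(enrichment_factor(s, 0.2), (7 / 22) / 0.2, tolerance = 1e-12)
  # perfect ranking attains the 1/f bound when the top slice holds exactly
  # all actives (5 actives of 25, f = 0.2)
  perf <- screen_from_pattern(rep(c(TRUE, FALSE), c(5, 20)))
  expect_equal(enrichment_factor(perf, 0.2), 5)
  # no actives in the slice
  worst <- screen_from_pattern(rep(c(FALSE, TRUE), c(6, 22)))
  expect_equal(enrichment_factor(worst, 0.2), 0)
  expect_error(enrichment_factor(s, 0), "top_fraction")
})

test_that("EF at the full list is always 1", {
  for (seed in 1:20) {
    set.seed(seed)
    pat <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    if (!any(pat) || all(pat)) next
    expect_equal(enrichment_factor(screen_from_pattern(pat), 1), 1)
  }
})

test_that("accumulation curve matches brute-force integration", {
  s <- perfect_screen_22_28()
  acc <- accumulation_curve(s)
  expect_equal(acc$auac, bruteforce_auac(s), tolerance = 1e-12)
  expect_true(all(diff(acc$curve$fraction_actives_found) >= 0))
  expect_equal(tail(acc$curve$fraction_actives_found, 1), 1)
  # reversed < perfect
  worst <- screen_from_pattern(rep(c(FALSE, TRUE), c(6, 22)))
  expect_lt(accumulation_curve(worst)$auac, acc$auac)
  for (seed in 1:20) {
    set.seed(seed)
    pat <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(pat) || all(pat)) next
    s2 <- screen_from_pattern(pat)
    expect_equal(accumulation_curve(s2)$auac, bruteforce_auac(s2))
  }
})

test_that("random-ranking AUAC averages to 0.5", {
  auac <- numeric(2000)
  for (i in seq_len(2000)) {
    set.seed(10000 + i)
    auac[i] <- accumulation_curve(screen_from_pattern(
      sample(rep(c(TRUE, FALSE), c(11, 14)))))$auac
  }
  expect_equal(mean(auac), 0.5, tolerance = 0.03)
})

test_that("actives recovered at a decoy fraction match the worked values", {
  # 7 of 22 actives precede the rank of the 2nd decoy (20% of 6 decoys)
  pat <- c(rep(TRUE, 7), FALSE, FALSE, rep(TRUE, 15), rep(FALSE, 4))
  s <- screen_from_pattern(pat)
  expect_equal(s$n_actives, 22)
  expect_equal(s$n_decoys, 6)
  expect_equal(round(actives_at_decoy_fraction(s, 0.2), 1), 31.8)
  # 2 of 16 actives precede the 20%-decoy rank among 24 ligands
  pat2 <- c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 14), rep(FALSE, 6))
  s2 <- screen_from_pattern(pat2)
  expect_equal(s2$n_actives, 16)
  expect_equal(s2$n_decoys, 8)
  expect_equal(actives_at_decoy_fraction(s2, 0.2), 12.5)
  # all actives before any decoy
  expect_equal(actives_at_decoy_fraction(perfect_screen_22_28(), 0.2), 100)
})

test_that("screen CSV round-trips and the full report is coherent", {
  s <- gen_ranked_screen(n_actives = 12, n_decoys = 18, separation = 1.5,
                         seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(s, f)
  back <- read_screen_csv(f)
  expect_equal(back$entries$id, s$entries$id)
  expect_equal(back$entries$score, s$entries$score, tolerance = 1e-15)
  rep <- enrichment_report(s)
  expect_equal(rep$roc_auc, roc_auc(s))
  expect_equal(rep$bedroc, bedroc_rie(s)$bedroc)
  # EF bound allowing for the ceiling of the top-slice size
  N <- s$n_actives + s$n_decoys
  f_grid <- c(0.01, 0.05, 0.2)
  expect_true(all(rep$ef <= ceiling(f_grid * N) / (s$n_actives * f_grid) +
                    1e-9))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,score", "a,1"), f2)
  expect_error(read_screen_csv(f2), "active")
})
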