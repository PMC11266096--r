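test_that("named presets carry their fixed thresholds and reject overrides", {
  m <- threshold_preset("moderate")
  expect_equal(c(m$quality, m$multi_pair_margin, m$single_pair_junk),
               c(0.85, 0.03, 0.80))
  l <- threshold_preset("lenient")
  expect_equal(c(l$quality, l$multi_pair_margin, l$single_pair_junk),
               c(0.80, 0.02, 0.70))
  s <- threshold_preset("stringent")
  expect_equal(c(s$quality, s$multi_pair_margin, s$single_pair_junk),
               c(0.90, 0.035, 0.85))
  expect_error(threshold_preset("moderate", quality = 0.5), "immutable")
  expect_error(threshold_preset("custom", quality = 0.5,
                                multi_pair_margin = 0.1,
                                single_pair_junk = 0.9), "single_pair_junk")
})

test_that("a one-to-one family is kept at the single-pair bar", {
  sc <- scores_df("a1", "b1", 0.82)
  out <- select_proxies(sc, orth_from_pairs(sc), "moderate")
  expect_identical(nrow(out), 1L)
  expect_identical(out$class, "one_to_one")
  out2 <- select_proxies(scores_df("a1", "b1", 0.79), orth_from_pairs(sc),
                         "moderate")
  expect_identical(nrow(out2), 0L)
})

test_that("the 2x1 margin example keeps or drops the best pair as the margin dictates", {
  sc <- scores_df(c("a1", "a2"), c("b1", "b1"), c(0.90, 0.85))
  out <- select_proxies(sc, orth_from_pairs(sc), "moderate")
  expect_identical(pair_key(out), "a1 b1")
  expect_identical(out$class, "proxy")
  sc2 <- scores_df(c("a1", "a2"), c("b1", "b1"), c(0.90, 0.88))
  out2 <- select_proxies(sc2, orth_from_pairs(sc2), "moderate")
  expect_identical(nrow(out2), 0L)
})

test_that("margin scope: all candidates compete by default, survivors-only on request", {
  # a2-b1 fails quality (0.84 < 0.85) but still competes in the default
  # margin (0.86 - 0.84 = 0.02 < 0.03); the surviving-only variant ignores it
  sc <- scores_df(c("a1", "a2"), c("b1", "b1"), c(0.86, 0.84))
  orth <- orth_from_pairs(sc)
  expect_identical(nrow(select_proxies(sc, orth, "moderate")), 0L)
  out <- select_proxies(sc, orth, "moderate", margin_scope = "surviving")
  expect_identical(pair_key(out), "a1 b1")
})

test_that("random families match the literal rule-by-rule oracle at all presets", {
  withr::local_seed(31)
  for (i in 1:60) {
    n_a <- sample(1:5, 1); n_b <- sample(1:5, 1)
    df <- expand.grid(gene_a = paste0("a", seq_len(n_a)),
                      gene_b = paste0("b", seq_len(n_b)),
                      stringsAsFactors = FALSE)
    df$group_id <- "og1"
    df$score <- runif(nrow(df), 0.5, 1)
    sc <- structure(df, class = c("conservation_scores", "data.frame"))
    orth <- orth_from_pairs(df)
    for (p in c("lenient", "moderate", "stringent")) {
      preset <- threshold_preset(p)
      got <- select_proxies(sc, orth, preset)
      want <- oracle_select_family(df, preset, n_a, n_b)
      expect_setequal(pair_key(got), paste(want$gene_a, want$gene_b))
    }
  }
})

test_that("stricter presets only remove pairs (nesting) and margins are monotone", {
  withr::local_seed(32)
  for (i in 1:25) {
    df <- expand.grid(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4),
                      stringsAsFactors = FALSE)
    df$group_id <- "og1"
    df$score <- runif(16, 0.6, 1)
    sc <- structure(df, class = c("conservation_scores", "data.frame"))
    orth <- orth_from_pairs(df)
    keys <- lapply(c("stringent", "moderate", "lenient"), function(p)
      pair_key(select_proxies(sc, orth, p)))
    expect_true(all(keys[[1]] %in% keys[[2]]))
    expect_true(all(keys[[2]] %in% keys[[3]]))
    wide <- pair_key(select_proxies(sc, orth,
      threshold_preset("custom", quality = 0.85, multi_pair_margin = 0.10,
                       single_pair_junk = 0.80)))
    expect_true(all(wide %in% pair_key(select_proxies(sc, orth, "moderate"))))
  }
})

test_that("selected multi-family pairs are reciprocal best hits with unique genes", {
  withr::local_seed(33)
  df <- expand.grid(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                    stringsAsFactors = FALSE)
  df$group_id <- "og1"
  df$score <- runif(25, 0.8, 1)
  sc <- structure(df, class = c("conservation_scores", "data.frame"))
  out <- select_proxies(sc, orth_from_pairs(df), "lenient")
  expect_false(anyDuplicated(out$gene_a) > 0)
  expect_false(anyDuplicated(out$gene_b) > 0)
  for (i in seq_len(nrow(out))) {
    s <- out$score[i]
    expect_gte(s, max(df$score[df$gene_a == out$gene_a[i]]))
    expect_gte(s, max(df$score[df$gene_b == out$gene_b[i]]))
  }
})

test_that("worst-proxy control takes minimum-score pairs greedily", {
  sc <- scores_df(c("a1", "a1", "a2"), c("b1", "b2", "b1"), c(0.9, 0.5, 0.7))
  out <- select_worst_proxies(sc, orth_from_pairs(sc))
  expect_identical(out$score[1], 0.5)
  expect_setequal(pair_key(out), c("a1 b2", "a2 b1"))

  one <- scores_df("a1", "b1", 0.95)
  expect_identical(pair_key(select_worst_proxies(one, orth_from_pairs(one))),
                   "a1 b1")

  sc2 <- scores_df(c("a1", "a1", "a2", "a2"), c("b1", "b2", "b1", "b2"),
                   c(0.9, 0.3, 0.4, 0.8))
  out2 <- select_worst_proxies(sc2, orth_from_pairs(sc2))
  expect_setequal(pair_key(out2), c("a1 b2", "a2 b1"))
})

test_that("random pair control is seed-reproducible without gene reuse", {
  ga <- paste0("a", 1:100); gb <- paste0("b", 1:100)
  r1 <- random_pairs(ga, gb, 50, seed = 7)
  r2 <- random_pairs(ga, gb, 50, seed = 7)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- random_pairs(ga, gb, 50, seed = 8)
  expect_false(identical(r1$gene_a, r3$gene_a) && identical(r1$gene_b, r3$gene_b))
  expect_false(anyDuplicated(r1$gene_a) > 0)
  expect_false(anyDuplicated(r1$gene_b) > 0)
  full <- random_pairs(ga, gb, 100, seed = 1)
  expect_setequal(full$gene_a, ga)
  expect_setequal(full$gene_b, gb)
  expect_error(random_pairs(ga, gb, 101, seed = 1), "exceeds")
})
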