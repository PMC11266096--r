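test_that("AUROC handles separation, ties, and the worked 4-gene case", {
  s <- c(g1 = 0.9, g2 = 0.8, g3 = 0.2, g4 = 0.1)
  expect_equal(auroc_from_scores(s, c("g1", "g2")), 1)
  expect_equal(auroc_from_scores(rep(c(a = 0.5, b = 0.5, c = 0.5), 1),
                                 "a"), 0.5)
  s2 <- c(g1 = 0.9, g2 = 0.7, g3 = 0.5, g4 = 0.3)
  expect_equal(auroc_from_scores(s2, c("g1", "g3")), 0.75)
  expect_equal(oracle_auroc(s2, c("g1", "g3")), 0.75)
})

test_that("AUROC equals the O(n^2) concordant-pair oracle on random inputs", {
  withr::local_seed(11)
  for (i in 1:50) {
    n <- sample(4:25, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    names(scores) <- paste0("g", seq_len(n))
    pos <- sample(names(scores), sample(seq_len(n - 1), 1))
    expect_equal(auroc_from_scores(scores, pos), oracle_auroc(scores, pos),
                 tolerance = 1e-12)
  }
})

test_that("AUROC reversal antisymmetry holds for tie-free scores", {
  withr::local_seed(12)
  for (i in 1:20) {
    scores <- stats::setNames(sample(seq(0.01, 0.99, length.out = 15)),
                              paste0("g", 1:15))
    pos <- paste0("g", 1:4)
    expect_equal(auroc_from_scores(scores, pos) +
                   auroc_from_scores(-scores, pos), 1, tolerance = 1e-12)
  }
})

test_that("degenerate AUROC inputs are errors for the caller to handle", {
  s <- c(a = 1, b = 2)
  expect_error(auroc_from_scores(s, character()), "positives")
  expect_error(auroc_from_scores(s, c("a", "b")), "negatives")
  expect_error(auroc_from_scores(unname(s), "a"), "named")
})

make_anchor_fixture <- function(n = 12, seed = 21) {
  withr::local_seed(seed)
  ga <- c("qa", paste0("a", seq_len(n)))
  gb <- c("qb", paste0("b", seq_len(n)))
  list(net_a = random_toy_network(ga), net_b = random_toy_network(gb),
       anchor = stats::setNames(paste0("b", seq_len(n)), paste0("a", seq_len(n))))
}

test_that("directional conservation hits 1 on perfect conservation and 0.5 on flat ranks", {
  fx <- make_anchor_fixture()
  top <- top_partners(fx$net_a, "qa", 10, names(fx$anchor))
  wb <- fx$net_b$weights
  wb[] <- 0.5
  # qb's strongest edges are exactly the anchor images of qa's top partners
  for (g in unname(fx$anchor[top])) wb["qb", g] <- wb[g, "qb"] <- 0.99
  diag(wb) <- 1
  net_b2 <- coex_network(wb)
  expect_equal(directional_conservation(fx$net_a, net_b2, "qa", "qb",
                                        fx$anchor, k = 10), 1)
  flat <- wb; flat[] <- 0.5; diag(flat) <- 1
  expect_equal(directional_conservation(fx$net_a, coex_network(flat), "qa",
                                        "qb", fx$anchor, k = 10), 0.5)
})

test_that("directional conservation equals hand computation through the AUROC oracle", {
  fx <- make_anchor_fixture(seed = 22)
  k <- 5
  partners <- top_partners(fx$net_a, "qa", k, names(fx$anchor))
  positives <- unname(fx$anchor[partners])
  candidates <- unname(fx$anchor)
  scores <- fx$net_b$weights["qb", candidates]
  names(scores) <- candidates
  expect_equal(
    directional_conservation(fx$net_a, fx$net_b, "qa", "qb", fx$anchor, k = k),
    oracle_auroc(scores, positives), tolerance = 1e-12)
})

test_that("too few mapped partners yields undefined, not an error", {
  fx <- make_anchor_fixture(seed = 23)
  expect_true(is.na(directional_conservation(fx$net_a, fx$net_b, "qa", "qb",
                                             fx$anchor[1:2], k = 10,
                                             min_positives = 3)))
  expect_error(directional_conservation(fx$net_a, fx$net_b, "missing", "qb",
                                        fx$anchor), "absent")
})

test_that("the pair score averages directions and is species-symmetric", {
  fx <- make_anchor_fixture(seed = 24)
  s <- conservation_score(fx$net_a, fx$net_b, "qa", "qb", fx$anchor, k = 6)
  expect_equal(s$score, (s$auroc_ab + s$auroc_ba) / 2)
  rev_anchor <- stats::setNames(names(fx$anchor), unname(fx$anchor))
  s_rev <- conservation_score(fx$net_b, fx$net_a, "qb", "qa", rev_anchor, k = 6)
  expect_equal(s$score, s_rev$score, tolerance = 1e-12)
})

test_that("conservation matrix enumerates within-family candidates", {
  withr::local_seed(25)
  # 12 one-to-one anchor groups + one 2x1 multi-gene group
  tab <- rbind(
    data.frame(group_id = rep(paste0("og", 1:12), each = 2),
               species_id = rep(c("A", "B"), 12),
               gene_id = as.vector(rbind(paste0("a", 1:12), paste0("b", 1:12)))),
    data.frame(group_id = "ogX", species_id = c("A", "A", "B"),
               gene_id = c("qa", "qa2", "qb")))
  ga <- c(paste0("a", 1:12), "qa", "qa2")
  gb <- c(paste0("b", 1:12), "qb")
  net_a <- random_toy_network(ga)
  net_b <- random_toy_network(gb)
  orth <- orthology_map(tab, species = c("A", "B"))
  cm <- conservation_matrix(net_a, net_b, orth, k = 5, min_positives = 3)
  # the 2x1 family contributes its two candidate pairs
  expect_true(all(cm$group_id[cm$gene_a %in% c("qa", "qa2")] == "ogX"))
  expect_identical(sum(cm$group_id == "ogX"), 2L)
  expect_true(all(cm$score >= 0 & cm$score <= 1))
  expect_error(conservation_matrix(net_a, net_b, orth, k = 20),
               "anchors")
})

test_that("conservation matrix is invariant to gene ordering of its inputs", {
  fx <- make_anchor_fixture(seed = 26)
  tab <- rbind(
    data.frame(group_id = rep(paste0("og", 1:12), each = 2),
               species_id = rep(c("A", "B"), 12),
               gene_id = as.vector(rbind(paste0("a", 1:12), paste0("b", 1:12)))),
    data.frame(group_id = "ogQ", species_id = c("A", "B"),
               gene_id = c("qa", "qb")))
  orth <- orthology_map(tab, species = c("A", "B"))
  cm1 <- conservation_matrix(fx$net_a, fx$net_b, orth, k = 5)
  perm <- sample(rownames(fx$net_a$weights))
  net_a2 <- coex_network(fx$net_a$weights[perm, perm])
  cm2 <- conservation_matrix(net_a2, fx$net_b, orth, k = 5)
  m1 <- cm1[order(cm1$gene_a, cm1$gene_b), ]
  m2 <- cm2[order(cm2$gene_a, cm2$gene_b), ]
  expect_equal(m1$score, m2$score, tolerance = 1e-12)
})
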