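two_type_expr <- function(n_cells = 60, seed = 41, species = "A",
                          prefix = species) {
  withr::local_seed(seed)
  types <- rep(c("t1", "t2"), length.out = n_cells)
  mu <- cbind(c(20, 20, 1, 1), c(1, 1, 20, 20))  # genes x type means
  m <- sapply(seq_len(n_cells), function(i)
    rnbinom(4, mu = mu[, (i - 1) %% 2 + 1], size = 5))
  dimnames(m) <- list(paste0(prefix, "_g", 1:4),
                      paste0(prefix, "_c", seq_len(n_cells)))
  expression_matrix(m + 0, cell_types = types, species = species)
}

test_that("identity alignment of duplicated data gives identical blocks", {
  ea <- two_type_expr()
  eb <- ea; eb$species <- "B"
  pairs <- proxy_list(rownames(ea$values), rownames(ea$values))
  ad <- align_gene_spaces(ea, eb, pairs)
  va <- ad$values[ad$dataset_labels == "a", ]
  vb <- ad$values[ad$dataset_labels == "b", ]
  expect_equal(unname(va), unname(vb))
  expect_identical(ncol(ad$values), 4L)
})

test_that("a single proxy pair yields a one-column aligned dataset", {
  ea <- two_type_expr(seed = 42)
  eb <- two_type_expr(seed = 43, species = "B")
  ad <- align_gene_spaces(ea, eb, proxy_list("A_g1", "B_g2"))
  expect_identical(ncol(ad$values), 1L)
  expect_equal(unname(ad$values[ad$dataset_labels == "a", 1]),
               unname(cpm(ea)["A_g1", ]))
  expect_equal(unname(ad$values[ad$dataset_labels == "b", 1]),
               unname(cpm(eb)["B_g2", ]))
})

test_that("missing proxy genes are dropped pairwise; zero-count cells warn", {
  ea <- two_type_expr(seed = 44)
  eb <- two_type_expr(seed = 45, species = "B")
  expect_warning(
    ad <- align_gene_spaces(ea, eb, proxy_list(c("A_g1", "A_gX"),
                                               c("B_g1", "B_g2"))),
    "missing")
  expect_identical(ncol(ad$values), 1L)
  expect_error(suppressWarnings(
    align_gene_spaces(ea, eb, proxy_list("A_gX", "B_gX"))), "usable")

  ez <- ea
  ez$values[, 1] <- 0
  expect_warning(cpm(ez), "zero total")
})

test_that("mixing metrics apply the 30-70% and >60% definitions literally", {
  cl <- rep(1, 100)
  ds <- rep(c("a", "b"), c(40, 60))
  m <- mixing_metrics(cl, ds)
  expect_true(m$per_cluster$mixed[1])
  expect_equal(m$fraction_in_mixed_clusters, 1)

  ds2 <- rep(c("a", "b"), c(80, 20))
  m2 <- mixing_metrics(cl, ds2)
  expect_equal(m2$fraction_in_mixed_clusters, 0)

  types <- rep(c("phloem", "xylem"), c(61, 39))
  m3 <- mixing_metrics(cl, ds, types)
  expect_identical(m3$per_cluster$majority_type[1], "phloem")
  # a phloem cell counts as matched because its cluster is mixed AND phloem
  expect_equal(m3$fraction_celltype_matched, 0.61)
  m4 <- mixing_metrics(cl, ds2, types)
  expect_equal(m4$fraction_celltype_matched, 0)
})

test_that("headline fractions recompute from the per-cluster table", {
  withr::local_seed(46)
  cl <- sample(1:4, 200, replace = TRUE)
  ds <- sample(c("a", "b"), 200, replace = TRUE)
  ty <- sample(c("t1", "t2", "t3"), 200, replace = TRUE)
  m <- mixing_metrics(cl, ds, ty)
  per <- m$per_cluster
  expect_equal(sum(per$size[per$mixed]) / 200, m$fraction_in_mixed_clusters)
  expect_lte(m$fraction_celltype_matched, m$fraction_in_mixed_clusters)
})

test_that("profile distances follow Euclidean geometry on per-type means", {
  # two datasets engineered so per-type mean CPM profiles are exact
  mk <- function(prefix, v1, v2, v3) {
    m <- rbind(rep(c(v1[1], v1[2], v1[3]), each = 2),
               rep(c(v2[1], v2[2], v2[3]), each = 2),
               rep(c(v3[1], v3[2], v3[3]), each = 2))
    dimnames(m) <- list(paste0(prefix, c("x", "y", "z")),
                        paste0(prefix, 1:6))
    expression_matrix(m, cell_types = rep(c("u", "v", "w"), each = 2),
                      species = prefix)
  }
  # column sums are constant (4), so CPM is a fixed rescaling by 1e6 / 4
  ea <- mk("a", c(0, 0, 3), c(0, 4, 0), c(4, 0, 1))
  eb <- mk("b", c(0, 0, 3), c(0, 4, 0), c(4, 0, 1))
  scale <- 1e6 / 4
  pd <- profile_distance_eval(ea, eb,
                              proxy_list(c("ax", "ay"), c("bx", "by")),
                              proxy_list("ax", "by"))
  acc <- pd$per_pair[pd$per_pair$list == "accepted", ]
  expect_equal(acc$distance, c(0, 0))  # identical per-type profiles
  riv <- pd$per_pair[pd$per_pair$list == "rival", ]
  # (0,0,3) vs (0,4,0): the 3-4-5 triangle
  expect_equal(riv$distance, 5 * scale)
  expect_gt(pd$pct_further, 0)
})

test_that("planted pairs sit closer than worst pairs in every quartile", {
  bm <- split_benchmark()
  pd <- suppressWarnings(profile_distance_eval(
    bm$split$pseudo_a, bm$split$pseudo_b, bm$selected, bm$worst))
  qm <- pd$quartile_means
  expect_true(all(qm[, "accepted"] < qm[, "rival"], na.rm = TRUE))
  expect_gt(pd$pct_further, 0)
})

test_that("clustering separates planted types and mixes identical datasets", {
  ea <- two_type_expr(n_cells = 80, seed = 47)
  eb <- ea; eb$species <- "B"
  pairs <- proxy_list(rownames(ea$values), rownames(ea$values))
  ad <- align_gene_spaces(ea, eb, pairs)
  cl <- joint_embed_cluster(ad, n_pcs = 4, seed = 1)
  m <- mixing_metrics(cl, ad$dataset_labels, ad$cell_types)
  expect_gte(length(unique(cl)), 2)
  expect_true(all(m$per_cluster$majority_frac > 0.9))
  expect_true(all(abs(m$per_cluster$frac_a - 0.5) <= 0.15))
  expect_equal(m$fraction_in_mixed_clusters, 1)
  expect_error(joint_embed_cluster(ad, n_pcs = 0), ">= 1")
})

test_that("neighbor voting is high on duplicated data, symmetric, and null under shuffling", {
  ea <- two_type_expr(n_cells = 60, seed = 48)
  eb <- ea; eb$species <- "B"
  ad <- align_gene_spaces(ea, eb, proxy_list(rownames(ea$values),
                                             rownames(ea$values)))
  nv <- neighbor_voting_auroc(ad)
  expect_true(all(diag(nv) >= 0.95))
  expect_true(all(nv[upper.tri(nv)] <= 0.5))
  flip <- ifelse(ad$dataset_labels == "a", "b", "a")
  nv_flip <- neighbor_voting_auroc(ad, dataset_labels = flip)
  expect_equal(nv, nv_flip)
  expect_error(neighbor_voting_auroc(ad, cell_types = rep("t", 120)),
               "2 cell types")
})

test_that("swap trajectories have the promised length and monotone bookkeeping", {
  ea <- two_type_expr(n_cells = 40, seed = 49)
  eb <- two_type_expr(n_cells = 40, seed = 50, species = "B")
  proxies <- proxy_list(paste0("A_g", 1:3), paste0("B_g", 1:3),
                        score = c(0.9, 0.8, 0.7))
  tr <- swap_experiment(ea, eb, proxies, n_random_start = 4, swap_size = 2,
                        seed = 1)
  expect_length(tr$metric, ceiling(3 / 2) + 1)
  expect_identical(tr$n_proxies_in, c(0L, 2L, 3L))
  expect_error(swap_experiment(ea, eb, proxies, 4, swap_size = 0), "swap_size")
})
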