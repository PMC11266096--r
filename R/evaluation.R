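#' Align two gene spaces with a proxy list
#'
#' CPM-normalizes each dataset per cell, then assembles one shared feature
#' per proxy pair: column j holds gene_a_j's CPM for species-A cells and
#' gene_b_j's CPM for species-B cells. Pairs whose gene is missing from its
#' dataset are dropped pairwise with a warning.
#'
#' @param expr_a,expr_b [expression_matrix()]s of the two datasets.
#' @param proxies a [proxy_list()] defining the shared features.
#' @return An object of class `aligned_dataset`: list with `values`
#'   ((cells_a + cells_b) x n_pairs matrix), `dataset_labels` (`"a"`/`"b"`),
#'   `cell_types`, and `pairs` (the proxy rows actually used).
#' @export
align_gene_spaces <- function(expr_a, expr_b, proxies) {
  pr <- as.data.frame(proxies)
  if (!all(c("gene_a", "gene_b") %in% names(pr)))
    cx_input_error("'proxies' needs gene_a and gene_b columns")
  ok <- pr$gene_a %in% gene_ids(expr_a) & pr$gene_b %in% gene_ids(expr_b)
  if (any(!ok))
    warning(sprintf("dropping %d proxy pair(s) with genes missing from the data",
                    sum(!ok)))
  pr <- pr[ok, , drop = FALSE]
  if (!nrow(pr)) cx_input_error("no usable proxy pairs after matching genes")
  ca <- cpm(expr_a); cb <- cpm(expr_b)
  vals <- rbind(t(ca[pr$gene_a, , drop = FALSE]),
                t(cb[pr$gene_b, , drop = FALSE]))
  colnames(vals) <- paste(pr$gene_a, pr$gene_b, sep = "|")
  structure(list(
    values = vals,
    dataset_labels = c(rep("a", ncol(ca)), rep("b", ncol(cb))),
    cell_types = c(if (is.null(expr_a$cell_types)) rep(NA_character_, ncol(ca))
                   else expr_a$cell_types,
                   if (is.null(expr_b$cell_types)) rep(NA_character_, ncol(cb))
                   else expr_b$cell_types),
    pairs = pr), class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset> %d + %d cells x %d shared features\n",
              sum(x$dataset_labels == "a"), sum(x$dataset_labels == "b"),
              ncol(x$values)))
  invisible(x)
}

# k-nearest-neighbour graph (union of directed kNN lists) on rows of m.
knn_graph <- function(m, k) {
  d <- as.matrix(stats::dist(m))
  n <- nrow(d)
  k <- min(k, n - 1)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, -i])[seq_len(k)]
    j <- seq_len(n)[-i][nb]
    cbind(i, j)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Joint embedding and Leiden clustering
#'
#' The baseline self-contained integrator: log1p transform, per-feature
#' standardization, PCA, k-nearest-neighbour graph and a Leiden partition.
#' Defaults follow standard single-cell practice: 50 principal components,
#' 15 neighbours, resolution 0.5. Deterministic given `seed`. External
#' integrators slot in via the same cells-x-features-in, labels-out contract
#' (see `integrate_fn` in [swap_experiment()]).
#'
#' @param ad an `aligned_dataset` (or a plain cells x features matrix).
#' @param n_pcs number of principal components (>= 1).
#' @param n_neighbors neighbours for the kNN graph.
#' @param resolution Leiden resolution (modularity objective).
#' @param seed RNG seed for the Leiden refinement.
#' @return Integer cluster label per cell.
#' @export
joint_embed_cluster <- function(ad, n_pcs = 50, n_neighbors = 15,
                                resolution = 0.5, seed = 0) {
  if (n_pcs < 1) cx_input_error("'n_pcs' must be >= 1")
  m <- if (inherits(ad, "aligned_dataset")) ad$values else ad
  if (nrow(m) < 4) cx_input_error("need at least 4 cells")
  x <- log1p(m)
  sds <- apply(x, 2, stats::sd)
  x <- sweep(x, 2, colMeans(x))
  x[, sds > 0] <- sweep(x[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  rank_max <- min(n_pcs, nrow(x) - 1, ncol(x))
  pcs <- stats::prcomp(x, center = FALSE, rank. = rank_max)$x
  g <- knn_graph(pcs, n_neighbors)
  cl <- with_seed(seed,
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5))
  igraph::membership(cl)
}

#' Cluster-mixing metrics
#'
#' A cluster is *mixed* when each dataset contributes between `mix_low` and
#' `mix_high` of its cells; a cluster is *of cell type t* when more than
#' `type_majority` of its cells carry label t. `fraction_in_mixed_clusters`
#' is the share of all cells lying in mixed clusters;
#' `fraction_celltype_matched` is the share of cells whose cluster is both
#' mixed and of that cell's own type (so matched <= mixed always).
#'
#' @param clusters cluster label per cell.
#' @param dataset_labels dataset of origin per cell (two levels).
#' @param cell_types cell-type label per cell (`NULL` disables type
#'   matching).
#' @param mix_low,mix_high dataset-fraction window defining a mixed cluster.
#' @param type_majority fraction above which a cluster is of one cell type.
#' @return A list of class `mixing_report`: the two headline fractions and a
#'   `per_cluster` data.frame (size, dataset fractions, majority type) they
#'   can be recomputed from.
#' @export
mixing_metrics <- function(clusters, dataset_labels, cell_types = NULL,
                           mix_low = 0.30, mix_high = 0.70,
                           type_majority = 0.60) {
  n <- length(clusters)
  if (length(dataset_labels) != n ||
      (!is.null(cell_types) && length(cell_types) != n))
    cx_input_error("label vectors must have equal length")
  ds <- sort(unique(dataset_labels))
  per <- do.call(rbind, lapply(split(seq_len(n), clusters), function(idx) {
    fr <- vapply(ds, function(d) mean(dataset_labels[idx] == d), 0)
    maj_type <- NA_character_; maj_frac <- NA_real_
    if (!is.null(cell_types)) {
      tt <- table(cell_types[idx])
      maj_frac <- max(tt) / length(idx)
      maj_type <- if (maj_frac > type_majority) names(tt)[which.max(tt)]
                  else NA_character_
    }
    data.frame(size = length(idx),
               frac_a = fr[1], frac_b = if (length(fr) > 1) fr[2] else 0,
               mixed = all(fr >= mix_low & fr <= mix_high),
               majority_type = maj_type, majority_frac = maj_frac,
               stringsAsFactors = FALSE)
  }))
  per$cluster <- rownames(per)
  frac_mixed <- sum(per$size[per$mixed]) / n
  frac_matched <- NA_real_
  if (!is.null(cell_types)) {
    cl_chr <- as.character(clusters)
    row <- match(cl_chr, per$cluster)
    matched <- per$mixed[row] & !is.na(per$majority_type[row]) &
      per$majority_type[row] == cell_types
    frac_matched <- mean(matched)
  }
  structure(list(fraction_in_mixed_clusters = frac_mixed,
                 fraction_celltype_matched = frac_matched,
                 per_cluster = per,
                 mix_low = mix_low, mix_high = mix_high,
                 type_majority = type_majority),
            class = "mixing_report")
}

#' @export
print.mixing_report <- function(x, ...) {
  cat(sprintf(
    "<mixing_report> %.1f%% of cells in mixed clusters; %.1f%% cell-type matched (%d clusters)\n",
    100 * x$fraction_in_mixed_clusters,
    100 * x$fraction_celltype_matched, nrow(x$per_cluster)))
  invisible(x)
}

# Mean CPM per cell type for the listed genes; columns = shared types.
type_profiles_cpm <- function(expr, genes, types) {
  m <- cpm(expr)[genes, , drop = FALSE]
  prof <- matrix(0, nrow(m), length(types),
                 dimnames = list(genes, types))
  for (t in types)
    prof[, t] <- rowMeans(m[, expr$cell_types == t, drop = FALSE])
  prof
}

#' Per-cell-type profile distance of accepted vs rival pairs
#'
#' For each pair, the Euclidean distance between the target gene's
#' per-cell-type mean-CPM profile (in dataset A) and its partner's profile
#' (in dataset B). Pairs are binned by the target gene's overall mean CPM
#' quartile; the summary reports the mean distance per quartile for each
#' list and the overall ratio — how much further rival pairs sit from the
#' target's expression than accepted pairs, as a percentage.
#'
#' @param expr_a,expr_b the two datasets, with cell-type labels.
#' @param target_pairs accepted proxy pairs (targets are `gene_a`).
#' @param rival_pairs rejected/control pairs to compare against.
#' @return A list of class `profile_distance_report`: `per_pair`
#'   (data.frame: list, gene_a, gene_b, distance, quartile),
#'   `quartile_means` (quartile x list matrix), `pct_further`
#'   (100 * (mean rival / mean accepted - 1)).
#' @export
profile_distance_eval <- function(expr_a, expr_b, target_pairs, rival_pairs) {
  if (is.null(expr_a$cell_types) || is.null(expr_b$cell_types))
    cx_input_error("both datasets need cell-type labels")
  shared <- intersect(unique(expr_a$cell_types), unique(expr_b$cell_types))
  only <- c(setdiff(unique(expr_a$cell_types), shared),
            setdiff(unique(expr_b$cell_types), shared))
  if (length(only))
    warning(sprintf("cell type(s) absent from one dataset excluded: %s",
                    paste(only, collapse = ", ")))
  if (!length(shared)) cx_input_error("no shared cell types")
  one_list <- function(pr, label) {
    pr <- as.data.frame(pr)
    ok <- pr$gene_a %in% gene_ids(expr_a) & pr$gene_b %in% gene_ids(expr_b)
    pr <- pr[ok, , drop = FALSE]
    pa <- type_profiles_cpm(expr_a, pr$gene_a, shared)
    pb <- type_profiles_cpm(expr_b, pr$gene_b, shared)
    data.frame(list = label, gene_a = pr$gene_a, gene_b = pr$gene_b,
               distance = sqrt(rowSums((pa - pb)^2)),
               target_mean = rowMeans(cpm(expr_a))[pr$gene_a],
               stringsAsFactors = FALSE)
  }
  per <- rbind(one_list(target_pairs, "accepted"),
               one_list(rival_pairs, "rival"))
  if (!nrow(per)) cx_input_error("no usable pairs in either list")
  breaks <- quantile(unique(per$target_mean), probs = seq(0, 1, 0.25))
  per$quartile <- cut(per$target_mean, breaks = breaks, labels = paste0("Q", 1:4),
                      include.lowest = TRUE)
  qm <- tapply(per$distance, list(per$quartile, per$list), mean)
  acc <- mean(per$distance[per$list == "accepted"])
  riv <- mean(per$distance[per$list == "rival"])
  structure(list(per_pair = per, quartile_means = qm,
                 pct_further = 100 * (riv / acc - 1)),
            class = "profile_distance_report")
}

#' @export
print.profile_distance_report <- function(x, ...) {
  cat(sprintf(
    "<profile_distance_report> rival pairs are on average %.0f%% further from the target's expression\n",
    x$pct_further))
  print(round(x$quartile_means, 2))
  invisible(x)
}

#' Neighbor-voting cell-type replicability
#'
#' A simplified neighbor-voting assessment of how well cell types replicate
#' across the two datasets after alignment. A cell-cell Spearman network on
#' the aligned (log1p) features is rank-standardized; training on dataset X
#' and type t, each dataset-Y cell is scored by its mean network weight to
#' X's type-t cells, and the score's AUROC for recovering Y's type-u cells
#' fills entry (t, u). The two train/test directions are averaged. Diagonal
#' entries are the replicability of each type.
#'
#' @param ad an `aligned_dataset`.
#' @param cell_types,dataset_labels overrides for the labels carried by `ad`.
#' @return A types x types numeric matrix of AUROCs (`NA` rows/columns for
#'   types absent from one dataset).
#' @export
neighbor_voting_auroc <- function(ad, cell_types = ad$cell_types,
                                  dataset_labels = ad$dataset_labels) {
  types <- sort(unique(cell_types))
  if (length(types) < 2) cx_input_error("need at least 2 cell types")
  x <- log1p(t(ad$values))                 # features x cells
  w <- cor(x, method = "spearman")
  w <- rank_standardize(w)
  score_dir <- function(train_ds, test_ds) {
    tr <- dataset_labels == train_ds
    te <- dataset_labels == test_ds
    out <- matrix(NA_real_, length(types), length(types),
                  dimnames = list(types, types))
    for (t in types) {
      pos_tr <- tr & cell_types == t
      if (!any(pos_tr)) next
      votes <- rowMeans(w[te, pos_tr, drop = FALSE])
      names(votes) <- which(te)
      for (u in types) {
        pos_te <- cell_types[te] == u
        if (!any(pos_te) || all(pos_te)) next
        out[t, u] <- auroc_from_scores(votes, names(votes)[pos_te])
      }
    }
    out
  }
  ab <- score_dir("a", "b"); ba <- score_dir("b", "a")
  (ab + ba) / 2
}

#' Random-to-proxy swap experiment
#'
#' Starts from `n_random_start` random gene pairs and iteratively replaces
#' `swap_size` of them with coexpression proxies (best-scoring first),
#' re-running the integration and metric after each swap — tracking how much
#' integration quality the proxies contribute over the pluggable
#' integrator's own flexibility.
#'
#' @param expr_a,expr_b the two datasets.
#' @param proxies a [proxy_list()] to swap in.
#' @param n_random_start size of the initial random pair set.
#' @param swap_size pairs replaced per iteration (>= 1).
#' @param integrate_fn `function(ad, seed)` returning a cluster label per
#'   cell; default [joint_embed_cluster()].
#' @param metric_fn `function(clusters, ad)` returning a scalar; default
#'   `fraction_in_mixed_clusters` from [mixing_metrics()].
#' @param seed integer seed.
#' @return A list of class `swap_trajectory`: `n_proxies_in` and `metric`
#'   vectors, one entry per run (first entry = all-random baseline).
#' @export
swap_experiment <- function(expr_a, expr_b, proxies, n_random_start,
                            swap_size = 7, integrate_fn = NULL,
                            metric_fn = NULL, seed = 0) {
  if (swap_size < 1) cx_input_error("'swap_size' must be >= 1")
  if (is.null(integrate_fn))
    integrate_fn <- function(ad, seed) joint_embed_cluster(ad, seed = seed)
  if (is.null(metric_fn))
    metric_fn <- function(clusters, ad)
      mixing_metrics(clusters, ad$dataset_labels,
                     ad$cell_types)$fraction_in_mixed_clusters
  pr <- as.data.frame(proxies)
  pr <- pr[order(-ifelse(is.na(pr$score), 0, pr$score)), , drop = FALSE]
  n_use <- min(nrow(pr), n_random_start)
  rand <- as.data.frame(random_pairs(gene_ids(expr_a), gene_ids(expr_b),
                                     n_random_start, sub_seed(seed, 1)))
  current <- rand
  # the evolving pair set mixes random and proxy rows, so a gene may
  # transiently back two features; alignment takes the plain data.frame
  run_once <- function(cur, i) {
    suppressWarnings({
      ad <- align_gene_spaces(expr_a, expr_b, cur)
      metric_fn(integrate_fn(ad, seed = sub_seed(seed, 100 + i)), ad)
    })
  }
  metric <- run_once(current, 0)
  n_in <- 0L
  step <- 0L
  while (n_in < n_use) {
    step <- step + 1L
    add <- seq_len(min(swap_size, n_use - n_in)) + n_in
    # replace the first remaining random rows with the next proxies
    repl <- which(is.na(current$group_id))[seq_along(add)]
    current[repl, ] <- pr[add, c("gene_a", "gene_b", "group_id", "score", "class")]
    n_in <- n_in + length(add)
    metric <- c(metric, run_once(current, step))
  }
  structure(list(n_proxies_in = c(0L, as.integer(pmin(seq_len(step) * swap_size, n_use))),
                 metric = metric), class = "swap_trajectory")
}

#' @export
print.swap_trajectory <- function(x, ...) {
  cat(sprintf("<swap_trajectory> %d runs, metric %0.3f -> %0.3f\n",
              length(x$metric), x$metric[1], x$metric[length(x$metric)]))
  invisible(x)
}
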