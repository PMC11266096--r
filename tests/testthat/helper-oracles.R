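# Independent brute-force oracles used to pin expected values.

# Average-tie ranks computed by explicit run-length walking (no rank()).
avg_rank <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1L
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1L]] == v[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# O(n^2) AUROC: fraction of (positive, negative) pairs won, ties 1/2.
oracle_auroc <- function(scores, positives) {
  pos <- scores[names(scores) %in% positives]
  neg <- scores[!names(scores) %in% positives]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Full brute-force network pipeline: per-gene average-tie ranks, Pearson on
# the ranks (the definition of Spearman), then joint off-diagonal
# rank-standardization by explicit sorting.
oracle_rank_standardize <- function(m) {
  ut <- upper.tri(m)
  r <- avg_rank(m[ut]) / sum(ut)
  out <- m
  out[ut] <- r
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 1
  out
}

oracle_network <- function(values) {
  ranks <- t(apply(values, 1, avg_rank))
  cc <- matrix(0, nrow(values), nrow(values),
               dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(nrow(values))) for (j in seq_len(nrow(values))) {
    x <- ranks[i, ]; y <- ranks[j, ]
    cc[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  oracle_rank_standardize(cc)
}

# Literal re-check of the selection rules for one family: quality filter,
# reciprocal best hit among survivors, margin over the best competing
# defined option on both sides.
oracle_select_family <- function(df, preset, n_a, n_b) {
  df <- df[!is.na(df$score), , drop = FALSE]
  if (n_a == 1 && n_b == 1)
    return(df[df$score >= preset$single_pair_junk, , drop = FALSE])
  surv <- df[df$score >= preset$quality, , drop = FALSE]
  keep <- logical(nrow(surv))
  for (i in seq_len(nrow(surv))) {
    a <- surv$gene_a[i]; b <- surv$gene_b[i]; s <- surv$score[i]
    surv_a <- surv[surv$gene_a == a & surv$gene_b != b, ]
    surv_b <- surv[surv$gene_b == b & surv$gene_a != a, ]
    rbh <- all(s >= surv_a$score) && all(s >= surv_b$score)
    comp_a <- df[df$gene_a == a & df$gene_b != b, ]
    comp_b <- df[df$gene_b == b & df$gene_a != a, ]
    marg <- (nrow(comp_a) == 0 ||
               s - max(comp_a$score) >= preset$multi_pair_margin) &&
            (nrow(comp_b) == 0 ||
               s - max(comp_b$score) >= preset$multi_pair_margin)
    keep[i] <- rbh && marg
  }
  surv[keep, , drop = FALSE]
}

# Score-table / orthology fixtures shared across selection tests.
scores_df <- function(gene_a, gene_b, score, group = "og1") {
  structure(data.frame(gene_a = gene_a, gene_b = gene_b, group_id = group,
                       score = score, stringsAsFactors = FALSE),
            class = c("conservation_scores", "data.frame"))
}

orth_from_pairs <- function(df) {
  tab <- rbind(data.frame(group_id = df$group_id, species_id = "A",
                          gene_id = df$gene_a),
               data.frame(group_id = df$group_id, species_id = "B",
                          gene_id = df$gene_b))
  orthology_map(unique(tab), species = c("A", "B"))
}

# Random symmetric toy network with weights in (0, 1].
random_toy_network <- function(genes) {
  n <- length(genes)
  w <- matrix(runif(n * n, min = 1e-6), n, n, dimnames = list(genes, genes))
  w <- (w + t(w)) / 2
  diag(w) <- 1
  coex_network(w)
}

# Small expression fixture with named genes/samples.
random_expr <- function(n_genes, n_samples, species = "A") {
  m <- matrix(rpois(n_genes * n_samples, lambda = 8) +
                runif(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, species = species)
}

pair_key <- function(pl) paste(pl$gene_a, pl$gene_b)
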