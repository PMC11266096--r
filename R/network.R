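#' Construct a coexpression network
#'
#' A symmetric genes x genes matrix of rank-standardized similarities:
#' off-diagonal entries are the average-tie ranks of the underlying
#' correlations over all unordered gene pairs, divided by the number of
#' pairs, so values lie in (0, 1] and the strongest pair scores 1 (ties at
#' the top permitting). The diagonal is fixed at 1.
#'
#' @param weights symmetric numeric matrix with identical row/column gene
#'   names.
#' @param n_datasets number of datasets aggregated into this network.
#' @return An object of class `coex_network`.
#' @export
coex_network <- function(weights, n_datasets = 1L) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    cx_input_error("'weights' must be a square matrix")
  if (is.null(rownames(weights)) ||
      !identical(rownames(weights), colnames(weights)))
    cx_input_error("'weights' needs identical gene row/column names")
  if (anyDuplicated(rownames(weights)))
    cx_input_error("duplicate gene IDs in network")
  if (max(abs(weights - t(weights))) > 1e-12)
    cx_input_error("'weights' must be symmetric")
  od <- weights[upper.tri(weights)]
  if (length(od) && (min(od) <= 0 || max(od) > 1))
    cx_input_error("off-diagonal weights must lie in (0, 1]")
  diag(weights) <- 1
  structure(list(weights = weights, n_datasets = as.integer(n_datasets)),
            class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf("<coex_network> %d genes, %d dataset(s) aggregated\n",
              nrow(x$weights), x$n_datasets))
  invisible(x)
}

network_genes <- function(net) rownames(net$weights)

# Joint rank standardization of a symmetric matrix: rank the unordered-pair
# (upper-triangle) values once with average ties, divide by the number of
# pairs, mirror to both triangles, diagonal = 1. Ranking the unordered set
# once guarantees symmetry even under ties.
rank_standardize <- function(m) {
  ut <- upper.tri(m)
  v <- m[ut]
  r <- rank(v, ties.method = "average") / length(v)
  out <- m
  out[ut] <- r
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 1
  out
}

#' Build a rank-standardized coexpression network
#'
#' Computes gene-gene Spearman correlations across samples, then jointly
#' rank-standardizes the off-diagonal entries (average ties, divided by the
#' maximum rank) so networks from different datasets are on a common (0, 1]
#' scale. Genes expressed in fewer than `min_expressing_samples` samples, and
#' genes with zero variance (Spearman undefined), are dropped with a warning
#' and recorded in the `dropped` attribute.
#'
#' @param expr a [expression_matrix()] with at least 3 samples.
#' @param min_expressing_samples minimum number of samples with a non-zero
#'   value for a gene to be kept. Default 1 suits bulk data; raise it for
#'   sparse single-cell counts.
#' @param method `"spearman"` (default, robust for counts) or `"pearson"`.
#' @return A [coex_network()] with attribute `dropped` listing removed genes.
#' @export
build_rank_network <- function(expr, min_expressing_samples = 1L,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- expr$values
  if (ncol(v) < 3) cx_input_error("need at least 3 samples to build a network")
  expressed <- rowSums(v > 0) >= min_expressing_samples
  dropped_expr <- rownames(v)[!expressed]
  v <- v[expressed, , drop = FALSE]
  constant <- apply(v, 1, function(x) length(unique(x)) == 1L)
  if (any(constant))
    warning(sprintf("dropping %d zero-variance gene(s): %s",
                    sum(constant),
                    paste(head(rownames(v)[constant], 5), collapse = ", ")))
  dropped_var <- rownames(v)[constant]
  v <- v[!constant, , drop = FALSE]
  if (nrow(v) == 0) cx_input_error("no genes retained after filtering")
  cc <- cor(t(v), method = method)
  stopifnot(!anyNA(cc))
  net <- coex_network(rank_standardize(cc), n_datasets = 1L)
  attr(net, "dropped") <- list(low_expression = dropped_expr,
                               zero_variance = dropped_var)
  net
}

#' Aggregate coexpression networks
#'
#' Element-wise mean of rank-standardized weights over networks on the same
#' gene set (aligned by gene ID), re-rank-standardized so the result again
#' satisfies the network invariants. Aggregation sharpens consistently
#' supported edges across datasets.
#'
#' @param networks list of [coex_network()] objects on identical gene sets
#'   (order may differ).
#' @return A [coex_network()] with `n_datasets` equal to the inputs' sum.
#' @export
aggregate_networks <- function(networks) {
  if (!length(networks)) cx_input_error("need at least one network")
  ref <- sort(network_genes(networks[[1]]))
  for (net in networks) {
    g <- sort(network_genes(net))
    if (!identical(g, ref)) {
      diff <- c(setdiff(ref, g), setdiff(g, ref))
      cx_input_error(sprintf("gene sets differ; symmetric difference: %s",
                             paste(head(diff, 10), collapse = ", ")))
    }
  }
  acc <- Reduce(`+`, lapply(networks, function(net) net$weights[ref, ref]))
  mean_w <- acc / length(networks)
  coex_network(rank_standardize(mean_w),
               n_datasets = sum(vapply(networks, function(n) n$n_datasets, 1L)))
}

#' Restrict a network to a gene subset
#'
#' Subsets the weight matrix and re-rank-standardizes it so the restricted
#' network again satisfies the (0, 1] joint-rank invariants. Used by the
#' pseudo-species split harness to carry a full-genome network onto each
#' genome half.
#'
#' @param net a [coex_network()].
#' @param genes gene IDs to keep (must be present; at least 2).
#' @return A [coex_network()] on `genes`.
#' @export
subset_network <- function(net, genes) {
  missing <- setdiff(genes, network_genes(net))
  if (length(missing))
    cx_input_error(sprintf("genes absent from network: %s",
                           paste(head(missing, 5), collapse = ", ")))
  if (length(genes) < 2) cx_input_error("need at least 2 genes")
  coex_network(rank_standardize(net$weights[genes, genes]),
               n_datasets = net$n_datasets)
}

#' Top coexpression partners of a gene
#'
#' The `k` eligible genes with the highest edge weight to `gene`, strongest
#' first. The gene itself is never a candidate. Ties are broken
#' lexicographically by gene ID, so the result is deterministic and
#' seed-free.
#'
#' @param net a [coex_network()].
#' @param gene query gene ID (must be in the network).
#' @param k number of partners (`k >= 1`); if fewer eligible genes exist,
#'   all are returned.
#' @param eligible candidate gene IDs (default: all network genes).
#' @return Character vector of at most `k` gene IDs.
#' @export
top_partners <- function(net, gene, k, eligible = NULL) {
  if (k < 1) cx_input_error("'k' must be >= 1")
  g <- network_genes(net)
  if (!gene %in% g) cx_input_error(sprintf("gene '%s' absent from network", gene))
  if (is.null(eligible)) eligible <- g
  cand <- setdiff(intersect(eligible, g), gene)
  if (!length(cand)) return(character())
  w <- net$weights[gene, cand]
  cand[order(-w, cand)][seq_len(min(k, length(cand)))]
}

#' Write a network as a dense TSV
#' @param net a [coex_network()].
#' @param path output path; header row and first column hold gene IDs.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  df <- data.frame(gene_id = network_genes(net),
                   formatC(net$weights, format = "g", digits = 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", network_genes(net))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path dense TSV path.
#' @param n_datasets aggregation count to attach (not stored in the TSV).
#' @return A [coex_network()].
#' @export
read_network <- function(path, n_datasets = 1L) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  coex_network(m, n_datasets = n_datasets)
}
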