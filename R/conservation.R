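#' AUROC from a score vector
#'
#' Probability that a uniformly chosen positive outscores a uniformly chosen
#' negative, with ties counting 1/2 (the Mann-Whitney midrank convention).
#' Computed from rank sums; equivalent to exhaustive concordant-pair
#' counting.
#'
#' @param candidate_scores named numeric vector: one score per candidate
#'   gene.
#' @param positives character vector of positive gene IDs; must be a
#'   non-empty strict subset of the candidates.
#' @return A number in \[0, 1\].
#' @export
auroc_from_scores <- function(candidate_scores, positives) {
  genes <- names(candidate_scores)
  if (is.null(genes)) cx_input_error("'candidate_scores' must be named by gene")
  if (!length(positives)) cx_input_error("no positives")
  if (!all(positives %in% genes))
    cx_input_error("positives must be a subset of the candidates")
  n_pos <- length(positives)
  n_neg <- length(genes) - n_pos
  if (n_neg == 0) cx_input_error("no negatives: positives equal the candidate set")
  r <- rank(candidate_scores, ties.method = "average")
  (sum(r[genes %in% positives]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# One direction of the conservation score. Returns NA_real_ (undefined) when
# fewer than min_positives source partners map through the anchor; errors
# only on genes absent from their networks.
directional_conservation_map <- function(net_src, net_dst, gene_src, gene_dst,
                                         map_src_to_dst, k = 10,
                                         min_positives = 3) {
  if (!gene_src %in% network_genes(net_src))
    cx_input_error(sprintf("gene '%s' absent from source network", gene_src))
  if (!gene_dst %in% network_genes(net_dst))
    cx_input_error(sprintf("gene '%s' absent from destination network", gene_dst))
  src_anchor <- names(map_src_to_dst)
  # the query genes never serve as their own evidence: drop gene_src and the
  # anchor pre-image of gene_dst from the eligible set, so the destination
  # candidate universe (the anchor image of the eligible set) excludes
  # gene_dst and the two directions stay exactly symmetric
  eligible <- setdiff(src_anchor, c(gene_src, src_anchor[map_src_to_dst == gene_dst]))
  eligible <- intersect(eligible, network_genes(net_src))
  partners <- top_partners(net_src, gene_src, k, eligible)
  positives <- unname(map_src_to_dst[partners])
  candidates <- unname(map_src_to_dst[eligible])
  keep <- candidates %in% network_genes(net_dst)
  candidates <- candidates[keep]
  positives <- intersect(positives, candidates)
  if (length(positives) < min_positives ||
      length(candidates) - length(positives) < 1)
    return(c(auroc = NA_real_, n_pos = length(positives)))
  scores <- net_dst$weights[gene_dst, candidates]
  names(scores) <- candidates
  c(auroc = auroc_from_scores(scores, positives), n_pos = length(positives))
}

#' Directional conservation of coexpression
#'
#' Takes `gene_src`'s top-`k` coexpression partners among the anchored
#' (one-to-one orthologue) genes of the source species, maps them through the
#' anchor into the destination species, and asks how highly `gene_dst`'s
#' coexpression ranks place those mapped partners among all anchor-image
#' genes — an AUROC. Undefined (`NA`) rather than an error when fewer than
#' `min_positives` partners map.
#'
#' @param net_src,net_dst source and destination [coex_network()]s.
#' @param gene_src,gene_dst the gene pair being scored.
#' @param anchor named character vector mapping source genes to destination
#'   genes (see [one_to_one_anchor()]).
#' @param k number of top partners to use (default 10).
#' @param min_positives minimum mapped partners for a defined score.
#' @return A number in \[0, 1\], or `NA` if undefined.
#' @export
directional_conservation <- function(net_src, net_dst, gene_src, gene_dst,
                                     anchor, k = 10, min_positives = 3) {
  unname(directional_conservation_map(net_src, net_dst, gene_src, gene_dst,
                                      anchor, k, min_positives)[["auroc"]])
}

#' Conservation-of-coexpression score for a cross-species gene pair
#'
#' Mean of the two directional AUROCs (A predicting B's partners and B
#' predicting A's); undefined if either direction is undefined. Invariant
#' under swapping the species arguments.
#'
#' @inheritParams directional_conservation
#' @param net_a,net_b the two species' networks.
#' @param gene_a,gene_b the candidate pair.
#' @param anchor named character vector mapping species-A genes to species-B
#'   genes.
#' @return A list: `score` (number or `NA`), `n_pos_ab`, `n_pos_ba` (mapped
#'   partner counts actually used in each direction).
#' @export
conservation_score <- function(net_a, net_b, gene_a, gene_b, anchor,
                               k = 10, min_positives = 3) {
  rev_anchor <- stats::setNames(names(anchor), unname(anchor))
  ab <- directional_conservation_map(net_a, net_b, gene_a, gene_b, anchor,
                                     k, min_positives)
  ba <- directional_conservation_map(net_b, net_a, gene_b, gene_a, rev_anchor,
                                     k, min_positives)
  score <- if (is.na(ab[["auroc"]]) || is.na(ba[["auroc"]])) NA_real_
           else (ab[["auroc"]] + ba[["auroc"]]) / 2
  list(score = score, auroc_ab = unname(ab[["auroc"]]),
       auroc_ba = unname(ba[["auroc"]]),
       n_pos_ab = unname(ab[["n_pos"]]), n_pos_ba = unname(ba[["n_pos"]]))
}

#' Conservation score matrix between two species
#'
#' Scores candidate cross-species gene pairs with [conservation_score()],
#' anchored on the one-to-one orthologues of `orthology`. With
#' `scope = "within_families"` (default) candidates are all cross-species
#' pairs inside each orthogroup — the only pairs proxy selection ever
#' consults; `scope = "all_pairs"` scores every gene of A against every gene
#' of B (exploratory; quadratic cost).
#'
#' @param net_a,net_b the two species' [coex_network()]s.
#' @param orthology an [orthology_map()] covering both species.
#' @param scope `"within_families"` or `"all_pairs"`.
#' @param k top-partner count (default 10).
#' @param min_positives minimum mapped partners per direction (default 3).
#' @param species_a,species_b species IDs in `orthology` (defaults: its
#'   first two).
#' @return A data.frame of class `conservation_scores` with columns
#'   `gene_a`, `gene_b`, `group_id`, `score`, `n_pos_ab`, `n_pos_ba`
#'   (defined pairs only). Attributes: `k`, `min_positives`, `anchor`, and
#'   `n_undefined` (candidate pairs whose score was undefined).
#' @export
conservation_matrix <- function(net_a, net_b, orthology,
                                scope = c("within_families", "all_pairs"),
                                k = 10, min_positives = 3,
                                species_a = NULL, species_b = NULL) {
  scope <- match.arg(scope)
  anchor <- one_to_one_anchor(orthology, net_a, net_b, species_a, species_b)
  if (!length(anchor)) cx_input_error("no usable one-to-one anchors")
  if (length(anchor) < k + min_positives)
    cx_input_error(sprintf(
      "only %d one-to-one anchors; need at least k + min_positives = %d (reduce k or add anchors)",
      length(anchor), k + min_positives))
  ga <- network_genes(net_a); gb <- network_genes(net_b)
  if (scope == "within_families") {
    fam <- Filter(function(f) f$usable, families(orthology, species_a, species_b))
    cand <- do.call(rbind, lapply(fam, function(f) {
      a <- intersect(f$a, ga); b <- intersect(f$b, gb)
      if (!length(a) || !length(b)) return(NULL)
      grid <- expand.grid(gene_a = a, gene_b = b, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      grid$group_id <- f$group_id
      grid
    }))
  } else {
    cand <- expand.grid(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    cand$group_id <- NA_character_
  }
  if (is.null(cand) || !nrow(cand)) cx_input_error("no candidate pairs in scope")
  rownames(cand) <- NULL
  res <- mapply(function(a, b) {
    s <- conservation_score(net_a, net_b, a, b, anchor, k, min_positives)
    c(s$score, s$n_pos_ab, s$n_pos_ba)
  }, cand$gene_a, cand$gene_b)
  cand$score <- res[1, ]
  cand$n_pos_ab <- as.integer(res[2, ])
  cand$n_pos_ba <- as.integer(res[3, ])
  n_undef <- sum(is.na(cand$score))
  out <- cand[!is.na(cand$score), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = k, min_positives = min_positives, anchor = anchor,
            n_undefined = n_undef,
            class = c("conservation_scores", "data.frame"))
}

#' @export
print.conservation_scores <- function(x, ...) {
  cat(sprintf(
    "<conservation_scores> %d scored pairs (k = %d, min_positives = %d, %d undefined)\n",
    nrow(x), attr(x, "k"), attr(x, "min_positives"), attr(x, "n_undefined")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' Write / read a conservation score table
#' @param scores a `conservation_scores` data.frame.
#' @param path TSV path.
#' @return `path` (writer) or the reconstructed table (reader).
#' @export
write_conservation <- function(scores, path) {
  df <- as.data.frame(scores)
  df$score <- formatC(df$score, format = "g", digits = 15)
  hdr <- sprintf("# k=%d min_positives=%d", attr(scores, "k"),
                 attr(scores, "min_positives"))
  writeLines(hdr, path)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}

#' @rdname write_conservation
#' @export
read_conservation <- function(path) {
  first <- readLines(path, n = 1L)
  k <- 10L; mp <- 3L
  if (grepl("^# k=", first)) {
    k <- as.integer(sub("^# k=(\\d+).*", "\\1", first))
    mp <- as.integer(sub(".*min_positives=(\\d+).*", "\\1", first))
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  structure(df, k = k, min_positives = mp, n_undefined = NA_integer_,
            class = c("conservation_scores", "data.frame"))
}
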