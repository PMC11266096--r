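#' Threshold presets for proxy selection
#'
#' Each preset is a triple: `quality` (minimum conservation AUROC for a pair
#' in a multi-gene family), `multi_pair_margin` (how much a pair must exceed
#' its best competing option, on both sides), and `single_pair_junk` (the
#' lower bar applied to one-to-one families). The three named presets are
#' moderate (0.85, 0.03, 0.80), lenient (0.80, 0.02, 0.70) and stringent
#' (0.90, 0.035, 0.85); the moderate triple sits at the elbow of the
#' proxy-count curve and the others bracket it.
#'
#' @param name `"moderate"`, `"lenient"`, `"stringent"`, or `"custom"`.
#' @param quality,multi_pair_margin,single_pair_junk numeric thresholds,
#'   required (and only allowed) for `name = "custom"`. Must satisfy
#'   `0 <= single_pair_junk <= quality <= 1` and `multi_pair_margin >= 0`.
#' @return A list of class `threshold_preset`.
#' @export
threshold_preset <- function(name = c("moderate", "lenient", "stringent", "custom"),
                             quality = NULL, multi_pair_margin = NULL,
                             single_pair_junk = NULL) {
  name <- match.arg(name)
  fixed <- list(
    moderate  = c(0.85, 0.030, 0.80),
    lenient   = c(0.80, 0.020, 0.70),
    stringent = c(0.90, 0.035, 0.85))
  if (name != "custom") {
    if (!is.null(quality) || !is.null(multi_pair_margin) || !is.null(single_pair_junk))
      cx_input_error("named presets are immutable; use name = 'custom' to override")
    v <- fixed[[name]]
    quality <- v[1]; multi_pair_margin <- v[2]; single_pair_junk <- v[3]
  } else {
    if (is.null(quality) || is.null(multi_pair_margin) || is.null(single_pair_junk))
      cx_input_error("custom preset needs quality, multi_pair_margin and single_pair_junk")
  }
  if (!(single_pair_junk >= 0 && single_pair_junk <= quality && quality <= 1))
    cx_input_error("need 0 <= single_pair_junk <= quality <= 1")
  if (multi_pair_margin < 0) cx_input_error("multi_pair_margin must be >= 0")
  structure(list(name = name, quality = quality,
                 multi_pair_margin = multi_pair_margin,
                 single_pair_junk = single_pair_junk),
            class = "threshold_preset")
}

#' @export
print.threshold_preset <- function(x, ...) {
  cat(sprintf("<threshold_preset> %s: quality %g, margin %g, single-pair %g\n",
              x$name, x$quality, x$multi_pair_margin, x$single_pair_junk))
  invisible(x)
}

# Selection rule for one multi-gene family. df: gene_a, gene_b, score
# (defined scores only). The margin is measured against the best competing
# *defined* option by default ("all_candidates"), which makes stricter
# presets select subsets of looser ones; "surviving" restricts competitors
# to quality-passing pairs (strictly weaker nesting guarantees).
select_family_multi <- function(df, quality, margin,
                                margin_scope = "all_candidates") {
  surv <- df[df$score >= quality, , drop = FALSE]
  if (!nrow(surv)) return(surv)
  pool <- if (margin_scope == "surviving") surv else df
  keep <- logical(nrow(surv))
  for (i in seq_len(nrow(surv))) {
    a <- surv$gene_a[i]; b <- surv$gene_b[i]; s <- surv$score[i]
    sa <- surv$score[surv$gene_a == a]
    sb <- surv$score[surv$gene_b == b]
    if (s < max(sa) || s < max(sb)) next          # not a reciprocal best hit
    comp_a <- pool$score[pool$gene_a == a & pool$gene_b != b]
    comp_b <- pool$score[pool$gene_b == b & pool$gene_a != a]
    ok_a <- !length(comp_a) || s - max(comp_a) >= margin
    ok_b <- !length(comp_b) || s - max(comp_b) >= margin
    keep[i] <- ok_a && ok_b
  }
  out <- surv[keep, , drop = FALSE]
  # with margin = 0 exact ties can pass on both sides; resolve
  # deterministically, best score first, lexicographic gene IDs on ties
  out <- out[order(-out$score, out$gene_a, out$gene_b), , drop = FALSE]
  used_a <- character(); used_b <- character(); take <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (out$gene_a[i] %in% used_a || out$gene_b[i] %in% used_b) next
    take[i] <- TRUE
    used_a <- c(used_a, out$gene_a[i]); used_b <- c(used_b, out$gene_b[i])
  }
  out[take, , drop = FALSE]
}

#' Select coexpression proxies
#'
#' Trims each orthogroup to one-to-one gene pairs. One-to-one (1x1) families
#' keep their pair iff its conservation score reaches `single_pair_junk`
#' (class `one_to_one`). In multi-gene families (any family with more than
#' one gene on either side), pairs below `quality` are discarded; a surviving
#' pair is kept iff it is a reciprocal best hit among survivors and its score
#' exceeds each gene's best competing option by at least `multi_pair_margin`
#' on both sides (a side with no competitor passes vacuously); class
#' `proxy`. With the default `margin_scope = "all_candidates"` the margin is
#' measured against every defined competitor, which guarantees that stricter
#' presets select subsets of looser ones; `"surviving"` measures it only
#' against quality-passing competitors (a strictly weaker filter offered for
#' sensitivity analysis). Pairs with undefined conservation scores are
#' non-candidates: they neither pass quality nor compete in margins.
#'
#' @param scores a `conservation_scores` table (see [conservation_matrix()]).
#' @param orthology the [orthology_map()] the scores were computed from.
#' @param preset a [threshold_preset()] (or a preset name).
#' @param margin_scope `"all_candidates"` (default) or `"surviving"`.
#' @param species_a,species_b species IDs in `orthology`.
#' @return A [proxy_list()]; no gene appears in two pairs.
#' @export
select_proxies <- function(scores, orthology, preset = "moderate",
                           margin_scope = c("all_candidates", "surviving"),
                           species_a = NULL, species_b = NULL) {
  margin_scope <- match.arg(margin_scope)
  if (is.character(preset)) preset <- threshold_preset(preset)
  if (!inherits(preset, "threshold_preset"))
    cx_input_error("'preset' must be a threshold_preset or preset name")
  fam <- Filter(function(f) f$usable, families(orthology, species_a, species_b))
  sc <- as.data.frame(scores)
  sc <- sc[!is.na(sc$score), , drop = FALSE]
  picked <- lapply(fam, function(f) {
    df <- sc[sc$group_id == f$group_id, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    if (length(f$a) == 1 && length(f$b) == 1) {
      df <- df[df$score >= preset$single_pair_junk, , drop = FALSE]
      if (!nrow(df)) return(NULL)
      df$class <- "one_to_one"
      return(df[, c("gene_a", "gene_b", "group_id", "score", "class")])
    }
    df <- select_family_multi(df, preset$quality, preset$multi_pair_margin,
                              margin_scope)
    if (!nrow(df)) return(NULL)
    df$class <- "proxy"
    df[, c("gene_a", "gene_b", "group_id", "score", "class")]
  })
  out <- do.call(rbind, picked)
  if (is.null(out)) return(proxy_list())
  proxy_list(out$gene_a, out$gene_b, out$group_id, out$score, out$class)
}

#' Worst-proxy control selection
#'
#' For each family, greedily emits the lowest-scoring defined pair(s) such
#' that no gene is used twice — the control that asks how much of proxy
#' performance comes from orthology alone rather than conserved coexpression.
#' No thresholds are applied.
#'
#' @inheritParams select_proxies
#' @return A [proxy_list()] with class `"proxy"` throughout.
#' @export
select_worst_proxies <- function(scores, orthology,
                                 species_a = NULL, species_b = NULL) {
  fam <- Filter(function(f) f$usable, families(orthology, species_a, species_b))
  sc <- as.data.frame(scores)
  sc <- sc[!is.na(sc$score), , drop = FALSE]
  picked <- lapply(fam, function(f) {
    df <- sc[sc$group_id == f$group_id, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    df <- df[order(df$score, df$gene_a, df$gene_b), , drop = FALSE]
    used_a <- character(); used_b <- character(); take <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$gene_a[i] %in% used_a || df$gene_b[i] %in% used_b) next
      take[i] <- TRUE
      used_a <- c(used_a, df$gene_a[i]); used_b <- c(used_b, df$gene_b[i])
    }
    df <- df[take, , drop = FALSE]
    df$class <- "proxy"
    df[, c("gene_a", "gene_b", "group_id", "score", "class")]
  })
  out <- do.call(rbind, picked)
  if (is.null(out)) return(proxy_list())
  proxy_list(out$gene_a, out$gene_b, out$group_id, out$score, out$class)
}

#' Random gene-pair control
#'
#' Samples `n` cross-species pairs uniformly without replacement on both
#' sides — the negative control for integration experiments.
#'
#' @param genes_a,genes_b gene ID pools for each species.
#' @param n number of pairs; must not exceed either pool.
#' @param seed integer seed; the same seed reproduces the same pairs and the
#'   caller's RNG state is left untouched.
#' @return A [proxy_list()] with `NA` group and score.
#' @export
random_pairs <- function(genes_a, genes_b, n, seed) {
  if (n > min(length(genes_a), length(genes_b)))
    cx_input_error(sprintf("n = %d exceeds the smaller gene pool (%d)",
                           n, min(length(genes_a), length(genes_b))))
  with_seed(seed, {
    a <- sample(genes_a, n)
    b <- sample(genes_b, n)
    proxy_list(a, b, NA_character_, NA_real_, "proxy")
  })
}
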