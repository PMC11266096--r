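#' Construct a proxy list
#'
#' The end product of proxy selection: one-to-one cross-species gene pairs
#' usable as shared features for integration. Each gene may appear in at most
#' one pair; scores are conservation-of-coexpression AUROCs in \[0, 1\].
#' `class` records whether a pair came from a true one-to-one orthogroup
#' (`"one_to_one"`) or was trimmed out of a multi-gene family (`"proxy"`).
#'
#' @param gene_a,gene_b character vectors of paired gene IDs.
#' @param group_id orthogroup of each pair (`NA` allowed for random pairs).
#' @param score numeric in \[0, 1\] (`NA` allowed for control selections).
#' @param class `"one_to_one"` or `"proxy"` per pair.
#' @return A data.frame of class `proxy_list`.
#' @export
proxy_list <- function(gene_a = character(), gene_b = character(),
                       group_id = NA_character_, score = NA_real_,
                       class = "proxy") {
  n <- length(gene_a)
  if (length(gene_b) != n) cx_input_error("gene_a and gene_b lengths differ")
  df <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   group_id = rep_len(as.character(group_id), n),
                   score = rep_len(as.numeric(score), n),
                   class = rep_len(as.character(class), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_a) || anyDuplicated(df$gene_b))
    cx_input_error("a gene appears in more than one proxy pair")
  bad <- which(!is.na(df$score) & (df$score < 0 | df$score > 1))
  if (length(bad))
    cx_input_error(sprintf("score %g for pair (%s, %s) is outside [0, 1]",
                           df$score[bad[1]], df$gene_a[bad[1]], df$gene_b[bad[1]]))
  if (!all(df$class %in% c("one_to_one", "proxy")))
    cx_input_error("class must be 'one_to_one' or 'proxy'")
  structure(df, class = c("proxy_list", "data.frame"))
}

#' @export
print.proxy_list <- function(x, ...) {
  cat(sprintf("<proxy_list> %d pairs (%d one_to_one, %d proxy)\n",
              nrow(x), sum(x$class == "one_to_one"), sum(x$class == "proxy")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' Write a proxy list
#'
#' TSV with header `gene_a, gene_b, group_id, score, class`. Scores are
#' serialized with 6 significant digits (AUROCs carry no more meaningful
#' precision); [read_proxy_list()] then inverts the writer exactly.
#'
#' @param proxies a `proxy_list`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_proxy_list <- function(proxies, path) {
  df <- as.data.frame(proxies)
  df$score <- ifelse(is.na(df$score), "NA", formatC(df$score, format = "g", digits = 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proxy list
#' @param path a TSV written by [write_proxy_list()].
#' @return A `proxy_list`. Scores outside \[0, 1\] are a hard error.
#' @export
read_proxy_list <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "numeric", "character"))
  proxy_list(df$gene_a, df$gene_b, df$group_id, df$score, df$class)
}
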