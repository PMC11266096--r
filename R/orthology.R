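#' Construct an orthology map
#'
#' Holds orthogroup membership as a long table (`group_id`, `species_id`,
#' `gene_id`). A gene may belong to at most one group per species; duplicate
#' memberships are resolved by keeping the first occurrence (input order)
#' with a warning — precomputed orthology at a fixed level should not contain
#' duplicates, but malformed input must not crash the tool.
#'
#' @param table data.frame with character columns `group_id`, `species_id`,
#'   `gene_id`.
#' @param species optional character vector restricting the map to the given
#'   species (rows for other species are dropped).
#' @return An object of class `orthology_map`: the (deduplicated) table with
#'   attribute `species_ids`.
#' @export
orthology_map <- function(table, species = NULL) {
  need <- c("group_id", "species_id", "gene_id")
  if (!all(need %in% names(table)))
    cx_input_error("orthogroup table needs columns group_id, species_id, gene_id")
  tab <- as.data.frame(lapply(table[need], as.character),
                       stringsAsFactors = FALSE)
  if (!is.null(species)) tab <- tab[tab$species_id %in% species, , drop = FALSE]
  if (!nrow(tab)) cx_input_error("orthogroup table has no rows (after species filter)")
  key <- paste(tab$species_id, tab$gene_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    offenders <- unique(tab$gene_id[dup])
    warning(sprintf(
      "%d gene(s) listed in more than one orthogroup; keeping first occurrence: %s",
      length(offenders), paste(head(offenders, 5), collapse = ", ")))
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(tab,
            species_ids = if (is.null(species)) sort(unique(tab$species_id))
                          else as.character(species),
            class = c("orthology_map", "data.frame"))
}

#' @export
print.orthology_map <- function(x, ...) {
  cat(sprintf("<orthology_map> %d groups, %d genes, species: %s\n",
              length(unique(x$group_id)), nrow(x),
              paste(attr(x, "species_ids"), collapse = ", ")))
  invisible(x)
}

#' Read an orthogroup table
#'
#' Reads a tab-separated file with columns `group_id`, `species_id`,
#' `gene_id` (header optional; `'#'` comments and CRLF endings accepted).
#' Groups with genes in only one of the requested species are retained but
#' yield no candidate pairs downstream.
#'
#' @param path path to the TSV file.
#' @param species optional two-species restriction, passed to
#'   [orthology_map()].
#' @return An `orthology_map`.
#' @export
read_orthogroups <- function(path, species = NULL) {
  lines <- read_clean_lines(path)
  if (!length(lines)) cx_input_error(sprintf("'%s' contains no orthogroup rows", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    cx_input_error(sprintf("'%s': every row needs 3 tab-separated columns", path))
  tab <- data.frame(group_id   = vapply(fields, `[[`, "", 1L),
                    species_id = vapply(fields, `[[`, "", 2L),
                    gene_id    = vapply(fields, `[[`, "", 3L),
                    stringsAsFactors = FALSE)
  if (identical(unname(tolower(unlist(tab[1, ]))),
                c("group_id", "species_id", "gene_id")))
    tab <- tab[-1, , drop = FALSE]
  orthology_map(tab, species = species)
}

#' Write an orthogroup table
#' @param orth an `orthology_map`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(orth, path) {
  write.table(as.data.frame(orth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Per-group gene lists for one species.
group_genes <- function(orth, species) {
  sub <- orth[orth$species_id == species, , drop = FALSE]
  split(sub$gene_id, factor(sub$group_id, levels = unique(orth$group_id)))
}

#' Enumerate gene families between two species
#'
#' @param orth an `orthology_map`.
#' @param species_a,species_b the two species IDs (defaults: the map's first
#'   two species).
#' @return A list, one element per group having at least one gene in either
#'   species: `list(group_id, a = genes in species A, b = genes in species B)`.
#'   Groups with genes in only one species are flagged `usable = FALSE`.
#' @export
families <- function(orth, species_a = NULL, species_b = NULL) {
  sp <- attr(orth, "species_ids")
  if (is.null(species_a)) species_a <- sp[1]
  if (is.null(species_b)) species_b <- sp[2]
  ga <- group_genes(orth, species_a)
  gb <- group_genes(orth, species_b)
  ids <- unique(orth$group_id)
  out <- lapply(ids, function(g) {
    a <- ga[[g]]; b <- gb[[g]]
    list(group_id = g, a = if (is.null(a)) character() else a,
         b = if (is.null(b)) character() else b,
         usable = length(a) > 0 && length(b) > 0)
  })
  names(out) <- ids
  out
}

#' One-to-one orthologue anchors
#'
#' The basis set for conservation scoring: groups with exactly one gene in
#' each of the two species, both genes present in their species' network.
#'
#' @param orth an `orthology_map`.
#' @param net_a,net_b coexpression networks of species A and B (used to drop
#'   anchors whose genes are absent); pass `NULL` to skip the check.
#' @param species_a,species_b the two species IDs.
#' @return A named character vector mapping species-A genes to species-B
#'   genes (a bijection).
#' @export
one_to_one_anchor <- function(orth, net_a = NULL, net_b = NULL,
                              species_a = NULL, species_b = NULL) {
  fam <- families(orth, species_a, species_b)
  one <- Filter(function(f) length(f$a) == 1 && length(f$b) == 1, fam)
  a <- vapply(one, function(f) f$a, "")
  b <- vapply(one, function(f) f$b, "")
  keep <- rep(TRUE, length(a))
  if (!is.null(net_a)) keep <- keep & a %in% network_genes(net_a)
  if (!is.null(net_b)) keep <- keep & b %in% network_genes(net_b)
  a <- a[keep]; b <- b[keep]
  # bijectivity is guaranteed by per-species dedup at load, but keep it honest
  stopifnot(!anyDuplicated(a), !anyDuplicated(b))
  stats::setNames(b, a)
}
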