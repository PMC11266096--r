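#' Simulation parameters for the two-species generator
#'
#' Defaults describe the study conditions the rest of the package is
#' exercised under: 200 orthogroups over 6 latent coexpression modules,
#' 40 bulk samples per species for network building, and 300 cells across 5
#' cell types per species for integration evaluation. Half the families are
#' one-to-one so that anchors per module comfortably exceed the default
#' top-partner count k = 10 — the scaled-down counterpart of the thousands
#' of one-to-one orthologue anchors a real species pair provides, without
#' which the conservation AUROC cannot reach its ceiling. `dispersion` is the
#' negative-binomial dispersion of single-cell counts (variance =
#' mu + dispersion * mu^2); bulk samples use `dispersion / 10`, reflecting
#' the far lower technical noise of aggregate RNA-seq. `divergence_noise`
#' in \[0, 1\] shifts that fraction of each planted species-B gene's loading
#' onto a random other module, eroding the conserved signal.
#'
#' @param n_modules number of latent coexpression modules.
#' @param genes_per_module module capacity per species (total gene capacity
#'   is `n_modules * genes_per_module`).
#' @param n_families number of orthogroups to plant.
#' @param family_shape_probs named probabilities over family shapes
#'   `"1x1"`, `"1x2"`, `"2x1"`, `"2x2"`, `"2x3"` (A genes x B genes).
#' @param n_bulk_samples bulk samples per species.
#' @param n_cells cells per species.
#' @param n_cell_types number of cell types (at most `n_modules`).
#' @param dispersion single-cell negative-binomial dispersion (> 0).
#' @param divergence_noise loading perturbation of planted pairs in \[0, 1\].
#' @param seed master seed; all randomness flows from it through a
#'   documented sub-seed scheme.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_modules = 6, genes_per_module = 60,
                       n_families = 200,
                       family_shape_probs = c("1x1" = 0.50, "1x2" = 0.125,
                                              "2x1" = 0.125, "2x2" = 0.15,
                                              "2x3" = 0.10),
                       n_bulk_samples = 40, n_cells = 300, n_cell_types = 5,
                       dispersion = 0.5, divergence_noise = 0, seed = 1) {
  shapes <- c("1x1", "1x2", "2x1", "2x2", "2x3")
  if (!all(names(family_shape_probs) %in% shapes) ||
      abs(sum(family_shape_probs) - 1) > 1e-8)
    cx_input_error("family_shape_probs must be named over 1x1..2x3 and sum to 1")
  counts <- c(n_modules, genes_per_module, n_families, n_bulk_samples,
              n_cells, n_cell_types)
  if (any(counts < 1)) cx_input_error("all counts must be positive")
  if (n_cell_types > n_modules)
    cx_input_error("n_cell_types must not exceed n_modules")
  if (dispersion <= 0) cx_input_error("dispersion must be positive")
  if (divergence_noise < 0 || divergence_noise > 1)
    cx_input_error("divergence_noise must lie in [0, 1]")
  structure(list(n_modules = n_modules, genes_per_module = genes_per_module,
                 n_families = n_families,
                 family_shape_probs = family_shape_probs,
                 n_bulk_samples = n_bulk_samples, n_cells = n_cells,
                 n_cell_types = n_cell_types, dispersion = dispersion,
                 divergence_noise = divergence_noise, seed = seed),
            class = "sim_params")
}

# Draw a module with free capacity; 'forbid' excludes modules, 'cap' is the
# remaining per-module slot count (modified in the caller).
draw_module <- function(cap, forbid = integer()) {
  ok <- setdiff(which(cap > 0), forbid)
  if (!length(ok)) cx_input_error(
    "infeasible family shapes: more genes demanded than n_modules * genes_per_module allows")
  if (length(ok) == 1) ok else sample(ok, 1)
}

# Sparse cell-type activity profiles: each type activates a subset of
# modules (gamma draws with shape < 1), scaled to mean activity 1.
draw_type_profiles <- function(n_cell_types, n_modules) {
  p <- matrix(rgamma(n_cell_types * n_modules, shape = 0.4, rate = 1),
              n_cell_types, n_modules)
  p <- p + 0.02                      # leaky floor: no module fully silent
  p / rowMeans(p)
}

# Negative-binomial counts for genes with (module, alt_module, mix_w, base)
# given a module-activity matrix (modules x samples).
nb_counts <- function(genes, act, dispersion) {
  mix <- act[genes$module, , drop = FALSE] * (1 - genes$w) +
         act[genes$alt,    , drop = FALSE] * genes$w
  mu <- genes$base * mix
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nrow(mu))
  dimnames(counts) <- list(genes$id, colnames(act))
  counts
}

make_bulk <- function(genes, n_samples, n_modules, dispersion, species, prefix) {
  act <- matrix(rlnorm(n_modules * n_samples, meanlog = 0, sdlog = 1),
                n_modules, n_samples,
                dimnames = list(NULL, sprintf("%s_s%03d", prefix, seq_len(n_samples))))
  expression_matrix(nb_counts(genes, act, dispersion), species = species)
}

make_cells <- function(genes, n_cells, type_profiles, dispersion, species, prefix) {
  n_types <- nrow(type_profiles)
  types <- rep_len(seq_len(n_types), n_cells)
  n_modules <- ncol(type_profiles)
  noise <- matrix(rgamma(n_modules * n_cells, shape = 5, rate = 5),
                  n_modules, n_cells)
  act <- t(type_profiles)[, types, drop = FALSE] * noise
  colnames(act) <- sprintf("%s_c%05d", prefix, seq_len(n_cells))
  expression_matrix(nb_counts(genes, act, dispersion),
                    cell_types = sprintf("type%d", types), species = species)
}

#' Simulate a ground-truthed two-species dataset
#'
#' Genes in each species belong to latent coexpression modules; module
#' activities drive negative-binomial counts, giving bulk samples (for
#' network building) and single-cell data with cell-type labels (cell types
#' are characteristic sparse module-activity profiles, shared between the
#' species). Orthogroups are planted per `family_shape_probs`: in every
#' family exactly one cross-species gene pair shares its ancestral module —
#' the planted proxy — while surplus duplicates are reassigned to random
#' other modules (divergence). 1x1 families are planted pairs by
#' construction. `divergence_noise` perturbs even the planted species-B
#' genes' loadings. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return A list: `bulk_a`, `bulk_b`, `sc_a`, `sc_b`
#'   ([expression_matrix()]s), `orthology` ([orthology_map()]), and `truth`
#'   (list with `planted_pairs` — a [proxy_list()] —, per-species
#'   `modules_a` / `modules_b` assignments, and the cell-type labels).
#' @export
simulate_two_species <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params

  # -- structure: families, module assignments ------------------------------
  structure_draw <- with_seed(sub_seed(p$seed, 1), {
    shapes <- sample(names(p$family_shape_probs), p$n_families, replace = TRUE,
                     prob = p$family_shape_probs)
    na <- as.integer(substr(shapes, 1, 1))
    nb <- as.integer(substr(shapes, 3, 3))
    if (sum(na) > p$n_modules * p$genes_per_module ||
        sum(nb) > p$n_modules * p$genes_per_module)
      cx_input_error(
        "infeasible family shapes: more genes demanded than n_modules * genes_per_module allows")
    cap_a <- rep(p$genes_per_module, p$n_modules)
    cap_b <- rep(p$genes_per_module, p$n_modules)
    gene_row <- function(id, module, alt, w)
      data.frame(id = id, module = module, alt = alt, w = w,
                 stringsAsFactors = FALSE)
    genes_a <- list(); genes_b <- list(); orth <- list(); planted <- list()
    ai <- 0L; bi <- 0L
    for (f in seq_len(p$n_families)) {
      gid <- sprintf("og%04d", f)
      m <- draw_module(pmin(cap_a, cap_b))
      cap_a[m] <- cap_a[m] - 1L; cap_b[m] <- cap_b[m] - 1L
      ids_a <- sprintf("A_g%04d", ai + seq_len(na[f])); ai <- ai + na[f]
      ids_b <- sprintf("B_g%04d", bi + seq_len(nb[f])); bi <- bi + nb[f]
      # planted pair: first gene on each side keeps the ancestral module
      alt_b <- draw_module(cap_b, forbid = m)
      genes_a[[length(genes_a) + 1L]] <- gene_row(ids_a[1], m, m, 0)
      genes_b[[length(genes_b) + 1L]] <-
        gene_row(ids_b[1], m, alt_b, p$divergence_noise)
      # surplus duplicates diverge to random other modules
      for (g in ids_a[-1]) {
        d <- draw_module(cap_a, forbid = m); cap_a[d] <- cap_a[d] - 1L
        genes_a[[length(genes_a) + 1L]] <- gene_row(g, d, d, 0)
      }
      for (g in ids_b[-1]) {
        d <- draw_module(cap_b, forbid = m); cap_b[d] <- cap_b[d] - 1L
        genes_b[[length(genes_b) + 1L]] <- gene_row(g, d, d, 0)
      }
      orth[[f]] <- data.frame(
        group_id = gid,
        species_id = c(rep("A", na[f]), rep("B", nb[f])),
        gene_id = c(ids_a, ids_b), stringsAsFactors = FALSE)
      planted[[f]] <- data.frame(
        gene_a = ids_a[1], gene_b = ids_b[1], group_id = gid,
        class = if (na[f] == 1 && nb[f] == 1) "one_to_one" else "proxy",
        stringsAsFactors = FALSE)
    }
    list(genes_a = do.call(rbind, genes_a), genes_b = do.call(rbind, genes_b),
         orth = do.call(rbind, orth), planted = do.call(rbind, planted))
  })
  ga <- structure_draw$genes_a; gb <- structure_draw$genes_b

  # -- gene base expression and shared cell-type profiles -------------------
  with_seed(sub_seed(p$seed, 2), {
    ga$base <- rlnorm(nrow(ga), meanlog = log(5), sdlog = 0.4)
    gb$base <- rlnorm(nrow(gb), meanlog = log(5), sdlog = 0.4)
    profiles <- draw_type_profiles(p$n_cell_types, p$n_modules)
  })

  disp_bulk <- p$dispersion / 10
  bulk_a <- with_seed(sub_seed(p$seed, 3),
    make_bulk(ga, p$n_bulk_samples, p$n_modules, disp_bulk, "A", "A"))
  bulk_b <- with_seed(sub_seed(p$seed, 4),
    make_bulk(gb, p$n_bulk_samples, p$n_modules, disp_bulk, "B", "B"))
  sc_a <- with_seed(sub_seed(p$seed, 5),
    make_cells(ga, p$n_cells, profiles, p$dispersion, "A", "A"))
  sc_b <- with_seed(sub_seed(p$seed, 6),
    make_cells(gb, p$n_cells, profiles, p$dispersion, "B", "B"))

  planted <- structure_draw$planted
  list(bulk_a = bulk_a, bulk_b = bulk_b, sc_a = sc_a, sc_b = sc_b,
       orthology = orthology_map(structure_draw$orth, species = c("A", "B")),
       truth = list(
         planted_pairs = proxy_list(planted$gene_a, planted$gene_b,
                                    planted$group_id, 1, planted$class),
         modules_a = stats::setNames(ga$module, ga$id),
         modules_b = stats::setNames(gb$module, gb$id),
         cell_types_a = sc_a$cell_types, cell_types_b = sc_b$cell_types),
       params = p)
}

#' Simulate a single-species cell-type dataset with planted gene families
#'
#' The companion generator for the pseudo-species split harness: one species,
#' single-cell counts with cell-type labels plus matched bulk samples, and
#' planted within-species gene families. Anchor families hold two genes of
#' the same module (after a random genome split these become the one-to-one
#' anchor pairs); proxy families hold a target and a same-module paralog
#' plus one partially diverged member whose loading retains a
#' `diverged_share` fraction of the ancestral module — so rejected proxies
#' carry partial signal, as diverging paralogs do.
#'
#' @param n_cell_types,n_cells,n_modules,n_bulk_samples,dispersion as in
#'   [sim_params()].
#' @param n_anchor_families number of 2-gene same-module families.
#' @param n_proxy_families number of 3-gene families (2 same-module + 1
#'   diverged).
#' @param diverged_share ancestral-loading fraction kept by diverged members.
#' @param seed master seed.
#' @return A list: `sc`, `bulk` ([expression_matrix()]s, species `"S"`),
#'   `families` (single-species [orthology_map()]), `truth` (module
#'   assignment and per-gene role `target` / `paralog` / `diverged`).
#' @export
simulate_celltype_dataset <- function(n_cell_types = 5, n_cells = 2000,
                                      n_modules = 6,
                                      n_anchor_families = 160,
                                      n_proxy_families = 160,
                                      n_bulk_samples = 40, dispersion = 0.5,
                                      diverged_share = 0.3, seed = 1) {
  n_genes <- 2 * n_anchor_families + 3 * n_proxy_families
  structure_draw <- with_seed(sub_seed(seed, 11), {
    genes <- list(); orth <- list(); role <- character()
    gi <- 0L
    for (f in seq_len(n_anchor_families + n_proxy_families)) {
      is_anchor <- f <= n_anchor_families
      gid <- sprintf("fam%04d", f)
      m <- sample.int(n_modules, 1)
      n_in_fam <- if (is_anchor) 2L else 3L
      ids <- sprintf("S_g%04d", gi + seq_len(n_in_fam)); gi <- gi + n_in_fam
      genes[[f]] <- data.frame(
        id = ids,
        module = c(m, m, if (!is_anchor) sample(setdiff(seq_len(n_modules), m), 1)),
        stringsAsFactors = FALSE)
      genes[[f]]$alt <- c(genes[[f]]$module[1:2], if (!is_anchor) m)
      genes[[f]]$w <- c(0, 0, if (!is_anchor) diverged_share)
      role <- c(role, c("target", "paralog", if (!is_anchor) "diverged"))
      orth[[f]] <- data.frame(group_id = gid, species_id = "S", gene_id = ids,
                              stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, genes)
    list(genes = g, orth = do.call(rbind, orth), role = role)
  })
  g <- structure_draw$genes
  stopifnot(nrow(g) == n_genes)
  with_seed(sub_seed(seed, 12), {
    g$base <- rlnorm(nrow(g), meanlog = log(5), sdlog = 0.4)
    profiles <- draw_type_profiles(n_cell_types, n_modules)
  })
  bulk <- with_seed(sub_seed(seed, 13),
    make_bulk(g, n_bulk_samples, n_modules, dispersion / 10, "S", "S"))
  sc <- with_seed(sub_seed(seed, 14),
    make_cells(g, n_cells, profiles, dispersion, "S", "S"))
  list(sc = sc, bulk = bulk,
       families = orthology_map(structure_draw$orth, species = "S"),
       truth = list(modules = stats::setNames(g$module, g$id),
                    role = stats::setNames(structure_draw$role, g$id)))
}

#' Split one dataset into two pseudo-species
#'
#' Partitions cells and genes uniformly at random into halves: pseudo-species
#' A is cell-half 1 restricted to gene-half 1, pseudo-species B is cell-half
#' 2 restricted to gene-half 2. The two halves share cell types but no genes
#' — a ground-truthed integration task that is impossible without expanding
#' the shared feature space. The input's gene families are re-expressed
#' between the halves (half-1 genes as species `"A"`, half-2 as `"B"`);
#' families with no gene in one half are discarded.
#'
#' @param sc an [expression_matrix()] with cell-type labels (>= 4 cells and
#'   >= 4 genes).
#' @param families an [orthology_map()] grouping the dataset's genes (any
#'   species labels; matched by gene ID).
#' @param seed integer seed for the two random partitions.
#' @return A list: `pseudo_a`, `pseudo_b` ([expression_matrix()]s),
#'   `families` (cross-half [orthology_map()] over species `"A"`/`"B"`),
#'   `gene_half` and `cell_half` (named 1/2 assignments).
#' @export
split_dataset <- function(sc, families, seed) {
  genes <- gene_ids(sc); cells <- sample_ids(sc)
  if (length(cells) < 4 || length(genes) < 4)
    cx_input_error("need at least 4 cells and 4 genes to split")
  halves <- with_seed(seed, list(
    g = sample(rep(1:2, length.out = length(genes))),
    c = sample(rep(1:2, length.out = length(cells)))))
  g1 <- genes[halves$g == 1]; g2 <- genes[halves$g == 2]
  c1 <- cells[halves$c == 1]; c2 <- cells[halves$c == 2]
  if (!length(g1) || !length(g2) || !length(c1) || !length(c2))
    cx_input_error("a half ended up empty")
  sub_expr <- function(gs, cs, tag) expression_matrix(
    sc$values[gs, cs, drop = FALSE],
    cell_types = if (is.null(sc$cell_types)) NULL
                 else sc$cell_types[match(cs, cells)],
    species = tag)
  fam_tab <- as.data.frame(families)
  fam_tab <- fam_tab[fam_tab$gene_id %in% genes, , drop = FALSE]
  fam_tab$species_id <- ifelse(fam_tab$gene_id %in% g1, "A", "B")
  per_group <- split(fam_tab$species_id, fam_tab$group_id)
  keep <- names(per_group)[vapply(per_group, function(s)
    all(c("A", "B") %in% s), TRUE)]
  fam_tab <- fam_tab[fam_tab$group_id %in% keep, , drop = FALSE]
  if (!nrow(fam_tab))
    cx_input_error("no family spans both genome halves")
  list(pseudo_a = sub_expr(g1, c1, "A"), pseudo_b = sub_expr(g2, c2, "B"),
       families = orthology_map(fam_tab, species = c("A", "B")),
       gene_half = stats::setNames(halves$g, genes),
       cell_half = stats::setNames(halves$c, cells))
}
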