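#' eGRAM parameters
#'
#' @param affinity_min minimum DBS binding affinity for a regulator-gene
#'   targeting edge (default 60).
#' @param pearson_min minimum absolute Pearson correlation for
#'   co-regulator grouping and regulator-target correlation (default 0.5).
#' @param module_size minimum number of genes in a reported module
#'   (default 50).
#' @param enrich_fdr BH-FDR cutoff for reported pathway enrichments
#'   (default 0.01).
#' @param signed_r when `TRUE` only positive correlations count;
#'   default `FALSE` uses `|r|`.
#' @return list of class `egram_params`.
#' @export
egram_params <- function(affinity_min = 60, pearson_min = 0.5,
                         module_size = 50, enrich_fdr = 0.01,
                         signed_r = FALSE) {
  stopifnot(affinity_min > 0, pearson_min > 0, pearson_min < 1,
            module_size >= 1, enrich_fdr > 0)
  structure(list(affinity_min = affinity_min, pearson_min = pearson_min,
                 module_size = module_size, enrich_fdr = enrich_fdr,
                 signed_r = signed_r), class = "egram_params")
}

.r_ok <- function(r, params) {
  if (params$signed_r) r >= params$pearson_min else abs(r) >= params$pearson_min
}

#' Co-regulator sets from regulator expression
#'
#' Groups regulators whose pairwise expression correlations all reach
#' `pearson_min` into co-regulator sets: the maximal cliques of the
#' correlation graph (singletons included for isolated regulators). A
#' connected-components mode is available for a looser grouping.
#'
#' @param expr regulator x sample expression matrix (rownames =
#'   regulator ids).
#' @param params an [egram_params()].
#' @param mode `"clique"` (default) or `"component"`.
#' @return list of character vectors, deterministically ordered.
#' @export
coregulator_sets <- function(expr, params = egram_params(),
                             mode = c("clique", "component")) {
  mode <- match.arg(mode)
  ids <- rownames(expr)
  stopifnot(length(ids) >= 1)
  if (length(ids) == 1) return(list(ids))
  r <- stats::cor(t(expr))
  adj <- .r_ok(r, params)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  sets <- if (mode == "clique") {
    lapply(igraph::max_cliques(g), function(v) sort(ids[as.integer(v)]))
  } else {
    comp <- igraph::components(g)$membership
    lapply(split(ids, comp), sort)
  }
  sets <- unique(sets)
  sets[order(vapply(sets, function(s) paste(s, collapse = ","), character(1)))]
}

#' Target genes of one regulator
#'
#' A gene is a target of a regulator when the regulator has a DBS (or
#' TFBS) in the gene with binding affinity at least `affinity_min` and the
#' regulator-gene expression correlation reaches `pearson_min`.
#'
#' @param regulator regulator id.
#' @param binding data frame: `regulator`, `gene`, `affinity`.
#' @param expr expression matrix containing the regulator and genes
#'   (rownames = ids).
#' @param params an [egram_params()].
#' @return character vector of target gene ids.
#' @export
regulator_targets <- function(regulator, binding, expr,
                              params = egram_params()) {
  b <- binding[binding$regulator == regulator &
                 binding$affinity >= params$affinity_min, , drop = FALSE]
  genes <- intersect(unique(b$gene), rownames(expr))
  if (length(genes) == 0) return(character(0))
  r <- as.numeric(stats::cor(expr[regulator, ],
                             t(expr[genes, , drop = FALSE])))
  sort(genes[.r_ok(r, params)])
}

#' Form regulatory modules from co-regulator sets and their targets
#'
#' One candidate module per co-regulator set: the union of the member
#' regulators' target genes. Candidates with fewer than `module_size`
#' genes are dropped; modules may overlap.
#'
#' @param reg_sets list of co-regulator sets from [coregulator_sets()].
#' @param binding,expr,params as in [regulator_targets()].
#' @return list of modules, each a list with `regulators`, `genes`,
#'   `mean_r` (mean pairwise Pearson correlation among module genes).
#' @export
form_modules <- function(reg_sets, binding, expr, params = egram_params()) {
  mods <- list()
  for (rs in reg_sets) {
    genes <- sort(unique(unlist(lapply(rs, regulator_targets,
                                       binding = binding, expr = expr,
                                       params = params))))
    if (length(genes) < params$module_size) next
    r <- stats::cor(t(expr[genes, , drop = FALSE]))
    mean_r <- mean(r[upper.tri(r)])
    mods[[length(mods) + 1L]] <- list(regulators = rs, genes = genes,
                                      mean_r = mean_r)
  }
  mods
}

#' Hypergeometric pathway enrichment of a module
#'
#' Upper-tail hypergeometric test per pathway (over-representation of
#' pathway genes in the module relative to the universe), BH-corrected
#' over the tested pathways; pathways with FDR <= `enrich_fdr` are
#' returned. Pathways with no gene in the universe are skipped.
#'
#' @param module_genes character vector.
#' @param pathways named list of gene-id vectors (e.g. read from a GMT
#'   file).
#' @param universe character vector of all candidate genes (typically the
#'   expression matrix rows).
#' @param enrich_fdr FDR cutoff.
#' @return data frame: `pathway`, `overlap`, `pathway_size`, `p`, `fdr`.
#' @export
enrich_pathways <- function(module_genes, pathways, universe,
                            enrich_fdr = 0.01) {
  stopifnot(all(module_genes %in% universe))
  res <- list()
  for (pw in names(pathways)) {
    pg <- intersect(pathways[[pw]], universe)
    if (length(pg) == 0) next
    q <- length(intersect(module_genes, pg))
    p <- stats::phyper(q - 1, length(pg), length(universe) - length(pg),
                       length(module_genes), lower.tail = FALSE)
    res[[length(res) + 1L]] <- data.frame(
      pathway = pw, overlap = q, pathway_size = length(pg), p = p,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0) {
    return(data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), p = numeric(),
                      fdr = numeric()))
  }
  tab <- do.call(rbind, res)
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[tab$fdr <= enrich_fdr, , drop = FALSE]
  tab[order(tab$p), ]
}

#' Cross-tabulate lncRNA-module and TF-module gene regulation
#'
#' Flags every gene appearing in either module list as co-regulated (in a
#' lncRNA module and a TF module), lncRNA-only, or TF-only.
#'
#' @param lnc_modules,tf_modules module lists as from [form_modules()]
#'   (either may be empty).
#' @return data frame: `gene`, `regulation` in
#'   `c("co-regulated", "lncRNA-only", "TF-only")`.
#' @export
cross_module_check <- function(lnc_modules, tf_modules) {
  lg <- unique(unlist(lapply(lnc_modules, `[[`, "genes")))
  tg <- unique(unlist(lapply(tf_modules, `[[`, "genes")))
  genes <- sort(union(lg, tg))
  reg <- ifelse(genes %in% lg & genes %in% tg, "co-regulated",
                ifelse(genes %in% lg, "lncRNA-only", "TF-only"))
  data.frame(gene = genes, regulation = reg, stringsAsFactors = FALSE)
}

#' Compare modules across species
#'
#' For each species-A module, reports the fraction of its genes whose
#' orthologs fall in any species-B module, and the mean within-module-set
#' Pearson correlation in B versus A (orthologs only). Low fractions and
#' correlation ratios indicate that the module structure is not conserved
#' in species B.
#'
#' @param modules_a species-A module list (from [form_modules()]).
#' @param expr_a,expr_b expression matrices for the two species.
#' @param ortholog_map named character vector: species-A gene ->
#'   species-B gene.
#' @param binding_b,params used to build species-B modules on `expr_b`
#'   (same pipeline); pass `modules_b` directly to skip.
#' @param modules_b optional precomputed species-B modules.
#' @return data frame: `module`, `n_genes`, `ortholog_coverage`,
#'   `fraction_in_b_modules`, `mean_r_a`, `mean_r_b`.
#' @export
compare_species_modules <- function(modules_a, expr_a, expr_b, ortholog_map,
                                    binding_b = NULL,
                                    params = egram_params(),
                                    modules_b = NULL) {
  if (is.null(modules_b)) {
    stopifnot(!is.null(binding_b))
    regs_b <- intersect(unique(binding_b$regulator), rownames(expr_b))
    sets_b <- coregulator_sets(expr_b[regs_b, , drop = FALSE], params)
    modules_b <- form_modules(sets_b, binding_b, expr_b, params)
  }
  bg <- unique(unlist(lapply(modules_b, `[[`, "genes")))
  rows <- lapply(seq_along(modules_a), function(k) {
    m <- modules_a[[k]]
    orth <- ortholog_map[m$genes]
    cov <- mean(!is.na(orth) & orth %in% rownames(expr_b))
    if (cov < 0.5) {
      warning("module ", k, ": ortholog map covers < 50% of genes")
    }
    present <- orth[!is.na(orth) & orth %in% rownames(expr_b)]
    frac <- if (length(present)) mean(present %in% bg) else NA_real_
    ra <- stats::cor(t(expr_a[m$genes, , drop = FALSE]))
    rb <- if (length(present) >= 2) {
      stats::cor(t(expr_b[present, , drop = FALSE]))
    } else NULL
    data.frame(module = k, n_genes = length(m$genes),
               ortholog_coverage = cov, fraction_in_b_modules = frac,
               mean_r_a = mean(ra[upper.tri(ra)]),
               mean_r_b = if (is.null(rb)) NA_real_ else
                 mean(rb[upper.tri(rb)]))
  })
  do.call(rbind, rows)
}
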