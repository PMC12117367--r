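# Candidate metabolic gene-cluster calling on annotated chromosomes.
#
# A cluster is a contiguous run of genes on one chromosome that (1) contains
# at least `min_metabolic_genes` enzyme-annotated genes, (2) carries at least
# `min_distinct_reactions` distinct MetaCyc reaction IDs, (3) lies in one
# continuous region (no assembly sequencing gap of `gap_break_bp` or more
# inside its span, no run of more than K consecutive non-metabolic genes),
# and (4) is not composed solely of local repeats of one gene family.

#' Cluster-calling parameters
#'
#' @param min_metabolic_genes minimum enzyme-annotated genes per cluster
#'   (default 3).
#' @param min_distinct_reactions minimum distinct reaction IDs per cluster
#'   (default 2).
#' @param max_intervening_nonmetabolic K, the longest run of non-metabolic
#'   genes allowed between consecutive metabolic members (default 5; see
#'   [compute_gap_heuristic()] for a data-driven choice).
#' @param gap_break_bp sequencing gaps at least this long break candidate
#'   clusters (default 10000).
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(min_metabolic_genes = 3L,
                           min_distinct_reactions = 2L,
                           max_intervening_nonmetabolic = 5L,
                           gap_break_bp = 10000) {
  stopifnot(min_metabolic_genes >= 1, min_distinct_reactions >= 0,
            max_intervening_nonmetabolic >= 0, gap_break_bp >= 1)
  structure(list(min_metabolic_genes = as.integer(min_metabolic_genes),
                 min_distinct_reactions = as.integer(min_distinct_reactions),
                 max_intervening_nonmetabolic = as.integer(max_intervening_nonmetabolic),
                 gap_break_bp = as.numeric(gap_break_bp)),
            class = "cluster_params")
}

#' Is a gene metabolic?
#'
#' A gene counts as metabolic when it carries at least one reaction ID;
#' pathway-only annotation is not sufficient. Unknown genes are non-metabolic.
#'
#' @param gene_id character vector of gene identifiers.
#' @param enzymes an [enzyme_annotation].
#' @return logical vector.
#' @export
is_metabolic <- function(gene_id, enzymes) {
  vapply(gene_id, function(g) length(gene_reactions(enzymes, g)) > 0, TRUE,
         USE.NAMES = FALSE)
}

#' Heuristic for the maximum allowed run of non-metabolic genes
#'
#' Computes, from genome-scale quantities: the mean distance between
#' metabolic genes (genome size G divided by the number of metabolic genes
#' M), the duplication impact factor (duplicate-family gene count D divided
#' by G), and their product with the non-metabolic family size F. The
#' product simplifies algebraically to D*F/M and, floored to an integer,
#' is used as K in [cluster_params()].
#'
#' @param genome_size_bp G, total assembly length in bp.
#' @param n_metabolic M, number of metabolic genes.
#' @param duplicate_family_genes D, total genes in families of size >= 2.
#' @param nonmetabolic_genes F, size of the non-metabolic gene family.
#' @return list with `distance`, `impact_factor`, `max_nonmetabolic_raw`
#'   (the product, unrounded) and `max_nonmetabolic` (floored, >= 0).
#' @export
compute_gap_heuristic <- function(genome_size_bp, n_metabolic,
                                  duplicate_family_genes, nonmetabolic_genes) {
  vals <- c(genome_size_bp, n_metabolic, duplicate_family_genes, nonmetabolic_genes)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all gap-heuristic inputs must be positive", call. = FALSE)
  distance <- genome_size_bp / n_metabolic
  impact_factor <- duplicate_family_genes / genome_size_bp
  raw <- distance * impact_factor * nonmetabolic_genes
  list(distance = distance,
       impact_factor = impact_factor,
       max_nonmetabolic_raw = raw,
       max_nonmetabolic = max(0L, as.integer(floor(raw))))
}

#' Derive gene families from shared Pfam domain content
#'
#' Proxy family assignment supporting the tandem-repeat criterion: genes with
#' identical Pfam accession sets share a family (family id = sorted,
#' comma-joined accessions); genes without domains get singleton families
#' `solo:<gene_id>`.
#'
#' @param domains a [domain_annotation].
#' @param gene_ids optional vector of all genes to cover (genes absent from
#'   `domains` become singletons).
#' @return named character vector, gene_id -> family_id, with attribute
#'   `provenance = "pfam_proxy"`.
#' @export
assign_families_by_pfam_proxy <- function(domains, gene_ids = NULL) {
  d <- unclass(domains)
  gene_ids <- union(gene_ids %||% character(), names(d))
  fam <- vapply(gene_ids, function(g) {
    pf <- d[[g]]
    if (is.null(pf) || length(pf) == 0) paste0("solo:", g)
    else paste(sort(pf), collapse = ",")
  }, "")
  names(fam) <- gene_ids
  attr(fam, "provenance") <- "pfam_proxy"
  fam
}

# family lookup with singleton fallback
family_of <- function(families, gene_id) {
  if (is.null(families)) return(paste0("solo:", gene_id))
  f <- unname(families[gene_id])
  f[is.na(f)] <- paste0("solo:", gene_id[is.na(f)])
  f
}

#' Gap-heuristic inputs measured from loaded data
#'
#' D is the number of genes belonging to families of size >= 2 and F the
#' number of non-metabolic genes; both can be overridden in configuration.
#'
#' @param annotation a [genome_annotation].
#' @param enzymes an [enzyme_annotation].
#' @param families named family vector (see [assign_families_by_pfam_proxy()]).
#' @return list with `genome_size_bp`, `n_metabolic`,
#'   `duplicate_family_genes`, `nonmetabolic_genes`.
#' @export
gap_heuristic_inputs <- function(annotation, enzymes, families) {
  ids <- annotation$genes$gene_id
  met <- is_metabolic(ids, enzymes)
  fam <- family_of(families, ids)
  fam_sizes <- table(fam)
  list(genome_size_bp = annotation$genome_size_bp,
       n_metabolic = sum(met),
       duplicate_family_genes = sum(fam_sizes[fam_sizes >= 2]),
       nonmetabolic_genes = sum(!met))
}

# ---- cluster construction ---------------------------------------------------

# Build a gene_cluster object from a slice of a chromosome's gene table
# (rows first..last, in ordinal order).
new_gene_cluster <- function(chr_genes, first_idx, last_idx, enzymes, metabolic_flags) {
  members <- chr_genes[first_idx:last_idx, , drop = FALSE]
  met_ids <- members$gene_id[metabolic_flags[first_idx:last_idx]]
  start_bp <- members$start[1]
  end_bp <- max(effective_end(members))
  cl <- list(
    cluster_id = sprintf("%s:%d-%d", members$chromosome_id[1],
                         members$ordinal[1], members$ordinal[nrow(members)]),
    chromosome_id = members$chromosome_id[1],
    first_ordinal = members$ordinal[1],
    last_ordinal = members$ordinal[nrow(members)],
    member_gene_ids = members$gene_id,
    metabolic_gene_ids = met_ids,
    reaction_ids = sort(unique(unlist(lapply(met_ids, gene_reactions, enzymes = enzymes)))),
    pathway_ids = sort(unique(unlist(lapply(members$gene_id, gene_pathways, enzymes = enzymes)))),
    start_bp = start_bp,
    end_bp = end_bp,
    span_bp = end_bp - start_bp + 1,
    flags = NULL)
  class(cl) <- "gene_cluster"
  cl
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("gene_cluster %s: %d genes (%d metabolic), %.1f kb\n",
              x$cluster_id, length(x$member_gene_ids),
              length(x$metabolic_gene_ids), x$span_bp / 1000))
  invisible(x)
}

# Segment index per gene: genes separated by a sequencing gap of at least
# gap_break_bp fall into different segments. A gene lies after a gap when its
# start (1-based) exceeds the gap's half-open end.
gap_segments <- function(chr_genes, gaps, gap_break_bp) {
  if (is.null(gaps) || nrow(gaps) == 0) return(rep(0L, nrow(chr_genes)))
  big <- gaps[gaps$end - gaps$start >= gap_break_bp, , drop = FALSE]
  if (nrow(big) == 0) return(rep(0L, nrow(chr_genes)))
  vapply(chr_genes$start, function(s) sum(big$end < s), 0L)
}

# Does a cluster window pass the reaction/family criteria?
window_passes <- function(chr_genes, idx_first, idx_last, enzymes, families,
                          metabolic_flags, params) {
  met_idx <- which(metabolic_flags[idx_first:idx_last]) + idx_first - 1L
  if (length(met_idx) < params$min_metabolic_genes) return(FALSE)
  met_ids <- chr_genes$gene_id[met_idx]
  rxn <- unique(unlist(lapply(met_ids, gene_reactions, enzymes = enzymes)))
  if (length(rxn) < params$min_distinct_reactions) return(FALSE)
  fams <- unique(family_of(families, met_ids))
  length(fams) >= 2
}

#' Call candidate metabolic gene clusters
#'
#' Each chromosome is first segmented at sequencing gaps of at least
#' `gap_break_bp`; within a segment, maximal runs of genes are formed in
#' which consecutive metabolic genes are separated by at most K non-metabolic
#' genes, each run is trimmed to its outermost metabolic genes, and a run is
#' emitted when it meets the metabolic-gene, distinct-reaction and
#' family-diversity criteria. Output is sorted by chromosome and first
#' ordinal; clusters are pairwise non-overlapping.
#'
#' @param annotation a [genome_annotation].
#' @param enzymes an [enzyme_annotation].
#' @param families optional named family vector (gene_id -> family_id);
#'   when `NULL` every gene is a singleton family, which disables the
#'   tandem-repeat rejection in all but single-gene cases.
#' @param params a [cluster_params()].
#' @return list of `gene_cluster` objects.
#' @export
find_candidate_clusters <- function(annotation, enzymes, families = NULL,
                                    params = cluster_params()) {
  unknown <- setdiff(names(enzymes$reactions)[vapply(enzymes$reactions, length, 0L) > 0],
                     annotation$genes$gene_id)
  if (length(unknown) > 0)
    warning(length(unknown), " enzyme-annotated gene(s) absent from the genome annotation; ignored",
            call. = FALSE)
  K <- params$max_intervening_nonmetabolic
  out <- list()
  for (chr in chromosome_ids(annotation)) {
    cg <- genes_on(annotation, chr)
    met <- is_metabolic(cg$gene_id, enzymes)
    seg <- gap_segments(cg, annotation$gaps[[chr]], params$gap_break_bp)
    met_pos <- which(met)
    if (length(met_pos) == 0) next
    # split metabolic positions into runs: break when the gap segment changes
    # or more than K non-metabolic genes intervene
    breaks <- which(diff(met_pos) - 1 > K | diff(seg[met_pos]) != 0)
    run_id <- cumsum(c(0L, seq_along(met_pos)[-1] %in% (breaks + 1L)))
    for (r in split(met_pos, run_id)) {
      first_idx <- r[1]; last_idx <- r[length(r)]
      if (window_passes(cg, first_idx, last_idx, enzymes, families, met, params))
        out[[length(out) + 1L]] <- new_gene_cluster(cg, first_idx, last_idx,
                                                    enzymes, met)
    }
  }
  out
}

#' Brute-force cluster enumeration (test oracle)
#'
#' Enumerates every contiguous window trimmed to metabolic boundaries,
#' keeps the windows satisfying all cluster criteria (including the K
#' constraint and gap segmentation) and retains only windows that are
#' maximal under containment. Quadratic in the number of metabolic genes;
#' intended for small instances as an independent check of
#' [find_candidate_clusters()].
#'
#' @inheritParams find_candidate_clusters
#' @return list of `gene_cluster` objects.
#' @export
enumerate_clusters_bruteforce <- function(annotation, enzymes, families = NULL,
                                          params = cluster_params()) {
  K <- params$max_intervening_nonmetabolic
  out <- list()
  for (chr in chromosome_ids(annotation)) {
    cg <- genes_on(annotation, chr)
    met <- is_metabolic(cg$gene_id, enzymes)
    seg <- gap_segments(cg, annotation$gaps[[chr]], params$gap_break_bp)
    met_pos <- which(met)
    t <- length(met_pos)
    if (t == 0) next
    valid <- list()
    for (a in seq_len(t)) {
      for (b in a:t) {
        i <- met_pos[a]; j <- met_pos[b]
        if (seg[i] != seg[j]) next
        if (b > a && any(diff(met_pos[a:b]) - 1 > K)) next
        if (!window_passes(cg, i, j, enzymes, families, met, params)) next
        valid[[length(valid) + 1L]] <- c(i, j)
      }
    }
    if (length(valid) == 0) next
    vm <- do.call(rbind, valid)
    maximal <- vapply(seq_len(nrow(vm)), function(q) {
      !any(vm[, 1] <= vm[q, 1] & vm[, 2] >= vm[q, 2] &
             (vm[, 1] < vm[q, 1] | vm[, 2] > vm[q, 2]))
    }, TRUE)
    vm <- vm[maximal, , drop = FALSE]
    vm <- vm[order(vm[, 1]), , drop = FALSE]
    for (q in seq_len(nrow(vm)))
      out[[length(out) + 1L]] <- new_gene_cluster(cg, vm[q, 1], vm[q, 2],
                                                  enzymes, met)
  }
  out
}
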