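# High-confidence screening funnel: TPS/CYP signature pairing, copathway
# evidence (shared pathway, distinct reactions), percentile-thresholded
# Pearson coexpression, and the final terpene-quality designation.

#' Pfam signature rules for terpene clusters
#'
#' Terpene synthases (TPS) are recognised by PF01397 or PF03936 and
#' cytochrome P450s (CYP) by PF00067.
#'
#' @param tps_pfams Pfam accessions identifying TPS genes.
#' @param cyp_pfams Pfam accessions identifying CYP genes.
#' @return object of class `signature_rules`.
#' @export
signature_rules <- function(tps_pfams = c("PF01397", "PF03936"),
                            cyp_pfams = "PF00067") {
  stopifnot(length(tps_pfams) > 0, length(cyp_pfams) > 0,
            length(intersect(tps_pfams, cyp_pfams)) == 0)
  structure(list(tps_pfams = tps_pfams, cyp_pfams = cyp_pfams),
            class = "signature_rules")
}

#' Coexpression screening parameters
#'
#' @param percentile background percentile p defining the threshold r*
#'   (default 99).
#' @param transform expression transform for Pearson correlation:
#'   `"log2_fpkm_plus_1"` (default) or `"raw_fpkm"`.
#' @param background_pairs number of random gene pairs sampled for the
#'   background distribution (default 100000; all pairs are enumerated
#'   instead when the genome has no more than this many pairs).
#' @param pair_rule which within-cluster pairs may satisfy the stage:
#'   `"tps_cyp_pair"` (default) or `"any_pair"`.
#' @param min_samples minimum number of expression samples (default 3).
#' @param seed RNG seed for background pair sampling.
#' @return object of class `coexpression_params`.
#' @export
coexpression_params <- function(percentile = 99, transform = c("log2_fpkm_plus_1", "raw_fpkm"),
                                background_pairs = 100000L,
                                pair_rule = c("tps_cyp_pair", "any_pair"),
                                min_samples = 3L, seed = 1L) {
  transform <- match.arg(transform)
  pair_rule <- match.arg(pair_rule)
  stopifnot(percentile > 0, percentile < 100, background_pairs >= 1000,
            min_samples >= 3)
  structure(list(percentile = percentile, transform = transform,
                 background_pairs = as.integer(background_pairs),
                 pair_rule = pair_rule, min_samples = as.integer(min_samples),
                 seed = as.integer(seed)),
            class = "coexpression_params")
}

transform_expression <- function(expr, transform) {
  switch(transform,
         log2_fpkm_plus_1 = log2(expr + 1),
         raw_fpkm = expr,
         stop("unknown transform: ", transform, call. = FALSE))
}

#' Classify a gene as TPS and/or CYP from its Pfam domains
#'
#' @param gene_id single gene identifier.
#' @param domains a [domain_annotation].
#' @param rules a [signature_rules()].
#' @return character vector, a subset of `c("TPS", "CYP")`.
#' @export
classify_signature <- function(gene_id, domains, rules = signature_rules()) {
  pf <- gene_domains(domains, gene_id)
  out <- character()
  if (any(pf %in% rules$tps_pfams)) out <- c(out, "TPS")
  if (any(pf %in% rules$cyp_pfams)) out <- c(out, "CYP")
  out
}

cluster_signature_genes <- function(cluster, domains, rules) {
  cls <- lapply(cluster$member_gene_ids, classify_signature, domains = domains,
                rules = rules)
  list(tps = cluster$member_gene_ids[vapply(cls, function(x) "TPS" %in% x, TRUE)],
       cyp = cluster$member_gene_ids[vapply(cls, function(x) "CYP" %in% x, TRUE)])
}

#' Stage 1: require a TPS and a CYP gene in the cluster
#'
#' @param clusters list of gene clusters.
#' @param domains a [domain_annotation].
#' @param rules a [signature_rules()].
#' @return the clusters, with `flags$has_tps`, `flags$has_cyp` and
#'   `flags$tps_cyp_pass` set.
#' @export
filter_tps_cyp <- function(clusters, domains, rules = signature_rules()) {
  lapply(clusters, function(cl) {
    sig <- cluster_signature_genes(cl, domains, rules)
    cl$flags <- c(cl$flags %||% list(),
                  list(has_tps = length(sig$tps) > 0,
                       has_cyp = length(sig$cyp) > 0))
    cl$flags$tps_cyp_pass <- cl$flags$has_tps && cl$flags$has_cyp
    cl
  })
}

#' Stage 2: copathway evidence
#'
#' Passes when the cluster holds two genes sharing a pathway ID whose
#' reaction sets are non-empty, not identical (each has a reaction absent
#' from the other or one set strictly differs). The first qualifying pair in
#' gene order is recorded as evidence, with all pathways that pair shares.
#'
#' @param clusters list of gene clusters.
#' @param enzymes an [enzyme_annotation].
#' @return the clusters, with `flags$copathway_pass` and
#'   `flags$copathway_evidence` set.
#' @export
filter_copathway <- function(clusters, enzymes) {
  lapply(clusters, function(cl) {
    cl$flags <- cl$flags %||% list()
    cl$flags$copathway_pass <- FALSE
    cl$flags$copathway_evidence <- NULL
    ids <- cl$member_gene_ids
    n <- length(ids)
    found <- FALSE
    for (a in seq_len(max(0, n - 1))) {
      if (found) break
      pa <- gene_pathways(enzymes, ids[a])
      ra <- gene_reactions(enzymes, ids[a])
      if (length(pa) == 0 || length(ra) == 0) next
      for (b in (a + 1):n) {
        shared <- intersect(pa, gene_pathways(enzymes, ids[b]))
        if (length(shared) == 0) next
        rb <- gene_reactions(enzymes, ids[b])
        if (length(rb) == 0) next
        if (setequal(ra, rb)) next
        cl$flags$copathway_pass <- TRUE
        cl$flags$copathway_evidence <- list(gene_a = ids[a], gene_b = ids[b],
                                            shared_pathways = sort(shared))
        found <- TRUE
        break
      }
    }
    cl
  })
}

#' Pearson product-moment correlation for one gene pair
#'
#' Returns `NA` (the undefined-correlation signal; such pairs are skipped)
#' when either vector is constant.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Correlations for a set of index pairs over a row-standardized matrix.
pair_correlations <- function(z, pairs) {
  rowSums(z[pairs[, 1], , drop = FALSE] * z[pairs[, 2], , drop = FALSE])
}

#' Genome-wide background coexpression threshold r*
#'
#' Draws `background_pairs` random distinct gene pairs (all pairs are
#' enumerated when the genome has no more than that many), computes the
#' Pearson correlation of each on the transformed expression values, and
#' returns the `percentile`-th value under the nearest-rank rule. Pairs with
#' a constant gene are skipped.
#'
#' @param expr expression matrix (genes x samples).
#' @param params a [coexpression_params()].
#' @return the threshold r*, with attributes `n_pairs_used` (correlations
#'   entering the percentile) and `enumerated` (logical).
#' @export
background_threshold <- function(expr, params = coexpression_params()) {
  if (ncol(expr) < params$min_samples)
    stop("need at least ", params$min_samples, " expression samples", call. = FALSE)
  n <- nrow(expr)
  if (n < 2) stop("need at least 2 genes for a background distribution", call. = FALSE)
  z <- standardize_rows(transform_expression(expr, params$transform))
  total <- n_pairs(n)
  enumerated <- total <= params$background_pairs
  pairs <- if (enumerated) {
    pair_from_index(seq_len(total), n)
  } else {
    ks <- with_seed(params$seed,
                    sort(sample(total, params$background_pairs, replace = FALSE)))
    pair_from_index(ks, n)
  }
  r <- pair_correlations(z, pairs)
  r <- r[!is.na(r)]
  if (length(r) == 0) stop("no background pair had defined correlation", call. = FALSE)
  rstar <- nearest_rank_percentile(r, params$percentile)
  attr(rstar, "n_pairs_used") <- length(r)
  attr(rstar, "enumerated") <- enumerated
  rstar
}

#' Stage 3: percentile-thresholded coexpression
#'
#' Under `pair_rule = "tps_cyp_pair"` the cluster passes when some
#' (TPS gene, CYP gene) pair reaches `r >= r*`; under `"any_pair"` any
#' within-cluster pair suffices. Cluster genes absent from the expression
#' matrix are skipped; a cluster with no eligible expressed pair fails with
#' reason `"insufficient expression data"`. When a gene-to-module table is
#' supplied, the evidence pair must additionally share a module.
#'
#' @param clusters list of gene clusters (flags from earlier stages kept).
#' @param expr expression matrix (genes x samples).
#' @param domains a [domain_annotation] (used for the TPS/CYP pair rule).
#' @param params a [coexpression_params()].
#' @param rules a [signature_rules()].
#' @param r_star precomputed threshold; computed via [background_threshold()]
#'   when `NULL`.
#' @param modules optional named character vector gene_id -> module id.
#' @return the clusters, with `flags$coexpress_pass`,
#'   `flags$coexpress_evidence` (best pair and its r) and `flags$r_star` set.
#' @export
filter_coexpression <- function(clusters, expr, domains,
                                params = coexpression_params(),
                                rules = signature_rules(), r_star = NULL,
                                modules = NULL) {
  if (is.null(r_star)) r_star <- background_threshold(expr, params)
  z <- standardize_rows(transform_expression(expr, params$transform))
  lapply(clusters, function(cl) {
    cl$flags <- cl$flags %||% list()
    cl$flags$r_star <- as.numeric(r_star)
    cl$flags$coexpress_pass <- FALSE
    cl$flags$coexpress_evidence <- NULL
    present <- intersect(cl$member_gene_ids, rownames(expr))
    if (length(present) < length(cl$member_gene_ids))
      cl$flags$missing_expression <- setdiff(cl$member_gene_ids, present)
    pairs <- if (params$pair_rule == "tps_cyp_pair") {
      sig <- cluster_signature_genes(cl, domains, rules)
      tps <- intersect(sig$tps, present)
      cyp <- intersect(sig$cyp, present)
      if (length(tps) == 0 || length(cyp) == 0) NULL
      else {
        p <- expand.grid(a = tps, b = cyp, stringsAsFactors = FALSE)
        p <- p[p$a != p$b, , drop = FALSE]
        if (nrow(p) == 0) NULL else p
      }
    } else {
      if (length(present) < 2) NULL
      else {
        idx <- pair_from_index(seq_len(n_pairs(length(present))), length(present))
        data.frame(a = present[idx[, 1]], b = present[idx[, 2]],
                   stringsAsFactors = FALSE)
      }
    }
    if (!is.null(pairs) && !is.null(modules)) {
      ma <- unname(modules[pairs$a]); mb <- unname(modules[pairs$b])
      pairs <- pairs[!is.na(ma) & !is.na(mb) & ma == mb, , drop = FALSE]
      if (nrow(pairs) == 0) pairs <- NULL
    }
    if (is.null(pairs)) {
      cl$flags$reason <- "insufficient expression data"
      return(cl)
    }
    r <- vapply(seq_len(nrow(pairs)), function(q)
      sum(z[pairs$a[q], ] * z[pairs$b[q], ]), 0)
    ok <- !is.na(r)
    if (!any(ok)) {
      cl$flags$reason <- "insufficient expression data"
      return(cl)
    }
    best <- which(ok)[which.max(r[ok])]
    cl$flags$coexpress_evidence <- list(gene_a = pairs$a[best],
                                        gene_b = pairs$b[best],
                                        r = r[best], r_star = as.numeric(r_star))
    cl$flags$coexpress_pass <- r[best] >= as.numeric(r_star)
    cl
  })
}

#' Pathways linked to TPS genes (default terpene pathway set)
#'
#' The default "terpene pathway" vocabulary for [designate_quality()]: the
#' union of pathway IDs annotated to any TPS-classified gene in the genome.
#'
#' @param domains a [domain_annotation].
#' @param enzymes an [enzyme_annotation].
#' @param rules a [signature_rules()].
#' @return character vector of pathway IDs.
#' @export
default_terpene_pathways <- function(domains, enzymes, rules = signature_rules()) {
  genes <- names(unclass(domains))
  tps <- genes[vapply(genes, function(g) "TPS" %in% classify_signature(g, domains, rules), TRUE)]
  sort(unique(unlist(lapply(tps, gene_pathways, enzymes = enzymes))))
}

#' Final stage: terpene-quality designation
#'
#' A reconstruction of the final funnel column: a coexpression-passing
#' cluster is "quality" when its copathway evidence pair shares a pathway
#' belonging to the configured terpene pathway set.
#'
#' @param clusters list of gene clusters carrying copathway/coexpression flags.
#' @param enzymes an [enzyme_annotation].
#' @param terpene_pathway_ids character vector of terpene pathway IDs (see
#'   [default_terpene_pathways()]).
#' @param strict error when `terpene_pathway_ids` is empty (default TRUE).
#' @return the clusters, with `flags$quality` set.
#' @export
designate_quality <- function(clusters, enzymes, terpene_pathway_ids,
                              strict = TRUE) {
  if (strict && length(terpene_pathway_ids) == 0)
    stop("terpene_pathway_ids is empty", call. = FALSE)
  lapply(clusters, function(cl) {
    cl$flags <- cl$flags %||% list()
    ev <- cl$flags$copathway_evidence
    cl$flags$quality <- isTRUE(cl$flags$coexpress_pass) && !is.null(ev) &&
      length(intersect(ev$shared_pathways, terpene_pathway_ids)) > 0
    cl
  })
}

#' Run the full screening funnel
#'
#' Applies the stages in the fixed order raw -> TPS+CYP -> copathway ->
#' coexpress -> quality, each stage evaluated only on the survivors of the
#' previous one, and returns nested (monotone non-increasing) stage counts.
#'
#' @param clusters raw candidate clusters from [find_candidate_clusters()].
#' @param domains a [domain_annotation].
#' @param enzymes an [enzyme_annotation].
#' @param expr expression matrix (genes x samples).
#' @param params a [coexpression_params()].
#' @param rules a [signature_rules()].
#' @param terpene_pathway_ids terpene pathway set for the quality stage;
#'   defaults to [default_terpene_pathways()].
#' @param r_star precomputed background threshold (computed when `NULL`).
#' @param modules optional gene -> module table (coexpression pre-filter).
#' @param species label carried into the funnel summary.
#' @return object of class `tgc_funnel`: list with `clusters` (all raw
#'   clusters, flags attached; later-stage flags are `NA` for clusters
#'   eliminated earlier), `funnel` (named counts), `r_star`,
#'   `quality_clusters` and `flags` (data frame).
#' @export
run_funnel <- function(clusters, domains, enzymes, expr,
                       params = coexpression_params(),
                       rules = signature_rules(),
                       terpene_pathway_ids = NULL, r_star = NULL,
                       modules = NULL, species = "unspecified") {
  if (is.null(terpene_pathway_ids))
    terpene_pathway_ids <- default_terpene_pathways(domains, enzymes, rules)
  ids <- vapply(clusters, function(cl) cl$cluster_id, "")

  s1 <- filter_tps_cyp(clusters, domains, rules)
  surv1 <- vapply(s1, function(cl) isTRUE(cl$flags$tps_cyp_pass), TRUE)

  s2 <- s1
  s2[surv1] <- filter_copathway(s1[surv1], enzymes)
  surv2 <- vapply(s2, function(cl) isTRUE(cl$flags$copathway_pass), TRUE)

  if (is.null(r_star) && any(surv2))
    r_star <- background_threshold(expr, params)
  s3 <- s2
  if (any(surv2))
    s3[surv2] <- filter_coexpression(s2[surv2], expr, domains, params, rules,
                                     r_star = r_star, modules = modules)
  surv3 <- vapply(s3, function(cl) isTRUE(cl$flags$coexpress_pass), TRUE)

  s4 <- s3
  if (any(surv3))
    s4[surv3] <- designate_quality(s3[surv3], enzymes, terpene_pathway_ids,
                                   strict = FALSE)
  surv4 <- vapply(s4, function(cl) isTRUE(cl$flags$quality), TRUE)

  funnel <- c(raw = length(clusters), tps_cyp = sum(surv1),
              copathway = sum(surv2), coexpress = sum(surv3),
              quality = sum(surv4))
  structure(list(clusters = s4, funnel = funnel,
                 r_star = if (is.null(r_star)) NA_real_ else as.numeric(r_star),
                 quality_clusters = s4[surv4],
                 terpene_pathway_ids = terpene_pathway_ids,
                 species = species,
                 flags = clusters_to_df(s4)),
            class = "tgc_funnel")
}

#' @export
print.tgc_funnel <- function(x, ...) {
  cat(sprintf("screening funnel (%s):\n", x$species))
  cat(sprintf("  %-10s %d\n", names(x$funnel), x$funnel), sep = "")
  if (!is.na(x$r_star)) cat(sprintf("  r* = %.4f\n", x$r_star))
  invisible(x)
}

#' Evaluate each screening stage independently on every cluster
#'
#' Unlike [run_funnel()], every stage is applied to all clusters regardless
#' of earlier stages — used to check that simulated decoys fail exactly
#' their designated stage.
#'
#' @inheritParams run_funnel
#' @param pair_rule pair rule for the isolated coexpression stage
#'   (default `"any_pair"`, so signature-free clusters can still be scored).
#' @return data frame with one row per cluster and logical columns
#'   `tps_cyp`, `copathway`, `coexpress`.
#' @export
evaluate_stages <- function(clusters, domains, enzymes, expr,
                            params = coexpression_params(),
                            rules = signature_rules(), r_star = NULL,
                            pair_rule = "any_pair") {
  params$pair_rule <- pair_rule
  s1 <- filter_tps_cyp(clusters, domains, rules)
  s2 <- filter_copathway(clusters, enzymes)
  s3 <- filter_coexpression(clusters, expr, domains, params, rules,
                            r_star = r_star)
  data.frame(
    cluster_id = vapply(clusters, function(cl) cl$cluster_id, ""),
    tps_cyp = vapply(s1, function(cl) isTRUE(cl$flags$tps_cyp_pass), TRUE),
    copathway = vapply(s2, function(cl) isTRUE(cl$flags$copathway_pass), TRUE),
    coexpress = vapply(s3, function(cl) isTRUE(cl$flags$coexpress_pass), TRUE),
    stringsAsFactors = FALSE)
}

#' Cluster span and gene-count summaries
#'
#' Spans are measured in kb from the first member gene's start to the last
#' member's end (start when ends are absent). The 33-284 kb span band and
#' the 3-18 gene-count band (bounds inclusive) are the ranges typical of
#' experimentally verified plant metabolic clusters.
#'
#' @param clusters list of gene clusters.
#' @return object of class `cluster_stats` with fields `n`, `median_span_kb`,
#'   `mean_span_kb`, `fraction_span_lt_300kb`, `fraction_span_in_33_284kb`,
#'   `median_gene_count`, `fraction_gene_count_3_18`; the numeric fields are
#'   `NA` when `n = 0`.
#' @export
summarize_clusters <- function(clusters) {
  n <- length(clusters)
  if (n == 0) {
    out <- list(n = 0L, median_span_kb = NA_real_, mean_span_kb = NA_real_,
                fraction_span_lt_300kb = NA_real_,
                fraction_span_in_33_284kb = NA_real_,
                median_gene_count = NA_real_, fraction_gene_count_3_18 = NA_real_)
    class(out) <- "cluster_stats"
    return(out)
  }
  span_kb <- vapply(clusters, function(cl) cl$span_bp, 0) / 1000
  ngenes <- vapply(clusters, function(cl) length(cl$member_gene_ids), 0L)
  out <- list(n = n,
              median_span_kb = stats::median(span_kb),
              mean_span_kb = mean(span_kb),
              fraction_span_lt_300kb = mean(span_kb < 300),
              fraction_span_in_33_284kb = mean(span_kb >= 33 & span_kb <= 284),
              median_gene_count = stats::median(ngenes),
              fraction_gene_count_3_18 = mean(ngenes >= 3 & ngenes <= 18))
  class(out) <- "cluster_stats"
  out
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("cluster stats (n = %d):\n", x$n))
  if (x$n > 0) {
    cat(sprintf("  median span %.1f kb (mean %.1f); %.0f%% < 300 kb; %.0f%% in 33-284 kb\n",
                x$median_span_kb, x$mean_span_kb,
                100 * x$fraction_span_lt_300kb, 100 * x$fraction_span_in_33_284kb))
    cat(sprintf("  median %g genes; %.0f%% with 3-18 genes\n",
                x$median_gene_count, 100 * x$fraction_gene_count_3_18))
  }
  invisible(x)
}

#' FPKM from a raw fragment count
#'
#' FPKM = count / ((gene length / 1000) * (mapped reads / 1e6)).
#'
#' @param count non-negative fragment count (vectorized).
#' @param gene_length_bp positive gene/transcript length in bp.
#' @param mapped_reads positive library size (mapped fragments).
#' @return FPKM value(s).
#' @export
fpkm_from_counts <- function(count, gene_length_bp, mapped_reads) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be positive", call. = FALSE)
  if (any(mapped_reads <= 0)) stop("mapped_reads must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count / ((gene_length_bp / 1000) * (mapped_reads / 1e6))
}
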