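# In-code fixtures shared across test files.

# A tiny chromosome: gene ids g1..gn at 10 kb spacing, 3 kb genes.
toy_annotation <- function(n = 10, chr = "chr1", spacing = 10000, gaps = list()) {
  start <- seq_len(n) * spacing
  genome_annotation(data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), chromosome_id = rep(chr, n),
    start = start, end = start + 3000, strand = rep("+", n),
    stringsAsFactors = FALSE), gaps = gaps)
}

# Enzyme annotation where `metabolic` (1-based gene indices) carry one
# unique reaction each and share pathway PWY-X.
toy_enzymes <- function(n = 10, metabolic = seq_len(n),
                        reactions = NULL, pathways = NULL) {
  ids <- sprintf("g%02d", metabolic)
  rx <- reactions %||% as.list(sprintf("RXN-%02d", metabolic))
  pw <- pathways %||% rep(list("PWY-X"), length(metabolic))
  enzyme_annotation(stats::setNames(rx, ids), stats::setNames(pw, ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random cluster-calling instance for the oracle-equivalence property:
# one chromosome of n genes, random metabolic density, random families
# drawn from a small pool (so tandem rejection is exercised), random
# reaction sharing, and optional sequencing gaps.
random_instance <- function(seed, max_genes = 200) {
  set.seed(seed)
  n <- sample(20:max_genes, 1)
  start <- cumsum(sample(500:20000, n, replace = TRUE))
  dens <- runif(1, 0.05, 0.40)
  met <- runif(n) < dens
  ids <- sprintf("g%03d", seq_len(n))
  rx <- lapply(which(met), function(i)
    sprintf("RXN-%02d", sample.int(6, sample.int(2, 1))))
  pw <- lapply(which(met), function(i) sprintf("PWY-%d", sample.int(3, 1)))
  gaps <- list()
  wide <- which(diff(start) >= 5000)
  if (runif(1) < 0.5 && length(wide) > 0) {
    at <- wide[sample.int(length(wide), 1)]
    g0 <- start[at] + 3100
    gaps <- list(chr1 = data.frame(start = g0, end = g0 + 20000))
    start[(at + 1):n] <- start[(at + 1):n] + 20000
  }
  ann <- genome_annotation(data.frame(
    gene_id = ids, chromosome_id = "chr1", start = start, end = start + 3000,
    strand = "+", stringsAsFactors = FALSE), gaps = gaps)
  fams <- stats::setNames(sprintf("fam%d", sample.int(5, n, replace = TRUE)), ids)
  list(annotation = ann,
       enzymes = enzyme_annotation(stats::setNames(rx, ids[met]),
                                   stats::setNames(pw, ids[met])),
       families = fams,
       params = cluster_params(max_intervening_nonmetabolic = sample(0:4, 1),
                               gap_break_bp = 10000))
}

# Compact signature of a cluster list for equality assertions.
cluster_signature <- function(clusters) {
  vapply(clusters, function(cl)
    sprintf("%s|%s", cl$cluster_id, paste(cl$member_gene_ids, collapse = ",")), "")
}

# Direct two-pass product-moment formula, independent of stats::cor.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}

# Small simulation scenario used by funnel/decoy tests (fast).
small_config <- function(seed, ...) {
  simulation_config(n_chromosomes = 2L, genes_per_chromosome = 150L,
                    n_true_clusters = 2L,
                    decoys = c(no_tps = 1L, no_cyp = 1L, no_copathway = 1L,
                               no_coexpression = 1L, tandem_only = 1L,
                               two_metabolic = 1L),
                    seed = seed, ...)
}
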