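# Reading, validating and writing the on-disk inputs of the pipeline:
# gene-location (glof) and gene-transcript-protein (gtpf) tables, enzyme and
# Pfam-domain tables, FPKM expression matrices, FASTA sequencing-gap scans,
# and the cluster reports (TSV/BED/JSON).

# ---- genome annotation container ------------------------------------------

#' Construct a genome annotation from a gene table
#'
#' Genes are grouped by chromosome, sorted by start coordinate (ties broken by
#' `gene_id` so ordinals are deterministic) and assigned 0-based ordinals.
#' Coordinates are stored 1-based inclusive, as in GFF3.
#'
#' @param genes data frame with columns `gene_id`, `chromosome_id`, `start`
#'   and optionally `end` (defaults to `start` when absent/NA) and `strand`
#'   (`"+"` or `"-"`, default `"+"`).
#' @param gaps named list (by chromosome) of data frames with columns
#'   `start`, `end` giving 0-based half-open sequencing-gap intervals.
#' @param genome_size_bp total assembly length in bp; when `NULL` it is
#'   estimated as the sum over chromosomes of the largest gene end.
#' @return an object of class `genome_annotation` with elements `genes`
#'   (one data frame, ordered), `gaps` and `genome_size_bp`.
#' @export
genome_annotation <- function(genes, gaps = list(), genome_size_bp = NULL) {
  required <- c("gene_id", "chromosome_id", "start")
  if (!all(required %in% names(genes)))
    stop("genes must have columns: ", paste(required, collapse = ", "), call. = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome_id <- as.character(genes$chromosome_id)
  genes$start <- as.numeric(genes$start)
  if (is.null(genes$end)) genes$end <- rep(NA_real_, nrow(genes))
  genes$end <- as.numeric(genes$end)
  if (is.null(genes$strand)) genes$strand <- rep("+", nrow(genes))
  if (nrow(genes) > 0 && !all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0)
    stop("duplicate gene_id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  bad_end <- !is.na(genes$end) & genes$end < genes$start
  if (any(bad_end))
    stop("end < start for gene(s): ",
         paste(genes$gene_id[bad_end], collapse = ", "), call. = FALSE)

  ord <- order(genes$chromosome_id, genes$start, genes$gene_id)
  genes <- genes[ord, c("gene_id", "chromosome_id", "start", "end", "strand"), drop = FALSE]
  genes$ordinal <- stats::ave(seq_len(nrow(genes)), genes$chromosome_id,
                              FUN = seq_along) - 1L
  rownames(genes) <- NULL

  gaps <- lapply(gaps, function(g) {
    g <- as.data.frame(g)
    stopifnot(all(c("start", "end") %in% names(g)))
    g <- g[order(g$start), c("start", "end"), drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop("gap intervals must be disjoint and sorted", call. = FALSE)
    rownames(g) <- NULL
    g
  })

  if (is.null(genome_size_bp)) {
    eff_end <- ifelse(is.na(genes$end), genes$start, genes$end)
    genome_size_bp <- if (nrow(genes) > 0)
      sum(tapply(eff_end, genes$chromosome_id, max)) else 0
  }
  structure(list(genes = genes, gaps = gaps, genome_size_bp = genome_size_bp),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  nchr <- length(unique(x$genes$chromosome_id))
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s), %d gap interval(s)\n",
              nrow(x$genes), nchr, sum(vapply(x$gaps, nrow, 0L))))
  invisible(x)
}

# genes of one chromosome, in ordinal order
genes_on <- function(annotation, chromosome_id) {
  g <- annotation$genes
  g[g$chromosome_id == chromosome_id, , drop = FALSE]
}

chromosome_ids <- function(annotation) unique(annotation$genes$chromosome_id)

# effective end coordinate (start when end is absent)
effective_end <- function(genes) ifelse(is.na(genes$end), genes$start, genes$end)

# ---- enzyme / domain containers -------------------------------------------

#' Construct an enzyme annotation (MetaCyc-style reaction and pathway sets)
#'
#' @param reactions named list, `gene_id` to character vector of reaction IDs.
#' @param pathways named list, `gene_id` to character vector of pathway IDs.
#' @return object of class `enzyme_annotation` with elements `reactions`,
#'   `pathways` and `n_metabolic` (count of genes with at least one reaction).
#' @export
enzyme_annotation <- function(reactions = list(), pathways = list()) {
  clean <- function(l) lapply(l, function(v) sort(unique(v[nzchar(v)])))
  reactions <- clean(reactions)
  pathways <- clean(pathways)
  n_metabolic <- sum(vapply(reactions, length, 0L) > 0)
  structure(list(reactions = reactions, pathways = pathways,
                 n_metabolic = n_metabolic),
            class = "enzyme_annotation")
}

gene_reactions <- function(enzymes, gene_id) enzymes$reactions[[gene_id]] %||% character()
gene_pathways <- function(enzymes, gene_id) enzymes$pathways[[gene_id]] %||% character()

#' Construct a Pfam domain annotation
#'
#' @param domains named list, `gene_id` to character vector of Pfam
#'   accessions (`PF` followed by five digits).
#' @return object of class `domain_annotation`.
#' @export
domain_annotation <- function(domains = list()) {
  domains <- lapply(domains, function(v) sort(unique(v[nzchar(v)])))
  bad <- unlist(domains)[!grepl("^PF[0-9]{5}$", unlist(domains))]
  if (length(bad) > 0)
    stop("malformed Pfam accession(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  structure(domains, class = "domain_annotation")
}

gene_domains <- function(domains, gene_id) {
  d <- unclass(domains)[[gene_id]]
  if (is.null(d)) character() else d
}

# ---- glof / gtpf -----------------------------------------------------------

#' Read a gene-location (glof) table
#'
#' Tab-separated, one gene per line: `gene_id`, `start`, `chromosome_id`,
#' `strand` and optionally `end` as a fifth column. Lines starting with `#`
#' are ignored.
#'
#' @param path file path.
#' @param dialect named integer vector mapping field names
#'   (`gene_id`, `start`, `chromosome`, `strand`, `end`) to column positions;
#'   set `end` to `NA` for files without an end column.
#' @return a [genome_annotation].
#' @export
read_glof <- function(path, dialect = c(gene_id = 1L, start = 2L,
                                        chromosome = 3L, strand = 4L, end = 5L)) {
  tl <- read_tsv_lines(path)
  need <- max(dialect[c("gene_id", "start", "chromosome", "strand")])
  n <- length(tl$lines)
  gene_id <- chromosome <- strand <- character(n)
  start <- end <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- split_tsv(tl$lines[i])
    if (length(f) < need)
      parse_error(path, tl$lineno[i],
                  sprintf("expected at least %d tab-separated fields, got %d",
                          need, length(f)))
    s <- suppressWarnings(as.numeric(f[dialect[["start"]]]))
    if (is.na(s) || s <= 0 || s != floor(s))
      parse_error(path, tl$lineno[i],
                  sprintf("start position '%s' is not a positive integer",
                          f[dialect[["start"]]]))
    st <- f[dialect[["strand"]]]
    if (!st %in% c("+", "-"))
      parse_error(path, tl$lineno[i], sprintf("strand '%s' not in {+, -}", st))
    gene_id[i] <- f[dialect[["gene_id"]]]
    chromosome[i] <- f[dialect[["chromosome"]]]
    start[i] <- s
    strand[i] <- st
    if (!is.na(dialect["end"]) && length(f) >= dialect[["end"]] &&
        nzchar(f[dialect[["end"]]])) {
      e <- suppressWarnings(as.numeric(f[dialect[["end"]]]))
      if (is.na(e) || e != floor(e))
        parse_error(path, tl$lineno[i],
                    sprintf("end position '%s' is not an integer", f[dialect[["end"]]]))
      end[i] <- e
    }
  }
  genome_annotation(data.frame(gene_id = gene_id, chromosome_id = chromosome,
                               start = start, end = end, strand = strand,
                               stringsAsFactors = FALSE))
}

#' Write a genome annotation back to the glof format
#'
#' @param annotation a [genome_annotation].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_glof <- function(annotation, path) {
  g <- annotation$genes
  lines <- if (all(is.na(g$end))) {
    sprintf("%s\t%d\t%s\t%s", g$gene_id, as.integer(g$start), g$chromosome_id, g$strand)
  } else {
    sprintf("%s\t%d\t%s\t%s\t%d", g$gene_id, as.integer(g$start),
            g$chromosome_id, g$strand, as.integer(effective_end(g)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-transcript-protein (gtpf) table
#'
#' Tab-separated, two columns (`gene_id`, `protein_id`) or three
#' (`gene_id`, `transcript_id`, `protein_id`). Rows are kept as given;
#' transcripts are not deduplicated.
#'
#' @param path file path.
#' @return a data frame of class `gene_protein_map` with columns
#'   `gene_id`, `transcript_id` (NA when absent) and `protein_id`.
#' @export
read_gtpf <- function(path) {
  tl <- read_tsv_lines(path)
  n <- length(tl$lines)
  gene_id <- transcript_id <- protein_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    f <- split_tsv(tl$lines[i])
    if (length(f) < 2)
      parse_error(path, tl$lineno[i], "expected 2 or 3 tab-separated fields, got 1")
    gene_id[i] <- f[1]
    if (length(f) >= 3) {
      transcript_id[i] <- f[2]
      protein_id[i] <- f[3]
    } else {
      protein_id[i] <- f[2]
    }
  }
  structure(data.frame(gene_id = gene_id, transcript_id = transcript_id,
                       protein_id = protein_id, stringsAsFactors = FALSE),
            class = c("gene_protein_map", "data.frame"))
}

#' Write a gene-protein map to the gtpf format
#' @param map a `gene_protein_map` data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_gtpf <- function(map, path) {
  lines <- ifelse(is.na(map$transcript_id),
                  sprintf("%s\t%s", map$gene_id, map$protein_id),
                  sprintf("%s\t%s\t%s", map$gene_id, map$transcript_id, map$protein_id))
  writeLines(lines, path)
  invisible(path)
}

#' Check that glof and gtpf describe the same gene set
#'
#' The pipeline requires the gene counts of the two files to be synchronized;
#' this returns a non-fatal report listing genes present in only one input.
#'
#' @param annotation a [genome_annotation].
#' @param map a `gene_protein_map` from [read_gtpf()].
#' @return list with `pass` (logical), `only_in_annotation`, `only_in_map`.
#' @export
validate_gene_counts <- function(annotation, map) {
  a <- unique(annotation$genes$gene_id)
  b <- unique(map$gene_id)
  res <- list(pass = setequal(a, b),
              only_in_annotation = sort(setdiff(a, b)),
              only_in_map = sort(setdiff(b, a)))
  class(res) <- "tgc_validation"
  res
}

#' @export
print.tgc_validation <- function(x, ...) {
  cat("gene-count validation:", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$only_in_annotation))
    cat("  only in annotation:", paste(x$only_in_annotation, collapse = ", "), "\n")
  if (length(x$only_in_map))
    cat("  only in gene-protein map:", paste(x$only_in_map, collapse = ", "), "\n")
  invisible(x)
}

# ---- GFF3 / FASTA ----------------------------------------------------------

#' Build a genome annotation from a GFF3 file
#'
#' Selects features of `feature_type` and takes the gene identifier from
#' `id_attribute`. GFF3 1-based inclusive coordinates are preserved as-is.
#'
#' @param path GFF3 file path.
#' @param feature_type GFF3 `type` to select (default `"gene"`).
#' @param id_attribute attribute holding the gene identifier (default `"ID"`).
#' @return a [genome_annotation].
#' @export
convert_gff3_to_glof <- function(path, feature_type = "gene", id_attribute = "ID") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0)
    return(genome_annotation(data.frame(gene_id = character(),
                                        chromosome_id = character(),
                                        start = numeric())))
  ids <- S4Vectors::mcols(gr)[[id_attribute]]
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  if (anyNA(ids)) {
    miss <- which(is.na(ids))[1]
    lines <- readLines(path, warn = FALSE)
    pat <- sprintf("^%s\t[^\t]*\t%s\t%d\t",
                   as.character(GenomicRanges::seqnames(gr))[miss],
                   feature_type, GenomicRanges::start(gr)[miss])
    ln <- grep(pat, lines)[1]
    stop(sprintf("%s: line %s: %s feature at %s:%d lacks attribute '%s'",
                 path, ifelse(is.na(ln), "?", ln), feature_type,
                 as.character(GenomicRanges::seqnames(gr))[miss],
                 GenomicRanges::start(gr)[miss], id_attribute), call. = FALSE)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  genome_annotation(data.frame(
    gene_id = as.character(ids),
    chromosome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE))
}

#' Locate sequencing gaps (runs of N) in a genome FASTA
#'
#' Assemblies encode sequencing gaps as runs of the letter N; cluster calling
#' must not span them. Returns, per sequence, the maximal runs of `N`/`n` of
#' length at least `min_gap_bp` as 0-based half-open intervals.
#'
#' @param fasta FASTA file path (sequence names are truncated at whitespace).
#' @param min_gap_bp minimum run length to report, default 100.
#' @return named list of data frames with columns `start`, `end`.
#' @export
find_sequencing_gaps <- function(fasta, min_gap_bp = 100L) {
  stopifnot(min_gap_bp >= 1)
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  out <- lapply(seq_along(seqs), function(i) {
    s <- toupper(as.character(seqs[[i]]))
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1) return(data.frame(start = numeric(), end = numeric()))
    w <- attr(m, "match.length")
    keep <- w >= min_gap_bp
    data.frame(start = as.numeric(m[keep]) - 1,
               end = as.numeric(m[keep]) - 1 + w[keep])
  })
  names(out) <- names(seqs)
  out
}

# ---- enzyme / domain / expression tables ------------------------------------

#' Read an enzyme annotation table
#'
#' Tab-separated with columns `gene_id`, semicolon-joined reaction IDs,
#' semicolon-joined pathway IDs (either list may be empty). A gene is
#' "metabolic" when it has at least one reaction ID.
#'
#' @param path file path.
#' @return an [enzyme_annotation].
#' @export
read_enzyme_annotation <- function(path) {
  tl <- read_tsv_lines(path)
  reactions <- list()
  pathways <- list()
  split_ids <- function(x) {
    v <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    v[nzchar(v)]
  }
  for (i in seq_along(tl$lines)) {
    f <- split_tsv(tl$lines[i], min_fields = 3L)
    if (!nzchar(f[1])) parse_error(path, tl$lineno[i], "empty gene_id")
    g <- f[1]
    reactions[[g]] <- c(reactions[[g]], split_ids(f[2]))
    pathways[[g]] <- c(pathways[[g]], split_ids(f[3]))
  }
  enzyme_annotation(reactions, pathways)
}

#' Write an enzyme annotation table
#' @param enzymes an [enzyme_annotation].
#' @param path output file path.
#' @param gene_ids optional gene order; defaults to the annotated genes, sorted.
#' @return the path, invisibly.
#' @export
write_enzyme_annotation <- function(enzymes, path, gene_ids = NULL) {
  if (is.null(gene_ids))
    gene_ids <- sort(union(names(enzymes$reactions), names(enzymes$pathways)))
  lines <- vapply(gene_ids, function(g) {
    sprintf("%s\t%s\t%s", g,
            paste(gene_reactions(enzymes, g), collapse = ";"),
            paste(gene_pathways(enzymes, g), collapse = ";"))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pfam domain table
#'
#' Tab-separated with columns `gene_id`, Pfam accession (one accession per
#' row, as in an InterProScan TSV subset).
#'
#' @param path file path.
#' @return a [domain_annotation].
#' @export
read_domain_table <- function(path) {
  tl <- read_tsv_lines(path)
  out <- list()
  for (i in seq_along(tl$lines)) {
    f <- split_tsv(tl$lines[i])
    if (length(f) < 2)
      parse_error(path, tl$lineno[i], "expected 2 tab-separated fields")
    if (!grepl("^PF[0-9]{5}$", f[2]))
      parse_error(path, tl$lineno[i],
                  sprintf("malformed Pfam accession '%s'", f[2]))
    out[[f[1]]] <- c(out[[f[1]]], f[2])
  }
  domain_annotation(out)
}

#' Write a Pfam domain table
#' @param domains a [domain_annotation].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  d <- unclass(domains)
  genes <- sort(names(d))
  lines <- unlist(lapply(genes, function(g) sprintf("%s\t%s", g, d[[g]])),
                  use.names = FALSE)
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Read a genes-by-samples FPKM expression matrix
#'
#' Tab-separated; header row `gene_id` followed by sample identifiers, then
#' one row per gene. Values must be non-negative.
#'
#' @param path file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(path, ": expression table needs a gene column and at least one sample", call. = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop(path, ": duplicate gene_id(s) in expression matrix", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(path, ": non-numeric or missing expression values", call. = FALSE)
  if (any(m < 0)) stop(path, ": negative expression values", call. = FALSE)
  rownames(m) <- genes
  m
}

#' Write a genes-by-samples expression matrix
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

# ---- cluster reports --------------------------------------------------------

#' Flatten a cluster list into a report data frame
#'
#' @param clusters list of gene clusters from [find_candidate_clusters()],
#'   optionally carrying screening flags from [run_funnel()].
#' @return data frame, one row per cluster (zero-row with the full header
#'   when `clusters` is empty).
#' @export
clusters_to_df <- function(clusters) {
  base_cols <- data.frame(
    cluster_id = character(), chromosome_id = character(),
    first_ordinal = integer(), last_ordinal = integer(),
    start_bp = numeric(), end_bp = numeric(), span_bp = numeric(),
    n_genes = integer(), n_metabolic = integer(),
    member_gene_ids = character(), metabolic_gene_ids = character(),
    reaction_ids = character(), pathway_ids = character(),
    has_tps = logical(), has_cyp = logical(), tps_cyp_pass = logical(),
    copathway_pass = logical(), copathway_evidence = character(),
    coexpress_pass = logical(), coexpress_evidence = character(),
    coexpress_r = numeric(), quality = logical(), reason = character(),
    stringsAsFactors = FALSE)
  if (length(clusters) == 0) return(base_cols)
  rows <- lapply(clusters, function(cl) {
    fl <- cl$flags %||% list()
    ev_cp <- fl$copathway_evidence
    ev_ce <- fl$coexpress_evidence
    data.frame(
      cluster_id = cl$cluster_id, chromosome_id = cl$chromosome_id,
      first_ordinal = cl$first_ordinal, last_ordinal = cl$last_ordinal,
      start_bp = cl$start_bp, end_bp = cl$end_bp, span_bp = cl$span_bp,
      n_genes = length(cl$member_gene_ids),
      n_metabolic = length(cl$metabolic_gene_ids),
      member_gene_ids = paste(cl$member_gene_ids, collapse = ","),
      metabolic_gene_ids = paste(cl$metabolic_gene_ids, collapse = ","),
      reaction_ids = join_set(cl$reaction_ids),
      pathway_ids = join_set(cl$pathway_ids),
      has_tps = fl$has_tps %||% NA,
      has_cyp = fl$has_cyp %||% NA,
      tps_cyp_pass = fl$tps_cyp_pass %||% NA,
      copathway_pass = fl$copathway_pass %||% NA,
      copathway_evidence = if (is.null(ev_cp)) "" else
        sprintf("%s|%s|%s", ev_cp$gene_a, ev_cp$gene_b,
                paste(ev_cp$shared_pathways, collapse = ";")),
      coexpress_pass = fl$coexpress_pass %||% NA,
      coexpress_evidence = if (is.null(ev_ce)) "" else
        sprintf("%s|%s", ev_ce$gene_a, ev_ce$gene_b),
      coexpress_r = if (is.null(ev_ce)) NA_real_ else ev_ce$r,
      quality = fl$quality %||% NA,
      reason = fl$reason %||% "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise within-cluster correlation matrices (heat-map export)
#'
#' @param clusters list of gene clusters.
#' @param expr expression matrix (genes x samples).
#' @param params a [coexpression_params()]; controls the transform.
#' @return named list (by cluster_id) of correlation matrices over the
#'   cluster's expressed member genes.
#' @export
cluster_correlation_matrices <- function(clusters, expr, params = coexpression_params()) {
  te <- transform_expression(expr, params$transform)
  out <- lapply(clusters, function(cl) {
    genes <- intersect(cl$member_gene_ids, rownames(te))
    if (length(genes) < 2) return(NULL)
    stats::cor(t(te[genes, , drop = FALSE]))
  })
  names(out) <- vapply(clusters, function(cl) cl$cluster_id, "")
  out[!vapply(out, is.null, TRUE)]
}

#' Write the cluster report files
#'
#' Writes `clusters.tsv` (one row per cluster with screening flags),
#' `clusters.bed` (0-based half-open cluster spans), `funnel.json` (stage
#' counts), `stats.json` (span/gene-count summaries) and, when an expression
#' matrix is supplied, one `cor_<cluster_id>.tsv` per cluster for heat maps.
#' All outputs are byte-identical across reruns on identical inputs.
#'
#' @param clusters list of gene clusters (with or without flags).
#' @param funnel named stage counts from [run_funnel()], or `NULL`.
#' @param stats a `cluster_stats` object from [summarize_clusters()], or `NULL`.
#' @param out_dir output directory (created if needed).
#' @param expr optional expression matrix for per-cluster correlation exports.
#' @param params [coexpression_params()] used for the correlation transform.
#' @return character vector of written file paths, invisibly.
#' @export
write_cluster_report <- function(clusters, funnel = NULL, stats = NULL, out_dir,
                                 expr = NULL, params = coexpression_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  df <- clusters_to_df(clusters)
  p <- file.path(out_dir, "clusters.tsv")
  write_tsv_file(df, p)
  written <- c(written, p)

  p <- file.path(out_dir, "clusters.bed")
  bed <- sprintf("%s\t%d\t%d\t%s", df$chromosome_id,
                 as.integer(df$start_bp) - 1L, as.integer(df$end_bp), df$cluster_id)
  writeLines(bed, p)
  written <- c(written, p)

  if (!is.null(funnel)) {
    p <- file.path(out_dir, "funnel.json")
    jsonlite::write_json(as.list(funnel), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }
  if (!is.null(stats)) {
    p <- file.path(out_dir, "stats.json")
    jsonlite::write_json(unclass(stats), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }
  if (!is.null(expr)) {
    mats <- cluster_correlation_matrices(clusters, expr, params)
    for (id in names(mats)) {
      p <- file.path(out_dir, sprintf("cor_%s.tsv", gsub("[^A-Za-z0-9._-]", "_", id)))
      m <- mats[[id]]
      write_tsv_file(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                     p)
      written <- c(written, p)
    }
  }
  invisible(written)
}
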