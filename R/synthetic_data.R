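# Synthetic study generator: chromosomes of ordered genes with sparse
# metabolic annotation, planted TPS+CYP clusters sharing a pathway,
# stage-specific decoy clusters, tandem arrays, sequencing gaps, and FPKM
# expression matrices with controlled intra-cluster Pearson correlation.
# Emits a ground-truth manifest for recovery scoring.

#' Planted-cluster layout
#'
#' Metabolic members are laid out in an interleaved TPS/CYP/other order with
#' runs of non-metabolic genes between consecutive metabolic members.
#'
#' @param n_tps number of TPS genes (>= 1 for true clusters).
#' @param n_cyp number of CYP genes (>= 1 for true clusters).
#' @param n_other_metabolic other enzyme-annotated members.
#' @param intervening_runs non-metabolic run lengths between consecutive
#'   metabolic members (length `n_met - 1`); default one gene between each.
#' @return object of class `planted_cluster_spec`.
#' @export
planted_cluster_spec <- function(n_tps = 2L, n_cyp = 2L, n_other_metabolic = 2L,
                                 intervening_runs = NULL) {
  n_met <- n_tps + n_cyp + n_other_metabolic
  stopifnot(n_met >= 1)
  if (is.null(intervening_runs)) intervening_runs <- rep(1L, max(0L, n_met - 1L))
  stopifnot(length(intervening_runs) == n_met - 1, all(intervening_runs >= 0))
  structure(list(n_tps = as.integer(n_tps), n_cyp = as.integer(n_cyp),
                 n_other_metabolic = as.integer(n_other_metabolic),
                 intervening_runs = as.integer(intervening_runs)),
            class = "planted_cluster_spec")
}

#' Simulation configuration
#'
#' Defaults define the standard benchmark scenario: 3 chromosomes of 300
#' genes, 5 true (quality) clusters, 2 decoys per class, intra-cluster
#' correlation rho = 0.9 over 30 samples.
#'
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes per chromosome.
#' @param intergenic_bp_mean mean intergenic distance in bp (exponential).
#' @param gene_length_bp_range uniform range of gene lengths in bp.
#' @param background_metabolic_density probability that a background gene is
#'   enzyme-annotated.
#' @param n_true_clusters number of planted quality clusters.
#' @param true_cluster_spec a [planted_cluster_spec()] for true clusters.
#' @param decoys named integer vector of decoy counts per class
#'   (`no_tps`, `no_cyp`, `no_copathway`, `no_coexpression`, `tandem_only`,
#'   `two_metabolic`).
#' @param gaps_per_chromosome sequencing gaps inserted per chromosome
#'   (in intergenic background regions).
#' @param gap_length_bp length of each inserted gap.
#' @param n_samples expression samples (>= 3).
#' @param rho_intra target within-cluster Pearson correlation on the log2
#'   scale, in `[0, 1)`.
#' @param noise_sd log2-scale standard deviation of the latent factor and
#'   noise.
#' @param baseline_log2 log2-scale mean expression.
#' @param assumed_k K assumed when spacing planted clusters and thinning
#'   background metabolic runs (match the caller's K; default 5).
#' @param seed mandatory RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 3L, genes_per_chromosome = 300L,
                              intergenic_bp_mean = 8000,
                              gene_length_bp_range = c(2000, 5000),
                              background_metabolic_density = 0.10,
                              n_true_clusters = 5L,
                              true_cluster_spec = planted_cluster_spec(),
                              decoys = c(no_tps = 2L, no_cyp = 2L,
                                         no_copathway = 2L, no_coexpression = 2L,
                                         tandem_only = 2L, two_metabolic = 2L),
                              gaps_per_chromosome = 1L, gap_length_bp = 50000,
                              n_samples = 30L, rho_intra = 0.9, noise_sd = 1,
                              baseline_log2 = 5, assumed_k = 5L, seed) {
  if (missing(seed) || is.null(seed)) stop("simulation seed is mandatory", call. = FALSE)
  stopifnot(n_chromosomes >= 1, genes_per_chromosome >= 10,
            background_metabolic_density >= 0, background_metabolic_density <= 1,
            rho_intra >= 0, rho_intra < 1, n_samples >= 3, noise_sd > 0)
  known <- c("no_tps", "no_cyp", "no_copathway", "no_coexpression",
             "tandem_only", "two_metabolic")
  full <- stats::setNames(integer(length(known)), known)
  full[names(decoys)] <- as.integer(decoys)
  if (!all(names(decoys) %in% known))
    stop("unknown decoy class(es): ",
         paste(setdiff(names(decoys), known), collapse = ", "), call. = FALSE)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 intergenic_bp_mean = intergenic_bp_mean,
                 gene_length_bp_range = gene_length_bp_range,
                 background_metabolic_density = background_metabolic_density,
                 n_true_clusters = as.integer(n_true_clusters),
                 true_cluster_spec = true_cluster_spec,
                 decoys = full,
                 gaps_per_chromosome = as.integer(gaps_per_chromosome),
                 gap_length_bp = gap_length_bp,
                 n_samples = as.integer(n_samples), rho_intra = rho_intra,
                 noise_sd = noise_sd, baseline_log2 = baseline_log2,
                 assumed_k = as.integer(assumed_k), seed = as.integer(seed)),
            class = "simulation_config")
}

# ---- block descriptors ------------------------------------------------------

# Role layouts per block class; roles are TPS / CYP / OTH (generic metabolic)
# and TDM (tandem copy of one family).
block_roles <- function(fate, spec) {
  switch(fate,
    quality = {
      roles <- c(rep("TPS", spec$n_tps), rep("CYP", spec$n_cyp),
                 rep("OTH", spec$n_other_metabolic))
      # interleave so signature genes are spread across the cluster
      roles[order(seq_along(roles) %% 3, seq_along(roles))]
    },
    no_tps = c("CYP", "OTH", "CYP", "OTH"),
    no_cyp = c("TPS", "OTH", "TPS", "OTH"),
    no_copathway = c("TPS", "CYP", "OTH", "OTH"),
    no_coexpression = c("TPS", "CYP", "OTH"),
    tandem_only = c("TDM", "TDM", "TDM"),
    two_metabolic = c("TPS", "CYP"),
    stop("unknown block fate: ", fate, call. = FALSE))
}

# Build the list of planted blocks (true clusters first, then decoys).
plan_blocks <- function(config) {
  blocks <- list()
  add <- function(fate, spec = NULL) {
    idx <- length(blocks) + 1L
    roles <- block_roles(fate, spec %||% config$true_cluster_spec)
    n_met <- length(roles)
    runs <- if (fate == "quality" && !is.null(spec))
      spec$intervening_runs else rep(1L, max(0L, n_met - 1L))
    blocks[[idx]] <<- list(label = sprintf("B%02d", idx), fate = fate,
                           roles = roles, intervening_runs = runs,
                           n_genes = n_met + sum(runs),
                           shared_pathway = fate != "no_copathway",
                           correlated = fate != "no_coexpression")
  }
  for (i in seq_len(config$n_true_clusters)) add("quality", config$true_cluster_spec)
  for (fate in names(config$decoys))
    for (i in seq_len(config$decoys[[fate]])) add(fate)
  blocks
}

# ---- genome generation ------------------------------------------------------

#' Generate a synthetic annotated genome with planted clusters
#'
#' Deterministic given `config$seed`. True clusters satisfy all four
#' structural criteria and carry TPS+CYP signatures plus a shared pathway
#' with distinct reactions; each decoy violates exactly its designated
#' stage. Background genes are enzyme-annotated with probability
#' `background_metabolic_density`; background runs that could themselves be
#' called (>= 3 metabolic genes within K) are thinned deterministically and
#' the count recorded.
#'
#' @param config a [simulation_config()].
#' @return list of class `tgc_genome_sim` with elements `annotation`,
#'   `enzymes`, `domains`, `families`, `manifest` (ground-truth data frame),
#'   `gene_protein_map` and `config`.
#' @export
generate_genome <- function(config) {
  with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  n <- config$genes_per_chromosome
  buffer <- config$assumed_k + 3L
  blocks <- plan_blocks(config)
  # round-robin assignment of blocks to chromosomes
  chr_of <- rep(seq_len(config$n_chromosomes), length.out = length(blocks))
  genes_rows <- list()
  reactions <- list(); pathways <- list(); domains <- list()
  manifest_rows <- list()
  generic_pool <- sprintf("PF09%03d", 1:500)
  thinned <- 0L
  gaps <- list()

  for (c_i in seq_len(config$n_chromosomes)) {
    chr <- sprintf("chr%02d", c_i)
    ids <- sprintf("%s_g%04d", chr, seq_len(n))
    # per-gene role table for this chromosome
    role <- rep("BG", n)
    block_of <- rep(NA_integer_, n)
    my_blocks <- which(chr_of == c_i)
    m <- length(my_blocks)
    if (m > 0) {
      seg_len <- n %/% m
      for (q in seq_along(my_blocks)) {
        b <- blocks[[my_blocks[q]]]
        lo <- (q - 1L) * seg_len + buffer + 1L
        hi <- q * seg_len - buffer - b$n_genes
        if (hi < lo)
          stop("unsatisfiable simulation config: planted cluster of ",
               b$n_genes, " genes does not fit on chromosome ", chr, call. = FALSE)
        pos <- sample(lo:hi, 1L)
        # lay out roles with intervening non-metabolic genes
        layout <- character(0)
        for (k in seq_along(b$roles)) {
          layout <- c(layout, b$roles[k])
          if (k < length(b$roles))
            layout <- c(layout, rep("IVN", b$intervening_runs[k]))
        }
        span <- pos:(pos + length(layout) - 1L)
        role[span] <- layout
        block_of[span] <- my_blocks[q]
      }
    }
    # background metabolic assignment, cleared near planted blocks
    bg <- which(role == "BG")
    met_bg <- bg[stats::runif(length(bg)) < config$background_metabolic_density]
    planted_idx <- which(!is.na(block_of))
    if (length(planted_idx) > 0 && length(met_bg) > 0) {
      near <- vapply(met_bg, function(i) any(abs(i - planted_idx) <= buffer), TRUE)
      met_bg <- met_bg[!near]
    }
    # thin background runs that could satisfy the metabolic-count criterion
    met_flag <- rep(FALSE, n)
    met_flag[met_bg] <- TRUE
    repeat {
      pos_met <- which(met_flag)
      if (length(pos_met) < 3) break
      runs <- split(pos_met, cumsum(c(0L, diff(pos_met) - 1 > config$assumed_k)))
      long <- Filter(function(r) length(r) >= 3, runs)
      if (length(long) == 0) break
      for (r in long) {
        mid <- r[ceiling(length(r) / 2)]
        met_flag[mid] <- FALSE
        thinned <- thinned + 1L
      }
    }
    met_bg <- which(met_flag)

    # coordinates
    intergap <- round(stats::rexp(n, 1 / config$intergenic_bp_mean)) + 200
    glen <- round(stats::runif(n, config$gene_length_bp_range[1],
                               config$gene_length_bp_range[2]))
    start <- cumsum(c(intergap[1] + 1, intergap[-1] + glen[-n] + 1))
    end <- start + glen - 1
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # sequencing gaps in background intergenic positions
    chr_gaps <- data.frame(start = numeric(), end = numeric())
    if (config$gaps_per_chromosome > 0) {
      eligible <- which(role[-n] == "BG" & role[-1] == "BG")
      eligible <- eligible[eligible > buffer & eligible < n - buffer]
      take <- sort(eligible[sample.int(length(eligible),
                                       min(config$gaps_per_chromosome, length(eligible)))])
      for (g_at in take) {
        L <- config$gap_length_bp
        shift <- seq_len(n) > g_at
        gap_start0 <- end[g_at] + 100  # 0-based; gap occupies [start, start+L)
        start[shift] <- start[shift] + L
        end[shift] <- end[shift] + L
        chr_gaps <- rbind(chr_gaps,
                          data.frame(start = gap_start0, end = gap_start0 + L))
      }
    }
    gaps[[chr]] <- chr_gaps[order(chr_gaps$start), , drop = FALSE]

    # annotations per gene
    for (i in seq_len(n)) {
      g <- ids[i]
      b_idx <- block_of[i]
      r <- role[i]
      if (!is.na(b_idx) && r != "IVN") {
        b <- blocks[[b_idx]]
        j <- sum(!is.na(block_of[1:i]) & block_of[1:i] == b_idx & role[1:i] != "IVN")
        reactions[[g]] <- sprintf("RXN-S%03d-%02d", b_idx, j)
        pathways[[g]] <- if (b$shared_pathway) sprintf("PWY-S%03d", b_idx)
                         else sprintf("PWY-D%03d-%02d", b_idx, j)
        domains[[g]] <- switch(r,
          TPS = if (j %% 2 == 1) "PF01397" else "PF03936",
          CYP = "PF00067",
          OTH = generic_pool[(b_idx * 10 + j) %% length(generic_pool) + 1L],
          TDM = "PF08392")
      } else if (is.na(b_idx) && i %in% met_bg) {
        reactions[[g]] <- sprintf("RXN-B%s", g)
        pathways[[g]] <- sprintf("PWY-B%03d", sample.int(40, 1))
        if (stats::runif(1) < 0.5)
          domains[[g]] <- generic_pool[sample.int(length(generic_pool), 1)]
      } else if (is.na(b_idx) && stats::runif(1) < 0.3) {
        domains[[g]] <- generic_pool[sample.int(length(generic_pool), 1)]
      }
    }

    genes_rows[[chr]] <- data.frame(gene_id = ids, chromosome_id = chr,
                                    start = start, end = end, strand = strand,
                                    stringsAsFactors = FALSE)
    # manifest entries for this chromosome's blocks
    for (b_i in my_blocks) {
      span <- which(!is.na(block_of) & block_of == b_i)
      members <- ids[span]
      met_members <- ids[span[role[span] != "IVN"]]
      manifest_rows[[length(manifest_rows) + 1L]] <- data.frame(
        label = blocks[[b_i]]$label, fate = blocks[[b_i]]$fate,
        chromosome_id = chr,
        first_ordinal = span[1] - 1L, last_ordinal = span[length(span)] - 1L,
        gene_ids = paste(members, collapse = ","),
        metabolic_gene_ids = paste(met_members, collapse = ","),
        correlated = blocks[[b_i]]$correlated,
        stringsAsFactors = FALSE)
    }
  }

  genes <- do.call(rbind, genes_rows)
  rownames(genes) <- NULL
  annotation <- genome_annotation(genes, gaps = gaps)
  enzymes <- enzyme_annotation(reactions, pathways)
  dom <- domain_annotation(domains)
  manifest <- if (length(manifest_rows) > 0) do.call(rbind, manifest_rows) else
    data.frame(label = character(), fate = character(),
               chromosome_id = character(), first_ordinal = integer(),
               last_ordinal = integer(), gene_ids = character(),
               metabolic_gene_ids = character(), correlated = logical(),
               stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$label), , drop = FALSE]
  rownames(manifest) <- NULL
  gpm <- structure(data.frame(gene_id = genes$gene_id,
                              transcript_id = paste0("t.", genes$gene_id),
                              protein_id = paste0("p.", genes$gene_id),
                              stringsAsFactors = FALSE),
                   class = c("gene_protein_map", "data.frame"))
  structure(list(annotation = annotation, enzymes = enzymes, domains = dom,
                 families = assign_families_by_pfam_proxy(dom, genes$gene_id),
                 manifest = manifest, gene_protein_map = gpm,
                 background_runs_thinned = thinned, config = config),
            class = "tgc_genome_sim")
}

#' @export
print.tgc_genome_sim <- function(x, ...) {
  cat(sprintf("synthetic genome: %d genes, %d chromosomes, %d planted blocks (%d quality)\n",
              nrow(x$annotation$genes), x$config$n_chromosomes,
              nrow(x$manifest), sum(x$manifest$fate == "quality")))
  invisible(x)
}

# ---- expression generation --------------------------------------------------

#' Generate an FPKM expression matrix with planted correlation structure
#'
#' On the log2 scale each gene of a correlated planted block follows
#' `baseline + sqrt(rho) * f_c + sqrt(1 - rho) * eps`, with a per-block
#' latent sample profile `f_c` and independent noise `eps` of equal
#' variance, so the expected within-block Pearson correlation is `rho`.
#' Background genes and `no_coexpression` decoy genes are independent
#' draws; `no_coexpression` blocks are redrawn (bounded retries, count in
#' attribute `resampled_blocks`) until no within-block pair exceeds
#' r = 0.35 on the log2 scale, so spurious correlation cannot mimic a
#' passing cluster. Values are mapped to FPKM as `2^x - 1`, clipped at 0.
#'
#' @param annotation a [genome_annotation] from [generate_genome()].
#' @param manifest the ground-truth manifest from the same simulation.
#' @param config the [simulation_config()] used.
#' @return numeric FPKM matrix (genes x samples), attribute
#'   `resampled_blocks`.
#' @export
generate_expression <- function(annotation, manifest, config) {
  with_seed(config$seed + 1L, generate_expression_impl(annotation, manifest, config))
}

generate_expression_impl <- function(annotation, manifest, config) {
  ids <- annotation$genes$gene_id
  ns <- config$n_samples
  rho <- config$rho_intra
  sdv <- config$noise_sd
  x <- matrix(stats::rnorm(length(ids) * ns, 0, sdv), nrow = length(ids),
              dimnames = list(ids, sprintf("sample%02d", seq_len(ns))))
  resampled <- 0L
  for (q in seq_len(nrow(manifest))) {
    members <- strsplit(manifest$gene_ids[q], ",", fixed = TRUE)[[1]]
    rows <- match(members, ids)
    if (manifest$correlated[q] && rho > 0) {
      f <- stats::rnorm(ns, 0, sdv)
      x[rows, ] <- sqrt(rho) * matrix(f, length(rows), ns, byrow = TRUE) +
        sqrt(1 - rho) * matrix(stats::rnorm(length(rows) * ns, 0, sdv),
                               length(rows), ns)
    } else if (!manifest$correlated[q]) {
      # independent draws, resampled away from spurious correlation
      for (try in seq_len(50L)) {
        block <- matrix(stats::rnorm(length(rows) * ns, 0, sdv), length(rows), ns)
        z <- standardize_rows(block)
        pr <- pair_from_index(seq_len(n_pairs(length(rows))), length(rows))
        if (max(pair_correlations(z, pr)) < 0.35) break
        resampled <- resampled + 1L
      }
      x[rows, ] <- block
    }
  }
  fpkm <- pmax(2^(x + config$baseline_log2) - 1, 0)
  attr(fpkm, "resampled_blocks") <- resampled
  fpkm
}

#' Generate a complete synthetic study (genome + expression)
#'
#' @param config a [simulation_config()].
#' @return the `tgc_genome_sim` list with an added `expression` element.
#' @export
simulate_study <- function(config) {
  sim <- generate_genome(config)
  sim$expression <- generate_expression(sim$annotation, sim$manifest, config)
  sim
}

# ---- recovery scoring -------------------------------------------------------

#' Score called clusters against the planted ground truth
#'
#' A called cluster matches a planted one when the Jaccard overlap of their
#' gene-id sets is at least `min_jaccard`; matching is one-to-one greedy by
#' descending overlap. With `scope = "quality"` only quality-fate planted
#' clusters count as truth (for scoring the full funnel); with
#' `scope = "all"` every planted block counts (for scoring the raw caller).
#'
#' @param called list of gene clusters (e.g. quality clusters).
#' @param manifest ground-truth manifest from [generate_genome()].
#' @param min_jaccard matching threshold, default 0.5.
#' @param scope `"quality"` or `"all"`.
#' @return list with `precision`, `recall`, `f1`, `n_called`, `n_truth` and
#'   a `matches` data frame (truth label, called cluster id, jaccard).
#' @export
score_recovery <- function(called, manifest, min_jaccard = 0.5,
                           scope = c("quality", "all")) {
  scope <- match.arg(scope)
  truth <- if (scope == "quality")
    manifest[manifest$fate == "quality", , drop = FALSE] else manifest
  truth_sets <- lapply(strsplit(truth$gene_ids, ",", fixed = TRUE), unique)
  called_sets <- lapply(called, function(cl) unique(cl$member_gene_ids))
  nt <- length(truth_sets); nc <- length(called_sets)
  jac <- matrix(0, nrow = nt, ncol = nc)
  for (i in seq_len(nt)) for (j in seq_len(nc)) {
    a <- truth_sets[[i]]; b <- called_sets[[j]]
    jac[i, j] <- length(intersect(a, b)) / length(union(a, b))
  }
  matches <- data.frame(truth_label = character(), called_cluster_id = character(),
                        jaccard = numeric(), stringsAsFactors = FALSE)
  used_t <- logical(nt); used_c <- logical(nc)
  while (TRUE) {
    jj <- jac
    jj[used_t, ] <- -1
    jj[, used_c] <- -1
    if (length(jj) == 0 || max(jj) < min_jaccard) break
    w <- which(jj == max(jj), arr.ind = TRUE)[1, ]
    used_t[w[1]] <- TRUE; used_c[w[2]] <- TRUE
    matches <- rbind(matches, data.frame(
      truth_label = truth$label[w[1]],
      called_cluster_id = called[[w[2]]]$cluster_id,
      jaccard = jac[w[1], w[2]], stringsAsFactors = FALSE))
  }
  n_matched <- nrow(matches)
  precision <- if (nc == 0) 1 else n_matched / nc
  recall <- if (nt == 0) 1 else n_matched / nt
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_called = nc, n_truth = nt, matches = matches)
}

# ---- on-disk emission -------------------------------------------------------

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Writes `glof.txt`, `gtpf.txt`, `enzymes.tsv`, `domains.tsv`,
#' `families.tsv`, `expression.tsv` and `truth.json`; optionally a genome
#' FASTA with the planted sequencing gaps as runs of N.
#'
#' @param sim result of [simulate_study()] (or [generate_genome()] plus an
#'   `expression` element).
#' @param out_dir output directory (created if needed).
#' @param write_fasta also write `genome.fa` (random sequence with N-gaps);
#'   off by default because the file is large.
#' @return character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, out_dir, write_fasta = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    glof = file.path(out_dir, "glof.txt"),
    gtpf = file.path(out_dir, "gtpf.txt"),
    enzymes = file.path(out_dir, "enzymes.tsv"),
    domains = file.path(out_dir, "domains.tsv"),
    families = file.path(out_dir, "families.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_glof(sim$annotation, paths["glof"])
  write_gtpf(sim$gene_protein_map, paths["gtpf"])
  write_enzyme_annotation(sim$enzymes, paths["enzymes"],
                          gene_ids = sim$annotation$genes$gene_id)
  write_domain_table(sim$domains, paths["domains"])
  write_tsv_file(data.frame(gene_id = names(sim$families),
                            family_id = unname(sim$families),
                            stringsAsFactors = FALSE), paths["families"])
  write_expression(sim$expression, paths["expression"])
  jsonlite::write_json(sim$manifest, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (write_fasta) {
    fa <- file.path(out_dir, "genome.fa")
    seqs <- with_seed(sim$config$seed + 2L, {
      lapply(chromosome_ids(sim$annotation), function(chr) {
        g <- genes_on(sim$annotation, chr)
        len <- max(effective_end(g)) + 1000
        s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        gp <- sim$annotation$gaps[[chr]]
        if (!is.null(gp)) for (q in seq_len(nrow(gp)))
          s[(gp$start[q] + 1):gp$end[q]] <- "N"
        paste(s, collapse = "")
      })
    })
    names(seqs) <- chromosome_ids(sim$annotation)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)), fa)
    paths <- c(paths, fasta = fa)
  }
  invisible(paths)
}
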