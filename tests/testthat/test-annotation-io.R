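# Readers, writers and validation of the on-disk formats.

test_that("read_glof parses rows, sorts by start and assigns ordinals", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "g1\t500\tchr1\t+", "g2\t100\tchr1\t-",
               "g3\t300\tchr1\t+", "g4\t50\tchr2\t+"), p)
  ann <- read_glof(p)
  chr1 <- ann$genes[ann$genes$chromosome_id == "chr1", ]
  expect_equal(chr1$gene_id, c("g2", "g3", "g1"))
  expect_equal(chr1$start, c(100, 300, 500))
  expect_equal(chr1$ordinal, 0:2)
  expect_equal(chr1$strand, c("-", "+", "+"))
  expect_true(all(is.na(chr1$end)))
  expect_equal(ann$genes$ordinal[ann$genes$gene_id == "g4"], 0L)
})

test_that("read_glof handles the optional end column and empty files", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines("g1\t1000\tchr1\t+\t2500", p)
  ann <- read_glof(p)
  expect_equal(ann$genes$end, 2500)
  writeLines(character(), p)
  expect_equal(nrow(read_glof(p)$genes), 0L)
})

test_that("read_glof rejects malformed rows with line numbers and duplicates", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("g1\t100\tchr1\t+", "g2\tabc\tchr1\t+"), p)
  expect_error(read_glof(p), "line 2.*positive integer")
  writeLines(c("g1\t100\tchr1\t+", "g2\t200\tchr1\t*"), p)
  expect_error(read_glof(p), "strand")
  writeLines(c("g1\t100\tchr1"), p)
  expect_error(read_glof(p), "line 1.*fields")
  writeLines(c("g1\t100\tchr1\t+", "g1\t200\tchr1\t+"), p)
  expect_error(read_glof(p), "duplicate")
})

test_that("ordinal ties on start are broken by gene id", {
  ann <- genome_annotation(data.frame(
    gene_id = c("b", "a"), chromosome_id = "chr1", start = c(100, 100)))
  expect_equal(ann$genes$gene_id[ann$genes$ordinal == 0], "a")
})

test_that("read_gtpf dispatches on column count and rejects 1-column rows", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("g1\tt1\tp1", "g2\tp2"), p)
  m <- read_gtpf(p)
  expect_equal(m$transcript_id, c("t1", NA))
  expect_equal(m$protein_id, c("p1", "p2"))
  writeLines("only_gene", p)
  expect_error(read_gtpf(p), "2 or 3")
  writeLines(character(), p)
  expect_equal(nrow(read_gtpf(p)), 0L)
})

test_that("validate_gene_counts reports asymmetric differences", {
  ann <- toy_annotation(3)
  map <- data.frame(gene_id = c("g01", "g02", "g03"),
                    transcript_id = NA, protein_id = "p")
  expect_true(validate_gene_counts(ann, map)$pass)
  expect_true(validate_gene_counts(toy_annotation(0), map[0, ])$pass)
  ann4 <- toy_annotation(4)
  v <- validate_gene_counts(ann4, map)
  expect_false(v$pass)
  expect_equal(v$only_in_annotation, "g04")
  expect_equal(v$only_in_map, character(0))
})

test_that("convert_gff3_to_glof selects features, keeps 1-based coordinates and sorts", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=m1;Parent=g1",
               "chr1\tsrc\tgene\t50\t80\t.\t-\t.\tID=g2"), p)
  ann <- convert_gff3_to_glof(p)
  expect_equal(ann$genes$gene_id, c("g2", "g1"))
  expect_equal(ann$genes$start, c(50, 100))
  expect_equal(ann$genes$end, c(80, 900))
  expect_equal(ann$genes$ordinal, 0:1)
  # mRNA-only file with feature_type = gene -> empty
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=m1"), p)
  expect_equal(nrow(convert_gff3_to_glof(p)$genes), 0L)
  # missing ID attribute is an error naming the location
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tName=x"), p)
  expect_error(convert_gff3_to_glof(p), "lacks attribute")
})

test_that("find_sequencing_gaps reports maximal N-runs above threshold", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGTNNNNNACGT",
               ">chr2", "ACGTACGT", ">chr3", "NNNN"), p)
  gaps <- find_sequencing_gaps(p, min_gap_bp = 5)
  expect_equal(gaps$chr1, data.frame(start = 4, end = 9))
  expect_equal(nrow(gaps$chr2), 0L)
  expect_equal(nrow(gaps$chr3), 0L)  # run of 4 < 5
  gaps1 <- find_sequencing_gaps(p, min_gap_bp = 1)
  expect_equal(gaps1$chr3, data.frame(start = 0, end = 4))
})

test_that("sequencing-gap intervals match a per-character oracle on random strings", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(50:2000, 1)
    s <- paste(sample(c("A", "C", "G", "T", "N", "n"), n, replace = TRUE,
                      prob = c(rep(0.2, 4), 0.1, 0.1)), collapse = "")
    min_gap <- sample(1:4, 1)
    p <- tempfile(fileext = ".fa")
    writeLines(c(">s", s), p)
    got <- find_sequencing_gaps(p, min_gap_bp = min_gap)$s
    # oracle: position-by-position scan
    isN <- strsplit(toupper(s), "")[[1]] == "N"
    covered <- rep(FALSE, n)
    r <- rle(isN)
    ends <- cumsum(r$lengths)
    for (q in which(r$values & r$lengths >= min_gap))
      covered[(ends[q] - r$lengths[q] + 1):ends[q]] <- TRUE
    got_cov <- rep(FALSE, n)
    for (q in seq_len(nrow(got))) got_cov[(got$start[q] + 1):got$end[q]] <- TRUE
    expect_identical(got_cov, covered)
    if (nrow(got) > 1) {
      expect_true(all(diff(got$start) > 0))
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    }
    expect_true(all(got$end - got$start >= min_gap))
    unlink(p)
  }
})

test_that("enzyme, domain and expression tables parse and validate", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tRXN-1;RXN-2\tPWY-A", "g2\t\t", "g3\tRXN-3\tPWY-A;PWY-B"), p)
  enz <- read_enzyme_annotation(p)
  expect_setequal(enz$reactions$g1, c("RXN-1", "RXN-2"))
  expect_equal(enz$pathways$g1, "PWY-A")
  expect_false(is_metabolic("g2", enz))
  expect_equal(enz$n_metabolic, 2L)

  writeLines(c("g3\tPF00067", "g3\tPF01397", "g4\tPF99999"), p)
  dom <- read_domain_table(p)
  expect_equal(unclass(dom)$g3, c("PF00067", "PF01397"))
  writeLines("g5\tPFAM1", p)
  expect_error(read_domain_table(p), "malformed Pfam")

  m <- matrix(c(0, 1.5, 2, 3), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  write_expression(m, p)
  expect_equal(read_expression(p), m)
  writeLines(c("gene_id\ts1", "g1\t-1"), p)
  expect_error(read_expression(p), "negative")
})

test_that("glof, enzyme, domain and expression tables round-trip", {
  sim <- generate_genome(simulation_config(n_chromosomes = 1L,
                                           genes_per_chromosome = 60L,
                                           n_true_clusters = 1L,
                                           decoys = c(no_tps = 1L), seed = 11))
  d <- withr::local_tempdir()
  write_glof(sim$annotation, file.path(d, "glof.txt"))
  back <- read_glof(file.path(d, "glof.txt"))
  expect_equal(back$genes[, c("gene_id", "start", "end", "strand", "ordinal")],
               sim$annotation$genes[, c("gene_id", "start", "end", "strand", "ordinal")])
  # idempotence of write/read on ordinals and coordinates
  write_glof(back, file.path(d, "glof2.txt"))
  expect_identical(readLines(file.path(d, "glof.txt")),
                   readLines(file.path(d, "glof2.txt")))

  write_enzyme_annotation(sim$enzymes, file.path(d, "enz.tsv"))
  enz2 <- read_enzyme_annotation(file.path(d, "enz.tsv"))
  expect_equal(enz2$reactions[order(names(enz2$reactions))],
               sim$enzymes$reactions[order(names(sim$enzymes$reactions))])
  expect_equal(enz2$n_metabolic, sim$enzymes$n_metabolic)

  write_domain_table(sim$domains, file.path(d, "dom.tsv"))
  dom2 <- read_domain_table(file.path(d, "dom.tsv"))
  expect_equal(unclass(dom2)[order(names(unclass(dom2)))],
               unclass(sim$domains)[order(names(unclass(sim$domains)))])
})

test_that("cluster reports: empty input, funnel keys, BED convention", {
  d <- withr::local_tempdir()
  write_cluster_report(list(), funnel = c(raw = 4, tps_cyp = 3, copathway = 2,
                                          coexpress = 1, quality = 1),
                       out_dir = d)
  tsv <- read.delim(file.path(d, "clusters.tsv"))
  expect_equal(nrow(tsv), 0L)
  expect_true(all(c("cluster_id", "span_bp", "quality") %in% names(tsv)))
  fj <- jsonlite::read_json(file.path(d, "funnel.json"))
  expect_equal(names(fj), c("raw", "tps_cyp", "copathway", "coexpress", "quality"))

  ann <- toy_annotation(5, spacing = 1000)
  ann$genes$start <- c(1000, 2000, 3000, 4000, 5000)
  ann$genes$end <- c(1400, 2400, 3400, 4400, 5000)
  enz <- toy_enzymes(5, metabolic = c(1, 3, 5),
                     reactions = list("RXN-1", "RXN-2", "RXN-3"))
  cl <- find_candidate_clusters(ann, enz)
  expect_length(cl, 1)
  write_cluster_report(cl, out_dir = d)
  bed <- readLines(file.path(d, "clusters.bed"))
  expect_equal(strsplit(bed, "\t")[[1]][1:3], c("chr1", "999", "5000"))
})
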