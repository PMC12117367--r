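# Screening stages: signatures, copathway, coexpression, quality, funnel.

test_that("classify_signature follows the Pfam signature rules", {
  dom <- domain_annotation(list(g1 = "PF01397", g2 = "PF00067",
                                g3 = "PF00001", g4 = c("PF01397", "PF00067"),
                                g5 = "PF03936"))
  expect_equal(classify_signature("g1", dom), "TPS")
  expect_equal(classify_signature("g5", dom), "TPS")
  expect_equal(classify_signature("g2", dom), "CYP")
  expect_equal(classify_signature("g3", dom), character(0))
  expect_setequal(classify_signature("g4", dom), c("TPS", "CYP"))
  expect_equal(classify_signature("absent", dom), character(0))
})

test_that("TPS+CYP stage requires both signatures in a cluster", {
  ann <- toy_annotation(6)
  enz <- toy_enzymes(6, metabolic = c(1, 2, 3))
  fams <- stats::setNames(sprintf("fam%d", 1:6), sprintf("g%02d", 1:6))
  cl <- find_candidate_clusters(ann, enz, fams)
  dom_both <- domain_annotation(list(g01 = "PF01397", g02 = "PF00067"))
  dom_tps <- domain_annotation(list(g01 = "PF01397"))
  expect_true(filter_tps_cyp(cl, dom_both)[[1]]$flags$tps_cyp_pass)
  f <- filter_tps_cyp(cl, dom_tps)[[1]]$flags
  expect_true(f$has_tps); expect_false(f$has_cyp); expect_false(f$tps_cyp_pass)
  expect_length(filter_tps_cyp(list(), dom_both), 0)
})

test_that("copathway stage needs a shared pathway and distinct reaction sets", {
  ann <- toy_annotation(3)
  fams <- stats::setNames(sprintf("fam%d", 1:3), sprintf("g%02d", 1:3))
  mk <- function(rx, pw) {
    enz <- toy_enzymes(3, reactions = rx, pathways = pw)
    cl <- find_candidate_clusters(ann, enz, fams)
    filter_copathway(cl, enz)[[1]]$flags
  }
  # shared pathway, distinct reactions -> pass, first pair as evidence
  f <- mk(list("RXN-1", "RXN-2", "RXN-3"),
          list("PWY-X", "PWY-X", "PWY-Y"))
  expect_true(f$copathway_pass)
  expect_equal(f$copathway_evidence$gene_a, "g01")
  expect_equal(f$copathway_evidence$gene_b, "g02")
  expect_equal(f$copathway_evidence$shared_pathways, "PWY-X")
  # identical reaction sets -> that pair does not qualify
  f2 <- mk(list("RXN-1", "RXN-1", "RXN-2"),
           list("PWY-X", "PWY-X", "PWY-Z"))
  expect_false(f2$copathway_pass)
  # disjoint pathways -> fail
  f3 <- mk(list("RXN-1", "RXN-2", "RXN-3"),
           list("PWY-X", "PWY-Y", "PWY-Z"))
  expect_false(f3$copathway_pass)
})

test_that("pearson_r matches hand-checked values and signals constant vectors", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 7)), 15 / sqrt(228), tolerance = 1e-12)
  expect_true(is.na(pearson_r(c(1, 1, 1), x)))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("pearson_r agrees with a direct two-pass formula on random pairs", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_lt(abs(pearson_r(x, y) - pearson_oracle(x, y)), 1e-12)
  }
})

test_that("background threshold uses nearest-rank over enumerated pairs", {
  # 20 genes -> 190 pairs, all enumerated; r* is the 189th order statistic
  set.seed(5)
  m <- matrix(2^rnorm(20 * 12, 5), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:12)))
  pars <- coexpression_params(percentile = 99, background_pairs = 1000, seed = 1)
  rstar <- background_threshold(m, pars)
  expect_true(attr(rstar, "enumerated"))
  expect_equal(attr(rstar, "n_pairs_used"), 190L)
  lm2 <- log2(m + 1)
  allr <- sort(apply(t(combn(20, 2)), 1, function(p)
    pearson_oracle(lm2[p[1], ], lm2[p[2], ])))
  expect_equal(as.numeric(rstar), allr[ceiling(0.99 * 190)], tolerance = 1e-12)
  # p = 50 on the same background equals the nearest-rank median
  pars50 <- coexpression_params(percentile = 50, background_pairs = 1000, seed = 1)
  expect_equal(as.numeric(background_threshold(m, pars50)),
               allr[ceiling(0.5 * 190)], tolerance = 1e-12)
  # degenerate background: all pairs share the same r exactly
  v <- 2^seq(1, 12)
  md <- matrix(rep(v, each = 4), nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
  md <- md * matrix(2^runif(4), 4, 12)  # scale rows; log2 keeps r = 1
  expect_equal(as.numeric(background_threshold(log2(md), coexpression_params(
    transform = "raw_fpkm", background_pairs = 1000))), 1, tolerance = 1e-9)
})

test_that("nearest-rank leaves at most ceil(1%) of pairs strictly above r*", {
  set.seed(6)
  m <- matrix(2^rnorm(60 * 10, 5), nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:10)))
  pars <- coexpression_params(percentile = 99, background_pairs = 2000, seed = 2)
  rstar <- background_threshold(m, pars)
  lm2 <- log2(m + 1)
  allr <- apply(t(combn(60, 2)), 1, function(p)
    pearson_oracle(lm2[p[1], ], lm2[p[2], ]))
  expect_lte(sum(allr > as.numeric(rstar)), ceiling(0.01 * length(allr)))
})

test_that("coexpression stage passes on a strong TPS-CYP pair and records evidence", {
  ann <- toy_annotation(4)
  enz <- toy_enzymes(4)
  fams <- stats::setNames(sprintf("fam%d", 1:4), sprintf("g%02d", 1:4))
  cl <- find_candidate_clusters(ann, enz, fams)
  dom <- domain_annotation(list(g01 = "PF01397", g03 = "PF00067"))
  set.seed(8)
  base <- rnorm(10)
  expr <- rbind(g01 = 2^(5 + base), g03 = 2^(5 + base + rnorm(10, 0, 0.05)),
                g02 = 2^rnorm(10, 5), g04 = 2^rnorm(10, 5))
  colnames(expr) <- sprintf("s%02d", 1:10)
  pars <- coexpression_params(background_pairs = 1000, seed = 3)
  out <- filter_coexpression(cl, expr, dom, pars, r_star = 0.95)[[1]]$flags
  expect_true(out$coexpress_pass)
  expect_setequal(c(out$coexpress_evidence$gene_a, out$coexpress_evidence$gene_b),
                  c("g01", "g03"))
  expect_gte(out$coexpress_evidence$r, 0.95)
  # threshold above the best pair -> fail
  out2 <- filter_coexpression(cl, expr, dom, pars, r_star = 0.9999)[[1]]$flags
  expect_false(out2$coexpress_pass)
  # TPS gene absent from the matrix under the TPS-CYP rule -> reasoned failure
  out3 <- filter_coexpression(cl, expr[c("g02", "g03", "g04"), ], dom, pars,
                              r_star = 0.5)[[1]]$flags
  expect_false(out3$coexpress_pass)
  expect_equal(out3$reason, "insufficient expression data")
  # any_pair rule accepts a non-signature pair
  pars_any <- coexpression_params(background_pairs = 1000, seed = 3,
                                  pair_rule = "any_pair")
  out4 <- filter_coexpression(cl, expr, domain_annotation(list()), pars_any,
                              r_star = 0.95)[[1]]$flags
  expect_true(out4$coexpress_pass)
})

test_that("quality designation requires a terpene-linked copathway pathway", {
  ann <- toy_annotation(3)
  enz <- toy_enzymes(3)
  fams <- stats::setNames(sprintf("fam%d", 1:3), sprintf("g%02d", 1:3))
  cl <- find_candidate_clusters(ann, enz, fams)
  cl <- filter_copathway(cl, enz)
  cl[[1]]$flags$coexpress_pass <- TRUE
  expect_true(designate_quality(cl, enz, "PWY-X")[[1]]$flags$quality)
  expect_false(designate_quality(cl, enz, "PWY-OTHER")[[1]]$flags$quality)
  cl[[1]]$flags$coexpress_pass <- FALSE
  expect_false(designate_quality(cl, enz, "PWY-X")[[1]]$flags$quality)
  expect_error(designate_quality(cl, enz, character(0)), "empty")
})

test_that("default terpene pathways are those of TPS-classified genes", {
  dom <- domain_annotation(list(g1 = "PF01397", g2 = "PF00067"))
  enz <- enzyme_annotation(reactions = list(g1 = "RXN-1", g2 = "RXN-2"),
                           pathways = list(g1 = c("PWY-T1", "PWY-T2"),
                                           g2 = "PWY-C"))
  expect_equal(default_terpene_pathways(dom, enz), c("PWY-T1", "PWY-T2"))
})

test_that("the funnel nests stages in order on a constructed scenario", {
  # 5 clusters: 1 full quality, then one failing each successive stage
  ann <- toy_annotation(25)
  ids <- sprintf("g%02d", 1:25)
  fams <- stats::setNames(sprintf("fam%d", 1:25), ids)
  starts <- c(1, 6, 11, 16, 21)
  rx <- list(); pw <- list(); dom <- list()
  for (q in seq_along(starts)) {
    trio <- ids[starts[q] + 0:2]
    for (k in 1:3) rx[[trio[k]]] <- sprintf("RXN-%d-%d", q, k)
    shared <- q != 5  # cluster 5 fails copathway
    for (k in 1:3) pw[[trio[k]]] <- if (shared) sprintf("PWY-%d", q)
                                    else sprintf("PWY-%d-%d", q, k)
    if (q != 4) {  # cluster 4 fails the TPS+CYP stage (TPS only)
      dom[[trio[1]]] <- "PF01397"; dom[[trio[2]]] <- "PF00067"
    } else dom[[trio[1]]] <- "PF01397"
  }
  enz <- enzyme_annotation(rx, pw)
  dom <- domain_annotation(dom)
  cl <- find_candidate_clusters(ann, enz, fams,
                                cluster_params(max_intervening_nonmetabolic = 1))
  expect_length(cl, 5)
  set.seed(10)
  f <- rnorm(12)
  expr <- matrix(2^rnorm(25 * 12, 5), 25, 12, dimnames = list(ids, paste0("s", 1:12)))
  correlated <- c(1, 2)  # clusters 3 fails coexpression; 1 and 2 pass
  for (q in correlated)
    expr[starts[q] + 0:2, ] <- 2^(5 + matrix(f, 3, 12, byrow = TRUE) +
                                    matrix(rnorm(36, 0, 0.1), 3, 12))
  # cluster 2's shared pathway is stripped from the terpene set -> not quality
  terpene <- "PWY-1"
  res <- run_funnel(cl, dom, enz, expr,
                    params = coexpression_params(background_pairs = 1000, seed = 4),
                    terpene_pathway_ids = terpene, r_star = 0.95)
  expect_equal(unname(res$funnel), c(5, 4, 3, 2, 1))
  expect_true(all(diff(res$funnel) <= 0))
  expect_equal(res$quality_clusters[[1]]$member_gene_ids, ids[1:3])
  # later-stage flags stay NA for clusters eliminated earlier
  flags4 <- res$clusters[[4]]$flags
  expect_false(flags4$tps_cyp_pass)
  expect_null(flags4$copathway_pass)
})

test_that("the funnel handles an empty cluster list", {
  res <- run_funnel(list(), domain_annotation(list()),
                    enzyme_annotation(), matrix(0, 0, 0))
  expect_equal(unname(res$funnel), c(0, 0, 0, 0, 0))
})

test_that("screening is invariant under consistent gene relabeling", {
  sim <- simulate_study(small_config(31))
  relabel <- function(x) chartr("g", "x", x)
  ann2 <- sim$annotation
  ann2$genes$gene_id <- relabel(ann2$genes$gene_id)
  ann2 <- genome_annotation(ann2$genes, gaps = ann2$gaps)
  ren <- function(l) stats::setNames(l, relabel(names(l)))
  enz2 <- enzyme_annotation(ren(sim$enzymes$reactions), ren(sim$enzymes$pathways))
  dom2 <- domain_annotation(ren(unclass(sim$domains)))
  fam2 <- stats::setNames(unname(sim$families), relabel(names(sim$families)))
  expr2 <- sim$expression
  rownames(expr2) <- relabel(rownames(expr2))

  pars <- coexpression_params(background_pairs = 20000, seed = 5)
  f1 <- run_funnel(find_candidate_clusters(sim$annotation, sim$enzymes,
                                           sim$families),
                   sim$domains, sim$enzymes, sim$expression, pars)
  f2 <- run_funnel(find_candidate_clusters(ann2, enz2, fam2),
                   dom2, enz2, expr2, pars)
  expect_equal(f1$funnel, f2$funnel)
  expect_equal(f1$r_star, f2$r_star)
})

test_that("raising the percentile never increases coexpression survivors", {
  sim <- simulate_study(small_config(32))
  cl <- find_candidate_clusters(sim$annotation, sim$enzymes, sim$families)
  passed <- vapply(c(50, 90, 99, 99.9), function(p) {
    pars <- coexpression_params(percentile = p, background_pairs = 20000, seed = 6)
    f <- run_funnel(cl, sim$domains, sim$enzymes, sim$expression, pars)
    unname(f$funnel["coexpress"])
  }, 0)
  expect_true(all(diff(passed) <= 0))
})

test_that("cluster summaries use midpoint medians and inclusive bands", {
  mk <- function(span_bp, n_genes) {
    list(cluster_id = "c", chromosome_id = "chr1", first_ordinal = 0,
         last_ordinal = n_genes - 1,
         member_gene_ids = sprintf("m%d", seq_len(n_genes)),
         metabolic_gene_ids = character(), reaction_ids = character(),
         pathway_ids = character(), start_bp = 1, end_bp = span_bp,
         span_bp = span_bp, flags = NULL)
  }
  st <- summarize_clusters(list(mk(50000, 4), mk(90000, 18), mk(300000, 20)))
  expect_equal(st$median_span_kb, 90)
  expect_equal(st$fraction_span_lt_300kb, 2 / 3)
  expect_equal(st$fraction_gene_count_3_18, 2 / 3)
  expect_equal(st$fraction_span_in_33_284kb, 2 / 3)
  st1 <- summarize_clusters(list(mk(72000, 5)))
  expect_equal(st1$median_span_kb, 72)
  st0 <- summarize_clusters(list())
  expect_equal(st0$n, 0L)
  expect_true(is.na(st0$median_span_kb))
  # even n -> midpoint rule
  st2 <- summarize_clusters(list(mk(40000, 4), mk(80000, 6)))
  expect_equal(st2$median_span_kb, 60)
})

test_that("fpkm_from_counts implements the FPKM formula", {
  expect_equal(fpkm_from_counts(0, 2000, 1e6), 0)
  expect_equal(fpkm_from_counts(10, 2000, 1e6), 5)
  expect_equal(fpkm_from_counts(10, 2000, 2e6), 2.5)
  expect_error(fpkm_from_counts(10, 0, 1e6), "positive")
  expect_error(fpkm_from_counts(10, 2000, 0), "positive")
  expect_error(fpkm_from_counts(-1, 2000, 1e6), "non-negative")
})
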