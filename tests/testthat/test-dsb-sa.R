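test_that("graph extension applies the per-event factors", {
  p <- toy_sa_params()
  r <- graph_root(p)
  nd <- extend_graph_node(r, "d", p, a = "A")
  expect_equal(nd$s_x, "A"); expect_equal(nd$s_y, "")
  expect_equal(nd$p_joint, p$q_deletion * unname(p$p_d["A"]))
  ni <- extend_graph_node(r, "i", p, b = "G")
  expect_equal(ni$p_joint, p$q_insertion * unname(p$p_i["G"]))
  nm <- extend_graph_node(r, "m", p, a = "A", b = "C")
  expect_equal(nm$p_joint, p$q_match * unname(p$p_m["A", "C"]))
  expect_error(extend_graph_node(r, "m", p, a = "A"), "y base")
  expect_error(extend_graph_node(r, "d", p, a = "N"), "x base")
  rp <- r; rp$status <- "pruned"
  expect_error(extend_graph_node(rp, "d", p, a = "A"), "pruned")
})

test_that("merging the three predecessor orders equals the pair DP", {
  p <- toy_sa_params()
  r <- graph_root(p)
  via_m <- extend_graph_node(r, "m", p, a = "A", b = "C")
  via_di <- extend_graph_node(extend_graph_node(r, "d", p, a = "A"),
                              "i", p, b = "C")
  via_id <- extend_graph_node(extend_graph_node(r, "i", p, b = "C"),
                              "d", p, a = "A")
  merged <- merge_graph_nodes(list(via_m, via_di, via_id))
  expect_equal(log(merged$p_joint), sa_joint_probability(p, "A", "C"),
               tolerance = 1e-12)
  expect_error(merge_graph_nodes(list(via_m, extend_graph_node(r, "d", p, a = "A"))),
               "share")
})

test_that("graph node masses equal the pair-prefix DP recomputed from scratch", {
  # no pruning and no early acceptance: every node's merged mass must be the
  # full prefix DP value
  p <- sa_params_dna(0.1, 0.12, 0.08)
  idx <- suppressWarnings(build_graph(p, build_config(
    max_depth = 6, accept_ratio = Inf, final_accept_ratio = 0,
    prune_threshold = 0), alpha_sims = 100, seed = 1))
  b <- idx$buckets
  expect_gt(nrow(b), 100)
  for (k in sample(nrow(b), 50)) {
    expect_equal(log(b$p_joint[k]),
                 sa_joint_probability(p, b$s_x[k], b$s_y[k]),
                 tolerance = 1e-12)
  }
})

test_that("with q_insertion = q_deletion = 0 the graph reduces to the tree", {
  pm <- matrix(0.01, 4, 4); diag(pm) <- 0.21
  pm <- pm / sum(pm)
  psa <- sa_params(pm, rep(0.25, 4), rep(0.25, 4), 1, 0, 0)
  # induced pair-emission HMM: one hidden state emitting from p_m
  phmm <- hmm_params("s", c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                     1, matrix(1, 1, 1), array(pm, c(4, 4, 1)))
  g <- suppressWarnings(build_graph(psa, build_config(
    max_depth = 8, accept_ratio = 4, final_accept_ratio = 1,
    prune_threshold = 1e-6), alpha_sims = 100, seed = 1))
  t <- suppressWarnings(build_tree(phmm, build_config(
    max_depth = 4, accept_ratio = 4, final_accept_ratio = 1,
    prune_threshold = 1e-6)))
  gk <- sort(paste(g$buckets$s_x, g$buckets$s_y))
  tk <- sort(paste(t$buckets$s_x, t$buckets$s_y))
  expect_identical(gk, tk)
})

test_that("indel-tolerant buckets appear and clear the enrichment ratio", {
  pm <- matrix(0.05 / 12, 4, 4); diag(pm) <- 0.95 / 4
  p <- sa_params(pm, rep(0.25, 4), rep(0.25, 4), 0.8, 0.1, 0.1)
  idx <- suppressWarnings(build_graph(p, build_config(
    max_depth = 10, accept_ratio = 4, prune_threshold = 1e-8),
    alpha_sims = 100, seed = 1))
  uneq <- idx$buckets[idx$buckets$len_x != idx$buckets$len_y]
  expect_gt(nrow(uneq), 0)
  k <- which.max(uneq$p_joint)
  dp <- exp(sa_joint_probability(p, uneq$s_x[k], uneq$s_y[k]))
  expect_gte(dp / (uneq$p_x[k] * uneq$p_y[k]), 4)
})

test_that("an over-aggressive prune threshold empties the graph", {
  p <- sa_params_dna(0.05, 0.1, 0.1)
  expect_error(suppressWarnings(build_graph(p, build_config(
    max_depth = 6, accept_ratio = 4,
    prune_threshold = p$q_match * max(p$p_m) + 1e-9), alpha_sims = 100)),
    "index empty")
})

test_that("alpha estimation respects coverage limits and union bounds", {
  p <- sa_params_dna(0.1, 0.1, 0.1)
  # every depth-1 node accepted: any non-empty pair shares a bucket
  idx1 <- suppressWarnings(build_graph(p, build_config(
    max_depth = 1, accept_ratio = 0, final_accept_ratio = 0,
    prune_threshold = 0), alpha_sims = 200, seed = 2))
  expect_gte(idx1$alpha, 0.99)
  # sandwich: estimate within union bounds up to Monte-Carlo error
  idx <- suppressWarnings(build_graph(p, build_config(
    max_depth = 8, accept_ratio = 16, final_accept_ratio = 16),
    alpha_sims = 400, seed = 3))
  est <- estimate_alpha(idx, p, n_sim = 400, seed = 4)
  lo <- max(idx$buckets$p_joint); hi <- sum(idx$buckets$p_joint)
  expect_gte(est$alpha, lo - 3 * est$se - 1e-9)
  expect_lte(est$alpha, hi + 3 * est$se)
  expect_error(estimate_alpha(idx, p, n_sim = 50), "n_sim")
})

test_that("per-axis mapping handles unequal-length bucket strings", {
  idx <- manual_index(s_x = c("AC", "GG"), s_y = c("C", "GGT"),
                      alphabet = c("A", "C", "G", "T"), type = "sa")
  expect_true(1L %in% map_sequence_sa(idx, "ACGTACGT", "x", 1))
  expect_true(1L %in% map_sequence_sa(idx, "CTGA", "y", 1))
  expect_false(2L %in% map_sequence_sa(idx, "ACGTACGT", "x", 1))
  # literal scan agreement across bands
  p <- sa_params_dna(0.1, 0.1, 0.1)
  built <- suppressWarnings(build_graph(p, build_config(
    max_depth = 8, accept_ratio = 16, final_accept_ratio = 8),
    alpha_sims = 100, seed = 5))
  for (seed in 1:4) {
    sq <- rand_seq(20, c("A", "C", "G", "T"), seed)
    for (j in c(1, 5, 12)) {
      expect_setequal(map_sequence_sa(built, sq, "x", j),
                      scan_map(built, sq, "x", j))
      expect_setequal(map_sequence_sa(built, sq, "y", j),
                      scan_map(built, sq, "y", j))
    }
  }
})

test_that("windowed LLR finds embedded reads and rejects background", {
  p <- sa_params_dna(0.05, 0.05, 0.05)
  set.seed(9)
  genome <- rand_seq(4000, c("A", "C", "G", "T"), 9)
  read <- substr(genome, 1501, 2100)
  expect_gt(sa_llr_window(p, substr(genome, 1301, 2300), read), 0)
  decoy <- rand_seq(600, c("A", "C", "G", "T"), 99)
  expect_lt(sa_llr_window(p, substr(genome, 1301, 2300), decoy), 0)
})

test_that("read search recovers exact copies and reports sound scores", {
  p <- sa_params_dna(0.02, 0.02, 0.02)
  idx <- suppressWarnings(build_graph(p, build_config(
    max_depth = 14, accept_ratio = 256, final_accept_ratio = 256,
    prune_threshold = 1e-10), alpha_sims = 200, seed = 6))
  set.seed(31)
  genome <- c(ref1 = rand_seq(8000, c("A", "C", "G", "T"), 31))
  reads <- setNames(vapply(1:5, function(i)
    substr(genome, 1000 * i, 1000 * i + 499), ""), paste0("rd", 1:5))
  res <- dsb_sa_search(idx, genome, reads, p)
  expect_setequal(unique(res$hits$query_id), names(reads))
  expect_true(all(res$hits$score > 0))
  expect_true(all(res$hits$strand == "+"))
  # hit windows contain the true origins
  for (i in 1:5) {
    h <- res$hits[res$hits$query_id == paste0("rd", i), ]
    expect_true(any(h$ref_start <= 1000 * i - 1 & h$ref_end >= 1000 * i + 499))
  }
  # soundness: scores equal the windowed LLR recomputed from coordinates
  for (r in seq_len(nrow(res$hits))) {
    h <- res$hits[r, ]
    win <- substr(genome[[h$ref_id]], h$ref_start + 1, h$ref_end)
    rd <- reads[[h$query_id]]
    if (h$strand == "-") rd <- dsbucket:::revcomp(rd)
    expect_equal(h$score, sa_llr_window(p, win, rd))
  }
})

test_that("reverse-complemented reads are found on the minus strand, reversed reads nowhere", {
  p <- sa_params_dna(0.02, 0.02, 0.02)
  idx <- suppressWarnings(build_graph(p, build_config(
    max_depth = 14, accept_ratio = 256, final_accept_ratio = 256,
    prune_threshold = 1e-10), alpha_sims = 200, seed = 6))
  set.seed(77)
  genome <- c(ref1 = rand_seq(6000, c("A", "C", "G", "T"), 77))
  fwd <- substr(genome, 2001, 2600)
  reads <- c(rc = dsbucket:::revcomp(fwd),
             rev = paste(rev(strsplit(fwd, "")[[1]]), collapse = ""))
  res <- dsb_sa_search(idx, genome, reads, p)
  rc_hits <- res$hits[res$hits$query_id == "rc", ]
  expect_gt(nrow(rc_hits), 0)
  expect_true(all(rc_hits$strand == "-"))
  expect_equal(nrow(res$hits[res$hits$query_id == "rev", ]), 0L)
})

test_that("relaxing the final accept threshold never loses recovered reads", {
  p <- sa_params_dna(0.1, 0.09, 0.09)
  cfg_hi <- build_config(max_depth = 14, accept_ratio = Inf,
                         final_accept_ratio = 1024, prune_threshold = 1e-10)
  cfg_lo <- build_config(max_depth = 14, accept_ratio = Inf,
                         final_accept_ratio = 256, prune_threshold = 1e-10)
  idx_hi <- suppressWarnings(build_graph(p, cfg_hi, alpha_sims = 200, seed = 8))
  idx_lo <- suppressWarnings(build_graph(p, cfg_lo, alpha_sims = 200, seed = 8))
  keys <- function(i) paste(i$buckets$s_x, i$buckets$s_y)
  expect_true(all(keys(idx_hi) %in% keys(idx_lo)))  # bucket superset
  sim <- make_genome_reads(20000, 30, mean_len = 400, total_error = 0.3,
                           seed = 21)
  hits_hi <- dsb_sa_search(idx_hi, sim$reference, sim$reads, p,
                           min_votes = 10, max_candidates = 50)
  hits_lo <- dsb_sa_search(idx_lo, sim$reference, sim$reads, p,
                           min_votes = 10, max_candidates = 50)
  rec <- function(h) unique(h$hits$query_id[h$hits$score >= 0])
  expect_true(all(rec(hits_hi) %in% rec(hits_lo)))
})

test_that("exact-match ablation keeps only symmetric buckets", {
  p <- sa_params_dna(0.1, 0.09, 0.09)
  idx <- suppressWarnings(build_graph(p, build_config(
    max_depth = 12, accept_ratio = 64, final_accept_ratio = 64,
    prune_threshold = 1e-10), alpha_sims = 200, seed = 4))
  abl <- ablate_exact_buckets(idx, p, alpha_sims = 200, seed = 4)
  expect_true(all(abl$buckets$s_x == abl$buckets$s_y))
  expect_lte(nrow(abl$buckets), nrow(idx$buckets))
  expect_lte(abl$beta, idx$beta)
})
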