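test_that("extend_node advances prefixes, probabilities and backgrounds", {
  mu <- hmm_binary_model(0.25, 0.3)
  r <- tree_root(mu)
  ch <- extend_node(r, "0", "1", mu)
  expect_equal(ch$p_joint, 0.25)       # uniform emissions
  expect_equal(ch$s_x, "0"); expect_equal(ch$s_y, "1")
  m <- hmm_binary_model(0.1, 0.2)
  n <- extend_node(extend_node(tree_root(m), "0", "0", m), "1", "0", m)
  expect_equal(n$p_joint, exp(enum_hmm_joint(m, "01", "00")), tolerance = 1e-12)
  expect_equal(n$p_x, 0.25); expect_equal(n$p_y, 0.25)
  expect_error(extend_node(tree_root(m), "2", "0", m), "unknown x symbol")
  pr <- tree_root(m); pr$status <- "pruned"
  expect_error(extend_node(pr, "0", "0", m), "pruned")
})

test_that("children conserve and never exceed the parent joint mass", {
  m <- hmm_binary_model(0.1, 0.2)
  nodes <- list(tree_root(m))
  for (d in 1:4) {
    nxt <- list()
    for (v in nodes) {
      kids <- list()
      for (a in c("0", "1")) for (b in c("0", "1"))
        kids[[paste0(a, b)]] <- extend_node(v, a, b, m)
      expect_equal(sum(vapply(kids, `[[`, 0, "p_joint")), v$p_joint,
                   tolerance = 1e-12)
      expect_true(all(vapply(kids, `[[`, 0, "p_joint") <= v$p_joint + 1e-15))
      nxt <- c(nxt, kids)
    }
    nodes <- nxt[seq_len(min(8, length(nxt)))]  # keep the walk tractable
  }
})

test_that("the complete depth-1 tree is the brute-force-equivalent limit", {
  m <- hmm_binary_model(0.1, 0.2)
  idx <- build_tree(m, build_config(max_depth = 1, accept_ratio = 0,
                                    prune_threshold = 0))
  expect_equal(nrow(idx$buckets), 4L)
  s <- tree_stats(idx)
  expect_equal(unname(s["alpha"]), 1)
  expect_equal(unname(s["beta"]), 1)
  expect_equal(unname(s["gamma_x"]), 2)
  expect_equal(unname(s["gamma_y"]), 2)
})

test_that("an over-aggressive prune threshold empties the index", {
  m <- hmm_binary_model(0.1, 0.2)
  expect_error(
    build_tree(m, build_config(max_depth = 3, prune_threshold = 0.9)),
    "index empty")
})

test_that("build_tree reproduces an independent accept/prune/branch recursion", {
  m <- hmm_binary_model(0.05, 0.05)
  cfg <- build_config(max_depth = 6, accept_ratio = 4, prune_threshold = 1e-4)
  idx <- suppressWarnings(build_tree(m, cfg))
  # independent recursion: explicit node objects, no layer vectorisation
  found <- list()
  recurse <- function(node) {
    if (node$depth > 0) {
      if (node$p_joint < 1e-4) return()
      ratio <- node$p_joint / (node$p_x * node$p_y)
      accept <- ratio >= 4 || (node$depth == 6 && ratio >= 1)
      if (accept) {
        found[[length(found) + 1L]] <<- node
        return()
      }
      if (node$depth == 6) return()
    }
    for (a in c("0", "1")) for (b in c("0", "1"))
      recurse(extend_node(node, a, b, m))
  }
  recurse(tree_root(m))
  want <- data.frame(s_x = vapply(found, `[[`, "", "s_x"),
                     s_y = vapply(found, `[[`, "", "s_y"),
                     p_joint = vapply(found, `[[`, 0, "p_joint"))
  want <- want[order(want$s_x, want$s_y), ]
  got <- as.data.frame(idx$buckets[order(s_x, s_y), .(s_x, s_y, p_joint)])
  expect_equal(got$s_x, want$s_x)
  expect_equal(got$s_y, want$s_y)
  expect_equal(got$p_joint, want$p_joint, tolerance = 1e-12)
})

test_that("band planning follows J = ceiling(-log(eps) / alpha)", {
  expect_equal(choose_bands(1, 0.05), 3L)
  expect_equal(choose_bands(0.01, 0.05), 300L)
  expect_equal(choose_bands(0.5, 0.5), 2L)
  expect_error(choose_bands(0, 0.05), "no true-positive mass")
})

test_that("predicted TPR follows 1 - (1 - alpha)^J and its bound", {
  expect_equal(predicted_tpr(0.5, 1), 0.5)
  expect_equal(predicted_tpr(0.5, 2), 0.75)
  J <- choose_bands(0.1, 0.05)
  expect_equal(J, 30L)
  expect_gte(predicted_tpr(0.1, J), 0.95)
  expect_equal(predicted_tpr(0.3, 5, bound = TRUE), 1 - exp(-1.5))
  expect_lte(predicted_tpr(0.3, 5, bound = TRUE), predicted_tpr(0.3, 5))
})

test_that("prefix mapping matches the worked band example and the scan", {
  idx <- manual_index(s_x = "1011", s_y = "1011")
  X <- "01011100"
  expect_equal(map_sequence(idx, X, "x", 2), 1L)
  for (j in c(1, 3:8)) expect_length(map_sequence(idx, X, "x", j), 0)
  expect_length(map_sequence(idx, X, "x", 100), 0)  # suffix too short
  expect_error(map_sequence(idx, X, "x", 0), ">= 1")
  # complete depth-1 tree: every band maps to the bucket of that character
  m <- hmm_binary_model(0.1, 0.2)
  d1 <- build_tree(m, build_config(max_depth = 1, accept_ratio = 0,
                                   prune_threshold = 0))
  s <- "0110"
  for (j in 1:4) {
    got <- map_sequence(d1, s, "x", j)
    expect_length(got, 2L)   # both y-symbols for the observed x-symbol
    expect_true(all(d1$buckets$s_x[got] == substr(s, j, j)))
  }
  # literal char-by-char scan agrees on a built tree
  idx2 <- suppressWarnings(build_tree(hmm_binary_model(0.05, 0.05),
    build_config(max_depth = 6, accept_ratio = 4, prune_threshold = 1e-4)))
  for (seed in 1:5) {
    sq <- rand_seq(15, c("0", "1"), seed)
    for (j in c(1, 4, 9)) {
      expect_setequal(map_sequence(idx2, sq, "x", j), scan_map(idx2, sq, "x", j))
      expect_setequal(map_sequence(idx2, sq, "y", j), scan_map(idx2, sq, "y", j))
    }
  }
})

test_that("a jointly generated pair lands in at most one bucket per band", {
  m <- hmm_binary_model(0.05, 0.05)
  idx <- suppressWarnings(build_tree(m, build_config(
    max_depth = 8, accept_ratio = 16, final_accept_ratio = 4)))
  for (s in 1:40) {
    p <- sample_hmm_pair(m, 30, seed = 300 + s)
    for (j in c(1, 7, 15)) {
      common <- intersect(map_sequence(idx, p$x, "x", j),
                          map_sequence(idx, p$y, "y", j))
      expect_lte(length(common), 1L)
    }
  }
})

test_that("empirical band hit rate and multi-band TPR follow the analysis", {
  m <- hmm_binary_model(0.05, 0.05)
  Tlen <- 100; n <- 3000
  pairs <- lapply(seq_len(n), function(i) sample_hmm_pair(m, Tlen, seed = 7 * i))
  xs <- vapply(pairs, `[[`, "", "x"); ys <- vapply(pairs, `[[`, "", "y")
  for (cf in list(c(4, 1, 8), c(16, 4, 10), c(64, 16, 12))) {
    idx <- suppressWarnings(build_tree(m, build_config(
      max_depth = cf[3], accept_ratio = cf[1], final_accept_ratio = cf[2])))
    bands <- band_positions(Tlen, idx$j_bands, max(idx$buckets$len_x))
    memx <- dsbucket:::bucket_memberships(idx, xs, "x", bands)
    memy <- dsbucket:::bucket_memberships(idx, ys, "y", bands)
    sh <- merge(memx, memy, by = c("seq", "band", "bucket"))
    # single-band hit rate = alpha
    hit1 <- length(unique(sh$seq[sh$band == bands[1]])) / n
    expect_lt(abs(hit1 - idx$alpha), 3 * sqrt(idx$alpha * (1 - idx$alpha) / n))
    # spread bands: TPR matches 1 - (1 - alpha)^J
    tpr <- length(unique(sh$seq)) / n
    pred <- predicted_tpr(idx$alpha, length(bands))
    expect_lt(abs(tpr - pred), 3 * sqrt(pred * (1 - pred) / n))
  }
})

test_that("bucketed search is sound: subset of brute force, identical scores", {
  m <- hmm_binary_model(0.05, 0.05)
  ds <- make_hmm_dataset(0.05, 0.05, T = 100, N = 60, seed = 5)
  idx <- suppressWarnings(build_tree(m, build_config(
    max_depth = 10, accept_ratio = 16, final_accept_ratio = 4)))
  res <- dsb_search(idx, ds$database, ds$queries, m, llr_threshold = 0,
                    top_k = 3)
  bf <- brute_force_search(ds$database, ds$queries, m, top_k = 60)
  bf <- bf[bf$score >= 0, ]
  key <- paste(bf$query_id, bf$ref_id)
  expect_true(all(paste(res$matches$query_id, res$matches$ref_id) %in% key))
  bfscore <- setNames(bf$score, key)
  expect_equal(res$matches$score,
               unname(bfscore[paste(res$matches$query_id, res$matches$ref_id)]),
               tolerance = 1e-12)
  expect_gt(res$n_verified, 0)
  expect_lte(nrow(res$matches), 3 * length(ds$queries))
})

test_that("disjoint sequence sets produce no candidates and no verifications", {
  idx <- manual_index(s_x = "0000000", s_y = "0000000")
  m <- hmm_binary_model(0.05, 0.05)
  res <- suppressWarnings(   # hand-built index: fingerprint mismatch expected
    dsb_search(idx, c(d = strrep("01", 10)), c(q = strrep("10", 10)), m))
  expect_equal(nrow(res$matches), 0L)
  expect_equal(res$n_verified, 0L)
})

test_that("the cost planner prefers stricter trees as N grows", {
  m <- hmm_binary_model(0.05, 0.05)
  # one cheap-to-map tree with many verifications, one strict deep tree:
  # verification cost beta*M*N must dominate before the strict tree pays off
  lad <- list(c(64, 64, 12), c(1024, 512, 16))
  idxs <- build_ladder(m, ladder = lad)
  small <- plan_hmm_index(m, 100, 100, ladder = lad, indexes = idxs)
  big <- plan_hmm_index(m, 20000, 20000, ladder = lad, indexes = idxs)
  expect_equal(small$config, lad[[1]])
  expect_equal(big$config, lad[[2]])
})
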