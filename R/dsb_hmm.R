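## Decision-tree bucketing for the pair HMM: grow a tree over pairs of
## prefixes (S_x, S_y), keep high-enrichment leaves as buckets, map database
## and query sequences into buckets across bands, verify co-occurrences.

#' Construction knobs for bucket indexes
#'
#' @param max_depth maximum tree depth (HMM: symbols per side; alignment
#'   graph: total emitted length `|S_x| + |S_y|`).
#' @param prune_threshold prune any node whose joint prefix probability falls
#'   below this value.  `NULL` (default) disables absolute pruning and relies
#'   on `beam_width`; [build_tree()] warns if the resulting per-band true
#'   positive rate is below `10 * eps_miss`.
#' @param accept_ratio enrichment ratio `p_joint / (p_x p_y)` at which a node
#'   is frozen into a bucket.
#' @param eps_miss target probability of missing a true pair across all bands;
#'   drives the band count `J = ceiling(-log(eps_miss) / alpha)`.
#' @param beam_width deterministic cap on the number of nodes expanded per
#'   level (the highest-`p_joint` nodes are kept; ties broken by node key).
#' @param final_accept_ratio enrichment ratio required to accept a node that
#'   reaches `max_depth` without crossing `accept_ratio` (default 1: joint at
#'   least as likely as independent, matching the tree construction rule).
#' @param db_size_m,query_size_n optional expected problem sizes, used only to
#'   report the predicted verification cost `J * beta * M * N`.
#' @return list of class `BuildConfig`.
#' @export
build_config <- function(max_depth = 12L, prune_threshold = NULL,
                         accept_ratio = 4, eps_miss = 0.05,
                         beam_width = 200000L, final_accept_ratio = 1,
                         db_size_m = NULL, query_size_n = NULL) {
  stopifnot(max_depth >= 1L, eps_miss > 0, eps_miss < 1, accept_ratio >= 0,
            beam_width >= 1L, final_accept_ratio >= 0)
  if (!is.null(prune_threshold)) stopifnot(prune_threshold >= 0)
  structure(list(max_depth = as.integer(max_depth),
                 prune_threshold = prune_threshold,
                 accept_ratio = accept_ratio, eps_miss = eps_miss,
                 beam_width = as.integer(beam_width),
                 final_accept_ratio = final_accept_ratio,
                 db_size_m = db_size_m, query_size_n = query_size_n),
            class = "BuildConfig")
}

#' Root node of the decision tree
#'
#' @param params an [hmm_params()] object.
#' @return `TreeNode` with empty strings, `p_joint = p_x = p_y = 1` and the
#'   initial-state distribution as forward state.
#' @export
tree_root <- function(params) {
  structure(list(s_x = "", s_y = "", depth = 0L,
                 forward_state = setNames(params$p_init, params$hidden_states),
                 p_joint = 1, p_x = 1, p_y = 1, status = "branched"),
            class = "TreeNode")
}

#' Extend a tree node by one symbol pair
#'
#' Child of `parent` along edge `(a, b)`: appends `a` to `S_x` and `b` to
#' `S_y` and advances the joint forward state by one emission (the root uses
#' `p_init` without a transition).  `p_joint` is the probability that a
#' jointly generated pair starts with exactly these prefixes; `p_x`, `p_y`
#' accumulate the background factors.
#'
#' @param parent a `TreeNode` (see [tree_root()]); must not be pruned.
#' @param a,b single symbols from the x / y alphabets.
#' @param params an [hmm_params()] object.
#' @return child `TreeNode`.
#' @export
extend_node <- function(parent, a, b, params) {
  if (identical(parent$status, "pruned")) stop("cannot extend a pruned node",
                                               call. = FALSE)
  ai <- match(a, params$obs_alphabet_x)
  bi <- match(b, params$obs_alphabet_y)
  if (is.na(ai)) stop("unknown x symbol '", a, "'", call. = FALSE)
  if (is.na(bi)) stop("unknown y symbol '", b, "'", call. = FALSE)
  f <- if (parent$depth == 0L) parent$forward_state
       else as.numeric(parent$forward_state %*% params$p_trans)
  f <- f * params$p_emit[ai, bi, ]
  structure(list(
    s_x = paste0(parent$s_x, a), s_y = paste0(parent$s_y, b),
    depth = parent$depth + 1L,
    forward_state = setNames(f, params$hidden_states),
    p_joint = sum(f),
    p_x = parent$p_x * params$px_background[ai],
    p_y = parent$p_y * params$py_background[bi],
    status = "branched"), class = "TreeNode")
}

# Little-endian packing of 0-based codes: key = sum codes[t] * base^(t-1).
pack_codes <- function(codes, base) sum(codes * base^(seq_along(codes) - 1L))

unpack_key <- function(key, len, base, alphabet) {
  if (len == 0L) return("")
  codes <- integer(len)
  for (t in seq_len(len)) {
    codes[t] <- key %% base
    key <- key %/% base
  }
  paste(alphabet[codes + 1L], collapse = "")
}

#' Build the decision-tree bucket index for a pair HMM
#'
#' Breadth-first growth from the root.  At each node: prune when `p_joint`
#' falls below `prune_threshold`; accept as a bucket when the enrichment
#' ratio `p_joint / (p_x p_y)` reaches `accept_ratio` (or, at `max_depth`,
#' `final_accept_ratio`); otherwise branch into all `|A| x |B|` children.
#' Construction is deterministic.  The returned index carries the per-band
#' statistics `alpha` (true-positive mass, exact for trees), `beta`
#' (false-positive mass), `gamma_x`/`gamma_y` (expected memberships), and the
#' band count `J` from [choose_bands()].
#'
#' @param params an [hmm_params()] object.
#' @param cfg a [build_config()].
#' @return object of class `dsb_index` (subtype `hmm`).
#' @export
build_tree <- function(params, cfg = build_config()) {
  stopifnot(inherits(params, "HMMParams"), inherits(cfg, "BuildConfig"))
  nA <- length(params$obs_alphabet_x); nB <- length(params$obs_alphabet_y)
  nH <- length(params$hidden_states)
  theta <- cfg$prune_threshold %||% 0

  ab <- expand.grid(a = seq_len(nA) - 1L, b = seq_len(nB) - 1L)
  emit_ab <- t(apply(ab, 1, function(r) params$p_emit[r[1] + 1L, r[2] + 1L, ]))
  dim(emit_ab) <- c(nrow(ab), nH)

  # active frontier: packed keys, background probs, forward matrix F (n x H)
  act <- data.table(kx = 0, ky = 0, px = 1, py = 1)
  Fm <- matrix(params$p_init, nrow = 1)
  buckets <- vector("list", cfg$max_depth)

  for (d in seq_len(cfg$max_depth)) {
    n <- nrow(act)
    if (n == 0L) break
    M <- if (d == 1L) Fm else Fm %*% params$p_trans
    kids <- vector("list", nrow(ab))
    Fk <- vector("list", nrow(ab))
    for (e in seq_len(nrow(ab))) {
      Fe <- M * matrix(emit_ab[e, ], n, nH, byrow = TRUE)
      kids[[e]] <- data.table(
        kx = act$kx + ab$a[e] * nA^(d - 1L),
        ky = act$ky + ab$b[e] * nB^(d - 1L),
        px = act$px * params$px_background[ab$a[e] + 1L],
        py = act$py * params$py_background[ab$b[e] + 1L],
        p_joint = rowSums(Fe))
      Fk[[e]] <- Fe
    }
    layer <- rbindlist(kids)
    Fm <- do.call(rbind, Fk)

    keep <- layer$p_joint >= theta & layer$p_joint > 0
    ratio <- layer$p_joint / (layer$px * layer$py)
    acc_at <- if (d == cfg$max_depth) cfg$final_accept_ratio else cfg$accept_ratio
    accept <- keep & ratio >= acc_at
    if (any(accept)) {
      bdt <- layer[accept]
      bdt[, depth := d]
      buckets[[d]] <- bdt
    }
    branch <- which(keep & !accept & d < cfg$max_depth)
    if (length(branch) > cfg$beam_width) {
      ord <- branch[order(-layer$p_joint[branch], layer$kx[branch],
                          layer$ky[branch])]
      branch <- ord[seq_len(cfg$beam_width)]
    }
    act <- layer[branch, .(kx, ky, px, py)]
    Fm <- Fm[branch, , drop = FALSE]
  }

  bdt <- rbindlist(buckets)
  if (nrow(bdt) == 0L) stop("index empty: relax thresholds", call. = FALSE)
  setorder(bdt, depth, kx, ky)
  bdt[, s_x := mapply(unpack_key, kx, depth, MoreArgs = list(
    base = nA, alphabet = params$obs_alphabet_x))]
  bdt[, s_y := mapply(unpack_key, ky, depth, MoreArgs = list(
    base = nB, alphabet = params$obs_alphabet_y))]
  buckets_df <- data.table(bucket = seq_len(nrow(bdt)), s_x = bdt$s_x,
                           s_y = bdt$s_y, len_x = bdt$depth,
                           len_y = bdt$depth, p_joint = bdt$p_joint,
                           p_x = bdt$px, p_y = bdt$py)
  new_index("hmm", buckets_df, params, cfg,
            alpha = sum(buckets_df$p_joint), alpha_exact = TRUE)
}

new_index <- function(type, buckets, params, cfg, alpha, alpha_exact,
                      alpha_se = 0) {
  beta <- sum(buckets$p_x * buckets$p_y)
  if (alpha <= 0) stop("index empty: relax thresholds", call. = FALSE)
  idx <- structure(list(
    type = type, buckets = buckets,
    alpha = alpha, alpha_exact = alpha_exact, alpha_se = alpha_se,
    beta = beta,
    gamma_x = sum(buckets$p_x), gamma_y = sum(buckets$p_y),
    eps_miss = cfg$eps_miss,
    j_bands = choose_bands(alpha, cfg$eps_miss),
    cfg = cfg, model_hash = model_hash(params),
    alphabet_x = if (inherits(params, "SAParams")) DNA else params$obs_alphabet_x,
    alphabet_y = if (inherits(params, "SAParams")) DNA else params$obs_alphabet_y
  ), class = c(paste0("dsb_", type, "_index"), "dsb_index"))
  # design rule for recovery-oriented trees: alpha >= 10 * eps_miss keeps J
  # small; dense-banded graph searches work at much lower per-band alpha
  if (type == "hmm" && alpha < 10 * cfg$eps_miss)
    warning(sprintf(
      "per-band true-positive rate alpha = %.4g is below 10 * eps_miss = %.3g; consider relaxing thresholds",
      alpha, 10 * cfg$eps_miss))
  idx
}

#' @export
print.dsb_index <- function(x, ...) {
  cat(sprintf(
    "DSB %s index: %d buckets | alpha = %.4g%s, beta = %.4g, gamma = (%.3g, %.3g), J = %d (eps_miss = %g)\n",
    x$type, nrow(x$buckets), x$alpha,
    if (x$alpha_exact) "" else sprintf(" (MC est, se %.3g)", x$alpha_se),
    x$beta, x$gamma_x, x$gamma_y, x$j_bands, x$eps_miss))
  invisible(x)
}

#' Per-band index statistics
#'
#' Recomputes from the bucket table: `alpha` = total joint prefix mass of the
#' buckets (the per-band true-positive rate; exact for trees, where a pair
#' follows exactly one root-to-leaf path), `beta` = total background mass
#' (per-band false-positive rate), and the expected bucket membership counts
#' `gamma_x`, `gamma_y`.  These drive the expected verification cost
#' `J * beta * M * N`.
#'
#' @param index a `dsb_index`.
#' @return named numeric vector `(alpha, beta, gamma_x, gamma_y)`.
#' @export
tree_stats <- function(index) {
  b <- index$buckets
  if (nrow(b) == 0L) stop("empty bucket set", call. = FALSE)
  c(alpha = sum(b$p_joint), beta = sum(b$p_x * b$p_y),
    gamma_x = sum(b$p_x), gamma_y = sum(b$p_y))
}

#' Number of bands needed for a target miss rate
#'
#' `J = ceiling(-log(eps_miss) / alpha)`, at least 1: with `J` independent
#' bands the overall true-positive rate `1 - (1 - alpha)^J` is at least
#' `1 - eps_miss`.
#'
#' @param alpha per-band true-positive rate in `(0, 1]`.
#' @param eps_miss tolerated miss probability in `(0, 1)`.
#' @return integer band count.
#' @export
choose_bands <- function(alpha, eps_miss) {
  if (alpha <= 0) stop("no true-positive mass", call. = FALSE)
  stopifnot(alpha <= 1, eps_miss > 0, eps_miss < 1)
  max(1L, as.integer(ceiling(-log(eps_miss) / alpha)))
}

#' Predicted true-positive rate over J bands
#'
#' @param alpha per-band true-positive rate.
#' @param J number of bands (>= 1).
#' @param bound if `TRUE`, return the lower bound `1 - exp(-alpha * J)`
#'   instead of the exact `1 - (1 - alpha)^J`.
#' @return probability.
#' @export
predicted_tpr <- function(alpha, J, bound = FALSE) {
  stopifnot(J >= 1)
  if (bound) 1 - exp(-alpha * J) else 1 - (1 - alpha)^J
}

#' Choose a decision-tree configuration for a given problem size
#'
#' Builds a ladder of candidate configurations (loose, shallow trees through
#' strict, deep ones) and picks the one minimising the expected search cost
#' `J * ((M * gamma_x + N * gamma_y) + beta * M * N)` — the mapping-plus-
#' verification complexity of the bucketed search.  Larger problems favour
#' stricter, deeper trees (smaller `beta` at the price of more bands), which
#' is what makes the verified-pair count grow sub-quadratically in `N`.
#'
#' @param params an [hmm_params()] object.
#' @param M,N expected database and query counts.
#' @param eps_miss target miss rate passed to every candidate config.
#' @param ladder list of `c(accept_ratio, final_accept_ratio, max_depth)`
#'   triples; the default spans enrichment 4..1024 and depth 8..16.
#' @param indexes optional pre-built indexes for `ladder` (from
#'   [build_ladder()]), so several problem sizes can share one ladder.
#' @return list with the chosen `index`, its `config` triple, and a `table`
#'   of predicted costs for every candidate.
#' @export
plan_hmm_index <- function(params, M, N, eps_miss = 0.05, ladder = NULL,
                           indexes = NULL) {
  ladder <- ladder %||% default_ladder()
  idxs <- indexes %||% build_ladder(params, eps_miss, ladder)
  tab <- data.frame(
    accept_ratio = vapply(ladder, `[`, 0, 1),
    final_accept_ratio = vapply(ladder, `[`, 0, 2),
    max_depth = vapply(ladder, `[`, 0, 3),
    alpha = vapply(idxs, `[[`, 0, "alpha"),
    beta = vapply(idxs, `[[`, 0, "beta"),
    j_bands = vapply(idxs, `[[`, 0L, "j_bands"))
  tab$cost <- tab$j_bands *
    ((M * vapply(idxs, `[[`, 0, "gamma_x") +
      N * vapply(idxs, `[[`, 0, "gamma_y")) + tab$beta * M * N)
  best <- which.min(tab$cost)
  list(index = idxs[[best]], config = ladder[[best]], table = tab)
}

default_ladder <- function() {
  list(c(4, 1, 8), c(16, 4, 10), c(64, 16, 12), c(64, 64, 12),
       c(256, 256, 14), c(1024, 512, 16))
}

#' @rdname plan_hmm_index
#' @export
build_ladder <- function(params, eps_miss = 0.05, ladder = NULL) {
  ladder <- ladder %||% default_ladder()
  lapply(ladder, function(cf)
    suppressWarnings(build_tree(params, build_config(
      max_depth = cf[3], accept_ratio = cf[1], final_accept_ratio = cf[2],
      eps_miss = eps_miss))))
}

#' Band positions for a sequence of a given length
#'
#' Returns `J` suffix start positions (1-based) spread evenly across the
#' mappable range `1 .. T - depth + 1`.  The multi-band true-positive rate
#' `1 - (1 - alpha)^J` assumes bands are (near-)independent; adjacent
#' positions share almost the whole prefix window a bucket looks at, so
#' spreading the bands with spacing well above the bucket depth is what
#' makes the formula hold in practice.
#'
#' @param T sequence length.
#' @param J number of bands requested.
#' @param depth maximum bucket string length.
#' @return integer vector of at most `J` distinct positions.
#' @export
band_positions <- function(T, J, depth) {
  hi <- max(1L, T - depth + 1L)
  unique(as.integer(round(seq(1L, hi, length.out = min(J, hi)))))
}

#' Map one sequence into buckets at one band
#'
#' Returns every bucket whose axis string is a prefix of the `band_j`-th
#' suffix of `s` (1-based, so `band_j = 1` is the whole sequence).  A band
#' beyond the end of the sequence yields the empty set rather than an error.
#'
#' @param index a `dsb_index`.
#' @param s sequence (character string).
#' @param axis `"x"` (database / reference side) or `"y"` (query side).
#' @param band_j band position, `band_j >= 1`.
#' @return integer vector of bucket ids (rows of `index$buckets`).
#' @export
map_sequence <- function(index, s, axis = c("x", "y"), band_j = 1L) {
  axis <- match.arg(axis)
  if (band_j < 1L) stop("band_j must be >= 1", call. = FALSE)
  if (band_j > nchar(s)) return(integer(0))
  suf <- substr(s, band_j, nchar(s))
  strs <- if (axis == "x") index$buckets$s_x else index$buckets$s_y
  hit <- substring(suf, 1L, nchar(strs)) == strs & nchar(strs) <= nchar(suf)
  index$buckets$bucket[hit]
}

#' @rdname map_sequence
#' @export
map_sequence_sa <- function(index, s, axis = c("x", "y"), band_j = 1L) {
  map_sequence(index, s, axis, band_j)
}

# Batched membership computation via rolling packed keys.
# seqs: character vector; returns data.table(seq, band, bucket).
bucket_memberships <- function(index, seqs, axis, bands) {
  alph <- if (axis == "x") index$alphabet_x else index$alphabet_y
  base <- length(alph)
  b <- index$buckets
  lens <- if (axis == "x") b$len_x else b$len_y
  strs <- if (axis == "x") b$s_x else b$s_y
  codes <- lapply(seqs, encode_seq, alphabet = alph)
  out <- list()
  for (L in sort(unique(lens))) {
    sel <- which(lens == L)
    if (L == 0L) {  # empty-string bucket matches every band
      grid <- data.table(expand.grid(band = bands, seq = seq_along(seqs)))
      for (bk in sel) out[[length(out) + 1L]] <-
          data.table(seq = grid$seq, band = grid$band, bucket = b$bucket[bk])
      next
    }
    keytab <- data.table(
      key1 = vapply(strs[sel], function(sx)
        pack_codes(encode_seq(sx, alph), base), 0),
      bucket = b$bucket[sel])
    setkey(keytab, key1)
    rows <- lapply(seq_along(seqs), function(i) {
      v <- codes[[i]]
      js <- bands[bands + L - 1L <= length(v)]
      if (!length(js)) return(NULL)
      k <- numeric(length(js))
      for (t in 0:(L - 1L)) k <- k + v[js + t] * base^t
      data.table(seq = i, band = js, key1 = k)
    })
    dtm <- rbindlist(rows)
    if (nrow(dtm) == 0L) next
    m <- keytab[dtm, on = "key1", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(m)) out[[length(out) + 1L]] <- m[, .(seq, band, bucket)]
  }
  if (!length(out)) return(data.table(seq = integer(), band = integer(),
                                      bucket = integer()))
  rbindlist(out)
}

#' Bucketed likelihood-ratio search under the HMM
#'
#' Algorithm: map every database sequence (x axis) and query sequence (y
#' axis) into buckets for each band `j = 1..J`; collect candidate pairs that
#' co-occur in at least one bucket (deduplicated across bands and buckets);
#' verify each candidate once with the exact [hmm_llr()]; report pairs whose
#' score clears `llr_threshold`, ranked per query.
#'
#' @param index a `dsb_index` built by [build_tree()] from `params`.
#' @param database,queries character vectors of equal-length sequences.
#' @param params the same [hmm_params()] the index was built from.
#' @param llr_threshold minimum reported log-likelihood ratio (default 0:
#'   joint model more likely than independent).
#' @param top_k matches kept per query.
#' @return list of class `dsb_hits`: `matches` (data.frame `query_id`,
#'   `ref_id`, `rank`, `score`), `n_candidates` (distinct verified pairs),
#'   `n_verified`, and `j_bands` actually used.
#' @export
dsb_search <- function(index, database, queries, params, llr_threshold = 0,
                       top_k = 1L) {
  stopifnot(inherits(index, "dsb_hmm_index"), inherits(params, "HMMParams"))
  if (!identical(index$alphabet_x, params$obs_alphabet_x) ||
      !identical(index$alphabet_y, params$obs_alphabet_y))
    stop("index and params alphabets differ", call. = FALSE)
  if (!identical(index$model_hash, model_hash(params)))
    warning("index was built from different parameter values")
  Tlen <- unique(nchar(c(database, queries)))
  if (length(Tlen) != 1L) stop("all sequences must share one length", call. = FALSE)
  maxd <- max(index$buckets$len_x)
  J <- index$j_bands
  if (J > Tlen - maxd + 1L) {
    J <- max(1L, Tlen - maxd + 1L)
    warning(sprintf("band count capped at %d by sequence length", J))
  }
  bands <- band_positions(Tlen, J, maxd)
  memx <- bucket_memberships(index, database, "x", bands)
  memy <- bucket_memberships(index, queries, "y", bands)
  cand <- merge(memx, memy, by = c("band", "bucket"),
                allow.cartesian = TRUE, suffixes = c(".db", ".q"))
  cand <- unique(cand[, .(db = seq.db, q = seq.q)])
  dbid <- seq_ids(database, "db"); qid <- seq_ids(queries, "q")
  if (nrow(cand) == 0L) {
    return(structure(list(
      matches = data.frame(query_id = character(), ref_id = character(),
                           rank = integer(), score = numeric()),
      n_candidates = 0L, n_verified = 0L, j_bands = J), class = "dsb_hits"))
  }
  nA <- length(params$obs_alphabet_x); nB <- length(params$obs_alphabet_y)
  dbm <- vapply(database, encode_seq, integer(Tlen),
                alphabet = params$obs_alphabet_x)
  qm <- vapply(queries, encode_seq, integer(Tlen),
               alphabet = params$obs_alphabet_y)
  joint <- .hmm_forward_batch_cpp(dbm, qm, cand$db - 1L, cand$q - 1L,
                                  params$p_init, params$p_trans,
                                  as.numeric(params$p_emit), nA, nB)
  lbx <- log(params$px_background); lby <- log(params$py_background)
  mx <- colSums(matrix(lbx[dbm + 1L], nrow = Tlen))
  my <- colSums(matrix(lby[qm + 1L], nrow = Tlen))
  cand[, score := joint - mx[db] - my[q]]
  hits <- cand[score >= llr_threshold]
  setorder(hits, q, -score, db)   # stable: ties keep database order
  hits <- hits[, head(.SD, top_k), by = q]
  hits[, rank := seq_len(.N), by = q]
  structure(list(
    matches = data.frame(query_id = qid[hits$q], ref_id = dbid[hits$db],
                         rank = hits$rank, score = hits$score,
                         stringsAsFactors = FALSE),
    n_candidates = nrow(cand), n_verified = nrow(cand), j_bands = J),
    class = "dsb_hits")
}

#' @export
print.dsb_hits <- function(x, ...) {
  cat(sprintf("DSB search: %d matches, %d candidate pairs verified over %d bands\n",
              nrow(x$matches), x$n_verified, x$j_bands))
  invisible(x)
}
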