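## Decision-graph bucketing for the sequence alignment model.  Nodes hold
## unequal-length string pairs (S_x, S_y); edges are match, insertion, and
## deletion events, and a node reachable along several event orders is merged
## so its joint mass equals the pair-prefix DP value.

#' Root of the decision graph
#'
#' @param params an [sa_params()] object.
#' @return `GraphNode` with empty strings and unit probabilities.
#' @export
graph_root <- function(params) {
  structure(list(s_x = "", s_y = "", p_joint = 1, p_x = 1, p_y = 1,
                 status = "branched"), class = "GraphNode")
}

#' Extend a graph node by one alignment event
#'
#' A match event `m(a, b)` appends `a` to `S_x` and `b` to `S_y` with factor
#' `q_match * p_m(a, b)`; a deletion `d(a)` appends `a` to `S_x` only with
#' factor `q_deletion * p_d(a)`; an insertion `i(b)` appends `b` to `S_y`
#' only with factor `q_insertion * p_i(b)`.  The returned node carries the
#' mass contributed along this single path; when the same `(S_x, S_y)` pair
#' is reached along several event orders, [merge_graph_nodes()] (and
#' [build_graph()] internally) accumulates the contributions so that the
#' merged `p_joint` equals the pair-prefix DP value.
#'
#' @param parent a `GraphNode`; must not be pruned.
#' @param event `"m"`, `"i"`, or `"d"`.
#' @param params an [sa_params()] object.
#' @param a,b bases consumed on the x / y side (as required by the event).
#' @return child `GraphNode`.
#' @export
extend_graph_node <- function(parent, event = c("m", "i", "d"), params,
                              a = NULL, b = NULL) {
  event <- match.arg(event)
  if (identical(parent$status, "pruned"))
    stop("cannot extend a pruned node", call. = FALSE)
  chkbase <- function(z, side) {
    if (is.null(z) || !z %in% DNA)
      stop("event '", event, "' needs a valid ", side, " base", call. = FALSE)
    z
  }
  if (event == "m") {
    a <- chkbase(a, "x"); b <- chkbase(b, "y")
    fac <- params$q_match * params$p_m[a, b]
    sx <- paste0(parent$s_x, a); sy <- paste0(parent$s_y, b)
    px <- parent$p_x * params$px_background[a]
    py <- parent$p_y * params$py_background[b]
  } else if (event == "d") {
    a <- chkbase(a, "x")
    fac <- params$q_deletion * params$p_d[a]
    sx <- paste0(parent$s_x, a); sy <- parent$s_y
    px <- parent$p_x * params$px_background[a]; py <- parent$p_y
  } else {
    b <- chkbase(b, "y")
    fac <- params$q_insertion * params$p_i[b]
    sx <- parent$s_x; sy <- paste0(parent$s_y, b)
    px <- parent$p_x; py <- parent$p_y * params$py_background[b]
  }
  structure(list(s_x = sx, s_y = sy, p_joint = unname(parent$p_joint * fac),
                 p_x = unname(px), p_y = unname(py), status = "branched"),
            class = "GraphNode")
}

#' Merge graph nodes that share the same string pair
#'
#' @param nodes list of `GraphNode`s with identical `(s_x, s_y)`.
#' @return one `GraphNode` with summed `p_joint`.
#' @export
merge_graph_nodes <- function(nodes) {
  stopifnot(length(nodes) >= 1L)
  key <- vapply(nodes, function(n) paste(n$s_x, n$s_y, sep = "\r"), "")
  if (length(unique(key)) != 1L)
    stop("nodes to merge must share (s_x, s_y)", call. = FALSE)
  out <- nodes[[1]]
  out$p_joint <- sum(vapply(nodes, `[[`, 0, "p_joint"))
  out
}

#' Build the decision-graph bucket index for the sequence alignment model
#'
#' Frontier expansion by total emitted length `|S_x| + |S_y|`, merging
#' duplicate string pairs so each node's joint mass equals the pair-prefix DP
#' value over all surviving event orders.  Accept/prune/branch uses the same
#' enrichment rule as [build_tree()]; accepted buckets are removed from
#' further expansion.  Because graph buckets overlap as events, the per-band
#' true-positive rate `alpha` is estimated by simulation
#' ([estimate_alpha()]) with the recorded seed; `beta` and the `gamma`s are
#' exact sums.
#'
#' @param params an [sa_params()] object.
#' @param cfg a [build_config()]; `max_depth` bounds the total emitted length.
#' @param alpha_sims number of simulated joint pairs for the `alpha` estimate.
#' @param seed seed for the `alpha` estimate (recorded in the index).
#' @return object of class `dsb_index` (subtype `sa`).
#' @export
build_graph <- function(params, cfg = build_config(max_depth = 14L),
                        alpha_sims = 500L, seed = 1L) {
  stopifnot(inherits(params, "SAParams"), inherits(cfg, "BuildConfig"))
  theta <- cfg$prune_threshold %||% 0
  L <- cfg$max_depth
  bgx <- unname(params$px_background); bgy <- unname(params$py_background)
  mf <- params$q_match * unname(params$p_m)
  df <- params$q_deletion * unname(params$p_d)
  iff <- params$q_insertion * unname(params$p_i)

  empty_layer <- data.table(kx = numeric(), ky = numeric(), lx = numeric(),
                            ly = numeric(), p_joint = numeric(),
                            px = numeric(), py = numeric())
  act <- vector("list", L + 1L)   # act[[l + 1]] = frontier at emitted length l
  act[[1]] <- data.table(kx = 0, ky = 0, lx = 0, ly = 0, p_joint = 1,
                         px = 1, py = 1)
  buckets <- list()

  children_of <- function(p, events) {
    kids <- list()
    if (nrow(p) == 0L) return(kids)
    if ("d" %in% events) {
      for (a in 0:3) kids[[length(kids) + 1L]] <- data.table(
        kx = p$kx + a * 4^p$lx, ky = p$ky, lx = p$lx + 1, ly = p$ly,
        p_joint = p$p_joint * df[a + 1L],
        px = p$px * bgx[a + 1L], py = p$py)
    }
    if ("i" %in% events) {
      for (b in 0:3) kids[[length(kids) + 1L]] <- data.table(
        kx = p$kx, ky = p$ky + b * 4^p$ly, lx = p$lx, ly = p$ly + 1,
        p_joint = p$p_joint * iff[b + 1L],
        px = p$px, py = p$py * bgy[b + 1L])
    }
    if ("m" %in% events) {
      for (a in 0:3) for (b in 0:3) kids[[length(kids) + 1L]] <- data.table(
        kx = p$kx + a * 4^p$lx, ky = p$ky + b * 4^p$ly,
        lx = p$lx + 1, ly = p$ly + 1,
        p_joint = p$p_joint * mf[a + 1L, b + 1L],
        px = p$px * bgx[a + 1L], py = p$py * bgy[b + 1L])
    }
    kids
  }

  # lookahead bound: the enrichment ratio gains at most `mu` per emitted
  # symbol (best match pair per two symbols, best single indel per one), so a
  # node whose ratio cannot reach the accept threshold within the remaining
  # layers can be dropped early; this leaves the accepted set unchanged
  # whenever beam_width is not binding (with a binding beam it changes only
  # which borderline nodes the beam retains)
  mu <- max(sqrt(max(mf / outer(bgx, bgy))), max(df / bgx), max(iff / bgy), 1)

  for (l in seq_len(L)) {
    kids <- c(children_of(act[[l]], c("d", "i")),
              if (l >= 2L) children_of(act[[l - 1L]], "m"))
    kids <- kids[!vapply(kids, is.null, TRUE)]
    layer <- if (length(kids)) rbindlist(kids) else empty_layer
    if (nrow(layer) == 0L) { act[[l + 1L]] <- empty_layer; next }
    layer <- layer[, .(p_joint = sum(p_joint), px = px[1], py = py[1]),
                   by = .(lx, kx, ly, ky)]
    keep <- layer$p_joint >= theta & layer$p_joint > 0
    ratio <- layer$p_joint / (layer$px * layer$py)
    acc_at <- if (l == L) cfg$final_accept_ratio else cfg$accept_ratio
    accept <- keep & ratio >= acc_at
    if (any(accept)) buckets[[length(buckets) + 1L]] <- layer[accept]
    reachable <- if (l >= L) FALSE else
      (ratio * mu^(L - l) >= cfg$final_accept_ratio) |
      (l < L - 1L & ratio * mu^(L - 1L - l) >= cfg$accept_ratio)
    branch <- which(keep & !accept & reachable & l < L)
    if (length(branch) > cfg$beam_width) {
      ord <- branch[order(-layer$p_joint[branch], layer$kx[branch],
                          layer$ky[branch], layer$lx[branch])]
      branch <- ord[seq_len(cfg$beam_width)]
    }
    act[[l + 1L]] <- layer[branch]
  }

  bdt <- rbindlist(buckets)
  if (nrow(bdt) == 0L) stop("index empty: relax thresholds", call. = FALSE)
  setorder(bdt, lx, ly, kx, ky)
  bdt[, s_x := mapply(unpack_key, kx, lx, MoreArgs = list(base = 4L, alphabet = DNA))]
  bdt[, s_y := mapply(unpack_key, ky, ly, MoreArgs = list(base = 4L, alphabet = DNA))]
  buckets_df <- data.table(bucket = seq_len(nrow(bdt)), s_x = bdt$s_x,
                           s_y = bdt$s_y, len_x = as.integer(bdt$lx),
                           len_y = as.integer(bdt$ly), p_joint = bdt$p_joint,
                           p_x = bdt$px, p_y = bdt$py)
  idx <- new_index("sa", buckets_df, params, cfg,
                   alpha = min(1, sum(buckets_df$p_joint)), alpha_exact = FALSE)
  est <- estimate_alpha(idx, params, n_sim = alpha_sims, seed = seed)
  idx$alpha <- max(est$alpha, 1 / (2 * alpha_sims))  # guard against 0 when J is formed
  idx$alpha_se <- est$se
  idx$alpha_seed <- seed
  idx$j_bands <- choose_bands(idx$alpha, cfg$eps_miss)
  idx
}

#' Restrict an index to exact-match buckets
#'
#' Keeps only buckets with `S_x == S_y`, which reduces the bucketed search to
#' the classical exact-substring seeding that popular seed-and-extend
#' aligners rely on.  Error-tolerant buckets (`S_x != S_y`) are what lets the
#' full index keep finding alignments when reads carry many errors; this
#' ablation quantifies that difference.  `beta` and the `gamma`s are
#' recomputed; `alpha` is re-estimated by simulation.
#'
#' @param index a `dsb_sa_index`.
#' @param params the [sa_params()] that built it.
#' @param alpha_sims,seed passed to [estimate_alpha()].
#' @return a `dsb_sa_index` with the reduced bucket set.
#' @export
ablate_exact_buckets <- function(index, params, alpha_sims = 500L, seed = 1L) {
  stopifnot(inherits(index, "dsb_sa_index"))
  b <- index$buckets[index$buckets$s_x == index$buckets$s_y]
  if (nrow(b) == 0L) stop("no exact-match buckets in index", call. = FALSE)
  b$bucket <- seq_len(nrow(b))
  idx <- index
  idx$buckets <- b
  idx$beta <- sum(b$p_x * b$p_y)
  idx$gamma_x <- sum(b$p_x); idx$gamma_y <- sum(b$p_y)
  est <- estimate_alpha(idx, params, n_sim = alpha_sims, seed = seed)
  idx$alpha <- max(est$alpha, 1 / (2 * alpha_sims))
  idx$alpha_se <- est$se
  idx$j_bands <- choose_bands(idx$alpha, idx$eps_miss)
  idx
}

#' Monte-Carlo estimate of the per-band true-positive rate
#'
#' Graph buckets overlap as events, so `alpha` cannot be read off the index
#' as a sum (the bucket masses union-bound it).  This samples jointly
#' generated pairs with [sample_sa_pair()], maps both sides at band 1, and
#' returns the fraction sharing at least one bucket, with its binomial
#' standard error.
#'
#' @param index a `dsb_sa_index`.
#' @param params the [sa_params()] that built it.
#' @param n_sim number of simulated pairs (at least 100).
#' @param seed optional seed.
#' @param S latent events per simulated pair; default three times the
#'   maximum emitted length so mapped prefixes are unconstrained by pair length.
#' @return list with `alpha`, `se`, `n_sim`.
#' @export
estimate_alpha <- function(index, params, n_sim = 500L, seed = NULL, S = NULL) {
  stopifnot(inherits(index, "dsb_sa_index"), n_sim >= 100L)
  S <- S %||% (3L * index$cfg$max_depth)
  seeds <- derive_seeds(seed, n_sim)
  pairs <- lapply(seq_len(n_sim), function(i)
    sample_sa_pair(params, S, seed = seeds[[i]]))
  xs <- vapply(pairs, `[[`, "", "x"); ys <- vapply(pairs, `[[`, "", "y")
  # empty sequences cannot be mapped; they count as misses
  ok <- nzchar(xs) & nzchar(ys)
  memx <- bucket_memberships(index, xs[ok], "x", bands = 1L)
  memy <- bucket_memberships(index, ys[ok], "y", bands = 1L)
  shared <- merge(memx, memy, by = c("seq", "bucket"))
  a <- length(unique(shared$seq)) / n_sim
  list(alpha = a, se = sqrt(a * (1 - a) / n_sim), n_sim = n_sim)
}

#' Windowed log-likelihood-ratio score
#'
#' Likelihood-ratio evidence that the read `y` aligns somewhere inside the
#' reference window `x`.  The read must be consumed in full; any prefix and
#' suffix of the window are attributed to the background model at no cost,
#' and the ratio is summed over all window substrings and alignments (a
#' "glocal" analogue of [sa_llr()]; when the window is exactly the aligned
#' region the two scores agree up to the substring sum).  Positive values
#' indicate alignment evidence.
#'
#' @param params an [sa_params()] object.
#' @param window reference-side DNA string.
#' @param read query-side DNA string.
#' @return log-likelihood ratio.
#' @export
sa_llr_window <- function(params, window, read) {
  xi <- encode_seq(window, DNA, "window"); yi <- encode_seq(read, DNA, "read")
  f <- sa_window_factors(params)
  .sa_window_llr_cpp(xi, yi, f$mfn, f$dfn, f$ifn)
}

sa_window_factors <- function(params) {
  bgx <- unname(params$px_background); bgy <- unname(params$py_background)
  list(mfn = params$q_match * unname(params$p_m) / outer(bgx, bgy),
       dfn = params$q_deletion * unname(params$p_d) / bgx,
       ifn = params$q_insertion * unname(params$p_i) / bgy)
}

revcomp <- function(s) {
  vapply(s, function(z) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", z), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Bucketed read-to-reference search under the sequence alignment model
#'
#' Every reference position is a band on the x side (the reference is
#' indexed densely); each read (and its reverse complement) is mapped on the
#' y side from suffix positions spaced `read_band_step` apart.  Each bucket
#' co-occurrence votes for a reference-minus-read diagonal; votes within a
#' diagonal tolerance are clustered, clusters with at least `min_votes`
#' votes define candidate windows (`read length + 2 * window_pad`), and each
#' window is verified with the exact [sa_llr_window()] score.  Hits with
#' score at or above `llr_threshold` are returned.
#'
#' @param index a `dsb_sa_index` built from `params`.
#' @param reference named character vector of reference sequences.
#' @param reads named character vector of reads.
#' @param params the [sa_params()] the index was built from.
#' @param llr_threshold minimum reported score (default 0).
#' @param window_pad reference window padding per side; default
#'   `0.25 * read length` (indel drift allowance).
#' @param min_votes minimum bucket votes for a candidate diagonal cluster;
#'   default `NULL` derives it per read as `max(5, 0.4 * alpha * n_bands)` —
#'   well below the expected true-diagonal vote count (`alpha` per band) and
#'   far above the background rate per diagonal bin.
#' @param read_band_step spacing of read-side bands (1 = every position).
#' @param max_candidates cap on verified clusters per read and strand,
#'   highest-voted first.
#' @param diag_tol diagonal clustering tolerance; default `0.35 * read length`.
#' @param strands strands to search (`"+"`, `"-"`).
#' @return list of class `dsb_sa_hits`: `hits` (PAF-like data.frame),
#'   `n_candidates` (clusters verified), `n_votes`, `j_bands`.
#' @export
dsb_sa_search <- function(index, reference, reads, params, llr_threshold = 0,
                          window_pad = NULL, min_votes = NULL,
                          read_band_step = 1L, max_candidates = 20L,
                          diag_tol = NULL, strands = c("+", "-")) {
  stopifnot(inherits(index, "dsb_sa_index"), inherits(params, "SAParams"))
  if (!identical(index$model_hash, model_hash(params)))
    warning("index was built from different parameter values")
  refs <- as.character(reference); names(refs) <- seq_ids(reference, "ref")
  rds <- as.character(reads); names(rds) <- seq_ids(reads, "read")
  maxlx <- max(index$buckets$len_x)
  if (min(nchar(refs)) < maxlx)
    stop("reference shorter than the longest bucket x-string", call. = FALSE)

  gmem <- bucket_memberships(index, refs, "x", bands = seq_len(max(nchar(refs))))
  data.table::setnames(gmem, c("seq", "band"), c("ref", "gpos"))

  # read instances: forward and (optionally) reverse-complement
  inst <- data.table(read = rep(seq_along(rds), each = length(strands)),
                     strand = rep(strands, times = length(rds)))
  inst_seq <- ifelse(inst$strand == "+", rds[inst$read], revcomp(rds[inst$read]))
  bands <- seq(1L, max(nchar(rds)), by = read_band_step)
  rmem <- bucket_memberships(index, inst_seq, "y", bands = bands)
  data.table::setnames(rmem, c("seq", "band"), c("iread", "rpos"))

  votes <- merge(rmem, gmem, by = "bucket", allow.cartesian = TRUE)
  n_votes <- nrow(votes)
  hits <- list(); n_cand <- 0L
  if (n_votes > 0L) {
    votes[, diag := gpos - rpos]
    verify_x <- list(); verify_y <- list(); meta <- list()
    for (grp in split(seq_len(n_votes),
                      list(votes$iread, votes$ref), drop = TRUE)) {
      iread <- votes$iread[grp[1]]; refi <- votes$ref[grp[1]]
      rlen <- nchar(inst_seq[iread]); G <- nchar(refs[refi])
      tol <- diag_tol %||% ceiling(0.35 * rlen)
      pad <- window_pad %||% ceiling(0.25 * rlen)
      nb <- length(seq(1L, rlen, by = read_band_step))
      mv <- min_votes %||% max(5, ceiling(0.4 * index$alpha * nb))
      d <- sort(votes$diag[grp])
      # fixed-width diagonal bins at two phase offsets (so a drifting true
      # diagonal straddling a bin edge is still collected in one bin)
      cands <- rbindlist(lapply(c(0, floor(tol / 2)), function(off) {
        bin <- floor((d + off) / tol)
        dt <- data.table(diag = d, bin = bin)[, .(
          votes = .N, center = as.numeric(stats::median(diag))), by = bin]
        dt[votes >= mv, .(votes, center)]
      }))
      if (nrow(cands) == 0L) next
      # greedy non-maximum suppression: strongest bins first, drop centers
      # within one tolerance of an already-kept candidate
      setorder(cands, -votes, center)
      keep <- numeric(0)
      for (r in seq_len(nrow(cands))) {
        if (length(keep) >= max_candidates) break
        if (!length(keep) || min(abs(keep - cands$center[r])) > tol)
          keep <- c(keep, cands$center[r])
      }
      tab <- cands[match(keep, center)]
      for (r in seq_len(nrow(tab))) {
        ws <- max(1, floor(tab$center[r] + 1 - pad))
        we <- min(G, ceiling(tab$center[r] + rlen + pad))
        verify_x[[length(verify_x) + 1L]] <-
          encode_seq(substr(refs[refi], ws, we), DNA)
        verify_y[[length(verify_y) + 1L]] <- encode_seq(inst_seq[iread], DNA)
        meta[[length(meta) + 1L]] <- data.table(
          iread = iread, ref = refi, ws = ws, we = we,
          n_bucket_votes = tab$votes[r])
      }
    }
    n_cand <- length(verify_x)
    if (n_cand > 0L) {
      f <- sa_window_factors(params)
      sc <- .sa_window_llr_batch_cpp(verify_x, verify_y, f$mfn, f$dfn, f$ifn)
      mdt <- rbindlist(meta)
      mdt[, score := sc]
      mdt <- mdt[score >= llr_threshold]
      if (nrow(mdt)) {
        hits <- data.frame(
          query_id = names(rds)[inst$read[mdt$iread]],
          query_len = nchar(rds)[inst$read[mdt$iread]],
          query_start = 0L,
          query_end = nchar(rds)[inst$read[mdt$iread]],
          strand = inst$strand[mdt$iread],
          ref_id = names(refs)[mdt$ref],
          ref_len = nchar(refs)[mdt$ref],
          ref_start = mdt$ws - 1L,          # 0-based half-open window
          ref_end = mdt$we,
          n_bucket_votes = mdt$n_bucket_votes,
          window_len = mdt$we - mdt$ws + 1L,
          score = mdt$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.data.frame(hits))
    hits <- data.frame(query_id = character(), query_len = integer(),
                       query_start = integer(), query_end = integer(),
                       strand = character(), ref_id = character(),
                       ref_len = integer(), ref_start = integer(),
                       ref_end = integer(), n_bucket_votes = integer(),
                       window_len = integer(), score = numeric(),
                       stringsAsFactors = FALSE)
  structure(list(hits = hits, n_candidates = n_cand, n_votes = n_votes,
                 j_bands = index$j_bands,
                 stats = tree_stats(index)), class = "dsb_sa_hits")
}

#' @export
print.dsb_sa_hits <- function(x, ...) {
  cat(sprintf(
    "DSB-SA search: %d hits from %d verified windows (%d bucket votes)\n",
    nrow(x$hits), x$n_candidates, x$n_votes))
  invisible(x)
}
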