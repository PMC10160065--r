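# Independent oracles: exhaustive enumerations and literal re-implementations
# kept deliberately naive so they cannot share bugs with the package's DP and
# index code paths.

# log P(X, Y) by summing over every hidden path.
enum_hmm_joint <- function(params, x, y) {
  xi <- match(strsplit(x, "")[[1]], params$obs_alphabet_x)
  yi <- match(strsplit(y, "")[[1]], params$obs_alphabet_y)
  T <- length(xi)
  nH <- length(params$hidden_states)
  paths <- as.matrix(expand.grid(rep(list(seq_len(nH)), T)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    h <- paths[r, ]
    p <- params$p_init[h[1]]
    if (T > 1) for (t in 2:T) p <- p * params$p_trans[h[t - 1], h[t]]
    for (t in seq_len(T)) p <- p * params$p_emit[xi[t], yi[t], h[t]]
    tot <- tot + p
  }
  log(tot)
}

# log P^x(s) by summing exp(enum_hmm_joint) over every partner sequence.
enum_hmm_marginal_x <- function(params, s) {
  T <- nchar(s)
  others <- apply(
    expand.grid(rep(list(params$obs_alphabet_y), T)), 1, paste, collapse = "")
  log(sum(vapply(others, function(y) exp(enum_hmm_joint(params, s, y)), 0)))
}

# All latent event strings consuming exactly |x| and |y| symbols.
enum_sa_latents <- function(nx, ny) {
  if (nx == 0 && ny == 0) return("")
  out <- character(0)
  if (nx > 0 && ny > 0)
    out <- c(out, paste0("m", enum_sa_latents(nx - 1, ny - 1)))
  if (nx > 0) out <- c(out, paste0("d", enum_sa_latents(nx - 1, ny)))
  if (ny > 0) out <- c(out, paste0("i", enum_sa_latents(nx, ny - 1)))
  out
}

# log P(X, Y) under the alignment model by enumerating latent strings and
# scoring each with sa_path_probability.
enum_sa_joint <- function(params, x, y) {
  nx <- nchar(x); ny <- nchar(y)
  lats <- enum_sa_latents(nx, ny)
  lps <- vapply(lats, function(h) {
    ev <- strsplit(h, "")[[1]]
    xb <- character(length(ev)); yb <- character(length(ev))
    xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
    ix <- 0; iy <- 0
    for (t in seq_along(ev)) {
      if (ev[t] %in% c("m", "d")) { ix <- ix + 1; xb[t] <- xs[ix] } else xb[t] <- "-"
      if (ev[t] %in% c("m", "i")) { iy <- iy + 1; yb[t] <- ys[iy] } else yb[t] <- "-"
    }
    sa_path_probability(params, h, paste(xb, collapse = ""),
                        paste(yb, collapse = ""))
  }, 0)
  m <- max(lps)
  m + log(sum(exp(lps - m)))
}

# Literal prefix scan (the Prefix^x / Prefix^y definition, char by char).
scan_map <- function(index, s, axis, band_j) {
  strs <- if (axis == "x") index$buckets$s_x else index$buckets$s_y
  sc <- strsplit(s, "")[[1]]
  hits <- integer(0)
  for (k in seq_along(strs)) {
    bs <- strsplit(strs[k], "")[[1]]
    if (band_j + length(bs) - 1 > length(sc)) next
    if (length(bs) == 0 || all(sc[band_j + seq_along(bs) - 1] == bs))
      hits <- c(hits, index$buckets$bucket[k])
  }
  hits
}

# A hand-built index around explicit bucket strings (for mapping semantics).
manual_index <- function(s_x, s_y, alphabet = c("0", "1"), type = "hmm") {
  b <- data.table::data.table(
    bucket = seq_along(s_x), s_x = s_x, s_y = s_y,
    len_x = nchar(s_x), len_y = nchar(s_y),
    p_joint = rep(1 / length(s_x), length(s_x)),
    p_x = (1 / length(alphabet))^nchar(s_x),
    p_y = (1 / length(alphabet))^nchar(s_y))
  structure(list(type = type, buckets = b, alpha = sum(b$p_joint),
                 alpha_exact = TRUE, alpha_se = 0,
                 beta = sum(b$p_x * b$p_y), gamma_x = sum(b$p_x),
                 gamma_y = sum(b$p_y), eps_miss = 0.05, j_bands = 1L,
                 cfg = build_config(max_depth = max(nchar(c(s_x, s_y)), 1)),
                 model_hash = "manual",
                 alphabet_x = alphabet, alphabet_y = alphabet),
            class = c(paste0("dsb_", type, "_index"), "dsb_index"))
}

# Small structured alignment model with distinct entries (catches transposed
# index bugs that uniform tables would hide).
toy_sa_params <- function() {
  pm <- matrix(1:16, 4, 4)
  pm <- pm / sum(pm)
  sa_params(p_m = pm, p_i = c(0.1, 0.2, 0.3, 0.4), p_d = c(0.4, 0.3, 0.2, 0.1),
            q_match = 0.6, q_insertion = 0.15, q_deletion = 0.25)
}

rand_seq <- function(n, alphabet, seed) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
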