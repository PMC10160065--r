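## Exact probability computations and samplers for the two generative models.

#' Joint log-probability of an equal-length sequence pair under the HMM
#'
#' Computes \eqn{\log P(X, Y) = \log \sum_H P(X, Y | H) P(H)} by the forward
#' algorithm in \eqn{O(T |H|^2)} time.  The recursion is rescaled at every
#' step, so sequences thousands of symbols long do not underflow.
#'
#' @param params an [hmm_params()] object.
#' @param x,y character strings of equal length over the model's alphabets.
#' @return log-probability (scalar).
#' @export
hmm_forward_joint <- function(params, x, y) {
  xi <- encode_seq(x, params$obs_alphabet_x, "x")
  yi <- encode_seq(y, params$obs_alphabet_y, "y")
  if (length(xi) != length(yi)) stop("unequal lengths: |x| = ", length(xi),
                                     ", |y| = ", length(yi), call. = FALSE)
  if (length(xi) < 1L) stop("sequences must be non-empty", call. = FALSE)
  .hmm_forward_joint_cpp(xi, yi, params$p_init, params$p_trans,
                         as.numeric(params$p_emit),
                         length(params$obs_alphabet_x),
                         length(params$obs_alphabet_y))
}

#' Marginal log-probability of one sequence
#'
#' The independent ("background") model for a single sequence.  With
#' `method = "background"` (the default) this is the i.i.d. product of the
#' background table.  With `method = "exact"` the true marginal of the joint
#' HMM is computed by a forward pass over the emission table summed along the
#' other axis.
#'
#' @param params an [hmm_params()] object.
#' @param s character string over the axis alphabet.
#' @param axis `"x"` or `"y"`.
#' @param method `"background"` or `"exact"`.
#' @return log-probability.
#' @export
hmm_marginal <- function(params, s, axis = c("x", "y"),
                         method = c("background", "exact")) {
  axis <- match.arg(axis); method <- match.arg(method)
  alph <- if (axis == "x") params$obs_alphabet_x else params$obs_alphabet_y
  si <- encode_seq(s, alph, axis)
  if (length(si) < 1L) stop("sequence must be non-empty", call. = FALSE)
  if (method == "background") {
    bg <- if (axis == "x") params$px_background else params$py_background
    return(sum(log(bg[si + 1L])))
  }
  emitm <- if (axis == "x") apply(params$p_emit, c(1, 3), sum)
           else apply(params$p_emit, c(2, 3), sum)
  .hmm_forward_marginal_cpp(si, params$p_init, params$p_trans, emitm)
}

#' Log-likelihood-ratio alignment score under the HMM
#'
#' The alignment score \eqn{\log C_{X,Y} = \log P(X,Y) - \log P^x(X) - \log
#' P^y(Y)}.  Positive values favour the joint (truly aligned) model over the
#' independent one.
#'
#' @inheritParams hmm_forward_joint
#' @param marginal marginal mode passed to [hmm_marginal()].
#' @return log-likelihood ratio.
#' @export
hmm_llr <- function(params, x, y, marginal = c("background", "exact")) {
  marginal <- match.arg(marginal)
  hmm_forward_joint(params, x, y) -
    hmm_marginal(params, x, "x", marginal) -
    hmm_marginal(params, y, "y", marginal)
}

#' Log-probability of one explicit alignment path
#'
#' Given the latent event string and the gapped pre-sequences, multiplies the
#' per-event factors: `q_match * p_m(a, b)` for a match/mismatch column,
#' `q_deletion * p_d(a)` for a deletion column (gap in Y), and
#' `q_insertion * p_i(b)` for an insertion column (gap in X).  Returns
#' \eqn{\log P(X, Y | H) + \log P(H)}.
#'
#' @param params an [sa_params()] object.
#' @param latent string over `{m, i, d}`.
#' @param xbar,ybar gapped sequences of the same length as `latent`, with "-"
#'   exactly where `latent` is `i` (for `xbar`) or `d` (for `ybar`).
#' @return log-probability; 0 for the empty path.
#' @export
sa_path_probability <- function(params, latent, xbar, ybar) {
  ev <- strsplit(latent, "", fixed = TRUE)[[1]]
  xc <- strsplit(xbar, "", fixed = TRUE)[[1]]
  yc <- strsplit(ybar, "", fixed = TRUE)[[1]]
  if (length(xc) != length(ev) || length(yc) != length(ev))
    stop("latent, xbar, ybar must have equal lengths", call. = FALSE)
  if (length(ev) == 0L) return(0)
  bad <- which(!(ev %in% c("m", "i", "d")))
  if (length(bad)) stop("unknown event '", ev[bad[1]], "' at position ", bad[1],
                        call. = FALSE)
  for (t in seq_along(ev)) {
    gx <- xc[t] == "-"; gy <- yc[t] == "-"
    ok <- switch(ev[t], m = !gx && !gy, i = gx && !gy, d = !gx && gy)
    if (!ok) stop(sprintf(
      "gap pattern inconsistent with event '%s' at position %d", ev[t], t),
      call. = FALSE)
  }
  lp <- 0
  for (t in seq_along(ev)) {
    lp <- lp + switch(ev[t],
      m = log(params$q_match) + log(params$p_m[xc[t], yc[t]]),
      d = log(params$q_deletion) + log(params$p_d[xc[t]]),
      i = log(params$q_insertion) + log(params$p_i[yc[t]]))
  }
  unname(lp)
}

sa_factors <- function(params) {
  list(mf = params$q_match * params$p_m,
       df = params$q_deletion * unname(params$p_d),
       iff = params$q_insertion * unname(params$p_i))
}

#' Joint log-probability of a pair under the sequence alignment model
#'
#' Sums \eqn{P(X, Y | H) P(H)} over every latent event string consistent with
#' the observed lengths (exactly `|x|` non-insertion and `|y|` non-deletion
#' events) by the standard \eqn{O(|x| |y|)} pair dynamic programme
#' `F(i, j) = q_match p_m(x_i, y_j) F(i-1, j-1) + q_deletion p_d(x_i) F(i-1, j)
#' + q_insertion p_i(y_j) F(i, j-1)`, `F(0, 0) = 1`.
#'
#' @param params an [sa_params()] object.
#' @param x,y DNA strings (may be empty).
#' @return log-probability.
#' @export
sa_joint_probability <- function(params, x, y) {
  xi <- encode_seq(x, DNA, "x"); yi <- encode_seq(y, DNA, "y")
  f <- sa_factors(params)
  .sa_forward_cpp(xi, yi, f$mf, f$df, f$iff)
}

#' Log-likelihood-ratio alignment score under the sequence alignment model
#'
#' `sa_joint_probability(x, y)` minus the background log-probabilities of each
#' sequence.  Positive values favour a true alignment.
#'
#' @inheritParams sa_joint_probability
#' @return log-likelihood ratio; 0 when both sequences are empty.
#' @export
sa_llr <- function(params, x, y) {
  xi <- encode_seq(x, DNA, "x"); yi <- encode_seq(y, DNA, "y")
  f <- sa_factors(params)
  .sa_forward_cpp(xi, yi, f$mf, f$df, f$iff) -
    sum(log(unname(params$px_background)[xi + 1L])) -
    sum(log(unname(params$py_background)[yi + 1L]))
}

# Batched LLR for candidate verification; xs, ys are lists of 0-based codes.
sa_llr_batch <- function(params, xs, ys) {
  f <- sa_factors(params)
  lpx <- log(unname(params$px_background))
  lpy <- log(unname(params$py_background))
  joint <- .sa_forward_batch_cpp(xs, ys, f$mf, f$df, f$iff)
  joint - vapply(xs, function(v) sum(lpx[v + 1L]), 0) -
    vapply(ys, function(v) sum(lpy[v + 1L]), 0)
}

#' Sample a jointly generated pair from the HMM
#'
#' Simulates the hidden chain from `p_init` / `p_trans`, then one symbol pair
#' per step from `p_emit`.
#'
#' @param params an [hmm_params()] object.
#' @param T sequence length (>= 1).
#' @param seed optional integer; the call is deterministic given the seed and
#'   leaves the global RNG untouched.
#' @return list with `x`, `y` (strings) and `latent` (hidden-state names).
#' @export
sample_hmm_pair <- function(params, T, seed = NULL) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  with_seed(seed, {
    nH <- length(params$hidden_states)
    h <- integer(T)
    h[1] <- sample.int(nH, 1L, prob = params$p_init)
    if (T > 1) {
      u <- runif(T - 1L)
      cum <- t(apply(params$p_trans, 1, cumsum))
      for (t in 2:T) h[t] <- findInterval(u[t - 1L], cum[h[t - 1L], ]) + 1L
    }
    nA <- length(params$obs_alphabet_x); nB <- length(params$obs_alphabet_y)
    # joint emission: draw a cell of the |A| x |B| table, grouped by state
    cells <- integer(T)
    for (st in unique(h)) {
      at <- which(h == st)
      cells[at] <- sample.int(nA * nB, length(at), replace = TRUE,
                              prob = as.numeric(params$p_emit[, , st]))
    }
    xi <- (cells - 1L) %% nA
    yi <- (cells - 1L) %/% nA
    list(x = decode_seq(xi, params$obs_alphabet_x),
         y = decode_seq(yi, params$obs_alphabet_y),
         latent = params$hidden_states[h])
  })
}

#' Sample a jointly generated pair from the sequence alignment model
#'
#' Draws `S` latent events i.i.d. from `(q_match, q_insertion, q_deletion)`,
#' emits the gapped pre-sequences from the event tables, and strips the gaps.
#'
#' @param params an [sa_params()] object.
#' @param S number of latent events (>= 0).
#' @param seed optional integer seed.
#' @return list with `x`, `y`, `latent`, `xbar`, `ybar`.
#' @export
sample_sa_pair <- function(params, S, seed = NULL) {
  if (S < 0) stop("S must be >= 0", call. = FALSE)
  with_seed(seed, {
    if (S == 0) return(list(x = "", y = "", latent = "", xbar = "", ybar = ""))
    ev <- sample(c("m", "i", "d"), S, replace = TRUE,
                 prob = c(params$q_match, params$q_insertion, params$q_deletion))
    xb <- character(S); yb <- character(S)
    im <- ev == "m"
    if (any(im)) {
      cells <- sample.int(16L, sum(im), replace = TRUE,
                          prob = as.numeric(params$p_m))
      xb[im] <- DNA[(cells - 1L) %% 4L + 1L]
      yb[im] <- DNA[(cells - 1L) %/% 4L + 1L]
    }
    id <- ev == "d"
    if (any(id)) {
      xb[id] <- sample(DNA, sum(id), replace = TRUE, prob = params$p_d)
      yb[id] <- "-"
    }
    ii <- ev == "i"
    if (any(ii)) {
      yb[ii] <- sample(DNA, sum(ii), replace = TRUE, prob = params$p_i)
      xb[ii] <- "-"
    }
    list(x = paste(xb[xb != "-"], collapse = ""),
         y = paste(yb[yb != "-"], collapse = ""),
         latent = paste(ev, collapse = ""),
         xbar = paste(xb, collapse = ""), ybar = paste(yb, collapse = ""))
  })
}
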