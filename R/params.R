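#' Hidden Markov model over paired observations
#'
#' Constructs the joint generative model for equal-length sequence pairs
#' \eqn{(X, Y)}: a Markov chain of hidden states emits one symbol pair
#' \eqn{(x_t, y_t)} per step.  Truly aligned pairs are modelled as draws from
#' this joint model; unrelated pairs as draws from the independent background
#' models \eqn{P^x \cdot P^y}.
#'
#' @param hidden_states character vector naming the hidden states.
#' @param obs_alphabet_x,obs_alphabet_y character vectors of single-character
#'   observation symbols for the x and y sides.
#' @param p_init numeric vector of initial hidden-state probabilities.
#' @param p_trans row-stochastic transition matrix, `p_trans[i, j]` =
#'   P(next state = j | current = i).
#' @param p_emit numeric array of dimension `|A| x |B| x |H|`;
#'   `p_emit[a, b, h]` = P(x = a, y = b | state h).  Each slice must sum to 1.
#' @param px_background,py_background background symbol frequencies used by the
#'   independent model; default uniform.
#' @return An object of class `HMMParams`.
#' @examples
#' m <- hmm_binary_model(eps_error = 0.1, delta = 0.2)
#' hmm_llr(m, "0101", "0101")
#' @export
hmm_params <- function(hidden_states, obs_alphabet_x, obs_alphabet_y,
                       p_init, p_trans, p_emit,
                       px_background = NULL, py_background = NULL) {
  hidden_states  <- as.character(hidden_states)
  obs_alphabet_x <- as.character(obs_alphabet_x)
  obs_alphabet_y <- as.character(obs_alphabet_y)
  nH <- length(hidden_states); nA <- length(obs_alphabet_x); nB <- length(obs_alphabet_y)
  if (is.null(px_background)) px_background <- rep(1 / nA, nA)
  if (is.null(py_background)) py_background <- rep(1 / nB, nB)
  p_init <- as.numeric(p_init); p_trans <- as.matrix(p_trans)
  p_emit <- array(as.numeric(p_emit), dim = c(nA, nB, nH))
  obj <- structure(list(
    hidden_states = hidden_states,
    obs_alphabet_x = obs_alphabet_x, obs_alphabet_y = obs_alphabet_y,
    p_init = p_init, p_trans = p_trans, p_emit = p_emit,
    px_background = as.numeric(px_background),
    py_background = as.numeric(py_background)
  ), class = "HMMParams")
  validate_hmm_params(obj)
  obj
}

validate_hmm_params <- function(p, tol = 1e-8) {
  nH <- length(p$hidden_states)
  nA <- length(p$obs_alphabet_x); nB <- length(p$obs_alphabet_y)
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(nH >= 1 && nA >= 1 && nB >= 1, "empty alphabet")
  chk(!anyDuplicated(p$obs_alphabet_x) && !anyDuplicated(p$obs_alphabet_y),
      "duplicated observation symbols")
  chk(all(nchar(p$obs_alphabet_x) == 1L) && all(nchar(p$obs_alphabet_y) == 1L),
      "observation symbols must be single characters")
  probs <- c(p$p_init, p$p_trans, p$p_emit, p$px_background, p$py_background)
  chk(all(probs >= -tol & probs <= 1 + tol), "probabilities must lie in [0, 1]")
  chk(abs(sum(p$p_init) - 1) < tol, "p_init does not sum to 1")
  chk(length(p$p_init) == nH, "p_init length mismatch")
  chk(all(dim(p$p_trans) == c(nH, nH)), "p_trans dimension mismatch")
  chk(all(abs(rowSums(p$p_trans) - 1) < tol), "p_trans rows do not sum to 1")
  chk(all(dim(p$p_emit) == c(nA, nB, nH)), "p_emit dimension mismatch")
  esums <- apply(p$p_emit, 3, sum)
  chk(all(abs(esums - 1) < tol), "p_emit slices do not sum to 1")
  chk(abs(sum(p$px_background) - 1) < tol, "px_background does not sum to 1")
  chk(abs(sum(p$py_background) - 1) < tol, "py_background does not sum to 1")
  invisible(p)
}

#' Canonical two-state binary pair HMM
#'
#' The binary-alphabet instance used throughout the simulation experiments:
#' hidden state 0 emits mostly matching bits, hidden state 1 mostly
#' mismatching bits, and the chain flips state with probability `delta`.
#' Emission slice for state 0 is `[[0.5 - eps, eps], [eps, 0.5 - eps]]` and
#' for state 1 the complement; `eps_error` is the within-state error rate.
#'
#' @param eps_error error rate in `[0, 0.25]`..`[0, 0.5)`; off-diagonal mass of
#'   the matching state.
#' @param delta probability of switching hidden state between steps.
#' @param p_init initial state distribution (default uniform; the model
#'   definition leaves it free).
#' @return `HMMParams` over alphabets `{"0","1"}` with states `match`/`mismatch`.
#' @export
hmm_binary_model <- function(eps_error, delta, p_init = c(0.5, 0.5)) {
  stopifnot(eps_error >= 0, eps_error <= 0.5, delta >= 0, delta <= 1)
  e0 <- matrix(c(0.5 - eps_error, eps_error, eps_error, 0.5 - eps_error), 2, 2)
  e1 <- matrix(c(eps_error, 0.5 - eps_error, 0.5 - eps_error, eps_error), 2, 2)
  hmm_params(
    hidden_states = c("match", "mismatch"),
    obs_alphabet_x = c("0", "1"), obs_alphabet_y = c("0", "1"),
    p_init = p_init,
    p_trans = matrix(c(1 - delta, delta, delta, 1 - delta), 2, 2, byrow = TRUE),
    p_emit = array(c(e0, e1), dim = c(2, 2, 2)),
    px_background = c(0.5, 0.5), py_background = c(0.5, 0.5)
  )
}

DNA <- c("A", "C", "G", "T")

#' Sequence alignment model parameters
#'
#' The pair-HMM-like generator with insertions and deletions.  A latent event
#' string over `{m, i, d}` is drawn i.i.d. from
#' `(q_match, q_insertion, q_deletion)`; an `m` event emits a (possibly
#' mismatching) base pair jointly from `p_m`, a `d` event emits one base into
#' X from `p_d`, an `i` event one base into Y from `p_i`.  `q_match` covers
#' both matches and mismatches; substitution rate lives in the off-diagonal
#' mass of `p_m`.
#'
#' @param p_m 4x4 joint emission table over `{A,C,G,T} x {A,C,G,T}` (sums to 1).
#' @param p_i,p_d length-4 emission tables for insertion / deletion events.
#' @param q_match,q_insertion,q_deletion event probabilities, summing to 1.
#' @param px_background,py_background background base frequencies of the
#'   independent model (default uniform).
#' @return An object of class `SAParams`.
#' @examples
#' p <- sa_params_dna(sub_rate = 0.1, q_insertion = 0.1, q_deletion = 0.1)
#' sa_llr(p, "ACGTACGT", "ACGTACGT")
#' @export
sa_params <- function(p_m, p_i, p_d, q_match, q_insertion, q_deletion,
                      px_background = rep(0.25, 4), py_background = rep(0.25, 4)) {
  obj <- structure(list(
    p_m = matrix(as.numeric(p_m), 4, 4,
                 dimnames = list(DNA, DNA)),
    p_i = setNames(as.numeric(p_i), DNA),
    p_d = setNames(as.numeric(p_d), DNA),
    q_match = as.numeric(q_match), q_insertion = as.numeric(q_insertion),
    q_deletion = as.numeric(q_deletion),
    px_background = setNames(as.numeric(px_background), DNA),
    py_background = setNames(as.numeric(py_background), DNA)
  ), class = "SAParams")
  validate_sa_params(obj)
  obj
}

validate_sa_params <- function(p, tol = 1e-8) {
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  qs <- c(p$q_match, p$q_insertion, p$q_deletion)
  chk(all(qs >= -tol & qs <= 1 + tol), "event probabilities must lie in [0, 1]")
  chk(abs(sum(qs) - 1) < tol, "q_match + q_insertion + q_deletion must equal 1")
  chk(all(p$p_m >= -tol), "p_m entries must be non-negative")
  chk(abs(sum(p$p_m) - 1) < tol, "p_m does not sum to 1 over its 16 cells")
  chk(abs(sum(p$p_i) - 1) < tol, "p_i does not sum to 1")
  chk(abs(sum(p$p_d) - 1) < tol, "p_d does not sum to 1")
  chk(abs(sum(p$px_background) - 1) < tol, "px_background does not sum to 1")
  chk(abs(sum(p$py_background) - 1) < tol, "py_background does not sum to 1")
  invisible(p)
}

#' Convenience DNA sequence alignment model
#'
#' Builds an [sa_params()] object from interpretable error rates: uniform base
#' composition, `p_m` with diagonal mass `(1 - sub_rate)` split evenly over the
#' four bases and off-diagonal mass `sub_rate` split over the 12 mismatch
#' cells, and uniform insertion/deletion emissions.
#'
#' @param sub_rate substitution probability given a match event.
#' @param q_insertion,q_deletion event probabilities; `q_match` is the
#'   complement.
#' @return `SAParams`.
#' @export
sa_params_dna <- function(sub_rate, q_insertion, q_deletion) {
  stopifnot(sub_rate >= 0, sub_rate < 1, q_insertion >= 0, q_deletion >= 0,
            q_insertion + q_deletion < 1)
  pm <- matrix(0.25 * sub_rate / 3, 4, 4)
  diag(pm) <- 0.25 * (1 - sub_rate)
  sa_params(p_m = pm, p_i = rep(0.25, 4), p_d = rep(0.25, 4),
            q_match = 1 - q_insertion - q_deletion,
            q_insertion = q_insertion, q_deletion = q_deletion)
}

#' @export
print.HMMParams <- function(x, ...) {
  cat("Joint pair HMM:", length(x$hidden_states), "hidden states,",
      "alphabets", paste0("{", paste(x$obs_alphabet_x, collapse = ","), "}"),
      "x", paste0("{", paste(x$obs_alphabet_y, collapse = ","), "}\n"))
  invisible(x)
}

#' @export
print.SAParams <- function(x, ...) {
  cat(sprintf(
    "Sequence alignment model: q = (match %.3f, ins %.3f, del %.3f), P_m diag mass %.3f\n",
    x$q_match, x$q_insertion, x$q_deletion, sum(diag(x$p_m))))
  invisible(x)
}

## ---- symbol encoding -------------------------------------------------------

# Encode a string as 0-based integer codes over `alphabet`.  Errors name the
# first offending position.
encode_seq <- function(s, alphabet, what = "sequence") {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    stop(sprintf("unknown symbol '%s' at position %d of %s", chars[p], p, what),
         call. = FALSE)
  }
  idx - 1L
}

decode_seq <- function(codes, alphabet) paste(alphabet[codes + 1L], collapse = "")

## ---- config files ----------------------------------------------------------

#' Read model parameters from a YAML config file
#'
#' The file must contain `model: hmm` or `model: sa` plus the constructor
#' fields of [hmm_params()] / [sa_params()] (matrices as nested lists).  All
#' model invariants are validated and the first violation reported.
#'
#' @param path path to a YAML file.
#' @return `HMMParams` or `SAParams`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must name a 'model' (hmm or sa)")
  if (identical(cfg$model, "hmm")) {
    if (!is.null(cfg$eps_error)) {
      return(hmm_binary_model(cfg$eps_error, cfg$delta,
                              p_init = cfg$p_init %||% c(0.5, 0.5)))
    }
    hmm_params(
      hidden_states = cfg$hidden_states,
      obs_alphabet_x = cfg$obs_alphabet_x, obs_alphabet_y = cfg$obs_alphabet_y,
      p_init = unlist(cfg$p_init),
      p_trans = do.call(rbind, cfg$p_trans),
      p_emit = array(unlist(cfg$p_emit),
                     dim = c(length(cfg$obs_alphabet_x),
                             length(cfg$obs_alphabet_y),
                             length(cfg$hidden_states))),
      px_background = unlist(cfg$px_background),
      py_background = unlist(cfg$py_background)
    )
  } else if (identical(cfg$model, "sa")) {
    if (!is.null(cfg$sub_rate)) {
      return(sa_params_dna(cfg$sub_rate, cfg$q_insertion, cfg$q_deletion))
    }
    sa_params(
      p_m = do.call(rbind, cfg$p_m), p_i = unlist(cfg$p_i),
      p_d = unlist(cfg$p_d),
      q_match = cfg$q_match, q_insertion = cfg$q_insertion,
      q_deletion = cfg$q_deletion,
      px_background = unlist(cfg$px_background) %||% rep(0.25, 4),
      py_background = unlist(cfg$py_background) %||% rep(0.25, 4)
    )
  } else stop("unknown model type: ", cfg$model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable fingerprint of a model's numeric content, used to pair indexes with
# the parameters that built them (FNV-1a over the formatted parameter dump).
model_hash <- function(params) {
  txt <- paste(
    class(params)[1],
    paste(sprintf("%.17g", unlist(params[vapply(params, is.numeric, TRUE)])),
          collapse = ","),
    paste(unlist(params[!vapply(params, is.numeric, TRUE)]), collapse = ","),
    sep = "|")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}
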