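## Simulators for all experiments: HMM pair datasets, synthetic genomes with
## noisy long reads (tracked ground truth), and the sensitivity / false
## positive evaluation.

#' Simulate a database/query dataset from the binary pair HMM
#'
#' Draws `N` jointly generated pairs from the two-state binary model
#' ([hmm_binary_model()]): the x sides form the database, the y sides the
#' queries, and the truth table records the pairing.
#'
#' @param eps_error within-state error rate, `0 <= eps_error < 0.5`.
#' @param delta state-switch probability in `[0, 1]`.
#' @param T sequence length.
#' @param N number of pairs.
#' @param seed optional integer seed (byte-identical datasets per seed).
#' @return list with `database`, `queries` (named character vectors) and
#'   `truth` (`data.frame` with `db_id`, `query_id`).
#' @export
make_hmm_dataset <- function(eps_error, delta, T = 2000L, N = 100L,
                             seed = NULL) {
  stopifnot(eps_error >= 0, eps_error < 0.5, delta >= 0, delta <= 1, N >= 1)
  params <- hmm_binary_model(eps_error, delta)
  seeds <- derive_seeds(seed, N)
  pairs <- lapply(seq_len(N), function(i) sample_hmm_pair(params, T, seeds[[i]]))
  db <- setNames(vapply(pairs, `[[`, "", "x"), paste0("db", seq_len(N)))
  qs <- setNames(vapply(pairs, `[[`, "", "y"), paste0("q", seq_len(N)))
  list(database = db, queries = qs,
       truth = data.frame(db_id = names(db), query_id = names(qs),
                          stringsAsFactors = FALSE),
       params = params)
}

#' Simulate a reference genome and noisy long reads
#'
#' Uniform-random genome; read origins uniform; per-template-base error
#' process: deletion with probability `total_error * indel_frac / 2`,
#' substitution with `total_error * (1 - indel_frac)`, and an insertion of a
#' random base after each template base with `total_error * indel_frac / 2`.
#' Read lengths are jittered uniformly by +/-20% around `mean_len`; half the
#' reads are reverse-complemented (recorded in the truth strand).  Emulates
#' long noisy reads at a chosen total error rate; homopolymer-biased or
#' quality-aware error profiles are deliberately out of scope.
#'
#' @param genome_len reference length in bases.
#' @param n_reads number of reads.
#' @param mean_len mean read length (must be below `genome_len`).
#' @param total_error total per-base error rate (substitution + indel), `< 1`.
#' @param indel_frac fraction of the error budget spent on indels (split
#'   evenly between insertions and deletions); default 2/3, indel-dominant as
#'   in long-read chemistry.
#' @param seed optional integer seed.
#' @return list with `reference`, `reads` (named character vectors) and
#'   `truth` (`data.frame`: `read_id`, `ref_id`, `true_start`, `true_end`
#'   0-based half-open, `strand`, `error_rate_applied`).
#' @export
make_genome_reads <- function(genome_len, n_reads, mean_len = 700L,
                              total_error = 0.3, indel_frac = 2 / 3,
                              seed = NULL) {
  stopifnot(mean_len < genome_len, total_error >= 0, total_error < 1,
            indel_frac >= 0, indel_frac <= 1, n_reads >= 1)
  p_sub <- total_error * (1 - indel_frac)
  p_ind <- total_error * indel_frac / 2      # each of insertion, deletion
  with_seed(seed, {
    genome <- paste(sample(DNA, genome_len, replace = TRUE), collapse = "")
    reads <- character(n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      len <- round(mean_len * runif(1, 0.8, 1.2))
      len <- min(len, genome_len)
      start <- sample.int(genome_len - len + 1L, 1L)   # 1-based
      tmpl <- strsplit(substr(genome, start, start + len - 1L), "")[[1]]
      # one event draw per template base (a base cannot be both deleted and
      # substituted), plus an independent insertion slot after each base, so
      # the expected error count is exactly total_error per template base
      u <- runif(len)
      u_del <- u < p_ind
      u_sub <- u >= p_ind & u < p_ind + p_sub
      u_ins <- runif(len) < p_ind
      subs <- which(u_sub)
      if (length(subs)) {
        # substitute with one of the three other bases
        off <- sample.int(3L, length(subs), replace = TRUE)
        tmpl[subs] <- DNA[((match(tmpl[subs], DNA) - 1L + off) %% 4L) + 1L]
      }
      ins_base <- sample(DNA, len, replace = TRUE)
      keep <- !u_del
      # interleave surviving bases and insertions in template order
      parts <- character(2L * len)
      parts[2L * seq_len(len) - 1L] <- ifelse(keep, tmpl, "")
      parts[2L * seq_len(len)] <- ifelse(u_ins, ins_base, "")
      readseq <- paste(parts, collapse = "")
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") readseq <- revcomp(readseq)
      reads[i] <- readseq
      n_err <- sum(u_del) + length(subs) + sum(u_ins)
      truth[[i]] <- data.frame(
        read_id = paste0("read", i), ref_id = "ref1",
        true_start = start - 1L, true_end = start - 1L + len,
        strand = strand, error_rate_applied = n_err / len,
        stringsAsFactors = FALSE)
    }
    names(reads) <- paste0("read", seq_len(n_reads))
    list(reference = c(ref1 = genome), reads = reads,
         truth = do.call(rbind, truth))
  })
}

#' Score reported hits against simulation ground truth
#'
#' A truth row is recovered when some hit for that read, on the same
#' reference and strand, overlaps the true interval by at least
#' `overlap_frac` of the true length.  Hits overlapping no truth row at that
#' threshold are false positives.
#'
#' @param hits `data.frame` of hits (the `hits` element of
#'   [dsb_sa_search()] output), with `query_id`, `ref_id`, `strand`,
#'   `ref_start`, `ref_end`.
#' @param truth truth table from [make_genome_reads()].
#' @param overlap_frac required overlap fraction in `(0, 1]` (default 0.5).
#' @return list of class `EvalReport`: `sensitivity`, `n_true`,
#'   `n_recovered`, `n_false_positive`.
#' @export
evaluate_hits <- function(hits, truth, overlap_frac = 0.5) {
  if (is.null(truth) || nrow(truth) == 0L) stop("empty truth table", call. = FALSE)
  stopifnot(overlap_frac > 0, overlap_frac <= 1)
  n_true <- nrow(truth)
  if (nrow(hits) == 0L) {
    return(structure(list(sensitivity = 0, n_true = n_true, n_recovered = 0L,
                          n_false_positive = 0L), class = "EvalReport"))
  }
  m <- merge(hits, truth,
             by.x = c("query_id", "ref_id", "strand"),
             by.y = c("read_id", "ref_id", "strand"))
  if (nrow(m)) {
    m$ov <- pmin(m$ref_end, m$true_end) - pmax(m$ref_start, m$true_start)
    m$good <- m$ov >= overlap_frac * (m$true_end - m$true_start)
  }
  recovered <- if (nrow(m)) unique(m$query_id[m$good]) else character(0)
  # a hit is a false positive if it matches no truth row at the threshold
  hit_key <- paste(hits$query_id, hits$ref_id, hits$strand,
                   hits$ref_start, hits$ref_end)
  good_key <- if (nrow(m)) unique(paste(m$query_id, m$ref_id, m$strand,
                                        m$ref_start, m$ref_end)[m$good])
              else character(0)
  n_fp <- sum(!hit_key %in% good_key)
  structure(list(sensitivity = length(recovered) / n_true, n_true = n_true,
                 n_recovered = length(recovered),
                 n_false_positive = as.integer(n_fp)), class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("sensitivity %.3f (%d / %d recovered), %d false positive hit(s)\n",
              x$sensitivity, x$n_recovered, x$n_true, x$n_false_positive))
  invisible(x)
}
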