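# Planted-signal synthetic benchmark: random protein sequences, pseudo-PSSM
# profiles with an optional shared conservation motif injected into the
# PSSMs of interacting pairs, and balanced labeled pair sets. Gives every
# downstream stage a dataset with a known, tunable effect size.

#' Specify a synthetic PPI dataset
#'
#' Bundles the generator parameters. The interaction signal is a dataset-
#' level "motif": a 20-vector of residue-channel offsets added (scaled by
#' `signal_strength`) over a contiguous window of PSSM rows in both members
#' of every positive pair; negative-pair proteins carry no motif. White
#' noise of sd `noise_sd` is added to every PSSM, so `signal_strength = 0`
#' makes the two classes exchangeable.
#'
#' @param n_pos,n_neg Numbers of positive and negative pairs (each >= 1).
#' @param length_range Two-element integer range of sequence lengths,
#'   minimum >= 50 (mirroring the benchmark fragment filter).
#' @param signal_strength Non-negative scale of the planted motif
#'   (separation of the class-conditional descriptor means); default 3.
#' @param noise_sd Positive sd of the per-entry PSSM noise; default 1.
#' @param motif_len Rows of the motif window (default 20).
#' @param matrix_name Substitution matrix behind [pseudo_pssm()].
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 100, n_neg = 100,
                           length_range = c(50L, 150L),
                           signal_strength = 3, noise_sd = 1,
                           motif_len = 20L,
                           matrix_name = c("BLOSUM62", "PAM250"),
                           seed = 1L) {
  matrix_name <- match.arg(matrix_name)
  stopifnot(n_pos >= 1, n_neg >= 1, length(length_range) == 2L,
            length_range[[1L]] >= 50, length_range[[2L]] >= length_range[[1L]],
            signal_strength >= 0, noise_sd > 0,
            motif_len >= 1, motif_len <= length_range[[1L]])
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 signal_strength = signal_strength, noise_sd = noise_sd,
                 motif_len = as.integer(motif_len),
                 matrix_name = matrix_name, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate random protein sequences
#'
#' Sequences are i.i.d. uniform over the 20-letter alphabet with lengths
#' uniform in `spec$length_range`.
#'
#' @param n_proteins Number of sequences.
#' @param spec A [synthetic_spec()] (only `length_range` and `seed` are
#'   used).
#' @param id_prefix Prefix of the generated ids.
#' @return Tibble with `id` and `sequence` columns.
#' @export
gen_proteins <- function(n_proteins, spec = synthetic_spec(),
                         id_prefix = "syn") {
  stopifnot(n_proteins >= 1)
  set.seed(spec$seed)
  random_proteins(n_proteins, spec$length_range, id_prefix)
}

# Sequence generation under the caller's RNG state.
random_proteins <- function(n_proteins, length_range, id_prefix = "syn") {
  lens <- length_range[[1L]] - 1L +
    sample.int(length_range[[2L]] - length_range[[1L]] + 1L, n_proteins,
               replace = TRUE)
  tibble::tibble(
    id = sprintf("%s%04d", id_prefix, seq_len(n_proteins)),
    sequence = vapply(lens, function(L) {
      paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
    }, character(1)))
}

#' Synthesize one noisy, optionally motif-carrying PSSM
#'
#' Starts from the [pseudo_pssm()] of the sequence; if `motif` is given,
#' `signal_strength * motif` is added to each row of a contiguous window of
#' `motif_len` rows placed uniformly at random, and white noise of sd
#' `noise_sd` is added everywhere. In the limit `signal_strength = 0`,
#' `noise_sd -> 0` the output equals the pseudo-PSSM.
#'
#' @param sequence,protein_id Protein to profile.
#' @param motif Optional numeric 20-vector of residue-channel offsets.
#' @param spec A [synthetic_spec()] supplying `signal_strength`, `noise_sd`,
#'   `motif_len` and `matrix_name`. The caller's RNG state is used (seed the
#'   session, or use [gen_ppi_dataset()] which seeds from the spec).
#' @return A [new_pssm()] object.
#' @export
gen_synthetic_pssm <- function(sequence, protein_id, motif = NULL,
                               spec = synthetic_spec()) {
  base <- pseudo_pssm(sequence, protein_id, spec$matrix_name)
  scores <- unclass(base)
  L <- nrow(scores)
  if (!is.null(motif)) {
    stopifnot(length(motif) == 20L)
    w <- min(spec$motif_len, L)
    start <- sample.int(L - w + 1L, 1L)
    rows <- start:(start + w - 1L)
    scores[rows, ] <- scores[rows, ] +
      matrix(spec$signal_strength * motif, nrow = w, ncol = 20L, byrow = TRUE)
  }
  scores <- scores + matrix(stats::rnorm(L * 20L, sd = spec$noise_sd), L, 20L)
  rownames(scores) <- rownames(base)
  new_pssm(scores, protein_id)
}

#' Generate a labeled synthetic PPI dataset
#'
#' Draws one dataset-level motif (20 i.i.d. standard-normal channel
#' offsets), then builds `2 * (n_pos + n_neg)` proteins, each used in
#' exactly one pair: both members of a positive pair carry the motif in
#' their PSSMs, negative-pair proteins do not. The returned pair list is
#' shuffled.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `proteins` (tibble), `pssms` (named list of
#'   [new_pssm()] objects), `pairs` (tibble `id_a`, `id_b`, `label`), and
#'   `motif`.
#' @export
#' @examples
#' d <- gen_ppi_dataset(synthetic_spec(n_pos = 5, n_neg = 5, seed = 42))
#' d$pairs
gen_ppi_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  motif <- stats::rnorm(20L)
  n_pairs <- spec$n_pos + spec$n_neg
  proteins <- random_proteins(2L * n_pairs, spec$length_range)

  # proteins 1..2*n_pos form positive pairs, the rest negative pairs
  pssms <- vector("list", nrow(proteins))
  names(pssms) <- proteins$id
  for (i in seq_len(nrow(proteins))) {
    carries_motif <- i <= 2L * spec$n_pos
    pssms[[i]] <- gen_synthetic_pssm(
      proteins$sequence[[i]], proteins$id[[i]],
      motif = if (carries_motif) motif else NULL, spec = spec)
  }

  pairs <- tibble::tibble(
    id_a = proteins$id[seq(1L, 2L * n_pairs, by = 2L)],
    id_b = proteins$id[seq(2L, 2L * n_pairs, by = 2L)],
    label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg)))
  pairs <- pairs[sample.int(nrow(pairs)), ]

  list(proteins = proteins, pssms = pssms, pairs = pairs, motif = motif)
}
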