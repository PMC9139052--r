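# Sequence and PSSM input: FASTA reading, PSI-BLAST ASCII PSSM parsing,
# and a substitution-matrix pseudo-PSSM fallback so the pipeline runs
# without an external PSI-BLAST installation.

#' Canonical amino-acid channel order
#'
#' All PSSMs in this package carry their 20 amino-acid columns in the fixed
#' alphabetical-by-code order `ARNDCQEGHILKMFPSTWYV` (the PSI-BLAST header
#' order), so downstream linear algebra is order-stable regardless of the
#' source file's column layout.
#'
#' @return Character vector of the 20 standard amino-acid one-letter codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Construct a PSSM object
#'
#' A `pssm` is an L x 20 numeric matrix of per-position amino-acid scores
#' (rows: sequence positions; columns: residue channels in [aa_alphabet()]
#' order) with the source protein id attached. Row names hold the residue
#' letters of the query sequence when known.
#'
#' @param scores Numeric L x 20 matrix, all entries finite.
#' @param protein_id Non-empty string identifying the protein.
#' @return A `pssm` object.
#' @export
new_pssm <- function(scores, protein_id) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    rlang::abort("`scores` must be a numeric matrix")
  }
  if (ncol(scores) != 20L) {
    rlang::abort(sprintf("a PSSM must have exactly 20 columns, got %d", ncol(scores)))
  }
  if (nrow(scores) < 1L) {
    rlang::abort("a PSSM must have at least one row")
  }
  if (!all(is.finite(scores))) {
    rlang::abort("all PSSM entries must be finite")
  }
  if (!is.character(protein_id) || length(protein_id) != 1L || !nzchar(protein_id)) {
    rlang::abort("`protein_id` must be a single non-empty string")
  }
  storage.mode(scores) <- "double"
  colnames(scores) <- aa_alphabet()
  structure(scores, class = c("pssm", "matrix", "array"), protein_id = protein_id)
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> protein '%s': %d positions x 20 residue channels\n",
              attr(x, "protein_id"), nrow(x)))
  print(utils::head(unclass(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   each header) and `sequence` (upper-cased), one row per record, file
#'   order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) rlang::abort(sprintf("no FASTA records in %s", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    rlang::abort(sprintf("duplicate id %s in %s", dup[[1L]], path))
  }
  tibble::tibble(id = ids, sequence = unname(toupper(as.character(set))))
}

#' Drop sequence fragments below a minimum length
#'
#' Benchmark PPI sets conventionally exclude fragments shorter than 50
#' residues before profile construction; this applies that filter.
#'
#' @param proteins Tibble with `id` and `sequence` columns, as from
#'   [read_fasta()].
#' @param min_len Minimum retained sequence length (default 50).
#' @return The input tibble restricted to sequences of length >= `min_len`,
#'   order preserved.
#' @export
filter_min_length <- function(proteins, min_len = 50) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  dplyr::filter(proteins, nchar(.data$sequence) >= min_len)
}

#' Build a pseudo-PSSM from a substitution matrix
#'
#' Stand-in profile for pipelines without PSI-BLAST output: row m of the
#' result is the substitution-matrix row of residue m, so conserved residue
#' identity (but no alignment-derived information) is encoded. Non-standard
#' residues (X, B, Z, U, ...) map to an all-zero row: no information is
#' invented for them.
#'
#' @param sequence Amino-acid sequence string.
#' @param protein_id Identifier stored in the result.
#' @param matrix_name `"BLOSUM62"` (default) or `"PAM250"`.
#' @return A [new_pssm()] object of dimension `nchar(sequence)` x 20.
#' @export
#' @examples
#' pseudo_pssm("MKVLA", "demo")
pseudo_pssm <- function(sequence, protein_id = "protein",
                        matrix_name = c("BLOSUM62", "PAM250")) {
  matrix_name <- match.arg(matrix_name)
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  subst <- get_subst_matrix(matrix_name)
  letters20 <- aa_alphabet()
  residues <- strsplit(toupper(sequence), "")[[1L]]
  scores <- matrix(0, nrow = length(residues), ncol = 20L)
  known <- residues %in% letters20
  scores[known, ] <- subst[residues[known], letters20, drop = FALSE]
  rownames(scores) <- residues
  new_pssm(scores, protein_id)
}

# Substitution matrices shipped with Biostrings, fetched once per call.
get_subst_matrix <- function(matrix_name) {
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  env[[matrix_name]]
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the standard text PSSM emitted by `psiblast -out_ascii_pssm`:
#' header lines, then one row per residue holding the position index, the
#' residue letter, a first block of 20 integer log-odds scores and a second
#' block of 20 weighted percentages. The first (log-odds) block is returned;
#' columns are reordered from the file's header order to [aa_alphabet()].
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_id Identifier for the result; defaults to the file name
#'   without extension.
#' @return A [new_pssm()] object; `rownames()` give the query sequence.
#' @export
parse_psiblast_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])

  # Column-order header: the first line whose tokens are >= 20 single
  # amino-acid letters (it appears doubled, once per score block).
  is_header <- vapply(toks, function(tk) {
    length(tk) >= 20L && all(nchar(tk) == 1L) && all(tk[1:20] %in% aa_alphabet())
  }, logical(1))
  if (!any(is_header)) {
    rlang::abort(sprintf("no PSSM column header found in %s", path))
  }
  file_order <- toks[[which(is_header)[1L]]][1:20]

  # Residue rows: "<pos> <letter> <20 ints> [<20 ints> <extras>]"
  residues <- character(0)
  rows <- list()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) < 2L) next
    if (!grepl("^[0-9]+$", tk[[1L]])) next
    if (!(nchar(tk[[2L]]) == 1L && grepl("^[A-Za-z]$", tk[[2L]]))) next
    nums <- suppressWarnings(as.numeric(tk[-(1:2)]))
    nums <- nums[!is.na(nums)]
    if (length(nums) < 20L) {
      rlang::abort(sprintf(
        "malformed PSSM row at line %d of %s: expected 20 scores, found %d",
        i, path, length(nums)))
    }
    residues <- c(residues, toupper(tk[[2L]]))
    rows[[length(rows) + 1L]] <- nums[1:20]
  }
  if (length(rows) == 0L) {
    rlang::abort(sprintf("no residue rows found in %s", path))
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- file_order
  scores <- scores[, aa_alphabet(), drop = FALSE]
  rownames(scores) <- residues
  new_pssm(scores, protein_id)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Emits the minimal standard layout ([parse_psiblast_pssm()] round-trips it
#' bit-exactly on integer scores): two header lines, residue rows with the
#' log-odds block duplicated as the second block, and a blank footer.
#'
#' @param pssm A [new_pssm()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  letters20 <- aa_alphabet()
  residues <- rownames(pssm)
  if (is.null(residues)) residues <- rep("X", nrow(pssm))
  header <- paste0("          ",
                   paste(sprintf("%4s", c(letters20, letters20)), collapse = ""))
  body <- vapply(seq_len(nrow(pssm)), function(m) {
    sc <- sprintf("%4d", as.integer(round(pssm[m, ])))
    paste0(sprintf("%5d %s ", m, residues[[m]]),
           paste(c(sc, sc), collapse = ""))
  }, character(1))
  writeLines(c("", "Last position-specific scoring matrix computed", header, body, ""),
             path)
  invisible(path)
}

#' Optional logistic squashing of PSSM scores
#'
#' Element-wise `1 / (1 + exp(-x))`, mapping log-odds scores to (0, 1).
#' Off by default throughout the pipeline; exposed for users who prefer
#' bounded profile values.
#'
#' @param pssm A [new_pssm()] object.
#' @return A `pssm` with squashed scores.
#' @export
squash_pssm <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  out <- 1 / (1 + exp(-unclass(pssm)))
  rownames(out) <- rownames(pssm)
  new_pssm(out, attr(pssm, "protein_id"))
}

#' Read a protein-pair list
#'
#' Three tab- or comma-delimited columns `id_a`, `id_b`, `label` (label in
#' \{0, 1\}; 1 = interacting) with an optional header line; the label column
#' may be absent for prediction-only inputs.
#'
#' @param path Path to the pair list.
#' @return Tibble with columns `id_a`, `id_b` and, when present, integer
#'   `label`.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) rlang::abort(sprintf("empty pair list: %s", path))
  delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
  has_header <- grepl("id_a|id_b|label", first, ignore.case = TRUE)
  df <- readr::read_delim(path, delim = delim,
                          col_names = has_header,
                          show_col_types = FALSE, progress = FALSE,
                          comment = "#")
  if (!has_header) {
    names(df) <- c("id_a", "id_b", "label")[seq_len(ncol(df))]
  }
  if (!all(c("id_a", "id_b") %in% names(df))) {
    rlang::abort(sprintf("pair list %s must have columns id_a, id_b[, label]", path))
  }
  df$id_a <- as.character(df$id_a)
  df$id_b <- as.character(df$id_b)
  if ("label" %in% names(df)) {
    df$label <- as.integer(df$label)
    if (!all(df$label %in% c(0L, 1L))) {
      rlang::abort(sprintf("labels in %s must be 0 or 1", path))
    }
  }
  tibble::as_tibble(df)
}
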