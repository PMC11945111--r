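# SMILES handling: canonicalization, atom-level tokenization, vocabulary
# construction, Bemis-Murcko scaffold extraction and corpus file I/O.

# the standard atom-level SMILES token pattern: bracket atoms, two-letter
# halogens, %nn ring bonds, then single-character atoms/bonds/punctuation.
smiles_token_pattern <- paste0(
  "(\\[[^\\]]+\\]|Br|Cl|%[0-9]{2}|[0-9]|\\(|\\)|\\.|=|#|\\+|-|:|/|\\\\|~|",
  "\\*|\\$|@|>|[BCNOPSFI]|[bcnops])"
)

#' Canonicalize SMILES strings
#'
#' Maps each string to its toolkit-canonical form, so that string equality is
#' molecule identity (the basis of the uniqueness and novelty metrics).
#' Idempotent.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES.
#' @examples
#' \dontrun{smiles_canonicalize("OCC")  # "CCO"}
#' @export
smiles_canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), all(nzchar(smiles)))
  out <- rdkit_call("canon", smiles)
  bad <- !nzchar(out)
  if (any(bad)) {
    stop(
      "invalid SMILES (failed sanitization): ",
      paste(utils::head(smiles[bad], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# canonical form or NA for invalid input, no error
smiles_canonical_or_na <- function(smiles) {
  if (!length(smiles)) return(character(0))
  ok <- nzchar(smiles)
  out <- rep(NA_character_, length(smiles))
  if (any(ok)) {
    res <- rdkit_call("canon", smiles[ok])
    res[!nzchar(res)] <- NA_character_
    out[ok] <- res
  }
  out
}

#' Check SMILES validity
#'
#' @param smiles Character vector.
#' @return Logical vector: parses and sanitizes under the chemistry toolkit.
#' @export
smiles_is_valid <- function(smiles) !is.na(smiles_canonical_or_na(smiles))

#' Tokenize a SMILES string into atom-level tokens
#'
#' Multi-character units (`Cl`, `Br`, bracket atoms such as `[C@@H]`,
#' two-digit ring bonds `%10`) are single tokens. Tokenization does not
#' require chemical validity, only lexical well-formedness.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens whose concatenation reproduces the
#'   input exactly.
#' @examples
#' smiles_tokenize("c1ccccc1Cl")
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr(smiles_token_pattern, smiles, perl = TRUE)[[1]]
  tokens <- regmatches(smiles, list(m))[[1]]
  if (paste(tokens, collapse = "") != smiles) {
    stop("cannot tokenize SMILES '", smiles, "': unrecognized character span",
         call. = FALSE)
  }
  tokens
}

#' Reassemble tokens into a SMILES string
#'
#' Pure concatenation; the inverse of [smiles_tokenize()].
#' @param tokens Character vector of tokens.
#' @return A single string.
#' @export
smiles_detokenize <- function(tokens) paste(tokens, collapse = "")

#' Extract the Bemis-Murcko scaffold
#'
#' The ring systems plus the linkers connecting them, side chains removed;
#' acyclic molecules have an empty scaffold, returned as `""`.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of canonical scaffold SMILES (possibly `""`).
#' @export
extract_scaffold <- function(smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  out <- rdkit_call("scaffold", smiles)
  bad <- out == backend_invalid
  if (any(bad)) {
    stop(
      "invalid SMILES passed to extract_scaffold: ",
      paste(utils::head(smiles[bad], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

## ---- vocabulary -----------------------------------------------------------

vocab_specials <- c("<pad>", "<bos>", "<eos>")

#' Build a token vocabulary from a SMILES corpus
#'
#' The vocabulary holds the special tokens (PAD, BOS, EOS) followed by the
#' sorted union of all chemical tokens in the corpus, with bidirectional
#' token/index maps. Construction is deterministic: the same multiset of
#' SMILES always yields a byte-identical vocabulary.
#'
#' @param smiles Character vector of SMILES (the corpus).
#' @return A `smiles_vocabulary` object.
#' @export
build_vocabulary <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  toks <- unique(unlist(lapply(unique(smiles), smiles_tokenize)))
  toks <- sort(toks, method = "radix") # locale-independent order
  index_to_token <- c(vocab_specials, toks)
  token_to_index <- stats::setNames(seq_along(index_to_token), index_to_token)
  structure(
    list(
      index_to_token = index_to_token,
      token_to_index = token_to_index,
      pad_id = 1L, bos_id = 2L, eos_id = 3L
    ),
    class = "smiles_vocabulary"
  )
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<SMILES vocabulary: %d tokens (%d chemical + %d special)>\n",
    length(x$index_to_token), length(x$index_to_token) - length(vocab_specials),
    length(vocab_specials)
  ))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$index_to_token)

tokens_to_ids <- function(tokens, vocab, context = "sequence") {
  ids <- unname(vocab$token_to_index[tokens])
  if (anyNA(ids)) {
    stop(
      "out-of-vocabulary token(s) in ", context, ": ",
      paste(unique(tokens[is.na(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  as.integer(ids)
}

#' Encode a corpus tibble into padded id matrices and masks
#'
#' Each molecule row is `[token ids..., EOS, PAD...]`; the mask is `TRUE`
#' exactly on non-PAD positions. Scaffold rows follow the same convention,
#' with an empty scaffold encoding to `[EOS, PAD...]`.
#'
#' @param records Tibble with `smiles` and `scaffold` character columns (see
#'   [read_smiles()] / [generate_toy_corpus()]).
#' @param vocab A [build_vocabulary()] object.
#' @param max_len Maximum encoded length including the terminal EOS.
#' @return List with integer matrices `mol_ids`, `scaf_ids` and logical
#'   matrices `mol_mask`, `scaf_mask` (rows = molecules).
#' @export
encode_smiles_batch <- function(records, vocab, max_len = 128L) {
  stopifnot(is.data.frame(records), all(c("smiles", "scaffold") %in% names(records)))
  n <- nrow(records)
  stopifnot(n > 0L)
  encode_one <- function(s, what, i) {
    toks <- if (nzchar(s)) smiles_tokenize(s) else character(0)
    ids <- tokens_to_ids(toks, vocab, context = sprintf("%s of record %d ('%s')", what, i, s))
    if (length(ids) + 1L > max_len) {
      stop(sprintf("record %d: %s '%s' exceeds max_len %d", i, what, s, max_len),
           call. = FALSE)
    }
    c(ids, vocab$eos_id)
  }
  mols <- lapply(seq_len(n), function(i) encode_one(records$smiles[i], "molecule", i))
  scafs <- lapply(seq_len(n), function(i) encode_one(records$scaffold[i], "scaffold", i))
  to_mat <- function(rows) {
    L <- max(lengths(rows))
    ids <- matrix(vocab$pad_id, n, L)
    mask <- matrix(FALSE, n, L)
    for (i in seq_len(n)) {
      k <- length(rows[[i]])
      ids[i, seq_len(k)] <- rows[[i]]
      mask[i, seq_len(k)] <- TRUE
    }
    list(ids = ids, mask = mask)
  }
  m <- to_mat(mols)
  s <- to_mat(scafs)
  list(mol_ids = m$ids, mol_mask = m$mask, scaf_ids = s$ids, scaf_mask = s$mask)
}

## ---- file I/O -------------------------------------------------------------

#' Read a SMILES corpus from disk
#'
#' Accepts plain text (one SMILES per line, no header) or CSV with a named
#' SMILES column. Invalid lines are skipped with a warning and counted;
#' surviving records carry canonical SMILES and their Bemis-Murcko scaffold
#' (taken from `scaffold_column` when present and valid, otherwise computed).
#'
#' @param path File path.
#' @param smiles_column,scaffold_column Column names used when the file is a
#'   CSV (detected from the `.csv` extension or a header containing
#'   `smiles_column`).
#' @return A tibble with columns `smiles`, `scaffold` and attribute
#'   `n_skipped`.
#' @export
read_smiles <- function(path, smiles_column = "smiles",
                        scaffold_column = "scaffold") {
  stopifnot(file.exists(path))
  first <- c(readLines(path, n = 1L, warn = FALSE), "")[1]
  is_csv <- grepl("\\.csv$", path, ignore.case = TRUE) ||
    grepl(smiles_column, first, fixed = TRUE)
  if (is_csv) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!smiles_column %in% names(df)) {
      stop("CSV file lacks a '", smiles_column, "' column", call. = FALSE)
    }
    raw <- as.character(df[[smiles_column]])
    scaf_raw <- if (scaffold_column %in% names(df)) {
      as.character(df[[scaffold_column]])
    } else {
      NULL
    }
  } else {
    raw <- readLines(path, warn = FALSE)
    scaf_raw <- NULL
  }
  raw <- trimws(raw)
  keep_line <- nzchar(raw)
  raw <- raw[keep_line]
  if (!is.null(scaf_raw)) scaf_raw <- scaf_raw[keep_line]
  canon <- smiles_canonical_or_na(raw)
  valid <- !is.na(canon)
  n_skipped <- sum(!valid)
  if (n_skipped > 0L) {
    warning(n_skipped, " invalid SMILES line(s) skipped in ", path,
            call. = FALSE)
  }
  if (!any(valid)) stop("zero valid records in ", path, call. = FALSE)
  canon <- canon[valid]
  if (!is.null(scaf_raw)) {
    scaf <- scaf_raw[valid]
    scaf[is.na(scaf)] <- ""
    has <- nzchar(scaf)
    if (any(has)) scaf[has] <- smiles_canonicalize(scaf[has])
  } else {
    scaf <- extract_scaffold(canon)
  }
  out <- tibble::tibble(smiles = canon, scaffold = scaf)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a SMILES corpus
#'
#' `format = "smi"` writes one SMILES per line; `format = "csv"` writes
#' `smiles` and `scaffold` columns.
#'
#' @param records Tibble with at least a `smiles` column.
#' @param path Output file.
#' @param format `"smi"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(records, path, format = c("smi", "csv")) {
  format <- match.arg(format)
  if (format == "smi") {
    writeLines(records$smiles, path)
  } else {
    df <- tibble::tibble(
      smiles = records$smiles,
      scaffold = if ("scaffold" %in% names(records)) records$scaffold else ""
    )
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}
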