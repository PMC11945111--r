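# Seeded synthetic SMILES corpora: small ring systems decorated with side
# chains, valid by construction, so training, sampling and every metric can
# be exercised without any dataset download.

default_ring_systems <- c(
  "c1ccccc1",    # benzene
  "C1CCCCC1",    # cyclohexane
  "c1ccncc1",    # pyridine
  "C1CCCC1",     # cyclopentane
  "c1ccoc1",     # furan
  "C1CCNCC1"     # piperidine
)

default_side_chains <- c("C", "CC", "CCC", "O", "N", "F", "Cl", "OC")

#' Specification of a synthetic toy corpus
#'
#' Molecules are assembled by attaching side-chain fragments at substitutable
#' ring carbons of a template ring system, then canonicalizing. Generation is
#' a pure function of the spec (including its seed).
#'
#' @param n_molecules Number of molecules to draw (duplicates allowed — the
#'   corpus is a sample).
#' @param seed Integer seed.
#' @param ring_systems Character vector of scaffold SMILES templates.
#' @param side_chains Character vector of substituent fragments, attached as
#'   `(fragment)` branches.
#' @param max_substituents Maximum substituents per molecule.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules = 100L,
                         seed = 1L,
                         ring_systems = default_ring_systems,
                         side_chains = default_side_chains,
                         max_substituents = 2L) {
  stopifnot(
    n_molecules >= 0L, length(ring_systems) > 0L, length(side_chains) > 0L,
    max_substituents >= 0L
  )
  structure(
    list(
      n_molecules = as.integer(n_molecules),
      seed = as.integer(seed),
      ring_systems = ring_systems,
      side_chains = side_chains,
      max_substituents = as.integer(max_substituents)
    ),
    class = "fixture_spec"
  )
}

# positions (in token space) after which a "(chain)" branch may be inserted:
# ring carbons, skipping past any ring-closure digits that follow the atom
substitutable_positions <- function(tokens) {
  out <- integer(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (tokens[i] %in% c("C", "c")) {
      j <- i
      while (j < n && grepl("^[0-9]$|^%[0-9]{2}$", tokens[j + 1L])) j <- j + 1L
      out <- c(out, j)
    }
    i <- i + 1L
  }
  out
}

assemble_molecule <- function(template_tokens, positions, chains) {
  toks <- template_tokens
  ord <- order(positions, decreasing = TRUE)
  for (k in ord) {
    p <- positions[k]
    toks <- append(toks, c("(", smiles_tokenize(chains[k]), ")"), after = p)
  }
  smiles_detokenize(toks)
}

#' Generate a seeded toy SMILES corpus
#'
#' Every returned SMILES is valid and canonical; every record's scaffold
#' equals `extract_scaffold(smiles)`, which by construction is one of the
#' spec's ring systems.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble with columns `smiles` and `scaffold`, `spec$n_molecules`
#'   rows.
#' @export
generate_toy_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_molecules == 0L) {
    return(tibble::tibble(smiles = character(0), scaffold = character(0)))
  }
  tok_templates <- lapply(spec$ring_systems, smiles_tokenize)
  sub_pos <- lapply(tok_templates, substitutable_positions)
  raw <- local_seed(spec$seed, {
    vapply(seq_len(spec$n_molecules), function(i) {
      t_idx <- sample.int(length(tok_templates), 1L)
      pos <- sub_pos[[t_idx]]
      k <- sample.int(min(spec$max_substituents, length(pos)) + 1L, 1L) - 1L
      if (k > 0L) {
        at <- sort(pos[sample.int(length(pos), k)])
        chains <- sample(spec$side_chains, k, replace = TRUE)
        assemble_molecule(tok_templates[[t_idx]], at, chains)
      } else {
        smiles_detokenize(tok_templates[[t_idx]])
      }
    }, character(1))
  })
  canon <- smiles_canonical_or_na(raw)
  if (anyNA(canon)) {
    stop(
      "toy-corpus assembly produced invalid SMILES: ",
      paste(utils::head(raw[is.na(canon)], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(smiles = canon, scaffold = extract_scaffold(canon))
}

#' Corrupt a valid SMILES string (negative controls)
#'
#' Produces a string that fails chemical validity: `drop_ring_closure`
#' removes a ring-bond digit, `unbalance_paren` removes a closing
#' parenthesis, `bad_valence` grafts four fluorines onto one atom (re-drawn a
#' bounded number of times if the result happens to stay valid).
#'
#' @param smiles A single valid SMILES string.
#' @param mode One of `"drop_ring_closure"`, `"unbalance_paren"`,
#'   `"bad_valence"`.
#' @param seed Integer seed (used by `bad_valence` position draws).
#' @param max_retries Retry budget for `bad_valence`.
#' @return A single invalid SMILES string.
#' @export
corrupt_smiles <- function(smiles,
                           mode = c("drop_ring_closure", "unbalance_paren",
                                    "bad_valence"),
                           seed = 1L, max_retries = 10L) {
  mode <- match.arg(mode)
  stopifnot(length(smiles) == 1L, smiles_is_valid(smiles))
  toks <- smiles_tokenize(smiles)
  if (mode == "drop_ring_closure") {
    ring <- grep("^[0-9]$|^%[0-9]{2}$", toks)
    if (!length(ring)) {
      stop("no ring closure to drop in '", smiles, "'", call. = FALSE)
    }
    return(smiles_detokenize(toks[-ring[length(ring)]]))
  }
  if (mode == "unbalance_paren") {
    close <- which(toks == ")")
    if (!length(close)) {
      stop("no parenthesis to unbalance in '", smiles, "'", call. = FALSE)
    }
    return(smiles_detokenize(toks[-close[length(close)]]))
  }
  # bad_valence
  atom_pos <- which(toks %in% c("C", "c", "N", "n", "O", "o", "S", "s") |
                      grepl("^\\[", toks))
  if (!length(atom_pos)) stop("no atom to overload in '", smiles, "'", call. = FALSE)
  local_seed(seed, {
    for (r in seq_len(max_retries)) {
      p <- atom_pos[sample.int(length(atom_pos), 1L)]
      cand <- smiles_detokenize(
        append(toks, rep(c("(", "F", ")"), 4L), after = p)
      )
      if (!smiles_is_valid(cand)) return(cand)
    }
    stop("could not produce an invalid variant of '", smiles, "' within ",
         max_retries, " retries", call. = FALSE)
  })
}
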