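# Generative-chemistry evaluation: validity, uniqueness, novelty, internal
# diversity (Morgan/Tanimoto), scaffold-count cosine similarity, novel
# scaffold counting, QED/SAS/LogP profiling and Pareto-front selection.
# Except for validity, everything is computed on the valid subset.

valid_canonical <- function(smiles) {
  canon <- smiles_canonical_or_na(smiles)
  canon[!is.na(canon)]
}

#' Fraction of generated strings that are valid molecules
#'
#' @param gen Character vector of generated SMILES (possibly invalid).
#' @return Fraction in `[0, 1]`.
#' @export
mol_validity <- function(gen) {
  stopifnot(length(gen) > 0L)
  mean(smiles_is_valid(gen))
}

#' Fraction of distinct molecules among the valid ones
#'
#' Identity is canonical-SMILES string equality.
#' @inheritParams mol_validity
#' @export
mol_uniqueness <- function(gen) {
  canon <- valid_canonical(gen)
  if (!length(canon)) stop("no valid molecules to assess", call. = FALSE)
  length(unique(canon)) / length(canon)
}

#' Fraction of valid generated molecules absent from the training set
#'
#' @inheritParams mol_validity
#' @param train Character vector of training SMILES.
#' @export
mol_novelty <- function(gen, train) {
  canon <- valid_canonical(gen)
  if (!length(canon)) stop("no valid molecules to assess", call. = FALSE)
  train_canon <- valid_canonical(train)
  mean(!canon %in% train_canon)
}

# Morgan fingerprints (radius 2, 1024 bits) as a binary matrix over the
# valid subset; invalid inputs are dropped
fingerprint_matrix <- function(smiles) {
  res <- rdkit_call("fp", smiles)
  ok <- res != backend_invalid
  res <- res[ok]
  M <- matrix(0L, length(res), 1024L)
  for (i in seq_along(res)) {
    if (nzchar(res[i])) {
      M[i, as.integer(strsplit(res[i], " ", fixed = TRUE)[[1]]) + 1L] <- 1L
    }
  }
  M
}

# full pairwise Tanimoto matrix from a binary fingerprint matrix
tanimoto_matrix <- function(M) {
  inter <- tcrossprod(M)
  n_bits <- rowSums(M)
  union <- outer(n_bits, n_bits, "+") - inter
  T <- inter / union
  T[union == 0] <- 1 # two empty fingerprints are indistinguishable
  T
}

#' Internal diversity of a generated set
#'
#' `IntDiv_p = 1 - (mean over all ordered pairs, self-pairs included, of
#' T(s1, s2)^p)^(1/p)` with Tanimoto similarity over Morgan fingerprints
#' (radius 2, 1024 bits), computed on the valid subset.
#'
#' @inheritParams mol_validity
#' @param p Power of the mean (1 or 2).
#' @return Value in `[0, 1]`.
#' @export
internal_diversity <- function(gen, p = 1) {
  stopifnot(p %in% c(1, 2))
  canon <- valid_canonical(gen)
  if (!length(canon)) stop("no valid molecules to assess", call. = FALSE)
  T <- tanimoto_matrix(fingerprint_matrix(canon))
  1 - mean(T^p)^(1 / p)
}

#' Scaffold occurrence counts of a molecule set
#'
#' Bemis-Murcko scaffold per valid molecule; acyclic molecules count under
#' the empty-string key. Invalid molecules are skipped.
#'
#' @inheritParams mol_validity
#' @return Named integer vector of counts (names are canonical scaffold
#'   SMILES, possibly `""`).
#' @export
scaffold_counts <- function(gen) {
  canon <- valid_canonical(gen)
  if (!length(canon)) return(stats::setNames(integer(0), character(0)))
  scafs <- extract_scaffold(canon)
  tab <- table(factor(scafs, levels = sort(unique(scafs), method = "radix")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Cosine similarity between scaffold count vectors
#'
#' Over the union of scaffolds appearing in either set:
#' `sum(c_s(G) c_s(R)) / sqrt(sum c_s(G)^2) / sqrt(sum c_s(R)^2)`.
#'
#' @param gen,ref Character vectors of SMILES, or named count vectors from
#'   [scaffold_counts()].
#' @param drop_empty Drop the empty (acyclic) scaffold key before comparing.
#' @return Value in `[0, 1]`.
#' @export
scaffold_similarity <- function(gen, ref, drop_empty = FALSE) {
  as_counts <- function(x) {
    if (is.character(x) && is.null(names(x))) scaffold_counts(x) else x
  }
  cg <- as_counts(gen)
  cr <- as_counts(ref)
  if (drop_empty) {
    cg <- cg[names(cg) != ""]
    cr <- cr[names(cr) != ""]
  }
  if (!sum(cg) || !sum(cr)) {
    stop("scaffold count vector is empty", call. = FALSE)
  }
  # index-based assignment: the empty (acyclic) scaffold key "" is a legal
  # name here, and name-based replacement would silently append for it
  all_s <- union(names(cg), names(cr))
  g <- rep(0, length(all_s))
  r <- rep(0, length(all_s))
  g[match(names(cg), all_s)] <- cg
  r[match(names(cr), all_s)] <- cr
  sum(g * r) / (sqrt(sum(g^2)) * sqrt(sum(r^2)))
}

#' Count generated molecules carrying a novel (unseen) scaffold
#'
#' A molecule counts if it is valid, its Bemis-Murcko scaffold is non-empty,
#' and that scaffold is absent from `known_scaffolds`.
#'
#' @inheritParams mol_validity
#' @param known_scaffolds Character vector of canonical scaffold SMILES.
#' @return Integer count.
#' @export
count_novel_scaffolds <- function(gen, known_scaffolds) {
  canon <- valid_canonical(gen)
  if (!length(canon)) return(0L)
  scafs <- extract_scaffold(canon)
  sum(nzchar(scafs) & !scafs %in% known_scaffolds)
}

#' Per-molecule property profile: QED, SAS, LogP
#'
#' Drug-likeness (QED, in `[0,1]`), synthetic accessibility (SAS, 1 easy to
#' 10 hard) and Crippen LogP, computed on the valid subset.
#'
#' @inheritParams mol_validity
#' @return Tibble with columns `smiles`, `qed`, `sas`, `logp`, one row per
#'   valid molecule.
#' @export
property_profile <- function(gen) {
  canon <- valid_canonical(gen)
  if (!length(canon)) {
    return(tibble::tibble(smiles = character(0), qed = numeric(0),
                          sas = numeric(0), logp = numeric(0)))
  }
  res <- rdkit_call("props", canon)
  ok <- res != backend_invalid
  vals <- do.call(rbind, lapply(strsplit(res[ok], "\t", fixed = TRUE), as.numeric))
  tibble::tibble(
    smiles = canon[ok],
    qed = vals[, 1], sas = vals[, 2], logp = vals[, 3]
  )
}

#' Pareto front of a multi-objective matrix
#'
#' Returns the (1-based, input-order-stable) indices of rows not dominated
#' by any other row. Row `j` dominates row `i` when `j` is at least as good
#' in every objective and strictly better in at least one; `directions`
#' gives the sense per column.
#'
#' @param objectives Numeric matrix or data frame, one row per candidate.
#' @param directions Character vector (length 1 or `ncol`), each
#'   `"maximize"` or `"minimize"`.
#' @return Integer vector of non-dominated row indices.
#' @export
pareto_front <- function(objectives, directions = "maximize") {
  X <- as.matrix(objectives)
  stopifnot(nrow(X) >= 1L, is.numeric(X))
  if (anyNA(X) || any(!is.finite(X))) {
    stop("objectives must be finite and non-missing", call. = FALSE)
  }
  directions <- match.arg(directions, c("maximize", "minimize"),
                          several.ok = TRUE)
  if (length(directions) == 1L) directions <- rep(directions, ncol(X))
  stopifnot(length(directions) == ncol(X))
  X[, directions == "minimize"] <- -X[, directions == "minimize"]
  n <- nrow(X)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    ge <- rowSums(X >= matrix(X[i, ], n, ncol(X), byrow = TRUE)) == ncol(X)
    gt <- rowSums(X > matrix(X[i, ], n, ncol(X), byrow = TRUE)) > 0
    if (any(ge & gt)) keep[i] <- FALSE
  }
  which(keep)
}

#' Full evaluation report for a generated set
#'
#' Runs validity, uniqueness, novelty, IntDiv1/2 and (when a reference set
#' is supplied) scaffold similarity.
#'
#' @param gen Character vector of generated SMILES, or a file path readable
#'   by [read_smiles()].
#' @param train Training corpus (character vector or path) for novelty.
#' @param ref Optional reference set (character vector or path) for scaffold
#'   similarity; defaults to the training set.
#' @return One-row tibble (a metrics report).
#' @export
evaluate_molecules <- function(gen, train, ref = NULL) {
  as_smiles <- function(x) {
    if (length(x) == 1L && file.exists(x)) {
      read_smiles(x)$smiles
    } else {
      x
    }
  }
  gen <- as_smiles(gen)
  train <- as_smiles(train)
  ref <- if (is.null(ref)) train else as_smiles(ref)
  canon <- valid_canonical(gen)
  tibble::tibble(
    n_generated = length(gen),
    n_valid = length(canon),
    n_unique = length(unique(canon)),
    validity = mol_validity(gen),
    uniqueness = mol_uniqueness(gen),
    novelty = mol_novelty(gen, train),
    intdiv1 = internal_diversity(gen, p = 1),
    intdiv2 = internal_diversity(gen, p = 2),
    scaff = scaffold_similarity(gen, ref)
  )
}
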