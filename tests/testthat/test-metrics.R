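# Evaluation suite: closed forms, brute-force oracles, invariances

# independent double-loop IntDiv oracle working on on-bit index lists
intdiv_oracle <- function(smiles, p) {
  res <- md$rdkit_call("fp", smiles)
  bits <- lapply(strsplit(res, " ", fixed = TRUE), as.integer)
  n <- length(bits)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      inter <- length(intersect(bits[[i]], bits[[j]]))
      uni <- length(union(bits[[i]], bits[[j]]))
      t_ij <- if (uni == 0) 1 else inter / uni
      total <- total + t_ij^p
    }
  }
  1 - (total / n^2)^(1 / p)
}

test_that("validity, uniqueness and novelty match direct counting", {
  expect_identical(mol_validity(c("CCO", "c1ccccc1")), 1)
  expect_identical(mol_validity(c("CCO", "C1CC")), 0.5)
  corpus <- generate_toy_corpus(fixture_spec(n_molecules = 100, seed = 4))
  expect_identical(mol_validity(corpus$smiles), 1)

  expect_identical(mol_uniqueness(c("CCO", "OCC")), 0.5)
  expect_identical(mol_uniqueness(c("CCO", "CCN")), 1)
  expect_equal(mol_uniqueness(rep("CCO", 4)), 1 / 4)
  expect_error(mol_uniqueness(c("C1CC")), "no valid molecules")

  expect_identical(mol_novelty(c("CCO", "CCN"), c("CCO", "CCN")), 0)
  expect_identical(mol_novelty(c("CCO", "CCN"), c("c1ccccc1")), 1)
  expect_identical(mol_novelty(c("CCO", "CCN"), c("CCO")), 0.5)
  # canonical-form identity: OCC in gen is CCO in train
  expect_identical(mol_novelty(c("OCC"), c("CCO")), 0)
})

test_that("internal diversity agrees with the double-loop oracle", {
  corpus <- generate_toy_corpus(fixture_spec(n_molecules = 80, seed = 31))
  mols <- unique(corpus$smiles)[1:50]
  expect_length(mols, 50L)
  for (p in c(1, 2)) {
    expect_lt(abs(internal_diversity(mols, p = p) - intdiv_oracle(mols, p)),
              1e-9)
  }
})

test_that("internal diversity hits its closed forms at the extremes", {
  expect_equal(internal_diversity(rep("c1ccccc1", 5), p = 1), 0)
  expect_equal(internal_diversity(rep("c1ccccc1", 5), p = 2), 0)
  # two molecules with Tanimoto t: IntDiv1 = (1 - t) / 2
  pair <- c("CCO", "c1ccccc1")
  res <- md$rdkit_call("fp", pair)
  bits <- lapply(strsplit(res, " ", fixed = TRUE), as.integer)
  t12 <- length(intersect(bits[[1]], bits[[2]])) /
    length(union(bits[[1]], bits[[2]]))
  expect_equal(internal_diversity(pair, p = 1), (1 - t12) / 2, tolerance = 1e-12)
  # zero-similarity 4-set bound: IntDiv2 = 1 - (1/4)^(1/2) = 0.5 using a
  # synthetic zero-overlap fingerprint matrix
  M <- diag(4)
  T <- md$tanimoto_matrix(M)
  expect_equal(1 - mean(T^2)^(1 / 2), 0.5)
  expect_equal(1 - mean(T^1), 1 - 1 / 4)
})

test_that("scaffold counts and cosine similarity match hand arithmetic", {
  counts <- scaffold_counts(c("CC(=O)Nc1ccccc1", "CCc1ccccc1"))
  expect_identical(counts, c("c1ccccc1" = 2L))
  expect_identical(scaffold_counts("CCO"), c(1L) |> stats::setNames(""))
  expect_identical(scaffold_counts(character(0)),
                   stats::setNames(integer(0), character(0)))

  same <- c("CCc1ccccc1", "CC(=O)Nc1ccccc1", "CCC1CCCCC1")
  expect_equal(scaffold_similarity(same, same), 1, tolerance = 1e-12)
  expect_equal(scaffold_similarity(c("CCc1ccccc1"), c("CCC1CCCCC1")), 0)
  # G = {benzene: 2, pyridine: 1}, R = {benzene: 1} -> 2 / sqrt(5)
  g <- c("CCc1ccccc1", "CC(=O)Nc1ccccc1", "CCc1ccncc1")
  r <- c("Cc1ccccc1")
  expect_equal(scaffold_similarity(g, r), 2 / sqrt(5), tolerance = 1e-12)
  # symmetry and count-scale invariance
  expect_equal(scaffold_similarity(g, r), scaffold_similarity(r, g))
  expect_equal(scaffold_similarity(c(g, g), r), scaffold_similarity(g, r),
               tolerance = 1e-12)
  expect_error(scaffold_similarity(character(0), g), "empty")
  # acyclic molecules contribute the empty-string key on both sides
  with_acyclic <- c("CCO", "CCc1ccccc1")
  expect_equal(scaffold_similarity(with_acyclic, with_acyclic), 1,
               tolerance = 1e-12)
  expect_equal(
    scaffold_similarity(c("CCO", "CCc1ccccc1"), c("CCN", "Cc1ccccc1")),
    1, tolerance = 1e-12
  )
  expect_equal(scaffold_similarity(with_acyclic, with_acyclic, drop_empty = TRUE),
               1, tolerance = 1e-12)
  # one common scaffold out of {"", benzene} vs {benzene}: 1 / sqrt(2)
  expect_equal(scaffold_similarity(with_acyclic, "Cc1ccccc1"), 1 / sqrt(2),
               tolerance = 1e-12)
})

test_that("novel-scaffold counting excludes empty and known scaffolds", {
  known <- c("c1ccccc1")
  expect_identical(count_novel_scaffolds(c("CCc1ccccc1"), known), 0L)
  expect_identical(count_novel_scaffolds(c("CCc1ccncc1"), known), 1L)
  expect_identical(count_novel_scaffolds(c("CCO", "CCN"), known), 0L)
  expect_identical(count_novel_scaffolds(c("CCc1ccncc1", "CC1CCCCC1"), known), 2L)
})

test_that("property profiles have the documented ranges and signs", {
  mols <- c("CCO", "c1ccccc1", "CC(=O)Nc1ccccc1", "CCN")
  prof <- property_profile(mols)
  expect_identical(nrow(prof), 4L)
  expect_true(all(prof$qed >= 0 & prof$qed <= 1))
  expect_true(all(prof$sas >= 1 & prof$sas <= 10))
  expect_lt(prof$logp[prof$smiles == "CCO"], 0)   # ethanol is hydrophilic
  expect_gt(prof$logp[prof$smiles == "c1ccccc1"], 1)
  empty <- property_profile(character(0))
  expect_identical(nrow(empty), 0L)
})

test_that("pareto_front matches brute-force domination on random matrices", {
  brute <- function(X, dirs) {
    Y <- X
    Y[, dirs == "minimize"] <- -Y[, dirs == "minimize"]
    n <- nrow(Y)
    keep <- logical(n)
    for (i in seq_len(n)) {
      dominated <- FALSE
      for (j in seq_len(n)) {
        if (j == i) next
        if (all(Y[j, ] >= Y[i, ]) && any(Y[j, ] > Y[i, ])) {
          dominated <- TRUE
          break
        }
      }
      keep[i] <- !dominated
    }
    which(keep)
  }
  expect_identical(
    pareto_front(rbind(c(1, 1), c(2, 0), c(0, 2), c(0.5, 0.5))),
    c(1L, 2L, 3L)
  )
  expect_identical(pareto_front(matrix(c(1, 2), 1)), 1L)
  dup <- rbind(c(1, 2), c(1, 2), c(0, 0))
  expect_identical(pareto_front(dup), c(1L, 2L))
  expect_error(pareto_front(rbind(c(1, NA))), "finite")

  set.seed(77)
  for (rep in 1:100) {
    n <- sample(2:200, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k), n, k)
    if (rep %% 3 == 0) X[sample(n, 1), ] <- X[sample(n, 1), ] # inject ties
    dirs <- sample(c("maximize", "minimize"), k, replace = TRUE)
    got <- pareto_front(X, dirs)
    want <- brute(X, dirs)
    expect_identical(got, want)
  }
})

test_that("the evaluation report assembles all metrics coherently", {
  corpus <- generate_toy_corpus(fixture_spec(n_molecules = 40, seed = 2))
  rep1 <- evaluate_molecules(corpus$smiles, corpus$smiles)
  expect_identical(rep1$validity, 1)
  expect_identical(rep1$novelty, 0)
  expect_equal(rep1$scaff, 1, tolerance = 1e-12)
  expect_true(all(dplyr::select(rep1, validity:scaff) >= 0 &
                    dplyr::select(rep1, validity:scaff) <= 1))
  # from files, with one invalid generated line
  gen_path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c(corpus$smiles[1:9], "C1CC"), gen_path)
  train_path <- withr::local_tempfile(fileext = ".smi")
  write_smiles(corpus, train_path)
  suppressWarnings(rep2 <- evaluate_molecules(gen_path, train_path))
  expect_identical(rep2$n_generated, 9L)  # invalid line dropped at read time
  expect_identical(rep2$novelty, 0)
})
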