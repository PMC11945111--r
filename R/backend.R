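# Bridge to the bundled RDKit helper. All chemistry primitives -- validity,
# canonicalization, Bemis-Murcko scaffolds, Morgan fingerprints and property
# calculators -- run in one batched Python subprocess call per request, with a
# session-level cache so repeated queries are free.

.backend_cache <- new.env(parent = emptyenv())

backend_script <- function() {
  path <- system.file("python", "rdkit_backend.py", package = "moldistill")
  if (!nzchar(path)) {
    # during in-source development (pkgload) inst/ is mapped directly
    path <- system.file("inst", "python", "rdkit_backend.py", package = "moldistill")
  }
  if (!nzchar(path)) stop("rdkit_backend.py not found in installation", call. = FALSE)
  path
}

python_binary <- function() {
  bin <- Sys.getenv("MOLDISTILL_PYTHON", "python")
  if (!nzchar(Sys.which(bin))) {
    stop(
      "No '", bin, "' binary on PATH. The chemistry layer needs Python with ",
      "the rdkit package (see SystemRequirements).",
      call. = FALSE
    )
  }
  bin
}

rdkit_raw_call <- function(op, smiles) {
  infile <- tempfile("moldistill_smi_")
  outfile <- tempfile("moldistill_out_")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(smiles, infile, useBytes = TRUE)
  status <- system2(
    python_binary(), c(backend_script(), op),
    stdin = infile, stdout = outfile, stderr = FALSE
  )
  if (!identical(status, 0L)) {
    stop("RDKit backend call '", op, "' failed (status ", status, ")",
         call. = FALSE)
  }
  out <- readLines(outfile, warn = FALSE)
  if (length(out) != length(smiles)) {
    stop("RDKit backend returned ", length(out), " lines for ",
         length(smiles), " inputs", call. = FALSE)
  }
  out
}

# Vectorized, cached call. Returns a character vector aligned with `smiles`;
# the per-op invalid marker is preserved verbatim.
rdkit_call <- function(op, smiles) {
  stopifnot(is.character(smiles))
  if (!length(smiles)) return(character(0))
  cache_name <- paste0("op_", op)
  if (!exists(cache_name, envir = .backend_cache, inherits = FALSE)) {
    assign(cache_name, new.env(parent = emptyenv()), envir = .backend_cache)
  }
  cache <- get(cache_name, envir = .backend_cache)
  key <- paste0("s:", smiles) # avoid empty-string names
  miss <- !vapply(key, exists, logical(1), envir = cache, inherits = FALSE,
                  USE.NAMES = FALSE)
  todo <- unique(smiles[miss])
  if (length(todo)) {
    res <- rdkit_raw_call(op, todo)
    for (i in seq_along(todo)) {
      assign(paste0("s:", todo[i]), res[[i]], envir = cache)
    }
  }
  vapply(key, get, character(1), envir = cache, USE.NAMES = FALSE)
}

backend_invalid <- "__INVALID__"
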