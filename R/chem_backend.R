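#' Chemistry backend: a persistent RDKit helper process
#'
#' All chemistry in the package (sanitization, canonical SMILES, graph edits,
#' descriptors, fingerprints) goes through one long-lived helper process
#' running `inst/python/chem_worker.py` under the system `python`. Requests
#' and responses are single JSON lines, so a round trip costs about a
#' millisecond; results are memoized per canonical SMILES on the R side.
#'
#' @name chem-backend
NULL

chem_python <- function() {
  opt <- getOption("moldqn.python", Sys.getenv("MOLDQN_PYTHON", ""))
  if (nzchar(opt)) return(opt)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(unname(path))
  }
  stop("no python interpreter found on PATH; set options(moldqn.python=)")
}

chem_worker_script <- function() {
  path <- system.file("python", "chem_worker.py", package = "moldqn")
  if (!nzchar(path)) stop("chem_worker.py not found in the installed package")
  path
}

chem_worker_start <- function() {
  p <- processx::process$new(
    chem_python(), chem_worker_script(),
    stdin = "|", stdout = "|", stderr = "|"
  )
  .moldqn$worker <- p
  .moldqn$buf <- ""
  # First request doubles as a readiness check (rdkit import takes ~1 s).
  info <- chem_request("hello")
  .moldqn$backend_info <- list(rdkit = info$rdkit, python = chem_python())
  invisible(p)
}

chem_worker <- function() {
  p <- .moldqn$worker
  if (is.null(p) || !p$is_alive()) chem_worker_start()
  .moldqn$worker
}

#' Shut down the chemistry helper process
#'
#' Called automatically when the package is unloaded; safe to call at any
#' time (a new worker is started lazily on the next chemistry call).
#' @return Invisibly `TRUE`.
#' @export
chem_shutdown <- function() {
  p <- .moldqn$worker
  if (!is.null(p) && p$is_alive()) p$kill()
  .moldqn$worker <- NULL
  invisible(TRUE)
}

#' Report which chemistry backend is in use
#'
#' @return A list with the python interpreter path and RDKit version.
#' @export
chem_backend_info <- function() {
  chem_worker()
  .moldqn$backend_info
}

chem_read_line <- function(p, timeout_s = 300) {
  deadline <- Sys.time() + timeout_s
  repeat {
    nl <- regexpr("\n", .moldqn$buf, fixed = TRUE)
    if (nl > 0) {
      line <- substr(.moldqn$buf, 1L, nl - 1L)
      .moldqn$buf <- substr(.moldqn$buf, nl + 1L, nchar(.moldqn$buf))
      return(line)
    }
    if (!p$is_alive()) {
      err <- tryCatch(p$read_all_error(), error = function(e) "")
      stop("chemistry worker died: ", err)
    }
    p$poll_io(200)
    chunk <- p$read_output()
    if (nzchar(chunk)) .moldqn$buf <- paste0(.moldqn$buf, chunk)
    if (Sys.time() > deadline) stop("timeout waiting for chemistry worker")
  }
}

chem_request <- function(op, ...) {
  p <- if (op == "hello") .moldqn$worker else chem_worker()
  req <- list(op = op, ...)
  json <- jsonlite::toJSON(req, auto_unbox = TRUE, na = "null", digits = NA)
  p$write_input(paste0(json, "\n"))
  resp <- jsonlite::fromJSON(chem_read_line(p), simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) stop("chemistry backend error: ", resp$error)
  resp
}

cache_env <- function(name) {
  if (is.null(.moldqn[[name]])) .moldqn[[name]] <- new.env(parent = emptyenv())
  .moldqn[[name]]
}

#' Clear the package's chemistry memoization caches
#' @return Invisibly `TRUE`.
#' @export
chem_cache_reset <- function() {
  for (nm in c("parse_cache", "props_cache", "fp_cache", "action_cache", "seed_cache"))
    .moldqn[[nm]] <- new.env(parent = emptyenv())
  invisible(TRUE)
}

#' Parse and sanitize a molecule
#'
#' Parses a SMILES string with the backend, applies standard sanitization
#' (valence and aromaticity perception) and returns the canonical form plus
#' atom/bond tables. Stereochemistry is outside the edit operators' scope and
#' is dropped with a warning. The empty string denotes the empty molecule.
#'
#' @param smiles A single SMILES string (`""` for the empty molecule).
#' @return A list with elements `smiles` (canonical), `natoms`, `atoms`
#'   (data frame: `i` 0-based index, `el`, `fv` free valence, `ring`),
#'   `bonds` (data frame: `a`, `b`, `order`, `arom`, `ring`).
#' @export
parse_molecule <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  cache <- cache_env("parse_cache")
  hit <- cache[[paste0("s:", smiles)]]
  if (!is.null(hit)) return(hit)
  resp <- chem_request("parse", smiles = smiles)
  if (isTRUE(resp$had_stereo))
    warning("stereochemistry dropped from input molecule: ", smiles)
  out <- list(
    smiles = resp$smiles,
    natoms = resp$natoms,
    atoms = list_to_df(resp$atoms, c("i", "el", "fv", "ring")),
    bonds = list_to_df(resp$bonds, c("a", "b", "order", "arom", "ring"))
  )
  cache[[paste0("s:", smiles)]] <- out
  if (!identical(out$smiles, smiles)) cache[[paste0("s:", out$smiles)]] <- out
  out
}

list_to_df <- function(lst, cols) {
  if (length(lst) == 0L) {
    out <- lapply(cols, function(x) logical(0))
    names(out) <- cols
    return(as.data.frame(out))
  }
  out <- lapply(cols, function(cl) unlist(lapply(lst, `[[`, cl), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

seed_atoms <- function(elements) {
  cache <- cache_env("seed_cache")
  key <- paste(elements, collapse = ",")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  resp <- chem_request("seeds", elements = I(elements))
  out <- unlist(lapply(resp$smiles, function(x) if (is.null(x)) NA_character_ else x))
  out <- unique(out[!is.na(out)])
  cache[[key]] <- out
  out
}

# Apply a batch of single graph edits to one parent molecule.
# `edits` is a data frame with columns op ("addatom"/"bond") and the
# per-op fields (atom/el/order or a/b/order). Returns a data frame with
# ok, smiles, and a list-column `rings` of SSSR ring sizes through a newly
# created bond (empty for other edit types).
apply_edits <- function(smiles, edits) {
  if (nrow(edits) == 0L) {
    return(data.frame(ok = logical(0), smiles = character(0)))
  }
  # jsonlite serializes a data frame as an array of row objects, which is
  # exactly the worker's edit-list format (NA fields become null).
  resp <- chem_request("edits", smiles = smiles, edits = edits)
  res <- resp$results
  data.frame(
    ok = vapply(res, function(r) isTRUE(r$ok), logical(1)),
    smiles = vapply(res, function(r) if (is.null(r$smiles)) NA_character_ else r$smiles,
                    character(1)),
    rings = I(lapply(res, function(r) as.integer(unlist(r$rings)))),
    stringsAsFactors = FALSE
  )
}

#' Molecular property descriptors
#'
#' Vectorized descriptor lookup through the chemistry backend, memoized per
#' canonical SMILES. Available fields: `logp` (Wildman-Crippen logP), `sa`
#' (synthetic accessibility score), `qed` (quantitative estimate of
#' drug-likeness), `maxring` (largest SSSR ring size), `nring_gt6` (number of
#' rings with more than six atoms), `natoms`. The empty molecule scores 0 on
#' every field by convention.
#'
#' @param smiles Character vector of SMILES (may include `""`).
#' @param fields Character vector of descriptor names.
#' @return A data frame with one column per field, rows matching `smiles`.
#' @export
mol_props <- function(smiles, fields) {
  stopifnot(is.character(smiles), is.character(fields))
  cache <- cache_env("props_cache")
  out <- matrix(NA_real_, nrow = length(smiles), ncol = length(fields),
                dimnames = list(NULL, fields))
  need <- rep(FALSE, length(smiles))
  for (i in seq_along(smiles)) {
    hit <- cache[[paste0("s:", smiles[i])]]
    for (f in fields) {
      v <- if (is.null(hit)) NULL else hit[[f]]
      if (is.null(v)) need[i] <- TRUE else out[i, f] <- v
    }
  }
  if (any(need)) {
    todo <- unique(smiles[need])
    resp <- chem_request("props", smiles = I(todo), fields = I(fields))
    vals <- lapply(resp$props, function(col) vapply(col, as.numeric, numeric(1)))
    for (j in seq_along(todo)) {
      key <- paste0("s:", todo[j])
      hit <- cache[[key]]
      if (is.null(hit)) hit <- list()
      for (f in fields) hit[[f]] <- vals[[f]][j]
      cache[[key]] <- hit
    }
    idx <- match(smiles[need], todo)
    for (f in fields) out[need, f] <- vals[[f]][idx]
  }
  as.data.frame(out)
}

#' Morgan fingerprint on-bits
#'
#' Hashed circular-substructure (Morgan/ECFP-style) binary fingerprints,
#' returned as sorted 1-based on-bit indices. The empty molecule has no
#' substructures and maps to the all-zero fingerprint.
#'
#' @param smiles Character vector of SMILES.
#' @param radius Neighborhood radius (3 for the Q-network features, 2 for
#'   Tanimoto similarity).
#' @param nbits Fingerprint length in bits.
#' @return A list of integer vectors (possibly empty) of on-bit positions in
#'   `1:nbits`.
#' @export
morgan_onbits <- function(smiles, radius = 3L, nbits = 2048L) {
  stopifnot(is.character(smiles))
  cache <- cache_env("fp_cache")
  keys <- paste0(radius, ":", nbits, ":", smiles)
  out <- vector("list", length(smiles))
  need <- rep(FALSE, length(smiles))
  for (i in seq_along(smiles)) {
    hit <- cache[[keys[i]]]
    if (is.null(hit)) need[i] <- TRUE else out[[i]] <- hit
  }
  if (any(need)) {
    todo_idx <- which(need)
    todo <- smiles[todo_idx]
    uniq <- unique(todo)
    resp <- chem_request("fps", smiles = I(uniq), radius = radius, nbits = nbits)
    bits <- lapply(resp$onbits, function(b) as.integer(unlist(b)) + 1L)
    for (j in seq_along(uniq)) cache[[paste0(radius, ":", nbits, ":", uniq[j])]] <- bits[[j]]
    out[todo_idx] <- bits[match(todo, uniq)]
  }
  out
}

.onUnload <- function(libpath) {
  try(chem_shutdown(), silent = TRUE)
}
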