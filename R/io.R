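# File formats, fixtures and run manifests.
#
# Coordinates in all text formats are raw lattice integers so the
# invariants stay integer-exact; the Angstrom scaling exists only in the
# PDB C-alpha writer.

#' Read amino-acid sequences from a FASTA file
#'
#' Residues are uppercased and validated against the 20-letter alphabet;
#' ambiguity/non-standard codes (B, J, O, U, X, Z) are rejected with the
#' record name and position.
#'
#' @param path FASTA file.
#' @return A list of \code{\link{aa_sequence}} objects, in file order,
#'   named by record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("read_fasta needs the Biostrings package", call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path),
                              call. = FALSE)
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    chars <- toupper(strsplit(as.character(set[[k]]), "")[[1L]])
    bad <- which(!(chars %in% AA_ALPHABET))
    if (length(bad))
      stop(sprintf(
        "record '%s': non-standard residue '%s' at position %d",
        names(set)[k], chars[bad[1L]], bad[1L]), call. = FALSE)
    out[[k]] <- aa_sequence(chars)
  }
  names(out) <- names(set)
  out
}

#' Write / read a conformation as TSV
#'
#' Tab-separated text with a header and columns index, residue, x, y, z
#' (raw lattice integers). The reader re-validates every conformation
#' invariant and reports the offending row on failure; write-then-read is
#' the identity.
#'
#' @param conf an \code{"fcc_conformation"}.
#' @param path output/input file.
#' @return \code{read_conformation} returns the conformation;
#'   \code{write_conformation} returns \code{path} invisibly.
#' @export
write_conformation <- function(conf, path) {
  validate_conformation(conf)
  d <- data.frame(index = seq_along(conf$seq), residue = unclass(conf$seq),
                  x = conf$positions[, 1L], y = conf$positions[, 2L],
                  z = conf$positions[, 3L])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conformation
#' @export
read_conformation <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("index", "residue", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop(sprintf("conformation file must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  d <- d[order(d$index), ]
  seq <- aa_sequence(d$residue)
  pos <- as.matrix(d[, c("x", "y", "z")])
  conf <- tryCatch(conformation(seq, pos),
                   error = function(e)
                     stop(sprintf("invalid conformation in %s: %s", path,
                                  conditionMessage(e)), call. = FALSE))
  conf
}

#' Write a PDB C-alpha trace of a conformation
#'
#' One CA ATOM record per residue (chain A, residues 1..n). Lattice points
#' are scaled by 3.8/sqrt(2) Angstrom so sequence-adjacent residues sit
#' 3.8 Angstrom apart, the canonical CA-CA distance.
#'
#' @param conf an \code{"fcc_conformation"}.
#' @param path output PDB file.
#' @return \code{path}, invisibly.
#' @export
write_ca_trace <- function(conf, path) {
  validate_conformation(conf)
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("write_ca_trace needs the bio3d package", call. = FALSE)
  n <- length(conf$seq)
  xyz <- as.numeric(t(conf$positions)) * (3.8 / sqrt(2))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = seq_len(n),
                   resid = bio3d::aa123(unclass(conf$seq)),
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = rep("A", n))
  invisible(path)
}

#' Write / read a contact-potential table as plain text
#'
#' First line: the 20 one-letter codes (whitespace-separated) giving the
#' row/column order. Then 20 rows: either a full 20 x 20 matrix (validated
#' for symmetry to 1e-9) or a lower triangle (row i holding i values),
#' which is mirrored.
#'
#' @param table a \code{"contact_potential"}.
#' @param path file path.
#' @return \code{read_potential} returns the table.
#' @export
write_potential <- function(table, path) {
  stopifnot(inherits(table, "contact_potential"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(AA_ALPHABET, collapse = " "), con)
  for (i in 1:20)
    writeLines(paste(format(table$entries[i, ], digits = 10,
                            scientific = FALSE, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 21L)
    stop("potential file must be a header line plus 20 matrix rows",
         call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (!setequal(header, AA_ALPHABET) || length(header) != 20L)
    stop("header must list the 20 one-letter amino-acid codes",
         call. = FALSE)
  rows <- lapply(lines[-1L],
                 function(x) as.numeric(strsplit(trimws(x), "\\s+")[[1L]]))
  len <- lengths(rows)
  m <- matrix(NA_real_, 20L, 20L)
  if (all(len == 20L)) {
    for (i in 1:20) m[i, ] <- rows[[i]]
    if (max(abs(m - t(m))) > 1e-9)
      stop("full potential matrix is not symmetric (tolerance 1e-9)",
           call. = FALSE)
  } else if (all(len == seq_len(20L))) {
    for (i in 1:20) {
      m[i, 1:i] <- rows[[i]]
      m[1:i, i] <- rows[[i]]
    }
  } else {
    stop("matrix rows must form a full 20 x 20 or a lower triangle",
         call. = FALSE)
  }
  dimnames(m) <- list(header, header)
  potential_table(m, source_label = basename(path))
}

#' Generate seeded test fixtures
#'
#' \code{kind = "random_sequence"}: a FASTA file of random sequences over
#' the 20-letter alphabet (\code{params$length}, \code{params$count});
#' \code{kind = "uniform_table"}: a potential file with every pair at
#' \code{params$value}; \code{kind = "hp_table"}: hydrophobic-pair entries
#' at \code{params$value}, everything else 0. Identical seed and params
#' give identical files.
#'
#' @param kind one of "random_sequence", "uniform_table", "hp_table".
#' @param params list of kind-specific parameters (see above).
#' @param seed integer seed.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
generate_fixture <- function(kind = c("random_sequence", "uniform_table",
                                      "hp_table"),
                             params = list(), seed = 1L, path) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "random_sequence") {
    len <- params$length %||% 30L
    count <- params$count %||% 1L
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_len(count)) {
      writeLines(sprintf(">random_%d length=%d seed=%d", k, len, seed), con)
      writeLines(paste(sample(AA_ALPHABET, len, replace = TRUE),
                       collapse = ""), con)
    }
  } else if (kind == "uniform_table") {
    write_potential(uniform_potential(params$value %||% -1), path)
  } else {
    write_potential(hp_potential(params$value %||% -1), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random amino-acid sequence (in memory)
#'
#' Convenience wrapper used by tests and the acceptance script: a seeded
#' random sequence of the requested length over the 20-letter alphabet,
#' drawn from R's global RNG (seed upstream).
#'
#' @param n sequence length.
#' @return An \code{\link{aa_sequence}}.
#' @export
random_sequence <- function(n) {
  aa_sequence(sample(AA_ALPHABET, n, replace = TRUE))
}

#' Write a run manifest
#'
#' Every CLI run emits one JSON manifest next to its outputs recording the
#' command, input paths, configuration snapshot, seed, package version and
#' timestamps, so the run can be reproduced from the manifest alone.
#'
#' @param command command name.
#' @param inputs named list/character of input paths.
#' @param config configuration snapshot (list).
#' @param seed integer seed.
#' @param path output JSON path.
#' @param started,finished POSIXct timestamps.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(command, inputs, config, seed, path,
                           started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
    command = command,
    inputs = inputs,
    config = config,
    seed = seed,
    tool_version = as.character(utils::packageVersion("fccfold")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
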