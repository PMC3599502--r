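#' Read C-alpha traces from a PDB file
#'
#' Minimal fixed-column PDB reader tailored to alignment input: keeps ATOM
#' records with atom name `CA`, first altloc only (blank or `A`), first
#' MODEL only, and returns one [point_sequence()] per chain, in file order.
#' Coordinates are in Angstroms with the file's three-decimal precision
#' preserved; use [scale_to_integral()] for the integral regime.
#'
#' @param path PDB file path.
#' @param chains optional character vector of chain identifiers to keep.
#' @return named list of [point_sequence()]s (names are chain IDs).
#' @export
read_pdb_ca <- function(path, chains = NULL) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom) == 0L) stop("no ATOM records in ", path)
  name <- trimws(substr(atom, 13L, 16L))
  altloc <- substr(atom, 17L, 17L)
  keep <- name == "CA" & altloc %in% c(" ", "A", "")
  atom <- atom[keep]
  if (length(atom) == 0L) stop("no CA atoms in ", path)
  chain <- substr(atom, 22L, 22L)
  x <- as.numeric(substr(atom, 31L, 38L))
  y <- as.numeric(substr(atom, 39L, 46L))
  z <- as.numeric(substr(atom, 47L, 54L))
  if (is.null(chains)) chains <- unique(chain)
  out <- list()
  for (ch in chains) {
    idx <- which(chain == ch)
    if (length(idx) == 0L) next
    out[[ch]] <- point_sequence(cbind(x[idx], y[idx], z[idx]),
                                name = ch, protein_mode = FALSE)
  }
  out
}

#' Read a plain coordinate table
#'
#' One point per line, three columns (`x y z`), whitespace- or
#' comma-separated; integer or decimal values; lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @param ... passed to [point_sequence()] (e.g. `integral = TRUE`).
#' @return a [point_sequence()].
#' @export
read_points <- function(path, ...) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!startsWith(trimws(txt), "#") & nzchar(trimws(txt))]
  sep_comma <- any(grepl(",", txt, fixed = TRUE))
  m <- do.call(rbind, lapply(strsplit(txt, if (sep_comma) "[,[:space:]]+"
                                           else "[[:space:]]+"),
                             function(f) as.numeric(f[nzchar(f)])))
  point_sequence(m, name = basename(path), ...)
}

#' Write a plain coordinate table
#' @param P a [point_sequence()] or coordinate matrix.
#' @param path output file path.
#' @param sep column separator (default single space).
#' @export
write_points <- function(P, path, sep = " ") {
  m <- as_coord_matrix(P)
  utils::write.table(m, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rigid transform from a 12-number file
#'
#' Whitespace-separated: 9 numbers row-major rotation, then 3 translation.
#' @param path file path.
#' @return a [rigid_transform()].
#' @export
read_transform <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) != 12L) stop("transform file must contain 12 numbers")
  rigid_transform(matrix(v[1:9], 3L, byrow = TRUE), v[10:12], tol = 1e-6)
}

#' Read an index-pair mapping from a TSV file
#'
#' Two columns (i, j), 1-based, tab- or whitespace-separated; `#` comments
#' allowed.
#' @param path file path.
#' @return a [pair_mapping()].
#' @export
read_mapping <- function(path) {
  m <- utils::read.table(path, comment.char = "#",
                         col.names = c("i", "j"))
  pair_mapping(as.matrix(m))
}

#' Write an alignment result
#'
#' Writes the mapping as TSV (columns i, j, residual under the result's
#' transform) and returns the JSON summary (size, rmsd, method) invisibly.
#'
#' @param result an [alignment_result()].
#' @param P,Q the aligned [point_sequence()]s (for residuals).
#' @param path TSV output path, or `NULL` to skip the file.
#' @return (invisibly) the JSON summary string.
#' @export
write_alignment <- function(result, P, Q, path = NULL) {
  tab <- data.frame(i = result$mapping$pairs[, 1L],
                    j = result$mapping$pairs[, 2L])
  if (nrow(tab) > 0L && !is.null(result$transform)) {
    mc <- mapped_coords(P, Q, result$mapping)
    tab$residual <- sqrt(rowSums(
      (transform_points(mc$Q, result$transform) - mc$P)^2))
  }
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  js <- jsonlite::toJSON(list(size = result$size, rmsd = result$rmsd,
                              method = result$method, exact = result$exact),
                         auto_unbox = TRUE, digits = NA)
  invisible(as.character(js))
}
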