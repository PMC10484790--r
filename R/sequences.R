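#' Canonical amino-acid alphabet
#'
#' The fixed ordering of the 20 standard amino acids used for every
#' log-probability and LLR matrix in the package. All matrix rows/columns
#' named by amino acid follow this order.
#'
#' @return Character vector of 20 one-letter amino-acid codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_IDX <- stats::setNames(seq_along(.AA), .AA)

#' Construct a validated protein sequence
#'
#' @param id Character identifier.
#' @param residues Character scalar over the 20 canonical one-letter
#'   amino-acid codes (uppercased on input).
#' @param sanitize If `TRUE`, non-canonical letters (`U`, `X`, `B`, `Z`, `O`,
#'   `J`, `*`) are replaced by the placeholder residue `"A"` and the affected
#'   positions are recorded in the `sanitized_positions` field; if `FALSE`
#'   (default) any non-canonical letter is an error naming its position.
#' @return An object of class `protein_sequence` with fields `id`, `residues`
#'   and `length`.
#' @examples
#' p <- protein_sequence("prot1", "MKTAYIAKQR")
#' p$length
#' @export
protein_sequence <- function(id, residues, sanitize = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (length(chars) < 1L) {
    stop("protein sequence '", id, "' is empty", call. = FALSE)
  }
  bad <- which(!chars %in% .AA)
  sanitized <- integer(0)
  if (length(bad) > 0L) {
    if (!sanitize) {
      stop("non-canonical residue '", chars[bad[1]], "' at position ",
           bad[1], " in sequence '", id, "'", call. = FALSE)
    }
    chars[bad] <- "A"
    sanitized <- bad
    residues <- paste(chars, collapse = "")
  }
  structure(
    list(id = id, residues = residues, length = length(chars),
         sanitized_positions = sanitized),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (L = %d)\n", x$id, x$length))
  head <- substr(x$residues, 1, 60)
  cat(" ", head, if (x$length > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) x$length

# integer codes 1..20 in canonical alphabet order for each residue
aa_codes <- function(seq) {
  unname(.AA_IDX[strsplit(seq$residues, "", fixed = TRUE)[[1]]])
}

# subsequence extraction keeping a provenance-tagged id
subseq_protein <- function(seq, start, end, tag = NULL) {
  stopifnot(start >= 1L, end <= seq$length, start <= end)
  id <- if (is.null(tag)) seq$id else paste0(seq$id, "|", tag)
  protein_sequence(id, substr(seq$residues, start, end))
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]. Record ids are taken
#' from headers up to the first whitespace, sequences are uppercased, and a
#' trailing stop symbol `*` is stripped with a warning.
#'
#' @param path Path to a FASTA file.
#' @param sanitize Passed to [protein_sequence()].
#' @return A named list of `protein_sequence` objects.
#' @export
read_fasta <- function(path, sanitize = FALSE) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id '", ids[duplicated(ids)][1], "' in '", path, "'",
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) == 0L) stop("empty FASTA record '", ids[i], "'", call. = FALSE)
    if (endsWith(s, "*")) {
      warning("stripping trailing stop symbol '*' from record '", ids[i], "'",
              call. = FALSE)
      s <- substr(s, 1L, nchar(s) - 1L)
    }
    out[[i]] <- protein_sequence(ids[i], s, sanitize = sanitize)
  }
  stats::setNames(out, ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs List of `protein_sequence` objects.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    starts <- seq(1L, s$length, by = width)
    writeLines(substring(s$residues, starts,
                         pmin(starts + width - 1L, s$length)), con)
  }
  invisible(path)
}
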