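#' Aligned clone sequence sets
#'
#' An `aligned_clone_set` holds a gapped multiple alignment of clone
#' sequences over the alphabet `A, C, G, T, N, -`. All rows must have the
#' same width and clone identifiers must be unique and non-empty. This is
#' the raw observable of the whole screening procedure: clones are compared
#' to a majority-rule consensus and their deviations treated as candidate
#' PCR errors.
#'
#' Leading and trailing runs of `-` in a clone are interpreted as partial
#' read padding (reads shorter than the amplicon), not as deletions;
#' interior gaps are deletion events. The read span of a clone is the
#' interval from its first to its last non-gap column.
#'
#' @param sequences character vector of aligned sequences (may contain
#'   `-` gaps and `N`), or a named character vector.
#' @param ids clone identifiers; defaults to `names(sequences)`.
#' @return An object of class `aligned_clone_set`: a list with elements
#'   `ids` (character), `mat` (character matrix, clones x columns, upper
#'   case), `width`, and `n`.
#' @examples
#' acs <- aligned_clone_set(c(cl1 = "ACGT", cl2 = "ACGA", cl3 = "AC-T"))
#' acs$width
#' @export
aligned_clone_set <- function(sequences, ids = names(sequences)) {
  if (length(sequences) == 0L) {
    stop("empty input: at least one aligned sequence is required")
  }
  if (is.null(ids)) ids <- names(sequences) # before names are stripped
  sequences <- toupper(as.character(sequences))
  if (is.null(ids)) {
    ids <- paste0("clone", seq_along(sequences))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("clone ids must be unique and non-empty")
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop(sprintf(
      "ragged alignment: row widths differ (%s)",
      paste(range(widths), collapse = "-")
    ))
  }
  if (widths[1] < 1L) stop("alignment width must be >= 1")
  mat <- matrix(
    unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
    nrow = length(sequences), byrow = TRUE,
    dimnames = list(ids, NULL)
  )
  bad <- setdiff(unique(as.vector(mat)), PCRSCREEN_STATES)
  if (length(bad) > 0L) {
    stop(sprintf(
      "unsupported characters in alignment: %s (IUPAC ambiguity codes other than N are rejected)",
      paste(sQuote(bad), collapse = ", ")
    ))
  }
  structure(
    list(ids = ids, mat = mat, width = widths[1], n = length(sequences)),
    class = "aligned_clone_set"
  )
}

#' @export
print.aligned_clone_set <- function(x, ...) {
  cat(sprintf(
    "aligned_clone_set: %d clones x %d columns\n", x$n, x$width
  ))
  invisible(x)
}

#' @export
as.character.aligned_clone_set <- function(x, ...) {
  setNames(apply(x$mat, 1, paste, collapse = ""), x$ids)
}

#' Read span of each clone
#'
#' First and last non-gap column of every clone; all-gap rows get span
#' `(NA, NA)`. Columns outside the span are partial-read padding and are
#' never scored.
#'
#' @param clones an [aligned_clone_set()].
#' @return integer matrix with columns `first` and `last`, one row per clone.
#' @export
read_spans <- function(clones) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  t(apply(clones$mat != "-", 1, function(ng) {
    w <- which(ng)
    if (length(w) == 0L) c(NA_integer_, NA_integer_) else range(w)
  })) -> sp
  colnames(sp) <- c("first", "last")
  rownames(sp) <- clones$ids
  sp
}

# logical matrix: TRUE where a clone scores the column, i.e. the column
# lies within the read span and the clone's state is not N
scored_matrix <- function(clones) {
  sp <- read_spans(clones)
  cols <- seq_len(clones$width)
  within <- !is.na(sp[, 1]) &
    outer(sp[, 1], cols, `<=`) & outer(sp[, 2], cols, `>=`)
  within & clones$mat != "N"
}

#' Read an aligned FASTA file of clone sequences
#'
#' Gap character `-`, case-insensitive; `N` is the only ambiguity code
#' accepted (other IUPAC codes are rejected with an informative error).
#'
#' @param path path to an aligned FASTA file.
#' @return an [aligned_clone_set()].
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read FASTA file: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(seqs))
  aligned_clone_set(as.character(seqs), ids = ids)
}

#' Write an aligned clone set to FASTA
#'
#' @param clones an [aligned_clone_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(clones, path) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  seqs <- as.character(clones)
  writeLines(
    as.vector(rbind(paste0(">", names(seqs)), unname(seqs))),
    path
  )
  invisible(path)
}
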