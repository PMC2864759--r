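#' Replicon constructor
#'
#' A replicon is an independently replicating DNA molecule (chromosome or
#' plasmid). Sequences are upper-cased on construction and validated against
#' the DNA alphabet `A/C/G/T/N`; `U` is rejected (DNA-only scope).
#'
#' @param id Replicon identifier.
#' @param seq Nucleotide sequence (string).
#' @param circular Is the molecule circular? Default `TRUE`.
#' @return An object of class `replicon` with fields `id`, `seq`, `circular`
#'   and `length`.
#' @export
replicon <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id),
            is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("replicon '", id, "': empty sequence")
  check_alphabet(seq, "nucleotide", id)
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 length = nchar(seq)),
            class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

check_alphabet <- function(seq, alphabet = c("nucleotide", "protein"), id = "?") {
  alphabet <- match.arg(alphabet)
  allowed <- if (alphabet == "nucleotide") NUC_ALPHABET else AA_ALPHABET
  bad <- regexpr(sprintf("[^%s]", paste(allowed, collapse = "")), seq)
  if (bad > 0) {
    stop(sprintf("record '%s': illegal %s character '%s' at offset %d",
                 id, alphabet, substr(seq, bad, bad), as.integer(bad)))
  }
  invisible(TRUE)
}

#' Read a FASTA file with strict validation
#'
#' Records are upper-cased and validated against the requested alphabet
#' (nucleotide: `ACGTN`; protein: the 20 standard residues plus `X`).
#' Duplicate identifiers, illegal characters and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Named character vector of sequences, input order preserved.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: '", dup[1], "'")
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop("record '", ids[i], "': empty sequence")
    check_alphabet(seqs[[i]], alphabet, ids[i])
  }
  seqs
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

ANNOTATION_COLUMNS <- c("gene_id", "replicon", "category", "cog_classes",
                        "feature_type", "element_name")
ANNOTATION_CATEGORIES <- c("assigned", "conserved_hypothetical", "hypothetical")
FEATURE_TYPES <- c("CDS", "tRNA", "rRNA", "IS_element", "transposon", "other")

#' Read a gene annotation table
#'
#' The annotation dialect is a TSV with header columns `gene_id`, `replicon`,
#' `category`, `cog_classes`, `feature_type`, `element_name`. `category` must
#' be one of `assigned`, `conserved_hypothetical`, `hypothetical`;
#' `feature_type` one of `CDS`, `tRNA`, `rRNA`, `IS_element`, `transposon`,
#' `other`. `cog_classes` is a string of single-letter COG class codes
#' (possibly empty); letters outside the 25 standard classes are rejected.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of validated annotation rows.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  missing <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing))
    stop("annotation table missing column: '", missing[1], "'")
  df <- df[, ANNOTATION_COLUMNS]
  validate_annotation(df)
  df
}

validate_annotation <- function(df) {
  bad <- which(!df$category %in% ANNOTATION_CATEGORIES)
  if (length(bad))
    stop(sprintf("line %d: unknown category '%s'", bad[1] + 1L,
                 df$category[bad[1]]))
  bad <- which(!df$feature_type %in% FEATURE_TYPES)
  if (length(bad))
    stop(sprintf("line %d: unknown feature_type '%s'", bad[1] + 1L,
                 df$feature_type[bad[1]]))
  letters_ok <- vapply(strsplit(df$cog_classes, ""), function(x)
    all(x %in% COG_CLASSES), logical(1))
  if (any(!letters_ok)) {
    bad <- which(!letters_ok)[1]
    stop(sprintf("line %d: invalid COG class string '%s'", bad + 1L,
                 df$cog_classes[bad]))
  }
  invisible(df)
}

#' Write motif hits as BED6
#'
#' Intervals are 0-based half-open; the BED score column carries the mismatch
#' count and the name column the motif name. Input must be sorted by start.
#'
#' @param hits Data.frame of motif hits (columns `start`, `end`, `strand`,
#'   `mismatches`, `motif`), as returned by [scan_motif()].
#' @param replicon_id Chromosome name for the BED `chrom` column.
#' @param path Output path.
#' @param L Optional replicon length; if given, intervals extending past `L`
#'   (circular wrap-around hits) are an error.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, replicon_id, path, L = NULL) {
  if (nrow(hits)) {
    if (is.unsorted(hits$start)) stop("hits must be sorted by start")
    if (any(hits$start < 0) || any(hits$end <= hits$start))
      stop("invalid interval: need 0 <= start < end")
    if (!is.null(L) && any(hits$end > L))
      stop("interval extends past replicon length ", L,
           " (circular wrap-around hit); linearize before BED export")
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", replicon_id,
                     as.integer(hits$start), as.integer(hits$end),
                     hits$motif, as.integer(hits$mismatches), hits$strand)
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of motif hits
#'
#' Inverse of [write_bed()]; used for round-tripping hit sets.
#'
#' @param path Path to a BED6 file.
#' @return Data.frame with columns `start`, `end`, `strand`, `mismatches`,
#'   `motif` (empty if the file is empty).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      motif = character(0), stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 6) stop("not a BED6 file: ", path)
  data.frame(start = as.integer(df[[2]]), end = as.integer(df[[3]]),
             strand = df[[6]], mismatches = as.integer(df[[5]]),
             motif = df[[4]], stringsAsFactors = FALSE)
}
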