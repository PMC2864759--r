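IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Parse a degenerate consensus motif
#'
#' Accepts plain bases, parenthesized alternation (`"(A/T)"`) and IUPAC
#' ambiguity codes, e.g. the DnaA box `"TTATCCACA"` or the RepA repeat
#' `"CGCAGAA(A/T)(C/T)(A/G)GGTACG(C/T)"`.
#'
#' @param text Consensus string.
#' @param name Motif name (defaults to the consensus text).
#' @return A list of class `motif`: `name`, `positions` (list of allowed-base
#'   sets), `length`, `n_expansions` (product of set sizes).
#' @export
parse_consensus <- function(text, name = text) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  chars <- strsplit(toupper(text), "")[[1]]
  positions <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      close <- which(chars == ")" & seq_along(chars) > i)
      if (!length(close)) stop("unbalanced parentheses in consensus: ", text)
      close <- close[1]
      inner <- chars[(i + 1):(close - 1)]
      alts <- inner[inner != "/"]
      if (!length(alts) || length(alts) != sum(inner == "/") + 1)
        stop("malformed alternation in consensus: ", text)
      set <- unique(unlist(lapply(alts, function(a) {
        if (is.null(IUPAC_SETS[[a]])) stop("illegal character '", a,
                                           "' in consensus: ", text)
        IUPAC_SETS[[a]]
      })))
      positions[[length(positions) + 1L]] <- sort(set)
      i <- close + 1
    } else if (ch == ")") {
      stop("unbalanced parentheses in consensus: ", text)
    } else {
      if (is.null(IUPAC_SETS[[ch]]))
        stop("illegal character '", ch, "' in consensus: ", text)
      positions[[length(positions) + 1L]] <- IUPAC_SETS[[ch]]
      i <- i + 1
    }
  }
  structure(list(name = name, positions = positions,
                 length = length(positions),
                 n_expansions = prod(lengths(positions))),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s: length %d, %d expansion(s)\n", x$name, x$length,
              x$n_expansions))
  invisible(x)
}

#' Built-in named motifs
#'
#' `dnaA_box` is the 9-bp DnaA-binding box consensus `TTATCCACA`
#' (conventionally scanned with a budget of two mismatches); `repA_repeat`
#' is the 17-nt RepA-binding repeat consensus
#' `CGCAGAA(A/T)(C/T)(A/G)GGTACG(C/T)` (scanned exactly).
#'
#' @param name One of `"dnaA_box"`, `"repA_repeat"`.
#' @return A `motif` (see [parse_consensus()]).
#' @export
builtin_motif <- function(name = c("dnaA_box", "repA_repeat")) {
  name <- match.arg(name)
  switch(name,
         dnaA_box = parse_consensus("TTATCCACA", "dnaA_box"),
         repA_repeat = parse_consensus("CGCAGAA(A/T)(C/T)(A/G)GGTACG(C/T)",
                                       "repA_repeat"))
}

motif_mask <- function(motif) {
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(motif$positions, function(s) sum(bit[s]), integer(1))
}

#' Scan a replicon for a degenerate motif with a mismatch budget
#'
#' A window matches with `m` mismatches where `m` counts positions whose
#' base is outside the allowed set (a base matching any member of a
#' degenerate position costs 0; `N` in the subject never matches). Minus
#' strand hits are matches of the reverse-complemented motif, reported in
#' forward coordinates (start of the leftmost matched base). Circular scans
#' wrap across the origin, in which case `end` may exceed `L`. All
#' overlapping hits are reported; output is sorted by `(start, strand)`.
#'
#' @param rep A [replicon()] (or a plain sequence string).
#' @param motif A `motif` from [parse_consensus()]/[builtin_motif()], or a
#'   consensus string.
#' @param max_mismatches Mismatch budget; must be `< motif length`.
#' @param strands `"+"`, `"-"` or `"both"`.
#' @param circular Wrap across the origin? Defaults to the replicon's flag.
#' @return Data.frame with columns `start`, `end` (0-based half-open),
#'   `strand`, `mismatches`, `motif`.
#' @export
scan_motif <- function(rep, motif, max_mismatches = 0, strands = "both",
                       circular = NULL) {
  if (is.character(rep)) rep <- replicon("seq", rep, circular = TRUE)
  stopifnot(inherits(rep, "replicon"))
  if (is.character(motif)) motif <- parse_consensus(motif)
  stopifnot(inherits(motif, "motif"))
  if (max_mismatches >= motif$length)
    stop("max_mismatches must be smaller than the motif length")
  strands <- match.arg(strands, c("+", "-", "both"))
  circular <- circular %||% rep$circular
  hits <- .scan_motif(rep$seq, motif_mask(motif), as.integer(max_mismatches),
                      strands %in% c("+", "both"),
                      strands %in% c("-", "both"), circular)
  hits$end <- hits$start + motif$length
  hits$motif <- rep(motif$name, nrow(hits))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("start", "end", "strand", "mismatches", "motif")]
}

#' Cluster motif hits into box regions
#'
#' Single-linkage clustering on the 1-D start coordinates: consecutive hits
#' whose start gap is at most `max_gap` join one cluster. On circular
#' replicons (when `L` is given) the first and last clusters merge if they
#' are within `max_gap` across the origin.
#'
#' @param hits Data.frame of hits from [scan_motif()].
#' @param max_gap Maximum start-to-start gap (bp) within a cluster.
#' @param L Replicon length, enabling the circular wrap merge.
#' @return List of clusters, each a list with `hits` (data.frame),
#'   `span_start`, `span_end`, `n`, `n_perfect`; sorted by `span_start`.
#' @export
cluster_hits <- function(hits, max_gap, L = NULL) {
  if (!nrow(hits)) return(list())
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  gaps <- diff(hits$start)
  cl_id <- cumsum(c(1L, as.integer(gaps > max_gap)))
  clusters <- lapply(split(seq_len(nrow(hits)), cl_id), function(idx) {
    h <- hits[idx, , drop = FALSE]
    list(hits = h, span_start = min(h$start), span_end = max(h$end),
         n = nrow(h), n_perfect = sum(h$mismatches == 0))
  })
  names(clusters) <- NULL
  if (!is.null(L) && length(clusters) > 1) {
    first <- clusters[[1]]; last <- clusters[[length(clusters)]]
    wrap_gap <- (first$hits$start[1] + L) - max(last$hits$start)
    if (wrap_gap <= max_gap) {
      merged <- list(hits = rbind(last$hits, first$hits),
                     span_start = last$span_start,
                     span_end = first$span_end, # wraps the origin
                     n = last$n + first$n,
                     n_perfect = last$n_perfect + first$n_perfect)
      clusters <- c(list(merged), clusters[-c(1L, length(clusters))])
    }
  }
  clusters[order(vapply(clusters, `[[`, numeric(1), "span_start"))]
}
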