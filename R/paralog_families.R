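#' Mask low-complexity protein segments
#'
#' Sliding-window Shannon-entropy filter: every window of `window` residues
#' whose entropy (bits) falls below `entropy_threshold` is replaced by `X`
#' runs. Masking is applied iteratively until a fixed point, so the
#' operation is idempotent. This plays the role of the usual low-complexity
#' filters run before all-vs-all similarity searches, which exist to stop
#' compositionally biased segments (homopolymer runs, simple repeats) from
#' creating spurious similarity edges.
#'
#' Entropy is computed over the non-`X` residues of each window (so already
#' masked material neither re-triggers nor hides the filter), windows more
#' than half masked are left alone, and masking iterates to a fixed point,
#' which makes the operation idempotent.
#'
#' @param seq Protein sequence.
#' @param window Window length (default 12).
#' @param entropy_threshold Entropy cutoff in bits (default 2.2; a uniform
#'   random 12-mer over 20 residues has entropy about 3.4 bits, a
#'   homopolymer 0).
#' @return The masked sequence.
#' @export
mask_low_complexity <- function(seq, window = 12, entropy_threshold = 2.2) {
  chars <- strsplit(seq, "")[[1]]
  if (window > length(chars)) return(seq)
  repeat {
    ent <- window_entropy(chars, window)
    low <- which(ent < entropy_threshold)
    changed <- FALSE
    for (s in low) {
      idx <- s:(s + window - 1)
      if (any(chars[idx] != "X")) { chars[idx] <- "X"; changed <- TRUE }
    }
    if (!changed) break
  }
  paste(chars, collapse = "")
}

window_entropy <- function(chars, window) {
  n <- length(chars) - window + 1
  vapply(seq_len(n), function(s) {
    w <- chars[s:(s + window - 1)]
    w <- w[w != "X"]
    if (length(w) < window / 2) return(Inf) # mostly masked: leave alone
    tab <- table(w)
    p <- tab / length(w)
    -sum(p * log2(p))
  }, numeric(1))
}

#' Build a within-proteome similarity graph
#'
#' All-vs-all search of a (masked) proteome against itself; a directed edge
#' `u -> v` is recorded for every above-threshold hit of query `u`
#' (self-hits excluded). Thresholds are percent identity and coverage of
#' the smaller protein, a deliberate proxy for an E-value cutoff.
#'
#' @param proteome Named character vector of protein sequences.
#' @param min_identity Minimal percent identity for an edge (default 30).
#' @param min_coverage Minimal coverage of the smaller protein (default 0.5).
#' @param mask Apply [mask_low_complexity()] before searching? Default TRUE.
#' @param ... Passed to the search ([all_vs_all()] parameters:
#'   `prefilter_kmer`, `min_shared_kmers`, scoring).
#' @return A list of class `sim_graph`: `nodes`, `edges` (data.frame with
#'   `from`, `to`, `score`, `identity_pct`, `coverage_smaller`, query-span
#'   columns), `params`, and `seqs` (the masked sequences, kept for
#'   re-alignment during symmetrification).
#' @export
build_similarity_graph <- function(proteome, min_identity = 30,
                                   min_coverage = 0.5, mask = TRUE, ...) {
  stopifnot(is.character(proteome), !is.null(names(proteome)))
  seqs <- if (mask) vapply(proteome, mask_low_complexity, character(1))
          else proteome
  df <- sw_search_df(seqs, seqs, exclude_same_id = TRUE, ...)
  keep <- df$identity_pct >= min_identity & df$coverage_smaller >= min_coverage
  edges <- df[keep, , drop = FALSE]
  edges <- data.frame(from = edges$query, to = edges$subject,
                      score = edges$score, identity_pct = edges$identity_pct,
                      coverage_smaller = edges$coverage_smaller,
                      q_start = edges$q_start, q_end = edges$q_end,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = names(proteome), edges = edges,
                 params = list(min_identity = min_identity,
                               min_coverage = min_coverage),
                 seqs = seqs),
            class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("<sim_graph> %d proteins, %d directed edges (identity >= %g%%, coverage >= %g)\n",
              length(x$nodes), nrow(x$edges), x$params$min_identity,
              x$params$min_coverage))
  invisible(x)
}

#' Flag putative multi-domain proteins
#'
#' A protein with at least two similarity neighbors is flagged when some two
#' of its neighbors (i) align to spans of the protein that overlap by less
#' than `overlap_frac` of the shorter span and (ii) are not themselves
#' connected in the graph - the signature of a fusion of unrelated domains,
#' which would otherwise glue unrelated families together during transitive
#' closure.
#'
#' @param graph A `sim_graph` from [build_similarity_graph()].
#' @param overlap_frac Minimum span overlap (fraction of the shorter span)
#'   below which two neighbors are considered to hit separate domains
#'   (default 0.2).
#' @return Character vector of flagged protein ids.
#' @export
flag_multidomain <- function(graph, overlap_frac = 0.2) {
  e <- graph$edges
  connected <- function(u, v)
    any(e$from == u & e$to == v) || any(e$from == v & e$to == u)
  flagged <- character(0)
  for (u in unique(e$from)) {
    eu <- e[e$from == u, , drop = FALSE]
    if (nrow(eu) < 2) next
    for (i in seq_len(nrow(eu) - 1)) {
      for (j in (i + 1):nrow(eu)) {
        ov <- min(eu$q_end[i], eu$q_end[j]) - max(eu$q_start[i], eu$q_start[j])
        shorter <- min(eu$q_end[i] - eu$q_start[i],
                       eu$q_end[j] - eu$q_start[j])
        if (ov < overlap_frac * shorter &&
            !connected(eu$to[i], eu$to[j])) {
          flagged <- c(flagged, u)
          break
        }
      }
      if (length(flagged) && flagged[length(flagged)] == u) break
    }
  }
  unique(flagged)
}

#' Symmetrify the similarity graph and close it into paralog families
#'
#' Asymmetric edges (`u -> v` without `v -> u`, as can arise from the
#' k-mer prefilter or masking asymmetries) are re-checked with a fresh full
#' Smith-Waterman alignment of the reverse direction; the edge is kept only
#' if the re-alignment passes the graph's thresholds. Multi-domain proteins
#' are excluded before closure. Families are the connected components (>= 2
#' members) of the resulting undirected graph - i.e. paralogy is taken as
#' the transitive closure of pairwise similarity.
#'
#' @param graph A `sim_graph` from [build_similarity_graph()].
#' @param exclude Protein ids to remove before closure (typically
#'   `flag_multidomain(graph)`).
#' @param matrix,gap_open,gap_extend Scoring for re-alignments.
#' @return A list with `families` (list of member id vectors, >= 2 each,
#'   sorted by decreasing size then first member), `singletons`, and
#'   `excluded`.
#' @export
symmetrify_and_close <- function(graph, exclude = character(0),
                                 matrix = "BLOSUM62", gap_open = 11,
                                 gap_extend = 1) {
  e <- graph$edges
  seqs <- graph$seqs
  has_edge <- paste(e$from, e$to) # directed edge keys
  sym <- rep(TRUE, nrow(e))
  for (i in seq_len(nrow(e))) {
    if (paste(e$to[i], e$from[i]) %in% has_edge) next
    # asymmetric: fresh full alignment of the missing direction
    aln <- local_align(seqs[e$to[i]], seqs[e$from[i]], matrix = matrix,
                       gap_open = gap_open, gap_extend = gap_extend)
    ok <- !aln$no_alignment &&
      aln$identity_pct >= graph$params$min_identity &&
      aln$coverage_smaller >= graph$params$min_coverage
    if (!ok) sym[i] <- FALSE
  }
  e <- e[sym, , drop = FALSE]
  keep_nodes <- setdiff(graph$nodes, exclude)
  e <- e[e$from %in% keep_nodes & e$to %in% keep_nodes, , drop = FALSE]
  if (nrow(e)) {
    und <- unique(data.frame(
      a = pmin(e$from, e$to), b = pmax(e$from, e$to),
      stringsAsFactors = FALSE))
    g <- igraph::graph_from_data_frame(und, directed = FALSE,
                                       vertices = keep_nodes)
  } else {
    g <- igraph::make_empty_graph() + igraph::vertices(keep_nodes)
  }
  comp <- igraph::components(g)
  parts <- split(names(comp$membership), comp$membership)
  families <- Filter(function(m) length(m) >= 2, parts)
  families <- lapply(families, sort)
  ord <- order(-lengths(families),
               vapply(families, `[`, character(1), 1))
  singletons <- sort(unlist(Filter(function(m) length(m) == 1, parts),
                            use.names = FALSE))
  list(families = unname(families[ord]),
       singletons = as.character(singletons),
       excluded = sort(intersect(exclude, graph$nodes)))
}

#' Construct paralog families within one proteome
#'
#' Convenience wrapper: low-complexity masking, all-vs-all similarity graph,
#' multi-domain exclusion, symmetrification and transitive closure.
#'
#' @inheritParams build_similarity_graph
#' @param drop_multidomain Exclude flagged multi-domain proteins
#'   (default TRUE).
#' @return As [symmetrify_and_close()].
#' @export
paralog_families <- function(proteome, min_identity = 30, min_coverage = 0.5,
                             mask = TRUE, drop_multidomain = TRUE, ...) {
  g <- build_similarity_graph(proteome, min_identity, min_coverage,
                              mask = mask, ...)
  excl <- if (drop_multidomain) flag_multidomain(g) else character(0)
  symmetrify_and_close(g, exclude = excl)
}

#' Paralogy summary statistics
#'
#' Counts proteins with at least one paralog, singletons, excluded
#' (multi-domain) proteins, and membership of large clusters. Percentages
#' use the analyzed proteome (families + singletons, multi-domain proteins
#' excluded) as denominator and are rounded half-up to integers.
#'
#' @param families List of family member vectors (each >= 2).
#' @param singletons Character vector of singleton ids.
#' @param excluded Character vector of excluded (multi-domain) ids.
#' @param large_threshold Minimal size of a "large" cluster (default 10).
#' @return A list of class `family_stats`: `n_with_paralog`, `n_singletons`,
#'   `n_excluded`, `n_analyzed`, `pct_with_paralog`, `pct_singletons`,
#'   `n_large_clusters`, `n_in_large_clusters`, `pct_in_large_clusters`,
#'   `large_threshold`.
#' @export
family_stats <- function(families, singletons, excluded = character(0),
                         large_threshold = 10) {
  members <- unlist(families, use.names = FALSE)
  all_ids <- c(members, singletons, excluded)
  if (anyDuplicated(all_ids))
    stop("families, singletons and excluded must be disjoint (saw '",
         all_ids[duplicated(all_ids)][1], "' twice)")
  if (any(lengths(families) < 2)) stop("families must have >= 2 members")
  n_with <- length(members)
  n_single <- length(singletons)
  n_analyzed <- n_with + n_single
  large <- lengths(families) >= large_threshold
  structure(list(
    n_with_paralog = n_with, n_singletons = n_single,
    n_excluded = length(excluded), n_analyzed = n_analyzed,
    pct_with_paralog = round_half_up(100 * n_with / n_analyzed),
    pct_singletons = round_half_up(100 * n_single / n_analyzed),
    n_large_clusters = sum(large),
    n_in_large_clusters = sum(lengths(families)[large]),
    pct_in_large_clusters = round_half_up(
      100 * sum(lengths(families)[large]) / n_analyzed),
    large_threshold = large_threshold), class = "family_stats")
}

#' @export
print.family_stats <- function(x, ...) {
  cat(sprintf(paste0("<family_stats> analyzed %d proteins ",
                     "(+%d multi-domain excluded)\n",
                     "  with >=1 paralog: %d (%d%%); singletons: %d (%d%%)\n",
                     "  clusters of >=%d members: %d, holding %d proteins (%d%%)\n"),
              x$n_analyzed, x$n_excluded, x$n_with_paralog,
              x$pct_with_paralog, x$n_singletons, x$pct_singletons,
              x$large_threshold, x$n_large_clusters, x$n_in_large_clusters,
              x$pct_in_large_clusters))
  invisible(x)
}
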