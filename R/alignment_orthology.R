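KNOWN_MATRICES <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                    "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                    "PAM250")

get_submatrix <- function(name) {
  if (is.matrix(name)) return(name)
  if (!name %in% KNOWN_MATRICES) stop("unknown substitution matrix: ", name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' Dynamic-programming local alignment with affine gap penalties (a gap of
#' length `k` costs `gap_open + k * gap_extend`) and deterministic traceback
#' (ties broken diagonal > up > left). Percent identity is computed over
#' aligned residue-residue columns (gap columns excluded, the BLAST
#' convention); `coverage_smaller` is the fraction of the shorter protein
#' spanned by the alignment. Defaults are the classic protein-BLAST
#' parameters (BLOSUM62, 11/1).
#'
#' @param a,b Protein sequences (strings), or length-1 named vectors.
#' @param matrix Substitution matrix name (a `Biostrings` scoring matrix)
#'   or an actual matrix.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return A list of class `alignment`: `query_id`, `subject_id`, `score`,
#'   `identity_pct`, `n_ident`, `aligned_cols`, `query_span`, `subject_span`
#'   (0-based half-open), `coverage_smaller`, `no_alignment`.
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                        gap_extend = 1) {
  qid <- names(a) %||% "query"; sid <- names(b) %||% "subject"
  a <- unname(a); b <- unname(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- .sw_align_pair(a, b, get_submatrix(matrix), gap_open, gap_extend)
  smaller <- min(nchar(a), nchar(b))
  if (!r$found) {
    return(structure(list(query_id = qid, subject_id = sid, score = 0,
                          identity_pct = 0, n_ident = 0L, aligned_cols = 0L,
                          query_span = c(0L, 0L), subject_span = c(0L, 0L),
                          coverage_smaller = 0, no_alignment = TRUE),
                     class = "alignment"))
  }
  span_small <- if (nchar(a) <= nchar(b)) r$q_end - r$q_start
                else r$s_end - r$s_start
  structure(list(query_id = qid, subject_id = sid, score = r$score,
                 identity_pct = 100 * r$n_ident / r$aligned_cols,
                 n_ident = r$n_ident, aligned_cols = r$aligned_cols,
                 query_span = c(r$q_start, r$q_end),
                 subject_span = c(r$s_start, r$s_end),
                 coverage_smaller = span_small / smaller,
                 no_alignment = FALSE),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  if (x$no_alignment) cat("<alignment> no positive-scoring local alignment\n")
  else cat(sprintf("<alignment> %s vs %s: score %.0f, identity %.1f%%, coverage %.2f\n",
                   x$query_id, x$subject_id, x$score, x$identity_pct,
                   x$coverage_smaller))
  invisible(x)
}

# Shared search core: all candidate alignments (k-mer prefilter optional),
# with identity/coverage derived per pair.
sw_search_df <- function(queries, subjects, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1, prefilter_kmer = 4,
                         min_shared_kmers = 2, exclude_same_id = FALSE) {
  stopifnot(is.character(queries), is.character(subjects),
            !is.null(names(queries)), !is.null(names(subjects)))
  df <- .sw_search(queries, subjects, get_submatrix(matrix), gap_open,
                   gap_extend, as.integer(prefilter_kmer),
                   as.integer(min_shared_kmers), exclude_same_id)
  if (!nrow(df)) return(cbind(df, identity_pct = numeric(0),
                              coverage_smaller = numeric(0)))
  qlen <- nchar(queries)[df$query]; slen <- nchar(subjects)[df$subject]
  span_small <- ifelse(qlen <= slen, df$q_end - df$q_start,
                       df$s_end - df$s_start)
  df$identity_pct <- 100 * df$n_ident / df$aligned_cols
  df$coverage_smaller <- span_small / pmin(qlen, slen)
  df
}

#' Best-hit search of one proteome against another
#'
#' For every query, the subject with maximal Smith-Waterman score among
#' candidates sharing at least `min_shared_kmers` distinct k-mers (the
#' prefilter; disable with `min_shared_kmers = 0` for the exhaustive
#' reference mode). Score ties break to the lexicographically smaller
#' subject id. Queries with no positive-scoring candidate are omitted.
#'
#' @param query_set,subject_set Named character vectors of protein sequences.
#' @param prefilter_kmer K-mer length for the prefilter (default 4).
#' @param min_shared_kmers Minimum shared distinct k-mers (default 2);
#'   0 disables the prefilter.
#' @param matrix,gap_open,gap_extend See [local_align()].
#' @param exclude_same_id Skip subjects with the same id as the query (for
#'   within-proteome searches).
#' @return Data.frame with one row per query that has a best hit: `query`,
#'   `subject`, `score`, `identity_pct`, `coverage_smaller`, plus span
#'   columns.
#' @export
all_vs_all <- function(query_set, subject_set, prefilter_kmer = 4,
                       min_shared_kmers = 2, matrix = "BLOSUM62",
                       gap_open = 11, gap_extend = 1,
                       exclude_same_id = FALSE) {
  df <- sw_search_df(query_set, subject_set, matrix, gap_open, gap_extend,
                     prefilter_kmer, min_shared_kmers, exclude_same_id)
  if (!nrow(df)) return(df)
  # deterministic reduction: max score, ties to smaller subject id
  df <- df[order(df$query, -df$score, df$subject), , drop = FALSE]
  best <- df[!duplicated(df$query), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Call orthologs between two species by reciprocal best hit
#'
#' Two proteins are orthologs when (i) their percent sequence identity is at
#' least `min_identity`, (ii) they are each other's best hit across the two
#' proteomes, and (iii) the alignment covers at least `min_coverage` of the
#' smaller protein.
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences from two different species (disjoint id sets).
#' @param min_identity Minimal percent identity (default 35).
#' @param min_coverage Minimal coverage of the smaller protein (default 0.8).
#' @param ... Passed to [all_vs_all()] (prefilter and scoring parameters).
#' @return Data.frame of ortholog pairs sorted by `protein_a`: `protein_a`,
#'   `protein_b`, `identity_pct`, `coverage_smaller`, `score`.
#' @export
call_orthologs <- function(proteome_a, proteome_b, min_identity = 35,
                           min_coverage = 0.8, ...) {
  if (length(intersect(names(proteome_a), names(proteome_b))))
    stop("proteomes must have disjoint protein ids")
  ab <- all_vs_all(proteome_a, proteome_b, ...)
  ba <- all_vs_all(proteome_b, proteome_a, ...)
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      identity_pct = numeric(0), coverage_smaller = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(ab) || !nrow(ba)) return(empty)
  back <- setNames(ba$subject, ba$query)
  keep <- !is.na(back[ab$subject]) & back[ab$subject] == ab$query &
    ab$identity_pct >= min_identity & ab$coverage_smaller >= min_coverage
  out <- ab[keep, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out <- data.frame(protein_a = out$query, protein_b = out$subject,
                    identity_pct = out$identity_pct,
                    coverage_smaller = out$coverage_smaller,
                    score = out$score, stringsAsFactors = FALSE)
  out <- out[order(out$protein_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build cross-species ortholog groups
#'
#' Groups are the connected components (single linkage) of the graph whose
#' edges are reciprocal-best-hit pairs pooled over all species pairs.
#'
#' @param pairs Data.frame of ortholog pairs (columns `protein_a`,
#'   `protein_b`), typically `rbind`-ed over species pairs.
#' @param species_map Named character vector mapping protein id to species.
#' @return List of groups, each a list with `members` (ids) and `species`
#'   (sorted unique species set).
#' @export
build_ortholog_groups <- function(pairs, species_map) {
  if (!nrow(pairs)) return(list())
  g <- igraph::graph_from_data_frame(
    pairs[, c("protein_a", "protein_b")], directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  unname(lapply(groups, function(m) {
    m <- sort(m)
    sp <- species_map[m]
    if (anyNA(sp)) stop("protein(s) missing from species_map: ",
                        paste(m[is.na(sp)], collapse = ", "))
    list(members = m, species = sort(unique(unname(sp))))
  }))
}

#' Venn partition of ortholog groups over species subsets
#'
#' Counts, for every non-empty subset of 2-4 species, the ortholog groups
#' whose species set equals that subset (`n_groups`) and the proteins they
#' contain (`n_proteins`). Single-species regions count proteins belonging
#' to no multi-species group, which requires the per-species protein ids.
#'
#' @param groups Groups from [build_ortholog_groups()].
#' @param species_list Character vector of 2-4 species.
#' @param proteome_ids Optional named list (per species) of all protein ids,
#'   used to fill the single-species regions.
#' @return Data.frame with columns `region` (species joined by `&`),
#'   `n_species`, `n_groups`, `n_proteins`.
#' @export
venn_partition <- function(groups, species_list, proteome_ids = NULL) {
  n <- length(species_list)
  if (n < 2 || n > 4) stop("species_list must contain 2 to 4 species")
  subsets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(species_list, k, simplify = FALSE)), recursive = FALSE)
  key <- function(sp) paste(sort(sp), collapse = "&")
  group_keys <- vapply(groups, function(g) key(g$species), character(1))
  group_sizes <- vapply(groups, function(g) length(g$members), integer(1))
  in_group <- unlist(lapply(groups, `[[`, "members"))
  out <- data.frame(region = vapply(subsets, key, character(1)),
                    n_species = lengths(subsets),
                    n_groups = 0L, n_proteins = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    if (out$n_species[i] == 1) {
      sp <- subsets[[i]]
      if (!is.null(proteome_ids)) {
        ids <- proteome_ids[[sp]]
        if (is.null(ids)) stop("no proteome ids for species '", sp, "'")
        out$n_proteins[i] <- sum(!ids %in% in_group)
      }
    } else {
      hit <- group_keys == out$region[i]
      out$n_groups[i] <- sum(hit)
      out$n_proteins[i] <- sum(group_sizes[hit])
    }
  }
  out
}

#' Detect syntons (conserved gene-order blocks) from ortholog pairs
#'
#' A synton is a maximal run of ortholog pairs whose order indices are
#' co-monotone on both replicons (same or inverted orientation), allowing at
#' most `max_gap` intervening unmatched genes on either replicon between
#' consecutive pairs. Runs shorter than `min_synton_size` are discarded.
#'
#' @param pairs Data.frame of ortholog pairs (`protein_a`, `protein_b`).
#' @param order_a,order_b Named integer vectors: protein id -> 0-based gene
#'   order index on its replicon.
#' @param min_synton_size Minimal number of pairs per synton (default 3, the
#'   conventional synton size).
#' @param max_gap Maximal intervening unmatched genes (default 1).
#' @return List of syntons, each a list with `pairs` (data.frame with order
#'   indices), `size`, `orientation` (`"same"` or `"inverted"`).
#' @export
find_syntons <- function(pairs, order_a, order_b, min_synton_size = 3,
                         max_gap = 1) {
  if (!nrow(pairs)) return(list())
  ia <- order_a[pairs$protein_a]; ib <- order_b[pairs$protein_b]
  if (anyNA(ia) || anyNA(ib)) stop("order index missing for some pair member")
  m <- data.frame(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
                  ia = as.integer(ia), ib = as.integer(ib),
                  stringsAsFactors = FALSE)
  m <- m[order(m$ia), , drop = FALSE]
  step_max <- max_gap + 1L
  syntons <- list()
  for (dir in c(1L, -1L)) {
    used <- rep(FALSE, nrow(m))
    for (s in seq_len(nrow(m))) {
      if (used[s]) next
      chain <- s; last <- s
      repeat {
        cand <- which(!used & seq_len(nrow(m)) > last &
                        m$ia - m$ia[last] >= 1L &
                        m$ia - m$ia[last] <= step_max &
                        dir * (m$ib - m$ib[last]) >= 1L &
                        dir * (m$ib - m$ib[last]) <= step_max)
        if (!length(cand)) break
        nxt <- cand[which.min(m$ia[cand])]
        chain <- c(chain, nxt)
        last <- nxt
      }
      if (length(chain) >= min_synton_size) {
        used[chain] <- TRUE
        syntons[[length(syntons) + 1L]] <- list(
          pairs = m[chain, , drop = FALSE],
          size = length(chain),
          orientation = if (dir == 1L) "same" else "inverted")
      }
    }
  }
  # a run that is monotone both ways cannot exist for size >= 2, but the two
  # orientation passes may pick overlapping chains; keep all, sorted
  syntons[order(vapply(syntons, function(s) min(s$pairs$ia), numeric(1)))]
}
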