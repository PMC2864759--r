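#' Ortholog-count distance between two replicons
#'
#' `d = 1 - n_orthologs / min(size_a, size_b)`: the shared-gene content
#' normalized by the protein count of the smaller replicon, so identical
#' proteomes are at distance 0 and proteomes sharing nothing at distance 1.
#'
#' @param n_orthologs Number of ortholog pairs between the two replicons.
#' @param size_a,size_b Protein counts of the two replicons (positive).
#' @return Distance in `[0, 1]`.
#' @export
replicon_distance <- function(n_orthologs, size_a, size_b) {
  stopifnot(size_a > 0, size_b > 0, n_orthologs >= 0)
  if (n_orthologs > min(size_a, size_b))
    stop("n_orthologs exceeds the smaller proteome size")
  1 - n_orthologs / min(size_a, size_b)
}

#' Pairwise replicon distance matrix from proteomes
#'
#' Runs [call_orthologs()] for every proteome pair and converts the pair
#' counts with [replicon_distance()].
#'
#' @param proteomes Named list (>= 2) of named character vectors of protein
#'   sequences, one per replicon/species.
#' @param ... Passed to [call_orthologs()].
#' @return Symmetric numeric matrix with zero diagonal, labeled by proteome
#'   names.
#' @export
build_distance_matrix <- function(proteomes, ...) {
  stopifnot(is.list(proteomes), length(proteomes) >= 2,
            !is.null(names(proteomes)))
  labs <- names(proteomes)
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pairs <- call_orthologs(proteomes[[i]], proteomes[[j]], ...)
      d[i, j] <- d[j, i] <- replicon_distance(
        nrow(pairs), length(proteomes[[i]]), length(proteomes[[j]]))
    }
  }
  d
}

#' Single-linkage hierarchical clustering with deterministic tie-breaking
#'
#' Agglomerative clustering where the distance between clusters is the
#' minimum pairwise distance. Ties are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labeled by its smallest
#' member), making the merge order fully deterministic. Single linkage
#' guarantees non-decreasing merge heights.
#'
#' @param d Symmetric distance matrix with labels and zero diagonal.
#' @return A list of class `sl_dendrogram`: `labels`, `merges` (data.frame
#'   with the two merged cluster labels and the height), `heights`, and
#'   `newick` (ultrametric Newick string, leaf depth = height/2).
#' @export
single_linkage <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  labs <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n <- nrow(d)
  # active clusters: label = smallest member label; track newick + height
  cl <- lapply(seq_len(n), function(i)
    list(label = labs[i], newick = labs[i], height = 0, members = i))
  dm <- d
  merges <- data.frame(a = character(0), b = character(0),
                       height = numeric(0), stringsAsFactors = FALSE)
  active <- seq_len(n)
  while (length(active) > 1) {
    # find the minimal inter-cluster distance, tie-break by label pair
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        h <- dm[i, j]
        li <- sort(c(cl[[i]]$label, cl[[j]]$label))
        if (is.null(best) || h < best$h - 1e-15 ||
            (abs(h - best$h) <= 1e-15 &&
             (li[1] < best$l1 || (li[1] == best$l1 && li[2] < best$l2)))) {
          best <- list(i = i, j = j, h = h, l1 = li[1], l2 = li[2])
        }
      }
    }
    i <- best$i; j <- best$j; h <- best$h
    bl <- function(height, child) max(0, height / 2 - child$height / 2)
    ci <- cl[[i]]; cj <- cl[[j]]
    if (cj$label < ci$label) { tmp <- ci; ci <- cj; cj <- tmp }
    newick <- sprintf("(%s:%.10g,%s:%.10g)", ci$newick, bl(h, ci),
                      cj$newick, bl(h, cj))
    merges <- rbind(merges, data.frame(a = ci$label, b = cj$label,
                                       height = h, stringsAsFactors = FALSE))
    cl[[i]] <- list(label = min(ci$label, cj$label), newick = newick,
                    height = h, members = c(ci$members, cj$members))
    # single linkage: new distance = min of the two
    for (k in active) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <- min(dm[i, k], dm[j, k])
    }
    active <- setdiff(active, j)
  }
  root <- cl[[active]]
  structure(list(labels = labs, merges = merges, heights = merges$height,
                 newick = paste0(root$newick, ";")),
            class = "sl_dendrogram")
}

#' @export
print.sl_dendrogram <- function(x, ...) {
  cat("<sl_dendrogram>", length(x$labels), "leaves;", x$newick, "\n")
  invisible(x)
}

#' Write a dendrogram as a Newick file
#'
#' @param dend An `sl_dendrogram` from [single_linkage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "sl_dendrogram"))
  writeLines(dend$newick, path)
  invisible(path)
}

#' Protein similarity distance matrix
#'
#' Pairwise local alignment of a set of proteins with the distance
#' `d = 100 - similarity`. Similarity is measured over the whole protein:
#' the number of identical aligned residues (`mode = "identity"`, default)
#' or of aligned residue pairs with a positive substitution score
#' (`mode = "positive"`), as a percentage of the smaller protein's length.
#' Identical proteins are at distance 0; unrelated proteins, whose local
#' alignment covers only a short segment, end up close to 100. Symmetry is
#' enforced by aligning each pair in canonical id order.
#'
#' @param seqs Named character vector of >= 2 protein sequences.
#' @param mode `"identity"` or `"positive"`.
#' @param matrix,gap_open,gap_extend See [local_align()].
#' @return Symmetric matrix of distances in `[0, 100]`, zero diagonal.
#' @export
protein_similarity_distance <- function(seqs, mode = c("identity", "positive"),
                                        matrix = "BLOSUM62", gap_open = 11,
                                        gap_extend = 1) {
  mode <- match.arg(mode)
  stopifnot(is.character(seqs), length(seqs) >= 2, !is.null(names(seqs)))
  labs <- names(seqs)
  n <- length(seqs)
  d <- base::matrix(0, n, n, dimnames = list(labs, labs))
  submat <- get_submatrix(matrix)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # canonical argument order makes d symmetric by construction
      ord <- order(c(labs[i], labs[j]))
      pair <- c(i, j)[ord]
      aln <- local_align(seqs[pair[1]], seqs[pair[2]], matrix = submat,
                         gap_open = gap_open, gap_extend = gap_extend)
      smaller <- min(nchar(seqs[[pair[1]]]), nchar(seqs[[pair[2]]]))
      sim <- if (aln$no_alignment) 0
        else if (mode == "identity") 100 * aln$n_ident / smaller
        else {
          pp <- positive_pct(seqs[[pair[1]]], seqs[[pair[2]]], aln, submat)
          pp * aln$aligned_cols / smaller
        }
      d[i, j] <- d[j, i] <- 100 - min(100, sim)
    }
  }
  d
}

# Percentage of aligned residue-residue columns scoring > 0 under the
# substitution matrix, recomputed by re-walking the aligned spans with a
# second alignment restricted to them.
positive_pct <- function(a, b, aln, submat) {
  qa <- substr(a, aln$query_span[1] + 1, aln$query_span[2])
  sb <- substr(b, aln$subject_span[1] + 1, aln$subject_span[2])
  p <- Biostrings::pairwiseAlignment(Biostrings::AAString(qa),
                                     Biostrings::AAString(sb),
                                     type = "global",
                                     substitutionMatrix = submat,
                                     gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1]]
  res <- pa != "-" & ps != "-"
  if (!sum(res)) return(0)
  pos <- mapply(function(x, y) submat[x, y] > 0, pa[res], ps[res])
  100 * sum(pos) / sum(res)
}

#' Write a labeled distance matrix as TSV
#'
#' @param d Square labeled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
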