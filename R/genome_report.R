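#' Summarize an annotation table into per-replicon genome statistics
#'
#' Counts CDSs (split by functional category), RNA genes and mobile
#' elements per replicon, with totals and derived percentages (one decimal,
#' rounded half-up). For annotation-row input the three CDS categories
#' partition the CDS count by construction.
#'
#' @param rows Annotation data.frame from [read_annotation_table()].
#' @param replicon_meta Data.frame with columns `replicon`, `size_bp`,
#'   `gc_pct`; every replicon in `rows` must appear here.
#' @return A list of class `genome_summary` with `per_replicon` (data.frame)
#'   and `totals` (named list, including `pct_assigned` and
#'   `pct_hypothetical` of total CDSs).
#' @export
summarize_annotation <- function(rows, replicon_meta) {
  stopifnot(all(c("replicon", "size_bp", "gc_pct") %in% names(replicon_meta)))
  unknown <- setdiff(unique(rows$replicon), replicon_meta$replicon)
  if (length(unknown)) stop("unknown replicon id: '", unknown[1], "'")
  reps <- replicon_meta$replicon
  count <- function(rep, what) {
    r <- rows[rows$replicon == rep, , drop = FALSE]
    switch(what,
           cds = sum(r$feature_type == "CDS"),
           assigned = sum(r$feature_type == "CDS" & r$category == "assigned"),
           conserved_hypothetical = sum(r$feature_type == "CDS" &
                                          r$category == "conserved_hypothetical"),
           hypothetical = sum(r$feature_type == "CDS" &
                                r$category == "hypothetical"),
           tRNA = sum(r$feature_type == "tRNA"),
           rRNA = sum(r$feature_type == "rRNA"),
           IS_elements = sum(r$feature_type == "IS_element"),
           transposons = sum(r$feature_type == "transposon"))
  }
  fields <- c("cds", "assigned", "conserved_hypothetical", "hypothetical",
              "tRNA", "rRNA", "IS_elements", "transposons")
  per <- data.frame(replicon = reps, size_bp = replicon_meta$size_bp,
                    gc_pct = replicon_meta$gc_pct, stringsAsFactors = FALSE)
  for (f in fields) per[[f]] <- vapply(reps, count, numeric(1), what = f)
  make_genome_summary(per)
}

#' Genome summary from a transcribed count table
#'
#' Builds a `genome_summary` directly from per-replicon counts (e.g.
#' transcribed from a published genome table), without per-gene rows. The
#' category counts need not partition the CDS total here, since published
#' tables may leave some CDSs uncategorized.
#'
#' @param counts Data.frame with columns `replicon`, `size_bp`, `gc_pct`,
#'   `cds`, `assigned`, `conserved_hypothetical`, `hypothetical`, `tRNA`,
#'   `rRNA`, `IS_elements`, `transposons`.
#' @return A `genome_summary` (see [summarize_annotation()]).
#' @export
genome_summary_from_counts <- function(counts) {
  need <- c("replicon", "size_bp", "gc_pct", "cds", "assigned",
            "conserved_hypothetical", "hypothetical", "tRNA", "rRNA",
            "IS_elements", "transposons")
  missing <- setdiff(need, names(counts))
  if (length(missing)) stop("missing column: '", missing[1], "'")
  make_genome_summary(counts[, need])
}

make_genome_summary <- function(per) {
  num <- setdiff(names(per), c("replicon", "gc_pct"))
  totals <- as.list(colSums(per[, num, drop = FALSE]))
  tot_cds <- totals$cds
  totals$pct_assigned <- if (tot_cds > 0)
    round_half_up(100 * totals$assigned / tot_cds, 1) else 0
  totals$pct_hypothetical <- if (tot_cds > 0)
    round_half_up(100 * totals$hypothetical / tot_cds, 1) else 0
  if (tot_cds == 0) warning("zero CDSs: percentages reported as 0")
  structure(list(per_replicon = per, totals = totals),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  print(x$per_replicon, row.names = FALSE)
  t <- x$totals
  cat(sprintf(paste0("Totals: %s bp, %d CDSs (%g%% assigned, ",
                     "%g%% hypothetical), %d tRNA, %d IS, %d transposons\n"),
              format(t$size_bp, big.mark = ","), t$cds, t$pct_assigned,
              t$pct_hypothetical, t$tRNA, t$IS_elements, t$transposons))
  invisible(x)
}

#' Normalized COG-class ratio between two replicons
#'
#' For each COG functional class, the ratio of class proportions
#' `(n2/N2) / (n1/N1)`, where `n` is the number of CDSs of that class on
#' a replicon and `N` the replicon's normalization total. A ratio of 1 means the
#' class is evenly distributed over the two replicons once their different
#' gene totals are accounted for; by default values above 1 indicate
#' enrichment on `replicon_2` (conventionally the smaller replicon). A class
#' absent from replicon 1 but present on replicon 2 yields an infinite
#' ratio, flagged rather than dropped.
#'
#' @param rows Annotation data.frame (CDS rows carry `cog_classes` strings).
#' @param replicon_1,replicon_2 Replicon ids (denominator / numerator of
#'   the proportion ratio, respectively).
#' @param denominator `"cog_assigned"` (CDSs with >= 1 COG class, default)
#'   or `"cds"` (all CDSs) as the normalization total `N`.
#' @return Data.frame with columns `cog_class`, `n1`, `n2`, `ratio` (rounded
#'   to 3 decimals, half-up; `Inf` allowed), `infinite`.
#' @export
cog_normalized_ratio <- function(rows, replicon_1, replicon_2,
                                 denominator = c("cog_assigned", "cds")) {
  denominator <- match.arg(denominator)
  cds <- rows[rows$feature_type == "CDS", , drop = FALSE]
  r1 <- cds[cds$replicon == replicon_1, , drop = FALSE]
  r2 <- cds[cds$replicon == replicon_2, , drop = FALSE]
  N1 <- if (denominator == "cds") nrow(r1) else sum(nzchar(r1$cog_classes))
  N2 <- if (denominator == "cds") nrow(r2) else sum(nzchar(r2$cog_classes))
  if (N1 == 0 || N2 == 0)
    stop("both replicons need at least one COG-classified CDS")
  count_class <- function(r, cl)
    sum(vapply(strsplit(r$cog_classes, ""), function(x) cl %in% x, logical(1)))
  present <- sort(unique(unlist(strsplit(c(r1$cog_classes, r2$cog_classes), ""))))
  out <- data.frame(cog_class = present,
                    n1 = vapply(present, count_class, numeric(1), r = r1),
                    n2 = vapply(present, count_class, numeric(1), r = r2),
                    stringsAsFactors = FALSE)
  raw <- (out$n2 / N2) / (out$n1 / N1)
  out$ratio <- ifelse(is.infinite(raw), Inf, round_half_up(raw, 3))
  out$infinite <- is.infinite(raw)
  rownames(out) <- NULL
  out
}

#' Normalized class ratio from plain counts
#'
#' The same proportion ratio as [cog_normalized_ratio()] computed from
#' explicit counts, e.g. values transcribed from a published table:
#' `(n2/N2) / (n1/N1)`, rounded to 3 decimals.
#'
#' @param n1,N1 Class count and normalization total on replicon 1.
#' @param n2,N2 Class count and normalization total on replicon 2.
#' @return The rounded ratio (possibly `Inf`).
#' @export
class_ratio_from_counts <- function(n1, N1, n2, N2) {
  stopifnot(N1 > 0, N2 > 0)
  if (n1 == 0) return(Inf)
  round_half_up((n2 / N2) / (n1 / N1), 3)
}

#' Tally mobile genetic elements per replicon
#'
#' Contingency tables (element x replicon, with row and column totals) for
#' IS elements and transposons. Every IS/transposon row must carry an
#' `element_name`.
#'
#' @param rows Annotation data.frame.
#' @param replicons Optional replicon order for the table columns.
#' @return A list with matrices `IS_element` and `transposon` (rows:
#'   elements plus `Total`; columns: replicons plus `Total`). An element
#'   type absent from the input yields a 1x1 `Total = 0` matrix.
#' @export
tally_mobile_elements <- function(rows, replicons = NULL) {
  mob <- rows[rows$feature_type %in% c("IS_element", "transposon"), ,
              drop = FALSE]
  if (nrow(mob) && any(!nzchar(mob$element_name)))
    stop("IS/transposon row lacking element_name (gene ",
         mob$gene_id[!nzchar(mob$element_name)][1], ")")
  reps <- replicons %||% sort(unique(rows$replicon))
  one <- function(type) {
    r <- mob[mob$feature_type == type, , drop = FALSE]
    if (!nrow(r)) return(matrix(0, 1, 1, dimnames = list("Total", "Total")))
    tab <- table(factor(r$element_name), factor(r$replicon, levels = reps))
    m <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
    m <- cbind(m, Total = rowSums(m))
    rbind(m, Total = colSums(m))
  }
  list(IS_element = one("IS_element"), transposon = one("transposon"))
}

#' Load a transcription of a published per-replicon genome feature table
#'
#' Ships with the package: per-replicon sizes, G+C percentages, CDS
#' category counts and RNA/mobile-element counts for the four replicons of
#' the metal-resistant beta-proteobacterium *Cupriavidus metallidurans*
#' CH34 (two chromosomes and two megaplasmids), as published.
#'
#' @return Data.frame suitable for [genome_summary_from_counts()].
#' @export
ch34_genome_table <- function() {
  path <- system.file("extdata", "ch34_genome_table.tsv",
                      package = "replicomp", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Load transcriptions of the published CH34 mobile-element tables
#'
#' Per-element, per-replicon copy numbers of the insertion sequences and
#' transposons of *C. metallidurans* CH34, expanded to one annotation row
#' per element copy so they can be fed to [tally_mobile_elements()].
#'
#' @return Annotation data.frame (one row per IS/transposon copy).
#' @export
ch34_mobile_elements <- function() {
  path <- system.file("extdata", "ch34_mobile_elements.tsv",
                      package = "replicomp", mustWork = TRUE)
  counts <- utils::read.delim(path, check.names = FALSE)
  expand_element_counts(counts)
}

#' Expand a per-element count table into annotation rows
#'
#' @param counts Data.frame with columns `element`, `feature_type` and one
#'   column per replicon holding copy numbers.
#' @return Annotation data.frame with one row per element copy.
#' @export
expand_element_counts <- function(counts) {
  reps <- setdiff(names(counts), c("element", "feature_type"))
  rows <- list()
  k <- 0
  for (i in seq_len(nrow(counts))) {
    for (r in reps) {
      n <- counts[[r]][i]
      if (is.na(n) || n == 0) next
      for (cp in seq_len(n)) {
        k <- k + 1
        rows[[k]] <- data.frame(
          gene_id = sprintf("%s_%s_%d", counts$element[i], r, cp),
          replicon = r, category = "assigned", cog_classes = "",
          feature_type = counts$feature_type[i],
          element_name = counts$element[i], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic full-genome annotation table
#'
#' Expands a per-replicon count table (as from [ch34_genome_table()]) into
#' one synthetic annotation row per feature, with generated gene ids and
#' empty COG strings. CDS rows beyond the three category counts (published
#' tables may leave CDSs uncategorized) are emitted as `assigned`.
#' Useful for exercising the annotation reader and summarizer at realistic
#' scale without shipping a large fixture.
#'
#' @param counts Data.frame as in [genome_summary_from_counts()].
#' @return Annotation data.frame.
#' @export
expand_genome_counts <- function(counts) {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    rep <- counts$replicon[i]
    n_cds <- counts$cds[i]
    n_con <- counts$conserved_hypothetical[i]
    n_hyp <- counts$hypothetical[i]
    n_asg <- n_cds - n_con - n_hyp
    stopifnot(n_asg >= 0)
    cat_vec <- c(rep("assigned", n_asg),
                 rep("conserved_hypothetical", n_con),
                 rep("hypothetical", n_hyp))
    ft <- c(rep("CDS", n_cds), rep("tRNA", counts$tRNA[i]),
            rep("rRNA", counts$rRNA[i]))
    rows[[i]] <- data.frame(
      gene_id = sprintf("%s_g%05d", rep, seq_along(ft)),
      replicon = rep,
      category = c(cat_vec, rep("assigned", length(ft) - n_cds)),
      cog_classes = "", feature_type = ft, element_name = "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
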