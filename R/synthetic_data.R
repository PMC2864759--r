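#' Specification for a simulated replicon
#'
#' Describes a circular replicon whose strand composition is biased between
#' the planted origin and terminus: on the leading strand (clockwise arc
#' ori -> ter) each base is G with probability `gc/2 + delta/2` and C with
#' probability `gc/2 - delta/2`; the bias is mirrored on the other
#' replichore. This reproduces the sign change of the windowed GC skew at
#' ori and ter seen on real bacterial chromosomes.
#'
#' @param length Replicon length in bp.
#' @param gc_fraction Overall G+C fraction in `[0, 1]`.
#' @param ori_pos,ter_pos Planted origin/terminus, 0-based positions.
#' @param skew_delta Excess probability of G over C on the leading strand;
#'   must be `< min(gc_fraction, 1 - gc_fraction)`.
#' @param planted_motifs Optional data.frame with columns `consensus`,
#'   `position`, `strand`, `mismatches` describing motif copies written over
#'   the background (reverse-complemented for strand `"-"`).
#' @param seed Integer seed; the whole simulation is deterministic under it.
#' @return A list of class `replicon_sim_spec`.
#' @export
replicon_sim_spec <- function(length, gc_fraction = 0.5, ori_pos = 0,
                              ter_pos = floor(length / 2), skew_delta = 0.2,
                              planted_motifs = NULL, seed = 1) {
  stopifnot(length >= 10, gc_fraction > 0, gc_fraction < 1,
            ori_pos >= 0, ori_pos < length, ter_pos >= 0, ter_pos < length)
  if (ori_pos == ter_pos) stop("ori_pos and ter_pos must differ")
  if (skew_delta < 0 || skew_delta >= min(gc_fraction, 1 - gc_fraction))
    stop("skew_delta must be in [0, min(gc_fraction, 1 - gc_fraction))")
  if (!is.null(planted_motifs)) {
    stopifnot(all(c("consensus", "position", "strand", "mismatches") %in%
                    names(planted_motifs)))
  }
  structure(list(length = as.integer(length), gc_fraction = gc_fraction,
                 ori_pos = as.integer(ori_pos), ter_pos = as.integer(ter_pos),
                 skew_delta = skew_delta, planted_motifs = planted_motifs,
                 seed = as.integer(seed)),
            class = "replicon_sim_spec")
}

#' Simulate a circular replicon with a planted GC-skew switch
#'
#' Bases are drawn i.i.d. with replichore-specific G/C probabilities (see
#' [replicon_sim_spec()]); planted motif copies then overwrite the background
#' at their stated positions. Overlapping planted motifs are an error.
#'
#' @param spec A [replicon_sim_spec()].
#' @param id Identifier for the emitted replicon.
#' @return A list with elements `replicon` (a [replicon()]) and `truth`
#'   (list with `ori`, `ter`, and `motifs`, a data.frame of planted hits).
#' @export
simulate_replicon <- function(spec, id = "sim_rep") {
  stopifnot(inherits(spec, "replicon_sim_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  L <- spec$length; gc <- spec$gc_fraction; d <- spec$skew_delta
  at <- (1 - gc) / 2
  p_lead <- c(A = at, C = gc / 2 - d / 2, G = gc / 2 + d / 2, T = at)
  p_lag  <- c(A = at, C = gc / 2 + d / 2, G = gc / 2 - d / 2, T = at)
  # clockwise arc ori -> ter carries the leading-strand composition
  pos0 <- seq_len(L) - 1L
  on_lead <- arc_contains(pos0, spec$ori_pos, spec$ter_pos, L)
  bases <- character(L)
  bases[on_lead] <- sample(names(p_lead), sum(on_lead), TRUE, p_lead)
  bases[!on_lead] <- sample(names(p_lag), sum(!on_lead), TRUE, p_lag)

  truth_motifs <- data.frame(start = integer(0), end = integer(0),
                             strand = character(0), mismatches = integer(0),
                             motif = character(0), stringsAsFactors = FALSE)
  pm <- spec$planted_motifs
  if (!is.null(pm) && nrow(pm)) {
    occupied <- rep(FALSE, L)
    for (i in seq_len(nrow(pm))) {
      motif <- parse_consensus(pm$consensus[i])
      inst <- realize_motif_instance(motif, pm$mismatches[i])
      if (pm$strand[i] == "-") inst <- reverse_complement(inst)
      w <- nchar(inst)
      idx <- ((pm$position[i] + seq_len(w) - 1L) %% L) + 1L
      if (any(occupied[idx]))
        stop("planted motif at position ", pm$position[i],
             " overlaps another planted motif")
      occupied[idx] <- TRUE
      bases[idx] <- strsplit(inst, "")[[1]]
      truth_motifs <- rbind(truth_motifs, data.frame(
        start = pm$position[i], end = pm$position[i] + w,
        strand = pm$strand[i], mismatches = as.integer(pm$mismatches[i]),
        motif = motif$name, stringsAsFactors = FALSE))
    }
  }
  rep <- replicon(id, paste(bases, collapse = ""), circular = TRUE)
  list(replicon = rep,
       truth = list(ori = spec$ori_pos, ter = spec$ter_pos,
                    motifs = truth_motifs))
}

# Is 0-based position p on the clockwise arc [from, to)?
arc_contains <- function(p, from, to, L) {
  if (from < to) p >= from & p < to else p >= from | p < to
}

# Draw a concrete motif instance with exactly n mismatches to the consensus:
# matching positions take the first allowed base, mismatching positions an
# arbitrary disallowed base.
realize_motif_instance <- function(motif, n_mismatches) {
  w <- motif$length
  if (n_mismatches >= w) stop("cannot plant >= length mismatches")
  bases <- vapply(motif$positions, function(s) s[1], character(1))
  if (n_mismatches > 0) {
    at <- sample.int(w, n_mismatches)
    for (i in at) {
      disallowed <- setdiff(c("A", "C", "G", "T"), motif$positions[[i]])
      if (!length(disallowed))
        stop("position ", i, " allows every base; cannot plant a mismatch")
      bases[i] <- disallowed[sample.int(length(disallowed), 1)]
    }
  }
  paste(bases, collapse = "")
}

#' Mutate a protein to a target percent identity
#'
#' Substitution-only divergence: exactly `round(L * (100 - target) / 100)`
#' positions (chosen uniformly without replacement) are replaced by a
#' different residue, so the realized identity equals the target to within
#' one percentage point and coverage stays 1 by construction.
#'
#' @param seq Protein sequence (string over the 20 residues plus X).
#' @param target_identity Target percent identity in `[20, 100]`.
#' @param seed Integer seed.
#' @param positions Optional explicit 1-based positions to substitute
#'   (overrides the uniform draw; used to plant exactly-known pairwise
#'   identities between several descendants of one ancestor).
#' @return The mutated sequence.
#' @export
mutate_to_identity <- function(seq, target_identity, seed = 1,
                               positions = NULL) {
  if (target_identity < 20 || target_identity > 100)
    stop("target_identity must be in [20, 100]")
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- round(L * (100 - target_identity) / 100)
  if (is.null(positions)) positions <- sample.int(L, k) else k <- length(positions)
  for (i in positions) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Specification for simulated multi-species proteomes
#'
#' Core genes are descendants of shared random ancestors, mutated so that
#' every cross-species pair realizes the target percent identity exactly
#' (disjoint substitution sets per species). Accessory genes are
#' species-private random sequences. Paralog families are built inside the
#' first species by duplication-divergence from a family seed sequence.
#'
#' @param species Character vector of species names (>= 2).
#' @param genes_per_species Genes per species (before paralog families).
#' @param core_fraction Fraction of genes that are core (shared by all
#'   species); `core_fraction * genes_per_species >= 1`.
#' @param pairwise_identity Target percent identity of planted orthologs,
#'   in `[20, 100]`. With `n` species the scheme needs
#'   `n * (100 - t) / 200 <= 1`, i.e. `t >= 100 - 200/n`.
#' @param paralog_families Optional data.frame with columns `size` and
#'   `identity` (within-family percent identity), one row per family.
#' @param protein_length_mean,protein_length_sd Protein length distribution
#'   (normal, truncated below at 50 residues).
#' @param order_conserved_fraction Fraction of each non-reference species'
#'   genes that keep the ancestral gene order (for synteny tests).
#' @param seed Integer seed.
#' @return A list of class `proteome_sim_spec`.
#' @export
proteome_sim_spec <- function(species, genes_per_species, core_fraction = 0.62,
                              pairwise_identity = 70, paralog_families = NULL,
                              protein_length_mean = 250,
                              protein_length_sd = 50,
                              order_conserved_fraction = 1.0, seed = 1) {
  stopifnot(length(species) >= 2, !anyDuplicated(species),
            genes_per_species >= 1, core_fraction >= 0, core_fraction <= 1)
  if (pairwise_identity < 20)
    stop("pairwise_identity below 20% is indistinguishable from random")
  if (pairwise_identity > 100) stop("pairwise_identity must be <= 100")
  n_core <- round(core_fraction * genes_per_species)
  if (core_fraction > 0 && n_core < 1)
    stop("core_fraction * genes_per_species must be >= 1")
  per_species_frac <- (100 - pairwise_identity) / 200
  if (length(species) * per_species_frac > 1)
    stop("pairwise_identity too low for ", length(species),
         " species: need identity >= ", 100 - 200 / length(species))
  if (!is.null(paralog_families))
    stopifnot(all(c("size", "identity") %in% names(paralog_families)),
              all(paralog_families$size >= 2),
              all(paralog_families$identity >= 20 &
                    paralog_families$identity <= 100))
  structure(list(species = species,
                 genes_per_species = as.integer(genes_per_species),
                 core_fraction = core_fraction, n_core = as.integer(n_core),
                 pairwise_identity = pairwise_identity,
                 paralog_families = paralog_families,
                 protein_length_mean = protein_length_mean,
                 protein_length_sd = protein_length_sd,
                 order_conserved_fraction = order_conserved_fraction,
                 seed = as.integer(seed)),
            class = "proteome_sim_spec")
}

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

#' Simulate multi-species proteomes with planted ortholog and paralog truth
#'
#' @param spec A [proteome_sim_spec()].
#' @return A list with elements:
#'   * `proteomes`: named list (per species) of data.frames with columns
#'     `id`, `species`, `replicon`, `order_index`, `seq`;
#'   * `truth`: list with `ortholog_groups` (list of id vectors, one per
#'     planted core gene) and `paralog_families` (list of id vectors).
#' @export
simulate_proteomes <- function(spec) {
  stopifnot(inherits(spec, "proteome_sim_spec"))
  restore <- local_seed(spec$seed)
  on.exit(restore(), add = TRUE)
  sp <- spec$species; n_sp <- length(sp)
  n_core <- spec$n_core
  n_acc <- spec$genes_per_species - n_core
  draw_len <- function() max(50L, round(rnorm(1, spec$protein_length_mean,
                                              spec$protein_length_sd)))

  gene_tabs <- setNames(vector("list", n_sp), sp)
  for (s in sp) gene_tabs[[s]] <- list()
  ortholog_groups <- list()

  # Core genes: one ancestor each; species copies mutate pairwise-disjoint
  # position sets so every cross-species identity is exact.
  for (g in seq_len(n_core)) {
    L <- draw_len()
    anc <- random_protein(L)
    d <- round(L * (100 - spec$pairwise_identity) / 200)
    pool <- sample.int(L, min(L, n_sp * d))
    ids <- character(n_sp)
    for (i in seq_len(n_sp)) {
      pos <- if (d > 0) pool[((i - 1) * d + 1):(i * d)] else integer(0)
      mut <- mutate_to_identity(anc, 100, seed = derive_seed(spec$seed, g * 97 + i),
                                positions = pos)
      id <- sprintf("%s_core%04d", sp[i], g)
      ids[i] <- id
      gene_tabs[[sp[i]]][[length(gene_tabs[[sp[i]]]) + 1L]] <-
        list(id = id, seq = mut)
    }
    ortholog_groups[[g]] <- ids
  }

  # Accessory genes: species-private random sequences.
  for (i in seq_len(n_sp)) {
    for (g in seq_len(n_acc)) {
      id <- sprintf("%s_acc%04d", sp[i], g)
      gene_tabs[[sp[i]]][[length(gene_tabs[[sp[i]]]) + 1L]] <-
        list(id = id, seq = random_protein(draw_len()))
    }
  }

  # Paralog families inside the first species: disjoint substitution sets
  # around a family seed give exact within-family pairwise identities.
  paralog_truth <- list()
  pf <- spec$paralog_families
  if (!is.null(pf) && nrow(pf)) {
    for (f in seq_len(nrow(pf))) {
      size <- pf$size[f]; t_id <- pf$identity[f]
      L <- draw_len()
      d <- round(L * (100 - t_id) / 200)
      seed_seq <- random_protein(L)
      # disjoint substitution sets give exact pairwise identities when the
      # family is small enough; larger families fall back to independent
      # position draws (pairwise identity ~ target, slightly above)
      if (size * d <= L) {
        pool <- sample.int(L, size * d)
        pos_list <- lapply(seq_len(size), function(m)
          if (d > 0) pool[((m - 1) * d + 1):(m * d)] else integer(0))
      } else {
        pos_list <- lapply(seq_len(size), function(m) sample.int(L, d))
      }
      ids <- character(size)
      for (m in seq_len(size)) {
        pos <- pos_list[[m]]
        mut <- mutate_to_identity(seed_seq, 100,
                                  seed = derive_seed(spec$seed, 7919 + f * 131 + m),
                                  positions = pos)
        id <- sprintf("%s_par%02d_%02d", sp[1], f, m)
        ids[m] <- id
        gene_tabs[[sp[1]]][[length(gene_tabs[[sp[1]]]) + 1L]] <-
          list(id = id, seq = mut)
      }
      paralog_truth[[f]] <- ids
    }
  }

  # Gene order: ancestral order is the emission order; a configurable
  # fraction of each non-reference species' genes is relocated.
  proteomes <- setNames(vector("list", n_sp), sp)
  for (i in seq_len(n_sp)) {
    tab <- gene_tabs[[sp[i]]]
    n <- length(tab)
    ord_ids <- seq_len(n) # gene indices in ancestral order
    if (i > 1 && spec$order_conserved_fraction < 1) {
      n_move <- floor((1 - spec$order_conserved_fraction) * n)
      if (n_move > 0) {
        movers <- sample.int(n, n_move)
        ord_ids <- setdiff(ord_ids, movers)
        for (m in movers) { # relocate each mover to a random slot
          at <- sample.int(length(ord_ids) + 1L, 1)
          ord_ids <- append(ord_ids, m, after = at - 1L)
        }
      }
    }
    proteomes[[sp[i]]] <- data.frame(
      id = vapply(tab, `[[`, character(1), "id"),
      species = sp[i], replicon = "chr",
      order_index = match(seq_len(n), ord_ids) - 1L,
      seq = vapply(tab, `[[`, character(1), "seq"),
      stringsAsFactors = FALSE)
  }

  list(proteomes = proteomes,
       truth = list(ortholog_groups = ortholog_groups,
                    paralog_families = paralog_truth))
}

#' Extract a named sequence vector from a simulated proteome table
#'
#' @param proteome A per-species data.frame from [simulate_proteomes()].
#' @return Named character vector `id -> seq`.
#' @export
proteome_seqs <- function(proteome) {
  setNames(proteome$seq, proteome$id)
}

#' Write simulated proteomes and truth tables to a directory
#'
#' Emits one protein FASTA per species plus `ortholog_groups.tsv` and
#' `paralogs.tsv` truth tables.
#'
#' @param sim Result of [simulate_proteomes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_proteome_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$proteomes)) {
    write_fasta(proteome_seqs(sim$proteomes[[s]]),
                file.path(dir, paste0(s, ".faa")))
  }
  og <- sim$truth$ortholog_groups
  writeLines(c("group\tmembers",
               sprintf("og%04d\t%s", seq_along(og),
                       vapply(og, paste, character(1), collapse = ","))),
             file.path(dir, "ortholog_groups.tsv"))
  pf <- sim$truth$paralog_families
  writeLines(c("family\tmembers",
               if (length(pf)) sprintf("pf%02d\t%s", seq_along(pf),
                       vapply(pf, paste, character(1), collapse = ","))),
             file.path(dir, "paralogs.tsv"))
  invisible(dir)
}
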