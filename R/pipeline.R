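PIPELINE_DEFAULTS <- list(
  seed = 1,
  simulate = list(
    replicon = list(length = 100000, gc_fraction = 0.5, ori_pos = 0,
                    ter_pos = 50000, skew_delta = 0.3),
    proteomes = list(species = c("spA", "spB"), genes_per_species = 60,
                     core_fraction = 0.62, pairwise_identity = 70)),
  skew = list(window = 2000, step = 0), # step 0 means "use window"
  scan = list(motif = "TTATCCACA", max_mismatches = 2, cluster_gap = 500),
  orthologs = list(min_identity = 35, min_coverage = 0.8,
                   prefilter_kmer = 4, min_shared_kmers = 2),
  paralogs = list(min_identity = 30, min_coverage = 0.5))

PIPELINE_RANGES <- list(
  "skew.window" = c(1, Inf), "scan.max_mismatches" = c(0, 8),
  "scan.cluster_gap" = c(0, Inf),
  "orthologs.min_identity" = c(0, 100), "orthologs.min_coverage" = c(0, 1),
  "orthologs.prefilter_kmer" = c(0, 12),
  "orthologs.min_shared_kmers" = c(0, Inf),
  "paralogs.min_identity" = c(0, 100), "paralogs.min_coverage" = c(0, 1),
  "simulate.replicon.length" = c(1000, Inf),
  "simulate.replicon.gc_fraction" = c(0.01, 0.99),
  "simulate.replicon.skew_delta" = c(0, 0.99),
  "simulate.proteomes.genes_per_species" = c(1, Inf),
  "simulate.proteomes.core_fraction" = c(0, 1),
  "simulate.proteomes.pairwise_identity" = c(20, 100))

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent nested list), rejects unknown
#' keys, injects defaults (2 kb skew windows, DnaA-box scanning with two
#' mismatches, orthology at 35% identity and 0.8 coverage, paralogy at
#' 30%/0.5) and range-checks every numeric parameter. Validation is a
#' fixpoint: validating an already-validated configuration returns it
#' unchanged.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return The effective configuration (class `replicomp_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- merge_defaults(unclass(config), PIPELINE_DEFAULTS, path = "")
  if (is.null(cfg$skew$step) || cfg$skew$step == 0)
    cfg$skew$step <- cfg$skew$window
  for (key in names(PIPELINE_RANGES)) {
    v <- cfg[[strsplit(key, ".", fixed = TRUE)[[1]]]]
    r <- PIPELINE_RANGES[[key]]
    if (!is.null(v) && is.numeric(v) && (v < r[1] || v > r[2]))
      stop(sprintf("config value %s = %s out of range [%s, %s]",
                   key, v, r[1], r[2]))
  }
  structure(cfg, class = "replicomp_config")
}

merge_defaults <- function(user, defaults, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key: '",
         sub("^\\.", "", paste0(path, ".", unknown[1])), "'")
  out <- defaults
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      out[[k]] <- merge_defaults(user[[k]], defaults[[k]],
                                 paste0(path, ".", k))
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

#' Run the full synthetic comparative-genomics pipeline
#'
#' Stages, in dependency order: simulate a skewed replicon and multi-species
#' proteomes; windowed GC content/skew and ori/ter prediction; motif scan
#' and box clustering; reciprocal-best-hit orthologs for every species pair
#' with ortholog groups and Venn partition; replicon distance matrix with
#' single-linkage tree; paralog families of the first species; summary
#' statistics. All artifacts are written under `out_dir`, and a manifest
#' records each output file's MD5 checksum, so a rerun with the same
#' configuration is byte-reproducible.
#'
#' @param config A `replicomp_config` (or something [validate_config()]
#'   accepts).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the per-stage results and the `manifest`
#'   data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)

  # 1. simulate
  rspec <- cfg$simulate$replicon
  sim_rep <- simulate_replicon(replicon_sim_spec(
    length = rspec$length, gc_fraction = rspec$gc_fraction,
    ori_pos = rspec$ori_pos, ter_pos = rspec$ter_pos,
    skew_delta = rspec$skew_delta, seed = derive_seed(cfg$seed, 1)))
  write_fasta(setNames(sim_rep$replicon$seq, sim_rep$replicon$id),
              file.path(out_dir, "replicon.fa"))
  pspec <- cfg$simulate$proteomes
  sim_prot <- simulate_proteomes(proteome_sim_spec(
    species = pspec$species, genes_per_species = pspec$genes_per_species,
    core_fraction = pspec$core_fraction,
    pairwise_identity = pspec$pairwise_identity,
    seed = derive_seed(cfg$seed, 2)))
  write_proteome_sim(sim_prot, file.path(out_dir, "proteomes"))
  res$simulation <- list(replicon = sim_rep, proteomes = sim_prot)

  # 2. skew / ori-ter
  write_skew_tsv(sim_rep$replicon, file.path(out_dir, "skew.tsv"),
                 window = cfg$skew$window, step = cfg$skew$step)
  call <- predict_ori_ter(sim_rep$replicon, window = cfg$skew$window)
  writeLines(c("key\tvalue", paste0("ori\t", call$ori),
               paste0("ter\t", call$ter)),
             file.path(out_dir, "ori_ter.tsv"))
  res$ori_ter <- call

  # 3. motif scan
  hits <- scan_motif(sim_rep$replicon, cfg$scan$motif,
                     max_mismatches = cfg$scan$max_mismatches)
  write_bed(hits[hits$end <= sim_rep$replicon$length, , drop = FALSE],
            sim_rep$replicon$id, file.path(out_dir, "motif_hits.bed"))
  res$motif_hits <- hits
  res$box_clusters <- cluster_hits(hits, cfg$scan$cluster_gap,
                                   L = sim_rep$replicon$length)

  # 4. orthologs
  seqsets <- lapply(sim_prot$proteomes, proteome_seqs)
  species <- names(seqsets)
  pairs_all <- list()
  for (i in seq_len(length(species) - 1)) {
    for (j in (i + 1):length(species)) {
      p <- call_orthologs(seqsets[[i]], seqsets[[j]],
                          min_identity = cfg$orthologs$min_identity,
                          min_coverage = cfg$orthologs$min_coverage,
                          prefilter_kmer = cfg$orthologs$prefilter_kmer,
                          min_shared_kmers = cfg$orthologs$min_shared_kmers)
      pairs_all[[paste(species[i], species[j], sep = "-")]] <- p
    }
  }
  pairs <- do.call(rbind, pairs_all)
  utils::write.table(pairs, file.path(out_dir, "ortholog_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  species_map <- unlist(lapply(species, function(s)
    setNames(rep(s, length(seqsets[[s]])), names(seqsets[[s]]))))
  groups <- build_ortholog_groups(pairs, species_map)
  res$ortholog_pairs <- pairs
  res$ortholog_groups <- groups
  if (length(species) >= 2 && length(species) <= 4) {
    res$venn <- venn_partition(groups, species,
                               proteome_ids = lapply(seqsets, names))
    utils::write.table(res$venn, file.path(out_dir, "venn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # 5. replicon clustering
  dmat <- build_distance_matrix(seqsets,
                                min_identity = cfg$orthologs$min_identity,
                                min_coverage = cfg$orthologs$min_coverage)
  write_distance_matrix(dmat, file.path(out_dir, "replicon_distances.tsv"))
  dend <- single_linkage(dmat)
  write_newick(dend, file.path(out_dir, "replicon_tree.nwk"))
  res$distance_matrix <- dmat
  res$dendrogram <- dend

  # 6. paralogs (first species)
  fam <- paralog_families(seqsets[[1]],
                          min_identity = cfg$paralogs$min_identity,
                          min_coverage = cfg$paralogs$min_coverage)
  fam_lines <- c("family_id\tmembers",
                 if (length(fam$families))
                   sprintf("f%03d\t%s", seq_along(fam$families),
                           vapply(fam$families, paste, character(1),
                                  collapse = ",")))
  writeLines(fam_lines, file.path(out_dir, "paralog_families.tsv"))
  res$paralogs <- fam
  res$family_stats <- family_stats(fam$families, fam$singletons,
                                   fam$excluded)

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$manifest <- manifest
  invisible(res)
}
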