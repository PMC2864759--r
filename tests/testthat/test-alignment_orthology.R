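test_that("local alignment handles identity, no-alignment and unknown matrix", {
  set.seed(51)
  s <- random_protein_str(50)
  al <- local_align(s, s)
  expect_equal(al$identity_pct, 100)
  expect_equal(al$coverage_smaller, 1.0)
  expect_false(al$no_alignment)

  # all pair scores negative: reported as no alignment
  al0 <- local_align("AAAA", "CCCC")
  expect_true(al0$no_alignment)
  expect_equal(al0$score, 0)

  expect_error(local_align(s, s, matrix = "NOSUCH"), "unknown")
  expect_error(local_align("", s), "non-empty")
})

test_that("alignment scores equal an independent implementation on random pairs", {
  suppressMessages(library(Biostrings))
  set.seed(52)
  for (i in 1:20) {
    a <- random_protein_str(sample(5:30, 1))
    b <- random_protein_str(sample(5:30, 1))
    mine <- local_align(a, b)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = blosum62, gapOpening = 11, gapExtension = 1)
    expect_equal(mine$score, max(0, Biostrings::score(ref)))
  }
})

test_that("alignment scores equal the all-substring-pairs brute force", {
  set.seed(53)
  for (i in 1:5) {
    a <- random_protein_str(sample(6:10, 1))
    b <- random_protein_str(sample(6:10, 1))
    mine <- local_align(a, b)
    expect_equal(mine$score, oracle_local_bruteforce(a, b, blosum62))
  }
  # a related pair with an indel, where gaps actually occur
  a <- "MKVLAWHEAG"
  b <- "MKVLWHEAG"
  expect_equal(local_align(a, b)$score,
               oracle_local_bruteforce(a, b, blosum62))
})

test_that("best-hit search honors the prefilter contract and tie rule", {
  set.seed(54)
  subjects <- setNames(vapply(1:50, function(i) random_protein_str(80),
                              character(1)), sprintf("s%02d", 1:50))
  queries <- setNames(c(subjects[[7]], vapply(1:9, function(i)
    random_protein_str(80), character(1))), sprintf("q%02d", 1:10))
  best <- all_vs_all(queries, subjects, min_shared_kmers = 0)
  expect_equal(best$subject[best$query == "q01"], "s07")
  expect_equal(best$identity_pct[best$query == "q01"], 100)

  # prefilter disabled reproduces the exhaustive best hit for every query
  # (independent R-side oracle: align against every subject)
  for (q in names(queries)) {
    scores <- vapply(names(subjects), function(s)
      local_align(queries[q], subjects[s])$score, numeric(1))
    if (max(scores) <= 0) {
      expect_false(q %in% best$query)
    } else {
      top <- sort(names(scores)[scores == max(scores)])
      expect_equal(best$subject[best$query == q], top[1])
    }
  }
  # a strong homolog passes the default k-mer prefilter with the same hit
  filt <- all_vs_all(queries, subjects)
  expect_equal(filt$subject[filt$query == "q01"], "s07")

  # equal-scoring subjects: lexicographically smaller id wins
  twin <- setNames(c(subjects[[7]], subjects[[7]]), c("pB", "pA"))
  b2 <- all_vs_all(queries["q01"], twin, min_shared_kmers = 0)
  expect_equal(b2$subject, "pA")
})

test_that("reciprocal-best-hit orthology applies all three criteria", {
  set.seed(55)
  anc <- random_protein_str(200)
  # (i)+(ii)+(iii) pass: planted 90% pair with no competitors
  a90 <- mutate_to_identity(anc, 95, seed = 1)
  b90 <- mutate_to_identity(anc, 95, seed = 2)
  pa <- c(a1 = a90, a_noise = random_protein_str(200))
  pb <- c(b1 = b90, b_noise = random_protein_str(200))
  pairs <- call_orthologs(pa, pb)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$protein_a, "a1")
  expect_equal(pairs$protein_b, "b1")
  expect_gte(pairs$identity_pct, 85)

  # criterion (i): 30% identity pair rejected at the 35% threshold
  # (disjoint substitution sets of 70 positions each: identity exactly 30%)
  a30 <- mutate_to_identity(anc, 65, seed = 3)
  untouched <- which(strsplit(a30, "")[[1]] == strsplit(anc, "")[[1]])
  set.seed(30)
  b30 <- mutate_to_identity(anc, 65, seed = 4,
                            positions = sample(untouched, 70))
  # direct recount of the planted identity
  ident <- mean(strsplit(a30, "")[[1]] == strsplit(b30, "")[[1]]) * 100
  expect_lt(ident, 35)
  p30 <- call_orthologs(c(a = a30), c(b = b30), min_shared_kmers = 0)
  expect_equal(nrow(p30), 0)

  # criterion (ii): one-sided best hit is not an ortholog
  base <- random_protein_str(150)
  pa2 <- c(a1 = base, a2 = base) # b's best is a1 (lexicographic tie rule)
  pb2 <- c(b1 = mutate_to_identity(base, 90, seed = 5))
  p2 <- call_orthologs(pa2, pb2, min_shared_kmers = 0)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$protein_a, "a1")

  # criterion (iii): high identity over a short span fails coverage
  half <- c(x = paste0(substr(base, 1, 60), random_protein_str(90)))
  p3 <- call_orthologs(c(a = base), half, min_shared_kmers = 0)
  expect_equal(nrow(p3), 0)
  p3b <- call_orthologs(c(a = base), half, min_coverage = 0.3,
                        min_shared_kmers = 0)
  expect_equal(nrow(p3b), 1)

  expect_error(call_orthologs(c(x = base), c(x = base)), "disjoint")
})

test_that("orthology is symmetric and monotone in its thresholds", {
  sim <- simulate_proteomes(proteome_sim_spec(c("A", "B"), 15,
                                              core_fraction = 0.6,
                                              pairwise_identity = 75,
                                              seed = 56))
  pa <- proteome_seqs(sim$proteomes$A); pb <- proteome_seqs(sim$proteomes$B)
  ab <- call_orthologs(pa, pb)
  ba <- call_orthologs(pb, pa)
  expect_setequal(paste(ab$protein_a, ab$protein_b),
                  paste(ba$protein_b, ba$protein_a))
  strict <- call_orthologs(pa, pb, min_identity = 60, min_coverage = 0.95)
  expect_true(all(paste(strict$protein_a, strict$protein_b) %in%
                    paste(ab$protein_a, ab$protein_b)))
  # substitution-only divergence gives essentially full-length alignments
  # (local alignment may trim a few terminal mismatching residues)
  expect_gte(min(ab$coverage_smaller), 0.95)
})

test_that("ortholog groups are connected components labeled with species", {
  pairs <- data.frame(protein_a = c("a1", "b1"), protein_b = c("b1", "c1"),
                      stringsAsFactors = FALSE)
  spmap <- c(a1 = "A", b1 = "B", c1 = "C")
  groups <- build_ortholog_groups(pairs, spmap)
  expect_length(groups, 1)
  expect_equal(groups[[1]]$members, c("a1", "b1", "c1"))
  expect_equal(groups[[1]]$species, c("A", "B", "C"))
  expect_length(build_ortholog_groups(pairs[0, ], spmap), 0)
  expect_error(build_ortholog_groups(pairs, spmap[-1]), "missing")
})

test_that("Venn partition counts groups and private proteins consistently", {
  sim <- simulate_proteomes(proteome_sim_spec(c("A", "B"), 10,
                                              core_fraction = 1,
                                              pairwise_identity = 90,
                                              seed = 57))
  seqs <- lapply(sim$proteomes, proteome_seqs)
  pairs <- call_orthologs(seqs$A, seqs$B)
  spmap <- c(setNames(rep("A", 10), names(seqs$A)),
             setNames(rep("B", 10), names(seqs$B)))
  groups <- build_ortholog_groups(pairs, spmap)
  venn <- venn_partition(groups, c("A", "B"),
                         proteome_ids = lapply(seqs, names))
  expect_equal(venn$n_groups[venn$region == "A&B"], 10)
  expect_equal(venn$n_proteins[venn$region == "A"], 0)
  expect_equal(venn$n_proteins[venn$region == "B"], 0)
  # partition property: groups + private proteins are fully accounted for
  expect_equal(sum(venn$n_groups) +
                 sum(venn$n_proteins[venn$n_species == 1]),
               length(groups) + 0)
  expect_error(venn_partition(groups, c("A", "B", "C", "D", "E")), "2 to 4")
})

test_that("four-species Venn partition matches the planted design", {
  sim <- simulate_proteomes(proteome_sim_spec(c("A", "B", "C", "D"), 25,
                                              core_fraction = 0.6,
                                              pairwise_identity = 80,
                                              seed = 58))
  seqs <- lapply(sim$proteomes, proteome_seqs)
  sp <- names(seqs)
  pairs <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    pairs[[paste(i, j)]] <- call_orthologs(seqs[[i]], seqs[[j]])
  }
  pairs <- do.call(rbind, pairs)
  spmap <- unlist(lapply(sp, function(s)
    setNames(rep(s, length(seqs[[s]])), names(seqs[[s]]))))
  groups <- build_ortholog_groups(pairs, spmap)
  venn <- venn_partition(groups, sp, proteome_ids = lapply(seqs, names))
  n_core <- length(sim$truth$ortholog_groups)
  expect_equal(venn$n_groups[venn$region == "A&B&C&D"], n_core)
  expect_equal(venn$n_proteins[venn$region == "A&B&C&D"], 4 * n_core)
  # accessory genes are private
  expect_equal(venn$n_proteins[venn$region == "A"], 25 - n_core)
})

test_that("synton detection finds collinear and inverted runs", {
  n <- 10
  pairs <- data.frame(protein_a = sprintf("a%02d", 1:n),
                      protein_b = sprintf("b%02d", 1:n),
                      stringsAsFactors = FALSE)
  oa <- setNames(0:(n - 1), pairs$protein_a)
  ob <- setNames(0:(n - 1), pairs$protein_b)
  s <- find_syntons(pairs, oa, ob, min_synton_size = 3)
  expect_length(s, 1)
  expect_equal(s[[1]]$size, 10)
  expect_equal(s[[1]]$orientation, "same")

  s_inv <- find_syntons(pairs, oa, setNames((n - 1):0, pairs$protein_b),
                        min_synton_size = 3)
  expect_length(s_inv, 1)
  expect_equal(s_inv[[1]]$size, 10)
  expect_equal(s_inv[[1]]$orientation, "inverted")

  # runs below the minimum size are dropped
  short <- pairs[1:2, ]
  expect_length(find_syntons(short, oa, ob, min_synton_size = 3), 0)
})

test_that("synton gap handling matches exhaustive enumeration on a hand-built map", {
  # 8 genes, one transposed: b order is 0 1 2 7 3 4 5 6
  pairs <- data.frame(protein_a = sprintf("a%d", 1:8),
                      protein_b = sprintf("b%d", 1:8),
                      stringsAsFactors = FALSE)
  oa <- setNames(0:7, pairs$protein_a)
  ob <- setNames(c(0, 1, 2, 7, 3, 4, 5, 6), pairs$protein_b)
  got <- find_syntons(pairs, oa, ob, min_synton_size = 3, max_gap = 1)
  # exhaustive enumeration of maximal co-monotone runs with gaps <= 1:
  # a1-a2-a3 continues to a5-a6-a7-a8 (skipping transposed a4, gap 1 on both
  # axes), so the maximal run is {a1,a2,a3,a5,a6,a7,a8}
  expect_length(got, 1)
  expect_equal(got[[1]]$pairs$protein_a,
               c("a1", "a2", "a3", "a5", "a6", "a7", "a8"))
  # with no gaps allowed the run breaks at the transposition
  got0 <- find_syntons(pairs, oa, ob, min_synton_size = 3, max_gap = 0)
  sizes <- sort(vapply(got0, `[[`, numeric(1), "size"))
  expect_equal(sizes, c(3, 4))
})
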