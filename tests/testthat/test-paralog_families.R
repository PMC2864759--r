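test_that("low-complexity masking is entropy-driven and idempotent", {
  expect_equal(mask_low_complexity("QQQQQQQQQQQQ"), "XXXXXXXXXXXX")
  set.seed(71)
  # random windows over 20 residues essentially never dip below 2.0 bits
  for (i in 1:20) {
    s <- random_protein_str(60)
    expect_identical(mask_low_complexity(s, entropy_threshold = 2.0), s)
  }
  # masking is idempotent
  s <- paste0(random_protein_str(30), strrep("PA", 12), random_protein_str(30))
  m1 <- mask_low_complexity(s)
  expect_identical(mask_low_complexity(m1), m1)
  expect_true(grepl("X", m1))
  # short sequences are left alone
  expect_identical(mask_low_complexity("MK"), "MK")
})

test_that("similarity graph edges match an exhaustive alignment oracle", {
  set.seed(72)
  a <- random_protein_str(120)
  prot <- c(p1 = a, p2 = mutate_to_identity(a, 80, seed = 1),
            p3 = random_protein_str(120))
  g <- build_similarity_graph(prot, min_shared_kmers = 0)
  expect_setequal(paste(g$edges$from, g$edges$to), c("p1 p2", "p2 p1"))

  # threshold above every score: empty graph
  g0 <- build_similarity_graph(prot, min_identity = 101, min_shared_kmers = 0)
  expect_equal(nrow(g0$edges), 0)

  # random proteome: edges equal brute-force pairwise-alignment decisions
  set.seed(73)
  prot2 <- setNames(c(vapply(1:8, function(i) random_protein_str(100),
                             character(1)),
                      mutate_to_identity(a, 75, seed = 2), a),
                    sprintf("q%02d", 1:10))
  g2 <- build_similarity_graph(prot2, min_shared_kmers = 0, mask = FALSE)
  want <- character(0)
  for (u in names(prot2)) for (v in names(prot2)) {
    if (u == v) next
    al <- local_align(prot2[u], prot2[v])
    if (!al$no_alignment && al$identity_pct >= 30 &&
        al$coverage_smaller >= 0.5)
      want <- c(want, paste(u, v))
  }
  expect_setequal(paste(g2$edges$from, g2$edges$to), want)
})

test_that("transitive closure builds families; chains merge; empty graphs dont", {
  set.seed(74)
  # chain: A ~ B ~ C with A and C too diverged for a direct edge; closure
  # still puts them in one family
  b <- random_protein_str(150)
  a <- mutate_to_identity(b, 62, seed = 1)
  cc <- mutate_to_identity(b, 62, seed = 2,
                           positions = sample(which(strsplit(a, "")[[1]] ==
                                                      strsplit(b, "")[[1]]),
                                              57))
  prot <- c(A = a, B = b, C = cc)
  g <- build_similarity_graph(prot, min_identity = 55, min_coverage = 0.5,
                              min_shared_kmers = 0)
  # verify the chain premise: A-B and B-C edges but no A-C edge
  keys <- paste(g$edges$from, g$edges$to)
  expect_true(all(c("A B", "B C") %in% keys))
  expect_false("A C" %in% keys)
  fam <- symmetrify_and_close(g)
  expect_length(fam$families, 1)
  expect_equal(fam$families[[1]], c("A", "B", "C"))

  # empty graph: all singletons
  prot5 <- setNames(vapply(1:5, function(i) random_protein_str(80),
                           character(1)), paste0("s", 1:5))
  g5 <- build_similarity_graph(prot5, min_shared_kmers = 0)
  fam5 <- symmetrify_and_close(g5)
  expect_length(fam5$families, 0)
  expect_length(fam5$singletons, 5)
})

test_that("planted duplication-divergence families are recovered exactly", {
  for (seed in 1:5) {
    spec <- proteome_sim_spec(c("A", "B"), 8, core_fraction = 0,
                              paralog_families = data.frame(
                                size = c(3, 5, 12),
                                identity = c(70, 70, 70)),
                              seed = seed)
    sim <- simulate_proteomes(spec)
    prot <- proteome_seqs(sim$proteomes$A)
    fam <- paralog_families(prot)
    expect_identical(canon_partition(fam$families),
                     canon_partition(sim$truth$paralog_families))
  }
})

test_that("family membership is invariant under input order", {
  spec <- proteome_sim_spec(c("A", "B"), 5, core_fraction = 0,
                            paralog_families = data.frame(size = c(3, 4),
                                                          identity = 75),
                            seed = 76)
  prot <- proteome_seqs(simulate_proteomes(spec)$proteomes$A)
  f1 <- paralog_families(prot)
  set.seed(1)
  f2 <- paralog_families(sample(prot))
  expect_identical(canon_partition(f1$families), canon_partition(f2$families))
})

test_that("lowering the similarity threshold never splits a family", {
  spec <- proteome_sim_spec(c("A", "B"), 6, core_fraction = 0,
                            paralog_families = data.frame(size = c(4, 3),
                                                          identity = 65),
                            seed = 77)
  prot <- proteome_seqs(simulate_proteomes(spec)$proteomes$A)
  strict <- paralog_families(prot, min_identity = 50)
  loose <- paralog_families(prot, min_identity = 25)
  # every strict family is contained in one loose family
  for (f in strict$families) {
    containing <- Filter(function(g) all(f %in% g), loose$families)
    expect_length(containing, 1)
  }
})

test_that("fusion proteins are flagged as multi-domain and excluded", {
  set.seed(78)
  x <- random_protein_str(120)
  y <- random_protein_str(120)
  prot <- c(fus = paste0(x, y),
            px = mutate_to_identity(x, 90, seed = 1),
            py = mutate_to_identity(y, 90, seed = 2))
  g <- build_similarity_graph(prot, min_shared_kmers = 0)
  expect_equal(flag_multidomain(g), "fus")
  fam <- symmetrify_and_close(g, exclude = flag_multidomain(g))
  expect_equal(fam$excluded, "fus")
  expect_length(fam$families, 0)

  # two partners hitting the same span: not flagged
  prot2 <- c(core = x, p1 = mutate_to_identity(x, 85, seed = 3),
             p2 = mutate_to_identity(x, 85, seed = 4))
  g2 <- build_similarity_graph(prot2, min_shared_kmers = 0)
  expect_length(flag_multidomain(g2), 0)
  # single-neighbor proteins are never flagged
  g3 <- build_similarity_graph(c(a = x, b = mutate_to_identity(x, 90, seed = 5)),
                               min_shared_kmers = 0)
  expect_length(flag_multidomain(g3), 0)
})

test_that("family statistics count and round as documented", {
  st <- family_stats(list(c("A", "B"), c("C", "D", "E")), "F")
  expect_equal(st$n_with_paralog, 5)
  expect_equal(st$n_singletons, 1)
  expect_equal(st$pct_with_paralog, 83)
  expect_equal(st$n_analyzed, 6)

  expect_error(family_stats(list(c("A", "B"), c("B", "C")), character(0)),
               "disjoint")
  expect_error(family_stats(list("A"), "B"), ">= 2")

  # counts conserve: families + singletons + excluded = proteome
  spec <- proteome_sim_spec(c("A", "B"), 10, core_fraction = 0,
                            paralog_families = data.frame(size = 4,
                                                          identity = 75),
                            seed = 79)
  prot <- proteome_seqs(simulate_proteomes(spec)$proteomes$A)
  fam <- paralog_families(prot)
  st2 <- family_stats(fam$families, fam$singletons, fam$excluded)
  expect_equal(st2$n_with_paralog + st2$n_singletons + st2$n_excluded,
               length(prot))
})
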