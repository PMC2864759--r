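test_that("consensus parsing handles plain, alternation and IUPAC syntax", {
  m <- parse_consensus("TTATCCACA")
  expect_equal(m$length, 9)
  expect_equal(m$n_expansions, 1)
  expect_true(all(lengths(m$positions) == 1))

  repa <- parse_consensus("CGCAGAA(A/T)(C/T)(A/G)GGTACG(C/T)")
  expect_equal(repa$length, 17)
  expect_equal(repa$n_expansions, 16)

  expect_equal(parse_consensus("N")$positions[[1]], c("A", "C", "G", "T"))
  expect_equal(parse_consensus("R")$positions[[1]], c("A", "G"))

  expect_error(parse_consensus("AC(G/T"), "unbalanced")
  expect_error(parse_consensus("ACG)T"), "unbalanced")
  expect_error(parse_consensus("ACQT"), "illegal character 'Q'")
  expect_identical(builtin_motif("dnaA_box")$length, 9L)
  expect_identical(builtin_motif("repA_repeat")$n_expansions, 16)
})

test_that("exact and budgeted scanning behave on forced examples", {
  hits <- scan_motif(replicon("r", "TTATCCACA", circular = FALSE),
                     "TTATCCACA", 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  r1 <- replicon("r", "TTATCCACT", circular = FALSE)
  expect_equal(nrow(scan_motif(r1, "TTATCCACA", 0, strands = "+")), 0)
  h1 <- scan_motif(r1, "TTATCCACA", 1, strands = "+")
  expect_equal(h1$mismatches, 1)

  # degenerate positions match free of charge; N in the subject never matches
  rdeg <- replicon("r", "CGCAGAATCAGGTACGT", circular = FALSE)
  expect_equal(nrow(scan_motif(rdeg, builtin_motif("repA_repeat"), 0,
                               strands = "+")), 1)
  rn <- replicon("r", "TTATCCACN", circular = FALSE)
  expect_equal(scan_motif(rn, "TTATCCACA", 1, strands = "+")$mismatches, 1)

  expect_error(scan_motif(r1, "ACGT", 4), "smaller than the motif length")
})

test_that("minus-strand hits are reverse-complement matches in forward coordinates", {
  core <- "TTATCCACA"
  seq <- paste0("AAAA", chartr("ACGT", "TGCA",
                               paste(rev(strsplit(core, "")[[1]]),
                                     collapse = "")), "AAAA")
  hits <- scan_motif(replicon("r", seq, circular = FALSE), core, 0)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 4)
})

test_that("circular scanning finds wrap-around hits", {
  # plant a motif across the origin: last 4 bases + first 5 bases
  seq <- paste0("CCACA", random_dna(200), "TTAT")
  hits <- scan_motif(replicon("r", seq, circular = TRUE), "TTATCCACA", 0,
                     strands = "+")
  expect_true(any(hits$start == nchar(seq) - 4))
  hits_lin <- scan_motif(replicon("r", seq, circular = FALSE), "TTATCCACA",
                         0, strands = "+")
  expect_false(any(hits_lin$start == nchar(seq) - 4))
})

test_that("scanner agrees exactly with the exhaustive oracle", {
  set.seed(41)
  seq <- random_dna(2000)
  r <- replicon("r", seq)
  motif <- parse_consensus("TTATCCACA")
  for (budget in 0:2) {
    got <- scan_motif(r, motif, budget)
    want <- oracle_scan(seq, motif$positions, budget)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
  # degenerate motif, sequence containing N
  seqN <- paste0(substr(seq, 1, 900), "NNNNNNNNNN", substr(seq, 911, 2000))
  rN <- replicon("r", seqN)
  repa <- builtin_motif("repA_repeat")
  for (budget in 0:2) {
    got <- scan_motif(rN, repa, budget)
    want <- oracle_scan(seqN, repa$positions, budget)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("hit sets are monotone in the budget and strand-symmetric", {
  set.seed(43)
  seq <- random_dna(3000)
  r <- replicon("r", seq)
  key <- function(h) paste(h$start, h$strand, h$mismatches)
  prev <- character(0)
  for (budget in 0:3) {
    h <- scan_motif(r, "TTATCCACA", budget)
    expect_true(all(prev %in% key(h)))
    prev <- key(h)
  }
  # reverse-complementing the subject mirrors the hit multiset
  L <- nchar(seq)
  rc <- replicon("rc", chartr("ACGT", "TGCA",
                              paste(rev(strsplit(seq, "")[[1]]),
                                    collapse = "")))
  h <- scan_motif(r, "TTATCCACA", 2)
  hrc <- scan_motif(rc, "TTATCCACA", 2)
  mapped <- data.frame(start = (L - h$start - 9) %% L,
                       strand = ifelse(h$strand == "+", "-", "+"),
                       mismatches = h$mismatches)
  expect_equal(
    mapped[order(mapped$start, mapped$strand), , drop = FALSE],
    hrc[order(hrc$start, hrc$strand), c("start", "strand", "mismatches")],
    ignore_attr = TRUE)
})

test_that("hit clustering equals the transitive closure of the gap relation", {
  mk <- function(starts) data.frame(start = starts, end = starts + 9L,
                                    strand = rep("+", length(starts)),
                                    mismatches = rep(0L, length(starts)),
                                    motif = rep("m", length(starts)),
                                    stringsAsFactors = FALSE)
  cl <- cluster_hits(mk(c(0, 30, 500)), max_gap = 100)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$n, 2)
  expect_equal(cl[[1]]$span_start, 0)
  expect_equal(cl[[1]]$span_end, 39)
  expect_equal(cl[[2]]$n, 1)

  expect_length(cluster_hits(mk(integer(0)), 100), 0)

  set.seed(47)
  for (i in 1:20) {
    starts <- sort(sample(0:2000, sample(2:40, 1)))
    gap <- sample(c(5, 50, 200), 1)
    got <- cluster_hits(mk(starts), gap)
    # oracle: transitive closure of |si - sj| <= gap on sorted starts
    breaks <- which(diff(starts) > gap)
    want_sizes <- diff(c(0, breaks, length(starts)))
    expect_equal(vapply(got, `[[`, numeric(1), "n"), want_sizes)
  }
})

test_that("circular clustering merges across the origin", {
  mk <- function(starts) data.frame(start = starts, end = starts + 9L,
                                    strand = "+", mismatches = 0L,
                                    motif = "m", stringsAsFactors = FALSE)
  cl <- cluster_hits(mk(c(5, 990)), max_gap = 20, L = 1000)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n, 2)
  # far apart around the origin: no merge
  expect_length(cluster_hits(mk(c(5, 900)), max_gap = 20, L = 1000), 2)
})
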