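# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

AA20_TEST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein_str <- function(len) paste(sample(AA20_TEST, len, TRUE),
                                          collapse = "")
random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                  collapse = "")

# --- window statistics: direct per-window counting -------------------------
oracle_window_counts <- function(seq, window, step, stat) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  starts <- seq(0, L - 1, by = step)
  vapply(starts, function(s) {
    idx <- ((s + seq_len(window) - 1) %% L) + 1
    w <- chars[idx]
    g <- sum(w == "G"); cc <- sum(w == "C"); nn <- sum(w == "N")
    if (stat == "gc_content") {
      if (window - nn == 0) 0 else (g + cc) / (window - nn)
    } else {
      if (g + cc == 0) 0 else (g - cc) / (g + cc)
    }
  }, numeric(1))
}

# --- motif scanning: enumerate every position x strand ---------------------
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_scan <- function(seq, consensus_sets, max_mm, circular = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars); w <- length(consensus_sets)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev_sets <- lapply(rev(consensus_sets), function(s) unname(comp[s]))
  starts <- if (circular) 0:(L - 1) else 0:(L - w)
  res <- list()
  for (s in starts) {
    for (strand in c("+", "-")) {
      sets <- if (strand == "+") consensus_sets else rev_sets
      mm <- 0
      for (j in seq_len(w)) {
        base <- chars[((s + j - 1) %% L) + 1]
        if (!(base %in% sets[[j]])) mm <- mm + 1
      }
      if (mm <= max_mm)
        res[[length(res) + 1]] <- data.frame(start = s, strand = strand,
                                             mismatches = mm,
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(data.frame(start = integer(0),
                                      strand = character(0),
                                      mismatches = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), , drop = FALSE]
}

# --- alignment: global affine-gap (Gotoh) + all-substring-pairs local ------
oracle_global_gotoh <- function(a, b, submat, open, ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  if (n >= 1) for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[ca[i - 1], cb[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# best local score = max over all substring pairs of the global score
# (empty alignment scores 0); O(n^2 m^2) global alignments
oracle_local_bruteforce <- function(a, b, submat, open = 11, ext = 1) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in 1:na) for (i2 in i1:na) {
    sa <- substr(a, i1, i2)
    for (j1 in 1:nb) for (j2 in j1:nb) {
      sb <- substr(b, j1, j2)
      best <- max(best, oracle_global_gotoh(sa, sb, submat, open, ext))
    }
  }
  best
}

# --- single linkage: naive O(n^3) agglomeration ----------------------------
oracle_single_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- min(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# cophenetic matrix implied by naive single linkage (height of first merge
# containing both leaves)
oracle_single_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- min(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    for (x in clusters[[bi]]) for (y in clusters[[bj]])
      coph[x, y] <- coph[y, x] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  coph
}

# --- partition comparison --------------------------------------------------
# Rand index between two partitions given as lists of member vectors over
# the same element universe (elements not listed form their own singletons).
rand_index <- function(partition1, partition2, universe) {
  lab <- function(p) {
    l <- setNames(rep(NA_integer_, length(universe)), universe)
    for (i in seq_along(p)) l[p[[i]]] <- i
    k <- max(c(0L, l), na.rm = TRUE)
    l[is.na(l)] <- k + seq_len(sum(is.na(l)))
    l
  }
  l1 <- lab(partition1); l2 <- lab(partition2)
  n <- length(universe)
  agree <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if ((l1[i] == l1[j]) == (l2[i] == l2[j])) agree <- agree + 1
  }
  agree / tot
}

# canonical form for comparing families/groups ignoring order
canon_partition <- function(p) {
  s <- lapply(p, function(x) sort(as.character(x)))
  s[order(vapply(s, `[`, character(1), 1))]
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
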