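# Internal helpers shared across modules.

# Round half away from zero (so 9.05 -> 9.1, 21.5 -> 22), the convention used
# for all printed percentages and ratios in reports.
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Seed scoping: set the RNG deterministically for the duration of the caller,
# restoring the caller's RNG state on exit. Usage:
#   restore <- local_seed(seed); on.exit(restore(), add = TRUE)
local_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
    invisible(NULL)
  }
}

# Derive per-component seeds from one master seed by fixed offsets, kept
# within the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")
AA20 <- setdiff(AA_ALPHABET, "X")
COG_CLASSES <- c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z",
                 "W", "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")

reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
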