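#' Windowed G+C content of a replicon
#'
#' Computes `(G + C) / (A + C + G + T)` in fixed windows; `N` bases are
#' excluded from numerator and denominator. On circular replicons windows
#' wrap across the origin.
#'
#' @param rep A [replicon()].
#' @param window Window size in bp (default 2000, the display convention for
#'   bacterial genome maps).
#' @param step Step between window starts; defaults to `window`
#'   (non-overlapping).
#' @return A list of class `skew_profile` with fields `positions` (0-based
#'   window starts), `values`, `window`, `step`, `stat`.
#' @export
gc_content_windows <- function(rep, window = 2000, step = window) {
  window_stat(rep, window, step, "gc_content")
}

#' Windowed GC skew of a replicon
#'
#' Computes `S_w = (G - C) / (G + C)` in fixed windows; a window with no G or
#' C emits 0 with a warning. The sign of `S_w` typically switches at the
#' replication origin and terminus.
#'
#' @inheritParams gc_content_windows
#' @return A `skew_profile` (see [gc_content_windows()]).
#' @export
gc_skew_windows <- function(rep, window = 2000, step = window) {
  window_stat(rep, window, step, "gc_skew")
}

window_stat <- function(rep, window, step, stat) {
  stopifnot(inherits(rep, "replicon"))
  if (window <= 0) stop("window must be positive")
  if (step <= 0) stop("step must be positive")
  L <- rep$length
  if (window > L) stop("window larger than replicon")
  chars <- strsplit(rep$seq, "")[[1]]
  isG <- as.integer(chars == "G"); isC <- as.integer(chars == "C")
  isN <- as.integer(chars == "N")
  # doubled cumulative sums make circular wrap-around windows O(1)
  ext <- function(x) cumsum(c(0L, x, x))
  cG <- ext(isG); cC <- ext(isC); cN <- ext(isN)
  starts <- seq(0L, L - 1L, by = step)
  if (!rep$circular) starts <- starts[starts + window <= L]
  rng <- function(cs, s) cs[s + window + 1L] - cs[s + 1L]
  nG <- rng(cG, starts); nC <- rng(cC, starts); nN <- rng(cN, starts)
  if (stat == "gc_content") {
    denom <- window - nN
    if (any(denom == 0)) warning("window(s) with only N bases emit 0")
    values <- ifelse(denom == 0, 0, (nG + nC) / denom)
  } else {
    denom <- nG + nC
    if (any(denom == 0)) warning("window(s) with no G or C emit 0")
    values <- ifelse(denom == 0, 0, (nG - nC) / denom)
  }
  structure(list(positions = as.integer(starts), values = as.numeric(values),
                 window = as.integer(window), step = as.integer(step),
                 stat = stat),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> %s: %d windows of %d bp (step %d)\n",
              x$stat, length(x$values), x$window, x$step))
  invisible(x)
}

#' Cumulative GC skew
#'
#' Per-base running sum `c[i] = sum_{j <= i} (+1 if G, -1 if C, 0 otherwise)`.
#' On a circular chromosome with leading-strand G enrichment the detrended
#' curve attains its minimum at the origin and its maximum at the terminus.
#'
#' @param rep A [replicon()].
#' @return Numeric vector of length `L`.
#' @export
cumulative_skew <- function(rep) {
  stopifnot(inherits(rep, "replicon"))
  chars <- strsplit(rep$seq, "")[[1]]
  cumsum((chars == "G") - (chars == "C"))
}

#' Predict replication origin and terminus from GC skew
#'
#' The cumulative skew is detrended by subtracting its linear trend over one
#' full circle (removing the dependence on the arbitrary start coordinate of
#' a circular sequence); the origin is called at the curve minimum and the
#' terminus at the maximum, under the convention that the leading strand is
#' G-rich. If DnaA-box clusters are supplied and a cluster of >= 3 boxes
#' lies within `snap_within` of the skew minimum, the origin call snaps to
#' that cluster's midpoint.
#'
#' A flat profile (range below the `2 * sqrt(L)` noise floor of a driftless
#' random walk) yields a call flagged `confident = FALSE` rather than an
#' error.
#'
#' @param rep A [replicon()]; length must be at least `10 * window`.
#' @param box_clusters Optional list of box clusters from [cluster_hits()].
#' @param window Window size used for the length precondition and reporting.
#' @param snap_within Maximum distance (bp) between the skew minimum and a
#'   box cluster for refinement (default 20000).
#' @param leading_strand_g_rich Sign convention; set `FALSE` to swap the
#'   roles of minimum and maximum.
#' @return A list of class `ori_ter_call`: `ori`, `ter` (0-based positions),
#'   `replichore_lengths`, `asymmetry` (longer/shorter), `refined_by_boxes`,
#'   `confident`.
#' @export
predict_ori_ter <- function(rep, box_clusters = NULL, window = 2000,
                            snap_within = 20000,
                            leading_strand_g_rich = TRUE) {
  stopifnot(inherits(rep, "replicon"))
  L <- rep$length
  if (L < 10 * window)
    stop("replicon too short for ori/ter prediction (need >= 10 windows)")
  cs <- cumulative_skew(rep)
  detr <- cs - seq_len(L) * cs[L] / L
  if (!leading_strand_g_rich) detr <- -detr
  confident <- (max(detr) - min(detr)) >= 2 * sqrt(L)
  ori <- which.min(detr) %% L # transition occurs after the extreme base
  ter <- which.max(detr) %% L
  refined <- FALSE
  if (!is.null(box_clusters) && length(box_clusters)) {
    mids <- vapply(box_clusters, function(cl)
      floor((cl$span_start + cl$span_end) / 2), numeric(1))
    sizes <- vapply(box_clusters, function(cl) cl$n, numeric(1))
    dist <- pmin((mids - ori) %% L, (ori - mids) %% L)
    eligible <- sizes >= 3 & dist <= snap_within
    if (any(eligible)) {
      best <- which(eligible)[which.min(dist[eligible])]
      ori <- as.integer(mids[best]) %% L
      refined <- TRUE
    }
  }
  rl <- replichore_lengths(ori, ter, L)
  structure(list(ori = as.integer(ori), ter = as.integer(ter),
                 replichore_lengths = rl,
                 asymmetry = max(rl) / min(rl),
                 refined_by_boxes = refined, confident = confident),
            class = "ori_ter_call")
}

#' @export
print.ori_ter_call <- function(x, ...) {
  cat(sprintf(paste0("<ori_ter_call> ori=%d ter=%d replichores=%d/%d bp ",
                     "asymmetry=%.3f%s%s\n"),
              x$ori, x$ter, x$replichore_lengths[1], x$replichore_lengths[2],
              x$asymmetry,
              if (x$refined_by_boxes) " [box-refined]" else "",
              if (!x$confident) " [NO CONFIDENT CALL]" else ""))
  invisible(x)
}

#' Replichore lengths of a circular replicon
#'
#' The two arcs between origin and terminus: clockwise `ori -> ter` and
#' `ter -> ori`. They always sum to the replicon length.
#'
#' @param ori,ter 0-based positions, distinct.
#' @param L Replicon length in bp.
#' @return Integer vector of the two arc lengths (clockwise first).
#' @export
replichore_lengths <- function(ori, ter, L) {
  stopifnot(ori >= 0, ori < L, ter >= 0, ter < L)
  if (ori == ter) stop("ori and ter must differ")
  cw <- (ter - ori) %% L
  c(as.integer(cw), as.integer(L - cw))
}

#' Write a skew profile as TSV
#'
#' Columns: `start`, `gc_content`, `gc_skew` (computed at matching windows).
#'
#' @param rep A [replicon()].
#' @param path Output path.
#' @param window,step Window parameters, as in [gc_skew_windows()].
#' @return `path`, invisibly.
#' @export
write_skew_tsv <- function(rep, path, window = 2000, step = window) {
  gc <- gc_content_windows(rep, window, step)
  sk <- gc_skew_windows(rep, window, step)
  df <- data.frame(start = gc$positions, gc_content = gc$values,
                   gc_skew = sk$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
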