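# Window decomposition of SNP variance: sliding sums of n consecutive SNPs
# per chromosome, then a greedy exclusive tiling keeping the highest-variance
# windows (leftmost on ties); gaps shorter than n between or flanking
# selected windows become short windows, so the tiling is disjoint and
# exhaustive and conserves the per-SNP variance total.

#' Sliding window variance sums
#'
#' For each map index i, the sum of per-SNP variances of SNPs
#' i..min(i + n - 1, chromosome end).  Windows never span chromosomes.
#'
#' @param variances per-SNP variances in map order.
#' @param map marker map data.frame (`snp`, `chr`, `pos`), sorted.
#' @param n window size in SNPs (default 20).
#' @return data.frame with `index`, `snp`, `chr`, `start`, `end`,
#'   `windowVariance` (start == index; end is truncated at the chromosome
#'   end).
#' @export
slidingWindowVariances <- function(variances, map, n = 20L) {
  stopifnot(length(variances) == nrow(map), n >= 1)
  out <- lapply(split(seq_len(nrow(map)),
                      factor(map$chr, levels = unique(map$chr))),
                function(ii) {
    v <- variances[ii]
    mc <- length(v)
    cs <- cumsum(c(0, v))
    ends <- pmin(seq_len(mc) + n - 1L, mc)
    data.frame(index = ii, snp = map$snp[ii], chr = map$chr[ii][1],
               start = ii, end = ii[ends],
               windowVariance = cs[ends + 1L] - cs[seq_len(mc)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exclusive window tiling
#'
#' Per chromosome: repeatedly select the highest-variance sliding window that
#' does not overlap an already-selected one (ties broken by the leftmost
#' start), until no candidate fits; remaining uncovered runs (necessarily
#' shorter than n, or chromosome-edge remnants) become short windows.  The
#' result is a disjoint, exhaustive tiling whose window variances sum to the
#' per-SNP variance total.
#'
#' @param sliding output of [slidingWindowVariances()].
#' @param variances the per-SNP variances the sliding sums were computed from.
#' @param map the marker map used for the sliding sums.
#' @param n window size.
#' @return A [WindowSet-class].
#' @export
exclusiveTiling <- function(sliding, variances, map, n = 20L) {
  total <- sum(variances)
  res <- list()
  for (ch in unique(map$chr)) {
    ii <- which(map$chr == ch)
    loc <- sliding[sliding$chr == ch, , drop = FALSE]
    mc <- length(ii)
    first <- ii[1]
    s <- loc$start - first + 1L      # local coordinates 1..mc
    e <- loc$end - first + 1L
    w <- loc$windowVariance
    covered <- logical(mc)
    chosen <- integer(0)
    active <- seq_along(s)
    while (length(active)) {
      best <- active[order(-w[active], s[active])][1]
      chosen <- c(chosen, best)
      covered[s[best]:e[best]] <- TRUE
      active <- active[!(s[active] <= e[best] & e[active] >= s[best])]
    }
    win <- data.frame(start = s[chosen], end = e[chosen],
                      variance = w[chosen])
    # uncovered runs -> short windows
    if (any(!covered)) {
      r <- rle(covered)
      stops <- cumsum(r$lengths)
      starts <- stops - r$lengths + 1L
      for (k in which(!r$values)) {
        vloc <- variances[ii]
        win <- rbind(win, data.frame(start = starts[k], end = stops[k],
                                     variance = sum(vloc[starts[k]:stops[k]])))
      }
    }
    win <- win[order(win$start), , drop = FALSE]
    res[[length(res) + 1L]] <- data.frame(
      chr = ch, start = win$start + first - 1L, end = win$end + first - 1L,
      firstSnp = map$snp[win$start + first - 1L],
      lastSnp = map$snp[win$end + first - 1L],
      nSnps = win$end - win$start + 1L,
      variance = win$variance, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, res)
  rownames(d) <- NULL
  d$pct <- if (total > 0) d$variance / total * 100 else 0
  ws <- new("WindowSet", data = d, totalVariance = total,
            windowSize = as.integer(n))
  validObject(ws)
  ws
}

#' Window variances from per-SNP variances in one call
#'
#' @inheritParams slidingWindowVariances
#' @return A [WindowSet-class].
#' @export
windowVariances <- function(variances, map, n = 20L) {
  exclusiveTiling(slidingWindowVariances(variances, map, n), variances,
                  map, n)
}

#' Top-k windows by variance explained
#'
#' @param ws a [WindowSet-class].
#' @param k how many windows (default 10; fewer if the set is smaller).
#' @return data.frame of the k largest windows, descending by variance, with
#'   `pct` = window variance / total SNP variance x 100.
#' @export
topWindows <- function(ws, k = 10L) {
  d <- ws@data
  if (!nrow(d)) stop("empty WindowSet")
  d <- d[order(-d$variance, factor(d$chr, levels = unique(d$chr)), d$start),
         , drop = FALSE]
  head(d, k)
}

#' Manhattan-style plot of window variance shares
#'
#' @param ws a [WindowSet-class].
#' @param k highlight the top-k windows.
#' @param main plot title.
#' @export
plotWindowVariances <- function(ws, k = 10L, main = "Variance explained by SNP windows") {
  d <- ws@data
  chrF <- factor(d$chr, levels = unique(d$chr))
  mid <- (d$start + d$end) / 2
  cols <- c("grey30", "steelblue")[(as.integer(chrF) %% 2) + 1L]
  graphics::plot(mid, d$pct, col = cols, pch = 16, xlab = "SNP map index",
                 ylab = "% of SNP variance", main = main)
  top <- topWindows(ws, k)
  graphics::abline(v = (top$start + top$end) / 2, col = "red", lty = 3)
  invisible(NULL)
}
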