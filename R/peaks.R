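# Shared local-maximum finder.
#
# A peak is the EARLIEST sample of a run that is strictly higher than the
# value before the run and strictly higher than the value after it (plateaus
# count once, at their first sample). Candidates below `min_height` are
# dropped; a minimum separation is then enforced greedily in order of
# decreasing amplitude, as is conventional for peak pickers.

find_peaks <- function(x, min_height = -Inf, min_separation_n = 0L) {
  n <- length(x)
  if (n < 3L) return(integer())
  dx <- diff(x)
  change <- dx != 0
  # collapse plateaus: value of each run + index of its first sample
  run_start <- c(1L, which(change) + 1L)
  y <- x[run_start]
  m <- length(y)
  if (m < 3L) return(integer())
  core <- 2:(m - 1L)
  is_pk <- y[core] > y[core - 1L] & y[core] > y[core + 1L]
  idx <- run_start[core][is_pk]
  idx <- idx[x[idx] > min_height]
  if (length(idx) <= 1L || min_separation_n <= 0L) return(sort(idx))
  ord <- idx[order(x[idx], idx, decreasing = c(TRUE, FALSE), method = "radix")]
  kept <- integer()
  for (i in ord) {
    if (length(kept) == 0L || min(abs(kept - i)) >= min_separation_n)
      kept <- c(kept, i)
  }
  sort(kept)
}
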