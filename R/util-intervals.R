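# Interval arithmetic on 0-based half-open intervals, represented as
# data.frames with integer columns `start`, `end` (end exclusive).
# These back the genome layout (CDS, masks) and the neutral-region logic.

new_intervals <- function(start = integer(), end = integer()) {
  stopifnot(length(start) == length(end))
  df <- data.frame(start = as.integer(start), end = as.integer(end))
  if (any(df$end <= df$start)) stop("intervals must have end > start")
  df[order(df$start), , drop = FALSE]
}

#' @keywords internal
merge_intervals <- function(iv, adjacent = TRUE) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  ss <- integer(); ee <- integer()
  gap <- if (adjacent) 0L else -1L
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv$start[k] <= out_e + gap) {
      out_e <- max(out_e, iv$end[k])
    } else {
      ss <- c(ss, out_s); ee <- c(ee, out_e)
      out_s <- iv$start[k]; out_e <- iv$end[k]
    }
  }
  data.frame(start = c(ss, out_s), end = c(ee, out_e))
}

# complement of iv within [0, L)
complement_intervals <- function(iv, L) {
  if (nrow(iv) == 0) return(data.frame(start = 0L, end = as.integer(L)))
  iv <- merge_intervals(iv)
  starts <- c(0L, iv$end)
  ends <- c(iv$start, as.integer(L))
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

# for each position, TRUE if covered by some interval
positions_in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, iv$start)
  idx > 0 & pos < iv$end[pmax(idx, 1L)]
}

# index of covering interval (NA if none); intervals assumed disjoint sorted
interval_index_of <- function(pos, iv) {
  if (nrow(iv) == 0) return(rep(NA_integer_, length(pos)))
  idx <- findInterval(pos, iv$start)
  hit <- idx > 0 & pos < iv$end[pmax(idx, 1L)]
  ifelse(hit, idx, NA_integer_)
}

total_length <- function(iv) sum(iv$end - iv$start)
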