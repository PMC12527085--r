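# Interval algebra on tibbles with columns start_s / end_s.
# All intervals are half-open [start_s, end_s) in seconds.

empty_intervals <- function() {
  tibble(start_s = double(), end_s = double())
}

as_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(empty_intervals())
  stopifnot(all(c("start_s", "end_s") %in% names(x)))
  tibble(start_s = as.double(x$start_s), end_s = as.double(x$end_s))
}

# Sort and union overlapping or abutting intervals (canonical form).
canonicalize_intervals <- function(x) {
  x <- as_intervals(x)
  if (nrow(x) == 0) return(x)
  x <- arrange(x, .data$start_s, .data$end_s)
  out_s <- x$start_s[1]
  out_e <- x$end_s[1]
  k <- 1
  if (nrow(x) > 1) {
    for (i in 2:nrow(x)) {
      if (x$start_s[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], x$end_s[i])
      } else {
        k <- k + 1
        out_s[k] <- x$start_s[i]
        out_e[k] <- x$end_s[i]
      }
    }
  }
  tibble(start_s = out_s, end_s = out_e)
}

interval_measure <- function(x) {
  x <- canonicalize_intervals(x)
  sum(x$end_s - x$start_s)
}

# Measure of overlap between one interval [a, b) and a canonical interval set.
overlap_with_set <- function(a, b, set) {
  if (nrow(set) == 0) return(rep(0, length(a)))
  lo <- outer(a, set$start_s, pmax)
  hi <- outer(b, set$end_s, pmin)
  rowSums(pmax(hi - lo, 0))
}

# Intersect a canonical interval set with one interval [a, b).
clip_intervals <- function(x, a, b) {
  x <- as_intervals(x)
  s <- pmax(x$start_s, a)
  e <- pmin(x$end_s, b)
  keep <- e > s
  tibble(start_s = s[keep], end_s = e[keep])
}

# Complement of a canonical set within [0, duration).
complement_of <- function(x, duration_s) {
  x <- canonicalize_intervals(x)
  if (nrow(x) == 0) {
    if (duration_s <= 0) return(empty_intervals())
    return(tibble(start_s = 0, end_s = duration_s))
  }
  starts <- c(0, x$end_s)
  ends <- c(x$start_s, duration_s)
  keep <- ends > starts
  tibble(start_s = starts[keep], end_s = ends[keep])
}
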