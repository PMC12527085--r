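# Independent brute-force oracle for the merge rules, written naively:
# (a) concatenate gaps < gap_s within each track, (b) drop Transitions whose
# majority lies outside every no-Walking segment, (c) drop Sit pieces in
# segments with no surviving Transition, (d) span surviving Sit pieces per
# segment.
oracle_concat <- function(iv, gap_s) {
  iv <- iv[order(iv$start_s), , drop = FALSE]
  res <- NULL
  for (i in seq_len(nrow(iv))) {
    if (is.null(res) || iv$start_s[i] - res$end_s[nrow(res)] >= gap_s) {
      res <- rbind(res, iv[i, c("start_s", "end_s")])
    } else {
      res$end_s[nrow(res)] <- max(res$end_s[nrow(res)], iv$end_s[i])
    }
  }
  if (is.null(res)) iv[, c("start_s", "end_s")] else res
}

oracle_merge <- function(sit, tra, segs, gap_s = 1.5) {
  sit <- as.data.frame(oracle_concat(as.data.frame(sit), gap_s))
  tra <- as.data.frame(oracle_concat(as.data.frame(tra), gap_s))
  seg_of <- function(a, b) {
    ov <- pmax(0, pmin(b, segs$end_s) - pmax(a, segs$start_s))
    if (length(ov) == 0 || max(ov) <= 0 || max(ov) < (b - a) / 2 - 1e-12)
      return(NA_integer_)
    which.max(ov)
  }
  tra_segs <- unique(stats::na.omit(
    mapply(seg_of, tra$start_s, tra$end_s)))
  phases <- NULL
  for (s in seq_len(nrow(segs))) {
    if (!(s %in% tra_segs)) next
    lo <- segs$start_s[s]; hi <- segs$end_s[s]
    pieces <- sit[pmin(sit$end_s, hi) > pmax(sit$start_s, lo), , drop = FALSE]
    if (nrow(pieces) == 0) next
    ps <- pmax(pieces$start_s, lo); pe <- pmin(pieces$end_s, hi)
    keep <- mapply(seg_of, ps, pe) == s
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) next
    phases <- rbind(phases, data.frame(start_s = min(ps[keep]),
                                       end_s = max(pe[keep])))
  }
  if (is.null(phases)) data.frame(start_s = double(), end_s = double())
  else phases[order(phases$start_s), , drop = FALSE]
}

random_merge_instance <- function(duration = 100, gap_s = 1.5) {
  # no-Walking segments separated by at least gap_s of walking
  n_seg <- sample(1:4, 1)
  cuts <- sort(runif(n_seg * 2, 0, duration - 2 * n_seg * gap_s))
  starts <- cuts[seq(1, 2 * n_seg, 2)] + (seq_len(n_seg) - 1) * 2 * gap_s
  ends <- cuts[seq(2, 2 * n_seg, 2)] + (seq_len(n_seg) - 1) * 2 * gap_s + gap_s
  segs <- tibble::tibble(start_s = starts, end_s = ends)
  segs <- segs[segs$end_s > segs$start_s + 0.5, , drop = FALSE]
  list(sit = random_intervals(sample(0:8, 1), duration),
       tra = random_intervals(sample(0:8, 1), duration),
       segs = segs)
}
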