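# Shared fixtures and independent oracles, all generated in code.

cset <- gorilla_consensuses()

cseq <- function(name) consensus_entry(name, cset)$sequence

# mutate a sequence with i.i.d. substitutions (test-side twin of the
# simulator's mutation model; intentionally re-implemented here)
mutate_subs <- function(seq, rate) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  paste(s, collapse = "")
}

# brute-force HOR oracle: for every unit size k, partition the monomer
# indices into congruence classes mod k and average the p-distance over
# all within-class pairs; apply the same qualification thresholds as the
# detector and return the smallest qualifying k (NA if none).
oracle_hor_period <- function(dist_matrix, max_dist = 0.10,
                              dominance = 0.5, min_units = 2) {
  n <- nrow(dist_matrix)
  ks <- seq_len(n %/% 2)
  m <- vapply(ks, function(k) {
    vals <- c()
    for (r in seq_len(k)) {
      idx <- seq(r, n, by = k)
      if (length(idx) >= 2) {
        pairs <- utils::combn(idx, 2)
        vals <- c(vals, dist_matrix[t(pairs)])
      }
    }
    mean(vals)
  }, numeric(1))
  for (k in ks) {
    if (n %/% k < min_units) next
    if (m[k] > max_dist) next
    off <- ks[ks %% k != 0]
    if (length(off) && m[k] > dominance * stats::median(m[off])) next
    return(k)
  }
  NA_integer_
}
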