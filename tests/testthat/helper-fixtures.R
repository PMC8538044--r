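# Shared fixture builders for the test suite.

# A single-replicate course on the standard 13-point grid whose raw values
# are given directly (useful for constructing exact normalized shapes).
make_course <- function(values, replicate_id = "rep1", reporter = "slug") {
  stopifnot(length(values) == 13)
  data.frame(reporter = reporter, replicate_id = replicate_id,
             time_h = seq(0, 24, by = 2), fluorescence = values,
             stringsAsFactors = FALSE)
}

# A normalized course whose weakest-peak mean sits exactly at `k / 13`:
# one elevated point, the rest equal.
make_peak_course <- function(k, peak_index = 7) {
  v <- rep((1 - k / 13) / 12, 13)
  v[peak_index] <- k / 13
  normalize_course(make_course(v))
}

# Multi-replicate course from a matrix (replicates x 13).
make_course_reps <- function(mat, reporter = "slug") {
  do.call(rbind, lapply(seq_len(nrow(mat)), function(r)
    make_course(mat[r, ], replicate_id = sprintf("rep%d", r),
                reporter = reporter)))
}

# Brute-force upper-tail hypergeometric by enumeration of all draws
# (universe size <= 12): probability that drawing K elements from N yields
# at least k of the n marked ones.
brute_hyper <- function(k, n, N, K) {
  draws <- utils::combn(N, K)
  marked <- seq_len(n)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}
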