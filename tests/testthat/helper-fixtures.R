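# shared fixtures and independent oracles, built in code at test time

# quick recording from a channels x samples matrix
mk_recording <- function(signal, fs = 1000, subject = "t01",
                         population = "non-sport", condition = "home") {
  new_recording(signal, fs = fs, subject_id = subject,
                population = population, condition = condition)
}

# O(n^2) counting oracle for the rank-biserial statistic
rb_brute <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  2 * sum(cmp) / (length(x) * length(y)) - 1
}

# exact two-sided rank-sum p-value by full enumeration of rank assignments
ranksum_enum_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  w_all <- apply(utils::combn(n, length(a)), 2L, function(i) sum(r[i]))
  lo <- mean(w_all <= w_obs); hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# a small broadband test signal with reproducible content
broadband <- function(n, seed = 1) {
  set.seed(seed)
  rnorm(n)
}
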