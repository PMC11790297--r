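# shared fixtures: group truths at the cohort means, a long timeline, and
# small deterministic helpers used across test files

hvTruth <- subjectTruth("HV")
dpTruth <- subjectTruth("DP")

longTimeline <- AcquisitionTimeline(postExerciseSpan = 3600)

# exact two-tailed Mann-Whitney p by full enumeration of rank assignments
enumMannWhitneyP <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(ix) sum(ix) - n * (n + 1) / 2)
  pl <- mean(us <= u); pg <- mean(us >= u)
  min(1, 2 * min(pl, pg))
}

# exact two-tailed Wilcoxon signed-rank p by enumeration of all 2^n signs
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  pl <- mean(vs <= v); pg <- mean(vs >= v)
  min(1, 2 * min(pl, pg))
}
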