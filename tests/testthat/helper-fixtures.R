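# Shared fixture builders; everything is generated in code.

# Small simulated experiment with known truth.
smallSim <- function(nNull = 300, nUp = 30, nDown = 30, K = 3, seed = 101) {
  simulateTweedieData(SimulationConfig(nNull = nNull, nUp = nUp,
                                       nDown = nDown, kReplicates = K,
                                       seed = seed))
}

# Random count matrix (Poisson, so ties are common) with a group factor.
randomCounts <- function(nGenes, n1, n2, lambda = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * (n1 + n2), lambda), nrow = nGenes)
  rownames(m) <- sprintf("g%03d", seq_len(nGenes))
  colnames(m) <- sprintf("s%02d", seq_len(n1 + n2))
  list(m = m, groups = factor(rep(c("A", "B"), c(n1, n2))))
}

# Matrix whose per-sample totals are all equal, so the per-sample
# normalization inside the DEF statistic is the identity up to a constant.
equalLibraryMatrix <- function(rows) {
  m <- do.call(rbind, rows)
  tot <- max(colSums(m))
  balance <- tot - colSums(m) + 1
  rbind(m, balance = balance)
}
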