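# Independent oracles and small fixture builders for the test suite.
# These stay deliberately naive (enumeration / closed form) and never call
# the code paths they check.

# Exact pmf of the number of distinct values among N uniform draws with
# replacement from P cells, by dynamic programming over draws.
occupancyPmf <- function(N, P) {
  q <- c(1, numeric(N))  # q[u + 1] = P(distinct = u)
  for (i in seq_len(N)) {
    qn <- numeric(N + 1)
    for (u in 0:(i - 1)) {
      if (q[u + 1] == 0) next
      qn[u + 1] <- qn[u + 1] + q[u + 1] * u / P
      qn[u + 2] <- qn[u + 2] + q[u + 1] * (P - u) / P
    }
    q <- qn
  }
  q
}

# Exact lower-tail P(distinct < obs) for the intraspecies null.
occupancyLowerTail <- function(obs, N, P) {
  pmf <- occupancyPmf(N, P)
  if (obs <= 0) 0 else sum(pmf[seq_len(min(obs, N + 1))])
}

# Exact upper-tail P(X >= k) for X ~ Hypergeometric: U draws without
# replacement from P proteins of which A are annotated, via enumeration.
hyperUpperTail <- function(k, A, P, U) {
  sum(vapply(k:min(A, U), function(i)
    choose(A, i) * choose(P - A, U - i) / choose(P, U), 1))
}

# Binomial Monte-Carlo standard error of an empirical p at truth p0.
mcSE <- function(p0, reps) sqrt(p0 * (1 - p0) / reps)

toyNetwork <- function(edges, organism = "Si", space = "toy") {
  effectorHostNetwork(edges, organism = organism, space = space)
}

toyReference <- function(pairs) {
  referenceInteractome(data.frame(a = pairs[, 1], b = pairs[, 2],
                                  stringsAsFactors = FALSE))
}

hostIdsForTest <- function(n) sprintf("AT%dG%05d", ((seq_len(n) - 1L) %% 5L) + 1L, 10L * seq_len(n))

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
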