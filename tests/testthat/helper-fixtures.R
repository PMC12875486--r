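# Shared fixtures, all built in code.

# Tiny template with a single annotated adenine in a GAC context.
toy_template <- function() template_repeat("GACG", id = "toy")

# Read set of literal sequences.
reads_of <- function(...) read_set(c(...))

# Brute-force Mann-Whitney oracle: U by pair counting and the exact two-sided
# p-value by enumerating every assignment of the pooled values to the x slots.
mw_oracle <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  n <- length(x)
  mu <- n * length(y) / 2
  combos <- utils::combn(length(pooled), n)
  devs <- apply(combos, 2, function(idx) {
    abs(u_of(pooled[idx], pooled[-idx]) - mu)
  })
  list(u = u_obs, p_value = mean(devs >= abs(u_obs - mu) - 1e-12))
}

# Reverse complement, independent of the package internals.
dna_revcomp_for_tests <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Closed-form codon-fate probability for the uniform spectrum: a specific
# outcome differing from the source at j of its k adenines (and nowhere else)
# has probability (p/3)^j * (1-p)^(k-j).
uniform_outcome_prob <- function(codon, outcome, p) {
  src <- strsplit(codon, "")[[1]]
  out <- strsplit(outcome, "")[[1]]
  if (any(src != "A" & out != src)) return(0)
  k <- sum(src == "A")
  j <- sum(src == "A" & out != src)
  (p / 3)^j * (1 - p)^(k - j)
}
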