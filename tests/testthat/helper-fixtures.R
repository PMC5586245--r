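# Shared fixtures and independent oracles.

SPHERE_RG_FACTOR <- sqrt(3 / 5)

# vertebrate calmodulin, mature chain (residues 2-149 of the precursor;
# the protein sequence is identical across vertebrates)
CAM_SEQ <- paste0(
  "ADQLTEEQIAEFKEAFSLFDKDGDGTITTKELGTVMRSLGQNPTEAELQDMINEVDADGNGTIDFPEF",
  "LTMMARKMKDTDSEEEIREAFRVFDKDGNGYISAAELRHVMTNLGEKLTDEEVDEMIREADIDGDGQV",
  "NYEEFVQMMTAK")

default_q <- function(n = 400) seq(0.007, 0.31, length.out = n)

sphere_profile <- function(R = 30, noise = Inf, seed = 1, q = default_q()) {
  synth_generate(synth_spec("sphere", R = R, q = q,
                            counts_at_qmin = noise, seed = seed))
}

# closed-form sphere distance distribution, free scale
sphere_pr_theory <- function(r, R) {
  x <- r / (2 * R)
  ifelse(x <= 1, r^2 * (1 - 1.5 * x + 0.5 * x^3), 0)
}

# exact longest-run tail probabilities by exhaustive enumeration over all
# 2^n sign strings, vectorized over the strings with bit operations
brute_longest_run_tail <- function(n) {
  s <- 0:(2^n - 1)
  mask <- 2^n - 1
  run_ge <- function(x, k) {
    # TRUE where x (as an n-bit string) contains a run of >= k ones
    y <- x
    if (k > 1) for (i in seq_len(k - 1)) y <- bitwAnd(y, bitwShiftR(y, 1))
    y > 0
  }
  longest <- integer(length(s))
  ones <- s
  zeros <- bitwAnd(bitwNot(s), mask)
  for (k in seq_len(n)) {
    hit <- run_ge(ones, k) | run_ge(zeros, k)
    longest[hit] <- k
  }
  vapply(seq_len(n), function(L) mean(longest >= L), numeric(1))
}
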