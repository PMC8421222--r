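# Independent closed-form oracle for the per-position edited-base frequency
# of a simulated standards run.  Derived directly from the generative model:
# class c has yield y_c = e_p + (1 - e_p) a_p (1 when matched), sampling
# weight abund_c * y_c, and shows the variant with probability e_p / y_c.
# The marginal edited fraction at position p is therefore
#   sum_{c: var at p} abund_c e_p / sum_c abund_c y_c.
# Kept independent of the package's internals on purpose.
oracle_edit_freq <- function(variant_pos, abundance, e_by_pos, a_by_pos, p) {
  eff <- function(q) if (q >= 1 && q <= length(e_by_pos)) e_by_pos[q] else 0
  pen <- function(q) if (q >= 1 && q <= length(a_by_pos)) a_by_pos[q] else 1
  y <- vapply(variant_pos, function(q) {
    if (q == 0) 1 else eff(q) + (1 - eff(q)) * pen(q)
  }, numeric(1))
  num <- sum(abundance[variant_pos == p]) * eff(p)
  num / sum(abundance * y)
}

# Hamming distance between two equal-length strings, brute force.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# 3-SE binomial tolerance for an observed proportion at sample size n.
binom_tol <- function(p, n, k = 3) k * sqrt(p * (1 - p) / n) + 1e-12

# Shared small fixtures -----------------------------------------------------

test_template <- function(seed = 101) synthetic_template(seed = seed)

test_constructs <- function(window = 10, seed = 1) {
  build_construct_set(test_template(), window = window, seed = seed)
}

# Simulate, merge and profile in one step; error-free fast path by default.
profile_run <- function(constructs, editing, penalty = penalty_profile(),
                        n_reads = 50000, seed = 11, error_rate = 0) {
  run <- simulate_standards_run(
    constructs, editing = editing, penalty = penalty,
    cfg = sim_config(n_reads = n_reads, error_rate = error_rate, seed = seed)
  )
  merged <- merge_pairs(run$reads1, run$reads2)
  profile_primer_region(merged, attr(constructs, "scheme")$fwd_locus)
}

inject_errors <- function(seq, n_err) {
  if (n_err == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_err)
  for (i in pos) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}
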