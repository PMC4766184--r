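# Shared fixtures: the illustrative phenotype-fitness pair used throughout
# (anoxia phenotype: 2.63-fold gain in anoxia, 0.335 relative fitness in
# normoxia) and a brute-force enumerator of balanced binary sequences.

pf_illustrative <- function() phenotype_fitness_from_w(2.63, 0.335)

# all balanced sequences of length n (n/2 of each label), as a character
# matrix with one sequence per row
enumerate_balanced <- function(n) {
  stopifnot(n %% 2 == 0)
  pos <- utils::combn(n, n / 2)
  t(apply(pos, 2, function(a_at) {
    x <- rep("N", n)
    x[a_at] <- "A"
    x
  }))
}

count_equal_pairs <- function(x, lag = 1) {
  n <- length(x)
  sum(x[seq_len(n - lag)] == x[seq_len(n - lag) + lag])
}

# random transition-frequency matrix (entries positive, sum 1)
random_transition_freqs <- function() {
  p <- matrix(stats::rexp(4) + 0.01, 2, 2)
  transition_freqs(p / sum(p))
}
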