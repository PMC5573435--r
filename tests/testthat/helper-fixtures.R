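# Shared fixtures, built in code at test time and cached per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# brute-force k-mer tally: dictionary of substrings, the independent oracle
brute_kmer_counts <- function(sequence, k) {
  l <- nchar(sequence)
  if (l < k) return(table(character(0)))
  words <- substring(sequence, seq_len(l - k + 1), seq_len(l - k + 1) + k - 1)
  words <- words[!grepl("[^ACGT]", words)]
  table(words)
}

# small, well-separated 3-species dataset used across module tests
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    make_dataset(synthetic_spec(
      n_species = 3, genomes_per_species = 2,
      validation_genomes_per_species = 1, genome_length = 8000,
      divergence = 0.02, seed = 101
    ))
  })
}

tiny_ensemble <- function() {
  fixture("tiny_ensemble", function() {
    train_ensemble(tiny_dataset()$reference_fragments, kset = c(4, 5, 6),
                   omega = 32)
  })
}

# BFGS on the primal objective: independent reference minimizer for the
# L2-loss SVM (the objective is differentiable, so optim is a valid oracle)
svm_oracle_objective <- function(X, y, omega) {
  X <- as.matrix(X)
  f <- function(w) 0.5 * sum(w^2) +
    omega * sum(pmax(1 - as.numeric(X %*% w) * y, 0)^2)
  g <- function(w) {
    m <- 1 - as.numeric(X %*% w) * y
    act <- m > 0
    w - 2 * omega * as.numeric(t(X[act, , drop = FALSE]) %*% (m[act] * y[act]))
  }
  o <- stats::optim(rep(0, ncol(X)), f, g, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-14))
  o$value
}
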