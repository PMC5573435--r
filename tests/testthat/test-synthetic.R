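# synthetic genome collections: Markov models, shredding, errors

test_that("species models are valid row-stochastic matrices", {
  m0 <- sample_species_model(2, order = 0, seed = 1)
  expect_identical(dim(m0[[1]]), c(1L, 4L))
  expect_equal(rowSums(m0[[1]]), 1)
  m3 <- sample_species_model(3, order = 3, seed = 1)
  for (m in m3) {
    expect_identical(dim(m), c(64L, 4L))
    expect_equal(unname(rowSums(m)), rep(1, 64), tolerance = 1e-12)
  }
  # same seed -> identical models; different species are distinct
  again <- sample_species_model(3, order = 3, seed = 1)
  expect_identical(m3, again)
  expect_false(identical(m3[[1]], m3[[2]]))
  # infinite concentration -> uniform composition
  mu <- sample_species_model(2, order = 1, concentration = Inf, seed = 1)
  expect_true(all(mu[[1]] == 0.25))
})

test_that("a degenerate all-A chain generates a run of A", {
  m <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_identical(generate_genome(m, 10, seed = 1), "AAAAAAAAAA")
})

test_that("generation is reproducible and alphabet-clean", {
  m <- sample_species_model(1, order = 2, seed = 3)[[1]]
  g1 <- generate_genome(m, 5000, seed = 42)
  g2 <- generate_genome(m, 5000, seed = 42)
  expect_identical(g1, g2)
  expect_false(grepl("[^ACGT]", g1))
  expect_identical(nchar(g1), 5000L)
})

test_that("long-run 2-mer frequencies converge to the chain's law", {
  # order-1 chain: stationary distribution is computable exactly
  set.seed(8)
  m <- sample_species_model(1, order = 1, seed = 8)[[1]]
  g <- generate_genome(m, 1e5, seed = 9)
  ev <- eigen(t(m))
  pi <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi <- pi / sum(pi)
  dimer <- count_kmers(g, 2)
  obs <- numeric(16)
  obs[dimer$index + 1] <- dimer$count
  n <- sum(obs)
  # P(ab) = pi_a * P(b|a); profile index (a,b) = 4a + b (row-major flatten)
  expected_ab <- as.numeric(t(pi * m))
  sigma <- sqrt(n * expected_ab * (1 - expected_ab))
  # 4 sigma per cell: simultaneous bound over the 16 dimer cells
  expect_true(all(abs(obs - n * expected_ab) <= 4 * sigma + 1))
})

test_that("shredding is non-overlapping with the tail dropped", {
  g <- random_seq(1000)
  fr <- shred_genome(g, 400, id = "g")
  expect_identical(nrow(fr), 2L)
  expect_identical(fr$id, c("g_0", "g_400"))
  expect_identical(fr$sequence, c(substr(g, 1, 400), substr(g, 401, 800)))
  expect_identical(nrow(shred_genome(random_seq(400), 400)), 1L)
  fr25 <- shred_genome(random_seq(10000), 400)
  expect_identical(nrow(fr25), 25L)
  expect_true(all(nchar(fr25$sequence) == 400))
  # fragments below the 75 bp floor are never emitted
  expect_identical(nrow(shred_genome(random_seq(1000), 50)), 0L)
})

test_that("substitution errors hit at the requested rate", {
  s <- random_seq(1000)
  expect_identical(mutate_sequences(s, 0), s)
  full <- mutate_sequences(s, 1, seed = 2)
  expect_true(all(strsplit(full, "")[[1]] != strsplit(s, "")[[1]]))
  # 1e5 bases at 2%: observed fraction within 3 binomial sigmas
  long <- strrep("ACGT", 25000)
  mut <- mutate_sequences(long, 0.02, seed = 5)
  d <- sum(strsplit(mut, "")[[1]] != strsplit(long, "")[[1]])
  sigma <- sqrt(1e5 * 0.02 * 0.98)
  expect_lt(abs(d - 2000), 3 * sigma)
  expect_identical(nchar(mut), nchar(long))
})

test_that("datasets are pure functions of their spec", {
  spec <- synthetic_spec(n_species = 2, genomes_per_species = 1,
                         validation_genomes_per_species = 1,
                         genome_length = 2000, seed = 77)
  d1 <- make_dataset(spec)
  d2 <- make_dataset(spec)
  expect_identical(d1$reference_fragments, d2$reference_fragments)
  expect_identical(d1$validation_fragments, d2$validation_fragments)
})

test_that("validation genomes share species but not sequences with reference", {
  ds <- tiny_dataset()
  expect_identical(sort(unique(ds$validation_fragments$label)),
                   sort(unique(ds$reference_fragments$label)))
  expect_false(any(ds$validation_genomes$sequence %in%
                     ds$reference_genomes$sequence))
  # every species label appears in both manifests
  spec8 <- synthetic_spec(n_species = 8, genomes_per_species = 1,
                          validation_genomes_per_species = 1,
                          genome_length = 1200, seed = 3)
  d8 <- make_dataset(spec8)
  expect_identical(dplyr::n_distinct(d8$reference_fragments$label), 8L)
  expect_identical(dplyr::n_distinct(d8$validation_fragments$label), 8L)
})

test_that("zero validation genomes give an empty but valid validation set", {
  ds <- make_dataset(synthetic_spec(n_species = 2, genomes_per_species = 1,
                                    validation_genomes_per_species = 0,
                                    genome_length = 1000, seed = 4))
  expect_identical(nrow(ds$validation_fragments), 0L)
  expect_gt(nrow(ds$reference_fragments), 0L)
})

test_that("spec validation catches impossible parameters", {
  expect_error(synthetic_spec(n_species = 1), "n_species")
  expect_error(synthetic_spec(genome_length = 100, fragment_length = 400),
               "genome_length")
  expect_error(synthetic_spec(error_rate = 1.5), "error_rate")
})
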