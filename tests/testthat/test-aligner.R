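# seed index, best-hit local alignment, fallback policy, tabular adapter

make_ref <- function(n = 2, len = 1200, seed = 5) {
  set.seed(seed)
  as_fragments(tibble::tibble(
    id = sprintf("g%s", LETTERS[seq_len(n)]),
    sequence = vapply(seq_len(n), function(i) random_seq(len), ""),
    label = sprintf("sp%s", LETTERS[seq_len(n)])
  ))
}

test_that("the index stores every word posting (brute-force check)", {
  set.seed(31)
  ref <- as_fragments(tibble::tibble(id = "r", sequence = random_seq(60),
                                     label = "s"))
  idx <- build_reference_index(ref, word_size = 11)
  l <- nchar(ref$sequence)
  words <- substring(ref$sequence, 1:(l - 10), 11:l)
  # brute-force oracle: each queried word must return exactly the offsets
  # where a naive scan finds it
  for (w in unique(words)) {
    post <- index_lookup(idx, encode_kmer(w))
    expect_identical(sort(post$pos), which(words == w))
    expect_true(all(post$subject == 1L))
  }
  # an absent word returns no postings
  absent <- setdiff(c("AAAAAAAAAAA", "ACACACACACA", "GGGGGGGGGGG"), words)[1]
  expect_identical(nrow(index_lookup(idx, encode_kmer(absent))), 0L)
})

test_that("reference sequences must be labelled and non-empty", {
  expect_error(build_reference_index(tibble::tibble(id = character(0),
                                                    sequence = character(0))),
               "empty")
  expect_error(
    build_reference_index(tibble::tibble(id = "x", sequence = "ACGTACGTACGT")),
    "x")
})

test_that("an exact substring query returns a maximal hit to its source", {
  ref <- make_ref()
  idx <- build_reference_index(ref)
  q <- substr(ref$sequence[1], 301, 500)
  h <- best_hit(q, idx)
  expect_identical(h$subject_id, "gA")
  expect_identical(h$subject_species, "spA")
  expect_equal(h$percent_identity, 100)
  expect_identical(h$alignment_length, 200L)
  expect_lte(h$e_value, fallback_policy()$e_value_cutoff)
  # raw score 2 * 200 under +2/-3: bit score from the Karlin-Altschul map
  expect_equal(h$bit_score, (0.625 * 400 - log(0.41)) / log(2), tolerance = 1e-9)
  # strict policy still accepts it (identity 100 >= 97.5)
  hs <- best_hit(q, idx, fallback_policy("strict"))
  expect_identical(hs$subject_id, "gA")
})

test_that("both reference strands are reachable", {
  ref <- make_ref()
  idx <- build_reference_index(ref)
  q <- revcomp(substr(ref$sequence[2], 101, 280))
  h <- best_hit(q, idx)
  expect_identical(h$subject_id, "gB")
  expect_identical(h$strand, "-")
  expect_equal(h$percent_identity, 100)
})

test_that("queries sharing no seed word yield no hit (absence is a value)", {
  ref <- make_ref()
  idx <- build_reference_index(ref)
  set.seed(77)
  rq <- random_seq(60) # random 60-mer: no shared 11-word with 2.4 kb reference
  expect_null(best_hit(rq, idx))
  # shorter than the word size: no hit either
  expect_null(best_hit("ACGTACGT", idx))
})

test_that("e-value decreases strictly as bit score increases", {
  e <- vapply(c(50, 100, 200, 400), function(s) {
    alignment_evalue(s, 200, 1e6)$e_value
  }, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("policy thresholds gate hits", {
  ref <- make_ref()
  idx <- build_reference_index(ref)
  q <- mutate_sequences(substr(ref$sequence[1], 301, 500), 0.05, seed = 3)
  h <- best_hit(q, idx)
  expect_identical(h$subject_id, "gA")
  expect_lt(h$percent_identity, 97.5)
  # the strict identity floor rejects the same alignment
  expect_null(best_hit(q, idx, fallback_policy("strict")))
  # an absurdly small e-value cutoff rejects everything
  expect_null(best_hit(q, idx, fallback_policy(e_value_cutoff = 1e-300)))
})

test_that("tabular mode reproduces internal assignments on exact queries", {
  ref <- make_ref()
  idx <- build_reference_index(ref)
  queries <- as_fragments(tibble::tibble(
    id = c("q1", "q2"),
    sequence = c(substr(ref$sequence[1], 1, 200),
                 substr(ref$sequence[2], 501, 700))
  ))
  internal <- align_best_hits(queries, idx)
  # write the internal hits in the standard 12-column layout and re-read
  tab <- tibble::tibble(
    qseqid = internal$id, sseqid = internal$subject_id,
    pident = internal$percent_identity, length = internal$alignment_length,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 200L,
    sstart = 1L, send = 200L,
    evalue = internal$e_value, bitscore = internal$bit_score
  )
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path, col_names = FALSE)
  ext <- best_hits_tabular(read_alignment_tab(path),
                           setNames(ref$label, ref$id))
  expect_identical(setNames(ext$subject_species, ext$id),
                   setNames(internal$subject_species, internal$id))
})

test_that("tabular best hits follow the e-value/bitscore/subject tie rules", {
  hits <- tibble::tibble(
    qseqid = "q", sseqid = c("s2", "s1", "s3"),
    pident = c(99, 99, 90), length = 100L, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = c(1e-10, 1e-10, 1e-20), bitscore = c(120, 120, 80)
  )
  lab <- c(s1 = "A", s2 = "B", s3 = "C")
  # lowest e-value wins outright
  expect_identical(best_hits_tabular(hits, lab)$subject_id, "s3")
  # equal e-value and bitscore: lowest subject id
  expect_identical(best_hits_tabular(hits[1:2, ], lab)$subject_id, "s1")
})

test_that("blastn agrees with the internal aligner on exact-substring queries", {
  ref <- make_ref(n = 3, len = 2000, seed = 9)
  idx <- build_reference_index(ref)
  set.seed(10)
  starts <- sample(1500, 6)
  queries <- as_fragments(tibble::tibble(
    id = sprintf("q%d", 1:6),
    sequence = substr(rep(ref$sequence, 2)[1:6], starts, starts + 249)
  ))
  dir <- tempfile(); dir.create(dir)
  write_fragments_fasta(ref, file.path(dir, "ref.fasta"))
  write_fragments_fasta(queries, file.path(dir, "q.fasta"))
  ok <- system2("makeblastdb",
                c("-in", file.path(dir, "ref.fasta"), "-dbtype", "nucl"),
                stdout = FALSE, stderr = FALSE)
  expect_identical(ok, 0L)
  out <- file.path(dir, "hits.tsv")
  system2("blastn", c("-query", file.path(dir, "q.fasta"),
                      "-db", file.path(dir, "ref.fasta"),
                      "-outfmt", "6", "-out", out),
          stdout = FALSE, stderr = FALSE)
  ext <- best_hits_tabular(read_alignment_tab(out), setNames(ref$label, ref$id))
  internal <- align_best_hits(queries, idx)
  shared <- intersect(ext$id, internal$id)
  expect_identical(setNames(ext$subject_species, ext$id)[shared],
                   setNames(internal$subject_species, internal$id)[shared])
})
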