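# Synthetic genome collections: species-distinct Markov composition,
# within-species divergence, non-overlapping shredding, substitution
# errors. Stands in for a real multi-species reference/validation
# download; the whole dataset is a pure function of the spec (seed
# included).

#' Specification of a synthetic dataset
#'
#' Defines a multi-species genome collection. Each species gets its own
#' order-`markov_order` Markov composition model (rows drawn from a
#' symmetric Dirichlet with the given `concentration`; smaller
#' concentration = more species-distinct composition, `Inf` = uniform
#' composition, indistinguishable species). Per species, an ancestor
#' genome is sampled from the model and every reference and validation
#' genome is an independent copy of that ancestor with `divergence`
#' substitutions applied, so validation genomes are never present in the
#' reference set but originate from the same species. Genomes are shred
#' into non-overlapping `fragment_length` windows; `error_rate`
#' substitutions are applied to validation fragments only (sequencing
#' error simulation).
#'
#' @param n_species Number of species (>= 2).
#' @param genomes_per_species Reference genomes per species.
#' @param validation_genomes_per_species Validation genomes per species.
#' @param genome_length Genome length in bp.
#' @param markov_order Order of the per-species Markov composition model.
#' @param concentration Dirichlet concentration of the model rows.
#' @param divergence Per-base substitution rate between a species
#'   ancestor and each of its genomes (within-species divergence).
#' @param fragment_length Shredding window (bp), default 400.
#' @param error_rate Per-base substitution rate applied to validation
#'   fragments, default 0 (use 0.02 for the error-robustness study).
#' @param seed Integer seed; the dataset is reproducible from the spec.
#' @return A `synthetic_spec` list.
#' @examples
#' synthetic_spec(n_species = 3, genome_length = 10000, seed = 1)
#' @export
synthetic_spec <- function(n_species = 5, genomes_per_species = 10,
                           validation_genomes_per_species = 2,
                           genome_length = 50000, markov_order = 3,
                           concentration = 1, divergence = 0.02,
                           fragment_length = 400, error_rate = 0,
                           seed = 1) {
  spec <- list(
    n_species = as.integer(n_species),
    genomes_per_species = as.integer(genomes_per_species),
    validation_genomes_per_species = as.integer(validation_genomes_per_species),
    genome_length = as.integer(genome_length),
    markov_order = as.integer(markov_order),
    concentration = concentration,
    divergence = divergence,
    fragment_length = as.integer(fragment_length),
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  if (spec$n_species < 2) abort("`n_species` must be >= 2.")
  if (spec$genome_length < spec$fragment_length || spec$fragment_length < 1) {
    abort("Need `genome_length` >= `fragment_length` >= 1.")
  }
  for (r in c("divergence", "error_rate")) {
    if (spec[[r]] < 0 || spec[[r]] > 1) abort(sprintf("`%s` must be in [0, 1].", r))
  }
  structure(spec, class = "synthetic_spec")
}

#' Sample per-species Markov composition models
#'
#' Each species model is a 4^order x 4 row-stochastic transition matrix
#' with rows drawn from a symmetric Dirichlet(concentration); with
#' `concentration = Inf` every row is uniform (1/4), removing all
#' compositional signal between species.
#'
#' @param n_species Number of species.
#' @param order Markov order (>= 0; order 0 is a single base-frequency
#'   row).
#' @param concentration Dirichlet concentration (default 1).
#' @param seed Integer seed.
#' @return A list of `n_species` transition matrices (named
#'   `species_01`, ...), each with rows summing to 1.
#' @export
sample_species_model <- function(n_species, order = 3, concentration = 1,
                                 seed = 1) {
  if (order < 0) abort("`order` must be >= 0.")
  set.seed(seed)
  nrow <- 4^order
  models <- lapply(seq_len(n_species), function(i) {
    if (is.infinite(concentration)) {
      m <- matrix(0.25, nrow, 4)
    } else {
      g <- matrix(stats::rgamma(nrow * 4, shape = concentration), nrow, 4)
      m <- g / rowSums(g)
    }
    m
  })
  names(models) <- species_names(n_species)
  models
}

species_names <- function(n) sprintf("species_%02d", seq_len(n))

#' Generate a genome from a Markov composition model
#'
#' @param model A row-stochastic 4^order x 4 transition matrix.
#' @param length Genome length (>= order + 1).
#' @param seed Optional integer seed (set for reproducibility).
#' @return A single A/C/G/T sequence string.
#' @export
generate_genome <- function(model, length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  order <- round(log(nrow(model)) / log(4))
  cum <- t(apply(model, 1, cumsum))[, 1:3, drop = FALSE]
  if (nrow(model) == 1) cum <- matrix(cum, nrow = 1)
  digits_to_seq(markov_generate(cum, order, as.integer(length)))
}

#' Shred a genome into non-overlapping fragments
#'
#' Cuts consecutive windows of `fragment_length` bp from the given
#' strand; the trailing remainder shorter than the window is dropped.
#' Fragments shorter than 75 bp are never emitted (short reads below the
#' typical sequencing range are unclassifiable and excluded upstream).
#'
#' @param sequence Genome sequence (single string).
#' @param fragment_length Window size in bp (default 400).
#' @param id Genome id; fragment ids are `<id>_<offset>` with the
#'   0-based window start.
#' @param label Optional species label to attach to each fragment.
#' @return A fragment tibble.
#' @examples
#' shred_genome(strrep("ACGT", 250), 400, id = "g") # 2 fragments, tail dropped
#' @export
shred_genome <- function(sequence, fragment_length = 400, id = "genome",
                         label = NULL) {
  if (fragment_length < 1) abort("`fragment_length` must be >= 1.")
  n <- floor(nchar(sequence) / fragment_length)
  if (n < 1 || fragment_length < 75) {
    out <- tibble(id = character(0), sequence = character(0))
    if (!is.null(label)) out$label <- character(0)
    return(out)
  }
  starts <- (seq_len(n) - 1L) * fragment_length
  out <- tibble(
    id = sprintf("%s_%d", id, starts),
    sequence = substring(sequence, starts + 1L, starts + fragment_length)
  )
  if (!is.null(label)) out$label <- label
  out
}

#' Apply random substitutions to sequences
#'
#' Each base is independently substituted with probability `error_rate`,
#' uniformly over the three alternative bases; length is preserved and
#' the result is deterministic given the RNG state (set `seed`).
#'
#' @param x Character vector of A/C/G/T sequences.
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Character vector of mutated sequences.
#' @export
mutate_sequences <- function(x, error_rate, seed = NULL) {
  if (error_rate < 0 || error_rate > 1) abort("`error_rate` must be in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  if (error_rate == 0) return(x)
  vapply(x, function(s) {
    d <- seq_to_digits(s)
    hit <- which(runif(length(d)) < error_rate & !is.na(d))
    if (length(hit)) {
      # shift by 1..3 mod 4: always lands on a different base
      d[hit] <- (d[hit] + sample.int(3, length(hit), replace = TRUE)) %% 4L
    }
    digits_to_seq(d)
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a full reference/validation dataset
#'
#' Runs the whole simulator for a [synthetic_spec()]: species models,
#' ancestor genomes, diverged reference and validation genomes, shredded
#' fragments, and validation-only sequencing errors. The result is a
#' pure function of the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A `fragment_dataset` list: `reference_genomes`,
#'   `validation_genomes` (fragment tibbles of whole genomes),
#'   `reference_fragments`, `validation_fragments` (shredded, labelled),
#'   and `spec`.
#' @examples
#' ds <- make_dataset(synthetic_spec(n_species = 2, genome_length = 2000,
#'                                   genomes_per_species = 1, seed = 7))
#' dplyr::count(ds$reference_fragments, label)
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  models <- sample_species_model(spec$n_species, spec$markov_order,
                                 spec$concentration, seed = spec$seed)
  set.seed(spec$seed + 1L)
  ref_genomes <- list()
  val_genomes <- list()
  for (sp in names(models)) {
    ancestor <- generate_genome(models[[sp]], spec$genome_length)
    for (g in seq_len(spec$genomes_per_species)) {
      ref_genomes[[length(ref_genomes) + 1L]] <- tibble(
        id = sprintf("%s_ref%02d", sp, g),
        sequence = mutate_sequences(ancestor, spec$divergence),
        label = sp
      )
    }
    for (g in seq_len(spec$validation_genomes_per_species)) {
      val_genomes[[length(val_genomes) + 1L]] <- tibble(
        id = sprintf("%s_val%02d", sp, g),
        sequence = mutate_sequences(ancestor, spec$divergence),
        label = sp
      )
    }
  }
  ref_genomes <- dplyr::bind_rows(ref_genomes)
  val_genomes <- dplyr::bind_rows(val_genomes)
  shred_all <- function(genomes) {
    if (!nrow(genomes)) {
      return(tibble(id = character(0), sequence = character(0),
                    label = character(0)))
    }
    dplyr::bind_rows(purrr::pmap(genomes, function(id, sequence, label) {
      shred_genome(sequence, spec$fragment_length, id = id, label = label)
    }))
  }
  ref_frags <- shred_all(ref_genomes)
  val_frags <- shred_all(val_genomes)
  if (spec$error_rate > 0 && nrow(val_frags)) {
    val_frags$sequence <- mutate_sequences(val_frags$sequence, spec$error_rate)
  }
  structure(
    list(reference_genomes = ref_genomes, validation_genomes = val_genomes,
         reference_fragments = ref_frags, validation_fragments = val_frags,
         spec = spec),
    class = "fragment_dataset"
  )
}

#' @export
print.fragment_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic dataset: %d species | reference %d genomes / %d fragments | validation %d genomes / %d fragments\n",
    x$spec$n_species, nrow(x$reference_genomes), nrow(x$reference_fragments),
    nrow(x$validation_genomes), nrow(x$validation_fragments)))
  invisible(x)
}

#' Write a dataset to disk (FASTA + label TSV + manifest)
#'
#' Emits `reference.fasta`, `reference_labels.tsv`, `validation.fasta`,
#' `validation_labels.tsv` (shredded fragments with ground truth) plus
#' `reference_genomes.fasta`/`reference_genome_labels.tsv` and a JSON
#' manifest of the generating spec.
#'
#' @param dataset A `fragment_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_fragments_fasta(dataset$reference_genomes, p("reference_genomes.fasta"),
                        labels = p("reference_genome_labels.tsv"))
  write_fragments_fasta(dataset$reference_fragments, p("reference.fasta"),
                        labels = p("reference_labels.tsv"))
  write_fragments_fasta(dataset$validation_fragments, p("validation.fasta"),
                        labels = p("validation_labels.tsv"))
  jsonlite::write_json(unclass(dataset$spec), p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
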