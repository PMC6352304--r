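# Seeded synthetic genomes. The descriptors are composition and
# dinucleotide statistics plus the skew curve's growth angle, so the
# simulator controls exactly those levers: per-species base composition
# (i.i.d. or first-order Markov) and a two-replichore G/C strand skew that
# gives the cumulated phase its characteristic arrow shape. Strains within
# a species are derived from one ancestor by random substitutions,
# optionally followed by a random rotation of the circular record.

.base_codes <- utf8ToInt("ACGT")

# Evaluate `code` with the RNG seeded at `seed` (NULL = use current RNG
# state), restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.check_composition <- function(composition) {
  stopifnot(is.numeric(composition), length(composition) == 4L)
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-8)
    stop("composition must be 4 non-negative probabilities (A, C, G, T) ",
         "summing to 1", call. = FALSE)
  unname(composition)
}

.codes_to_genome <- function(codes, id, circular = TRUE) {
  structure(list(id = as.character(id),
                 seq = intToUtf8(.base_codes[codes]),
                 circular = circular),
            class = "wgp_genome")
}

#' Random i.i.d. genome
#'
#' Draws `length` residues independently from a base composition
#' (probabilities of A, C, G, T in that order).
#'
#' @param length Number of residues.
#' @param composition Numeric vector of 4 probabilities (A, C, G, T).
#' @param id Genome identifier.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A `wgp_genome`.
#' @examples
#' random_genome(100, c(0.3, 0.2, 0.2, 0.3), seed = 1)
#' @export
random_genome <- function(length, composition = rep(0.25, 4),
                          id = "genome", seed = NULL) {
  stopifnot(length >= 1)
  composition <- .check_composition(composition)
  with_seed(seed, {
    codes <- sample.int(4L, size = length, replace = TRUE,
                        prob = composition)
    .codes_to_genome(codes, id)
  })
}

#' Random first-order Markov genome
#'
#' Generates a sequence from a 4x4 transition matrix (rows and columns in
#' A, C, G, T order; rows sum to 1), which lets dinucleotide fractions be
#' controlled independently of the marginal base composition.
#'
#' @param length Number of residues.
#' @param transition 4x4 row-stochastic matrix.
#' @param init Initial-state probabilities; default uniform.
#' @inheritParams random_genome
#' @return A `wgp_genome`.
#' @export
markov_genome <- function(length, transition, init = rep(0.25, 4),
                          id = "genome", seed = NULL) {
  stopifnot(length >= 1, is.matrix(transition),
            all(dim(transition) == c(4L, 4L)), all(transition >= 0),
            all(abs(rowSums(transition) - 1) < 1e-8))
  init <- .check_composition(init)
  with_seed(seed, {
    cum <- t(apply(transition, 1L, cumsum))
    u <- runif(length)
    codes <- integer(length)
    codes[1L] <- sample.int(4L, 1L, prob = init)
    for (k in seq_len(length - 1L))
      codes[k + 1L] <- findInterval(u[k + 1L], cum[codes[k], ]) + 1L
    .codes_to_genome(codes, id)
  })
}

#' Two-replichore GC-skew genome
#'
#' Emulates the strand skew of bacterial chromosomes. The first half of the
#' record (the leading replichore, read from the replication origin) is
#' enriched in G over C by `gc_skew` and in T over A by `at_skew`; the
#' second half mirrors both biases, so the whole chromosome keeps strand
#' parity (A ~ T and G ~ C globally) while each replichore is skewed, as in
#' real bacterial chromosomes. The cumulated phase of such a genome rises
#' from the origin to a global maximum near the terminus and falls back --
#' the arrow shape that gives the origin-anchoring rearrangement a
#' well-defined maximum and minimum and makes the average growth angle
#' meaningful. The expected rise per position is
#' `pi/4 * (6 * gc_skew - 2 * at_skew)`, which must be positive for the
#' arrow to point upwards.
#'
#' The lagging replichore is built as a shuffled complement of the leading
#' one, so the residue counts of the two halves pair off exactly and the
#' cumulated phase closes at 0 (for odd `length`, the unpaired middle
#' residue is drawn from A/G so the closing value stays non-negative).
#' Real closed chromosomes behave the same way -- strand parity holds
#' genome-wide while each replichore is skewed -- and an exactly closing
#' walk is what makes the origin anchor a property of the circular genome
#' rather than of the record start.
#'
#' @param length Number of residues (>= 2).
#' @param gc Overall G+C fraction.
#' @param gc_skew Excess of G over C within the leading replichore
#'   (`|gc_skew| <= gc/2`).
#' @param at_skew Excess of T over A within the leading replichore
#'   (`|at_skew| <= (1 - gc)/2`).
#' @inheritParams random_genome
#' @return A `wgp_genome` whose record starts at the emulated origin.
#' @export
gc_skew_genome <- function(length, gc = 0.5, gc_skew = 0.05, at_skew = 0,
                           id = "genome", seed = NULL) {
  stopifnot(length >= 2, gc > 0, gc < 1,
            abs(gc_skew) <= gc / 2,
            abs(at_skew) <= (1 - gc) / 2)
  a0 <- (1 - gc) / 2
  lead <- c(a0 - at_skew, gc / 2 - gc_skew, gc / 2 + gc_skew,
            a0 + at_skew)                                    # G+T rich
  h <- length %/% 2L
  with_seed(seed, {
    lead_codes <- sample.int(4L, h, TRUE, prob = lead)
    # lagging replichore: complement (A<->T, C<->G) of the shuffled leader
    lag_codes <- 5L - sample(lead_codes)
    extra <- if (length %% 2L == 1L) sample(c(1L, 3L), 1L) else integer(0)
    .codes_to_genome(c(lead_codes, extra, lag_codes), id)
  })
}

#' Randomly substitute residues
#'
#' Each position is substituted independently with probability `rate` by a
#' base drawn uniformly from the three alternatives. Models strain-level
#' divergence within a species; length is preserved, indels are out of
#' scope.
#'
#' @param x A `wgp_genome` (A/C/G/T residues) or character sequence.
#' @param rate Substitution probability per position, in [0, 0.5).
#' @inheritParams random_genome
#' @return A `wgp_genome` with the same id unless `id` is given.
#' @export
mutate_genome <- function(x, rate, id = NULL, seed = NULL) {
  stopifnot(is.numeric(rate), rate >= 0, rate < 0.5)
  s <- as_sequence_string(x)
  codes <- match(utf8ToInt(s), .base_codes)
  if (anyNA(codes))
    stop("mutate_genome() requires A/C/G/T residues only", call. = FALSE)
  out_id <- id %||% genome_id(x)
  with_seed(seed, {
    hit <- which(runif(length(codes)) < rate)
    if (length(hit)) {
      # offset 1..3 from the current base, wrapping around the alphabet
      shift <- sample.int(3L, length(hit), replace = TRUE)
      codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
    }
    .codes_to_genome(codes, out_id)
  })
}

#' Default species profiles for the cluster simulator
#'
#' One row per species: G+C content spread over the bacterial range
#' 0.32-0.62, a replichore G/C skew growing from 0.02 to 0.08, and a
#' replichore T/A skew at half the G/C skew scaled down across species.
#' The spread keeps the species pairwise distinct in the descriptors while
#' staying within realistic bacterial composition bounds, and every
#' profile's expected cumulated-phase rise `pi/4 * (6 gc_skew - 2 at_skew)`
#' stays well above the random-walk noise so each genome has a clear arrow.
#'
#' @param n_species Number of species.
#' @return data.frame with columns `species`, `gc`, `gc_skew`, `at_skew`.
#' @export
default_species_profiles <- function(n_species = 7) {
  stopifnot(n_species >= 1)
  gc <- if (n_species == 1L) 0.47 else
    seq(0.32, 0.62, length.out = n_species)
  gc_skew <- if (n_species == 1L) 0.05 else
    seq(0.02, 0.08, length.out = n_species)
  at_skew <- 0.5 * gc_skew *
    (if (n_species == 1L) 0.5 else seq(1, 0, length.out = n_species))
  data.frame(species = sprintf("species_%02d", seq_len(n_species)),
             gc = gc, gc_skew = gc_skew, at_skew = at_skew)
}

.profile_composition <- function(profile) {
  # whole-chromosome composition; replichore skews cancel globally
  a <- (1 - profile$gc) / 2
  c(a, profile$gc / 2, profile$gc / 2, a)
}

#' Simulate species clusters of mutation-derived strains
#'
#' Generates `n_species` ancestor genomes from per-species composition/skew
#' profiles ([gc_skew_genome()]), derives `strains_per_species - 1`
#' additional strains per species by random substitution at
#' `substitution_rate`, optionally rotates every record by a random offset
#' (exercising the origin-anchoring rearrangement), and emits species
#' labels. A stand-in, at reduced scale, for a validation dataset of
#' labeled conspecific genome groups.
#'
#' @param n_species Number of species clusters.
#' @param strains_per_species Genomes per species (>= 1).
#' @param genome_length Residues per genome.
#' @param profiles data.frame as in [default_species_profiles()]; rows are
#'   recycled checked against `n_species`.
#' @param substitution_rate Per-position substitution probability for
#'   derived strains, in [0, 0.5).
#' @param rotate Logical; apply a random rotation to every genome.
#' @param min_tv Warn when two species' mean compositions are closer than
#'   this total-variation distance (delineation may then legitimately
#'   fail).
#' @param seed Optional integer seed for the whole dataset.
#' @return List with `genomes` (list of `wgp_genome`), `labels`
#'   (data.frame `genome_id`, `species`) and `profiles`.
#' @examples
#' sim <- simulate_species_clusters(n_species = 2, strains_per_species = 2,
#'                                  genome_length = 2000, seed = 7)
#' sim$labels
#' @export
simulate_species_clusters <- function(n_species = 7,
                                      strains_per_species = 5,
                                      genome_length = 200000,
                                      profiles = NULL,
                                      substitution_rate = 0.01,
                                      rotate = FALSE,
                                      min_tv = 0.02,
                                      seed = NULL) {
  stopifnot(n_species >= 1, strains_per_species >= 1, genome_length >= 2,
            substitution_rate >= 0, substitution_rate < 0.5)
  if (is.null(profiles)) profiles <- default_species_profiles(n_species)
  stopifnot(is.data.frame(profiles), nrow(profiles) == n_species,
            all(c("species", "gc", "at_skew", "gc_skew") %in%
                  names(profiles)))
  comps <- t(vapply(seq_len(n_species),
                    function(i) .profile_composition(profiles[i, ]),
                    numeric(4L)))
  if (n_species > 1L) {
    for (i in seq_len(n_species - 1L)) for (j in (i + 1L):n_species) {
      tv <- sum(abs(comps[i, ] - comps[j, ])) / 2 +
        abs(profiles$gc_skew[i] - profiles$gc_skew[j]) +
        abs(profiles$at_skew[i] - profiles$at_skew[j])
      if (tv < min_tv)
        warning("species profiles ", profiles$species[i], " and ",
                profiles$species[j], " are nearly identical ",
                "(separation ", signif(tv, 3), " < ", min_tv,
                "); delineation may legitimately fail", call. = FALSE)
    }
  }
  with_seed(seed, {
    genomes <- vector("list", n_species * strains_per_species)
    labels <- data.frame(genome_id = character(0), species = character(0))
    k <- 0L
    for (i in seq_len(n_species)) {
      pr <- profiles[i, ]
      anc <- gc_skew_genome(genome_length, gc = pr$gc,
                            at_skew = pr$at_skew, gc_skew = pr$gc_skew,
                            id = sprintf("%s_st01", pr$species))
      for (j in seq_len(strains_per_species)) {
        g <- if (j == 1L) anc else
          mutate_genome(anc, substitution_rate,
                        id = sprintf("%s_st%02d", pr$species, j))
        if (rotate)
          g <- rotate_genome(g, sample.int(genome_length, 1L) - 1L)
        k <- k + 1L
        genomes[[k]] <- g
        labels <- rbind(labels,
                        data.frame(genome_id = g$id,
                                   species = pr$species,
                                   stringsAsFactors = FALSE))
      }
    }
    list(genomes = genomes, labels = labels, profiles = profiles)
  })
}
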