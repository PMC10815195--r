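#' Specify a synthetic genome
#'
#' Bundles the parameters of one simulated genome: length, target GC
#' content (for i.i.d. generation), an optional 4x4 nucleotide transition
#' matrix (for first-order Markov generation), an optional planted
#' periodic dinucleotide, and the RNG seed. Defaults emulate the two
#' study genomes: linear dsDNA of ~165 kb / ~151 kb with GC near 35.4%
#' and 42.3%.
#'
#' @param length Genome length in bp (>= 50).
#' @param gc_target Target GC fraction in `[0, 1]`.
#' @param transition_matrix Optional 4x4 row-stochastic matrix over
#'   `A, C, G, T` (rows = current base, columns = next base).
#' @param planted_motif Optional list with elements `dinucleotide`
#'   (a 2-mer), `period` (bp, >= 2) and `offset` (1-based start, >= 1).
#' @param seed Integer RNG seed; the same spec and seed always produce
#'   the same sequence.
#' @return An object of class `genome_spec`.
#' @export
#' @examples
#' genome_spec(length = 1000, gc_target = 0.354, seed = 1)
genome_spec <- function(length, gc_target = NULL, transition_matrix = NULL,
                        planted_motif = NULL, seed = 1L) {
  if (length < 50) {
    stop_phagemech("genome length must be >= 50 bp", "phagemech_spec_error")
  }
  if (!is.null(gc_target) && (gc_target < 0 || gc_target > 1)) {
    stop_phagemech("gc_target must lie in [0, 1]", "phagemech_spec_error")
  }
  if (!is.null(transition_matrix)) {
    tm <- as.matrix(transition_matrix)
    if (!all(dim(tm) == c(4L, 4L)) || any(tm < 0) ||
        any(abs(rowSums(tm) - 1) > 1e-9)) {
      stop_phagemech("transition_matrix must be 4x4 row-stochastic",
                     "phagemech_spec_error")
    }
  }
  if (!is.null(planted_motif)) {
    stopifnot(all(c("dinucleotide", "period", "offset") %in%
                    names(planted_motif)))
    if (planted_motif$period < 2) {
      stop_phagemech("planted period must be >= 2", "phagemech_spec_error")
    }
  }
  structure(
    list(length = as.integer(length), gc_target = gc_target,
         transition_matrix = transition_matrix,
         planted_motif = planted_motif, seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' Generate an i.i.d. synthetic genome
#'
#' Draws independent bases with `P(G) = P(C) = gc_target / 2` and
#' `P(A) = P(T) = (1 - gc_target) / 2`. Deterministic for a fixed spec
#' and seed. If the spec carries a `planted_motif`, it is applied via
#' [plant_periodic_motif()] after generation.
#'
#' @param spec A [genome_spec()] with `gc_target` set.
#' @param id Identifier for the generated record.
#' @return A one-row genome tibble (see [genome_tbl()]).
#' @export
#' @examples
#' g <- generate_iid(genome_spec(1000, gc_target = 0.5, seed = 7))
#' gc_content(g)
generate_iid <- function(spec, id = "synthetic_iid") {
  if (is.null(spec$gc_target)) {
    stop_phagemech("generate_iid requires gc_target", "phagemech_spec_error")
  }
  q <- spec$gc_target
  p <- c(A = (1 - q) / 2, C = q / 2, G = q / 2, T = (1 - q) / 2)
  seqc <- withr::with_seed(spec$seed, {
    paste(sample(names(p), spec$length, replace = TRUE, prob = p),
          collapse = "")
  })
  out <- genome_tbl(id, seqc)
  maybe_plant(out, spec)
}

# Stationary distribution of a 4-state chain via the eigen decomposition
# of t(P); fails on reducible chains (non-simple unit eigenvalue).
stationary_distribution <- function(tm) {
  e <- eigen(t(tm))
  i <- which(abs(e$values - 1) < 1e-8)
  if (length(i) != 1L) {
    stop_phagemech("transition matrix has no unique stationary distribution",
                   "phagemech_reducible_chain")
  }
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Generate a first-order Markov synthetic genome
#'
#' Simulates a chain over `A, C, G, T` from the spec's transition matrix;
#' the initial base is drawn from the stationary distribution, so the
#' empirical dinucleotide frequencies converge to
#' `stationary[i] * P[i, j]`.
#'
#' @inheritParams generate_iid
#' @return A one-row genome tibble.
#' @export
generate_markov <- function(spec, id = "synthetic_markov") {
  if (is.null(spec$transition_matrix)) {
    stop_phagemech("generate_markov requires a transition_matrix",
                   "phagemech_spec_error")
  }
  tm <- as.matrix(spec$transition_matrix)
  bases <- c("A", "C", "G", "T")
  pi0 <- stationary_distribution(tm)
  L <- spec$length
  seqc <- withr::with_seed(spec$seed, {
    # inverse-CDF sampling against precomputed row CDFs keeps this O(L)
    cdf <- t(apply(tm, 1L, cumsum))
    u <- stats::runif(L)
    states <- integer(L)
    states[1L] <- findInterval(u[1L], cumsum(pi0)) + 1L
    for (i in 2:L) {
      states[i] <- findInterval(u[i], cdf[states[i - 1L], ],
                                left.open = TRUE) + 1L
    }
    paste(bases[states], collapse = "")
  })
  out <- genome_tbl(id, seqc)
  maybe_plant(out, spec)
}

maybe_plant <- function(genomes, spec) {
  if (is.null(spec$planted_motif)) return(genomes)
  m <- spec$planted_motif
  plant_periodic_motif(genomes, m$dinucleotide, m$period, m$offset)
}

#' Plant a periodic dinucleotide into a genome
#'
#' Overwrites (never inserts) the given 2-mer at positions `offset`,
#' `offset + period`, `offset + 2 * period`, ... so that the genome
#' length and window grid are preserved and the planted copies recur
#' with an exact period.
#'
#' @param genomes A genome tibble (each row is planted independently).
#' @param dinucleotide A 2-mer over `A, C, G, T`.
#' @param period Spacing between planted copies, in bp (>= 2).
#' @param offset 1-based position of the first planted copy.
#' @return The genome tibble with modified sequences.
#' @export
#' @examples
#' g <- genome_tbl("bg", strrep("C", 100))
#' planted <- plant_periodic_motif(g, "AA", period = 10, offset = 1)
#' dinucleotide_counts(planted)
plant_periodic_motif <- function(genomes, dinucleotide, period, offset = 1L) {
  if (!dinucleotide %in% DINUCLEOTIDES) {
    stop_phagemech("dinucleotide must be a 2-mer over A/C/G/T",
                   "phagemech_bad_dinucleotide")
  }
  if (period < 2) {
    stop_phagemech("period must be >= 2", "phagemech_spec_error")
  }
  genomes$sequence <- purrr::map_chr(genomes$sequence, function(s) {
    L <- nchar(s)
    if (offset + 1L > L) {
      stop_phagemech("offset + 2 exceeds genome length",
                     "phagemech_spec_error")
    }
    starts <- seq.int(offset, L - 1L, by = period)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    d <- strsplit(dinucleotide, "", fixed = TRUE)[[1]]
    ch[starts] <- d[1L]
    ch[starts + 1L] <- d[2L]
    paste(ch, collapse = "")
  })
  genomes$n_ambiguous <- genomes$length -
    stringr::str_count(genomes$sequence, "[ACGT]")
  genomes
}

#' Generate the default two-genome study pair
#'
#' Convenience wrapper producing one AT-enriched and one GC-enriched
#' i.i.d. genome emulating the study conditions: lengths 165,282 and
#' 151,205 bp with GC targets 35.37% and 42.30%. Lengths may be scaled
#' down for quick runs.
#'
#' @param seed Integer seed; the two genomes use `seed` and `seed + 1`.
#' @param scale Multiplier in `(0, 1]` applied to both lengths.
#' @return A two-row genome tibble with ids `synthA` (AT-rich) and
#'   `synthB` (GC-rich).
#' @export
synthetic_study_pair <- function(seed = 1L, scale = 1) {
  la <- max(50L, as.integer(round(165282 * scale)))
  lb <- max(50L, as.integer(round(151205 * scale)))
  bind_rows(
    generate_iid(genome_spec(la, gc_target = 0.3537, seed = seed),
                 id = "synthA"),
    generate_iid(genome_spec(lb, gc_target = 0.4230, seed = seed + 1L),
                 id = "synthB")
  )
}
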