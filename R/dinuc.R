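#' Overlapping dinucleotide counts
#'
#' Counts every adjacent base pair along each genome (so `AAA` contains
#' two `AA`); pairs containing an ambiguous base (`N`) are skipped.
#'
#' @param genomes A genome tibble (see [read_fasta()]).
#' @return A tibble with columns `genome_id`, `dinucleotide` (in the fixed
#'   order `AA`..`TT`) and `count`, 16 rows per genome.
#' @export
#' @examples
#' dinucleotide_counts(genome_tbl("g", "AAAA"))
dinucleotide_counts <- function(genomes) {
  purrr::map2(genomes$id, genomes$sequence, function(id, s) {
    if (nchar(s) < 2L) {
      stop_phagemech("genome must be at least 2 bp for dinucleotide counts",
                     "phagemech_too_short")
    }
    idx <- dinuc_indices(s)
    tibble(
      genome_id = id,
      dinucleotide = DINUCLEOTIDES,
      count = tabulate(idx, nbins = 16L)
    )
  }) |>
    bind_rows()
}

#' Dinucleotide frequencies
#'
#' Frequencies are counts divided by the genome length `L` (not by the
#' `L - 1` dinucleotide sites); with an `N`-free sequence the 16 values
#' therefore sum to `(L - 1) / L`. The per-site probability used by the
#' PDDF expectation is the separate `site_probability` column
#' (count / number of N-free sites).
#'
#' @param genomes A genome tibble.
#' @return A tibble with columns `genome_id`, `dinucleotide`, `count`,
#'   `frequency` (count / L) and `site_probability` (count / (L - 1)),
#'   carrying attribute `denominator_convention = "genome_length"`.
#' @export
#' @examples
#' dinucleotide_frequency(genome_tbl("g", "AAAA"))
dinucleotide_frequency <- function(genomes) {
  counts <- dinucleotide_counts(genomes)
  lens <- tibble(genome_id = genomes$id, .len = genomes$length)
  out <- counts |>
    left_join(lens, by = "genome_id") |>
    mutate(
      frequency = .data$count / .data$.len,
      site_probability = .data$count / (.data$.len - 1L)
    ) |>
    select(-".len")
  attr(out, "denominator_convention") <- "genome_length"
  out
}

#' 16 x 16 differential dinucleotide frequency matrix
#'
#' Crosses every dinucleotide frequency of one genome with every
#' frequency of the other, yielding 256 differential values
#' `D[i, j] = f_row[i] - f_col[j]` (default orientation). Rows are
#' labelled by the first (row) genome, columns by the second.
#'
#' @param freqs A frequency tibble from [dinucleotide_frequency()]
#'   containing both genomes.
#' @param row_genome,col_genome Identifiers of the row and column genome.
#' @param orientation `"row_minus_col"` (default; an AT-enriched row
#'   genome gives positive rows for AT-class dinucleotides) or
#'   `"col_minus_row"`.
#' @return A tibble of 256 rows with columns `row_dinucleotide`,
#'   `col_dinucleotide` and `difference`, of class `diff_freq_matrix`.
#'   Use [diff_matrix_wide()] for the 16 x 16 layout.
#' @export
differential_frequency_matrix <- function(freqs, row_genome, col_genome,
                                          orientation = c("row_minus_col",
                                                          "col_minus_row")) {
  orientation <- match.arg(orientation)
  f <- function(g) {
    x <- freqs |> filter(.data$genome_id == g)
    if (nrow(x) != 16L) {
      stop_phagemech(paste0("genome ", g, " lacks a complete 16-entry ",
                            "frequency vector"), "phagemech_bad_frequency")
    }
    x$frequency[match(DINUCLEOTIDES, x$dinucleotide)]
  }
  fr <- f(row_genome)
  fc <- f(col_genome)
  grid <- tidyr::expand_grid(
    row_dinucleotide = DINUCLEOTIDES,
    col_dinucleotide = DINUCLEOTIDES
  )
  d <- fr[match(grid$row_dinucleotide, DINUCLEOTIDES)] -
    fc[match(grid$col_dinucleotide, DINUCLEOTIDES)]
  if (orientation == "col_minus_row") d <- -d
  out <- grid |> mutate(difference = d)
  attr(out, "row_genome") <- row_genome
  attr(out, "col_genome") <- col_genome
  attr(out, "orientation") <- orientation
  class(out) <- c("diff_freq_matrix", class(out))
  out
}

#' Differential frequency matrix in 16 x 16 layout
#'
#' @param d A `diff_freq_matrix` from [differential_frequency_matrix()].
#' @return A 16 x 16 numeric matrix with dinucleotide dimnames in the
#'   fixed order `AA`..`TT`.
#' @export
diff_matrix_wide <- function(d) {
  m <- matrix(d$difference, nrow = 16L, byrow = TRUE,
              dimnames = list(DINUCLEOTIDES, DINUCLEOTIDES))
  m
}

#' Binary indicator track for one dinucleotide
#'
#' Marks each of the `L - 1` dinucleotide sites of a genome with 1 where
#' the site equals the given 2-mer and 0 elsewhere (sites overlapping an
#' `N` are 0).
#'
#' @param genome A one-row genome tibble.
#' @param dinucleotide A 2-mer over `A, C, G, T`.
#' @return A tibble with columns `site` (1-based start of the pair) and
#'   `indicator` (0/1).
#' @export
#' @examples
#' indicator_track(genome_tbl("g", "ACAC"), "CA")
indicator_track <- function(genome, dinucleotide) {
  stopifnot(nrow(genome) == 1L)
  tibble(
    site = seq_len(genome$length - 1L),
    indicator = indicator_vector(genome$sequence, dinucleotide)
  )
}

indicator_vector <- function(sequence, dinucleotide) {
  target <- match(dinucleotide, DINUCLEOTIDES)
  if (is.na(target)) {
    stop_phagemech("dinucleotide must be a 2-mer over A/C/G/T",
                   "phagemech_bad_dinucleotide")
  }
  idx <- dinuc_indices(sequence)
  as.integer(!is.na(idx) & idx == target)
}

#' Pairwise distance distribution function (PDDF)
#'
#' For each dinucleotide, measures how often two occurrences sit exactly
#' `s` sites apart, for lags `s = 1..max_lag`, and normalizes by the
#' i.i.d. expectation. With the 0/1 indicator track `b` over the
#' `M = L - 1` sites, the observed co-occurrence frequency is
#' `O(s) = sum(b[i] * b[i + s]) / (M - s)` and the expectation under
#' randomness is `p^2` with `p = count / M`, so the reported ratio is
#' `O(s) / p^2` (1 = random; the ratio is `NA` when `p = 0`). Note that
#' at `s = 1` co-occurrence is structurally impossible for `XY` with
#' `X != Y` and inflated for `XX`; the ratio is reported as computed.
#'
#' @param genomes A genome tibble.
#' @param dinucs Character vector of 2-mers (default all 16).
#' @param max_lag Largest lag in bp (default 100); must satisfy
#'   `max_lag < L - 2`.
#' @return A tibble of class `pddf_profile` with columns `genome_id`,
#'   `dinucleotide`, `lag`, `observed`, `expected`, `ratio` and
#'   `site_probability`.
#' @export
#' @examples
#' g <- genome_tbl("g", strrep("A", 200))
#' pddf(g, "AA", max_lag = 10)
pddf <- function(genomes, dinucs = dinucleotides(), max_lag = 100L) {
  max_lag <- as.integer(max_lag)
  purrr::map2(genomes$id, genomes$sequence, function(id, s) {
    L <- nchar(s)
    if (max_lag >= L - 2L) {
      stop_phagemech("max_lag must be < L - 2", "phagemech_bad_lag")
    }
    idx <- dinuc_indices(s)
    M <- length(idx)
    purrr::map(dinucs, function(d) {
      target <- match(d, DINUCLEOTIDES)
      if (is.na(target)) {
        stop_phagemech("dinucleotide must be a 2-mer over A/C/G/T",
                       "phagemech_bad_dinucleotide")
      }
      b <- as.integer(!is.na(idx) & idx == target)
      p <- sum(b) / M
      lags <- seq_len(max_lag)
      obs <- vapply(lags, function(s2) {
        sum(b[seq_len(M - s2)] * b[(1L + s2):M]) / (M - s2)
      }, numeric(1))
      tibble(
        genome_id = id, dinucleotide = d, lag = lags,
        observed = obs, expected = p^2,
        ratio = if (p > 0) obs / p^2 else NA_real_,
        site_probability = p
      )
    }) |>
      bind_rows()
  }) |>
    bind_rows() |>
    structure(class = c("pddf_profile", "tbl_df", "tbl", "data.frame"))
}

#' Spectral scan of a PDDF profile for periodicity
#'
#' Mean-detrends each ratio series over the lag window and, for every
#' integer candidate period `p` in `lag_range`, projects the series onto
#' the pulse train supported at the multiples of `p`: the comb power is
#' `(sum of the detrended ratios at lags p, 2p, ...)^2 / (number of such
#' lags)`. Unlike a plain sinusoidal periodogram, this statistic
#' concentrates the full signal of a periodically recurring dinucleotide
#' at its fundamental period (sinusoidal leakage cannot distinguish two
#' in-window harmonics of a long period from their immediate
#' neighbours), and the variance normalization makes the noise floor
#' comparable across periods. The dominant period is the comb-power
#' argmax; prominence is the ratio of the maximum comb power to the
#' median over all candidates. Series with essentially zero power (e.g.
#' constant ratios) report `dominant_period = NA` and prominence 1.
#'
#' @param profile A `pddf_profile` from [pddf()].
#' @param lag_range Two integers, the inclusive lag window (default
#'   `c(2, 100)`; lag 1 is excluded by default because of its structural
#'   self-overlap bias).
#' @param prominence_threshold Minimum prominence for the `periodic`
#'   flag (default 3).
#' @return A tibble with one row per (`genome_id`, `dinucleotide`):
#'   `dominant_period`, `spectral_power`, `prominence`, `periodic`.
#' @export
periodicity_scan <- function(profile, lag_range = c(2L, 100L),
                             prominence_threshold = 3) {
  stopifnot(length(lag_range) == 2L, lag_range[1] >= 1L,
            lag_range[2] > lag_range[1])
  profile |>
    filter(.data$lag >= lag_range[1], .data$lag <= lag_range[2]) |>
    group_by(.data$genome_id, .data$dinucleotide) |>
    summarise(scan_one(.data$lag, .data$ratio), .groups = "drop") |>
    mutate(periodic = !is.na(.data$dominant_period) &
             .data$prominence >= prominence_threshold)
}

scan_one <- function(lags, ratio) {
  if (anyNA(ratio)) {
    stop_phagemech("undefined PDDF ratios inside the scan window",
                   "phagemech_undefined_ratio")
  }
  x <- ratio - mean(ratio)
  periods <- seq.int(min(lags), max(lags))
  periods <- periods[periods >= 2L]
  power <- vapply(periods, function(p) {
    at <- lags %% p == 0L
    sum(x[at])^2 / sum(at)
  }, numeric(1))
  pmax_ <- max(power)
  if (pmax_ < 1e-12) {
    return(tibble(dominant_period = NA_integer_, spectral_power = 0,
                  prominence = 1))
  }
  med <- median(power)
  tibble(
    dominant_period = as.integer(periods[which.max(power)]),
    spectral_power = pmax_,
    prominence = if (med > 0) pmax_ / med else Inf
  )
}
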