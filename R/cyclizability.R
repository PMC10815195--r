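#' Number of sliding windows on a genome
#'
#' With width `w` and stride `s` on a linear genome of length `L`
#' (first window at position 1, no wraparound), the grid holds
#' `floor((L - w) / s) + 1` windows. At the defaults (50 bp windows,
#' 7 bp stride) the two study genome lengths 165,282 and 151,205 give
#' 23,605 and 21,594 windows, whose pooled ANOVA total df is 45,198.
#'
#' @param L Genome length in bp.
#' @param width Window width in bp (default 50).
#' @param stride Step between window starts in bp (default 7).
#' @return Integer number of windows.
#' @export
#' @examples
#' count_windows(165282)
count_windows <- function(L, width = 50L, stride = 7L) {
  if (any(L < width)) {
    stop_phagemech("genome shorter than the window width",
                   "phagemech_bad_grid")
  }
  stopifnot(width >= 1L, stride >= 1L)
  as.integer(floor((L - width) / stride) + 1L)
}

#' Window grid for a genome
#'
#' @param genome A one-row genome tibble, or an integer length.
#' @inheritParams count_windows
#' @return A list of class `window_grid` with elements `genome_id`,
#'   `width`, `stride`, `starts` (1-based) and `n_windows`.
#' @export
window_grid <- function(genome, width = 50L, stride = 7L) {
  if (is.numeric(genome)) {
    L <- as.integer(genome)
    id <- NA_character_
  } else {
    stopifnot(nrow(genome) == 1L)
    L <- genome$length
    id <- genome$id
  }
  n <- count_windows(L, width, stride)
  structure(
    list(genome_id = id, width = as.integer(width),
         stride = as.integer(stride),
         starts = seq.int(1L, by = as.integer(stride), length.out = n),
         n_windows = n),
    class = "window_grid"
  )
}

#' Extract window sequences
#'
#' @param genome A one-row genome tibble.
#' @param grid A [window_grid()] consistent with the genome.
#' @return A tibble with columns `window` (index), `start` (1-based),
#'   `sequence` and `has_n` (flag: window overlaps an ambiguous base).
#' @export
extract_windows <- function(genome, grid) {
  stopifnot(nrow(genome) == 1L, inherits(grid, "window_grid"))
  if (max(grid$starts) + grid$width - 1L > genome$length) {
    stop_phagemech("window grid extends past the genome end",
                   "phagemech_bad_grid")
  }
  seqs <- stringr::str_sub(
    genome$sequence, grid$starts, grid$starts + grid$width - 1L
  )
  tibble(
    window = seq_along(grid$starts),
    start = grid$starts,
    sequence = seqs,
    has_n = stringr::str_detect(seqs, "[^ACGT]")
  )
}

#' Construct a linear cyclizability model
#'
#' A cyclizability model scores a fixed-width window as
#' `intercept + sum over the width - 1 dinucleotide sites of the weight
#' of the dinucleotide at that site`. Weights are either one value per
#' dinucleotide (`weights`, length 16) or position-specific
#' (`positional_weights`, a 16 x (width - 1) matrix, rows in the fixed
#' order `AA`..`TT`), in which case the positional matrix takes
#' precedence. Scores live on the natural-log scale of the looped /
#' control population ratio that defines experimental cyclizability.
#'
#' @param name Model name.
#' @param intercept Unitless intercept.
#' @param weights Named numeric vector of 16 dinucleotide weights.
#' @param positional_weights Optional 16 x (width - 1) matrix.
#' @param width Window width the model applies to (default 50).
#' @param provenance Free-text provenance string.
#' @return An object of class `cyc_model`.
#' @export
cyc_model <- function(name, intercept, weights, positional_weights = NULL,
                      width = 50L, provenance = "user-supplied") {
  w <- weights[DINUCLEOTIDES]
  if (anyNA(w)) {
    stop_phagemech("weights must name all 16 dinucleotides",
                   "phagemech_bad_model")
  }
  if (!is.null(positional_weights)) {
    pw <- as.matrix(positional_weights)
    if (!all(dim(pw) == c(16L, width - 1L))) {
      stop_phagemech("positional_weights must be 16 x (width - 1)",
                     "phagemech_bad_model")
    }
    rownames(pw) <- DINUCLEOTIDES
    positional_weights <- pw
  }
  structure(
    list(name = name, intercept = as.numeric(intercept), weights = w,
         positional_weights = positional_weights,
         width = as.integer(width), provenance = provenance),
    class = "cyc_model"
  )
}

#' Built-in placeholder cyclizability model
#'
#' A simple documented model encoding the mechanistic direction that
#' A/T-only dinucleotide steps bend more readily than G/C-only steps:
#' weight +0.02 for `AA`, `AT`, `TA`, `TT`, -0.02 for `CC`, `CG`, `GC`,
#' `GG`, 0 for mixed steps, intercept -0.1. It reproduces the direction
#' of AT-rich vs GC-rich contrasts; its absolute scores are not
#' calibrated against any experimental loop-seq coefficients.
#'
#' @return A `cyc_model`.
#' @export
default_cyc_model <- function() {
  w <- stats::setNames(rep(0, 16L), DINUCLEOTIDES)
  w[c("AA", "AT", "TA", "TT")] <- 0.02
  w[c("CC", "CG", "GC", "GG")] <- -0.02
  cyc_model("at-flex-1", intercept = -0.1, weights = w,
            provenance = "phagemech built-in placeholder (AT-positive, GC-negative)")
}

#' Read / write a cyclizability model file
#'
#' Models are stored as YAML with keys `name`, `provenance`,
#' `intercept`, `width`, a 16-entry `weights` map and an optional
#' `positional_weights` block (list of 16 rows of width - 1 values).
#' The round trip is lossless.
#'
#' @param path File path.
#' @return [read_cyc_model()] returns a `cyc_model`;
#'   [write_cyc_model()] returns `path` invisibly.
#' @export
read_cyc_model <- function(path) {
  y <- yaml::read_yaml(path)
  pw <- NULL
  if (!is.null(y$positional_weights)) {
    pw <- do.call(rbind, lapply(y$positional_weights, as.numeric))
  }
  cyc_model(
    name = y$name, intercept = y$intercept,
    weights = unlist(y$weights)[DINUCLEOTIDES],
    positional_weights = pw,
    width = y$width %||% 50L,
    provenance = y$provenance %||% "unspecified"
  )
}

#' @rdname read_cyc_model
#' @param model A `cyc_model`.
#' @export
write_cyc_model <- function(model, path) {
  y <- list(
    name = model$name, provenance = model$provenance,
    intercept = model$intercept, width = model$width,
    weights = as.list(model$weights)
  )
  if (!is.null(model$positional_weights)) {
    y$positional_weights <- apply(model$positional_weights, 1L, as.numeric,
                                  simplify = FALSE)
  }
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

# Sum of per-site model weights over each window given the genome-wide
# dinucleotide index vector; NA where a window overlaps an N.
window_scores_from_indices <- function(idx, starts, model) {
  nsites <- model$width - 1L
  if (is.null(model$positional_weights)) {
    w <- model$weights[idx]            # NA propagates from N-containing sites
    w0 <- ifelse(is.na(w), 0, w)
    cs <- c(0, cumsum(w0))
    cn <- c(0L, cumsum(is.na(w)))
    tot <- unname(cs[starts + nsites] - cs[starts])
    nna <- unname(cn[starts + nsites] - cn[starts])
    ifelse(nna > 0L, NA_real_, model$intercept + tot)
  } else {
    pos <- outer(starts - 1L, seq_len(nsites), `+`)  # site index matrix
    di <- matrix(idx[pos], nrow = length(starts))
    val <- matrix(model$positional_weights[cbind(as.vector(di),
                                                 rep(seq_len(nsites),
                                                     each = length(starts)))],
                  nrow = length(starts))
    model$intercept + rowSums(val)
  }
}

#' Score individual windows
#'
#' @param windows Character vector of window sequences, each of the
#'   model's width.
#' @param model A `cyc_model`.
#' @return Numeric scores; `NA` for windows containing `N`.
#' @export
#' @examples
#' score_window(strrep("A", 50), default_cyc_model())
score_window <- function(windows, model) {
  vapply(windows, function(s) {
    if (nchar(s) != model$width) {
      stop_phagemech("window length does not match the model width",
                     "phagemech_bad_window")
    }
    if (stringr::str_detect(s, "[^ACGTN]")) {
      stop_phagemech("window contains characters outside A/C/G/T/N",
                     "phagemech_illegal_characters")
    }
    idx <- dinuc_indices(s)
    window_scores_from_indices(idx, 1L, model)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sliding-window cyclizability profile of a genome
#'
#' Builds the window grid (default 50 bp windows every 7 bp), scores
#' every window under the model, and attaches per-genome summary
#' statistics. Windows overlapping an ambiguous base are scored `NA`
#' and excluded from summaries (their count is reported).
#'
#' @param genomes A genome tibble.
#' @param model A `cyc_model` (default [default_cyc_model()]).
#' @param width,stride Window grid parameters (defaults 50 and 7 bp).
#' @return A tibble of class `cyc_profile` with columns `genome_id`,
#'   `window`, `start` and `score`; use [glance()] for per-genome
#'   summaries and [boxplot_stats()] for the boxplot convention.
#' @export
#' @examples
#' g <- generate_iid(genome_spec(2000, gc_target = 0.35, seed = 3))
#' p <- profile_genome(g)
#' glance(p)
profile_genome <- function(genomes, model = default_cyc_model(),
                           width = 50L, stride = 7L) {
  model$width <- as.integer(width)
  out <- purrr::map2(genomes$id, genomes$sequence, function(id, s) {
    grid <- window_grid(genome_tbl(id, s), width, stride)
    idx <- dinuc_indices(s)
    tibble(
      genome_id = id,
      window = seq_len(grid$n_windows),
      start = grid$starts,
      score = window_scores_from_indices(idx, grid$starts, model)
    )
  }) |>
    bind_rows()
  attr(out, "model_name") <- model$name
  attr(out, "width") <- as.integer(width)
  attr(out, "stride") <- as.integer(stride)
  class(out) <- c("cyc_profile", class(out))
  out
}

#' @method tidy cyc_profile
#' @export
tidy.cyc_profile <- function(x, ...) {
  as_tibble(unclass_profile(x))
}

#' @method glance cyc_profile
#' @export
glance.cyc_profile <- function(x, ...) {
  as_tibble(unclass_profile(x)) |>
    group_by(.data$genome_id) |>
    summarise(
      n_windows = dplyr::n(),
      n_undefined = sum(is.na(.data$score)),
      mean = mean(.data$score, na.rm = TRUE),
      sd = sd(.data$score, na.rm = TRUE),
      min = min(.data$score, na.rm = TRUE),
      max = max(.data$score, na.rm = TRUE),
      .groups = "drop"
    )
}

unclass_profile <- function(x) {
  class(x) <- setdiff(class(x), c("cyc_profile", "pddf_profile"))
  x
}

#' @method autoplot cyc_profile
#' @export
autoplot.cyc_profile <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$start, y = .data$score)
  ) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~genome_id, ncol = 1L, scales = "free_x") +
    ggplot2::labs(x = "genome position (bp)",
                  y = "predicted cyclizability (log ratio)")
}

#' Ratio of mean cyclizability magnitudes
#'
#' `|mean_b| / |mean_a|`: how many times lower (more negative, on the
#' log-ratio scale) genome B's average intrinsic cyclizability is than
#' genome A's.
#'
#' @param mean_a,mean_b Mean scores of the two genomes; `mean_a` must be
#'   nonzero.
#' @return The magnitude ratio.
#' @export
#' @examples
#' ratio_of_mean_magnitudes(-0.12567, -0.16482)
ratio_of_mean_magnitudes <- function(mean_a, mean_b) {
  if (mean_a == 0) {
    stop_phagemech("mean_a must be nonzero", "phagemech_zero_division")
  }
  abs(mean_b) / abs(mean_a)
}
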