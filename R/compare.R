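#' Configuration for a two-genome comparison run
#'
#' @param genomes A genome tibble (see [read_fasta()]) or a character
#'   vector of FASTA paths; at least two genomes must resolve. The first
#'   two genomes are the comparison pair (first = "A", second = "B").
#' @param pentamer_table Optional pentamer shape table (tibble) or path
#'   to one; `NULL` omits the shape section.
#' @param model A `cyc_model` or path to a model file (default the
#'   built-in placeholder).
#' @param max_lag PDDF lag range upper end (default 100).
#' @param width,stride Cyclizability window grid (defaults 50 and 7 bp).
#' @param alpha ANOVA significance level (default 0.05).
#' @param heatmap_width Columns used when wrapping tracks into heatmaps
#'   (default 1000).
#' @param diff_orientation Sign convention of the differential matrix
#'   (see [differential_frequency_matrix()]).
#' @param seed Integer seed recorded in the report (the comparison is
#'   deterministic given its inputs; the seed matters only when genomes
#'   are simulated upstream).
#' @return A list of class `mech_config`.
#' @export
mech_config <- function(genomes, pentamer_table = NULL,
                        model = default_cyc_model(),
                        max_lag = 100L, width = 50L, stride = 7L,
                        alpha = 0.05, heatmap_width = 1000L,
                        diff_orientation = "row_minus_col", seed = 1L) {
  structure(
    list(genomes = genomes, pentamer_table = pentamer_table, model = model,
         max_lag = as.integer(max_lag), width = as.integer(width),
         stride = as.integer(stride), alpha = alpha,
         heatmap_width = as.integer(heatmap_width),
         diff_orientation = diff_orientation, seed = as.integer(seed)),
    class = "mech_config"
  )
}

resolve_genomes <- function(genomes) {
  if (is.character(genomes)) {
    genomes <- bind_rows(lapply(genomes, read_fasta))
  }
  if (!is.data.frame(genomes) || nrow(genomes) < 2L) {
    stop_phagemech("at least two genomes are required",
                   "phagemech_bad_config")
  }
  genomes
}

#' Run the full two-genome mechanical comparison
#'
#' Executes the pipeline end to end: per-genome dinucleotide
#' frequencies and the 16 x 16 differential matrix, PDDF profiles for
#' all 16 dinucleotides with a periodicity scan, sliding-window
#' cyclizability profiles with one-way ANOVA, a Mann-Whitney U test and
#' the magnitude ratio of the two means, and (when a pentamer table is
#' supplied) the four DNA shape tracks with per-feature summaries,
#' correlations, and between-genome Mann-Whitney tests. Deterministic
#' for fixed inputs.
#'
#' @param config A [mech_config()].
#' @return An object of class `phage_comparison`: a named list of
#'   sections (`genomes`, `frequency`, `diff_matrix`, `pddf`,
#'   `periodicity`, `cyclizability`, `cyc_summary`, `anova`,
#'   `mann_whitney_cyc`, `mean_magnitude_ratio`, `boxplots`, and when a
#'   table is given `shape`, `shape_summary`, `shape_correlations`,
#'   `mann_whitney_shape`). Optional sections are absent, never empty.
#' @export
#' @examples
#' pair <- synthetic_study_pair(seed = 1, scale = 0.01)
#' rep <- run_compare(mech_config(pair, max_lag = 50))
#' glance(rep$cyclizability)
run_compare <- function(config) {
  stopifnot(inherits(config, "mech_config"))
  genomes <- resolve_genomes(config$genomes)
  model <- config$model
  if (is.character(model)) model <- read_cyc_model(model)
  ga <- genomes$id[1]; gb <- genomes$id[2]

  freq <- dinucleotide_frequency(genomes)
  dmat <- differential_frequency_matrix(freq, ga, gb,
                                        orientation = config$diff_orientation)
  pd <- pddf(genomes, max_lag = config$max_lag)
  per <- periodicity_scan(pd, lag_range = c(2L, config$max_lag))

  prof <- profile_genome(genomes, model,
                         width = config$width, stride = config$stride)
  cyc_sum <- glance(prof)
  scores <- split(prof$score, prof$genome_id)[c(ga, gb)]
  anova <- one_way_anova(scores, alpha = config$alpha)
  mwu_cyc <- mann_whitney_u(scores[[ga]], scores[[gb]], mode = "approx")
  ratio <- ratio_of_mean_magnitudes(
    cyc_sum$mean[cyc_sum$genome_id == ga],
    cyc_sum$mean[cyc_sum$genome_id == gb]
  )
  boxes <- lapply(scores, boxplot_stats)

  report <- list(
    genomes = gc_content(genomes),
    frequency = freq,
    diff_matrix = dmat,
    pddf = pd,
    periodicity = per,
    cyclizability = prof,
    cyc_summary = cyc_sum,
    anova = anova,
    mann_whitney_cyc = mwu_cyc,
    mean_magnitude_ratio = ratio,
    boxplots = boxes,
    config = config[c("max_lag", "width", "stride", "alpha",
                      "heatmap_width", "diff_orientation", "seed")],
    model_name = model$name
  )

  tb <- config$pentamer_table
  if (!is.null(tb)) {
    if (is.character(tb)) tb <- load_pentamer_table(tb)
    shp <- predict_shape_tracks(genomes, tb)
    report$shape <- shp
    report$shape_summary <- glance(shp)
    report$shape_correlations <- shape_correlation_matrix(shp)
    sx <- as_tibble(unclass_shape(shp))
    report$mann_whitney_shape <- lapply(
      stats::setNames(SHAPE_FEATURES, SHAPE_FEATURES),
      function(f) {
        mann_whitney_u(sx[[f]][sx$genome_id == ga],
                       sx[[f]][sx$genome_id == gb], mode = "approx")
      }
    )
  }
  structure(report, class = "phage_comparison")
}

#' @export
print.phage_comparison <- function(x, ...) {
  cat("Two-genome mechanical comparison:",
      paste(x$genomes$id, collapse = " vs "), "\n")
  cat("sections:", paste(setdiff(names(x), c("config", "model_name")),
                         collapse = ", "), "\n")
  g <- glance(x$anova)
  cat(sprintf("cyclizability ANOVA: F = %.3f (F-crit %.3f), p = %.3g\n",
              g$f_ratio, g$f_critical, g$p_value))
  cat(sprintf("mean-magnitude ratio |B|/|A| = %.3f\n",
              x$mean_magnitude_ratio))
  invisible(x)
}

#' Export all report tables with a manifest
#'
#' Writes one TSV/JSON file per populated section of a comparison
#' report (absent optional sections produce no file) plus a
#' `manifest.tsv` listing file, section and MD5 checksum. Identical
#' runs produce identical checksums.
#'
#' @param report A `phage_comparison` from [run_compare()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
export_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2L) != 0L) {
    stop_phagemech(paste0("output directory not writable: ", dir),
                   "phagemech_io_error")
  }
  files <- character(0); sections <- character(0)
  put <- function(section, file, writer) {
    path <- file.path(dir, file)
    writer(path)
    files <<- c(files, path); sections <<- c(sections, section)
  }
  put("genomes", "genomes.tsv",
      function(p) readr::write_tsv(report$genomes, p, na = "NA"))
  put("frequency", "dinucleotide_frequency.tsv",
      function(p) readr::write_tsv(report$frequency, p, na = "NA"))
  put("diff_matrix", "differential_matrix.tsv", function(p) {
    wide <- as.data.frame(diff_matrix_wide(report$diff_matrix))
    readr::write_tsv(tibble::rownames_to_column(wide, "dinucleotide"), p)
  })
  put("pddf", "pddf.tsv",
      function(p) readr::write_tsv(tibble::as_tibble(report$pddf), p,
                                   na = "NA"))
  put("periodicity", "periodicity.tsv",
      function(p) readr::write_tsv(report$periodicity, p, na = "NA"))
  put("cyclizability", "cyclizability_scores.tsv",
      function(p) readr::write_tsv(tidy(report$cyclizability), p, na = "NA"))
  put("cyc_summary", "cyclizability_summary.json", function(p) {
    s <- report$cyc_summary
    s$boxplot <- lapply(report$boxplots[s$genome_id],
                        function(b) tidy(b))
    jsonlite::write_json(s, p, auto_unbox = TRUE, digits = NA)
  })
  put("anova", "anova.tsv", function(p) {
    tab <- tidy(report$anova)
    names(tab) <- c("Source of Variation", "SS", "df", "MS", "F", "p",
                    "F-critical")
    readr::write_tsv(tab, p, na = "")
  })
  put("mann_whitney", "mann_whitney.json", function(p) {
    mw <- list(cyclizability = tidy(report$mann_whitney_cyc))
    if (!is.null(report$mann_whitney_shape)) {
      mw$shape <- lapply(report$mann_whitney_shape, tidy)
    }
    jsonlite::write_json(mw, p, auto_unbox = TRUE, digits = NA)
  })
  if (!is.null(report$shape)) {
    put("shape_summary", "shape_summary.tsv",
        function(p) readr::write_tsv(report$shape_summary, p, na = "NA"))
    put("shape_correlations", "shape_correlations.tsv",
        function(p) readr::write_tsv(
          tibble::as_tibble(report$shape_correlations), p, na = "NA"))
  }
  put("config", "config.json", function(p) {
    jsonlite::write_json(
      c(report$config, list(model = report$model_name)),
      p, auto_unbox = TRUE, digits = NA
    )
  })
  manifest <- tibble(
    file = basename(files), section = sections,
    checksum = unname(tools::md5sum(files))
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Wrap a track into a row-major heatmap matrix
#'
#' @param track Numeric vector (NA = undefined).
#' @param width Number of columns (>= 1).
#' @return A `ceiling(length(track) / width)` x `width` matrix filled
#'   row-major, padded with `NA` on the last row.
#' @export
wrap_track <- function(track, width) {
  stopifnot(width >= 1L)
  if (length(track) == 0L) {
    stop_phagemech("track is empty", "phagemech_empty_track")
  }
  nrows <- ceiling(length(track) / width)
  padded <- c(track, rep(NA_real_, nrows * width - length(track)))
  matrix(padded, nrow = nrows, ncol = width, byrow = TRUE)
}

#' Unwrap a heatmap matrix back to a track
#'
#' @param m A matrix from [wrap_track()].
#' @param n Original track length (to drop padding).
#' @return The numeric track.
#' @export
unwrap_track <- function(m, n = nrow(m) * ncol(m)) {
  as.vector(t(m))[seq_len(n)]
}

#' Render a genomic track as a wrapped heatmap
#'
#' Wraps the track row-major into `width` columns and renders it with
#' `ggplot2::geom_raster`; undefined values get the `na_fill` colour.
#'
#' @param track Numeric vector.
#' @param width Columns per row (default 1000).
#' @param path Optional output path (`.png`/`.svg`/`.pdf`); when given
#'   the plot is saved there.
#' @param na_fill Colour for undefined cells.
#' @return The ggplot object, invisibly.
#' @export
render_heatmap <- function(track, width = 1000L, path = NULL,
                           na_fill = "grey70") {
  m <- wrap_track(track, width)
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$value <- as.vector(t(m))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red",
                                  midpoint = mean(d$value, na.rm = TRUE),
                                  na.value = na_fill) +
    ggplot2::labs(x = sprintf("position (row-major, %d bp per row)", width),
                  y = NULL, fill = "value")
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 5, dpi = 150)
  }
  invisible(p)
}

#' @method autoplot pddf_profile
#' @export
autoplot.pddf_profile <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$lag, y = .data$ratio, colour = .data$genome_id)
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~dinucleotide, ncol = 4L) +
    ggplot2::labs(x = "separation (dinucleotide steps)",
                  y = "observed / expected co-occurrence")
}

#' @method autoplot diff_freq_matrix
#' @export
autoplot.diff_freq_matrix <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$col_dinucleotide, y = .data$row_dinucleotide,
                 fill = .data$difference)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::scale_y_discrete(limits = rev(DINUCLEOTIDES)) +
    ggplot2::labs(
      x = attr(object, "col_genome"), y = attr(object, "row_genome"),
      fill = "difference"
    )
}
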