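#' All 1024 pentamers
#'
#' @return Character vector of the 4^5 pentamers over `A, C, G, T` in
#'   alphabetical order.
#' @export
all_pentamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = b, p4 = b, p3 = b, p2 = b, p1 = b,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4, g$p5))
}

SHAPE_FEATURES <- c("mgw", "prot", "roll", "helt")

#' Synthetic pentamer shape table
#'
#' A complete, deterministic stand-in for a published pentamer shape
#' query table, for testing and simulation. Values are generated by a
#' fixed rule, not measured: minor groove width narrows and propeller
#' twist becomes more negative as the A/T content of the pentamer
#' grows, roll and helical twist respond to the A/T character of the
#' central steps, and a smooth pentamer-dependent term adds
#' within-class variation. Ranges are physically plausible (MGW in
#' Angstrom around 5, ProT in degrees around -8, Roll around 0, HelT
#' around 34.5) but the table is SYNTHETIC and must not be used to
#' reproduce published shape values.
#'
#' @return A tibble with columns `pentamer`, `MGW`, `ProT`, `Roll1`,
#'   `Roll2`, `HelT1`, `HelT2` (one row per pentamer, 1024 rows).
#' @export
synthetic_pentamer_table <- function() {
  p <- all_pentamers()
  code <- seq_along(p) - 1L
  chars <- do.call(rbind, strsplit(p, "", fixed = TRUE))
  is_at <- chars %in% c("A", "T")
  dim(is_at) <- dim(chars)
  n_at <- rowSums(is_at)
  # deterministic smooth jitter, same for every build
  jit <- function(k) sin(0.731 * code + 1.37 * k)
  # A/T-ness of the two central steps (positions 2-3 and 3-4)
  s1 <- (is_at[, 2L] + is_at[, 3L]) - 1
  s2 <- (is_at[, 3L] + is_at[, 4L]) - 1
  tibble(
    pentamer = p,
    MGW = 5.0 - 0.40 * (n_at - 2.5) + 0.30 * jit(1),
    ProT = -8.0 - 1.20 * (n_at - 2.5) + 1.50 * jit(2),
    Roll1 = -0.8 + 1.20 * s1 + 0.80 * jit(3),
    Roll2 = -0.8 + 1.20 * s2 + 0.80 * jit(4),
    HelT1 = 34.5 - 0.60 * s1 + 0.50 * jit(5),
    HelT2 = 34.5 - 0.60 * s2 + 0.50 * jit(6)
  )
}

#' Load / write a pentamer shape table
#'
#' The on-disk format is TSV with columns `pentamer`, `MGW`, `ProT`,
#' `Roll1`, `Roll2`, `HelT1`, `HelT2`. Lookups are case-insensitive
#' (pentamers are uppercased on load); duplicate pentamers are an
#' error. A table need not be complete — [predict_shape_tracks()]
#' raises an error naming the first missing pentamer it needs.
#'
#' @param path File path.
#' @return [load_pentamer_table()] returns the table as a tibble with
#'   attribute `completeness` (entries present / 1024);
#'   [write_pentamer_table()] returns `path` invisibly.
#' @export
load_pentamer_table <- function(path) {
  cols <- c("pentamer", "MGW", "ProT", "Roll1", "Roll2", "HelT1", "HelT2")
  tb <- readr::read_tsv(path, col_types = readr::cols(
    pentamer = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(cols %in% names(tb))) {
    stop_phagemech(paste0("pentamer table must have columns ",
                          paste(cols, collapse = ", ")),
                   "phagemech_bad_table")
  }
  tb$pentamer <- toupper(tb$pentamer)
  if (anyDuplicated(tb$pentamer)) {
    stop_phagemech("duplicate pentamer rows in shape table",
                   "phagemech_duplicate_pentamer")
  }
  if (any(is.na(tb[cols[-1]]))) {
    stop_phagemech("malformed (non-numeric or missing) shape values",
                   "phagemech_bad_table")
  }
  out <- tb[cols]
  attr(out, "completeness") <- sum(all_pentamers() %in% out$pentamer)
  out
}

#' @rdname load_pentamer_table
#' @param table A pentamer shape table.
#' @export
write_pentamer_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Predict DNA shape tracks from pentamer context
#'
#' Slides a 5-bp window along each genome: the pentamer centered at
#' position `i` (for `i` in `3..L-2`) supplies the per-base minor
#' groove width and propeller twist at `i`, and contributes roll and
#' helical twist values to its two central base steps. A step covered
#' by two pentamers receives their average; the first and last covered
#' steps are single-pentamer values. Per the pentamer-model edge rule,
#' MGW/ProT are undefined at the two terminal bases of each end and
#' Roll/HelT at the first and last step, giving `L - 4` defined
#' per-base values and `L - 3` defined per-step values. Step `s`
#' (between bases `s` and `s + 1`) is reported at base position `s`.
#' Positions whose pentamer overlaps an `N` are undefined (`NA`).
#'
#' @param genomes A genome tibble.
#' @param table A pentamer shape table (default the synthetic built-in).
#' @return A tibble of class `shape_profile` with columns `genome_id`,
#'   `position`, `mgw`, `prot`, `roll`, `helt`.
#' @export
#' @examples
#' g <- genome_tbl("g", "ACGTACGTAC")
#' predict_shape_tracks(g)
predict_shape_tracks <- function(genomes, table = synthetic_pentamer_table()) {
  pent <- all_pentamers()
  idx_of <- match(pent, table$pentamer)
  lut <- function(col) as.numeric(table[[col]])[idx_of]
  mgw_t <- lut("MGW"); prot_t <- lut("ProT")
  r1_t <- lut("Roll1"); r2_t <- lut("Roll2")
  h1_t <- lut("HelT1"); h2_t <- lut("HelT2")

  purrr::map2(genomes$id, genomes$sequence, function(id, s) {
    L <- nchar(s)
    if (L < 5L) {
      stop_phagemech("genome must be at least 5 bp for shape prediction",
                     "phagemech_too_short")
    }
    b <- base_codes(s)
    centers <- 3:(L - 2L)
    code <- 256L * b[centers - 2L] + 64L * b[centers - 1L] +
      16L * b[centers] + 4L * b[centers + 1L] + b[centers + 2L] + 1L
    needed <- unique(code[!is.na(code)])
    miss <- needed[is.na(idx_of[needed])]
    if (length(miss) > 0L) {
      stop_phagemech(paste0("pentamer missing from shape table: ",
                            pent[miss[1L]]),
                     "phagemech_missing_pentamer")
    }
    # per-center values (NA where the pentamer overlaps an N)
    val <- function(tab) ifelse(is.na(code), NA_real_, tab[code])
    mgw_c <- val(mgw_t); prot_c <- val(prot_t)
    r1 <- val(r1_t); r2 <- val(r2_t)
    h1 <- val(h1_t); h2 <- val(h2_t)

    mgw <- rep(NA_real_, L); prot <- rep(NA_real_, L)
    mgw[centers] <- mgw_c; prot[centers] <- prot_c

    # step s (bases s..s+1): Roll2 of the pentamer centered at s plus
    # Roll1 of the pentamer centered at s+1, averaged where both exist
    roll <- rep(NA_real_, L); helt <- rep(NA_real_, L)
    steps <- 2:(L - 2L)
    left <- rep(NA_real_, L); right <- rep(NA_real_, L)
    left[centers] <- r2; right[centers] <- r1
    roll[steps] <- rowMeans(cbind(left[steps], right[steps + 1L]),
                            na.rm = TRUE)
    left[centers] <- h2; right[centers] <- h1
    helt[steps] <- rowMeans(cbind(left[steps], right[steps + 1L]),
                            na.rm = TRUE)
    # a step is defined only if at least one covering pentamer is N-free;
    # rowMeans(na.rm) yields NaN when both are NA -> normalize to NA
    roll[is.nan(roll)] <- NA_real_
    helt[is.nan(helt)] <- NA_real_

    tibble(genome_id = id, position = seq_len(L),
           mgw = mgw, prot = prot, roll = roll, helt = helt)
  }) |>
    bind_rows() |>
    structure(class = c("shape_profile", "tbl_df", "tbl", "data.frame"))
}

#' @method tidy shape_profile
#' @export
tidy.shape_profile <- function(x, ...) {
  as_tibble(unclass_shape(x)) |>
    tidyr::pivot_longer(dplyr::all_of(SHAPE_FEATURES),
                        names_to = "feature", values_to = "value")
}

#' @method glance shape_profile
#' @export
glance.shape_profile <- function(x, ...) {
  tidy.shape_profile(x) |>
    group_by(.data$genome_id, .data$feature) |>
    summarise(
      n_defined = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      min = min(.data$value, na.rm = TRUE),
      max = max(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}

unclass_shape <- function(x) {
  class(x) <- setdiff(class(x), "shape_profile")
  x
}

#' @method autoplot shape_profile
#' @export
autoplot.shape_profile <- function(object, ...) {
  ggplot2::ggplot(
    tidy.shape_profile(object),
    ggplot2::aes(x = .data$position, y = .data$value)
  ) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::facet_grid(feature ~ genome_id, scales = "free") +
    ggplot2::labs(x = "genome position (bp)", y = "predicted shape value")
}

#' Pairwise Pearson correlation of the four shape tracks
#'
#' For each genome, computes the Pearson coefficient between every pair
#' of the four tracks over the positions where both are defined
#' (per-step tracks are aligned to the base position of the step's
#' 5-prime end). Zero-variance tracks give a flagged `NA` coefficient
#' rather than a silent number; the diagonal is 1 by definition.
#'
#' @param profile A `shape_profile` from [predict_shape_tracks()].
#' @return A tibble of class `shape_cor_matrix` with one row per genome
#'   and ordered feature pair: `feature_a`, `feature_b`, `r`, `n_pairs`,
#'   `zero_variance`.
#' @export
shape_correlation_matrix <- function(profile) {
  x <- as_tibble(unclass_shape(profile))
  out <- x |>
    group_by(.data$genome_id) |>
    dplyr::group_modify(function(d, key) {
      purrr::map(SHAPE_FEATURES, function(fa) {
        purrr::map(SHAPE_FEATURES, function(fb) {
          ok <- !is.na(d[[fa]]) & !is.na(d[[fb]])
          n <- sum(ok)
          if (n < 3L) {
            stop_phagemech("fewer than 3 jointly defined positions",
                           "phagemech_too_short")
          }
          zv <- sd(d[[fa]][ok]) == 0 || sd(d[[fb]][ok]) == 0
          r <- if (fa == fb) 1 else if (zv) NA_real_ else
            stats::cor(d[[fa]][ok], d[[fb]][ok])
          tibble(feature_a = fa, feature_b = fb, r = r, n_pairs = n,
                 zero_variance = zv && fa != fb)
        }) |> bind_rows()
      }) |> bind_rows()
    }) |>
    ungroup()
  class(out) <- c("shape_cor_matrix", class(out))
  out
}

#' Shape correlation matrix in 4 x 4 layout
#'
#' @param m A `shape_cor_matrix`.
#' @param genome Genome id to extract (default the first).
#' @return A 4 x 4 numeric matrix with feature dimnames.
#' @export
shape_cor_wide <- function(m, genome = m$genome_id[1]) {
  d <- m[m$genome_id == genome, ]
  matrix(d$r, nrow = 4L, byrow = TRUE,
         dimnames = list(SHAPE_FEATURES, SHAPE_FEATURES))
}
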