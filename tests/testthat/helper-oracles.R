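# Brute-force oracles and fixture builders, independent of the package's
# vectorized code paths.

random_genome <- function(L, seed, probs = c(A = .25, C = .25, G = .25, T = .25),
                          id = "rnd") {
  s <- withr::with_seed(seed, paste(
    sample(names(probs), L, replace = TRUE, prob = probs), collapse = ""))
  genome_tbl(id, s)
}

# naive double-loop dinucleotide co-occurrence counts at lag s
naive_cooccurrence <- function(sequence, dinuc, s) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  M <- length(ch) - 1L
  hit <- function(i) paste0(ch[i], ch[i + 1L]) == dinuc
  total <- 0L
  for (i in seq_len(M - s)) {
    if (hit(i) && hit(i + s)) total <- total + 1L
  }
  total
}

# naive per-site window score under a cyc_model
naive_window_score <- function(window, model) {
  ch <- strsplit(window, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
  total <- model$intercept
  for (j in seq_len(nchar(window) - 1L)) {
    d <- paste0(ch[j], ch[j + 1L])
    total <- total + if (is.null(model$positional_weights)) {
      model$weights[[d]]
    } else {
      model$positional_weights[d, j]
    }
  }
  unname(total)
}

# exact two-sided Mann-Whitney p by enumerating every labeling
brute_force_mwu_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  labelings <- utils::combn(length(pool), n1)
  us <- apply(labelings, 2L, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# a pentamer table where every feature takes one constant value
constant_pentamer_table <- function(v = 1) {
  tibble::tibble(
    pentamer = all_pentamers(),
    MGW = v, ProT = v, Roll1 = v, Roll2 = v, HelT1 = v, HelT2 = v
  )
}
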