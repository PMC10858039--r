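# Independent oracles used to check the package implementations.

# Brute-force maximal-perfect-run scanner: per-position leftmost-anchored
# extension, one unit size at a time. Independent of the run-length-encoding
# method used by detect_perfect_strs().
oracle_detect_strs <- function(sequence, min_lengths = c(9, 4, 4, 3, 3, 3),
                               chrom = "seq") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  rows <- list()
  for (u in 1:6) {
    i <- 1L
    while (i + u <= n) {
      if (!all(valid[i:(i + u - 1L)])) {
        i <- i + 1L
        next
      }
      j <- i + u
      while (j <= n && valid[j] && chars[j] == chars[j - u]) j <- j + 1L
      region_len <- j - i
      if (region_len > u) {
        left_max <- i == 1L || !valid[i - 1L] ||
          chars[i - 1L] != chars[i - 1L + u]
        units <- region_len %/% u
        motif <- paste(chars[i:(i + u - 1L)], collapse = "")
        if (left_max && units >= min_lengths[u] &&
            estrpipe:::is_primitive_motif(motif)) {
          start0 <- i - 1L
          end0 <- start0 + u * units
          canon <- canonical_motif(motif)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = start0, end = end0,
            locus_id = sprintf("%s:%d-%d:%s", chrom, start0, end0, canon),
            motif = canon, unit_size = u, ref_length = units,
            region = NA_character_, stringsAsFactors = FALSE)
        }
        i <- max(i + 1L, j - u + 1L)
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(rows)) {
    return(estrpipe:::empty_panel())
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$unit_size), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Two-sided Fisher exact p by hypergeometric enumeration (relative
# likelihood definition), for a 2x2 matrix.
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up BH enumeration: q_(i) = min_{j >= i} m * p_(j) / j.
oracle_bh_q <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Random DNA with optional embedded tandem repeats so the detector oracle
# comparison exercises real runs.
random_dna <- function(n, n_repeats = 3L) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, n, replace = TRUE)
  for (k in seq_len(n_repeats)) {
    u <- sample.int(6L, 1L)
    reps <- sample(c(9, 4, 4, 3, 3, 3)[u] + 0:6, 1L)
    motif <- strsplit(estrpipe:::random_primitive_motif(u), "")[[1]]
    pos <- sample.int(n - u * reps, 1L)
    s[pos:(pos + u * reps - 1L)] <- rep(motif, reps)
  }
  paste(s, collapse = "")
}

expect_same_loci <- function(a, b) {
  key <- function(df) {
    sort(sprintf("%s|%d|%d|%s|%d|%d", df$chrom, df$start, df$end, df$motif,
                 df$unit_size, df$ref_length))
  }
  expect_identical(key(a), key(b))
}
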