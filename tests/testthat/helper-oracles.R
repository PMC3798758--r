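# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (loops over risk sets, O(n^3) linkage recomputation) so
# they share no code path with the package implementation.

# --- brute-force average linkage on a distance matrix --------------------
# Returns the multiset of merged member sets with their merge heights.
bf_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  sets <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_d)
    sets[[length(sets) + 1L]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, sets = sets)
}

# member sets implied by an hclust merge matrix, in merge order
hclust_sets <- function(hc) {
  merge <- hc$merge
  out <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    grab <- function(v) if (v < 0) -v else out[[v]]
    out[[i]] <- sort(c(grab(merge[i, 1]), grab(merge[i, 2])))
  }
  out
}

# --- brute-force log-rank over explicit risk sets ------------------------
bf_logrank <- function(times, events, group) {
  group <- as.integer(factor(group))
  k <- max(group)
  te <- sort(unique(times[events == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in te) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    for (j in seq_len(k)) {
      nj <- sum(at_risk & group == j)
      O[j] <- O[j] + sum(times == t & events == 1 & group == j)
      E[j] <- E[j] + d * nj / n
      for (l in seq_len(k)) {
        nl <- sum(at_risk & group == l)
        if (n > 1) {
          V[j, l] <- V[j, l] +
            if (j == l) d * (nj / n) * (1 - nj / n) * (n - d) / (n - 1)
            else -d * nj * nl / n^2 * (n - d) / (n - 1)
        }
      }
    }
  }
  dvec <- (O - E)[-k]
  chi2 <- if (all(abs(dvec) < 1e-12)) 0
          else as.numeric(t(dvec) %*% solve(V[-k, -k, drop = FALSE], dvec))
  list(chi2 = chi2, df = k - 1,
       p_value = pchisq(chi2, k - 1, lower.tail = FALSE))
}

# --- brute-force Benjamini-Hochberg --------------------------------------
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- rank(p, ties.method = "first")
  sorted <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  q_sorted[r]
}

# --- fixture builders ----------------------------------------------------
make_clinical <- function(times, events, study = "study_1", er = "+",
                          subtype = NULL, ids = NULL) {
  n <- length(times)
  df <- data.frame(
    sample_id = ids %||% sprintf("s%04d", seq_len(n)),
    dmfs_time = times,
    dmfs_event = events,
    er_status = rep_len(er, n),
    ln_status = "-",
    tumor_size_class = "T1",
    grade = "2",
    age_years = 55,
    treatment = "none",
    study = rep_len(study, n),
    stringsAsFactors = FALSE
  )
  if (!is.null(subtype)) df$subtype <- rep_len(subtype, n)
  clinical_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# expression matrix with correlated blocks: each block loads on its own
# latent factor; remaining probes are pure noise
make_block_expr <- function(block_sizes, n_background, n_samples, loading,
                            noise_sd = 1, seed = 1) {
  set.seed(seed)
  n_probes <- sum(block_sizes) + n_background
  f <- matrix(rnorm(length(block_sizes) * n_samples),
              nrow = length(block_sizes))
  x <- matrix(rnorm(n_probes * n_samples, sd = noise_sd), nrow = n_probes)
  row <- 0
  for (b in seq_along(block_sizes)) {
    idx <- row + seq_len(block_sizes[b])
    x[idx, ] <- x[idx, ] + loading * rep(f[b, ], each = block_sizes[b])
    row <- row + block_sizes[b]
  }
  rownames(x) <- sprintf("p%04d", seq_len(n_probes))
  colnames(x) <- sprintf("s%04d", seq_len(n_samples))
  attr(x, "block") <- rep(c(seq_along(block_sizes), 0),
                          c(block_sizes, n_background))
  x
}
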