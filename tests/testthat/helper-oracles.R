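# Independent brute-force oracles, written as plain double loops so they
# share no code path with the package implementations.

# long panel tibble from an image x rater matrix
panel_from_matrix <- function(m) {
  tibble::tibble(
    image_id = rep(sprintf("i%03d", seq_len(nrow(m))), times = ncol(m)),
    rater_id = rep(sprintf("r%02d", seq_len(ncol(m))), each = nrow(m)),
    label = as.vector(m)
  )
}

# Fleiss' kappa by direct tabulation
oracle_fleiss <- function(m, categories = sort(unique(as.vector(m)))) {
  n <- nrow(m); k <- ncol(m)
  nij <- matrix(0, n, length(categories))
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      c_idx <- which(categories == m[i, j])
      nij[i, c_idx] <- nij[i, c_idx] + 1
    }
  }
  p_i <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (c in seq_along(categories)) s <- s + nij[i, c]^2
    p_i[i] <- (s - k) / (k * (k - 1))
  }
  p_bar <- mean(p_i)
  p_j <- numeric(length(categories))
  for (c in seq_along(categories)) p_j[c] <- sum(nij[, c]) / (n * k)
  p_e <- sum(p_j^2)
  (p_bar - p_e) / (1 - p_e)
}

# ICC(2,1) via an explicit two-way ANOVA decomposition
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ssb <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (mean(m[i, ]) - gm)^2
  ssr <- 0
  for (j in seq_len(k)) ssr <- ssr + n * (mean(m[, j]) - gm)^2
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + gm)^2
    }
  }
  msb <- ssb / (n - 1)
  msr <- ssr / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msb - mse) / (msb + (k - 1) * mse + (k / n) * (msr - mse))
}

# per-image label multiplicity tally for consensus voting
oracle_consensus <- function(m, threshold) {
  out <- data.frame(row = seq_len(nrow(m)), modal_count = 0L,
                    retained = FALSE, label = NA)
  for (i in seq_len(nrow(m))) {
    labs <- unique(m[i, ])
    counts <- integer(length(labs))
    for (l in seq_along(labs)) {
      for (j in seq_len(ncol(m))) {
        if (m[i, j] == labs[l]) counts[l] <- counts[l] + 1L
      }
    }
    out$modal_count[i] <- max(counts)
    out$retained[i] <- max(counts) >= threshold
    if (out$retained[i]) out$label[i] <- labs[which.max(counts)]
  }
  out
}

# random categorical panel with at least two categories present
random_cat_panel <- function(n_images, n_raters, n_cats) {
  repeat {
    m <- matrix(sample(letters[seq_len(n_cats)], n_images * n_raters,
                       replace = TRUE), n_images, n_raters)
    if (length(unique(as.vector(m))) >= 2L) return(m)
  }
}
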