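# Independent oracles used across the suite. Each re-derives the quantity
# from first principles by a different route than the package code.

# --- digestion: brute-force enumeration of rule-consistent peptides --------
# Enumerates every substring and keeps those whose flanks are valid
# boundaries with an internal-cut count within the missed-cleavage budget.
oracle_digest <- function(sequence, rule, max_missed, site_mods = NULL) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  blocked_states <- names(rule$methyl_blocks)[rule$methyl_blocks]
  methyl_at <- rep(FALSE, n)
  if (!is.null(site_mods) && nrow(site_mods) > 0) {
    methyl_at[site_mods$position[site_mods$kind %in% blocked_states]] <- TRUE
  }
  cut <- vapply(seq_len(n), function(i) {
    if (i >= n) return(FALSE)
    if (!chars[i] %in% rule$cleave_after) return(FALSE)
    if (chars[i] %in% rule$proline_blocked && chars[i + 1] == "P") return(FALSE)
    if (methyl_at[i]) return(FALSE)
    TRUE
  }, logical(1))
  cumcut <- c(0, cumsum(cut))
  grid <- expand.grid(start = 1:n, end = 1:n)
  grid <- grid[grid$start <= grid$end, ]
  left_ok <- grid$start == 1 | cut[pmax(grid$start - 1, 1)]
  right_ok <- grid$end == n | cut[grid$end]
  internal <- cumcut[grid$end] - cumcut[grid$start]
  keep <- left_ok & right_ok & internal <= max_missed
  out <- grid[keep, ]
  out$missed <- internal[keep]
  out$sequence <- substring(sequence, out$start, out$end)
  rownames(out) <- NULL
  out[order(out$start, out$end), ]
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}

# --- studentized range CDF by numerical integration ------------------------
# P(Q <= q | k, df) = int_0^inf f_S(s) * F_range(q * s) ds, with S the
# square root of a chi-square/df variable and F_range the range CDF of k
# standard normals. Gauss-Legendre quadrature on both integrals.
oracle_ptukey <- function(q, k, df, n_outer = 160, n_inner = 240) {
  if (!is.finite(q)) return(if (q > 0) 1 else 0)
  if (q <= 0) return(0)
  gl_in <- pracma::gaussLegendre(n_inner, 0, 1)
  range_cdf <- function(r) {
    if (r <= 0) return(0)
    a <- -9; b <- r + 9
    u <- a + (b - a) * gl_in$x; w <- (b - a) * gl_in$w
    sum(w * k * stats::dnorm(u) *
          (stats::pnorm(u) - stats::pnorm(u - r))^(k - 1))
  }
  s_hi <- max(6, 1 + 12 / sqrt(df))
  gl0 <- pracma::gaussLegendre(n_outer, 0, 1)
  s <- 1e-10 + (s_hi - 1e-10) * gl0$x
  w <- (s_hi - 1e-10) * gl0$w
  log_fs <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
    (df - 1) * log(s) - df * s^2 / 2
  fr <- vapply(s, function(si) range_cdf(q * si), numeric(1))
  sum(w * exp(log_fs) * fr)
}

# --- topological overlap by triple loop ------------------------------------
oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) { tom[i, j] <- 1; next }
      shared <- 0
      for (u in 1:n) if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      tom[i, j] <- (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# --- BH step-up by hand -----------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- hypergeometric upper tail by direct summation --------------------------
oracle_hyper_upper <- function(overlap, set_size, universe_size, module_size) {
  ks <- overlap:min(set_size, module_size)
  sum(exp(lchoose(set_size, ks) +
            lchoose(universe_size - set_size, module_size - ks) -
            lchoose(universe_size, module_size)))
}
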