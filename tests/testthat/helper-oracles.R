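# Independent oracles used by unit and acceptance tests. These deliberately
# reimplement the target computations by direct enumeration / naive loops and
# must stay independent of the package's code paths.

# --- brute-force SSR scanner -------------------------------------------------

oracle_primitive <- function(unit) {
  k <- nchar(unit)
  if (k <= 1L) return(TRUE)
  for (d in seq_len(k %/% 2)) {
    if (k %% d == 0L) {
      ok <- TRUE
      for (r in seq_len(k %/% d - 1L)) {
        if (substr(unit, r * d + 1L, (r + 1L) * d) != substr(unit, 1L, d)) {
          ok <- FALSE; break
        }
      }
      if (ok) return(FALSE)
    }
  }
  TRUE
}

# Enumerate maximal whole-unit perfect arrays by direct extension from every
# start position, then apply the documented thresholds and overlap rules
# (longest array, then smaller unit, then leftmost).
oracle_scan_ssrs <- function(s, min_len = c(`2` = 12L, `3` = 12L, `4` = 12L,
                                            `5` = 20L, `6` = 18L)) {
  n <- nchar(s)
  rows <- list()
  for (k in 2:6) {
    i <- 1L
    while (i + 2L * k - 1L <= n) {
      unit <- substr(s, i, i + k - 1L)
      if (grepl("N", unit, fixed = TRUE) || !oracle_primitive(unit)) {
        i <- i + 1L; next
      }
      j <- i + k; nu <- 1L
      while (j + k - 1L <= n && substr(s, j, j + k - 1L) == unit) {
        nu <- nu + 1L; j <- j + k
      }
      left_ext <- i - k >= 1L && substr(s, i - k, i - 1L) == unit
      if (nu >= 2L && !left_ext && nu * k >= min_len[[as.character(k)]]) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = i - 1L, end = i - 1L + nu * k, unit = unit,
                     unit_length = k, n_units = nu, array_length = nu * k,
                     stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      unit_length = integer(), n_units = integer(),
                      array_length = integer(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$array_length, cand$unit_length, cand$start), , drop = FALSE]
  occupied <- logical(n)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    span <- (cand$start[r] + 1L):cand$end[r]
    if (!any(occupied[span])) { keep[r] <- TRUE; occupied[span] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All strings of a given length over an alphabet.
all_strings <- function(len, alphabet = c("A", "C")) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(as.matrix(grid), 1L, paste, collapse = "")
}

random_dna_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- exact hypergeometric tail by direct summation ---------------------------

oracle_exact_tail <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; K <- a + c_
  xs <- seq(a, min(m1, K))
  if (!length(xs) || a > min(m1, K)) return(0)
  sum(exp(lchoose(m1, xs) + lchoose(m2, K - xs) - lchoose(m1 + m2, K)))
}

# --- naive interval intersection ---------------------------------------------

oracle_overlap_bp <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}

oracle_region_content <- function(regions, annotations, family) {
  a <- annotations[annotations$family == family, , drop = FALSE]
  bp <- 0L; hits <- 0L
  for (i in seq_len(nrow(regions))) {
    got <- FALSE
    for (j in seq_len(nrow(a))) {
      if (regions$contig[i] != a$contig[j]) next
      w <- oracle_overlap_bp(regions$start[i], regions$end[i], a$start[j], a$end[j])
      if (w > 0L) { bp <- bp + w; got <- TRUE }
    }
    if (got) hits <- hits + 1L
  }
  list(bp = bp, hits = hits, content = bp / sum(regions$end - regions$start))
}

# --- GLS regression / ancestral-state oracles --------------------------------

oracle_gls_slope <- function(tree, x, y) {
  V <- ape::vcv(tree)
  x <- x[rownames(V)]; y <- y[rownames(V)]
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  beta[2L]
}

# --- small tree / trait fixtures ---------------------------------------------

random_ultrametric <- function(n, seed) {
  set.seed(seed)
  ape::rcoal(n)
}
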