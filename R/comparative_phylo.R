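# Phylogenetic-comparative statistics: independent contrasts (own pruning
# implementation, cross-checked against GLS in the tests), contrast
# regressions through the origin, censored two-rate Brownian-motion tests
# with simulation p-values, BM ancestral states, Kruskal-Wallis + Dunn/BH,
# normality/homoscedasticity gating, and trimmed-median Ne summaries.

.check_binary <- function(tree) {
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    tree <- ape::multi2di(tree)
    tree$edge.length[is.na(tree$edge.length)] <- 0
    message("polytomies resolved to zero-length binary branches")
  }
  tree
}

.match_traits <- function(tree, x) {
  if (is.null(names(x))) stop("trait values must be named by species")
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("missing trait value for tip(s): ",
                         paste(miss, collapse = ", "))
  x[tree$tip.label]
}

# Internal nodes in postorder (children before parents), via children lists.
.postorder_nodes <- function(tree) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  root <- n + 1L
  out <- integer(0); stack <- root; visit <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    visit <- c(visit, nd)
    kids <- children[[as.character(nd)]]
    stack <- c(stack, kids[kids > n])
  }
  rev(visit)
}

# Pruning pass shared by pic_contrasts() and .pic_operator(): tip "values"
# are rows of a matrix, so running it on the identity yields the linear
# operator C with contrasts = C %*% x.
.pic_engine <- function(tree, tipmat) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  el <- numeric(nnode)
  el[tree$edge[, 2L]] <- tree$edge.length
  val <- matrix(0, nrow = nnode, ncol = ncol(tipmat))
  val[seq_len(n), ] <- tipmat
  vv <- numeric(nnode)
  Cmat <- matrix(0, nrow = tree$Nnode, ncol = ncol(tipmat))
  node_order <- .postorder_nodes(tree)
  for (nd in node_order) {
    ch <- children[[as.character(nd)]]
    if (length(ch) != 2L) stop("tree must be binary")
    v1 <- el[ch[1L]] + vv[ch[1L]]
    v2 <- el[ch[2L]] + vv[ch[2L]]
    Cmat[nd - n, ] <- (val[ch[1L], ] - val[ch[2L], ]) / sqrt(v1 + v2)
    val[nd, ] <- (v2 * val[ch[1L], ] + v1 * val[ch[2L], ]) / (v1 + v2)
    vv[nd] <- v1 * v2 / (v1 + v2)
  }
  list(contrasts = Cmat, node_values = val[(n + 1L):nnode, , drop = FALSE],
       node_variances = vv[(n + 1L):nnode])
}

#' Phylogenetic independent contrasts (Felsenstein pruning)
#'
#' At each internal node the contrast is `(x_left - x_right) /
#' sqrt(v_left + v_right)`; the node receives the variance-weighted mean of
#' its daughters and its parent branch is extended by
#' `v_left * v_right / (v_left + v_right)`. On a binary tree with `n` tips
#' this yields `n - 1` contrasts that are i.i.d. `N(0, sigma^2)` under
#' Brownian motion.
#'
#' @param tree A rooted `phylo` with branch lengths; polytomies are resolved
#'   to zero-length binary branches.
#' @param x Named numeric vector of tip values (names = tip labels).
#' @return Object of class `"contrast_set"`: `contrasts` (named by internal
#'   node number), `node_values`, `node_variances`, `trait` name, `tree`.
#' @export
pic_contrasts <- function(tree, x) {
  trait_name <- deparse(substitute(x))
  tree <- .check_binary(tree)
  x <- .match_traits(tree, x)
  n <- length(tree$tip.label)
  eng <- .pic_engine(tree, matrix(unname(x), ncol = 1L))
  contrasts <- stats::setNames(eng$contrasts[, 1L],
                               as.character((n + 1L):(n + tree$Nnode)))
  structure(list(contrasts = contrasts,
                 node_values = stats::setNames(eng$node_values[, 1L], names(contrasts)),
                 node_variances = eng$node_variances,
                 trait = trait_name, tree = tree),
            class = "contrast_set")
}

# Linear operator C (n-1 x n) with C %*% x = contrasts; columns named by tip.
.pic_operator <- function(tree) {
  tree <- .check_binary(tree)
  n <- length(tree$tip.label)
  C <- .pic_engine(tree, diag(n))$contrasts
  colnames(C) <- tree$tip.label
  C
}

#' Regression through the origin of one contrast set on another
#'
#' Contrasts have arbitrary sign, so the regression is forced through the
#' origin; the two-sided t test on the slope (df = n - 1) is reported.
#'
#' @param y_contrasts,x_contrasts Numeric vectors of equal length (>= 3),
#'   or `"contrast_set"` objects.
#' @return List: `slope`, `se`, `t`, `df`, `p_value`, `n`.
#' @export
pic_regression <- function(y_contrasts, x_contrasts) {
  y <- if (inherits(y_contrasts, "contrast_set")) y_contrasts$contrasts else y_contrasts
  x <- if (inherits(x_contrasts, "contrast_set")) x_contrasts$contrasts else x_contrasts
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 contrasts")
  sxx <- sum(x^2)
  if (sxx == 0) stop("x contrasts have zero variance")
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  df <- length(x) - 1L
  se <- sqrt(rss / df / sxx)
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  list(slope = slope, se = se, t = tval, df = df,
       p_value = 2 * stats::pt(-abs(tval), df), n = length(x))
}

# Simulate BM tip values on a tree: tips x nsim matrix, root state 0.
.sim_bm_tips <- function(tree, sigma2, nsim) {
  tr <- stats::reorder(tree, "cladewise")
  n <- length(tr$tip.label)
  nnode <- n + tr$Nnode
  X <- matrix(0, nrow = nnode, ncol = nsim)
  s2 <- if (length(sigma2) == 1L) rep(sigma2, nrow(tr$edge)) else sigma2
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    X[ch, ] <- X[p, ] + stats::rnorm(nsim, 0, sqrt(s2[i] * tr$edge.length[i]))
  }
  out <- X[seq_len(n), , drop = FALSE]
  rownames(out) <- tr$tip.label
  out
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Trait starts at 0 at the root; each branch adds an independent
#' `Normal(0, sigma2 * length)` increment. `sigma2` may be a scalar or a
#' per-edge vector (for regime-painted simulations).
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param sigma2 BM rate (scalar or per-edge vector in `tree$edge` order).
#' @param seed Integer seed.
#' @param nsim Number of replicate traits.
#' @return If `nsim == 1`, a named numeric vector of tip values; otherwise a
#'   tips x nsim matrix.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, seed = NULL, nsim = 1L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  X <- .sim_bm_tips(tree, sigma2, nsim)
  if (nsim == 1L) stats::setNames(X[, 1L], rownames(X)) else X
}

#' Censored two-rate Brownian-motion test
#'
#' Tips are partitioned into regimes; the censored design computes
#' independent contrasts separately within each regime's induced subtree, so
#' every contrast belongs wholly to one regime. REML rate estimates are the
#' mean squared contrasts per regime; the likelihood ratio against a single
#' shared rate is calibrated by parametric simulation of single-rate BM on
#' the full tree (default 1000 simulations), `p` = fraction of simulations
#' with LR at least the observed.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param x Named numeric tip values.
#' @param regimes Named character/factor over the same tips assigning each
#'   to a regime; every regime needs >= 3 tips (>= 2 contrasts).
#' @param n_sims Number of parametric simulations (default 1000).
#' @param seed Integer seed for the simulations.
#' @return Object of class `"rate_test_result"`: `sigma2_single`,
#'   `sigma2_per_regime`, `sigma_per_regime`, `lnL_single`, `lnL_multi`,
#'   `LR`, `p_value`, `n_sims`, `n_contrasts_per_regime`.
#' @export
censored_rate_test <- function(tree, x, regimes, n_sims = 1000L, seed = NULL) {
  tree <- .check_binary(tree)
  x <- .match_traits(tree, x)
  regimes <- regimes[tree$tip.label]
  if (anyNA(regimes)) stop("every tip needs a regime")
  reg_levels <- unique(as.character(regimes))
  if (length(reg_levels) < 2L && n_sims > 0L)
    message("single regime supplied; multi-rate model collapses to single-rate")
  tipsets <- split(tree$tip.label, as.character(regimes))
  bad <- names(tipsets)[lengths(tipsets) < 3L]
  if (length(bad)) stop("regime(s) with fewer than 2 contrasts (need >= 3 tips): ",
                        paste(bad, collapse = ", "))
  subtrees <- lapply(tipsets, function(tp) ape::keep.tip(tree, tp))
  ops <- lapply(subtrees, .pic_operator)
  obs_u <- lapply(names(subtrees), function(r)
    as.numeric(ops[[r]] %*% x[colnames(ops[[r]])]))
  names(obs_u) <- names(subtrees)
  lr_stat <- function(u_list) {
    n_r <- lengths(u_list)
    ss_r <- vapply(u_list, function(u) sum(u^2), 0)
    s2_r <- ss_r / n_r
    N <- sum(n_r)
    s2_s <- sum(ss_r) / N
    list(LR = N * log(s2_s) - sum(n_r * log(s2_r)), s2_r = s2_r, s2_s = s2_s)
  }
  obs <- lr_stat(obs_u)
  N <- sum(lengths(obs_u))
  lnL <- function(u, s2) sum(stats::dnorm(u, 0, sqrt(s2), log = TRUE))
  lnL_single <- sum(mapply(function(u, r) lnL(u, obs$s2_s), obs_u, names(obs_u)))
  lnL_multi <- sum(mapply(function(u, r) lnL(u, obs$s2_r[[r]]), obs_u, names(obs_u)))
  p <- NA_real_
  if (n_sims > 0L) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    X <- .sim_bm_tips(tree, obs$s2_s, n_sims)
    U <- lapply(names(subtrees), function(r) ops[[r]] %*% X[colnames(ops[[r]]), , drop = FALSE])
    n_r <- vapply(U, nrow, 0L)
    ss <- vapply(U, function(u) colSums(u^2), numeric(n_sims))
    if (n_sims == 1L) ss <- matrix(ss, nrow = 1L)
    s2_r <- sweep(ss, 2L, n_r, `/`)
    s2_s <- rowSums(ss) / sum(n_r)
    LR_sim <- sum(n_r) * log(s2_s) - as.numeric(log(s2_r) %*% n_r)
    p <- mean(LR_sim >= obs$LR - 1e-12)
  }
  structure(list(sigma2_single = obs$s2_s,
                 sigma2_per_regime = obs$s2_r,
                 sigma_per_regime = sqrt(obs$s2_r),
                 lnL_single = lnL_single, lnL_multi = lnL_multi,
                 LR = max(0, obs$LR), p_value = p, n_sims = n_sims,
                 n_contrasts_per_regime = lengths(obs_u)),
            class = "rate_test_result")
}

#' @export
print.rate_test_result <- function(x, ...) {
  cat("censored Brownian-motion rate test\n")
  cat(sprintf("  sigma2 single: %.4g\n", x$sigma2_single))
  for (r in names(x$sigma2_per_regime))
    cat(sprintf("  sigma2[%s] = %.4g (sigma = %.4g, %d contrasts)\n", r,
                x$sigma2_per_regime[[r]], x$sigma_per_regime[[r]],
                x$n_contrasts_per_regime[[r]]))
  cat(sprintf("  LR = %.4g, p = %s (%d simulations)\n", x$LR,
              format(x$p_value), x$n_sims))
  invisible(x)
}

#' Brownian-motion ancestral state reconstruction
#'
#' Generalized-least-squares (maximum-likelihood) BM states: the root state
#' is the GLS mean (equal to the PIC-weighted mean), and each internal node
#' gets `mu + K V^-1 (x - mu)` where `V` is the tip covariance (shared path
#' lengths) and `K` the node-tip covariances.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param x Named numeric tip values.
#' @return Named numeric vector of states for internal nodes (names = node
#'   numbers, root first).
#' @export
asr_bm <- function(tree, x) {
  tree <- .check_binary(tree)
  x <- .match_traits(tree, x)
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  cov_all <- matrix(depth[mr], nrow = nrow(mr))
  tips <- seq_len(n); internal <- (n + 1L):(n + tree$Nnode)
  V <- cov_all[tips, tips]
  K <- cov_all[internal, tips, drop = FALSE]
  Vi <- solve(V + diag(1e-12, n))
  one <- rep(1, n)
  mu <- as.numeric((one %*% Vi %*% x) / (one %*% Vi %*% one))
  states <- as.numeric(mu + K %*% Vi %*% (x - mu))
  stats::setNames(states, as.character(internal))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H with tie correction and a chi-square p-value on k - 1 df.
#' When every value is identical, H = 0 and p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @return List: `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L, all(lengths(groups) >= 1L))
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rbar^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(list(H = 0, df = length(groups) - 1L, p_value = 1, n = N))
  H <- H / C
  df <- length(groups) - 1L
  list(H = H, df = df, p_value = stats::pchisq(H, df, lower.tail = FALSE), n = N)
}

#' Benjamini-Hochberg step-up adjustment
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values (monotone in the raw values, capped at 1).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Dunn post hoc test with Benjamini-Hochberg correction
#'
#' Pairwise z statistics on mean ranks with the standard tie correction,
#' two-sided normal p-values, BH-adjusted across all pairs.
#'
#' @param groups Named list of numeric vectors (>= 3 groups).
#' @return `data.frame`: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_bh <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 3L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2L)
  res <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    sd_ij <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[i] + 1 / ns[j]))
    z <- if (sd_ij > 0) (rbar[i] - rbar[j]) / sd_ij else 0
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = names(groups)[pairs[1L, ]],
                    group2 = names(groups)[pairs[2L, ]],
                    z = res[1L, ], p_value = res[2L, ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Gate an analysis scale on normality and homoscedasticity
#'
#' Runs Shapiro-Wilk (and Bartlett when `groups` is given) on the raw and
#' log-transformed values; linear analyses should use the first scale that
#' passes both at `alpha`, falling back to rank tests when neither does.
#' Non-positive values make the log transform impossible: rather than a
#' silent offset, the log scale is marked unavailable and the rank path is
#' recommended.
#'
#' @param values Positive numeric vector.
#' @param groups Optional grouping for Bartlett's variance-homogeneity test.
#' @param alpha Gate level (default 0.05).
#' @return List: `scale` in `{"raw","log","rank"}`, `transformed` (values on
#'   the chosen scale; raw values for `"rank"`), `report` (`data.frame` of
#'   tests and p-values).
#' @export
gate_and_transform <- function(values, groups = NULL, alpha = 0.05) {
  stopifnot(is.numeric(values), length(values) >= 3L)
  run_gate <- function(v) {
    if (length(unique(v)) < 3L) return(c(shapiro = NA_real_, bartlett = NA_real_))
    sw <- stats::shapiro.test(v)$p.value
    bt <- if (!is.null(groups)) stats::bartlett.test(v, factor(groups))$p.value else NA_real_
    c(shapiro = sw, bartlett = bt)
  }
  raw_p <- run_gate(values)
  log_ok <- all(values > 0)
  log_p <- if (log_ok) run_gate(log(values)) else c(shapiro = NA_real_, bartlett = NA_real_)
  raw_pass <- !is.na(raw_p[["shapiro"]]) && all(raw_p > alpha, na.rm = TRUE)
  log_pass <- log_ok && !is.na(log_p[["shapiro"]]) && all(log_p > alpha, na.rm = TRUE)
  scale <- if (raw_pass) "raw" else if (log_pass) "log" else "rank"
  report <- data.frame(scale = c("raw", "raw", "log", "log"),
                       test = c("shapiro", "bartlett", "shapiro", "bartlett"),
                       p_value = c(raw_p, log_p), row.names = NULL)
  if (!log_ok)
    message("non-positive values: log scale unavailable; rank tests recommended")
  list(scale = scale,
       transformed = switch(scale, raw = values, log = log(values), rank = values),
       report = report)
}

#' Trimmed median of an effective-population-size series
#'
#' Summarizes a coalescent Ne-over-time series by a median after one of the
#' standard robustness filters: dropping the first and last time points
#' (default), dropping 10% or 25% of points split between the two extremes,
#' or keeping only points between 20 kyBP and 10 myBP.
#'
#' @param series An `"ne_series"` ([ne_series()]).
#' @param scheme Filtering scheme.
#' @return Median Ne of the retained points.
#' @export
median_ne <- function(series,
                      scheme = c("trim_endpoints", "trim_10pct", "trim_25pct",
                                 "window_20ky_10my")) {
  scheme <- match.arg(scheme)
  pts <- series$points
  n <- nrow(pts)
  keep <- switch(scheme,
    trim_endpoints = seq_len(n)[-c(1L, n)],
    trim_10pct = {
      k <- ceiling(0.10 * n / 2)
      seq_len(n)[-c(seq_len(k), (n - k + 1L):n)]
    },
    trim_25pct = {
      k <- ceiling(0.25 * n / 2)
      seq_len(n)[-c(seq_len(k), (n - k + 1L):n)]
    },
    window_20ky_10my = which(pts$time >= 2e4 & pts$time <= 1e7))
  if (!length(keep)) stop("no points retained under scheme ", scheme)
  stats::median(pts$ne[keep])
}
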