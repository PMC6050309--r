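# LINE life-history statistics from reads mapped to a family consensus:
# the 3':5' normalized read-depth ratio (5'-truncation prevalence) and
# subfamily-filtered pairwise divergence from the consensus (relative age).

#' Normalized coverage profile of a LINE consensus
#'
#' Per-position depth is summarized over (i) 10 bp tiling windows, (ii) the
#' first (5') and second (3') half, and (iii) thirds; all summaries are
#' divided by the total number of reads aligned to the full-length reference
#' so that profiles are comparable across sequencing depths. The 3':5' ratio
#' is the mean depth of the 3' half over the mean depth of the 5' half; a
#' ratio above 1 indicates prevalent 5'-truncated copies. "Sliding" windows
#' are tiled (step = width): halves and thirds, the quantities used
#' downstream, are step-independent.
#'
#' @param alignments Alignment `data.frame` ([map_reads()]).
#' @param consensus_length Reference length (bases).
#' @param window Window width (default 10).
#' @param element_family Optional family label.
#' @return Object of class `"coverage_profile"`: `window_depth`
#'   (`data.frame`: start, end, depth, norm_depth), `half_depth`,
#'   `third_depth`, `ratio_3p_5p` (`NA` if the 5' half has zero depth),
#'   `n_reads_total`, `depth` (raw per-position).
#' @export
coverage_profile <- function(alignments, consensus_length, window = 10L,
                             element_family = NA_character_) {
  if (!nrow(alignments)) stop("no alignments")
  L <- consensus_length
  depth <- colSums(.pileup_counts(alignments, L))
  n_total <- nrow(alignments)
  w_start <- seq(0L, L - 1L, by = window)
  w_end <- pmin(L, w_start + window)
  w_depth <- vapply(seq_along(w_start),
                    function(i) mean(depth[(w_start[i] + 1L):w_end[i]]), 0)
  half_cut <- L %/% 2L
  halves <- c(`5p` = mean(depth[seq_len(half_cut)]),
              `3p` = mean(depth[(half_cut + 1L):L]))
  t1 <- L %/% 3L; t2 <- (2L * L) %/% 3L
  thirds <- c(`5p` = mean(depth[seq_len(t1)]),
              mid = mean(depth[(t1 + 1L):t2]),
              `3p` = mean(depth[(t2 + 1L):L]))
  ratio <- if (halves[["5p"]] > 0) halves[["3p"]] / halves[["5p"]] else NA_real_
  structure(list(
    element_family = element_family,
    window_depth = data.frame(start = w_start, end = w_end, depth = w_depth,
                              norm_depth = w_depth / n_total),
    half_depth = halves / n_total,
    third_depth = thirds / n_total,
    ratio_3p_5p = ratio,
    n_reads_total = n_total,
    depth = as.integer(depth)
  ), class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage profile%s: %d reads, 3':5' ratio = %s\n",
              if (!is.na(x$element_family)) paste0(" (", x$element_family, ")") else "",
              x$n_reads_total,
              if (is.na(x$ratio_3p_5p)) "NA" else sprintf("%.3f", x$ratio_3p_5p)))
  invisible(x)
}

#' Per-column frequency of the most frequent base
#'
#' @param alignments Alignment `data.frame`.
#' @param consensus_length Reference length.
#' @return Numeric vector of length `consensus_length`: frequency of the
#'   modal base per column (`NA` for uncovered columns), with attribute
#'   `"depth"`.
#' @export
column_major_frequency <- function(alignments, consensus_length) {
  m <- .pileup_counts(alignments, consensus_length)
  depth <- colSums(m)
  f <- ifelse(depth > 0L, apply(m, 2L, max) / pmax(depth, 1L), NA_real_)
  attr(f, "depth") <- as.integer(depth)
  f
}

#' Identify consensus sites that define separate subfamilies
#'
#' The per-column frequencies of the most frequent base are histogrammed in
#' bins of `bin_width` (default 0.01) and the mode bin located. Columns whose
#' modal-base frequency falls more than `max_bin_distance` bins (default 3)
#' from the mode are flagged as subfamily-diagnostic and excluded from
#' divergence estimates: at such sites two co-existing element lineages, not
#' age, drive the mismatch signal.
#'
#' @param column_freq Numeric vector of modal-base frequencies per consensus
#'   column ([column_major_frequency()]); `NA` columns are skipped with a
#'   warning.
#' @param bin_width Histogram bin width (default 0.01).
#' @param max_bin_distance Maximum allowed distance from the mode bin in bins
#'   (default 3).
#' @param min_depth Columns covered by fewer reads than this are not assessed
#'   (default 30): at lower depth the frequency estimate itself spans several
#'   bins of sampling noise. Depths are taken from the `"depth"` attribute
#'   that [column_major_frequency()] attaches; pass `min_depth = 0` to
#'   disable.
#' @return Integer vector of excluded (1-based) consensus positions, with
#'   attributes `mode_bin` and `bins` (per-column bin index).
#' @export
subfamily_site_filter <- function(column_freq, bin_width = 0.01,
                                  max_bin_distance = 3L, min_depth = 30L) {
  depth <- attr(column_freq, "depth")
  usable <- which(!is.na(column_freq))
  if (!is.null(depth) && min_depth > 0L)
    usable <- usable[depth[usable] >= min_depth]
  if (!length(usable)) stop("no columns with observations")
  if (length(usable) < length(column_freq))
    warning(length(column_freq) - length(usable), " empty column(s) skipped")
  f <- column_freq[usable]
  bins <- as.integer(floor(round(f / bin_width, 9)))  # f = 1 -> top bin
  tab <- table(bins)
  mode_bin <- as.integer(names(tab)[which.max(tab)])
  excluded <- usable[abs(bins - mode_bin) > max_bin_distance]
  attr(excluded, "mode_bin") <- mode_bin
  bin_all <- rep(NA_integer_, length(column_freq))
  bin_all[usable] <- bins
  attr(excluded, "bins") <- bin_all
  excluded
}

#' Pairwise divergence of reads from a consensus (pairwise pi)
#'
#' Per read, pi = mismatches / comparable sites, where comparable sites are
#' covered consensus positions that are not masked (`N`) and not excluded by
#' the subfamily filter. Reads with fewer than `min_sites` comparable sites
#' are dropped (below that, per-read pi is dominated by sampling noise). The
#' median over reads is the family's age proxy.
#'
#' @param alignments Alignment `data.frame`.
#' @param consensus Consensus string (masked positions as `N`).
#' @param excluded_sites Integer vector of 1-based positions to exclude
#'   ([subfamily_site_filter()]).
#' @param min_sites Minimum comparable sites per read (default 30).
#' @param element_family Optional label.
#' @return Object of class `"divergence_profile"`: `per_read_pi`,
#'   `median_pi`, `excluded_sites`, `n_reads_used`, `n_reads_dropped`.
#' @export
pairwise_pi <- function(alignments, consensus, excluded_sites = integer(0),
                        min_sites = 30L, element_family = NA_character_) {
  L <- nchar(consensus)
  cc <- strsplit(consensus, "", fixed = TRUE)[[1]]
  site_ok <- cc != "N"
  if (length(excluded_sites)) site_ok[excluded_sites] <- FALSE
  pis <- rep(NA_real_, nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    off0 <- alignments$ref_start[i]
    sc <- strsplit(alignments$seq[i], "", fixed = TRUE)[[1]]
    a <- max(0L, off0); b <- min(L, off0 + length(sc))
    if (b <= a) next
    rp <- (a + 1L):b
    rb <- sc[(a - off0 + 1L):(b - off0)]
    comp <- site_ok[rp] & rb != "N"
    n_comp <- sum(comp)
    if (n_comp < min_sites) next
    pis[i] <- sum(rb[comp] != cc[rp][comp]) / n_comp
  }
  used <- !is.na(pis)
  if (!any(used)) stop("all reads dropped (fewer than ", min_sites,
                       " comparable sites each)")
  structure(list(element_family = element_family,
                 per_read_pi = pis[used],
                 median_pi = stats::median(pis[used]),
                 excluded_sites = as.integer(excluded_sites),
                 n_reads_used = sum(used),
                 n_reads_dropped = sum(!used)),
            class = "divergence_profile")
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf("divergence profile%s: median pi = %.4f (%d reads, %d excluded site(s))\n",
              if (!is.na(x$element_family)) paste0(" (", x$element_family, ")") else "",
              x$median_pi, x$n_reads_used, length(x$excluded_sites)))
  invisible(x)
}
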