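# Perfect-microsatellite detection and genome-landscape summaries.
#
# Scanner semantics: a locus is a maximal whole-unit perfect tandem array of
# a primitive 2-6 bp unit. Arrays of 2-4 bp units must span >= 12 bp; arrays
# of 5-6 bp units must span > 15 bp. With whole-unit counting the effective
# minima are 12/12/12/20/18 bp for 2/3/4/5/6-mers. Any mismatch or N
# terminates an array. Homopolymer runs are detected separately and never
# enter landscape totals.

.SSR_MIN_LEN <- c(`1` = 12L, `2` = 12L, `3` = 12L, `4` = 12L, `5` = 20L, `6` = 18L)

.rotations <- function(s) {
  k <- nchar(s)
  if (k == 1L) return(s)
  d <- paste0(s, s)
  vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), "")
}

#' Is a repeat unit primitive (not itself a tandem repeat)?
#' @param unit Character vector of units.
#' @return Logical vector; `FALSE` for e.g. `"ATAT"` (period 2).
#' @export
is_primitive_unit <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    if (k <= 1L) return(TRUE)
    for (d in seq_len(k %/% 2)) {
      if (k %% d == 0L &&
          u == strrep(substr(u, 1L, d), k %/% d)) return(FALSE)
    }
    TRUE
  }, TRUE, USE.NAMES = FALSE)
}

#' Canonical (strand- and rotation-normalized) microsatellite motif
#'
#' The canonical motif is the lexicographically smallest string among all
#' rotations of the unit and all rotations of its reverse complement, so that
#' e.g. TAGAA, CTATT and AATAG pool into a single class ("AATAG"). Reducible
#' units (themselves tandem repeats of a shorter unit, e.g. "ATAT") are
#' canonicalized through their primitive root and flagged in the `"reducible"`
#' attribute.
#'
#' @param unit Character vector of repeat units (length 1-6, alphabet ACGT).
#' @return Character vector of canonical motifs with a logical `"reducible"`
#'   attribute.
#' @export
canonicalize_motif <- function(unit) {
  if (any(!grepl("^[ACGT]+$", unit)) || any(nchar(unit) < 1L | nchar(unit) > 6L))
    stop("units must be 1-6 bp over {A,C,G,T}")
  red <- !is_primitive_unit(unit)
  primitive <- unit
  for (i in which(red)) {
    u <- unit[i]; k <- nchar(u)
    for (d in seq_len(k %/% 2)) {
      if (k %% d == 0L && u == strrep(substr(u, 1L, d), k %/% d)) {
        primitive[i] <- substr(u, 1L, d); break
      }
    }
  }
  canon <- vapply(primitive, function(u) {
    min(c(.rotations(u), .rotations(revcomp(u))))
  }, "", USE.NAMES = FALSE)
  structure(canon, reducible = red)
}

# Maximal periodic runs for one period k on one contig (character vector cs).
# Returns data.frame(start, len) of maximal stretches [start, start+len) that
# are periodic with period k, len >= 2k (at least two full units), 0-based.
.periodic_runs <- function(cs, k) {
  n <- length(cs)
  if (n < 2L * k) return(NULL)
  ok <- cs != "N"
  eq <- cs[seq_len(n - k)] == cs[(k + 1L):n] & ok[seq_len(n - k)] & ok[(k + 1L):n]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= k  # run of r TRUEs spans r + k bases
  if (!any(sel)) return(NULL)
  data.frame(start = starts[sel] - 1L, len = r$lengths[sel] + k)
}

#' Scan an assembly for perfect microsatellite loci
#'
#' Finds maximal whole-unit perfect tandem arrays of primitive units. Scanning
#' is forward-strand only; [canonicalize_motif()] makes counts
#' strand-symmetric. Overlapping candidates of different unit lengths are
#' resolved deterministically: longer array wins, ties go to the smaller unit,
#' remaining ties to the leftmost array.
#'
#' @param genome A genome assembly (named character vector, see
#'   [as_genome_assembly()]).
#' @param min_len Named integer vector of minimum array lengths per unit
#'   length (defaults: 12 bp for 2-4mers, 20/18 bp for 5/6mers, i.e. arrays
#'   of 5-6 bp units must exceed 15 bp in whole units).
#' @param report_homopolymers Also report homopolymer (1-mer) runs >= 12 bp?
#'   They are returned with `unit_length == 1` and are excluded from
#'   [summarize_landscape()] totals.
#' @return `data.frame` of loci: `contig`, `start`, `end` (0-based half-open),
#'   `unit`, `canonical_motif`, `unit_length`, `n_units`, `array_length`.
#' @export
scan_ssrs <- function(genome, min_len = .SSR_MIN_LEN, report_homopolymers = FALSE) {
  ks <- if (report_homopolymers) 1:6 else 2:6
  res <- lapply(names(genome), function(cn) {
    cs <- strsplit(unclass(genome)[[cn]], "", fixed = TRUE)[[1]]
    cand <- list()
    for (k in ks) {
      runs <- .periodic_runs(cs, k)
      if (is.null(runs)) next
      unit <- vapply(runs$start, function(s)
        paste(cs[(s + 1L):(s + k)], collapse = ""), "")
      keep <- is_primitive_unit(unit)  # reducible arrays surface at their true period
      if (!any(keep)) next
      runs <- runs[keep, , drop = FALSE]; unit <- unit[keep]
      n_units <- runs$len %/% k
      alen <- n_units * k
      thr <- min_len[[as.character(k)]]
      sel <- alen >= thr
      if (!any(sel)) next
      cand[[length(cand) + 1L]] <- data.frame(
        contig = cn, start = runs$start[sel], end = runs$start[sel] + alen[sel],
        unit = unit[sel], unit_length = k, n_units = n_units[sel],
        array_length = alen[sel], stringsAsFactors = FALSE)
    }
    if (!length(cand)) return(NULL)
    cand <- do.call(rbind, cand)
    # overlap resolution: longest array, then smaller unit, then leftmost
    o <- order(-cand$array_length, cand$unit_length, cand$start)
    cand <- cand[o, , drop = FALSE]
    occupied <- logical(length(cs))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      span <- (cand$start[i] + 1L):cand$end[i]
      if (!any(occupied[span])) {
        keep[i] <- TRUE
        occupied[span] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    cand[order(cand$start), , drop = FALSE]
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(contig = character(), start = integer(), end = integer(),
                      unit = character(), unit_length = integer(),
                      n_units = integer(), array_length = integer(),
                      stringsAsFactors = FALSE)
  res$canonical_motif <- if (nrow(res)) as.character(canonicalize_motif(res$unit)) else character()
  rownames(res) <- NULL
  res[, c("contig", "start", "end", "unit", "canonical_motif", "unit_length",
          "n_units", "array_length")]
}

#' Summarize a microsatellite landscape as loci/Mbp and bp/Mbp
#'
#' @param loci Locus table from [scan_ssrs()].
#' @param genome_size Assembly size in bases.
#' @param species Optional species label.
#' @return Object of class `"ssr_landscape"`: list with `species`,
#'   `genome_size_mbp`, `per_motif` and `per_unit_length` density tables, and
#'   `totals` (loci/Mbp and bp/Mbp over all 2-6mer loci). Homopolymer rows
#'   (`unit_length == 1`) are excluded from all summaries.
#' @export
summarize_landscape <- function(loci, genome_size, species = NA_character_) {
  stopifnot(genome_size > 0)
  loci <- loci[loci$unit_length >= 2L, , drop = FALSE]
  mbp <- genome_size / 1e6
  per <- function(key) {
    if (!nrow(loci)) {
      return(data.frame(key = character(), n_loci = integer(), bp = integer(),
                        loci_per_mbp = numeric(), bp_per_mbp = numeric()))
    }
    n <- tapply(loci$array_length, loci[[key]], length)
    b <- tapply(loci$array_length, loci[[key]], sum)
    data.frame(key = names(n), n_loci = as.integer(n), bp = as.integer(b),
               loci_per_mbp = as.integer(n) / mbp, bp_per_mbp = as.integer(b) / mbp,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  pm <- per("canonical_motif"); names(pm)[1] <- "canonical_motif"
  pm$unit_length <- nchar(pm$canonical_motif)
  pu <- per("unit_length"); names(pu)[1] <- "unit_length"
  pu$unit_length <- as.integer(pu$unit_length)
  structure(list(
    species = species,
    genome_size_mbp = mbp,
    per_motif = pm,
    per_unit_length = pu,
    totals = c(n_loci = nrow(loci),
               bp = sum(loci$array_length),
               loci_per_mbp = nrow(loci) / mbp,
               bp_per_mbp = sum(loci$array_length) / mbp)
  ), class = "ssr_landscape")
}

#' @export
print.ssr_landscape <- function(x, ...) {
  cat("SSR landscape", if (!is.na(x$species)) paste0("for ", x$species), "\n")
  cat(sprintf("  genome size: %.3f Mbp\n", x$genome_size_mbp))
  cat(sprintf("  total: %d loci (%.1f loci/Mbp), %d bp (%.1f bp/Mbp)\n",
              x$totals[["n_loci"]], x$totals[["loci_per_mbp"]],
              x$totals[["bp"]], x$totals[["bp_per_mbp"]]))
  cat("  per unit length:\n")
  print(x$per_unit_length, row.names = FALSE)
  invisible(x)
}

#' Fold variation (max/min) of a positive quantity across species
#'
#' @param values Numeric vector (>= 2 strictly positive values), e.g.
#'   per-species loci/Mbp.
#' @return `max(values) / min(values)`.
#' @export
fold_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values)) || any(values <= 0)) stop("values must be strictly positive")
  max(values) / min(values)
}

#' Genomic GC content
#'
#' @param genome Genome assembly or character vector of sequences.
#' @return Fraction `(G+C)/(A+C+G+T)`; `N` bases are excluded from the
#'   denominator.
#' @export
gc_content <- function(genome) {
  s <- paste(unclass(genome), collapse = "")
  n_gc <- nchar(gsub("[^GC]", "", s))
  n_acgt <- nchar(gsub("[^ACGT]", "", s))
  if (n_acgt == 0L) stop("no non-N bases")
  n_gc / n_acgt
}

#' Genomic TE content per family and class
#'
#' Overlapping annotations of the same family are merged so no base is
#' counted twice within a family; the grand total merges across everything.
#'
#' @param annotations Annotation `data.frame` (`contig`, `start`, `end`,
#'   `family`, `te_class`).
#' @param genome_size Assembly size in bases.
#' @param lengths Optional named contig lengths for bounds checking.
#' @return List with `per_family`, `per_class` (`data.frame`s of bp and
#'   percent of genome) and `total_percent` (merged across all annotations).
#' @export
te_landscape_summary <- function(annotations, genome_size, lengths = NULL) {
  a <- annotations
  stopifnot(genome_size > 0)
  if (any(a$start < 0L) || any(a$start >= a$end))
    stop("invalid annotation intervals")
  if (!is.null(lengths)) {
    if (any(a$end > lengths[a$contig]))
      stop("annotation extends past contig end")
  }
  merged_bp <- function(df) {
    if (!nrow(df)) return(0L)
    sum(vapply(split(df, df$contig), function(d) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = d$start + 1L, end = d$end))))
    }, 0L))
  }
  by_key <- function(key) {
    keys <- unique(a[[key]])
    bp <- vapply(keys, function(k) merged_bp(a[a[[key]] == k, , drop = FALSE]), 0L)
    data.frame(key = keys, bp = bp, percent = 100 * bp / genome_size,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  pf <- by_key("family"); names(pf)[1] <- "family"
  pc <- by_key("te_class"); names(pc)[1] <- "te_class"
  list(per_family = pf, per_class = pc,
       total_bp = merged_bp(a), total_percent = 100 * merged_bp(a) / genome_size)
}

#' Subsample a shotgun read set to a target cumulative size
#'
#' Reads are drawn uniformly without replacement until the cumulative length
#' first reaches the target, mirroring fixed-Mbp subsampling of unassembled
#' shotgun datasets (3, 5, 8, 10, 30, 50, 100, 250 Mbp in the original
#' robustness analysis).
#'
#' @param reads Named character vector of reads.
#' @param target_mbp Target cumulative size in Mbp.
#' @param seed Integer seed; the same seed reproduces the same subsample.
#' @return Named character vector (a subset of `reads`, in sampled order).
#' @export
subsample_reads <- function(reads, target_mbp, seed) {
  target <- target_mbp * 1e6
  total <- sum(nchar(reads))
  if (target > total) stop("target exceeds available bases (",
                           round(total / 1e6, 3), " Mbp)")
  if (target == total) return(reads)
  set.seed(as.integer(seed))
  perm <- sample.int(length(reads))
  cum <- cumsum(nchar(reads)[perm])
  n_take <- which(cum >= target)[1L]
  reads[perm[seq_len(n_take)]]
}
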