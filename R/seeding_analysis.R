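# Microsatellite-seeding analysis: are particular TE families enriched in
# the 400 bp flanks of a target SSR motif relative to randomly placed genomic
# backgrounds? Presence/absence of a family per region feeds a one-tailed
# exact (hypergeometric) test; base-fraction content gives the adjacent vs
# background ratio.

.regions_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Extract flanking regions around SSR loci
#'
#' Per locus, up to two regions `[start - width, start)` and
#' `[end, end + width)`, clipped at contig bounds; the SSR array itself is
#' never part of a flank. Zero-length regions are dropped.
#'
#' @param loci Locus table ([scan_ssrs()]), optionally pre-filtered to one
#'   canonical motif.
#' @param genome Genome assembly, or a named integer vector of contig lengths.
#' @param width Flank width in bases (default 400).
#' @param target_motif Optional motif label stored on the result.
#' @return Object of class `"flank_set"`: list with `target_motif`,
#'   `flank_width` and `regions` (`data.frame`: `contig`, `start`, `end`,
#'   `side` in `{"5p","3p"}`, `source_locus` row index).
#' @export
extract_flanks <- function(loci, genome, width = 400L, target_motif = NA_character_) {
  if (width <= 0L) stop("width must be positive")
  lens <- if (is.numeric(genome)) genome else contig_lengths(genome)
  if (any(loci$end > lens[loci$contig])) stop("loci extend past contig ends")
  up <- data.frame(contig = loci$contig,
                   start = pmax(0L, loci$start - as.integer(width)),
                   end = loci$start, side = "5p",
                   source_locus = seq_len(nrow(loci)), stringsAsFactors = FALSE)
  dn <- data.frame(contig = loci$contig,
                   start = loci$end,
                   end = pmin(lens[loci$contig], loci$end + as.integer(width)),
                   side = "3p",
                   source_locus = seq_len(nrow(loci)), stringsAsFactors = FALSE)
  regions <- rbind(up, dn)
  regions <- regions[regions$end > regions$start, , drop = FALSE]
  regions <- regions[order(regions$source_locus, regions$side == "3p"), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(target_motif = target_motif, flank_width = as.integer(width),
                 regions = regions), class = "flank_set")
}

# N-gap intervals (runs of >= min_n Ns), 0-based half-open, per contig.
.assembly_gaps <- function(genome, min_n = 10L) {
  lapply(unclass(genome), function(s) {
    m <- gregexpr(sprintf("N{%d,}", min_n), s)[[1L]]
    if (m[1L] == -1L) return(NULL)
    IRanges::IRanges(start = as.integer(m),
                     width = attr(m, "match.length"))
  })
}

#' Sample random genomic background region sets
#'
#' Each replicate contains the same number of regions with the same length
#' multiset as the flank set, placed uniformly at random over contigs
#' (weighted by placeable length). Regions overlapping assembly gaps (runs of
#' >= 10 N) or extending past contig ends are rejected and redrawn;
#' background regions may overlap each other. Five replicates is the
#' conventional default.
#'
#' @param genome Genome assembly, or named contig lengths (no gap rejection
#'   possible in that case).
#' @param flanks A `"flank_set"` whose region lengths are to be matched.
#' @param n_replicates Number of independent background sets (default 5).
#' @param seed Integer seed; same seed, same backgrounds.
#' @param max_tries Per-region rejection budget multiplier.
#' @return List of `n_replicates` region `data.frame`s (`contig`, `start`,
#'   `end`).
#' @export
sample_background <- function(genome, flanks, n_replicates = 5L, seed = 1L,
                              max_tries = 100L) {
  lens <- if (is.numeric(genome)) genome else contig_lengths(genome)
  gaps <- if (is.numeric(genome)) NULL else .assembly_gaps(genome)
  widths <- flanks$regions$end - flanks$regions$start
  set.seed(as.integer(seed))
  lapply(seq_len(n_replicates), function(rep_i) {
    place_one <- function(w) {
      for (try_i in seq_len(max_tries)) {
        room <- pmax(0L, lens - w + 1L)
        if (sum(room) == 0L) stop("no contig can hold a region of width ", w)
        ci <- sample.int(length(lens), 1L, prob = room)
        s0 <- sample.int(room[ci], 1L) - 1L
        if (!is.null(gaps[[ci]]) && length(gaps[[ci]])) {
          hit <- IRanges::countOverlaps(
            IRanges::IRanges(start = s0 + 1L, width = w), gaps[[ci]])
          if (hit > 0L) next
        }
        return(c(ci, s0))
      }
      stop("could not place background region within retry budget")
    }
    placed <- vapply(widths, place_one, numeric(2))
    data.frame(contig = names(lens)[placed[1L, ]],
               start = as.integer(placed[2L, ]),
               end = as.integer(placed[2L, ] + widths),
               stringsAsFactors = FALSE)
  })
}

#' Per-family TE content of a region set
#'
#' @param regions Region `data.frame` (`contig`, `start`, `end`) or a
#'   `"flank_set"`.
#' @param annotations TE annotation `data.frame`.
#' @param families Families to report (default: all present in
#'   `annotations`).
#' @return `data.frame` per family: `bp` (annotated bases intersecting the
#'   regions, counted per region), `content` (fraction of total region
#'   bases), `n_regions_hit` (regions with >= 1 overlap), plus attributes
#'   `n_regions`, `total_bp`.
#' @export
region_te_content <- function(regions, annotations, families = NULL) {
  if (inherits(regions, "flank_set")) regions <- regions$regions
  if (is.null(families)) families <- sort(unique(annotations$family))
  total_bp <- sum(regions$end - regions$start)
  n_regions <- nrow(regions)
  out <- data.frame(family = families, bp = 0L, content = 0,
                    n_regions_hit = 0L, stringsAsFactors = FALSE)
  if (n_regions > 0L && nrow(annotations) > 0L) {
    for (cn in unique(regions$contig)) {
      r <- which(regions$contig == cn)
      a <- which(annotations$contig == cn & annotations$family %in% families)
      if (!length(a)) next
      ir_r <- .regions_to_iranges(regions[r, , drop = FALSE])
      ir_a <- .regions_to_iranges(annotations[a, , drop = FALSE])
      ov <- IRanges::findOverlaps(ir_r, ir_a)
      if (!length(ov)) next
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(ir_r[qi], ir_a[si]))
      fam <- annotations$family[a][si]
      bp_add <- tapply(w, fam, sum)
      hit_add <- tapply(qi, fam, function(q) length(unique(q)))
      idx <- match(names(bp_add), out$family)
      out$bp[idx] <- out$bp[idx] + as.integer(bp_add)
      out$n_regions_hit[idx] <- out$n_regions_hit[idx] + as.integer(hit_add)
    }
  }
  out$content <- if (total_bp > 0L) out$bp / total_bp else 0
  attr(out, "n_regions") <- n_regions
  attr(out, "total_bp") <- total_bp
  out
}

#' One-tailed exact tail probability of a 2x2 enrichment table
#'
#' Direct hypergeometric upper tail: the probability, with margins fixed, of
#' seeing at least `a` flank regions hit. Equivalent to a one-tailed Fisher
#' exact test with alternative "greater".
#'
#' @param a,b Flank regions with / without a hit of the family.
#' @param c_,d Background regions with / without a hit.
#' @return P(X >= a), X hypergeometric.
#' @export
exact_enrichment_p <- function(a, b, c_, d) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  # X ~ Hyper(white = a + c_, black = b + d, drawn = a + b)
  stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}

#' Test TE-family enrichment in SSR flanks against genomic backgrounds
#'
#' For each family: `content` fraction in the flanks, mean content over the
#' background replicates, their ratio, and a one-tailed exact test on the
#' 2x2 table of region-level presence/absence (flank regions vs pooled
#' background regions), alternative = enrichment in flanks.
#'
#' Region-level presence/absence (rather than base counts) is used because
#' bases within a region are not independent trials. When a family has zero
#' content in both flanks and backgrounds, the ratio is defined as 1 and a
#' message is logged.
#'
#' @param flanks A `"flank_set"`.
#' @param backgrounds List of background region sets ([sample_background()]).
#' @param annotations TE annotation `data.frame`. Simple-repeat and
#'   low-complexity rows are excluded automatically so a family's content
#'   never includes the target motif's own bases.
#' @param alpha Significance level (default 0.01).
#' @param families Families to test (default: all TE families present).
#' @return `data.frame` of class `"enrichment_result"`: per family
#'   `adjacent_content`, `background_content`, `ratio`, `log2_ratio`,
#'   `p_value`, `flagged`, `n_flanks`, `n_background_regions`, hit counts.
#' @export
enrichment_test <- function(flanks, backgrounds, annotations, alpha = 0.01,
                            families = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (length(backgrounds) < 1L) stop("need at least one background replicate")
  te <- annotations[!annotations$te_class %in% c("Simple_repeat", "Low_complexity"), ,
                    drop = FALSE]
  if (is.null(families)) families <- sort(unique(te$family))
  fc <- region_te_content(flanks, te, families)
  bg <- lapply(backgrounds, region_te_content, annotations = te, families = families)
  bg_content <- rowMeans(do.call(cbind, lapply(bg, `[[`, "content")))
  bg_hits <- rowSums(do.call(cbind, lapply(bg, `[[`, "n_regions_hit")))
  n_flank <- attr(fc, "n_regions")
  n_bg <- sum(vapply(bg, attr, 0L, "n_regions"))
  ratio <- ifelse(bg_content > 0, fc$content / bg_content,
                  ifelse(fc$content > 0, Inf, 1))
  if (any(bg_content == 0 & fc$content == 0))
    message(sum(bg_content == 0 & fc$content == 0),
            " family(ies) absent from both flanks and backgrounds; ratio set to 1")
  p <- mapply(exact_enrichment_p,
              a = fc$n_regions_hit, b = n_flank - fc$n_regions_hit,
              c_ = bg_hits, d = n_bg - bg_hits)
  out <- data.frame(
    family = fc$family,
    adjacent_content = fc$content,
    background_content = bg_content,
    ratio = ratio,
    log2_ratio = log2(ifelse(ratio > 0, ratio, NA)),
    p_value = p,
    flagged = p < alpha,
    n_flanks = n_flank,
    n_flanks_hit = fc$n_regions_hit,
    n_background_regions = n_bg,
    n_background_hit = bg_hits,
    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Joint and conditional probabilities of SSR/TE co-occurrence
#'
#' `conditional_prob` is the fraction of SSR loci with at least one
#' annotation of the family within `flank_width` on either side.
#' `joint_prob` is the fraction of non-overlapping genome tiles containing
#' both an SSR locus of the motif and an annotation of the family. The
#' default tile width, `2 * flank_width + median SSR array length`, is the
#' footprint of a flanked locus so the two probabilities are commensurable;
#' under genuine adjacency the conditional probability exceeds the
#' joint-derived expectation, under independence they agree.
#'
#' @param loci SSR locus table (one motif).
#' @param annotations TE annotation `data.frame`.
#' @param genome Genome assembly or named contig lengths.
#' @param families Families to report (default all TE families present).
#' @param flank_width Adjacency distance (default 400).
#' @param tile_width Genome tile width; default `2*flank_width + median
#'   array length`.
#' @return `data.frame`: `family`, `joint_prob`, `conditional_prob`,
#'   `n_loci`, `n_tiles`.
#' @export
co_occurrence <- function(loci, annotations, genome, families = NULL,
                          flank_width = 400L, tile_width = NULL) {
  lens <- if (is.numeric(genome)) genome else contig_lengths(genome)
  te <- annotations[!annotations$te_class %in% c("Simple_repeat", "Low_complexity"), ,
                    drop = FALSE]
  if (is.null(families)) families <- sort(unique(te$family))
  if (is.null(tile_width)) {
    med <- if (nrow(loci)) stats::median(loci$end - loci$start) else 0
    tile_width <- as.integer(2L * flank_width + med)
  }
  if (tile_width <= 0L) stop("tile_width must be positive")
  tiles <- do.call(rbind, lapply(names(lens), function(cn) {
    starts <- seq(0L, lens[[cn]] - 1L, by = tile_width)
    data.frame(contig = cn, start = starts,
               end = pmin(lens[[cn]], starts + tile_width),
               stringsAsFactors = FALSE)
  }))
  # windows around each locus for the conditional probability
  halo <- data.frame(contig = loci$contig,
                     start = pmax(0L, loci$start - as.integer(flank_width)),
                     end = pmin(lens[loci$contig], loci$end + as.integer(flank_width)),
                     stringsAsFactors = FALSE)
  tiles_with_ssr <- rep(FALSE, nrow(tiles))
  if (nrow(loci)) {
    for (cn in unique(tiles$contig)) {
      ti <- which(tiles$contig == cn); li <- which(loci$contig == cn)
      if (!length(li)) next
      tiles_with_ssr[ti] <- IRanges::countOverlaps(
        .regions_to_iranges(tiles[ti, , drop = FALSE]),
        .regions_to_iranges(loci[li, c("start", "end"), drop = FALSE])) > 0L
    }
  }
  out <- lapply(families, function(fam) {
    afam <- te[te$family == fam, , drop = FALSE]
    tiles_with_te <- rep(FALSE, nrow(tiles))
    halo_hit <- rep(FALSE, nrow(halo))
    if (nrow(afam)) {
      for (cn in unique(afam$contig)) {
        ai <- which(afam$contig == cn)
        ir_a <- .regions_to_iranges(afam[ai, , drop = FALSE])
        ti <- which(tiles$contig == cn)
        tiles_with_te[ti] <- IRanges::countOverlaps(
          .regions_to_iranges(tiles[ti, , drop = FALSE]), ir_a) > 0L
        hi <- which(halo$contig == cn)
        if (length(hi))
          halo_hit[hi] <- IRanges::countOverlaps(
            .regions_to_iranges(halo[hi, , drop = FALSE]), ir_a) > 0L
      }
    }
    data.frame(family = fam,
               joint_prob = mean(tiles_with_ssr & tiles_with_te),
               conditional_prob = if (nrow(loci)) mean(halo_hit) else NA_real_,
               n_loci = nrow(loci), n_tiles = nrow(tiles),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
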