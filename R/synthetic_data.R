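# Synthetic genomes, reads, and traits with known truth, emulating the
# structure the pipeline assumes: planted LINE families with
# subfamily-diagnostic sites, 5'-truncated copies, optional 3' SSR tails
# (e.g. AATAG), standalone background SSR loci, and shotgun reads with a
# per-base substitution error rate. Substitution-only (no indels) so that
# ungapped mapping and pairwise pi are exact.

.random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.mutate_sites <- function(chars, sites) {
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  if (!length(sites)) return(chars)
  picks <- substring(alt[chars[sites]],
                     s <- sample.int(3L, length(sites), replace = TRUE), s)
  chars[sites] <- picks
  chars
}

#' Describe one TE family for the simulator
#'
#' @param name Family label (e.g. `"CR1-L3"`).
#' @param consensus_length Element length in bp.
#' @param copy_number Copies to plant.
#' @param divergence Per-copy substitution rate from the family consensus
#'   (applied i.i.d. over non-diagnostic sites).
#' @param truncation_q Fraction of copies missing their 5' prefix.
#' @param truncation_extent Fraction of the element removed from the 5' end
#'   of a truncated copy (default 0.5: truncated copies lack exactly the 5'
#'   half, so the expected 3':5' depth ratio is `1/(1-q)`).
#' @param ssr_tail Optional list `list(motif=, n_units=)`: a perfect SSR tail
#'   appended at the 3' end of every copy (the microsatellite-seeding
#'   scenario).
#' @param n_subfamilies,n_diagnostic_sites Subfamily structure: diagnostic
#'   sites carry fixed differences between subfamilies, shared within each.
#' @param te_class Annotation class.
#' @return A `te_family_config` list.
#' @export
te_family_config <- function(name, consensus_length = 1000L, copy_number = 20L,
                             divergence = 0.05, truncation_q = 0,
                             truncation_extent = 0.5, ssr_tail = NULL,
                             n_subfamilies = 1L, n_diagnostic_sites = 0L,
                             te_class = "LINE") {
  stopifnot(divergence >= 0, divergence <= 1, truncation_q >= 0, truncation_q <= 1,
            consensus_length > 0, copy_number >= 0)
  structure(list(name = name, consensus_length = as.integer(consensus_length),
                 copy_number = as.integer(copy_number), divergence = divergence,
                 truncation_q = truncation_q, truncation_extent = truncation_extent,
                 ssr_tail = ssr_tail, n_subfamilies = as.integer(n_subfamilies),
                 n_diagnostic_sites = as.integer(n_diagnostic_sites),
                 te_class = te_class),
            class = "te_family_config")
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale genome that preserves the statistical
#' structure of a squamate repeat landscape: ~44% GC background, LINE
#' families at modest copy number, 30x shotgun coverage of 150 bp reads at a
#' 1% per-base error rate.
#'
#' @param seed Integer seed; every downstream draw is deterministic given it.
#' @param genome_length Total genome length (bp).
#' @param gc_fraction Background GC content.
#' @param te_families List of [te_family_config()] objects.
#' @param background_ssr Optional `data.frame(motif, n_units, count)` of
#'   standalone SSR loci to plant.
#' @param read_length,read_depth,read_error_rate Shotgun read parameters.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, genome_length = 1e5L, gc_fraction = 0.44,
                              te_families = list(), background_ssr = NULL,
                              read_length = 150L, read_depth = 30,
                              read_error_rate = 0.01) {
  stopifnot(gc_fraction >= 0, gc_fraction <= 1, genome_length > 0)
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, te_families = te_families,
                 background_ssr = background_ssr, read_length = as.integer(read_length),
                 read_depth = read_depth, read_error_rate = read_error_rate),
            class = "simulation_config")
}

# Build one copy of a family from its consensus machinery. Returns the copy
# sequence (5'->3' of the element, tail included) plus truth fields.
.make_copy <- function(fam, consensus_chars, diag_sites, diag_bases) {
  L <- length(consensus_chars)
  sub_id <- sample.int(fam$n_subfamilies, 1L)
  chars <- consensus_chars
  if (length(diag_sites))
    chars[diag_sites] <- diag_bases[[sub_id]]
  non_diag <- setdiff(seq_len(L), diag_sites)
  n_mut <- stats::rbinom(1L, length(non_diag), fam$divergence)
  chars <- .mutate_sites(chars, sample(non_diag, n_mut))
  truncated <- stats::runif(1L) < fam$truncation_q
  cut <- if (truncated) floor(L * fam$truncation_extent) else 0L
  body <- chars[(cut + 1L):L]
  tail_len <- 0L
  if (!is.null(fam$ssr_tail)) {
    tail_seq <- strrep(fam$ssr_tail$motif, fam$ssr_tail$n_units)
    tail_len <- nchar(tail_seq)
    body <- c(body, strsplit(tail_seq, "", fixed = TRUE)[[1]])
  }
  list(seq = paste(body, collapse = ""), truncated = truncated,
       cut = cut, subfamily = sub_id, tail_len = tail_len,
       tail_motif = if (is.null(fam$ssr_tail)) NA_character_ else fam$ssr_tail$motif)
}

#' Simulate a genome with planted repeats and a truth table
#'
#' The background is i.i.d. with the configured GC. Each TE family gets a
#' random consensus; copies diverge from it at the configured rate, share
#' fixed diagnostic differences within subfamilies, lose their 5' prefix
#' with probability `truncation_q`, and carry a perfect SSR tail at their 3'
#' end when configured. Standalone SSR loci and TE copies are placed
#' uniformly without overlap (rejection sampling, 100x placement budget);
#' each insertion replaces background bases so genome length is preserved.
#' Inserted elements are reverse-complemented on the `-` strand.
#'
#' @param config A [simulation_config()].
#' @return List: `genome` (single-contig assembly), `truth` (list with
#'   `te_insertions`, `ssr_loci`, `consensus` per family, `diagnostic_sites`
#'   per family, `per_family_bp`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  G <- config$genome_length
  genome_chars <- strsplit(.random_dna(G, config$gc_fraction), "", fixed = TRUE)[[1]]

  consensi <- list(); diag_sites <- list(); diag_bases <- list()
  pieces <- list()   # things to place: list(seq, kind, family, ...)
  for (fam in config$te_families) {
    cons <- strsplit(.random_dna(fam$consensus_length, 0.5), "", fixed = TRUE)[[1]]
    consensi[[fam$name]] <- paste(cons, collapse = "")
    ds <- integer(0); db <- NULL
    if (fam$n_subfamilies > 1L && fam$n_diagnostic_sites > 0L) {
      ds <- sort(sample.int(fam$consensus_length, fam$n_diagnostic_sites))
      db <- lapply(seq_len(fam$n_subfamilies), function(s) {
        if (s == 1L) cons[ds] else .mutate_sites(cons, ds)[ds]
      })
    }
    diag_sites[[fam$name]] <- ds
    diag_bases[[fam$name]] <- db
    for (ci in seq_len(fam$copy_number)) {
      cp <- .make_copy(fam, cons, ds, db)
      pieces[[length(pieces) + 1L]] <- c(cp, list(kind = "te", family = fam$name,
                                                  te_class = fam$te_class))
    }
  }
  if (!is.null(config$background_ssr)) {
    for (i in seq_len(nrow(config$background_ssr))) {
      row <- config$background_ssr[i, ]
      for (j in seq_len(row$count)) {
        pieces[[length(pieces) + 1L]] <- list(
          seq = strrep(row$motif, row$n_units), kind = "ssr",
          family = row$motif, truncated = FALSE, cut = 0L,
          subfamily = NA_integer_, tail_len = 0L, tail_motif = NA_character_,
          te_class = NA_character_)
      }
    }
  }
  total_planted <- sum(vapply(pieces, function(p) nchar(p$seq), 0))
  if (total_planted >= G) stop("planted bases exceed genome length")

  # non-overlapping placement by rejection sampling
  occupied <- logical(G)
  te_rows <- list(); ssr_rows <- list()
  budget <- 100L * length(pieces)
  tries <- 0L
  for (p in pieces) {
    w <- nchar(p$seq)
    repeat {
      tries <- tries + 1L
      if (tries > budget)
        stop("could not place planted features without overlap within budget")
      s0 <- sample.int(G - w + 1L, 1L) - 1L   # 0-based start
      span <- (s0 + 1L):(s0 + w)
      if (!any(occupied[span])) break
    }
    occupied[span] <- TRUE
    strand <- if (p$kind == "te" && stats::runif(1L) < 0.5) "-" else "+"
    ins <- if (strand == "-") revcomp(p$seq) else p$seq
    genome_chars[span] <- strsplit(ins, "", fixed = TRUE)[[1]]
    if (p$kind == "te") {
      body_len <- w - p$tail_len
      tail_iv <- if (p$tail_len > 0L) {
        if (strand == "+") c(s0 + body_len, s0 + w) else c(s0, s0 + p$tail_len)
      } else c(NA_integer_, NA_integer_)
      te_rows[[length(te_rows) + 1L]] <- data.frame(
        family = p$family, te_class = p$te_class, contig = "chr1",
        start = if (strand == "+") s0 else s0 + p$tail_len,
        end = if (strand == "+") s0 + body_len else s0 + w,
        strand = strand, truncated = p$truncated, cut_5p = p$cut,
        subfamily = p$subfamily,
        tail_start = tail_iv[1L], tail_end = tail_iv[2L],
        tail_motif = p$tail_motif,
        stringsAsFactors = FALSE)
    } else {
      ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
        contig = "chr1", start = s0, end = s0 + w, motif = p$family,
        n_units = w %/% nchar(p$family), stringsAsFactors = FALSE)
    }
  }
  te_df <- if (length(te_rows)) do.call(rbind, te_rows) else
    data.frame(family = character(), te_class = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               truncated = logical(), cut_5p = integer(), subfamily = integer(),
               tail_start = integer(), tail_end = integer(),
               tail_motif = character(), stringsAsFactors = FALSE)
  ssr_df <- if (length(ssr_rows)) do.call(rbind, ssr_rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               motif = character(), n_units = integer(), stringsAsFactors = FALSE)
  # keep planted SSR arrays exactly as planted: if a flanking background base
  # happens to continue the repeat period, the scanner would (correctly)
  # report a longer array; break the period just outside each planted array
  break_period <- function(gc, start0, end0, k) {
    p <- start0                      # 0-based position before the array
    if (p >= 1L && !occupied[p] && gc[p] == gc[p + k]) {
      cand <- setdiff(c("A", "C", "G", "T"), c(gc[p + k], gc[p]))
      gc[p] <- cand[1L]
    }
    q <- end0 + 1L                   # 1-based position just after the array
    if (q <= length(gc) && !occupied[q] && gc[q] == gc[q - k]) {
      cand <- setdiff(c("A", "C", "G", "T"), c(gc[q - k], gc[q]))
      gc[q] <- cand[1L]
    }
    gc
  }
  if (nrow(ssr_df)) for (i in seq_len(nrow(ssr_df)))
    genome_chars <- break_period(genome_chars, ssr_df$start[i], ssr_df$end[i],
                                 nchar(ssr_df$motif[i]))
  tails <- te_df[!is.na(te_df$tail_start), , drop = FALSE]
  if (nrow(tails)) for (i in seq_len(nrow(tails)))
    genome_chars <- break_period(genome_chars, tails$tail_start[i],
                                 tails$tail_end[i], nchar(tails$tail_motif[i]))
  per_family_bp <- if (nrow(te_df)) tapply(te_df$end - te_df$start, te_df$family, sum)
    else integer(0)
  genome <- as_genome_assembly(stats::setNames(paste(genome_chars, collapse = ""), "chr1"))
  list(genome = genome,
       truth = list(te_insertions = te_df, ssr_loci = ssr_df,
                    consensus = consensi, diagnostic_sites = diag_sites,
                    per_family_bp = per_family_bp,
                    config = config))
}

#' Planted TE insertions as an annotation table
#'
#' Converts a truth table to the annotation `data.frame` the analysis
#' functions consume (the role RepeatMasker output plays on real data). SSR
#' tails of TE copies are annotated as `Simple_repeat` rows so they can be
#' excluded from TE content like real simple-repeat annotations.
#'
#' @param truth The `truth` element of [simulate_genome()] output.
#' @param include_tails Annotate tail intervals as `Simple_repeat` rows?
#' @return Annotation `data.frame` (`contig`, `start`, `end`, `strand`,
#'   `family`, `te_class`).
#' @export
truth_annotations <- function(truth, include_tails = TRUE) {
  te <- truth$te_insertions
  out <- te[, c("contig", "start", "end", "strand", "family", "te_class")]
  if (include_tails && any(!is.na(te$tail_start))) {
    tl <- te[!is.na(te$tail_start), , drop = FALSE]
    out <- rbind(out, data.frame(contig = tl$contig, start = tl$tail_start,
                                 end = tl$tail_end, strand = tl$strand,
                                 family = paste0("(", tl$tail_motif, ")n"),
                                 te_class = "Simple_repeat",
                                 stringsAsFactors = FALSE))
  }
  ssr <- truth$ssr_loci
  if (nrow(ssr))
    out <- rbind(out, data.frame(contig = ssr$contig, start = ssr$start,
                                 end = ssr$end, strand = "+",
                                 family = ssr$motif, te_class = "Simple_repeat",
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Simulate uniform shotgun reads from a genome
#'
#' Read start positions are uniform over placeable positions (contigs
#' weighted by length), strands equiprobable, and each base substituted
#' independently at `error_rate`.
#'
#' @param genome Genome assembly.
#' @param depth Expected mean depth; `n_reads = round(depth * G /
#'   read_length)`.
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Named character vector of reads with attribute `"truth"`
#'   (`data.frame`: `contig`, `start` 0-based, `strand`).
#' @export
simulate_reads <- function(genome, depth = 30, read_length = 150L,
                           error_rate = 0.01, seed = 1L) {
  set.seed(as.integer(seed))
  lens <- contig_lengths(genome)
  if (any(lens < read_length)) stop("read_length exceeds a contig length")
  G <- sum(lens)
  n_reads <- max(1L, as.integer(round(depth * G / read_length)))
  room <- lens - read_length + 1L
  ci <- sample.int(length(lens), n_reads, replace = TRUE, prob = room)
  s0 <- vapply(room[ci], function(r) sample.int(r, 1L), 1L) - 1L
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(unclass(genome)[ci], s0 + 1L, s0 + read_length)
  flip <- strand == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  if (error_rate > 0) {
    n_err <- stats::rbinom(n_reads, read_length, error_rate)
    for (i in which(n_err > 0L)) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      chars <- .mutate_sites(chars, sample.int(read_length, n_err[i]))
      seqs[i] <- paste(chars, collapse = "")
    }
  }
  names(seqs) <- sprintf("read%06d", seq_len(n_reads))
  attr(seqs, "truth") <- data.frame(contig = names(lens)[ci], start = s0,
                                    strand = strand, stringsAsFactors = FALSE)
  seqs
}

#' Simulate reads from the copies of one planted family
#'
#' Convenience wrapper for consensus/coverage/divergence tests: extracts the
#' planted copies of `family` from the genome (reoriented 5'->3' of the
#' element, without the SSR tail) and shotgun-samples reads from them so
#' that every read originates in the family.
#'
#' @param sim Output of [simulate_genome()].
#' @param family Family name.
#' @inheritParams simulate_reads
#' @return Named character vector of reads.
#' @export
simulate_family_reads <- function(sim, family, depth = 30, read_length = 150L,
                                  error_rate = 0.01, seed = 1L) {
  te <- sim$truth$te_insertions
  te <- te[te$family == family, , drop = FALSE]
  if (!nrow(te)) stop("no planted copies of ", family)
  g <- unclass(sim$genome)
  copies <- vapply(seq_len(nrow(te)), function(i) {
    s <- substring(g[[te$contig[i]]], te$start[i] + 1L, te$end[i])
    if (te$strand[i] == "-") revcomp(s) else s
  }, "")
  names(copies) <- sprintf("%s_copy%03d", family, seq_len(nrow(te)))
  keep <- nchar(copies) >= read_length
  simulate_reads(as_genome_assembly(copies[keep]), depth = depth,
                 read_length = read_length, error_rate = error_rate, seed = seed)
}
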