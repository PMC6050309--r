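# Species-specific LINE consensus building from shotgun reads: ungapped
# seed-and-extend mapping to a starting reference (the consensus of the most
# closely related species), majority-rule consensus, and iterative re-mapping
# until no additional reads are recovered. Coverage masks: < 10x from the
# second iteration, < 20x at the final pass.
#
# The internal mapper is ungapped; synthetic data is indel-free so this is
# exact there, and externally produced alignments can be fed to
# majority_consensus()/coverage_profile() for gapped real data.

.BASE4 <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# kmer index of a reference: list mapping kmer string -> integer start
# positions (1-based). Kmers containing N are skipped.
.kmer_index <- function(reference, k) {
  L <- nchar(reference)
  if (L < k) return(list())
  starts <- seq_len(L - k + 1L)
  kmers <- substring(reference, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  split(starts[keep], kmers[keep])
}

#' Map reads to a reference by ungapped seed-and-extend
#'
#' Exact k-mer seeds (both strands) anchor candidate ungapped placements;
#' each candidate is scored by mismatches over the read/reference overlap and
#' the best placement per read is kept if its mismatch rate is at most
#' `max_mismatch_rate`. Ties go to fewer mismatches, then the leftmost
#' reference start, then the forward orientation.
#'
#' @param reads Named character vector of reads.
#' @param reference Reference sequence (single string); masked positions may
#'   be `N` (they seed nothing and never count as matches).
#' @param k Seed length (default 17).
#' @param max_mismatch_rate Maximum mismatches / overlap (default 0.2).
#' @param seed_step Distance between seed start positions along the read
#'   (default `max(1, floor(k/2))`).
#' @param min_overlap Minimum read/reference overlap for a valid placement.
#' @return List with `alignments` (`data.frame`: `read_id`, `ref_start`
#'   0-based, possibly negative when the read overhangs the 5' end,
#'   `orientation`, `n_mismatches`, `overlap`, `seq` oriented to the
#'   reference) and `unmapped` (read names).
#' @export
map_reads <- function(reads, reference, k = 17L, max_mismatch_rate = 0.2,
                      seed_step = NULL, min_overlap = NULL) {
  L <- nchar(reference)
  if (L < k) stop("reference shorter than seed length")
  if (is.null(seed_step)) seed_step <- max(1L, k %/% 2L)
  if (is.null(min_overlap)) min_overlap <- k
  idx <- .kmer_index(reference, k)
  idx_names <- names(idx)
  ref_int <- utf8ToInt(reference)
  ref_int[ref_int == 78L] <- 0L          # 'N' never matches anything
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  rls <- nchar(reads)
  n <- length(reads)
  empty <- data.frame(read_id = character(), ref_start = integer(),
                      orientation = character(), n_mismatches = integer(),
                      overlap = integer(), seq = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(list(alignments = empty, unmapped = character(0)))
  rl <- rls[1L]
  if (any(rls != rl))
    stop("map_reads requires equal-length reads; split the input by length")
  seqs_fwd <- unname(reads)
  seqs_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs_fwd)))
  seed_starts <- unique(c(seq(1L, max(1L, rl - k + 1L), by = seed_step),
                          max(1L, rl - k + 1L)))
  seed_starts <- seed_starts[seed_starts + k - 1L <= rl]

  # candidate (read, orientation, offset) triples from exact seed hits
  gather <- function(seqs, orient) {
    cand_r <- list(); cand_o <- list()
    for (s0 in seed_starts) {
      km <- substring(seqs, s0, s0 + k - 1L)
      mi <- match(km, idx_names)
      hit <- which(!is.na(mi))
      if (!length(hit)) next
      pos <- idx[mi[hit]]
      nh <- lengths(pos)
      cand_r[[length(cand_r) + 1L]] <- rep(hit, nh)
      cand_o[[length(cand_o) + 1L]] <- unlist(pos, use.names = FALSE) - s0
    }
    if (!length(cand_r)) return(NULL)
    cand_r <- unlist(cand_r); cand_o <- unlist(cand_o)
    keep <- !duplicated(cand_r * (L + rl + 1) + cand_o)
    data.frame(read = cand_r[keep], off = cand_o[keep],
               orient = orient, stringsAsFactors = FALSE)
  }
  cand <- rbind(gather(seqs_fwd, "+"), gather(seqs_rev, "-"))
  if (is.null(cand) || !nrow(cand))
    return(list(alignments = empty, unmapped = names(reads)))

  int_fwd <- .read_int_matrix(seqs_fwd)  # rl x n
  int_rev <- .read_int_matrix(seqs_rev)
  mm <- integer(nrow(cand)); ov <- integer(nrow(cand))
  inb <- which(cand$off >= 0L & cand$off + rl <= L)
  # fully contained placements: vectorized in chunks
  if (length(inb)) for (chunk in split(inb, ceiling(seq_along(inb) / 50000L))) {
    pm <- outer(cand$off[chunk], seq_len(rl), "+")      # ncand x rl, 1-based ref pos
    rv <- matrix(ref_int[pm], nrow = length(chunk))
    use_rev <- cand$orient[chunk] == "-"
    qv <- t(int_fwd[, cand$read[chunk], drop = FALSE])
    if (any(use_rev)) qv[use_rev, ] <- t(int_rev[, cand$read[chunk][use_rev], drop = FALSE])
    mm[chunk] <- as.integer(rowSums(qv != rv))
    ov[chunk] <- rl
  }
  # overhanging placements: small scalar loop
  outb <- setdiff(seq_len(nrow(cand)), inb)
  for (i in outb) {
    off0 <- cand$off[i]
    a <- max(0L, off0); b <- min(L, off0 + rl)
    ov[i] <- b - a
    if (ov[i] < min_overlap) { mm[i] <- NA_integer_; next }
    qint <- if (cand$orient[i] == "+") int_fwd[, cand$read[i]] else int_rev[, cand$read[i]]
    mm[i] <- sum(qint[(a - off0 + 1L):(b - off0)] != ref_int[(a + 1L):b])
  }
  valid <- !is.na(mm) & ov >= min_overlap & mm / ov <= max_mismatch_rate
  cand <- cand[valid, , drop = FALSE]
  mm <- mm[valid]; ov <- ov[valid]
  if (!nrow(cand)) return(list(alignments = empty, unmapped = names(reads)))
  o <- order(cand$read, mm, cand$off, cand$orient != "+")
  first <- o[!duplicated(cand$read[o])]
  best <- cand[first, , drop = FALSE]
  alignments <- data.frame(
    read_id = names(reads)[best$read],
    ref_start = best$off,
    orientation = best$orient,
    n_mismatches = mm[first],
    overlap = ov[first],
    seq = ifelse(best$orient == "+", seqs_fwd[best$read], seqs_rev[best$read]),
    stringsAsFactors = FALSE)
  alignments <- alignments[order(best$read), , drop = FALSE]
  rownames(alignments) <- NULL
  list(alignments = alignments,
       unmapped = setdiff(names(reads), alignments$read_id))
}

# Integer matrix (read_length x n_reads) of equal-length sequences; N -> -1
# so it never equals a reference value (reference N is coded 0).
.read_int_matrix <- function(seqs) {
  if (!length(seqs)) return(matrix(integer(0), nrow = 0L))
  v <- utf8ToInt(paste(seqs, collapse = ""))
  v[v == 78L] <- -1L
  matrix(v, nrow = nchar(seqs[1L]))
}

# Pileup counts: 4 x L matrix of base counts per reference position.
.pileup_counts <- function(alignments, reference_length) {
  L <- reference_length
  m <- matrix(0L, nrow = 4L, ncol = L)
  if (!nrow(alignments)) return(m)
  rls <- nchar(alignments$seq)
  rl <- rls[1L]
  full <- rls == rl & alignments$ref_start >= 0L & alignments$ref_start + rls <= L
  if (any(full)) {
    qm <- .read_int_matrix(alignments$seq[full])           # rl x nfull
    bidx <- match(as.integer(qm), c(65L, 67L, 71L, 84L))   # A C G T
    posm <- outer(seq_len(rl), alignments$ref_start[full], "+")  # 1-based ref pos
    keep <- !is.na(bidx)
    tab <- tabulate((as.integer(posm)[keep] - 1L) * 4L + bidx[keep], nbins = 4L * L)
    m[] <- m + tab
  }
  for (i in which(!full)) {
    off0 <- alignments$ref_start[i]
    qint <- utf8ToInt(alignments$seq[i])
    a <- max(0L, off0); b <- min(L, off0 + length(qint))
    if (b <= a) next
    rp <- (a + 1L):b
    bb <- match(qint[(a - off0 + 1L):(b - off0)], c(65L, 67L, 71L, 84L))
    keep <- !is.na(bb)
    if (any(keep))
      m[] <- m + tabulate((rp[keep] - 1L) * 4L + bb[keep], nbins = 4L * L)
  }
  m
}

#' Majority-rule consensus from read alignments
#'
#' Per position, the most frequent base among covering reads; ties prefer the
#' previous consensus base (avoiding oscillation between iterations), then
#' alphabetical order. Positions with depth below `depth_threshold` are
#' masked.
#'
#' @param alignments Alignment `data.frame` from [map_reads()].
#' @param reference_length Consensus length.
#' @param depth_threshold Minimum depth; below it a position is masked
#'   (`N` in the sequence, `TRUE` in `masked`).
#' @param prev_consensus Optional previous consensus string for tie-breaking.
#' @return Object of class `"consensus_model"`: list with `sequence` (masked
#'   positions as `N`), `bases` (unmasked majority calls), `masked` (logical),
#'   `depth` (integer per position), `n_reads_mapped`, `iteration`.
#' @export
majority_consensus <- function(alignments, reference_length, depth_threshold = 0L,
                               prev_consensus = NULL) {
  if (!nrow(alignments)) stop("no mapped reads")
  L <- reference_length
  m <- .pileup_counts(alignments, L)
  depth <- colSums(m)
  top <- apply(m, 2L, max)
  pick <- max.col(t(m), ties.method = "first")  # alphabetical tie-break
  if (!is.null(prev_consensus)) {
    pc <- .BASE4[strsplit(prev_consensus, "", fixed = TRUE)[[1]]]
    use_prev <- !is.na(pc) & m[cbind(pc, seq_len(L))] == top & depth > 0L
    pick[use_prev] <- pc[use_prev]
  }
  bases <- names(.BASE4)[pick]
  bases[depth == 0L] <- "N"
  masked <- depth < depth_threshold
  seq_out <- bases
  seq_out[masked] <- "N"
  structure(list(sequence = paste(seq_out, collapse = ""),
                 bases = paste(bases, collapse = ""),
                 masked = masked, depth = as.integer(depth),
                 n_reads_mapped = nrow(alignments), iteration = NA_integer_),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus model: %d bp, %d reads mapped, %d masked position(s)%s\n",
              nchar(x$sequence), x$n_reads_mapped, sum(x$masked),
              if (!is.na(x$iteration)) sprintf(", iteration %d", x$iteration) else ""))
  invisible(x)
}

#' Iteratively build a LINE consensus from reads
#'
#' Repeats map -> majority consensus, each round using the new consensus as
#' the mapping reference, until the mapped-read count stops increasing (or
#' the consensus is unchanged, or `max_iter` is reached). Coverage masking
#' follows the <10x-after-second-iteration / <20x-final rule.
#'
#' @param reads Named character vector of reads.
#' @param initial_reference Starting reference (typically the consensus of
#'   the most closely related species).
#' @param k,max_mismatch_rate Passed to [map_reads()].
#' @param depth_mid Mask threshold from the second iteration on (default 10).
#' @param depth_final Mask threshold for the final consensus (default 20).
#' @param max_iter Iteration cap (default 10); hitting it returns the best
#'   model with a warning.
#' @param count_rule `"count"` stops when the mapped-read count does not
#'   increase; `"distinct"` stops when no previously unmapped read id maps.
#' @return A `"consensus_model"` with `iteration` set and an
#'   `n_reads_history` element.
#' @export
build_consensus_iterative <- function(reads, initial_reference, k = 17L,
                                      max_mismatch_rate = 0.2,
                                      depth_mid = 10L, depth_final = 20L,
                                      max_iter = 10L,
                                      count_rule = c("count", "distinct")) {
  count_rule <- match.arg(count_rule)
  stopifnot(nchar(initial_reference) > 0L)
  ref <- toupper(initial_reference)
  prev_model <- NULL
  prev_ids <- character(0)
  history <- integer(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mp <- map_reads(reads, ref, k = k, max_mismatch_rate = max_mismatch_rate)
    if (!nrow(mp$alignments)) {
      if (is.null(prev_model)) stop("no reads mapped to the initial reference")
      break
    }
    thr <- if (it >= 2L) depth_mid else 0L
    model <- majority_consensus(mp$alignments, nchar(ref), depth_threshold = thr,
                                prev_consensus = ref)
    model$iteration <- it
    history <- c(history, model$n_reads_mapped)
    new_ids <- mp$alignments$read_id
    no_gain <- if (count_rule == "count") {
      !is.null(prev_model) && model$n_reads_mapped <= prev_model$n_reads_mapped
    } else {
      !is.null(prev_model) && length(setdiff(new_ids, prev_ids)) == 0L
    }
    same_seq <- !is.null(prev_model) && identical(model$bases, prev_model$bases)
    prev_model <- model
    prev_ids <- union(prev_ids, new_ids)
    final_alignments <- mp$alignments
    if (no_gain || same_seq) { converged <- TRUE; break }
    # remap against the unmasked majority calls: masking is a reporting-level
    # filter, and an N-masked reference would shed edge reads and break the
    # monotone growth of the mapped-read count
    ref <- model$bases
  }
  if (!converged)
    warning("consensus did not converge within ", max_iter, " iterations")
  final <- majority_consensus(final_alignments, nchar(prev_model$bases),
                              depth_threshold = depth_final,
                              prev_consensus = prev_model$bases)
  final$iteration <- prev_model$iteration
  final$n_reads_history <- history
  final$alignments <- final_alignments
  final
}

#' Write a consensus model to FASTA with soft-masked positions
#'
#' Masked positions are written lowercase; a companion BED of masked spans is
#' written when `bed` is given.
#'
#' @param model A `"consensus_model"`.
#' @param path Output FASTA path.
#' @param name Sequence name.
#' @param bed Optional path for a BED file of masked spans.
#' @export
write_consensus <- function(model, path, name = "consensus", bed = NULL) {
  chars <- strsplit(model$bases, "", fixed = TRUE)[[1]]
  chars[model$masked] <- tolower(chars[model$masked])
  write_fasta(stats::setNames(paste(chars, collapse = ""), name), path)
  if (!is.null(bed)) {
    r <- rle(model$masked)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    sel <- r$values
    write_bed(data.frame(contig = name, start = starts[sel], end = ends[sel],
                         family = "masked"), bed)
  }
  invisible(path)
}
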