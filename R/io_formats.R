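# Readers/writers for the external formats the pipeline touches.
# Internal convention: all coordinates are 0-based half-open; conversion to
# and from 1-based inclusive happens only at format boundaries (RepeatMasker
# .out, BED is already half-open).

#' Read a FASTA file into a genome assembly
#'
#' Residues are uppercased and any character outside `{A,C,G,T,N}` is mapped
#' to `N`; the number of substituted characters is reported via a message.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of contig sequences (class
#'   `"genome_assembly"`), one element per header, names taken from the first
#'   whitespace-delimited token of each header.
#' @export
parse_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA format error: no records in ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (any(nm == "")) stop("FASTA format error: empty record name")
  if (anyDuplicated(nm)) stop("FASTA format error: duplicate record names")
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  n_sub <- sum(nchar(seqs)) - sum(nchar(gsub("[^ACGTN]", "", seqs)))
  if (n_sub > 0L)
    message(n_sub, " non-ACGTN residue(s) mapped to N in ", basename(path))
  as_genome_assembly(cleaned)
}

#' Construct a genome assembly from named sequences
#'
#' @param seqs Named character vector of contig sequences over `{A,C,G,T,N}`.
#' @return The same vector with class `"genome_assembly"`.
#' @export
as_genome_assembly <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) > 0L,
            !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  structure(seqs, class = "genome_assembly")
}

#' Contig lengths of an assembly
#' @param genome A genome assembly (named character vector).
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (assembly, reads or consensus).
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(unclass(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read shotgun reads from FASTA or FASTQ
#'
#' Base qualities of FASTQ input are ignored: no downstream analysis uses
#' them. Residues are uppercased; non-ACGTN characters become `N`.
#'
#' @param path Path to a FASTA or FASTQ file (plain text).
#' @param format `"auto"` sniffs the first character (`>` vs `@`).
#' @return Named character vector of reads.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readChar(path, 1L)
    format <- if (identical(first, "@")) "fastq" else "fasta"
  }
  if (format == "fasta") return(unclass(parse_fasta(path)))
  ss <- Biostrings::readBStringSet(path, format = "fastq")
  out <- gsub("[^ACGTN]", "N", toupper(as.character(ss)))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

# RepeatMasker class/family column -> (family, te_class). The class column
# looks like "LINE/CR1", "SINE/tRNA", "Simple_repeat", "Low_complexity",
# "DNA/TcMar-Tc1", "LTR/Gypsy", "Unknown".
.parse_rm_class <- function(class_col, name_col) {
  top <- sub("/.*$", "", class_col)
  te_class <- rep("other", length(top))
  te_class[top %in% c("LINE", "SINE", "LTR", "DNA")] <- top[top %in% c("LINE", "SINE", "LTR", "DNA")]
  te_class[top == "Simple_repeat"] <- "Simple_repeat"
  te_class[top == "Low_complexity"] <- "Low_complexity"
  sub_fam <- ifelse(grepl("/", class_col), sub("^[^/]*/", "", class_col), "")
  # family label: prefer an informative join of superfamily and element name,
  # e.g. class "LINE/CR1" + name "L3_Xp" -> "CR1-L3"
  family <- name_col
  cr1 <- te_class == "LINE" & sub_fam == "CR1"
  family[cr1 & grepl("L3", name_col)] <- "CR1-L3"
  family[cr1 & grepl("L2", name_col)] <- "CR1-L2"
  bovb <- te_class == "LINE" & grepl("BovB", paste(name_col, sub_fam))
  family[bovb] <- "BovB"
  rex <- te_class == "LINE" & grepl("Rex", paste(name_col, sub_fam))
  family[rex] <- "Rex"
  list(family = family, te_class = te_class)
}

#' Parse a RepeatMasker `.out` annotation file
#'
#' Targets the modern fixed-column `.out` layout: 3 header lines, then
#' whitespace-separated columns with 1-based inclusive query coordinates and
#' strand `+` or `C` (complement). Coordinates are converted to 0-based
#' half-open and `C` to `-`. Simple-repeat and low-complexity rows stay
#' separable from TE rows through `te_class`.
#'
#' @param path Path to a `.out` file.
#' @param drop_simple If `TRUE`, drop `Simple_repeat`/`Low_complexity` rows.
#' @return A `data.frame` with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`), `family`, `te_class`.
#' @export
parse_repeatmasker_out <- function(path, drop_simple = FALSE) {
  lines <- readLines(path)
  if (length(lines) > 0L && grepl("^\\s*SW|^\\s*score", lines[1]))
    lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), family = character(),
                      te_class = character(), stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "\\s+")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 11L)
  if (length(bad))
    stop("malformed RepeatMasker row at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  get <- function(i) vapply(fields, `[[`, "", i)
  begin1 <- suppressWarnings(as.integer(get(6L)))
  end1 <- suppressWarnings(as.integer(get(7L)))
  if (anyNA(begin1) || anyNA(end1))
    stop("malformed RepeatMasker coordinates at line(s): ",
         paste(which(is.na(begin1) | is.na(end1)), collapse = ", "))
  strand <- ifelse(get(9L) == "C", "-", "+")
  parsed <- .parse_rm_class(get(11L), get(10L))
  out <- data.frame(contig = get(5L),
                    start = begin1 - 1L, end = end1,
                    strand = strand,
                    family = parsed$family, te_class = parsed$te_class,
                    stringsAsFactors = FALSE)
  if (any(out$start < 0L | out$start >= out$end))
    stop("invalid coordinates after conversion (begin must be >= 1 and <= end)")
  if (drop_simple)
    out <- out[!out$te_class %in% c("Simple_repeat", "Low_complexity"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write annotations as a RepeatMasker-style `.out` file
#'
#' Inverse of [parse_repeatmasker_out()] for the fields this package models;
#' the score/divergence columns are written as zeros.
#'
#' @param annotations Annotation `data.frame` (see [parse_repeatmasker_out()]).
#' @param path Output path.
#' @param class_col Optional character vector of raw class strings; defaults
#'   to the `te_class` column.
#' @export
write_repeatmasker_out <- function(annotations, path, class_col = NULL) {
  a <- annotations
  if (is.null(class_col)) class_col <- a$te_class
  hdr <- c("   SW   perc perc perc  query     position in query    matching repeat",
           "score   div. del. ins.  sequence  begin end   (left)   repeat class/family",
           "")
  rows <- sprintf("%5d %6.1f %4.1f %4.1f  %s %d %d (0) %s %s %s",
                  0L, 0, 0, 0, a$contig, a$start + 1L, a$end,
                  ifelse(a$strand == "-", "C", "+"), a$family, class_col)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read/write BED6 intervals with a family name field
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate conversion happens.
#'
#' @param path Path to a BED file (>= 4 columns: contig, start, end, name;
#'   optional score and strand).
#' @return `data.frame` with `contig`, `start`, `end`, `family` (name field),
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED format error: need at least 3 columns")
  names(df)[1:3] <- c("contig", "start", "end")
  df$family <- if (ncol(df) >= 4L) as.character(df[[4L]]) else "."
  df$score <- if (ncol(df) >= 5L) df[[5L]] else 0
  df$strand <- if (ncol(df) >= 6L) as.character(df[[6L]]) else "+"
  df[, c("contig", "start", "end", "family", "score", "strand")]
}

#' @rdname read_bed
#' @param intervals `data.frame` with columns `contig`, `start`, `end` and
#'   optionally `family`/`name`, `score`, `strand`.
#' @export
write_bed <- function(intervals, path) {
  x <- intervals
  name <- if (!is.null(x$family)) x$family else if (!is.null(x$name)) x$name else "."
  score <- if (!is.null(x$score)) x$score else 0
  strand <- if (!is.null(x$strand)) x$strand else "+"
  utils::write.table(
    data.frame(x$contig, x$start, x$end, name, score, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Path to a Newick file containing a single rooted tree with
#'   branch lengths.
#' @return An `ape::phylo` object. Polytomies are allowed but flagged with a
#'   message (they are resolved to zero-length branches by the comparative
#'   functions).
#' @export
parse_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, got ", length(tr))
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!ape::is.binary(tr))
    message("tree contains polytomies; they will be resolved to zero-length branches")
  tr
}

#' Read a PSMC-style effective-population-size series
#'
#' Expects a two-column numeric table (time before present in years, Ne),
#' such as the per-species text output of PSMC plotting utilities. Points are
#' sorted by time. The default generation time of 3 years matches the
#' cross-species average used for squamates.
#'
#' @param path Path to a whitespace- or tab-separated two-column table.
#' @param species Species label.
#' @param generation_time Generation time in years (default 3).
#' @param mutation_rate Substitution rate per site per year (metadata only).
#' @return An object of class `"ne_series"`: list with `species`, `points`
#'   (`data.frame(time, ne)`), `generation_time`, `mutation_rate`.
#' @export
read_ne_series <- function(path, species = basename(path), generation_time = 3,
                           mutation_rate = 2.4e-9) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("Ne series must have two columns (time, Ne)")
  if (!all(vapply(df[1:2], is.numeric, TRUE))) stop("non-numeric cells in Ne series")
  ne_series(species, time = df[[1L]], ne = df[[2L]],
            generation_time = generation_time, mutation_rate = mutation_rate)
}

#' @rdname read_ne_series
#' @param time,ne Numeric vectors of time points (years BP) and Ne values.
#' @export
ne_series <- function(species, time, ne, generation_time = 3,
                      mutation_rate = 2.4e-9) {
  if (length(time) < 3L) stop("need at least 3 points to trim endpoints and take a median")
  o <- order(time)
  time <- time[o]; ne <- ne[o]
  if (anyDuplicated(time)) stop("duplicated time points in Ne series")
  if (any(ne <= 0)) stop("Ne must be positive at every point")
  structure(list(species = species,
                 points = data.frame(time = time, ne = ne),
                 generation_time = generation_time,
                 mutation_rate = mutation_rate),
            class = "ne_series")
}

#' Read a per-species trait table
#'
#' @param path TSV with a `species` column (or rownames) and numeric trait
#'   columns (repeat percentages, SSR densities, body mass, truncation ratio,
#'   median Ne, ...).
#' @return `data.frame` with species as rownames.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if ("species" %in% names(df)) {
    rownames(df) <- df$species
    df$species <- NULL
  }
  df
}

#' Reverse-complement of DNA strings
#' @param x Character vector over `{A,C,G,T,N}`.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}
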