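# Per-intron descriptors: extraction from gene models, GC content, splice
# signals, proto-splice (MAG^R) compliance, ultrasmall flags, and perfect
# simple-repeat detection.

#' Extract introns from a gene model
#'
#' One record per inter-exon gap, in transcription order. All
#' sequence-derived fields (donor/acceptor dinucleotides, flanking
#' contexts, GC) are reported in transcript orientation; genomic
#' coordinates stay on the plus reference, 1-based inclusive.
#'
#' @param model a [gene_model()] with at least one exon.
#' @param genomes named character vector of genome sequences (or a single
#'   sequence string).
#' @param ultrasmall_threshold passed to [flag_ultrasmall()].
#' @return data.frame with one row per intron: `gene_id`, `index`,
#'   `start`, `end`, `length`, `cds_offset` (coding nucleotides 5' of the
#'   insertion point), `donor2`, `acceptor2`, `upstream4` (four exonic
#'   bases before the insertion point, '.'-padded at sequence edges),
#'   `downstream4` (first four intron bases), `downstream_exon_base`
#'   (first exonic base after the intron, `NA` at the transcript end),
#'   `gc_percent`, `ultrasmall`.
#' @export
extract_introns <- function(model, genomes, ultrasmall_threshold = 60L) {
  seq <- .resolve_sequence(model, genomes)
  ex <- model$exons
  n <- nrow(ex)
  empty <- data.frame(gene_id = character(), index = integer(),
                      start = integer(), end = integer(), length = integer(),
                      cds_offset = integer(), donor2 = character(),
                      acceptor2 = character(), upstream4 = character(),
                      downstream4 = character(),
                      downstream_exon_base = character(),
                      gc_percent = numeric(), ultrasmall = logical(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  gaps <- cbind(start = ex[-n, 2L] + 1L, end = ex[-1L, 1L] - 1L)
  if (any(gaps[, 1L] > gaps[, 2L]))
    stop("gene '", model$gene_id, "': abutting exons (zero-length gap)")

  exon_seqs <- substring(seq, ex[, 1L], ex[, 2L])
  intron_seqs <- substring(seq, gaps[, 1L], gaps[, 2L])
  if (model$strand == "-") {
    exon_seqs <- rev(vapply(exon_seqs, revcomp, ""))
    intron_seqs <- rev(vapply(intron_seqs, revcomp, ""))
    gaps <- gaps[rev(seq_len(nrow(gaps))), , drop = FALSE]
  }
  # exon_seqs / intron_seqs now in transcript order & orientation
  cum <- cumsum(nchar(exon_seqs))
  rows <- lapply(seq_len(n - 1L), function(i) {
    iseq <- intron_seqs[i]
    ilen <- nchar(iseq)
    upstream <- paste(exon_seqs[seq_len(i)], collapse = "")
    up4 <- substr(upstream, nchar(upstream) - 3L, nchar(upstream))
    if (nchar(upstream) < 4L)
      up4 <- paste0(strrep(".", 4L - nchar(upstream)), upstream)
    down4 <- substr(iseq, 1L, 4L)
    if (ilen < 4L) down4 <- paste0(down4, strrep(".", 4L - ilen))
    nxt <- substr(exon_seqs[i + 1L], 1L, 1L)
    data.frame(gene_id = model$gene_id, index = i,
               start = gaps[i, 1L], end = gaps[i, 2L], length = ilen,
               cds_offset = max(cum[i] - model$codon_start_offset, 0L),
               donor2 = substr(iseq, 1L, 2L),
               acceptor2 = substr(iseq, ilen - 1L, ilen),
               upstream4 = up4, downstream4 = down4,
               downstream_exon_base = nxt,
               gc_percent = gc_content(iseq),
               ultrasmall = flag_ultrasmall(ilen, ultrasmall_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' GC content of a nucleotide string, percent
#'
#' `100 * (#G + #C) / length`, case-insensitive. N (and any other
#' non-G/C character) counts in the denominator only. Rounded to one
#' decimal, half up, matching how the field's tables print GC.
#'
#' @param seq non-empty nucleotide string.
#' @return percent in \[0, 100\], one decimal.
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("gc_content: empty sequence")
  gc <- n - nchar(gsub("[GC]", "", seq))
  round_half_up(100 * gc / n, 1L)
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Classify the terminal splice signal of an intron
#'
#' @param intron_seq intron sequence, transcript orientation, length >= 4.
#' @return list with `canonical` (TRUE iff GT...AG), `donor2`, `acceptor2`.
#' @export
splice_signal <- function(intron_seq) {
  intron_seq <- toupper(intron_seq)
  n <- nchar(intron_seq)
  if (n < 4L) stop("splice_signal: intron shorter than 4 nt")
  donor2 <- substr(intron_seq, 1L, 2L)
  acceptor2 <- substr(intron_seq, n - 1L, n)
  list(canonical = donor2 == "GT" && acceptor2 == "AG",
       donor2 = donor2, acceptor2 = acceptor2)
}

#' Proto-splice-site (MAG^R) compliance of an insertion context
#'
#' The proto-splice consensus is MAG^R: the three exonic bases 5' of the
#' insertion point match M = A/C, A, G, and the first exonic base 3' of
#' the intron matches R = A/G. R is evaluated only when that downstream
#' base is supplied.
#'
#' @param upstream4 exonic bases 5' of the insertion point (>= 3 usable
#'   bases; only the last three are scored).
#' @param intron_first4 first intron bases (carried through for reporting;
#'   not scored).
#' @param downstream_exon_base first exonic base after the intron, or NULL.
#' @return list: `upstream3`, `downstream_exon_base`, `matches_MAG`,
#'   `matches_R` (NA when no downstream base), `deviations` (subset of
#'   `c("M","A","G","R")`).
#' @export
classify_proto_splice <- function(upstream4, intron_first4 = NULL,
                                  downstream_exon_base = NULL) {
  up <- toupper(upstream4)
  if (nchar(up) < 3L) stop("classify_proto_splice: need >= 3 upstream bases")
  up3 <- substr(up, nchar(up) - 2L, nchar(up))
  if (grepl("[^ACGT]", up3))
    stop("classify_proto_splice: non-nucleotide character in '", up3, "'")
  b <- strsplit(up3, "")[[1L]]
  dev <- character()
  if (!b[1L] %in% c("A", "C")) dev <- c(dev, "M")
  if (b[2L] != "A") dev <- c(dev, "A")
  if (b[3L] != "G") dev <- c(dev, "G")
  matches_R <- NA
  if (!is.null(downstream_exon_base) && !is.na(downstream_exon_base)) {
    dbase <- toupper(downstream_exon_base)
    if (grepl("[^ACGT]", dbase))
      stop("classify_proto_splice: non-nucleotide downstream base")
    matches_R <- dbase %in% c("A", "G")
    if (!matches_R) dev <- c(dev, "R")
  }
  list(upstream3 = up3,
       downstream_exon_base = if (is.null(downstream_exon_base)) NA_character_
                              else toupper(downstream_exon_base),
       matches_MAG = !any(dev %in% c("M", "A", "G")),
       matches_R = matches_R,
       deviations = dev)
}

#' Flag ultrasmall introns
#'
#' Introns far below the minimal length for efficient vertebrate splicing.
#' The default cutoff of 60 bp flags the documented 18 and 33 bp cases
#' while passing 87 bp, the smallest ordinary intron in the reference set.
#'
#' @param length intron length in bp (>= 1).
#' @param threshold cutoff in bp; lengths strictly below are flagged.
#' @return logical.
#' @export
flag_ultrasmall <- function(length, threshold = 60L) {
  if (any(length < 1L)) stop("flag_ultrasmall: length must be >= 1")
  length < threshold
}

#' Find perfect simple (tandem) repeats
#'
#' Detects maximal perfect tandem runs of units of 1-6 nt. A maximal
#' period-u run is trimmed at its 5' end to a whole number of copies, so
#' every reported interval starts on a unit boundary and `copies` is an
#' integer. Units are primitive (not themselves a repeat of a shorter
#' unit). Overlapping runs are resolved longest-run-wins (ties: earlier
#' start, then shorter unit). Coordinates are 1-based within `seq`.
#'
#' @param seq nucleotide string.
#' @param max_unit maximum unit length.
#' @param min_total minimum run length in bp.
#' @param min_copies minimum number of copies.
#' @return data.frame: `unit`, `start`, `end`, `length`, `copies`.
#' @export
find_simple_repeats <- function(seq, max_unit = 6L, min_total = 12L,
                                min_copies = 3L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("find_simple_repeats: empty sequence")
  empty <- data.frame(unit = character(), start = integer(), end = integer(),
                      length = integer(), copies = numeric(),
                      stringsAsFactors = FALSE)
  if (n < min_total) return(empty)
  chars <- strsplit(seq, "")[[1L]]
  cand <- list()
  for (u in seq_len(min(max_unit, n - 1L))) {
    eq <- chars[(u + 1L):n] == chars[seq_len(n - u)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_start <- starts[k]          # index into eq
      run_len <- r$lengths[k] + u     # bases covered: run_start..run_start+run_len-1
      # trim the 5' remainder so the interval holds whole copies
      trim <- run_len %% u
      s <- run_start + trim
      e <- run_start + run_len - 1L
      len <- e - s + 1L
      copies <- len %/% u
      if (len < min_total || copies < min_copies) next
      unit <- substr(seq, s, s + u - 1L)
      if (!.is_primitive(unit)) next
      cand[[length(cand) + 1L]] <-
        data.frame(unit = unit, start = s, end = e, length = len,
                   copies = as.numeric(copies), stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$length, cand$start, nchar(cand$unit)), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(covered[span])) {
      keep[i] <- TRUE
      covered[span] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# a unit is primitive iff it is not a whole-number repeat of a shorter unit
.is_primitive <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L && unit == strrep(substr(unit, 1L, p), u / p))
      return(FALSE)
  }
  TRUE
}

#' Read a pre-computed repeat annotation table
#'
#' Complex repetitive elements (SINE/LINE/DNA transposons, ...) come from
#' external annotation, not from this package. Expected columns:
#' `species`, `gene`, `position_label`, `type`, `class`, `direction`
#' (d = direct, c = complementary), `from`, `to`. Rows whose interval
#' extends past a supplied intron length are kept with a warning.
#'
#' @param tsv_file path.
#' @param intron_lengths optional named numeric vector
#'   (`species|gene|position_label` -> length) for range checking.
#' @return data.frame of annotations.
#' @export
read_repeat_annotation <- function(tsv_file, intron_lengths = NULL) {
  tab <- utils::read.delim(tsv_file, stringsAsFactors = FALSE,
                           na.strings = c("NA", "."))
  need <- c("species", "gene", "position_label", "type", "direction",
            "from", "to")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("repeat annotation lacks column(s): ",
         paste(missing, collapse = ", "))
  bad_dir <- !is.na(tab$direction) & !tab$direction %in% c("d", "c")
  if (any(bad_dir)) stop("direction must be 'd' or 'c'")
  if (!is.null(intron_lengths)) {
    key <- paste(tab$species, tab$gene, tab$position_label, sep = "|")
    len <- intron_lengths[key]
    over <- !is.na(len) & !is.na(tab$to) & tab$to > len
    if (any(over))
      warning("repeat interval(s) beyond the stated intron length: ",
              paste(key[over], collapse = ", "), call. = FALSE)
  }
  tab
}
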