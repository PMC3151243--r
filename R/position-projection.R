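# Insertion-point arithmetic and projection: CDS offset -> codon + phase
# letter, then query codon -> reference-protein numbering through a
# protein alignment. Labels look like "41a" / "140c", with a taxon suffix
# ("225c-TRU") when the reference has a gap at the insertion column and
# query-local numbering is the fallback.

#' Codon index and phase letter of a CDS offset
#'
#' Phase letters follow the a/b/c convention: an intron sitting after the
#' first, second, or third base of codon k is labelled ka, kb, kc. Phase c
#' therefore falls between codons k and k+1.
#'
#' @param cds_offset coding nucleotides 5' of the insertion point (>= 0).
#' @return list with `codon` (integer, NA for offset 0) and `phase`
#'   (`"a"`, `"b"`, `"c"`, or `"5'UTR"` for offset 0).
#' @export
assign_phase <- function(cds_offset) {
  stopifnot(length(cds_offset) == 1L, cds_offset >= 0)
  cds_offset <- as.integer(cds_offset)
  if (cds_offset == 0L) return(list(codon = NA_integer_, phase = "5'UTR"))
  r <- cds_offset %% 3L
  list(codon = as.integer(ceiling(cds_offset / 3)),
       phase = c("c", "a", "b")[r + 1L])
}

#' Standard 0/1/2 phase of a phase letter
#'
#' Letter a = phase 1 (after the first base), b = phase 2, c = phase 0
#' (between codons), matching the usual intron-phase convention.
#'
#' @param phase_letter `"a"`, `"b"`, or `"c"`.
#' @return integer 0, 1 or 2.
#' @export
as_standard_phase <- function(phase_letter) {
  unname(c(a = 1L, b = 2L, c = 0L)[phase_letter])
}

#' Construct a position label
#'
#' @param residue positive integer residue index.
#' @param phase phase letter `"a"`, `"b"`, or `"c"`.
#' @param reference_id id of the numbering frame (the reference protein
#'   when `native`, the query otherwise).
#' @param native FALSE when reference numbering was unavailable and the
#'   label is in query-local numbering.
#' @return class `position_label`.
#' @export
position_label <- function(residue, phase, reference_id = NA_character_,
                           native = TRUE) {
  stopifnot(residue >= 1L, phase %in% c("a", "b", "c"))
  structure(list(residue = as.integer(residue), phase = phase,
                 reference_id = reference_id, native = native),
            class = "position_label")
}

#' @export
format.position_label <- function(x, ...) {
  base <- paste0(x$residue, x$phase)
  if (isTRUE(x$native) || is.na(x$reference_id)) base
  else paste0(base, "-", x$reference_id)
}

#' @export
print.position_label <- function(x, ...) {
  cat("<position_label>", format(x),
      if (!isTRUE(x$native)) "(query-local numbering)", "\n")
  invisible(x)
}

#' Parse a position label string
#'
#' @param label e.g. `"41a"`, `"140c"`, `"225c-TRU"`.
#' @return class `position_label`.
#' @export
parse_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)([abc])(?:-([A-Za-z0-9_.]+))?$",
                                 label))[[1L]]
  if (!length(m)) stop("malformed position label: '", label, "'")
  position_label(as.integer(m[2L]), m[3L],
                 reference_id = if (nzchar(m[4L])) m[4L] else NA_character_,
                 native = !nzchar(m[4L]))
}

#' CDS offset encoded by a position label
#'
#' Inverse of [assign_phase()], in the numbering frame of the label:
#' a -> 3(residue-1)+1, b -> 3(residue-1)+2, c -> 3*residue.
#'
#' @param label a `position_label` or a label string.
#' @return integer CDS offset.
#' @export
label_to_offset <- function(label) {
  if (is.character(label)) label <- parse_label(label)
  r <- label$residue
  switch(label$phase,
         a = 3L * (r - 1L) + 1L,
         b = 3L * (r - 1L) + 2L,
         c = 3L * r)
}

#' Project a query codon index onto reference-protein numbering
#'
#' Finds the alignment column holding residue `codon_index` of the query
#' row. If the reference row has a residue in that column the label is the
#' reference's ungapped index there (`native = TRUE`). If the reference
#' has a gap, snapping to a neighbouring residue would merge
#' non-homologous positions, so the label falls back to query-local
#' numbering with the query id as suffix (`native = FALSE`).
#'
#' @param codon_index residue index in the ungapped query (>= 1).
#' @param query_id,reference_id row names in `alignment`.
#' @param alignment a [protein_alignment()].
#' @param phase optional phase letter carried through unchanged.
#' @return class `position_label`.
#' @export
project_to_reference <- function(codon_index, query_id, alignment,
                                 reference_id, phase = "c") {
  for (id in c(query_id, reference_id))
    if (!id %in% names(alignment))
      stop("row '", id, "' not present in the alignment")
  q <- strsplit(unclass(alignment)[[query_id]], "")[[1L]]
  r <- strsplit(unclass(alignment)[[reference_id]], "")[[1L]]
  qres <- cumsum(q != "-")
  if (codon_index > qres[length(qres)])
    stop("codon ", codon_index, " beyond ungapped length of '", query_id, "'")
  col <- which(q != "-" & qres == codon_index)[1L]
  if (r[col] != "-") {
    position_label(sum(r[seq_len(col)] != "-"), phase,
                   reference_id = reference_id, native = TRUE)
  } else {
    position_label(codon_index, phase, reference_id = query_id,
                   native = FALSE)
  }
}

#' Project one gene's extracted introns onto reference numbering
#'
#' Convenience wrapper: runs [assign_phase()] on each intron's CDS offset
#' and [project_to_reference()] on the resulting codon. Introns upstream
#' of the CDS (offset 0) are reported with label `"5'UTR"` and skipped
#' from projection.
#'
#' @param introns data.frame from [extract_introns()].
#' @param query_id,reference_id alignment row ids (`query_id` is the
#'   gene's own protein).
#' @param alignment a [protein_alignment()].
#' @return data.frame: `gene_id`, `index`, `cds_offset`, `codon`,
#'   `phase`, `residue`, `reference_id`, `native`, `label`.
#' @export
project_introns <- function(introns, query_id, alignment, reference_id) {
  if (nrow(introns) == 0L)
    return(data.frame(gene_id = character(), index = integer(),
                      cds_offset = integer(), codon = integer(),
                      phase = character(), residue = integer(),
                      reference_id = character(), native = logical(),
                      label = character(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    off <- introns$cds_offset[i]
    ph <- assign_phase(off)
    if (is.na(ph$codon)) {
      return(data.frame(gene_id = introns$gene_id[i], index = introns$index[i],
                        cds_offset = off, codon = NA_integer_,
                        phase = "5'UTR", residue = NA_integer_,
                        reference_id = NA_character_, native = NA,
                        label = "5'UTR", stringsAsFactors = FALSE))
    }
    lab <- project_to_reference(ph$codon, query_id, alignment, reference_id,
                                phase = ph$phase)
    data.frame(gene_id = introns$gene_id[i], index = introns$index[i],
               cds_offset = off, codon = ph$codon, phase = ph$phase,
               residue = lab$residue, reference_id = lab$reference_id,
               native = lab$native, label = format(lab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
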