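# DRY / DRY-like motif machinery: motif scanning over protein+CDS pairs,
# proto-splice competence of the motif's first two codons, 9-position
# codon-usage count matrices, and comparison between genome sets.

#' Default DRY-like motif pattern
#'
#' Position sets covering all observed variants of the rhodopsin-family
#' DRY tripeptide: \[DEHLIS\]\[R\]\[YFSN\].
#' @export
DRY_PATTERN <- list(p1 = c("D", "E", "H", "L", "I", "S"),
                    p2 = "R",
                    p3 = c("Y", "F", "S", "N"))

#' Scan a protein/CDS pair for DRY-like motifs
#'
#' Every tripeptide window matching the pattern is reported with its
#' three codons, a canonical flag (residues exactly DRY) and its
#' proto-splice competence (see [proto_splice_competent()]). The CDS must
#' translate to the protein under the standard genetic code.
#'
#' @param protein amino-acid string (no stop).
#' @param cds coding sequence, `3 * nchar(protein)` nucleotides.
#' @param protein_id identifier carried into the output.
#' @param pattern list of three character vectors of allowed residues per
#'   motif position; default [DRY_PATTERN].
#' @return data.frame: `protein_id`, `start_residue`, `residues`,
#'   `codon1..3`, `is_canonical_DRY`, `proto_splice_competent`,
#'   `formed_triplet`, `intron_observed` (NA; supplied externally).
#' @export
scan_dry_motifs <- function(protein, cds, protein_id = "query",
                            pattern = DRY_PATTERN) {
  protein <- toupper(protein)
  cds <- toupper(cds)
  n <- nchar(protein)
  if (nchar(cds) != 3L * n)
    stop("CDS length must be 3x protein length (stop codon excluded)")
  translated <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  if (translated != protein)
    stop("CDS does not translate to the supplied protein (first mismatch ",
         "at residue ",
         which(strsplit(translated, "")[[1L]] !=
                 strsplit(protein, "")[[1L]])[1L], ")")
  aa <- strsplit(protein, "")[[1L]]
  hits <- list()
  for (i in seq_len(max(n - 2L, 0L))) {
    if (aa[i] %in% pattern$p1 && aa[i + 1L] %in% pattern$p2 &&
        aa[i + 2L] %in% pattern$p3) {
      codons <- substring(cds, 3L * (i - 1L) + c(1L, 4L, 7L),
                          3L * (i - 1L) + c(3L, 6L, 9L))
      comp <- proto_splice_competent(codons[1L], codons[2L])
      hits[[length(hits) + 1L]] <- data.frame(
        protein_id = protein_id, start_residue = i,
        residues = paste(aa[i:(i + 2L)], collapse = ""),
        codon1 = codons[1L], codon2 = codons[2L], codon3 = codons[3L],
        is_canonical_DRY = paste(aa[i:(i + 2L)], collapse = "") == "DRY",
        proto_splice_competent = comp$competent,
        formed_triplet = comp$triplet,
        intron_observed = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(protein_id = character(), start_residue = integer(),
                      residues = character(), codon1 = character(),
                      codon2 = character(), codon3 = character(),
                      is_canonical_DRY = logical(),
                      proto_splice_competent = logical(),
                      formed_triplet = character(), intron_observed = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

#' Proto-splice competence of a motif's first two codons
#'
#' The third base of the motif's first codon plus the first two bases of
#' its second (arginine) codon form the exonic triplet 5' of a phase-c
#' insertion point inside the motif. The site is proto-splice competent
#' when that triplet matches MAG (M = A/C) - which requires an
#' AGR-family arginine codon (AGA/AGG), never CGN.
#'
#' @param codon1,codon2 codon strings for motif positions 1 and 2.
#' @return list with `competent` (logical) and `triplet` (the formed
#'   3-mer).
#' @export
proto_splice_competent <- function(codon1, codon2) {
  codon1 <- toupper(codon1); codon2 <- toupper(codon2)
  if (nchar(codon1) != 3L || nchar(codon2) != 3L ||
      grepl("[^ACGT]", paste0(codon1, codon2)))
    stop("codons must be 3-letter nucleotide strings")
  triplet <- paste0(substr(codon1, 3L, 3L), substr(codon2, 1L, 2L))
  list(competent = grepl("^[AC]AG$", triplet), triplet = triplet)
}

#' Codon-usage count matrix over motif hits
#'
#' Per-position nucleotide counts over the 9-nt coding strings of a hit
#' collection. The insertion-point marker sits between positions 5 and 6
#' (i.e. inside the arginine codon, after its second base - the phase-c
#' DRY insertion point).
#'
#' @param hits data.frame from [scan_dry_motifs()] (>= 1 row).
#' @return class `codon_usage_matrix`: 4 x 9 integer matrix (rows A, C,
#'   G, T), attribute `insertion_after = 5`.
#' @export
codon_usage_matrix <- function(hits) {
  if (nrow(hits) < 1L) stop("codon_usage_matrix: no hits")
  nine <- paste0(hits$codon1, hits$codon2, hits$codon3)
  mat <- matrix(0L, nrow = 4L, ncol = 9L,
                dimnames = list(c("A", "C", "G", "T"),
                                paste0("pos", 1:9)))
  for (s in nine) {
    b <- strsplit(s, "")[[1L]]
    for (j in 1:9) mat[b[j], j] <- mat[b[j], j] + 1L
  }
  structure(mat, insertion_after = 5L, class = "codon_usage_matrix")
}

#' @export
print.codon_usage_matrix <- function(x, ...) {
  cat("<codon_usage_matrix>", sum(x[, 1L]), "hits; ^ = insertion point\n")
  m <- unclass(x)
  hdr <- colnames(m)
  hdr[attr(x, "insertion_after")] <- paste0(hdr[attr(x, "insertion_after")], "^")
  colnames(m) <- hdr
  print(m)
  invisible(x)
}

#' Write a codon-usage matrix as TSV
#'
#' @param mat a `codon_usage_matrix`.
#' @param file output path.
#' @export
write_codon_usage <- function(mat, file) {
  df <- data.frame(base = rownames(mat), unclass(mat), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Per-position nucleotide-frequency differences between two hit sets
#'
#' Converts each count matrix to column frequencies and subtracts,
#' giving the per-position, per-nucleotide usage shift between two
#' genome sets (e.g. compacted vs non-compacted genomes).
#'
#' @param matrix_a,matrix_b `codon_usage_matrix` objects.
#' @return 4 x 9 numeric matrix of frequency deltas (A - B).
#' @export
compare_genome_sets <- function(matrix_a, matrix_b) {
  fa <- sweep(unclass(matrix_a), 2L, colSums(matrix_a), "/")
  fb <- sweep(unclass(matrix_b), 2L, colSums(matrix_b), "/")
  fa - fb
}
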