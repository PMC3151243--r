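# Domain types and readers/writers: genome sequences, gene models,
# protein alignments, dated species trees. All external coordinates are
# 1-based inclusive (GFF3 convention); strand-dependent quantities
# (flanks, offsets, donor/acceptor) are reported in transcript orientation.

GENE_MODEL_COLS <- c("gene_id", "seq_id", "strand", "exon_start", "exon_end")

#' Validate and normalise a genome sequence
#'
#' Sequences are stored uppercase over the alphabet A, C, G, T, N.
#'
#' @param id sequence identifier.
#' @param seq nucleotide string (case-insensitive on input).
#' @return a length-1 named character vector (name = `id`), uppercase.
#' @export
genome_sequence <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(as.character(seq))
  if (nchar(seq) < 1L) stop("genome sequence '", id, "' is empty")
  if (grepl("[^ACGTN]", seq))
    stop("genome sequence '", id, "' contains characters outside {A,C,G,T,N}")
  stats::setNames(seq, id)
}

#' Construct a gene model
#'
#' A gene model is one gene's ordered exon intervals on one sequence, plus
#' strand and the number of bases to skip before the first complete codon
#' (GFF3 phase of the first CDS segment, normally 0).
#'
#' @param gene_id,seq_id identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of 1-based inclusive
#'   start/end intervals; stored sorted ascending on the + reference.
#' @param codon_start_offset integer >= 0; coding bases to skip before the
#'   first complete codon.
#' @param validated logical; `FALSE` flags models whose declared CDS length
#'   is not a codon multiple.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, codon_start_offset = 0L,
                       validated = TRUE) {
  stopifnot(strand %in% c("+", "-"), codon_start_offset >= 0)
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  if (any(exons[, 1L] > exons[, 2L]))
    stop("gene '", gene_id, "': exon start > end")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("gene '", gene_id, "': overlapping exons")
  dimnames(exons) <- list(NULL, c("start", "end"))
  structure(list(gene_id = gene_id, seq_id = seq_id, strand = strand,
                 exons = exons,
                 codon_start_offset = as.integer(codon_start_offset),
                 validated = validated),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s (%s), %d exon(s), offset %d%s\n",
              x$gene_id, x$seq_id, x$strand, nrow(x$exons),
              x$codon_start_offset,
              if (isTRUE(x$validated)) "" else " [non-validated]"))
  invisible(x)
}

#' Exons of a model in transcription order
#'
#' On the minus strand exons are iterated 3'->5' of the reference so that
#' the first row is the transcript's first exon. Coordinates stay in
#' reference (plus-strand) space.
#'
#' @param model a `gene_model`.
#' @return integer matrix with columns start, end.
#' @export
exons_in_transcript_order <- function(model) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  ex
}

#' Assemble the spliced CDS of a gene model
#'
#' Concatenates exon sequences in transcript order; minus-strand models are
#' reverse complemented. `codon_start_offset` bases are *not* trimmed: the
#' returned string is the full spliced transcript-side sequence.
#'
#' @param model a `gene_model`.
#' @param genomes named character vector of genome sequences (see
#'   [genome_sequence()]), or a single unnamed sequence string.
#' @return spliced nucleotide string in transcript orientation.
#' @export
spliced_cds <- function(model, genomes) {
  seq <- .resolve_sequence(model, genomes)
  ex <- model$exons
  parts <- substring(seq, ex[, 1L], ex[, 2L])
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string (A, C, G, T, N; case preserved as upper).
#' @return the reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.resolve_sequence <- function(model, genomes) {
  if (length(genomes) == 1L && is.null(names(genomes))) return(toupper(genomes))
  if (!model$seq_id %in% names(genomes))
    stop("sequence '", model$seq_id, "' (gene '", model$gene_id,
         "') not found among supplied genome sequences")
  seq <- toupper(genomes[[model$seq_id]])
  if (max(model$exons) > nchar(seq))
    stop("gene '", model$gene_id, "': exon beyond end of sequence '",
         model$seq_id, "'")
  seq
}

.check_cds_multiple <- function(model) {
  len <- sum(model$exons[, 2L] - model$exons[, 1L] + 1L) -
    model$codon_start_offset
  if (len %% 3L != 0L) {
    warning("gene '", model$gene_id, "': CDS length ", len,
            " is not a multiple of 3; model flagged non-validated",
            call. = FALSE)
    model$validated <- FALSE
  }
  model
}

#' Read gene models from GFF3 + FASTA
#'
#' CDS features are grouped by their `Parent` attribute (falling back to
#' `ID`); one model is built per group. The GFF3 phase column of the first
#' CDS segment in transcript order becomes `codon_start_offset`.
#'
#' @param gff_file path to a GFF3 file.
#' @param fasta_file path to the matching FASTA file.
#' @return list with elements `models` (list of [gene_model()]) and
#'   `genomes` (named character vector of sequences).
#' @export
read_gene_models <- function(gff_file, fasta_file) {
  genomes <- read_genome_fasta(fasta_file)
  gr <- rtracklayer::import(gff_file, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) stop("no CDS features in ", gff_file)
  parent <- sapply(seq_along(cds), function(i) {
    p <- cds$Parent[[i]]
    if (length(p) >= 1L) as.character(p[1L])
    else if (!is.null(cds$ID) && !is.na(cds$ID[i])) cds$ID[i]
    else stop("CDS feature without Parent or ID at line for ",
              as.character(GenomicRanges::seqnames(cds))[i], ":",
              GenomicRanges::start(cds)[i])
  })
  models <- lapply(split(seq_along(cds), parent), function(idx) {
    sub <- cds[idx]
    seq_id <- unique(as.character(GenomicRanges::seqnames(sub)))
    if (length(seq_id) != 1L)
      stop("CDS group '", parent[idx[1L]], "' spans multiple sequences")
    if (!seq_id %in% names(genomes))
      stop("sequence id '", seq_id, "' referenced by feature group '",
           parent[idx[1L]], "' (", seq_id, ":",
           min(GenomicRanges::start(sub)), "-", max(GenomicRanges::end(sub)),
           ") is missing from the FASTA")
    strand <- unique(as.character(BiocGenerics::strand(sub)))
    if (length(strand) != 1L || !strand %in% c("+", "-"))
      stop("CDS group '", parent[idx[1L]], "': bad or mixed strand")
    ex <- cbind(GenomicRanges::start(sub), GenomicRanges::end(sub))
    ord <- order(ex[, 1L])
    ex <- ex[ord, , drop = FALSE]
    ph <- suppressWarnings(as.integer(as.character(sub$phase)))[ord]
    first <- if (strand == "+") 1L else nrow(ex)
    off <- ph[first]
    if (is.na(off)) off <- 0L
    m <- gene_model(parent[idx[1L]], seq_id, strand, ex, off)
    .check_cds_multiple(m)
  })
  list(models = unname(models), genomes = genomes)
}

#' Read genome sequences from FASTA
#'
#' @param fasta_file path.
#' @return named character vector, uppercase.
#' @export
read_genome_fasta <- function(fasta_file) {
  ss <- Biostrings::readDNAStringSet(fasta_file)
  ids <- sub("\\s.*$", "", names(ss))
  out <- stats::setNames(toupper(as.character(ss)), ids)
  mapply(genome_sequence, ids, out)  # validates
  out
}

#' Read gene models from a plain exon table
#'
#' Alternate simple input: a TSV with header
#' `gene_id  seq_id  strand  exon_start  exon_end`, one row per exon.
#' Rows may be in any order; overlapping exons within a gene are fatal.
#'
#' @param tsv_file path to the table.
#' @return list of [gene_model()].
#' @export
read_exon_table <- function(tsv_file) {
  tab <- utils::read.delim(tsv_file, stringsAsFactors = FALSE)
  missing <- setdiff(GENE_MODEL_COLS, names(tab))
  if (length(missing))
    stop("exon table lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(tab$exon_start) || !is.numeric(tab$exon_end))
    stop("exon coordinates must be integers")
  lapply(split(tab, tab$gene_id), function(g) {
    strand <- unique(g$strand)
    seq_id <- unique(g$seq_id)
    if (length(strand) != 1L || length(seq_id) != 1L)
      stop("gene '", g$gene_id[1L], "': inconsistent strand or seq_id")
    gene_model(g$gene_id[1L], seq_id, strand,
               cbind(g$exon_start, g$exon_end))
  }) |> unname()
}

#' Write gene models as GFF3 (plus optional FASTA)
#'
#' Emits gene/mRNA/CDS rows with correct GFF3 phase values so that
#' [read_gene_models()] round-trips coordinate-identically.
#'
#' @param models list of [gene_model()].
#' @param gff_file output GFF3 path.
#' @param genomes optional named sequence vector to write alongside.
#' @param fasta_file output FASTA path (required when `genomes` given).
#' @return `gff_file`, invisibly.
#' @export
write_gene_models <- function(models, gff_file, genomes = NULL,
                              fasta_file = NULL) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- range(m$exons)
    lines <- c(lines,
      paste(m$seq_id, "introgain", "gene", span[1L], span[2L], ".",
            m$strand, ".", paste0("ID=", m$gene_id, ".gene"), sep = "\t"),
      paste(m$seq_id, "introgain", "mRNA", span[1L], span[2L], ".",
            m$strand, ".", paste0("ID=", m$gene_id, ";Parent=",
                                  m$gene_id, ".gene"), sep = "\t"))
    ex <- exons_in_transcript_order(m)
    # GFF3 phase: bases to skip at the start of this CDS segment
    phase <- integer(nrow(ex))
    carried <- m$codon_start_offset
    for (i in seq_len(nrow(ex))) {
      phase[i] <- carried
      seg <- ex[i, 2L] - ex[i, 1L] + 1L
      carried <- (3L - ((seg - carried) %% 3L)) %% 3L
    }
    ord <- if (m$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    for (i in ord) {
      lines <- c(lines,
        paste(m$seq_id, "introgain", "CDS", ex[i, 1L], ex[i, 2L], ".",
              m$strand, phase[i],
              paste0("ID=", m$gene_id, ".cds;Parent=", m$gene_id),
              sep = "\t"))
    }
  }
  writeLines(lines, gff_file)
  if (!is.null(genomes)) {
    if (is.null(fasta_file)) stop("fasta_file required when genomes supplied")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genomes), fasta_file)
  }
  invisible(gff_file)
}

#' Read a protein multiple alignment from aligned FASTA
#'
#' @param fasta_file path to aligned FASTA ('-' gaps).
#' @return named character vector of equal-length aligned rows, class
#'   `protein_alignment`.
#' @export
read_alignment <- function(fasta_file) {
  ss <- Biostrings::readAAStringSet(fasta_file)
  rows <- stats::setNames(toupper(as.character(ss)),
                          sub("\\s.*$", "", names(ss)))
  protein_alignment(rows)
}

#' Construct a protein alignment from aligned rows
#'
#' @param rows named character vector; equal lengths, '-' for gaps.
#' @return class `protein_alignment`.
#' @export
protein_alignment <- function(rows) {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows must carry unique names")
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("ragged alignment: row lengths ", paste(nchar(rows), collapse = ", "))
  bad <- grepl("[^A-Z*-]", rows)
  if (any(bad))
    stop("alignment row(s) with invalid characters: ",
         paste(names(rows)[bad], collapse = ", "))
  structure(rows, class = "protein_alignment")
}

#' Read a dated species tree
#'
#' Two dialects are accepted, never mixed within one file:
#' \describe{
#'   \item{node-age labels}{internal nodes labelled `name#age` (age in MY);
#'     leaves have age 0.}
#'   \item{branch lengths}{all edges carry lengths in MY and `root_age`
#'     supplies the root's age; node ages are `root_age` minus the path
#'     length from the root.}
#' }
#'
#' @param source path to a newick file, or a newick string.
#' @param root_age numeric root age in MY (branch-length dialect only).
#' @return class `dated_tree`: list with `phy` (ape phylo), `ages`
#'   (numeric, indexed by ape node number), `root_age`.
#' @export
read_dated_tree <- function(source, root_age = NULL) {
  phy <- if (length(source) == 1L && grepl("\\(", source))
    ape::read.tree(text = source) else ape::read.tree(source)
  if (is.null(phy)) stop("could not parse newick input")
  dated_tree(phy, root_age = root_age)
}

#' Attach node ages to an ape phylo
#'
#' @param phy rooted `phylo` object.
#' @param root_age root age in MY when ages must be derived from branch
#'   lengths; ignored (and an error if also labelled) otherwise.
#' @return class `dated_tree`.
#' @export
dated_tree <- function(phy, root_age = NULL) {
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labels_have_ages <- !is.null(phy$node.label) &&
    all(grepl("#[0-9.]+$", phy$node.label))
  ages <- numeric(ntip + nnode)
  if (labels_have_ages) {
    if (!is.null(root_age))
      stop("tree carries node-age labels; do not also supply root_age")
    ages[ntip + seq_len(nnode)] <-
      as.numeric(sub("^.*#", "", phy$node.label))
    phy$node.label <- sub("#[0-9.]+$", "", phy$node.label)
  } else {
    if (is.null(phy$edge.length))
      stop("tree has neither node-age labels nor branch lengths")
    if (any(phy$edge.length < 0)) stop("negative branch length")
    if (is.null(root_age))
      stop("root_age is required when only branch lengths are given")
    depth <- ape::node.depth.edgelength(phy)
    ages <- root_age - depth
    ages[seq_len(ntip)][abs(ages[seq_len(ntip)]) < 1e-6] <- 0
    if (any(ages[seq_len(ntip)] < -1e-6))
      stop("root_age smaller than the tree height")
  }
  # parent age must dominate child age
  pa <- ages[phy$edge[, 1L]]
  ch <- ages[phy$edge[, 2L]]
  if (any(pa < ch - 1e-6)) stop("parent younger than child: not a dated tree")
  structure(list(phy = phy, ages = ages,
                 root_age = ages[ntip + 1L]),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("<dated_tree> %d leaves, root age %g MY\n",
              length(x$phy$tip.label), x$root_age))
  invisible(x)
}

#' Age of a node in a dated tree
#'
#' @param tree a `dated_tree`.
#' @param node leaf label, internal node label, or ape node number.
#' @return age in MY.
#' @export
node_age <- function(tree, node) {
  tree$ages[resolve_node(tree, node)]
}

# leaf label / node label / numeric id -> ape node number
resolve_node <- function(tree, node) {
  if (is.numeric(node)) return(as.integer(node))
  phy <- tree$phy
  i <- match(node, phy$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(phy$node.label)) {
    j <- match(node, phy$node.label)
    if (!is.na(j)) return(length(phy$tip.label) + j)
  }
  stop("node '", node, "' not found in tree")
}

# human-readable name for an ape node number
node_name <- function(tree, num) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  if (num <= ntip) return(phy$tip.label[num])
  lbl <- if (!is.null(phy$node.label)) phy$node.label[num - ntip] else ""
  if (is.na(lbl) || !nzchar(lbl)) paste0("node", num) else lbl
}
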