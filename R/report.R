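# Bundled reference fixtures (the published MC-receptor intron table, its
# repeat annotations, and the dated fish/tetrapod tree) plus the
# consolidated per-intron report and TSV writers.

introgain_extdata <- function(file) {
  p <- system.file("extdata", file, package = "introgain")
  if (!nzchar(p)) stop("fixture '", file, "' not found; is introgain installed?")
  p
}

#' Published novel-intron feature table for MC2R/MC5R
#'
#' The 18 novel introns reported in MC5R and MC2R of four
#' acanthopterygian fishes (Takifugu rubripes, Tetraodon nigroviridis,
#' Gasterosteus aculeatus, Oryzias latipes), transcribed as a TSV:
#' position label in human-MC5R numbering, size, flanking context
#' (`XXXX^YYYY`, `^` the insertion point), GC percent, splice-signal and
#' ultrasmall flags, and the proto-splice deviations implied by the
#' MAG^R rule (M = A/C).
#'
#' @return data.frame, one row per intron.
#' @export
mcr_intron_table <- function() {
  utils::read.delim(introgain_extdata("mcr_novel_introns.tsv"),
                    stringsAsFactors = FALSE, na.strings = ".")
}

#' Published repeat annotations for the MC-receptor introns
#'
#' Externally predicted repetitive elements (complex elements and simple
#' repeats) inside the novel introns; direction d = direct,
#' c = complementary; coordinates 1-based within the intron. One
#' annotation extends past its intron's stated length and is kept with a
#' warning.
#'
#' @return data.frame of repeat intervals.
#' @export
mcr_intron_repeats <- function() {
  tab <- mcr_intron_table()
  lens <- stats::setNames(tab$intron_size,
                          paste(tab$species, tab$gene, tab$position_label,
                                sep = "|"))
  read_repeat_annotation(introgain_extdata("mcr_intron_repeats.tsv"),
                         intron_lengths = lens)
}

#' Presence matrix for the MC-receptor survey
#'
#' Builds the taxon-gene x position matrix behind the conservation
#' queries: the four acanthopterygians carry the tabulated introns;
#' zebrafish and tetrapods were analysed and are intronless at every
#' position.
#'
#' @return a `presence_matrix` (see [build_presence_matrix()]).
#' @export
mcr_presence_matrix <- function() {
  tab <- mcr_intron_table()
  projected <- data.frame(taxon = tab$species, gene = tab$gene,
                          label = tab$position_label, native = TRUE,
                          stringsAsFactors = FALSE)
  taxa <- c("T.rubripes", "T.nigroviridis", "G.aculeatus", "O.latipes",
            "zebrafish", "tetrapods")
  build_presence_matrix(projected, taxa = taxa,
                        genes = c("MC5R", "MC2R"))
}

#' Dated fish/tetrapod species tree
#'
#' Seven-taxon tree (the four acanthopterygians, zebrafish, tetrapods)
#' with node ages in MY as internal-node labels. The two anchor ages are
#' the zebrafish/Acanthopterygii split at 320 MY and the crown of the
#' four fishes at 190 MY; remaining ages are round interpolations kept
#' configurable through the newick file.
#'
#' @return a [dated_tree()].
#' @export
acanthopterygii_tree <- function() {
  read_dated_tree(introgain_extdata("acanthopterygii_timetree.nwk"))
}

#' Map taxon names of the intron table onto the tree's tip labels
#'
#' @return named character vector (table species -> tree tip).
#' @export
mcr_taxon_map <- function() {
  c("T.rubripes" = "Takifugu", "T.nigroviridis" = "Tetraodon",
    "G.aculeatus" = "stickleback", "O.latipes" = "medaka",
    "zebrafish" = "zebrafish", "tetrapods" = "tetrapods")
}

#' Per-intron feature table from extraction output
#'
#' Serialises extraction (+ optional projection) results into the
#' package's per-intron TSV shape: `species`, `gene`, `position_label`,
#' `intron_size`, `flank_context` (`XXXX^YYYY`), `gc_percent`,
#' `canonical_splice`, `ultrasmall`.
#'
#' @param introns data.frame from [extract_introns()].
#' @param projections optional data.frame from [project_introns()]
#'   (matched on gene_id + index) supplying the position labels.
#' @param species species name for the output rows.
#' @param gene gene name (defaults to the model's gene_id).
#' @return data.frame.
#' @export
intron_feature_table <- function(introns, projections = NULL,
                                 species = NA_character_, gene = NULL) {
  lab <- rep(NA_character_, nrow(introns))
  if (!is.null(projections)) {
    m <- match(paste(introns$gene_id, introns$index),
               paste(projections$gene_id, projections$index))
    lab <- projections$label[m]
  }
  data.frame(species = species,
             gene = if (is.null(gene)) introns$gene_id else gene,
             position_label = lab,
             intron_size = introns$length,
             flank_context = paste0(introns$upstream4, "^",
                                    introns$downstream4),
             gc_percent = introns$gc_percent,
             canonical_splice = introns$donor2 == "GT" &
               introns$acceptor2 == "AG",
             ultrasmall = introns$ultrasmall,
             stringsAsFactors = FALSE)
}

#' Consolidated intron report
#'
#' Joins per-intron features with repeat annotations into one table in
#' the published layout: one row per intron-repeat pair, plus a single
#' row with `.`-valued repeat columns for introns without repeats.
#'
#' @param features per-intron table ([mcr_intron_table()] shape).
#' @param repeats optional repeat annotation table
#'   ([mcr_intron_repeats()] shape).
#' @return data.frame: `species`, `gene`, `intron`, `intron_size`,
#'   `flanking_sequences`, `percentage_gc_content`, `repeat_type`,
#'   `repeat_class`, `direction`, `from`, `to`.
#' @export
intron_report <- function(features, repeats = NULL) {
  key <- paste(features$species, features$gene, features$position_label,
               sep = "|")
  rows <- lapply(seq_len(nrow(features)), function(i) {
    base <- data.frame(species = features$species[i],
                       gene = features$gene[i],
                       intron = features$position_label[i],
                       intron_size = features$intron_size[i],
                       flanking_sequences = features$flank_context[i],
                       percentage_gc_content = features$gc_percent[i],
                       stringsAsFactors = FALSE)
    hits <- if (is.null(repeats)) NULL else
      repeats[paste(repeats$species, repeats$gene, repeats$position_label,
                    sep = "|") == key[i], , drop = FALSE]
    if (is.null(hits) || nrow(hits) == 0L) {
      cbind(base, repeat_type = ".", repeat_class = ".", direction = ".",
            from = ".", to = ".", stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(seq_len(nrow(hits)), function(j)
        cbind(base, repeat_type = hits$type[j],
              repeat_class = if (is.null(hits$class)) "." else hits$class[j],
              direction = hits$direction[j],
              from = as.character(hits$from[j]),
              to = as.character(hits$to[j]), stringsAsFactors = FALSE)))
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Write a data.frame as the package's standard TSV
#'
#' UTF-8, tab-separated, `.` for missing values, no quoting.
#'
#' @param df data.frame.
#' @param file output path.
#' @export
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(file)
}
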