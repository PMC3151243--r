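# Seeded synthetic-data generator: an intronless ancestral CDS evolved
# along a dated species tree by stop-free Jukes-Cantor-style
# substitutions, with intron insertions materialised on all descendants
# of chosen branches and a ground-truth table for end-to-end testing.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.sense_codons <- function() {
  all64 <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                 paste0), c("T", "C", "A", "G"), paste0))
  sort(setdiff(all64, STOP_CODONS))
}

#' Specify one intron insertion for the simulator
#'
#' @param branch label of the tree node *below* the gain edge (a tip or
#'   internal node label); every tip descending from it receives the
#'   intron.
#' @param codon,phase insertion point in ancestral/reference numbering
#'   (phase letter a/b/c).
#' @param length intron length in bp, 18-10000 (the observed novel-intron
#'   scale).
#' @param gc_target target GC percent of the whole intron; achieved to
#'   within 1 percentage point by rejection sampling.
#' @param gene_id gene receiving the intron.
#' @param repeat_unit,repeat_copies optional perfect simple repeat (unit
#'   1-6 nt) embedded in the intron interior at a recorded interval.
#' @param enforce_proto_splice when TRUE the three exonic bases 5' of the
#'   site are set to a MAG-matching triplet by synonymous codon changes
#'   (the spec is rejected if no synonymous combination exists).
#' @return class `insertion_spec`.
#' @export
insertion_spec <- function(branch, codon, phase, length, gc_target = 45,
                           gene_id = "gene1", repeat_unit = NULL,
                           repeat_copies = NULL,
                           enforce_proto_splice = TRUE) {
  stopifnot(phase %in% c("a", "b", "c"), codon >= 1L,
            gc_target >= 0, gc_target <= 100)
  if (length < 18L || length > 10000L)
    stop("intron length must be within 18-10000 bp")
  if (!is.null(repeat_unit)) {
    if (nchar(repeat_unit) < 1L || nchar(repeat_unit) > 6L)
      stop("repeat unit must be 1-6 nt")
    if (is.null(repeat_copies) || repeat_copies < 2L)
      stop("repeat_copies (>= 2) required with repeat_unit")
    if (nchar(repeat_unit) * repeat_copies > length - 4L)
      stop("repeat does not fit inside the intron interior ",
           "(GT/AG termini are fixed)")
  }
  structure(list(branch = branch, codon = as.integer(codon), phase = phase,
                 length = as.integer(length), gc_target = gc_target,
                 gene_id = gene_id, repeat_unit = repeat_unit,
                 repeat_copies = repeat_copies,
                 enforce_proto_splice = enforce_proto_splice),
            class = "insertion_spec")
}

#' Simulate gene structures with known intron-gain ground truth
#'
#' An ancestral CDS (ATG followed by codons drawn uniformly from the 61
#' sense codons) is evolved along `tree` with per-branch substitution
#' probability `substitution_rate * branch_length_MY` per site; mutated
#' codons that would become stops are re-drawn. Coding sequence carries
#' no indels, so the true protein alignment is the gap-free stack of tip
#' translations and projected labels are exactly recoverable at any
#' substitution rate. Each [insertion_spec()] materialises one intron
#' sequence (GT...AG termini, interior rejection-sampled to `gc_target`
#' within 1 percentage point, optional embedded repeat) on every tip
#' descending from its branch.
#'
#' @param tree a [dated_tree()].
#' @param n_codons ancestral CDS length in codons (default 350, a
#'   typical single-domain GPCR).
#' @param substitution_rate expected substitutions per site per MY.
#' @param specs list of [insertion_spec()].
#' @param seed mandatory integer seed; identical seed + configuration
#'   gives byte-identical output.
#' @return list: `genomes` (named sequences, one per taxon x gene, ids
#'   `taxon_gene`), `models` (list of [gene_model()]), `alignments`
#'   (per gene, a [protein_alignment()] of tip translations), `truth`
#'   (data.frame, one row per materialised intron), `tree`, `seed`.
#' @export
simulate_intron_gain <- function(tree, n_codons = 350L,
                                 substitution_rate = 0, specs = list(),
                                 seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(substitution_rate >= 0, n_codons >= 10L)
  if (inherits(specs, "insertion_spec")) specs <- list(specs)
  set.seed(as.integer(seed))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  genes <- unique(vapply(specs, function(s) s$gene_id, ""))
  if (!length(genes)) genes <- "gene1"
  sense <- .sense_codons()

  genomes <- character()
  models <- list()
  alignments <- list()
  truth <- list()

  for (gene in genes) {
    gspecs <- Filter(function(s) s$gene_id == gene, specs)
    # ancestral CDS; proto-splice windows are seeded with a MAG-compatible
    # codon context and held invariant during evolution (the site is under
    # the same constraint that makes it an insertion hotspot)
    anc <- c("ATG", sample(sense, n_codons - 1L, replace = TRUE))
    protected <- integer(0)
    for (s in gspecs) {
      off <- label_to_offset(position_label(s$codon, s$phase))
      if (off > 3L * n_codons)
        stop("insertion spec at codon ", s$codon, s$phase,
             ": site beyond the ", n_codons, "-codon CDS")
      if (isTRUE(s$enforce_proto_splice)) {
        anc <- .ensure_proto_splice(anc, off, sense, s)
        protected <- c(protected, (off - 2L):off)
      }
    }
    node_seq <- vector("list", ntip + phy$Nnode)
    root <- ntip + 1L
    node_seq[[root]] <- anc
    ord <- .preorder_edges(phy)
    for (e in ord) {
      par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      bl <- tree$ages[par] - tree$ages[ch]
      node_seq[[ch]] <- .evolve_codons(node_seq[[par]],
                                       min(substitution_rate * bl, 0.75),
                                       sense, protected)
    }
    # one intron sequence per spec, shared by all descendants of its branch
    intron_seqs <- lapply(gspecs, .build_intron)
    spec_tips <- lapply(gspecs, function(s)
      .descendant_tips(phy, resolve_node(tree, s$branch)))

    for (t in seq_len(ntip)) {
      taxon <- phy$tip.label[t]
      codons <- node_seq[[t]]
      here <- which(vapply(spec_tips, function(tips) t %in% tips, TRUE))
      offs <- vapply(here, function(k)
        label_to_offset(position_label(gspecs[[k]]$codon,
                                       gspecs[[k]]$phase)), 0L)
      if (anyDuplicated(offs)) stop("two insertions at one site in '",
                                    taxon, "'")
      cds <- paste(codons, collapse = "")
      seq_id <- paste(taxon, gene, sep = "_")
      # insert introns 3'-most first so earlier offsets stay valid
      ordk <- here[order(offs, decreasing = TRUE)]
      gseq <- cds
      for (k in ordk) {
        off <- label_to_offset(position_label(gspecs[[k]]$codon,
                                              gspecs[[k]]$phase))
        gseq <- paste0(substr(gseq, 1L, off), intron_seqs[[k]]$seq,
                       substring(gseq, off + 1L))
      }
      # exon structure from sorted offsets
      if (length(here)) {
        o <- sort(offs)
        ok <- here[order(offs)]
        lens <- vapply(ok, function(k) gspecs[[k]]$length, 0L)
        shift <- cumsum(c(0L, lens[-length(lens)]))
        istart <- o + shift + 1L
        iend <- istart + lens - 1L
        ex_start <- c(1L, iend + 1L)
        ex_end <- c(istart - 1L, nchar(gseq))
        exons <- cbind(ex_start, ex_end)
        for (j in seq_along(ok)) {
          k <- ok[j]
          s <- gspecs[[k]]
          truth[[length(truth) + 1L]] <- data.frame(
            taxon = taxon, gene = gene, seq_id = seq_id,
            label = paste0(s$codon, s$phase), codon = s$codon,
            phase = s$phase, cds_offset = o[j], length = s$length,
            gc_target = s$gc_target,
            gc_actual = intron_seqs[[k]]$gc,
            repeat_unit = if (is.null(s$repeat_unit)) NA_character_
                          else s$repeat_unit,
            repeat_start = intron_seqs[[k]]$rep_start,
            repeat_end = intron_seqs[[k]]$rep_end,
            gain_branch = s$branch,
            intron_start = istart[j], intron_end = iend[j],
            stringsAsFactors = FALSE)
        }
      } else {
        exons <- cbind(1L, nchar(gseq))
      }
      genomes[seq_id] <- gseq
      models[[seq_id]] <- gene_model(seq_id, seq_id, "+", exons)
      node_seq[[t]] <- codons  # synonymous fixes included
    }
    alignments[[gene]] <- protein_alignment(stats::setNames(
      vapply(seq_len(ntip), function(t)
        as.character(Biostrings::translate(
          Biostrings::DNAString(paste(node_seq[[t]], collapse = "")),
          no.init.codon = TRUE)), ""),
      phy$tip.label))
  }
  truth <- if (length(truth)) do.call(rbind, c(truth,
                                               list(make.row.names = FALSE)))
           else data.frame()
  list(genomes = genomes, models = unname(models), alignments = alignments,
       truth = truth, tree = tree, seed = seed)
}

# edges in root-to-tip order
.preorder_edges <- function(phy) {
  ntip <- length(phy$tip.label)
  out <- integer(0)
  walk <- function(node) {
    es <- which(phy$edge[, 1L] == node)
    for (e in es) {
      out <<- c(out, e)
      walk(phy$edge[e, 2L])
    }
  }
  walk(ntip + 1L)
  out
}

.descendant_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  tips <- integer(0)
  walk <- function(n) {
    if (n <= ntip) tips <<- c(tips, n)
    else for (ch in phy$edge[phy$edge[, 1L] == n, 2L]) walk(ch)
  }
  walk(node)
  tips
}

# mutate a codon vector: per-site substitution probability p, stops
# resolved by re-drawing the affected codon's mutated sites; `protected`
# flat positions (proto-splice windows) never mutate
.evolve_codons <- function(codons, p, sense, protected = integer(0)) {
  if (p <= 0) return(codons)
  n <- length(codons)
  flat <- strsplit(paste(codons, collapse = ""), "")[[1L]]
  hit <- setdiff(which(stats::runif(length(flat)) < p), protected)
  if (!length(hit)) return(codons)
  bases <- c("A", "C", "G", "T")
  for (i in hit)
    flat[i] <- sample(setdiff(bases, flat[i]), 1L)
  out <- substring(paste(flat, collapse = ""),
                   3L * seq_len(n) - 2L, 3L * seq_len(n))
  bad <- which(out %in% STOP_CODONS)
  for (i in bad) {
    repeat {
      cand <- strsplit(codons[i], "")[[1L]]
      sites <- intersect(hit, (3L * i - 2L):(3L * i)) - (3L * i - 3L)
      for (s2 in sites) cand[s2] <- sample(setdiff(bases, cand[s2]), 1L)
      cand <- paste(cand, collapse = "")
      if (!cand %in% STOP_CODONS) { out[i] <- cand; break }
    }
  }
  out
}

# one intron sequence: GT + interior + AG; interior rejection-sampled to
# the GC target; optional repeat embedded at a recorded interval
.build_intron <- function(spec) {
  L <- spec$length
  interior_len <- L - 4L
  rep_seq <- if (!is.null(spec$repeat_unit))
    strrep(spec$repeat_unit, spec$repeat_copies) else ""
  rlen <- nchar(rep_seq)
  free_len <- interior_len - rlen
  rep_pos <- if (rlen > 0L) {
    if (free_len > 0L) sample.int(free_len + 1L, 1L) else 1L
  } else NA_integer_
  fixed_gc <- 2L + if (rlen) rlen - nchar(gsub("[GC]", "",
                                               toupper(rep_seq))) else 0L
  need <- spec$gc_target / 100 * L - fixed_gc
  q <- if (free_len > 0L) min(max(need / free_len, 0), 1) else 0
  for (try in seq_len(10000L)) {
    free <- if (free_len > 0L)
      paste(ifelse(stats::runif(free_len) < q,
                   sample(c("G", "C"), free_len, replace = TRUE),
                   sample(c("A", "T"), free_len, replace = TRUE)),
            collapse = "") else ""
    interior <- if (rlen > 0L)
      paste0(substr(free, 1L, rep_pos - 1L), rep_seq,
             substring(free, rep_pos)) else free
    seq <- paste0("GT", interior, "AG")
    gc_raw <- 100 * (nchar(seq) - nchar(gsub("[GC]", "", seq))) / L
    if (abs(gc_raw - spec$gc_target) <= 1) {
      return(list(seq = seq, gc = gc_content(seq),
                  rep_start = if (rlen) 2L + rep_pos else NA_integer_,
                  rep_end = if (rlen) 2L + rep_pos + rlen - 1L
                            else NA_integer_))
    }
  }
  stop("insertion spec at codon ", spec$codon, spec$phase,
       ": GC target ", spec$gc_target,
       "% is unachievable with GT...AG termini",
       if (rlen) paste0(" and the embedded ", spec$repeat_unit, " repeat"))
}

# seed a MAG proto-splice context at the three coding bases 5' of
# `offset` in the ancestral CDS: synonymous recoding where the random
# amino acids allow it, otherwise the affected codon(s) are re-drawn
# uniformly from the sense-codon combinations that form the context
.ensure_proto_splice <- function(codons, offset, sense, spec) {
  fixed <- tryCatch(.force_proto_splice(codons, offset, sense, spec),
                    error = function(e) NULL)
  if (!is.null(fixed)) return(fixed)
  win <- (offset - 2L):offset
  ci <- unique(ceiling(win / 3))
  combos <- expand.grid(rep(list(sense), length(ci)),
                        stringsAsFactors = FALSE)
  ok <- integer(0)
  for (r in seq_len(nrow(combos))) {
    trial <- codons
    trial[ci] <- unlist(combos[r, ])
    tf <- strsplit(paste(trial[ci], collapse = ""), "")[[1L]]
    # window relative to the affected codon block
    rel <- win - 3L * (ci[1L] - 1L)
    if (grepl("^[AC]AG$", paste(tf[rel], collapse = ""))) ok <- c(ok, r)
  }
  pick <- ok[sample.int(length(ok), 1L)]
  codons[ci] <- unlist(combos[pick, ])
  codons
}

# set the three coding bases 5' of `offset` to a MAG triplet by
# synonymous substitution; error when no synonymous combination exists
.force_proto_splice <- function(codons, offset, sense, spec) {
  if (offset < 3L)
    stop("insertion spec at codon ", spec$codon, spec$phase,
         ": fewer than 3 coding bases upstream; proto-splice context ",
         "cannot be enforced")
  win <- (offset - 2L):offset
  ci <- unique(ceiling(win / 3))
  code <- Biostrings::GENETIC_CODE
  flat <- strsplit(paste(codons, collapse = ""), "")[[1L]]
  cur <- paste(flat[win], collapse = "")
  if (grepl("^[AC]AG$", cur)) return(codons)
  options <- lapply(ci, function(i) {
    aa <- code[[codons[i]]]
    sort(names(code)[code == aa & !names(code) %in% STOP_CODONS])
  })
  combos <- expand.grid(options, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    trial <- codons
    trial[ci] <- unlist(combos[r, ])
    tf <- strsplit(paste(trial, collapse = ""), "")[[1L]]
    if (grepl("^[AC]AG$", paste(tf[win], collapse = "")))
      return(trial)
  }
  stop("insertion spec at codon ", spec$codon, spec$phase,
       ": no synonymous codon combination forms a MAG proto-splice ",
       "context (site rejected)")
}

#' Write a simulation to FASTA/GFF3/TSV files
#'
#' @param sim result of [simulate_intron_gain()].
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genomes.fa")
  gff <- file.path(dir, "genes.gff3")
  write_gene_models(sim$models, gff, genomes = sim$genomes,
                    fasta_file = fasta)
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  aln_paths <- vapply(names(sim$alignments), function(g) {
    p <- file.path(dir, paste0("alignment_", g, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(unclass(sim$alignments[[g]])), p)
    p
  }, "")
  list(fasta = fasta, gff = gff, truth = truth, alignments = aln_paths)
}
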