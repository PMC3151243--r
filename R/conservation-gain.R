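# Cross-taxon / cross-gene intron position matrices, conserved-position
# queries, and Dollo-parsimony gain mapping (one gain, losses free) with
# age intervals read off a dated species tree.

#' Build a taxon-gene by position presence matrix
#'
#' Cells are `"P"` (a projected intron exists), `"A"` (the gene was
#' analysed for that taxon and no intron maps to the label) or `"U"`
#' (gene not available for that taxon: uninformative, never evidence of
#' loss). Only natively-numbered labels become columns; query-local
#' fallback labels are not comparable across taxa.
#'
#' @param projected data.frame with columns `taxon`, `gene`, `label` and
#'   optionally `native` (default all TRUE).
#' @param taxa,genes character vectors defining the row grid.
#' @param analyzed optional data.frame (`taxon`, `gene`) of pairs that
#'   were actually examined; defaults to every taxon x gene combination.
#' @return class `presence_matrix`: list with `cells` (character matrix,
#'   rows `taxon|gene`, columns labels), `taxa`, `genes`, `rows`
#'   (data.frame taxon/gene per matrix row).
#' @export
build_presence_matrix <- function(projected, taxa, genes, analyzed = NULL) {
  if (is.null(analyzed))
    analyzed <- expand.grid(taxon = taxa, gene = genes,
                            stringsAsFactors = FALSE)
  if (nrow(projected) > 0L) {
    if (is.null(projected$native)) projected$native <- TRUE
    projected <- projected[!is.na(projected$label) &
                             projected$native %in% TRUE, , drop = FALSE]
    key <- paste(projected$taxon, projected$gene, projected$label, sep = "|")
    if (anyDuplicated(key)) {
      warning("duplicate (taxon, gene, label) record(s) collapsed: ",
              paste(unique(key[duplicated(key)]), collapse = ", "),
              call. = FALSE)
      projected <- projected[!duplicated(key), , drop = FALSE]
    }
  }
  labels <- sort(unique(projected$label))
  rows <- expand.grid(taxon = taxa, gene = genes, stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$gene, genes), match(rows$taxon, taxa)), ]
  cells <- matrix("A", nrow = nrow(rows), ncol = length(labels),
                  dimnames = list(paste(rows$taxon, rows$gene, sep = "|"),
                                  labels))
  akey <- paste(analyzed$taxon, analyzed$gene, sep = "|")
  cells[!rownames(cells) %in% akey, ] <- "U"
  if (nrow(projected) > 0L) {
    for (i in seq_len(nrow(projected))) {
      rk <- paste(projected$taxon[i], projected$gene[i], sep = "|")
      if (rk %in% rownames(cells))
        cells[rk, projected$label[i]] <- "P"
    }
  }
  structure(list(cells = cells, taxa = taxa, genes = genes, rows = rows),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d taxon-gene rows x %d positions\n",
              nrow(x$cells), ncol(x$cells)))
  print(x$cells, quote = FALSE)
  invisible(x)
}

#' Write a presence matrix as TSV (P/A/U cells)
#'
#' @param pm a `presence_matrix`.
#' @param file output path.
#' @export
write_presence_matrix <- function(pm, file) {
  df <- data.frame(taxon = pm$rows$taxon, gene = pm$rows$gene,
                   pm$cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Positions conserved across taxa
#'
#' @param pm a `presence_matrix`.
#' @param min_taxa minimum number of taxa in which the position must be
#'   present.
#' @param genes restrict to these genes (default: all in the matrix).
#' @return data.frame `gene`, `label`, `taxon_count`, sorted by gene then
#'   label.
#' @export
conserved_positions <- function(pm, min_taxa = 2L, genes = NULL) {
  if (is.null(genes)) genes <- pm$genes
  out <- list()
  for (g in genes) {
    sel <- pm$rows$gene == g
    sub <- pm$cells[sel, , drop = FALSE]
    counts <- colSums(sub == "P")
    hit <- counts[counts >= min_taxa]
    if (length(hit))
      out[[g]] <- data.frame(gene = g, label = names(hit),
                             taxon_count = as.integer(hit),
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(), label = character(),
                      taxon_count = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$gene, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Positions shared by all of a set of genes
#'
#' Intersection of the genes' conserved-position label sets.
#'
#' @param pm a `presence_matrix`.
#' @param genes character vector of gene ids (>= 1).
#' @param min_taxa conservation threshold applied per gene before
#'   intersecting.
#' @return character vector of labels.
#' @export
shared_across_genes <- function(pm, genes, min_taxa = 1L) {
  sets <- lapply(genes, function(g)
    conserved_positions(pm, min_taxa = min_taxa, genes = g)$label)
  sort(Reduce(intersect, sets))
}

#' Presence vector of one (gene, label) column
#'
#' @param pm a `presence_matrix`.
#' @param gene,label column selector.
#' @return named vector over taxa with values 1 (present), 0 (absent),
#'   NA (unknown), suitable for [dollo_gain()].
#' @export
presence_vector <- function(pm, gene, label) {
  sel <- pm$rows$gene == gene
  cells <- pm$cells[sel, label]
  out <- ifelse(cells == "P", 1L, ifelse(cells == "A", 0L, NA_integer_))
  stats::setNames(out, pm$rows$taxon[sel])
}

#' Dollo-parsimony gain mapping of a binary character on a dated tree
#'
#' Under Dollo parsimony a character arises exactly once and may be lost
#' any number of times. The gain is placed on the edge above the MRCA of
#' all taxa carrying the character; the age interval of the gain is
#' bounded below by the MRCA's age and above by the age of the MRCA's
#' parent node (the gain happened somewhere on that edge). Losses are the
#' minimal set of edges below the MRCA whose subtrees contain absences
#' but no presences; subtrees containing only unknowns never create
#' losses.
#'
#' @param tree a [dated_tree()].
#' @param presence named vector over taxa: 1/0/NA (or "P"/"A"/"U").
#' @return `NULL` when no taxon is present, else class `gain_event`: list
#'   with `gain_edge` (c(parent, child) names), `mrca` (node name),
#'   `age_interval` (c(younger, older) in MY), `losses` (list of
#'   c(parent, child) edges), `n_losses`.
#' @export
dollo_gain <- function(tree, presence) {
  st <- .normalize_presence(presence)
  phy <- tree$phy
  unknown_taxa <- setdiff(names(st), phy$tip.label)
  if (length(unknown_taxa))
    stop("taxa not in tree: ", paste(unknown_taxa, collapse = ", "))
  present <- names(st)[!is.na(st) & st == 1L]
  if (!length(present)) return(NULL)
  ntip <- length(phy$tip.label)
  mrca <- if (length(present) == 1L) match(present, phy$tip.label)
          else ape::getMRCA(phy, present)
  parent_of <- function(node) {
    e <- phy$edge[phy$edge[, 2L] == node, 1L]
    if (length(e)) e else NA_integer_
  }
  children_of <- function(node) phy$edge[phy$edge[, 1L] == node, 2L]
  tip_state <- function(node) {
    lbl <- phy$tip.label[node]
    if (lbl %in% names(st)) st[[lbl]] else NA_integer_
  }
  # subtree summaries
  has_present <- has_absent <- logical(ntip + phy$Nnode)
  fill <- function(node) {
    if (node <= ntip) {
      s <- tip_state(node)
      has_present[node] <<- !is.na(s) && s == 1L
      has_absent[node] <<- !is.na(s) && s == 0L
    } else {
      for (ch in children_of(node)) fill(ch)
      ch <- children_of(node)
      has_present[node] <<- any(has_present[ch])
      has_absent[node] <<- any(has_absent[ch])
    }
  }
  root <- ntip + 1L
  fill(root)
  # minimal losses: walk down from the MRCA; a loss is charged to the
  # topmost edge whose subtree has absences but no presences
  losses <- list()
  walk <- function(node) {
    for (ch in children_of(node)) {
      if (has_present[ch]) walk(ch)
      else if (has_absent[ch])
        losses[[length(losses) + 1L]] <<-
          c(node_name(tree, node), node_name(tree, ch))
    }
  }
  walk(mrca)
  par <- parent_of(mrca)
  parent_age <- if (is.na(par)) tree$ages[mrca] else tree$ages[par]
  structure(list(
    gain_edge = c(if (is.na(par)) "root" else node_name(tree, par),
                  node_name(tree, mrca)),
    mrca = node_name(tree, mrca),
    mrca_node = mrca,
    age_interval = c(tree$ages[mrca], parent_age),
    losses = losses,
    n_losses = length(losses)), class = "gain_event")
}

.normalize_presence <- function(presence) {
  if (is.null(names(presence))) stop("presence vector must be named by taxon")
  if (is.character(presence)) {
    map <- c(P = 1L, A = 0L, U = NA_integer_,
             present = 1L, absent = 0L, unknown = NA_integer_,
             "1" = 1L, "0" = 0L)
    out <- map[presence]
    if (any(is.na(out) & !presence %in% c("U", "unknown", NA)))
      stop("unrecognised presence state(s)")
    stats::setNames(as.integer(out), names(presence))
  } else {
    stopifnot(all(presence %in% c(0L, 1L, NA)))
    stats::setNames(as.integer(presence), names(presence))
  }
}

#' @export
print.gain_event <- function(x, ...) {
  cat(sprintf("<gain_event> gain on edge %s -> %s, age %g-%g MY, %d loss(es)\n",
              x$gain_edge[1L], x$gain_edge[2L],
              x$age_interval[1L], x$age_interval[2L], x$n_losses))
  invisible(x)
}

#' Tabulate gain events for every conserved position
#'
#' Runs [dollo_gain()] over each (gene, label) column of a presence
#' matrix and collects the results.
#'
#' @param pm a `presence_matrix`.
#' @param tree a [dated_tree()] covering the matrix's taxa.
#' @param min_taxa restrict to positions conserved in at least this many
#'   taxa.
#' @return data.frame: `gene`, `label`, `gain_parent`, `gain_child`,
#'   `age_young`, `age_old`, `n_losses`.
#' @export
gain_table <- function(pm, tree, min_taxa = 1L) {
  cons <- conserved_positions(pm, min_taxa = min_taxa)
  rows <- lapply(seq_len(nrow(cons)), function(i) {
    ev <- dollo_gain(tree, presence_vector(pm, cons$gene[i], cons$label[i]))
    if (is.null(ev)) return(NULL)
    data.frame(gene = cons$gene[i], label = cons$label[i],
               gain_parent = ev$gain_edge[1L], gain_child = ev$gain_edge[2L],
               age_young = ev$age_interval[1L], age_old = ev$age_interval[2L],
               n_losses = ev$n_losses, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), label = character(),
                      gain_parent = character(), gain_child = character(),
                      age_young = numeric(), age_old = numeric(),
                      n_losses = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
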