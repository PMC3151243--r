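# Independent oracles and fixture builders used across the suite.

# Brute-force Dollo: enumerate all 0/1 assignments to free nodes (unscored
# leaves and all internal nodes), keep assignments with exactly one gain
# (a 0->1 edge, or a root in state 1 = gain on the root edge), and return
# the minimum loss count plus the set of gain-edge child nodes achieving it.
oracle_dollo <- function(tree, presence) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  obs <- rep(NA_integer_, nn)
  idx <- match(names(presence), phy$tip.label)
  obs[idx[!is.na(idx)]] <- as.integer(presence[!is.na(idx)])
  fixed <- which(!is.na(obs))
  free <- setdiff(seq_len(nn), fixed)
  m <- length(free)
  root <- ntip + 1L
  best <- Inf
  gain_children <- integer(0)
  for (mask in 0:(2^m - 1L)) {
    s <- obs
    if (m > 0L) s[free] <- bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L)
    ps <- s[phy$edge[, 1L]]
    cs <- s[phy$edge[, 2L]]
    gains_e <- which(ps == 0L & cs == 1L)
    n_gain <- length(gains_e) + as.integer(s[root] == 1L)
    if (n_gain != 1L) next
    n_loss <- sum(ps == 1L & cs == 0L)
    child <- if (s[root] == 1L) root else phy$edge[gains_e, 2L]
    if (n_loss < best) {
      best <- n_loss
      gain_children <- child
    } else if (n_loss == best) {
      gain_children <- union(gain_children, child)
    }
  }
  list(min_losses = best, gain_children = gain_children)
}

# Full-copy tandem-repeat scan: for every start position and unit size,
# count whole copies of the leading unit; keep primitive-unit candidates
# that are left-maximal (no full preceding copy) and right-maximal (the
# next base does not continue the period), then apply the same
# longest-run-wins selection as the detector.
oracle_simple_repeats <- function(seq, max_unit = 6L, min_total = 12L,
                                  min_copies = 3L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  primitive <- function(unit) {
    u <- nchar(unit)
    for (p in seq_len(u - 1L))
      if (u %% p == 0L && unit == strrep(substr(unit, 1L, p), u / p))
        return(FALSE)
    TRUE
  }
  cand <- list()
  for (s in seq_len(n)) {
    for (u in seq_len(max_unit)) {
      if (s + u - 1L > n) next
      unit <- substr(seq, s, s + u - 1L)
      if (!primitive(unit)) next
      k <- 0L
      while (s + (k + 1L) * u - 1L <= n &&
             substr(seq, s + k * u, s + (k + 1L) * u - 1L) == unit)
        k <- k + 1L
      len <- k * u
      if (k < min_copies || len < min_total) next
      e <- s + len - 1L
      if (s - u >= 1L && substr(seq, s - u, s - 1L) == unit) next
      if (e + 1L <= n &&
          substr(seq, e + 1L, e + 1L) == substr(seq, e + 1L - u, e + 1L - u))
        next
      cand[[length(cand) + 1L]] <-
        data.frame(unit = unit, start = s, end = e, length = len,
                   copies = as.numeric(k), stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(unit = character(), start = integer(), end = integer(),
                      length = integer(), copies = numeric(),
                      stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand), , drop = FALSE]
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

# random ultrametric dated tree with n leaves
random_dated_tree <- function(n, root_age = 100) {
  phy <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
  phy$edge.length <- phy$edge.length / max(ape::node.depth.edgelength(phy)) *
    root_age
  dated_tree(phy, root_age = root_age)
}

# random intronless coding genome + matching CDS model on the plus strand
random_cds_model <- function(n_codons = 50L, gene_id = "g",
                             seq_id = "chr") {
  sense <- setdiff(as.vector(outer(outer(c("T", "C", "A", "G"),
                                         c("T", "C", "A", "G"), paste0),
                                   c("T", "C", "A", "G"), paste0)),
                   c("TAA", "TAG", "TGA"))
  cds <- paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)),
               collapse = "")
  list(cds = cds,
       genome = stats::setNames(cds, seq_id),
       model = gene_model(gene_id, seq_id, "+", cbind(1L, nchar(cds))))
}

# mirror a plus-strand model: reverse-complement the genome and flip the
# exon coordinates; the mirrored minus-strand model must splice to the
# same transcript
mirror_model <- function(model, genome) {
  L <- nchar(genome)
  ex <- model$exons
  gene_model(model$gene_id, model$seq_id, "-",
             cbind(L - ex[, 2L] + 1L, L - ex[, 1L] + 1L),
             model$codon_start_offset)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

fixture_path <- function(file) system.file("extdata", file,
                                           package = "introgain")
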