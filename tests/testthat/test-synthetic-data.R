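# The seeded simulator and end-to-end recovery of its ground truth.

sim_tree <- function() acanthopterygii_tree()

test_that("identical seed and configuration give identical output", {
  spec <- insertion_spec("acanthopterygii", codon = 41, phase = "a",
                         length = 120, gc_target = 40)
  a <- simulate_intron_gain(sim_tree(), n_codons = 60, specs = spec, seed = 42)
  b <- simulate_intron_gain(sim_tree(), n_codons = 60, specs = spec, seed = 42)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth, b$truth)
  c <- simulate_intron_gain(sim_tree(), n_codons = 60, specs = spec, seed = 43)
  expect_false(identical(a$genomes, c$genomes))
})

test_that("no specs yields single-exon genes with no introns anywhere", {
  sim <- simulate_intron_gain(sim_tree(), n_codons = 50, seed = 1)
  expect_equal(nrow(sim$truth), 0L)
  for (m in sim$models) {
    expect_equal(nrow(m$exons), 1L)
    expect_equal(nrow(extract_introns(m, sim$genomes)), 0L)
  }
})

test_that("a stem insertion reaches all four descendants and is exactly recovered", {
  spec <- insertion_spec("acanthopterygii", codon = 41, phase = "a",
                         length = 120, gc_target = 40)
  sim <- simulate_intron_gain(sim_tree(), n_codons = 60, specs = spec,
                              seed = 7)
  expect_setequal(unique(sim$truth$taxon),
                  c("Takifugu", "Tetraodon", "medaka", "stickleback"))
  expect_equal(nrow(sim$truth), 4L)
  for (m in sim$models) {
    taxon <- sub("_gene1$", "", m$gene_id)
    introns <- extract_introns(m, sim$genomes)
    row <- sim$truth[sim$truth$seq_id == m$gene_id, ]
    if (nrow(row) == 0L) {
      expect_equal(nrow(introns), 0L)
      next
    }
    expect_equal(nrow(introns), 1L)
    expect_equal(introns$length, 120L)
    expect_equal(introns$cds_offset, 121L)
    ph <- assign_phase(introns$cds_offset)
    expect_equal(ph$codon, 41L)
    expect_identical(ph$phase, "a")
    expect_equal(c(introns$start, introns$end),
                 c(row$intron_start, row$intron_end))
    expect_lte(abs(introns$gc_percent - 40), 1)
    expect_identical(introns$donor2, "GT")
    expect_identical(introns$acceptor2, "AG")
    # enforced proto-splice context
    expect_true(classify_proto_splice(introns$upstream4)$matches_MAG)
  }
})

test_that("an embedded repeat is recovered at its recorded interval", {
  spec <- insertion_spec("stickleback", codon = 36, phase = "a", length = 33,
                         gc_target = 93.9, repeat_unit = "CGG",
                         repeat_copies = 9)
  sim <- simulate_intron_gain(sim_tree(), n_codons = 50, specs = spec,
                              seed = 5)
  expect_equal(nrow(sim$truth), 1L)
  m <- sim$models[[which(vapply(sim$models, function(m)
    m$gene_id == "stickleback_gene1", TRUE))]]
  introns <- extract_introns(m, sim$genomes)
  expect_equal(introns$length, 33L)
  expect_gte(introns$gc_percent, 90)
  expect_true(introns$ultrasmall)
  iseq <- substr(sim$genomes[[m$seq_id]], introns$start, introns$end)
  found <- find_simple_repeats(iseq)
  # the embedded CGG run (possibly extended by chance flanking bases)
  hit <- found[found$unit %in% c("CGG", "GGC", "GCG"), ]
  expect_equal(nrow(hit), 1L)
  expect_gte(hit$length, 27L)
  overlap <- min(hit$end, sim$truth$repeat_end) -
    max(hit$start, sim$truth$repeat_start) + 1L
  expect_gte(overlap, 25L)
})

test_that("unachievable GC targets and infeasible repeats are rejected", {
  expect_error(
    simulate_intron_gain(sim_tree(), n_codons = 50, seed = 2,
                         specs = insertion_spec("medaka", codon = 10,
                                                phase = "c", length = 30,
                                                gc_target = 0)),
    "unachievable")
  expect_error(insertion_spec("medaka", codon = 10, phase = "c", length = 20,
                              repeat_unit = "CGG", repeat_copies = 9),
               "does not fit")
  expect_error(insertion_spec("medaka", codon = 10, phase = "c", length = 5),
               "18-10000")
})

test_that("recovery is exact under substitution noise and Dollo finds the true branch", {
  specs <- list(
    insertion_spec("acanthopterygii", codon = 41, phase = "a", length = 120,
                   gc_target = 40),
    insertion_spec("acanthopterygii", codon = 77, phase = "c", length = 87,
                   gc_target = 55),
    insertion_spec("tetraodontidae", codon = 140, phase = "c", length = 200,
                   gc_target = 45))
  tree <- sim_tree()
  sim <- simulate_intron_gain(tree, n_codons = 200,
                              substitution_rate = 0.002, specs = specs,
                              seed = 11)
  expect_equal(nrow(sim$truth), 4L + 4L + 2L)
  rec <- list()
  for (m in sim$models) {
    taxon <- sub("_gene1$", "", m$gene_id)
    introns <- extract_introns(m, sim$genomes)
    truth <- sim$truth[sim$truth$seq_id == m$gene_id, ]
    truth <- truth[order(truth$cds_offset), ]
    expect_equal(nrow(introns), nrow(truth))
    if (nrow(truth) == 0L) next
    expect_equal(introns$length, truth$length)
    expect_equal(introns$cds_offset, truth$cds_offset)
    for (i in seq_len(nrow(introns))) {
      ph <- assign_phase(introns$cds_offset[i])
      expect_equal(ph$codon, truth$codon[i])
      expect_identical(ph$phase, truth$phase[i])
      expect_lte(abs(introns$gc_percent[i] - truth$gc_target[i]), 1)
      rec[[length(rec) + 1L]] <- data.frame(taxon = taxon, gene = "gene1",
                                            label = paste0(ph$codon,
                                                           ph$phase))
    }
  }
  rec <- do.call(rbind, rec)
  pm <- build_presence_matrix(rec, taxa = tree$phy$tip.label,
                              genes = "gene1")
  for (s in specs) {
    ev <- dollo_gain(tree, presence_vector(pm, "gene1",
                                           paste0(s$codon, s$phase)))
    expect_identical(ev$gain_edge[2L], s$branch)
    expect_equal(ev$n_losses, 0L)
  }
})

test_that("the true alignment projects simulated introns onto ancestral numbering", {
  spec <- insertion_spec("smegmamorpha", codon = 33, phase = "b",
                         length = 60, gc_target = 50)
  sim <- simulate_intron_gain(sim_tree(), n_codons = 80,
                              substitution_rate = 0.001, specs = spec,
                              seed = 23)
  aln <- sim$alignments$gene1
  for (taxon in c("medaka", "stickleback")) {
    m <- sim$models[[which(vapply(sim$models, function(m)
      m$gene_id == paste0(taxon, "_gene1"), TRUE))]]
    introns <- extract_introns(m, sim$genomes)
    proj <- project_introns(introns, taxon, aln, "Takifugu")
    expect_identical(proj$label, "33b")
    expect_true(proj$native)
  }
})

test_that("simulations serialise to FASTA/GFF3 and read back identically", {
  spec <- insertion_spec("medaka", codon = 20, phase = "c", length = 45,
                         gc_target = 60)
  sim <- simulate_intron_gain(sim_tree(), n_codons = 40, specs = spec,
                              seed = 3)
  dir <- tempfile("simout")
  paths <- write_simulation(sim, dir)
  back <- read_gene_models(paths$gff, paths$fasta)
  expect_equal(length(back$models), length(sim$models))
  medaka <- back$models[[which(vapply(back$models, function(m)
    m$gene_id == "medaka_gene1", TRUE))]]
  orig <- sim$models[[which(vapply(sim$models, function(m)
    m$gene_id == "medaka_gene1", TRUE))]]
  expect_equal(medaka$exons, orig$exons)
  truth <- utils::read.delim(paths$truth)
  expect_equal(nrow(truth), nrow(sim$truth))
})
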