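# Intron extraction and the per-intron descriptors: GC, splice signals,
# proto-splice compliance, ultrasmall flags, simple repeats.

test_that("extraction finds the inter-exon gap with correct coordinates and offset", {
  set.seed(5)
  genome <- stats::setNames(random_dna(220L), "chr")
  m <- gene_model("g", "chr", "+", cbind(c(1L, 161L), c(60L, 220L)))
  introns <- extract_introns(m, genome)
  expect_equal(nrow(introns), 1L)
  expect_equal(introns$start, 61L)
  expect_equal(introns$end, 160L)
  expect_equal(introns$length, 100L)
  expect_equal(introns$cds_offset, 60L)
  expect_identical(introns$upstream4, unname(substr(genome, 57, 60)))
  expect_identical(introns$downstream4, unname(substr(genome, 61, 64)))
  expect_identical(introns$downstream_exon_base,
                   unname(substr(genome, 161, 161)))
})

test_that("single-exon models yield no introns; abutting exons are fatal", {
  genome <- stats::setNames(strrep("ACGT", 50), "chr")
  single <- gene_model("g", "chr", "+", cbind(1L, 90L))
  expect_equal(nrow(extract_introns(single, genome)), 0L)
  abut <- gene_model("g", "chr", "+", cbind(c(1L, 61L), c(60L, 120L)))
  expect_error(extract_introns(abut, genome), "zero-length gap")
})

test_that("minus-strand extraction mirrors the plus-strand model", {
  set.seed(9)
  for (rep in 1:5) {
    genome <- random_dna(300L)
    cuts <- sort(sample(20:280, 4L))
    ex <- cbind(c(1L, cuts[2L], cuts[4L]), c(cuts[1L], cuts[3L], 300L))
    plus <- gene_model("g", "chr", "+", ex)
    minus <- mirror_model(plus, genome)
    ip <- extract_introns(plus, stats::setNames(genome, "chr"))
    im <- extract_introns(minus, stats::setNames(revcomp(genome), "chr"))
    expect_equal(im$cds_offset, ip$cds_offset)
    expect_equal(im$length, ip$length)
    expect_identical(im$upstream4, ip$upstream4)
    expect_identical(im$downstream4, ip$downstream4)
    expect_identical(im$donor2, ip$donor2)
  }
})

test_that("GC content is computed as percent with half-up one-decimal rounding", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCGC"), 100)
  set.seed(2)
  seq120 <- paste(sample(c(rep("G", 24), rep("C", 24), rep("A", 36),
                           rep("T", 36))), collapse = "")
  expect_equal(gc_content(seq120), 40)
  # 559 GC in 1000 -> 55.9; 555/999 = 55.5555 -> 55.6 (half-up)
  expect_equal(gc_content(paste0(strrep("G", 559), strrep("A", 441))), 55.9)
  expect_equal(gc_content(paste0(strrep("C", 555), strrep("T", 444))), 55.6)
  # N counts in the denominator only
  expect_equal(gc_content("GCNN"), 50)
  expect_error(gc_content(""), "empty")
})

test_that("GC content is invariant under reverse complement", {
  set.seed(4)
  for (rep in 1:10) {
    s <- random_dna(sample(20:500, 1L))
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("splice signals classify GT...AG as canonical", {
  expect_true(splice_signal("GTAAGTTTTAG")$canonical)
  gc_intron <- splice_signal(paste0("GCAAG", strrep("T", 20), "AG"))
  expect_false(gc_intron$canonical)
  expect_identical(gc_intron$donor2, "GC")
  expect_error(splice_signal("GTA"), "shorter than 4")
})

test_that("proto-splice classification scores M, A, G and R slots", {
  full <- classify_proto_splice("GCAG", "GTGA")
  expect_true(full$matches_MAG)
  expect_length(full$deviations, 0L)

  m_dev <- classify_proto_splice("AGAG", "GTCT")
  expect_false(m_dev$matches_MAG)
  expect_identical(m_dev$deviations, "M")

  a_dev <- classify_proto_splice("ACCG")
  expect_identical(a_dev$deviations, "A")

  with_r <- classify_proto_splice("AAAG", downstream_exon_base = "A")
  expect_true(with_r$matches_MAG)
  expect_true(with_r$matches_R)
  expect_length(with_r$deviations, 0L)

  r_dev <- classify_proto_splice("ACAG", downstream_exon_base = "T")
  expect_identical(r_dev$deviations, "R")

  expect_error(classify_proto_splice("AC.G"), "non-nucleotide")
})

test_that("extracted flank deviations stay within the MAG^R slot set", {
  set.seed(12)
  genome <- random_dna(400L)
  ex <- cbind(c(1L, 101L, 301L), c(80L, 250L, 400L))
  m <- gene_model("g", "chr", "+", ex)
  introns <- extract_introns(m, stats::setNames(genome, "chr"))
  for (i in seq_len(nrow(introns))) {
    rep_ <- classify_proto_splice(introns$upstream4[i],
                                  introns$downstream4[i],
                                  introns$downstream_exon_base[i])
    expect_true(all(rep_$deviations %in% c("M", "A", "G", "R")))
  }
})

test_that("ultrasmall flag uses a strict threshold", {
  expect_true(flag_ultrasmall(18))
  expect_true(flag_ultrasmall(33))
  expect_false(flag_ultrasmall(87))
  expect_false(flag_ultrasmall(60))
  expect_true(flag_ultrasmall(87, threshold = 100))
  expect_error(flag_ultrasmall(0), ">= 1")
})

test_that("simple-repeat detection matches the spec'd worked examples", {
  r1 <- find_simple_repeats(paste0("AA", strrep("TG", 15), "C"))
  expect_equal(nrow(r1), 1L)
  expect_identical(r1$unit, "TG")
  expect_equal(r1$start, 3L)
  expect_equal(r1$end, 32L)
  expect_equal(r1$copies, 15)

  r2 <- find_simple_repeats(paste0("GTG", strrep("CGG", 10)))
  expect_equal(nrow(r2), 1L)
  expect_identical(r2$unit, "CGG")
  expect_equal(r2$start, 4L)
  expect_equal(r2$end, 33L)
  expect_equal(r2$copies, 10)

  expect_equal(nrow(find_simple_repeats("ACGTACGA")), 0L)
})

test_that("every reported repeat interval re-validates against its unit", {
  set.seed(21)
  for (rep_i in 1:10) {
    s <- paste0(random_dna(20), strrep("CAG", sample(4:9, 1)),
                random_dna(15), strrep("AT", sample(6:12, 1)),
                random_dna(10))
    found <- find_simple_repeats(s)
    for (i in seq_len(nrow(found))) {
      sub <- substr(s, found$start[i], found$end[i])
      expect_identical(sub, strrep(found$unit[i], found$copies[i]))
    }
  }
})

test_that("repeat detection agrees with the exhaustive full-copy oracle", {
  set.seed(33)
  for (rep_i in 1:12) {
    # low-entropy alphabet so repeats arise spontaneously
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE,
                      prob = c(.4, .1, .1, .4)), collapse = "")
    s <- paste0(s, strrep(sample(c("TA", "CGG", "T"), 1), sample(3:8, 1)))
    got <- find_simple_repeats(s, min_total = 8L, min_copies = 3L)
    want <- oracle_simple_repeats(s, min_total = 8L, min_copies = 3L)
    expect_equal(got, want)
  }
})

test_that("repeat annotation importer keeps out-of-range rows with a warning", {
  expect_warning(rep_tab <- mcr_intron_repeats(),
                 "beyond the stated intron length")
  expect_true(any(rep_tab$type == "UnaL2" & rep_tab$to == 2929))
  expect_equal(nrow(rep_tab), 25L)
})
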