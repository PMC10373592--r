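# locus model: construction, haplotype sequences, in-silico PCR, digestion

test_that("demo locus satisfies its structural contract", {
  loc <- demo_locus
  expect_s3_class(loc, "locus_model")
  expect_equal(nchar(loc$reference), 586L)
  expect_length(loc$haplotypes, 15L)
  expect_length(loc$variable_positions, 36L)
  expect_equal(vapply(loc$targets, `[[`, integer(1), "cut_site"),
               c(sgRNA1 = 214L, sgRNA2 = 314L))
  # cut sites 100 bp apart, PAM NGG on both targets
  for (t in loc$targets) expect_match(t$pam, "^.GG$")
  # copy6 is the doubly-uneditable donor allele
  expect_false(any(loc$haplotypes$copy6$editable_per_target))
  expect_true(all(loc$haplotypes$copy1$editable_per_target))
  for (p in names(loc$indicators)) validate_indicator(loc, loc$indicators[[p]])
})

test_that("locus config round-trips through disk with full validation", {
  dir <- withr::local_tempdir()
  write_locus(demo_locus, dir)
  loc2 <- load_locus(dir)
  expect_equal(loc2$reference, demo_locus$reference)
  expect_equal(names(loc2$haplotypes), names(demo_locus$haplotypes))
  expect_equal(loc2$variable_positions, demo_locus$variable_positions)
  expect_equal(haplotype_sequence(loc2, "copy6"),
               haplotype_sequence(demo_locus, "copy6"))
  expect_equal(vapply(loc2$variants, `[[`, "", "expected"),
               vapply(demo_locus$variants, `[[`, "", "expected"))
})

test_that("load_locus rejects broken configs with located errors", {
  dir <- withr::local_tempdir()
  write_locus(demo_locus, dir)
  # protospacer absent from the reference
  tg <- read.delim(file.path(dir, "targets.tsv"))
  tg$protospacer[1] <- strrep("A", 20)
  write.table(tg, file.path(dir, "targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_locus(dir), "not found in reference")
  # SNP position out of range
  write_locus(demo_locus, dir)
  hp <- read.delim(file.path(dir, "haplotypes.tsv"))
  hp$position[1] <- 9999L
  write.table(hp, file.path(dir, "haplotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_locus(dir), "out of range")
  # missing reference
  unlink(file.path(dir, "reference.fa"))
  expect_error(load_locus(dir), "missing reference")
})

test_that("zero haplotypes degenerates to a reference-only haplotype set", {
  loc <- locus_model(demo_locus$reference, list(), demo_locus$targets,
                     demo_locus$primers, demo_locus$enzymes)
  expect_length(loc$haplotypes, 1L)
  expect_equal(haplotype_sequence(loc, "reference"), loc$reference)
})

test_that("haplotype_sequence applies profiles exactly at their keys", {
  expect_equal(haplotype_sequence(demo_locus, "copy1"), demo_locus$reference)
  expect_error(haplotype_sequence(demo_locus, "copy99"), "unknown haplotype")
  # single-substitution case
  p100 <- substr(demo_locus$reference, 101, 101)
  alt <- setdiff(c("A", "C", "G", "T"), p100)[1]
  loc <- locus_model(demo_locus$reference,
                     list(haplotype("h", setNames(alt, "100"))),
                     demo_locus$targets, demo_locus$primers, demo_locus$enzymes)
  s <- haplotype_sequence(loc, "h")
  d <- which(strsplit(s, "")[[1]] != strsplit(loc$reference, "")[[1]])
  expect_equal(d, 101L)
  # every demo haplotype differs from the reference exactly at its profile keys
  refc <- strsplit(demo_locus$reference, "")[[1]]
  for (h in demo_locus$haplotypes) {
    sc <- strsplit(haplotype_sequence(demo_locus, h$id), "")[[1]]
    expect_equal(which(sc != refc) - 1L,
                 as.integer(names(h$snp_profile)), info = h$id)
  }
  # all 15 sequences pairwise distinct
  seqs <- vapply(names(demo_locus$haplotypes),
                 function(h) haplotype_sequence(demo_locus, h), character(1))
  expect_length(unique(seqs), 15L)
})

test_that("uneditable flags correspond to altered target strings", {
  for (h in demo_locus$haplotypes) {
    s <- haplotype_sequence(demo_locus, h$id)
    for (t in demo_locus$targets) {
      w <- c(t$pam_start - 20L, t$pam_start + 3L)
      obs <- substr(s, w[1] + 1L, w[2])
      canon <- paste0(t$protospacer, t$pam)
      expect_equal(h$editable_per_target[[t$id]], obs == canon,
                   info = paste(h$id, t$id))
    }
  }
})

test_that("in_silico_pcr yields the diagnostic product sizes", {
  expect_equal(nchar(in_silico_pcr(demo_locus$reference, demo_locus$primers$CAPS)),
               586L)
  expect_equal(nchar(in_silico_pcr(demo_locus$reference, demo_locus$primers$CE1)),
               224L)
  expect_equal(nchar(in_silico_pcr(demo_locus$reference, demo_locus$primers$CE2)),
               216L)
  # dropout template: 100 bp removed between the cuts -> 486 bp product
  dropout <- paste0(substr(demo_locus$reference, 1, 214),
                    substr(demo_locus$reference, 315, 586))
  expect_equal(nchar(in_silico_pcr(dropout, demo_locus$primers$CAPS)), 486L)
  # absent primer -> no product
  foreign <- primer_pair("x", strrep("A", 20), demo_locus$primers$CAPS$reverse)
  expect_equal(in_silico_pcr(demo_locus$reference, foreign), "")
  # idempotence: PCR on its own product returns the product
  prod <- in_silico_pcr(demo_locus$reference, demo_locus$primers$CE2)
  expect_equal(in_silico_pcr(prod, demo_locus$primers$CE2), prod)
  # ambiguous binding is an error
  amb <- primer_pair("amb", "ACGT", "ACGT")
  expect_error(in_silico_pcr(strrep("ACGT", 30), amb), "multiple binding")
})

test_that("digestion produces the expected fragments and conserves length", {
  ref <- demo_locus$reference
  expect_equal(digest(ref, demo_locus$enzymes$KflI), c(314L, 272L))
  # no site -> single fragment
  expect_equal(digest(strrep("A", 50), demo_locus$enzymes$KflI), 50L)
  # 1 bp deletion at the cut destroying the site -> resistant full-length band
  mut <- paste0(substr(ref, 1, 314), substr(ref, 316, 586))  # deletes the A of GGGACCC
  expect_equal(digest(mut, demo_locus$enzymes$KflI), nchar(mut))
  # IUPAC degenerate recognition
  enzN <- restriction_enzyme("degN", "GGNACCC", 3L)
  amp <- paste0(strrep("A", 20), "GGTACCC", strrep("C", 13))
  expect_equal(digest(amp, enzN), c(23L, 17L))
  # property: length conservation over random amplicons and enzymes
  set.seed(7)
  for (i in 1:20) {
    amp <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    enz <- restriction_enzyme("e", paste(sample(c("A", "C", "G", "T"), 4,
                                                replace = TRUE), collapse = ""),
                              sample(0:4, 1))
    expect_equal(sum(digest(amp, enz)), 300L)
  }
})

test_that("pam_relative maps coordinates to display labels", {
  t1 <- demo_locus$targets$sgRNA1
  expect_equal(pam_relative(t1, 216L), "-1")   # adjacent to the PAM
  expect_equal(pam_relative(t1, 213L), "-4")
  expect_equal(pam_relative(t1, 197L), "-20")
  expect_equal(pam_relative(t1, 217L), "P1")
  expect_true(is.na(pam_relative(t1, 100L)))
})
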