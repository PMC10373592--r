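# synthetic data: determinism, truth conservation, forced scenarios

test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(seed = 5, n_reads = 500, error_rate = 0.005,
                    truncate_prob = 0.05, revcomp_prob = 0.5, n_lineages = 3)
  run <- function() {
    lin <- simulate_lineages(cfg, demo_locus)
    d <- withr::local_tempdir()
    g <- generate_reads(lin, cfg, demo_locus,
                        fastq = file.path(d, "r.fq"),
                        truth_path = file.path(d, "t.tsv"))
    list(fq = readLines(file.path(d, "r.fq")), tt = readLines(file.path(d, "t.tsv")),
         g = g)
  }
  a <- run()
  b <- run()
  expect_identical(a$fq, b$fq)
  expect_identical(a$tt, b$tt)
  # truth table rows and emitted reads are bijective
  expect_identical(a$g$truth$read_id, names(a$g$reads))
})

test_that("cut probability 0 leaves every copy unedited", {
  cfg <- sim_config(seed = 2, cut_prob = 0, large_del_prob = 0)
  lin <- simulate_lineages(cfg, demo_locus)
  expect_true(all(vapply(lin[[1]]$copies, function(cp) length(cp$events) == 0L,
                         logical(1))))
})

test_that("forced HDR with a whole-amplicon tract copies the donor genotype", {
  ev <- edit_event("hdr_conversion", 0, size = 586, donor_hap = "copy6",
                   tract_start = 0, tract_end = 586)
  lin <- list(cell_lineage("L1", 1, list(list(hap_id = "copy2", events = list(ev)))))
  cfg <- sim_config(seed = 3, n_reads = 10, exact_counts = TRUE)
  g <- generate_reads(lin, cfg, demo_locus)
  expect_true(all(g$reads == haplotype_sequence(demo_locus, "copy6")))
})

test_that("uneditable haplotypes never receive NHEJ or dropout events", {
  cfg <- sim_config(seed = 9, cut_prob = 1, large_del_prob = 0.3,
                    dosage = c(copy1 = 2, copy3 = 1, copy6 = 2, copy15 = 1),
                    n_lineages = 5)
  lin <- simulate_lineages(cfg, demo_locus)
  for (L in lin) for (cp in L$copies) {
    ed <- demo_locus$haplotypes[[cp$hap_id]]$editable_per_target
    for (e in cp$events) {
      expect_false(e$kind == "large_deletion" && !all(ed))
      if (e$kind %in% c("insertion", "deletion"))
        expect_true(ed[[e$target_id]], info = cp$hap_id)
    }
  }
})

test_that("realized edited-copy fraction follows the cut probability", {
  cfg <- sim_config(seed = 4, cut_prob = c(sgRNA1 = 0, sgRNA2 = 0.73),
                    large_del_prob = 0, n_lineages = 10,
                    dosage = c(copy1 = 1, copy2 = 1, copy4 = 1, copy5 = 1))
  lin <- simulate_lineages(cfg, demo_locus)
  edited <- unlist(lapply(lin, function(L) vapply(L$copies, function(cp)
    length(cp$events) > 0L, logical(1))))
  n <- length(edited)   # 40 editable copies
  expect_equal(n, 40L)
  # binomial 3 sigma around 0.73
  expect_lt(abs(mean(edited) - 0.73), 3 * sqrt(0.73 * 0.27 / n))
})

test_that("error-free reads reproduce molecule sequences and exact class counts", {
  lin <- edited_fraction_lineage(0.6)
  cfg <- sim_config(seed = 8, n_reads = 10000)
  g <- generate_reads(lin, cfg, demo_locus)
  # every read equals a molecule sequence exactly
  expect_true(all(nchar(g$reads) %in% c(586L, 587L)))
  edited_frac <- mean(g$truth$class_sgRNA2 == "edited")
  expect_lt(abs(edited_frac - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
  # exact_counts pins the composition exactly
  cfg2 <- sim_config(seed = 8, n_reads = 10000, exact_counts = TRUE)
  g2 <- generate_reads(lin, cfg2, demo_locus)
  expect_equal(sum(g2$truth$class_sgRNA2 == "edited"), 6000L)
  # all-WT pool: reads equal the haplotype sequence
  linwt <- list(cell_lineage("W", 1, list(list(hap_id = "copy2"))))
  gwt <- generate_reads(linwt, sim_config(seed = 1, n_reads = 50), demo_locus)
  expect_true(all(gwt$reads == haplotype_sequence(demo_locus, "copy2")))
})

test_that("clone reads: n = 1 emits one record; ids bijective with truth", {
  lin <- edited_fraction_lineage(0.5)
  cfg <- sim_config(seed = 6, n_clones = 1)
  d <- withr::local_tempdir()
  g <- generate_clone_reads(lin, cfg, demo_locus, fasta = file.path(d, "c.fa"))
  expect_length(g$reads, 1L)
  back <- read_reads(file.path(d, "c.fa"))
  expect_identical(back, g$reads)
  expect_identical(g$truth$read_id, names(g$reads))
})

test_that("dropout molecules at 35% appear at the expected clone frequency", {
  cut1 <- demo_locus$targets$sgRNA1$cut_site
  cut2 <- demo_locus$targets$sgRNA2$cut_site
  lin <- list(cell_lineage("L1", 1, list(
    list(hap_id = "copy1", weight = 0.35,
         events = list(edit_event("large_deletion", cut1, size = cut2 - cut1))),
    list(hap_id = "copy1", weight = 0.65))))
  cfg <- sim_config(seed = 12, n_clones = 80, exact_counts = TRUE)
  g <- generate_clone_reads(lin, cfg, demo_locus)
  expect_equal(sum(g$truth$large_deletion), 28L)
  expect_equal(sum(nchar(g$reads) == 486L), 28L)
})

test_that("truncated reads lose the downstream indicator", {
  lin <- edited_fraction_lineage(0)
  cfg <- sim_config(seed = 13, n_reads = 10000, truncate_prob = 0.05)
  g <- generate_reads(lin, cfg, demo_locus)
  n_trunc <- sum(g$truth$truncated)
  expect_lt(abs(n_trunc - 500), 3 * sqrt(10000 * 0.05 * 0.95))
  fl <- filter_reads(g$reads, demo_locus$indicators[["sgRNA2.A"]])
  expect_equal(fl$excluded, n_trunc)
})

test_that("peak tables reflect molecule composition", {
  # classes {0: 0.5, -4: 0.5} at wt_size 216 -> equal peaks at 216 and 212
  cut2 <- demo_locus$targets$sgRNA2$cut_site
  lin <- list(cell_lineage("L1", 1, list(
    list(hap_id = "copy1", weight = 0.5),
    list(hap_id = "copy1", weight = 0.5,
         events = list(edit_event("deletion", cut2 - 2L, size = 4L,
                                  target_id = "sgRNA2"))))))
  pt <- generate_peak_table(lin, demo_locus, "sgRNA2", 216)
  expect_equal(sort(pt$size), c(212, 216))
  expect_equal(pt$height[1], pt$height[2])
  # four edit classes -> four mutant peaks with heights matching fractions
  fr <- c(0.4, 0.3, 0.2, 0.1)
  szs <- c(1L, 2L, 4L, 5L)
  copies <- lapply(1:4, function(i)
    list(hap_id = "copy1", weight = fr[i],
         events = list(edit_event("deletion", cut2 - 1L, size = szs[i],
                                  target_id = "sgRNA2"))))
  lin4 <- list(cell_lineage("L1", 1, copies))
  pt4 <- generate_peak_table(lin4, demo_locus, "sgRNA2", 216, max_rfu = 400)
  expect_equal(nrow(pt4), 4L)
  expect_equal(sort(pt4$size), sort(216 - szs))
  expect_equal(pt4$height[order(pt4$size, decreasing = TRUE)][1:2] /
                 max(pt4$height), c(1, 0.75))
})

test_that("sim configs survive the JSON round trip", {
  cfg <- sim_config(seed = 99, hdr_prob = 0.27, donor = "copy6",
                    dosage = c(copy1 = 1, copy6 = 0.03))
  p <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg2[order(names(cfg2))], cfg[order(names(cfg))])
})
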