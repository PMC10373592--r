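# indicator-pair filtering, per-read calling, oracle equivalence, summaries

# invert the display label back to an absolute 0-based coordinate
lab_to_abs <- function(lab, target) {
  if (grepl("^P", lab)) return(target$pam_start + as.integer(sub("P", "", lab)) - 1L)
  v <- as.integer(lab)
  if (v < 0) target$pam_start + v else v
}

apply_indel <- function(ref, kind, pos, size, bases = "") {
  if (kind == "deletion")
    paste0(substr(ref, 1, pos), substr(ref, pos + size + 1, nchar(ref)))
  else
    paste0(substr(ref, 1, pos), bases, substr(ref, pos + 1, nchar(ref)))
}

test_that("filter_reads keeps exactly the reads covering the window", {
  pair <- demo_locus$indicators[["sgRNA2.A"]]
  ref <- demo_locus$reference
  reads <- c(full = ref,
             rc = crispamp::revcomp(ref),
             no_right = substr(ref, 1, 340),      # truncated before right anchor
             no_left = substr(ref, 300, 586),
             unrelated = strrep("ACGT", 150))
  fl <- filter_reads(reads, pair)
  expect_setequal(names(fl$used), c("full", "rc"))
  expect_equal(fl$excluded, 3L)
  # orientation normalized: both retained reads identical
  expect_equal(unname(fl$used["rc"]), unname(fl$used["full"]))
})

test_that("call_read matches the worked single-read cases", {
  ref <- demo_locus$reference
  t1 <- demo_locus$targets$sgRNA1
  # identical to reference -> WT with no events
  c0 <- call_read(ref, demo_locus, "sgRNA1")
  expect_equal(c0$status, "WT")
  expect_equal(c0$events, "")
  # single G inserted 3 bp upstream of the sgRNA1 PAM (at the cut)
  rd <- apply_indel(ref, "insertion", t1$cut_site, 1L, "G")
  c1 <- call_read(rd, demo_locus, "sgRNA1")
  expect_equal(c1$status, "edited")
  expect_equal(c1$net_indel, 1L)
  expect_true(c1$frameshift)
  expect_match(c1$events, ":\\+1G$")
  # 3 bp deletion at the cut: edited but in-frame
  rd3 <- apply_indel(ref, "deletion", t1$cut_site - 2L, 3L)
  c3 <- call_read(rd3, demo_locus, "sgRNA1")
  expect_equal(c3$status, "edited")
  expect_equal(c3$net_indel, -3L)
  expect_false(c3$frameshift)
  # substitution inside the WT window: edited, net 0, no indel
  ch <- strsplit(ref, "")[[1]]
  ch[t1$cut_site + 1L] <- setdiff(c("A", "C", "G", "T"), ch[t1$cut_site + 1L])[1]
  cs <- call_read(paste(ch, collapse = ""), demo_locus, "sgRNA1")
  expect_equal(cs$status, "edited")
  expect_equal(cs$net_indel, 0L)
  expect_false(cs$has_indel)
  expect_false(cs$frameshift)
})

test_that("call_read equals the brute-force single-indel oracle", {
  ref <- mini_locus$reference
  t1 <- mini_locus$targets$t1
  params <- call_params(comparison_range = 10, wt_marker = 5)
  checked <- 0L
  for (size in 1:3) {
    for (pos in (t1$cut_site - 5L):(t1$cut_site + 4L)) {
      for (kind in c("deletion", "insertion")) {
        bases <- if (kind == "insertion")
          paste(rep(c("G", "A", "T"), length.out = size), collapse = "") else ""
        rd <- apply_indel(ref, kind, pos, size, bases)
        wt_win <- substr(ref, t1$cut_site - 4L, t1$cut_site + 5L)
        if (grepl(wt_win, rd, fixed = TRUE)) next  # window intact: WT by design
        cl <- call_read(rd, mini_locus, "t1", params)
        ora <- oracle_single_indel(ref, rd)
        expect_false(is.null(ora))
        expect_equal(cl$status, "edited")
        expect_equal(cl$n_events, 1L)
        lab <- sub("^.*:", "", cl$events)
        expect_equal(cl$net_indel,
                     if (ora$kind == "insertion") ora$size else -ora$size)
        # event position: recover the absolute coordinate from the label
        ev_pos <- lab_to_abs(sub(":.*$", "", cl$events), t1)
        expect_equal(ev_pos, ora$position, info = sprintf("%s size %d at %d",
                                                          kind, size, pos))
        if (ora$kind == "insertion")
          expect_equal(sub("^\\+\\d+", "", lab), ora$bases)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 30L)
})

test_that("left-alignment normalizes homopolymer-equivalent placements", {
  ref <- mini_locus$reference
  # the A4 run sits at positions 40..43 (0-based); deleting any one A is the
  # same molecule and must give one normalized event
  calls <- lapply(40:43, function(p)
    call_read(apply_indel(ref, "deletion", p, 1L), mini_locus, "t1",
              call_params(comparison_range = 10)))
  evs <- vapply(calls, `[[`, "", "events")
  expect_length(unique(evs), 1L)
  # same for inserting one extra A anywhere in the run
  calls_i <- lapply(40:44, function(p)
    call_read(apply_indel(ref, "insertion", p, 1L, "A"), mini_locus, "t1",
              call_params(comparison_range = 10)))
  expect_length(unique(vapply(calls_i, `[[`, "", "events")), 1L)
})

test_that("a larger WT marker window is stricter", {
  lin <- edited_fraction_lineage(0.5)
  cfg <- sim_config(seed = 21, n_reads = 400, error_rate = 0.01)
  g <- generate_reads(lin, cfg, demo_locus)
  fl <- filter_reads(g$reads, demo_locus$indicators[["sgRNA2.A"]])
  wt5 <- call_reads(fl$used, demo_locus, "sgRNA2", call_params(wt_marker = 5))
  wt2 <- call_reads(fl$used, demo_locus, "sgRNA2", call_params(wt_marker = 2))
  ids5 <- wt5$read_id[wt5$status == "WT"]
  ids2 <- wt2$read_id[wt2$status == "WT"]
  expect_true(all(ids5 %in% ids2))
  expect_gt(length(ids2), 0L)
})

test_that("partition and frameshift invariants hold on a noisy pool", {
  lin <- edited_fraction_lineage(0.4)
  cfg <- sim_config(seed = 22, n_reads = 2000, error_rate = 0.005,
                    truncate_prob = 0.03)
  g <- generate_reads(lin, cfg, demo_locus)
  fl <- filter_reads(g$reads, demo_locus$indicators[["sgRNA2.A"]])
  expect_equal(length(fl$used) + fl$excluded, length(g$reads))
  calls <- call_reads(fl$used, demo_locus, "sgRNA2")
  expect_equal(sum(calls$status == "WT") + sum(calls$status == "edited") +
                 sum(calls$status == "excluded"), length(fl$used))
  # WT implies no events; frameshift flag equals net mod 3 check
  expect_true(all(calls$events[calls$status == "WT"] == ""))
  expect_equal(calls$frameshift, calls$net_indel %% 3L != 0L)
})

test_that("detect_large_deletion flags exactly the dropout molecules", {
  cut1 <- demo_locus$targets$sgRNA1$cut_site
  cut2 <- demo_locus$targets$sgRNA2$cut_site
  lin <- list(cell_lineage("L1", 1, list(
    list(hap_id = "copy1", weight = 0.35,
         events = list(edit_event("large_deletion", cut1, size = cut2 - cut1))),
    list(hap_id = "copy2", weight = 0.55),
    list(hap_id = "copy2", weight = 0.10,
         events = list(edit_event("deletion", cut2 - 1L, 1L, target_id = "sgRNA2"))))))
  cfg <- sim_config(seed = 23, n_reads = 1000, exact_counts = TRUE)
  g <- generate_reads(lin, cfg, demo_locus)
  flags <- detect_large_deletion(g$reads, demo_locus)
  expect_equal(unname(flags), g$truth$large_deletion)
  # 1 bp deletion at one target only is not a dropout
  expect_false(any(flags & g$truth$events == "313:-1"))
})

test_that("summarize_site reproduces printed-table rounding and filtering", {
  # 4905 used reads, 3596 with indels -> 73%
  calls <- data.frame(
    read_id = sprintf("r%04d", 1:4905), target_id = "sgRNA2",
    status = c(rep("edited", 3596), rep("WT", 1309)),
    events = c(rep("-4:-1", 3000), rep("-4:+1G", 596), rep("", 1309)),
    n_events = c(rep(1L, 3596), rep(0L, 1309)),
    net_indel = c(rep(-1L, 3000), rep(1L, 596), rep(0L, 1309)),
    has_indel = c(rep(TRUE, 3596), rep(FALSE, 1309)),
    frameshift = c(rep(TRUE, 3596), rep(FALSE, 1309)),
    large_deletion = FALSE, stringsAsFactors = FALSE)
  s <- summarize_site(calls, total_reads = 128598L)
  expect_equal(s$indel_pct, 73)
  expect_equal(s$frameshift_pct, 73)
  expect_equal(s$reads_used, 4905L)
  # below-10 percentages keep one decimal (91/10513 -> 0.9)
  calls2 <- calls
  calls2$has_indel <- c(rep(TRUE, 44), rep(FALSE, 4861))
  calls2$status <- c(rep("edited", 44), rep("WT", 4861))
  calls2$events[45:4905] <- ""
  s2 <- summarize_site(calls2)
  expect_equal(s2$indel_pct, crispamp::printed_pct(44, 4905))
  expect_lt(s2$indel_pct, 1)
  # min-frequency filtering drops rare patterns from the table, not the totals
  s3 <- summarize_site(calls, call_params(min_frequency = 1000))
  expect_equal(names(s3$pattern_table), "-4:-1")
  expect_equal(s3$indel_reads, 3596L)
  # zero used reads -> percentages missing
  s0 <- summarize_site(calls[0, ])
  expect_true(is.na(s0$indel_pct))
})

test_that("zero edited reads give 0% indels", {
  lin <- edited_fraction_lineage(0)
  cfg <- sim_config(seed = 24, n_reads = 200)
  g <- generate_reads(lin, cfg, demo_locus)
  fl <- filter_reads(g$reads, demo_locus$indicators[["sgRNA2.A"]])
  s <- summarize_site(call_reads(fl$used, demo_locus, "sgRNA2"))
  expect_equal(s$indel_pct, 0)
  expect_equal(s$indel_reads, 0L)
})
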