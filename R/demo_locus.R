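# Deterministic construction of the bundled demonstration locus: a 586 bp
# amplicon with two Cas9 targets whose blunt cut sites lie 100 bp apart,
# 15 haplotypes distinguished at 36 variable positions, diagnostic restriction
# sites overlapping both cuts, screening/CE primer pairs, indicator pairs for
# read filtering, and a catalog of native target-region variants.
#
# Fixed geometry (0-based, half-open):
#   amplicon           [0, 586)
#   screening primers  F [0,20), R [566,586)            -> 586 bp product
#   target t1          protospacer [197,217), PAM [217,220), cut 214
#   target t2          protospacer [297,317), PAM [317,320), cut 314
#   enzyme 1           recognition planted [211,217), top-strand cut at 214
#   enzyme 2           recognition planted [311,318), top-strand cut at 314
#                      -> digestion of the WT amplicon yields [314, 272]
#   CE pair 1          F [14,34),  R rc of [218,238)    -> 224 bp product
#   CE pair 2          F [290,310), R rc of [486,506)   -> 216 bp product
#   indicator A pairs  10-mers at cut -45..-35 / +35..+45
#   indicator B pairs  10-mers just outside protospacer+PAM
#
# A ~100 bp dropout deletion joining the cuts ([214,314)) shortens the
# screening product to 486 bp and removes the inner indicators, so dropout
# molecules are excluded from per-target read analyses, as in the assays this
# emulates.

DEMO_LEN <- 586L
DEMO_CUT1 <- 214L
DEMO_CUT2 <- 314L

demo_intervals <- function() {
  list(fwd = c(0L, 20L), rev = c(566L, 586L),
       ce1f = c(14L, 34L), ce1r = c(218L, 238L),
       ce2f = c(290L, 310L), ce2r = c(486L, 506L),
       t1 = c(197L, 220L), t2 = c(297L, 320L),
       enz1 = c(211L, 217L), enz2 = c(311L, 318L),
       a1l = c(169L, 179L), a1r = c(249L, 259L),
       a2l = c(269L, 279L), a2r = c(349L, 359L),
       b1l = c(183L, 193L), b1r = c(224L, 234L),
       b2l = c(283L, 293L), b2r = c(324L, 334L))
}

#' Build the bundled demonstration locus
#'
#' Generates, deterministically for a given seed, a fully configured
#' [locus_model()] with the geometry described in the package vignette: a
#' 586 bp amplicon, two targets with cut sites 100 bp apart, 15 haplotypes
#' over 36 variable positions (five of them inside the target seed/PAM
#' regions), primers, enzymes, indicator pairs and a native-variant catalog.
#'
#' Haplotype `copy1` is the reference allele. `copy6` carries seed/PAM
#' substitutions at both targets and is therefore uneditable at both — the
#' rare-donor allele used in HDR scenarios. `copy3` and `copy15` are
#' uneditable at one target each.
#'
#' @param seed integer master seed.
#' @param enzyme_profile `"canonical"` (default) or `"as_printed"`; selects the
#'   recognition-string configuration profile planted for enzyme 1.
#' @return a [locus_model()].
#' @export
build_demo_locus <- function(seed = 1, enzyme_profile = c("canonical", "as_printed")) {
  enzyme_profile <- match.arg(enzyme_profile)
  enz1_rec <- if (enzyme_profile == "canonical") "CAGCTG" else "CATCTG"
  enz2_rec <- "GGGACCC"
  iv <- demo_intervals()

  with_seed(seed, {
    ch <- sample(DNA_BASES, DEMO_LEN, replace = TRUE)

    plant <- function(ch, start, s) {
      ch[(start + 1L):(start + nchar(s))] <- strsplit(s, "")[[1L]]
      ch
    }
    ch <- plant(ch, iv$enz1[1], enz1_rec)       # overlaps t1 protospacer tail
    ch <- plant(ch, iv$enz2[1], enz2_rec)       # overlaps t2 protospacer tail
    ch[218:219 + 1L] <- c("G", "G")             # PAM NGG for t1
    ch[318:319 + 1L] <- c("G", "G")             # PAM NGG for t2 (317 = C from enz2)

    ref <- paste(ch, collapse = "")

    protected <- iv
    feature_strings <- function(ref) {
      g <- function(k) substr0(ref, iv[[k]][1], iv[[k]][2])
      u <- c(g("fwd"), g("rev"), g("ce1f"), g("ce1r"), g("ce2f"), g("ce2r"),
             g("t1"), g("t2"), enz1_rec, enz2_rec,
             g("a1l"), g("a1r"), g("a2l"), g("a2r"),
             g("b1l"), g("b1r"), g("b2l"), g("b2r"))
      names(u) <- c(names(iv)[1:8], "enz1", "enz2", names(iv)[11:18])
      u
    }
    in_protected <- function(p)
      any(vapply(protected, function(z) p >= z[1] && p < z[2], logical(1)))

    # enforce single-occurrence of every anchor string (and absence of
    # indicator reverse complements) by mutating background collisions
    for (iter in 1:50) {
      fs <- feature_strings(ref)
      bad <- integer(0)
      for (j in seq_along(fs)) {
        occ <- find_all(fs[[j]], ref)
        extra <- occ[occ != min(occ) | duplicated(occ)]
        # the planted copy is the one inside its own interval; all others are background
        home <- if (names(fs)[j] == "enz1") iv$enz1[1]
                else if (names(fs)[j] == "enz2") iv$enz2[1]
                else iv[[names(fs)[j]]][1]
        extra <- occ[occ != home]
        bad <- c(bad, unlist(lapply(extra, function(s) s:(s + nchar(fs[[j]]) - 1L))))
      }
      for (s in c(fs[grep("^(a|b)", names(fs))])) {
        rc <- revcomp(s)
        if (rc != s)
          bad <- c(bad, unlist(lapply(find_all(rc, ref), function(p)
            p:(p + nchar(s) - 1L))))
      }
      bad <- unique(bad[!vapply(bad, in_protected, logical(1))])
      if (!length(bad)) break
      chs <- strsplit(ref, "")[[1L]]
      p <- bad[[1L]]
      chs[p + 1L] <- other_base(chs[p + 1L])
      ref <- paste(chs, collapse = "")
    }
    if (length(bad)) stop("demo locus: could not resolve anchor collisions", call. = FALSE)

    base_at <- function(p) substr0(ref, p, p + 1L)

    targets <- list(
      target_site("sgRNA1", substr0(ref, 197L, 217L), substr0(ref, 217L, 220L),
                  "+", 217L),
      target_site("sgRNA2", substr0(ref, 297L, 317L), substr0(ref, 317L, 320L),
                  "+", 317L))

    # variable positions: 5 inside the target windows + 31 in the flanks
    window_vp <- c(213L, 215L, 219L, 313L, 315L)
    pool <- c(40:168, 359:485, 506:555)
    flank_vp <- sort(sample(pool, 31L))
    variable_positions <- sort(c(window_vp, flank_vp))

    alt <- function(p) other_base(base_at(p))

    # copy6: rare donor, seed/PAM SNPs at both targets
    copy6_window <- c(stats::setNames(alt(213L), 213L), stats::setNames(alt(215L), 215L),
                      stats::setNames(alt(313L), 313L), stats::setNames(alt(315L), 315L))
    copy3_window <- stats::setNames(alt(219L), 219L)   # PAM-disrupting, target 1
    copy15_window <- stats::setNames(alt(313L), 313L)  # seed SNP, target 2
    # copy15 must differ from copy6 at 313
    while (copy15_window[[1]] == copy6_window[["313"]])
      copy15_window <- stats::setNames(alt(313L), 313L)

    rand_profile <- function() {
      k <- sample(4:10, 1L)
      pos <- sort(sample(flank_vp, k))
      stats::setNames(vapply(pos, alt, character(1)), pos)
    }

    haps <- vector("list", 15L)
    haps[[1]] <- haplotype("copy1")
    repeat {
      for (i in 2:15) {
        prof <- rand_profile()
        if (i == 3L) prof <- c(prof, copy3_window)
        if (i == 6L) prof <- c(prof, copy6_window)
        if (i == 15L) prof <- c(prof, copy15_window)
        haps[[i]] <- haplotype(sprintf("copy%d", i), prof)
      }
      # pairwise distinct with a margin: Hamming distance >= 2 on the full profile
      seqs <- lapply(haps, function(h) {
        v <- rep(NA_character_, length(variable_positions))
        names(v) <- variable_positions
        v[] <- vapply(variable_positions, base_at, character(1))
        if (length(h$snp_profile)) v[names(h$snp_profile)] <- h$snp_profile
        v
      })
      dmin <- Inf
      for (i in 1:14) for (j in (i + 1):15)
        dmin <- min(dmin, sum(seqs[[i]] != seqs[[j]]))
      if (dmin >= 2L) break
    }

    primers <- list(
      CAPS = primer_pair("CAPS", substr0(ref, 0L, 20L),
                         revcomp(substr0(ref, 566L, 586L))),
      CE1 = primer_pair("CE1", substr0(ref, 14L, 34L),
                        revcomp(substr0(ref, 218L, 238L)), labelled = TRUE),
      CE2 = primer_pair("CE2", substr0(ref, 290L, 310L),
                        revcomp(substr0(ref, 486L, 506L)), labelled = TRUE))

    enzymes <- list(
      PvuII = restriction_enzyme("PvuII", enz1_rec, 3L),
      KflI = restriction_enzyme("KflI", enz2_rec, 3L))

    indicators <- list(
      sgRNA1.A = indicator_pair("sgRNA1", substr0(ref, iv$a1l[1], iv$a1l[2]),
                                substr0(ref, iv$a1r[1], iv$a1r[2])),
      sgRNA2.A = indicator_pair("sgRNA2", substr0(ref, iv$a2l[1], iv$a2l[2]),
                                substr0(ref, iv$a2r[1], iv$a2r[2])),
      sgRNA1.B = indicator_pair("sgRNA1", substr0(ref, iv$b1l[1], iv$b1l[2]),
                                substr0(ref, iv$b1r[1], iv$b1r[2])),
      sgRNA2.B = indicator_pair("sgRNA2", substr0(ref, iv$b2l[1], iv$b2l[2]),
                                substr0(ref, iv$b2r[1], iv$b2r[2])))

    win1 <- substr0(ref, 197L, 220L)
    win2 <- substr0(ref, 297L, 320L)
    sub_in <- function(w, off, p, b) {
      substr(w, p - off + 1L, p - off + 1L) <- b
      w
    }
    ins_at <- function(w, off, p, b)
      paste0(substr0(w, 0L, p - off), b, substr0(w, p - off, nchar(w)))
    del_at <- function(w, off, p)
      paste0(substr0(w, 0L, p - off), substr0(w, p - off + 1L, nchar(w)))

    v2b1 <- alt(199L); v2b2 <- alt(202L)
    v6b <- alt(199L)
    while (v6b == v2b1) v6b <- alt(199L)  # keep V2 and V6 strings distinct at 199
    variants <- list(
      variant_def("V1", "sgRNA1", ins_at(win1, 197L, 214L, "A"), "insertion",
                  "insertion of A at the sgRNA1 cut (position -4/-3 boundary)"),
      variant_def("V2", "sgRNA1", sub_in(sub_in(win1, 197L, 199L, v2b1), 197L, 202L, v2b2),
                  "substitution", "substitutions at sgRNA1 positions -18 and -15"),
      variant_def("V3", "sgRNA1", ins_at(win1, 197L, 214L, "C"), "insertion",
                  "insertion of C at the sgRNA1 cut"),
      variant_def("V4", "sgRNA1", sub_in(win1, 197L, 215L, alt(215L)), "substitution",
                  "substitution at sgRNA1 position -2"),
      variant_def("V5", "sgRNA1", sub_in(win1, 197L, 219L, copy3_window[["219"]]),
                  "pam_substitution", "substitution in the third PAM nucleotide of sgRNA1"),
      variant_def("V6", "sgRNA1", sub_in(win1, 197L, 199L, v6b), "substitution",
                  "substitution at sgRNA1 position -18"),
      variant_def("V7", "sgRNA2", del_at(win2, 297L, 313L), "deletion",
                  "1 bp deletion 4 bp upstream of the sgRNA2 PAM"),
      variant_def("V8", "sgRNA2", sub_in(win2, 297L, 300L, alt(300L)), "substitution",
                  "substitution at sgRNA2 position -17"),
      variant_def("C6T1", "sgRNA1",
                  sub_in(sub_in(win1, 197L, 213L, copy6_window[["213"]]),
                         197L, 215L, copy6_window[["215"]]),
                  "substitution", "donor-allele (copy6) seed SNPs at sgRNA1"),
      variant_def("C6T2", "sgRNA2",
                  sub_in(sub_in(win2, 297L, 313L, copy6_window[["313"]]),
                         297L, 315L, copy6_window[["315"]]),
                  "substitution", "donor-allele (copy6) seed SNPs at sgRNA2"))
    names(variants) <- vapply(variants, `[[`, "", "id")

    locus_model(ref, haps, targets, primers, enzymes,
                variable_positions = variable_positions,
                indicators = indicators, variants = variants)
  })
}
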