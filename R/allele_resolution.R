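# Allele resolution of clone (long) reads by SNP profile, HDR-signature
# detection with conversion-tract bounding, and the background-corrected HDR
# frequency estimate.
#
# Profiles are Hamming (substitution-only) comparisons at the locus's variable
# positions; variable positions inside the target windows (cut +/- R) are
# excluded from flank profiling so that edits never masquerade as allele SNPs.
# Indel-bearing reads are profiled on aligned columns.

# read base at each variable position, NA where gapped/uncovered.
# Fast path for reads whose length equals the reference (no indels).
profile_positions <- function(read, locus, positions) {
  ref <- locus$reference
  if (nchar(read) == nchar(ref)) {
    return(vapply(positions, function(p) substr0(read, p, p + 1L), character(1)))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(read),
                                       Biostrings::DNAString(ref),
                                       type = "global", substitutionMatrix = mat,
                                       gapOpening = 6, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  refpos <- cumsum(s != "-") - 1L
  out <- rep(NA_character_, length(positions))
  hit <- match(positions, refpos)
  ok <- !is.na(hit)
  bases <- p[hit[ok]]
  bases[bases == "-"] <- NA_character_
  out[ok] <- bases
  out
}

# haplotype base matrix at given positions (haplotypes x positions)
hap_base_matrix <- function(locus, positions) {
  refb <- vapply(positions, function(p) substr0(locus$reference, p, p + 1L),
                 character(1))
  t(vapply(locus$haplotypes, function(h) {
    b <- refb
    if (length(h$snp_profile)) {
      idx <- match(as.integer(names(h$snp_profile)), positions)
      ok <- !is.na(idx)
      b[idx[ok]] <- h$snp_profile[ok]
    }
    b
  }, character(length(positions))))
}

flank_positions <- function(locus, comparison_range) {
  vp <- locus$variable_positions
  inside <- rep(FALSE, length(vp))
  for (t in locus$targets)
    inside <- inside | (vp >= t$cut_site - comparison_range &
                          vp < t$cut_site + comparison_range)
  vp[!inside]
}

#' Assign a clone read to a haplotype by SNP profile
#'
#' Nearest haplotype by Hamming distance over the informative (non-target)
#' variable positions; unassigned on a tie, on distance above `max_mismatch`,
#' or when the read covers fewer than 80% of the informative positions.
#'
#' @param read a read sequence (reference orientation).
#' @param locus a [locus_model()].
#' @param max_mismatch maximum tolerated profile mismatches (default 1).
#' @param comparison_range half-width of the excluded target windows
#'   (default 30).
#' @return list: `hap_id` (or `"unassigned"`), `mismatches`,
#'   `informative_positions_used`, `reason`.
#' @export
assign_allele <- function(read, locus, max_mismatch = 1L, comparison_range = 30L) {
  pos <- flank_positions(locus, comparison_range)
  prof <- profile_positions(read, locus, pos)
  covered <- !is.na(prof)
  if (mean(covered) < 0.8) {
    return(list(hap_id = "unassigned", mismatches = NA_integer_,
                informative_positions_used = sum(covered),
                reason = "covers <80% of informative positions"))
  }
  hb <- hap_base_matrix(locus, pos)
  d <- apply(hb[, covered, drop = FALSE], 1L,
             function(b) sum(b != prof[covered]))
  best <- min(d)
  if (best > max_mismatch) {
    return(list(hap_id = "unassigned", mismatches = as.integer(best),
                informative_positions_used = sum(covered),
                reason = "exceeds max_mismatch"))
  }
  if (sum(d == best) > 1L) {
    return(list(hap_id = "unassigned", mismatches = as.integer(best),
                informative_positions_used = sum(covered), reason = "tie"))
  }
  list(hap_id = names(which.min(d)), mismatches = as.integer(best),
       informative_positions_used = sum(covered), reason = NA_character_)
}

#' Assign many clone reads
#'
#' Vectorized [assign_allele()] with deduplication of identical reads.
#'
#' @param reads named character vector.
#' @inheritParams assign_allele
#' @return data.frame: read_id, hap_id, mismatches,
#'   informative_positions_used, reason.
#' @export
assign_alleles <- function(reads, locus, max_mismatch = 1L, comparison_range = 30L) {
  uniq <- unique(unname(reads))
  res <- lapply(uniq, assign_allele, locus = locus, max_mismatch = max_mismatch,
                comparison_range = comparison_range)
  m <- match(unname(reads), uniq)
  data.frame(read_id = names(reads),
             hap_id = vapply(res, `[[`, "", "hap_id")[m],
             mismatches = vapply(res, `[[`, integer(1), "mismatches")[m],
             informative_positions_used =
               vapply(res, `[[`, integer(1), "informative_positions_used")[m],
             reason = vapply(res, `[[`, "", "reason")[m],
             stringsAsFactors = FALSE)
}

donor_window_strings <- function(locus, donor) {
  dseq <- haplotype_sequence(locus, donor)
  dh <- locus$haplotypes[[donor]]
  out <- list()
  for (t in locus$targets) {
    if (dh$editable_per_target[[t$id]]) next  # donor matches canonical here
    w <- target_window(t)
    out[[t$id]] <- substr0(dseq, w[1], w[2])
  }
  out
}

#' Detect HDR-signature recombinant reads
#'
#' A read is an HDR candidate iff its target-window genotype equals a donor's
#' (uneditable) target genotype at every donor-variant target while its
#' flanking SNP profile matches a different haplotype. Reads matching the
#' donor everywhere are not candidates (they may be the donor allele itself).
#' Conversion-tract bounds come from informative SNPs (positions where donor
#' and recipient differ): the minimal tract spans the farthest donor-matching
#' SNPs (plus the target windows); the maximal tract extends to the nearest
#' recipient-matching SNPs on either side, or is flagged unbounded.
#'
#' @param reads named character vector (reference orientation).
#' @param locus a [locus_model()].
#' @param donors haplotype ids to consider as donors; defaults to all
#'   haplotypes uneditable at one or more targets.
#' @param max_mismatch tolerated flank-profile mismatches (default 0).
#' @param comparison_range half-width of the target windows (default 30).
#' @return data.frame of candidates: read_id, donor, class, flank_hap,
#'   tract bounds (`tract_min_*` inside `tract_max_*`), unbounded flag.
#' @export
detect_hdr <- function(reads, locus, donors = NULL, max_mismatch = 0L,
                       comparison_range = 30L) {
  if (is.null(donors)) {
    donors <- names(locus$haplotypes)[vapply(locus$haplotypes, function(h)
      any(!h$editable_per_target), logical(1))]
  }
  vp <- locus$variable_positions
  fpos <- flank_positions(locus, comparison_range)
  out <- list()
  uniq <- unique(unname(reads))
  ucand <- lapply(uniq, function(rd) {
    cands <- list()
    for (d in donors) {
      ws <- donor_window_strings(locus, d)
      if (!length(ws)) next
      if (!all(vapply(ws, function(s) grepl(s, rd, fixed = TRUE), logical(1))))
        next
      dseq <- haplotype_sequence(locus, d)
      prof <- profile_positions(rd, locus, vp)
      dbase <- vapply(vp, function(p) substr0(dseq, p, p + 1L), character(1))
      diff_d <- which(!is.na(prof) & prof != dbase)
      if (!length(diff_d)) next  # identical to the donor: not a candidate
      wspan <- range(unlist(lapply(names(ws), function(tid)
        target_window(locus$targets[[tid]]))))
      # recipient: haplotype whose profile explains the read outside one
      # contiguous conversion tract containing the target window(s); scored
      # by the number of positions the tract must absorb (parsimony)
      fidx <- match(fpos, vp)
      fprof <- prof[fidx]
      hbf <- hap_base_matrix(locus, fpos)
      cand_h <- setdiff(rownames(hbf), d)
      fits <- lapply(cand_h, function(h) {
        hb <- hbf[h, ]
        db <- dbase[fidx]
        obs <- !is.na(fprof)
        xh <- fpos[obs & fprof != hb]                  # must lie in the tract
        err <- sum(fprof[obs & fpos %in% xh] != db[obs & fpos %in% xh])
        hull <- range(c(xh, wspan))
        inside <- obs & fpos > hull[1] & fpos < hull[2]
        conflicts <- sum(inside & fprof == hb & hb != db)  # recipient SNPs inside hull
        list(h = h, score = length(xh), err = err + conflicts)
      })
      valid <- Filter(function(f) f$err <= max_mismatch, fits)
      if (!length(valid)) next
      scores <- vapply(valid, `[[`, numeric(1), "score")
      best <- min(scores)
      if (sum(scores == best) > 1L) next               # ambiguous flank: skip
      recip <- valid[[which.min(scores)]]$h
      rseq <- haplotype_sequence(locus, recip)
      rbase <- vapply(vp, function(p) substr0(rseq, p, p + 1L), character(1))
      informative <- which(dbase != rbase)
      ok <- informative[!is.na(prof[informative])]
      i_d <- vp[ok][prof[ok] == dbase[ok]]    # read matches donor
      i_r <- vp[ok][prof[ok] == rbase[ok]]    # read matches recipient
      min_start <- min(c(i_d, wspan[1]))
      min_end <- max(c(i_d + 1L, wspan[2]))
      left_r <- i_r[i_r < min_start]
      right_r <- i_r[i_r >= min_end]
      unbounded <- !length(left_r) || !length(right_r)
      max_start <- if (length(left_r)) max(left_r) + 1L else 0L
      max_end <- if (length(right_r)) min(right_r) else nchar(locus$reference)
      cands[[length(cands) + 1L]] <- data.frame(
        donor = d, class = sprintf("%s.WT-type", d), flank_hap = recip,
        tract_min_start = min_start, tract_min_end = min_end,
        tract_max_start = max_start, tract_max_end = max_end,
        unbounded = unbounded, stringsAsFactors = FALSE)
    }
    if (length(cands)) do.call(rbind, cands) else NULL
  })
  m <- match(unname(reads), uniq)
  rows <- lapply(seq_along(reads), function(i) {
    cc <- ucand[[m[i]]]
    if (is.null(cc)) return(NULL)
    cbind(data.frame(read_id = names(reads)[i], stringsAsFactors = FALSE), cc)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(read_id = character(0), donor = character(0),
                      class = character(0), flank_hap = character(0),
                      tract_min_start = integer(0), tract_min_end = integer(0),
                      tract_max_start = integer(0), tract_max_end = integer(0),
                      unbounded = logical(0)))
  }
  do.call(rbind, rows)
}

#' Donor-type component percentages in a clone-read pool
#'
#' The two read classes entering the HDR estimate, defined by target-window
#' genotype: reads carrying the donor's (uneditable) window genotype at every
#' donor-variant target that are identical to the donor allele at all covered
#' variable positions (native donor molecules or full-length conversions),
#' and those that depart from the donor elsewhere (recombinants: donor-type
#' windows on a different SNP background). Flank-haplotype resolution of the
#' recombinants is the business of [detect_hdr()]; the class counts here do
#' not require it. Percentages are of all reads supplied.
#'
#' @inheritParams detect_hdr
#' @param donor donor haplotype id.
#' @return named numeric vector: `donor_identical_pct`, `recombinant_pct`.
#' @export
hdr_components <- function(reads, locus, donor, comparison_range = 30L) {
  ws <- donor_window_strings(locus, donor)
  stopifnot(length(ws) > 0L)
  uniq <- unique(unname(reads))
  win_hit <- vapply(uniq, function(rd)
    all(vapply(ws, function(s) grepl(s, rd, fixed = TRUE), logical(1))),
    logical(1))
  dseq <- haplotype_sequence(locus, donor)
  vp <- locus$variable_positions
  dbase <- vapply(vp, function(p) substr0(dseq, p, p + 1L), character(1))
  identical_d <- vapply(seq_along(uniq), function(i) {
    if (!win_hit[i]) return(FALSE)
    prof <- profile_positions(uniq[i], locus, vp)
    all(is.na(prof) | prof == dbase)
  }, logical(1))
  m <- match(unname(reads), uniq)
  n <- length(reads)
  donor_identical <- sum(identical_d[m])
  recomb <- sum(win_hit[m] & !identical_d[m])
  c(donor_identical_pct = 100 * donor_identical / n,
    recombinant_pct = 100 * recomb / n)
}

#' Background-corrected HDR frequency estimate
#'
#' Sums the component percentages (donor-type read classes) and subtracts the
#' donor allele's native background share, clamped at zero; the corrected
#' figure is reported at one decimal.
#'
#' @param component_pcts numeric vector of component percentages in `[0,100]`.
#' @param background_pct native background percentage of the donor allele.
#' @return an object of class `hdr_estimate`: components, `total_pct`,
#'   `background_pct`, `corrected_pct`.
#' @export
estimate_hdr_frequency <- function(component_pcts, background_pct) {
  stopifnot(all(component_pcts >= 0 & component_pcts <= 100),
            background_pct >= 0, background_pct <= 100)
  total <- sum(component_pcts)
  corrected <- total - background_pct
  if (corrected < 0) {
    warning("background exceeds total; corrected HDR frequency clamped to 0")
    corrected <- 0
  }
  structure(list(component_pcts = component_pcts,
                 total_pct = total, background_pct = background_pct,
                 corrected_pct = round_half_up(corrected, 1L)),
            class = "hdr_estimate")
}

#' @export
print.hdr_estimate <- function(x, ...) {
  cat(sprintf("HDR estimate: components (%s) total %.2f%% - background %.2f%% = %.1f%%\n",
              paste(sprintf("%.2f", x$component_pcts), collapse = " + "),
              x$total_pct, x$background_pct, x$corrected_pct))
  invisible(x)
}
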