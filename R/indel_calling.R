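# Indicator-pair read filtering and alignment-based indel calling.
#
# A read is analysed at a target only if both 10-mer indicator sequences
# flanking the target window are present (exact match, left before right, in
# either orientation). A read whose cut-site window (cut +/- r bp) matches the
# reference exactly is wild type; otherwise the segment between the indicators
# is globally aligned to the matching reference segment, indel events are
# left-normalized, and events within +/- R bp of the cut are reported.

#' Indicator pair
#'
#' Two short anchor sequences flanking a target window; their joint presence
#' certifies that a read fully covers the window.
#'
#' @param target_id target the pair belongs to.
#' @param left,right anchor sequences 5' and 3' of the target window on the
#'   reference.
#' @return an object of class `indicator_pair`.
#' @export
indicator_pair <- function(target_id, left, right) {
  structure(list(target_id = target_id, left = toupper(left),
                 right = toupper(right)), class = "indicator_pair")
}

#' Validate an indicator pair against a locus
#'
#' Checks that both anchors occur exactly once in the reference, left 5' of
#' the target window and right 3' of it.
#'
#' @param locus a [locus_model()].
#' @param pair an [indicator_pair()].
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_indicator <- function(locus, pair) {
  l <- find_all(pair$left, locus$reference)
  r <- find_all(pair$right, locus$reference)
  if (length(l) != 1L || length(r) != 1L)
    stop("indicator anchors must occur exactly once in the reference", call. = FALSE)
  w <- target_window(locus$targets[[pair$target_id]])
  if (l + nchar(pair$left) > w[1] || r < w[2])
    stop("indicator anchors must flank the target window", call. = FALSE)
  invisible(TRUE)
}

#' Indel-calling parameters
#'
#' @param comparison_range R: events are counted within +/- R bp of the cut
#'   site (default 30).
#' @param wt_marker r: half-width of the exact-match window around the cut
#'   required for a wild-type call (default 5).
#' @param min_frequency n: minimum reads per distinct mutation pattern
#'   retained in the pattern table (default 1).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return an object of class `call_params`.
#' @export
call_params <- function(comparison_range = 30L, wt_marker = 5L, min_frequency = 1L,
                        match = 2, mismatch = -4, gap_open = -6, gap_extend = -1) {
  stopifnot(comparison_range >= wt_marker, wt_marker >= 1L, min_frequency >= 1L)
  structure(list(comparison_range = as.integer(comparison_range),
                 wt_marker = as.integer(wt_marker),
                 min_frequency = as.integer(min_frequency),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "call_params")
}

#' Filter reads by an indicator pair
#'
#' A read is used iff both anchors occur (exact match) in the read or in its
#' reverse complement, in left-to-right order; used reads are normalized to
#' reference orientation.
#'
#' @param reads named character vector of read sequences.
#' @param pair an [indicator_pair()].
#' @return list with `used` (normalized reads) and `excluded` (count).
#' @export
filter_reads <- function(reads, pair) {
  stopifnot(length(reads) > 0L)
  nl <- nchar(pair$left)
  ok_fwd <- function(x) {
    lp <- regexpr(pair$left, x, fixed = TRUE)
    rp <- regexpr(pair$right, x, fixed = TRUE)
    lp > 0L & rp > 0L & (lp + nl <= rp)
  }
  fwd <- ok_fwd(reads)
  out <- reads
  if (any(!fwd)) {
    rc <- revcomp(reads[!fwd])
    rcok <- ok_fwd(rc)
    out[!fwd][rcok] <- rc[rcok]
    used_mask <- fwd
    used_mask[!fwd][rcok] <- TRUE
  } else used_mask <- fwd
  list(used = out[used_mask], excluded = sum(!used_mask))
}

# events within one aligned segment, in absolute reference coordinates.
# p, s: equal-length gapped pattern (read) and subject (reference) strings.
extract_events <- function(p, s, ref, seg_start) {
  pc <- strsplit(p, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  gap_s <- sc == "-"
  gap_p <- pc == "-"
  state <- ifelse(gap_s, "I", ifelse(gap_p, "D", ifelse(pc != sc, "X", "M")))
  # reference coordinate of each column (position of the subject base; for
  # insertion columns, the coordinate of the next subject base = inter-base pos)
  refpos <- seg_start + c(0L, cumsum(!gap_s))[seq_along(state)]
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  events <- list()
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == "M") next
    i0 <- starts[k]; i1 <- ends[k]
    if (v == "I") {
      pos <- refpos[i0]
      bases <- paste(pc[i0:i1], collapse = "")
      norm <- left_align_insertion(ref, pos, bases)
      events[[length(events) + 1L]] <-
        list(kind = "insertion", position = norm$pos, size = i1 - i0 + 1L,
             bases = norm$bases)
    } else if (v == "D") {
      pos <- refpos[i0]
      size <- i1 - i0 + 1L
      pos <- left_align_deletion(ref, pos, size)
      events[[length(events) + 1L]] <-
        list(kind = "deletion", position = pos, size = size, bases = "")
    } else {
      events[[length(events) + 1L]] <-
        list(kind = "substitution", position = refpos[i0], size = i1 - i0 + 1L,
             bases = paste(pc[i0:i1], collapse = ""))
    }
  }
  events
}

# shift a deletion [pos, pos+size) left while the flanking base repeats
left_align_deletion <- function(ref, pos, size) {
  while (pos > 0L && substr0(ref, pos - 1L, pos) == substr0(ref, pos + size - 1L, pos + size))
    pos <- pos - 1L
  pos
}

# shift an insertion left while the base 5' of the insertion point equals the
# last inserted base (rotating the inserted string)
left_align_insertion <- function(ref, pos, bases) {
  k <- nchar(bases)
  while (pos > 0L && substr0(ref, pos - 1L, pos) == substr(bases, k, k)) {
    bases <- paste0(substr(bases, k, k), substr(bases, 1L, k - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, bases = bases)
}

event_label <- function(e, target) {
  lab <- pam_relative(target, e$position)
  if (is.na(lab)) lab <- as.character(e$position)
  switch(e$kind,
         insertion = sprintf("%s:+%d%s", lab, e$size, e$bases),
         deletion = sprintf("%s:-%d", lab, e$size),
         substitution = sprintf("%s:>%s", lab, e$bases))
}

#' Call indel status of reads at a target
#'
#' Vectorized caller. Reads must already have passed [filter_reads()] for this
#' target's indicator pair (reference orientation). Wild type is an exact
#' reference match over the cut +/- r window; all other reads are globally
#' aligned over the indicator-delimited segment, with indels left-normalized
#' and only events within +/- R of the cut reported. Substitution-only reads
#' are `edited` with `net_indel = 0` and do not count as indel reads.
#'
#' @param reads named character vector of filtered, normalized reads.
#' @param locus a [locus_model()].
#' @param target_id target id.
#' @param params a [call_params()].
#' @param pair indicator pair; defaults to the locus's `<target>.A` pair.
#' @return data.frame of calls: read_id, target_id, status
#'   (`WT`/`edited`/`excluded`), events (compact string), n_events, net_indel,
#'   frameshift, large_deletion.
#' @export
call_reads <- function(reads, locus, target_id, params = call_params(),
                       pair = NULL) {
  if (is.null(pair)) pair <- locus$indicators[[paste0(target_id, ".A")]]
  stopifnot(!is.null(pair))
  target <- locus$targets[[target_id]]
  ref <- locus$reference
  cut <- target$cut_site
  r <- params$wt_marker
  R <- params$comparison_range
  wt_window <- substr0(ref, cut - r, cut + r)
  seg_start <- find_all(pair$left, ref)
  seg_end <- find_all(pair$right, ref) + nchar(pair$right)
  ref_seg <- substr0(ref, seg_start, seg_end)

  n <- length(reads)
  status <- rep("edited", n)
  events_str <- character(n)
  n_events <- integer(n)
  net <- integer(n)
  large <- logical(n)
  has_indel <- logical(n)

  is_wt <- grepl(wt_window, reads, fixed = TRUE)
  status[is_wt] <- "WT"

  todo <- which(!is_wt)
  if (length(todo)) {
    lp <- regexpr(pair$left, reads[todo], fixed = TRUE)
    rp <- regexpr(pair$right, reads[todo], fixed = TRUE)
    segs <- substr(reads[todo], lp, rp + nchar(pair$right) - 1L)
    uniq <- unique(segs)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                    mismatch = params$mismatch)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(uniq), Biostrings::DNAString(ref_seg),
      type = "global", substitutionMatrix = mat,
      gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    lo <- cut - R
    hi <- cut + R
    ucalls <- lapply(seq_along(uniq), function(i) {
      evs <- extract_events(ap[i], as_[i], ref, seg_start)
      keep <- vapply(evs, function(e) {
        e_end <- if (e$kind == "insertion") e$position else e$position + e$size
        e$position <= hi && e_end >= lo
      }, logical(1))
      evs <- evs[keep]
      ldel <- any(vapply(evs, function(e)
        e$kind == "deletion" && spans_all_cuts(e, locus), logical(1)))
      nind <- sum(vapply(evs, function(e)
        switch(e$kind, insertion = e$size, deletion = -e$size, 0L), integer(1)))
      list(status = if (length(evs)) "edited" else "WT",
           events = paste(vapply(evs, event_label, "", target = target),
                          collapse = ";"),
           n_events = length(evs), net = nind, large = ldel,
           has_indel = any(vapply(evs, function(e)
             e$kind %in% c("insertion", "deletion"), logical(1))))
    })
    m <- match(segs, uniq)
    status[todo] <- vapply(ucalls, `[[`, "", "status")[m]
    events_str[todo] <- vapply(ucalls, `[[`, "", "events")[m]
    n_events[todo] <- vapply(ucalls, `[[`, integer(1), "n_events")[m]
    net[todo] <- vapply(ucalls, `[[`, integer(1), "net")[m]
    large[todo] <- vapply(ucalls, `[[`, logical(1), "large")[m]
    has_indel[todo] <- vapply(ucalls, `[[`, logical(1), "has_indel")[m]
  }

  data.frame(read_id = if (!is.null(names(reads))) names(reads)
             else sprintf("read%06d", seq_len(n)),
             target_id = target_id, status = status, events = events_str,
             n_events = n_events, net_indel = net, has_indel = has_indel,
             frameshift = net %% 3L != 0L,
             large_deletion = large, stringsAsFactors = FALSE)
}

# TRUE iff some equivalent placement of the deletion (the event is stored
# left-aligned; repeats allow a range of placements) contains every cut site
spans_all_cuts <- function(e, locus) {
  cuts <- vapply(locus$targets, `[[`, integer(1), "cut_site")
  ref <- locus$reference
  pos_r <- e$position
  while (pos_r + e$size < nchar(ref) &&
         substr0(ref, pos_r, pos_r + 1L) == substr0(ref, pos_r + e$size, pos_r + e$size + 1L))
    pos_r <- pos_r + 1L
  max(e$position, max(cuts) - e$size) <= min(pos_r, min(cuts))
}

#' Call a single read
#'
#' Convenience wrapper around [call_reads()] returning a one-row data.frame.
#'
#' @inheritParams call_reads
#' @param read a single read sequence.
#' @return one-row data.frame (see [call_reads()]).
#' @export
call_read <- function(read, locus, target_id, params = call_params(), pair = NULL) {
  call_reads(stats::setNames(read, "read"), locus, target_id, params, pair)
}

#' Detect cut-to-cut dropout deletions
#'
#' A read carries a dropout iff a single deletion event spans both cut sites
#' (its interval contains both cut coordinates). Reads are anchored by the
#' outermost indicator anchors (left anchor of the first target, right anchor
#' of the last); reads lacking either anchor return `NA`.
#'
#' @param reads named character vector (any orientation).
#' @param locus a [locus_model()].
#' @param params a [call_params()].
#' @return logical vector (`NA` where the read lacks the outer anchors).
#' @export
detect_large_deletion <- function(reads, locus, params = call_params()) {
  stopifnot(length(locus$targets) >= 2L)
  ord <- order(vapply(locus$targets, `[[`, integer(1), "cut_site"))
  t_first <- locus$targets[[ord[1L]]]$id
  t_last <- locus$targets[[ord[length(ord)]]]$id
  pl <- locus$indicators[[paste0(t_first, ".A")]]
  pr <- locus$indicators[[paste0(t_last, ".A")]]
  pair <- indicator_pair("span", pl$left, pr$right)
  fl <- filter_reads(reads, pair)
  out <- rep(NA, length(reads))
  names(out) <- names(reads)
  if (!length(fl$used)) return(out)
  ref <- locus$reference
  seg_start <- find_all(pair$left, ref)
  seg_end <- find_all(pair$right, ref) + nchar(pair$right)
  ref_seg <- substr0(ref, seg_start, seg_end)
  lp <- regexpr(pair$left, fl$used, fixed = TRUE)
  rp <- regexpr(pair$right, fl$used, fixed = TRUE)
  segs <- substr(fl$used, lp, rp + nchar(pair$right) - 1L)
  uniq <- unique(segs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(uniq), Biostrings::DNAString(ref_seg),
    type = "global", substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  uflag <- vapply(seq_along(uniq), function(i) {
    evs <- extract_events(ap[i], as_[i], ref, seg_start)
    any(vapply(evs, function(e)
      e$kind == "deletion" && spans_all_cuts(e, locus), logical(1)))
  }, logical(1))
  out[names(fl$used)] <- uflag[match(segs, uniq)]
  out
}

#' Summarize calls at one target site
#'
#' Aggregates per-read calls into the per-site summary: reads used, indel
#' reads and frequency, frameshift reads and frequency, and the
#' mutation-pattern table (patterns below `min_frequency` are dropped from the
#' table but still counted in the totals). Percentages follow the printed
#' precision convention: one decimal below 10, integer at or above 10.
#'
#' @param calls data.frame from [call_reads()].
#' @param params a [call_params()].
#' @param total_reads optional total read count before indicator filtering.
#' @return an object of class `site_summary` (a list).
#' @export
summarize_site <- function(calls, params = call_params(), total_reads = NULL) {
  stopifnot(length(unique(calls$target_id)) <= 1L)
  used <- calls[calls$status != "excluded", , drop = FALSE]
  reads_used <- nrow(used)
  indel <- used[used$has_indel, , drop = FALSE]
  indel_reads <- nrow(indel)
  frameshift_reads <- sum(used$frameshift & used$has_indel)
  sub_only_reads <- sum(used$status == "edited" & !used$has_indel)
  pat <- table(used$events[used$status == "edited"])
  pat <- pat[pat >= params$min_frequency]
  pat <- sort(pat, decreasing = TRUE)
  pct <- function(x) if (reads_used > 0) fmt_pct_value(100 * x / reads_used) else NA_real_
  structure(list(
    target_id = if (nrow(calls)) calls$target_id[1L] else NA_character_,
    total_reads = if (is.null(total_reads)) nrow(calls) else total_reads,
    reads_used = reads_used,
    indel_reads = indel_reads,
    indel_pct = pct(indel_reads),
    indel_pct_raw = if (reads_used > 0) 100 * indel_reads / reads_used else NA_real_,
    frameshift_reads = frameshift_reads,
    frameshift_pct = pct(frameshift_reads),
    substitution_only_reads = sub_only_reads,
    pattern_table = pat), class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf("site_summary %s: %d used / %d total; indels %d (%s%%); frameshifts %d (%s%%)\n",
              x$target_id, x$reads_used, x$total_reads, x$indel_reads,
              format(x$indel_pct), x$frameshift_reads, format(x$frameshift_pct)))
  invisible(x)
}
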