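# Tracking of native target-region variants in read pools.
#
# Variants are specific small differences inside the protospacer+PAM window;
# after orientation normalization, assignment is by exact occurrence of the
# variant's expected window string (longest first, then catalog order), which
# keeps the canonical/variant/other partition crisp.

#' Define a native target-region variant
#'
#' @param id variant id (e.g. `"V7"`).
#' @param target_id target the variant lies in.
#' @param expected the full protospacer+PAM window string with the variant
#'   applied.
#' @param class one of `substitution`, `insertion`, `deletion`,
#'   `pam_substitution`.
#' @param description free-text description.
#' @param flag optional QC flag (e.g. `"possibly sequencing error"` for
#'   variants seen only in short-read data).
#' @return an object of class `variant_def`.
#' @export
variant_def <- function(id, target_id, expected, class, description = "",
                        flag = NA_character_) {
  class <- match.arg(class, c("substitution", "insertion", "deletion",
                              "pam_substitution"))
  structure(list(id = id, target_id = target_id, expected = toupper(expected),
                 class = class, description = description, flag = flag),
            class = "variant_def")
}

#' Count cataloged variants in a read pool
#'
#' Filters reads with the target's "B" indicator pair, then assigns each used
#' read to at most one variant by exact occurrence of the variant's expected
#' window string; reads carrying the canonical window are `canonical`, the
#' rest (including de-novo edits) are `other`. Assignment priority: longest
#' expected string first, then catalog order.
#'
#' @param reads named character vector of read sequences (any orientation).
#' @param locus a [locus_model()].
#' @param target_id target id.
#' @param catalog list of [variant_def()]; defaults to the locus catalog
#'   entries for this target.
#' @param pair indicator pair; defaults to the locus's `<target>.B` pair.
#' @param sample_id label carried into the result.
#' @return an object of class `variant_counts`.
#' @export
track_variants <- function(reads, locus, target_id, catalog = NULL, pair = NULL,
                           sample_id = "sample") {
  if (is.null(catalog))
    catalog <- Filter(function(v) v$target_id == target_id, locus$variants)
  if (!length(catalog)) stop("empty variant catalog", call. = FALSE)
  if (is.null(pair)) pair <- locus$indicators[[paste0(target_id, ".B")]]
  stopifnot(!is.null(pair))
  exp_strings <- vapply(catalog, `[[`, "", "expected")
  if (anyDuplicated(exp_strings))
    stop("variants with identical expected strings", call. = FALSE)
  target <- locus$targets[[target_id]]
  w <- target_window(target)
  canonical <- substr0(locus$reference, w[1], w[2])

  fl <- filter_reads(reads, pair)
  used <- fl$used
  reads_used <- length(used)

  ids <- vapply(catalog, `[[`, "", "id")
  ord <- order(-nchar(exp_strings), seq_along(catalog))
  assigned <- rep(NA_character_, reads_used)
  for (k in ord) {
    hit <- is.na(assigned) & grepl(exp_strings[k], used, fixed = TRUE)
    assigned[hit] <- ids[k]
  }
  can_hit <- is.na(assigned) & grepl(canonical, used, fixed = TRUE)
  assigned[can_hit] <- "canonical"
  assigned[is.na(assigned)] <- "other"

  counts <- stats::setNames(integer(length(ids) + 2L), c("canonical", ids, "other"))
  tab <- table(assigned)
  counts[names(tab)] <- as.integer(tab)
  pct_raw <- if (reads_used > 0) 100 * counts / reads_used else counts * NA_real_
  structure(list(sample_id = sample_id, target_id = target_id,
                 total_reads = length(reads), reads_used = reads_used,
                 counts = counts, pct_raw = pct_raw,
                 pct = fmt_pct_value(pct_raw),
                 flags = stats::setNames(vapply(catalog, `[[`, "", "flag"), ids)),
            class = "variant_counts")
}

#' @export
print.variant_counts <- function(x, ...) {
  cat(sprintf("variant_counts %s (%s): %d used / %d total\n",
              x$sample_id, x$target_id, x$reads_used, x$total_reads))
  cells <- fmt_count_pct(x$counts, x$reads_used)
  for (i in seq_along(cells)) cat(sprintf("  %-10s %s\n", names(x$counts)[i], cells[i]))
  invisible(x)
}

#' Variant enrichment over background
#'
#' Percentage-point difference of a variant's frequency between a line and a
#' background sample, computed on the reported (printed-precision)
#' percentages, matching the arithmetic of the tables this reproduces.
#'
#' @param line,background [track_variants()] results over the same catalog.
#' @param variant_id variant id.
#' @return numeric percentage-point difference (negative allowed).
#' @export
enrichment_delta <- function(line, background, variant_id) {
  if (!variant_id %in% names(line$counts) || !variant_id %in% names(background$counts))
    stop(sprintf("variant %s absent from a catalog run", variant_id), call. = FALSE)
  unname(line$pct[variant_id] - background$pct[variant_id])
}
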