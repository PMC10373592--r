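# Locus model: the multi-haplotype amplicon, its sgRNA targets, primers and
# restriction enzymes; in-silico PCR and CAPS digestion.
#
# All coordinates are 0-based, half-open on the + strand of the reference
# amplicon. PAM-relative labels (-1..-20, -1 adjacent to the PAM) are used for
# display only; see pam_relative().

#' Define an sgRNA target site
#'
#' A Cas9 target on the reference amplicon. The blunt cut is placed 3 nt 5' of
#' the PAM (between protospacer positions -4 and -3, with -1 adjacent to the
#' PAM), the canonical SpCas9 geometry.
#'
#' @param id label, e.g. `"sgRNA1"`.
#' @param protospacer 20-nt uppercase DNA string (the sgRNA spacer sequence).
#' @param pam 3-nt PAM matching `NGG`.
#' @param strand `"+"` or `"-"` relative to the reference amplicon.
#' @param pam_start 0-based offset of the leftmost base of the 3-bp PAM tract
#'   on the + strand of the reference.
#' @return an object of class `target_site`.
#' @export
target_site <- function(id, protospacer, pam, strand = "+", pam_start) {
  stopifnot(nchar(protospacer) == 20L, nchar(pam) == 3L, strand %in% c("+", "-"))
  if (substr(pam, 2L, 3L) != "GG")
    stop(sprintf("target %s: PAM %s does not match NGG", id, pam), call. = FALSE)
  pam_start <- as.integer(pam_start)
  cut_site <- if (strand == "+") pam_start - 3L else pam_start + 6L
  structure(list(id = id, protospacer = toupper(protospacer), pam = toupper(pam),
                 strand = strand, pam_start = pam_start, cut_site = cut_site),
            class = "target_site")
}

#' Define a haplotype by its SNP profile
#'
#' @param id label, e.g. `"copy1"`.
#' @param snp_profile named character vector; names are 0-based reference
#'   coordinates, values single bases. Substitution-only: indel-bearing native
#'   variants are expressed as [variant_def()] entries instead.
#' @return an object of class `haplotype`.
#' @export
haplotype <- function(id, snp_profile = character(0)) {
  if (length(snp_profile)) {
    stopifnot(!is.null(names(snp_profile)), all(nchar(snp_profile) == 1L))
    snp_profile <- snp_profile[order(as.integer(names(snp_profile)))]
  }
  structure(list(id = id, snp_profile = snp_profile,
                 editable_per_target = logical(0)), class = "haplotype")
}

#' Define a primer pair
#'
#' @param name label.
#' @param forward,reverse primer sequences, each written 5'->3' on its own
#'   strand. Matching is exact (0 mismatches).
#' @param labelled logical; `TRUE` for fluorophore-labelled CE primers
#'   (metadata only).
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, labelled = FALSE) {
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse), labelled = isTRUE(labelled)),
            class = "primer_pair")
}

#' Define a restriction enzyme
#'
#' @param name label.
#' @param recognition IUPAC DNA recognition string, length >= 4.
#' @param cut_offset integer offset of the top-strand cut within the
#'   recognition site, in `[0, nchar(recognition)]`.
#' @return an object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  stopifnot(nchar(recognition) >= 4L)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset outside recognition site", call. = FALSE)
  structure(list(name = name, recognition = recognition, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' Assemble and validate a locus model
#'
#' Binds the reference amplicon to its haplotypes, sgRNA targets, primers,
#' enzymes and (optionally) indicator pairs and a native-variant catalog, and
#' checks all structural invariants. Editability of each haplotype at each
#' target is derived: a haplotype is uneditable at a target when its
#' protospacer+PAM window differs from the canonical target string.
#'
#' @param reference amplicon DNA string.
#' @param haplotypes list of [haplotype()]. An empty list yields a
#'   reference-only haplotype set (single haplotype `"reference"`).
#' @param targets list of [target_site()].
#' @param primers list of [primer_pair()].
#' @param enzymes list of [restriction_enzyme()].
#' @param variable_positions optional sorted integer vector of 0-based variable
#'   coordinates; derived from the haplotype profiles when `NULL`.
#' @param indicators optional list of [indicator_pair()] (keyed by
#'   `target_id.set`, e.g. `"sgRNA1.A"`).
#' @param variants optional list of [variant_def()].
#' @return an object of class `locus_model`.
#' @export
locus_model <- function(reference, haplotypes, targets, primers = list(),
                        enzymes = list(), variable_positions = NULL,
                        indicators = list(), variants = list()) {
  reference <- toupper(reference)
  if (!nchar(reference)) stop("empty reference", call. = FALSE)
  if (!length(haplotypes)) haplotypes <- list(haplotype("reference"))
  names(targets) <- vapply(targets, `[[`, "", "id")
  names(haplotypes) <- vapply(haplotypes, `[[`, "", "id")
  if (anyDuplicated(names(haplotypes))) stop("duplicate haplotype ids", call. = FALSE)

  # targets: protospacer+PAM must occur contiguously at the stated position,
  # and target windows must not overlap each other
  for (t in targets) {
    w <- target_window(t)
    if (w[1] < 0 || w[2] > nchar(reference))
      stop(sprintf("target %s outside reference", t$id), call. = FALSE)
    obs <- substr0(reference, w[1], w[2])
    exp <- target_string_canonical(t)
    if (obs != exp)
      stop(sprintf("target %s: protospacer+PAM not found in reference at position %d (saw %s)",
                   t$id, w[1], obs), call. = FALSE)
  }
  if (length(targets) > 1L) {
    ws <- t(vapply(targets, target_window, integer(2)))
    o <- order(ws[, 1])
    ws <- ws[o, , drop = FALSE]
    if (any(ws[-1, 1] < ws[-nrow(ws), 2]))
      stop("target windows overlap", call. = FALSE)
  }

  # haplotype profiles: in-range, and within the declared variable positions
  prof_pos <- sort(unique(unlist(lapply(haplotypes, function(h)
    as.integer(names(h$snp_profile))))))
  if (is.null(variable_positions)) variable_positions <- prof_pos
  variable_positions <- sort(unique(as.integer(variable_positions)))
  if (length(prof_pos) && any(prof_pos < 0 | prof_pos >= nchar(reference)))
    stop("SNP position out of range of the reference", call. = FALSE)
  if (length(setdiff(prof_pos, variable_positions)))
    stop("haplotype SNP at a position not in variable_positions", call. = FALSE)

  # primers must match the reference exactly and define a positive product
  for (p in primers) {
    f <- find_all(p$forward, reference)
    r <- find_all(revcomp(p$reverse), reference)
    if (length(f) != 1L || length(r) != 1L)
      stop(sprintf("primer pair %s: primers must each match the reference exactly once",
                   p$name), call. = FALSE)
    if (r + nchar(p$reverse) <= f)
      stop(sprintf("primer pair %s: non-positive product", p$name), call. = FALSE)
  }

  loc <- structure(list(reference = reference, haplotypes = haplotypes,
                        targets = targets, variable_positions = variable_positions,
                        primers = primers, enzymes = enzymes,
                        indicators = indicators, variants = variants),
                   class = "locus_model")

  # derived editability flags
  for (h in names(loc$haplotypes)) {
    seqh <- haplotype_sequence(loc, h)
    flags <- vapply(loc$targets, function(t) {
      w <- target_window(t)
      substr0(seqh, w[1], w[2]) == target_string_canonical(t)
    }, logical(1))
    loc$haplotypes[[h]]$editable_per_target <- flags
  }
  loc
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("locus_model: %d bp reference, %d haplotypes, %d targets, %d variable positions\n",
              nchar(x$reference), length(x$haplotypes), length(x$targets),
              length(x$variable_positions)))
  for (t in x$targets)
    cat(sprintf("  %s (%s) PAM@%d cut@%d\n", t$id, t$strand, t$pam_start, t$cut_site))
  invisible(x)
}

# [start, end) of protospacer+PAM on the + strand
target_window <- function(target) {
  if (target$strand == "+")
    c(target$pam_start - 20L, target$pam_start + 3L)
  else
    c(target$pam_start, target$pam_start + 23L)
}

# canonical protospacer+PAM as it reads on the + strand of the reference
target_string_canonical <- function(target) {
  if (target$strand == "+") paste0(target$protospacer, target$pam)
  else revcomp(paste0(target$protospacer, target$pam))
}

#' PAM-relative label of a reference coordinate
#'
#' Maps a 0-based reference coordinate to the display convention used for
#' protospacer positions: -1..-20 counting away from the PAM (-1 adjacent),
#' "P1".."P3" inside the PAM, `NA` outside the target window.
#'
#' @param target a [target_site()].
#' @param pos 0-based reference coordinate(s).
#' @return character vector of labels.
#' @export
pam_relative <- function(target, pos) {
  w <- target_window(target)
  vapply(as.integer(pos), function(p) {
    if (p < w[1] || p >= w[2]) return(NA_character_)
    if (target$strand == "+") {
      if (p >= target$pam_start) paste0("P", p - target$pam_start + 1L)
      else as.character(p - target$pam_start)
    } else {
      if (p < target$pam_start + 3L) paste0("P", target$pam_start + 3L - p)
      else as.character(target$pam_start + 2L - p)
    }
  }, character(1))
}

#' Sequence of a haplotype
#'
#' Applies the haplotype's substitution profile to the reference; length is
#' preserved.
#'
#' @param locus a [locus_model()].
#' @param hap_id haplotype id.
#' @return DNA string.
#' @export
haplotype_sequence <- function(locus, hap_id) {
  h <- locus$haplotypes[[hap_id]]
  if (is.null(h)) stop(sprintf("unknown haplotype id %s", hap_id), call. = FALSE)
  s <- locus$reference
  if (length(h$snp_profile)) {
    pos <- as.integer(names(h$snp_profile))
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[pos + 1L] <- unname(h$snp_profile)
    s <- paste(ch, collapse = "")
  }
  s
}

#' In-silico PCR
#'
#' Exact-match PCR: the product runs from the forward-primer start through the
#' reverse-primer end, inclusive of both primers. An empty string is returned
#' when either primer is absent from the template; multiple binding sites for
#' either primer are an error (ambiguous product).
#'
#' @param template DNA string.
#' @param pair a [primer_pair()].
#' @return product DNA string (possibly `""`).
#' @export
in_silico_pcr <- function(template, pair) {
  f <- find_all(pair$forward, template)
  r <- find_all(revcomp(pair$reverse), template)
  if (length(f) > 1L || length(r) > 1L)
    stop(sprintf("primer pair %s: multiple binding sites (ambiguous product)", pair$name),
         call. = FALSE)
  if (!length(f) || !length(r)) return("")
  end <- r + nchar(pair$reverse)
  if (end <= f) return("")
  substr0(template, f, end)
}

#' In-silico restriction digestion
#'
#' Finds recognition sites on the top strand (IUPAC degenerate bases per the
#' standard code) and returns fragment lengths ordered 5'->3'. Zero sites yield
#' a single fragment; lengths always sum to the amplicon length.
#'
#' @param amplicon DNA string.
#' @param enzyme a [restriction_enzyme()].
#' @return integer vector of fragment lengths.
#' @export
digest <- function(amplicon, enzyme) {
  n <- nchar(amplicon)
  stopifnot(n > 0L)
  hits <- Biostrings::matchPattern(enzyme$recognition, Biostrings::DNAString(amplicon),
                                   fixed = FALSE)
  cuts <- sort(unique(BiocGenerics::start(hits) - 1L + enzyme$cut_offset))
  cuts <- cuts[cuts > 0L & cuts < n]
  as.integer(diff(c(0L, cuts, n)))
}
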