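# Ground-truthed simulation of edited cell-lineage mixtures, short amplicon
# reads, clone (Sanger-like) reads and CE peak tables.
#
# All randomness flows from a single master seed in the SimConfig; operations
# that draw independently (lineages vs. reads vs. clones) use seeds derived
# deterministically from it, so identical configs give byte-identical outputs.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + k) %% 2147483647)
}

#' Edit event
#'
#' One mutation applied to one gene copy. Kinds: `insertion` (at an inter-base
#' `position`, with `bases`), `deletion` (`size` bp starting at `position`),
#' `substitution` (`bases` replacing the reference starting at `position`),
#' `large_deletion` (single deletion joining the two cut sites), and
#' `hdr_conversion` (the donor haplotype's genotype copied over the tract
#' `[tract_start, tract_end)`).
#'
#' @param kind event kind (see above).
#' @param position 0-based coordinate (inter-base for insertions).
#' @param size event size in bp.
#' @param bases inserted/substituted bases.
#' @param target_id target the event is attributed to (`NA` for whole-amplicon
#'   events).
#' @param donor_hap,tract_start,tract_end HDR conversions only.
#' @return an object of class `edit_event`.
#' @export
edit_event <- function(kind, position, size = 1L, bases = "", target_id = NA_character_,
                       donor_hap = NA_character_, tract_start = NA_integer_,
                       tract_end = NA_integer_) {
  kind <- match.arg(kind, c("insertion", "deletion", "substitution",
                            "large_deletion", "hdr_conversion"))
  if (kind != "substitution" && kind != "hdr_conversion") stopifnot(size >= 1L)
  structure(list(kind = kind, position = as.integer(position),
                 size = as.integer(size), bases = bases, target_id = target_id,
                 donor_hap = donor_hap, tract_start = as.integer(tract_start),
                 tract_end = as.integer(tract_end)),
            class = "edit_event")
}

#' Cell lineage
#'
#' One clonal cell population: a fraction of the simulated pool and the edit
#' state of each gene copy. `copies` is a list of `list(hap_id, weight,
#' events)`; `weight` generalizes integer copy dosage so that rare alleles
#' (e.g. an under-amplified donor copy) can be given fractional template
#' shares.
#'
#' @param id lineage label.
#' @param fraction proportion of the cell population in `[0, 1]`.
#' @param copies list of copies (see above).
#' @return an object of class `cell_lineage`.
#' @export
cell_lineage <- function(id, fraction, copies) {
  stopifnot(fraction >= 0, fraction <= 1)
  copies <- lapply(copies, function(cp) {
    if (is.null(cp$weight)) cp$weight <- 1
    if (is.null(cp$events)) cp$events <- list()
    cp
  })
  structure(list(id = id, fraction = fraction, copies = copies),
            class = "cell_lineage")
}

#' Simulation configuration
#'
#' Defaults state the simulated world: amplicon-wide reads, an NHEJ spectrum
#' dominated by single-base events at the cut, rare ~100 bp dropout deletions
#' between the two cuts, and no HDR unless requested.
#'
#' @param seed master seed; every draw derives from it.
#' @param dosage named numeric vector of template weights per haplotype.
#' @param cut_prob per-target cut probability (scalar or named by target id).
#' @param indel_size_dist named probabilities over signed indel sizes
#'   (names like `"+1"`, `"-2"`).
#' @param large_del_prob probability a doubly-editable copy carries the
#'   cut-to-cut dropout deletion instead of per-target repair.
#' @param hdr_prob per-copy probability that an editable copy is repaired by
#'   conversion from the donor (one tract covering the donor-variant target
#'   windows).
#' @param donor donor haplotype id; `NULL` selects the haplotype uneditable at
#'   every target (the rare-allele donor).
#' @param error_rate per-base substitution error rate of short reads.
#' @param n_reads,n_clones read counts for the short-read pool and the clone
#'   (Sanger-like) pool.
#' @param clone_error_rate per-base error rate of clone reads (0: error-free).
#' @param n_lineages number of lineages; fractions are drawn Dirichlet(alpha).
#' @param lineage_alpha Dirichlet concentration for lineage fractions.
#' @param truncate_prob fraction of short reads truncated (incomplete
#'   molecules); truncated reads keep their first `truncate_len` bases.
#' @param truncate_len retained prefix length of truncated reads.
#' @param revcomp_prob fraction of reads emitted in reverse-complement
#'   orientation.
#' @param exact_counts logical; allocate reads to molecule classes
#'   deterministically by largest remainder instead of multinomially.
#' @param max_rfu peak-height scale for simulated CE tables.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       dosage = c(copy1 = 1, copy2 = 1, copy4 = 1, copy5 = 1),
                       cut_prob = 0.8,
                       indel_size_dist = c(`+1` = 0.4, `-1` = 0.3, `-2` = 0.1,
                                           `-3` = 0.05, `+2` = 0.05, `-4` = 0.04,
                                           `+3` = 0.03, `-5` = 0.02, `-6` = 0.01),
                       large_del_prob = 0.05, hdr_prob = 0, donor = NULL,
                       error_rate = 0, n_reads = 10000L, n_clones = 80L,
                       clone_error_rate = 0, n_lineages = 1L, lineage_alpha = 1,
                       truncate_prob = 0, truncate_len = 250L,
                       revcomp_prob = 0, exact_counts = FALSE, max_rfu = 1000) {
  stopifnot(all(dosage > 0), all(cut_prob >= 0 & cut_prob <= 1),
            large_del_prob >= 0, large_del_prob <= 1,
            hdr_prob >= 0, hdr_prob <= 1, error_rate >= 0, error_rate < 1,
            truncate_prob >= 0, truncate_prob <= 1,
            revcomp_prob >= 0, revcomp_prob <= 1,
            abs(sum(indel_size_dist) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), dosage = dosage, cut_prob = cut_prob,
                 indel_size_dist = indel_size_dist,
                 large_del_prob = large_del_prob, hdr_prob = hdr_prob,
                 donor = donor, error_rate = error_rate,
                 n_reads = as.integer(n_reads), n_clones = as.integer(n_clones),
                 clone_error_rate = clone_error_rate,
                 n_lineages = as.integer(n_lineages), lineage_alpha = lineage_alpha,
                 truncate_prob = truncate_prob, truncate_len = as.integer(truncate_len),
                 revcomp_prob = revcomp_prob, exact_counts = isTRUE(exact_counts),
                 max_rfu = max_rfu),
            class = "sim_config")
}

#' Write / read a simulation scenario config
#'
#' JSON round-trip of a [sim_config()] for reproducibility.
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$dosage <- as.list(x$dosage)                  # keep names in JSON objects
  x$indel_size_dist <- as.list(x$indel_size_dist)
  if (!is.null(names(x$cut_prob))) x$cut_prob <- as.list(x$cut_prob)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("dosage", "indel_size_dist", "cut_prob"))
    if (is.list(x[[f]])) x[[f]] <- unlist(x[[f]])
  do.call(sim_config, x[!vapply(x, is.null, logical(1))])
}

cut_prob_for <- function(cfg, target_id) {
  cp <- cfg$cut_prob
  if (is.null(names(cp))) cp[[1L]] else if (target_id %in% names(cp)) cp[[target_id]] else 0
}

default_donor <- function(locus) {
  unedit <- vapply(locus$haplotypes, function(h) all(!h$editable_per_target), logical(1))
  if (!any(unedit)) return(NULL)
  names(locus$haplotypes)[which(unedit)[1L]]
}

# draw an HDR conversion tract whose endpoints fall uniformly among the
# inter-SNP intervals flanking `span` (= union of the windows to convert)
draw_tract <- function(locus, span) {
  vp <- locus$variable_positions
  left_snps <- sort(vp[vp < span[1]], decreasing = TRUE)
  right_snps <- sort(vp[vp >= span[2]])
  nl <- sample.int(length(left_snps) + 1L, 1L) - 1L   # SNPs absorbed on the left
  nr <- sample.int(length(right_snps) + 1L, 1L) - 1L
  start <- if (nl == 0L) span[1] else left_snps[nl]
  end <- if (nr == 0L) span[2] else right_snps[nr] + 1L
  c(start, end)
}

#' Simulate edited cell lineages
#'
#' Draws, per lineage and per gene copy, the edit state: uneditable haplotypes
#' (seed/PAM SNPs) never receive NHEJ or dropout events; doubly-editable
#' copies may carry the cut-to-cut dropout deletion; cut targets repair by
#' NHEJ (configured size spectrum) or by HDR conversion from the donor, whose
#' tract always contains the converted target window(s).
#'
#' @param cfg a [sim_config()].
#' @param locus a [locus_model()].
#' @return list of [cell_lineage()].
#' @export
simulate_lineages <- function(cfg, locus) {
  if (!all(names(cfg$dosage) %in% names(locus$haplotypes)))
    stop("dosage names must be haplotype ids", call. = FALSE)
  if (!length(cfg$dosage) || all(cfg$dosage <= 0))
    stop("dosage zero for all haplotypes", call. = FALSE)
  donor <- if (is.null(cfg$donor)) default_donor(locus) else cfg$donor
  targets <- locus$targets
  cuts <- sort(vapply(targets, `[[`, integer(1), "cut_site"))

  with_seed(derive_seed(cfg$seed, 1L), {
    frac <- if (cfg$n_lineages == 1L) 1 else {
      g <- stats::rgamma(cfg$n_lineages, shape = cfg$lineage_alpha)
      g / sum(g)
    }
    lapply(seq_len(cfg$n_lineages), function(li) {
      copies <- list()
      for (h in names(cfg$dosage)) {
        w <- cfg$dosage[[h]]
        n_int <- if (w == floor(w)) as.integer(w) else 1L
        wt <- if (w == floor(w)) 1 else w
        hap <- locus$haplotypes[[h]]
        for (ci in seq_len(n_int)) {
          events <- list()
          editable <- hap$editable_per_target
          if (any(editable)) {
            # per-copy repair outcome: conversion from the donor (probability
            # hdr_prob, one tract covering the donor-variant target windows),
            # or the cut-to-cut dropout, or per-target NHEJ -- events on one
            # copy never overlap
            if (!is.null(donor) && donor != h && stats::runif(1) < cfg$hdr_prob) {
              dhap <- locus$haplotypes[[donor]]
              dtw <- t(vapply(targets[!dhap$editable_per_target],
                              target_window, integer(2)))
              span <- c(min(dtw[, 1]), max(dtw[, 2]))
              tr <- draw_tract(locus, span)
              events <- list(edit_event("hdr_conversion", tr[1],
                                        size = tr[2] - tr[1],
                                        donor_hap = donor,
                                        tract_start = tr[1], tract_end = tr[2]))
            } else if (length(targets) == 2L && all(editable) &&
                       stats::runif(1) < cfg$large_del_prob) {
              events <- list(edit_event("large_deletion", cuts[1],
                                        size = cuts[2] - cuts[1]))
            } else {
              for (t in targets) {
                if (!editable[[t$id]]) next
                if (stats::runif(1) >= cut_prob_for(cfg, t$id)) next
                sz <- sample(names(cfg$indel_size_dist), 1L,
                             prob = cfg$indel_size_dist)
                k <- abs(as.integer(sz))
                if (substr(sz, 1L, 1L) == "+") {
                  events <- c(events, list(edit_event("insertion", t$cut_site,
                                                      size = k,
                                                      bases = random_dna(k),
                                                      target_id = t$id)))
                } else {
                  start <- t$cut_site - as.integer(ceiling(k / 2))
                  events <- c(events, list(edit_event("deletion", start, size = k,
                                                      target_id = t$id)))
                }
              }
            }
          }
          copies <- c(copies, list(list(hap_id = h, weight = wt, events = events)))
        }
      }
      cell_lineage(sprintf("L%02d", li), frac[li], copies)
    })
  })
}

# classify a copy's truth at each target and materialize its sequence
molecule_from_copy <- function(locus, cp) {
  hap <- locus$haplotypes[[cp$hap_id]]
  s <- haplotype_sequence(locus, cp$hap_id)
  cuts <- vapply(locus$targets, `[[`, integer(1), "cut_site")
  cls <- vapply(locus$targets, function(t)
    if (hap$editable_per_target[[t$id]]) "WT" else "variant", character(1))
  large_del <- FALSE

  evs <- cp$events
  # substitution-type events first (no coordinate shifts), then indels right-to-left
  is_indel <- vapply(evs, function(e) e$kind %in% c("insertion", "deletion",
                                                    "large_deletion"), logical(1))
  for (e in evs[!is_indel]) {
    if (e$kind == "hdr_conversion") {
      dseq <- haplotype_sequence(locus, e$donor_hap)
      substr(s, e$tract_start + 1L, e$tract_end) <-
        substr(dseq, e$tract_start + 1L, e$tract_end)
      for (t in locus$targets) {
        w <- target_window(t)
        if (w[1] >= e$tract_start && w[2] <= e$tract_end)
          cls[[t$id]] <- "hdr"
      }
    } else if (e$kind == "substitution") {
      substr(s, e$position + 1L, e$position + nchar(e$bases)) <- e$bases
      for (t in locus$targets) {
        w <- target_window(t)
        if (e$position >= w[1] && e$position < w[2] && cls[[t$id]] == "WT")
          cls[[t$id]] <- "edited"
      }
    }
  }
  ind <- evs[is_indel]
  if (length(ind)) {
    ord <- order(vapply(ind, `[[`, integer(1), "position"), decreasing = TRUE)
    for (e in ind[ord]) {
      if (e$kind == "insertion") {
        s <- paste0(substr0(s, 0L, e$position), e$bases,
                    substr0(s, e$position, nchar(s)))
      } else {
        s <- paste0(substr0(s, 0L, e$position),
                    substr0(s, e$position + e$size, nchar(s)))
      }
      if (e$kind == "large_deletion") {
        large_del <- TRUE
        span <- c(e$position, e$position + e$size)
        for (t in locus$targets)
          if (span[1] <= t$cut_site && t$cut_site <= span[2])
            cls[[t$id]] <- "edited"
      } else if (!is.na(e$target_id)) {
        cls[[e$target_id]] <- "edited"
      }
    }
  }
  list(seq = s, classes = cls, large_deletion = large_del,
       events_str = compact_events_str(evs))
}

compact_events_str <- function(evs) {
  if (!length(evs)) return("")
  paste(vapply(evs, function(e) switch(e$kind,
    insertion = sprintf("%d:+%d%s", e$position, e$size, e$bases),
    deletion = sprintf("%d:-%d", e$position, e$size),
    substitution = sprintf("%d:>%s", e$position, e$bases),
    large_deletion = sprintf("%d:-%d(dropout)", e$position, e$size),
    hdr_conversion = sprintf("%d-%d:hdr(%s)", e$tract_start, e$tract_end, e$donor_hap)),
    character(1)), collapse = ";")
}

# expand lineages into the distinct molecule classes with pool weights
molecule_classes <- function(lineages, locus) {
  rows <- list()
  for (L in lineages) for (ci in seq_along(L$copies)) {
    cp <- L$copies[[ci]]
    m <- molecule_from_copy(locus, cp)
    rows[[length(rows) + 1L]] <- c(list(lineage_id = L$id, hap_id = cp$hap_id,
                                        weight = L$fraction * cp$weight), m)
  }
  w <- vapply(rows, `[[`, numeric(1), "weight")
  for (i in seq_along(rows)) rows[[i]]$weight <- w[i] / sum(w)
  rows
}

allocate_counts <- function(weights, n, exact) {
  if (exact) {
    raw <- weights * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      o <- order(raw - base, decreasing = TRUE)
      base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
    }
    as.integer(base)
  } else {
    as.integer(stats::rmultinom(1L, n, weights))
  }
}

apply_seq_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  lens <- nchar(reads)
  nerr <- stats::rbinom(length(reads), lens, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(reads[i], "")[[1L]]
    for (p in pos) ch[p] <- other_base(ch[p])
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

build_truth <- function(ids, classes, locus) {
  tr <- data.frame(read_id = ids, stringsAsFactors = FALSE)
  tr$lineage_id <- vapply(classes, `[[`, "", "lineage_id")
  tr$hap_id <- vapply(classes, `[[`, "", "hap_id")
  tr$events <- vapply(classes, `[[`, "", "events_str")
  tr$large_deletion <- vapply(classes, `[[`, logical(1), "large_deletion")
  for (t in locus$targets)
    tr[[paste0("class_", t$id)]] <- vapply(classes, function(m)
      m$classes[[t$id]], character(1))
  tr
}

#' Generate short amplicon reads with ground truth
#'
#' Emits full-amplicon reads (amplicon sequencing, not fragmented) from the
#' lineage mixture: read counts follow the (lineage fraction x copy weight)
#' composition, per-base substitution errors occur at the configured rate, and
#' each read carries exactly one ground-truth record.
#'
#' @param lineages list of [cell_lineage()].
#' @param cfg a [sim_config()].
#' @param locus a [locus_model()].
#' @param fastq optional path; writes the reads as FASTQ (constant quality "I").
#' @param truth_path optional path; writes the truth table as TSV.
#' @return list with `reads` (named character vector) and `truth` (data.frame).
#' @export
generate_reads <- function(lineages, cfg, locus, fastq = NULL, truth_path = NULL) {
  classes <- molecule_classes(lineages, locus)
  with_seed(derive_seed(cfg$seed, 2L), {
    counts <- allocate_counts(vapply(classes, `[[`, numeric(1), "weight"),
                              cfg$n_reads, cfg$exact_counts)
    idx <- rep(seq_along(classes), counts)
    reads <- vapply(classes, `[[`, "", "seq")[idx]
    ids <- sprintf("read%06d", seq_along(reads))
    names(reads) <- ids
    truth <- build_truth(ids, classes[idx], locus)
    truth$truncated <- FALSE
    if (cfg$truncate_prob > 0) {
      tr <- stats::runif(length(reads)) < cfg$truncate_prob
      reads[tr] <- substr(reads[tr], 1L, cfg$truncate_len)
      truth$truncated <- tr
    }
    reads <- apply_seq_errors(reads, cfg$error_rate)
    if (cfg$revcomp_prob > 0) {
      rc <- stats::runif(length(reads)) < cfg$revcomp_prob
      reads[rc] <- revcomp(reads[rc])
    }
    if (!is.null(fastq)) write_fastq(reads, fastq)
    if (!is.null(truth_path))
      utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Generate clone (Sanger-like) reads with ground truth
#'
#' One FASTA record per sampled molecule; error-free by default
#' (`clone_error_rate`), emulating cloned-amplicon Sanger reads.
#'
#' @inheritParams generate_reads
#' @param fasta optional path; writes the reads as FASTA.
#' @return list with `reads` and `truth` as in [generate_reads()].
#' @export
generate_clone_reads <- function(lineages, cfg, locus, fasta = NULL,
                                 truth_path = NULL) {
  classes <- molecule_classes(lineages, locus)
  with_seed(derive_seed(cfg$seed, 3L), {
    counts <- allocate_counts(vapply(classes, `[[`, numeric(1), "weight"),
                              cfg$n_clones, cfg$exact_counts)
    idx <- rep(seq_along(classes), counts)
    reads <- vapply(classes, `[[`, "", "seq")[idx]
    ids <- sprintf("clone%04d", seq_along(reads))
    names(reads) <- ids
    truth <- build_truth(ids, classes[idx], locus)
    reads <- apply_seq_errors(reads, cfg$clone_error_rate)
    if (!is.null(fasta)) write_fasta(reads, fasta)
    if (!is.null(truth_path))
      utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Generate a CE peak table from a lineage mixture
#'
#' Sizes each molecule's labelled-primer product by in-silico PCR and emits
#' one peak per distinct product size, height proportional to class abundance
#' scaled to `cfg$max_rfu`. Molecules whose product is lost (e.g. dropout
#' deletions removing a primer site) contribute no peak.
#'
#' @param lineages list of [cell_lineage()].
#' @param locus a [locus_model()].
#' @param target_id target whose CE assay to emulate.
#' @param wt_size expected WT product size (bp) of the labelled pair.
#' @param pair optional [primer_pair()]; defaults to the labelled pair whose
#'   WT product length equals `wt_size`.
#' @param sample_id sample label for the table.
#' @param max_rfu peak-height scale.
#' @return data.frame with columns sample, dye, size, height.
#' @export
generate_peak_table <- function(lineages, locus, target_id, wt_size, pair = NULL,
                                sample_id = "sim", max_rfu = 1000) {
  if (is.null(pair)) {
    for (p in locus$primers) {
      if (!p$labelled) next
      if (nchar(in_silico_pcr(locus$reference, p)) == wt_size) { pair <- p; break }
    }
    if (is.null(pair))
      stop("no labelled primer pair with the requested WT product size", call. = FALSE)
  }
  classes <- molecule_classes(lineages, locus)
  sizes <- vapply(classes, function(m) nchar(in_silico_pcr(m$seq, pair)), integer(1))
  w <- vapply(classes, `[[`, numeric(1), "weight")
  keep <- sizes > 0L
  agg <- tapply(w[keep], sizes[keep], sum)
  if (!length(agg)) {
    return(data.frame(sample = character(0), dye = character(0),
                      size = numeric(0), height = numeric(0)))
  }
  heights <- as.numeric(agg) / max(agg) * max_rfu
  data.frame(sample = sample_id, dye = "6-FAM",
             size = as.numeric(names(agg)), height = heights,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ / FASTA
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @param quality constant placeholder quality character for FASTQ.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  lines <- character(4L * length(reads))
  lines[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", names(reads))
  lines[seq(2L, by = 4L, length.out = length(reads))] <- unname(reads)
  lines[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(reads))] <-
    vapply(nchar(reads), function(n) strrep(quality, n), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path) {
  lines <- character(2L * length(reads))
  lines[seq(1L, by = 2L, length.out = length(reads))] <- paste0(">", names(reads))
  lines[seq(2L, by = 2L, length.out = length(reads))] <- unname(reads)
  writeLines(lines, path)
  invisible(path)
}

#' Read sequence records from FASTA/FASTQ
#'
#' @param path input path; format detected from the extension
#'   (`.fq`/`.fastq` vs `.fa`/`.fasta`).
#' @return named character vector of sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}
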