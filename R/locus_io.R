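# Plain-text serialization of a locus configuration.
#
# A locus config is a directory holding:
#   reference.fa    single-record FASTA reference amplicon
#   haplotypes.tsv  hap_id, position (0-based), base      (may list zero rows)
#   targets.tsv     id, protospacer, pam, strand, pam_start
#   primers.tsv     name, forward, reverse, labelled
#   enzymes.tsv     name, recognition, cut_offset
#   indicators.tsv  target_id, set, left, right           (optional)
#   variants.tsv    id, target_id, class, expected, description (optional)

read_tsv_checked <- function(path, required, optional = FALSE) {
  if (!file.exists(path)) {
    if (optional) return(NULL)
    stop(sprintf("%s: missing config table", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_locus(path, 1L, sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  df
}

#' Load a locus configuration from disk
#'
#' Reads a locus config directory (see package vignette for the schema),
#' validates every invariant via [locus_model()], and reports violations with
#' file and line context.
#'
#' @param config_path path to the config directory.
#' @return a [locus_model()].
#' @export
load_locus <- function(config_path) {
  ref_path <- file.path(config_path, "reference.fa")
  if (!file.exists(ref_path)) stop(sprintf("%s: missing reference", ref_path), call. = FALSE)
  ref_set <- Biostrings::readDNAStringSet(ref_path)
  if (length(ref_set) != 1L)
    stop_locus(ref_path, 1L, "reference FASTA must hold exactly one record")
  reference <- as.character(ref_set[[1L]])

  hp <- read_tsv_checked(file.path(config_path, "haplotypes.tsv"),
                         c("hap_id", "position", "base"))
  haps <- list()
  if (nrow(hp)) {
    # rows with an empty position declare a profile-less haplotype
    decl <- is.na(hp$position) | hp$position == ""
    for (i in which(!decl)) {
      p <- suppressWarnings(as.integer(hp$position[i]))
      if (is.na(p) || p < 0L || p >= nchar(reference))
        stop_locus(file.path(config_path, "haplotypes.tsv"), i + 1L,
                   sprintf("SNP position %s out of range", hp$position[i]))
    }
    for (id in unique(hp$hap_id)) {
      rows <- hp[hp$hap_id == id & !decl, , drop = FALSE]
      prof <- if (nrow(rows))
        stats::setNames(toupper(rows$base), rows$position) else character(0)
      haps[[id]] <- haplotype(id, prof)
    }
  }

  tg <- read_tsv_checked(file.path(config_path, "targets.tsv"),
                         c("id", "protospacer", "pam", "strand", "pam_start"))
  targets <- lapply(seq_len(nrow(tg)), function(i)
    target_site(tg$id[i], tg$protospacer[i], tg$pam[i], tg$strand[i], tg$pam_start[i]))

  pr <- read_tsv_checked(file.path(config_path, "primers.tsv"),
                         c("name", "forward", "reverse", "labelled"))
  primers <- lapply(seq_len(nrow(pr)), function(i)
    primer_pair(pr$name[i], pr$forward[i], pr$reverse[i], as.logical(pr$labelled[i])))
  names(primers) <- pr$name

  en <- read_tsv_checked(file.path(config_path, "enzymes.tsv"),
                         c("name", "recognition", "cut_offset"))
  enzymes <- lapply(seq_len(nrow(en)), function(i)
    restriction_enzyme(en$name[i], en$recognition[i], en$cut_offset[i]))
  names(enzymes) <- en$name

  ind <- read_tsv_checked(file.path(config_path, "indicators.tsv"),
                          c("target_id", "set", "left", "right"), optional = TRUE)
  indicators <- list()
  if (!is.null(ind) && nrow(ind)) {
    indicators <- lapply(seq_len(nrow(ind)), function(i)
      indicator_pair(ind$target_id[i], ind$left[i], ind$right[i]))
    names(indicators) <- paste(ind$target_id, ind$set, sep = ".")
  }

  va <- read_tsv_checked(file.path(config_path, "variants.tsv"),
                         c("id", "target_id", "class", "expected", "description"),
                         optional = TRUE)
  variants <- list()
  if (!is.null(va) && nrow(va)) {
    variants <- lapply(seq_len(nrow(va)), function(i)
      variant_def(va$id[i], va$target_id[i], va$expected[i], va$class[i],
                  va$description[i]))
    names(variants) <- va$id
  }

  locus_model(reference, haps, targets, primers, enzymes,
              indicators = indicators, variants = variants)
}

#' Write a locus configuration to disk
#'
#' Inverse of [load_locus()]; emits the plain-text config directory.
#'
#' @param locus a [locus_model()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(">reference", locus$reference), file.path(dir, "reference.fa"))
  rows <- do.call(rbind, lapply(locus$haplotypes, function(h) {
    if (!length(h$snp_profile))
      return(data.frame(hap_id = h$id, position = NA_integer_, base = "",
                        stringsAsFactors = FALSE))
    data.frame(hap_id = h$id, position = as.integer(names(h$snp_profile)),
               base = unname(h$snp_profile), stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(hap_id = character(0), position = integer(0),
                       base = character(0))
  utils::write.table(rows, file.path(dir, "haplotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tg <- do.call(rbind, lapply(locus$targets, function(t)
    data.frame(id = t$id, protospacer = t$protospacer, pam = t$pam,
               strand = t$strand, pam_start = t$pam_start)))
  utils::write.table(tg, file.path(dir, "targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pr <- do.call(rbind, lapply(locus$primers, function(p)
    data.frame(name = p$name, forward = p$forward, reverse = p$reverse,
               labelled = p$labelled)))
  if (is.null(pr)) pr <- data.frame(name = character(0), forward = character(0),
                                    reverse = character(0), labelled = logical(0))
  utils::write.table(pr, file.path(dir, "primers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  en <- do.call(rbind, lapply(locus$enzymes, function(e)
    data.frame(name = e$name, recognition = e$recognition, cut_offset = e$cut_offset)))
  if (is.null(en)) en <- data.frame(name = character(0), recognition = character(0),
                                    cut_offset = integer(0))
  utils::write.table(en, file.path(dir, "enzymes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(locus$indicators)) {
    keys <- names(locus$indicators)
    ind <- do.call(rbind, lapply(seq_along(locus$indicators), function(i)
      data.frame(target_id = locus$indicators[[i]]$target_id,
                 set = sub("^.*\\.", "", keys[i]),
                 left = locus$indicators[[i]]$left,
                 right = locus$indicators[[i]]$right)))
    utils::write.table(ind, file.path(dir, "indicators.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (length(locus$variants)) {
    va <- do.call(rbind, lapply(locus$variants, function(v)
      data.frame(id = v$id, target_id = v$target_id, class = v$class,
                 expected = v$expected, description = v$description)))
    utils::write.table(va, file.path(dir, "variants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
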