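# Shared fixtures, built in code. The demo locus is deterministic for a given
# seed, so building it once per test run keeps everything reproducible.

demo_locus <- build_demo_locus(seed = 1)

# A tiny 80 bp locus for the brute-force alignment oracle: one target, short
# indicator anchors, everything hand-placed.
mini_locus <- local({
  set.seed(42)
  n <- 80L
  repeat {
    ch <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    # homopolymer run crossing the cut (positions 40..43) to exercise
    # left-alignment; PAM NGG at [45,48)
    ch[41:44] <- "A"
    ch[47:48] <- "G"
    ref <- paste(ch, collapse = "")
    proto <- substr(ref, 26, 45)
    pam <- substr(ref, 46, 48)
    loc <- try(locus_model(
      ref, list(haplotype("copy1")),
      list(target_site("t1", proto, pam, "+", 45L)),
      primers = list(), enzymes = list(),
      indicators = list(t1.A = indicator_pair("t1", substr(ref, 6, 15),
                                              substr(ref, 56, 65)))),
      silent = TRUE)
    if (!inherits(loc, "try-error") &&
        length(find_anchor <- gregexpr(substr(ref, 6, 15), ref, fixed = TRUE)[[1]]) == 1 &&
        length(gregexpr(substr(ref, 56, 65), ref, fixed = TRUE)[[1]]) == 1)
      break
  }
  loc
})

# brute-force single-indel oracle: all (kind, position, size) whose application
# to `ref` yields `read`; returns the leftmost (= left-aligned) match
oracle_single_indel <- function(ref, read) {
  nr <- nchar(ref)
  nd <- nchar(read)
  hits <- list()
  if (nd < nr) {               # deletion of size nr - nd
    k <- nr - nd
    for (i in 0:(nr - k)) {
      cand <- paste0(substr(ref, 1, i), substr(ref, i + k + 1, nr))
      if (cand == read) hits[[length(hits) + 1L]] <-
          list(kind = "deletion", position = i, size = k, bases = "")
    }
  } else if (nd > nr) {        # insertion of size nd - nr
    k <- nd - nr
    for (i in 0:(nd - k)) {
      cand <- paste0(substr(read, 1, i), substr(read, i + k + 1, nd))
      if (cand == ref) hits[[length(hits) + 1L]] <-
          list(kind = "insertion", position = i, size = k,
               bases = substr(read, i + 1, i + k))
    }
  }
  if (!length(hits)) return(NULL)
  hits[[which.min(vapply(hits, `[[`, numeric(1), "position"))]]
}

# single-lineage scenario with an exact edited fraction at one target
edited_fraction_lineage <- function(frac, target_id = "sgRNA2", locus = demo_locus) {
  cut <- locus$targets[[target_id]]$cut_site
  list(cell_lineage("L1", 1, list(
    list(hap_id = "copy1", weight = frac,
         events = list(edit_event("insertion", cut, 1L, "G", target_id = target_id))),
    list(hap_id = "copy1", weight = 1 - frac))))
}
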