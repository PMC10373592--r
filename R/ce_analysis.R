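# Capillary-electrophoresis fragment analysis: peak classification,
# peak-height mutation frequency, and chimerism assessment from subsamples.

#' Read a CE peak table
#'
#' Tab-separated export with columns sample, dye, size, height (compatible
#' with common fragment-analysis software exports).
#'
#' @param path TSV path.
#' @return data.frame with columns sample, dye, size, height.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "dye", "size", "height"), names(df))
  if (length(miss))
    stop_locus(path, 1L, sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  stopifnot(all(df$height >= 0), all(df$size > 0))
  df
}

#' Classify CE peaks as WT or mutant
#'
#' Peaks below `noise_floor` times the tallest peak are discarded; a retained
#' peak is WT iff its size is within `tolerance` bp of the expected WT size,
#' mutant otherwise. The inferred net indel is the size difference rounded to
#' the nearest integer (CE sizes are fractional).
#'
#' @param peaks data.frame with columns size and height (e.g. from
#'   [read_peak_table()]).
#' @param expected_wt_size expected WT product size in bp.
#' @param tolerance WT size tolerance in bp (default 0.5).
#' @param noise_floor fraction of the maximum height below which peaks are
#'   noise (default 0.01).
#' @return the peaks retained, with columns `class` (`"WT"`/`"mutant"`) and
#'   `net_indel` added; zero rows (with a warning) when everything is noise.
#' @export
classify_peaks <- function(peaks, expected_wt_size, tolerance = 0.5,
                           noise_floor = 0.01) {
  stopifnot(nrow(peaks) > 0L)
  keep <- peaks$height > 0 & peaks$height >= noise_floor * max(peaks$height)
  out <- peaks[keep, , drop = FALSE]
  if (!nrow(out)) {
    warning("all peaks below the noise floor")
    out$class <- character(0)
    out$net_indel <- integer(0)
    return(out)
  }
  out$class <- ifelse(abs(out$size - expected_wt_size) <= tolerance, "WT", "mutant")
  out$net_indel <- as.integer(round(out$size - expected_wt_size))
  out
}

#' Peak-height mutation frequency
#'
#' Applies (sum mutant peak heights) / (sum mutant and WT peak heights) * 100.
#'
#' @param classified output of [classify_peaks()].
#' @param sample_id,target_id labels carried into the result.
#' @return an object of class `ce_result`: height sums, the raw frequency and
#'   its one-decimal rendering, and the mutant net-indel set.
#' @export
mutation_frequency <- function(classified, sample_id = NA_character_,
                               target_id = NA_character_) {
  stopifnot(nrow(classified) >= 1L)
  wt <- sum(classified$height[classified$class == "WT"])
  mut <- sum(classified$height[classified$class == "mutant"])
  freq <- if (wt + mut > 0) 100 * mut / (wt + mut) else NA_real_
  structure(list(sample_id = sample_id, target_id = target_id,
                 wt_height_sum = wt, mutant_height_sum = mut,
                 mutation_frequency_raw = freq,
                 mutation_frequency_pct = round_half_up(freq, 1L),
                 mutant_net_indels = sort(unique(
                   classified$net_indel[classified$class == "mutant"])),
                 peaks = classified), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("ce_result %s/%s: mutation frequency %.1f%% (WT %.0f, mutant %.0f RFU)\n",
              x$sample_id, x$target_id, x$mutation_frequency_pct,
              x$wt_height_sum, x$mutant_height_sum))
  invisible(x)
}

#' Assess uniformity vs. chimerism across subsamples
#'
#' Subsamples of one line are uniform iff every pairwise mutation-frequency
#' difference is within `freq_tol` percentage points and (when required) their
#' mutant-peak net-indel sets are identical; otherwise the line is chimeric.
#'
#' @param results list of [mutation_frequency()] results (>= 2 subsamples).
#' @param freq_tol pairwise frequency tolerance in percentage points
#'   (default 5).
#' @param require_same_peaks also require identical mutant net-indel sets
#'   (default TRUE).
#' @return `"uniform"` or `"chimeric"`.
#' @export
assess_uniformity <- function(results, freq_tol = 5, require_same_peaks = TRUE) {
  if (length(results) < 2L)
    stop("insufficient evidence: need at least two subsamples", call. = FALSE)
  freqs <- vapply(results, `[[`, numeric(1), "mutation_frequency_raw")
  if (max(freqs) - min(freqs) > freq_tol) return("chimeric")
  if (require_same_peaks) {
    sets <- lapply(results, `[[`, "mutant_net_indels")
    for (i in seq_along(sets)[-1])
      if (!identical(sets[[i]], sets[[1]])) return("chimeric")
  }
  "uniform"
}
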