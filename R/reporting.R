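# Summary statistics and table-style reports: transformation/editing/
# uniformity rates, progeny recovery, greenness reductions, one-way ANOVA
# with Tukey HSD compact letter display, and TSV/JSON rendering.
#
# Percentages are exact rational arithmetic rounded half-away-from-zero at
# the printed precision (one decimal for efficiencies/reductions, integers
# for read percentages at or above 10).

#' Experiment tally
#'
#' Counts from one transformation experiment.
#'
#' @param explants bombarded explants.
#' @param transgenic transgenic (marker-positive) lines.
#' @param edited sequence-confirmed edited lines.
#' @param uniform,mosaic uniformly-edited and mosaic line counts
#'   (`uniform + mosaic == edited`).
#' @param visible_phenotype lines with a visible mutant phenotype.
#' @param id experiment label.
#' @return an object of class `experiment_tally`.
#' @export
experiment_tally <- function(explants, transgenic, edited, uniform, mosaic,
                             visible_phenotype = NA_integer_, id = "exp") {
  stopifnot(uniform + mosaic == edited, edited <= transgenic,
            transgenic <= explants)
  structure(list(id = id, explants = explants, transgenic = transgenic,
                 edited = edited, uniform = uniform, mosaic = mosaic,
                 visible_phenotype = visible_phenotype),
            class = "experiment_tally")
}

#' Transformation efficiency
#'
#' 100 * transgenic / explants per experiment; with vector inputs the mean of
#' the per-experiment efficiencies is returned. One decimal.
#'
#' @param transgenic,explants counts (vectors of equal length for
#'   multi-experiment averaging).
#' @return percentage at one decimal.
#' @export
transformation_efficiency <- function(transgenic, explants) {
  stopifnot(length(transgenic) == length(explants), all(explants > 0))
  round_half_up(mean(100 * transgenic / explants), 1L)
}

#' Editing efficiency
#'
#' 100 * edited / transgenic, integer rendering.
#' @param edited,transgenic counts.
#' @return integer percentage.
#' @export
editing_efficiency <- function(edited, transgenic) {
  stopifnot(transgenic > 0)
  round_half_up(100 * edited / transgenic, 0L)
}

#' Uniform / mosaic rates among edited lines
#'
#' @param uniform,mosaic counts.
#' @return named numeric vector `c(uniform_pct, mosaic_pct)` at one decimal.
#' @export
uniformity_rates <- function(uniform, mosaic) {
  edited <- uniform + mosaic
  stopifnot(edited > 0)
  c(uniform_pct = round_half_up(100 * uniform / edited, 1L),
    mosaic_pct = round_half_up(100 * mosaic / edited, 1L))
}

#' Recovery rate of uniform progeny
#'
#' @param uniform_progeny,germinated counts.
#' @return percentage at one decimal.
#' @export
progeny_recovery_rate <- function(uniform_progeny, germinated) {
  stopifnot(germinated > 0)
  round_half_up(100 * uniform_progeny / germinated, 1L)
}

#' Percent reduction relative to a reference mean
#'
#' 100 * (reference - line) / reference; negative values indicate an increase.
#' @param reference_mean,line_mean group means (reference > 0).
#' @return percentage at one decimal.
#' @export
percent_reduction <- function(reference_mean, line_mean) {
  stopifnot(reference_mean > 0)
  round_half_up(100 * (reference_mean - line_mean) / reference_mean, 1L)
}

#' Printed-precision percentage of a count
#'
#' Renders `100 * count / total` at the table convention used throughout the
#' reports: one decimal below 10 percent, integer at or above 10 percent
#' (half-away-from-zero rounding).
#'
#' @param count,total counts (`total > 0`).
#' @return numeric percentage at printed precision.
#' @export
printed_pct <- function(count, total) {
  stopifnot(all(total > 0))
  fmt_pct_value(100 * count / total)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Balanced one-way ANOVA decomposition with the equal-n Tukey Honest
#' Significant Difference: HSD = q(1-alpha, k, df_within) * sqrt(MSE / n).
#' Groups whose mean difference is within HSD share a letter; letters are
#' maximal windows of the mean-sorted groups, so shared letters are
#' transitive-closure consistent.
#'
#' @param groups named list of equal-length numeric vectors, or a data.frame
#'   with columns `group` and `value`.
#' @param alpha significance level (default 0.05).
#' @return list: `F`, `p_value`, `df`, `MSE`, `q_crit`, `HSD`, and a `table`
#'   data.frame (group, n, mean, letters) ordered by decreasing mean.
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  stopifnot(length(groups) >= 2L)
  ns <- lengths(groups)
  if (length(unique(ns)) != 1L)
    stop("unequal group sizes: the balanced HSD variant requires equal n; use an unbalanced post hoc alternative",
         call. = FALSE)
  n <- ns[[1L]]
  stopifnot(n >= 2L)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(unlist(groups))
  ssb <- n * sum((means - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2),
                    numeric(1)))
  dfb <- k - 1L
  dfw <- k * (n - 1L)
  msb <- ssb / dfb
  mse <- ssw / dfw
  f <- if (mse == 0) { if (msb == 0) 0 else Inf } else msb / mse
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  q_crit <- stats::qtukey(1 - alpha, k, dfw)
  hsd <- q_crit * sqrt(mse / n)

  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]
  # maximal windows of consecutive sorted means with spread <= HSD
  windows <- list()
  i <- 1L
  while (i <= k) {
    j <- i
    while (j < k && ms[i] - ms[j + 1L] <= hsd) j <- j + 1L
    if (!length(windows) || windows[[length(windows)]][2L] < j)
      windows[[length(windows) + 1L]] <- c(i, j)
    if (j == k) break
    i <- i + 1L
  }
  letter_of <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(windows, function(wd)
      g >= wd[1L] && g <= wd[2L], logical(1)))], collapse = "")
  }, character(1))
  tab <- data.frame(group = names(ms), n = n, mean = unname(ms),
                    letters = letter_of, stringsAsFactors = FALSE)
  list(F = f, p_value = p, df = c(between = dfb, within = dfw), MSE = mse,
       q_crit = q_crit, HSD = hsd, table = tab)
}

#' Render table-style reports
#'
#' Produces the three report layouts as data.frames and optionally writes
#' them as TSV plus a JSON bundle: experiment tallies with efficiencies,
#' per-site indel summaries, and variant-frequency tables with `N (P)` cells.
#'
#' @param tallies list of [experiment_tally()].
#' @param site_summaries list of [summarize_site()] results.
#' @param variant_counts list of [track_variants()] results.
#' @param dir optional output directory for TSV/JSON files.
#' @return named list of data.frames, invisibly when `dir` is given.
#' @export
render_reports <- function(tallies = list(), site_summaries = list(),
                           variant_counts = list(), dir = NULL) {
  tally_df <- if (length(tallies)) do.call(rbind, lapply(tallies, function(x) {
    ur <- uniformity_rates(x$uniform, x$mosaic)
    data.frame(experiment = x$id, explants = x$explants,
               transgenic = x$transgenic,
               transformation_pct = transformation_efficiency(x$transgenic, x$explants),
               edited = x$edited,
               editing_pct = editing_efficiency(x$edited, x$transgenic),
               uniform = x$uniform, uniform_pct = ur[["uniform_pct"]],
               mosaic = x$mosaic, mosaic_pct = ur[["mosaic_pct"]],
               stringsAsFactors = FALSE)
  })) else data.frame(experiment = character(0), explants = integer(0),
                      transgenic = integer(0), transformation_pct = numeric(0),
                      edited = integer(0), editing_pct = numeric(0),
                      uniform = integer(0), uniform_pct = numeric(0),
                      mosaic = integer(0), mosaic_pct = numeric(0))

  site_df <- if (length(site_summaries)) do.call(rbind, lapply(site_summaries,
    function(s) data.frame(target = s$target_id, total_reads = s$total_reads,
                           reads_used = s$reads_used,
                           indel_reads = s$indel_reads, indel_pct = s$indel_pct,
                           frameshift_reads = s$frameshift_reads,
                           frameshift_pct = s$frameshift_pct,
                           stringsAsFactors = FALSE)))
    else data.frame(target = character(0), total_reads = integer(0),
                    reads_used = integer(0), indel_reads = integer(0),
                    indel_pct = numeric(0), frameshift_reads = integer(0),
                    frameshift_pct = numeric(0))

  variant_df <- if (length(variant_counts)) do.call(rbind, lapply(variant_counts,
    function(v) {
      cells <- fmt_count_pct(v$counts, v$reads_used)
      df <- data.frame(sample = v$sample_id, target = v$target_id,
                       total_reads = v$total_reads, reads_used = v$reads_used,
                       stringsAsFactors = FALSE)
      for (i in seq_along(cells)) df[[names(v$counts)[i]]] <- cells[i]
      df
    })) else data.frame(sample = character(0), target = character(0),
                        total_reads = integer(0), reads_used = integer(0))

  out <- list(tallies = tally_df, sites = site_df, variants = variant_df)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      utils::write.table(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out, file.path(dir, "reports.json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
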