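# Quantification module: count reads per TE subfamily under the compared
# counting modes and score estimated vs true abundance.

#' The supported counting modes
#'
#' Character vector of the five per-subfamily counting modes understood by
#' [count_te_families()], in comparison order.
#' @export
COUNT_MODES <- c("unique", "random", "fraction_hits", "fraction_families",
                 "total")

#' Count reads per TE subfamily
#'
#' Counting modes (the unit is the read for SE, the fragment for PE, with
#' mate intervals assessed jointly):
#' * `unique`: units with a single reported alignment (`NH = 1`) add 1.
#' * `random`: the primary alignment adds 1.
#' * `fraction_hits`: every reported alignment adds `1 / n_hits` when it
#'   overlaps a copy.
#' * `fraction_families`: a unit adds `1 / f` to each of the `f` distinct
#'   subfamilies its alignments overlap.
#' * `total`: every reported alignment adds 1.
#'
#' Alignments are assigned to the overlapping copy with the largest overlap
#' (ties to the leftmost copy), strand-agnostic; copies roll up to subfamily
#' by summation. For the fraction modes the input must contain all reported
#' alignments with `NH` set (a multi-mode SAM).
#'
#' @param x SAM/BAM path, SAM tibble, or observations from
#'   [load_alignments()].
#' @param copies Copy table ([merge_te_fragments()] / [read_te_bed()]).
#' @param mode One of `"unique"`, `"random"`, `"fraction_hits"`,
#'   `"fraction_families"`, `"total"`.
#' @param library_type `"SE"` or `"PE"` (ignored when `x` is already an
#'   observation table).
#' @return A `te_count_table` tibble: `subfamily`, `family`, `class`,
#'   `count`, `mode`; attributes `n_assigned` (total weight assigned) and
#'   `n_ambiguous` (units whose chosen alignment overlapped more than one
#'   copy).
#' @export
count_te_families <- function(x, copies, mode = COUNT_MODES,
                              library_type = c("SE", "PE")) {
  mode <- match.arg(mode)
  obs <- if (!is.null(attr(x, "library_type"))) x
         else load_alignments(x, match.arg(library_type))
  lt <- attr(obs, "library_type")

  if (mode %in% c("fraction_hits", "fraction_families", "total") &&
      any(is.na(obs$n_hits))) {
    abort("Fraction/total counting needs all reported alignments with NH set.")
  }

  # One interval row per alignment record; `aln` indexes the reported
  # alignment (a pair counts as one alignment with two intervals).
  if (lt == "SE") {
    ivals <- obs %>%
      mutate(aln = row_number()) %>%
      select("read_id", "aln", "chrom", "start", "width", "is_primary",
             "n_hits") %>%
      mutate(end = .data$start + .data$width)
  } else {
    obs2 <- mutate(obs, aln = row_number())
    ivals <- bind_rows(
      select(obs2, "read_id", "aln", "chrom", start = "r1_start",
             width = "r1_width", "is_primary", "n_hits"),
      select(obs2, "read_id", "aln", "chrom", start = "r2_start",
             width = "r2_width", "is_primary", "n_hits")
    ) %>% mutate(end = .data$start + .data$width)
  }

  asg <- assign_to_copies(
    mutate(ivals, unit = paste0(.data$read_id, "\r", .data$aln)) %>%
      select("unit", "chrom", "start", "end"),
    copies
  ) %>%
    tidyr::separate_wider_delim("unit", "\r", names = c("read_id", "aln")) %>%
    mutate(aln = as.integer(.data$aln))

  meta <- ivals %>% distinct(.data$read_id, .data$aln, .data$is_primary,
                             .data$n_hits)
  asg <- inner_join(asg, meta, by = c("read_id", "aln"))

  weights <- switch(
    mode,
    unique = asg %>% filter(.data$n_hits == 1L) %>% mutate(wt = 1),
    random = asg %>% filter(.data$is_primary) %>% mutate(wt = 1),
    total = mutate(asg, wt = 1),
    fraction_hits = mutate(asg, wt = 1 / .data$n_hits),
    fraction_families = asg %>%
      distinct(.data$read_id, .data$subfamily, .keep_all = TRUE) %>%
      group_by(.data$read_id) %>%
      mutate(wt = 1 / n()) %>%
      ungroup()
  )

  counts <- copies %>%
    distinct(.data$subfamily, .data$family, .data$class) %>%
    left_join(
      weights %>% group_by(.data$subfamily) %>%
        summarise(count = sum(.data$wt), .groups = "drop"),
      by = "subfamily"
    ) %>%
    mutate(count = dplyr::coalesce(.data$count, 0), mode = mode) %>%
    arrange(.data$subfamily)

  attr(counts, "n_assigned") <- sum(weights$wt)
  attr(counts, "n_ambiguous") <- sum(asg$n_candidates > 1)
  class(counts) <- c("te_count_table", class(counts))
  counts
}

#' True per-subfamily abundance from the simulation truth
#'
#' Counts simulated fragments per originating subfamily; fragments without a
#' TE assignment (genome-wide libraries) are excluded.
#'
#' @param truth Annotated truth tibble from [filter_te_reads()].
#' @return A `te_count_table` tibble with `mode = "truth"`.
#' @export
true_abundance <- function(truth) {
  if (!"subfamily" %in% names(truth)) {
    abort("`truth` lacks a subfamily column; run filter_te_reads() first.")
  }
  counts <- truth %>%
    filter(!is.na(.data$subfamily)) %>%
    group_by(.data$subfamily, .data$family, .data$class) %>%
    summarise(count = as.numeric(n()), .groups = "drop") %>%
    mutate(mode = "truth") %>%
    arrange(.data$subfamily)
  attr(counts, "n_assigned") <- sum(counts$count)
  class(counts) <- c("te_count_table", class(counts))
  counts
}

#' Compare estimated with true abundance
#'
#' Computes the squared Pearson correlation (R^2) of estimated vs true
#' per-subfamily counts (optionally on the `log10(x + 1)` scale) and a
#' per-subfamily estimate/truth ratio table. At least three subfamilies must
#' be in common.
#'
#' @param estimate A count table from [count_te_families()].
#' @param truth A count table from [true_abundance()].
#' @param log10_scale Correlate on `log10(x + 1)` instead of raw counts.
#' @return A `te_abundance_comparison` object; see [tidy()] for the ratio
#'   table and [glance()] for `r_squared`, `n`, `mode`.
#' @export
compare_abundance <- function(estimate, truth, log10_scale = FALSE) {
  joined <- inner_join(
    select(as_tibble(estimate), "subfamily", estimated = "count"),
    select(as_tibble(truth), "subfamily", "family", "class",
           true = "count"),
    by = "subfamily"
  )
  if (nrow(joined) < 3) {
    abort(sprintf("Only %d subfamilies in common; need at least 3.",
                  nrow(joined)))
  }
  xs <- if (log10_scale) log10(joined$estimated + 1) else joined$estimated
  ys <- if (log10_scale) log10(joined$true + 1) else joined$true
  r2 <- suppressWarnings(cor(xs, ys))^2
  tab <- joined %>%
    mutate(ratio = ifelse(.data$true == 0, NA_real_,
                          .data$estimated / .data$true),
           zero_truth = .data$true == 0) %>%
    arrange(.data$subfamily)
  structure(list(r_squared = r2, n = nrow(tab),
                 mode = attr(estimate, "mode") %||%
                   unique(as_tibble(estimate)$mode)[1],
                 log10_scale = log10_scale, table = tab),
            class = "te_abundance_comparison")
}

#' @export
print.te_abundance_comparison <- function(x, ...) {
  cat(sprintf("<te_abundance_comparison> mode %s: R^2 = %.4f over %d subfamilies%s\n",
              x$mode, x$r_squared, x$n,
              if (x$log10_scale) " (log10 scale)" else ""))
  print(x$table, ...)
  invisible(x)
}

#' @export
tidy.te_abundance_comparison <- function(x, ...) x$table

#' @export
glance.te_abundance_comparison <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n, mode = x$mode,
         log10_scale = x$log10_scale)
}
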