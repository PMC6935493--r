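# Evaluation module: compare alignments against simulation truth — mapping
# percentage and hit-weighted true-positive rate, library-wide and per family.

#' Load alignments into per-unit observations
#'
#' Accepts a SAM/BAM path or a SAM record tibble from [micromap()].
#' Supplementary and unmapped records are dropped; the number of reported
#' hits per read comes from the `NH` tag when present, otherwise from the
#' record count. The inferred read start is the reported position minus any
#' leading soft clip, 0-based. For paired-end libraries the unit is the
#' fragment: a unit is mapped only when both mates align as a proper pair,
#' and each reported pair becomes one row.
#'
#' @param x SAM/BAM path, or SAM tibble.
#' @param library_type `"SE"` or `"PE"`.
#' @return A tibble of reported alignments. SE: `read_id`, `chrom`, `start`,
#'   `strand`, `width`, `is_primary`, `n_hits`. PE: `read_id`, `chrom`,
#'   `r1_start`, `r1_strand`, `r2_start`, `r2_strand`, `r1_width`,
#'   `r2_width`, `is_primary`, `n_hits`. Unmapped units are absent. The
#'   `library_type` is carried as an attribute.
#' @export
load_alignments <- function(x, library_type = c("SE", "PE")) {
  library_type <- match.arg(library_type)
  rec <- if (is.character(x) && length(x) == 1) read_sam_records(x)
         else sam_tibble_records(x)
  rec <- rec %>%
    filter(bitwAnd(.data$flag, 2048L) == 0L, bitwAnd(.data$flag, 4L) == 0L) %>%
    mutate(
      clip = dplyr::coalesce(
        suppressWarnings(as.integer(stringr::str_match(.data$cigar, "^(\\d+)S")[, 2])), 0L),
      start = .data$pos - 1L - .data$clip,
      width = cigar_ref_width(.data$cigar),
      strand = ifelse(bitwAnd(.data$flag, 16L) > 0L, "-", "+"),
      is_primary = bitwAnd(.data$flag, 256L) == 0L
    )

  if (library_type == "SE") {
    out <- rec %>%
      group_by(.data$qname) %>%
      mutate(n_hits = dplyr::coalesce(first(.data$nh), n())) %>%
      ungroup() %>%
      select(read_id = "qname", "chrom", "start", "strand", "width",
             "is_primary", "n_hits")
  } else {
    proper <- filter(rec, bitwAnd(.data$flag, 2L) > 0L)
    r1 <- filter(proper, bitwAnd(.data$flag, 64L) > 0L)
    r2 <- filter(proper, bitwAnd(.data$flag, 128L) > 0L)
    out <- inner_join(
      select(r1, read_id = "qname", "chrom", r1_pos = "pos",
             r1_start = "start", r1_strand = "strand", r1_width = "width",
             r1_mpos = "mpos", "is_primary", "nh"),
      select(r2, read_id = "qname", chrom2 = "chrom", r2_pos = "pos",
             r2_start = "start", r2_strand = "strand", r2_width = "width",
             r2_mpos = "mpos"),
      by = c("read_id", r1_pos = "r2_mpos", r1_mpos = "r2_pos"),
      relationship = "many-to-many"
    ) %>%
      filter(.data$chrom == .data$chrom2, .data$r1_strand != .data$r2_strand) %>%
      distinct(.data$read_id, .data$r1_start, .data$r2_start, .data$r1_strand,
               .keep_all = TRUE) %>%
      group_by(.data$read_id) %>%
      mutate(n_hits = dplyr::coalesce(first(.data$nh), n())) %>%
      ungroup() %>%
      select("read_id", "chrom", "r1_start", "r1_strand", "r1_width",
             "r2_start", "r2_strand", "r2_width", "is_primary", "n_hits")
  }
  attr(out, "library_type") <- library_type
  out
}

# Read records from a SAM or BAM file via Rsamtools.
read_sam_records <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "mpos"), tag = "NH")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  tibble(
    qname = b$qname, flag = b$flag, chrom = as.character(b$rname),
    pos = b$pos, cigar = b$cigar, mpos = b$mpos, nh = b$tag$NH
  )
}

sam_tibble_records <- function(sam) {
  sam <- as_tibble(sam)
  tibble(
    qname = sam$qname, flag = sam$flag, chrom = sam$rname, pos = sam$pos,
    cigar = sam$cigar, mpos = sam$pnext,
    nh = suppressWarnings(as.integer(stringr::str_match(sam$tags, "NH:i:(\\d+)")[, 2]))
  )
}

# Reference-space width of simple CIGARs (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    m <- stringr::str_match_all(cg, "(\\d+)([MIDNSHP=X])")[[1]]
    sum(as.integer(m[, 2])[m[, 3] %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Is a reported alignment congruent with the simulated origin?
#'
#' Congruent means: same chromosome, same strand as the simulated mate, and
#' reported (soft-clip corrected) start within `tol` bp of the true mate
#' start.
#'
#' @param chrom,start,strand Reported alignment (vectorized).
#' @param true_chrom,true_start,true_strand Simulated origin (vectorized).
#' @param tol Position tolerance in bp (default 5).
#' @return Logical vector.
#' @export
is_congruent <- function(chrom, start, strand, true_chrom, true_start,
                         true_strand, tol = 5) {
  chrom == true_chrom & strand == true_strand &
    abs(start - true_start) <= tol
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Per-unit mapped flag and TP weight w = min(1, congruent / n_hits).
unit_scores <- function(obs, truth, tol = 5, max_hits = 10000) {
  lt <- attr(obs, "library_type") %||% "SE"
  unknown <- setdiff(unique(obs$read_id), truth$read_id)
  if (length(unknown) > 0) {
    abort(sprintf("Alignment read ids absent from truth (first: %s); inputs do not match.",
                  unknown[1]))
  }
  if (lt == "SE") {
    joined <- obs %>%
      inner_join(select(truth, "read_id", t_chrom = "chrom",
                        t_start = "r1_start", t_strand = "strand"),
                 by = "read_id") %>%
      mutate(congruent = is_congruent(.data$chrom, .data$start, .data$strand,
                                      .data$t_chrom, .data$t_start,
                                      .data$t_strand, tol))
  } else {
    joined <- obs %>%
      inner_join(select(truth, "read_id", t_chrom = "chrom",
                        t_r1 = "r1_start", t_r2 = "r2_start",
                        t_strand = "strand"),
                 by = "read_id") %>%
      mutate(congruent =
               is_congruent(.data$chrom, .data$r1_start, .data$r1_strand,
                            .data$t_chrom, .data$t_r1, .data$t_strand, tol) &
               is_congruent(.data$chrom, .data$r2_start, .data$r2_strand,
                            .data$t_chrom, .data$t_r2,
                            flip_strand(.data$t_strand), tol))
  }
  joined %>%
    group_by(.data$read_id) %>%
    summarise(n_hits = first(.data$n_hits), c = sum(.data$congruent),
              .groups = "drop") %>%
    mutate(w = ifelse(.data$n_hits > max_hits, 0,
                      pmin(1, .data$c / .data$n_hits)))
}

#' Library-level mapping percentage and true-positive rate
#'
#' `mapping_pct` is the percentage of simulated units (reads, or fragments
#' for PE) with a reported alignment (a proper pair for PE). `tp_rate` is the
#' hit-weighted true-positive rate over mapped units: each unit contributes
#' `w = min(1, congruent_alignments / n_hits)`, which penalizes reporting
#' many wrong positions. Units reporting more than `max_hits` positions count
#' as mapped with `w = 0`.
#'
#' @param obs Observations from [load_alignments()].
#' @param truth Truth tibble from [simulate_fragments()] (optionally
#'   filtered/annotated by [filter_te_reads()]).
#' @param tol Congruence tolerance in bp (default 5).
#' @param max_hits Reported-position ceiling (default 10000).
#' @return A one-row tibble: `scope`, `n_units`, `n_mapped`, `mapping_pct`,
#'   `tp_rate`.
#' @export
library_metrics <- function(obs, truth, tol = 5, max_hits = 10000) {
  if (nrow(truth) == 0) abort("Empty truth table.")
  sc <- unit_scores(obs, truth, tol, max_hits)
  tibble(
    scope = "library",
    n_units = nrow(truth),
    n_mapped = nrow(sc),
    mapping_pct = 100 * nrow(sc) / nrow(truth),
    tp_rate = if (nrow(sc) == 0) NA_real_ else 100 * mean(sc$w)
  )
}

#' Per-subfamily mapping percentage and true-positive rate
#'
#' Partitions simulated units by originating subfamily (the `subfamily`
#' column added by [filter_te_reads()]) and computes [library_metrics()]
#' within each partition. Subfamilies with fewer than `min_reads` simulated
#' units are flagged low-confidence.
#'
#' @inheritParams library_metrics
#' @param min_reads Minimum simulated units per subfamily (default 50).
#' @return A tibble sorted by subfamily: `scope` (subfamily), `n_units`,
#'   `n_mapped`, `mapping_pct`, `tp_rate`, `low_confidence`.
#' @export
family_metrics <- function(obs, truth, tol = 5, max_hits = 10000,
                           min_reads = 50) {
  if (!"subfamily" %in% names(truth)) {
    abort("`truth` lacks a subfamily column; run filter_te_reads() first.")
  }
  truth <- filter(truth, !is.na(.data$subfamily))
  sc <- unit_scores(obs, truth, tol, max_hits) %>%
    left_join(select(truth, "read_id", "subfamily"), by = "read_id")
  truth %>%
    group_by(scope = .data$subfamily) %>%
    summarise(n_units = n(), .groups = "drop") %>%
    left_join(
      sc %>% group_by(scope = .data$subfamily) %>%
        summarise(n_mapped = n(), w_sum = sum(.data$w), .groups = "drop"),
      by = "scope"
    ) %>%
    mutate(
      n_mapped = dplyr::coalesce(.data$n_mapped, 0L),
      mapping_pct = 100 * .data$n_mapped / .data$n_units,
      tp_rate = ifelse(.data$n_mapped == 0, NA_real_,
                       100 * .data$w_sum / .data$n_mapped),
      low_confidence = .data$n_units < min_reads
    ) %>%
    select(-"w_sum") %>%
    arrange(.data$scope)
}

#' Paired-end versus single-end gain
#'
#' Simple differences (PE minus SE) in mapping percentage and TP rate per
#' scope (library or subfamily). Both evaluations must derive from the same
#' simulated fragments. A scope present on one side only is reported with
#' the missing side marked in `status`.
#'
#' @param eval_pe,eval_se Metric tables from [library_metrics()] or
#'   [family_metrics()].
#' @return A tibble: `scope`, `mapping_pct_pe`, `mapping_pct_se`,
#'   `gain_mapping_pct`, `tp_rate_pe`, `tp_rate_se`, `gain_tp_rate`,
#'   `status`.
#' @export
pe_se_gain <- function(eval_pe, eval_se) {
  full_join(
    select(eval_pe, "scope", mapping_pct_pe = "mapping_pct",
           tp_rate_pe = "tp_rate"),
    select(eval_se, "scope", mapping_pct_se = "mapping_pct",
           tp_rate_se = "tp_rate"),
    by = "scope"
  ) %>%
    mutate(
      gain_mapping_pct = .data$mapping_pct_pe - .data$mapping_pct_se,
      gain_tp_rate = .data$tp_rate_pe - .data$tp_rate_se,
      status = case_when(
        is.na(.data$mapping_pct_pe) ~ "absent_in_pe",
        is.na(.data$mapping_pct_se) ~ "absent_in_se",
        TRUE ~ "ok"
      )
    ) %>%
    select("scope", "mapping_pct_pe", "mapping_pct_se", "gain_mapping_pct",
           "tp_rate_pe", "tp_rate_se", "gain_tp_rate", "status") %>%
    arrange(.data$scope)
}

#' Join per-family metrics with family metadata and rank-correlate
#'
#' Inner-joins a numeric per-subfamily attribute (for example family age)
#' onto a [family_metrics()] table and reports the Spearman rank correlation
#' between mapping percentage and the attribute.
#'
#' @param family_tbl Output of [family_metrics()].
#' @param metadata Tibble with `subfamily` plus one numeric column, or a path
#'   to such a TSV.
#' @param attribute Name of the metadata column to correlate (default: the
#'   first non-key column).
#' @return A `te_metadata_assoc` object: `$data` (joined tibble), `$rho`
#'   (Spearman correlation of `mapping_pct` with the attribute, `NA` when
#'   degenerate), `$n` (families joined), `$attribute`.
#' @export
join_metadata <- function(family_tbl, metadata, attribute = NULL) {
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- readr::read_tsv(metadata, col_types = readr::cols())
  }
  metadata <- as_tibble(metadata)
  if (!"subfamily" %in% names(metadata)) names(metadata)[1] <- "subfamily"
  attribute <- attribute %||% setdiff(names(metadata), "subfamily")[1]
  joined <- inner_join(family_tbl, metadata,
                       by = c(scope = "subfamily"))
  if (nrow(joined) == 0) {
    abort(paste0(
      "No subfamily names in common. Metrics: ",
      paste(head(family_tbl$scope, 5), collapse = ", "),
      " ... metadata: ",
      paste(head(metadata$subfamily, 5), collapse = ", ")))
  }
  a <- joined[[attribute]]
  rho <- if (length(unique(a)) < 2 || length(unique(joined$mapping_pct)) < 2) {
    NA_real_
  } else {
    suppressWarnings(cor(joined$mapping_pct, a, method = "spearman"))
  }
  structure(list(data = joined, rho = rho, n = nrow(joined),
                 attribute = attribute),
            class = "te_metadata_assoc")
}

#' @export
print.te_metadata_assoc <- function(x, ...) {
  cat(sprintf("<te_metadata_assoc> %d families; Spearman rho(mapping_pct, %s) = %s\n",
              x$n, x$attribute,
              if (is.na(x$rho)) "undefined" else format(round(x$rho, 3))))
  invisible(x)
}

#' @export
tidy.te_metadata_assoc <- function(x, ...) x$data

#' @export
glance.te_metadata_assoc <- function(x, ...) {
  tibble(rho = x$rho, n = x$n, attribute = x$attribute)
}
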