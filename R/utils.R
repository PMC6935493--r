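# Shared internal helpers.

#' Load a genome as a DNAStringSet
#'
#' Accepts a FASTA path or an existing [Biostrings::DNAStringSet]. Names are
#' truncated at the first whitespace, matching common aligner behaviour.
#' @param x FASTA file path or `DNAStringSet`.
#' @return A named `DNAStringSet`.
#' @keywords internal
load_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    g <- x
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    g <- Biostrings::readDNAStringSet(x)
  } else {
    abort("`genome` must be a DNAStringSet or a path to a FASTA file.")
  }
  if (is.null(names(g)) || anyNA(names(g))) {
    abort("Genome sequences must be named.")
  }
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Run `code` with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. With seed = NULL the global stream is used as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed fan-out from one global seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Reverse complement for plain character vectors.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert a TE copy table to GRanges
#' @param copies A copy table from [merge_te_fragments()] or [read_te_bed()].
#' @return A `GRanges` with `copy_id`, `subfamily`, `family`, `class` metadata.
#' @keywords internal
copies_to_granges <- function(copies) {
  GenomicRanges::GRanges(
    seqnames = copies$chrom,
    ranges = IRanges::IRanges(start = copies$start + 1L, end = copies$end),
    strand = copies$strand,
    copy_id = copies$copy_id,
    subfamily = copies$subfamily,
    family = copies$family,
    class = copies$class
  )
}

# Largest-overlap assignment of query intervals (0-based half-open tibble with
# columns chrom, start, end, and a `unit` key) to TE copies. Several rows may
# share a unit (PE mates, multiple alignments): overlaps are summed per
# (unit, copy). Ties break to the leftmost copy (smallest start, then copy_id).
# Returns one row per unit that overlaps anything: unit, copy_id, subfamily,
# family, class, overlap, n_candidates.
assign_to_copies <- function(query, copies) {
  if (nrow(query) == 0) {
    return(tibble(
      unit = character(), copy_id = character(), subfamily = character(),
      family = character(), class = character(), overlap = integer(),
      n_candidates = integer()
    ))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = query$chrom,
    ranges = IRanges::IRanges(start = query$start + 1L, end = query$end)
  )
  cg <- copies_to_granges(copies)
  ov <- GenomicRanges::findOverlaps(gr, cg, ignore.strand = TRUE)
  if (length(ov) == 0) {
    return(tibble(
      unit = character(), copy_id = character(), subfamily = character(),
      family = character(), class = character(), overlap = integer(),
      n_candidates = integer()
    ))
  }
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[qh], IRanges::ranges(cg)[sh]
  ))
  tibble(
    unit = query$unit[qh],
    copy_id = copies$copy_id[sh],
    copy_start = copies$start[sh],
    subfamily = copies$subfamily[sh],
    family = copies$family[sh],
    class = copies$class[sh],
    overlap = as.integer(w)
  ) %>%
    group_by(.data$unit, .data$copy_id, .data$copy_start, .data$subfamily,
             .data$family, .data$class) %>%
    summarise(overlap = sum(.data$overlap), .groups = "drop") %>%
    group_by(.data$unit) %>%
    mutate(n_candidates = n()) %>%
    arrange(dplyr::desc(.data$overlap), .data$copy_start, .data$copy_id,
            .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select("unit", "copy_id", "subfamily", "family", "class", "overlap",
           "n_candidates")
}

# Phred+33 quality string for a vector of per-base error probabilities.
phred33_string <- function(e, max_q = 40L) {
  q <- ifelse(e <= 0, max_q, pmin(max_q, pmax(2L, round(-10 * log10(e)))))
  intToUtf8(as.integer(q) + 33L)
}
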