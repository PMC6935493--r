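# Micro-aligner module: brute-force exact alignment for small genomes with
# unique / random / multi reporting modes, emitting SAM.

MICROALIGNER_GENOME_GUARD <- 1e6

#' Exhaustively find all alignment candidates for a set of reads
#'
#' Scans every position of every chromosome on both strands and keeps
#' positions with at most `max_mm` substitutions (mismatch-only scoring, no
#' gaps; `N` never matches). Guarded to genomes of 1 Mb or less.
#'
#' @param reads Tibble with `read_id`, `seq` (or a named character vector).
#' @param genome FASTA path or `DNAStringSet`.
#' @param max_mm Maximum substitutions per alignment (0-5).
#' @return A tibble `read_id`, `chrom`, `start` (0-based), `strand`, `mm`,
#'   sorted by (read order, chrom, start, strand). Reads without candidates
#'   are absent.
#' @export
micro_align <- function(reads, genome, max_mm = 3) {
  stopifnot(max_mm >= 0, max_mm <= 5)
  reads <- as_read_tibble(reads)
  genome <- load_genome(genome)
  if (sum(Biostrings::width(genome)) > MICROALIGNER_GENOME_GUARD) {
    abort("The brute-force micro-aligner is guarded to genomes of 1 Mb or less.")
  }
  hits <- cpp_scan_reads(toupper(reads$seq), as.character(genome),
                         as.integer(max_mm))
  tibble(
    read_id = reads$read_id[hits$read],
    chrom = names(genome)[hits$chrom],
    start = hits$start,
    strand = ifelse(hits$strand_minus == 1L, "-", "+"),
    mm = hits$mm,
    read_order = hits$read
  ) %>%
    arrange(.data$read_order, .data$chrom, .data$start, .data$strand) %>%
    select(-"read_order")
}

as_read_tibble <- function(reads) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    return(read_fastq(reads))
  }
  if (is.character(reads)) {
    if (is.null(names(reads))) abort("Character reads must be named by read id.")
    return(tibble(read_id = names(reads), seq = unname(reads)))
  }
  reads <- as_tibble(reads)
  if (!all(c("read_id", "seq") %in% names(reads))) {
    # Allow the simulate module's paired table to pass as R1.
    if (all(c("read_id", "seq1") %in% names(reads))) {
      return(tibble(read_id = reads$read_id, seq = reads$seq1))
    }
    abort("`reads` needs columns read_id and seq.")
  }
  select(reads, "read_id", "seq")
}

sam_columns <- function() {
  tibble(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    rnext = character(), pnext = integer(), tlen = integer(),
    seq = character(), qual = character(), tags = character()
  )
}

se_unmapped_rows <- function(reads, qual) {
  tibble(
    qname = reads$read_id, flag = 4L, rname = "*", pos = 0L, mapq = 0L,
    cigar = "*", rnext = "*", pnext = 0L, tlen = 0L, seq = reads$seq,
    qual = qual %||% "*", tags = ""
  )
}

#' Build single-end SAM records from a candidate table
#'
#' Only minimal-mismatch ("best") candidates are reported. `unique` mode maps
#' a read only when it has exactly one best candidate; `random` reports one
#' best candidate chosen uniformly (seeded); `multi` reports every best
#' candidate with an `NH` tag, the randomly chosen one primary and the rest
#' flagged secondary.
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param hits Candidate table from [micro_align()].
#' @param mode `"unique"`, `"random"` or `"multi"`.
#' @param seed Seed for the random candidate choice.
#' @param qual Optional per-cycle quality string applied to all reads.
#' @return A SAM record tibble (see [write_sam()]).
#' @export
sam_from_hits_se <- function(reads, hits, mode = c("unique", "random", "multi"),
                             seed = 1, qual = NULL) {
  mode <- match.arg(mode)
  reads <- as_read_tibble(reads)
  best <- hits %>%
    group_by(.data$read_id) %>%
    filter(.data$mm == min(.data$mm, Inf)) %>% # Inf: no warning on empty input
    mutate(n_best = n()) %>%
    ungroup()

  if (mode == "unique") {
    chosen <- best %>% filter(.data$n_best == 1L) %>% mutate(primary = TRUE)
  } else {
    chosen <- with_seed(seed, {
      picked <- best %>%
        group_by(.data$read_id) %>%
        mutate(primary = row_number() == sample.int(n(), 1)) %>%
        ungroup()
      if (mode == "random") filter(picked, .data$primary) else picked
    })
  }
  mapped_ids <- unique(chosen$read_id)
  rows <- chosen %>%
    left_join(reads, by = "read_id") %>%
    mutate(
      minus = .data$strand == "-",
      out_seq = ifelse(.data$minus, revcomp_chr(.data$seq), .data$seq),
      out_qual = sam_qual(qual, .data$minus),
      flag = ifelse(.data$minus, 16L, 0L) +
        ifelse(.data$primary, 0L, 256L),
      mapq = if (mode == "unique") 60L else 255L,
      nh = if (mode == "unique") 1L else .data$n_best
    )
  nh_out <- if (mode == "random") 1L else rows$nh
  sam <- tibble(
    qname = rows$read_id, flag = rows$flag, rname = rows$chrom,
    pos = rows$start + 1L, mapq = rows$mapq,
    cigar = paste0(nchar(rows$seq), "M"), rnext = "*", pnext = 0L,
    tlen = 0L, seq = as.character(rows$out_seq),
    qual = as.character(rows$out_qual),
    tags = paste0("NH:i:", nh_out)
  )
  un <- se_unmapped_rows(filter(reads, !.data$read_id %in% mapped_ids), qual)
  bind_rows(sam, un) %>%
    arrange(match(.data$qname, reads$read_id), .data$flag)
}

sam_qual <- function(qual, minus) {
  if (is.null(qual)) return(rep("*", length(minus)))
  rev_q <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
  ifelse(minus, rev_q, qual)
}

#' Build paired-end SAM records from two candidate tables
#'
#' A valid pair joins one candidate per mate on the same chromosome, opposite
#' strands in forward-reverse orientation, with an inferred fragment length
#' inside `[frag_min, frag_max]`. Pair score is the summed mismatch count and
#' only minimal-score pairs are reported; `unique` mode maps the pair only
#' when exactly one best pair exists (a mate that multi-maps alone can be
#' rescued by its uniquely pairing partner). `NH` is the number of best
#' pairs.
#'
#' @param reads1,reads2 Mate read tibbles (`read_id`, `seq`), same ids.
#' @param hits1,hits2 Candidate tables from [micro_align()] (same `max_mm`).
#' @param mode `"unique"`, `"random"` or `"multi"`.
#' @param frag_min,frag_max Allowed inferred fragment length range (bp,
#'   inclusive).
#' @param seed Seed for the random pair choice.
#' @param qual Optional per-cycle quality string.
#' @return A SAM record tibble (see [write_sam()]).
#' @export
sam_from_hits_pe <- function(reads1, reads2, hits1, hits2,
                             mode = c("unique", "random", "multi"),
                             frag_min = 100, frag_max = 500, seed = 1,
                             qual = NULL) {
  mode <- match.arg(mode)
  reads1 <- as_read_tibble(reads1)
  reads2 <- as_read_tibble(reads2)
  len1 <- setNames(nchar(reads1$seq), reads1$read_id)
  len2 <- setNames(nchar(reads2$seq), reads2$read_id)

  pairs <- inner_join(
    rename(hits1, start1 = "start", strand1 = "strand", mm1 = "mm"),
    rename(hits2, start2 = "start", strand2 = "strand", mm2 = "mm"),
    by = c("read_id", "chrom"), relationship = "many-to-many"
  ) %>%
    mutate(
      end1 = .data$start1 + len1[.data$read_id],
      end2 = .data$start2 + len2[.data$read_id],
      plus_start = ifelse(.data$strand1 == "+", .data$start1, .data$start2),
      minus_end = ifelse(.data$strand1 == "+", .data$end2, .data$end1),
      flen = .data$minus_end - .data$plus_start
    ) %>%
    filter(
      .data$strand1 != .data$strand2,
      .data$plus_start <= ifelse(.data$strand1 == "+", .data$start2, .data$start1),
      .data$flen >= frag_min, .data$flen <= frag_max
    ) %>%
    mutate(score = .data$mm1 + .data$mm2) %>%
    group_by(.data$read_id) %>%
    filter(.data$score == min(.data$score, Inf)) %>% # Inf: no warning on empty input
    mutate(n_best = n()) %>%
    ungroup() %>%
    arrange(match(.data$read_id, reads1$read_id), .data$chrom, .data$start1,
            .data$start2, .data$strand1)

  if (mode == "unique") {
    chosen <- pairs %>% filter(.data$n_best == 1L) %>% mutate(primary = TRUE)
  } else {
    chosen <- with_seed(seed, {
      picked <- pairs %>%
        group_by(.data$read_id) %>%
        mutate(primary = row_number() == sample.int(n(), 1)) %>%
        ungroup()
      if (mode == "random") filter(picked, .data$primary) else picked
    })
  }
  mapq <- if (mode == "unique") 60L else 255L
  nh <- if (mode %in% c("unique", "random")) 1L else chosen$n_best

  mk_mate <- function(first) {
    st <- if (first) chosen$strand1 else chosen$strand2
    ot <- if (first) chosen$strand2 else chosen$strand1
    ps <- if (first) chosen$start1 else chosen$start2
    pn <- if (first) chosen$start2 else chosen$start1
    rd <- if (first) reads1 else reads2
    seqs <- setNames(rd$seq, rd$read_id)[chosen$read_id]
    minus <- st == "-"
    tibble(
      qname = chosen$read_id,
      flag = 1L + 2L + ifelse(minus, 16L, 0L) + ifelse(ot == "-", 32L, 0L) +
        ifelse(first, 64L, 128L) + ifelse(chosen$primary, 0L, 256L),
      rname = chosen$chrom, pos = ps + 1L, mapq = mapq,
      cigar = paste0(nchar(seqs), "M"), rnext = "=", pnext = pn + 1L,
      tlen = ifelse(minus, -chosen$flen, chosen$flen),
      seq = as.character(ifelse(minus, revcomp_chr(seqs), seqs)),
      qual = as.character(sam_qual(qual, minus)),
      tags = paste0("NH:i:", nh)
    )
  }
  sam <- bind_rows(mk_mate(TRUE), mk_mate(FALSE))

  un_ids <- setdiff(reads1$read_id, chosen$read_id)
  un <- bind_rows(
    mutate(se_unmapped_rows(filter(reads1, .data$read_id %in% un_ids), qual),
           flag = 1L + 4L + 8L + 64L),
    mutate(se_unmapped_rows(filter(reads2, .data$read_id %in% un_ids), qual),
           flag = 1L + 4L + 8L + 128L)
  )
  bind_rows(sam, un) %>%
    arrange(match(.data$qname, reads1$read_id), .data$pos, .data$flag)
}

#' Align reads with the brute-force micro-aligner
#'
#' One-call wrapper: finds all candidates with [micro_align()] and reports
#' them in the requested mode ([sam_from_hits_se()] / [sam_from_hits_pe()]).
#'
#' @param r1 R1 reads: FASTQ path or tibble (`read_id`, `seq`).
#' @param genome FASTA path or `DNAStringSet`.
#' @param r2 Optional R2 reads for paired-end alignment.
#' @param mode `"unique"`, `"random"` or `"multi"`.
#' @param max_mm Maximum substitutions per alignment.
#' @param frag_min,frag_max Paired-end fragment length window (bp).
#' @param seed Seed for random reporting choices.
#' @param qual Optional per-cycle quality string for the SAM records.
#' @param out Optional path; when given the SAM file is written there.
#' @return The SAM record tibble, invisibly when `out` is given.
#' @export
micromap <- function(r1, genome, r2 = NULL,
                     mode = c("unique", "random", "multi"), max_mm = 3,
                     frag_min = 100, frag_max = 500, seed = 1, qual = NULL,
                     out = NULL) {
  mode <- match.arg(mode)
  genome <- load_genome(genome)
  r1 <- as_read_tibble(r1)
  if (is.null(r2)) {
    hits <- micro_align(r1, genome, max_mm)
    sam <- sam_from_hits_se(r1, hits, mode, seed = seed, qual = qual)
  } else {
    r2 <- as_read_tibble(r2)
    h1 <- micro_align(r1, genome, max_mm)
    h2 <- micro_align(r2, genome, max_mm)
    sam <- sam_from_hits_pe(r1, r2, h1, h2, mode, frag_min = frag_min,
                            frag_max = frag_max, seed = seed, qual = qual)
  }
  if (!is.null(out)) {
    write_sam(sam, genome, out)
    return(invisible(sam))
  }
  sam
}

#' Write SAM records to file
#'
#' Emits a conformant header (`@HD`, one `@SQ` per genome sequence, `@PG`)
#' followed by the records.
#'
#' @param sam SAM record tibble from the micro-aligner.
#' @param genome The genome the records refer to (for `@SQ` lines).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, genome, path) {
  genome <- load_genome(genome)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)),
    "@PG\tID:temark\tPN:temark"
  )
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
                  sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq, sam$cigar,
                  sam$rnext, sam$pnext, sam$tlen, sam$seq, sam$qual,
                  ifelse(nzchar(sam$tags), paste0("\t", sam$tags), ""))
  readr::write_lines(c(header, body), path)
  invisible(path)
}
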