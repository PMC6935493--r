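# Simulation module: Illumina-like paired-end fragments with exact ground
# truth, TE-overlap filtering, and matched single-end libraries.

#' Simulation parameters
#'
#' @param read_len Read length in bp (default 100, i.e. 2x100 bp pairs).
#' @param frag_mean Mean fragment length (default 200 bp).
#' @param frag_sd Fragment length standard deviation (default 20 bp).
#' @param coverage Fold coverage of the genome by read bases (default 10).
#' @param e0,e1 Per-base substitution error rate at the first and last read
#'   cycle; the rate ramps linearly along the read
#'   (`e(i) = e0 + (e1 - e0) * i / (read_len - 1)`). Defaults 0.001 and 0.01.
#' @param seed Integer seed for all randomness in the simulation.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(read_len = 100, frag_mean = 200, frag_sd = 20,
                       coverage = 10, e0 = 0.001, e1 = 0.01, seed = 1) {
  stopifnot(
    read_len >= 20, frag_mean >= read_len, frag_sd >= 0, coverage > 0,
    e0 >= 0, e1 >= e0, e1 < 0.25
  )
  structure(list(read_len = as.integer(read_len),
                 frag_mean = as.integer(frag_mean), frag_sd = frag_sd,
                 coverage = coverage, e0 = e0, e1 = e1,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate paired-end fragments with ground truth
#'
#' Draws `N = ceiling(coverage * genome_len / (2 * read_len))` fragments with
#' uniform start positions and Normal lengths (rounded, clamped to
#' `[read_len, 2 * frag_mean]`), picks the R1 strand uniformly, takes R1 as
#' the first `read_len` bases of the fragment on its strand and R2 as the
#' reverse complement of the other end, and applies position-dependent
#' substitution errors with matching Phred+33 qualities. Fragments touching
#' an `N` run are resampled. Read ids are `sim:<serial>`; the origin of every
#' fragment is recorded in a sidecar truth table.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param params A [sim_params()] object.
#' @param dir Optional output directory for `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>.truth.tsv`.
#' @param prefix File prefix under `dir`.
#' @return A `sim_library` list: `reads` tibble (`read_id`, `seq1`, `seq2`),
#'   `truth` tibble (`read_id`, `chrom`, `frag_start`, `frag_end`, `strand`
#'   of R1, `r1_start`, `r2_start`; 0-based half-open), `params`, `qual`
#'   (per-cycle quality string), and `paths` when files were written.
#' @export
simulate_fragments <- function(genome, params, dir = NULL, prefix = "sim") {
  stopifnot(inherits(params, "sim_params"))
  genome <- load_genome(genome)
  glen <- sum(Biostrings::width(genome))
  if (min(Biostrings::width(genome)) < params$frag_mean + 3 * params$frag_sd) {
    abort("Genome sequence shorter than frag_mean + 3 * frag_sd; cannot simulate.")
  }
  res <- with_seed(params$seed, simulate_fragments_impl(genome, params, glen))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    r1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
    r2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
    tr <- file.path(dir, paste0(prefix, ".truth.tsv"))
    write_fastq(res$reads$read_id, res$reads$seq1, res$qual, r1)
    write_fastq(res$reads$read_id, res$reads$seq2, res$qual, r2)
    readr::write_tsv(res$truth, tr)
    res$paths <- list(r1 = r1, r2 = r2, truth = tr)
  }
  res
}

simulate_fragments_impl <- function(genome, params, glen) {
  L <- params$read_len
  n_frag <- as.integer(ceiling(params$coverage * glen / (2 * L)))
  chrom_names <- names(genome)
  widths <- Biostrings::width(genome)

  draw <- function(n) {
    flen <- as.integer(pmin(pmax(round(rnorm(n, params$frag_mean, params$frag_sd)),
                                 L), 2L * params$frag_mean))
    ci <- sample.int(length(widths), n, replace = TRUE, prob = widths)
    start <- as.integer(floor(runif(n) * (widths[ci] - flen + 1L)))
    tibble(chrom_i = ci, frag_start = start, frag_len = flen)
  }

  chrom_str <- as.character(genome)
  frags <- draw(n_frag)
  # Resample fragments overlapping N runs.
  repeat {
    frag_chr <- substr(chrom_str[frags$chrom_i], frags$frag_start + 1L,
                       frags$frag_start + frags$frag_len)
    bad <- grepl("N", frag_chr, fixed = TRUE)
    if (!any(bad)) break
    frags[bad, ] <- draw(sum(bad))
  }

  strand <- sample(c("+", "-"), n_frag, replace = TRUE)
  r1_plus <- strand == "+"
  r1_start <- ifelse(r1_plus, frags$frag_start,
                     frags$frag_start + frags$frag_len - L)
  r2_start <- ifelse(r1_plus, frags$frag_start + frags$frag_len - L,
                     frags$frag_start)

  first_part <- substr(frag_chr, 1L, L)
  last_part <- substr(frag_chr, frags$frag_len - L + 1L, frags$frag_len)
  r1_seq <- ifelse(r1_plus, first_part, revcomp_chr(last_part))
  r2_seq <- ifelse(r1_plus, revcomp_chr(last_part), first_part)

  # Position-dependent substitution errors.
  e <- params$e0 + (params$e1 - params$e0) * (seq_len(L) - 1) / (L - 1)
  r1_seq <- apply_errors(r1_seq, e)
  r2_seq <- apply_errors(r2_seq, e)

  read_id <- paste0("sim:", seq_len(n_frag))
  list(
    reads = tibble(read_id = read_id, seq1 = r1_seq, seq2 = r2_seq),
    truth = tibble(
      read_id = read_id,
      chrom = chrom_names[frags$chrom_i],
      frag_start = frags$frag_start,
      frag_end = frags$frag_start + frags$frag_len,
      strand = strand,
      r1_start = as.integer(r1_start),
      r2_start = as.integer(r2_start)
    ),
    qual = phred33_string_vec(e),
    params = params
  )
}

phred33_string_vec <- function(e) phred33_string(e)

# Vectorized substitution errors at per-cycle rates `e` (length = read length).
apply_errors <- function(seqs, e) {
  if (all(e <= 0)) return(seqs)
  n <- length(seqs)
  L <- length(e)
  m <- matrix(runif(n * L), nrow = n, byrow = TRUE) <
    matrix(e, nrow = n, ncol = L, byrow = TRUE)
  hits <- which(m, arr.ind = TRUE)
  if (nrow(hits) == 0) return(seqs)
  chars <- substring(seqs[hits[, 1]], hits[, 2], hits[, 2])
  # Shift each hit base by 1-3 positions in the ACGT alphabet.
  alph <- c("A", "C", "G", "T")
  idx <- match(chars, alph)
  new <- alph[((idx - 1 + sample.int(3, nrow(hits), replace = TRUE)) %% 4) + 1]
  for (j in seq_len(nrow(hits))) {
    substr(seqs[hits[j, 1]], hits[j, 2], hits[j, 2]) <- new[j]
  }
  seqs
}

# Phred+33 FASTQ writer; one constant quality string for all reads.
write_fastq <- function(ids, seqs, qual, path) {
  dna <- Biostrings::DNAStringSet(setNames(seqs, ids))
  q <- Biostrings::BStringSet(rep(qual, length(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file.
#' @return A tibble `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)))
}

#' Keep simulated fragments that overlap TE copies
#'
#' A pair is kept when at least one mate interval overlaps at least one TE
#' copy by one or more bp. Each kept fragment is assigned to the copy with
#' the largest total overlap with the fragment interval (ties to the
#' leftmost copy), adding `copy_id`, `subfamily`, `family` and `class`
#' columns to the truth table.
#'
#' @param truth Truth tibble from [simulate_fragments()].
#' @param copies Copy table ([merge_te_fragments()] / [read_te_bed()]).
#' @param read_len Mate interval length in bp (the simulated read length).
#' @return The filtered, annotated truth tibble.
#' @export
filter_te_reads <- function(truth, copies, read_len = 100) {
  mates <- bind_rows(
    tibble(unit = truth$read_id, chrom = truth$chrom,
           start = truth$r1_start, end = truth$r1_start + read_len),
    tibble(unit = truth$read_id, chrom = truth$chrom,
           start = truth$r2_start, end = truth$r2_start + read_len)
  )
  gr <- GenomicRanges::GRanges(mates$chrom,
                               IRanges::IRanges(mates$start + 1L, mates$end))
  cg <- copies_to_granges(copies)
  hit_units <- unique(mates$unit[
    S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, cg, ignore.strand = TRUE))
  ])
  kept <- filter(truth, .data$read_id %in% hit_units)
  if (nrow(kept) == 0) {
    return(mutate(kept, copy_id = character(), subfamily = character(),
                  family = character(), class = character()))
  }
  frag_q <- tibble(unit = kept$read_id, chrom = kept$chrom,
                   start = kept$frag_start, end = kept$frag_end)
  asg <- assign_to_copies(frag_q, copies)
  kept %>%
    left_join(select(asg, "unit", "copy_id", "subfamily", "family", "class"),
              by = c(read_id = "unit"))
}

#' Subset a read table to a filtered truth table
#'
#' @param reads Read tibble from [simulate_fragments()] (`$reads`).
#' @param truth A (possibly filtered) truth tibble.
#' @return `reads` restricted to `truth$read_id`, in truth order.
#' @export
subset_reads <- function(reads, truth) {
  out <- semi_join(reads, truth, by = "read_id")
  out[match(truth$read_id, out$read_id), ]
}

#' Derive the matched single-end library
#'
#' The SE library is the R1 file verbatim (identical read ids), so SE and PE
#' evaluations share the same fragments and truth.
#'
#' @param r1 Path to the R1 FASTQ.
#' @param out Output path for the SE FASTQ.
#' @return `out`, invisibly.
#' @export
make_se_library <- function(r1, out) {
  if (!file.exists(r1)) abort(paste0("No such file: ", r1))
  file.copy(r1, out, overwrite = TRUE)
  invisible(out)
}
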