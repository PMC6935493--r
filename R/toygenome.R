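# Synthetic-genome module: planted TE families with controlled divergence,
# RepeatMasker-style annotation, and a machine-readable copy truth table.

#' Specify a planted TE family
#'
#' @param name Subfamily name. LTR-class families emit RepeatMasker records
#'   named `<name>-int` and `<name>_LTR`.
#' @param te_class `"LINE"`, `"SINE"` or `"LTR"`.
#' @param consensus_len Consensus length in bp (internal-sequence length for
#'   LTR families).
#' @param n_copies Number of planted copies (>= 1).
#' @param divergence Per-base substitution probability applied independently
#'   to each copy (0 to 0.3). A proxy for family age: young families have low
#'   divergence and near-identical copies.
#' @param truncation_prob Probability that a copy is 5'-truncated
#'   (LINE-like); the removed fraction is drawn uniformly on
#'   (0, `truncation_frac`].
#' @param truncation_frac Maximum fraction removed by truncation.
#' @param ltr_len LTR length in bp (LTR class only); copies are emitted as
#'   LTR-internal-LTR.
#' @param fragment_prob Probability that a copy's annotation is split into two
#'   records separated by an unannotated gap shorter than 1 kb (the genome
#'   sequence itself stays contiguous).
#' @return A validated `family_spec` list.
#' @export
family_spec <- function(name, te_class = c("LINE", "SINE", "LTR"),
                        consensus_len, n_copies, divergence,
                        truncation_prob = 0, truncation_frac = 0.5,
                        ltr_len = NULL, fragment_prob = 0) {
  te_class <- match.arg(te_class)
  stopifnot(
    is.character(name), nchar(name) > 0,
    consensus_len >= 50, n_copies >= 1,
    divergence >= 0, divergence <= 0.3,
    truncation_prob >= 0, truncation_prob <= 1,
    truncation_frac > 0, truncation_frac < 1,
    fragment_prob >= 0, fragment_prob <= 1
  )
  if (te_class == "LTR") {
    if (is.null(ltr_len)) abort("LTR families need `ltr_len`.")
    stopifnot(ltr_len >= 50)
  }
  structure(list(
    name = name, te_class = te_class, consensus_len = as.integer(consensus_len),
    n_copies = as.integer(n_copies), divergence = divergence,
    truncation_prob = truncation_prob, truncation_frac = truncation_frac,
    ltr_len = if (is.null(ltr_len)) NA_integer_ else as.integer(ltr_len),
    fragment_prob = fragment_prob
  ), class = "family_spec")
}

#' Specify a synthetic toy genome
#'
#' @param genome_len Length in bp of the unique background sequence (planted
#'   copies add to this).
#' @param families A list of [family_spec()] objects.
#' @param gc Background GC fraction (default 0.42, mammal-like).
#' @param seed Integer seed fixing all randomness.
#' @param chrom Chromosome name for the single toy sequence.
#' @return A validated `toy_genome_spec` list.
#' @export
toy_genome_spec <- function(genome_len, families, gc = 0.42, seed = 1,
                            chrom = "toy_chr1") {
  stopifnot(genome_len >= 1000, gc > 0, gc < 1, length(families) >= 1)
  if (inherits(families, "family_spec")) families <- list(families)
  for (f in families) {
    if (!inherits(f, "family_spec")) abort("`families` must be family_spec objects.")
  }
  planted <- sum(vapply(families, function(f) {
    len <- f$consensus_len + if (f$te_class == "LTR") 2L * f$ltr_len else 0L
    f$n_copies * len
  }, numeric(1)))
  if (planted > genome_len / 2) {
    abort(sprintf(
      "Planted TE length (%d bp) exceeds half the background (%d bp); enlarge genome_len.",
      planted, genome_len))
  }
  structure(list(genome_len = as.integer(genome_len), gc = gc,
                 families = families, seed = as.integer(seed), chrom = chrom),
            class = "toy_genome_spec")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute each base independently with probability `rate`; substituted
# bases become one of the three other bases uniformly. Returns the mutated
# string and the realized substitution count.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_sub = 0L))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(b)) < rate)
  if (length(hit) > 0) {
    alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    b[hit] <- vapply(b[hit], function(x) sample(alts[[x]], 1), character(1))
  }
  list(seq = paste(b, collapse = ""), n_sub = length(hit))
}

#' Generate a synthetic genome with planted TE families
#'
#' Builds an i.i.d. background sequence at the requested GC, draws one
#' consensus per family, derives each copy by independent per-base
#' substitution at the family's divergence (plus optional 5' truncation),
#' and splices the copies into the background at random non-overlapping
#' positions on random strands. Emits RepeatMasker-style annotation —
#' including deliberately fragmented records and LTR-internal-LTR composite
#' records — and a truth table of planted copies. Identical spec and seed
#' give byte-identical outputs.
#'
#' @param spec A [toy_genome_spec()].
#' @param dir Optional output directory; when given, writes
#'   `<prefix>.fa` (60-column FASTA), `<prefix>.out` (RepeatMasker format)
#'   and `<prefix>.copies.tsv`.
#' @param prefix File name prefix used under `dir`.
#' @return A `toy_genome` list: `genome` (named `DNAStringSet`), `rmsk`
#'   (annotation tibble in [read_rmsk()] conventions), `copies` (truth tibble
#'   with `copy_id`, span, `strand`, `subfamily`, `family`, `class`, realized
#'   `divergence`), `spec`, and `paths` when files were written.
#' @export
generate_toy_genome <- function(spec, dir = NULL, prefix = "toy") {
  stopifnot(inherits(spec, "toy_genome_spec"))
  res <- with_seed(spec$seed, generate_toy_genome_impl(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, paste0(prefix, ".fa"))
    outf <- file.path(dir, paste0(prefix, ".out"))
    tsv <- file.path(dir, paste0(prefix, ".copies.tsv"))
    Biostrings::writeXStringSet(res$genome, fa, width = 60L)
    write_rmsk_out(res$rmsk, outf)
    readr::write_tsv(res$copies, tsv)
    res$paths <- list(genome = fa, rmsk = outf, copies = tsv)
  }
  res
}

generate_toy_genome_impl <- function(spec) {
  background <- random_dna(spec$genome_len, spec$gc)

  # Per-family consensus sequences.
  consensi <- lapply(spec$families, function(f) {
    list(main = random_dna(f$consensus_len, 0.5),
         ltr = if (f$te_class == "LTR") random_dna(f$ltr_len, 0.5) else NULL)
  })
  names(consensi) <- vapply(spec$families, `[[`, character(1), "name")

  # Build all copies in consensus orientation first.
  plans <- list()
  for (fi in seq_along(spec$families)) {
    f <- spec$families[[fi]]
    cons <- consensi[[fi]]
    for (ci in seq_len(f$n_copies)) {
      if (f$te_class == "LTR") {
        l1 <- mutate_seq(cons$ltr, f$divergence)
        it <- mutate_seq(cons$main, f$divergence)
        l2 <- mutate_seq(cons$ltr, f$divergence)
        seq <- paste0(l1$seq, it$seq, l2$seq)
        len <- nchar(seq)
        il <- nchar(it$seq)
        recs <- tibble(
          lstart = c(0L, f$ltr_len, f$ltr_len + il),
          lend = c(f$ltr_len, f$ltr_len + il, len),
          rep_name = c(paste0(f$name, "_LTR"), paste0(f$name, "-int"),
                       paste0(f$name, "_LTR"))
        )
        n_sub <- l1$n_sub + it$n_sub + l2$n_sub
        subfam <- paste0(f$name, "-int")
      } else {
        cs <- cons$main
        if (runif(1) < f$truncation_prob) {
          frac <- runif(1, 0, f$truncation_frac)
          drop <- floor(nchar(cs) * frac)
          if (drop > 0) cs <- substr(cs, drop + 1, nchar(cs))
        }
        mut <- mutate_seq(cs, f$divergence)
        seq <- mut$seq
        len <- nchar(seq)
        n_sub <- mut$n_sub
        if (runif(1) < f$fragment_prob && len >= 400) {
          s <- as.integer(floor(runif(1, len / 3, 2 * len / 3)))
          gap <- as.integer(floor(runif(1, 50, min(400, len / 4))))
          gap <- min(gap, len - s - 50L) # keep the second record non-empty
          recs <- tibble(lstart = c(0L, s + gap), lend = c(s, len),
                         rep_name = f$name)
        } else {
          recs <- tibble(lstart = 0L, lend = len, rep_name = f$name)
        }
        subfam <- f$name
      }
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") {
        seq <- revcomp_chr(seq)
        len <- nchar(seq)
        recs <- tibble(lstart = len - recs$lend, lend = len - recs$lstart,
                       rep_name = rev(recs$rep_name)) %>%
          arrange(.data$lstart)
      }
      plans[[length(plans) + 1]] <- list(
        family_idx = fi, seq = seq, len = nchar(seq), strand = strand,
        recs = recs, divergence = n_sub / nchar(seq), subfamily = subfam,
        fam = f
      )
    }
  }

  # Random insertion points into the background. Points keep >= 1100 bp of
  # background between copies (and to the ends) so that distinct planted
  # copies can never satisfy the < 1000 bp annotation-merge rule; collisions
  # after rounding are resampled.
  k <- length(plans)
  min_sep <- 1100L
  avail <- spec$genome_len - (k + 1L) * min_sep
  if (avail < 0) {
    abort("Too many planted copies for the background length; enlarge genome_len.")
  }
  repeat {
    pts <- as.integer(round(sort(runif(k)) * avail)) + min_sep * seq_len(k)
    if (k < 2 || min(diff(pts)) >= min_sep) break
  }
  ord <- sample.int(k) # which copy goes at which point
  plans <- plans[ord]

  pieces <- character(2 * k + 1)
  cursor <- 0L
  offset <- 0L
  rmsk_rows <- list()
  copy_rows <- list()
  for (i in seq_len(k)) {
    p <- plans[[i]]
    pieces[2 * i - 1] <- substr(background, cursor + 1L, pts[i])
    pieces[2 * i] <- p$seq
    gstart <- pts[i] + offset
    f <- p$fam
    rmsk_rows[[i]] <- tibble(
      chrom = spec$chrom,
      start = gstart + p$recs$lstart,
      end = gstart + p$recs$lend,
      strand = p$strand,
      rep_name = p$recs$rep_name,
      rep_class = f$te_class,
      rep_family = f$name,
      divergence = round(p$divergence * 100, 2),
      rmsk_id = i
    )
    copy_rows[[i]] <- tibble(
      copy_id = sprintf("tcopy_%03d", i),
      chrom = spec$chrom, start = gstart, end = gstart + p$len,
      strand = p$strand, subfamily = p$subfamily, family = f$name,
      class = f$te_class, divergence = p$divergence, length = p$len
    )
    cursor <- pts[i]
    offset <- offset + p$len
  }
  pieces[2 * k + 1] <- substr(background, cursor + 1L, spec$genome_len)
  genome_seq <- paste(pieces, collapse = "")

  genome <- Biostrings::DNAStringSet(setNames(genome_seq, spec$chrom))
  structure(list(
    genome = genome,
    rmsk = bind_rows(rmsk_rows),
    copies = bind_rows(copy_rows),
    consensi = consensi,
    spec = spec
  ), class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> %s: %s bp, %d planted copies in %d families\n",
              x$spec$chrom,
              format(sum(Biostrings::width(x$genome)), big.mark = ","),
              nrow(x$copies), length(x$spec$families)))
  invisible(x)
}

#' Write an annotation tibble in RepeatMasker `.out` format
#'
#' Inverse of [read_rmsk()]: coordinates go back to 1-based inclusive and
#' minus strand is written as `C`, under the standard 3-line header.
#'
#' @param rmsk Annotation tibble in [read_rmsk()] conventions.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rmsk_out <- function(rmsk, path) {
  header <- c(
    "   SW  perc perc perc  query     position in query           matching repeat            position in  repeat",
    "score  div. del. ins.  sequence  begin     end    (left)    repeat         class/family  begin  end (left)   ID",
    ""
  )
  lines <- sprintf(
    "%5d %5.2f  0.0  0.0  %s %9d %9d (0) %s  %-15s %-15s %6d %6d (0) %5d",
    1000L, rmsk$divergence, rmsk$chrom, rmsk$start + 1L, rmsk$end,
    ifelse(rmsk$strand == "-", "C", "+"), rmsk$rep_name,
    paste0(rmsk$rep_class, "/", rmsk$rep_family),
    1L, rmsk$end - rmsk$start, dplyr::coalesce(rmsk$rmsk_id, 0L)
  )
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Brute-force per-family unique-mappability fraction
#'
#' The mappability oracle: for every `read_len` window inside each planted
#' copy, count the genome positions (either strand) matching the window with
#' at most `k_mismatch` substitutions, by exhaustive scan. Returns the
#' fraction of windows with exactly one such position per subfamily. Guarded
#' to small genomes; the scan is exact (counting stops at two hits, which the
#' unique fraction cannot distinguish from more).
#'
#' @param toy A `toy_genome` from [generate_toy_genome()].
#' @param read_len Window length in bp.
#' @param k_mismatch Allowed substitutions per window.
#' @param stride Enumerate every `stride`-th window start (default 1 = all).
#' @return A tibble: `subfamily`, `n_windows`, `unique_fraction`.
#' @export
expected_unique_fraction <- function(toy, read_len = 100, k_mismatch = 0,
                                     stride = 1) {
  stopifnot(inherits(toy, "toy_genome"), read_len >= 10, k_mismatch >= 0,
            stride >= 1)
  total <- sum(Biostrings::width(toy$genome))
  if (total > 200000) {
    abort(sprintf(
      "Genome is %d bp; the exhaustive mappability scan is guarded to 200 kb. Use a smaller fixture.",
      total))
  }
  chroms <- as.character(toy$genome)
  chrom_idx <- setNames(seq_along(chroms), names(toy$genome))
  wins <- toy$copies %>%
    filter(.data$end - .data$start >= read_len) %>%
    mutate(starts = purrr::map2(.data$start, .data$end, function(s, e) {
      seq.int(s, e - read_len, by = stride)
    })) %>%
    select("subfamily", "chrom", "starts") %>%
    tidyr::unnest("starts")
  if (nrow(wins) == 0) {
    return(tibble(subfamily = character(), n_windows = integer(),
                  unique_fraction = numeric()))
  }
  counts <- cpp_window_hit_counts(
    chroms, as.integer(chrom_idx[wins$chrom]), as.integer(wins$starts),
    as.integer(read_len), as.integer(k_mismatch), 2L
  )
  wins %>%
    mutate(unique = counts == 1L) %>%
    group_by(.data$subfamily) %>%
    summarise(n_windows = n(), unique_fraction = mean(.data$unique),
              .groups = "drop") %>%
    arrange(.data$subfamily)
}
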