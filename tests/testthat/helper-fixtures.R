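# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Full-coverage demo run shared by the acceptance and demo tests.
demo_full_run <- function() fixture("demo_full", function() {
  run_demo(dir = file.path(tempdir(), "temark_demo_full"), seed = 101,
           coverage = 10)
})

# Cheap demo runs (coverage 2) for wiring and determinism checks; two
# independent runs with the same seed.
demo_cov2_run <- function(i) fixture(paste0("demo_cov2_", i), function() {
  run_demo(dir = file.path(tempdir(), paste0("temark_demo_cov2_", i)),
           seed = 11, coverage = 2)
})

# Three same-shape LINE families differing only in divergence, used by the
# mappability-monotonicity tests (small enough for the exhaustive oracle).
mappability_toy <- function() fixture("mappability_toy", function() {
  generate_toy_genome(toy_genome_spec(
    genome_len = 35000,
    families = list(
      family_spec("MAP_young", "LINE", consensus_len = 900, n_copies = 6,
                  divergence = 0.005),
      family_spec("MAP_mid", "LINE", consensus_len = 900, n_copies = 6,
                  divergence = 0.05),
      family_spec("MAP_old", "LINE", consensus_len = 900, n_copies = 6,
                  divergence = 0.15)
    ),
    seed = 5
  ))
})

# One row in read_rmsk() conventions (0-based half-open).
rmsk_row <- function(chrom, start, end, strand, rep_name,
                     rep_class = "LINE", rep_family = rep_name,
                     divergence = 10, rmsk_id = NA) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, rep_name = rep_name, rep_class = rep_class,
    rep_family = rep_family, divergence = as.numeric(divergence),
    rmsk_id = as.integer(rmsk_id)
  )
}

# One row of a copy table as produced by merge_te_fragments().
copy_row <- function(copy_id, chrom, start, end, strand, subfamily,
                     family = subfamily, class = "LINE") {
  tibble::tibble(
    copy_id = copy_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand, subfamily = subfamily,
    family = family, class = class, n_fragments = 1L,
    fragments = list(tibble::tibble(start = as.integer(start),
                                    end = as.integer(end),
                                    rep_name = subfamily))
  )
}

# One single-end SAM record row as written by the micro-aligner.
sam_row <- function(qname, flag, rname, pos, cigar = "100M", nh = NA,
                    seq = "*", qual = "*", pnext = 0L, tlen = 0L,
                    rnext = "*", mapq = 255L) {
  tibble::tibble(
    qname = qname, flag = as.integer(flag), rname = rname,
    pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
    rnext = rnext, pnext = as.integer(pnext), tlen = as.integer(tlen),
    seq = seq, qual = qual,
    tags = ifelse(is.na(nh), "", paste0("NH:i:", nh))
  )
}

random_dna_string <- function(n, seed) {
  temark:::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# A genome with one 400 bp sequence planted twice (identical copies) between
# unique flanks, plus its copy table. Used by the duplicated-copy fixtures
# (fraction-count conservation, PE rescue).
dup_copy_genome <- function(seed = 21, copy_len = 400L, flank = 1500L) {
  fixture(paste0("dup_copy_", seed, "_", copy_len, "_", flank), function() {
    copy <- random_dna_string(copy_len, seed + 1)
    f1 <- random_dna_string(flank, seed + 2)
    f2 <- random_dna_string(flank, seed + 3)
    f3 <- random_dna_string(flank, seed + 4)
    gseq <- paste0(f1, copy, f2, copy, f3)
    genome <- Biostrings::DNAStringSet(stats::setNames(gseq, "dup_chr"))
    starts <- c(flank, flank + copy_len + flank)
    copies <- dplyr::bind_rows(
      copy_row("dup1", "dup_chr", starts[1], starts[1] + copy_len, "+", "DUP"),
      copy_row("dup2", "dup_chr", starts[2], starts[2] + copy_len, "+", "DUP")
    )
    list(genome = genome, gseq = gseq, copies = copies, copy_len = copy_len,
         starts = starts)
  })
}
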