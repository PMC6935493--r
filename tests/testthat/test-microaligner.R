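# Micro-aligner module: exhaustive candidate search, reporting modes, SAM
# emission, paired-end rescue.

planted_genome <- function() fixture("planted_genome", function() {
  bg <- random_dna_string(3000, 61)
  insert <- random_dna_string(100, 62)
  gseq <- paste0(substring(bg, 1, 1500), insert, substring(bg, 1501, 3000))
  list(
    genome = Biostrings::DNAStringSet(stats::setNames(gseq, "pg_chr")),
    gseq = gseq, insert = insert, insert_start = 1500L
  )
})

test_that("micro_align finds a planted read exactly once at the right place", {
  fx <- planted_genome()
  hits <- micro_align(tibble::tibble(read_id = "r1", seq = fx$insert),
                      fx$genome, max_mm = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$chrom, "pg_chr")
  expect_identical(hits$start, fx$insert_start)
  expect_identical(hits$strand, "+")
  expect_identical(hits$mm, 0L)
})

test_that("micro_align agrees with Biostrings::matchPattern at 0 and 1 mismatches", {
  fx <- dup_copy_genome(seed = 51, copy_len = 300L, flank = 1000L)
  reads <- tibble::tibble(
    read_id = c("a", "b", "c"),
    seq = c(substring(fx$gseq, fx$starts[1] + 1L, fx$starts[1] + 60L),
            substring(fx$gseq, 101L, 160L),
            temark:::revcomp_chr(substring(fx$gseq, 501L, 560L)))
  )
  for (mm in c(0L, 1L)) {
    hits <- micro_align(reads, fx$genome, max_mm = mm)
    subj <- Biostrings::DNAString(fx$gseq)
    for (i in seq_len(nrow(reads))) {
      fwd <- Biostrings::matchPattern(reads$seq[i], subj, max.mismatch = mm)
      rev <- Biostrings::matchPattern(
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(reads$seq[i]))), subj, max.mismatch = mm)
      got <- hits[hits$read_id == reads$read_id[i], ]
      expect_identical(sort(got$start[got$strand == "+"]),
                       sort(BiocGenerics::start(fwd) - 1L))
      expect_identical(sort(got$start[got$strand == "-"]),
                       sort(BiocGenerics::start(rev) - 1L))
    }
  }
})

test_that("a read with one substitution is recovered with the right mm count", {
  fx <- planted_genome()
  seq <- fx$insert
  ch <- substring(seq, 50, 50)
  substr(seq, 50, 50) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  hits <- micro_align(tibble::tibble(read_id = "mut", seq = seq),
                      fx$genome, max_mm = 1)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, fx$insert_start)
  expect_identical(hits$mm, 1L)
  expect_identical(nrow(micro_align(tibble::tibble(read_id = "mut", seq = seq),
                                    fx$genome, max_mm = 0)), 0L)
})

test_that("minus-strand reads report the forward-strand position", {
  fx <- planted_genome()
  hits <- micro_align(
    tibble::tibble(read_id = "rc", seq = temark:::revcomp_chr(fx$insert)),
    fx$genome, max_mm = 0)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, fx$insert_start)
  expect_identical(hits$strand, "-")
})

test_that("SE modes: unique suppresses ties, multi reports all with NH, random picks one", {
  fx <- dup_copy_genome(seed = 21)
  read <- tibble::tibble(
    read_id = "dup_read",
    seq = substring(fx$gseq, fx$starts[1] + 1L, fx$starts[1] + 80L))
  hits <- micro_align(read, fx$genome, max_mm = 0)
  expect_identical(nrow(hits), 2L)

  uni <- sam_from_hits_se(read, hits, "unique")
  expect_identical(nrow(uni), 1L)
  expect_identical(uni$flag, 4L)

  multi <- sam_from_hits_se(read, hits, "multi", seed = 3)
  expect_identical(nrow(multi), 2L)
  expect_identical(sum(bitwAnd(multi$flag, 256L) == 0L), 1L)
  expect_true(all(multi$tags == "NH:i:2"))
  expect_true(all(multi$mapq == 255L))
  expect_setequal(multi$pos - 1L, fx$starts)

  rnd <- sam_from_hits_se(read, hits, "random", seed = 3)
  expect_identical(nrow(rnd), 1L)
  expect_identical(rnd$tags, "NH:i:1")
  expect_true((rnd$pos - 1L) %in% fx$starts)
  # Identical seed, identical choice.
  expect_identical(rnd, sam_from_hits_se(read, hits, "random", seed = 3))
})

test_that("SE unique records carry MAPQ 60, NH 1, and the correct layout", {
  fx <- planted_genome()
  read <- tibble::tibble(read_id = "u1", seq = fx$insert)
  sam <- micromap(read, fx$genome, mode = "unique", max_mm = 0)
  expect_identical(sam$flag, 0L)
  expect_identical(sam$pos, fx$insert_start + 1L) # SAM is 1-based
  expect_identical(sam$mapq, 60L)
  expect_identical(sam$cigar, "100M")
  expect_identical(sam$tags, "NH:i:1")
  expect_identical(sam$seq, fx$insert)
  # A minus-strand read stores the reverse complement with flag 16.
  rc <- micromap(tibble::tibble(read_id = "u2",
                                seq = temark:::revcomp_chr(fx$insert)),
                 fx$genome, mode = "unique", max_mm = 0)
  expect_identical(rc$flag, 16L)
  expect_identical(rc$seq, fx$insert) # stored on the forward strand
})

test_that("multi mode conserves NH: records per read equal the NH tag", {
  demo <- demo_cov2_run(1)
  sam <- readLines(file.path(demo$dir, "te_se_multi.sam"))
  body <- sam[!startsWith(sam, "@")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  qname <- vapply(fields, `[[`, character(1), 1)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2))
  mapped <- bitwAnd(flag, 4L) == 0L
  nh <- as.integer(sub("^.*NH:i:(\\d+).*$", "\\1", body[mapped]))
  qmapped <- qname[mapped]
  # Every record of a read carries the same NH, equal to its record count.
  nh_levels <- tapply(nh, qmapped, unique, simplify = FALSE)
  expect_true(all(lengths(nh_levels) == 1L))
  per_read <- table(qmapped)
  expect_identical(as.integer(per_read[names(nh_levels)]),
                   as.integer(unlist(nh_levels)[names(nh_levels)]))
})

test_that("PE pairing rescues a multi-mapping mate and rejects bad geometry", {
  fx <- dup_copy_genome(seed = 21)
  off <- fx$copy_len - 120L
  frag_start <- fx$starts[1] + off
  r1 <- tibble::tibble(
    read_id = "pair1",
    seq = substring(fx$gseq, frag_start + 1L, frag_start + 100L))
  r2 <- tibble::tibble(
    read_id = "pair1",
    seq = temark:::revcomp_chr(
      substring(fx$gseq, frag_start + 101L, frag_start + 200L)))
  h1 <- micro_align(r1, fx$genome, max_mm = 0)
  h2 <- micro_align(r2, fx$genome, max_mm = 0)
  expect_identical(nrow(h1), 2L) # R1 alone is ambiguous
  expect_identical(nrow(h2), 1L)

  pe <- sam_from_hits_pe(r1, r2, h1, h2, "unique", frag_min = 100,
                         frag_max = 400)
  expect_identical(nrow(pe), 2L)
  expect_true(all(bitwAnd(pe$flag, 2L) == 2L)) # proper pair
  expect_identical(pe$pos[bitwAnd(pe$flag, 64L) == 64L], frag_start + 1L)
  expect_identical(sort(pe$tlen), c(-200L, 200L))
  expect_identical(pe$rnext, c("=", "="))
  expect_identical(pe$pnext, rev(pe$pos))
  # Out-of-range fragment window: no valid pair, both mates unmapped.
  far <- sam_from_hits_pe(r1, r2, h1, h2, "unique", frag_min = 100,
                          frag_max = 150)
  expect_identical(sort(far$flag), sort(c(77L, 141L)))
})

test_that("fully duplicated pairs stay ambiguous: unique unmaps, multi tags NH 2", {
  fx <- dup_copy_genome(seed = 21)
  # Both mates inside the duplicated copy: two equally good pairs.
  frag_start <- fx$starts[1] + 50L
  r1 <- tibble::tibble(
    read_id = "amb",
    seq = substring(fx$gseq, frag_start + 1L, frag_start + 100L))
  r2 <- tibble::tibble(
    read_id = "amb",
    seq = temark:::revcomp_chr(
      substring(fx$gseq, frag_start + 151L, frag_start + 250L)))
  h1 <- micro_align(r1, fx$genome, max_mm = 0)
  h2 <- micro_align(r2, fx$genome, max_mm = 0)
  uni <- sam_from_hits_pe(r1, r2, h1, h2, "unique")
  expect_identical(sort(uni$flag), sort(c(77L, 141L)))
  multi <- sam_from_hits_pe(r1, r2, h1, h2, "multi", seed = 2)
  expect_identical(nrow(multi), 4L) # two pairs x two mates
  expect_true(all(grepl("NH:i:2", multi$tags)))
  expect_identical(sum(bitwAnd(multi$flag, 256L) == 0L), 2L)
})

test_that("write_sam emits a conformant header and round-trips through Rsamtools", {
  fx <- planted_genome()
  reads <- tibble::tibble(
    read_id = c("w1", "w2"),
    seq = c(fx$insert, substring(fx$gseq, 201, 300)))
  path <- tempfile(fileext = ".sam")
  micromap(reads, fx$genome, mode = "unique", max_mm = 0, out = path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "@HD"))
  expect_true(any(grepl("^@SQ\tSN:pg_chr\tLN:3100$", lines)))
  obs <- load_alignments(path, "SE")
  expect_identical(nrow(obs), 2L)
  expect_setequal(obs$read_id, reads$read_id)
  expect_identical(obs$start[obs$read_id == "w1"], fx$insert_start)
  expect_identical(obs$n_hits[obs$read_id == "w1"], 1L)
  # The tibble path gives the same evaluation-ready table.
  sam_tbl <- micromap(reads, fx$genome, mode = "unique", max_mm = 0)
  obs2 <- load_alignments(sam_tbl, "SE")
  common <- c("read_id", "chrom", "start", "strand", "n_hits")
  expect_identical(as.data.frame(obs[common][order(obs$read_id), ]),
                   as.data.frame(obs2[common][order(obs2$read_id), ]))
})

test_that("the genome guard and input validation fire", {
  big <- Biostrings::DNAStringSet(stats::setNames(
    paste(rep("ACGT", 275000), collapse = ""), "big"))
  expect_error(micro_align(tibble::tibble(read_id = "x", seq = "ACGTACGTACGT"),
                           big, max_mm = 0), "1 Mb")
  fx <- planted_genome()
  expect_error(micro_align(tibble::tibble(id = "x", s = "ACGT"), fx$genome),
               "read_id")
  expect_error(micro_align(c("ACGTACGT"), fx$genome), "named")
})
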