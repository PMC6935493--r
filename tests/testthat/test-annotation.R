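# Annotation module: RepeatMasker parsing, LTR dictionary, fragment merging,
# feature file round-trips.

write_out_lines <- function(lines) {
  path <- tempfile(fileext = ".out")
  header <- c(
    "   SW  perc perc perc  query     position in query           matching repeat            position in  repeat",
    "score  div. del. ins.  sequence  begin     end    (left)    repeat         class/family  begin  end (left)   ID",
    ""
  )
  writeLines(c(header, lines), path)
  path
}

test_that("read_rmsk applies the .out conventions", {
  path <- write_out_lines(c(
    " 1000 12.50  0.0  0.0  chr1       101       200 (0) +  L1MdA    LINE/L1      1 100 (0)     7",
    "  900  5.00  0.0  0.0  chr1       501       700 (0) C  MERVL_LTR  LTR/ERVL   1 200 (0)     8",
    "  800  1.00  0.0  0.0  chr2      1001      1300 (0) +  Simple   Simple_repeat  1 300 (0)   9"
  ))
  rec <- read_rmsk(path)
  expect_identical(nrow(rec), 3L)
  # 1-based inclusive -> 0-based half-open.
  expect_identical(rec$start, c(100L, 500L, 1000L))
  expect_identical(rec$end, c(200L, 700L, 1300L))
  # C means minus.
  expect_identical(rec$strand, c("+", "-", "+"))
  # class/family split; no slash -> family = class.
  expect_identical(rec$rep_class, c("LINE", "LTR", "Simple_repeat"))
  expect_identical(rec$rep_family, c("L1", "ERVL", "Simple_repeat"))
  expect_identical(rec$divergence, c(12.5, 5, 1))
  expect_identical(rec$rmsk_id, c(7L, 8L, 9L))
})

test_that("read_rmsk rejects malformed records with the offending line number", {
  path <- write_out_lines(c(
    " 1000 12.50  0.0  0.0  chr1 101 200 (0) + L1MdA LINE/L1 1 100 (0) 7",
    " 1000 12.50  0.0  0.0  chr1 300"
  ))
  expect_error(read_rmsk(path), "line 5")

  path2 <- write_out_lines(
    " 1000 xx  0.0  0.0  chr1 101 200 (0) + L1MdA LINE/L1 1 100 (0) 7")
  expect_error(read_rmsk(path2), "line 4.*non-numeric")

  path3 <- write_out_lines(
    " 1000 12.50  0.0  0.0  chr1 101 200 (0) * L1MdA LINE/L1 1 100 (0) 7")
  expect_error(read_rmsk(path3), "strand")
})

test_that("read_rmsk warns and returns an empty table on header-only files", {
  path <- write_out_lines(character())
  expect_warning(rec <- read_rmsk(path), "no records")
  expect_identical(nrow(rec), 0L)
  expect_identical(names(rec), names(temark:::empty_rmsk()))
  expect_error(read_rmsk(tempfile()), "No such file")
})

test_that("build_ltr_dictionary finds pairs by name heuristic", {
  rmsk <- dplyr::bind_rows(
    rmsk_row("chr1", 0, 300, "+", "ERV1_LTR", rep_class = "LTR"),
    rmsk_row("chr1", 300, 2000, "+", "ERV1-int", rep_class = "LTR"),
    rmsk_row("chr1", 5000, 5300, "+", "MLT1A", rep_class = "LTR"),
    rmsk_row("chr1", 9000, 9100, "+", "L1MdA", rep_class = "LINE")
  )
  dict <- build_ltr_dictionary(rmsk)
  expect_identical(dict$internal, "ERV1-int")
  expect_identical(dict$ltr, "ERV1_LTR")
  expect_identical(dict$provenance, "name_heuristic")
})

test_that("build_ltr_dictionary adjacency tier requires min_support loci", {
  # Internal/LTR names that share no stem: only adjacency can link them.
  locus <- function(at, id) dplyr::bind_rows(
    rmsk_row("chr1", at, at + 300, "+", "WEIRD_LTR", rep_class = "LTR",
             rmsk_id = id),
    rmsk_row("chr1", at + 350, at + 2000, "+", "GYPSY-I", rep_class = "LTR",
             rmsk_id = id)
  )
  one <- locus(0, 1)
  two <- dplyr::bind_rows(one, locus(10000, 2))
  expect_identical(nrow(build_ltr_dictionary(one, min_support = 2)), 0L)
  dict <- build_ltr_dictionary(two, min_support = 2)
  expect_identical(dict$internal, "GYPSY-I")
  expect_identical(dict$ltr, "WEIRD_LTR")
  expect_identical(dict$provenance, "adjacency")
  # Distant records never pair.
  far <- dplyr::bind_rows(
    rmsk_row("chr1", 0, 300, "+", "WEIRD_LTR", rep_class = "LTR"),
    rmsk_row("chr1", 5000, 7000, "+", "GYPSY-I", rep_class = "LTR")
  )
  expect_identical(nrow(build_ltr_dictionary(far, min_support = 1)), 0L)
})

test_that("user pairs outrank the heuristic and unknown names warn", {
  rmsk <- dplyr::bind_rows(
    rmsk_row("chr1", 0, 300, "+", "ERV1_LTR", rep_class = "LTR"),
    rmsk_row("chr1", 300, 2000, "+", "ERV1-int", rep_class = "LTR")
  )
  expect_warning(
    dict <- build_ltr_dictionary(
      rmsk, user_pairs = tibble::tibble(internal = c("ERV1-int", "GHOST-int"),
                                        ltr = c("ERV1_LTR", "GHOST_LTR"))),
    "absent from annotation")
  pair <- dict[dict$internal == "ERV1-int", ]
  expect_identical(pair$provenance, "user")
  expect_true("GHOST-int" %in% dict$internal)
})

test_that("merge_te_fragments merges below 1000 bp and splits at exactly 1000", {
  mk <- function(gap) dplyr::bind_rows(
    rmsk_row("chr1", 0, 500, "+", "L1MdA", rmsk_id = 1),
    rmsk_row("chr1", 500 + gap, 900 + gap, "+", "L1MdA", rmsk_id = 1)
  )
  expect_identical(nrow(merge_te_fragments(mk(800))), 1L)
  expect_identical(nrow(merge_te_fragments(mk(999))), 1L)
  expect_identical(nrow(merge_te_fragments(mk(1000))), 2L)
  # Overlapping compatible fragments merge too.
  expect_identical(nrow(merge_te_fragments(mk(-100))), 1L)
  # max_gap = 0 merges nothing.
  expect_identical(nrow(merge_te_fragments(mk(0), max_gap = 0)), 2L)
  # Strand or chromosome mismatch prevents merging.
  cross <- mk(100)
  cross$strand[2] <- "-"
  expect_identical(nrow(merge_te_fragments(cross)), 2L)
  cross2 <- mk(100)
  cross2$chrom[2] <- "chr2"
  expect_identical(nrow(merge_te_fragments(cross2)), 2L)
})

test_that("merge_te_fragments links by rmsk_id and by the LTR dictionary", {
  # Different names, same linkage ID.
  by_id <- dplyr::bind_rows(
    rmsk_row("chr1", 0, 500, "+", "L1MdA", rmsk_id = 3),
    rmsk_row("chr1", 700, 1000, "+", "L1MdF", rmsk_id = 3)
  )
  expect_identical(nrow(merge_te_fragments(by_id)), 1L)
  # Different names, different IDs: stays apart despite the small gap.
  apart <- dplyr::bind_rows(
    rmsk_row("chr1", 0, 500, "+", "L1MdA", rmsk_id = 3),
    rmsk_row("chr1", 700, 1000, "+", "L1MdF", rmsk_id = 4)
  )
  expect_identical(nrow(merge_te_fragments(apart)), 2L)
  # LTR - internal - LTR triplet merges through the dictionary and takes the
  # internal name as subfamily.
  trip <- dplyr::bind_rows(
    rmsk_row("chr1", 0, 300, "+", "ERV1_LTR", rep_class = "LTR", rmsk_id = NA),
    rmsk_row("chr1", 300, 2000, "+", "ERV1-int", rep_class = "LTR",
             rmsk_id = NA),
    rmsk_row("chr1", 2000, 2300, "+", "ERV1_LTR", rep_class = "LTR",
             rmsk_id = NA)
  )
  dict <- build_ltr_dictionary(trip)
  copies <- merge_te_fragments(trip, dict)
  expect_identical(nrow(copies), 1L)
  expect_identical(copies$subfamily, "ERV1-int")
  expect_identical(copies$n_fragments, 3L)
  expect_identical(copies$start, 0L)
  expect_identical(copies$end, 2300L)
  # Without the dictionary the triplet stays in three pieces.
  expect_identical(nrow(merge_te_fragments(trip)), 3L)
})

test_that("merging partitions the records and ties go to the nearest open copy", {
  toy <- mappability_toy()
  copies <- merge_te_fragments(toy$rmsk)
  # Partition: every record lands in exactly one copy.
  expect_identical(sum(copies$n_fragments), nrow(toy$rmsk))
  # Empty input gives an empty copy table.
  expect_identical(nrow(merge_te_fragments(temark:::empty_rmsk())), 0L)
  # Nearest-open-copy rule: a fragment compatible with two open copies joins
  # the one with the larger end.
  rec <- dplyr::bind_rows(
    rmsk_row("chr1", 0, 100, "+", "L1MdA", rmsk_id = NA),
    rmsk_row("chr1", 300, 400, "+", "L1MdA", rmsk_id = NA),
    rmsk_row("chr1", 900, 1000, "+", "L1MdA", rmsk_id = NA)
  )
  copies <- merge_te_fragments(rec)
  expect_identical(nrow(copies), 1L) # chained merging keeps one copy
})

test_that("feature files round-trip through BED6 and TSV", {
  toy <- mappability_toy()
  copies <- merge_te_fragments(toy$rmsk)
  bed <- tempfile(fileext = ".bed")
  tsv <- tempfile(fileext = ".tsv")
  write_te_features(copies, bed, "BED6")
  write_te_features(copies, tsv, "TSV")

  core <- c("copy_id", "chrom", "start", "end", "strand", "subfamily",
            "family", "class")
  from_bed <- read_te_bed(bed)
  from_tsv <- read_te_features(tsv, "TSV")
  expect_identical(as.data.frame(from_bed[core]),
                   as.data.frame(copies[core]))
  expect_identical(as.data.frame(from_tsv[core]),
                   as.data.frame(copies[core]))
  expect_identical(from_tsv$n_fragments, copies$n_fragments)
  # TSV keeps the per-fragment spans.
  expect_identical(
    as.data.frame(from_tsv$fragments[[1]]),
    as.data.frame(copies$fragments[[1]])
  )
  # Reading a TSV as BED6 errors instead of returning shifted columns.
  expect_error(read_te_bed(tsv), "BED strand")
})
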