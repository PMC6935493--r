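# Annotation module: RepeatMasker `.out` parsing, LTR internal<->LTR
# dictionary construction, fragment-to-copy merging, feature file I/O.

INTERNAL_SUFFIX_RE <- "(-int|_I|-I)$"
LTR_SUFFIX_RE <- "(_LTR|-LTR)$"

#' Read a RepeatMasker `.out` annotation file
#'
#' Parses the standard whitespace-delimited RepeatMasker output. Coordinates
#' are converted from the file's 1-based inclusive convention to 0-based
#' half-open; the `C` strand code becomes `-`; the class/family column is
#' split on `/` (records without a `/` get `family = class`).
#'
#' @param path Path to a RepeatMasker `.out` file (3-line header expected;
#'   any leading lines before the first data record are skipped).
#' @return A tibble with one row per record: `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `rep_name`, `rep_class`,
#'   `rep_family`, `divergence` (percent), `rmsk_id` (integer, `NA` when the
#'   linkage column is absent).
#' @examples
#' out <- tempfile(fileext = ".out")
#' toy <- generate_toy_genome(toy_genome_spec(
#'   genome_len = 5000,
#'   families = list(family_spec("TOY1", "LINE", 400, 2, 0.05)),
#'   seed = 1
#' ))
#' write_rmsk_out(toy$rmsk, out)
#' read_rmsk(out)
#' @export
read_rmsk <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readr::read_lines(path)
  is_data <- grepl("^\\s*\\d+\\s", lines)
  if (!any(is_data)) {
    warn("RepeatMasker file contains a header but no records.")
    return(empty_rmsk())
  }
  idx <- which(is_data)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 14)
  if (length(bad) > 0) {
    abort(sprintf("Malformed RepeatMasker record at line %d (%d fields, need >= 14).",
                  idx[bad[1]], nf[bad[1]]))
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start1 <- suppressWarnings(as.integer(get(6)))
  end1 <- suppressWarnings(as.integer(get(7)))
  div <- suppressWarnings(as.numeric(get(2)))
  bad <- which(is.na(start1) | is.na(end1) | is.na(div))
  if (length(bad) > 0) {
    abort(sprintf("Malformed RepeatMasker record at line %d (non-numeric coordinate or divergence).",
                  idx[bad[1]]))
  }
  strand_raw <- get(9)
  bad <- which(!strand_raw %in% c("+", "C"))
  if (length(bad) > 0) {
    abort(sprintf("Malformed RepeatMasker record at line %d (strand '%s', expected '+' or 'C').",
                  idx[bad[1]], strand_raw[bad[1]]))
  }
  cls <- get(11)
  id <- vapply(fields, function(f) {
    if (length(f) >= 15 && grepl("^\\d+$", f[[15]])) f[[15]] else NA_character_
  }, character(1))
  tibble(
    chrom = get(5),
    start = start1 - 1L,
    end = end1,
    strand = ifelse(strand_raw == "C", "-", "+"),
    rep_name = get(10),
    rep_class = sub("/.*$", "", cls),
    rep_family = ifelse(grepl("/", cls), sub("^[^/]*/", "", cls), sub("/.*$", "", cls)),
    divergence = div,
    rmsk_id = as.integer(id)
  )
}

empty_rmsk <- function() {
  tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), rep_name = character(), rep_class = character(),
    rep_family = character(), divergence = numeric(), rmsk_id = integer()
  )
}

#' Build an LTR internal/LTR pairing dictionary
#'
#' LTR retrotransposons are annotated by RepeatMasker as separate internal
#' (`-int`, `_I`, `-I` suffixed) and LTR records that belong to one insertion.
#' This builds the pairing internal subfamily -> LTR subfamilies from three
#' sources, in priority order: user-supplied pairs, a name heuristic
#' (suffix-stripped stems must agree, or the LTR name equals `stem + "_LTR"`),
#' and genome-wide adjacency (an LTR-class record within `max_gap` of an
#' internal record on the same chromosome and strand, kept when seen at
#' `min_support` or more loci).
#'
#' @param rmsk A record table from [read_rmsk()].
#' @param user_pairs Optional: a two-column table (or path to a headerless TSV)
#'   of `internal, ltr` subfamily names. Always wins; unknown names are kept
#'   with a warning since annotation may be partial.
#' @param max_gap Maximum distance in bp between internal and LTR records for
#'   the adjacency rule (default 1000).
#' @param min_support Minimum number of supporting loci for an adjacency pair.
#' @return A tibble with columns `internal`, `ltr`, `provenance`
#'   (`user`, `name_heuristic`, or `adjacency`).
#' @export
build_ltr_dictionary <- function(rmsk, user_pairs = NULL, max_gap = 1000,
                                 min_support = 2) {
  pairs <- tibble(internal = character(), ltr = character(),
                  provenance = character())

  if (!is.null(user_pairs)) {
    if (is.character(user_pairs) && length(user_pairs) == 1) {
      user_pairs <- readr::read_tsv(user_pairs, col_names = c("internal", "ltr"),
                                    col_types = "cc", comment = "#")
    }
    up <- as_tibble(user_pairs)
    names(up)[1:2] <- c("internal", "ltr")
    known <- unique(rmsk$rep_name)
    unknown <- setdiff(unique(c(up$internal, up$ltr)), known)
    if (length(unknown) > 0) {
      warn(paste0("LTR dictionary names absent from annotation (kept): ",
                  paste(unknown, collapse = ", ")))
    }
    pairs <- bind_rows(pairs, mutate(select(up, "internal", "ltr"),
                                     provenance = "user"))
  }

  ltr_rec <- filter(rmsk, .data$rep_class == "LTR")
  int_names <- unique(ltr_rec$rep_name[grepl(INTERNAL_SUFFIX_RE, ltr_rec$rep_name)])
  ltr_names <- setdiff(unique(ltr_rec$rep_name), int_names)

  # Tier 2: name heuristic.
  if (length(int_names) > 0 && length(ltr_names) > 0) {
    stems <- sub(INTERNAL_SUFFIX_RE, "", int_names)
    ltr_stems <- sub(LTR_SUFFIX_RE, "", ltr_names)
    heur <- purrr::map2_dfr(int_names, stems, function(nm, st) {
      hit <- ltr_names[ltr_names == st | ltr_names == paste0(st, "_LTR") |
                         ltr_stems == st]
      if (length(hit) == 0) return(NULL)
      tibble(internal = nm, ltr = hit, provenance = "name_heuristic")
    })
    pairs <- bind_rows(pairs, heur)
  }

  # Tier 3: adjacency between internal and LTR records, genome-wide support.
  if (length(int_names) > 0 && length(ltr_names) > 0) {
    cand <- ltr_rec %>%
      filter(.data$rep_name %in% c(int_names, ltr_names)) %>%
      arrange(.data$chrom, .data$start)
    if (nrow(cand) > 1) {
      adj <- purrr::map_dfr(seq_len(nrow(cand) - 1), function(i) {
        a <- cand[i, ]
        b <- cand[i + 1, ]
        gap <- b$start - a$end
        if (a$chrom != b$chrom || a$strand != b$strand || gap >= max_gap) {
          return(NULL)
        }
        a_int <- a$rep_name %in% int_names
        b_int <- b$rep_name %in% int_names
        if (a_int == b_int) return(NULL)
        tibble(internal = if (a_int) a$rep_name else b$rep_name,
               ltr = if (a_int) b$rep_name else a$rep_name)
      })
      if (nrow(adj) > 0) {
        adj <- adj %>%
          count(.data$internal, .data$ltr, name = "support") %>%
          filter(.data$support >= min_support) %>%
          mutate(provenance = "adjacency") %>%
          select("internal", "ltr", "provenance")
        pairs <- bind_rows(pairs, adj)
      }
    }
  }

  # Keep the highest-priority provenance per pair; enforce that no name is
  # both an internal key and an LTR member.
  pairs <- pairs %>%
    mutate(prio = match(.data$provenance,
                        c("user", "name_heuristic", "adjacency"))) %>%
    arrange(.data$prio) %>%
    distinct(.data$internal, .data$ltr, .keep_all = TRUE)
  conflict <- intersect(pairs$internal, pairs$ltr)
  if (length(conflict) > 0) {
    warn(paste0("Dropping dictionary pairs where a name is both internal and LTR: ",
                paste(conflict, collapse = ", ")))
    pairs <- filter(pairs, !(.data$ltr %in% conflict))
  }
  pairs %>% select("internal", "ltr", "provenance") %>%
    arrange(.data$internal, .data$ltr)
}

# TRUE where records a and b may belong to the same copy by name/ID/dictionary.
name_compatible <- function(rec_name, rec_id, copy_names, copy_ids, ltr_dict) {
  if (rec_name %in% copy_names) return(TRUE)
  if (!is.na(rec_id) && any(!is.na(copy_ids) & copy_ids == rec_id)) return(TRUE)
  if (!is.null(ltr_dict) && nrow(ltr_dict) > 0) {
    linked <- c(
      ltr_dict$ltr[ltr_dict$internal == rec_name],
      ltr_dict$internal[ltr_dict$ltr == rec_name]
    )
    if (any(copy_names %in% linked)) return(TRUE)
  }
  FALSE
}

#' Merge RepeatMasker fragments into TE copies
#'
#' RepeatMasker reports one insertion as several fragments (interrupted
#' elements, LTR/internal structure). Fragments are merged greedily
#' left-to-right into copies when they lie on the same chromosome and strand,
#' the gap to the copy (next start minus current end) is strictly less than
#' `max_gap`, and the names are compatible: identical `rep_name`, equal
#' `rmsk_id` (when present), or linked through the LTR dictionary
#' (LTR-internal-LTR composition). Composite LTR copies take the internal
#' element's name as subfamily. Overlapping compatible fragments (negative
#' gap) merge.
#'
#' @param rmsk A record table from [read_rmsk()].
#' @param ltr_dict Optional dictionary from [build_ltr_dictionary()].
#' @param max_gap Merge fragments closer than this many bp (strict `<`;
#'   default 1000).
#' @return A tibble of copies: `copy_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `subfamily`, `family`, `class`, `n_fragments`, and
#'   a `fragments` list-column of per-fragment spans.
#' @export
merge_te_fragments <- function(rmsk, ltr_dict = NULL, max_gap = 1000) {
  stopifnot(max_gap >= 0)
  if (nrow(rmsk) == 0) return(empty_copies())
  rec <- arrange(rmsk, .data$chrom, .data$start, .data$end)

  copies <- vector("list", nrow(rec))
  n_copies <- 0L
  open <- list() # open copies on the current chromosome

  flush_copy <- function(cp) {
    n_copies <<- n_copies + 1L
    copies[[n_copies]] <<- cp
  }

  cur_chrom <- NULL
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    if (!identical(r$chrom, cur_chrom)) {
      for (cp in open) flush_copy(cp)
      open <- list()
      cur_chrom <- r$chrom
    }
    # Retire copies that can no longer accept anything (sorted input).
    if (length(open) > 0 && max_gap > 0) {
      still <- vapply(open, function(cp) r$start - cp$end < max_gap, logical(1))
      for (cp in open[!still]) flush_copy(cp)
      open <- open[still]
    } else if (max_gap == 0) {
      for (cp in open) flush_copy(cp)
      open <- list()
    }
    # Candidate copies: same strand, gap < max_gap, compatible names.
    cand <- which(vapply(open, function(cp) {
      cp$strand == r$strand && (r$start - cp$end) < max_gap &&
        name_compatible(r$rep_name, r$rmsk_id, cp$names, cp$ids, ltr_dict)
    }, logical(1)))
    if (length(cand) > 0) {
      # Nearest open compatible copy (largest end).
      j <- cand[which.max(vapply(open[cand], function(cp) cp$end, numeric(1)))]
      cp <- open[[j]]
      cp$end <- max(cp$end, r$end)
      cp$names <- c(cp$names, r$rep_name)
      cp$ids <- c(cp$ids, r$rmsk_id)
      cp$rows <- c(cp$rows, i)
      open[[j]] <- cp
    } else {
      open[[length(open) + 1]] <- list(
        chrom = r$chrom, start = r$start, end = r$end, strand = r$strand,
        names = r$rep_name, ids = r$rmsk_id, rows = i
      )
    }
  }
  for (cp in open) flush_copy(cp)
  copies <- copies[seq_len(n_copies)]

  internal_names <- if (!is.null(ltr_dict)) unique(ltr_dict$internal) else character()
  out <- purrr::map_dfr(copies, function(cp) {
    frag <- rec[cp$rows, ]
    # Representative: internal element name for LTR composites, else the
    # name covering the most bases.
    int_in <- intersect(unique(frag$rep_name), internal_names)
    if (length(int_in) > 0) {
      rep_row <- frag[frag$rep_name == int_in[1], ][1, ]
    } else {
      cover <- frag %>% group_by(.data$rep_name) %>%
        summarise(bp = sum(.data$end - .data$start)) %>%
        arrange(dplyr::desc(.data$bp))
      rep_row <- frag[frag$rep_name == cover$rep_name[1], ][1, ]
    }
    tibble(
      chrom = cp$chrom, start = cp$start, end = cp$end, strand = cp$strand,
      subfamily = rep_row$rep_name, family = rep_row$rep_family,
      class = rep_row$rep_class, n_fragments = nrow(frag),
      fragments = list(select(frag, "start", "end", "rep_name"))
    )
  })
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  out$copy_id <- sprintf("c%05d", seq_len(nrow(out)))
  select(out, "copy_id", "chrom", "start", "end", "strand", "subfamily",
         "family", "class", "n_fragments", "fragments")
}

empty_copies <- function() {
  tibble(
    copy_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), subfamily = character(),
    family = character(), class = character(), n_fragments = integer(),
    fragments = list()
  )
}

#' Write TE copies to BED6 or TSV
#'
#' BED6 uses 0-based half-open coordinates with
#' `name = subfamily|family|class|copy_id` and score 0. The TSV adds the
#' constituent fragment spans (`start-end:rep_name`, `;`-separated). Rows are
#' ordered by (chrom, start, copy_id).
#'
#' @param copies A copy table from [merge_te_fragments()].
#' @param path Output file.
#' @param format `"BED6"` or `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_te_features <- function(copies, path, format = c("BED6", "TSV")) {
  format <- match.arg(format)
  copies <- arrange(copies, .data$chrom, .data$start, .data$copy_id)
  if (format == "BED6") {
    lines <- sprintf("%s\t%d\t%d\t%s|%s|%s|%s\t0\t%s",
                     copies$chrom, copies$start, copies$end,
                     copies$subfamily, copies$family, copies$class,
                     copies$copy_id, copies$strand)
    readr::write_lines(lines, path)
  } else {
    frag_str <- vapply(copies$fragments, function(f) {
      paste(sprintf("%d-%d:%s", f$start, f$end, f$rep_name), collapse = ";")
    }, character(1))
    df <- copies %>%
      select("copy_id", "chrom", "start", "end", "strand", "subfamily",
             "family", "class", "n_fragments") %>%
      mutate(fragments = frag_str)
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Read TE copies back from files written by [write_te_features()]
#'
#' @param path A BED6 or TSV feature file.
#' @param format `"BED6"` or `"TSV"`.
#' @return A copy tibble in the same shape as [merge_te_fragments()] output
#'   (BED6 input yields single-span `fragments`).
#' @export
read_te_features <- function(path, format = c("BED6", "TSV")) {
  format <- match.arg(format)
  if (format == "BED6") {
    # Parse problems are diagnosed below (strand check); silence readr's own.
    df <- suppressWarnings(
      readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                          "score", "strand"),
                      col_types = "ciicic"))
    if (nrow(df) == 0) return(empty_copies())
    if (!all(df$strand %in% c("+", "-", "."))) {
      abort("Column 6 is not a BED strand; is this a TSV feature file?")
    }
    parts <- stringr::str_split_fixed(df$name, stringr::fixed("|"), 4)
    out <- tibble(
      copy_id = parts[, 4], chrom = df$chrom, start = df$start, end = df$end,
      strand = df$strand, subfamily = parts[, 1], family = parts[, 2],
      class = parts[, 3], n_fragments = 1L,
      fragments = purrr::pmap(list(df$start, df$end, parts[, 1]),
                              function(s, e, nm) tibble(start = s, end = e,
                                                        rep_name = nm))
    )
  } else {
    df <- readr::read_tsv(path, col_types = "cciiccccic")
    if (nrow(df) == 0) return(empty_copies())
    out <- df %>%
      mutate(fragments = purrr::map(.data$fragments, function(s) {
        pieces <- strsplit(s, ";", fixed = TRUE)[[1]]
        m <- stringr::str_match(pieces, "^(\\d+)-(\\d+):(.*)$")
        tibble(start = as.integer(m[, 2]), end = as.integer(m[, 3]),
               rep_name = m[, 4])
      }))
  }
  arrange(out, .data$chrom, .data$start, .data$copy_id)
}

#' Read a BED6 feature file of TE copies
#'
#' Convenience wrapper for `read_te_features(path, "BED6")`.
#' @inheritParams read_te_features
#' @export
read_te_bed <- function(path) read_te_features(path, "BED6")
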