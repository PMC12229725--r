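# Integration-site harmonization under the target-site-duplication model.
#
# Lentiviral integration duplicates 5 bp of host sequence, leaving one
# provirus-host junction at each end of the duplicated interval. Different
# laboratories report the same event as either junction, both junctions, or
# the bare coordinate range - in either order - which makes raw reports
# disagree by up to tsd_length - 1 bases. Canonicalizing every report to its
# duplication interval (1-based, inclusive) restores base-exact agreement.

normalize_site_string <- function(s) {
  s <- gsub("−|–|—", "-", s)     # unicode minus/dashes
  s <- gsub(",", "", s)                          # thousands separators
  s <- gsub("^[Cc][Hh][Rr]", "chr", trimws(s))
  s
}

#' Parse laboratory integration-site report strings
#'
#' Auto-detects the reporting dialect:
#' \describe{
#'   \item{junction_pair}{`chr1:45,634,495(+) - 45,634,499(-)` - both
#'     junctions with strands.}
#'   \item{bare_range}{`chr1:45,634,499-45,634,495` - two coordinates, no
#'     strands, either order.}
#'   \item{single_junction}{`chr1:45,634,495(+)` - one junction, one strand.}
#' }
#' Thousands separators, unicode minus signs and case variants of "chr" are
#' normalized. The literal `"not detected"` maps to an explicit empty report
#' (`detected = FALSE`).
#'
#' @param site_string Character vector of report strings.
#' @param sample,lab_id Optional vectors recycled against `site_string`.
#' @return A tibble with columns `sample`, `lab_id`, `site_string`,
#'   `detected`, `chrom`, `coord_a`, `strand_a`, `coord_b`, `strand_b`,
#'   `dialect`.
#' @examples
#' parse_site_report("chr1:45,634,495(+) - 45,634,499(−)")
#' @export
parse_site_report <- function(site_string, sample = NA_character_,
                              lab_id = NA_character_) {
  k <- length(site_string)
  sample <- rep_len(sample, k)
  lab_id <- rep_len(lab_id, k)
  norm <- normalize_site_string(site_string)

  re_pair <- "^(chr[0-9XYM]+):([0-9]+)\\s*\\(([+-])\\)\\s*-\\s*([0-9]+)\\s*\\(([+-])\\)$"
  re_range <- "^(chr[0-9XYM]+):\\s*([0-9]+)\\s*-\\s*([0-9]+)$"
  re_single <- "^(chr[0-9XYM]+):([0-9]+)\\s*\\(([+-])\\)$"

  one <- function(s, raw, smp, lab) {
    if (grepl("^not detected$", s, ignore.case = TRUE)) {
      return(tibble::tibble(sample = smp, lab_id = lab, site_string = raw,
                            detected = FALSE, chrom = NA_character_,
                            coord_a = NA_real_, strand_a = NA_character_,
                            coord_b = NA_real_, strand_b = NA_character_,
                            dialect = NA_character_))
    }
    if (grepl(re_pair, s)) {
      m <- stringr::str_match(s, re_pair)
      return(tibble::tibble(sample = smp, lab_id = lab, site_string = raw,
                            detected = TRUE, chrom = m[2],
                            coord_a = as.numeric(m[3]), strand_a = m[4],
                            coord_b = as.numeric(m[5]), strand_b = m[6],
                            dialect = "junction_pair"))
    }
    if (grepl(re_range, s)) {
      m <- stringr::str_match(s, re_range)
      return(tibble::tibble(sample = smp, lab_id = lab, site_string = raw,
                            detected = TRUE, chrom = m[2],
                            coord_a = as.numeric(m[3]), strand_a = NA_character_,
                            coord_b = as.numeric(m[4]), strand_b = NA_character_,
                            dialect = "bare_range"))
    }
    if (grepl(re_single, s)) {
      m <- stringr::str_match(s, re_single)
      return(tibble::tibble(sample = smp, lab_id = lab, site_string = raw,
                            detected = TRUE, chrom = m[2],
                            coord_a = as.numeric(m[3]), strand_a = m[4],
                            coord_b = NA_real_, strand_b = NA_character_,
                            dialect = "single_junction"))
    }
    stop_vcnref(paste0("unparseable integration-site report: '", raw, "'"),
                "vcnref_format_error")
  }
  out <- purrr::pmap(list(norm, site_string, sample, lab_id), one)
  dplyr::bind_rows(out)
}

#' Canonicalize reports to target-site-duplication intervals
#'
#' Maps every detected report onto its duplication interval. Two-coordinate
#' dialects span `min(coords)` to `max(coords)`; the implied length is
#' validated against `tsd_length` and mismatches are flagged (not fatal) in
#' `length_mismatch`. A single plus-strand junction marks the interval start
#' (`[coord, coord + tsd_length - 1]`); a single minus-strand junction marks
#' its end (`[coord - tsd_length + 1, coord]`).
#'
#' @param reports Output of [parse_site_report()].
#' @param tsd_length Duplication length in bp (default 5, the lentiviral
#'   integrase signature).
#' @return A tibble with `sample`, `lab_id`, `chrom`, `tsd_start`, `tsd_end`,
#'   `tsd_length`, `plus_junction`, `minus_junction`, `length_mismatch`.
#'   Undetected reports are dropped.
#' @export
canonicalize_sites <- function(reports, tsd_length = 5) {
  check_columns(reports, c("detected", "chrom", "coord_a", "coord_b",
                           "strand_a", "dialect"), "parsed reports")
  if (tsd_length < 1) {
    stop_vcnref("tsd_length must be at least 1", "vcnref_schema_error")
  }
  r <- dplyr::filter(reports, .data$detected)
  if (nrow(r) == 0) {
    return(tibble::tibble(sample = character(), lab_id = character(),
                          chrom = character(), tsd_start = numeric(),
                          tsd_end = numeric(), tsd_length = numeric(),
                          plus_junction = numeric(), minus_junction = numeric(),
                          length_mismatch = logical()))
  }
  two <- r$dialect %in% c("junction_pair", "bare_range")
  start <- ifelse(two, pmin(r$coord_a, r$coord_b),
                  ifelse(r$strand_a == "+", r$coord_a,
                         r$coord_a - tsd_length + 1))
  end <- ifelse(two, pmax(r$coord_a, r$coord_b),
                ifelse(r$strand_a == "+", r$coord_a + tsd_length - 1,
                       r$coord_a))
  mismatch <- two & (end - start + 1 != tsd_length)
  if (any(mismatch)) {
    warn(paste0(sum(mismatch), " two-coordinate report(s) imply a duplication",
                " length other than ", tsd_length, " bp (flagged)"))
  }
  tibble::tibble(
    sample = r$sample, lab_id = r$lab_id, chrom = r$chrom,
    tsd_start = start, tsd_end = end, tsd_length = end - start + 1,
    plus_junction = start, minus_junction = end,
    length_mismatch = mismatch
  )
}

#' Cross-laboratory integration-site consensus
#'
#' Groups canonicalized sites per sample by chromosome and start coordinate
#' (single-linkage chaining within `tolerance_bp`). A group is a consensus
#' site when it is supported by at least `min_support` distinct laboratories.
#' Groups whose members disagree in coordinates carry per-lab offsets in the
#' `discrepancies` list-column.
#'
#' @param canonical Output of [canonicalize_sites()].
#' @param tolerance_bp Maximum start-coordinate gap chained into one group
#'   (default 0: base-exact agreement).
#' @param min_support Labs required for consensus; default: all labs present
#'   in `canonical`.
#' @return A tibble with `sample`, `chrom`, `tsd_start`, `tsd_end`,
#'   `support`, `n_reports`, `spread_bp`, `consensus`, `discrepancies`.
#' @examples
#' panel <- fixture_panel()
#' cons <- parse_site_report(panel$reports$site_string, panel$reports$sample,
#'                           panel$reports$lab_id) |>
#'   canonicalize_sites() |>
#'   build_site_consensus()
#' sum(cons$consensus)
#' @export
build_site_consensus <- function(canonical, tolerance_bp = 0,
                                 min_support = NULL) {
  if (nrow(canonical) == 0) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          tsd_start = numeric(), tsd_end = numeric(),
                          support = integer(), n_reports = integer(),
                          spread_bp = numeric(), consensus = logical(),
                          discrepancies = list()))
  }
  if (is.null(min_support)) {
    min_support <- length(unique(canonical$lab_id))
  }
  canonical |>
    dplyr::arrange(.data$sample, .data$chrom, .data$tsd_start) |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::mutate(
      gap = .data$tsd_start - dplyr::lag(.data$tsd_start,
                                         default = -Inf),
      group = cumsum(.data$gap > tolerance_bp)
    ) |>
    dplyr::group_by(.data$sample, .data$chrom, .data$group) |>
    dplyr::summarise(
      support = length(unique(.data$lab_id)),
      n_reports = dplyr::n(),
      spread_bp = (max(.data$tsd_start) - min(.data$tsd_start)) +
        (max(.data$tsd_end) - min(.data$tsd_end)),
      discrepancies = list({
        if ((max(.data$tsd_start) > min(.data$tsd_start)) ||
            (max(.data$tsd_end) > min(.data$tsd_end))) {
          ids <- .data$lab_id
          so <- .data$tsd_start - round(median(.data$tsd_start))
          eo <- .data$tsd_end - round(median(.data$tsd_end))
          tibble::tibble(lab_id = ids, start_offset = so, end_offset = eo)
        } else NULL
      }),
      tsd_start = round(median(.data$tsd_start)),
      tsd_end = round(median(.data$tsd_end)),
      .groups = "drop"
    ) |>
    dplyr::relocate("tsd_start", "tsd_end", .after = "chrom") |>
    dplyr::mutate(consensus = .data$support >= min_support) |>
    dplyr::select(-"group") |>
    dplyr::arrange(.data$sample, .data$chrom, .data$tsd_start)
}

#' Compare consensus sites to a prior reference list
#'
#' Greedy per-sample pairing of reference positions against consensus
#' intervals: first exact matches of a reference position to either junction
#' (`exact`, offset 0); then nearest same-chromosome matches (`offset`, with
#' the minimum distance to either junction in bp); remaining pairs on
#' different chromosomes are `chrom_mismatch`; anything left unpaired is
#' `unmatched`.
#'
#' @param consensus Consensus tibble (rows with `consensus = TRUE` are used
#'   if the column is present).
#' @param reference Data frame with columns `sample`, `chrom`, `position`
#'   (1-based).
#' @return A tibble with one row per reference site: `sample`, `ref_chrom`,
#'   `ref_position`, `category`, `offset_bp`, `match_chrom`, `match_start`,
#'   `match_end`.
#' @export
compare_to_reference <- function(consensus, reference) {
  check_columns(reference, c("sample", "chrom", "position"), "reference list")
  if ("consensus" %in% names(consensus)) {
    consensus <- dplyr::filter(consensus, .data$consensus)
  }
  out <- list()
  for (smp in unique(reference$sample)) {
    refs <- reference[reference$sample == smp, , drop = FALSE]
    cons <- consensus[consensus$sample == smp, , drop = FALSE]
    used <- rep(FALSE, nrow(cons))
    res <- tibble::tibble(
      sample = refs$sample, ref_chrom = refs$chrom,
      ref_position = refs$position,
      category = NA_character_, offset_bp = NA_real_,
      match_chrom = NA_character_, match_start = NA_real_,
      match_end = NA_real_
    )
    dist_to <- function(pos, i) {
      min(abs(pos - cons$tsd_start[i]), abs(pos - cons$tsd_end[i]))
    }
    # pass 1: exact junction matches
    for (j in seq_len(nrow(refs))) {
      hit <- which(!used & cons$chrom == refs$chrom[j] &
                     (cons$tsd_start == refs$position[j] |
                        cons$tsd_end == refs$position[j]))
      if (length(hit) > 0) {
        i <- hit[1]
        used[i] <- TRUE
        res$category[j] <- "exact"
        res$offset_bp[j] <- 0
        res$match_chrom[j] <- cons$chrom[i]
        res$match_start[j] <- cons$tsd_start[i]
        res$match_end[j] <- cons$tsd_end[i]
      }
    }
    # pass 2: nearest same-chromosome matches, globally smallest first
    repeat {
      open_r <- which(is.na(res$category))
      cand <- expand.grid(j = open_r, i = which(!used))
      if (nrow(cand) == 0) break
      cand <- cand[cons$chrom[cand$i] == res$ref_chrom[cand$j], , drop = FALSE]
      if (nrow(cand) == 0) break
      cand$d <- mapply(function(j, i) dist_to(res$ref_position[j], i),
                       cand$j, cand$i)
      b <- cand[which.min(cand$d), ]
      used[b$i] <- TRUE
      res$category[b$j] <- "offset"
      res$offset_bp[b$j] <- b$d
      res$match_chrom[b$j] <- cons$chrom[b$i]
      res$match_start[b$j] <- cons$tsd_start[b$i]
      res$match_end[b$j] <- cons$tsd_end[b$i]
    }
    # pass 3: leftovers pair across chromosomes
    open_r <- which(is.na(res$category))
    open_c <- which(!used)
    n_pair <- min(length(open_r), length(open_c))
    if (n_pair > 0) {
      for (k in seq_len(n_pair)) {
        j <- open_r[k]; i <- open_c[k]
        used[i] <- TRUE
        res$category[j] <- "chrom_mismatch"
        res$match_chrom[j] <- cons$chrom[i]
        res$match_start[j] <- cons$tsd_start[i]
        res$match_end[j] <- cons$tsd_end[i]
      }
    }
    res$category[is.na(res$category)] <- "unmatched"
    out[[smp]] <- res
  }
  dplyr::bind_rows(out)
}

#' Expected structural-variant insertion length for an integrated provirus
#'
#' A long-read insertion call spanning an integration event measures the
#' provirus length plus any extra inserted bases, and - when the caller
#' includes the duplicated host sequence in the insertion - the
#' target-site-duplication length as well.
#'
#' @param provirus_length Expected provirus sequence length in bp.
#' @param extra_inserted_bases Signed count of additional bases observed in
#'   the integrated copy (default 0).
#' @param tsd_length Duplication length (default 5).
#' @param include_tsd Whether the caller's insertion length includes the
#'   duplicated host bases.
#' @return Length in bp (vectorized).
#' @examples
#' expected_insertion_length(4154, 1, include_tsd = TRUE)   # 4160
#' expected_insertion_length(4154, 1, include_tsd = FALSE)  # 4155
#' @export
expected_insertion_length <- function(provirus_length,
                                      extra_inserted_bases = 0,
                                      tsd_length = 5, include_tsd = FALSE) {
  if (any(provirus_length <= 0)) {
    stop_vcnref("provirus_length must be positive", "vcnref_schema_error")
  }
  provirus_length + extra_inserted_bases +
    ifelse(include_tsd, tsd_length, 0)
}

#' Annotate consensus sites against labeled genomic intervals
#'
#' Labels each site by the interval containing its plus junction. Intervals
#' are 1-based half-open `[start, end)`. When several intervals contain the
#' junction the label is chosen by the precedence exon > UTR > intron
#' (then first occurrence); sites in no interval are `"intergenic"`.
#'
#' @param sites Tibble with `chrom` and `tsd_start` (the plus junction).
#' @param annotation Data frame with `chrom`, `start`, `end`, `gene`,
#'   `region`.
#' @return `sites` with appended `gene` and `region` columns.
#' @export
annotate_sites <- function(sites, annotation) {
  check_columns(annotation, c("chrom", "start", "end", "gene", "region"),
                "annotation")
  precedence <- function(region) {
    r <- tolower(region)
    ifelse(grepl("exon", r), 1L, ifelse(grepl("utr", r), 2L,
           ifelse(grepl("intron", r), 3L, 4L)))
  }
  pick <- function(chrom, pos) {
    hit <- annotation[annotation$chrom == chrom &
                        annotation$start <= pos & pos < annotation$end, ,
                      drop = FALSE]
    if (nrow(hit) == 0) {
      return(tibble::tibble(gene = NA_character_, region = "intergenic"))
    }
    if (nrow(hit) > 1) {
      hit <- hit[order(precedence(hit$region)), , drop = FALSE]
      inform(paste0("overlapping annotations at ", chrom, ":", pos,
                    "; using '", hit$region[1], "' by precedence"))
    }
    tibble::tibble(gene = hit$gene[1], region = hit$region[1])
  }
  lab <- purrr::map2(sites$chrom, sites$tsd_start, pick)
  dplyr::bind_cols(sites, dplyr::bind_rows(lab))
}

#' Write consensus sites as BED6
#'
#' Converts the 1-based inclusive duplication intervals to the 0-based
#' half-open BED convention (`start - 1`, `end`). The name field is
#' `sample:index`, score 0, strand `"+"` (the duplication interval is
#' strand-symmetric; junction strands are a reporting convention, not a
#' property of the interval).
#'
#' @param sites Tibble with `sample`, `chrom`, `tsd_start`, `tsd_end`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  header <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (nrow(sites) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  name <- paste0(sites$sample, ":", stats::ave(seq_len(nrow(sites)),
                                               sites$sample, FUN = seq_along))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t+", sites$chrom,
                   as.integer(sites$tsd_start - 1), as.integer(sites$tsd_end),
                   name)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED file of duplication intervals back to 1-based coordinates
#'
#' Inverse of [write_sites_bed()].
#'
#' @param path BED file path.
#' @return A tibble with `sample`, `chrom`, `tsd_start`, `tsd_end` (1-based
#'   inclusive).
#' @export
read_sites_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          tsd_start = numeric(), tsd_end = numeric()))
  }
  f <- strsplit(lines, "\t")
  tibble::tibble(
    sample = sub(":.*$", "", vapply(f, `[`, "", 4)),
    chrom = vapply(f, `[`, "", 1),
    tsd_start = as.numeric(vapply(f, `[`, "", 2)) + 1,
    tsd_end = as.numeric(vapply(f, `[`, "", 3))
  )
}
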