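#' Mixing configuration
#'
#' @param indel_threshold Event-length threshold in bp (default 50).
#'   Substitution or indel events *strictly below* the threshold are
#'   corrected; events at or above it are left untouched.
#' @param skip_n Skip edits whose replacement sequence, or whose immediate
#'   (+/- 1 bp) SLR query context, contains `N` (default `TRUE`).
#' @param min_region_len Minimum target span (bp) for a resolved region to
#'   be re-aligned.
#' @return A list of class `mix_config`.
#' @export
mix_config <- function(indel_threshold = 50L, skip_n = TRUE,
                       min_region_len = 1L) {
  stopifnot(indel_threshold >= 1, min_region_len >= 1)
  structure(list(indel_threshold = as.integer(indel_threshold),
                 skip_n = isTRUE(skip_n),
                 min_region_len = as.integer(min_region_len)),
            class = "mix_config")
}

#' Target regions from a screening result
#'
#' Selected blocks become target regions, grouped by TGS contig and sorted
#' by target start (ties: longer region first).
#'
#' @param screen An `hb_screen` object, or a block tibble with a `status`
#'   column.
#' @return A region tibble sorted within contig.
#' @export
regions_from_screen <- function(screen) {
  blocks <- if (inherits(screen, "hb_screen")) screen$blocks else screen
  blocks |>
    dplyr::filter(.data$status == "selected") |>
    dplyr::select("tname", "tstart", "tend", "qname", "qstart", "qend",
                  "strand") |>
    cluster_regions()
}

#' Cluster regions by target contig and sort
#'
#' @param regions A region tibble (`tname`, `tstart`, `tend`, `qname`,
#'   `qstart`, `qend`, `strand`).
#' @return The same tibble sorted by contig, target start, then longer
#'   region first.
#' @export
cluster_regions <- function(regions) {
  regions |>
    dplyr::arrange(.data$tname, .data$tstart,
                   -(.data$tend - .data$tstart))
}

#' Resolve overlapping target regions
#'
#' Within each contig, sorted regions are made pairwise disjoint: a region
#' entirely contained in its predecessor is discarded; on partial overlap
#' the *later* region has priority and the earlier one is truncated at the
#' later region's start, its query interval shortened proportionally.
#'
#' @param regions A sorted region tibble (see [cluster_regions()]).
#' @return A disjoint, sorted region tibble.
#' @export
resolve_overlaps <- function(regions) {
  parts <- lapply(split(regions, regions$tname), resolve_overlaps_one)
  out <- dplyr::bind_rows(parts)
  if (nrow(out)) out <- dplyr::arrange(out, .data$tname, .data$tstart)
  out
}

resolve_overlaps_one <- function(regions) {
  regions <- dplyr::arrange(regions, .data$tstart,
                            -(.data$tend - .data$tstart))
  acc <- list()
  for (i in seq_len(nrow(regions))) {
    nxt <- regions[i, ]
    if (length(acc) == 0) { acc[[1]] <- nxt; next }
    prev <- acc[[length(acc)]]
    if (nxt$tstart >= prev$tstart && nxt$tend <= prev$tend) next  # rule (a)
    if (nxt$tstart < prev$tend) {                                  # rule (b)
      prev <- truncate_region_end(prev, nxt$tstart)
      if (is.null(prev)) acc[[length(acc)]] <- NULL
      else acc[[length(acc)]] <- prev
    }
    acc[[length(acc) + 1]] <- nxt
  }
  dplyr::bind_rows(acc)
}

# truncate a region's target end to `at`, shortening the query interval
# proportionally (strand-aware); NULL when nothing remains
truncate_region_end <- function(region, at) {
  cut <- region$tend - at
  tspan <- region$tend - region$tstart
  if (cut >= tspan) return(NULL)
  qspan <- region$qend - region$qstart
  qcut <- as.integer(round(cut * qspan / tspan))
  region$tend <- at
  if (region$strand == "+") region$qend <- region$qend - qcut
  else region$qstart <- region$qstart + qcut
  if (region$qend <= region$qstart) return(NULL)
  region
}

#' Extract edits from a base-level alignment of one region
#'
#' Aligns the SLR query segment (reverse-complemented first on `-` strand
#' regions, so all edits live in forward target coordinates) against the
#' TGS target segment and converts the resulting cs operations into edits
#' at absolute target positions.
#'
#' @param tgs_segment Target (TGS) segment sequence.
#' @param slr_segment Query (SLR) segment, already oriented to the target.
#' @param target_offset 0-based position of the segment start on the contig.
#' @param tname Contig name recorded on the edits.
#' @param ... Passed to [align_segments()].
#' @return An edit tibble (see [filter_edits()]).
#' @export
edits_from_alignment <- function(tgs_segment, slr_segment, target_offset = 0L,
                                 tname = "contig", ...) {
  aln <- align_segments(tgs_segment, slr_segment, ...)
  edits_from_cs(aln$cs, target_offset, tname, slr_segment)
}

#' Convert cs operations into absolute-coordinate edits
#'
#' @param cs A cs string over (target segment, query segment).
#' @param target_offset 0-based offset of the target segment on its contig.
#' @param tname Contig name.
#' @param query_seg The query segment (used for the N-context rule).
#' @return A tibble with columns `tname`, `pos` (0-based target position),
#'   `kind`, `ref` (target bases removed), `alt` (query bases inserted),
#'   `length` (event length, `max(|ref|, |alt|)`) and `near_n` (query
#'   context within +/- 1 bp of the event contains `N`).
#' @export
edits_from_cs <- function(cs, target_offset = 0L, tname = "contig",
                          query_seg = "") {
  ops <- parse_cs(cs)
  if (nrow(ops) == 0) return(empty_edits())
  t_consumed <- ifelse(ops$kind %in% c("match", "substitution", "deletion"),
                       ops$length, 0L)
  q_consumed <- ifelse(ops$kind %in% c("match", "substitution", "insertion"),
                       ops$length, 0L)
  tpos <- cumsum(c(0L, head(t_consumed, -1)))
  qpos <- cumsum(c(0L, head(q_consumed, -1)))
  ev <- ops$kind != "match"
  if (!any(ev)) return(empty_edits())
  qlo <- pmax(qpos[ev] - 1L, 0L)
  qhi <- pmin(qpos[ev] + q_consumed[ev] + 1L, nchar(query_seg))
  context <- substring(query_seg, qlo + 1L, qhi)
  tibble::tibble(
    tname = tname,
    pos = target_offset + tpos[ev],
    kind = ops$kind[ev],
    ref = ops$ref_seq[ev],
    alt = ops$alt_seq[ev],
    length = pmax(nchar(ops$ref_seq[ev]), nchar(ops$alt_seq[ev])),
    near_n = grepl("N", context, fixed = TRUE))
}

empty_edits <- function() {
  tibble::tibble(tname = character(), pos = integer(), kind = character(),
                 ref = character(), alt = character(), length = integer(),
                 near_n = logical())
}

#' Filter edits by the length threshold and N rule
#'
#' An edit whose replacement sequence contains `N`, or whose SLR query
#' context within +/- 1 bp contains `N`, is skipped regardless of length.
#' Remaining events strictly below the threshold are applied; events at or
#' above it are skipped as putative structural differences.
#'
#' @param edits An edit tibble from [edits_from_cs()].
#' @param cfg A [mix_config()].
#' @return The edit tibble with a `status` column (`applied`,
#'   `skipped_threshold`, `skipped_N`).
#' @export
filter_edits <- function(edits, cfg = mix_config()) {
  if (nrow(edits) == 0) return(dplyr::mutate(edits, status = character()))
  near_n <- if (is.null(edits$near_n)) rep(FALSE, nrow(edits)) else edits$near_n
  n_hit <- cfg$skip_n & (grepl("N", edits$alt, fixed = TRUE) | near_n)
  edits |>
    dplyr::mutate(status = dplyr::case_when(
      n_hit ~ "skipped_N",
      .data$length >= cfg$indel_threshold ~ "skipped_threshold",
      TRUE ~ "applied"))
}

#' Apply edits to a contig sequence
#'
#' Edits must be pairwise non-overlapping on their reference footprints
#' `[pos, pos + nchar(ref))`; they are applied with stable coordinate
#' offsetting so positions always refer to the *input* sequence.
#'
#' @param seq A contig sequence.
#' @param edits An edit tibble restricted to the edits to apply.
#' @return The corrected sequence.
#' @export
apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  edits <- dplyr::arrange(edits, .data$pos, .data$pos + nchar(.data$ref))
  ref_end <- edits$pos + nchar(edits$ref)
  if (any(edits$pos[-1] < head(ref_end, -1)))
    stop("apply_edits: overlapping edit footprints", call. = FALSE)
  if (tail(ref_end, 1) > nchar(seq))
    stop("apply_edits: edit beyond sequence end", call. = FALSE)
  keep_start <- c(0L, ref_end)
  keep_end <- c(edits$pos, nchar(seq))
  kept <- substring(seq, keep_start + 1L, keep_end)
  n <- length(kept)
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- kept
  pieces[seq(2L, 2L * n - 2L, by = 2L)] <- edits$alt
  paste(pieces, collapse = "")
}

#' Blend an SLR haplotype assembly into a TGS assembly
#'
#' Runs the full correction pipeline for one haplotype: whole-assembly
#' alignment (built-in anchored aligner unless a PAF is supplied), chaining
#' screen, per-contig region clustering and overlap resolution, base-level
#' re-alignment of each region, edit filtering by the length threshold and
#' N rule, and sequence replacement. Contigs without any selected block
#' pass through unchanged, so the output contig count equals the input one.
#'
#' @param tgs TGS assembly tibble ([read_fasta()] shape) - the contiguous,
#'   error-prone backbone being corrected.
#' @param slr One SLR haplotype assembly tibble - accurate, fragmented, may
#'   contain `N` runs.
#' @param paf Optional pre-computed whole-assembly PAF tibble (query = SLR,
#'   target = TGS). When `NULL`, [align_assemblies()] is used.
#' @param chain_cfg A [chain_config()].
#' @param mix_cfg A [mix_config()].
#' @param ... Passed to [align_segments()] / [align_assemblies()].
#' @return An object of class `hb_mix`: list with `assembly` (corrected
#'   contigs), `edits` (all edits with status), `report` (per-contig and
#'   global counts), and `screen` (the `hb_screen` object).
#' @export
mix_assemblies <- function(tgs, slr, paf = NULL,
                           chain_cfg = chain_config(),
                           mix_cfg = mix_config(), ...) {
  validate_fasta(tgs)
  validate_fasta(slr)
  if (is.null(paf)) {
    paf <- align_assemblies(slr, tgs, ...)
  } else {
    if (!all(paf$tname %in% tgs$name) || !all(paf$qname %in% slr$name))
      stop("PAF sequence names do not match the supplied assemblies",
           call. = FALSE)
  }
  screen <- screen_alignments(paf, chain_cfg)
  regions <- regions_from_screen(screen) |> resolve_overlaps()
  regions <- regions[regions$tend - regions$tstart >= mix_cfg$min_region_len, ]
  slr_seq <- setNames(slr$seq, slr$name)
  tgs_seq <- setNames(tgs$seq, tgs$name)
  edit_parts <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    tseg <- substr(tgs_seq[[r$tname]], r$tstart + 1L, r$tend)
    qseg <- substr(slr_seq[[r$qname]], r$qstart + 1L, r$qend)
    if (r$strand == "-") qseg <- revcomp(qseg)
    edits_from_alignment(tseg, qseg, target_offset = r$tstart,
                         tname = r$tname, ...)
  })
  edits <- dplyr::bind_rows(edit_parts)
  if (nrow(edits) == 0) edits <- empty_edits()
  edits <- filter_edits(edits, mix_cfg)
  corrected <- tgs
  for (contig in unique(edits$tname[edits$status == "applied"])) {
    idx <- which(corrected$name == contig)
    contig_edits <- edits[edits$tname == contig & edits$status == "applied", ]
    corrected$seq[idx] <- apply_edits(corrected$seq[idx], contig_edits)
  }
  report <- mix_report(tgs, corrected, edits)
  structure(list(assembly = corrected, edits = edits, report = report,
                 screen = screen, mix_cfg = mix_cfg),
            class = "hb_mix")
}

mix_report <- function(tgs, corrected, edits) {
  per_contig <- tibble::tibble(tname = tgs$name,
                               input_len = nchar(tgs$seq),
                               output_len = nchar(corrected$seq)) |>
    dplyr::left_join(
      edits |>
        dplyr::summarise(
          considered = dplyr::n(),
          applied = sum(.data$status == "applied"),
          skipped_threshold = sum(.data$status == "skipped_threshold"),
          skipped_N = sum(.data$status == "skipped_N"),
          bases_removed = sum(nchar(.data$ref[.data$status == "applied"])),
          bases_inserted = sum(nchar(.data$alt[.data$status == "applied"])),
          .by = "tname"),
      by = "tname") |>
    dplyr::mutate(dplyr::across(
      c("considered", "applied", "skipped_threshold", "skipped_N",
        "bases_removed", "bases_inserted"),
      ~ tidyr::replace_na(., 0)),
      net_length_change = .data$output_len - .data$input_len)
  global <- list(
    considered = sum(per_contig$considered),
    applied = sum(per_contig$applied),
    skipped_threshold = sum(per_contig$skipped_threshold),
    skipped_N = sum(per_contig$skipped_N),
    bases_removed = sum(per_contig$bases_removed),
    bases_inserted = sum(per_contig$bases_inserted),
    net_length_change = sum(per_contig$net_length_change))
  list(per_contig = per_contig, global = global)
}

#' @export
print.hb_mix <- function(x, ...) {
  g <- x$report$global
  cat("<hb_mix> ", nrow(x$assembly), " contig(s); edits considered ",
      g$considered, ": applied ", g$applied, ", skipped (length) ",
      g$skipped_threshold, ", skipped (N) ", g$skipped_N,
      "; net length change ", g$net_length_change, " bp\n", sep = "")
  invisible(x)
}
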