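#' Chaining configuration
#'
#' Parameters of the alignment-block chaining dynamic program. A pair of
#' blocks mapped to different target contigs or strands, or whose target
#' overlap exceeds `max_target_overlap_ratio` times the shorter block's
#' target span, receives `incompatible_penalty`, a sentinel so negative that
#' no realistic chain can absorb it.
#'
#' @param incompatible_penalty Sentinel penalty for incompatible block pairs.
#' @param max_target_overlap_ratio Maximum tolerated target-overlap fraction
#'   of the shorter block's target span (default 0.8).
#' @param min_block_len Minimum query span (bp) for a PAF record to become a
#'   block.
#' @param penalty_form `"gap_difference"` scores disjoint target intervals as
#'   `-|g_q - g_t|` and overlapping ones as `-(g_q + o_t)`;
#'   `"gap_sum"` scores every compatible pair as `-(g_q + g_t + overlap)`.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(incompatible_penalty = -1e9,
                         max_target_overlap_ratio = 0.8,
                         min_block_len = 0L,
                         penalty_form = c("gap_difference", "gap_sum")) {
  stopifnot(max_target_overlap_ratio > 0, max_target_overlap_ratio <= 1,
            incompatible_penalty < 0, min_block_len >= 0)
  structure(list(incompatible_penalty = incompatible_penalty,
                 max_target_overlap_ratio = max_target_overlap_ratio,
                 min_block_len = as.integer(min_block_len),
                 penalty_form = match.arg(penalty_form)),
            class = "chain_config")
}

#' Convert PAF records to alignment blocks
#'
#' Each PAF record becomes one alignment block; `qspan` (the block length
#' used by the chain score) is the aligned query interval length.
#'
#' @param paf A PAF tibble.
#' @param cfg A [chain_config()].
#' @return A tibble of blocks with a `block_id` key.
#' @export
blocks_from_paf <- function(paf, cfg = chain_config()) {
  blocks <- paf |>
    dplyr::transmute(
      qname = .data$qname, qstart = .data$qstart, qend = .data$qend,
      tname = .data$tname, tstart = .data$tstart, tend = .data$tend,
      strand = .data$strand, qspan = .data$qend - .data$qstart,
      paf_row = dplyr::row_number()) |>
    dplyr::filter(.data$qspan >= cfg$min_block_len) |>
    dplyr::mutate(block_id = dplyr::row_number(), .before = 1)
  blocks
}

#' Penalty for chaining two alignment blocks
#'
#' Blocks must come from the same query scaffold and be given in query
#' order. Incompatible pairs (different target contig, different strand, or
#' target overlap beyond the configured ratio of the shorter target span)
#' receive the sentinel penalty. Otherwise, with `g_q`/`g_t` the query and
#' target gaps (clamped at zero) and `ov` the target (plus any query)
#' overlap: disjoint pairs score `-|g_q - g_t|`, overlapping pairs
#' `-(g_q + g_t + ov)` under the default `"gap_difference"` form.
#'
#' @param prev,nxt Single blocks (one-row data frames or named lists) with
#'   fields `qname`, `qstart`, `qend`, `tname`, `tstart`, `tend`, `strand`.
#' @param cfg A [chain_config()].
#' @return A single non-positive penalty (bp).
#' @export
pair_penalty <- function(prev, nxt, cfg = chain_config()) {
  if (prev$qname != nxt$qname)
    stop("pair_penalty: blocks from different query scaffolds", call. = FALSE)
  if (prev$qstart > nxt$qstart)
    stop("pair_penalty: blocks not in query order", call. = FALSE)
  if (prev$tname != nxt$tname || prev$strand != nxt$strand)
    return(cfg$incompatible_penalty)
  span1 <- prev$tend - prev$tstart
  span2 <- nxt$tend - nxt$tstart
  o_geo <- max(0, min(prev$tend, nxt$tend) - max(prev$tstart, nxt$tstart))
  if (o_geo > cfg$max_target_overlap_ratio * min(span1, span2))
    return(cfg$incompatible_penalty)
  g_t_raw <- if (prev$strand == "+") nxt$tstart - prev$tend
             else prev$tstart - nxt$tend
  g_q_raw <- nxt$qstart - prev$qend
  g_q <- max(0, g_q_raw)
  g_t <- max(0, g_t_raw)
  ov <- max(0, -g_t_raw) + max(0, -g_q_raw)
  if (cfg$penalty_form == "gap_sum") return(-(g_q + g_t + ov))
  if (ov == 0) -abs(g_q - g_t) else -(g_q + g_t + ov)
}

#' Maximum-score chain over blocks of one scaffold
#'
#' Dynamic program over blocks sorted by query start (ties: target start,
#' then longer query span first): `s_i = len(b_i) + max(0, max_j (s_j +
#' p(b_j, b_i)))`. The chain is recovered by trace-back from the highest
#' `s_i`; the `max(0, .)` term lets a chain restart, so the returned chain
#' never crosses an incompatible pair.
#'
#' @param blocks A block tibble for a single scaffold (see
#'   [blocks_from_paf()]); a single strand is expected for the two-round
#'   screening but mixed strands are handled via the sentinel.
#' @param cfg A [chain_config()].
#' @return A list with `block_ids` (selected blocks in chain order), `score`
#'   and `strand` (of the selected blocks, `NA` for an empty chain).
#' @export
chain_blocks <- function(blocks, cfg = chain_config()) {
  if (nrow(blocks) == 0)
    return(list(block_ids = integer(), score = 0, strand = NA_character_))
  if (length(unique(blocks$qname)) != 1)
    stop("chain_blocks expects blocks from a single scaffold", call. = FALSE)
  ord <- order(blocks$qstart, blocks$tstart, -blocks$qspan)
  b <- blocks[ord, ]
  n <- nrow(b)
  rows <- lapply(seq_len(n), function(i) as.list(b[i, ]))
  s <- numeric(n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    best <- 0
    best_j <- 0L
    if (i > 1) for (j in seq_len(i - 1)) {
      cand <- s[j] + pair_penalty(rows[[j]], rows[[i]], cfg)
      if (cand > best) { best <- cand; best_j <- j }
    }
    s[i] <- b$qspan[i] + best
    pred[i] <- best_j
  }
  end <- which.max(s)
  sel <- integer()
  i <- end
  while (i != 0L) { sel <- c(i, sel); i <- pred[i] }
  list(block_ids = b$block_id[sel], score = s[end], strand = b$strand[sel[1]])
}

#' Screen whole-assembly alignments into per-scaffold chains
#'
#' For each SLR scaffold the chaining dynamic program is run twice, once
#' over its forward-strand blocks and once over its reverse-strand blocks;
#' the higher-scoring chain wins (ties favour the forward strand). Blocks
#' outside the winning chain are discarded, and discarded blocks mapped to a
#' different target contig or strand than the winning chain are additionally
#' flagged for downstream examination.
#'
#' @param paf A PAF tibble of whole-assembly alignments.
#' @param cfg A [chain_config()].
#' @return An object of class `hb_screen`: a list with `blocks` (all blocks
#'   with a `status` of `selected`/`discarded`/`flagged` and the winning
#'   `chain_score` of their scaffold) and `chains` (one row per scaffold).
#' @export
screen_alignments <- function(paf, cfg = chain_config()) {
  if (nrow(paf) == 0) {
    warning("empty PAF input: nothing to screen")
    blocks <- blocks_from_paf(empty_paf(), cfg) |>
      dplyr::mutate(status = character(), chain_score = numeric())
    return(structure(list(blocks = blocks,
                          chains = tibble::tibble(
                            qname = character(), strand = character(),
                            tname = character(), score = numeric(),
                            n_selected = integer(), n_flagged = integer())),
                     class = "hb_screen"))
  }
  blocks <- blocks_from_paf(paf, cfg)
  per_scaffold <- lapply(split(blocks, blocks$qname), function(bl) {
    ch_plus <- chain_blocks(bl[bl$strand == "+", ], cfg)
    ch_minus <- chain_blocks(bl[bl$strand == "-", ], cfg)
    ch <- if (ch_minus$score > ch_plus$score) ch_minus else ch_plus
    sel <- bl$block_id %in% ch$block_ids
    chain_tname <- if (any(sel)) bl$tname[sel][1] else NA_character_
    chain_strand <- if (any(sel)) bl$strand[sel][1] else NA_character_
    bl$status <- dplyr::case_when(
      sel ~ "selected",
      bl$tname != chain_tname | bl$strand != chain_strand ~ "flagged",
      TRUE ~ "discarded")
    bl$chain_score <- ch$score
    list(blocks = bl,
         chain = tibble::tibble(
           qname = bl$qname[1], strand = chain_strand, tname = chain_tname,
           score = ch$score, n_selected = sum(sel),
           n_flagged = sum(bl$status == "flagged")))
  })
  out_blocks <- dplyr::bind_rows(lapply(per_scaffold, `[[`, "blocks")) |>
    dplyr::arrange(.data$block_id)
  chains <- dplyr::bind_rows(lapply(per_scaffold, `[[`, "chain"))
  structure(list(blocks = out_blocks, chains = chains), class = "hb_screen")
}

#' @export
print.hb_screen <- function(x, ...) {
  cat("<hb_screen> ", nrow(x$chains), " scaffold(s), ",
      sum(x$blocks$status == "selected"), " selected / ",
      sum(x$blocks$status == "discarded"), " discarded / ",
      sum(x$blocks$status == "flagged"), " flagged block(s)\n", sep = "")
  invisible(x)
}

#' Write the screened block table as TSV
#'
#' @param screen An `hb_screen` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(screen, path) {
  write.table(screen$blocks, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
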