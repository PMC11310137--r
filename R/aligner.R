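#' Base-level alignment of a segment pair
#'
#' Globally aligns `query` against `target` (the reference for the cs
#' string) with affine gap costs, and returns a minimap2 short-form cs
#' difference string. Long near-identical pairs are first anchored with
#' unique shared k-mers and aligned piecewise between anchors, so memory
#' stays proportional to the chunk size times the band width; the band is
#' doubled adaptively whenever the optimal path touches its edge.
#'
#' @param target Target (reference) sequence, a single string.
#' @param query Query sequence, a single string.
#' @param band Initial band half-width in bp.
#' @param max_band Maximum band half-width before giving up on widening.
#' @param chunk Approximate piece length (bp) between anchor cut points.
#' @param anchor_k Anchor k-mer size.
#' @param mismatch,gap_open,gap_extend Alignment costs (a gap of length L
#'   costs `gap_open + L * gap_extend`). Affine costs keep large indel
#'   events contiguous in the cs string instead of fragmenting them through
#'   chance matches.
#' @return A list with elements `cs`, `cost`, `n_match`.
#' @export
align_segments <- function(target, query, band = 64L, max_band = 4096L,
                           chunk = 20000L, anchor_k = 21L, mismatch = 4L,
                           gap_open = 12L, gap_extend = 1L) {
  stopifnot(nchar(target) > 0, nchar(query) > 0)
  if (max(nchar(target), nchar(query)) <= chunk + anchor_k)
    return(banded_piece(target, query, band, max_band,
                        mismatch, gap_open, gap_extend))
  cuts <- anchor_cut_points(target, query, chunk, anchor_k)
  if (nrow(cuts) == 0)
    return(banded_piece(target, query, band, max_band,
                        mismatch, gap_open, gap_extend))
  tb <- c(0L, cuts$tpos, nchar(target))
  qb <- c(0L, cuts$qpos, nchar(query))
  pieces <- lapply(seq_len(length(tb) - 1), function(i) {
    banded_piece(substr(target, tb[i] + 1, tb[i + 1]),
                 substr(query, qb[i] + 1, qb[i + 1]),
                 band, max_band, mismatch, gap_open, gap_extend)
  })
  list(cs = join_cs(vapply(pieces, `[[`, character(1), "cs")),
       cost = sum(vapply(pieces, `[[`, numeric(1), "cost")),
       n_match = sum(vapply(pieces, `[[`, numeric(1), "n_match")))
}

banded_piece <- function(target, query, band, max_band,
                         mismatch, gap_open, gap_extend) {
  r <- .banded_align_cpp(target, query, as.integer(band),
                         as.integer(max_band), as.integer(mismatch),
                         as.integer(gap_open), as.integer(gap_extend))
  list(cs = r$cs, cost = r$cost, n_match = r$n_match)
}

# Collinear unique-anchor cut points between two near-identical sequences.
# Returned positions are 0-based prefix lengths (cut before the position),
# placed at anchor midpoints so both flanks of a cut are exact matches.
anchor_cut_points <- function(target, query, chunk, k) {
  hits <- .anchor_hits_cpp(target, query, as.integer(k))
  hits <- hits[hits$strand == "+", , drop = FALSE]
  if (nrow(hits) == 0) return(data.frame(tpos = integer(), qpos = integer()))
  hits <- hits[!(duplicated(hits$qpos) | duplicated(hits$qpos, fromLast = TRUE)), ,
               drop = FALSE]
  hits <- hits[!(duplicated(hits$tpos) | duplicated(hits$tpos, fromLast = TRUE)), ,
               drop = FALSE]
  hits <- hits[order(hits$tpos), , drop = FALSE]
  keep_q <- cummax_strict(hits$qpos)
  hits <- hits[keep_q, , drop = FALSE]
  if (nrow(hits) == 0) return(data.frame(tpos = integer(), qpos = integer()))
  mid <- as.integer(k %/% 2)
  sel <- integer()
  last_t <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$tpos[i] + mid - last_t >= chunk &&
        hits$tpos[i] + mid < nchar(target) &&
        hits$qpos[i] + mid < nchar(query)) {
      sel <- c(sel, i)
      last_t <- hits$tpos[i] + mid
    }
  }
  data.frame(tpos = hits$tpos[sel] + mid, qpos = hits$qpos[sel] + mid)
}

# indices forming a strictly increasing subsequence (greedy left-to-right)
cummax_strict <- function(x) {
  keep <- logical(length(x))
  best <- -Inf
  for (i in seq_along(x)) {
    if (x[i] > best) { keep[i] <- TRUE; best <- x[i] }
  }
  keep
}

# merge adjacent match runs across piece boundaries: ":3" + ":4" -> ":7"
join_cs <- function(parts) {
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) return("")
  out <- parts[1]
  for (p in parts[-1]) {
    tail_m <- regmatches(out, regexpr(":[0-9]+$", out))
    head_m <- regmatches(p, regexpr("^:[0-9]+", p))
    if (length(tail_m) == 1 && length(head_m) == 1) {
      n <- as.integer(substring(tail_m, 2)) + as.integer(substring(head_m, 2))
      out <- paste0(sub(":[0-9]+$", "", out), ":", n,
                    substring(p, nchar(head_m) + 1))
    } else {
      out <- paste0(out, p)
    }
  }
  out
}

#' Built-in whole-assembly aligner
#'
#' Maps each query (SLR) scaffold onto the target (TGS) contigs without
#' external binaries: unique target k-mers shared with the scaffold are
#' collected as anchors on both strands, clustered into collinear runs, and
#' each run is refined into one alignment block by banded affine base-level
#' alignment, yielding a PAF record with a short-form cs tag. Blocks are
#' extended outward over anchor-free flanks (bounded by scaffold N runs and
#' contig ends) so errors near block edges remain inside the alignment.
#'
#' @param query_fa,target_fa Sequence tibbles ([read_fasta()] shape); the
#'   query is the fragmented accurate assembly, the target the contiguous
#'   error-prone one.
#' @param anchor_k Anchor k-mer size.
#' @param min_anchors Minimum anchors per cluster to emit a block.
#' @param max_diag_drift Maximum diagonal change between consecutive anchors
#'   within one cluster (bp); larger jumps split the cluster.
#' @param max_anchor_gap Maximum query-position gap between consecutive
#'   anchors within one cluster (bp).
#' @param ... Passed to [align_segments()].
#' @return A PAF tibble (see [read_paf()]) with cs tags.
#' @export
align_assemblies <- function(query_fa, target_fa, anchor_k = 21L,
                             min_anchors = 3L, max_diag_drift = 1200L,
                             max_anchor_gap = 5000L, ...) {
  validate_fasta(query_fa)
  validate_fasta(target_fa)
  recs <- lapply(seq_len(nrow(query_fa)), function(qi) {
    align_one_scaffold(query_fa$seq[[qi]], query_fa$name[[qi]], target_fa,
                       anchor_k, min_anchors, max_diag_drift,
                       max_anchor_gap, ...)
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) empty_paf() else out
}

align_one_scaffold <- function(qseq, qname, target_fa, k, min_anchors,
                               max_diag_drift, max_anchor_gap, ...) {
  qlen <- nchar(qseq)
  hits <- .anchor_hits_cpp(target_fa$seq, qseq, as.integer(k))
  if (nrow(hits) == 0) return(NULL)
  dup <- duplicated(hits$qpos) | duplicated(hits$qpos, fromLast = TRUE)
  hits <- hits[!dup, , drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  hits$diag <- ifelse(hits$strand == "+",
                      hits$tpos - hits$qpos, hits$tpos + hits$qpos)
  hits <- hits[order(hits$tid, hits$strand, hits$qpos), , drop = FALSE]
  new_grp <- c(TRUE, diff(hits$qpos) > max_anchor_gap |
                 abs(diff(hits$diag)) > max_diag_drift |
                 diff(hits$tid) != 0 |
                 head(hits$strand, -1) != tail(hits$strand, -1))
  hits$cluster <- cumsum(new_grp)
  n_pos <- scaffold_n_runs(qseq)
  clusters <- split(hits, hits$cluster)
  recs <- lapply(clusters, function(cl) {
    if (nrow(cl) < min_anchors) return(NULL)
    cluster_to_paf(cl, qseq, qname, qlen, target_fa, k, n_pos, ...)
  })
  dplyr::bind_rows(recs)
}

# 0-based half-open intervals of N runs in a scaffold
scaffold_n_runs <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1) return(matrix(integer(), ncol = 2))
  cbind(as.integer(m) - 1L, as.integer(m) - 1L + attr(m, "match.length"))
}

cluster_to_paf <- function(cl, qseq, qname, qlen, target_fa, k, n_pos, ...) {
  tid <- cl$tid[1]
  strand <- cl$strand[1]
  tseq <- target_fa$seq[[tid]]
  tlen <- nchar(tseq)
  qs <- min(cl$qpos); qe <- max(cl$qpos) + k
  ts <- min(cl$tpos); te <- max(cl$tpos) + k
  # extension bounded by scaffold N runs / ends and contig ends
  q_left <- qs - n_boundary_left(n_pos, qs)
  q_right <- n_boundary_right(n_pos, qe, qlen) - qe
  if (strand == "+") {
    e1 <- min(q_left, ts); e2 <- min(q_right, tlen - te)
    qs <- qs - e1; ts <- ts - e1; qe <- qe + e2; te <- te + e2
  } else {
    e1 <- min(q_left, tlen - te); e2 <- min(q_right, ts)
    qs <- qs - e1; te <- te + e1; qe <- qe + e2; ts <- ts - e2
  }
  qseg <- substr(qseq, qs + 1, qe)
  if (strand == "-") qseg <- revcomp(qseg)
  tseg <- substr(tseq, ts + 1, te)
  aln <- align_segments(tseg, qseg, ...)
  ops <- parse_cs(aln$cs)
  tibble::tibble(
    qname = qname, qlen = qlen, qstart = qs, qend = qe, strand = strand,
    tname = target_fa$name[[tid]], tlen = tlen, tstart = ts, tend = te,
    nmatch = as.integer(aln$n_match), alen = as.integer(sum(ops$length)),
    mapq = 60L, cs = aln$cs, tags = paste0("cs:Z:", aln$cs))
}

n_boundary_left <- function(n_pos, pos) {
  if (nrow(n_pos) == 0) return(0L)
  ends <- n_pos[, 2][n_pos[, 2] <= pos]
  if (length(ends) == 0) 0L else max(ends)
}

n_boundary_right <- function(n_pos, pos, len) {
  if (nrow(n_pos) == 0) return(len)
  starts <- n_pos[, 1][n_pos[, 1] >= pos]
  if (length(starts) == 0) len else min(starts)
}
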