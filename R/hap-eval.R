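#' Canonical k-mer set of sequences or reads
#'
#' Builds the multiset of canonical k-mers (lexicographic minimum of each
#' k-mer and its reverse complement) over all input sequences; windows
#' containing `N` are skipped. K-mers with multiplicity below `min_count`
#' are dropped, which yields the "solid" k-mer set when `min_count > 1`.
#'
#' @param x A character vector of sequences, or a sequence tibble with a
#'   `seq` column.
#' @param k Odd k-mer size (21 is the field's usual default).
#' @param min_count Minimum multiplicity to retain a k-mer.
#' @return A tibble with columns `kmer` and `n` (multiplicity), with `k`
#'   stored as an attribute.
#' @export
kmerize <- function(x, k = 21L, min_count = 1L) {
  seqs <- if (is.data.frame(x)) x$seq else as.character(x)
  if (all(nchar(seqs) < k))
    warning("k = ", k, " larger than every input sequence")
  kmers <- .canonical_kmers_cpp(seqs, as.integer(k))
  ks <- tibble::tibble(kmer = kmers) |>
    dplyr::count(.data$kmer, name = "n") |>
    dplyr::filter(.data$n >= min_count)
  attr(ks, "k") <- as.integer(k)
  ks
}

kset <- function(x) {
  if (is.data.frame(x)) x$kmer else as.character(x)
}

kmer_k <- function(x) {
  k <- attr(x, "k")
  if (!is.null(k)) return(as.integer(k))
  s <- kset(x)
  if (length(s) == 0) return(NA_integer_)
  as.integer(nchar(s[[1]]))
}

check_same_k <- function(...) {
  ks <- vapply(list(...), kmer_k, integer(1))
  ks <- ks[!is.na(ks)]
  if (length(unique(ks)) > 1)
    stop("k-mer sets have mismatched k: ", paste(ks, collapse = ", "),
         call. = FALSE)
  invisible(ks[1])
}

#' Build haplotype-specific k-mer (hapmer) catalogs from a trio
#'
#' Paternal hapmers are the paternal-specific k-mers (paternal minus
#' maternal) that also occur in the offspring's reads, and symmetrically
#' for maternal hapmers; the two sets are disjoint by construction.
#'
#' @param pat_kmers,mat_kmers,offspring_kmers K-mer sets ([kmerize()]
#'   tibbles or character vectors) with equal k.
#' @return An object of class `hapmer_catalog`: list with character vectors
#'   `pat`, `mat` and the integer `k`.
#' @export
build_hapmers <- function(pat_kmers, mat_kmers, offspring_kmers) {
  k <- check_same_k(pat_kmers, mat_kmers, offspring_kmers)
  pat <- kset(pat_kmers); mat <- kset(mat_kmers); off <- kset(offspring_kmers)
  structure(list(pat = intersect(setdiff(pat, mat), off),
                 mat = intersect(setdiff(mat, pat), off),
                 k = k),
            class = "hapmer_catalog")
}

#' @export
print.hapmer_catalog <- function(x, ...) {
  cat("<hapmer_catalog> k=", x$k, ": ", length(x$pat), " paternal, ",
      length(x$mat), " maternal hapmers\n", sep = "")
  invisible(x)
}

#' Harmonic-mean F1 from precision and recall
#'
#' @param precision,recall Fractions (or percentages, as long as both use
#'   the same scale); vectorized.
#' @return `2 * p * r / (p + r)`, 0 where `p + r` is 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Haplotyping precision, recall and F1 of an assembly
#'
#' Precision is the fraction of hapmers found in the assembly that belong
#' to the expected haplotype; recall is the fraction of the offspring's
#' expected hapmers recovered; F1 is their harmonic mean.
#'
#' @param assembly_kmers K-mer set of the assembly under evaluation.
#' @param catalog A [build_hapmers()] catalog.
#' @param expected `"paternal"` or `"maternal"` - which haplotype the
#'   assembly is supposed to represent.
#' @return A one-row tibble with `precision`, `recall`, `f1`,
#'   `found_correct`, `found_total`, `expected_total`.
#' @export
haplotyping_metrics <- function(assembly_kmers, catalog,
                                expected = c("paternal", "maternal")) {
  expected <- match.arg(expected)
  check_same_k(assembly_kmers, catalog$pat, catalog$mat)
  if (length(catalog$pat) + length(catalog$mat) == 0)
    stop("empty hapmer catalog: haplotyping metrics undefined", call. = FALSE)
  asm <- unique(kset(assembly_kmers))
  exp_set <- if (expected == "paternal") catalog$pat else catalog$mat
  found_correct <- length(intersect(asm, exp_set))
  found_total <- length(intersect(asm, union(catalog$pat, catalog$mat)))
  precision <- if (found_total == 0) 0 else found_correct / found_total
  recall <- if (length(exp_set) == 0) 0 else found_correct / length(exp_set)
  tibble::tibble(expected = expected, precision = precision, recall = recall,
                 f1 = f1_score(precision, recall),
                 found_correct = found_correct, found_total = found_total,
                 expected_total = length(exp_set))
}

#' K-mer consensus quality value (QV)
#'
#' K-mers found exclusively in the assembly (absent from the read set) are
#' counted as assembly errors; the per-base error rate follows the k-mer
#' survival convention `p = 1 - (1 - bad/total)^(1/k)` and the QV is its
#' Phred scaling `-10 log10(p)`, capped at `qv_cap` for an error-free
#' assembly.
#'
#' @param assembly_kmers Non-empty k-mer set of the assembly.
#' @param read_kmers K-mer set of the offspring reads.
#' @param k K-mer size; inferred from the sets when `NULL`.
#' @param qv_cap QV reported when no assembly-only k-mer exists.
#' @return A one-row tibble with `qv`, `error_rate`, `bad`, `total`.
#' @export
kmer_qv <- function(assembly_kmers, read_kmers, k = NULL, qv_cap = 99) {
  asm <- unique(kset(assembly_kmers))
  if (length(asm) == 0) stop("empty assembly k-mer set", call. = FALSE)
  if (is.null(k)) k <- check_same_k(assembly_kmers, read_kmers)
  bad <- length(setdiff(asm, kset(read_kmers)))
  total <- length(asm)
  if (bad == 0)
    return(tibble::tibble(qv = qv_cap, error_rate = 0,
                          bad = 0L, total = total))
  p <- 1 - (1 - bad / total)^(1 / k)
  tibble::tibble(qv = -10 * log10(p), error_rate = p,
                 bad = bad, total = total)
}

#' K-mer completeness of an assembly
#'
#' Fraction of the solid (reliable) read k-mers recovered in the assembly.
#'
#' @param assembly_kmers K-mer set of the assembly.
#' @param solid_read_kmers Non-empty solid k-mer set of the reads (e.g.
#'   [kmerize()] with `min_count = 2`).
#' @return The recovered fraction in `[0, 1]`.
#' @export
kmer_completeness <- function(assembly_kmers, solid_read_kmers) {
  solid <- unique(kset(solid_read_kmers))
  if (length(solid) == 0) stop("empty solid k-mer set", call. = FALSE)
  length(intersect(unique(kset(assembly_kmers)), solid)) / length(solid)
}

#' Locate hapmer markers along assembly sequences
#'
#' Every window whose canonical k-mer is a paternal or maternal hapmer
#' contributes one marker at its position (a k-mer occurring at several
#' positions contributes each occurrence).
#'
#' @param fa An assembly tibble ([read_fasta()] shape).
#' @param catalog A [build_hapmers()] catalog.
#' @return A tibble with `name`, `pos` (0-based) and `hap`
#'   (`"pat"`/`"mat"`), sorted by sequence and position.
#' @export
hapmer_track <- function(fa, catalog) {
  validate_fasta(fa)
  parts <- lapply(seq_len(nrow(fa)), function(i) {
    tr <- .kmer_track_cpp(fa$seq[[i]], catalog$k)
    hap <- ifelse(tr$kmer %in% catalog$pat, "pat",
                  ifelse(tr$kmer %in% catalog$mat, "mat", NA_character_))
    keep <- !is.na(hap)
    tibble::tibble(name = fa$name[[i]], pos = tr$pos[keep], hap = hap[keep])
  })
  dplyr::bind_rows(parts) |> dplyr::arrange(.data$name, .data$pos)
}

#' Phase block configuration
#'
#' @param window Window (bp) within which an other-haplotype marker must
#'   revert to the block haplotype to be absorbed as a switch error
#'   (default 20 Kbp).
#' @param min_hapmers_per_block Minimum markers per reported block
#'   (default 3: "more than two hapmers").
#' @return A list of class `phase_block_config`.
#' @export
phase_block_config <- function(window = 20000L, min_hapmers_per_block = 3L) {
  stopifnot(window > 0, min_hapmers_per_block >= 1)
  structure(list(window = as.integer(window),
                 min_hapmers_per_block = as.integer(min_hapmers_per_block)),
            class = "phase_block_config")
}

#' Phase blocks and windowed switch errors from a hapmer track
#'
#' Maximal same-haplotype marker runs form candidate blocks. An
#' other-haplotype marker is absorbed as one switch error when a marker of
#' the block haplotype re-appears within `window` bp after it; a
#' non-reverting run, or a gap larger than `window` between consecutive
#' markers, terminates the block. Blocks with fewer than
#' `min_hapmers_per_block` markers are dropped.
#'
#' @param track A marker tibble from [hapmer_track()] (sorted by position
#'   within each sequence).
#' @param cfg A [phase_block_config()].
#' @return A list with `blocks` (tibble: `name`, `hap`, `start`, `end`,
#'   `span`, `n_markers`, `n_switch`), `n_switch`, `n_markers` and
#'   `switch_rate` over the retained blocks.
#' @export
phase_blocks <- function(track, cfg = phase_block_config()) {
  if (nrow(track) == 0)
    return(list(blocks = tibble::tibble(
      name = character(), hap = character(), start = integer(),
      end = integer(), span = integer(), n_markers = integer(),
      n_switch = integer()), n_switch = 0L, n_markers = 0L,
      switch_rate = NaN))
  parts <- lapply(split(track, track$name), function(tr) {
    if (is.unsorted(tr$pos)) stop("marker track not sorted", call. = FALSE)
    phase_blocks_one(tr$name[1], tr$pos, tr$hap, cfg)
  })
  blocks <- dplyr::bind_rows(parts) |>
    dplyr::filter(.data$n_markers >= cfg$min_hapmers_per_block)
  n_switch <- sum(blocks$n_switch)
  n_markers <- sum(blocks$n_markers)
  list(blocks = blocks, n_switch = n_switch, n_markers = n_markers,
       switch_rate = if (n_markers > 0) n_switch / n_markers else NaN)
}

phase_blocks_one <- function(name, pos, hap, cfg) {
  n <- length(pos)
  blocks <- list()
  i <- 1L
  while (i <= n) {
    h <- hap[i]
    start <- pos[i]; end <- pos[i]
    n_markers <- 1L; n_switch <- 0L
    j <- i + 1L
    while (j <= n) {
      if (pos[j] - pos[j - 1L] > cfg$window) break
      if (hap[j] == h) {
        end <- pos[j]; n_markers <- n_markers + 1L; j <- j + 1L
      } else {
        # does the block haplotype revert within the window?
        revert <- FALSE
        for (l in seq.int(j + 1L, length.out = max(0L, n - j))) {
          if (pos[l] - pos[j] > cfg$window) break
          if (hap[l] == h) { revert <- TRUE; break }
        }
        if (!revert) break
        n_switch <- n_switch + 1L
        n_markers <- n_markers + 1L
        j <- j + 1L
      }
    }
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      name = name, hap = h, start = start, end = end,
      span = end - start + 1L, n_markers = n_markers, n_switch = n_switch)
    i <- j
  }
  dplyr::bind_rows(blocks)
}

#' Variant-level switch errors by penalty-minimizing dynamic program
#'
#' Over phased heterozygous variants in genomic order, a binary-state
#' dynamic program chooses a global phase orientation per position: flipping
#' the orientation between consecutive variants costs `long_penalty` (one
#' long switch, flipping every subsequent variant), and a variant whose
#' phase disagrees with the current orientation costs 1 (one short switch).
#' The program minimizes `long_penalty * n_long + n_short` (ties resolved
#' toward fewer long switches). Phase blocks are the spans between long
#' switches.
#'
#' @param phases A tibble with columns `pos` (genomic position) and `match`
#'   (logical: does the assembly phase of this variant equal the benchmark
#'   phase?), optionally `name` for multiple sequences.
#' @param long_penalty Cost of one long switch relative to a short switch
#'   (default 5).
#' @return A list with `summary` (one-row tibble: `n_short`, `n_long`,
#'   `penalty`, `n_blocks`, `block_n50`) and `blocks` (tibble of phase
#'   blocks delimited by long switches).
#' @export
switch_errors <- function(phases, long_penalty = 5) {
  if (nrow(phases) == 0)
    return(list(summary = tibble::tibble(n_short = 0L, n_long = 0L,
                                         penalty = 0, n_blocks = 0L,
                                         block_n50 = NA_real_),
                blocks = tibble::tibble(name = character(), start = numeric(),
                                        end = numeric(), n_variants = integer(),
                                        span = numeric())))
  if (!"name" %in% names(phases)) phases$name <- "seq"
  parts <- lapply(split(phases, phases$name), function(ph) {
    ph <- dplyr::arrange(ph, .data$pos)
    switch_dp_one(ph$name[1], ph$pos, ph$match, long_penalty)
  })
  blocks <- dplyr::bind_rows(lapply(parts, `[[`, "blocks"))
  n_short <- sum(vapply(parts, `[[`, integer(1), "n_short"))
  n_long <- sum(vapply(parts, `[[`, integer(1), "n_long"))
  list(summary = tibble::tibble(
    n_short = n_short, n_long = n_long,
    penalty = long_penalty * n_long + n_short,
    n_blocks = nrow(blocks),
    block_n50 = if (nrow(blocks)) nx_stats(blocks$span)$n50 else NA_real_),
    blocks = blocks)
}

switch_dp_one <- function(name, pos, match, long_penalty) {
  n <- length(pos)
  mis <- cbind(as.numeric(!match), as.numeric(match))  # cost per orientation
  cost <- mis[1, ]
  nlong <- c(0L, 0L)
  choice <- matrix(0L, n, 2)  # previous orientation chosen (1 or 2)
  for (i in seq_len(n)[-1]) {
    new_cost <- numeric(2); new_nlong <- integer(2)
    for (o in 1:2) {
      stay <- c(cost[o], nlong[o])
      flip <- c(cost[3 - o] + long_penalty, nlong[3 - o] + 1L)
      pick_flip <- flip[1] < stay[1] ||
        (flip[1] == stay[1] && flip[2] < stay[2])
      if (pick_flip) {
        new_cost[o] <- flip[1] + mis[i, o]; new_nlong[o] <- as.integer(flip[2])
        choice[i, o] <- 3L - o
      } else {
        new_cost[o] <- stay[1] + mis[i, o]; new_nlong[o] <- as.integer(stay[2])
        choice[i, o] <- o
      }
    }
    cost <- new_cost; nlong <- new_nlong
  }
  end_o <- if (cost[2] < cost[1] || (cost[2] == cost[1] && nlong[2] < nlong[1]))
    2L else 1L
  orient <- integer(n)
  orient[n] <- end_o
  if (n > 1) for (i in n:2) orient[i - 1L] <- choice[i, orient[i]]
  n_long <- if (n > 1) sum(orient[-1] != orient[-n]) else 0L
  n_short <- sum(mis[cbind(seq_len(n), orient)])
  boundaries <- c(0L, which(orient[-1] != orient[-n]), n)
  blocks <- tibble::tibble(
    name = name,
    start = pos[head(boundaries, -1) + 1L],
    end = pos[boundaries[-1]],
    n_variants = diff(boundaries),
    span = pos[boundaries[-1]] - pos[head(boundaries, -1) + 1L] + 1)
  list(blocks = blocks, n_short = as.integer(n_short),
       n_long = as.integer(n_long))
}

#' Phased SNP ratio
#'
#' Ratio of common heterozygous SNPs (phased in both assembly and
#' benchmark) to heterozygous SNPs in the benchmark.
#'
#' @param n_common_het Count of common heterozygous SNPs.
#' @param n_benchmark_het Count of benchmark heterozygous SNPs (> 0).
#' @return A fraction.
#' @export
phased_snp_ratio <- function(n_common_het, n_benchmark_het) {
  if (n_benchmark_het <= 0)
    stop("benchmark heterozygous SNP count must be positive", call. = FALSE)
  n_common_het / n_benchmark_het
}

#' Nx length statistics
#'
#' N50 is the smallest length such that sequences at least that long cover
#' half the total assembly length; NG50 uses half the genome size instead.
#'
#' @param lengths Positive contig/block lengths.
#' @param genome_size Optional genome size for NG50.
#' @return A one-row tibble with `n50`, `ng50`, `max`, `total`, `n`.
#' @export
nx_stats <- function(lengths, genome_size = NULL) {
  if (length(lengths) == 0) stop("empty length vector", call. = FALSE)
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  n50 <- s[which(cum >= sum(s) / 2)[1]]
  ng50 <- NA_real_
  if (!is.null(genome_size)) {
    hit <- which(cum >= genome_size / 2)
    ng50 <- if (length(hit)) s[hit[1]] else NA_real_
  }
  tibble::tibble(n50 = n50, ng50 = ng50, max = max(s), total = sum(s),
                 n = length(s))
}
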