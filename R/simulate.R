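#' Simulation configuration
#'
#' Defines a synthetic diploid study system: a random reference carrying
#' heterozygous SNPs and short indels; a contiguous TGS-like assembly of one
#' (or a collapsed mixture of both) haplotype(s) bearing an exact number of
#' small (< 50 bp) errors plus a few large (>= 50 bp) events; and accurate,
#' fragmented, N-gapped SLR-like haplotype scaffolds. All draws are seeded,
#' so a fixed configuration reproduces byte-identical fixtures.
#'
#' @param genome_size Reference length in bp.
#' @param het_snp_rate Per-bp heterozygous SNP probability.
#' @param het_indel_rate Per-bp heterozygous indel probability.
#' @param het_indel_mean,het_indel_max Geometric mean and cap of
#'   heterozygous indel lengths (bp).
#' @param tgs_haplotype `"A"`, `"B"` or `"collapsed"` - which haplotype(s)
#'   the TGS-like assembly represents.
#' @param tgs_n_contigs Number of contigs the TGS assembly is split into.
#' @param collapse_segment Haplotype switch spacing (bp, reference
#'   coordinates) for the collapsed model.
#' @param tgs_n_small Exact number of small (< `tgs_small_max` bp)
#'   substitution/indel errors injected into the TGS contigs.
#' @param tgs_small_indel_mean,tgs_small_max Geometric mean and cap of
#'   small indel error lengths.
#' @param tgs_n_large Exact number of large (>= 50 bp) injected events.
#' @param tgs_large_range Length range (bp) of large events.
#' @param tgs_edge_margin Margin (bp) kept error-free at contig ends,
#'   emulating the well-supported consensus at assembly ends.
#' @param slr_fragment_mean Mean SLR fragment length (bp).
#' @param slr_gap_rate Probability that a fragment boundary becomes an
#'   N-gap within the scaffold rather than a scaffold break.
#' @param slr_n_run_range N-run length range (bp) at gapped boundaries.
#' @param seed Integer seed; sub-steps derive their own streams from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_size = 500000L,
                       het_snp_rate = 0.001,
                       het_indel_rate = 1e-4,
                       het_indel_mean = 3, het_indel_max = 20L,
                       tgs_haplotype = c("A", "B", "collapsed"),
                       tgs_n_contigs = 1L,
                       collapse_segment = 50000L,
                       tgs_n_small = 200L,
                       tgs_small_indel_mean = 3, tgs_small_max = 49L,
                       tgs_n_large = 5L,
                       tgs_large_range = c(50L, 500L),
                       tgs_edge_margin = 100L,
                       slr_fragment_mean = 50000L,
                       slr_gap_rate = 1,
                       slr_n_run_range = c(100L, 500L),
                       seed = 1L) {
  stopifnot(genome_size >= 1000, het_snp_rate >= 0, het_snp_rate <= 1,
            het_indel_rate >= 0, het_indel_rate <= 1,
            tgs_n_small >= 0, tgs_n_large >= 0,
            tgs_large_range[1] >= 50, slr_gap_rate >= 0, slr_gap_rate <= 1)
  structure(list(
    genome_size = as.integer(genome_size),
    het_snp_rate = het_snp_rate, het_indel_rate = het_indel_rate,
    het_indel_mean = het_indel_mean, het_indel_max = as.integer(het_indel_max),
    tgs_haplotype = match.arg(tgs_haplotype),
    tgs_n_contigs = as.integer(tgs_n_contigs),
    collapse_segment = as.integer(collapse_segment),
    tgs_n_small = as.integer(tgs_n_small),
    tgs_small_indel_mean = tgs_small_indel_mean,
    tgs_small_max = as.integer(tgs_small_max),
    tgs_n_large = as.integer(tgs_n_large),
    tgs_large_range = as.integer(tgs_large_range),
    tgs_edge_margin = as.integer(tgs_edge_margin),
    slr_fragment_mean = as.integer(slr_fragment_mean),
    slr_gap_rate = slr_gap_rate,
    slr_n_run_range = as.integer(slr_n_run_range),
    seed = as.integer(seed)), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a diploid genome with a full variant ledger
#'
#' Draws a uniform random reference, places heterozygous SNPs and short
#' indels by per-site draws (overlapping candidates are dropped), assigns
#' each alternate allele to one haplotype, and derives the two haplotype
#' sequences. Variants are recorded VCF-style (anchored `ref`/`alt`
#' substrings at 0-based reference positions) together with their position
#' on haplotype A, so replaying the ledger on haplotype A reproduces
#' haplotype B exactly.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `diploid_truth`: list with `reference`,
#'   `hapA`, `hapB` (strings) and `variants` (the ledger tibble).
#' @export
simulate_diploid <- function(cfg = sim_config()) {
  withr::with_seed(cfg$seed, {
    size <- cfg$genome_size
    reference <- random_dna(size)
    n_sites <- rbinom(2, size, c(cfg$het_snp_rate, cfg$het_indel_rate))
    cand <- dplyr::bind_rows(
      tibble::tibble(pos = sample.int(size - 2L, n_sites[1]),
                     type = "snp"),
      tibble::tibble(pos = sample.int(size - cfg$het_indel_max - 2L,
                                      n_sites[2]),
                     type = sample(c("ins", "del"), n_sites[2],
                                   replace = TRUE))) |>
      dplyr::arrange(.data$pos)
    variants <- place_variants(cand, reference, cfg)
    hapA <- apply_edits(reference,
                        variants |>
                          dplyr::filter(.data$hap == "A") |>
                          dplyr::select("pos", "ref", "alt"))
    hapB <- apply_edits(reference,
                        variants |>
                          dplyr::filter(.data$hap == "B") |>
                          dplyr::select("pos", "ref", "alt"))
    delta <- nchar(variants$alt) - nchar(variants$ref)
    shift_a <- cumsum(dplyr::lag(ifelse(variants$hap == "A", delta, 0L),
                                 default = 0L))
    variants$pos_a <- variants$pos + shift_a
    variants$allele_a <- ifelse(variants$hap == "A", variants$alt,
                                variants$ref)
    variants$allele_b <- ifelse(variants$hap == "B", variants$alt,
                                variants$ref)
    structure(list(reference = reference, hapA = hapA, hapB = hapB,
                   variants = variants, cfg = cfg),
              class = "diploid_truth")
  })
}

place_variants <- function(cand, reference, cfg) {
  kept <- list()
  last_end <- -2L
  for (i in seq_len(nrow(cand))) {
    pos <- cand$pos[i]
    if (pos <= last_end + 1L) next
    type <- cand$type[i]
    refb <- substr(reference, pos + 1L, pos + 1L)
    if (type == "snp") {
      ref <- refb; alt <- other_base(refb)
      last_end <- pos
    } else {
      len <- min(1L + rgeom(1, 1 / cfg$het_indel_mean), cfg$het_indel_max)
      if (type == "ins") {
        ref <- refb; alt <- paste0(refb, random_dna(len))
        last_end <- pos
      } else {
        ref <- substr(reference, pos + 1L, pos + 1L + len)
        alt <- refb
        last_end <- pos + len
      }
    }
    kept[[length(kept) + 1L]] <- tibble::tibble(
      pos = pos, type = type, ref = ref, alt = alt)
  }
  out <- dplyr::bind_rows(kept)
  if (nrow(out) == 0)
    return(tibble::tibble(pos = integer(), type = character(),
                          ref = character(), alt = character(),
                          hap = character()))
  out$hap <- sample(c("A", "B"), nrow(out), replace = TRUE)
  out
}

#' Replay the variant ledger on haplotype A
#'
#' Constructive check of the ledger: substituting each variant's A allele
#' by its B allele at the recorded haplotype-A position must reproduce
#' haplotype B byte-for-byte.
#'
#' @param truth A [simulate_diploid()] object.
#' @return The reconstructed haplotype B string.
#' @export
replay_variants <- function(truth) {
  v <- truth$variants
  if (nrow(v) == 0) return(truth$hapA)
  apply_edits(truth$hapA,
              tibble::tibble(pos = v$pos_a, ref = v$allele_a,
                             alt = v$allele_b))
}

hap_coord <- function(variants, hap, ref_pos) {
  v <- variants[variants$hap == hap, , drop = FALSE]
  delta <- nchar(v$alt) - nchar(v$ref)
  vapply(ref_pos, function(p) p + sum(delta[v$pos < p]), numeric(1))
}

# shift a reference cut point out of any variant footprint
clear_of_variants <- function(pos, variants) {
  repeat {
    hit <- which(variants$pos < pos & variants$pos + nchar(variants$ref) > pos)
    if (length(hit) == 0) return(pos)
    pos <- max(variants$pos[hit] + nchar(variants$ref[hit]))
  }
}

#' Simulate a TGS-like assembly with an exact error ledger
#'
#' Copies one haplotype (or a segment-wise collapsed mixture of both),
#' splits it into contigs, and injects exactly `tgs_n_small` small
#' substitution/indel errors and `tgs_n_large` large (>= 50 bp) events at
#' non-overlapping positions. The ledger records every event VCF-style in
#' pre-error contig coordinates, so replaying it on the clean contigs
#' reproduces the erroneous contigs byte-for-byte.
#'
#' @param truth A [simulate_diploid()] object.
#' @param cfg A [sim_config()] (defaults to the truth's own).
#' @return A list with `contigs` (erroneous assembly tibble),
#'   `truth_contigs` (pre-error contigs), `ledger` (error tibble) and
#'   `source` (haplotype segment table for the collapsed model).
#' @export
simulate_tgs_assembly <- function(truth, cfg = truth$cfg) {
  withr::with_seed(cfg$seed + 1L, {
    src <- tgs_source_sequence(truth, cfg)
    n_tigs <- max(1L, cfg$tgs_n_contigs)
    cuts <- round(seq(0, nchar(src$seq), length.out = n_tigs + 1))
    clean <- substring(src$seq, head(cuts, -1) + 1, cuts[-1])
    names <- paste0("tig", seq_len(n_tigs))
    lens <- nchar(clean)
    n_small_per <- distribute_counts(cfg$tgs_n_small, lens)
    n_large_per <- distribute_counts(cfg$tgs_n_large, lens)
    pieces <- lapply(seq_len(n_tigs), function(i) {
      inject_errors(clean[i], names[i], n_small_per[i], n_large_per[i], cfg)
    })
    list(contigs = fasta_tbl(names,
                             vapply(pieces, `[[`, character(1), "seq")),
         truth_contigs = fasta_tbl(names, clean),
         ledger = dplyr::bind_rows(lapply(pieces, `[[`, "ledger")),
         source = src$source)
  })
}

tgs_source_sequence <- function(truth, cfg) {
  if (cfg$tgs_haplotype == "A")
    return(list(seq = truth$hapA,
                source = tibble::tibble(ref_start = 0L,
                                        ref_end = nchar(truth$reference),
                                        hap = "A")))
  if (cfg$tgs_haplotype == "B")
    return(list(seq = truth$hapB,
                source = tibble::tibble(ref_start = 0L,
                                        ref_end = nchar(truth$reference),
                                        hap = "B")))
  # collapsed: alternate haplotype source every collapse_segment bp,
  # cutting only at reference positions clear of variant footprints
  size <- nchar(truth$reference)
  cuts <- seq(cfg$collapse_segment, size - 1L, by = cfg$collapse_segment)
  cuts <- vapply(cuts, clear_of_variants, numeric(1),
                 variants = truth$variants)
  bounds <- unique(c(0, cuts, size))
  haps <- rep(c("A", "B"), length.out = length(bounds) - 1)
  segs <- vapply(seq_along(haps), function(i) {
    hs <- hap_coord(truth$variants, haps[i], bounds[i])
    he <- hap_coord(truth$variants, haps[i], bounds[i + 1])
    hseq <- if (haps[i] == "A") truth$hapA else truth$hapB
    substr(hseq, hs + 1, he)
  }, character(1))
  list(seq = paste(segs, collapse = ""),
       source = tibble::tibble(ref_start = head(bounds, -1),
                               ref_end = bounds[-1], hap = haps))
}

distribute_counts <- function(n, lens) {
  if (n == 0) return(rep(0L, length(lens)))
  tab <- tabulate(sample.int(length(lens), n, replace = TRUE,
                             prob = lens / sum(lens)), nbins = length(lens))
  as.integer(tab)
}

inject_errors <- function(seq, contig, n_small, n_large, cfg) {
  n <- n_small + n_large
  if (n == 0)
    return(list(seq = seq, ledger = empty_error_ledger()))
  len <- nchar(seq)
  margin <- cfg$tgs_edge_margin
  max_len <- max(cfg$tgs_large_range[2], cfg$tgs_small_max) + 2L
  span <- len - 2L * margin - max_len
  cand <- sort(sample.int(span, min(span, 4L * n + 20L)) + margin)
  keep <- integer(0)
  last <- -Inf
  for (p in cand) if (p - last > max_len) { keep <- c(keep, p); last <- p }
  if (length(keep) < n)
    stop("could not place ", n, " non-overlapping errors on a ", len,
         " bp contig", call. = FALSE)
  pos <- sort(keep[sample.int(length(keep), n)])
  is_large <- seq_along(pos) %in% sample.int(n, n_large)
  rows <- lapply(seq_along(pos), function(i) {
    p <- pos[i]
    anchor <- substr(seq, p + 1L, p + 1L)
    if (is_large[i]) {
      type <- sample(c("ins", "del"), 1)
      elen <- sample(cfg$tgs_large_range[1]:cfg$tgs_large_range[2], 1)
      class <- "large"
    } else {
      type <- sample(c("sub", "ins", "del"), 1)
      elen <- if (type == "sub") 1L
              else min(1L + rgeom(1, 1 / cfg$tgs_small_indel_mean),
                       cfg$tgs_small_max)
      class <- "small"
    }
    if (type == "sub") {
      ref <- anchor; alt <- other_base(anchor)
    } else if (type == "ins") {
      ref <- anchor; alt <- paste0(anchor, random_dna(elen))
    } else {
      ref <- substr(seq, p + 1L, p + 1L + elen); alt <- anchor
    }
    tibble::tibble(contig = contig, pos = p, class = class, type = type,
                   len = elen, ref = ref, alt = alt)
  })
  ledger <- dplyr::bind_rows(rows)
  err_seq <- apply_edits(seq, dplyr::select(ledger, "pos", "ref", "alt"))
  list(seq = err_seq, ledger = ledger)
}

empty_error_ledger <- function() {
  tibble::tibble(contig = character(), pos = integer(), class = character(),
                 type = character(), len = integer(), ref = character(),
                 alt = character())
}

#' Replay an error ledger on clean contigs
#'
#' @param truth_contigs Clean contig tibble from [simulate_tgs_assembly()].
#' @param ledger The error ledger.
#' @param classes Which event classes to replay (default all).
#' @return A contig tibble with the selected events applied.
#' @export
replay_errors <- function(truth_contigs, ledger,
                          classes = c("small", "large")) {
  out <- truth_contigs
  for (i in seq_len(nrow(out))) {
    ed <- ledger[ledger$contig == out$name[i] & ledger$class %in% classes, ]
    out$seq[i] <- apply_edits(out$seq[i],
                              dplyr::select(ed, "pos", "ref", "alt"))
  }
  out
}

#' Simulate SLR-like haplotype scaffolds
#'
#' Cuts one haplotype sequence into fragments with roughly exponential
#' lengths around `slr_fragment_mean`; each internal boundary becomes an
#' N run (with probability `slr_gap_rate`) or a scaffold break. Non-N
#' scaffold bases are exact copies of the haplotype, and the coverage map
#' records which haplotype interval each scaffold interval represents.
#'
#' @param hap_seq A haplotype sequence string.
#' @param cfg A [sim_config()].
#' @param name_prefix Scaffold name prefix.
#' @return A list with `scaffolds` (sequence tibble) and `coverage`
#'   (tibble: `scaffold`, `scaf_start`, `scaf_end`, `hap_start`,
#'   `hap_end`; 0-based half-open).
#' @export
simulate_slr_assembly <- function(hap_seq, cfg = sim_config(),
                                  name_prefix = "scaf") {
  withr::with_seed(cfg$seed + 2L, {
    len <- nchar(hap_seq)
    bounds <- 0L
    while (tail(bounds, 1) < len) {
      frag <- max(1000L, as.integer(round(stats::rexp(1,
                                                      1 / cfg$slr_fragment_mean))))
      bounds <- c(bounds, min(len, tail(bounds, 1) + frag))
    }
    n_frag <- length(bounds) - 1L
    frag_seq <- substring(hap_seq, head(bounds, -1) + 1, bounds[-1])
    gap_here <- if (n_frag > 1)
      runif(n_frag - 1) < cfg$slr_gap_rate else logical(0)
    scaf_id <- cumsum(c(1L, as.integer(!gap_here)))
    scaffolds <- character(0)
    coverage <- list()
    for (s in unique(scaf_id)) {
      idx <- which(scaf_id == s)
      seqs <- character(0)
      offset <- 0L
      for (j in seq_along(idx)) {
        f <- idx[j]
        if (j > 1) {
          nrun <- sample(cfg$slr_n_run_range[1]:cfg$slr_n_run_range[2], 1)
          seqs <- c(seqs, strrep("N", nrun))
          offset <- offset + nrun
        }
        coverage[[length(coverage) + 1L]] <- tibble::tibble(
          scaffold = paste0(name_prefix, s),
          scaf_start = offset, scaf_end = offset + nchar(frag_seq[f]),
          hap_start = bounds[f], hap_end = bounds[f + 1L])
        seqs <- c(seqs, frag_seq[f])
        offset <- offset + nchar(frag_seq[f])
      }
      scaffolds <- c(scaffolds, paste(seqs, collapse = ""))
    }
    list(scaffolds = fasta_tbl(paste0(name_prefix, unique(scaf_id)),
                               scaffolds),
         coverage = dplyr::bind_rows(coverage))
  })
}

#' Simulate trio k-mer sets
#'
#' Parent 1 is homozygous for haplotype A, parent 2 for haplotype B; the
#' offspring's read k-mer set is their union, optionally contaminated with
#' random error k-mers.
#'
#' @param truth A [simulate_diploid()] object.
#' @param k K-mer size.
#' @param contamination_rate Fraction of additional random error k-mers
#'   added to the offspring set.
#' @return A list with [kmerize()] tibbles `pat`, `mat`, `offspring`.
#' @export
simulate_trio_kmers <- function(truth, k = 21L, contamination_rate = 0) {
  withr::with_seed(truth$cfg$seed + 3L, {
    pat <- kmerize(truth$hapA, k)
    mat <- kmerize(truth$hapB, k)
    offspring <- kmerize(c(truth$hapA, truth$hapB), k)
    if (contamination_rate > 0) {
      n_err <- max(1L, as.integer(round(contamination_rate * nrow(offspring))))
      junk <- vapply(seq_len(n_err), function(i) random_dna(k), character(1))
      junk <- .canonical_kmers_cpp(junk, as.integer(k))
      extra <- tibble::tibble(kmer = setdiff(junk, offspring$kmer), n = 1L)
      offspring <- dplyr::bind_rows(offspring, extra)
      attr(offspring, "k") <- as.integer(k)
    }
    list(pat = pat, mat = mat, offspring = offspring)
  })
}

#' Write a complete fixture set to disk
#'
#' Writes the truth haplotypes, TGS contigs, SLR scaffolds for both
#' haplotypes, the variant and error ledgers, and a manifest with MD5
#' checksums of every file.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
simulate_fixture_set <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_diploid(cfg)
  tgs <- simulate_tgs_assembly(truth, cfg)
  slrA <- simulate_slr_assembly(truth$hapA, cfg, name_prefix = "hap1_scaf")
  slrB <- simulate_slr_assembly(truth$hapB, cfg, name_prefix = "hap2_scaf")
  paths <- c(
    reference = "truth_reference.fa", hapA = "truth_hap1.fa",
    hapB = "truth_hap2.fa", tgs = "tgs_contigs.fa",
    slrA = "slr_hap1.fa", slrB = "slr_hap2.fa",
    variants = "variant_ledger.tsv", errors = "error_ledger.tsv")
  paths <- file.path(dir, paths)
  names(paths) <- c("reference", "hapA", "hapB", "tgs", "slrA", "slrB",
                    "variants", "errors")
  write_fasta(fasta_tbl("ref", truth$reference), paths["reference"])
  write_fasta(fasta_tbl("hap1", truth$hapA), paths["hapA"])
  write_fasta(fasta_tbl("hap2", truth$hapB), paths["hapB"])
  write_fasta(tgs$contigs, paths["tgs"])
  write_fasta(slrA$scaffolds, paths["slrA"])
  write_fasta(slrB$scaffolds, paths["slrB"])
  write.table(truth$variants, paths["variants"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tgs$ledger, paths["errors"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- tibble::tibble(file = basename(paths),
                             md5 = unname(tools::md5sum(paths)))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
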