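test_that("k-mer sets are canonical and window-counted", {
  ks <- kmerize("ACGT", k = 3)
  expect_equal(sum(ks$n), 2)  # n - k + 1 windows
  # a sequence and its reverse complement give identical canonical sets
  s <- "ACGTTGCAACGGT"
  expect_equal(dplyr::arrange(kmerize(s, 5), kmer),
               dplyr::arrange(kmerize(revcomp(s), 5), kmer),
               ignore_attr = TRUE)
  # windows containing N are skipped
  expect_equal(sum(kmerize("ACNGT", 3)$n), 0)
  expect_equal(sum(kmerize("ACGNACGT", 3)$n), 3)  # ACG, ACG, CGT survive
  # solid filter
  ks <- kmerize(c("ACGTA", "ACGTA"), 4, min_count = 2)
  expect_true(all(ks$n >= 2))
  expect_warning(kmerize("ACG", k = 21), "larger than every")
})

test_that("hapmer catalogs come from trio set algebra and stay disjoint", {
  pat <- c("AAA", "CCC", "GGA")
  mat <- c("AAA", "TTA")
  off <- c("CCC", "TTA", "GGA", "AAA")
  cat <- build_hapmers(pat, mat, off)
  expect_setequal(cat$pat, c("CCC", "GGA"))
  expect_setequal(cat$mat, "TTA")
  expect_length(intersect(cat$pat, cat$mat), 0)
  # identical parents: no haplotype-specific k-mers at all
  cat0 <- build_hapmers(pat, pat, off)
  expect_length(cat0$pat, 0)
  expect_length(cat0$mat, 0)
  expect_error(build_hapmers(kmerize("ACGTACG", 3), kmerize("ACGTACG", 5),
                             kmerize("ACGTACG", 5)), "mismatched k")
})

test_that("hapmer catalogs are disjoint for random trios", {
  set.seed(77)
  for (case in 1:20) {
    mk <- function(n) unique(replicate(n, paste(
      sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")))
    cat <- build_hapmers(mk(30), mk(30), mk(60))
    expect_length(intersect(cat$pat, cat$mat), 0)
  }
})

test_that("haplotyping metrics follow the precision/recall/F1 formulas", {
  # 50 correct + 50 wrong of 200 expected
  cat <- list(pat = paste0("P", 1:200), mat = paste0("M", 1:200), k = 2L)
  class(cat) <- "hapmer_catalog"
  asm <- c(paste0("P", 1:50), paste0("M", 1:50))
  m <- haplotyping_metrics(asm, cat, "paternal")
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.25)
  expect_equal(m$f1, 1 / 3)
  # an assembly holding exactly its own hapmers is perfect
  m2 <- haplotyping_metrics(paste0("P", 1:200), cat, "paternal")
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 1)
  expect_equal(m2$f1, 1)
  expect_error(haplotyping_metrics(asm, structure(
    list(pat = character(), mat = character(), k = 2L),
    class = "hapmer_catalog")), "empty hapmer catalog")
})

test_that("published precision/recall pairs reproduce their F1 scores", {
  # worked examples: trio-based haplotyping rows (percent scale)
  p <- c(72.65, 73.20, 94.27, 53.36, 46.79, 74.06)
  r <- c(49.14, 48.47, 51.79, 36.76, 37.04, 49.81)
  f1 <- c(58.63, 58.32, 66.85, 43.53, 41.35, 59.56)
  expect_equal(round(f1_score(p, r), 2), f1)
})

test_that("F1 is bounded by the arithmetic mean with equality iff p == r", {
  set.seed(13)
  p <- runif(200)
  r <- runif(200)
  expect_true(all(f1_score(p, r) <= (p + r) / 2 + 1e-12))
  expect_equal(f1_score(p, p), p)
})

test_that("k-mer QV follows the survival-rate convention", {
  asm <- paste0("K", 1:100)
  expect_equal(kmer_qv(asm, asm, k = 21)$qv, 99)         # error-free cap
  expect_equal(kmer_qv(asm, character(), k = 21)$qv, 0)  # all bad
  # closed-form check: 1000 bad of 1e6 at k = 21
  p <- 1 - (1 - 1000 / 1e6)^(1 / 21)
  expect_equal(-10 * log10(p), 43.2233, tolerance = 1e-4)
  expect_error(kmer_qv(character(), asm, k = 21), "empty assembly")
})

test_that("QV strictly decreases as bad k-mers accumulate", {
  reads <- paste0("R", 1:1000)
  qvs <- vapply(c(0, 5, 50, 200), function(nbad) {
    asm <- c(paste0("R", 1:800), if (nbad > 0) paste0("X", seq_len(nbad)))
    kmer_qv(asm, reads, k = 21)$qv
  }, numeric(1))
  expect_true(all(diff(qvs) < 0))
})

test_that("completeness is the recovered solid fraction", {
  solid <- paste0("S", 1:10000)
  expect_equal(kmer_completeness(solid, solid), 1)
  expect_equal(kmer_completeness(solid[1:9000], solid), 0.9)
  expect_equal(kmer_completeness(character(), solid), 0)
  expect_error(kmer_completeness(solid, character()), "empty solid")
})

test_that("phase blocks absorb reverting markers and split on persistent ones", {
  cfg <- phase_block_config(window = 1000)
  # five same-haplotype markers: one block, no switches
  tr <- tibble::tibble(name = "c", pos = c(0, 100, 200, 300, 400),
                       hap = "pat")
  pb <- phase_blocks(tr, cfg)
  expect_equal(nrow(pb$blocks), 1)
  expect_equal(pb$n_switch, 0)
  # P P P M P P with the M reverting within the window: one block, 1 switch
  tr <- tibble::tibble(name = "c", pos = c(0, 100, 200, 300, 400, 500),
                       hap = c("pat", "pat", "pat", "mat", "pat", "pat"))
  pb <- phase_blocks(tr, cfg)
  expect_equal(nrow(pb$blocks), 1)
  expect_equal(pb$n_switch, 1)
  expect_equal(pb$switch_rate, 1 / 6)
  # persistent other-haplotype run: two blocks, no absorbed switches
  tr <- tibble::tibble(name = "c", pos = c(0, 100, 200, 300, 400, 500),
                       hap = c(rep("pat", 3), rep("mat", 3)))
  pb <- phase_blocks(tr, cfg)
  expect_equal(nrow(pb$blocks), 2)
  expect_equal(pb$n_switch, 0)
  # a gap larger than the window terminates the block
  tr <- tibble::tibble(name = "c", pos = c(0, 100, 5000, 5100, 5200, 5300),
                       hap = "pat")
  pb <- phase_blocks(tr, cfg)
  expect_equal(nrow(pb$blocks), 1)  # 2-marker fragment dropped (min 3)
  expect_equal(pb$blocks$start, 5000)
})

test_that("switch DP reproduces trivial cases", {
  all_ok <- tibble::tibble(pos = seq(0, 900, by = 100), match = TRUE)
  res <- switch_errors(all_ok)
  expect_equal(res$summary$n_short, 0L)
  expect_equal(res$summary$n_long, 0L)
  # one isolated mismatch among 10: one short switch
  flags <- rep(TRUE, 10); flags[5] <- FALSE
  res <- switch_errors(tibble::tibble(pos = seq(0, 900, by = 100),
                                      match = flags))
  expect_equal(res$summary$n_short, 1L)
  expect_equal(res$summary$n_long, 0L)
  expect_equal(res$summary$penalty, 1)
  # last 10 of 20 flipped: one long switch beats ten short ones
  flags <- c(rep(TRUE, 10), rep(FALSE, 10))
  res <- switch_errors(tibble::tibble(pos = seq(0, 1900, by = 100),
                                      match = flags))
  expect_equal(res$summary$n_short, 0L)
  expect_equal(res$summary$n_long, 1L)
  expect_equal(res$summary$penalty, 5)
  expect_equal(res$summary$n_blocks, 2L)
  # empty input
  expect_equal(switch_errors(tibble::tibble(pos = numeric(),
                                            match = logical()))$summary$penalty,
               0)
})

test_that("switch DP equals exhaustive minimization on random instances", {
  set.seed(99)
  for (case in 1:200) {
    n <- sample(1:12, 1)
    match <- runif(n) < 0.7
    res <- switch_errors(tibble::tibble(pos = sort(sample.int(10000, n)),
                                        match = match))
    expect_equal(res$summary$penalty, brute_force_switch(match),
                 info = paste("case", case))
  }
})

test_that("phased SNP ratio is a guarded division", {
  expect_equal(phased_snp_ratio(0, 100), 0)
  expect_equal(phased_snp_ratio(100, 100), 1)
  expect_equal(phased_snp_ratio(6881, 10000), 0.6881)
  expect_error(phased_snp_ratio(1, 0), "positive")
})

test_that("Nx statistics follow the cumulative-length definition", {
  expect_equal(nx_stats(100)$n50, 100)
  st <- nx_stats(c(50, 40, 30, 20, 10))
  expect_equal(st$n50, 40)
  expect_equal(st$total, 150)
  expect_equal(st$max, 50)
  st <- nx_stats(c(50, 40, 30, 20, 10), genome_size = 150)
  expect_equal(st$ng50, st$n50)
  # NG50 >= N50 whenever the genome is no larger than the assembly
  set.seed(3)
  for (case in 1:20) {
    lens <- sample.int(1000, sample(3:12, 1))
    g <- round(sum(lens) * runif(1, 0.3, 1))
    st <- nx_stats(lens, genome_size = g)
    expect_gte(st$ng50, st$n50)
  }
  expect_error(nx_stats(numeric()), "empty")
})

test_that("hapmer tracks locate markers at heterozygous sites", {
  fx <- small_fixture(seed = 81L, genome = 30000L, n_small = 0L,
                      n_large = 0L)
  truth <- fx$truth
  trio <- simulate_trio_kmers(truth, k = 21)
  cat <- build_hapmers(trio$pat, trio$mat, trio$offspring)
  track <- hapmer_track(fasta_tbl("hapA", truth$hapA), cat)
  expect_gt(nrow(track), 0)
  expect_true(all(track$hap == "pat"))
  # every marker window overlaps a ledgered variant position on haplotype A
  k <- cat$k
  covered <- vapply(track$pos, function(p)
    any(truth$variants$pos_a >= p - 1 &
          truth$variants$pos_a < p + k + 1), logical(1))
  expect_true(all(covered))
})
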