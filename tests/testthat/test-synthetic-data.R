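test_that("fixtures are byte-identical under a fixed seed", {
  cfg <- sim_config(genome_size = 20000L, tgs_n_small = 10L,
                    tgs_n_large = 1L, seed = 42L)
  t1 <- simulate_diploid(cfg)
  t2 <- simulate_diploid(cfg)
  expect_identical(t1$hapA, t2$hapA)
  expect_identical(t1$variants, t2$variants)
  a1 <- simulate_tgs_assembly(t1, cfg)
  a2 <- simulate_tgs_assembly(t2, cfg)
  expect_identical(a1$contigs, a2$contigs)
  expect_identical(a1$ledger, a2$ledger)
  s1 <- simulate_slr_assembly(t1$hapA, cfg)
  s2 <- simulate_slr_assembly(t2$hapA, cfg)
  expect_identical(s1$scaffolds, s2$scaffolds)
  # different seed, different genome
  t3 <- simulate_diploid(sim_config(genome_size = 20000L, seed = 43L))
  expect_false(identical(t1$hapA, t3$hapA))
})

test_that("zero heterozygosity collapses the diploid to the reference", {
  cfg <- sim_config(genome_size = 10000L, het_snp_rate = 0,
                    het_indel_rate = 0, seed = 1L)
  truth <- simulate_diploid(cfg)
  expect_identical(truth$hapA, truth$reference)
  expect_identical(truth$hapB, truth$reference)
  expect_equal(nrow(truth$variants), 0)
})

test_that("SNP counts match the binomial placement model", {
  cfg <- sim_config(genome_size = 100000L, het_snp_rate = 0.001,
                    het_indel_rate = 0, seed = 5L)
  truth <- simulate_diploid(cfg)
  n <- sum(truth$variants$type == "snp")
  mu <- 100000 * 0.001
  sigma <- sqrt(mu * (1 - 0.001))
  expect_lt(abs(n - mu), 4 * sigma)
})

test_that("the variant ledger replays haplotype A into haplotype B", {
  for (seed in c(2L, 3L)) {
    cfg <- sim_config(genome_size = 50000L, seed = seed)
    truth <- simulate_diploid(cfg)
    expect_gt(nrow(truth$variants), 0)
    expect_identical(replay_variants(truth), truth$hapB)
    expect_true(all(diff(truth$variants$pos) > 0))
  }
})

test_that("the error ledger replays clean contigs into erroneous ones", {
  cfg <- sim_config(genome_size = 50000L, tgs_n_small = 20L,
                    tgs_n_large = 2L, seed = 8L)
  truth <- simulate_diploid(cfg)
  tgs <- simulate_tgs_assembly(truth, cfg)
  expect_equal(sum(tgs$ledger$class == "small"), 20)
  expect_equal(sum(tgs$ledger$class == "large"), 2)
  replayed <- replay_errors(tgs$truth_contigs, tgs$ledger)
  expect_identical(replayed$seq, tgs$contigs$seq)
  # event sizes respect the class boundary and do not overlap
  expect_true(all(tgs$ledger$len[tgs$ledger$class == "small"] < 50))
  expect_true(all(tgs$ledger$len[tgs$ledger$class == "large"] >= 50))
  led <- dplyr::arrange(tgs$ledger, contig, pos)
  ends <- led$pos + nchar(led$ref)
  expect_true(all(led$pos[-1] >= head(ends, -1) |
                    led$contig[-1] != head(led$contig, -1)))
})

test_that("zero error rates give clean contigs and an empty ledger", {
  cfg <- sim_config(genome_size = 20000L, tgs_n_small = 0L,
                    tgs_n_large = 0L, seed = 4L)
  truth <- simulate_diploid(cfg)
  tgs <- simulate_tgs_assembly(truth, cfg)
  expect_identical(tgs$contigs$seq, tgs$truth_contigs$seq)
  expect_equal(nrow(tgs$ledger), 0)
})

test_that("a collapsed assembly interleaves both haplotypes", {
  cfg <- sim_config(genome_size = 60000L, tgs_haplotype = "collapsed",
                    collapse_segment = 20000L, tgs_n_small = 0L,
                    tgs_n_large = 0L, seed = 6L)
  truth <- simulate_diploid(cfg)
  tgs <- simulate_tgs_assembly(truth, cfg)
  expect_setequal(unique(tgs$source$hap), c("A", "B"))
  # segment bounds tile the reference
  expect_equal(tgs$source$ref_start[1], 0)
  expect_equal(tail(tgs$source$ref_end, 1), nchar(truth$reference))
  expect_equal(tgs$source$ref_start[-1], head(tgs$source$ref_end, -1))
})

test_that("SLR scaffolds copy the haplotype exactly outside N runs", {
  cfg <- sim_config(genome_size = 60000L, slr_fragment_mean = 15000L,
                    slr_gap_rate = 0.6, seed = 9L)
  truth <- simulate_diploid(cfg)
  slr <- simulate_slr_assembly(truth$hapA, cfg)
  cov <- slr$coverage
  seqs <- setNames(slr$scaffolds$seq, slr$scaffolds$name)
  for (i in seq_len(nrow(cov))) {
    frag <- substr(seqs[[cov$scaffold[i]]], cov$scaf_start[i] + 1,
                   cov$scaf_end[i])
    expect_identical(frag, substr(truth$hapA, cov$hap_start[i] + 1,
                                  cov$hap_end[i]))
  }
  # coverage tiles the haplotype completely
  expect_equal(min(cov$hap_start), 0)
  expect_equal(max(cov$hap_end), nchar(truth$hapA))
  expect_equal(sort(cov$hap_start)[-1],
               sort(cov$hap_end)[-nrow(cov)])
  # scaffold length accounting: non-N bases + N bases
  total_n <- sum(vapply(slr$scaffolds$seq, function(s)
    sum(strsplit(s, "")[[1]] == "N"), numeric(1)))
  expect_equal(sum(nchar(slr$scaffolds$seq)),
               nchar(truth$hapA) + total_n)
})

test_that("a single uncut fragment reproduces the haplotype", {
  cfg <- sim_config(genome_size = 10000L, slr_fragment_mean = 100000L,
                    slr_gap_rate = 0, seed = 10L)
  truth <- simulate_diploid(cfg)
  slr <- simulate_slr_assembly(truth$hapA, cfg)
  expect_equal(nrow(slr$scaffolds), 1)
  expect_identical(slr$scaffolds$seq[1], truth$hapA)
})

test_that("trio k-mer sets obey their constructive relations", {
  cfg <- sim_config(genome_size = 30000L, seed = 12L)
  truth <- simulate_diploid(cfg)
  trio <- simulate_trio_kmers(truth, k = 21)
  expect_setequal(trio$offspring$kmer,
                  union(trio$pat$kmer, trio$mat$kmer))
  # with contamination the offspring gains k-mers absent from both parents
  trio_c <- simulate_trio_kmers(truth, k = 21, contamination_rate = 0.01)
  extra <- setdiff(trio_c$offspring$kmer,
                   union(trio_c$pat$kmer, trio_c$mat$kmer))
  expect_gt(length(extra), 0)
  # identical haplotypes leave no haplotype-specific k-mers
  cfg0 <- sim_config(genome_size = 10000L, het_snp_rate = 0,
                     het_indel_rate = 0, seed = 13L)
  truth0 <- simulate_diploid(cfg0)
  trio0 <- simulate_trio_kmers(truth0, k = 21)
  cat0 <- build_hapmers(trio0$pat, trio0$mat, trio0$offspring)
  expect_length(cat0$pat, 0)
  expect_length(cat0$mat, 0)
})

test_that("paternal-specific k-mers all cover a heterozygous site", {
  cfg <- sim_config(genome_size = 30000L, seed = 14L)
  truth <- simulate_diploid(cfg)
  trio <- simulate_trio_kmers(truth, k = 21)
  cat <- build_hapmers(trio$pat, trio$mat, trio$offspring)
  track <- hapmer_track(fasta_tbl("hapA", truth$hapA), cat)
  pat_pos <- track$pos[track$hap == "pat"]
  hits <- vapply(pat_pos, function(p)
    any(truth$variants$pos_a >= p - 1 &
          truth$variants$pos_a < p + 21 + 1), logical(1))
  expect_true(all(hits))
})
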