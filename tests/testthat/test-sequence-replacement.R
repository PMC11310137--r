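empty_edits_for_test <- function() {
  tibble::tibble(pos = integer(), ref = character(), alt = character())
}

region <- function(ts, te, qs = ts, qe = te, tname = "tigA",
                   qname = "scaf", strand = "+") {
  tibble::tibble(tname = tname, tstart = ts, tend = te, qname = qname,
                 qstart = qs, qend = qe, strand = strand)
}

test_that("regions cluster by contig and sort by start", {
  r <- dplyr::bind_rows(region(50, 100, tname = "Y"),
                        region(0, 40, tname = "X"),
                        region(10, 30, tname = "Y"),
                        region(60, 90, tname = "X"))
  out <- cluster_regions(r)
  expect_equal(out$tname, c("X", "X", "Y", "Y"))
  expect_equal(out$tstart, c(0, 60, 10, 50))
  expect_equal(nrow(cluster_regions(r[0, ])), 0)
})

test_that("overlap resolution follows the containment and priority rules", {
  # (a) containment: later region dropped
  out <- resolve_overlaps(dplyr::bind_rows(region(0, 100), region(20, 80)))
  expect_equal(out$tstart, 0)
  expect_equal(out$tend, 100)
  # (b) partial overlap: later region has priority, earlier truncated
  out <- resolve_overlaps(dplyr::bind_rows(region(0, 100), region(60, 160)))
  expect_equal(out$tstart, c(0, 60))
  expect_equal(out$tend, c(60, 160))
  expect_equal(out$qend[1], 60)  # query shortened proportionally
  # disjoint: unchanged
  out <- resolve_overlaps(dplyr::bind_rows(region(0, 50), region(60, 100)))
  expect_equal(out$tend, c(50, 100))
  # duplicates collapse through the containment rule
  out <- resolve_overlaps(dplyr::bind_rows(region(0, 50), region(0, 50)))
  expect_equal(nrow(out), 1)
})

test_that("resolved regions are always disjoint and sorted", {
  set.seed(31)
  for (case in 1:40) {
    n <- sample(2:8, 1)
    ts <- sample.int(500, n)
    r <- region(ts, ts + sample.int(200, n))
    out <- resolve_overlaps(cluster_regions(r))
    if (nrow(out) > 1) {
      expect_true(all(diff(out$tstart) > 0))
      expect_true(all(out$tstart[-1] >= head(out$tend, -1)))
    }
  }
})

test_that("cs operations convert to absolute-coordinate edits", {
  e <- edits_from_cs(":3*ga:4", target_offset = 10, tname = "t",
                     query_seg = "AAAAAAAA")
  expect_equal(e$pos, 13)
  expect_equal(e$ref, "G")
  expect_equal(e$alt, "A")

  e <- edits_from_cs(":5+tt:5", target_offset = 0, tname = "t",
                     query_seg = paste(rep("A", 12), collapse = ""))
  expect_equal(e$kind, "insertion")
  expect_equal(e$pos, 5)
  expect_equal(e$alt, "TT")
  expect_equal(e$length, 2)

  expect_equal(nrow(edits_from_cs(":10", 0, "t", "ACGTACGTAC")), 0)
})

test_that("identical segments produce no edits", {
  seqs <- strrep("ACGTGGTCA", 20)
  e <- edits_from_alignment(seqs, seqs)
  expect_equal(nrow(e), 0)
})

test_that("the length threshold is strict and the N rule dominates", {
  cfg <- mix_config()
  edits <- tibble::tibble(
    tname = "t", pos = c(0L, 100L, 200L, 300L),
    kind = c("deletion", "insertion", "insertion", "substitution"),
    ref = c(strrep("A", 49), "", "", "G"),
    alt = c("", strrep("C", 50), "ANA", "T"),
    length = c(49L, 50L, 3L, 1L),
    near_n = c(FALSE, FALSE, FALSE, TRUE))
  out <- filter_edits(edits, cfg)
  expect_equal(out$status, c("applied", "skipped_threshold", "skipped_N",
                             "skipped_N"))
  # N rule can be disabled
  out2 <- filter_edits(edits, mix_config(skip_n = FALSE))
  expect_equal(out2$status[3:4], c("applied", "applied"))
})

test_that("edit application preserves untouched bases and length accounting", {
  expect_equal(apply_edits("ACGTACGT", empty_edits_for_test()), "ACGTACGT")
  sub <- tibble::tibble(pos = 2L, ref = "G", alt = "T")
  expect_equal(apply_edits("ACGTACGT", sub), "ACTTACGT")
  del <- tibble::tibble(pos = 4L, ref = "AC", alt = "")
  expect_equal(apply_edits("ACGTACGT", del), "ACGTGT")
  ins <- tibble::tibble(pos = 4L, ref = "", alt = "GGG")
  expect_equal(apply_edits("ACGTACGT", ins), "ACGTGGGACGT")

  both <- tibble::tibble(pos = c(1L, 5L), ref = c("C", "C"),
                         alt = c("CTT", ""))
  out <- apply_edits("ACGTACGT", both)
  expect_equal(nchar(out), 8 + 2 - 1)
  expect_equal(substr(out, 1, 1), "A")

  overlap <- tibble::tibble(pos = c(2L, 3L), ref = c("GT", "TA"),
                            alt = c("", ""))
  expect_error(apply_edits("ACGTACGT", overlap), "overlapping")
})

test_that("mixing an assembly with itself changes nothing", {
  fx <- small_fixture(seed = 61L, genome = 30000L, n_small = 0L,
                      n_large = 0L)
  tgs <- fx$tgs$contigs
  mx <- mix_assemblies(tgs, tgs)
  expect_identical(mx$assembly$seq, tgs$seq)
  expect_equal(mx$report$global$applied, 0)
})

test_that("ledgered small events are corrected and large ones left alone", {
  fx <- small_fixture(seed = 62L)
  mx <- mix_assemblies(fx$tgs$contigs, fx$slr$scaffolds)
  g <- mx$report$global
  expect_equal(g$applied, 20)
  # the only over-threshold non-N events are the two injected large ones
  expect_equal(sum(mx$edits$status == "skipped_threshold" &
                     !grepl("N", mx$edits$alt, fixed = TRUE)), 2)
  expected <- replay_errors(fx$tgs$truth_contigs, fx$tgs$ledger,
                            classes = "large")
  expect_identical(mx$assembly$seq, expected$seq)
})

test_that("length conservation holds exactly", {
  fx <- small_fixture(seed = 63L)
  mx <- mix_assemblies(fx$tgs$contigs, fx$slr$scaffolds)
  applied <- mx$edits[mx$edits$status == "applied", ]
  delta <- sum(nchar(applied$alt)) - sum(nchar(applied$ref))
  expect_equal(sum(nchar(mx$assembly$seq)) - sum(nchar(fx$tgs$contigs$seq)),
               delta)
  # per contig as well
  for (i in seq_len(nrow(mx$assembly))) {
    a <- applied[applied$tname == mx$assembly$name[i], ]
    expect_equal(nchar(mx$assembly$seq[i]) - nchar(fx$tgs$contigs$seq[i]),
                 sum(nchar(a$alt)) - sum(nchar(a$ref)))
  }
})

test_that("bases outside applied edit footprints are untouched", {
  fx <- small_fixture(seed = 64L, genome = 40000L, n_small = 10L,
                      n_large = 1L)
  mx <- mix_assemblies(fx$tgs$contigs, fx$slr$scaffolds)
  applied <- mx$edits[mx$edits$status == "applied", ]
  input <- fx$tgs$contigs$seq[1]
  # mask out applied footprints (plus inserted bases) and compare flanks
  first <- min(applied$pos)
  expect_equal(substr(mx$assembly$seq[1], 1, first),
               substr(input, 1, first))
  tail_len <- nchar(input) - max(applied$pos + nchar(applied$ref))
  expect_equal(substring(mx$assembly$seq[1],
                         nchar(mx$assembly$seq[1]) - tail_len + 1),
               substring(input, nchar(input) - tail_len + 1))
})

test_that("a second mixing pass applies no further edits", {
  fx <- small_fixture(seed = 65L, n_large = 0L)
  mx1 <- mix_assemblies(fx$tgs$contigs, fx$slr$scaffolds)
  mx2 <- mix_assemblies(mx1$assembly, fx$slr$scaffolds)
  expect_lte(mx2$report$global$applied, mx1$report$global$applied)
  expect_equal(mx2$report$global$applied, 0)
  expect_identical(mx2$assembly$seq, mx1$assembly$seq)
})

test_that("mismatched PAF and assembly names fail before any work", {
  fx <- small_fixture(seed = 66L, genome = 30000L, n_small = 2L,
                      n_large = 0L)
  paf <- align_assemblies(fx$slr$scaffolds, fx$tgs$contigs)
  paf$tname <- "other"
  expect_error(mix_assemblies(fx$tgs$contigs, fx$slr$scaffolds, paf = paf),
               "do not match")
})
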