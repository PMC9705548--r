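test_that("baits are the 3' suffixes of collapsed isoacceptor sequences", {
  m1 <- paste0(strrep("G", 40), "AATCCTCTGACCTGGGTTCGAATCCCAGTACGACCT")
  catalog <- toy_catalog(c(m1, m1), isotype = "Gln", anticodon = "TTG")
  baits <- build_baits(catalog, bait_length = 36)
  expect_equal(nrow(baits), 1)  # identical isodecoders collapse
  expect_equal(baits$bait, "AATCCTCTGACCTGGGTTCGAATCCCAGTACGACCT")
  expect_equal(nchar(baits$bait), 36)
  expect_equal(baits$discriminator, "T")
})

test_that("bait collisions across isoacceptors are a hard error", {
  shared_suffix <- strrep("A", 10)
  catalog <- toy_catalog(c(paste0(strrep("G", 60), shared_suffix),
                           paste0(strrep("C", 60), shared_suffix)),
                         isotype = c("Gln", "Gly"),
                         anticodon = c("TTG", "GCC"))
  expect_error(build_baits(catalog, bait_length = 10), "collision")
  baits <- build_baits(catalog, bait_length = 20)
  expect_equal(nrow(baits), 2)
  expect_error(build_baits(catalog, bait_length = 100), "shortest")
})

test_that("fishing assigns exact substring matches and discards ambiguity", {
  catalog <- toy_catalog(c(paste0(strrep("G", 30), strrep("A", 10)),
                           paste0(strrep("C", 30), strrep("T", 8), "GA")),
                         isotype = c("Gln", "Gly"),
                         anticodon = c("TTG", "GCC"))
  baits <- build_baits(catalog, bait_length = 12)
  b1 <- baits$bait[1]; b2 <- baits$bait[2]
  reads <- c(paste0(b1, "CCA"),          # assigned, mature
             paste0("GG", b1, "TT"),     # assigned, U2
             paste0(b1, b2),             # ambiguous
             "ACGTACGTACGTACGT",         # unmatched
             paste0(substring(b1, 2), "CCA"))  # too short a match fragment
  fished <- fish_reads(reads, baits)
  expect_equal(attr(fished, "n_assigned"), 2)
  expect_equal(attr(fished, "n_ambiguous"), 1)
  expect_equal(attr(fished, "n_unmatched"), 2)
  # one internal mismatch breaks the exact-match contract
  mut <- paste0(sub("A", "C", b1), "CCA")
  expect_equal(attr(fish_reads(mut, baits), "n_assigned"), 0)
})

test_that("tail classification follows the CCA / U-run / cap rules", {
  bait <- "ACGTACGTACGC"  # aperiodic, so the bait anchor is unambiguous
  expect_equal(classify_tail(paste0(bait, "CCA"), bait), "CCA")
  expect_equal(classify_tail(paste0(bait, "TT"), bait), "U2")
  expect_equal(classify_tail(paste0(bait, strrep("T", 12)), bait), "U10")
  expect_equal(classify_tail(paste0(bait, "GTT"), bait), "UNCLASSIFIED")
  expect_equal(classify_tail(bait, bait), "UNCLASSIFIED")
  # rightmost occurrence anchors the suffix
  read <- paste0(bait, "AA", bait, "TTT")
  expect_equal(classify_tail(read, bait), "U3")
})

test_that("classify_tail agrees with a brute-force oracle on random reads", {
  withr::with_seed(13, {
    n <- 100000
    bait <- paste(sample(c("A", "C", "G"), 15, replace = TRUE), collapse = "")
    suffix_pool <- c("CCA", vapply(1:12, function(k) strrep("T", k), ""),
                     "", "GTT", "TCA", "CCAA", "TTA")
    suffixes <- sample(suffix_pool, n, replace = TRUE)
    reads <- paste0(sample(c("", "AC", "GGG"), n, replace = TRUE),
                    bait, suffixes)
    got <- classify_tail(reads, bait)
    idx <- sample(n, 2000)  # oracle is slow; spot-check a random subset
    want <- vapply(reads[idx], brute_tail_oracle, character(1), bait = bait,
                   USE.NAMES = FALSE)
    expect_identical(got[idx], want)
    # full-vector agreement with direct suffix arithmetic
    expect_identical(got, ifelse(suffixes == "CCA", "CCA",
                          ifelse(grepl("^T+$", suffixes),
                                 paste0("U", pmin(nchar(suffixes), 10)),
                                 "UNCLASSIFIED")))
  })
})

test_that("bin counts conserve assigned reads and CPM sums to one million", {
  sim <- simulate_genome(species_profile(n_genes = 40, n_isoacceptors = 10),
                         seed = 17)
  catalog <- extract_genes(sim$genome, sim$annotations)
  baits <- build_baits(catalog)
  rep1 <- simulate_reads(catalog, read_sim_config(depth = 5000), "input", "WT",
                         seed = 2)
  fished <- fish_reads(rep1$reads, baits)
  counts <- tabulate_bins(fished, baits, "rep1")
  expect_equal(sum(counts$count), attr(counts, "total_fished"))
  expect_equal(sum(counts$count), nrow(fished))
  cpm <- cpm_normalize(counts)
  expect_equal(sum(cpm$cpm), 1e6, tolerance = 1e-9)
  # doubling raw counts leaves CPM unchanged
  doubled <- counts; doubled$count <- doubled$count * 2L
  expect_equal(cpm_normalize(doubled)$cpm, cpm$cpm)
  # per-bin denominator normalises within bins
  per_bin <- cpm_normalize(counts, denominator = "bin")
  cca <- per_bin[per_bin$bin == "CCA", ]
  expect_equal(sum(cca$cpm), 1e6, tolerance = 1e-9)
})

test_that("cpm examples: {2,3,5} of 10 give {2,3,5}e5", {
  counts <- data.frame(replicate = "r", isoacceptor = c("a", "b", "c"),
                       bin = "CCA", count = c(2L, 3L, 5L))
  cpm <- cpm_normalize(counts)
  expect_equal(cpm$cpm, c(2e5, 3e5, 5e5))
  zero <- counts; zero$count <- 0L
  expect_error(cpm_normalize(zero), "zero fished")
})

test_that("fold enrichment sums premature bins and applies log2(fold + 1)", {
  ip <- toy_cpm(list(iso1 = c(U1 = 200, U2 = 100, CCA = 50)), "ip1")
  input <- toy_cpm(list(iso1 = c(U1 = 60, U2 = 40, CCA = 100)), "in1")
  en <- fold_enrichment(ip, input, pseudocount = 0)
  expect_equal(en$premature_fold, 3)
  expect_equal(en$premature_log2p1, 2)
  expect_equal(en$mature_log2p1, log2(0.5 + 1))
  # IP == input -> fold 1 -> log2(2) = 1
  en2 <- fold_enrichment(input, input, pseudocount = 0)
  expect_equal(en2$premature_log2p1, 1)
  # zero IP with pseudocount stays defined and near zero
  ip0 <- toy_cpm(list(iso1 = c(CCA = 100)), "ip1")
  en3 <- fold_enrichment(ip0, input, pseudocount = 0.01)
  expect_lt(en3$premature_log2p1, 0.001)
  expect_gte(en3$premature_log2p1, 0)
})

test_that("cumulative tail table is non-increasing under the >=-length rule", {
  cpm <- toy_cpm(list(iso1 = c(U1 = 10, U2 = 10)))
  cum <- cumulative_tail_table(cpm)
  expect_equal(cum$cumulative_cpm[cum$tail_length <= 3], c(20, 10, 0))
  expect_equal(cum$log10p1[1], log10(21))
  single <- cumulative_tail_table(toy_cpm(list(iso1 = c(U1 = 5))))
  expect_equal(single$cumulative_cpm[single$tail_length >= 2], rep(0, 9))
  # property: non-increasing on random tables
  withr::with_seed(23, {
    for (i in 1:10) {
      tb <- toy_cpm(list(x = setNames(rpois(10, 20), paste0("U", 1:10))))
      cc <- cumulative_tail_table(tb)
      expect_true(all(diff(cc$cumulative_cpm) <= 1e-12))
    }
  })
  # ==-length convention returns the per-length CPM
  eq <- cumulative_tail_table(cpm, convention = "eq")
  expect_equal(eq$cumulative_cpm[eq$tail_length <= 2], c(10, 10))
})

test_that("presence scoring is strictly greater than log10(2)", {
  cpm <- toy_cpm(list(iso1 = c(U1 = 0.30, U2 = 0.4, U3 = 0)))
  pr <- tail_presence(cpm)
  expect_false(pr$present[pr$tail_length == 1])   # 0.30 < log10(2)
  expect_true(pr$present[pr$tail_length == 2])
  expect_false(pr$present[pr$tail_length == 3])
})

test_that("two-way presence ANOVA matches a least-squares oracle and is null on identical data", {
  presence_df <- function(rep_id, counts) {
    # counts: named vector tail_length -> number of present isoacceptors (of 6)
    do.call(rbind, lapply(as.integer(names(counts)), function(L) {
      data.frame(replicate = rep_id,
                 isoacceptor = paste0("iso", 1:6),
                 tail_length = L,
                 cpm = 1,
                 present = seq_len(6) <= counts[[as.character(L)]])
    }))
  }
  wt <- rbind(presence_df("w1", c(`1` = 5, `2` = 3, `3` = 1)),
              presence_df("w2", c(`1` = 4, `2` = 2, `3` = 2)))
  ko <- rbind(presence_df("k1", c(`1` = 6, `2` = 5, `3` = 4)),
              presence_df("k2", c(`1` = 5, `2` = 6, `3` = 3)))
  res <- presence_anova(wt, ko)
  y <- c(5, 3, 1, 4, 2, 2, 6, 5, 4, 5, 6, 3)
  a <- rep(c("WT", "KO"), each = 6)
  b <- rep(rep(1:3, 2), 2)
  oracle <- twoway_oracle(y, a, b)
  expect_equal(res$anova["condition", "F value"], oracle$F_a, tolerance = 1e-8)
  expect_equal(res$anova["tail_length", "F value"], oracle$F_b, tolerance = 1e-8)
  expect_equal(res$anova["condition:tail_length", "F value"], oracle$F_ab,
               tolerance = 1e-8)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p - 1e-12))
  # identical WT and KO inputs -> all adjusted p = 1
  same <- presence_anova(wt, wt)
  expect_equal(same$pairwise$p_adj, rep(1, 3))
})

test_that("a uniform KO presence shift produces a condition main effect", {
  presence_df <- function(rep_id, base) {
    do.call(rbind, lapply(1:4, function(L) {
      data.frame(replicate = rep_id, isoacceptor = paste0("iso", 1:10),
                 tail_length = L, cpm = 1,
                 present = seq_len(10) <= base[L])
    }))
  }
  wt <- rbind(presence_df("w1", c(6, 4, 2, 1)), presence_df("w2", c(5, 4, 3, 1)))
  ko <- rbind(presence_df("k1", c(6, 4, 2, 1) + 3),
              presence_df("k2", c(5, 4, 3, 1) + 3))
  res <- presence_anova(wt, ko)
  expect_lt(res$anova["condition", "Pr(>F)"], 0.01)
})

test_that("correlation statistics behave on constructed vectors", {
  cpm <- c(Ala = 2, Gly = 4, Val = 8, Leu = 16)
  copies <- c(Ala = 1, Gly = 2, Val = 3, Leu = 4)
  expect_equal(copy_number_correlation(cpm, copies)$r, 1)
  anti <- c(Ala = 4, Gly = 3, Val = 2, Leu = 1)
  expect_equal(copy_number_correlation(cpm, anti)$r, -1)
  expect_error(copy_number_correlation(cpm[1:2], copies[1:2]), ">= 3")
  expect_error(copy_number_correlation(c(a = 2, b = 2, c = 2),
                                       c(a = 1, b = 2, c = 3)), "variance")

  en <- data.frame(isoacceptor = c("a", "b", "c", "d"),
                   premature_log2p1 = c(4, 3, 2, 1))
  tr <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(enrichment_vs_trailer(en, tr)$r, -1)
})
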