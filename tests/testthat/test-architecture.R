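test_that("scan_terminator finds the first k-T run offset", {
  expect_equal(scan_terminator("TTTTACG", 4)$trailer_length, 0L)
  expect_equal(scan_terminator("ATTTT", 4)$trailer_length, 1L)
  # frozen from the all-offsets oracle
  expect_equal(brute_scan_oracle("ACGTTTGTTTTA", 4), 7L)
  expect_equal(scan_terminator("ACGTTTGTTTTA", 4)$trailer_length, 7L)
  expect_equal(brute_scan_oracle("ACGTTTGTTTTA", 3), 3L)
  expect_equal(scan_terminator("ACGTTTGTTTTA", 3)$trailer_length, 3L)
  expect_false(scan_terminator("ACGACG", 4)$terminator_found)
  expect_false(scan_terminator("", 4)$terminator_found)
  # a run may not span an N
  expect_equal(scan_terminator("TTNTTTTT", 4)$trailer_length, 3L)
})

test_that("summarize_species applies the exclusion cap and tie-breaks the mode", {
  catalog <- toy_catalog(rep(strrep("G", 73), 3) |> paste0("A"),
                         downstream = c("TTTT", "ATTTT", "AATTTT"))
  calls <- scan_terminators(catalog)
  st <- summarize_species(calls, catalog)
  expect_equal(st$trailer_mean, 1)
  expect_equal(st$trailer_sd, 1)          # sample SD of 0,1,2
  expect_equal(st$trailer_mode, 0L)       # tie among 0,1,2 -> smallest
  expect_equal(sum(st$trailer_histogram), st$n_trailer_analyzed)

  catalog2 <- toy_catalog(rep(paste0(strrep("G", 73), "A"), 3),
                          downstream = c("TTTT", "TTTT",
                                         paste0(strrep("A", 21), "TTTT")))
  calls2 <- scan_terminators(catalog2, max_trailer = 20)
  st2 <- summarize_species(calls2, catalog2)
  expect_equal(st2$n_trailer_analyzed, 2L)
  expect_equal(st2$trailer_mean, 0)
  expect_true(calls2$excluded[3])
})

test_that("undetermined genes are excluded from stats unless requested", {
  catalog <- toy_catalog(rep(paste0(strrep("G", 73), "A"), 4),
                         isotype = c("Gln", "Gln", "Und", "Gln"),
                         downstream = c("TTTT", "ATTTT", "AAAATTTT", "TTTT"))
  calls <- scan_terminators(catalog)
  st <- summarize_species(calls, catalog)
  expect_equal(st$n_genes_total, 4L)
  expect_equal(st$n_genes_determined, 3L)
  expect_equal(st$n_trailer_analyzed, 3L)
  st_all <- summarize_species(calls, catalog, include_undetermined = TRUE)
  expect_equal(st_all$n_trailer_analyzed, 4L)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7))
  res <- compare_species_anova(groups)
  expect_equal(res$F, 13)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  # identical groups -> F = 0
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(compare_species_anova(same)$F, 0)
  # degenerate: no within-group variance at all
  expect_error(compare_species_anova(list(a = c(1, 1), b = c(2, 2))),
               "undefined")
  # random-case agreement with the oracle
  withr::with_seed(11, {
    for (i in 1:20) {
      g <- lapply(1:sample(2:5, 1), function(j) rnorm(sample(3:8, 1), j))
      names(g) <- paste0("g", seq_along(g))
      expect_equal(compare_species_anova(g)$F, anova_oracle(g)$F)
    }
  })
})

test_that("summary-statistic ANOVA reconstruction matches the per-value ANOVA", {
  withr::with_seed(3, {
    g <- list(a = rnorm(10), b = rnorm(12, 1), c = rnorm(8, 2))
    full <- compare_species_anova(g)
    summ <- anova_from_summary(lengths(g), sapply(g, mean), sapply(g, sd))
    expect_equal(summ$F, full$F)
    expect_equal(summ$p, full$p)
  })
})

test_that("Tukey post-hoc agrees with a studentized-range oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7))
  tk <- tukey_posthoc(groups)
  expect_equal(sort(tk$p_adj), sort(unname(tukey_oracle(groups))),
               tolerance = 1e-8)
  # two identical groups -> adjusted p = 1
  tk2 <- tukey_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(tk2$p_adj, 1, tolerance = 1e-9)
  # the far-outlying pair has the smallest adjusted p
  g3 <- list(a = c(1, 2, 3), b = c(1.5, 2.5, 3.5), c = c(50, 51, 52))
  tk3 <- tukey_posthoc(g3)
  expect_equal(tk3$comparison[which.min(tk3$p_adj)] %in% c("c-a", "a-c"), TRUE)
})

test_that("shuffled-label ANOVA F has the null mean df_w/(df_w - 2)", {
  withr::with_seed(19, {
    pooled <- rnorm(30)
    sizes <- c(10, 10, 10)
    fs <- replicate(1000, {
      x <- sample(pooled)
      compare_species_anova(split(x, rep(1:3, sizes)))$F
    })
    dfw <- 27
    expect_equal(mean(fs), dfw / (dfw - 2), tolerance = 0.1)
  })
})

test_that("leader logo counts and frequencies are consistent", {
  up <- c(paste0(strrep("C", 19), "A"),
          paste0(strrep("C", 19), "A"),
          paste0(strrep("C", 19), "A"))
  catalog <- toy_catalog(rep(paste0(strrep("G", 73), "A"), 3), upstream = up)
  lg <- leader_logo(catalog, window = 5)
  expect_equal(unname(lg$frequencies["A", "N-1"]), 1)
  expect_equal(unname(colSums(lg$frequencies)), rep(1, 5))
  expect_equal(sum(lg$counts), 5 * 3)
  # conditioned logos partition the unconditioned counts
  sim <- simulate_genome(species_profile(n_genes = 120, n_isoacceptors = 20),
                         seed = 33)
  catalog2 <- extract_genes(sim$genome, sim$annotations)
  lg_all <- leader_logo(catalog2)
  parts <- lapply(c("A", "C", "G", "T"), function(b)
    suppressWarnings(leader_logo(catalog2, condition = b))$counts)
  expect_equal(Reduce(`+`, parts), lg_all$counts)
  # short flanks are dropped with a warning
  catalog$upstream_flank[1] <- "ACG"
  expect_warning(leader_logo(catalog, window = 5), "short")
})

test_that("discriminator composition sums to one and errors on empty input", {
  catalog <- toy_catalog(c(paste0(strrep("G", 73), "A"),
                           paste0(strrep("G", 73), "A"),
                           paste0(strrep("G", 73), "G"),
                           paste0(strrep("G", 73), "T")))
  dc <- discriminator_composition(catalog)
  expect_equal(sum(dc), 1)
  expect_equal(unname(dc["A"]), 0.5)
  expect_error(discriminator_composition(catalog[0, ]), "empty")
})

test_that("pairing avoidance enumerates Watson-Crick complements", {
  # four genes: N73/N-1 = A/A, A/C, T/A, G/A (frozen enumeration)
  catalog <- toy_catalog(
    c(paste0(strrep("G", 73), "A"), paste0(strrep("G", 73), "A"),
      paste0(strrep("G", 73), "T"), paste0(strrep("G", 73), "G")),
    upstream = c(paste0(strrep("C", 19), "A"), paste0(strrep("C", 19), "C"),
                 paste0(strrep("C", 19), "A"), paste0(strrep("C", 19), "A")))
  pt <- pairing_avoidance(catalog)
  expect_equal(pt$wc_complement_frequency[pt$discriminator == "A"], 0)
  expect_equal(pt$wc_complement_frequency[pt$discriminator == "T"], 1)
  expect_equal(pt$wc_complement_frequency[pt$discriminator == "G"], 0)
  expect_equal(sum(pt$n_genes), 4)
  fr <- pt[pt$discriminator == "A", c("freq_A", "freq_C", "freq_G", "freq_T")]
  expect_equal(sum(fr), 1)
  # always-complementary set -> all frequencies 1
  catalog2 <- toy_catalog(
    c(paste0(strrep("G", 73), "A"), paste0(strrep("G", 73), "C")),
    upstream = c(paste0(strrep("C", 19), "T"), paste0(strrep("C", 19), "G")))
  pt2 <- pairing_avoidance(catalog2)
  expect_equal(pt2$wc_complement_frequency, rep(1, nrow(pt2)))
})

test_that("trailer length is monotone non-decreasing in the run length k", {
  withr::with_seed(7, {
    flanks <- random_flanks(300)
    prev <- scan_terminator(flanks, 3)$trailer_length
    for (k in 4:7) {
      cur <- scan_terminator(flanks, k)$trailer_length
      both <- !is.na(prev) & !is.na(cur)
      expect_true(all(cur[both] >= prev[both]))
      prev <- cur
    }
  })
})
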