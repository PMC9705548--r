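## Architecture analysis: 3'-trailer terminator scanning, mature lengths,
## per-species summaries, cross-species ANOVA/Tukey, leader logos and
## leader/trailer pairing-avoidance statistics.

#' Scan a downstream flank for a poly-T Pol III terminator
#'
#' The 3'-trailer length is the number of nucleotides between the
#' discriminator base and the first genomic stretch of at least `min_run`
#' consecutive Ts: the smallest offset `d >= 0` such that positions
#' `d..d+min_run-1` of the flank are all `T`. Runs may be longer than
#' `min_run` (only the start offset matters) and may not span an `N`.
#'
#' @param flank character vector of downstream flanks in transcript
#'   orientation, starting immediately 3' of N73.
#' @param min_run minimum run length `k >= 1` (default 4).
#' @return data.frame with columns `min_run`, `terminator_found`,
#'   `trailer_length` (NA when not found).
#' @export
scan_terminator <- function(flank, min_run = 4L) {
  stopifnot(min_run >= 1L)
  pos <- regexpr(paste0("T{", as.integer(min_run), "}"), flank)
  found <- !is.na(flank) & nzchar(flank) & pos > 0L
  data.frame(min_run = as.integer(min_run),
             terminator_found = found,
             trailer_length = ifelse(found, as.integer(pos) - 1L, NA_integer_))
}

#' Terminator scan over a gene catalog
#'
#' Applies [scan_terminator()] to every downstream flank and marks trailers
#' longer than `max_trailer` as excluded. Genes with an empty flank are
#' flagged `short_flank`.
#'
#' @param catalog a `trna_catalog`.
#' @param min_run minimum T-run length (default 4).
#' @param max_trailer trailers longer than this are excluded from the
#'   analysis (default 20).
#' @return data.frame with columns `gene_id`, `min_run`,
#'   `terminator_found`, `trailer_length`, `excluded`, `flags`.
#' @export
scan_terminators <- function(catalog, min_run = 4L, max_trailer = 20L) {
  sc <- scan_terminator(catalog$downstream_flank, min_run = min_run)
  out <- data.frame(gene_id = catalog$gene_id, sc,
                    excluded = !is.na(sc$trailer_length) &
                      sc$trailer_length > max_trailer,
                    flags = ifelse(nzchar(catalog$downstream_flank), "", "short_flank"),
                    stringsAsFactors = FALSE)
  out
}

#' Mature tRNA length
#'
#' Length of the spliced mature sequence, from nucleotide +1 to the
#' discriminator base N73, excluding introns (and the post-transcriptional
#' CCA, which is never genomic here).
#'
#' @param catalog a `trna_catalog` (or any data.frame with a
#'   `mature_sequence` column).
#' @return integer vector of lengths.
#' @export
mature_length <- function(catalog) {
  len <- nchar(catalog$mature_sequence)
  if (any(len == 0L)) stop_invariant("empty mature sequence in catalog")
  len
}

#' Per-species architecture summary
#'
#' Mean/SD of 3'-trailer length over genes with a terminator found and not
#' excluded by the `max_trailer` cap, mean/SD of mature length, and the
#' trailer length histogram with its mode (ties broken toward the smaller
#' length). Sample (n-1) standard deviations throughout. Genes with
#' undetermined isotype/anticodon are excluded unless
#' `include_undetermined = TRUE`.
#'
#' @param calls data.frame from [scan_terminators()].
#' @param catalog the matching `trna_catalog`.
#' @param include_undetermined include isotype `Und` / anticodon `NNN` genes.
#' @return an `architecture_stats` list: `species`, `n_genes_total`,
#'   `n_genes_determined`, `n_trailer_analyzed`, `trailer_mean`,
#'   `trailer_sd`, `trailer_mode`, `mature_mean`, `mature_sd`,
#'   `trailer_histogram` (named integer vector length -> count).
#' @export
summarize_species <- function(calls, catalog, include_undetermined = FALSE) {
  n_total <- nrow(catalog)
  det <- determined_genes(catalog)
  use_cat <- if (include_undetermined) catalog else det
  calls <- calls[match(use_cat$gene_id, calls$gene_id), , drop = FALSE]
  ok <- calls$terminator_found & !calls$excluded
  tl <- calls$trailer_length[ok]
  if (length(tl) == 0L) {
    warning("no analyzable trailers; statistics undefined")
    return(structure(list(species = unique(catalog$species),
                          n_genes_total = n_total,
                          n_genes_determined = nrow(det),
                          n_trailer_analyzed = 0L,
                          trailer_mean = NA_real_, trailer_sd = NA_real_,
                          trailer_mode = NA_integer_,
                          mature_mean = mean(mature_length(use_cat)),
                          mature_sd = sd(mature_length(use_cat)),
                          trailer_histogram = integer(0)),
                     class = "architecture_stats"))
  }
  hist <- table(factor(tl, levels = seq(min(tl), max(tl))))
  hist <- setNames(as.integer(hist), names(hist))
  mode_len <- as.integer(names(hist)[which.max(hist)])  # which.max: first = smallest length
  ml <- mature_length(use_cat)
  structure(list(species = unique(catalog$species),
                 n_genes_total = n_total,
                 n_genes_determined = nrow(det),
                 n_trailer_analyzed = length(tl),
                 trailer_mean = mean(tl), trailer_sd = sd(tl),
                 trailer_mode = mode_len,
                 mature_mean = mean(ml), mature_sd = sd(ml),
                 trailer_histogram = hist),
            class = "architecture_stats")
}

#' @export
print.architecture_stats <- function(x, ...) {
  cat(sprintf(
    "%s: %d genes (%d determined), %d trailers analyzed\n  trailer %.2f +/- %.2f nt (mode %s), mature %.1f +/- %.1f nt\n",
    x$species, x$n_genes_total, x$n_genes_determined, x$n_trailer_analyzed,
    x$trailer_mean, x$trailer_sd, x$trailer_mode, x$mature_mean, x$mature_sd))
  invisible(x)
}

#' One-way fixed-effects ANOVA across species
#'
#' Classic one-way ANOVA (`F = MS_between / MS_within`) over a named list of
#' per-species value vectors (trailer or mature lengths).
#'
#' @param groups named list of numeric vectors; `>= 2` groups with `>= 2`
#'   values each.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
compare_species_anova <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  ssw <- sum((y - stats::ave(y, g))^2)
  if (ssw <= 1e-12 * max(1, sum((y - mean(y))^2))) {
    stop_invariant("zero within-group variance in every group; F undefined")
  }
  tab <- anova(lm(y ~ g))
  list(F = unname(tab["g", "F value"]),
       df_between = unname(tab["g", "Df"]),
       df_within = unname(tab["Residuals", "Df"]),
       p = unname(tab["g", "Pr(>F)"]))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way fixed-effects F statistic from per-group sample
#' sizes, means and (sample) standard deviations, e.g. from a published
#' summary table.
#'
#' @param n,mean,sd equal-length numeric vectors of group summaries.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_from_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd), length(n) >= 2L)
  N <- sum(n); k <- length(n)
  grand <- sum(n * mean) / N
  ms_between <- sum(n * (mean - grand)^2) / (k - 1)
  ms_within <- sum((n - 1) * sd^2) / (N - k)
  if (ms_within == 0) stop_invariant("zero within-group variance; F undefined")
  F <- ms_between / ms_within
  list(F = F, df_between = k - 1L, df_within = as.integer(N - k),
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise comparisons with studentized-range adjusted p-values,
#' following a one-way ANOVA.
#'
#' @inheritParams compare_species_anova
#' @return data.frame with columns `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_posthoc <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  tk <- TukeyHSD(aov(y ~ g))$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 5'-leader position frequency matrix ("logo")
#'
#' Base counts and frequencies at leader positions `N-W .. N-1` (the W
#' 3'-most bases of the upstream flank), optionally restricted to genes with
#' a given discriminator base N73. Genes whose flank is shorter than the
#' window, or contains `N` inside it, are dropped with a warning.
#'
#' @param catalog a `trna_catalog`.
#' @param window window width W in nt (default 10).
#' @param condition optional discriminator base (`"A"`, `"C"`, `"G"`,
#'   `"T"`): restrict to genes with that N73.
#' @return a `leader_matrix` list: `counts` and `frequencies` (4 x W
#'   matrices, rows A/C/G/T, columns `N-W`..`N-1`), `window`, `condition`,
#'   `n_sequences`.
#' @export
leader_logo <- function(catalog, window = 10L, condition = NULL) {
  genes <- catalog
  if (!is.null(condition)) {
    stopifnot(condition %in% DNA_BASES)
    genes <- genes[genes$discriminator == condition, , drop = FALSE]
  }
  wseq <- substring(genes$upstream_flank,
                    nchar(genes$upstream_flank) - window + 1L,
                    nchar(genes$upstream_flank))
  ok <- nchar(genes$upstream_flank) >= window & !grepl("N", wseq, fixed = TRUE)
  if (any(!ok)) {
    warning("dropping ", sum(!ok),
            " gene(s) with short or ambiguous leader window")
  }
  wseq <- wseq[ok]
  positions <- paste0("N-", rev(seq_len(window)))
  counts <- matrix(0L, nrow = 4L, ncol = window,
                   dimnames = list(DNA_BASES, positions))
  if (length(wseq)) {
    chars <- matrix(unlist(strsplit(wseq, "", fixed = TRUE), use.names = FALSE),
                    ncol = window, byrow = TRUE)
    for (j in seq_len(window)) {
      tb <- table(factor(chars[, j], levels = DNA_BASES))
      counts[, j] <- as.integer(tb)
    }
  } else {
    warning("no qualifying genes; empty leader matrix")
  }
  freq <- sweep(counts, 2L, pmax(colSums(counts), 1L), "/")
  structure(list(counts = counts, frequencies = freq, window = window,
                 condition = condition, n_sequences = length(wseq)),
            class = "leader_matrix")
}

#' Discriminator base (N73) composition
#'
#' @param catalog a nonempty `trna_catalog`.
#' @return named numeric vector of A/C/G/T frequencies summing to 1.
#' @export
discriminator_composition <- function(catalog) {
  if (nrow(catalog) == 0L) stop_input("empty gene set")
  tb <- table(factor(catalog$discriminator, levels = DNA_BASES))
  as.numeric(tb) / sum(tb) -> f
  setNames(f, DNA_BASES)
}

#' Leader/trailer Watson-Crick pairing avoidance
#'
#' For each discriminator base `b`, the fraction of genes whose N-1 leader
#' base is the Watson-Crick DNA complement of `b` (A-T, C-G), compared with
#' the frequency expected under independence (the marginal N-1 frequency of
#' `complement(b)`). Quantifies avoidance of N73/N-1 base pairing.
#'
#' @param catalog a `trna_catalog`; genes with an empty upstream flank are
#'   dropped.
#' @return data.frame with one row per observed discriminator base:
#'   `discriminator`, `n_genes`, `freq_A/C/G/T` (N-1 composition),
#'   `wc_complement_frequency`, `expected_frequency`.
#' @export
pairing_avoidance <- function(catalog) {
  genes <- catalog[nzchar(catalog$upstream_flank), , drop = FALSE]
  if (nrow(genes) == 0L) stop_input("no genes with a defined N-1 base")
  nminus1 <- substring(genes$upstream_flank, nchar(genes$upstream_flank))
  keep <- nminus1 %in% DNA_BASES & genes$discriminator %in% DNA_BASES
  genes <- genes[keep, , drop = FALSE]; nminus1 <- nminus1[keep]
  marginal <- table(factor(nminus1, levels = DNA_BASES)) / length(nminus1)
  rows <- lapply(DNA_BASES, function(b) {
    sel <- genes$discriminator == b
    if (!any(sel)) return(NULL)
    comp <- wc_complement(b)
    f <- table(factor(nminus1[sel], levels = DNA_BASES)) / sum(sel)
    data.frame(discriminator = b, n_genes = sum(sel),
               freq_A = f[["A"]], freq_C = f[["C"]],
               freq_G = f[["G"]], freq_T = f[["T"]],
               wc_complement_frequency = f[[comp]],
               expected_frequency = marginal[[comp]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
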