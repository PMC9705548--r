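## Tail classification: bait construction, read fishing, 3'-end binning
## (CCA vs U1..U10), CPM normalisation, IP/input enrichment, cumulative
## tail tables, presence scoring and correlation statistics.

TAIL_BINS <- c("CCA", paste0("U", 1:10), "UNCLASSIFIED")

#' Build unique 3'-end bait sequences per isoacceptor
#'
#' Collapses identical-sequence isodecoders, then takes the `bait_length`-nt
#' 3' suffix of each spliced mature sequence (the bait ends at the
#' discriminator base). Baits must be unique across isoacceptors; a
#' collision is a hard error naming the colliding isoacceptors (increase
#' `bait_length`). Distinct isodecoder sequences within one isoacceptor get
#' separate bait entries (`bait_id` suffixed `#2`, `#3`, ...) whose counts
#' are aggregated per isoacceptor downstream.
#'
#' @param catalog a `trna_catalog`.
#' @param bait_length bait length B in nt (default 36, the length of the
#'   canonical Gln-TTG example bait).
#' @return a `bait_set` data.frame: `bait_id`, `isoacceptor`, `isotype`,
#'   `anticodon`, `bait`, `discriminator`.
#' @export
build_baits <- function(catalog, bait_length = 36L) {
  if (bait_length > min(nchar(catalog$mature_sequence))) {
    stop_input("bait_length ", bait_length,
               " exceeds the shortest mature sequence (",
               min(nchar(catalog$mature_sequence)), " nt)")
  }
  iso <- paste(catalog$isotype, catalog$anticodon, sep = "-")
  key <- paste(iso, catalog$mature_sequence)
  first <- !duplicated(key)
  df <- data.frame(isoacceptor = iso[first],
                   isotype = catalog$isotype[first],
                   anticodon = catalog$anticodon[first],
                   mature = catalog$mature_sequence[first],
                   stringsAsFactors = FALSE)
  df$bait <- substring(df$mature, nchar(df$mature) - bait_length + 1L)
  df$discriminator <- substring(df$bait, nchar(df$bait))
  ## same suffix from several isodecoders of one isoacceptor -> one entry
  df <- df[!duplicated(paste(df$isoacceptor, df$bait)), , drop = FALSE]
  ## any bait still duplicated now spans two distinct isoacceptors
  dup <- duplicated(df$bait) | duplicated(df$bait, fromLast = TRUE)
  if (any(dup)) {
    clash <- df[dup, , drop = FALSE]
    clash <- clash[order(clash$bait), ]
    stop_input("bait collision at length ", bait_length, " between: ",
               paste(unique(clash$isoacceptor), collapse = ", "),
               "; increase bait_length")
  }
  idx <- stats::ave(seq_len(nrow(df)), df$isoacceptor, FUN = seq_along)
  df$bait_id <- ifelse(idx == 1L, df$isoacceptor,
                       paste0(df$isoacceptor, "#", idx))
  out <- df[, c("bait_id", "isoacceptor", "isotype", "anticodon",
                "bait", "discriminator")]
  rownames(out) <- NULL
  class(out) <- c("bait_set", "data.frame")
  out
}

#' Read a FASTQ file into a character vector of read sequences
#'
#' @param path FASTQ file, optionally gzipped.
#' @return character vector of DNA read sequences (uppercase, U -> T).
#' @export
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) stop_input("FASTQ not found: ", path)
  reads <- Biostrings::readBStringSet(path, format = "fastq")
  chartr("U", "T", toupper(as.character(reads)))
}

#' Fish reads by exact bait match
#'
#' A read is assigned to an isoacceptor iff its sequence contains that
#' isoacceptor's bait as an exact substring (no mismatches). Reads matching
#' two or more baits are discarded as ambiguous; unmatched reads are
#' ignored. Both are counted for audit.
#'
#' @param reads character vector of read sequences, or a FASTQ path.
#' @param baits a `bait_set` from [build_baits()].
#' @return data.frame of assigned reads with columns `read_index`,
#'   `sequence`, `bait_id`, `isoacceptor`, `bait`; attributes `n_reads`,
#'   `n_assigned`, `n_ambiguous`, `n_unmatched`.
#' @export
fish_reads <- function(reads, baits) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq_sequences(reads)
  }
  n <- length(reads)
  hit_count <- integer(n)
  hit_idx <- integer(n)
  for (b in seq_len(nrow(baits))) {
    hits <- stringi::stri_detect_fixed(reads, baits$bait[b])
    hit_count <- hit_count + hits
    hit_idx[hits] <- b
  }
  assigned <- hit_count == 1L
  out <- data.frame(read_index = which(assigned),
                    sequence = reads[assigned],
                    bait_id = baits$bait_id[hit_idx[assigned]],
                    isoacceptor = baits$isoacceptor[hit_idx[assigned]],
                    bait = baits$bait[hit_idx[assigned]],
                    stringsAsFactors = FALSE)
  attr(out, "n_reads") <- n
  attr(out, "n_assigned") <- sum(assigned)
  attr(out, "n_ambiguous") <- sum(hit_count >= 2L)
  attr(out, "n_unmatched") <- sum(hit_count == 0L)
  out
}

#' Classify the 3' end of a fished read
#'
#' Uses the rightmost occurrence of the bait in the read (the bait ends at
#' the discriminator base) and inspects the suffix `S` after it:
#' `S == "CCA"` is a mature tRNA; `S == "T" x n` with `1 <= n <= 10` is a
#' uridylate-tailed precursor `Un` (tails longer than 10 are capped into
#' `U10`); anything else, including an empty suffix, is `UNCLASSIFIED`.
#' Reads are in DNA space, so uridylates appear as `T`.
#'
#' @param read_sequence,bait character vectors (recycled to a common
#'   length).
#' @return character vector of bins (`"CCA"`, `"U1"`..`"U10"`,
#'   `"UNCLASSIFIED"`).
#' @export
classify_tail <- function(read_sequence, bait) {
  loc <- stringi::stri_locate_last_fixed(read_sequence, bait)
  if (anyNA(loc[, 2])) stop_invariant("read does not contain its bait")
  suffix <- substring(read_sequence, loc[, 2] + 1L)
  bin <- rep("UNCLASSIFIED", length(suffix))
  bin[suffix == "CCA"] <- "CCA"
  is_u <- grepl("^T+$", suffix)
  bin[is_u] <- paste0("U", pmin(nchar(suffix[is_u]), 10L))
  bin
}

#' Tabulate fished reads into a bin-count table
#'
#' @param fished data.frame from [fish_reads()].
#' @param baits the `bait_set` used (defines the full isoacceptor set, so
#'   zero-count isoacceptors appear).
#' @param replicate replicate identifier.
#' @return long-format `bin_counts` data.frame: `replicate`, `isoacceptor`,
#'   `bin`, `count`; attribute `total_fished` (= number of assigned reads,
#'   equal to the sum of all counts including UNCLASSIFIED).
#' @export
tabulate_bins <- function(fished, baits, replicate = "rep1") {
  bin <- classify_tail(fished$sequence, fished$bait)
  iso_levels <- unique(baits$isoacceptor)
  tb <- table(factor(fished$isoacceptor, levels = iso_levels),
              factor(bin, levels = TAIL_BINS))
  out <- as.data.frame(tb, stringsAsFactors = FALSE)
  names(out) <- c("isoacceptor", "bin", "count")
  out <- data.frame(replicate = replicate, out, stringsAsFactors = FALSE)
  out$count <- as.integer(out$count)
  if (sum(out$count) != nrow(fished)) {
    stop_invariant("bin counts do not conserve assigned reads")
  }
  attr(out, "total_fished") <- nrow(fished)
  out
}

#' Counts-per-million normalisation
#'
#' `CPM(i, b) = count(i, b) / (total / 1e6)`. By default the denominator is
#' the total number of fished reads in the replicate (classified +
#' unclassified), so CPM sums to 1e6 per replicate. `denominator = "bin"`
#' instead normalises within each 3'-end bin (CPM sums to 1e6 per bin).
#'
#' @param counts a `bin_counts` data.frame (may contain several
#'   replicates).
#' @param denominator `"replicate"` (default) or `"bin"`.
#' @return the table with a `cpm` column added.
#' @export
cpm_normalize <- function(counts, denominator = c("replicate", "bin")) {
  denominator <- match.arg(denominator)
  key <- if (denominator == "replicate") counts$replicate
         else paste(counts$replicate, counts$bin)
  totals <- tapply(counts$count, key, sum)
  if (denominator == "replicate" && any(totals == 0)) {
    stop_input("replicate with zero fished reads")
  }
  tot <- as.numeric(totals[key])
  counts$cpm <- ifelse(tot > 0, counts$count / (tot / 1e6), 0)
  counts
}

mean_cpm_matrix <- function(cpm) {
  ## average CPM across replicates -> isoacceptor x bin matrix
  tb <- tapply(cpm$cpm, list(cpm$isoacceptor, factor(cpm$bin, levels = TAIL_BINS)),
               mean)
  tb[is.na(tb)] <- 0
  tb
}

#' IP/input fold enrichment per isoacceptor
#'
#' Premature CPMs are summed over U1..U10 before the ratio; mature is the
#' CCA bin. With several replicates per table the arithmetic mean CPM is
#' taken first. Enrichment is reported as `log2(fold + 1)`; the pseudocount
#' is added to numerator and denominator to keep ratios defined at zero
#' input.
#'
#' @param ip,input CPM tables from [cpm_normalize()] (any number of
#'   replicates each).
#' @param pseudocount CPM pseudocount added to both sides (default 0.01).
#' @return data.frame per isoacceptor: `premature_ip_cpm`,
#'   `premature_input_cpm`, `mature_ip_cpm`, `mature_input_cpm`,
#'   `premature_fold`, `mature_fold`, `premature_log2p1`, `mature_log2p1`.
#' @export
fold_enrichment <- function(ip, input, pseudocount = 0.01) {
  m_ip <- mean_cpm_matrix(ip); m_in <- mean_cpm_matrix(input)
  iso <- sort(intersect(rownames(m_ip), rownames(m_in)))
  if (!setequal(rownames(m_ip), rownames(m_in))) {
    stop_input("IP and input tables cover different isoacceptor sets")
  }
  u_bins <- paste0("U", 1:10)
  pre_ip <- rowSums(m_ip[iso, u_bins, drop = FALSE])
  pre_in <- rowSums(m_in[iso, u_bins, drop = FALSE])
  mat_ip <- m_ip[iso, "CCA"]; mat_in <- m_in[iso, "CCA"]
  pre_fold <- (pre_ip + pseudocount) / (pre_in + pseudocount)
  mat_fold <- (mat_ip + pseudocount) / (mat_in + pseudocount)
  data.frame(isoacceptor = iso,
             premature_ip_cpm = pre_ip, premature_input_cpm = pre_in,
             mature_ip_cpm = mat_ip, mature_input_cpm = mat_in,
             premature_fold = pre_fold, mature_fold = mat_fold,
             premature_log2p1 = log2(pre_fold + 1),
             mature_log2p1 = log2(mat_fold + 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative uridylate tail table
#'
#' For each isoacceptor and tail length L, the cumulative CPM of tails of
#' length >= L (default convention; `convention = "eq"` reports the
#' per-length CPM instead), displayed after a `log10(1 + x)` transform. The
#' >=-length convention is non-increasing in L.
#'
#' @param cpm a CPM table.
#' @param convention `"ge"` (tails >= L, default) or `"eq"` (exactly L).
#' @return long data.frame: `replicate`, `isoacceptor`, `tail_length`
#'   (1..10), `cumulative_cpm`, `log10p1`.
#' @export
cumulative_tail_table <- function(cpm, convention = c("ge", "eq")) {
  convention <- match.arg(convention)
  u <- cpm[cpm$bin %in% paste0("U", 1:10), , drop = FALSE]
  u$tail_length <- as.integer(sub("^U", "", u$bin))
  parts <- lapply(split(u, list(u$replicate, u$isoacceptor), drop = TRUE),
    function(d) {
      d <- d[order(d$tail_length), ]
      val <- if (convention == "ge") rev(cumsum(rev(d$cpm))) else d$cpm
      data.frame(replicate = d$replicate[1], isoacceptor = d$isoacceptor[1],
                 tail_length = d$tail_length, cumulative_cpm = val,
                 log10p1 = log10(1 + val), stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Score uridylate tail presence
#'
#' A tail length is scored present for an isoacceptor if its abundance in
#' CPM is strictly greater than the threshold (default `log10(2)`, i.e.
#' 0.3010...).
#'
#' @param cpm a CPM table.
#' @param threshold CPM presence threshold (default `log10(2)`).
#' @return long data.frame: `replicate`, `isoacceptor`, `tail_length`,
#'   `cpm`, `present`.
#' @export
tail_presence <- function(cpm, threshold = log10(2)) {
  u <- cpm[cpm$bin %in% paste0("U", 1:10), , drop = FALSE]
  data.frame(replicate = u$replicate, isoacceptor = u$isoacceptor,
             tail_length = as.integer(sub("^U", "", u$bin)),
             cpm = u$cpm, present = u$cpm > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-way ANOVA on tail-presence counts
#'
#' Response: per-replicate number of isoacceptors scored present at each
#' tail length. Factors: condition (e.g. WT vs KO) and tail length. Type-II
#' sums of squares accommodate unbalanced replicate structure. Per-tail
#' condition comparisons are Welch t-tests with Bonferroni correction over
#' the number of tail lengths.
#'
#' @param wt,ko presence tables from [tail_presence()], each with >= 2
#'   replicates.
#' @return list with `anova` (type-II ANOVA table), `pairwise` (data.frame
#'   `tail_length`, `mean_wt`, `mean_ko`, `p`, `p_adj`).
#' @export
presence_anova <- function(wt, ko) {
  count_present <- function(p, condition) {
    agg <- stats::aggregate(present ~ replicate + tail_length, data = p, FUN = sum)
    data.frame(condition = condition, agg, stringsAsFactors = FALSE)
  }
  d <- rbind(count_present(wt, "WT"), count_present(ko, "KO"))
  if (min(table(d$condition)) < 2L) stop_input("need >= 2 replicates per condition")
  d$condition <- factor(d$condition, levels = c("WT", "KO"))
  d$tail_length <- factor(d$tail_length)
  fit <- lm(present ~ condition * tail_length, data = d)
  a2 <- car::Anova(fit, type = 2)
  lengths <- levels(d$tail_length)
  pw <- do.call(rbind, lapply(lengths, function(L) {
    x <- d$present[d$condition == "WT" & d$tail_length == L]
    y <- d$present[d$condition == "KO" & d$tail_length == L]
    p <- if (sd(c(x, y)) == 0 || (sd(x) == 0 && sd(y) == 0)) {
      if (mean(x) == mean(y)) 1 else 0
    } else t.test(x, y)$p.value
    data.frame(tail_length = as.integer(L), mean_wt = mean(x),
               mean_ko = mean(y), p = p, stringsAsFactors = FALSE)
  }))
  pw$p_adj <- pmin(pw$p * length(lengths), 1)
  list(anova = a2, pairwise = pw)
}

#' Correlation of expression with genomic copy number
#'
#' Pearson correlation of log2-transformed CPM per isotype against the
#' number of genes encoding that isotype.
#'
#' @param cpm_per_isotype named numeric vector of CPM (names = isotypes).
#' @param gene_copies_per_isotype named numeric vector of gene counts.
#' @return list with `r`, `n`, `p`.
#' @export
copy_number_correlation <- function(cpm_per_isotype, gene_copies_per_isotype) {
  iso <- intersect(names(cpm_per_isotype)[cpm_per_isotype > 0],
                   names(gene_copies_per_isotype))
  if (length(iso) < 3L) stop_input("need >= 3 isotypes with positive CPM")
  x <- log2(cpm_per_isotype[iso]); y <- gene_copies_per_isotype[iso]
  if (sd(x) == 0 || sd(y) == 0) stop_input("zero variance; correlation undefined")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), n = length(iso), p = ct$p.value)
}

#' Correlation of premature enrichment with mean trailer length
#'
#' Pearson correlation of premature `log2(fold + 1)` enrichment against the
#' mean genomic 3'-trailer length per isotype/isoacceptor.
#'
#' @param enrichment data.frame from [fold_enrichment()].
#' @param trailer_means named numeric vector of mean trailer lengths keyed
#'   like `enrichment$isoacceptor`.
#' @return list with `r`, `n`, `p`.
#' @export
enrichment_vs_trailer <- function(enrichment, trailer_means) {
  iso <- intersect(enrichment$isoacceptor, names(trailer_means))
  if (length(iso) < 3L) stop_input("need >= 3 matched isoacceptors")
  x <- enrichment$premature_log2p1[match(iso, enrichment$isoacceptor)]
  y <- trailer_means[iso]
  if (sd(x) == 0 || sd(y) == 0) stop_input("zero variance; correlation undefined")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), n = length(iso), p = ct$p.value)
}
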