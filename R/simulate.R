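## Synthetic data: seeded genome/annotation and read-set generators with
## exported ground truth, so every pipeline stage is testable without
## external downloads.

#' Define a synthetic species profile
#'
#' Generative parameters for a synthetic tRNA gene complement. Defaults
#' emulate a Tetrahymena-like architecture: 686 genes, geometric 3'-trailer
#' lengths with mean 1.5 nt (`p = 0.4`), discriminator composition
#' dominated by A (~50%) then G (~25%), N-1 leader composition dominated by
#' A (~75%), and strong avoidance (`alpha = 0.9`) of a Watson-Crick
#' complementary N-1 given N73.
#'
#' @param n_genes number of tRNA gene loci.
#' @param trailer_dist trailer length distribution: `list(family="point",
#'   value=L)`, `list(family="geometric", p=...)` (support 0,1,2,...; mean
#'   `(1-p)/p`) or `list(family="empirical", lengths=..., probs=...)`.
#' @param terminator_run length of the generated poly-T terminator run
#'   (>= 4).
#' @param leader_length generated 5'-leader length in nt.
#' @param leader_composition marginal base probabilities at leader positions
#'   other than N-1.
#' @param nminus1_marginal marginal base probabilities at N-1 before
#'   avoidance conditioning.
#' @param alpha pairing-avoidance strength in [0, 1]: the N-1 probability of
#'   the Watson-Crick complement of N73 is multiplied by `1 - alpha` and the
#'   distribution renormalised (`alpha = 1`: the complement is never drawn).
#' @param discriminator_dist base probabilities of the discriminator N73.
#' @param mature_length_mean,mature_length_sd mature length distribution
#'   (rounded normal, clipped to `[66, 82]` nt).
#' @param intron_prob per-gene probability of a single intron.
#' @param intron_length_range inclusive intron length range in nt.
#' @param n_isoacceptors number of distinct isoacceptor families the genes
#'   are drawn from (all copies of an isoacceptor share one mature
#'   sequence).
#' @return a validated `species_profile` list.
#' @export
species_profile <- function(n_genes = 686L,
                            trailer_dist = list(family = "geometric", p = 0.4),
                            terminator_run = 6L,
                            leader_length = 20L,
                            leader_composition = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35),
                            nminus1_marginal = c(A = 0.75, C = 0.09, G = 0.08, T = 0.08),
                            alpha = 0.9,
                            discriminator_dist = c(A = 0.50, C = 0.15, G = 0.25, T = 0.10),
                            mature_length_mean = 74, mature_length_sd = 3.4,
                            intron_prob = 0.1,
                            intron_length_range = c(10L, 30L),
                            n_isoacceptors = 40L) {
  p <- list(n_genes = as.integer(n_genes), trailer_dist = trailer_dist,
            terminator_run = as.integer(terminator_run),
            leader_length = as.integer(leader_length),
            leader_composition = leader_composition / sum(leader_composition),
            nminus1_marginal = nminus1_marginal / sum(nminus1_marginal),
            alpha = alpha,
            discriminator_dist = discriminator_dist / sum(discriminator_dist),
            mature_length_mean = mature_length_mean,
            mature_length_sd = mature_length_sd,
            intron_prob = intron_prob,
            intron_length_range = as.integer(intron_length_range),
            n_isoacceptors = as.integer(n_isoacceptors))
  stopifnot(p$n_genes > 0, p$terminator_run >= 4L,
            p$alpha >= 0, p$alpha <= 1,
            all(names(p$leader_composition) == DNA_BASES),
            all(names(p$discriminator_dist) == DNA_BASES),
            p$trailer_dist$family %in% c("point", "geometric", "empirical"))
  class(p) <- "species_profile"
  p
}

draw_trailer_lengths <- function(dist, n) {
  switch(dist$family,
    point = rep(as.integer(dist$value), n),
    geometric = stats::rgeom(n, prob = dist$p),
    empirical = sample(as.integer(dist$lengths), n, replace = TRUE,
                       prob = dist$probs))
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  stringi::stri_flatten(sample(DNA_BASES, n, replace = TRUE, prob = probs))
}

## conditional N-1 distribution: complement of N73 down-weighted by (1-alpha)
nminus1_conditional <- function(marginal, n73, alpha) {
  probs <- marginal
  comp <- wc_complement(n73)
  probs[comp] <- probs[comp] * (1 - alpha)
  probs / sum(probs)
}

#' Simulate a genome with embedded tRNA genes
#'
#' Places `n_genes` loci on random strands of a single synthetic contig,
#' each with a drawn 5'-leader (N-1 conditioned on N73 with the profile's
#' avoidance `alpha`), a spliced mature body (optionally interrupted by one
#' intron), a 3'-trailer of the drawn length, and a poly-T terminator run.
#' Trailer bases are drawn from {A, C, G} so the drawn length is exactly
#' the offset of the first >= 4-T run. Outputs are byte-identical for
#' identical seeds.
#'
#' @param profile a [species_profile()].
#' @param seed integer seed.
#' @param species species label.
#' @param out_dir if non-NULL, write `genome.fa`, `genes.bed` (BED12) and
#'   `truth.tsv` (with a `# seed=... profile_hash=...` header) there.
#' @return list with `genome` (named character), `annotations` (BED12-style
#'   data.frame as from [parse_annotations()]), `truth` (data.frame of all
#'   drawn quantities per gene) and, when written, `paths`.
#' @export
simulate_genome <- function(profile = species_profile(), seed = 1L,
                            species = "synthetic", out_dir = NULL) {
  withr::with_seed(as.integer(seed), {
    n <- profile$n_genes
    ## one mature sequence per isoacceptor family; copies are identical
    ## isodecoders. Isotype labels cycle through a fixed set.
    isotypes <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                  "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                  "Thr", "Trp", "Tyr", "Val")
    k <- profile$n_isoacceptors
    fam_isotype <- isotypes[((seq_len(k) - 1L) %% length(isotypes)) + 1L]
    fam_anticodon <- vapply(seq_len(k), function(i) random_dna(3L), character(1))
    fam_disc <- sample(DNA_BASES, k, replace = TRUE,
                       prob = profile$discriminator_dist)
    fam_len <- pmin(pmax(round(stats::rnorm(k, profile$mature_length_mean,
                                            profile$mature_length_sd)), 66L), 82L)
    fam_mature <- vapply(seq_len(k), function(i) {
      paste0(random_dna(fam_len[i] - 1L), fam_disc[i])
    }, character(1))
    ## gene copies per family: skewed so copy numbers vary across isotypes
    fam_weight <- stats::rgamma(k, shape = 1.5)
    fam_of_gene <- sample.int(k, n, replace = TRUE, prob = fam_weight)

    trailer_len <- draw_trailer_lengths(profile$trailer_dist, n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    has_intron <- stats::runif(n) < profile$intron_prob
    intron_len <- ifelse(has_intron,
                         sample(seq(profile$intron_length_range[1],
                                    profile$intron_length_range[2]),
                                n, replace = TRUE), 0L)

    pieces <- character(0)
    cursor <- 0L
    bed <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      fam <- fam_of_gene[i]
      mature <- fam_mature[fam]
      disc <- fam_disc[fam]
      L <- profile$leader_length
      leader_head <- random_dna(L - 1L, profile$leader_composition)
      nm1 <- sample(DNA_BASES, 1L,
                    prob = nminus1_conditional(profile$nminus1_marginal, disc,
                                               profile$alpha))
      leader <- paste0(leader_head, nm1)
      trailer <- if (trailer_len[i] > 0)
        random_dna(trailer_len[i], c(A = 1, C = 1, G = 1, T = 0) / 3) else ""
      terminator <- strrep("T", profile$terminator_run)
      ## intron inserted after transcript position 37 (canonical location)
      if (has_intron[i]) {
        at <- min(37L, nchar(mature) - 2L)
        body <- paste0(substring(mature, 1L, at),
                       random_dna(intron_len[i]),
                       substring(mature, at + 1L))
      } else {
        body <- mature
      }
      locus_tx <- paste0(leader, body, trailer, terminator, "G")
      spacer <- random_dna(sample(100:200, 1L))
      locus_genomic <- if (strand[i] == "+") locus_tx else revcomp(locus_tx)
      gene_id <- sprintf("tRNA-%s-%s-%d", fam_isotype[fam], fam_anticodon[fam], i)
      ## genomic coordinates of the gene body (leader/trailer excluded)
      if (strand[i] == "+") {
        gstart <- cursor + nchar(spacer) + L
        gend <- gstart + nchar(body)
        intron_iv <- if (has_intron[i]) {
          cbind(start = gstart + min(37L, nchar(mature) - 2L),
                end = gstart + min(37L, nchar(mature) - 2L) + intron_len[i])
        } else cbind(start = integer(0), end = integer(0))
      } else {
        tail_len <- nchar(trailer) + profile$terminator_run + 1L
        gstart <- cursor + nchar(spacer) + tail_len
        gend <- gstart + nchar(body)
        intron_iv <- if (has_intron[i]) {
          at <- min(37L, nchar(mature) - 2L)
          ## transcript interval (at, at+intron_len) maps to genomic
          iv_end <- gend - at
          cbind(start = iv_end - intron_len[i], end = iv_end)
        } else cbind(start = integer(0), end = integer(0))
      }
      pieces <- c(pieces, spacer, locus_genomic)
      cursor <- cursor + nchar(spacer) + nchar(locus_genomic)
      bed[[i]] <- list(gene_id = gene_id, start = gstart, end = gend,
                       strand = strand[i], introns = intron_iv,
                       isotype = fam_isotype[fam], anticodon = fam_anticodon[fam])
      truth[[i]] <- data.frame(
        gene_id = gene_id, species = species,
        isoacceptor = paste(fam_isotype[fam], fam_anticodon[fam], sep = "-"),
        isotype = fam_isotype[fam], anticodon = fam_anticodon[fam],
        strand = strand[i], trailer_length = trailer_len[i],
        terminator_run = profile$terminator_run,
        discriminator = disc, nminus1 = nm1, leader = leader,
        mature_length = nchar(mature), has_intron = has_intron[i],
        intron_length = intron_len[i], stringsAsFactors = FALSE)
    }
    contig <- paste0(paste(pieces, collapse = ""), random_dna(200L))
    genome <- c(chrS1 = contig)
    ann <- data.frame(
      gene_id = vapply(bed, `[[`, character(1), "gene_id"),
      species = species,
      isotype = vapply(bed, `[[`, character(1), "isotype"),
      anticodon = vapply(bed, `[[`, character(1), "anticodon"),
      contig = "chrS1",
      start = vapply(bed, `[[`, integer(1), "start"),
      end = vapply(bed, `[[`, integer(1), "end"),
      strand = vapply(bed, `[[`, character(1), "strand"),
      stringsAsFactors = FALSE)
    ann$introns <- lapply(bed, `[[`, "introns")
    truth <- do.call(rbind, truth)
    out <- list(genome = genome, annotations = ann, truth = truth,
                profile = profile, seed = as.integer(seed))
    if (!is.null(out_dir)) out$paths <- write_simulated_genome(out, out_dir)
    out
  })
}

profile_hash <- function(profile) {
  substr(jsonlite::base64_enc(serialize(unclass(profile), NULL)), 1, 16)
}

write_simulated_genome <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "genome.fa")
  writeLines(c(">chrS1", sim$genome[["chrS1"]]), fa)
  bed_path <- file.path(out_dir, "genes.bed")
  ann <- sim$annotations
  bed_lines <- vapply(seq_len(nrow(ann)), function(i) {
    iv <- ann$introns[[i]]
    ex_start <- c(ann$start[i], iv[, 2])
    ex_end <- c(iv[, 1], ann$end[i])
    sizes <- ex_end - ex_start
    offs <- ex_start - ann$start[i]
    paste(ann$contig[i], ann$start[i], ann$end[i], ann$gene_id[i], 0,
          ann$strand[i], ann$start[i], ann$end[i], "0", length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(bed_lines, bed_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  hdr <- sprintf("# seed=%d profile_hash=%s", sim$seed, profile_hash(sim$profile))
  writeLines(hdr, truth_path)
  suppressWarnings(write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  c(genome = fa, bed = bed_path, truth = truth_path)
}

#' Define a read-simulation configuration
#'
#' Defaults reflect the study design being emulated: paired input/IP
#' libraries at 1e5 reads per replicate, an IP that enriches
#' uridylate-tailed precursors threefold over input, and a
#' wild-type-vs-knockout shift toward longer uridylate tails.
#'
#' @param mature_fraction input-library fraction of CCA-ended mature reads.
#' @param tail_probs_wt,tail_probs_ko tail length distributions over U1..U10
#'   (normalised internally).
#' @param ip_enrichment_factor realized premature CPM fold of IP over input:
#'   the IP premature read fraction is `factor * (1 - mature_fraction)`
#'   (must stay < 1).
#' @param depth reads per replicate.
#' @param read_length read length in nt.
#' @param expression_weights optional named per-isoacceptor weights shared
#'   by every replicate/library of the experiment; by default each
#'   isoacceptor's weight is its gene copy number in the catalog (see
#'   [draw_expression_weights()] for a noisy alternative).
#' @param error_rate per-base substitution rate (default 0; the matching
#'   pipeline is exact-match).
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(mature_fraction = 0.8,
                            tail_probs_wt = 0.55^(1:10),
                            tail_probs_ko = 0.85^(1:10),
                            ip_enrichment_factor = 3,
                            depth = 1e5, read_length = 50L,
                            expression_weights = NULL,
                            error_rate = 0) {
  cfg <- list(mature_fraction = mature_fraction,
              tail_probs_wt = tail_probs_wt / sum(tail_probs_wt),
              tail_probs_ko = tail_probs_ko / sum(tail_probs_ko),
              ip_enrichment_factor = ip_enrichment_factor,
              depth = as.integer(depth), read_length = as.integer(read_length),
              expression_weights = expression_weights,
              error_rate = error_rate)
  stopifnot(cfg$mature_fraction >= 0, cfg$mature_fraction <= 1, cfg$depth > 0,
            length(cfg$tail_probs_wt) == 10L, length(cfg$tail_probs_ko) == 10L)
  if (cfg$ip_enrichment_factor * (1 - cfg$mature_fraction) >= 1) {
    stop_input("ip_enrichment_factor * premature fraction must be < 1")
  }
  class(cfg) <- "read_sim_config"
  cfg
}

#' Simulate a tRNA-seq replicate
#'
#' Each read is the 3' portion of an isoacceptor's mature sequence followed
#' by `CCA` (mature) or by `n` Ts (uridylate-tailed precursor, `n` drawn
#' from the strain's tail distribution). IP replicates raise the premature
#' read fraction to `ip_enrichment_factor` times the input fraction, so the
#' realized premature CPM fold equals the factor. Deterministic per seed.
#'
#' @param catalog a `trna_catalog` (baits must be resolvable at the
#'   configured read length).
#' @param config a [read_sim_config()].
#' @param library `"input"` or `"IP"`.
#' @param strain `"WT"` or `"KO"` (selects the tail distribution).
#' @param seed integer seed.
#' @param out_fastq optional path; when given the replicate is written as
#'   FASTQ (constant `I` qualities) and the path returned in the result.
#' @return list with `reads` (character vector), `truth` (data.frame
#'   `isoacceptor`, `bin`, `count` of generated reads), `library`,
#'   `strain`, `seed` and optionally `path`.
#' @export
simulate_reads <- function(catalog, config = read_sim_config(),
                           library = c("input", "IP"),
                           strain = c("WT", "KO"), seed = 1L,
                           out_fastq = NULL) {
  library <- match.arg(library); strain <- match.arg(strain)
  baits_needed <- 36L
  if (config$read_length < baits_needed + 10L) {
    stop_input("read_length must cover a 36-nt bait plus a 10-nt tail")
  }
  iso <- paste(catalog$isotype, catalog$anticodon, sep = "-")
  first <- !duplicated(iso)
  mature <- setNames(catalog$mature_sequence[first], iso[first])
  ## expression weights are a property of the strain, not the replicate:
  ## default to gene copy number so IP/input replicates share one profile
  default_w <- table(iso)[names(mature)]
  withr::with_seed(as.integer(seed), {
    w <- config$expression_weights %||% setNames(as.numeric(default_w), names(mature))
    w <- w[names(mature)]
    if (anyNA(w)) stop_input("expression_weights must cover every isoacceptor")
    p_pre <- 1 - config$mature_fraction
    if (library == "IP") p_pre <- p_pre * config$ip_enrichment_factor
    tail_probs <- if (strain == "WT") config$tail_probs_wt else config$tail_probs_ko
    n <- config$depth
    gene <- sample(names(mature), n, replace = TRUE, prob = w)
    premature <- stats::runif(n) < p_pre
    tail_n <- ifelse(premature, sample.int(10L, n, replace = TRUE,
                                           prob = tail_probs), 0L)
    append <- ifelse(premature, strrep("T", tail_n), "CCA")
    body_len <- config$read_length - nchar(append)
    m <- mature[gene]
    body <- substring(m, pmax(nchar(m) - body_len + 1L, 1L), nchar(m))
    reads <- paste0(body, append)
    if (config$error_rate > 0) reads <- mutate_reads(reads, config$error_rate)
    bin <- ifelse(premature, paste0("U", tail_n), "CCA")
    truth <- as.data.frame(table(isoacceptor = gene,
                                 bin = factor(bin, levels = TAIL_BINS)),
                           stringsAsFactors = FALSE)
    names(truth)[3] <- "count"
    out <- list(reads = reads, truth = truth, library = library,
                strain = strain, seed = as.integer(seed))
    if (!is.null(out_fastq)) {
      write_fastq(reads, out_fastq,
                  prefix = sprintf("%s_%s_s%d", strain, library, seed))
      out$path <- out_fastq
    }
    out
  })
}

#' Draw per-isoacceptor expression weights
#'
#' Weights proportional to gene copy number with multiplicative log-normal
#' noise, drawn once per experiment and shared across its replicates and
#' libraries.
#'
#' @param catalog a `trna_catalog`.
#' @param seed integer seed.
#' @param noise_sd log-normal noise SD (default 0.5).
#' @return named numeric vector of weights keyed by isoacceptor.
#' @export
draw_expression_weights <- function(catalog, seed = 1L, noise_sd = 0.5) {
  iso <- paste(catalog$isotype, catalog$anticodon, sep = "-")
  copies <- table(iso)
  withr::with_seed(as.integer(seed), {
    setNames(as.numeric(copies) * stats::rlnorm(length(copies), 0, noise_sd),
             names(copies))
  })
}

mutate_reads <- function(reads, rate) {
  vapply(reads, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(ch)) < rate
    ch[hit] <- sample(DNA_BASES, sum(hit), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq <- function(reads, path, prefix = "read") {
  x <- Biostrings::BStringSet(reads)
  names(x) <- sprintf("%s_%06d", prefix, seq_along(reads))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  invisible(path)
}
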