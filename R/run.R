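## Run layer: one function per subcommand, each writing deterministic
## outputs plus a machine-readable run manifest.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a machine-readable run manifest
#'
#' Records the subcommand, effective parameter values, input paths with MD5
#' checksums, output paths with MD5 checksums, package and R versions and
#' the seed. No timestamp is recorded, so identical runs produce
#' byte-identical manifests.
#'
#' @param out_dir run output directory.
#' @param subcommand subcommand name.
#' @param params named list of effective parameters.
#' @param inputs named character vector of input paths.
#' @param outputs character vector of output paths.
#' @param seed integer seed or NULL.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, subcommand, params, inputs, outputs,
                               seed = NULL) {
  checksum <- function(paths) {
    if (length(paths) == 0) return(list())
    md5 <- tools::md5sum(paths)
    mapply(function(p, h) list(path = p, md5 = unname(h)),
           paths, md5, SIMPLIFY = FALSE, USE.NAMES = TRUE)
  }
  manifest <- list(subcommand = subcommand,
                   package = "pretrna",
                   package_version = as.character(packageVersion("pretrna")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = seed,
                   parameters = params,
                   inputs = checksum(inputs),
                   ## outputs recorded relative to out_dir so identical runs
                   ## in different directories stay byte-identical
                   outputs = {
                     cs <- checksum(setNames(outputs, basename(outputs)))
                     lapply(cs, function(x) list(path = basename(x$path),
                                                 md5 = x$md5))
                   })
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the architecture analysis pipeline
#'
#' Loads a genome and annotations, extracts the gene catalog, scans for
#' poly-T terminators, and writes the per-gene trailer table, per-species
#' summary, leader logo matrices (optionally split by discriminator base),
#' discriminator composition and pairing-avoidance table, plus a run
#' manifest.
#'
#' @param genome_path genome FASTA.
#' @param annotations_path BED12 or GtRNAdb-style TSV.
#' @param out_dir output directory (created).
#' @param species species label.
#' @param min_run minimum terminator T-run length k (default 4).
#' @param max_trailer exclusion cap for trailer lengths (default 20).
#' @param window leader logo window W (default 10).
#' @param split_by_discriminator also emit per-N73 logo matrices.
#' @param L_up,L_down flank lengths passed to [extract_genes()].
#' @param include_undetermined include `Und`/`NNN` genes in statistics.
#' @return list of computed objects (`catalog`, `calls`, `stats`, `logo`,
#'   `pairing`, `discriminator`), invisibly; files under `out_dir`.
#' @export
run_architecture <- function(genome_path, annotations_path, out_dir,
                             species = "species", min_run = 4L,
                             max_trailer = 20L, window = 10L,
                             split_by_discriminator = FALSE,
                             L_up = 20L, L_down = 60L,
                             include_undetermined = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- load_genome(genome_path)
  ann <- parse_annotations(annotations_path, species)
  catalog <- extract_genes(genome, ann, L_up = L_up, L_down = L_down)
  calls <- scan_terminators(catalog, min_run = min_run, max_trailer = max_trailer)
  stats <- summarize_species(calls, catalog,
                             include_undetermined = include_undetermined)
  stats_cat <- if (include_undetermined) catalog else determined_genes(catalog)
  logo <- leader_logo(stats_cat, window = window)
  disc <- discriminator_composition(stats_cat)
  pairing <- pairing_avoidance(stats_cat)

  outputs <- c(
    write_tsv(as.data.frame(catalog), file.path(out_dir, "catalog.tsv")),
    write_tsv(calls, file.path(out_dir, "trailers.tsv")),
    write_tsv(data.frame(
      species = stats$species, n_genes_total = stats$n_genes_total,
      n_genes_determined = stats$n_genes_determined,
      n_trailer_analyzed = stats$n_trailer_analyzed,
      trailer_mean = stats$trailer_mean, trailer_sd = stats$trailer_sd,
      trailer_mode = stats$trailer_mode,
      mature_mean = stats$mature_mean, mature_sd = stats$mature_sd),
      file.path(out_dir, "species_stats.tsv")),
    write_tsv(data.frame(length = as.integer(names(stats$trailer_histogram)),
                         count = as.integer(stats$trailer_histogram)),
              file.path(out_dir, "trailer_histogram.tsv")),
    write_tsv(data.frame(base = rownames(logo$counts), logo$counts,
                         check.names = FALSE),
              file.path(out_dir, "leader_counts.tsv")),
    write_tsv(data.frame(base = rownames(logo$frequencies), logo$frequencies,
                         check.names = FALSE),
              file.path(out_dir, "leader_frequencies.tsv")),
    write_tsv(data.frame(base = names(disc), frequency = as.numeric(disc)),
              file.path(out_dir, "discriminator_composition.tsv")),
    write_tsv(pairing, file.path(out_dir, "pairing_avoidance.tsv")))
  logos_split <- NULL
  if (split_by_discriminator) {
    logos_split <- lapply(setNames(DNA_BASES, DNA_BASES), function(b) {
      lg <- suppressWarnings(leader_logo(stats_cat, window = window, condition = b))
      outputs <<- c(outputs, write_tsv(
        data.frame(base = rownames(lg$frequencies), lg$frequencies,
                   check.names = FALSE),
        file.path(out_dir, sprintf("leader_frequencies_N73_%s.tsv", b))))
      lg
    })
  }
  write_run_manifest(out_dir, "architecture",
                     params = list(species = species, min_run = min_run,
                                   max_trailer = max_trailer, window = window,
                                   split_by_discriminator = split_by_discriminator,
                                   L_up = L_up, L_down = L_down,
                                   include_undetermined = include_undetermined),
                     inputs = c(genome = genome_path,
                                annotations = annotations_path),
                     outputs = outputs)
  invisible(list(catalog = catalog, calls = calls, stats = stats, logo = logo,
                 logos_split = logos_split, discriminator = disc,
                 pairing = pairing))
}

#' Run the read fishing / tail classification pipeline
#'
#' The replicate manifest is a TSV with columns `sample_id`, `strain`
#' (`WT`/`KO`), `library` (`input`/`IP`) and `path` (FASTQ). Counts, CPM,
#' enrichment (IP vs mean input, per strain), cumulative tail tables and
#' presence calls are written, plus a run manifest.
#'
#' @param catalog_path catalog TSV from [write_catalog()].
#' @param manifest_path replicate manifest TSV.
#' @param out_dir output directory.
#' @param bait_length bait length B (default 36).
#' @param threshold presence threshold in CPM (default `log10(2)`).
#' @param pseudocount enrichment pseudocount (default 0.01).
#' @param cpm_denominator `"replicate"` or `"bin"`.
#' @return list with `counts` (all replicates, long), `enrichment` (per
#'   strain), `presence`, `cumulative`, invisibly.
#' @export
run_tails <- function(catalog_path, manifest_path, out_dir, bait_length = 36L,
                      threshold = log10(2), pseudocount = 0.01,
                      cpm_denominator = "replicate") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- read_catalog(catalog_path)
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "strain", "library", "path")
  if (!all(need %in% names(manifest))) {
    stop_input("replicate manifest needs columns: ", paste(need, collapse = ", "))
  }
  baits <- build_baits(catalog, bait_length = bait_length)
  per_rep <- lapply(seq_len(nrow(manifest)), function(i) {
    fished <- fish_reads(manifest$path[i], baits)
    counts <- tabulate_bins(fished, baits, replicate = manifest$sample_id[i])
    counts <- cpm_normalize(counts, denominator = cpm_denominator)
    counts$strain <- manifest$strain[i]
    counts$library <- manifest$library[i]
    attr(counts, "audit") <- c(n_reads = attr(fished, "n_reads"),
                               n_assigned = attr(fished, "n_assigned"),
                               n_ambiguous = attr(fished, "n_ambiguous"),
                               n_unmatched = attr(fished, "n_unmatched"))
    counts
  })
  all_counts <- do.call(rbind, per_rep)
  enrichment <- list()
  for (st in unique(manifest$strain)) {
    ip <- all_counts[all_counts$strain == st & all_counts$library == "IP", ]
    input <- all_counts[all_counts$strain == st & all_counts$library == "input", ]
    if (nrow(ip) && nrow(input)) {
      enrichment[[st]] <- data.frame(
        strain = st, fold_enrichment(ip, input, pseudocount = pseudocount))
    }
  }
  input_counts <- all_counts[all_counts$library == "input", ]
  presence <- tail_presence(input_counts, threshold = threshold)
  cumulative <- cumulative_tail_table(input_counts)
  audit <- do.call(rbind, lapply(per_rep, function(x)
    data.frame(replicate = x$replicate[1], t(attr(x, "audit")))))
  outputs <- c(
    write_tsv(all_counts, file.path(out_dir, "bin_counts.tsv")),
    write_tsv(audit, file.path(out_dir, "fishing_audit.tsv")),
    write_tsv(presence, file.path(out_dir, "tail_presence.tsv")),
    write_tsv(cumulative, file.path(out_dir, "cumulative_tails.tsv")))
  if (length(enrichment)) {
    outputs <- c(outputs, write_tsv(do.call(rbind, enrichment),
                                    file.path(out_dir, "enrichment.tsv")))
  }
  write_run_manifest(out_dir, "tails",
                     params = list(bait_length = bait_length,
                                   threshold = threshold,
                                   pseudocount = pseudocount,
                                   cpm_denominator = cpm_denominator),
                     inputs = c(catalog = catalog_path,
                                manifest = manifest_path,
                                setNames(manifest$path, manifest$sample_id)),
                     outputs = outputs)
  invisible(list(counts = all_counts, enrichment = enrichment,
                 presence = presence, cumulative = cumulative, audit = audit))
}

#' Run the conservation annotation
#'
#' @param alignment_path aligned FASTA or Clustal file.
#' @param out_dir output directory.
#' @param reference reference row id (default: first row).
#' @return the `alignment_annotation`, invisibly.
#' @export
run_conserve <- function(alignment_path, out_dir, reference = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_protein_alignment(alignment_path)
  annotation <- annotate_alignment(aln, reference = reference %||% names(aln)[1])
  tsv <- file.path(out_dir, "conservation_classes.tsv")
  write_annotation_tsv(annotation, aln, tsv)
  txt <- file.path(out_dir, "conservation_rendering.txt")
  writeLines(render_annotation(annotation, aln), txt)
  summary_tsv <- write_tsv(annotation$column_summary,
                           file.path(out_dir, "conservation_columns.tsv"))
  write_run_manifest(out_dir, "conserve",
                     params = list(reference = annotation$reference),
                     inputs = c(alignment = alignment_path),
                     outputs = c(tsv, txt, summary_tsv))
  invisible(annotation)
}

#' Run the synthetic-data generator
#'
#' Writes a simulated genome (FASTA + BED12 + ground truth) and, when
#' `with_reads = TRUE`, paired input/IP FASTQ replicates with their ground
#' truth and a replicate manifest usable by [run_tails()].
#'
#' @param out_dir output directory.
#' @param profile a [species_profile()].
#' @param config a [read_sim_config()].
#' @param seed integer seed.
#' @param with_reads also simulate read sets.
#' @param n_replicates input and IP replicates each (default 2).
#' @return list with the simulated objects and paths, invisibly.
#' @export
run_simulate <- function(out_dir, profile = species_profile(),
                         config = read_sim_config(), seed = 1L,
                         with_reads = TRUE, n_replicates = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(profile, seed = seed, out_dir = out_dir)
  outputs <- unname(sim$paths)
  reads <- NULL
  if (with_reads) {
    catalog <- extract_genes(load_genome(sim$paths[["genome"]]),
                             sim$annotations)
    manifest <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      rbind(data.frame(sample_id = sprintf("input_rep%d", r), strain = "WT",
                       library = "input",
                       path = file.path(out_dir, sprintf("input_rep%d.fastq", r))),
            data.frame(sample_id = sprintf("ip_rep%d", r), strain = "WT",
                       library = "IP",
                       path = file.path(out_dir, sprintf("ip_rep%d.fastq", r))))
    }))
    reads <- lapply(seq_len(nrow(manifest)), function(i) {
      simulate_reads(catalog, config,
                     library = manifest$library[i], strain = manifest$strain[i],
                     seed = seed + i, out_fastq = manifest$path[i])
    })
    manifest_path <- write_tsv(manifest, file.path(out_dir, "replicates.tsv"))
    outputs <- c(outputs, manifest$path, manifest_path)
  }
  write_run_manifest(out_dir, "simulate",
                     params = list(profile = unclass(profile),
                                   config = if (with_reads) unclass(config),
                                   n_replicates = n_replicates),
                     inputs = character(0), outputs = outputs, seed = seed)
  invisible(list(sim = sim, reads = reads, out_dir = out_dir))
}

#' Merge a YAML config file with command-line overrides
#'
#' Flags win over file values. The threshold keyword `"log10_2"` is
#' translated to `log10(2)`.
#'
#' @param config_path YAML file or NULL.
#' @param flags named list of command-line values (NULLs ignored).
#' @return named list of effective parameters.
#' @export
load_run_config <- function(config_path = NULL, flags = list()) {
  cfg <- if (!is.null(config_path)) {
    if (!file.exists(config_path)) stop_input("config not found: ", config_path)
    yaml::read_yaml(config_path)
  } else list()
  flags <- Filter(Negate(is.null), flags)
  cfg[names(flags)] <- flags
  if (identical(cfg$threshold, "log10_2")) cfg$threshold <- log10(2)
  cfg
}
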