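## Gene catalog: genome + annotation ingest, transcript-oriented tRNA gene
## records with flanking sequence. All internal coordinates are 0-based
## half-open; GtRNAdb-style 1-based inclusive rows are converted on ingest.

#' Load a genome from FASTA
#'
#' Reads a (possibly gzipped) FASTA file into a named character vector of
#' uppercase DNA sequences. `U` is converted to `T`; characters outside
#' `{A,C,G,T,N}` are rejected.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per contig. Contig ids are the
#'   FASTA header up to the first whitespace.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop_input("genome FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop_input("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop_input("duplicate contig id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- chartr("U", "T", toupper(as.character(seqs)))
  if (any(!nzchar(x))) stop_input("empty sequence for contig: ",
                                  paste(ids[!nzchar(x)], collapse = ", "))
  bad <- !grepl("^[ACGTN]+$", x)
  if (any(bad)) {
    stop_input("contig ", ids[bad][1],
               " contains characters outside {A,C,G,T,N,U}")
  }
  names(x) <- ids
  x
}

#' Parse tRNA gene annotations (BED12 or GtRNAdb-style TSV)
#'
#' The dialect is auto-detected: a headerless 12-column tab file with numeric
#' columns 2-3 is treated as BED12 (0-based half-open, introns inferred from
#' gaps between blocks); otherwise a header line with columns
#' `gene_id, contig, start, end, strand, isotype, anticodon` (optionally
#' `intron_starts`, `intron_ends` as comma-separated lists) is treated as a
#' GtRNAdb-style table with 1-based inclusive coordinates, converted to
#' 0-based half-open on ingest.
#'
#' Records with an unknown strand symbol or with intron blocks outside the
#' gene body are dropped with a warning.
#'
#' @param path annotation file (gzip transparently supported).
#' @param species species label attached to every record.
#' @return data.frame with columns `gene_id`, `species`, `isotype`,
#'   `anticodon`, `contig`, `start`, `end`, `strand` and a list-column
#'   `introns` of two-column matrices (`start`, `end`; 0-based half-open,
#'   genomic orientation).
#' @export
parse_annotations <- function(path, species) {
  if (!file.exists(path)) stop_input("annotation file not found: ", path)
  lines <- readLines(con <- gzfile(path)); close(con)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) stop_input("no annotation records in ", path)
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  is_bed12 <- length(first) >= 12L &&
    !is.na(suppressWarnings(as.integer(first[2]))) &&
    !is.na(suppressWarnings(as.integer(first[3])))
  ann <- if (is_bed12) parse_bed12(lines, species) else parse_gtrnadb_tsv(lines, species)
  keep <- validate_annotations(ann)
  ann[keep, , drop = FALSE]
}

parse_bed12 <- function(lines, species) {
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(f)
  get <- function(i) vapply(f, `[`, character(1), i)
  start <- as.integer(get(2)); end <- as.integer(get(3))
  name <- get(4); strand <- get(6)
  block_sizes <- get(11); block_starts <- get(12)
  introns <- vector("list", n)
  for (i in seq_len(n)) {
    sizes <- as.integer(strsplit(block_sizes[i], ",")[[1]])
    offs <- as.integer(strsplit(block_starts[i], ",")[[1]])
    ex_start <- start[i] + offs
    ex_end <- ex_start + sizes
    if (length(sizes) > 1L) {
      introns[[i]] <- cbind(start = ex_end[-length(ex_end)], end = ex_start[-1])
    } else {
      introns[[i]] <- cbind(start = integer(0), end = integer(0))
    }
  }
  ia <- parse_isotype_anticodon(name)
  out <- data.frame(gene_id = name, species = species, isotype = ia$isotype,
                    anticodon = ia$anticodon, contig = get(1),
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  out$introns <- introns
  out
}

## gene names like "tRNA-Gln-TTG-1-1" or "Gln-TTG-3"; undetermined entries
## fall back to isotype "Und" / anticodon "NNN"
parse_isotype_anticodon <- function(name) {
  m <- stringi::stri_match_first_regex(
    name, "(?:tRNA-)?([A-Za-z]{3}|iMet|SeC|Sup|Und)-([A-Za-z?]{3})")
  isotype <- m[, 2]; anticodon <- toupper(m[, 3])
  isotype[is.na(isotype)] <- "Und"
  anticodon[is.na(anticodon) | grepl("[^ACGT]", anticodon)] <- "NNN"
  list(isotype = isotype, anticodon = anticodon)
}

parse_gtrnadb_tsv <- function(lines, species) {
  tab <- read.delim(text = paste(lines, collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "contig", "start", "end", "strand", "isotype", "anticodon")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop_input("annotation table lacks required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  introns <- vector("list", n)
  has_intron_cols <- all(c("intron_starts", "intron_ends") %in% names(tab))
  for (i in seq_len(n)) {
    istart <- if (has_intron_cols) as.character(tab$intron_starts[i]) else NA
    if (!is.na(istart) && nzchar(istart) && istart != "0") {
      is1 <- as.integer(strsplit(istart, ",")[[1]])
      ie1 <- as.integer(strsplit(as.character(tab$intron_ends[i]), ",")[[1]])
      introns[[i]] <- cbind(start = is1 - 1L, end = ie1)  # 1-based incl -> 0-based half-open
    } else {
      introns[[i]] <- cbind(start = integer(0), end = integer(0))
    }
  }
  out <- data.frame(gene_id = as.character(tab$gene_id), species = species,
                    isotype = as.character(tab$isotype),
                    anticodon = toupper(as.character(tab$anticodon)),
                    contig = as.character(tab$contig),
                    start = as.integer(tab$start) - 1L,
                    end = as.integer(tab$end),
                    strand = as.character(tab$strand),
                    stringsAsFactors = FALSE)
  out$introns <- introns
  out
}

validate_annotations <- function(ann) {
  keep <- rep(TRUE, nrow(ann))
  bad_strand <- !ann$strand %in% c("+", "-")
  if (any(bad_strand)) {
    warning("dropping ", sum(bad_strand), " record(s) with unknown strand: ",
            paste(ann$gene_id[bad_strand], collapse = ", "))
    keep[bad_strand] <- FALSE
  }
  for (i in which(keep)) {
    iv <- ann$introns[[i]]
    if (nrow(iv) == 0L) next
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    inside <- all(iv[, 1] > ann$start[i]) && all(iv[, 2] < ann$end[i]) &&
      all(iv[, 1] < iv[, 2])
    nonovl <- nrow(iv) < 2L || all(iv[-1, 1] >= iv[-nrow(iv), 2])
    if (!inside || !nonovl) {
      warning("dropping ", ann$gene_id[i],
              ": intron block outside gene body or overlapping")
      keep[i] <- FALSE
    }
  }
  keep
}

#' Extract transcript-oriented tRNA gene records
#'
#' Splices introns out of each annotated gene body, reverse-complements
#' minus-strand genes so that all sequences read 5'->3' along the transcript,
#' and attaches upstream/downstream flanking sequence. The discriminator base
#' N73 is the last base of the spliced mature sequence; the downstream flank
#' starts at the base immediately 3' of it; the 3'-most base of the upstream
#' flank is N-1.
#'
#' Flank windows are truncated at contig edges and flagged `short_flank`;
#' genes with `N` in the mature sequence are flagged `ambiguous_base`.
#'
#' @param genome named character vector from [load_genome()].
#' @param annotations data.frame from [parse_annotations()].
#' @param L_up upstream flank length in nt (default 20).
#' @param L_down downstream flank length in nt (default 60; must cover the
#'   20-nt trailer cap plus a terminator run).
#' @return a `trna_catalog` data.frame with columns `gene_id`, `species`,
#'   `isotype`, `anticodon`, `contig`, `start`, `end`, `strand`,
#'   `mature_sequence`, `discriminator`, `upstream_flank`,
#'   `downstream_flank`, `flags` (comma-separated, `""` if none).
#' @export
extract_genes <- function(genome, annotations, L_up = 20L, L_down = 60L) {
  n <- nrow(annotations)
  mature <- up <- down <- character(n)
  flags <- vector("list", n)
  for (i in seq_len(n)) {
    a <- annotations[i, ]
    if (!a$contig %in% names(genome)) stop_input("contig not in genome: ", a$contig)
    contig_seq <- genome[[a$contig]]
    clen <- nchar(contig_seq)
    if (a$start < 0L || a$end > clen || a$start >= a$end) {
      stop_input("gene body outside contig for ", a$gene_id)
    }
    iv <- annotations$introns[[i]]
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    ex_start <- c(a$start, iv[, 2])
    ex_end <- c(iv[, 1], a$end)
    body <- paste(substring(contig_seq, ex_start + 1L, ex_end), collapse = "")
    fl <- character(0)
    if (a$strand == "+") {
      u0 <- max(0L, a$start - L_up)
      upstream <- substring(contig_seq, u0 + 1L, a$start)
      d1 <- min(clen, a$end + L_down)
      downstream <- substring(contig_seq, a$end + 1L, d1)
    } else {
      body <- revcomp(body)
      d0 <- max(0L, a$start - L_down)
      downstream <- revcomp(substring(contig_seq, d0 + 1L, a$start))
      u1 <- min(clen, a$end + L_up)
      upstream <- revcomp(substring(contig_seq, a$end + 1L, u1))
    }
    if (nchar(upstream) < L_up || nchar(downstream) < L_down) fl <- c(fl, "short_flank")
    if (grepl("N", body, fixed = TRUE)) fl <- c(fl, "ambiguous_base")
    mature[i] <- body; up[i] <- upstream; down[i] <- downstream
    flags[[i]] <- fl
  }
  out <- data.frame(
    gene_id = annotations$gene_id, species = annotations$species,
    isotype = annotations$isotype, anticodon = annotations$anticodon,
    contig = annotations$contig, start = annotations$start,
    end = annotations$end, strand = annotations$strand,
    mature_sequence = mature,
    discriminator = substring(mature, nchar(mature)),
    upstream_flank = up, downstream_flank = down,
    flags = join_flags(flags), stringsAsFactors = FALSE)
  class(out) <- c("trna_catalog", "data.frame")
  out
}

#' Extract a single gene record
#'
#' Convenience wrapper around [extract_genes()] for one annotation row.
#'
#' @inheritParams extract_genes
#' @param annotation one-row data.frame from [parse_annotations()].
#' @return one-row `trna_catalog` data.frame.
#' @export
extract_gene <- function(genome, annotation, L_up = 20L, L_down = 60L) {
  extract_genes(genome, annotation, L_up = L_up, L_down = L_down)
}

#' Write / read a tRNA gene catalog TSV
#'
#' The TSV round-trips every field bit-exactly.
#'
#' @param catalog a `trna_catalog` data.frame.
#' @param path output path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   the catalog.
#' @export
write_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop_input("catalog not found: ", path)
  out <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = character(0))
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  class(out) <- c("trna_catalog", "data.frame")
  out
}

#' Restrict a catalog to determined isotypes/anticodons
#'
#' Genes with isotype `Und` or anticodon `NNN` are kept in the catalog but
#' excluded from architecture statistics by default.
#'
#' @param catalog a `trna_catalog`.
#' @return the filtered catalog.
#' @export
determined_genes <- function(catalog) {
  catalog[catalog$isotype != "Und" & catalog$anticodon != "NNN", , drop = FALSE]
}

#' @export
print.trna_catalog <- function(x, ...) {
  cat("tRNA gene catalog: ", nrow(x), " genes, ",
      length(unique(x$species)), " species\n", sep = "")
  NextMethod()
}
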