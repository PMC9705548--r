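## Tiny hand-built genome/annotation fixtures, constructed in code.

## A plus-strand gene with known leader / body / trailer structure embedded
## in a contig; returns the pieces and the genomic coordinates of the body.
make_locus <- function(leader, body, trailer, term = "TTTT",
                       pad5 = "GCGCGCGCGC", pad3 = "GCGCGCGCGC") {
  contig <- paste0(pad5, leader, body, trailer, term, "G", pad3)
  list(contig = contig,
       start = nchar(pad5) + nchar(leader),
       end = nchar(pad5) + nchar(leader) + nchar(body))
}

write_bed12_line <- function(contig, start, end, name, strand,
                             intron = NULL, path) {
  if (is.null(intron)) {
    sizes <- end - start; offs <- 0
  } else {
    sizes <- c(intron[1] - start, end - intron[2])
    offs <- c(0, intron[2] - start)
  }
  line <- paste(contig, start, end, name, 0, strand, start, end, "0",
                length(sizes),
                paste0(paste(sizes, collapse = ","), ","),
                paste0(paste(offs, collapse = ","), ","), sep = "\t")
  writeLines(line, path)
  path
}

write_fasta <- function(seqs, path) {
  writeLines(unlist(mapply(function(n, s) c(paste0(">", n), s),
                           names(seqs), seqs, SIMPLIFY = FALSE)), path)
  path
}

## minimal in-memory catalog row(s) for operations that only need a few
## catalog columns
toy_catalog <- function(mature, upstream = strrep("G", 20),
                        downstream = "TTTTACG", isotype = "Gln",
                        anticodon = "TTG", gene_id = NULL,
                        species = "toy") {
  n <- length(mature)
  out <- data.frame(
    gene_id = gene_id %||% paste0("g", seq_len(n)),
    species = species,
    isotype = rep_len(isotype, n), anticodon = rep_len(anticodon, n),
    contig = "c1", start = 0L, end = nchar(mature),
    strand = "+", mature_sequence = mature,
    discriminator = substring(mature, nchar(mature)),
    upstream_flank = rep_len(upstream, n),
    downstream_flank = rep_len(downstream, n),
    flags = "", stringsAsFactors = FALSE)
  class(out) <- c("trna_catalog", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## long-format CPM table from a named list isoacceptor -> c(CCA=..., U1=..., ...)
toy_cpm <- function(cells, replicate = "rep1") {
  bins <- c("CCA", paste0("U", 1:10), "UNCLASSIFIED")
  rows <- do.call(rbind, lapply(names(cells), function(iso) {
    v <- setNames(rep(0, length(bins)), bins)
    v[names(cells[[iso]])] <- cells[[iso]]
    data.frame(replicate = replicate, isoacceptor = iso, bin = bins,
               count = NA_integer_, cpm = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}
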