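## Conservation annotation of protein multiple sequence alignments against
## a reference row using five side-chain similarity groups.

#' Side-chain conservation groups
#'
#' The fixed partition of amino acids considered conserved substitutions of
#' one another, by side-chain character: acidic/amide (D, E, N, Q), basic
#' (K, R, H), aromatic (F, W, Y), aliphatic/hydrophobic (V, I, L, M) and
#' hydroxylic (S, T). G, A, C and P belong to no group.
#'
#' @return named list of five character vectors.
#' @export
conservation_groups <- function() {
  list(acidic_amide = c("D", "E", "N", "Q"),
       basic = c("K", "R", "H"),
       aromatic = c("F", "W", "Y"),
       aliphatic = c("V", "I", "L", "M"),
       hydroxylic = c("S", "T"))
}

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHARS <- c("-", ".")

group_index <- function(groups) {
  idx <- setNames(rep(NA_integer_, length(AA_ALPHABET20)), AA_ALPHABET20)
  for (g in seq_along(groups)) idx[groups[[g]]] <- g
  idx
}

#' Classify a residue pair against a reference residue
#'
#' `identical` if the residues are equal, `conserved` if distinct but in
#' the same side-chain group, `gap` if either is a gap character, `none`
#' otherwise. Vectorised; classification is symmetric in its arguments.
#'
#' @param ref_aa,other_aa character vectors of single-letter amino acids or
#'   gap (`-`/`.`), recycled to a common length.
#' @param groups conservation groups (default [conservation_groups()]).
#' @return character vector over
#'   `{"identical", "conserved", "none", "gap"}`.
#' @export
classify_residue_pair <- function(ref_aa, other_aa, groups = conservation_groups()) {
  n <- max(length(ref_aa), length(other_aa))
  ref_aa <- toupper(rep_len(ref_aa, n)); other_aa <- toupper(rep_len(other_aa, n))
  ref_gap <- ref_aa %in% GAP_CHARS; oth_gap <- other_aa %in% GAP_CHARS
  bad <- !(ref_gap | ref_aa %in% AA_ALPHABET20) |
    !(oth_gap | other_aa %in% AA_ALPHABET20)
  if (any(bad)) {
    i <- which(bad)[1]
    stop_input("unknown amino-acid letter '",
               if (ref_gap[i] || ref_aa[i] %in% AA_ALPHABET20) other_aa[i] else ref_aa[i],
               "' at position ", i)
  }
  idx <- group_index(groups)
  out <- rep("none", n)
  same_group <- !ref_gap & !oth_gap & !is.na(idx[ref_aa]) &
    !is.na(idx[other_aa]) & idx[ref_aa] == idx[other_aa]
  out[same_group] <- "conserved"
  out[!ref_gap & !oth_gap & ref_aa == other_aa] <- "identical"
  out[ref_gap | oth_gap] <- "gap"
  out
}

#' Read a protein multiple sequence alignment
#'
#' Aligned FASTA is read with Biostrings; Clustal format with seqinr. All
#' rows must have equal length.
#'
#' @param path alignment file.
#' @param format `"auto"` (default; by extension/content), `"fasta"` or
#'   `"clustal"`.
#' @return named character vector of equal-length aligned sequences.
#' @export
read_protein_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("alignment not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  aln <- if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
  } else {
    if (!requireNamespace("seqinr", quietly = TRUE)) {
      stop_input("reading Clustal alignments requires the seqinr package")
    }
    a <- seqinr::read.alignment(path, format = "clustal")
    setNames(toupper(unlist(a$seq)), a$nam)
  }
  if (length(unique(nchar(aln))) != 1L) {
    stop_input("alignment rows differ in length")
  }
  aln
}

#' Annotate an alignment against a reference row
#'
#' Every non-reference cell is classified against the reference residue in
#' the same column with [classify_residue_pair()]. Columns where the
#' reference is a gap are flagged unalignable. A per-column summary of the
#' fractions identical/conserved (over non-reference, non-gap cells) is
#' included.
#'
#' @param aln named character vector of aligned sequences (see
#'   [read_protein_alignment()]).
#' @param reference id of the reference row (default: first row).
#' @param groups conservation groups.
#' @return an `alignment_annotation` list: `classes` (rows x columns
#'   character matrix, reference row included as all-`identical`/`gap`),
#'   `reference`, `unalignable` (logical per column), `column_summary`
#'   (data.frame `column`, `frac_identical`, `frac_conserved`).
#' @export
annotate_alignment <- function(aln, reference = names(aln)[1],
                               groups = conservation_groups()) {
  if (!reference %in% names(aln)) stop_input("reference row not found: ", reference)
  width <- nchar(aln[[1]])
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(mat) <- names(aln)
  ref <- mat[reference, ]
  classes <- matrix("", nrow = nrow(mat), ncol = width,
                    dimnames = list(rownames(mat), NULL))
  for (r in rownames(mat)) {
    classes[r, ] <- classify_residue_pair(ref, mat[r, ], groups)
  }
  unalignable <- ref %in% GAP_CHARS
  others <- setdiff(rownames(mat), reference)
  cls_o <- classes[others, , drop = FALSE]
  n_eff <- pmax(colSums(cls_o != "gap"), 1L)
  column_summary <- data.frame(
    column = seq_len(width),
    frac_identical = colSums(cls_o == "identical") / n_eff,
    frac_conserved = colSums(cls_o == "conserved") / n_eff)
  structure(list(classes = classes, reference = reference,
                 unalignable = unalignable, column_summary = column_summary),
            class = "alignment_annotation")
}

#' Plain-text rendering of an alignment annotation
#'
#' Mirrors a three-tone shading scheme in text: identical residues are
#' uppercase, conserved residues lowercase, non-conserved residues `.`,
#' gaps `-`. The reference row is printed verbatim.
#'
#' @param annotation an `alignment_annotation`.
#' @param aln the alignment it was computed from.
#' @param block_width characters per output block (default 60).
#' @return character vector of text lines (also suitable for
#'   `writeLines`).
#' @export
render_annotation <- function(annotation, aln, block_width = 60L) {
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(mat) <- names(aln)
  cls <- annotation$classes
  disp <- mat
  for (r in rownames(mat)) {
    if (r == annotation$reference) next
    disp[r, cls[r, ] == "conserved"] <- tolower(mat[r, cls[r, ] == "conserved"])
    disp[r, cls[r, ] == "none"] <- "."
    disp[r, cls[r, ] == "gap" & mat[r, ] %in% GAP_CHARS] <- "-"
  }
  width <- ncol(mat)
  name_w <- max(nchar(rownames(mat)))
  lines <- character(0)
  for (s in seq(1L, width, by = block_width)) {
    e <- min(s + block_width - 1L, width)
    for (r in rownames(mat)) {
      lines <- c(lines, sprintf("%-*s %s", name_w, r,
                                paste(disp[r, s:e], collapse = "")))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Write per-cell conservation classes as TSV
#'
#' Long format: `row`, `column`, `residue`, `class`.
#'
#' @param annotation an `alignment_annotation`.
#' @param aln the alignment it was computed from.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, aln, path) {
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(mat) <- names(aln)
  long <- data.frame(
    row = rep(rownames(mat), each = ncol(mat)),
    column = rep(seq_len(ncol(mat)), times = nrow(mat)),
    residue = as.vector(t(mat)),
    class = as.vector(t(annotation$classes)),
    stringsAsFactors = FALSE)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
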