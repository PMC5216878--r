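# Data model and I/O: aligned loci, region annotations, population manifests.
#
# Internal conventions: alignments are character matrices (rows = accessions,
# columns = alignment positions) over {A,C,G,T,N,-}; coordinates are 0-based
# half-open internally, 1-based inclusive in annotation files (GFF-style);
# all loci are given on the coding strand; inbred accessions are single
# haploid rows.

#' Construct a locus alignment
#'
#' @param locus_id single string identifying the locus.
#' @param mat character matrix, rows named by accession, entries in
#'   `A,C,G,T,N,-` (lowercase is normalized).
#' @return an object of class `locus_alignment`.
#' @export
locus_alignment <- function(locus_id, mat) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L)
  if (!is.matrix(mat) || is.null(rownames(mat)))
    stop("`mat` must be a character matrix with accession rownames")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate accession ids in alignment")
  mat[] <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), DNA_CHARS)
  if (length(bad))
    stop("illegal alignment characters: ", paste(bad, collapse = ", "))
  structure(list(locus_id = locus_id, mat = mat), class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d sequences x %d columns\n",
              x$locus_id, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' @export
dim.locus_alignment <- function(x) dim(x$mat)

aln_accessions <- function(aln) rownames(aln$mat)

# Subset an alignment to a set of accessions (order preserved as given).
aln_subset <- function(aln, accessions) {
  miss <- setdiff(accessions, rownames(aln$mat))
  if (length(miss))
    stop("accessions absent from alignment: ", paste(miss, collapse = ", "))
  locus_alignment(aln$locus_id, aln$mat[accessions, , drop = FALSE])
}

#' Read one aligned locus from FASTA
#'
#' All records must have equal length; ids become accession ids. Lines
#' starting with `#` and CRLF line endings are tolerated.
#'
#' @param path FASTA file.
#' @param locus_id locus identifier; default is the file name without
#'   extension.
#' @return a [locus_alignment()].
#' @export
read_alignment <- function(path, locus_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L]) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  if (length(seqs) != length(ids)) stop("malformed FASTA: ", path)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: records of unequal length in ", path)
  mat <- matrix(unlist(strsplit(toupper(seqs), "")),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(ids, NULL))
  locus_alignment(locus_id, mat)
}

#' Write one aligned locus to FASTA
#' @param aln a [locus_alignment()].
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste0, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- rownames(aln$mat)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a population manifest
#'
#' Two-column TSV (accession, population label); labels must be one of
#' `MW, MD, AW, AD, PHI, OUT_PD, OUT_PC`.
#'
#' @param path TSV file.
#' @return named character vector accession -> label.
#' @export
read_manifest <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, col.names = c("accession", "label"))
  if (anyDuplicated(df$accession))
    stop("duplicate accession in manifest: ",
         paste(unique(df$accession[duplicated(df$accession)]), collapse = ", "))
  bad <- setdiff(unique(df$label), POP_LABELS)
  if (length(bad))
    stop("unknown population label: ", paste(bad, collapse = ", "))
  setNames(df$label, df$accession)
}

#' Write a population manifest
#' @param manifest named character vector accession -> label.
#' @param path output TSV.
#' @export
write_manifest <- function(manifest, path) {
  write.table(data.frame(names(manifest), unname(manifest)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a region annotation
#'
#' @param locus_id locus identifier.
#' @param intervals data.frame with columns `start`, `end` (0-based
#'   half-open), `class` (one of `exon, intron, utr5, utr3, unknown`).
#' @param frame_offset 0-2; phase of the first base of the concatenated
#'   exon sequence.
#' @param length optional alignment length used for range validation.
#' @return object of class `region_annotation`.
#' @export
region_annotation <- function(locus_id, intervals, frame_offset = 0L,
                              length = NULL) {
  stopifnot(all(c("start", "end", "class") %in% names(intervals)))
  intervals <- intervals[order(intervals$start), c("start", "end", "class")]
  rownames(intervals) <- NULL
  bad <- setdiff(unique(intervals$class), REGION_CLASSES)
  if (length(bad)) stop("unknown region class: ", paste(bad, collapse = ", "))
  if (any(intervals$end <= intervals$start))
    stop("annotation error: empty or reversed interval")
  if (any(intervals$start < 0))
    stop("annotation error: negative coordinate")
  if (!is.null(length) && any(intervals$end > length))
    stop("annotation error: interval beyond locus length")
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] < intervals$end[-nrow(intervals)]))
    stop("annotation error: overlapping intervals")
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  structure(list(locus_id = locus_id, intervals = intervals,
                 frame_offset = as.integer(frame_offset)),
            class = "region_annotation")
}

#' Read region annotations (GFF-style TSV)
#'
#' Columns: `locus_id, start, end, class, frame` with 1-based inclusive
#' coordinates; converted to the internal 0-based half-open convention.
#' Returns a named list of [region_annotation()] objects, one per locus.
#'
#' @param path TSV file.
#' @param lengths optional named vector of locus lengths for range checks.
#' @export
read_annotations <- function(path, lengths = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "start", "end", "class", "frame") %in% names(df)))
  out <- lapply(split(df, df$locus_id), function(d) {
    iv <- data.frame(start = d$start - 1L, end = d$end, class = d$class,
                     stringsAsFactors = FALSE)
    region_annotation(d$locus_id[1L], iv, frame_offset = d$frame[1L],
                      length = if (is.null(lengths)) NULL else
                        unname(lengths[d$locus_id[1L]]))
  })
  out[unique(df$locus_id)]
}

#' Write region annotations to a GFF-style TSV
#' @param annotations named list of [region_annotation()] objects.
#' @param path output TSV (1-based inclusive coordinates).
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a)
    data.frame(locus_id = a$locus_id, start = a$intervals$start + 1L,
               end = a$intervals$end, class = a$intervals$class,
               frame = a$frame_offset, stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the columns of selected region classes
#'
#' Columns of intervals whose class is in `classes` are concatenated in
#' genomic order. For pure exon slices the reading-frame offset is
#' propagated so codon phase remains recoverable. If no column matches,
#' `NULL` is returned (the "structurally absent region" signal; callers
#' skip the locus for that region, like the `/` cells of a per-region
#' report).
#'
#' @param aln a [locus_alignment()].
#' @param ann the matching [region_annotation()].
#' @param classes character vector of region classes.
#' @return a [locus_alignment()] of the selected columns, with attribute
#'   `frame_offset`, or `NULL` if the selection is empty.
#' @export
slice_region <- function(aln, ann, classes) {
  stopifnot(inherits(aln, "locus_alignment"), inherits(ann, "region_annotation"))
  if (ann$locus_id != aln$locus_id)
    stop("annotation is for locus ", ann$locus_id, ", alignment is ", aln$locus_id)
  if (any(ann$intervals$end > ncol(aln$mat)))
    stop("annotation error: interval beyond locus length")
  keep <- ann$intervals[ann$intervals$class %in% classes, , drop = FALSE]
  if (!nrow(keep)) return(NULL)
  cols <- unlist(Map(function(s, e) seq.int(s + 1L, e), keep$start, keep$end))
  out <- locus_alignment(aln$locus_id, aln$mat[, cols, drop = FALSE])
  attr(out, "frame_offset") <- if (identical(sort(unique(keep$class)), "exon"))
    ann$frame_offset else NA_integer_
  out
}

#' Usable-site mask (complete deletion)
#'
#' A column is unusable if any retained accession carries `-` or `N`;
#' different accession subsets therefore give different masks.
#'
#' @param aln a [locus_alignment()].
#' @param accessions subset of row names (default all rows).
#' @return logical vector, one entry per alignment column.
#' @export
usable_sites <- function(aln, accessions = NULL) {
  m <- aln$mat
  if (!is.null(accessions)) {
    if (!length(accessions)) stop("accession subset must be non-empty")
    m <- aln_subset(aln, accessions)$mat
  }
  colSums(m == "-" | m == "N") == 0L
}

#' Assemble a multi-locus dataset
#'
#' @param loci named list of [locus_alignment()] objects.
#' @param annotations named list of [region_annotation()] objects (loci
#'   without an annotation are analyzable only as whole sequence).
#' @param manifest named character vector accession -> population label.
#' @return object of class `bean_dataset`.
#' @export
bean_dataset <- function(loci, annotations = list(), manifest) {
  if (is.null(names(loci)))
    names(loci) <- vapply(loci, function(a) a$locus_id, "")
  accs <- unique(unlist(lapply(loci, aln_accessions)))
  miss <- setdiff(accs, names(manifest))
  if (length(miss))
    stop("accessions missing from manifest: ", paste(miss, collapse = ", "))
  bad <- setdiff(names(annotations), names(loci))
  if (length(bad))
    stop("annotations for unknown loci: ", paste(bad, collapse = ", "))
  for (id in names(annotations))
    if (any(annotations[[id]]$intervals$end > ncol(loci[[id]]$mat)))
      stop("annotation error: interval beyond locus length for ", id)
  structure(list(loci = loci, annotations = annotations, manifest = manifest),
            class = "bean_dataset")
}

#' @export
print.bean_dataset <- function(x, ...) {
  cat(sprintf("<bean_dataset> %d loci, %d accessions (%s)\n",
              length(x$loci), length(x$manifest),
              paste(sprintf("%s:%d", names(table(x$manifest)),
                            as.integer(table(x$manifest))), collapse = " ")))
  invisible(x)
}

#' Accessions belonging to one population
#' @param dataset a [bean_dataset()].
#' @param pop population label.
#' @export
pop_accessions <- function(dataset, pop) {
  names(dataset$manifest)[dataset$manifest == pop]
}

#' Write a dataset to a directory
#'
#' Layout: `loci/<locus>.fasta`, `annotations.tsv`, `manifest.tsv`, and
#' `truth.json` when a truth record is attached.
#'
#' @param dataset a [bean_dataset()].
#' @param dir output directory (created).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  for (aln in dataset$loci)
    write_alignment(aln, file.path(dir, "loci", paste0(aln$locus_id, ".fasta")))
  if (length(dataset$annotations))
    write_annotations(dataset$annotations, file.path(dir, "annotations.tsv"))
  write_manifest(dataset$manifest, file.path(dir, "manifest.tsv"))
  if (!is.null(attr(dataset, "truth")))
    jsonlite::write_json(attr(dataset, "truth"),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(dir)
}

#' Read a dataset directory
#'
#' Adapter for externally supplied data in the [write_dataset()] layout;
#' annotation and truth files are optional.
#'
#' @param dir dataset directory.
#' @return a [bean_dataset()].
#' @export
read_dataset <- function(dir) {
  files <- list.files(file.path(dir, "loci"), pattern = "\\.fasta$",
                      full.names = TRUE)
  if (!length(files)) stop("no FASTA loci under ", dir)
  loci <- lapply(files, read_alignment)
  names(loci) <- vapply(loci, function(a) a$locus_id, "")
  lengths <- vapply(loci, function(a) ncol(a$mat), 0L)
  ann_path <- file.path(dir, "annotations.tsv")
  anns <- if (file.exists(ann_path)) read_annotations(ann_path, lengths) else list()
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  ds <- bean_dataset(loci, anns, manifest)
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path))
    attr(ds, "truth") <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  ds
}
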