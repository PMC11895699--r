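#' Read a count table
#'
#' Reads a tab-separated count matrix (first column feature ids, header row
#' sample ids) and validates it: rectangular, unique ids, non-negative
#' integer counts.
#'
#' @param path path to a TSV file.
#' @return integer matrix (features x samples) with dimnames.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed count table header: need a feature-id column and at ",
         "least one sample column", call. = FALSE)
  sampleIds <- header[-1]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in count table header", call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(vapply(df[-1], is.numeric, logical(1))))
    stop("non-numeric count cells", call. = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- sampleIds
  .assertCountMatrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table as TSV
#'
#' @param counts integer matrix with feature rownames and sample colnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeCountTable <- function(counts, path) {
  .assertCountMatrix(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (BED6+biotype or GFF3)
#'
#' BED input is six standard columns plus one extra column carrying the
#' biotype; GFF3 input takes the biotype from a `gene_biotype` (or `biotype`)
#' attribute. Biotypes other than `protein_coding` and `lncRNA` are mapped to
#' `other`. Coordinates are returned as a [GenomicRanges::GRanges] (1-based
#' inclusive, the Bioconductor convention; BED's 0-based half-open intervals
#' are converted on read).
#'
#' @param path input file.
#' @param format `"bed"` or `"gff3"`.
#' @return GRanges with metadata columns `gene_id` and `biotype`.
#' @importFrom GenomicRanges GRanges mcols mcols<-
#' @export
readAnnotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(biotype = "character"))
    if (is.null(gr$name) || anyNA(gr$name))
      stop("BED annotation needs a name (gene id) column", call. = FALSE)
    mcols(gr) <- S4Vectors::DataFrame(gene_id = gr$name,
                                      biotype = gr$biotype)
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    bt <- if ("gene_biotype" %in% colnames(mcols(gr))) gr$gene_biotype
          else if ("biotype" %in% colnames(mcols(gr))) gr$biotype
          else rep(NA_character_, length(gr))
    id <- if ("ID" %in% colnames(mcols(gr))) gr$ID else gr$Name
    mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(id),
                                      biotype = as.character(bt))
  }
  gr$biotype <- ifelse(gr$biotype %in% .biotypeLevels, gr$biotype, "other")
  if (anyNA(gr$gene_id) || anyDuplicated(gr$gene_id))
    stop("gene ids must be present and unique", call. = FALSE)
  if (any(GenomicRanges::width(gr) < 1L))
    stop("empty intervals (start >= end) in annotation", call. = FALSE)
  gr
}

#' Write gene annotation as BED6+biotype
#'
#' @param annotation GRanges with `gene_id` and `biotype` metadata columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAnnotation <- function(annotation, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation) - 1L,  # BED is 0-based half-open
    end = GenomicRanges::end(annotation),
    name = annotation$gene_id,
    score = 0L,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(annotation))),
    biotype = annotation$biotype,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sample metadata CSV
#'
#' Expects columns `sample_id` and `stage` (one of 0, I, II, III, IV, NA);
#' further columns (subtype, receptor status, ...) are carried through.
#'
#' @param path CSV file.
#' @return data.frame of metadata.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("sample_id", "stage") %in% colnames(df)))
    stop("metadata needs sample_id and stage columns", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  df$stage[is.na(df$stage)] <- "NA"
  if (!all(df$stage %in% .stageLevels))
    stop("stage must be one of ", paste(.stageLevels, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a result table as TSV
#'
#' Columns are written in their current (deterministic) order; numeric
#' columns are rendered with a fixed number of significant digits so a
#' read-back reproduces the values to rendering precision.
#'
#' @param records data.frame (may have zero rows; the header is still
#'   written).
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6).
#' @return invisibly, `path`.
#' @export
writeResults <- function(records, path, digits = 6) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, digits))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [writeResults()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readResults <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
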