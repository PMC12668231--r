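## Tabular IO. One dialect throughout: tab-separated, UTF-8, '.' decimal,
## "NA" for missing values, '#'-prefixed header comments carrying
## provenance (config hash, seed). gzip is handled transparently by R's
## connections.

countsColumns <- c("gene_id", "condition", "replicate", "fraction", "counts")
annotationColumns <- c("gene_id", "length_total", "utr5_len", "utr3_len",
                       "regulon", "induced")
tpmColumns <- c("gene_id", "fraction", "tpm", "est_counts", "is_spike")

readTsv <- function(path, required, numericCols = character()) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in intersect(numericCols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "NA" & is.na(conv))
      if (length(bad)) {
        stop(sprintf("%s: malformed numeric value '%s' in column '%s' (data line %d)",
                     path, v[bad[1]], col, bad[1]))
      }
      df[[col]] <- conv
    }
  }
  df
}

#' Read a long-format fraction counts table
#'
#' Expects a TSV with columns `gene_id`, `condition`, `replicate`,
#' `fraction` (Total/Sup/Pellet) and `counts`. Extra columns are
#' preserved. Duplicate (gene, condition, replicate, fraction) keys and
#' malformed numeric fields are errors.
#'
#' @param path file path (plain or gzipped TSV).
#' @return data.frame of typed records.
#' @seealso [countsToExperiment()] to assemble a [SedSeqExperiment-class].
#' @export
readCountsTable <- function(path) {
  df <- readTsv(path, countsColumns, numericCols = c("replicate", "counts"))
  badFrac <- setdiff(unique(df$fraction), c("Total", "Sup", "Pellet"))
  if (length(badFrac)) {
    stop("unknown fraction label(s): ", paste(badFrac, collapse = ", "))
  }
  key <- paste(df$gene_id, df$condition, df$replicate, df$fraction, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    d <- df[dup[1], ]
    stop(sprintf("duplicated row for (%s, %s, %s, %s)",
                 d$gene_id, d$condition, d$replicate, d$fraction))
  }
  if (any(!is.na(df$counts) & df$counts < 0)) stop("negative counts")
  df
}

#' Write a data.frame as a provenance-stamped TSV
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list echoed as `# key: value` header comments
#'   (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, meta = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Convert a long counts table to a SedSeqExperiment
#'
#' @param counts long counts data.frame ([readCountsTable()] format).
#' @param annotation optional annotation data.frame keyed by `gene_id`.
#' @return A [SedSeqExperiment-class]; genes missing any fraction in an
#'   experiment get `NA` counts there (reported via a message).
#' @export
countsToExperiment <- function(counts, annotation = NULL) {
  genes <- sort(unique(counts$gene_id))
  expKey <- unique(counts[, c("condition", "replicate")])
  expKey <- expKey[order(expKey$condition, expKey$replicate), , drop = FALSE]
  sampleNames <- paste(expKey$condition, expKey$replicate, sep = "_")
  mats <- lapply(c("Total", "Sup", "Pellet"), function(f) {
    m <- matrix(NA_real_, length(genes), nrow(expKey),
                dimnames = list(genes, sampleNames))
    sub <- counts[counts$fraction == f, ]
    j <- match(paste(sub$condition, sub$replicate, sep = "_"), sampleNames)
    m[cbind(match(sub$gene_id, genes), j)] <- sub$counts
    m
  })
  nMissing <- sum(vapply(mats, function(m) sum(is.na(m)), 0))
  if (nMissing > 0) {
    message(nMissing, " gene-by-fraction entries missing; set to NA")
  }
  rd <- NULL
  if (!is.null(annotation)) {
    rd <- annotation[match(genes, annotation$gene_id), , drop = FALSE]
  }
  SedSeqExperiment(mats[[1]], mats[[2]], mats[[3]],
                   condition = expKey$condition,
                   replicate = expKey$replicate, rowData = rd)
}

#' Flatten a SedSeqExperiment to a long counts table
#'
#' Inverse of [countsToExperiment()]; round-trips losslessly through
#' [writeTsv()] / [readCountsTable()].
#'
#' @param object a [SedSeqExperiment-class].
#' @return long data.frame in [readCountsTable()] column order.
#' @export
experimentToCounts <- function(object) {
  cd <- colData(object)
  out <- do.call(rbind, lapply(c("Total", "Sup", "Pellet"), function(f) {
    m <- assay(object, f)
    data.frame(
      gene_id = rep(rownames(m), ncol(m)),
      condition = rep(cd$condition, each = nrow(m)),
      replicate = rep(cd$replicate, each = nrow(m)),
      fraction = f,
      counts = as.vector(m),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id, out$condition, out$replicate, out$fraction), ]
}

#' Read a transcript annotation table
#'
#' @param path TSV with columns `gene_id`, `length_total`, `utr5_len`,
#'   `utr3_len`, `regulon`, `induced`.
#' @return data.frame; errors on duplicate gene ids or non-positive
#'   lengths.
#' @export
readAnnotation <- function(path) {
  df <- readTsv(path, annotationColumns,
                numericCols = c("length_total", "utr5_len", "utr3_len"))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (any(df$length_total <= 0)) stop("non-positive transcript length")
  df$induced <- as.logical(df$induced)
  df
}

#' Read a long-format polysome TPM table
#'
#' @param path TSV with columns `gene_id`, `fraction`, `tpm`,
#'   `est_counts`, `is_spike`.
#' @return data.frame for [normalizeToSpikein()].
#' @export
readTpmTable <- function(path) {
  df <- readTsv(path, tpmColumns, numericCols = c("tpm", "est_counts"))
  df$is_spike <- as.logical(df$is_spike)
  df
}

#' Read a single-channel image or mask
#'
#' Thin wrapper for imaging inputs: `.csv` files are read as numeric
#' matrices; `.tif`/`.tiff` files are read with the `tiff` package when
#' available.
#'
#' @param path image path.
#' @return numeric matrix.
#' @export
readImageMatrix <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    as.matrix(read.csv(path, header = FALSE))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  } else {
    stop("unsupported image format: ", path)
  }
}
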