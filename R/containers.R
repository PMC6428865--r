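## Core in-memory containers. Plain data frames / matrices with light S3
## classes and strict validators; every reader funnels through these.

#' Construct a validated count table
#'
#' Bundles a gene-by-sample matrix of non-negative integer counts with
#' its sample metadata (assay, condition, replicate).
#'
#' @param counts integer matrix, rownames = gene ids, colnames = sample ids.
#' @param samples data frame with columns `sample_id`, `assay`
#'   (`"mRNA"`/`"RPF"`), `condition` (`"t0"`/`"t30"`), `replicate`.
#' @return an object of class `count_table` with elements `counts` and
#'   `samples`.
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    fail("count matrix must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    fail("duplicate gene ids: %s",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (!is_count_vector(as.vector(counts)))
    fail("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  samples <- validate_sample_meta(samples)
  if (!identical(colnames(counts), samples$sample_id))
    fail("count matrix columns do not match sample metadata order")
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s/%s:%d", x$samples$assay, x$samples$condition,
                            x$samples$replicate), collapse = " ")))
  invisible(x)
}

validate_sample_meta <- function(samples) {
  need <- c("sample_id", "assay", "condition", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) fail("sample metadata lacks columns: %s", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)[need]
  samples$sample_id <- as.character(samples$sample_id)
  samples$assay <- as.character(samples$assay)
  samples$condition <- as.character(samples$condition)
  if (anyDuplicated(samples$sample_id))
    fail("duplicate sample ids in metadata")
  bad <- !samples$assay %in% ASSAYS
  if (any(bad)) fail("unknown assay '%s' (expected mRNA/RPF)", samples$assay[which(bad)[1]])
  bad <- !samples$condition %in% CONDITIONS
  if (any(bad)) fail("unknown condition '%s' (expected t0/t30)", samples$condition[which(bad)[1]])
  if (!is_count_vector(samples$replicate) || any(samples$replicate < 1))
    fail("replicate must be a positive integer")
  samples$replicate <- as.integer(samples$replicate)
  key <- paste(samples$assay, samples$condition, samples$replicate)
  if (anyDuplicated(key))
    fail("duplicate (assay, condition, replicate) triple: %s", key[anyDuplicated(key)])
  cells <- table(samples$assay, samples$condition)
  if (!all(dim(cells) == c(2, 2)) || any(cells == 0))
    fail("need at least one sample per (assay, condition) combination")
  samples
}

#' Construct a validated gene annotation table
#'
#' Region lengths define the coordinate frame of all positional analyses:
#' transcript position 1 is the first 5'UTR nucleotide and the CDS starts
#' at `utr5_length + 1`.
#'
#' @param df data frame with columns `gene_id`, `utr5_length`,
#'   `cds_length`, `utr3_length` and optionally `is_membrane` (logical)
#'   and `srp_class` (`"dependent"`, `"independent"`, `"unknown"`).
#' @return a `gene_annotation` data frame.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "utr5_length", "cds_length", "utr3_length")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("annotation lacks columns: %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$gene_id <- as.character(df$gene_id)
  if (anyDuplicated(df$gene_id))
    fail("duplicate gene ids in annotation: %s",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  for (col in c("utr5_length", "cds_length", "utr3_length")) {
    if (!is_count_vector(df[[col]])) fail("%s must be non-negative integers", col)
    df[[col]] <- as.integer(df[[col]])
  }
  bad <- df$cds_length < 3 | df$cds_length %% 3 != 0
  if (any(bad))
    fail("cds_length must be a positive multiple of 3 (gene %s has %d)",
         df$gene_id[which(bad)[1]], df$cds_length[which(bad)[1]])
  if (is.null(df$is_membrane)) df$is_membrane <- NA
  df$is_membrane <- as.logical(df$is_membrane)
  if (is.null(df$srp_class)) df$srp_class <- "unknown"
  df$srp_class <- as.character(df$srp_class)
  bad <- !df$srp_class %in% c("dependent", "independent", "unknown")
  if (any(bad)) fail("invalid srp_class '%s'", df$srp_class[which(bad)[1]])
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

transcript_length <- function(annotation) {
  annotation$utr5_length + annotation$cds_length + annotation$utr3_length
}

## PARS profiles: named list of numeric vectors (NA = missing score).
validate_pars_profiles <- function(profiles, annotation = NULL) {
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    fail("PARS profiles must be uniquely named by gene id")
  for (g in names(profiles)) {
    p <- profiles[[g]]
    if (!is.numeric(p) || length(p) == 0)
      fail("PARS profile of %s must be a non-empty numeric vector", g)
  }
  if (!is.null(annotation)) {
    idx <- match(names(profiles), annotation$gene_id)
    shared <- which(!is.na(idx))
    for (i in shared) {
      g <- names(profiles)[i]
      want <- transcript_length(annotation)[idx[i]]
      if (length(profiles[[g]]) != want)
        fail("PARS profile of %s has %d scores but annotation implies %d",
             g, length(profiles[[g]]), want)
    }
  }
  invisible(profiles)
}

## Codon coverage: coverage[[sample_id]][[gene_id]] -> integer vector of
## per-codon RPF counts, length cds_length/3.
validate_codon_coverage <- function(coverage, annotation = NULL) {
  for (s in names(coverage)) {
    for (g in names(coverage[[s]])) {
      v <- coverage[[s]][[g]]
      if (!is_count_vector(v))
        fail("codon coverage of %s in %s must be non-negative integers", g, s)
      if (!is.null(annotation)) {
        i <- match(g, annotation$gene_id)
        if (!is.na(i) && length(v) != annotation$cds_length[i] / 3)
          fail("codon coverage of %s in %s has %d codons, expected %d",
               g, s, length(v), annotation$cds_length[i] / 3)
      }
    }
  }
  invisible(coverage)
}
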