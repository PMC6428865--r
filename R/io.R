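## Readers and writers for every on-disk artifact. Readers validate
## strictly and report offending lines; writers are byte-deterministic.
## Internal coordinates are 0-based half-open; the GFF3 boundary converts
## from 1-based inclusive at I/O time only.

#' Read a count table and its sample metadata
#'
#' The counts file is TSV with gene ids in the first column and one
#' column per sample; the metadata file is TSV with columns `sample_id`,
#' `assay`, `condition`, `replicate`. Malformed entries are rejected with
#' their file location, never coerced.
#'
#' @param counts_path path to the counts TSV.
#' @param meta_path path to the sample metadata TSV.
#' @return a [count_table]; column order of the counts file is preserved.
#' @export
read_counts <- function(counts_path, meta_path) {
  raw <- read.delim(counts_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) fail("%s: need a gene id column plus sample columns", counts_path)
  gene_ids <- raw[[1]]
  dup <- which(duplicated(gene_ids))
  if (length(dup))
    fail("%s: duplicate gene id '%s' at line %d", counts_path,
         gene_ids[dup[1]], dup[1] + 1L)
  mat <- matrix(NA_integer_, nrow(raw), ncol(raw) - 1L,
                dimnames = list(gene_ids, names(raw)[-1]))
  for (j in 2:ncol(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      fail("%s: invalid count '%s' for gene %s, sample %s (line %d)",
           counts_path, raw[[j]][bad[1]], gene_ids[bad[1]],
           names(raw)[j], bad[1] + 1L)
    mat[, j - 1L] <- as.integer(v)
  }
  meta <- read.delim(meta_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  meta <- validate_sample_meta(meta)
  missing_meta <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing_meta))
    fail("%s: sample(s) %s present in counts but absent from metadata",
         meta_path, paste(missing_meta, collapse = ", "))
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  count_table(mat, meta)
}

#' Write a count table and its sample metadata
#'
#' Inverse of [read_counts()]; integer counts round-trip exactly.
#'
#' @param table a [count_table].
#' @param counts_path,meta_path output TSV paths.
#' @export
write_counts <- function(table, counts_path, meta_path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(gene_id = rownames(table$counts),
                   as.data.frame(table$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_det(df, counts_path)
  write_tsv_det(table$samples, meta_path)
  invisible(counts_path)
}

#' Read gene models as region lengths
#'
#' GFF3 dialect: `five_prime_UTR` / `CDS` / `three_prime_UTR` features
#' (1-based inclusive coordinates) are grouped by their `Parent`
#' transcript, transcripts are mapped to genes through `mRNA`/
#' `transcript` features, and region lengths are the summed feature
#' spans, so multi-exon CDSs are handled naturally. Optional `membrane`
#' and `srp_class` attributes on gene features populate the labels. TSV
#' dialect: columns `gene_id`, `utr5_length`, `cds_length`,
#' `utr3_length`, `is_membrane`, `srp_class`.
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return a [gene_annotation].
#' @export
read_gene_models <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    return(gene_annotation(df))
  }
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  first_parent <- function(x) vapply(as.list(x), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  parent <- if (!is.null(gr$Parent)) first_parent(gr$Parent)
            else rep(NA_character_, length(gr))
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))

  tx <- type %in% c("mRNA", "transcript")
  tx2gene <- setNames(parent[tx], id[tx])
  feat <- type %in% c("five_prime_UTR", "CDS", "three_prime_UTR")
  if (!any(feat)) fail("%s: no UTR/CDS features found", path)
  fp <- parent[feat]
  if (anyNA(fp)) fail("%s: UTR/CDS feature without Parent attribute", path)
  gene <- ifelse(fp %in% names(tx2gene), unname(tx2gene[fp]), fp)
  width <- GenomicRanges::width(gr)[feat]
  ftype <- type[feat]
  gene_order <- unique(gene)
  sum_for <- function(what) {
    s <- tapply(width[ftype == what], gene[ftype == what], sum)
    out <- setNames(integer(length(gene_order)), gene_order)
    out[names(s)] <- as.integer(s)
    out
  }
  ann <- data.frame(gene_id = gene_order,
                    utr5_length = sum_for("five_prime_UTR"),
                    cds_length = sum_for("CDS"),
                    utr3_length = sum_for("three_prime_UTR"),
                    stringsAsFactors = FALSE)
  grow <- type == "gene"
  if (any(grow)) {
    gid <- id[grow]
    mcols <- S4Vectors::mcols(gr)
    if ("membrane" %in% names(mcols)) {
      memb <- as.character(mcols$membrane)[grow]
      ann$is_membrane <- memb[match(ann$gene_id, gid)] %in% c("1", "true", "TRUE")
    }
    if ("srp_class" %in% names(mcols)) {
      srp <- as.character(mcols$srp_class)[grow]
      ann$srp_class <- srp[match(ann$gene_id, gid)]
      ann$srp_class[is.na(ann$srp_class)] <- "unknown"
    }
  }
  rownames(ann) <- NULL
  gene_annotation(ann)
}

#' Write gene models
#'
#' GFF3 output lays synthetic genes head-to-tail on one contig (plus
#' strand, 100 nt gaps) with `gene`, `mRNA`, `five_prime_UTR`, `CDS` and
#' `three_prime_UTR` features; membrane/SRP labels become `membrane` and
#' `srp_class` attributes of the gene feature.
#'
#' @param annotation a [gene_annotation].
#' @param path output file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @export
write_gene_models <- function(annotation, path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- as.data.frame(annotation)
    df$is_membrane <- ifelse(is.na(df$is_membrane), "NA",
                             ifelse(df$is_membrane, "TRUE", "FALSE"))
    return(write_tsv_det(df, path))
  }
  lines <- "##gff-version 3"
  offset <- 1L
  for (i in seq_len(nrow(annotation))) {
    g <- annotation$gene_id[i]
    u5 <- annotation$utr5_length[i]; cd <- annotation$cds_length[i]
    u3 <- annotation$utr3_length[i]
    len <- u5 + cd + u3
    row <- function(type, s, e, attr)
      sprintf("chrS\triboTE\t%s\t%d\t%d\t.\t+\t.\t%s", type, s, e, attr)
    memb <- if (is.na(annotation$is_membrane[i])) "NA"
            else if (annotation$is_membrane[i]) "1" else "0"
    lines <- c(lines,
      row("gene", offset, offset + len - 1L,
          sprintf("ID=%s;membrane=%s;srp_class=%s", g, memb,
                  annotation$srp_class[i])),
      row("mRNA", offset, offset + len - 1L,
          sprintf("ID=%s.t1;Parent=%s", g, g)))
    if (u5 > 0)
      lines <- c(lines, row("five_prime_UTR", offset, offset + u5 - 1L,
                            sprintf("ID=%s.u5;Parent=%s.t1", g, g)))
    lines <- c(lines, row("CDS", offset + u5, offset + u5 + cd - 1L,
                          sprintf("ID=%s.cds;Parent=%s.t1", g, g)))
    if (u3 > 0)
      lines <- c(lines, row("three_prime_UTR", offset + u5 + cd,
                            offset + len - 1L,
                            sprintf("ID=%s.u3;Parent=%s.t1", g, g)))
    offset <- offset + len + 100L
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read per-nucleotide structure (PARS) scores
#'
#' Dialect: one gene per line, `gene_id TAB score;score;...` with the
#' token `NA` marking missing scores.
#'
#' @param path input file.
#' @return named list of numeric score vectors.
#' @export
read_pars_scores <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  profiles <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 1 && grepl("\t", lines[i], fixed = TRUE))
      fail("line %d: empty score list for gene %s", i, parts[1])
    if (length(parts) != 2)
      fail("line %d: expected 'gene_id<TAB>scores', got %d field(s)",
           i, length(parts))
    ids[i] <- parts[1]
    toks <- strsplit(parts[2], ";", fixed = TRUE)[[1]]
    if (length(toks) == 0 || !nzchar(parts[2]))
      fail("line %d: empty score list for gene %s", i, parts[1])
    vals <- suppressWarnings(as.numeric(toks))
    bad <- which(is.na(vals) & toks != "NA")
    if (length(bad))
      fail("line %d: non-numeric score '%s' for gene %s", i, toks[bad[1]], parts[1])
    profiles[[i]] <- vals
  }
  dup <- which(duplicated(ids))
  if (length(dup)) fail("line %d: duplicate gene line for %s", dup[1], ids[dup[1]])
  names(profiles) <- ids
  validate_pars_profiles(profiles)
  profiles
}

#' Write per-nucleotide structure (PARS) scores
#'
#' @param profiles named list of numeric score vectors.
#' @param path output file.
#' @param digits significant digits used for serialization (default 7).
#' @export
write_pars_scores <- function(profiles, path, digits = 7) {
  validate_pars_profiles(profiles)
  lines <- vapply(names(profiles), function(g) {
    v <- profiles[[g]]
    toks <- formatC(v, digits = digits, format = "g")
    toks[is.na(v)] <- "NA"
    paste0(g, "\t", paste(toks, collapse = ";"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read codon-level RPF coverage
#'
#' Dialect: one record per line, `gene_id TAB sample_id TAB
#' count;count;...`.
#'
#' @param path input file.
#' @return nested list `coverage[[sample_id]][[gene_id]]` of integer
#'   per-codon counts.
#' @export
read_codon_coverage <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  coverage <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      fail("line %d: expected 'gene_id<TAB>sample_id<TAB>counts'", i)
    vals <- suppressWarnings(as.integer(strsplit(parts[3], ";", fixed = TRUE)[[1]]))
    if (anyNA(vals) || any(vals < 0))
      fail("line %d: invalid codon counts for gene %s", i, parts[1])
    if (!is.null(coverage[[parts[2]]][[parts[1]]]))
      fail("line %d: duplicate coverage record for %s in %s", i, parts[1], parts[2])
    coverage[[parts[2]]][[parts[1]]] <- vals
  }
  validate_codon_coverage(coverage)
  coverage
}

#' Write codon-level RPF coverage
#'
#' @param coverage nested list `coverage[[sample_id]][[gene_id]]`.
#' @param path output file.
#' @export
write_codon_coverage <- function(coverage, path) {
  validate_codon_coverage(coverage)
  lines <- character(0)
  for (s in names(coverage)) {
    per <- coverage[[s]]
    lines <- c(lines, vapply(names(per), function(g)
      paste0(g, "\t", s, "\t", paste(per[[g]], collapse = ";")),
      character(1)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a result table as TSV
#'
#' Deterministic column order and fixed precision (6 significant digits
#' for floating-point columns), so identical inputs produce byte-
#' identical files.
#'
#' @param results a data frame (TE results, profiles, rate records, ...).
#' @param path output TSV path.
#' @export
write_results <- function(results, path) {
  write_tsv_det(as.data.frame(results), path)
}

#' Read a result table written by [write_results()]
#'
#' @param path TSV path.
#' @return data frame with default type inference.
#' @export
read_results <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
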