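## Internal helpers shared across modules.

TE_CLASSES <- c("activated_buffered", "activated_decreased",
                "activated_increased", "repressed_buffered",
                "repressed_decreased", "repressed_increased",
                "not_regulated")

ASSAYS <- c("mRNA", "RPF")
CONDITIONS <- c("t0", "t30")

#' Derive a component seed from a master seed
#'
#' One master seed drives every generator; each component derives its own
#' seed from the master seed and its name, so adding a new generator does
#' not perturb the random streams of existing ones. The derived value is
#' always a valid 32-bit integer seed.
#'
#' @param seed master seed (single integer-valued number).
#' @param component component name (single string).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "counts")
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(component), length(component) == 1L)
  codes <- utf8ToInt(component)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(seed) * 48271 + h * 7919 + 12345) %% 2147483646)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Stop with a message assembled sprintf-style.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

## Format numbers for TSV output: 6 significant digits, stable across runs.
fmt_num <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  out
}

## Deterministic TSV writer used by all output paths.
write_tsv_det <- function(df, path) {
  num <- vapply(df, function(col) is.double(col), logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}
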