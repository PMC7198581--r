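#' Read a tab-delimited table with schema validation
#'
#' Lines starting with `#` are treated as a metadata header and returned as
#' the `metadata` attribute. Gzip-compressed files are accepted
#' transparently. Columns are checked against `schema` (a named character
#' vector of `"numeric"`, `"integer"` or `"character"`); a schema mismatch or
#' a malformed numeric cell produces an error naming the offending column
#' (and row).
#'
#' @param path file path (.tsv or .tsv.gz)
#' @param schema named character vector of required column types; extra
#'   columns are kept as-is
#' @return data.frame with attribute `metadata` (character vector of header
#'   lines, `#` stripped)
#' @export
read_table_schema <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  meta <- sub("^#\\s?", "", grep("^#", lines, value = TRUE))
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(body) < 1) stop("no table content in ", path)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(df))
    if (length(missing) > 0)
      stop("schema mismatch in ", path, ": missing column(s) ",
           paste(missing, collapse = ", "))
    for (cn in names(schema)) {
      col <- df[[cn]]
      if (schema[[cn]] %in% c("numeric", "integer")) {
        conv <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(conv) & !is.na(col) & col != "NA")
        if (length(bad) > 0)
          stop("malformed numeric cell in column '", cn, "', row ", bad[1],
               " of ", path, ": '", col[bad[1]], "'")
        df[[cn]] <- if (schema[[cn]] == "integer") as.integer(conv) else conv
      } else {
        df[[cn]] <- as.character(col)
      }
    }
  }
  attr(df, "metadata") <- meta
  df
}

#' Write a tab-delimited table with optional metadata header
#'
#' @param df data.frame
#' @param path output path
#' @param metadata character vector written as `# ` comment lines above the
#'   header
#' @return `path`, invisibly
#' @export
write_table_meta <- function(df, path, metadata = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(metadata) > 0) writeLines(paste0("# ", metadata), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a fluctuation recording
#'
#' Two-column tab-delimited text (`time_s`, `displacement_m`) with the
#' generating parameters in a `#` metadata header. [read_fluctuation()]
#' restores the parameters needed downstream (sample rate, stiffness,
#' temperature); velocity is recovered by differencing in [estimate_psd()].
#'
#' @param rec a `fluctuation_recording`
#' @param path file path
#' @return `path` ([write_fluctuation()]) / a `fluctuation_recording`
#'   ([read_fluctuation()])
#' @export
write_fluctuation <- function(rec, path) {
  p <- rec$params
  meta <- sprintf("%s=%.15g", c("sample_rate", "K", "temperature", "f0", "Q",
                                "T_eff", "duration", "seed"),
                  c(p$sample_rate, p$K, p$temperature, p$f0, p$Q, p$T_eff,
                    p$duration, p$seed))
  write_table_meta(data.frame(time_s = rec$time_s,
                              displacement_m = rec$displacement_m),
                   path, metadata = meta)
}

#' @rdname write_fluctuation
#' @export
read_fluctuation <- function(path) {
  df <- read_table_schema(path, c(time_s = "numeric",
                                  displacement_m = "numeric"))
  meta <- attr(df, "metadata")
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
  rec <- list(time_s = df$time_s, displacement_m = df$displacement_m,
              velocity_m_s = NULL,
              params = as.list(vals))
  class(rec) <- "fluctuation_recording"
  rec
}

#' Write / read a gene-by-sample count matrix with its sample sheet
#'
#' The matrix is written genes-in-rows with a `gene` id column; the sample
#' sheet (`sample_id`, `age_day`, `sex`, `replicate`) goes to
#' `<path>_samples.tsv` (or the supplied path).
#'
#' @param counts an `age_series_counts`
#' @param path counts file path
#' @param samples_path sample sheet path; default derived from `path`
#' @return `path` / an `age_series_counts` (without truth labels)
#' @export
write_counts <- function(counts, path,
                         samples_path = sub("\\.tsv(\\.gz)?$", "_samples.tsv",
                                            path)) {
  m <- counts$counts
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_meta(df, path)
  write_table_meta(counts$samples, samples_path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path,
                        samples_path = sub("\\.tsv(\\.gz)?$", "_samples.tsv",
                                           path)) {
  df <- read_table_schema(path, c(gene = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  ss <- read_table_schema(samples_path,
                          c(sample_id = "character", age_day = "numeric",
                            replicate = "integer"))
  if (!all(colnames(m) %in% ss$sample_id))
    stop("sample sheet does not cover all count columns")
  ss <- ss[match(colnames(m), ss$sample_id), , drop = FALSE]
  structure(list(counts = m, samples = ss, truth = NULL, spec = NULL),
            class = "age_series_counts")
}

#' Write a gene list, one id per line (motif-tool submission format)
#'
#' @param genes character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
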