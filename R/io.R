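# Readers and writers for the plain-text interchange formats: count tables
# (plain TSV or mothur shared format), sample metadata, and YAML configs.

#' Read a samples-by-taxa count table
#'
#' Accepts either a plain TSV (first column sample ids, remaining columns
#' taxa) or a mothur "shared"-format TSV (columns `label`, `Group`, `numOtus`
#' followed by the OTU counts); the format is detected from the header. Both
#' parse to the same matrix.
#'
#' @param path file path.
#' @return numeric matrix with sample ids as row names and taxa as column
#'   names.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) bld_abort(paste("file not found:", path), "io")
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (length(header) >= 3 && identical(tolower(header[1:3]),
                                       c("label", "group", "numotus"))) {
    m <- as.matrix(df[, -(1:3), drop = FALSE])
    rownames(m) <- df[[2]]
  } else {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  bad <- which(!stats::complete.cases(m) | apply(m, 1, function(r) any(r < 0)))
  if (length(bad) > 0) {
    bld_abort(sprintf("malformed count rows (negative or missing) at line(s): %s",
                      paste(bad + 1, collapse = ", ")), "io")
  }
  storage.mode(m) <- "numeric"
  m
}

#' Write a count table as plain TSV
#'
#' @param table samples-by-taxa matrix with row names.
#' @param path destination path.
#' @param mothur_shared write mothur shared format instead of plain TSV.
#' @export
write_count_table <- function(table, path, mothur_shared = FALSE) {
  df <- if (mothur_shared) {
    data.frame(label = "0.03", Group = rownames(table),
               numOtus = ncol(table), table, check.names = FALSE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = rownames(table), table, check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV path.
#' @param required column names that must be present; a missing column raises
#'   a schema error naming it.
#' @return data frame.
#' @export
read_sample_metadata <- function(path,
                                 required = c("sample_id", "patient_id",
                                              "exacerbation_number",
                                              "encounter", "sample_type")) {
  if (!file.exists(path)) bld_abort(paste("file not found:", path), "io")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8",
                          na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    bld_abort(paste("metadata is missing required column(s):",
                    paste(missing, collapse = ", ")), "schema")
  }
  df
}

#' Write a data frame as TSV
#'
#' @param df data frame.
#' @param path destination path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a cohort configuration as YAML
#'
#' Round-trips a [cohort_config()] losslessly through YAML.
#'
#' @param path YAML file path.
#' @return for the reader, a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # named numeric vectors come back as lists; restore them
  relist <- function(x) if (is.list(x) && all(vapply(x, is.numeric, logical(1))) &&
                            !is.null(names(x))) unlist(x) else x
  for (nm in c("exacerbation_probs", "n_beta_lactam_probs",
               "literature_mssa_mic", "pa_fallback_mic", "sample_type_probs",
               "mic_grid")) {
    raw[[nm]] <- relist(raw[[nm]])
  }
  raw$community$theta <- lapply(raw$community$theta, unlist)
  raw$community$boost <- lapply(raw$community$boost, unlist)
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @param config a [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  # named atomic vectors must become YAML maps, not sequences, so their
  # names survive the round trip
  namify <- function(x) {
    if (is.list(x)) {
      lapply(x, namify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(namify(unclass(config)), path)
  invisible(path)
}
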