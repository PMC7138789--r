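#' Sample-by-feature microbiome profile matrix
#'
#' Container for the two profile types the pipeline consumes: strain-level
#' marker profiles (binary presence/absence of strain-specific gene markers,
#' up to ~1e5 features) and species-level relative-abundance profiles
#' (compositional values in \[0, 1\], rows summing to 1). Rows are samples.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: existing rownames or `S1..Sn`).
#' @param feature_ids Character vector of unique feature identifiers
#'   (default: existing colnames or `F1..Fp`).
#' @param kind `"marker"` (entries must be exactly 0/1) or `"abundance"`
#'   (entries in \[0, 1\]).
#' @return An object of class `profile_matrix`: the validated matrix with
#'   ids as dimnames and the profile kind attached.
#' @export
profile_matrix <- function(values, sample_ids = NULL, feature_ids = NULL,
                           kind = c("marker", "abundance")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    me_stop("values must be a numeric matrix")
  }
  sample_ids <- as.character(sample_ids %||% rownames(values) %||%
                               paste0("S", seq_len(nrow(values))))
  feature_ids <- as.character(feature_ids %||% colnames(values) %||%
                                paste0("F", seq_len(ncol(values))))
  if (length(sample_ids) != nrow(values)) {
    me_stop("length(sample_ids) must equal nrow(values)")
  }
  if (length(feature_ids) != ncol(values)) {
    me_stop("length(feature_ids) must equal ncol(values)")
  }
  if (anyDuplicated(sample_ids)) me_stop("duplicate sample ids")
  if (anyDuplicated(feature_ids)) me_stop("duplicate feature ids")
  if (anyNA(values) || any(!is.finite(values))) {
    me_stop("profile values must be finite and non-missing")
  }
  validate_profile_values(values, kind)
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values, kind = kind, class = c("profile_matrix", "matrix", "array"))
}

validate_profile_values <- function(values, kind) {
  if (kind == "marker") {
    bad <- which(values != 0 & values != 1)
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(values))
      me_stop(sprintf(
        "marker profile entries must be 0 or 1; found %g at sample row %d, feature column %d",
        values[bad[1L]], i[1L], i[2L]), class = "microembed_validation_error")
    }
  } else {
    bad <- which(values < 0 | values > 1)
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(values))
      me_stop(sprintf(
        "abundance profile entries must lie in [0, 1]; found %g at sample row %d, feature column %d",
        values[bad[1L]], i[1L], i[2L]), class = "microembed_validation_error")
    }
  }
  invisible(values)
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d samples x %d features, kind = %s\n",
              nrow(x), ncol(x), profile_kind(x)))
  invisible(x)
}

#' Profile kind of a profile matrix
#' @param x A `profile_matrix`.
#' @return `"marker"` or `"abundance"`.
#' @export
profile_kind <- function(x) attr(x, "kind") %||% "abundance"

# Strip class/attributes down to a plain numeric matrix.
profile_values <- function(x) {
  y <- unclass(x)
  attr(y, "kind") <- NULL
  y
}

#' Read a profile matrix from delimited text
#'
#' Expected layout: header row of feature ids (the first header field, if
#' any, names the sample-id column and is ignored), one row per sample with
#' the sample id in the first column.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param kind Profile kind to validate against, `"marker"` or `"abundance"`.
#' @param delim Field delimiter, `","` or `"\t"`.
#' @return A [profile_matrix()].
#' @export
load_profiles <- function(path, kind = c("marker", "abundance"), delim = ",") {
  kind <- match.arg(kind)
  if (!file.exists(path)) me_stop("profile file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"")
  vals <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(vals))
    me_stop(sprintf(
      "malformed numeric value '%s' at sample '%s' (row %d), feature '%s' (column %d)",
      as.matrix(df)[bad[1L]], rownames(df)[i[1L]], i[1L],
      colnames(df)[i[2L]], i[2L]), class = "microembed_parse_error")
  }
  profile_matrix(vals, sample_ids = rownames(df), feature_ids = colnames(df),
                 kind = kind)
}

#' Write a profile matrix to delimited text
#'
#' Inverse of [load_profiles()]: `load_profiles(save_profiles(x, f))`
#' reproduces `x` exactly (values are written at full precision).
#'
#' @param x A [profile_matrix()].
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
save_profiles <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "profile_matrix"))
  header <- paste(c("sample_id", colnames(x)), collapse = delim)
  body <- paste(rownames(x),
                apply(profile_values(x), 1L, function(r)
                  paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                        collapse = delim)),
                sep = delim)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a binary label vector
#'
#' Accepts either one label (0/1) per line, ordered as the profile rows, or
#' a two-column `sample_id<delim>label` form (no header).
#'
#' @param path Path to the label file.
#' @param delim Delimiter for the two-column form.
#' @return Integer vector of 0/1 labels; named when ids were present.
#' @export
load_labels <- function(path, delim = ",") {
  if (!file.exists(path)) me_stop("label file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, delim, fixed = TRUE)
  nfield <- lengths(parts)
  if (all(nfield == 2L)) {
    labs <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    names(labs) <- vapply(parts, `[`, "", 1L)
  } else if (all(nfield == 1L)) {
    labs <- suppressWarnings(as.numeric(lines))
  } else {
    me_stop("label file must have one or two fields per line")
  }
  if (anyNA(labs) || !all(labs %in% c(0, 1))) {
    me_stop("labels must be 0 (control) or 1 (patient)")
  }
  stats::setNames(as.integer(labs), names(labs))
}

#' Write a binary label vector
#'
#' @param labels Integer 0/1 vector; names, if present, are written as a
#'   `sample_id,label` two-column file.
#' @param path Output file path.
#' @param delim Delimiter for the two-column form.
#' @return `path`, invisibly.
#' @export
save_labels <- function(labels, path, delim = ",") {
  labels <- check_binary_labels(stats::setNames(as.vector(labels), names(labels)))
  if (!is.null(names(labels)) && any(nzchar(names(labels)))) {
    writeLines(paste(names(labels), labels, sep = delim), path)
  } else {
    writeLines(as.character(labels), path)
  }
  invisible(path)
}
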