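#' Read a log2 expression matrix from tab-separated text
#'
#' Reads a genes-by-samples table whose first column holds gene identifiers
#' and whose header row holds sample identifiers. The `series_matrix` dialect
#' additionally skips metadata lines starting with `!`, as found in GEO
#' Series-Matrix exports. Values are expected on the log2 scale and already
#' normalized; no normalization is performed here.
#'
#' Duplicate gene identifiers are collapsed by keeping the row with the
#' largest mean intensity (the usual probe-collapse convention when no
#' annotation service is available); the retained duplicates are reported via
#' a message and the `"collapsed_genes"` attribute.
#'
#' @param path Path to a TSV file.
#' @param dialect Either `"plain_tsv"` or `"series_matrix"`.
#' @return A numeric matrix (genes x samples) with unique rownames (gene ids)
#'   and colnames (sample ids).
#' @export
read_expression_matrix <- function(path, dialect = c("plain_tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path)
  }
  lines <- readLines(path)
  if (dialect == "series_matrix") {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression matrix must have a header line and at least one gene row")
  }
  df <- utils::read.delim(text = lines, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) {
    stop("expression matrix must contain at least 2 sample columns, found ",
         ncol(df) - 1L)
  }
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
    }
    vals[, j] <- num
  }
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("expression matrix contains missing or non-finite values; ",
         "impute or filter upstream")
  }
  collapsed <- character(0)
  if (anyDuplicated(gene_ids)) {
    means <- rowMeans(vals)
    keep <- unlist(lapply(split(seq_along(gene_ids), gene_ids), function(idx) {
      idx[which.max(means[idx])]
    }), use.names = FALSE)
    keep <- sort(keep)  # preserve original file order
    collapsed <- unique(gene_ids[duplicated(gene_ids)])
    message(length(collapsed), " duplicated gene identifier(s) collapsed ",
            "by maximum mean intensity")
    vals <- vals[keep, , drop = FALSE]
  }
  structure(vals, collapsed_genes = collapsed)
}

#' Read a sample-to-group design table
#'
#' Expects a two-column TSV with header `sample_id`, `group`; groups must be
#' `case` and `control`, each with at least two samples (control standard
#' deviations are needed downstream). When `expr` is supplied the design is
#' checked for consistency against its sample identifiers.
#'
#' @param path Path to a TSV file.
#' @param expr Optional expression matrix to validate against.
#' @return A data.frame with columns `sample_id` (character) and `group`
#'   (factor with levels `case`, `control`).
#' @export
read_design <- function(path, expr = NULL) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("design table needs columns sample_id and group")
  design <- data.frame(sample_id = df[[1L]], group = df[[2L]],
                       stringsAsFactors = FALSE)
  validate_design(design, expr)
}

#' Validate a design data.frame
#'
#' @param design A data.frame with columns `sample_id` and `group`.
#' @param expr Optional expression matrix whose colnames must cover the
#'   design's samples.
#' @return The validated design with `group` as a factor (`case`, `control`).
#' @export
validate_design <- function(design, expr = NULL) {
  allowed <- c("case", "control")
  if (!all(c("sample_id", "group") %in% colnames(design))) {
    stop("design must have columns sample_id and group")
  }
  bad <- setdiff(unique(as.character(design$group)), allowed)
  if (length(bad)) {
    stop("unknown group label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed labels are 'case' and 'control'")
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design")
  }
  design$group <- factor(as.character(design$group), levels = allowed)
  counts <- table(design$group)
  if (any(counts < 2L)) {
    stop("each group needs at least 2 samples (control SD is undefined ",
         "otherwise); got case=", counts[["case"]],
         ", control=", counts[["control"]])
  }
  if (!is.null(expr)) {
    missing <- setdiff(design$sample_id, colnames(expr))
    if (length(missing)) {
      stop("design samples absent from expression matrix: ",
           paste(missing, collapse = ", "))
    }
  }
  design
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member lists are
#' deduplicated; empty files yield an empty collection with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (set members), with a named
#'   character `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), description = character(0),
                     class = "gene_set_collection"))
  }
  sets <- list()
  descr <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop("GMT line ", i, " (set '", fields[1L], "') has no members")
    }
    sets[[fields[1L]]] <- members
    descr[fields[1L]] <- fields[2L]
  }
  structure(sets, description = descr, class = "gene_set_collection")
}

#' Write a result table as full-precision TSV
#'
#' Numeric columns are serialized with 17 significant digits so that
#' [read_result_table()] reproduces the values bit-identically. Empty tables
#' write a header-only file.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop("cannot write table to ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to a TSV file.
#' @param numeric_cols Character vector of column names to parse as numeric;
#'   `NULL` (default) autodetects by attempting numeric conversion.
#' @return A data.frame.
#' @export
read_result_table <- function(path, numeric_cols = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  for (j in seq_along(df)) {
    convert <- if (is.null(numeric_cols)) {
      all(!is.na(suppressWarnings(as.numeric(df[[j]]))) | df[[j]] == "NA") &&
        nrow(df) > 0
    } else {
      colnames(df)[j] %in% numeric_cols
    }
    if (convert) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      if (!any(is.na(num) & df[[j]] != "NA")) df[[j]] <- num
    }
    if (all(df[[j]] %in% c("TRUE", "FALSE"))) df[[j]] <- as.logical(df[[j]])
  }
  df
}
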