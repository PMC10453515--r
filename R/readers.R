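#' Read and clean raw accelerometer CSV (WISDM dialect)
#'
#' Parses the raw phone-accelerometer dialect: comma-separated
#' `user,activity,timestamp,x,y,z` rows terminated with `";"`. Cleaning is
#' never fatal: rows that are blank, do not split into exactly 6 fields
#' (covers duplicated columns and stray separators), or whose numeric fields
#' fail to parse are dropped and counted; exact duplicate rows (whole line
#' after separator normalization) are dropped and counted.
#'
#' @param x Character vector of lines, or a path to a file.
#' @return A list with `records`, a tibble of clean rows
#'   (`user`, `activity`, `timestamp`, `x`, `y`, `z`), and `report`, a
#'   one-row tibble with `n_blank_or_malformed`, `n_duplicates`, `n_kept`.
#' @examples
#' read_wisdm_raw("33,Jogging,49105962326000,-0.69,12.68,0.50;")
#' @export
read_wisdm_raw <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- sub(";\\s*$", "", trimws(lines))

  blank <- !nzchar(lines)
  fields <- strsplit(lines[!blank], ",", fixed = TRUE)
  ok_width <- lengths(fields) == 6L

  n_malformed <- sum(blank) + sum(!ok_width)
  fields <- fields[ok_width]

  if (length(fields) > 0) {
    m <- do.call(rbind, fields)
    num <- suppressWarnings(apply(m[, c(1, 3, 4, 5, 6), drop = FALSE], 2,
                                  as.numeric))
    if (is.null(dim(num))) num <- matrix(num, nrow = 1)
    ok_num <- stats::complete.cases(num)
    n_malformed <- n_malformed + sum(!ok_num)
    m <- m[ok_num, , drop = FALSE]
  } else {
    m <- matrix(character(), ncol = 6)
  }

  key <- apply(m, 1, paste, collapse = ",")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  m <- m[!dup, , drop = FALSE]

  records <- tibble::tibble(
    user = as.integer(as.numeric(m[, 1])),
    activity = m[, 2],
    timestamp = as.numeric(m[, 3]),
    x = as.numeric(m[, 4]),
    y = as.numeric(m[, 5]),
    z = as.numeric(m[, 6])
  )
  list(
    records = records,
    report = tibble::tibble(n_blank_or_malformed = n_malformed,
                            n_duplicates = n_dup,
                            n_kept = nrow(records))
  )
}

#' Read a processed feature table with numeric labels
#'
#' Loads a pre-featurized table in the smartphone-dataset style: one
#' whitespace-delimited row of features per record (e.g. 561 attributes),
#' with a parallel vector of numeric activity labels that are converted to
#' text via `label_map`. Row width must be constant and every numeric label
#' must be mapped; violations are errors, since a processed table is expected
#' to be already clean.
#'
#' @param features Character vector of whitespace-delimited feature lines, a
#'   path to such a file, or a numeric matrix/data frame.
#' @param labels Integer/numeric label vector, or a path/lines of one label
#'   per row.
#' @param label_map Named character vector mapping numeric label to activity
#'   name, e.g. `c("1" = "walking", ...)`.
#' @return A tibble with feature columns `V1..Vp` and a `label` column of
#'   activity names.
#' @export
read_processed_table <- function(features, labels, label_map) {
  if (is.character(features)) {
    lines <- if (length(features) == 1L && file.exists(features))
      readLines(features, warn = FALSE) else features
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(strsplit(trimws(lines), "\\s+"),
                   function(f) suppressWarnings(as.numeric(f)))
    if (length(rows) == 0) {
      feat <- matrix(numeric(), ncol = 0, nrow = 0)
    } else {
      widths <- lengths(rows)
      if (length(unique(widths)) > 1L) {
        bad <- which(widths != widths[1])[1]
        abort(paste0("ragged feature table: row ", bad, " has ", widths[bad],
                     " fields, expected ", widths[1]))
      }
      feat <- do.call(rbind, rows)
    }
  } else {
    feat <- as.matrix(features)
  }

  if (is.character(labels)) {
    lab_lines <- if (length(labels) == 1L && file.exists(labels))
      readLines(labels, warn = FALSE) else labels
    labels <- as.numeric(trimws(lab_lines[nzchar(trimws(lab_lines))]))
  }
  if (nrow(feat) != length(labels))
    abort("features and labels disagree in length")

  if (length(labels) > 0) {
    key <- as.character(labels)
    unmapped <- setdiff(unique(key), names(label_map))
    if (length(unmapped) > 0)
      abort(paste0("unmapped numeric label(s): ",
                   paste(unmapped, collapse = ", ")))
    text <- unname(label_map[key])
  } else {
    text <- character()
  }

  out <- tibble::as_tibble(as.data.frame(feat), .name_repair = "minimal")
  if (ncol(out) > 0) names(out) <- paste0("V", seq_len(ncol(out)))
  out$label <- text
  out
}
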