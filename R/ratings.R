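# Rating data: persons x items, integer responses 1..5. The user-facing
# representation is a tibble with an optional person-id column; internally
# most computations use a plain integer matrix.

#' Validate and normalise a table of 5-point ratings
#'
#' @param data A data frame with one row per respondent. Item columns must be
#'   integers in 1–5. A person-identifier column named `person` (or a first
#'   column that is non-numeric) is carried along but not treated as an item.
#' @return A tibble with a `person` column followed by integer item columns.
#' @examples
#' as_ratings(data.frame(i1 = c(1, 3, 5), i2 = c(2, 4, 3)))
#' @export
as_ratings <- function(data) {
  stopifnot(is.data.frame(data))
  df <- tibble::as_tibble(data)
  id_col <- NULL
  if ("person" %in% names(df)) {
    id_col <- "person"
  } else if (ncol(df) > 1 && !is.numeric(df[[1]])) {
    id_col <- names(df)[1]
  }
  if (is.null(id_col)) {
    person <- seq_len(nrow(df))
    items <- df
  } else {
    person <- df[[id_col]]
    items <- df[setdiff(names(df), id_col)]
  }
  if (ncol(items) < 1) stop("ratings need at least one item column", call. = FALSE)
  mat <- ratings_matrix_checked(items)
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- names(items)
  dplyr::bind_cols(tibble::tibble(person = person), out)
}

ratings_matrix_checked <- function(items) {
  mat <- as.matrix(items)
  if (!is.numeric(mat)) stop("item columns must be numeric", call. = FALSE)
  bad <- which(is.na(mat) | mat != round(mat) | mat < 1 | mat > 5, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid response at person %d, item '%s': %s (must be an integer in 1..5)",
      bad[1, 1], colnames(mat)[bad[1, 2]] %||% as.character(bad[1, 2]),
      as.character(as.matrix(items)[bad[1, 1], bad[1, 2]])
    ), call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: split a ratings tibble into matrix + ids.
ratings_parts <- function(ratings) {
  ratings <- as_ratings(ratings)
  item_cols <- setdiff(names(ratings), "person")
  list(
    y = ratings_matrix_checked(ratings[item_cols]),
    person = ratings$person,
    items = item_cols
  )
}

#' Read a ratings table from CSV/TSV
#'
#' Rows containing any missing or empty cell are excluded listwise (the
#' number excluded is reported with a message), mirroring the usual
#' preprocessing of self-report rating data before IRTree analysis.
#'
#' @param path Path to a delimited file with a header row of item names and
#'   one row per respondent. An optional first column with a non-numeric
#'   header is taken as person identifiers.
#' @param delim Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A ratings tibble (see [as_ratings()]).
#' @export
read_ratings <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  n0 <- nrow(df)
  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    message(sum(!complete), " respondent(s) excluded listwise for missing responses")
    df <- df[complete, , drop = FALSE]
  }
  as_ratings(df)
}
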