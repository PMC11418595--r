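# Pseudo-item decomposition of a 5-point rating into the three binary
# decision nodes of the tree: disagreement (node 0), neutrality (node 1),
# extremity (node 2). Nodes not traversed by a response are missing by
# design (NA), a pure function of the response value:
#
#   response   node0  node1  node2
#      1         1      -      1
#      2         1      -      0
#      3         0      1      -
#      4         0      0      0
#      5         0      0      1

NODE0 <- c(1L, 1L, 0L, 0L, 0L)
NODE1 <- c(NA, NA, 1L, 0L, 0L)
NODE2 <- c(1L, 0L, NA, 0L, 1L)

#' Decompose ratings into binary pseudo-items
#'
#' Recodes each observed 5-point response into outcomes of the three decision
#' nodes (disagreement, neutrality, extremity). A node that is not reached by
#' a response — the neutrality node after a disagreement, the extremity node
#' after choosing the middle category — is missing by design and coded `NA`.
#'
#' @param ratings A ratings tibble or data frame (see [as_ratings()]).
#' @return A tibble with the `person` column followed by `3 * J` integer
#'   columns named `<item>_node0`, `<item>_node1`, `<item>_node2` (grouped by
#'   item), where `NA` means missing by design.
#' @seealso [recompose_responses()] for the exact inverse.
#' @examples
#' decompose_responses(data.frame(i1 = c(1, 3, 5)))
#' @export
decompose_responses <- function(ratings) {
  parts <- ratings_parts(ratings)
  y <- parts$y
  out <- vector("list", 3L * ncol(y))
  nm <- character(3L * ncol(y))
  for (j in seq_len(ncol(y))) {
    out[[3 * j - 2]] <- NODE0[y[, j]]
    out[[3 * j - 1]] <- NODE1[y[, j]]
    out[[3 * j]] <- NODE2[y[, j]]
    nm[(3 * j - 2):(3 * j)] <- paste0(parts$items[j], "_node", 0:2)
  }
  names(out) <- nm
  dplyr::bind_cols(tibble::tibble(person = parts$person), tibble::as_tibble(out))
}

#' Reassemble ratings from pseudo-items
#'
#' Inverse of [decompose_responses()]: maps each triple of node outcomes back
#' to the original response category, erroring on any triple that is not a
#' valid coding pattern (for example an observed neutrality outcome after a
#' disagreement).
#'
#' @param table A tibble as produced by [decompose_responses()].
#' @return A ratings tibble.
#' @export
recompose_responses <- function(table) {
  stopifnot(is.data.frame(table))
  df <- tibble::as_tibble(table)
  person <- if ("person" %in% names(df)) df$person else NULL
  node_cols <- grep("_node[012]$", names(df), value = TRUE)
  items <- unique(sub("_node[012]$", "", node_cols))
  if (length(node_cols) != 3L * length(items)) {
    stop("expected three node columns per item", call. = FALSE)
  }
  # Key over (node0, node1, node2) with NA encoded as 2L.
  key <- function(a, b, c2) (ifelse(is.na(a), 2L, a) * 9L +
                             ifelse(is.na(b), 2L, b) * 3L +
                             ifelse(is.na(c2), 2L, c2))
  valid_keys <- key(NODE0, NODE1, NODE2)
  out <- vector("list", length(items))
  for (j in seq_along(items)) {
    k <- key(df[[paste0(items[j], "_node0")]],
             df[[paste0(items[j], "_node1")]],
             df[[paste0(items[j], "_node2")]])
    resp <- match(k, valid_keys)
    if (any(is.na(resp))) {
      p <- which(is.na(resp))[1]
      stop(sprintf("inconsistent pseudo-item pattern at person %d, item '%s'",
                   p, items[j]), call. = FALSE)
    }
    out[[j]] <- as.integer(resp)
  }
  names(out) <- items
  res <- tibble::as_tibble(out)
  if (!is.null(person)) res <- dplyr::bind_cols(tibble::tibble(person = person), res)
  as_ratings(res)
}
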