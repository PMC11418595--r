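# Item parameters. User-facing representation: a long tibble with one row
# per item x class, columns
#   item, class, alpha_theta, omega, alpha_ers, alpha_mrs, beta0, beta1, beta2
# alpha_theta and omega are class-invariant (repeated across a given item's
# rows); a response style that is not part of a class's strategy has its
# loading fixed at exactly 0 in that class. A single beta2 is shared by the
# agreement and disagreement branches of the extremity node.

#' Construct and validate an item-parameter table
#'
#' @param df A data frame with columns `item`, `class` (1–4), `alpha_theta`,
#'   `omega`, `alpha_ers`, `alpha_mrs`, `beta0`, `beta1`, `beta2`.
#' @return The validated tibble, classed `irtree_items`.
#' @details Validation enforces: `alpha_theta` and `omega` identical across
#'   classes within an item; `omega > 0`; free loadings non-negative; loadings
#'   of an inactive style exactly zero (`alpha_ers` in the "MRS only" and
#'   "0RS" classes, `alpha_mrs` in the "ERS only" and "0RS" classes).
#' @export
irtree_items <- function(df) {
  need <- c("item", "class", "alpha_theta", "omega", "alpha_ers",
            "alpha_mrs", "beta0", "beta1", "beta2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- tibble::as_tibble(df)[need]
  df$class <- match_class(df$class)
  num <- df[setdiff(need, c("item", "class"))]
  if (!all(vapply(num, is.numeric, TRUE)) || !all(is.finite(as.matrix(num)))) {
    stop("item parameters must be finite numerics", call. = FALSE)
  }
  inv <- dplyr::summarise(dplyr::group_by(df, .data$item),
                          d = max(.data$alpha_theta) - min(.data$alpha_theta) +
                              max(.data$omega) - min(.data$omega))
  if (any(inv$d > 0)) {
    stop("alpha_theta and omega must be class-invariant within an item",
         call. = FALSE)
  }
  if (any(df$alpha_theta <= 0) || any(df$omega <= 0)) {
    stop("alpha_theta and omega must be positive", call. = FALSE)
  }
  if (any(df$alpha_ers < 0) || any(df$alpha_mrs < 0)) {
    stop("response-style loadings must be non-negative", call. = FALSE)
  }
  if (any(df$alpha_ers[!ers_active(df$class)] != 0)) {
    stop("alpha_ers must be exactly 0 where ERS is inactive", call. = FALSE)
  }
  if (any(df$alpha_mrs[!mrs_active(df$class)] != 0)) {
    stop("alpha_mrs must be exactly 0 where MRS is inactive", call. = FALSE)
  }
  class(df) <- c("irtree_items", class(df))
  df
}

# Internal array form: list(item_ids, ath[J], omega, aers[J,4], amrs[J,4],
# beta[J,3,4]). Classes absent from the tibble get masked loadings and
# difficulties of 0 (only reachable when the caller never evaluates them).
items_arrays <- function(items) {
  items <- irtree_items(items)
  ids <- unique(items$item)
  J <- length(ids)
  ath <- numeric(J)
  aers <- matrix(0, J, 4)
  amrs <- matrix(0, J, 4)
  beta <- array(0, c(J, 3, 4))
  for (r in seq_len(nrow(items))) {
    j <- match(items$item[r], ids)
    c0 <- items$class[r]
    ath[j] <- items$alpha_theta[r]
    aers[j, c0] <- items$alpha_ers[r]
    amrs[j, c0] <- items$alpha_mrs[r]
    beta[j, , c0] <- c(items$beta0[r], items$beta1[r], items$beta2[r])
  }
  list(item_ids = ids, J = J, ath = ath, omega = items$omega[1],
       aers = aers, amrs = amrs, beta = beta,
       classes = sort(unique(items$class)))
}

arrays_to_items <- function(a, classes = a$classes) {
  rows <- tidyr::expand_grid(item = a$item_ids, class = classes)
  j <- match(rows$item, a$item_ids)
  irtree_items(tibble::tibble(
    item = rows$item, class = rows$class,
    alpha_theta = a$ath[j], omega = a$omega,
    alpha_ers = a$aers[cbind(j, rows$class)],
    alpha_mrs = a$amrs[cbind(j, rows$class)],
    beta0 = a$beta[cbind(j, 1L, rows$class)],
    beta1 = a$beta[cbind(j, 2L, rows$class)],
    beta2 = a$beta[cbind(j, 3L, rows$class)]
  ))
}

# Person-side container: tibble(person, theta, eta_ers, eta_mrs).
persons_parts <- function(persons) {
  need <- c("theta", "eta_ers", "eta_mrs")
  persons <- tibble::as_tibble(persons)
  miss <- setdiff(need, names(persons))
  if (length(miss)) stop("persons need columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!all(is.finite(as.matrix(persons[need])))) {
    stop("person parameters must be finite", call. = FALSE)
  }
  list(person = if ("person" %in% names(persons)) persons$person
                else seq_len(nrow(persons)),
       eta = as.matrix(persons[need]))
}
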