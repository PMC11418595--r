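# Latent response-strategy classes. The index order is fixed package-wide:
# 1 = "ERS only", 2 = "MRS only", 3 = "2RS", 4 = "0RS".

CLASS_LABELS <- c("ERS only", "MRS only", "2RS", "0RS")
CLASS_CODES <- c("ers", "mrs", "2rs", "0rs")

#' Response-strategy classes of the MM-IRTree model
#'
#' The mixture model distinguishes four latent classes of respondents by
#' which response-style (RS) traits enter their response process in addition
#' to the substantive trait: only the extreme response style (ERS), only the
#' midpoint response style (MRS), both, or neither. A style that is not part
#' of a class's strategy has its factor loadings fixed to zero for every item
#' in that class.
#'
#' @return A tibble with one row per class: integer `class` index (the
#'   package-wide enumeration 1–4), `code` (short label used in function
#'   arguments), `label`, and logical flags `ers_active`, `mrs_active`.
#' @examples
#' irtree_classes()
#' @export
irtree_classes <- function() {
  tibble::tibble(
    class = 1:4,
    code = CLASS_CODES,
    label = CLASS_LABELS,
    ers_active = c(TRUE, FALSE, TRUE, FALSE),
    mrs_active = c(FALSE, TRUE, TRUE, FALSE)
  )
}

# Resolve a class given as index, code or label to the integer index.
match_class <- function(class) {
  if (is.numeric(class)) {
    cl <- as.integer(class)
    if (any(is.na(cl)) || any(cl < 1L | cl > 4L)) {
      stop("class index must be in 1..4", call. = FALSE)
    }
    return(cl)
  }
  x <- tolower(as.character(class))
  idx <- match(x, CLASS_CODES)
  idx[is.na(idx)] <- match(tolower(CLASS_LABELS), tolower(CLASS_LABELS))[
    match(x[is.na(idx)], tolower(CLASS_LABELS))]
  if (any(is.na(idx))) {
    stop("unknown class: ", paste(class[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  as.integer(idx)
}

ers_active <- function(class) class %in% c(1L, 3L)
mrs_active <- function(class) class %in% c(2L, 3L)

# Single-class benchmark models reuse the class masks: fitting model "ers"
# means every respondent follows the "ERS only" component model.
MODEL_CODES <- c("mm", "ers", "mrs", "2rs", "0rs")
model_to_class <- function(model) {
  switch(model, ers = 1L, mrs = 2L, `2rs` = 3L, `0rs` = 4L,
         stop("not a single-class model: ", model, call. = FALSE))
}
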