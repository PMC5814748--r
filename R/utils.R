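check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1)
    stop("`alpha` must be a single number in [0, 1)")
  invisible(alpha)
}

#' Validate a genes-by-cells expression matrix
#'
#' Checks that `expr` is a nonnegative numeric matrix with unique rownames
#' (gene identifiers) and unique colnames (cell identifiers).
#'
#' @param expr matrix to validate.
#' @return the validated matrix, invisibly usable downstream.
#' @export
validate_expression <- function(expr) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr))
    stop("expression matrix must be numeric")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(expr)))
    stop(sprintf("duplicate gene identifier: '%s'",
                 rownames(expr)[duplicated(rownames(expr))][1]))
  if (anyDuplicated(colnames(expr)))
    stop(sprintf("duplicate cell identifier: '%s'",
                 colnames(expr)[duplicated(colnames(expr))][1]))
  if (anyNA(expr))
    stop("expression matrix contains missing values")
  if (any(expr < 0))
    stop("expression matrix contains negative values")
  expr
}
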