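#' Low-rank adapter updates
#'
#' Parameter-efficient fine-tuning expresses the update to a frozen weight
#' matrix \eqn{W_0 \in R^{d \times k}} as a low-rank product
#' \eqn{\Delta W = B A} with \eqn{B \in R^{d \times r}},
#' \eqn{A \in R^{r \times k}} and rank \eqn{r \ll \min(d, k)}. At merge time
#' the delta is scaled by \eqn{\alpha / r}, so the effective weights are
#' \eqn{W_0 + (\alpha / r) B A}. These two operations are implemented here as
#' standalone matrix arithmetic; model training is out of scope.
#'
#' @param A Numeric matrix of shape (rank, k).
#' @param B Numeric matrix of shape (d, rank).
#' @param alpha Positive scaling constant.
#' @return `lora_update()`: an object of class `"lora_update"` bundling `A`,
#'   `B`, `alpha` and the rank (`nrow(A)`, which must equal `ncol(B)`).
#' @examples
#' u <- lora_update(A = matrix(c(3, 4), 1), B = matrix(c(1, 2), 2), alpha = 1)
#' lora_delta(u)
#' lora_merge(diag(2), lora_update(matrix(c(0, 1), 1), matrix(c(1, 0), 2), 4))
#' @export
lora_update <- function(A, B, alpha = nrow(A)) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(B) != nrow(A)) {
    abort(sprintf("Rank mismatch: ncol(B) = %d but nrow(A) = %d.",
                  ncol(B), nrow(A)))
  }
  r <- nrow(A)
  if (r < 1L) abort("Rank r must be a positive integer.")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    abort("`alpha` must be a positive scalar.")
  }
  d <- nrow(B)
  k <- ncol(A)
  if (r > min(d, k)) {
    abort(sprintf("Rank r = %d exceeds min(d, k) = %d.", r, min(d, k)))
  }
  structure(list(A = A, B = B, alpha = alpha, r = r, d = d, k = k),
            class = "lora_update")
}

#' @rdname lora_update
#' @param update A `"lora_update"` object.
#' @return `lora_delta()`: the unscaled `d x k` matrix `B %*% A` (matrix rank
#'   at most `r`).
#' @export
lora_delta <- function(update) {
  stopifnot(inherits(update, "lora_update"))
  update$B %*% update$A
}

#' @rdname lora_update
#' @param W0 Base weight matrix of shape `d x k`.
#' @return `lora_merge()`: the merged matrix `W0 + (alpha / r) * B %*% A`.
#' @export
lora_merge <- function(W0, update) {
  stopifnot(inherits(update, "lora_update"))
  W0 <- as.matrix(W0)
  if (nrow(W0) != update$d || ncol(W0) != update$k) {
    abort(sprintf("W0 is %d x %d but the update expects %d x %d.",
                  nrow(W0), ncol(W0), update$d, update$k))
  }
  W0 + (update$alpha / update$r) * lora_delta(update)
}

#' @export
print.lora_update <- function(x, ...) {
  cat(sprintf("<lora_update> d = %d, k = %d, r = %d, alpha = %g (scale %g)\n",
              x$d, x$k, x$r, x$alpha, x$alpha / x$r))
  invisible(x)
}
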