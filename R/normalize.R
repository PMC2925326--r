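#' Quantile normalization per tissue
#'
#' Forces every sample's value distribution onto a common reference: the
#' across-sample mean of order statistics. Within-sample rank order is
#' preserved; values tied within a sample all receive the mean of the
#' reference values at the tied ranks, so the map is well defined and
#' idempotent.
#'
#' @param x an [expression_matrix()] with `normalized = FALSE` and at least
#'   two samples.
#' @return The normalized `expr_matrix` (`normalized = TRUE`).
#' @examples
#' m <- expression_matrix(cbind(s1 = c(1, 3, 5), s2 = c(2, 4, 6)) |>
#'        `rownames<-`(c("a", "b", "c")), tissue = "SAT")
#' quantile_normalize(m)$values  # both columns become (1.5, 3.5, 5.5)
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$normalized)
    stop("matrix is already normalized")
  v <- x$values
  if (ncol(v) < 2L)
    stop("quantile normalization needs at least 2 samples")
  ref <- rowMeans(apply(v, 2L, sort, method = "radix"))
  out <- apply(v, 2L, function(col) {
    o <- order(col)
    q <- numeric(length(col))
    q[o] <- ref
    # ties within the sample share the mean reference value of their ranks
    stats::ave(q, col, FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, tissue = x$tissue, normalized = TRUE)
}
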