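#' Evaluate a kernel between two feature vectors
#'
#' The radial kernel measures similarity as \eqn{\exp(-\gamma |x-y|^2)}, so it
#' equals 1 at zero distance and decays towards 0; the linear kernel is the
#' plain dot product; sigmoid and polynomial follow the usual libsvm
#' parameterization (\eqn{\tanh(\gamma x\cdot y + c_0)} and
#' \eqn{(\gamma x\cdot y + c_0)^d}).
#'
#' @param spec a [KernelSpec-class].
#' @param x,y numeric vectors of equal length.
#' @return a similarity scalar.
#' @examples
#' kernelValue(kernelSpec("radial", gamma = 0.5), c(1, 0), c(0, 0))  # exp(-0.5)
#' kernelValue(kernelSpec("linear"), c(1, 2), c(3, 4))               # 11
#' @export
kernelValue <- function(spec, x, y) {
  stopifnot(is(spec, "KernelSpec"))
  validObject(spec)
  if (length(x) != length(y))
    stop("x and y must have the same length")
  switch(spec@kind,
    radial = exp(-spec@gamma * sum((x - y)^2)),
    linear = sum(x * y),
    sigmoid = tanh(spec@gamma * sum(x * y) + spec@coef0),
    polynomial = (spec@gamma * sum(x * y) + spec@coef0)^spec@degree)
}

## Kernel matrix between the rows of A (n x p) and rows of B (m x p).
kernelMatrix_ <- function(spec, A, B) {
  ip <- A %*% t(B)
  switch(spec@kind,
    linear = ip,
    radial = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * ip
      d2[d2 < 0] <- 0
      exp(-spec@gamma * d2)
    },
    sigmoid = tanh(spec@gamma * ip + spec@coef0),
    polynomial = (spec@gamma * ip + spec@coef0)^spec@degree)
}
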