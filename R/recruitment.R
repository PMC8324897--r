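#' Sigmoidal fibril recruitment
#'
#' Micropillar surface roughness means that the flat punch does not touch all
#' fibrils at once: the fraction of the cross-section in contact grows with
#' the apparent strain as a sigmoid
#' `xi(eps) = 1 / (1 + exp(-(eps - mu) / beta))`. Interpreting `xi` as the
#' recruited fraction `n / N` of the `N` fibrils and inverting it gives each
#' element a strain offset
#' `eps_0n = -beta * log(N / n - 1) + mu`, assigned in element order so that
#' offsets are non-decreasing in `n`. Elements with `eps_0n <= 0` are in
#' contact from the start ("instantaneously recruited"). The expression is
#' singular at `n = N`; the last element receives the offset evaluated at
#' `n = N - 0.5`, continuing the midpoint convention of the sigmoid.
#'
#' @param mu sigmoid midpoint (apparent strain).
#' @param beta sigmoid shape parameter (apparent strain, positive).
#' @param n_elements number of elements `N` (at least 2).
#' @return An object of class `"recruitment_model"`: a list with `mu`,
#'   `beta`, `n_elements`, the raw `offsets` (which may be negative), the
#'   clipped `offsets_applied` used for the strain correction (negative
#'   offsets are treated as zero, the element is already in contact), and
#'   `n_instantaneous`, the count of elements with non-positive raw offset.
#' @export
#' @examples
#' rm <- recruitment_offsets(mu = 0.0215, beta = 0.00635, n_elements = 618)
#' rm$n_instantaneous # 20
recruitment_offsets <- function(mu, beta, n_elements) {
  stopifnot(beta > 0, n_elements >= 2)
  N <- as.integer(n_elements)
  n <- c(seq_len(N - 1L), N - 0.5)
  offsets <- -beta * log(N / n - 1) + mu
  structure(list(mu = mu, beta = beta, n_elements = N,
                 offsets = offsets,
                 offsets_applied = pmax(offsets, 0),
                 n_instantaneous = sum(offsets <= 0)),
            class = "recruitment_model")
}

#' @export
print.recruitment_model <- function(x, ...) {
  cat(sprintf(
    "Sigmoid recruitment: mu = %g, beta = %g, N = %d (%d instantaneous)\n",
    x$mu, x$beta, x$n_elements, x$n_instantaneous))
  invisible(x)
}

#' Recruitment sigmoid
#'
#' Fraction of fibrils in contact with the punch at apparent strain `eps`.
#'
#' @param eps apparent strain (vectorised).
#' @param mu,beta sigmoid midpoint and shape parameter.
#' @return Values in (0, 1), strictly increasing in `eps`.
#' @export
recruitment_fraction <- function(eps, mu, beta) {
  1 / (1 + exp(-(eps - mu) / beta))
}
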