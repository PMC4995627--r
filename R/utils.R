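#' @importFrom rlang abort %||% .data
#' @importFrom stats qnorm plogis dnorm kmeans sd var uniroot optim rexp runif
#' @importFrom utils write.csv read.csv
#' @importFrom tibble as_tibble tibble
NULL

#' @export
tibble::as_tibble

abort_design <- function(msg, ...) {
  abort(msg, class = "raschtraj_invalid_design", ...)
}

abort_scenario <- function(msg, ...) {
  abort(msg, class = "raschtraj_invalid_scenario", ...)
}

#' Derive independent replicate seeds from a master seed
#'
#' Draws `n` integer seeds from a stream initialised at `master`, so that
#' replicate r of an experiment is reproducible on its own and the whole
#' experiment is reproducible from the master seed alone.
#'
#' @param master single integer master seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`, all below 2^31.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  withr::with_seed(as.integer(master), sample.int(2147483646L, n))
}

## all k! permutations of 1..k, rows in lexicographic order (k small)
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
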