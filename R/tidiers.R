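#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a randomization test: one row per replicate
#'
#' @param x A `randomization_test`.
#' @param ... Unused.
#' @return Tibble: `replicate`, `statistic`.
#' @method tidy randomization_test
#' @export
tidy.randomization_test <- function(x, ...) {
  tibble(replicate = seq_along(x$null), statistic = x$null)
}

#' One-row summary of a randomization test
#'
#' @param x A `randomization_test`.
#' @param ... Unused.
#' @return Tibble: `method`, `observed`, `null_mean`, `null_sd`, `p_value`,
#'   `reps`.
#' @method glance randomization_test
#' @export
glance.randomization_test <- function(x, ...) {
  tibble(method = x$method, observed = x$observed,
         null_mean = mean(x$null), null_sd = sd(x$null),
         p_value = x$p_value, reps = x$reps)
}

#' Tidy conservation calls (passthrough as a plain tibble)
#'
#' @param x A `conservation_calls` tibble.
#' @param ... Unused.
#' @method tidy conservation_calls
#' @export
tidy.conservation_calls <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' One-row summary of conservation calls
#'
#' @param x A `conservation_calls` tibble.
#' @param ... Unused.
#' @return Tibble: `n_pairs`, `fraction_conserved`, `n_excluded`.
#' @method glance conservation_calls
#' @export
glance.conservation_calls <- function(x, ...) {
  s <- summarize_conservation(x)
  tibble(n_pairs = nrow(s$per_pair),
         fraction_conserved = s$fraction_conserved,
         n_excluded = s$n_excluded)
}

#' Tidy an entropy comparison: one row per case
#' @param x An `entropy_comparison`.
#' @param ... Unused.
#' @method tidy entropy_comparison
#' @export
tidy.entropy_comparison <- function(x, ...) x$cases

#' Per-class summary of an entropy comparison
#' @param x An `entropy_comparison`.
#' @param ... Unused.
#' @method glance entropy_comparison
#' @export
glance.entropy_comparison <- function(x, ...) x$summary

unclass_result <- function(x) {
  class(x) <- class(tibble())
  x
}
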