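#' Tidiers for fitted result objects
#'
#' broom-style accessors: `tidy()` returns the per-observation table of a
#' result, `glance()` a one-row model-level summary.
#'
#' @param x A `damage_length_cor` from [damage_length_correlation()].
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @method tidy damage_length_cor
#' @export
tidy.damage_length_cor <- function(x, ...) {
  x$per_length
}

#' @rdname tidy.damage_length_cor
#' @method glance damage_length_cor
#' @export
glance.damage_length_cor <- function(x, ...) {
  tibble(
    estimate = x$estimate,
    p.value = x$p_value,
    n_lengths = nrow(x$per_length),
    damage_class = x$damage_class
  )
}

#' @rdname tidy.damage_length_cor
#' @method glance divergence_curve
#' @export
glance.divergence_curve <- function(x, ...) {
  tibble(
    n_thresholds = nrow(x),
    max_bq = max(x$bq_threshold),
    divergence_at_max_bq = x$divergence[nrow(x)],
    gc_to_at_at_max_bq = x$gc_to_at_rate[nrow(x)]
  )
}

#' @export
generics::tidy

#' @export
generics::glance
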