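# broom-style accessors for fitted/simulated objects.

#' Tidy an NMSSE ensemble
#'
#' One row per time point: populations, coherence magnitude, vibrational
#' occupation and the Monte-Carlo standard error of the acceptor population.
#'
#' @param x An `nmsse_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `t`, `p_donor`, `p_acceptor`,
#'   `coherence_abs`, `n_vib`, `se_p_a`.
#' @method tidy nmsse_ensemble
#' @export
tidy.nmsse_ensemble <- function(x, ...) x$data

#' One-row ensemble summary
#'
#' @param x An `nmsse_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: bath kind, trajectory count, seed, window,
#'   maximum transfer probability and its time, final vibrational
#'   occupation.
#' @method glance nmsse_ensemble
#' @export
glance.nmsse_ensemble <- function(x, ...) {
  i <- which.max(x$data$p_acceptor)
  tibble(bath_kind = x$bath_kind,
         n_traj = x$n_traj,
         master_seed = x$master_seed,
         t_max = max(x$t_grid),
         max_p = x$data$p_acceptor[i],
         t_at_max = x$data$t[i],
         se_at_max = x$data$se_p_a[i],
         n_vib_final = x$data$n_vib[length(x$t_grid)])
}

#' Tidy a Delta-P scan
#'
#' @param x An `nmsse_scan`.
#' @param ... Unused.
#' @return The long cell tibble (delta, coupling, lam, bath, delta_p, se,
#'   regime, ...).
#' @method tidy nmsse_scan
#' @export
tidy.nmsse_scan <- function(x, ...) x$data

#' One-row scan summary
#'
#' @param x An `nmsse_scan`.
#' @param ... Unused.
#' @return A one-row tibble with cell counts and the extreme Delta-P values.
#' @method glance nmsse_scan
#' @export
glance.nmsse_scan <- function(x, ...) {
  ok <- !is.na(x$data$delta_p)
  tibble(n_cells = nrow(x$data),
         n_failed = sum(!ok),
         n_traj = x$n_traj,
         master_seed = x$master_seed,
         max_delta_p = if (any(ok)) max(x$data$delta_p[ok]) else NA_real_,
         min_delta_p = if (any(ok)) min(x$data$delta_p[ok]) else NA_real_)
}
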