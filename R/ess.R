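#' Classify the equilibria of the emission game and their stability
#'
#' Enumerates the equilibria of the replicator dynamics — the monomorphic
#' states `x_E = 0` and `x_E = 1`, plus the interior coexistence frequency
#' when it exists — and labels each as locally stable (an evolutionarily
#' stable state) or unstable from the sign of \eqn{dg/dx_E}, estimated by a
#' central finite difference.
#'
#' The stable set is determined by where `alpha1` falls relative to the two
#' closed-form bounds (see [coexistence_condition()]): below the lower bound
#' the all-emitter state is stable; between the bounds the interior
#' coexistence state is stable; above the viability threshold the
#' all-non-emitter state is stable. Parameter points lying numerically *on*
#' a bound (a measure-zero degeneracy) are labeled regime `"marginal"` and
#' no stability claim is made.
#'
#' @param params A [bvoc_params()] object.
#' @param h Step for the central finite difference (default `1e-6`).
#' @param boundary_tol Distance from a regime bound below which the point is
#'   declared marginal.
#' @return An object of class `bvoc_ess` with components `equilibria`
#'   (a tibble: `x_e`, `kind`, `dg_dx`, `stable`), `regime` (one of
#'   `"emitter_dominant"`, `"coexistent"`, `"nonemitter_dominant"`,
#'   `"marginal"`), `stable_density` (emitter frequency at the stable
#'   equilibrium), and `params`. Use [tidy()] / [glance()] to extract
#'   tibbles.
#' @examples
#' classify_ess(bvoc_params(alpha1 = 0.5, alpha2 = 0.9, n = 8))
#' @export
classify_ess <- function(params, h = 1e-6, boundary_tol = 1e-9) {
  stopifnot(inherits(params, "bvoc_params"))
  b <- regime_bounds(params)
  marginal <- abs(params$alpha1 - b$lower) < boundary_tol ||
    abs(params$alpha1 - b$upper) < boundary_tol

  x_int <- interior_equilibrium(params)
  x_eq <- c(0, 1, x_int[!is.na(x_int)])
  kind <- c("monomorphic_nonemitter", "monomorphic_emitter",
            rep("coexistent", length(x_eq) - 2L))
  dg <- vapply(x_eq, function(x) {
    (g_raw(x + h, params) - g_raw(x - h, params)) / (2 * h)
  }, numeric(1))
  stable <- if (marginal) rep(NA, length(x_eq)) else dg < 0

  regime <- if (marginal) {
    "marginal"
  } else if (params$alpha1 >= b$upper) {
    "nonemitter_dominant"
  } else if (params$alpha1 <= b$lower) {
    "emitter_dominant"
  } else {
    "coexistent"
  }
  stable_density <- switch(regime,
    nonemitter_dominant = 0,
    emitter_dominant    = 1,
    coexistent          = x_int,
    NA_real_
  )

  structure(
    list(
      equilibria = tibble(x_e = x_eq, kind = kind, dg_dx = dg, stable = stable),
      regime = regime,
      stable_density = stable_density,
      bounds = b,
      params = params
    ),
    class = "bvoc_ess"
  )
}

#' @export
print.bvoc_ess <- function(x, ...) {
  cat("<bvoc_ess> regime:", x$regime, "\n")
  cat(sprintf("  alpha1 = %g in bands (lower %.4g, viability threshold %.4g)\n",
              x$params$alpha1, x$bounds$lower, x$bounds$upper))
  print(x$equilibria)
  invisible(x)
}

#' @describeIn classify_ess One row per equilibrium.
#' @param x A `bvoc_ess` object.
#' @param ... Unused.
#' @export
tidy.bvoc_ess <- function(x, ...) x$equilibria

#' @describeIn classify_ess One-row summary: regime, stable emitter density,
#'   the two regime bounds on `alpha1`, and the interior frequency (NA when
#'   absent).
#' @export
glance.bvoc_ess <- function(x, ...) {
  tibble(
    regime = x$regime,
    stable_density = x$stable_density,
    x_interior = if (any(x$equilibria$kind == "coexistent"))
      x$equilibria$x_e[x$equilibria$kind == "coexistent"][1] else NA_real_,
    bound_lower = x$bounds$lower,
    viability_threshold = x$bounds$upper,
    alpha1 = x$params$alpha1,
    alpha2 = x$params$alpha2,
    n = x$params$n
  )
}

#' @describeIn classify_ess Plot the replicator flow \eqn{g(x_E)} with
#'   equilibria marked (filled = stable).
#' @param object A `bvoc_ess` object.
#' @export
autoplot.bvoc_ess <- function(object, ...) {
  xs <- seq(0, 1, length.out = 201)
  flow <- tibble(x_e = xs, g = replicator_rhs(xs, object$params))
  eq <- object$equilibria
  ggplot2::ggplot(flow, ggplot2::aes(x = .data$x_e, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = eq,
      ggplot2::aes(x = .data$x_e, y = 0, fill = .data$stable),
      shape = 21, size = 3
    ) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               na.value = "grey50", name = "stable") +
    ggplot2::labs(x = expression(x[E]), y = expression(g(x[E])),
                  title = sprintf("Replicator flow (regime: %s)", object$regime)) +
    ggplot2::theme_minimal()
}

#' Integrate the replicator dynamics forward in time
#'
#' Numerically solves \eqn{dx_E/dt = g(x_E)} from `x0` with `deSolve`'s
#' adaptive `lsoda` integrator, clipping the state to \[0, 1\] after each
#' output step (the flow cannot leave the interval analytically; clipping
#' guards round-off).
#'
#' @param x0 Initial emitter frequency in (0, 1).
#' @param params A [bvoc_params()] object.
#' @param t_max Integration horizon (replicator time units).
#' @param dt Output time step.
#' @return A tibble with columns `time` and `x_e`.
#' @examples
#' traj <- integrate_dynamics(0.5, bvoc_params(alpha1 = 0.9), t_max = 100)
#' tail(traj, 1)
#' @export
integrate_dynamics <- function(x0, params, t_max = 2000, dt = 1) {
  stopifnot(inherits(params, "bvoc_params"))
  check_range(x0, "x0", 0, 1)
  times <- seq(0, t_max, by = dt)
  rhs <- function(t, y, parms) list(g_raw(min(max(y, 0), 1), params))
  # stop once the flow has numerically converged: integrating a fully
  # stationary state for long stretches destabilizes the step-size control
  tol <- 1e-13 * max(1, params$fhat)
  conv <- function(t, y, parms) abs(g_raw(min(max(y, 0), 1), params)) - tol
  out <- deSolve::ode(y = c(x_e = x0), times = times, func = rhs,
                      parms = NULL, method = "lsodar", rootfun = conv)
  x <- pmin(pmax(out[, "x_e"], 0), 1)
  if (any(!is.finite(x))) abort("Integration produced non-finite state.")
  # map output rows onto the requested grid (the root point is off-grid) and
  # hold the stationary terminal value past early termination
  xg <- rep(NA_real_, length(times))
  pos <- match(round(out[, "time"], 9), round(times, 9))
  xg[pos[!is.na(pos)]] <- x[!is.na(pos)]
  if (anyNA(xg)) xg[is.na(xg)] <- x[length(x)]
  tibble(time = times, x_e = xg)
}

#' Mean-field phase diagram over the alpha1-alpha2 plane
#'
#' For every grid cell, records the emitter density at the stable
#' equilibrium (1 when emitters fix, the interior frequency under
#' coexistence, 0 when cheating wins) together with the regime label. The
#' regime boundaries are the closed-form curves
#' `alpha1 = (alpha2^n p - c) / (alpha2^n p (1 - c))` and
#' `alpha1 = (p - c) / (p (1 - c))`.
#'
#' @param alpha1_grid,alpha2_grid Ordered grids strictly inside (0, 1).
#' @param params_base A [bvoc_params()] supplying `p`, `c`, `n`.
#' @return A tibble: `alpha1`, `alpha2`, `stable_density`, `regime`.
#' @examples
#' pd <- phase_diagram_meanfield(seq(0.1, 0.9, 0.2), seq(0.1, 0.9, 0.2),
#'                               bvoc_params())
#' @export
phase_diagram_meanfield <- function(alpha1_grid = seq(0.01, 0.99, by = 0.01),
                                    alpha2_grid = seq(0.01, 0.99, by = 0.01),
                                    params_base = bvoc_params()) {
  stopifnot(all(alpha1_grid > 0 & alpha1_grid < 1),
            all(alpha2_grid > 0 & alpha2_grid < 1))
  tidyr::expand_grid(alpha1 = alpha1_grid, alpha2 = alpha2_grid) |>
    dplyr::mutate(purrr::map2_dfr(.data$alpha1, .data$alpha2, function(a1, a2) {
      ess <- classify_ess(update_params(params_base, alpha1 = a1, alpha2 = a2))
      tibble(stable_density = ess$stable_density, regime = ess$regime)
    }))
}
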