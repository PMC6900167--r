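#' Integration and convergence control settings
#'
#' Defaults: windowed integration with lsoda, window length 500 model time
#' units, horizon 3e4, windowed relative-change convergence tolerance 1e-6,
#' extinction threshold 1e-4 (also the persistence threshold of the initial
#' retention filter). The horizon is generous because a substantial fraction
#' of perturbed communities carries slowly damped oscillations: truncating at
#' 1e4 leaves over 40% of robustness tests unconverged and excluded, which
#' biases extinction summaries toward fast-settling (quieter) runs.
#'
#' @param t_window Length of one integration window.
#' @param t_max Total integration horizon before giving up (converged = FALSE).
#' @param rel_tol Convergence tolerance on max |dB/B| across one window,
#'   taken over species above the extinction threshold.
#' @param atol,rtol Integrator absolute/relative tolerances.
#' @param extinct_threshold Density below which a species is ignored by the
#'   convergence test (and classified extinct post hoc).
#' @param method deSolve integration method.
#' @return A list of control settings.
#' @export
dynamics_control <- function(t_window = 500, t_max = 3e4, rel_tol = 1e-6,
                             atol = 1e-10, rtol = 1e-8,
                             extinct_threshold = 1e-4, method = "lsoda") {
  list(t_window = t_window, t_max = t_max, rel_tol = rel_tol, atol = atol,
       rtol = rtol, extinct_threshold = extinct_threshold, method = method)
}

# Precompute incidence structures for fast rate evaluation. Dense 0/1
# incidence matrices beat sparse ones comfortably at these community sizes
# (S ~ 20-35), and the Gompertz terms are evaluated through precomputed
# constants (g = e alpha / sigma and the x = 0 anchor) so the inner
# derivative does no argument checking. Returns a closure rate_fn(t, B,
# parms) suitable for deSolve; the external mortality vector m is read from
# the community at build time.
build_rate_fn <- function(community, mode = c("none", "full", "pairwise")) {
  mode <- match.arg(mode)
  sp <- community$species
  lk <- community$links
  tims <- community$tims
  S <- nrow(sp)
  nL <- nrow(lk)
  r <- sp$r; m <- sp$m; K <- sp$K
  a <- lk$a; e <- lk$e
  res <- lk$resource; cons <- lk$consumer
  Mres <- matrix(0, S, nL); Mres[cbind(res, seq_len(nL))] <- 1
  Mcons <- matrix(0, S, nL); Mcons[cbind(cons, seq_len(nL))] <- 1
  rm0 <- r - m
  has_tims <- !is.null(tims) && nrow(tims) > 0L && mode != "none"
  if (has_tims) {
    nT <- nrow(tims)
    tim_link <- match(paste(tims$consumer, tims$resource),
                      paste(cons, res))
    if (anyNA(tim_link)) stop("TIM refers to a non-existent trophic link")
    if (mode == "pairwise" && anyDuplicated(tim_link)) {
      stop("pairwise mode requires at most one modifier per trophic link")
    }
    t_mod <- tims$modifier
    t_sigma <- tims$sigma
    t_g <- exp(1) * tims$alpha / t_sigma
    t_off <- tims$tau + log10(tims$Bk_star)  # x - tau on the log10(Bk) scale
    t_anchor <- t_sigma * exp(-exp(t_g * tims$tau))
    t_null <- tims$alpha == 0
    gomp <- function(Bk) {
      # log10 mu per TIM; alpha = 0 degenerates to 0 (mu = 1)
      l10 <- t_sigma * exp(-exp(-t_g * (log10(Bk) - t_off))) - t_anchor
      if (any(t_null)) l10[t_null] <- 0
      l10
    }
    if (mode == "pairwise") {
      B_star <- community$B_star
      coef_res <- a[tim_link] * B_star[cons[tim_link]]
      coef_cons <- e[tim_link] * a[tim_link] * B_star[res[tim_link]]
      Pres <- matrix(0, S, nT); Pres[cbind(tims$resource, seq_len(nT))] <- 1
      Pcons <- matrix(0, S, nT)
      Pcons[cbind(tims$consumer, seq_len(nT))] <- 1
    } else {
      Tlink <- matrix(0, nL, nT); Tlink[cbind(tim_link, seq_len(nT))] <- 1
    }
  }
  function(t, B, parms) {
    Bc <- pmax(B, 0)
    mu_link <- 1
    if (has_tims) {
      l10 <- gomp(Bc[t_mod])
      if (mode == "full") {
        mu_link <- 10^drop(Tlink %*% l10)
      }
    }
    loss <- drop(Mres %*% (mu_link * a * Bc[cons]))
    gain <- drop(Mcons %*% (mu_link * e * a * Bc[res]))
    percap <- rm0 - Bc / K - loss + gain
    if (has_tims && mode == "pairwise") {
      mu_t <- 10^l10
      percap <- percap +
        drop(Pres %*% (coef_res * (1 - mu_t))) +
        drop(Pcons %*% (coef_cons * (mu_t - 1)))
    }
    list(Bc * percap)
  }
}

#' Per-capita and absolute growth rates of a community state
#'
#' Evaluates the Lotka-Volterra system
#' \deqn{dB_i/dt = B_i (r_i - m_i - B_i/K_i - \sum_j \mu_{ij} a_{ij} B_j
#'   + \sum_l \mu_{li} e_{li} a_{li} B_l)}
#' in one of three modes: `"none"` (all mu = 1), `"full"` (mu_ij is the
#' multiplicative Gompertz combination evaluated at the live state), or
#' `"pairwise"` (mu = 1 trophic terms plus each TIM's two fixed-coefficient
#' non-trophic terms `a_ij B_j* (1 - mu_ijk)` on the resource and
#' `e_ij a_ij B_i* (mu_ijk - 1)` on the consumer, mu_ijk from the live
#' modifier density only).
#'
#' @param community A community (see [build_initial_community()]).
#' @param B Density vector; defaults to the stored equilibrium `B_star`.
#' @param mode One of `"none"`, `"full"`, `"pairwise"`.
#' @return List with `percapita` and `dB` numeric vectors.
#' @export
percapita_rates <- function(community, B = community$B_star,
                            mode = c("none", "full", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(length(B) == nrow(community$species))
  fn <- build_rate_fn(community, mode)
  dB <- fn(0, B, NULL)[[1L]]
  Bc <- pmax(B, 0)
  percap <- ifelse(Bc > 0, dB / Bc, 0)
  list(percapita = percap, dB = dB)
}

#' Integrate a community to a steady state
#'
#' Integrates in successive windows of length `t_window`; the run converges
#' when the largest relative density change across a window, over species
#' above the extinction threshold, drops below `rel_tol` (equivalently, when
#' all remaining change is confined to effectively extinct species). Runs
#' exceeding `t_max` return `converged = FALSE`; integrator failures
#' (non-finite state, step-size collapse) return `failed = TRUE` and are
#' excluded from experiment summaries.
#'
#' @param community A community list.
#' @param B0 Starting densities (defaults to `community$B_star`).
#' @param mode Dynamics mode passed to the rate function.
#' @param control See [dynamics_control()].
#' @return List with `B` (final densities, clamped non-negative),
#'   `converged`, `failed`, `time` (model time reached) and `n_windows`.
#' @export
integrate_to_steady_state <- function(community, B0 = community$B_star,
                                      mode = c("none", "full", "pairwise"),
                                      control = dynamics_control()) {
  mode <- match.arg(mode)
  fn <- build_rate_fn(community, mode)
  B <- pmax(as.numeric(B0), 0)
  t_now <- 0
  converged <- FALSE
  failed <- FALSE
  n_windows <- 0L
  while (t_now < control$t_max && !converged) {
    sol <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = B, times = c(0, control$t_window), func = fn, parms = NULL,
        method = control$method, atol = control$atol, rtol = control$rtol,
        maxsteps = 10000)),
      error = function(e) NULL)
    bad <- is.null(sol) || nrow(sol) < 2L ||
      any(!is.finite(sol[nrow(sol), -1L]))
    if (bad) {
      failed <- TRUE
      break
    }
    B_new <- pmax(as.numeric(sol[nrow(sol), -1L]), 0)
    live <- B_new > control$extinct_threshold
    if (!any(live)) {
      converged <- TRUE
    } else {
      rel <- abs(B_new[live] - B[live]) / pmax(B[live], .Machine$double.eps)
      converged <- max(rel) < control$rel_tol
    }
    B <- B_new
    t_now <- t_now + control$t_window
    n_windows <- n_windows + 1L
  }
  list(B = B, converged = converged && !failed, failed = failed,
       time = t_now, n_windows = n_windows)
}

#' Assemble and equilibrate a retained starting community
#'
#' Repeats: draw a niche web (default S = 35, C = 0.14), reject structurally
#' degenerate draws (disconnected, or consumers with no path to a producer),
#' parameterise allometrically, start every density at `B_init` and integrate
#' without TIMs to equilibrium, drop species below the persistence threshold,
#' and accept iff at least `retention_min` species persist and the pruned web
#' is connected. The accepted community's equilibrium densities are stored as
#' the reference vector `B_star` and briefly re-polished on the pruned
#' system.
#'
#' @param S,C Niche-model species count and connectance.
#' @param retention_min Minimum persisting species for acceptance (default 18).
#' @param B_init Starting density for every species (default 10).
#' @param max_attempts Attempts before giving up with an error.
#' @param mean_log10_ratio,sd_log10 Body-mass distribution settings (see
#'   [assign_body_masses()]).
#' @param control Convergence settings used during assembly; the default
#'   horizon accommodates the slowly damped transients from the uniform
#'   starting density, which would otherwise reject many dynamically fine
#'   webs.
#' @return A `community` object: list with `web`, `species`, `links`,
#'   `B_star`, `tims` (NULL until attached), `attempts`, `initial_S`.
#' @export
build_initial_community <- function(S = 35, C = 0.14, retention_min = 18,
                                    B_init = 10, max_attempts = 500,
                                    mean_log10_ratio = 2, sd_log10 = 0.5,
                                    control = dynamics_control()) {
  for (attempt in seq_len(max_attempts)) {
    web <- generate_niche_web(S, C)
    if (!is_connected(web)) next
    lvl <- tryCatch(trophic_levels(web), error = function(e) NULL)
    if (is.null(lvl)) next
    M <- assign_body_masses(lvl, mean_log10_ratio, sd_log10)
    species <- assign_species_params(M, lvl)
    links <- assign_link_params(web, M)
    comm <- structure(list(web = web, species = species, links = links,
                           B_star = rep(B_init, S), tims = NULL),
                      class = "community")
    eq <- integrate_to_steady_state(comm, B0 = rep(B_init, S), mode = "none",
                                    control = control)
    if (eq$failed || !eq$converged) next
    keep <- which(eq$B >= control$extinct_threshold)
    if (length(keep) < retention_min) next
    pruned_web <- subset_web(web, keep)
    if (!is_connected(pruned_web)) next
    # consumers must still hold at least one resource after pruning
    cons_left <- unique(pruned_web$links$consumer)
    lvl_kept <- species$level[keep]
    if (any(lvl_kept > 1L & !(seq_along(keep) %in% cons_left))) next
    l <- links[links$consumer %in% keep & links$resource %in% keep, ,
               drop = FALSE]
    remap <- integer(S); remap[keep] <- seq_along(keep)
    l$consumer <- remap[l$consumer]; l$resource <- remap[l$resource]
    rownames(l) <- NULL
    comm <- structure(list(web = pruned_web,
                           species = species[keep, , drop = FALSE],
                           links = l,
                           B_star = eq$B[keep],
                           tims = NULL,
                           attempts = attempt,
                           initial_S = S),
                      class = "community")
    rownames(comm$species) <- NULL
    # polish the equilibrium of the pruned system
    eq2 <- integrate_to_steady_state(comm, B0 = comm$B_star, mode = "none",
                                     control = control)
    if (eq2$failed || !eq2$converged ||
        any(eq2$B < control$extinct_threshold)) next
    comm$B_star <- eq2$B
    return(comm)
  }
  stop("no retained community after ", max_attempts, " attempts")
}

#' @export
print.community <- function(x, ...) {
  cat("equilibrated community: ", nrow(x$species), " species (from ",
      if (is.null(x$initial_S)) "?" else x$initial_S, " generated), ",
      nrow(x$links), " trophic links, ",
      if (is.null(x$tims)) 0L else nrow(x$tims), " TIMs attached\n", sep = "")
  invisible(x)
}

#' Attach a sampled TIM set to an equilibrated community
#'
#' Draws a TIM set with [sample_tims()] using the community's equilibrium
#' densities as the reference Bk_star; because mu(Bk_star) = 1, attachment
#' leaves the equilibrium unchanged.
#'
#' @param community An equilibrated community.
#' @param rate Per-(link, modifier) TIM probability.
#' @param ... Passed to [sample_tims()] (`alpha_range`, `sigma_range`,
#'   `tau_range`, `max_per_interaction`).
#' @return The community with `$tims` filled in.
#' @export
attach_tims <- function(community, rate, ...) {
  community$tims <- sample_tims(community$links, community$B_star, rate, ...)
  community
}
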