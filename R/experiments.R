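#' Classify a species' end state after a robustness test
#'
#' Against its starting (equilibrium) density, a species is `extinct` if its
#' final density fell below 1e-4, else `functionally_extinct` if below one
#' tenth of its start, else `exploded` if above ten times its start, else
#' `persisting`. The categories are exhaustive and mutually exclusive.
#'
#' @param B_final Final densities (vectorised).
#' @param B_start Starting densities (> 0).
#' @param extinct_threshold Hard extinction threshold (default 1e-4).
#' @return Character vector of statuses.
#' @export
classify_status <- function(B_final, B_start, extinct_threshold = 1e-4) {
  stopifnot(all(B_start > 0))
  n <- max(length(B_final), length(B_start))
  B_final <- rep_len(B_final, n); B_start <- rep_len(B_start, n)
  out <- rep("persisting", n)
  out[B_final > 10 * B_start] <- "exploded"
  out[B_final < B_start / 10] <- "functionally_extinct"
  out[B_final < extinct_threshold] <- "extinct"
  out
}

#' Run one targeted-mortality robustness test
#'
#' Sets the targeted species' external mortality to `m_target` (1 by
#' default), integrates the community from its stored equilibrium to a new
#' steady state in the requested dynamics mode, and classifies every species
#' against its reference density. The targeted species' own status is
#' recorded but excluded from the secondary-outcome counts.
#'
#' @param community An equilibrated community (TIMs attached or NULL).
#' @param target Index of the targeted species.
#' @param mode `"none"`, `"full"` or `"pairwise"`.
#' @param m_target Mortality applied to the target (default 1).
#' @param control See [dynamics_control()].
#' @return List with `target`, `mode`, `status` (per species), `converged`,
#'   `failed`, `B_final`, and secondary counts `n_extinct`, `n_functional`,
#'   `n_exploded`.
#' @export
run_robustness_test <- function(community, target,
                                mode = c("none", "full", "pairwise"),
                                m_target = 1, control = dynamics_control()) {
  mode <- match.arg(mode)
  S <- nrow(community$species)
  stopifnot(target >= 1L, target <= S)
  community$species$m[target] <- m_target
  run <- integrate_to_steady_state(community, B0 = community$B_star,
                                   mode = mode, control = control)
  status <- classify_status(run$B, community$B_star,
                            control$extinct_threshold)
  sec <- status[-target]
  list(target = target, mode = mode, status = status,
       converged = run$converged, failed = run$failed, B_final = run$B,
       n_extinct = sum(sec == "extinct"),
       n_functional = sum(sec == "functionally_extinct"),
       n_exploded = sum(sec == "exploded"))
}

#' Protocol settings for the three-mode comparison test
#'
#' Single-modifier protocol: TIM rate 0.05, alpha ~ U(-4, 4),
#' sigma ~ U(0.1, 4), tau ~ U(-1, 1), at most one modifier per interaction
#' (so the pairwise partition is exact), run in all three modes.
#' @return A named list of TIM-sampling settings.
#' @export
test1_config <- function() {
  list(rate = 0.05, alpha_range = c(-4, 4), sigma_range = c(0.1, 4),
       tau_range = c(-1, 1), max_per_interaction = 1,
       modes = c("none", "full", "pairwise"))
}

#' Protocol settings for the extinction-distribution test
#'
#' Multi-modifier protocol: TIM rate 0.08, alpha ~ U(-3, 3),
#' sigma ~ U(0.1, 3), tau ~ U(-1, 1), unlimited modifiers per interaction,
#' full-TIM mode only.
#' @return A named list of TIM-sampling settings.
#' @export
test2_config <- function() {
  list(rate = 0.08, alpha_range = c(-3, 3), sigma_range = c(0.1, 3),
       tau_range = c(-1, 1), max_per_interaction = Inf, modes = "full")
}

#' Generate a set of retained starting communities
#'
#' @param n Number of communities.
#' @param seed Optional master seed; spawns one recorded child seed per
#'   community so any community is regenerable in isolation.
#' @param ... Passed to [build_initial_community()].
#' @return List of communities, each carrying its `seed`.
#' @export
generate_communities <- function(n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    set.seed(child[i])
    comm <- build_initial_community(...)
    comm$seed <- child[i]
    comm
  })
}

#' Run a full robustness-test suite
#'
#' For each community: draw one TIM set (identical placements and shape
#' parameters across modes), then target every species in turn in each
#' requested mode. Failed integrations are flagged and carried in the table
#' (excluded from summaries downstream); non-converged runs are marked.
#'
#' @param communities List of equilibrated communities.
#' @param config TIM/protocol settings, e.g. [test1_config()] or
#'   [test2_config()].
#' @param seed Optional master seed for the TIM draws; spawns recorded
#'   per-community child seeds.
#' @param m_target Mortality applied to each target (default 1).
#' @param control See [dynamics_control()].
#' @param progress Print per-community progress to stderr.
#' @return List with `results` (one row per community x target x mode:
#'   counts, convergence flags, TIMs caused by the target split by sign,
#'   child seed), `status` (long table, one row per species per test),
#'   `tims` (per-community TIM tables) and `config`.
#' @export
run_suite <- function(communities, config = test1_config(), seed = NULL,
                      m_target = 1, control = dynamics_control(),
                      progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n_comm <- length(communities)
  child <- sample.int(.Machine$integer.max - 1L, n_comm)
  res_rows <- list()
  status_rows <- list()
  tim_sets <- vector("list", n_comm)
  for (ci in seq_len(n_comm)) {
    comm <- communities[[ci]]
    set.seed(child[ci])
    comm$tims <- sample_tims(comm$links, comm$B_star, config$rate,
                             alpha_range = config$alpha_range,
                             sigma_range = config$sigma_range,
                             tau_range = config$tau_range,
                             max_per_interaction = config$max_per_interaction)
    tim_sets[[ci]] <- comm$tims
    S <- nrow(comm$species)
    caused <- tabulate(comm$tims$modifier, nbins = S)
    caused_int <- tabulate(comm$tims$modifier[comm$tims$alpha < 0], nbins = S)
    caused_fac <- tabulate(comm$tims$modifier[comm$tims$alpha > 0], nbins = S)
    for (target in seq_len(S)) {
      for (mode in config$modes) {
        out <- run_robustness_test(comm, target, mode, m_target, control)
        res_rows[[length(res_rows) + 1L]] <- data.frame(
          community = ci, target = target, mode = mode,
          converged = out$converged, failed = out$failed,
          n_extinct = out$n_extinct, n_functional = out$n_functional,
          n_exploded = out$n_exploded,
          n_extinct_functional = out$n_extinct + out$n_functional,
          target_status = out$status[target],
          tims_caused = caused[target],
          interfering_caused = caused_int[target],
          facilitating_caused = caused_fac[target],
          child_seed = child[ci])
        status_rows[[length(status_rows) + 1L]] <- data.frame(
          community = ci, target = target, mode = mode,
          species = seq_len(S), status = out$status,
          converged = out$converged, failed = out$failed)
      }
    }
    if (progress) {
      message("community ", ci, "/", n_comm, ": S = ", S, ", ",
              nrow(comm$tims), " TIMs")
    }
  }
  list(results = do.call(rbind, res_rows),
       status = do.call(rbind, status_rows),
       tims = tim_sets,
       config = config,
       child_seeds = child)
}
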