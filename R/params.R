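#' Assign body masses by trophic level
#'
#' Body masses are drawn log-normally by trophic level class:
#' `log10(M) ~ Normal(mean_log10_ratio * (level - 1), sd_log10)`, i.e. a
#' mean consumer-resource body-mass ratio of `10^mean_log10_ratio` (100 by
#' default, a standard quarter-power-scaling community choice). Producers
#' have median mass 1.
#'
#' @param levels Integer trophic levels (from [trophic_levels()]).
#' @param mean_log10_ratio Mean log10 mass step per trophic level (default 2).
#' @param sd_log10 Standard deviation of log10 mass within a level (default 0.5).
#' @return Numeric vector of strictly positive masses.
#' @export
assign_body_masses <- function(levels, mean_log10_ratio = 2, sd_log10 = 0.5) {
  10^stats::rnorm(length(levels), mean_log10_ratio * (levels - 1), sd_log10)
}

#' Assign per-species allometric parameters
#'
#' Producers (level 1) get intrinsic growth rate r = 1 and carrying capacity
#' K ~ U(1, 10); consumers (level >= 2) get metabolic loss rate
#' r = -0.1 M^(-1/4) and K ~ 10^U(2, 3) (weak self-regulation). External
#' mortality m starts at 0.
#'
#' @param M Body masses.
#' @param levels Integer trophic levels.
#' @return data.frame with columns `M`, `r`, `K`, `m`, `level`.
#' @export
assign_species_params <- function(M, levels) {
  stopifnot(length(M) == length(levels), all(M > 0))
  producer <- levels == 1L
  r <- ifelse(producer, 1, -0.1 * M^(-0.25))
  K <- ifelse(producer,
              stats::runif(length(M), 1, 10),
              10^stats::runif(length(M), 2, 3))
  data.frame(M = M, r = r, K = K, m = 0, level = as.integer(levels))
}

#' Assign per-link trophic interaction parameters
#'
#' Attack rates follow consumer allometry with a fixed generality split:
#' a consumer j with n resources has omega = 1/n on each link and attack
#' rate a = omega * M_j^(-1/4). Assimilation efficiencies are drawn
#' independently from U(0.05, 0.15). omega is fixed at assignment and never
#' recalculated when resources are lost.
#'
#' @param web A `food_web`.
#' @param M Body masses (length `web$S`).
#' @return data.frame with columns `resource`, `consumer`, `a`, `e`, `omega`.
#' @export
assign_link_params <- function(web, M) {
  l <- web$links
  if (nrow(l) == 0L) stop("web has no trophic links")
  n_res <- table(factor(l$consumer, levels = seq_len(web$S)))
  omega <- 1 / as.numeric(n_res)[l$consumer]
  data.frame(resource = l$resource,
             consumer = l$consumer,
             a = omega * M[l$consumer]^(-0.25),
             e = stats::runif(nrow(l), 0.05, 0.15),
             omega = omega)
}
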