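#' Gompertz interaction-modification factor
#'
#' Evaluates the modification term mu_ijk applied multiplicatively to an
#' attack rate as a function of the modifier's density Bk relative to its
#' equilibrium reference Bk_star. On a base-10 log scale, with
#' `x = log10(Bk / Bk_star)` and `g = e * alpha / sigma`,
#'
#' \deqn{\log_{10}\mu = \sigma e^{-e^{-g(x-\tau)}} - \sigma e^{-e^{g\tau}}}
#'
#' which anchors mu(Bk_star) = 1 exactly, attains its maximum log-slope
#' |alpha| at x = tau, and spans a total range of sigma decades between its
#' two asymptotes (sup mu / inf mu = 10^sigma). alpha > 0 is a facilitating
#' modification (mu increases with Bk), alpha < 0 interfering; alpha = 0 is
#' the continuous limit mu = 1. Bk = 0 evaluates the finite lower (alpha > 0)
#' or upper (alpha < 0) asymptote.
#'
#' @param Bk Modifier density (>= 0); vectorised.
#' @param alpha Maximum slope of log10 mu per decade of modifier change.
#' @param tau Threshold location, in log10 units of proportional change from
#'   Bk_star (tau = 0.2 puts the steepest response at Bk = 10^0.2 Bk_star).
#' @param sigma Total span of log10 mu (> 0).
#' @param Bk_star Reference density at which mu = 1 (> 0).
#' @return mu (> 0), same length as the longest argument.
#' @examples
#' modification_factor(1, alpha = 2, tau = 0.2, sigma = 2, Bk_star = 1)  # 1
#' @export
modification_factor <- function(Bk, alpha, tau, sigma, Bk_star) {
  10^log10_modification(Bk, alpha, tau, sigma, Bk_star)
}

# log10 of the modification factor; vectorised over all arguments
log10_modification <- function(Bk, alpha, tau, sigma, Bk_star) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(Bk_star <= 0)) stop("Bk_star must be > 0")
  if (any(Bk < 0)) stop("Bk must be >= 0")
  n <- max(length(Bk), length(alpha), length(tau), length(sigma),
           length(Bk_star))
  Bk <- rep_len(Bk, n); alpha <- rep_len(alpha, n); tau <- rep_len(tau, n)
  sigma <- rep_len(sigma, n); Bk_star <- rep_len(Bk_star, n)
  out <- numeric(n)
  nz <- alpha != 0
  if (any(nz)) {
    g <- exp(1) * alpha[nz] / sigma[nz]
    x <- log10(Bk[nz] / Bk_star[nz])  # -Inf at Bk = 0 gives the asymptote
    out[nz] <- sigma[nz] * exp(-exp(-g * (x - tau[nz]))) -
      sigma[nz] * exp(-exp(g * tau[nz]))
  }
  out
}

#' Combined multiplicative modifier on one trophic link
#'
#' Multiple modifications of the same interaction combine synergistically:
#' mu_ij is the product of mu_ijk over every TIM on the link, and 1 when the
#' link carries none.
#'
#' @param resource,consumer Species indices identifying the link.
#' @param B Current community density vector.
#' @param tims A TIM table (see [sample_tims()]); may be NULL or empty.
#' @return mu_ij (> 0).
#' @export
combined_modifier <- function(resource, consumer, B, tims) {
  if (is.null(tims) || nrow(tims) == 0L) return(1)
  on_link <- tims$resource == resource & tims$consumer == consumer
  if (!any(on_link)) return(1)
  t <- tims[on_link, , drop = FALSE]
  10^sum(log10_modification(B[t$modifier], t$alpha, t$tau, t$sigma, t$Bk_star))
}

#' Sample a set of trophic interaction modifications
#'
#' Every (trophic link, candidate modifier) pair -- the modifier being any
#' extant species other than the link's consumer and resource -- carries an
#' independent Bernoulli(rate) chance of a TIM. Shape parameters are drawn
#' from uniform ranges, and each TIM's reference density Bk_star is the
#' modifier's current equilibrium density, so attaching the set leaves the
#' equilibrium unchanged (mu = 1 there).
#'
#' @param links Link table (`resource`, `consumer`, ...), typically
#'   `community$links`.
#' @param B_star Equilibrium density vector supplying Bk_star.
#' @param rate Per-(link, modifier) probability in \[0, 1\].
#' @param alpha_range,sigma_range,tau_range Uniform bounds for the shape
#'   parameters (defaults: the single-modifier protocol, alpha ~ U(-4,4),
#'   sigma ~ U(0.1,4), tau ~ U(-1,1)).
#' @param max_per_interaction Either `1` (links drawing several TIMs keep one
#'   chosen uniformly at random, allowing the exact pairwise partition) or
#'   `Inf` (unlimited).
#' @return data.frame with columns `resource`, `consumer`, `modifier`,
#'   `alpha`, `tau`, `sigma`, `Bk_star`.
#' @export
sample_tims <- function(links, B_star, rate,
                        alpha_range = c(-4, 4), sigma_range = c(0.1, 4),
                        tau_range = c(-1, 1), max_per_interaction = 1) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  S <- length(B_star)
  nL <- nrow(links)
  empty <- data.frame(resource = integer(), consumer = integer(),
                      modifier = integer(), alpha = numeric(),
                      tau = numeric(), sigma = numeric(), Bk_star = numeric())
  if (rate == 0 || nL == 0L || S < 3L) return(empty)
  link_id <- rep(seq_len(nL), each = S)
  modifier <- rep(seq_len(S), times = nL)
  ok <- modifier != links$resource[link_id] & modifier != links$consumer[link_id]
  link_id <- link_id[ok]; modifier <- modifier[ok]
  hit <- stats::runif(length(link_id)) < rate
  link_id <- link_id[hit]; modifier <- modifier[hit]
  if (length(link_id) == 0L) return(empty)
  if (is.finite(max_per_interaction) && max_per_interaction == 1) {
    # keep one TIM per link, uniformly at random among those drawn
    perm <- sample.int(length(link_id))
    keep <- perm[!duplicated(link_id[perm])]
    link_id <- link_id[keep]; modifier <- modifier[keep]
  }
  n <- length(link_id)
  data.frame(resource = links$resource[link_id],
             consumer = links$consumer[link_id],
             modifier = modifier,
             alpha = stats::runif(n, alpha_range[1], alpha_range[2]),
             tau = stats::runif(n, tau_range[1], tau_range[2]),
             sigma = stats::runif(n, sigma_range[1], sigma_range[2]),
             Bk_star = B_star[modifier])
}

#' Expected number of TIMs in a community
#'
#' With L = C S (S - 1) directed non-cannibalistic links and S - 2 candidate
#' modifiers per link, each combination carrying independent probability
#' `rate`, the expected TIM count is C S (S - 1) (S - 2) rate.
#'
#' @param S Species count.
#' @param C Trophic connectance (links over ordered non-self pairs).
#' @param rate Per-(link, modifier) probability.
#' @return Expected number of TIMs (real).
#' @examples
#' expected_tim_count(20, 0.14, 0.05)  # 47.88
#' @export
expected_tim_count <- function(S, C, rate) {
  C * S * (S - 1) * rate * (S - 2)
}
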