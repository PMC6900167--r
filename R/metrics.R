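#' Trophic distance between two species
#'
#' Number of trophic links between two species by the shortest route on the
#' undirected projection of the starting network.
#'
#' @param web A `food_web`.
#' @param s,t Species indices.
#' @return Non-negative integer; `NA` for a disconnected pair (cannot occur
#'   in retained communities).
#' @export
trophic_distance <- function(web, s, t) {
  g <- trophic_graph(web, directed = FALSE)
  d <- igraph::distances(g, v = s, to = t)[1L, 1L]
  if (!is.finite(d)) return(NA_integer_)
  as.integer(d)
}

# all-pairs undirected trophic distance matrix
trophic_distance_matrix <- function(web) {
  igraph::distances(trophic_graph(web, directed = FALSE))
}

#' Pooled trophic-distance distributions of secondary extinctions
#'
#' For every completed test, records the trophic distance (on the starting
#' network) from the targeted species to each secondarily extinct species
#' (observed) and to every other species (baseline). Histograms are pooled
#' across tests and communities.
#'
#' @param suite Output of [run_suite()].
#' @param communities The community list the suite was run on.
#' @param mode Which dynamics mode of the suite to tabulate.
#' @return List with integer-named `observed` and `baseline` count tables
#'   and the corresponding proportions `observed_frac`, `baseline_frac`.
#' @export
distance_distributions <- function(suite, communities, mode = "full") {
  st <- suite$status
  st <- st[st$mode == mode & !st$failed & st$converged, , drop = FALSE]
  dmats <- lapply(communities, function(cm) trophic_distance_matrix(cm$web))
  obs <- integer(0)
  base <- integer(0)
  for (ci in unique(st$community)) {
    d <- dmats[[ci]]
    sc <- st[st$community == ci, , drop = FALSE]
    for (target in unique(sc$target)) {
      rows <- sc[sc$target == target, , drop = FALSE]
      others <- rows$species != target
      base <- c(base, d[target, rows$species[others]])
      ext <- rows$species[others & rows$status == "extinct"]
      if (length(ext)) obs <- c(obs, d[target, ext])
    }
  }
  lv <- seq_len(max(c(obs, base, 1L)))
  observed <- table(factor(obs, levels = lv))
  baseline <- table(factor(base, levels = lv))
  list(observed = observed, baseline = baseline,
       observed_frac = if (sum(observed) > 0) observed / sum(observed) else
         observed,
       baseline_frac = baseline / sum(baseline))
}

#' Expected number of incoming NTEs for a species
#'
#' Under random TIM placement, a species participating in `d` trophic links
#' expects `d * (S - 2) * rate` incoming NTEs in total; with a sign-symmetric
#' alpha range this splits evenly into the beneficial and detrimental
#' classes.
#'
#' @param species Species index.
#' @param web A `food_web`.
#' @param rate Per-(link, modifier) TIM probability.
#' @param prob_positive Probability mass of the alpha range above zero
#'   (default 0.5, the sign-symmetric case).
#' @return List with `total`, `beneficial`, `detrimental` expectations.
#' @export
expected_incoming_ntes <- function(species, web, rate, prob_positive = 0.5) {
  d <- sum(web$links$consumer == species | web$links$resource == species)
  total <- d * (web$S - 2) * rate
  list(total = total, beneficial = total * prob_positive,
       detrimental = total * (1 - prob_positive))
}

#' Count incoming NTEs on a species
#'
#' Each TIM delivers one incoming NTE to its link's resource and one to its
#' consumer; signs follow [nte_sign()]. `scope = "from_target_only"`
#' restricts to TIMs whose modifier is the targeted species.
#'
#' @param species Focal species index.
#' @param tims TIM table.
#' @param scope `"all_modifiers"` or `"from_target_only"`.
#' @param target Targeted species (required for `"from_target_only"`).
#' @return List with `beneficial_in` and `detrimental_in` counts.
#' @export
count_incoming_ntes <- function(species, tims,
                                scope = c("all_modifiers", "from_target_only"),
                                target = NULL) {
  scope <- match.arg(scope)
  if (is.null(tims) || nrow(tims) == 0L) {
    return(list(beneficial_in = 0L, detrimental_in = 0L))
  }
  if (scope == "from_target_only") {
    stopifnot(!is.null(target))
    tims <- tims[tims$modifier == target, , drop = FALSE]
  }
  as_res <- tims$resource == species
  as_cons <- tims$consumer == species
  signs <- c(nte_sign(tims$alpha[as_res], "on_resource"),
             nte_sign(tims$alpha[as_cons], "on_consumer"))
  list(beneficial_in = sum(signs == "beneficial"),
       detrimental_in = sum(signs == "detrimental"))
}

#' Poisson regression of secondary extinctions on TIMs caused by the target
#'
#' Fits a log-link Poisson GLM of the per-test secondary extinction count on
#' the number of TIMs whose modifier is the targeted species, either as a
#' single predictor or split by TIM sign (interfering alpha < 0 vs
#' facilitating alpha > 0). `exp(beta) - 1` is reported as the percent
#' change in expected extinctions per additional TIM.
#'
#' @param results The `results` table of [run_suite()] (full-TIM rows are
#'   selected automatically if several modes are present).
#' @param split_by_sign Use interfering and facilitating counts as two
#'   predictors instead of the total.
#' @return List with the fitted `model`, its coefficient `table`, and
#'   `percent_per_tim` (named percent effects).
#' @export
fit_extinction_glm <- function(results, split_by_sign = FALSE) {
  d <- results[!results$failed & results$converged, , drop = FALSE]
  if ("full" %in% d$mode) d <- d[d$mode == "full", , drop = FALSE]
  if (nrow(d) < 2L) stop("too few completed tests to fit")
  if (split_by_sign) {
    if (length(unique(d$interfering_caused)) < 2L ||
        length(unique(d$facilitating_caused)) < 2L) {
      stop("need variation in both sign-split predictors")
    }
    fit <- stats::glm(n_extinct ~ interfering_caused + facilitating_caused,
                      family = stats::poisson(), data = d)
  } else {
    if (length(unique(d$tims_caused)) < 2L) {
      stop("need variation in the predictor")
    }
    fit <- stats::glm(n_extinct ~ tims_caused, family = stats::poisson(),
                      data = d)
  }
  tab <- summary(fit)$coefficients
  beta <- stats::coef(fit)[-1L]
  list(model = fit, table = tab,
       percent_per_tim = 100 * (exp(beta) - 1))
}

#' Mean shortest-path length between species pairs
#'
#' Mean over all unordered species pairs of the undirected shortest-path
#' length. When a TIM set is supplied, the graph additionally carries
#' undirected modifier-resource and modifier-consumer edges for every TIM
#' (the modifier touches both trophic participants).
#'
#' @param web A `food_web`.
#' @param tims Optional TIM table.
#' @return Mean path length; `NA` if the graph is disconnected.
#' @export
mean_path_length <- function(web, tims = NULL) {
  g <- trophic_graph(web, directed = FALSE)
  if (!is.null(tims) && nrow(tims) > 0L) {
    extra <- rbind(cbind(tims$modifier, tims$resource),
                   cbind(tims$modifier, tims$consumer))
    g <- igraph::add_edges(g, as.vector(t(extra)))
  }
  g <- igraph::simplify(g)
  if (!igraph::is_connected(g)) return(NA_real_)
  igraph::mean_distance(g, directed = FALSE)
}

#' Attack-rate change when a TIM's modifier is lost
#'
#' For each TIM, the multiplicative factor `max(mu(0), 1/mu(0))` by which
#' the modified attack rate changes between the modifier's equilibrium
#' reference (mu = 1) and its extinction (the Gompertz asymptote at Bk = 0).
#'
#' @param tims One TIM table or a list of them.
#' @return List with the per-TIM `factors` and their `median`.
#' @export
attack_rate_change_on_modifier_loss <- function(tims) {
  if (is.data.frame(tims)) tims <- list(tims)
  tims <- do.call(rbind, tims)
  if (is.null(tims) || nrow(tims) == 0L) {
    return(list(factors = numeric(0), median = NA_real_))
  }
  l10 <- log10_modification(rep(0, nrow(tims)), tims$alpha, tims$tau,
                            tims$sigma, tims$Bk_star)
  factors <- 10^abs(l10)
  list(factors = factors, median = stats::median(factors))
}

#' Sign census of growth-rate responses to a small density reduction
#'
#' For each trial, one randomly chosen species' density is reduced by a
#' fraction `delta` from the stored equilibrium, every species' instantaneous
#' per-capita growth rate is evaluated (full-TIM mode by default), and the
#' signs of the non-zero responses are pooled across trials and communities.
#'
#' @param communities List of TIM-attached equilibrated communities.
#' @param delta Fractional reduction (default 0.01).
#' @param n_trials Trials per community.
#' @param mode Dynamics mode for the rate evaluation.
#' @param zero_tol Absolute per-capita rate below which a response counts as
#'   zero (default 1e-10).
#' @return List with `positive_fraction`, `n_positive`, `n_negative`,
#'   `n_zero`.
#' @export
perturbation_response_census <- function(communities, delta = 0.01,
                                         n_trials = 100, mode = "full",
                                         zero_tol = 1e-10) {
  if (delta == 0) {
    return(list(positive_fraction = NA_real_, n_positive = 0L,
                n_negative = 0L, n_zero = 0L))
  }
  npos <- 0L; nneg <- 0L; nzero <- 0L
  for (comm in communities) {
    S <- nrow(comm$species)
    picks <- sample.int(S, n_trials, replace = TRUE)
    for (s in picks) {
      B <- comm$B_star
      B[s] <- B[s] * (1 - delta)
      pc <- percapita_rates(comm, B, mode)$percapita
      npos <- npos + sum(pc > zero_tol)
      nneg <- nneg + sum(pc < -zero_tol)
      nzero <- nzero + sum(abs(pc) <= zero_tol)
    }
  }
  list(positive_fraction = npos / (npos + nneg),
       n_positive = npos, n_negative = nneg, n_zero = nzero)
}
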