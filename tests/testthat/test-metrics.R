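test_that("trophic distances match the breadth-first oracle", {
  chain <- edges_to_web(4, rbind(c(2, 1), c(3, 2), c(4, 3)))
  expect_identical(trophic_distance(chain, 1, 2), 1L)  # direct prey
  expect_identical(trophic_distance(chain, 2, 2), 0L)  # self
  expect_identical(trophic_distance(chain, 1, 4), 3L)  # chain of length 3
  disjoint <- edges_to_web(4, rbind(c(2, 1), c(4, 3)))
  expect_true(is.na(trophic_distance(disjoint, 1, 3)))
  set.seed(51)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    edges <- random_digraph(n, 0.35)
    web <- edges_to_web(n, edges)
    s <- sample(n, 1); t <- sample(n, 1)
    oracle <- bfs_undirected_dist(n, edges, s)[t]
    got <- trophic_distance(web, s, t)
    expect_identical(got, oracle)
  }
})

test_that("mean path length matches enumeration", {
  complete4 <- edges_to_web(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3),
                                     c(2, 4), c(3, 4)))
  expect_equal(mean_path_length(complete4), 1)
  chain3 <- edges_to_web(3, rbind(c(2, 1), c(3, 2)))
  expect_equal(mean_path_length(chain3), 4 / 3)
  set.seed(52)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    edges <- random_digraph(n, 0.35)
    web <- edges_to_web(n, edges)
    expect_equal(mean_path_length(web), oracle_mean_path_length(n, edges))
  }
})

test_that("TIM edges shorten the path-length graph", {
  chain <- edges_to_web(4, rbind(c(2, 1), c(3, 2), c(4, 3)))
  tims <- data.frame(resource = 1L, consumer = 2L, modifier = 4L,
                     alpha = 1, tau = 0, sigma = 1, Bk_star = 1)
  # modifier 4 gains edges to 1 and 2: recomputed by hand over all 6 pairs
  # d(1,2)=1 d(1,3)=2 d(1,4)=1 d(2,3)=1 d(2,4)=1 d(3,4)=1 -> 7/6
  expect_equal(mean_path_length(chain, tims), 7 / 6)
  expect_lt(mean_path_length(chain, tims), mean_path_length(chain))
})

test_that("expected incoming NTEs scale with degree and rate", {
  web <- edges_to_web(6, rbind(c(2, 1), c(3, 1), c(3, 2)))
  none <- expected_incoming_ntes(6, web, 0.05)
  expect_identical(none$total, 0)
  # species 3 participates in 2 links: d (S-2) p in total, half per sign
  e3 <- expected_incoming_ntes(3, web, 0.05)
  expect_equal(e3$total, 2 * 4 * 0.05)
  expect_equal(e3$beneficial, e3$total / 2)
  expect_equal(expected_incoming_ntes(3, web, 0.025)$total, e3$total / 2)
  # enumeration oracle: count all (link, modifier) pairs touching species 1
  d1 <- 2
  expect_equal(expected_incoming_ntes(1, web, 0.1)$total, d1 * 4 * 0.1)
})

test_that("incoming NTE counts follow the sign rules and scope filter", {
  empty <- count_incoming_ntes(1, NULL)
  expect_identical(empty$beneficial_in + empty$detrimental_in, 0L)
  tims <- data.frame(resource = c(1L, 2L), consumer = c(2L, 3L),
                     modifier = c(4L, 5L), alpha = c(2, -1), tau = 0,
                     sigma = 1, Bk_star = 1)
  # species 2: consumer of a facilitating TIM (+1 beneficial) and resource of
  # an interfering TIM (+1 beneficial)
  c2 <- count_incoming_ntes(2, tims)
  expect_identical(c2$beneficial_in, 2L)
  expect_identical(c2$detrimental_in, 0L)
  c1 <- count_incoming_ntes(1, tims)
  expect_identical(c1$detrimental_in, 1L)
  # scope restriction to TIMs caused by the target
  c2t <- count_incoming_ntes(2, tims, scope = "from_target_only", target = 4)
  expect_identical(c2t$beneficial_in, 1L)
  expect_identical(c2t$detrimental_in, 0L)
  # invariant to row order
  c2r <- count_incoming_ntes(2, tims[2:1, ])
  expect_identical(c2r, c2)
})

test_that("the Poisson regression recovers known synthetic coefficients", {
  set.seed(53)
  n <- 10000
  x <- rpois(n, 3)
  b0 <- 0.2; b1 <- 0.07
  y <- rpois(n, exp(b0 + b1 * x))
  d <- data.frame(n_extinct = y, tims_caused = x, failed = FALSE,
                  converged = TRUE, mode = "full")
  fit <- fit_extinction_glm(d)
  est <- coef(fit$model)[2]
  se <- fit$table[2, 2]
  expect_lt(abs(est - b1), 3 * se)
  expect_lt(abs(est - b1) / b1, 0.1)
  expect_equal(fit$percent_per_tim[[1]], unname(100 * (exp(est) - 1)))
  # sign-split recovery with distinct rates
  xi <- rpois(n, 2); xf <- rpois(n, 2)
  y2 <- rpois(n, exp(0.2 + 0.10 * xi + 0.04 * xf))
  d2 <- data.frame(n_extinct = y2, interfering_caused = xi,
                   facilitating_caused = xf, failed = FALSE,
                   converged = TRUE, mode = "full")
  fit2 <- fit_extinction_glm(d2, split_by_sign = TRUE)
  b <- coef(fit2$model)
  expect_lt(abs(b[2] - 0.10), 3 * fit2$table[2, 2])
  expect_lt(abs(b[3] - 0.04), 3 * fit2$table[3, 2])
  # near-constant response gives a near-zero slope
  d3 <- data.frame(n_extinct = rep(c(2L, 2L, 2L, 2L), 50),
                   tims_caused = rep(0:3, 50), failed = FALSE,
                   converged = TRUE, mode = "full")
  fit3 <- fit_extinction_glm(d3)
  expect_equal(unname(coef(fit3$model)[2]), 0, tolerance = 1e-8)
})

test_that("attack-rate change factors derive from the Gompertz asymptote", {
  # vanishing span: factor tends to 1
  tiny <- data.frame(resource = 1L, consumer = 2L, modifier = 3L,
                     alpha = 1, tau = 0.2, sigma = 1e-6, Bk_star = 1)
  expect_equal(attack_rate_change_on_modifier_loss(tiny)$median, 1,
               tolerance = 1e-4)
  # factor is max(mu0, 1/mu0) and at least 1
  set.seed(54)
  tims <- data.frame(resource = 1L, consumer = 2L,
                     modifier = rep(3L, 500), alpha = runif(500, -3, 3),
                     tau = runif(500, -1, 1), sigma = runif(500, 0.1, 3),
                     Bk_star = 10^runif(500, -1, 1))
  out <- attack_rate_change_on_modifier_loss(tims)
  expect_true(all(out$factors >= 1))
  mu0 <- modification_factor(0, tims$alpha[1], tims$tau[1], tims$sigma[1],
                             tims$Bk_star[1])
  expect_equal(out$factors[1], max(mu0, 1 / mu0))
  # list input pools across communities
  pooled <- attack_rate_change_on_modifier_loss(list(tims[1:250, ],
                                                     tims[251:500, ]))
  expect_identical(pooled$factors, out$factors)
})

test_that("the response census matches the hand-solved food chain", {
  # 3-species chain: producer 1 <- consumer 2 <- top consumer 3
  species <- data.frame(M = c(1, 16, 256), r = c(1, -0.05, -0.005),
                        K = c(5, 500, 500), m = 0, level = 1:3)
  links <- data.frame(resource = c(1L, 2L), consumer = c(2L, 3L),
                      a = c(0.3, 0.2), e = c(0.1, 0.1), omega = 1)
  A <- rbind(c(1 / 5, 0.3, 0),
             c(-0.1 * 0.3, 1 / 500, 0.2),
             c(0, -0.1 * 0.2, 1 / 500))
  Bstar <- solve(A, c(1, -0.05, -0.005))
  comm <- make_community(species, links, Bstar)
  expect_true(all(Bstar > 0))
  sgn <- function(target) {
    B <- Bstar; B[target] <- B[target] * 0.99
    sign(round(percapita_rates(comm, B, "none")$percapita, 12))
  }
  # reducing the producer: own rate up, its consumer starves, top unaffected
  expect_identical(sgn(1), c(1, -1, 0))
  # reducing the mid consumer: prey released, predator starves
  expect_identical(sgn(2), c(1, 1, -1))
  # reducing the top consumer: its prey released, producer untouched
  expect_identical(sgn(3), c(0, 1, 1))
  # no perturbation means no informative responses
  out0 <- perturbation_response_census(list(comm), delta = 0)
  expect_true(is.na(out0$positive_fraction))
})

test_that("distance distributions pool observed and baseline histograms", {
  # miniature suite assembled by hand through run_suite on a tiny community
  set.seed(56)
  comm <- build_initial_community(S = 12, C = 0.25, retention_min = 6,
                                  max_attempts = 500)
  suite <- run_suite(list(comm), test1_config(), seed = 3)
  dd <- distance_distributions(suite, list(comm), mode = "none")
  S <- nrow(comm$species)
  completed <- sum(suite$results$mode == "none" & suite$results$converged &
                     !suite$results$failed)
  expect_identical(sum(dd$baseline), completed * (S - 1L))
  n_ext <- sum(suite$results$n_extinct[suite$results$mode == "none" &
                                         suite$results$converged &
                                         !suite$results$failed])
  expect_identical(sum(dd$observed), n_ext)
  expect_equal(sum(dd$baseline_frac), 1)
})
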