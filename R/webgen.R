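#' Generate a niche-model food web
#'
#' Draws a trophic topology from the niche model: each species receives a
#' niche value \eqn{n_i \sim U(0,1)}, a feeding range \eqn{r_i = n_i x} with
#' \eqn{x \sim Beta(1, 1/(2C) - 1)}, and a range centre
#' \eqn{c_i \sim U(r_i/2, n_i)}. Consumer \eqn{j} eats every species whose
#' niche value falls inside \eqn{[c_j - r_j/2, c_j + r_j/2]}. Cannibalistic
#' (self) links are removed afterwards by default.
#'
#' @param S Number of species (integer, >= 2).
#' @param C Target connectance, defined as L/S^2 in the generating model;
#'   must lie in (0, 0.5) so the Beta shape parameter is positive.
#' @param seed Optional integer seed; stored on the returned object so the
#'   topology can be regenerated exactly.
#' @param remove_cannibalism Drop self-links after generation (default TRUE).
#'
#' @return A `food_web` object: a list with `S`, `links` (data.frame with
#'   integer columns `consumer`, `resource`), `niche` (sorted niche values),
#'   `target_C` and `seed`.
#' @examples
#' web <- generate_niche_web(35, 0.14, seed = 1)
#' realized_connectance(web)
#' @export
generate_niche_web <- function(S, C, seed = NULL, remove_cannibalism = TRUE) {
  if (S < 2) stop("S must be at least 2")
  beta_shape <- 1 / (2 * C) - 1
  if (!is.finite(beta_shape) || beta_shape <= 0) {
    stop("C must lie in (0, 0.5): Beta shape parameter 1/(2C) - 1 must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- sort(stats::runif(S))
  r <- n * stats::rbeta(S, 1, beta_shape)
  centre <- stats::runif(S, r / 2, n)
  lo <- centre - r / 2
  hi <- centre + r / 2
  # consumer j eats all i with n_i inside its feeding interval
  eats <- outer(n, lo, ">=") & outer(n, hi, "<=")  # [i, j]: j eats i
  idx <- which(eats, arr.ind = TRUE)
  links <- data.frame(consumer = as.integer(idx[, 2L]),
                      resource = as.integer(idx[, 1L]))
  if (remove_cannibalism) {
    links <- links[links$consumer != links$resource, , drop = FALSE]
  }
  rownames(links) <- NULL
  structure(list(S = as.integer(S), links = links, niche = n,
                 target_C = C, seed = seed),
            class = "food_web")
}

#' @export
print.food_web <- function(x, ...) {
  cat("niche-model food web: ", x$S, " species, ", nrow(x$links),
      " trophic links (directed connectance ",
      format(realized_connectance(x), digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Realized directed connectance L / (S (S - 1))
#'
#' Link density of the (cannibalism-free) directed trophic network.
#' @param web A `food_web`.
#' @return A single numeric value.
#' @export
realized_connectance <- function(web) {
  nrow(web$links) / (web$S * (web$S - 1))
}

#' Shortest-path trophic levels
#'
#' Producers (species with no resources) sit at level 1; every consumer's
#' level is 1 plus the length of its shortest directed consumer-to-resource
#' path down to any producer. Integer levels are used because body masses and
#' rates are assigned by discrete level class.
#'
#' @param web A `food_web`.
#' @return Integer vector of length `S`. Consumers with no directed path to a
#'   producer (loops with no basal support) raise an error; such webs are
#'   rejected upstream during community assembly.
#' @export
trophic_levels <- function(web) {
  g <- trophic_graph(web, directed = TRUE)
  producers <- setdiff(seq_len(web$S), unique(web$links$consumer))
  if (length(producers) == 0L) stop("web has no producers: every species consumes")
  d <- igraph::distances(g, v = seq_len(web$S), to = producers, mode = "out")
  lvl <- 1 + apply(d, 1L, min)
  if (any(!is.finite(lvl))) {
    stop("consumer(s) with no directed path to a producer: ",
         paste(which(!is.finite(lvl)), collapse = ", "))
  }
  as.integer(lvl)
}

#' Is the trophic network a single connected component?
#'
#' Connectivity of the undirected projection of the link set, counting
#' isolated species as their own components.
#'
#' @param web A `food_web`.
#' @return TRUE iff one undirected component covers all `S` species.
#' @export
is_connected <- function(web) {
  if (web$S == 1L) return(TRUE)
  g <- trophic_graph(web, directed = FALSE)
  igraph::is_connected(g)
}

# igraph view of the trophic topology; keeps isolated vertices
trophic_graph <- function(web, directed = TRUE) {
  g <- igraph::make_empty_graph(n = web$S, directed = directed)
  if (nrow(web$links) > 0L) {
    ends <- rbind(web$links$consumer, web$links$resource)
    g <- igraph::add_edges(g, as.vector(ends))
  }
  g
}

#' Induced sub-web on a set of persisting species
#'
#' Keeps the listed species (re-indexed 1..length(keep), original indices
#' recorded) and every link whose consumer and resource both persist.
#'
#' @param web A `food_web`.
#' @param keep Integer indices of species to retain.
#' @return A `food_web` with an extra `original_id` field.
#' @export
subset_web <- function(web, keep) {
  keep <- sort(unique(as.integer(keep)))
  remap <- integer(web$S)
  remap[keep] <- seq_along(keep)
  l <- web$links
  l <- l[l$consumer %in% keep & l$resource %in% keep, , drop = FALSE]
  l$consumer <- remap[l$consumer]
  l$resource <- remap[l$resource]
  rownames(l) <- NULL
  structure(list(S = length(keep), links = l, niche = web$niche[keep],
                 target_C = web$target_C, seed = web$seed,
                 original_id = if (is.null(web$original_id)) keep else
                   web$original_id[keep]),
            class = "food_web")
}
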