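#' Partition TIMs into equivalent pairwise non-trophic effects
#'
#' Each TIM on link (i, j) splits into two pairwise NTEs from the modifier k:
#' one on the resource i with frozen coefficient `a_ij * B_j*` (per-capita
#' contribution `coefficient * (1 - mu_ijk)`) and one on the consumer j with
#' coefficient `e_ij * a_ij * B_i*` (contribution `coefficient *
#' (mu_ijk - 1)`), mu_ijk evaluated from the live modifier density only.
#' Coefficients are frozen at the starting equilibrium and never updated --
#' the defining difference from the full higher-order model, where the
#' modification's impact scales with the live density of the trophic partner
#' and vanishes with it.
#'
#' @param tims TIM table (at most one per trophic link).
#' @param B_star Reference equilibrium densities.
#' @param links Link parameter table (`resource`, `consumer`, `a`, `e`).
#' @return data.frame with one row per NTE: `source` (modifier), `target`,
#'   `role` (`"on_resource"` / `"on_consumer"`), `coefficient`, `sign`
#'   (`"beneficial"` / `"detrimental"` / `"null"`), `tim` (row index into
#'   `tims`).
#' @export
partition_tims <- function(tims, B_star, links) {
  empty <- data.frame(source = integer(), target = integer(),
                      role = character(), coefficient = numeric(),
                      sign = character(), tim = integer())
  if (is.null(tims) || nrow(tims) == 0L) return(empty)
  key <- paste(tims$consumer, tims$resource)
  if (anyDuplicated(key)) {
    stop("pairwise partition requires at most one modifier per trophic link")
  }
  link_id <- match(key, paste(links$consumer, links$resource))
  if (anyNA(link_id)) stop("TIM refers to a non-existent trophic link")
  a <- links$a[link_id]; e <- links$e[link_id]
  n <- nrow(tims)
  out <- data.frame(
    source = rep(tims$modifier, 2L),
    target = c(tims$resource, tims$consumer),
    role = rep(c("on_resource", "on_consumer"), each = n),
    coefficient = c(a * B_star[tims$consumer],
                    e * a * B_star[tims$resource]),
    tim = rep(seq_len(n), 2L))
  out$sign <- nte_sign(rep(tims$alpha, 2L), out$role)
  out[, c("source", "target", "role", "coefficient", "sign", "tim")]
}

#' Sign classification of a pairwise NTE
#'
#' A facilitating TIM (alpha > 0) is beneficial to the consumer and
#' detrimental to the resource, in the sense of the immediate impact of an
#' increase in the modifier; an interfering TIM (alpha < 0) reverses both.
#' alpha = 0 classifies as `"null"` and is excluded from NTE counts.
#'
#' @param alpha TIM slope parameter(s).
#' @param role `"on_resource"` or `"on_consumer"`; recycled against `alpha`.
#' @return Character vector in `{"beneficial", "detrimental", "null"}`.
#' @export
nte_sign <- function(alpha, role) {
  role <- match.arg(role, c("on_resource", "on_consumer"), several.ok = TRUE)
  n <- max(length(alpha), length(role))
  alpha <- rep_len(alpha, n); role <- rep_len(role, n)
  out <- rep("null", n)
  fac <- alpha > 0
  intf <- alpha < 0
  out[fac & role == "on_consumer"] <- "beneficial"
  out[fac & role == "on_resource"] <- "detrimental"
  out[intf & role == "on_consumer"] <- "detrimental"
  out[intf & role == "on_resource"] <- "beneficial"
  out
}
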