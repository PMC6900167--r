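#' Default run configuration
#'
#' All defaults equal the single-modifier comparison protocol: 35-species
#' niche webs at connectance 0.14, retention minimum 18, starting density 10,
#' TIM rate 0.05 with alpha ~ U(-4,4), sigma ~ U(0.1,4), tau ~ U(-1,1), one
#' modifier per link, targeted mortality 1, and the windowed integration
#' settings of [dynamics_control()].
#'
#' @return Nested named list with blocks `community`, `dynamics`, `tim`,
#'   `experiment`, and a `seed`.
#' @export
default_config <- function() {
  list(
    community = list(S = 35, C = 0.14, n_communities = 10,
                     retention_min = 18, B_init = 10,
                     mean_log10_ratio = 2, sd_log10 = 0.5),
    dynamics = dynamics_control(),
    tim = list(rate = 0.05, alpha_range = c(-4, 4), sigma_range = c(0.1, 4),
               tau_range = c(-1, 1), max_per_interaction = 1),
    experiment = list(modes = c("none", "full", "pairwise"), m_target = 1),
    seed = 1L
  )
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial) YAML file and merges it over
#' [default_config()]; unknown keys are rejected with a descriptive error,
#' as are out-of-range probabilities and non-positive sizes. An empty file
#' yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, prefix = "")
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user, prefix) {
  if (!is.list(user)) stop("config block '", prefix, "' must be a mapping")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]],
                                prefix = paste0(prefix, k, "."))
    } else {
      v <- user[[k]]
      if (is.list(v)) v <- unlist(v)
      base[[k]] <- v
    }
  }
  base
}

validate_config <- function(cfg) {
  tim <- cfg$tim
  if (tim$rate < 0 || tim$rate > 1) {
    stop("tim.rate must be a probability in [0, 1]")
  }
  if (cfg$community$S < 2) stop("community.S must be >= 2")
  if (cfg$community$C <= 0 || cfg$community$C >= 0.5) {
    stop("community.C must lie in (0, 0.5)")
  }
  if (tim$sigma_range[1] <= 0) stop("tim.sigma_range must be positive")
  if (cfg$dynamics$t_window <= 0 || cfg$dynamics$t_max <= 0) {
    stop("dynamics horizons must be positive")
  }
  invisible(cfg)
}

#' Save a configuration to YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# format a data.frame with full double precision for lossless CSV round-trips
write_csv17 <- function(df, path) {
  out <- df
  for (k in names(out)) {
    if (is.double(out[[k]])) out[[k]] <- sprintf("%.17g", out[[k]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Save a community bundle to a directory
#'
#' Writes plain-text components: `web.csv` (directed consumer, resource edge
#' list), `species.csv`, `links.csv`, `tims.csv` (if attached), and
#' `meta.json` (S, seed, niche values, B_star). All floating-point fields are
#' written with 17 significant digits and round-trip losslessly.
#'
#' @param community A community object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
save_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv17(community$web$links[, c("consumer", "resource")],
              file.path(dir, "web.csv"))
  write_csv17(community$species, file.path(dir, "species.csv"))
  write_csv17(community$links, file.path(dir, "links.csv"))
  if (!is.null(community$tims)) {
    write_csv17(community$tims, file.path(dir, "tims.csv"))
  }
  meta <- list(S = nrow(community$species),
               seed = community$seed,
               niche = community$web$niche,
               target_C = community$web$target_C,
               original_id = community$web$original_id,
               initial_S = community$initial_S,
               B_star = community$B_star)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a community bundle from a directory
#'
#' @param dir Directory written by [save_community()].
#' @return A community object.
#' @export
load_community <- function(dir) {
  need <- c("web.csv", "species.csv", "links.csv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("community bundle at ", dir, " is missing: ",
         paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  edges <- utils::read.csv(file.path(dir, "web.csv"))
  web <- structure(list(S = as.integer(meta$S),
                        links = data.frame(consumer = as.integer(edges$consumer),
                                           resource = as.integer(edges$resource)),
                        niche = as.numeric(meta$niche),
                        target_C = meta$target_C,
                        seed = meta$seed,
                        original_id = meta$original_id),
                   class = "food_web")
  tims_path <- file.path(dir, "tims.csv")
  structure(list(web = web,
                 species = utils::read.csv(file.path(dir, "species.csv")),
                 links = utils::read.csv(file.path(dir, "links.csv")),
                 B_star = as.numeric(meta$B_star),
                 tims = if (file.exists(tims_path))
                   utils::read.csv(tims_path) else NULL,
                 seed = meta$seed,
                 initial_S = meta$initial_S),
            class = "community")
}

#' Export a web (and optional TIM edges) to GraphML
#'
#' Trophic links are directed consumer-to-resource edges with
#' `type = "trophic"`; TIMs contribute `type = "modification"` edges from
#' the modifier to both trophic participants.
#'
#' @param web A `food_web`.
#' @param path Output `.graphml` path.
#' @param tims Optional TIM table.
#' @export
export_graphml <- function(web, path, tims = NULL) {
  g <- trophic_graph(web, directed = TRUE)
  igraph::E(g)$type <- "trophic"
  if (!is.null(tims) && nrow(tims) > 0L) {
    extra <- rbind(cbind(tims$modifier, tims$resource),
                   cbind(tims$modifier, tims$consumer))
    n0 <- igraph::ecount(g)
    g <- igraph::add_edges(g, as.vector(t(extra)))
    igraph::E(g)$type[(n0 + 1L):igraph::ecount(g)] <- "modification"
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
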