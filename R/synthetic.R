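## Synthetic areal data on regular lattices with the generative structure
## the geo-additive analysis assumes: an iCAR structured field, an i.i.d.
## unstructured field, linear fixed effects, smooth nonlinear covariate
## effects, and Gaussian or binomial observation noise.

#' Regular lattice neighbourhood graph
#'
#' @param rows,cols lattice dimensions (cells are unit squares).
#' @param scheme `"queen"` (edge or corner contact) or `"rook"` (edge
#'   contact only).
#' @return a [spatial_graph]; node ids are `"r<i>c<j>"` in row-major
#'   order.
#' @export
lattice_graph <- function(rows, cols, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  idx <- function(r, c) (r - 1L) * cols + c
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                           function(r, c) paste0("r", r, "c", c))))
  edges <- matrix(integer(0), ncol = 2L)
  steps <- if (scheme == "rook") list(c(0L, 1L), c(1L, 0L))
           else list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (r in seq_len(rows)) for (c in seq_len(cols)) for (s in steps) {
    r2 <- r + s[1L]; c2 <- c + s[2L]
    if (r2 >= 1L && r2 <= rows && c2 >= 1L && c2 <= cols)
      edges <- rbind(edges, c(idx(r, c), idx(r2, c2)))
  }
  g <- spatial_graph(ids, edges, scheme = "custom")
  g$scheme <- if (scheme == "queen") "queen" else "custom"
  g
}

#' Lattice cell centroids
#' @inheritParams lattice_graph
#' @return data frame `unit_id`, `x`, `y` (cell centres).
#' @export
lattice_centroids <- function(rows, cols) {
  grid <- expand.grid(c = seq_len(cols), r = seq_len(rows))
  data.frame(unit_id = paste0("r", grid$r, "c", grid$c),
             x = grid$c - 0.5, y = grid$r - 0.5,
             stringsAsFactors = FALSE)
}

#' Write lattice cell polygons as GeoJSON
#'
#' Emits one unit-square Polygon feature per lattice cell, with the cell
#' id in the `unit_id` property, so GeoJSON-driven workflows can be
#' exercised on synthetic data.
#'
#' @inheritParams lattice_graph
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lattice_geojson <- function(rows, cols, path) {
  feats <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    ring <- list(list(c - 1, r - 1), list(c, r - 1), list(c, r),
                 list(c - 1, r), list(c - 1, r - 1))
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(unit_id = paste0("r", r, "c", c)),
      geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Draw an intrinsic CAR (iCAR) field over a graph
#'
#' Samples from the intrinsic CAR distribution with precision
#' tau_u * (D - A), restricted to the sum-to-zero subspace: the structure
#' matrix is eigendecomposed, the null directions (one per graph
#' component) are removed, and each remaining eigen-direction e_k
#' receives an independent N(0, 1/(tau_u * lambda_k)) coefficient. The
#' returned field has mean exactly zero per graph component.
#'
#' @param graph a [spatial_graph].
#' @param tau_u positive precision of the structured field.
#' @param seed RNG seed.
#' @return numeric field named by the graph's node ids.
#' @export
sample_icar_field <- function(graph, tau_u, seed) {
  stopifnot(inherits(graph, "spatial_graph"))
  if (!is.numeric(tau_u) || tau_u <= 0) stop("tau_u must be positive")
  set.seed(seed)
  n <- length(graph$node_ids)
  Q <- icar_structure(graph)
  eig <- eigen(Q, symmetric = TRUE)
  lam <- eig$values
  keep <- lam > max(lam) * 1e-10
  z <- stats::rnorm(sum(keep)) / sqrt(tau_u * lam[keep])
  u <- as.numeric(eig$vectors[, keep, drop = FALSE] %*% z)
  u <- u - stats::ave(u, graph_components(graph))
  names(u) <- graph$node_ids
  u
}

## fixed library of smooth shapes on [0, 1], each centred so its mean
## under Uniform(0, 1) covariates is ~0
.smooth_library <- list(
  sinusoid = function(x) sin(2 * pi * x),
  quadratic = function(x) 4 * (x - 0.5)^2 - 1 / 3,
  changepoint = function(x) ifelse(x > 0.5, 0.5, -0.5),
  flat = function(x) rep(0, length(x))
)

#' Names of the available synthetic smooth shapes
#' @return character vector.
#' @export
smooth_shapes <- function() names(.smooth_library)

#' Generate a synthetic geo-additive lattice scenario
#'
#' Builds a rows x cols queen lattice, draws Uniform(0, 1) covariates per
#' cell, and forms the linear predictor
#' eta = beta0 + X beta + sum_j f_j(s_j) + u + v with u an iCAR field
#' (precision `tau_u`), v i.i.d. Gaussian (precision `tau_v`) and f_j
#' shapes drawn from a fixed named library (see [smooth_shapes]). Under
#' the Gaussian observation model y = eta + N(0, sigma_eps^2); under the
#' binomial model each cell records `events ~ Binomial(n_trials,
#' plogis(eta))` so the table mimics survey count data.
#'
#' @param rows,cols lattice dimensions, `rows * cols >= 16`.
#' @param beta named numeric vector of linear-effect sizes (one
#'   Uniform(0, 1) covariate is created per element; empty for none).
#' @param smooth_menu character vector of shape names from
#'   [smooth_shapes()] (one smooth covariate per entry; empty for none).
#' @param tau_u,tau_v precisions of the structured and unstructured
#'   fields (set to `Inf` to switch a field off).
#' @param sigma_eps Gaussian observation noise sd.
#' @param beta0 intercept (default 0).
#' @param observation_model `"gaussian"` or `"binomial"`.
#' @param n_trials binomial denominator per cell.
#' @param seed RNG seed (mandatory).
#' @return object of class `anc_scenario`: list with `graph`, `table` (a
#'   [region_table] with covariate columns `x*`/`s*` and, for the
#'   Gaussian model, response column `y`), `centroids`, `truth` (beta0,
#'   beta, smooth curves on a grid, u, v, eta, tau_u, tau_v, sigma_eps),
#'   `observation_model`, `seed`.
#' @export
make_scenario <- function(rows = 15L, cols = 15L,
                          beta = c(x1 = 1, x2 = -0.5),
                          smooth_menu = c("sinusoid"),
                          tau_u = 1, tau_v = 10, sigma_eps = 0.5,
                          beta0 = 0,
                          observation_model = c("gaussian", "binomial"),
                          n_trials = 500L, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  observation_model <- match.arg(observation_model)
  if (rows * cols < 16L) stop("lattice must have at least 16 cells")
  bad <- setdiff(smooth_menu, smooth_shapes())
  if (length(bad) > 0L)
    stop("unknown smooth shape(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(smooth_shapes(), collapse = ", "))
  graph <- lattice_graph(rows, cols, "queen")
  n <- rows * cols
  set.seed(seed)
  tab <- data.frame(unit_id = graph$node_ids, stringsAsFactors = FALSE)
  eta <- rep(beta0, n)
  if (length(beta) > 0L) {
    if (is.null(names(beta))) names(beta) <- paste0("x", seq_along(beta))
    for (k in seq_along(beta)) {
      x <- stats::runif(n)
      tab[[names(beta)[k]]] <- x
      eta <- eta + beta[k] * x
    }
  }
  truth_smooth <- list()
  grid <- seq(0, 1, length.out = 101L)
  if (length(smooth_menu) > 0L) {
    snames <- paste0("s", seq_along(smooth_menu))
    for (k in seq_along(smooth_menu)) {
      x <- stats::runif(n)
      fx <- .smooth_library[[smooth_menu[k]]](x)
      if (smooth_menu[k] != "flat") fx <- fx - mean(fx)
      tab[[snames[k]]] <- x
      eta <- eta + fx
      truth_smooth[[snames[k]]] <-
        data.frame(shape = smooth_menu[k], x = grid,
                   f = .smooth_library[[smooth_menu[k]]](grid))
    }
  }
  u <- if (is.finite(tau_u))
    sample_icar_field(graph, tau_u, seed = seed + 1L) else rep(0, n)
  set.seed(seed + 2L)
  v <- if (is.finite(tau_v)) stats::rnorm(n, 0, 1 / sqrt(tau_v)) else rep(0, n)
  eta <- eta + u + v
  if (observation_model == "gaussian") {
    tab$y <- eta + stats::rnorm(n, 0, sigma_eps)
    tab$sample <- 1L
    tab$events <- 0L
  } else {
    tab$sample <- as.integer(n_trials)
    tab$events <- stats::rbinom(n, n_trials, stats::plogis(eta))
  }
  table <- region_table(tab, covariates = setdiff(
    names(tab), c("unit_id", "sample", "events", "y")))
  structure(list(graph = graph, table = table,
                 centroids = lattice_centroids(rows, cols),
                 truth = list(beta0 = beta0, beta = beta,
                              smooths = truth_smooth,
                              smooth_menu = smooth_menu,
                              u = u, v = v, eta = eta,
                              tau_u = tau_u, tau_v = tau_v,
                              sigma_eps = sigma_eps),
                 observation_model = observation_model, seed = seed),
            class = "anc_scenario")
}

#' @export
print.anc_scenario <- function(x, ...) {
  cat("anc_scenario:", nrow(x$table), "cells |", x$observation_model,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Generate a country-level count table with survey-like heterogeneity
#'
#' Pseudo-countries with sample sizes between 1,000 and 20,000, survey
#' years spanning 2010-2023, and event probabilities spread (log-
#' uniformly) over 0.002-0.8, mimicking the wide range observed in
#' country-level recommended-ANC tables.
#'
#' @param n_countries number of pseudo-countries (>= 2).
#' @param seed RNG seed.
#' @return a [region_table] with `unit_id`, `country`, `survey_year`,
#'   `sample`, `events`.
#' @export
make_table2_like <- function(n_countries, seed) {
  if (n_countries < 2L) stop("need at least 2 countries")
  set.seed(seed)
  samp <- as.integer(round(stats::runif(n_countries, 1000, 20000)))
  p <- exp(stats::runif(n_countries, log(0.002), log(0.8)))
  region_table(data.frame(
    unit_id = sprintf("C%02d", seq_len(n_countries)),
    country = sprintf("Country%02d", seq_len(n_countries)),
    survey_year = sample(2010:2023, n_countries, replace = TRUE),
    sample = samp,
    events = stats::rbinom(n_countries, samp, p),
    stringsAsFactors = FALSE))
}

#' Write a synthetic scenario to disk
#'
#' Emits the region CSV, the lattice GeoJSON and the truth JSON, so the
#' file-based readers can be exercised end to end.
#'
#' @param scenario an [make_scenario] result.
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_scenario <- function(scenario, outdir) {
  stopifnot(inherits(scenario, "anc_scenario"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ids <- scenario$graph$node_ids
  rows <- max(as.integer(sub("r(\\d+)c\\d+", "\\1", ids)))
  cols <- max(as.integer(sub("r\\d+c(\\d+)", "\\1", ids)))
  paths <- c(region = file.path(outdir, "region.csv"),
             geojson = file.path(outdir, "lattice.geojson"),
             truth = file.path(outdir, "truth.json"))
  write_region_csv(scenario$table, paths["region"])
  write_lattice_geojson(rows, cols, paths["geojson"])
  truth <- scenario$truth
  truth$smooths <- lapply(truth$smooths, as.list)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  paths
}
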