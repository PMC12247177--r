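#' Specify a geo-additive model variant
#'
#' Defines the model y_i = X_i beta + sum_j f_j(x_ji) + u_i + v_i + e_i
#' on the transformed (Gaussian) response scale, where f_j are nonlinear
#' smooths with a second-order random-walk (RW2) prior over binned
#' covariate values, u is a spatially structured intrinsic CAR (iCAR)
#' effect over the neighbourhood graph, and v is an i.i.d. unstructured
#' effect. The classic model ladder is expressed through `variant`:
#'
#' * `"linear_fixed"` - intercept + linear fixed effects only;
#' * `"additive_fixed"` - adds the RW2 smooths;
#' * `"additive_iid"` - adds the unstructured effect v;
#' * `"bym"` - Besag-York-Mollie: both u (iCAR) and v.
#'
#' @param variant model variant, see above.
#' @param linear_terms character vector of covariate columns entering
#'   linearly (may be empty; the intercept is always present).
#' @param smooth_terms character vector of covariate columns entering as
#'   RW2 smooths; disjoint from `linear_terms`.
#' @param n_bins number of equal-width bins per smooth (default 20).
#' @param graph a [spatial_graph] over the table's unit ids (required for
#'   `"bym"`).
#' @param priors list of Gamma(shape, rate) priors for the precisions:
#'   elements `tau_eps`, `tau_u`, `tau_v`, `tau_smooth`, each a length-2
#'   numeric c(shape, rate). Default Gamma(1, 5e-5) throughout, a weak
#'   prior standard for latent Gaussian spatial models. Fixed effects get
#'   independent N(0, 1000^2) priors.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(variant = c("bym", "linear_fixed", "additive_fixed",
                                   "additive_iid"),
                       linear_terms = character(0),
                       smooth_terms = character(0),
                       n_bins = 20L,
                       graph = NULL,
                       priors = NULL) {
  variant <- match.arg(variant)
  both <- intersect(linear_terms, smooth_terms)
  if (length(both) > 0L)
    stop("covariate(s) in both linear and smooth terms: ",
         paste(both, collapse = ", "))
  if (variant == "linear_fixed" && length(smooth_terms) > 0L)
    stop("variant 'linear_fixed' admits no smooth terms")
  if (variant == "bym") {
    if (is.null(graph)) stop("variant 'bym' requires a spatial graph")
    stopifnot(inherits(graph, "spatial_graph"))
  }
  if (n_bins < 4L) stop("n_bins must be at least 4")
  default_prior <- c(1, 5e-5)
  pr <- list(tau_eps = default_prior, tau_u = default_prior,
             tau_v = default_prior, tau_smooth = default_prior)
  if (!is.null(priors)) {
    unknown <- setdiff(names(priors), names(pr))
    if (length(unknown) > 0L)
      stop("unknown prior name(s): ", paste(unknown, collapse = ", "))
    for (nm in names(priors)) {
      p <- priors[[nm]]
      if (length(p) != 2L || any(p <= 0))
        stop("prior '", nm, "' must be c(shape, rate), both positive")
      pr[[nm]] <- p
    }
  }
  structure(list(variant = variant, linear_terms = linear_terms,
                 smooth_terms = smooth_terms, n_bins = as.integer(n_bins),
                 graph = graph, priors = pr, beta_prec = 1e-6),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$variant, "|", length(x$linear_terms),
      "linear term(s),", length(x$smooth_terms), "smooth term(s)\n")
  invisible(x)
}

## RW2 structure matrix: K = D2' D2, rank B - 2
rw2_structure <- function(B) {
  if (B < 4L) stop("RW2 needs at least 4 coefficients")
  D2 <- diff(diag(B), differences = 2L)
  crossprod(D2)
}

## iCAR structure matrix D - A over the graph, dense
icar_structure <- function(graph) {
  n <- length(graph$node_ids)
  Q <- matrix(0, n, n)
  if (nrow(graph$edges) > 0L) {
    Q[graph$edges] <- -1
    Q[graph$edges[, c(2L, 1L), drop = FALSE]] <- -1
  }
  diag(Q) <- graph_degree(graph)
  Q
}

#' Build design matrices for a geo-additive model
#'
#' Standardizes every covariate to mean 0, sd 1, builds the fixed-effect
#' matrix X (intercept first), one one-hot binning incidence matrix A_j
#' per smooth with its RW2 penalty K_j, and (for spatial variants) the
#' iCAR structure matrix Q_u = D - A over the graph. Smooth covariates are
#' cut into `n_bins` equal-width bins over their observed range; empty
#' bins are merged into their nearest occupied neighbour, so every
#' retained bin has at least one observation.
#'
#' @param table a [region_table] carrying the covariate columns.
#' @param spec a [model_spec].
#' @return object of class `design_matrices`: list with `X`, `A` (list of
#'   incidence matrices), `K` (list of RW2 penalties), `Q_u` (or NULL),
#'   `components` (graph component labels), `scaling` (per-covariate mean
#'   and sd), `bin_mid` (per-smooth bin midpoints on the original
#'   covariate scale).
#' @export
build_designs <- function(table, spec) {
  stopifnot(inherits(table, "region_table"), inherits(spec, "model_spec"))
  n <- nrow(table)
  terms <- c(spec$linear_terms, spec$smooth_terms)
  miss <- setdiff(terms, names(table))
  if (length(miss) > 0L)
    stop("covariate column(s) absent from table: ",
         paste(miss, collapse = ", "))
  scaling <- list()
  std <- function(nm) {
    v <- table[[nm]]
    if (any(is.na(v))) stop("covariate '", nm, "' has missing values")
    s <- stats::sd(v)
    if (s == 0) stop("covariate '", nm, "' has zero variance")
    scaling[[nm]] <<- c(mean = mean(v), sd = s)
    (v - mean(v)) / s
  }
  X <- matrix(1, n, 1L, dimnames = list(table$unit_id, "(Intercept)"))
  for (nm in spec$linear_terms) X <- cbind(X, `colnames<-`(cbind(std(nm)), nm))
  A <- list(); K <- list(); bin_mid <- list()
  for (nm in spec$smooth_terms) {
    z <- std(nm)
    breaks <- seq(min(z), max(z), length.out = spec$n_bins + 1L)
    idx <- findInterval(z, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    occupied <- sort(unique(idx))
    if (length(occupied) < 4L)
      stop("covariate '", nm, "' occupies fewer than 4 bins; reduce n_bins")
    ## merge empty bins into the nearest occupied one
    idx <- occupied[vapply(idx, function(i)
      which.min(abs(occupied - i)), integer(1L))]
    pos <- match(idx, occupied)
    B <- length(occupied)
    Aj <- matrix(0, n, B)
    Aj[cbind(seq_len(n), pos)] <- 1
    A[[nm]] <- Aj
    K[[nm]] <- rw2_structure(B)
    mid_z <- (breaks[occupied] + breaks[occupied + 1L]) / 2
    bin_mid[[nm]] <- mid_z * scaling[[nm]]["sd"] + scaling[[nm]]["mean"]
  }
  Q_u <- NULL; components <- NULL
  if (spec$variant == "bym") {
    gid <- spec$graph$node_ids
    if (length(gid) != n || !setequal(gid, table$unit_id))
      stop("graph/table id mismatch: ",
           paste(c(setdiff(gid, table$unit_id),
                   setdiff(table$unit_id, gid)), collapse = ", "))
    ## reorder graph nodes to the table's row order
    perm <- match(table$unit_id, gid)
    Qg <- icar_structure(spec$graph)
    Q_u <- Qg[perm, perm, drop = FALSE]
    components <- graph_components(spec$graph)[perm]
  }
  structure(list(X = X, A = A, K = K, Q_u = Q_u, components = components,
                 scaling = scaling, bin_mid = bin_mid,
                 unit_id = table$unit_id),
            class = "design_matrices")
}
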